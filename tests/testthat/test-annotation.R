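one_model <- function(name = "tx1", chrom = "c1", strand = "+",
                      starts, ends, cds_start = NULL, cds_end = NULL,
                      frames = NULL) {
  tibble(name = name, chrom = chrom, strand = strand,
         tx_start = starts[1], tx_end = ends[length(ends)],
         cds_start = if (is.null(cds_start)) starts[1] else cds_start,
         cds_end = if (is.null(cds_end)) ends[length(ends)] else cds_end,
         exon_count = length(starts),
         exon_starts = list(as.integer(starts)), exon_ends = list(as.integer(ends)),
         score = 0L, name2 = toupper(name), cds_start_stat = "cmpl",
         cds_end_stat = "cmpl",
         exon_frames = list(if (is.null(frames)) rep(0L, length(starts)) else as.integer(frames)))
}

test_that("genePred tables round-trip losslessly, with and without bin", {
  gs <- sim_gene_scenario(seed = 71)
  path <- withr::local_tempfile(fileext = ".genePred")
  write_genepred(gs$models_old, path)
  back <- read_genepred(path)
  expect_equal(as.data.frame(back), as.data.frame(gs$models_old), ignore_attr = TRUE)
  # fixpoint: write -> read -> write reproduces the file
  path2 <- withr::local_tempfile(fileext = ".genePred")
  write_genepred(back, path2)
  expect_identical(readLines(path2), readLines(path))

  with_bin <- gs$models_old %>% mutate(bin = dplyr::row_number() + 100L)
  path3 <- withr::local_tempfile(fileext = ".genePred")
  write_genepred(with_bin, path3)
  back3 <- read_genepred(path3)
  expect_equal(back3$bin, with_bin$bin)

  # ragged exon lists are rejected
  bad <- readLines(path)
  f <- strsplit(bad[1], "\t")[[1]]
  f[8] <- "99"
  writeLines(c(paste(f, collapse = "\t"), bad[-1]), path)
  expect_error(read_genepred(path), class = "majorref_malformed_row")
})

test_that("gene models lift with interior snapping over deletions and insertions", {
  g <- c(c1 = "ACGTACGTAC")
  e <- tibble(chrom = "c1", pos = c(2L, 5L, 8L), ref = c("C", "AC", "T"),
              alt = c("G", "A", "TGG"), class = c("SNP", "INDEL", "INDEL"))
  m <- build_map(apply_edits(g, e)$log)

  # model upstream of all indels: untouched
  up <- one_model(starts = 0L, ends = 4L)
  lifted <- lift_gene_models(up, m)
  expect_equal(lifted$exon_starts[[1]], 0L)
  expect_equal(lifted$exon_ends[[1]], 4L)
  expect_false(lifted$snapped)

  # exon spanning the 1-base deletion (old 5-6) shrinks by one
  del_span <- one_model(starts = 3L, ends = 8L)
  lifted2 <- lift_gene_models(del_span, m)
  expect_equal(lifted2$exon_ends[[1]] - lifted2$exon_starts[[1]], 4L)

  # exon containing the 2-base insertion grows by two
  ins_span <- one_model(starts = 6L, ends = 10L)
  lifted3 <- lift_gene_models(ins_span, m)
  expect_equal(lifted3$exon_ends[[1]] - lifted3$exon_starts[[1]], 6L)

  # a model wholly inside a deleted region is reported unmapped
  g2 <- c(c1 = "ACGTACGTACGTACGT")
  e2 <- tibble(chrom = "c1", pos = 4L, ref = "TACGTACG", alt = "T")
  m2 <- build_map(apply_edits(g2, e2)$log)
  inside <- one_model(starts = 5L, ends = 10L)
  lifted4 <- lift_gene_models(inside, m2)
  expect_equal(nrow(lifted4), 0)
  expect_equal(attr(lifted4, "unmapped_models"), "tx1")
})

test_that("zero-length lifted introns are merged, longer ones kept", {
  m <- one_model(starts = c(10L, 20L), ends = c(20L, 30L))
  merged <- collapse_spurious_introns(m)
  expect_equal(merged$exon_count, 1L)
  expect_equal(merged$exon_starts[[1]], 10L)
  expect_equal(merged$exon_ends[[1]], 30L)
  expect_equal(merged$introns_merged, 1L)

  m5 <- one_model(starts = c(10L, 25L), ends = c(20L, 35L))  # 5 bp intron
  kept <- collapse_spurious_introns(m5)
  expect_equal(kept$exon_count, 2L)
  expect_equal(kept$introns_merged, 0L)
  # unless the threshold is raised
  expect_equal(collapse_spurious_introns(m5, min_intron = 5)$exon_count, 1L)
})

test_that("frames follow cumulative CDS length in transcription order", {
  # + strand, exon CDS lengths 5 then 6: frames 0 then 5 mod 3 = 2
  m <- one_model(starts = c(0L, 10L), ends = c(5L, 16L), cds_start = 0L, cds_end = 16L)
  f <- recompute_frames(m)
  expect_equal(f$exon_frames[[1]], c(0L, 2L))
  # fixpoint
  expect_equal(recompute_frames(f)$exon_frames[[1]], c(0L, 2L))

  # UTR-only first exon gets -1
  m2 <- one_model(starts = c(0L, 10L, 20L), ends = c(5L, 16L, 26L),
                  cds_start = 10L, cds_end = 26L)
  expect_equal(recompute_frames(m2)$exon_frames[[1]], c(-1L, 0L, 0L))

  # minus strand walks exons right to left
  m3 <- one_model(strand = "-", starts = c(0L, 10L), ends = c(5L, 16L),
                  cds_start = 0L, cds_end = 16L)
  expect_equal(recompute_frames(m3)$exon_frames[[1]], c(0L, 0L))

  # non-coding transcript: all -1
  m4 <- one_model(starts = c(0L, 10L), ends = c(5L, 16L), cds_start = 3L, cds_end = 3L)
  expect_equal(recompute_frames(m4)$exon_frames[[1]], c(-1L, -1L))
})

test_that("transcript extraction and CDS translation honour strand and frame", {
  g <- c(c1 = "ATGAAATAGC")
  m <- one_model(starts = 0L, ends = 9L, cds_start = 0L, cds_end = 9L)
  expect_equal(extract_transcripts(m, g)$mrna, "ATGAAATAG")
  tr <- translate_cds(m, g)
  expect_equal(tr$protein, "MK")
  expect_false(tr$internal_stop)

  # minus strand: genome carries revcomp(ATGTAG) = CTACAT
  g2 <- c(c1 = "GGCTACATGG")
  m2 <- one_model(strand = "-", starts = 2L, ends = 8L, cds_start = 2L, cds_end = 8L)
  expect_equal(extract_transcripts(m2, g2)$mrna, "ATGTAG")
  expect_equal(translate_cds(m2, g2)$protein, "M")

  # frame offset 2 skips the first two CDS bases
  # CDS "ATGAAATAG" read from offset 2 -> "GAAATAG" -> codons GAA, ATA -> EI
  m3 <- one_model(starts = 0L, ends = 9L, cds_start = 0L, cds_end = 9L,
                  frames = 2L)
  expect_equal(translate_cds(m3, g)$protein, "EI")

  # internal stop truncates and flags
  g3 <- c(c1 = "ATGTAGAAATAA")
  m4 <- one_model(starts = 0L, ends = 12L, cds_start = 0L, cds_end = 12L)
  tr4 <- translate_cds(m4, g3)
  expect_equal(tr4$protein, "M")
  expect_true(tr4$internal_stop)

  expect_error(translate_cds(one_model(starts = 0L, ends = 9L, cds_start = 2L,
                                       cds_end = 2L), g),
               class = "majorref_no_cds")
})

test_that("sanity checking counts exact matches and skips absent transcripts", {
  gs <- sim_gene_scenario(seed = 72, n_genes = 4L, n_spurious = 0L, n_split = 0L,
                          n_bg_snp = 0L, n_bg_indel = 0L)
  rep <- sanity_check(gs$models_old, gs$old_genome, gs$mrna_set, gs$protein_set)
  expect_equal(glance(rep)$mrna_match_pct, 100)
  expect_equal(glance(rep)$protein_match_pct, 100)

  # plant one nonsynonymous CDS edit: protein match drops to 3/4
  g2 <- gs$old_genome
  m1 <- gs$models_old[1, ]
  cdspos <- m1$cds_start + 4L  # inside the CDS of the first exon
  ch <- m1$chrom
  old <- substr(g2[[ch]], cdspos + 1L, cdspos + 1L)
  new <- setdiff(c("A", "C", "G", "T"), toupper(old))[1]
  substr(g2[[ch]], cdspos + 1L, cdspos + 1L) <- new
  rep2 <- sanity_check(gs$models_old, g2, gs$mrna_set, gs$protein_set)
  expect_equal(glance(rep2)$protein_match_pct, 75)
  expect_equal(sum(tidy(rep2)$mrna_status == "MISMATCH"), 1)

  # unknown transcripts are skipped, not failed
  renamed <- gs$models_old %>% mutate(name = paste0("missing_", name))
  rep3 <- sanity_check(renamed[1, ], gs$old_genome, gs$mrna_set, gs$protein_set)
  expect_equal(tidy(rep3)$mrna_status, "SKIPPED")

  # empty model set: percentages undefined
  rep4 <- sanity_check(gs$models_old[0, ], gs$old_genome, gs$mrna_set, gs$protein_set)
  expect_equal(glance(rep4)$n_transcripts, 0L)
  expect_true(is.na(glance(rep4)$mrna_match_pct))
})

test_that("migration repairs planted spurious introns and split exons to 100%", {
  for (seed in c(73, 74)) {
    gs <- sim_gene_scenario(seed = seed)
    kept <- resolve_colocated(select_major_alleles(gs$variants))$kept
    ap <- apply_edits(gs$old_genome, kept)
    map <- build_map(ap$log)
    mig <- migrate_annotation(gs$models_old, map, ap$genome,
                              mrna_set = gs$mrna_set, protein_set = gs$protein_set)
    s <- glance(mig$report)
    expect_equal(s$mrna_match_pct, 100)
    expect_equal(s$protein_match_pct, 100)
    expect_true(all(mig$models$status == "MIGRATED"))
    # planted genes actually exercised the merge path
    planted <- gs$gene_info$name[gs$gene_info$type != "normal"]
    expect_true(all(mig$models$introns_merged[mig$models$name %in% planted] >= 1))
    # total CDS length of matching transcripts is a codon multiple
    for (i in seq_len(nrow(mig$models))) {
      m <- mig$models[i, ]
      cds_len <- sum(pmax(0L, pmin(m$exon_ends[[1]], m$cds_end) -
                            pmax(m$exon_starts[[1]], m$cds_start)))
      expect_equal(cds_len %% 3L, 0L)
    }
    # exon lists stay sorted and non-overlapping
    for (i in seq_len(nrow(mig$models))) {
      es <- mig$models$exon_starts[[i]]; ee <- mig$models$exon_ends[[i]]
      expect_true(all(ee > es))
      if (length(es) > 1) expect_true(all(es[-1] >= ee[-length(ee)]))
    }
  }
})

test_that("transcripts away from any edit keep their protein after migration", {
  gs <- sim_gene_scenario(seed = 75, n_spurious = 2L, n_split = 1L)
  kept <- resolve_colocated(select_major_alleles(gs$variants))$kept
  ap <- apply_edits(gs$old_genome, kept)
  map <- build_map(ap$log)
  mig <- migrate_annotation(gs$models_old, map, ap$genome)
  normals <- gs$gene_info$name[gs$gene_info$type == "normal"]
  pre <- translate_cds(gs$models_old %>% filter(name %in% normals), gs$old_genome)
  post <- translate_cds(mig$models %>% filter(name %in% normals), ap$genome)
  expect_equal(post$protein, pre$protein)
})
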