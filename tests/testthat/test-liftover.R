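toy_log <- function() {
  g <- c(c1 = "ACGTACGTAC")
  e <- tibble(chrom = "c1", pos = c(2L, 5L, 8L), ref = c("C", "AC", "T"),
              alt = c("G", "A", "TGG"), af = c(.6, .7, .8),
              class = c("SNP", "INDEL", "INDEL"))
  apply_edits(g, e)$log
}

test_that("the coordinate map has the expected block structure", {
  m <- build_map(toy_log())
  expect_equal(m$blocks$new_start, c(0L, 5L, 9L))
  expect_equal(m$blocks$new_end,   c(5L, 7L, 11L))
  expect_equal(m$blocks$old_start, c(0L, 6L, 8L))
  expect_equal(m$blocks$old_end,   c(5L, 8L, 10L))

  # substitutions never split blocks
  g <- c(c1 = "ACGTACGTAC")
  snps <- tibble(chrom = "c1", pos = c(3L, 4L), ref = c("G", "T"), alt = c("T", "G"))
  m2 <- build_map(apply_edits(g, snps)$log)
  expect_equal(nrow(m2$blocks), 1)
  expect_equal(m2$blocks$new_end, 10L)

  # no edits at all: one full-length block
  m3 <- build_map(new_edit_log(tibble(), c(c1 = 10L), c(c1 = 10L)))
  expect_equal(as.integer(unlist(m3$blocks[, -1])), c(0L, 10L, 0L, 10L))
})

test_that("positions lift by block offset with explicit unmapped semantics", {
  m <- build_map(toy_log())
  lp <- lift_positions(tibble(chrom = "c1", pos = c(3L, 6L, 8L, 11L)), m, "new2old")
  expect_equal(lp$lifted_pos, c(3L, 7L, NA, 10L))
  expect_equal(lp$status, c("MAPPED", "MAPPED", "UNMAPPED", "MAPPED"))
  expect_equal(lp$reason[3], "INSERTED_IN_SOURCE")

  # deleted base on the old assembly is unmapped old->new
  lp2 <- lift_positions(tibble(chrom = "c1", pos = 6L), m, "old2new")
  expect_equal(lp2$status, "UNMAPPED")

  expect_error(lift_positions(tibble(chrom = "c1", pos = 12L), m, "new2old"),
               class = "majorref_out_of_bounds")
  expect_error(lift_positions(tibble(chrom = "nope", pos = 1L), m),
               class = "majorref_unknown_chrom")
})

test_that("chain files carry the expected body and satisfy both arithmetic identities", {
  log <- toy_log()
  ch <- build_chain(log)
  b <- ch$blocks[[1]]
  expect_equal(b$size, c(5L, 2L, 2L))
  expect_equal(b$dt[1:2], c(0L, 2L))
  expect_equal(b$dq[1:2], c(1L, 0L))
  expect_equal(ch$t_size, 11L)
  expect_equal(ch$q_size, 10L)
  expect_equal(ch$score, 9)

  for (seed in c(51, 52)) {
    sc <- make_scenario(seed)
    for (i in seq_len(nrow(sc$chain))) {
      h <- sc$chain[i, ]; bb <- h$blocks[[1]]
      expect_equal(sum(bb$size) + sum(bb$dt, na.rm = TRUE), h$t_end - h$t_start)
      expect_equal(sum(bb$size) + sum(bb$dq, na.rm = TRUE), h$q_end - h$q_start)
    }
  }

  # no edits: single bare size line
  ch0 <- build_chain(new_edit_log(tibble(), c(c1 = 10L), c(c1 = 10L)))
  expect_equal(ch0$blocks[[1]]$size, 10L)
  expect_equal(nrow(ch0$blocks[[1]]), 1)
})

test_that("chain serialization round-trips bit-identically", {
  sc <- make_scenario(53)
  path <- withr::local_tempfile(fileext = ".chain")
  write_chain(sc$chain, path)
  back <- read_chain(path)
  expect_equal(as.data.frame(back[, names(back) != "blocks"]),
               as.data.frame(sc$chain[, names(sc$chain) != "blocks"]),
               ignore_attr = TRUE)
  for (i in seq_len(nrow(back))) {
    expect_equal(as.data.frame(back$blocks[[i]]), as.data.frame(sc$chain$blocks[[i]]))
  }
  # writing the parsed chain again reproduces the file byte for byte
  path2 <- withr::local_tempfile(fileext = ".chain")
  write_chain(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("lifting agrees everywhere with literal per-base replay", {
  for (seed in c(61, 62, 63)) {
    g <- sim_genome(c(chr1 = 9000L), seed = seed)
    pv <- sim_population_vcf(g, seed = seed, n_snp = 80L, n_indel = 60L,
                             n_mnp = 8L, n_snp_indel = 8L, n_sv = 2L,
                             n_colocated = 5L, frac_major = 0.7)
    kept <- resolve_colocated(select_major_alleles(pv$variants))$kept
    ap <- apply_edits(g, kept)
    m <- build_map(ap$log)
    replay <- replay_alignment(g[["chr1"]], kept)
    expect_equal(replay$new_len, ap$log$new_len[["chr1"]])

    new_pos <- seq_len(replay$new_len)
    lp <- lift_positions(tibble(chrom = "chr1", pos = new_pos), m, "new2old")
    expect_equal(lp$lifted_pos, replay$new2old)

    old_pos <- seq_len(nchar(g[["chr1"]]))
    lp2 <- lift_positions(tibble(chrom = "chr1", pos = old_pos), m, "old2new")
    expect_equal(lp2$lifted_pos, replay$old2new)
  }
})

test_that("round-trip liftover is the identity and preserves order", {
  sc <- make_scenario(64)
  pos <- bind_rows(lapply(names(sc$applied$genome), function(ch)
    tibble(chrom = ch, pos = seq(1L, sc$applied$log$new_len[[ch]], by = 7L))))
  fwd <- lift_positions(pos, sc$map, "new2old")
  mapped <- fwd[fwd$status == "MAPPED", ]
  back <- lift_positions(mapped %>% transmute(chrom, pos = lifted_pos), sc$map, "old2new")
  expect_equal(back$lifted_pos, mapped$pos)
  # monotone within chromosome
  for (ch in unique(mapped$chrom)) {
    expect_false(is.unsorted(mapped$lifted_pos[mapped$chrom == ch]))
  }
})

test_that("VCF liftover keeps alleles, reports unmapped records and sorts output", {
  m <- build_map(toy_log())
  recs <- tibble(chrom = "c1", pos = c(3L, 8L, 11L), id = c("a", "b", "c"),
                 ref = c("G", "G", "C"), alt = c("T", "T", "A"),
                 qual = 50, dp = 20)
  r <- lift_vcf(recs, m, "new2old")
  expect_equal(r$lifted$id, c("a", "c"))
  expect_equal(r$lifted$pos, c(3L, 10L))
  expect_equal(r$lifted$ref, c("G", "C"))   # REF/ALT untouched
  expect_equal(r$unmapped$id, "b")
  expect_equal(r$unmapped$reason, "INSERTED_IN_SOURCE")
  expect_equal(nrow(r$unmapped) / nrow(recs), 1 / 3)

  # deletion spanning a gap: anchor maps, span flagged
  recs2 <- tibble(chrom = "c1", pos = 5L, ref = "ACGTA", alt = "A", qual = 50, dp = 9)
  r2 <- lift_vcf(recs2, m, "old2new")
  expect_equal(r2$lifted$pos, 5L)
  expect_true(r2$lifted$span_warning)
})

test_that("map-based and chain-based lifting are fully concordant; perturbation is caught", {
  sc <- make_scenario(65)
  pos <- bind_rows(lapply(names(sc$applied$genome), function(ch)
    tibble(chrom = ch, pos = seq_len(sc$applied$log$new_len[[ch]]))))
  cc <- concordance_check(pos, sc$map, sc$chain)
  expect_equal(cc$concordance, 1)
  expect_equal(nrow(cc$mismatches), 0)

  # vacuous agreement on an empty set
  expect_equal(concordance_check(pos[0, ], sc$map, sc$chain)$concordance, 1)

  # a deliberately perturbed chain disagrees and the mismatches are listed
  bad <- sc$chain
  blk <- bad$blocks[[1]]
  gap_row <- which(!is.na(blk$dq) & blk$dq > 0)[1]
  blk$dq[gap_row] <- blk$dq[gap_row] + 1L
  bad$blocks[[1]] <- blk
  cc2 <- concordance_check(pos, sc$map, bad)
  expect_lt(cc2$concordance, 1)
  expect_gt(nrow(cc2$mismatches), 0)
})

test_that("the generated chain is understood by an independent chain consumer", {
  log <- toy_log()
  path <- withr::local_tempfile(fileext = ".chain")
  write_chain(build_chain(log), path)
  chain <- rtracklayer::import.chain(path)
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(start = c(3, 6, 8, 11), width = 1))
  lifted <- rtracklayer::liftOver(gr, chain)
  got <- vapply(lifted, function(x) if (length(x) == 0) NA_integer_
                else as.integer(GenomicRanges::start(x)[1]), 1L)
  expect_equal(got, c(3L, 7L, NA, 10L))

  # and at scale against the direct map
  sc <- make_scenario(66)
  path2 <- withr::local_tempfile(fileext = ".chain")
  write_chain(sc$chain, path2)
  chain2 <- rtracklayer::import.chain(path2)
  pos <- bind_rows(lapply(names(sc$applied$genome), function(ch)
    tibble(chrom = ch, pos = seq(1L, sc$applied$log$new_len[[ch]], by = 13L))))
  gr2 <- GenomicRanges::GRanges(pos$chrom, IRanges::IRanges(start = pos$pos, width = 1))
  ext <- rtracklayer::liftOver(gr2, chain2)
  got2 <- vapply(ext, function(x) if (length(x) == 0) NA_integer_
                 else as.integer(GenomicRanges::start(x)[1]), 1L)
  ours <- lift_positions(pos, sc$map, "new2old")$lifted_pos
  expect_equal(got2, ours)
})
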