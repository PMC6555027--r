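# Seeded generators for every input the toolkit consumes: genomes, population
# VCFs with a controlled AF spectrum, gene models with planted spurious
# introns, and paired call sets with planted common/unique variants. All
# outputs are deterministic functions of their seed.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a genome
#'
#' Uniform random A/C/G/T sequence with optional soft-masked (lowercase) runs,
#' byte-identical for a given seed.
#'
#' @param lengths Named integer vector of chromosome lengths (each >= 100).
#' @param seed Integer seed.
#' @param softmask_frac Approximate fraction of soft-masked bases.
#' @return Named character vector.
#' @export
sim_genome <- function(lengths = c(chrA = 60000L, chrB = 40000L), seed = 1,
                       softmask_frac = 0.02) {
  stopifnot(all(lengths >= 100))
  with_seed(seed, {
    out <- vapply(lengths, function(L) {
      s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      if (softmask_frac > 0) {
        n_runs <- max(1L, round(L * softmask_frac / 50))
        starts <- sample.int(L - 60L, n_runs)
        for (st in starts) {
          w <- sample(20:50, 1)
          idx <- st:min(L, st + w)
          s[idx] <- tolower(s[idx])
        }
      }
      paste(s, collapse = "")
    }, "")
    names(out) <- names(lengths)
    out
  })
}

rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), toupper(b)), 1)

# AF vector for one record: `major` decides whether one allele exceeds 0.5
draw_afs <- function(n_alts, major, spike) {
  if (major) {
    af_major <- if (spike) stats::runif(1, 0.985, 1) else stats::runif(1, 0.52, 0.95)
    rest <- if (n_alts > 1) stats::runif(n_alts - 1, 0.005, max(0.01, (1 - af_major) / (n_alts - 1) * 0.9)) else numeric(0)
    which_major <- sample.int(n_alts, 1)
    af <- numeric(n_alts)
    af[which_major] <- af_major
    af[-which_major] <- rest
    list(af = af, major = which_major)
  } else {
    af <- stats::runif(n_alts, 0.02, 0.48)
    if (sum(af) > 0.98) af <- af / sum(af) * 0.95
    list(af = af, major = NA_integer_)
  }
}

#' Simulate a population VCF with a controlled allele-frequency spectrum
#'
#' Plants records of all five classes on a genome, with configurable fractions
#' of records whose top allele exceeds the selection threshold, a near-1 AF
#' spike emulating assembly sequencing errors, multi-allelic sites, co-located
#' SNP+INDEL conflict pairs and structural variants. Returns the record table
#' together with a ground-truth manifest of exactly the minimal edits that
#' selection at threshold 0.5 (with conflict resolution) must produce.
#'
#' @param genome Named character vector (e.g. from [sim_genome()]).
#' @param seed Integer seed.
#' @param n_snp,n_indel,n_mnp,n_snp_indel,n_sv Record counts per class.
#' @param frac_major Fraction of records (per class) whose top allele
#'   frequency exceeds 0.5.
#' @param frac_spike Among major records, fraction with AF near 1
#'   ("sequencing error" sites).
#' @param frac_multiallelic Fraction of SNP records carrying two ALT alleles.
#' @param n_colocated Number of planted overlapping SNP+deletion conflict
#'   pairs (both above threshold; the higher-AF edit must win).
#' @param spacing Minimum distance between independent records (bp).
#' @return A list: `variants` (population tibble, the shape of
#'   [read_population_vcf()]), `manifest` (expected kept edits: `chrom`,
#'   `pos`, `ref`, `alt`, `af`, `class`), `n_expected_dropped`.
#' @export
sim_population_vcf <- function(genome, seed = 1,
                               n_snp = 400L, n_indel = 120L, n_mnp = 20L,
                               n_snp_indel = 20L, n_sv = 10L,
                               frac_major = 0.4, frac_spike = 0.08,
                               frac_multiallelic = 0.1, n_colocated = 10L,
                               spacing = 25L) {
  with_seed(seed, {
    chroms <- names(genome)
    lens <- vapply(genome, nchar, 0L)
    # candidate anchors, spaced so independent records never overlap
    sites <- bind_rows(lapply(chroms, function(ch) {
      tibble(chrom = ch, pos = seq(10L, lens[[ch]] - 20L, by = spacing))
    }))
    sites <- sites[sample.int(nrow(sites)), ]
    need <- n_snp + n_indel + n_mnp + n_snp_indel + n_sv + n_colocated
    if (need > nrow(sites)) {
      stop_majorref("SPEC_TOO_DENSE", "requested variants exceed genome capacity")
    }
    take <- function(n) {
      if (n == 0) return(sites[0, , drop = FALSE])
      out <- sites[seq_len(n), , drop = FALSE]
      sites <<- sites[-seq_len(n), , drop = FALSE]
      out
    }
    recs <- list()
    manifest <- list()
    add_rec <- function(chrom, pos, ref, alts, afs, vclass) {
      recs[[length(recs) + 1]] <<- list(chrom = chrom, pos = as.integer(pos),
                                        ref = ref, alts = alts, afs = afs,
                                        vclass = vclass)
    }
    add_manifest <- function(chrom, pos, ref, alt, af, vclass) {
      m <- minimize_allele(pos, ref, alt)
      manifest[[length(manifest) + 1]] <<- list(
        chrom = chrom, pos = as.integer(m$pos), ref = m$ref, alt = m$alt,
        af = af, class = vclass)
    }
    base_at <- function(ch, p) toupper(genome_slice(genome, ch, p - 1L, p))
    # exact achieved fractions: choose which records are "major" (top AF > 0.5)
    # by count, not by coin flip, so manifests are unambiguous
    pick <- function(n, frac) {
      out <- rep(FALSE, n)
      if (n > 0 && frac > 0) out[sample.int(n, round(n * frac))] <- TRUE
      out
    }

    # SNP (some multi-allelic)
    s <- take(n_snp)
    snp_major <- pick(n_snp, frac_major)
    snp_multi <- pick(n_snp, frac_multiallelic)
    snp_spike <- pick(n_snp, frac_major * frac_spike) & snp_major
    for (i in seq_len(n_snp)) {
      ch <- s$chrom[i]; p <- s$pos[i]
      r <- base_at(ch, p)
      n_alts <- if (snp_multi[i]) 2L else 1L
      alts <- sample(setdiff(c("A", "C", "G", "T"), r), n_alts)
      d <- draw_afs(n_alts, snp_major[i], snp_spike[i])
      add_rec(ch, p, r, alts, d$af, "SNP")
      if (!is.na(d$major)) add_manifest(ch, p, r, alts[d$major], d$af[d$major], "SNP")
    }
    # INDEL (deletions and insertions)
    s <- take(n_indel)
    indel_major <- pick(n_indel, frac_major)
    indel_spike <- pick(n_indel, frac_major * frac_spike) & indel_major
    for (i in seq_len(n_indel)) {
      ch <- s$chrom[i]; p <- s$pos[i]
      L <- sample(2:8, 1)
      anchor <- base_at(ch, p)
      if (stats::runif(1) < 0.5) {  # deletion
        r <- toupper(genome_slice(genome, ch, p - 1L, p - 1L + L + 1L)); a <- anchor
      } else {                      # insertion
        r <- anchor; a <- paste0(anchor, rand_bases(L))
      }
      d <- draw_afs(1L, indel_major[i], indel_spike[i])
      add_rec(ch, p, r, a, d$af, "INDEL")
      if (!is.na(d$major)) add_manifest(ch, p, r, a, d$af, "INDEL")
    }
    # MNP: same-length multi-base substitution differing at every base
    s <- take(n_mnp)
    mnp_major <- pick(n_mnp, frac_major)
    for (i in seq_len(n_mnp)) {
      ch <- s$chrom[i]; p <- s$pos[i]
      L <- sample(2:3, 1)
      r <- toupper(genome_slice(genome, ch, p - 1L, p - 1L + L))
      a <- paste(vapply(strsplit(r, "")[[1]], other_base, ""), collapse = "")
      d <- draw_afs(1L, mnp_major[i], FALSE)
      add_rec(ch, p, r, a, d$af, "MNP")
      if (!is.na(d$major)) add_manifest(ch, p, r, a, d$af, "MNP")
    }
    # SNP_INDEL: one SNP allele plus one insertion allele at the same site
    s <- take(n_snp_indel)
    si_major <- pick(n_snp_indel, frac_major)
    for (i in seq_len(n_snp_indel)) {
      ch <- s$chrom[i]; p <- s$pos[i]
      r <- base_at(ch, p)
      alts <- c(other_base(r), paste0(r, rand_bases(sample(2:5, 1))))
      d <- draw_afs(2L, si_major[i], FALSE)
      add_rec(ch, p, r, alts, d$af, "SNP_INDEL")
      if (!is.na(d$major)) add_manifest(ch, p, r, alts[d$major], d$af[d$major], "SNP_INDEL")
    }
    # SV: symbolic, sometimes high AF, never selectable
    s <- take(n_sv)
    for (i in seq_len(n_sv)) {
      ch <- s$chrom[i]; p <- s$pos[i]
      add_rec(ch, p, base_at(ch, p), sample(c("<CN0>", "<DEL>", "<INS>"), 1),
              stats::runif(1, 0.1, 0.95), "SV")
    }
    # co-located SNP + deletion, both above threshold; higher AF wins
    s <- take(n_colocated)
    n_dropped <- 0L
    for (i in seq_len(n_colocated)) {
      ch <- s$chrom[i]; p <- s$pos[i]
      L <- sample(3:8, 1)
      del_ref <- toupper(genome_slice(genome, ch, p - 1L, p - 1L + L + 1L))
      del_alt <- substr(del_ref, 1, 1)
      q <- p + sample.int(L, 1)  # SNP inside the deleted span
      snp_ref <- base_at(ch, q)
      snp_alt <- other_base(snp_ref)
      af_win <- stats::runif(1, 0.72, 0.9)
      af_lose <- stats::runif(1, 0.52, 0.68)
      snp_wins <- stats::runif(1) < 0.5
      add_rec(ch, p, del_ref, del_alt, if (snp_wins) af_lose else af_win, "INDEL")
      add_rec(ch, q, snp_ref, snp_alt, if (snp_wins) af_win else af_lose, "SNP")
      if (snp_wins) add_manifest(ch, q, snp_ref, snp_alt, af_win, "SNP")
      else add_manifest(ch, p, del_ref, del_alt, af_win, "INDEL")
      n_dropped <- n_dropped + 1L
    }
    variants <- tibble(
      chrom = map_chr(recs, "chrom"), pos = map_int(recs, "pos"),
      id = sprintf("sim%05d", seq_along(recs)), ref = map_chr(recs, "ref"),
      alts = map(recs, "alts"), alt_freqs = map(recs, "afs"),
      vclass = map_chr(recs, "vclass"),
      multiallelic = lengths(map(recs, "alts")) > 1,
      af_source = "info") %>% arrange(.data$chrom, .data$pos)
    manifest <- tibble(
      chrom = map_chr(manifest, "chrom"), pos = map_int(manifest, "pos"),
      ref = map_chr(manifest, "ref"), alt = map_chr(manifest, "alt"),
      af = map_dbl(manifest, "af"), class = map_chr(manifest, "class")) %>%
      arrange(.data$chrom, .data$pos)
    list(variants = variants, manifest = manifest, n_expected_dropped = n_dropped)
  })
}

# codons without stop codons
sim_cds <- function(n_codons) {
  codons <- c()
  stops <- c("TAA", "TAG", "TGA")
  while (length(codons) < n_codons) {
    c3 <- rand_bases(3)
    if (!c3 %in% stops && c3 != "ATG") codons <- c(codons, c3)
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

#' Simulate a gene-annotation migration scenario
#'
#' Builds a source ("old") genome carrying genes whose structure emulates the
#' annotation errors a major-allele replacement corrects: genes with a planted
#' 2-8 bp spurious intron (an insertion in the old assembly, exactly covered
#' by a high-frequency deletion variant) and genes with an exon split into two
#' abutting pieces (bases missing from the old assembly, restored by a
#' high-frequency insertion variant). Companion mRNA/protein sets are derived
#' from the corrected (post-edit) truth, so a migrated annotation must score
#' 100%/100% in [sanity_check()]. Background SNP and INDEL variants shift
#' coordinates between genes.
#'
#' @param seed Integer seed.
#' @param chrom_len Old-assembly chromosome length.
#' @param n_genes Number of genes (plus/minus strand mixed).
#' @param n_spurious Genes with a planted spurious intron.
#' @param n_split Genes with a planted split exon (abutting pieces).
#' @param n_bg_snp,n_bg_indel Background intergenic variants with AF > 0.5.
#' @return A list: `old_genome`, `variants` (population tibble), `models_old`
#'   (genePred tibble with frames computed on the old structure), `mrna_set`,
#'   `protein_set` (named character vectors), `gene_info` (per-gene truth).
#' @export
sim_gene_scenario <- function(seed = 1, chrom_len = 30000L, n_genes = 8L,
                              n_spurious = 3L, n_split = 2L,
                              n_bg_snp = 20L, n_bg_indel = 10L) {
  stopifnot(n_spurious + n_split <= n_genes)
  with_seed(seed, {
    backbone <- strsplit(paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                               collapse = ""), "")[[1]]
    gene_types <- sample(c(rep("spurious", n_spurious), rep("split", n_split),
                           rep("normal", n_genes - n_spurious - n_split)))
    slot_width <- (chrom_len - 2000L) %/% n_genes
    recs <- list(); models <- list(); mrna_set <- character(0); prot_set <- character(0)
    info <- list()
    vid <- 0L
    add_var <- function(chrom, pos, ref, alt, af, vclass) {
      vid <<- vid + 1L
      recs[[length(recs) + 1]] <<- tibble(
        chrom = chrom, pos = as.integer(pos), id = sprintf("gv%04d", vid),
        ref = ref, alts = list(alt), alt_freqs = list(af), vclass = vclass,
        multiallelic = FALSE, af_source = "info")
    }
    for (g in seq_len(n_genes)) {
      type <- gene_types[g]
      strand <- sample(c("+", "-"), 1)
      name <- sprintf("TX%03d", g)
      u5 <- sample(c(0L, 6L), 1); u3 <- sample(c(0L, 6L), 1)
      cds <- sim_cds(sample(30:50, 1))
      mrna <- paste0(rand_bases(u5), cds, rand_bases(u3))
      k <- sample(2:4, 1)
      # split the mature transcript into k exon pieces of >= 12 bp
      cuts <- sort(sample(12:(nchar(mrna) - 12), k - 1))
      cuts <- cuts[c(TRUE, diff(cuts) >= 12)]
      k <- length(cuts) + 1
      bounds <- c(0L, cuts, nchar(mrna))
      exon_seq <- map2_chr(bounds[-length(bounds)] + 1L, bounds[-1],
                           ~ substr(mrna, .x, .y))
      introns <- vapply(seq_len(k - 1), function(i) rand_bases(sample(40:80, 1)), "")

      # old-assembly exon pieces: possibly perturbed
      old_pieces <- as.list(exon_seq)     # each element: one exon's old sequence
      old_gaps <- as.list(introns)        # old intron sequences between exons
      plant <- NULL
      if (type == "spurious") {
        # insert 2-8 extra bases inside one exon: old annotation sees two
        # exon pieces separated by a tiny intron of exactly those bases
        ei <- sample(seq_len(k), 1)
        L <- sample(2:8, 1)
        at <- sample(4:(nchar(exon_seq[ei]) - 4), 1)
        ins <- rand_bases(L)
        old_pieces[[ei]] <- c(substr(exon_seq[ei], 1, at),
                              substr(exon_seq[ei], at + 1, nchar(exon_seq[ei])))
        plant <- list(type = "spurious", exon = ei, at = at, seq = ins, len = L)
      } else if (type == "split") {
        # delete 2-8 bases from inside one exon: old annotation keeps the two
        # abutting pieces; the bases return via a major insertion
        ei <- sample(seq_len(k), 1)
        L <- sample(2:8, 1)
        at <- sample(4:(nchar(exon_seq[ei]) - 4 - L), 1)
        missing <- substr(exon_seq[ei], at + 1, at + L)
        old_pieces[[ei]] <- c(substr(exon_seq[ei], 1, at),
                              substr(exon_seq[ei], at + L + 1, nchar(exon_seq[ei])))
        plant <- list(type = "split", exon = ei, at = at, seq = missing, len = L)
      }

      # assemble the old-assembly gene region (sense orientation) and record
      # exon bounds relative to region start
      region <- character(0); rel_starts <- integer(0); rel_ends <- integer(0)
      cursor <- 0L
      plant_rel <- NA_integer_  # sense-strand offset of the planted event
      for (ei in seq_len(k)) {
        pieces <- old_pieces[[ei]]
        for (pi in seq_along(pieces)) {
          rel_starts <- c(rel_starts, cursor)
          region <- c(region, pieces[pi])
          cursor <- cursor + nchar(pieces[pi])
          rel_ends <- c(rel_ends, cursor)
          if (!is.null(plant) && plant$exon == ei && pi == 1 && length(pieces) == 2) {
            plant_rel <- cursor  # event sits right after the first piece
            if (plant$type == "spurious") {
              region <- c(region, plant$seq)
              cursor <- cursor + plant$len
            }
          }
        }
        if (ei < k) {
          region <- c(region, old_gaps[[ei]])
          cursor <- cursor + nchar(old_gaps[[ei]])
        }
      }
      region <- paste(region, collapse = "")
      region_len <- nchar(region)
      # CDS bounds on the mature transcript -> sense-region coordinates
      # (mRNA coordinates map into exon pieces; UTRs are confined to the
      #  first/last exon by construction of the cuts above)
      mrna_cds_s <- u5; mrna_cds_e <- u5 + nchar(cds)
      # mRNA offset where bases are missing from the old assembly (split genes)
      miss_at <- if (!is.null(plant) && plant$type == "split") {
        sum(nchar(exon_seq[seq_len(plant$exon - 1)])) + plant$at
      } else NA_integer_
      mrna_to_rel <- function(mp) {  # 0-based mRNA offset -> 0-based region offset
        if (!is.na(miss_at) && mp >= miss_at) {
          mp <- max(miss_at, mp - plant$len)
        }
        acc <- 0L
        for (x in seq_along(rel_starts)) {
          w <- rel_ends[x] - rel_starts[x]
          if (mp < acc + w) return(rel_starts[x] + (mp - acc))
          acc <- acc + w
        }
        rel_ends[length(rel_ends)]
      }
      cds_rel_s <- mrna_to_rel(mrna_cds_s)
      cds_rel_e <- mrna_to_rel(mrna_cds_e - 1L) + 1L

      locus <- 1000L + (g - 1L) * slot_width + sample.int(200L, 1)
      if (strand == "+") {
        abs_starts <- locus + rel_starts; abs_ends <- locus + rel_ends
        cds_s <- locus + cds_rel_s; cds_e <- locus + cds_rel_e
        backbone[(locus + 1):(locus + region_len)] <- strsplit(region, "")[[1]]
        plant_abs <- if (!is.na(plant_rel)) locus + plant_rel else NA_integer_
      } else {
        rc <- revcomp(region)
        abs_starts <- locus + region_len - rev(rel_ends)
        abs_ends <- locus + region_len - rev(rel_starts)
        cds_s <- locus + region_len - cds_rel_e
        cds_e <- locus + region_len - cds_rel_s
        backbone[(locus + 1):(locus + region_len)] <- strsplit(rc, "")[[1]]
        plant_abs <- if (!is.na(plant_rel)) locus + region_len - plant_rel else NA_integer_
      }
      models[[g]] <- tibble(
        name = name, chrom = "chrG", strand = strand,
        tx_start = abs_starts[1], tx_end = abs_ends[length(abs_ends)],
        cds_start = cds_s, cds_end = cds_e,
        exon_count = length(abs_starts),
        exon_starts = list(abs_starts), exon_ends = list(abs_ends),
        score = 0L, name2 = sprintf("GENE%03d", g),
        cds_start_stat = "cmpl", cds_end_stat = "cmpl",
        exon_frames = list(rep(0L, length(abs_starts))))
      mrna_set[name] <- mrna
      prot_set[name] <- translate_nt(cds)$protein
      info[[g]] <- tibble(name = name, type = type, strand = strand,
                          plant_len = if (is.null(plant)) NA_integer_ else plant$len)
      # the planted population variant, in old-assembly coordinates
      if (!is.null(plant)) {
        if (plant$type == "spurious") {
          planted_seq <- if (strand == "+") plant$seq else revcomp(plant$seq)
          # deletion of the inserted bases, anchored one base upstream
          anchor_pos <- plant_abs  # 1-based anchor (base before the insert on + strand)
          if (strand == "-") anchor_pos <- plant_abs - plant$len
          ref <- paste0(toupper(backbone[anchor_pos]),
                        paste(toupper(backbone[(anchor_pos + 1):(anchor_pos + plant$len)]), collapse = ""))
          add_var("chrG", anchor_pos, ref, substr(ref, 1, 1),
                  stats::runif(1, 0.9, 0.999), "INDEL")
        } else {
          planted_seq <- if (strand == "+") plant$seq else revcomp(plant$seq)
          anchor_pos <- plant_abs
          if (strand == "-") anchor_pos <- plant_abs
          ref <- toupper(backbone[anchor_pos])
          add_var("chrG", anchor_pos, ref, paste0(ref, planted_seq),
                  stats::runif(1, 0.9, 0.999), "INDEL")
        }
      }
    }
    old_genome <- c(chrG = paste(backbone, collapse = ""))
    # background intergenic variants (outside all gene regions)
    gene_iv <- bind_rows(models) %>%
      summarize(lo = min(.data$tx_start), hi = max(.data$tx_end))
    free <- setdiff(seq(20L, chrom_len - 20L, by = 30L),
                    unlist(map(models, ~ seq(.x$tx_start - 12L, .x$tx_end + 12L))))
    free <- sample(free)
    for (i in seq_len(min(n_bg_snp, length(free)))) {
      p <- free[i]
      r <- toupper(backbone[p])
      add_var("chrG", p, r, other_base(r), stats::runif(1, 0.55, 0.95), "SNP")
    }
    free <- free[-seq_len(min(n_bg_snp, length(free)))]
    for (i in seq_len(min(n_bg_indel, length(free)))) {
      p <- free[i]
      L <- sample(2:6, 1)
      r <- toupper(backbone[p])
      if (stats::runif(1) < 0.5) {
        ref <- paste0(r, paste(toupper(backbone[(p + 1):(p + L)]), collapse = ""))
        add_var("chrG", p, ref, r, stats::runif(1, 0.55, 0.95), "INDEL")
      } else {
        add_var("chrG", p, r, paste0(r, rand_bases(L)), stats::runif(1, 0.55, 0.95), "INDEL")
      }
    }
    variants <- if (length(recs) == 0) empty_population_tbl() else
      bind_rows(recs) %>% arrange(.data$chrom, .data$pos)
    models_old <- recompute_frames(bind_rows(models)) %>%
      arrange(.data$tx_start)
    list(old_genome = old_genome, variants = variants, models_old = models_old,
         mrna_set = mrna_set, protein_set = prot_set, gene_info = bind_rows(info))
  })
}

#' Simulate a pair of call sets with planted overlap structure
#'
#' Generates two call sets over a genome with known numbers of common
#' variants, set-specific unique variants, REF/ALT-swapped SNP pairs (same
#' site called against references carrying different alleles) and overlapping
#' INDEL pairs, per class. Quality and depth pass the default filters.
#'
#' @param genome Named character vector.
#' @param seed Integer seed.
#' @param n_common,n_unique_a,n_unique_b Planted counts (split between
#'   classes by `frac_indel`).
#' @param n_swap Planted swap pairs (SNP, counted in the common truth).
#' @param n_overlap_indel Planted INDEL pairs at offset positions with
#'   overlapping REF spans (counted in the common truth).
#' @param frac_indel Fraction of planted records that are INDELs.
#' @return A list: `a`, `b` (sorted call tibbles with `vclass`, `qual`,
#'   `dp`), `truth` (per-class `common`, `unique_a`, `unique_b`).
#' @export
sim_callsets <- function(genome, seed = 1, n_common = 50L, n_unique_a = 10L,
                         n_unique_b = 5L, n_swap = 5L, n_overlap_indel = 5L,
                         frac_indel = 0.3) {
  with_seed(seed, {
    lens <- vapply(genome, nchar, 0L)
    sites <- bind_rows(lapply(names(genome), function(ch) {
      tibble(chrom = ch, pos = seq(15L, lens[[ch]] - 15L, by = 20L))
    }))
    sites <- sites[sample.int(nrow(sites)), ]
    cursor <- 0L
    take <- function(n) {
      out <- sites[cursor + seq_len(n), , drop = FALSE]
      cursor <<- cursor + n
      out
    }
    mk <- function(site, cl) {
      r <- toupper(genome_slice(genome, site$chrom, site$pos - 1L, site$pos))
      if (cl == "SNP") {
        tibble(chrom = site$chrom, pos = site$pos, ref = r, alt = other_base(r),
               vclass = "SNP")
      } else {
        L <- sample(2:6, 1)
        if (stats::runif(1) < 0.5) {
          ref <- toupper(genome_slice(genome, site$chrom, site$pos - 1L, site$pos + L))
          tibble(chrom = site$chrom, pos = site$pos, ref = ref, alt = r, vclass = "INDEL")
        } else {
          tibble(chrom = site$chrom, pos = site$pos, ref = r,
                 alt = paste0(r, rand_bases(L)), vclass = "INDEL")
        }
      }
    }
    classes_for <- function(n) sample(c("INDEL", "SNP"), n, replace = TRUE,
                                      prob = c(frac_indel, 1 - frac_indel))
    a <- list(); b <- list()
    truth <- c(SNP_common = 0L, INDEL_common = 0L, SNP_ua = 0L, INDEL_ua = 0L,
               SNP_ub = 0L, INDEL_ub = 0L)
    cl <- classes_for(n_common)
    for (i in seq_len(n_common)) {
      rec <- mk(take(1), cl[i])
      a[[length(a) + 1]] <- rec; b[[length(b) + 1]] <- rec
      truth[paste0(cl[i], "_common")] <- truth[paste0(cl[i], "_common")] + 1L
    }
    for (i in seq_len(n_swap)) {  # swapped SNP pair: same pos, ref/alt exchanged
      s <- take(1)
      r <- toupper(genome_slice(genome, s$chrom, s$pos - 1L, s$pos))
      o <- other_base(r)
      a[[length(a) + 1]] <- tibble(chrom = s$chrom, pos = s$pos, ref = r, alt = o, vclass = "SNP")
      b[[length(b) + 1]] <- tibble(chrom = s$chrom, pos = s$pos, ref = o, alt = r, vclass = "SNP")
      truth["SNP_common"] <- truth["SNP_common"] + 1L
    }
    for (i in seq_len(n_overlap_indel)) {  # overlapping deletions at offset starts
      s <- take(1)
      ref1 <- toupper(genome_slice(genome, s$chrom, s$pos - 1L, s$pos + 4L))
      ref2 <- toupper(genome_slice(genome, s$chrom, s$pos, s$pos + 5L))
      a[[length(a) + 1]] <- tibble(chrom = s$chrom, pos = s$pos, ref = ref1,
                                   alt = substr(ref1, 1, 1), vclass = "INDEL")
      b[[length(b) + 1]] <- tibble(chrom = s$chrom, pos = s$pos + 1L, ref = ref2,
                                   alt = substr(ref2, 1, 1), vclass = "INDEL")
      truth["INDEL_common"] <- truth["INDEL_common"] + 1L
    }
    cl <- classes_for(n_unique_a)
    for (i in seq_len(n_unique_a)) {
      a[[length(a) + 1]] <- mk(take(1), cl[i])
      truth[paste0(cl[i], "_ua")] <- truth[paste0(cl[i], "_ua")] + 1L
    }
    cl <- classes_for(n_unique_b)
    for (i in seq_len(n_unique_b)) {
      b[[length(b) + 1]] <- mk(take(1), cl[i])
      truth[paste0(cl[i], "_ub")] <- truth[paste0(cl[i], "_ub")] + 1L
    }
    finish <- function(x) bind_rows(x) %>%
      mutate(qual = round(stats::runif(dplyr::n(), 20, 60), 1),
             dp = sample(5:60, dplyr::n(), replace = TRUE)) %>%
      arrange(.data$chrom, .data$pos)
    truth_tbl <- tibble(
      vclass = c("SNP", "INDEL"),
      common = c(truth[["SNP_common"]], truth[["INDEL_common"]]),
      unique_a = c(truth[["SNP_ua"]], truth[["INDEL_ua"]]),
      unique_b = c(truth[["SNP_ub"]], truth[["INDEL_ub"]])
    )
    list(a = finish(a), b = finish(b), truth = truth_tbl)
  })
}
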