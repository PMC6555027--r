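# Independent oracles used across the suite. These deliberately re-derive
# expected behaviour by different means than the implementation: literal
# per-base replay for coordinate lifting, pairwise scans for conflict
# resolution, descending in-place string surgery for editing, and
# utils::adist for edit-distance accounting.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# --- per-base replay of minimal anchored edits -------------------------------
# Returns 1-based mapping vectors old2new / new2old (NA where a base has no
# counterpart on the other assembly).
replay_alignment <- function(old_seq, edits) {
  old_len <- nchar(old_seq)
  edits <- edits[order(edits$pos), , drop = FALSE]
  old2new <- integer(0)  # grown per base
  new_len <- 0L
  cur_old <- 1L
  o2n <- rep(NA_integer_, old_len)
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]; ref <- edits$ref[i]; alt <- edits$alt[i]
    # untouched segment before the edit
    while (cur_old < p) {
      new_len <- new_len + 1L
      o2n[cur_old] <- new_len
      cur_old <- cur_old + 1L
    }
    # align the edit: common prefix maps 1:1, remainder is one-sided
    k <- 0L
    while (k < min(nchar(ref), nchar(alt)) &&
           substr(ref, k + 1L, k + 1L) == substr(alt, k + 1L, k + 1L)) k <- k + 1L
    if (nchar(ref) == nchar(alt)) k <- nchar(ref)  # substitution: aligned
    for (j in seq_len(k)) {
      new_len <- new_len + 1L
      o2n[cur_old] <- new_len
      cur_old <- cur_old + 1L
    }
    if (nchar(ref) > k) {            # deleted bases: old-only
      cur_old <- cur_old + (nchar(ref) - k)
    }
    if (nchar(alt) > k) {            # inserted bases: new-only
      new_len <- new_len + (nchar(alt) - k)
    }
  }
  while (cur_old <= old_len) {
    new_len <- new_len + 1L
    o2n[cur_old] <- new_len
    cur_old <- cur_old + 1L
  }
  n2o <- rep(NA_integer_, new_len)
  hit <- which(!is.na(o2n))
  n2o[o2n[hit]] <- hit
  list(old2new = o2n, new2old = n2o, new_len = new_len)
}

# --- brute-force major-allele selection --------------------------------------
oracle_trim <- function(pos, ref, alt) {
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, nchar(ref)) == substring(alt, nchar(alt))) {
    ref <- substring(ref, 1, nchar(ref) - 1)
    alt <- substring(alt, 1, nchar(alt) - 1)
  }
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substring(ref, 1, 1) == substring(alt, 1, 1)) {
    ref <- substring(ref, 2); alt <- substring(alt, 2); pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

oracle_select <- function(variants, threshold = 0.5) {
  out <- list()
  for (i in seq_len(nrow(variants))) {
    if (variants$vclass[i] == "SV") next
    f <- variants$alt_freqs[[i]]
    if (all(is.na(f))) next
    hits <- which(!is.na(f) & f > threshold)
    if (length(hits) == 0) next
    hit <- hits[which.max(f[hits])]
    t <- oracle_trim(variants$pos[i], variants$ref[i], variants$alts[[i]][hit])
    out[[length(out) + 1]] <- tibble(
      chrom = variants$chrom[i], pos = as.integer(t$pos), ref = t$ref,
      alt = t$alt, af = f[hit], class = variants$vclass[i])
  }
  bind_rows(out)
}

# pairwise-scan conflict resolution: repeatedly drop the weaker member of any
# overlapping pair until no overlaps remain
oracle_resolve <- function(edits) {
  e <- edits[order(edits$chrom, edits$pos), , drop = FALSE]
  alive <- rep(TRUE, nrow(e))
  s <- e$pos - 1L
  en <- e$pos - 1L + nchar(e$ref)
  pri <- function(i) c(e$af[i], as.numeric(e$class[i] == "SNP"), -e$pos[i])
  # edits are position-sorted, so any overlapping pair is adjacent among the
  # surviving records of a chromosome: sweep, resolve, repeat until clean
  repeat {
    idx <- which(alive)
    pair <- NULL
    for (k in seq_len(length(idx) - 1)) {
      a <- idx[k]; b <- idx[k + 1]
      if (e$chrom[a] == e$chrom[b] && s[a] < en[b] && s[b] < en[a]) {
        pair <- c(a, b)
        break
      }
    }
    if (is.null(pair)) break
    pa <- pri(pair[1]); pb <- pri(pair[2])
    cmp <- (pa - pb)[which(pa != pb)[1]]
    alive[if (cmp < 0) pair[1] else pair[2]] <- FALSE
  }
  e[alive, , drop = FALSE]
}

# --- descending in-place editing ---------------------------------------------
oracle_apply_desc <- function(genome, edits) {
  for (ch in unique(edits$chrom)) {
    e <- edits %>% filter(chrom == ch) %>% arrange(desc(pos))
    s <- genome[[ch]]
    for (i in seq_len(nrow(e))) {
      p <- e$pos[i]; ref <- e$ref[i]; alt <- e$alt[i]
      # the shared anchor base of an indel is context, not replacement:
      # its soft-mask case stays untouched
      if (nchar(ref) != nchar(alt) &&
          substr(ref, 1, 1) == substr(alt, 1, 1)) {
        p <- p + 1L
        ref <- substring(ref, 2)
        alt <- substring(alt, 2)
      }
      s <- paste0(substr(s, 1, p - 1), toupper(alt),
                  substr(s, p + nchar(ref), nchar(s)))
    }
    genome[[ch]] <- s
  }
  genome
}

# standard scenario used by several property suites
make_scenario <- function(seed, lengths = c(chrA = 8000L, chrB = 6000L), ...) {
  g <- sim_genome(lengths, seed = seed)
  pv <- sim_population_vcf(g, seed = seed, n_snp = 120L, n_indel = 60L,
                           n_mnp = 10L, n_snp_indel = 10L, n_sv = 4L,
                           n_colocated = 6L, frac_major = 0.6, ...)
  sel <- resolve_colocated(suppressWarnings(select_major_alleles(pv$variants)))
  ap <- apply_edits(g, sel$kept)
  list(genome = g, pv = pv, kept = sel$kept, dropped = sel$dropped,
       applied = ap, map = build_map(ap$log), chain = build_chain(ap$log))
}
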