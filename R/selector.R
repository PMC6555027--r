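#' Classify a variant record
#'
#' Assigns one of the five variant classes used throughout the toolkit, from
#' the raw REF and ALT alleles of a record:
#'
#' * `SV` — any symbolic or breakend ALT (`<CN0>`, `A[chr1:123[`, ...);
#' * `SNP_INDEL` — a site mixing a single-base substitution allele with a
#'   length-changing allele;
#' * `MNP` — some ALT has the same length as REF, both longer than one base;
#' * `INDEL` — some ALT differs in length from REF;
#' * `SNP` — otherwise (single-base substitution).
#'
#' @param ref REF allele string (non-empty, non-symbolic).
#' @param alts Character vector of ALT alleles.
#' @return A single class string.
#' @examples
#' classify_variant("A", c("G"))         # "SNP"
#' classify_variant("AT", c("A"))        # "INDEL"
#' classify_variant("A", c("G", "AGG"))  # "SNP_INDEL"
#' classify_variant("A", c("<CN0>"))     # "SV"
#' @export
classify_variant <- function(ref, alts) {
  if (length(alts) == 0 || all(is.na(alts)) || !nzchar(ref)) {
    stop_majorref("MALFORMED_RECORD", "record has no ALT alleles or empty REF")
  }
  if (any(is_symbolic_allele(alts))) return("SV")
  rl <- nchar(ref)
  al <- nchar(alts)
  has_snp <- any(al == rl & rl == 1L)
  has_len_change <- any(al != rl)
  if (has_snp && has_len_change) return("SNP_INDEL")
  if (any(al == rl & rl > 1L)) return("MNP")
  if (has_len_change) return("INDEL")
  "SNP"
}

#' Select major alternate alleles from a population variant table
#'
#' For every record, extracts the single ALT allele whose population frequency
#' strictly exceeds `threshold` (default 0.5 — the site where the assembly
#' carries the minor allele), reduces it to its minimal VCF representation and
#' returns one candidate replacement edit per selected record. Records with no
#' allele above the threshold, structural variants (deferred), and records
#' without usable frequencies (tallied, with a warning) yield no edit.
#'
#' @param variants Population variant tibble from [read_population_vcf()].
#' @param threshold Selection threshold on alternate allele frequency
#'   (strict inequality). Default 0.5.
#' @return A tibble of edits with columns `chrom`, `pos`, `ref`, `alt`, `af`,
#'   `class`, `id` (minimal representation, 1-based positions), sorted by
#'   chromosome and position. The number of frequency-less records skipped is
#'   attached as attribute `"no_frequency"`.
#' @export
select_major_alleles <- function(variants, threshold = 0.5) {
  no_freq <- 0L
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    if (variants$vclass[i] == "SV") next
    f <- variants$alt_freqs[[i]]
    if (all(is.na(f))) { no_freq <- no_freq + 1L; next }
    hit <- which(!is.na(f) & f > threshold)
    if (length(hit) == 0) next
    if (length(hit) > 1) {
      if (threshold >= 0.5) {
        stop_majorref("IMPOSSIBLE_FREQUENCIES",
                      sprintf("record %s:%d has %d alleles with AF > %g (frequencies cannot sum > 1)",
                              variants$chrom[i], variants$pos[i], length(hit), threshold))
      }
      hit <- hit[which.max(f[hit])]
    }
    alt <- variants$alts[[i]][hit]
    if (is_symbolic_allele(alt)) next
    m <- minimize_allele(variants$pos[i], variants$ref[i], alt)
    if (m$ref == m$alt) next  # degenerate (identical alleles)
    rows[[i]] <- list(chrom = variants$chrom[i], pos = as.integer(m$pos),
                      ref = m$ref, alt = m$alt, af = f[hit],
                      class = variants$vclass[i], id = variants$id[i],
                      src_pos = variants$pos[i])
  }
  if (no_freq > 0) {
    warn(sprintf("%d record(s) without INFO AF or genotypes skipped", no_freq))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- tibble(
    chrom = map_chr(rows, "chrom"), pos = map_int(rows, "pos"),
    ref = map_chr(rows, "ref"), alt = map_chr(rows, "alt"),
    af = map_dbl(rows, "af"), class = map_chr(rows, "class"),
    id = map_chr(rows, "id"), src_pos = map_int(rows, "src_pos"))
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), af = double(), class = character(),
                  id = character(), src_pos = integer())
  }
  out <- arrange(out, .data$chrom, .data$pos)
  attr(out, "no_frequency") <- no_freq
  out
}

#' Resolve co-located candidate edits into a non-overlapping set
#'
#' Among edits whose minimal REF intervals overlap, only the edit with the
#' highest allele frequency is kept (ties prefer SNP over INDEL, then the
#' lowest position); every other overlapping edit is dropped and logged. The
#' kept set is mutually non-overlapping and sorted, and the operation is
#' idempotent.
#'
#' @param edits Edit tibble from [select_major_alleles()], one chromosome set
#'   or genome-wide (resolution is per chromosome).
#' @return A list with elements `kept` and `dropped` (the latter with a
#'   `conflict_with` column naming the winning edit).
#' @export
resolve_colocated <- function(edits) {
  if (nrow(edits) == 0) return(list(kept = edits, dropped = mutate(edits, conflict_with = character(0))))
  e <- edits %>%
    mutate(.row = dplyr::row_number(),
           .start = .data$pos - 1L,
           .end = .data$pos - 1L + nchar(.data$ref),
           .snp = .data$class == "SNP")
  # greedy: accept in priority order (max AF, SNP before INDEL, leftmost),
  # dropping anything that overlaps an already-accepted edit on its chromosome
  ord <- order(-e$af, !e$.snp, e$pos)
  kept_idx <- integer(0)
  dropped_idx <- integer(0)
  winner_of <- character(0)
  acc <- list()  # per chromosome: matrix of accepted [start, end)
  for (i in ord) {
    ch <- e$chrom[i]
    ivs <- acc[[ch]]
    overlaps <- FALSE
    win <- NA_character_
    if (!is.null(ivs)) {
      hit <- which(e$.start[i] < ivs[, 2] & ivs[, 1] < e$.end[i])
      if (length(hit) > 0) {
        overlaps <- TRUE
        win <- rownames(ivs)[hit[1]]
      }
    }
    if (overlaps) {
      dropped_idx <- c(dropped_idx, i)
      winner_of <- c(winner_of, win)
    } else {
      kept_idx <- c(kept_idx, i)
      lab <- sprintf("%s:%d:%s>%s", ch, e$pos[i], e$ref[i], e$alt[i])
      acc[[ch]] <- rbind(ivs, matrix(c(e$.start[i], e$.end[i]), 1, 2,
                                     dimnames = list(lab, NULL)))
    }
  }
  kept <- e[sort(kept_idx), ] %>% select(-dplyr::starts_with(".")) %>%
    arrange(.data$chrom, .data$pos)
  dropped <- e[dropped_idx, ] %>% select(-dplyr::starts_with(".")) %>%
    mutate(conflict_with = winner_of) %>% arrange(.data$chrom, .data$pos)
  list(kept = kept, dropped = dropped)
}

#' Summarize a selection run
#'
#' Per-class totals in the input, selected counts, multi-allelic selected
#' counts, the number of conflict-dropped edits and the number of records
#' without usable frequencies.
#'
#' @param variants Population variant tibble (the selector input).
#' @param edits Kept edit tibble (after [resolve_colocated()]).
#' @param dropped Optional tibble of conflict-dropped edits.
#' @return A `selection_summary` object (a tibble with one row per class plus
#'   attributes `dropped_conflicts` and `no_frequency`).
#' @export
summarize_selection <- function(variants, edits, dropped = NULL) {
  classes <- c("SNP", "INDEL", "SNP_INDEL", "MNP", "SV")
  totals <- variants %>% count(.data$vclass, name = "total")
  multi <- variants %>% filter(.data$multiallelic) %>% count(.data$vclass, name = "total_multiallelic")
  sel <- edits %>% count(.data$class, name = "selected")
  sel_multi <- edits %>%
    semi_join(filter(variants, .data$multiallelic) %>%
                select("chrom", src_pos = "pos"),
              by = c("chrom", "src_pos")) %>%
    count(.data$class, name = "selected_multiallelic")
  out <- tibble(vclass = classes) %>%
    left_join(totals, by = "vclass") %>%
    left_join(multi, by = "vclass") %>%
    left_join(sel, by = c(vclass = "class")) %>%
    left_join(sel_multi, by = c(vclass = "class")) %>%
    mutate(across(-"vclass", ~ tidyr::replace_na(.x, 0L)))
  attr(out, "dropped_conflicts") <- if (is.null(dropped)) 0L else nrow(dropped)
  attr(out, "no_frequency") <- attr(edits, "no_frequency") %||% 0L
  class(out) <- c("selection_summary", class(out))
  out
}
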