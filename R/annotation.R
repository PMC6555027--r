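#' Read a genePred-extended (refGene) table
#'
#' Accepts the 15-column genePred-extended dialect or the 16-column UCSC dump
#' with a leading `bin` column (auto-detected). Exon start/end/frame lists are
#' parsed from their comma-terminated form into integer list-columns; the
#' round trip through [write_genepred()] is lossless.
#'
#' @param path Path to the tab-separated table (no header).
#' @return A gene-model tibble: `name`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `cds_start`, `cds_end`, `exon_count`, `exon_starts`,
#'   `exon_ends` (integer list-columns, 0-based half-open), `score`, `name2`,
#'   `cds_start_stat`, `cds_end_stat`, `exon_frames`, and `bin` if present.
#' @export
read_genepred <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_gene_models())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1 || !ncols %in% c(15L, 16L)) {
    stop_majorref("MALFORMED_ROW",
                  sprintf("expected 15 or 16 tab-separated columns, found %s",
                          paste(ncols, collapse = "/")))
  }
  has_bin <- ncols == 16L
  off <- if (has_bin) 1L else 0L
  col <- function(i) map_chr(fields, off + i)
  parse_list <- function(x) map(x, ~ as.integer(strsplit(.x, ",", fixed = TRUE)[[1]]))
  out <- tibble(
    name = col(1), chrom = col(2), strand = col(3),
    tx_start = as.integer(col(4)), tx_end = as.integer(col(5)),
    cds_start = as.integer(col(6)), cds_end = as.integer(col(7)),
    exon_count = as.integer(col(8)),
    exon_starts = parse_list(col(9)), exon_ends = parse_list(col(10)),
    score = as.integer(col(11)), name2 = col(12),
    cds_start_stat = col(13), cds_end_stat = col(14),
    exon_frames = parse_list(col(15))
  )
  ragged <- lengths(out$exon_starts) != out$exon_count |
    lengths(out$exon_ends) != out$exon_count |
    lengths(out$exon_frames) != out$exon_count
  if (any(ragged)) {
    stop_majorref("MALFORMED_ROW",
                  paste0("exon list length disagrees with exonCount for: ",
                         paste(out$name[ragged], collapse = ", ")))
  }
  if (has_bin) out$bin <- as.integer(map_chr(fields, 1))
  out
}

empty_gene_models <- function() {
  tibble(name = character(), chrom = character(), strand = character(),
         tx_start = integer(), tx_end = integer(), cds_start = integer(),
         cds_end = integer(), exon_count = integer(), exon_starts = list(),
         exon_ends = list(), score = integer(), name2 = character(),
         cds_start_stat = character(), cds_end_stat = character(),
         exon_frames = list())
}

#' @rdname read_genepred
#' @param models Gene-model tibble.
#' @export
write_genepred <- function(models, path) {
  fmt_list <- function(x) map_chr(x, ~ paste0(paste(.x, collapse = ","), ","))
  cols <- list(models$name, models$chrom, models$strand,
               models$tx_start, models$tx_end, models$cds_start, models$cds_end,
               models$exon_count, fmt_list(models$exon_starts),
               fmt_list(models$exon_ends), models$score, models$name2,
               models$cds_start_stat, models$cds_end_stat,
               fmt_list(models$exon_frames))
  if ("bin" %in% names(models)) cols <- c(list(models$bin), cols)
  writeLines(if (nrow(models) == 0) character(0) else do.call(paste, c(cols, sep = "\t")),
             path)
  invisible(path)
}

# lift a single 0-based boundary; starts snap right, ends snap left when they
# fall in a region deleted on the destination assembly
lift_boundary <- function(b, blocks, src, dst, kind = c("start", "end")) {
  kind <- match.arg(kind)
  ss <- blocks[[paste0(src, "_start")]]
  se <- blocks[[paste0(src, "_end")]]
  ds <- blocks[[paste0(dst, "_start")]]
  probe <- if (kind == "end") b - 1L else b
  k <- findInterval(probe, ss)
  if (k >= 1 && probe < se[k]) {
    return(list(pos = ds[k] + (probe - ss[k]) + if (kind == "end") 1L else 0L,
                snapped = FALSE))
  }
  if (kind == "start") {
    nxt <- which(ss >= probe)
    if (length(nxt) == 0) return(list(pos = NA_integer_, snapped = TRUE))
    list(pos = ds[nxt[1]], snapped = TRUE)
  } else {
    prev <- which(se <= probe + 1L)
    if (length(prev) == 0) return(list(pos = NA_integer_, snapped = TRUE))
    k <- prev[length(prev)]
    list(pos = ds[k] + (se[k] - ss[k]), snapped = TRUE)
  }
}

#' Lift gene models onto the other assembly
#'
#' Lifts every boundary coordinate of each transcript through the coordinate
#' map. Boundaries that fall in a region absent from the destination assembly
#' snap toward the feature interior (starts snap right, ends snap left) and
#' the model is flagged `snapped`. Exons whose lifted span becomes empty or
#' inverted are removed. A transcript lying entirely inside a deleted region
#' is dropped and reported in the `"unmapped_models"` attribute
#' (`UNMAPPED_MODEL`).
#'
#' The pre-lift exon bounds are carried along in `.src_exon_starts` /
#' `.src_exon_ends` so that [collapse_spurious_introns()] can recognise exon
#' pieces that abutted on the source assembly.
#'
#' @param models Gene-model tibble on the source assembly.
#' @param map A `coord_map`.
#' @param direction `"old2new"` (default: migrate annotation onto the
#'   normalized assembly) or `"new2old"`.
#' @return The lifted gene-model tibble.
#' @export
lift_gene_models <- function(models, map, direction = c("old2new", "new2old")) {
  direction <- match.arg(direction)
  src <- if (direction == "old2new") "old" else "new"
  dst <- if (direction == "old2new") "new" else "old"
  out <- vector("list", nrow(models))
  unmapped <- character(0)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    blocks <- map$blocks %>% filter(.data$chrom == m$chrom)
    if (nrow(blocks) == 0) { unmapped <- c(unmapped, m$name); next }
    snapped <- FALSE
    lift_s <- function(b) { r <- lift_boundary(b, blocks, src, dst, "start"); snapped <<- snapped || r$snapped; r$pos }
    lift_e <- function(b) { r <- lift_boundary(b, blocks, src, dst, "end"); snapped <<- snapped || r$snapped; r$pos }
    es <- vapply(m$exon_starts[[1]], lift_s, 0L)
    ee <- vapply(m$exon_ends[[1]], lift_e, 0L)
    keep <- !is.na(es) & !is.na(ee) & ee > es
    if (!any(keep)) { unmapped <- c(unmapped, m$name); next }
    es2 <- es[keep]; ee2 <- ee[keep]
    tx_s <- lift_s(m$tx_start); tx_e <- lift_e(m$tx_end)
    if (is.na(tx_s)) tx_s <- es2[1]
    if (is.na(tx_e)) tx_e <- ee2[length(ee2)]
    coding <- m$cds_start < m$cds_end
    cds_s <- if (coding) lift_s(m$cds_start) else tx_s
    cds_e <- if (coding) lift_e(m$cds_end) else tx_s
    if (coding && (is.na(cds_s) || is.na(cds_e) || cds_e <= cds_s)) {
      cds_s <- tx_s; cds_e <- tx_s  # CDS wholly deleted: becomes non-coding
      snapped <- TRUE
    }
    row <- m
    row$tx_start <- min(tx_s, es2[1]); row$tx_end <- max(tx_e, ee2[length(ee2)])
    row$cds_start <- cds_s; row$cds_end <- cds_e
    row$exon_count <- length(es2)
    row$exon_starts <- list(es2); row$exon_ends <- list(ee2)
    row$exon_frames <- list(m$exon_frames[[1]][keep])
    row$.src_exon_starts <- list(m$exon_starts[[1]][keep])
    row$.src_exon_ends <- list(m$exon_ends[[1]][keep])
    row$snapped <- snapped
    out[[i]] <- row
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    res <- empty_gene_models() %>%
      mutate(.src_exon_starts = list(), .src_exon_ends = list(), snapped = logical(0))
  }
  attr(res, "unmapped_models") <- unmapped
  res
}

#' Collapse spurious small introns after liftover
#'
#' Merges the flanking exons of every intron whose lifted length is at most
#' `min_intron` (default 0: only introns eliminated entirely by a replaced
#' deletion), or whose pre-lift length was at most `min_intron` (exon pieces
#' that abutted on the source assembly — the exon-split repair case, where the
#' replaced insertion lands between them and is absorbed into the merged
#' exon). Merge events are counted per model in `introns_merged`.
#'
#' @param models Lifted gene-model tibble (from [lift_gene_models()]).
#' @param min_intron Maximum intron length (bp) that is collapsed.
#' @return The tibble with merged exon lists, updated `exon_count` and an
#'   `introns_merged` column.
#' @export
collapse_spurious_introns <- function(models, min_intron = 0) {
  has_src <- all(c(".src_exon_starts", ".src_exon_ends") %in% names(models))
  merged_n <- integer(nrow(models))
  for (i in seq_len(nrow(models))) {
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    fr <- models$exon_frames[[i]]
    if (length(es) < 2) next
    intron_len <- es[-1] - ee[-length(ee)]
    src_len <- if (has_src) {
      ses <- models$.src_exon_starts[[i]]; see <- models$.src_exon_ends[[i]]
      ses[-1] - see[-length(see)]
    } else rep(Inf, length(intron_len))
    collapse <- intron_len <= min_intron | src_len <= min_intron
    if (!any(collapse)) next
    ns <- es[1]; starts <- integer(0); ends <- integer(0); frames <- integer(0)
    for (j in seq_along(collapse)) {
      if (!collapse[j]) {
        starts <- c(starts, ns); ends <- c(ends, ee[j]); frames <- c(frames, fr[j])
        ns <- es[j + 1]
      }
    }
    starts <- c(starts, ns); ends <- c(ends, ee[length(ee)])
    frames <- c(frames, fr[length(fr)])
    models$exon_starts[[i]] <- starts
    models$exon_ends[[i]] <- ends
    models$exon_frames[[i]] <- frames
    models$exon_count[i] <- length(starts)
    merged_n[i] <- sum(collapse)
  }
  models$introns_merged <- merged_n
  models
}

#' Recompute per-exon reading frames
#'
#' Walks the exons in transcription order (reversed for the minus strand) and
#' sets each coding exon's frame to the cumulative CDS length of the preceding
#' exons modulo 3; exons with no CDS overlap get frame -1. Non-coding
#' transcripts (`cds_start == cds_end`) get all frames -1. The operation is a
#' fixpoint.
#'
#' @param models Gene-model tibble.
#' @return The tibble with `exon_frames` rewritten.
#' @export
recompute_frames <- function(models) {
  for (i in seq_len(nrow(models))) {
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    n <- length(es)
    if (cs >= ce) { models$exon_frames[[i]] <- rep(-1L, n); next }
    cds_len <- pmax(0L, pmin(ee, ce) - pmax(es, cs))
    ord <- if (models$strand[i] == "-") rev(seq_len(n)) else seq_len(n)
    frames <- rep(-1L, n)
    cum <- 0L
    for (j in ord) {
      if (cds_len[j] > 0) {
        frames[j] <- cum %% 3L
        cum <- cum + cds_len[j]
      }
    }
    models$exon_frames[[i]] <- frames
  }
  models
}

#' Extract spliced transcript sequences from a genome
#'
#' Concatenates the exon slices of each model (reverse-complemented for minus
#' strand transcripts).
#'
#' @param models Gene-model tibble.
#' @param genome Named character vector.
#' @return A tibble with `name` and `mrna` (uppercase).
#' @export
extract_transcripts <- function(models, genome) {
  mrna <- map_chr(seq_len(nrow(models)), function(i) {
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    s <- paste(map2_chr(es, ee, ~ genome_slice(genome, models$chrom[i], .x, .y)),
               collapse = "")
    s <- toupper(s)
    if (models$strand[i] == "-") revcomp(s) else s
  })
  tibble(name = models$name, mrna = mrna)
}

#' Translate the CDS of gene models
#'
#' Builds the coding sequence from the CDS-overlapping part of each exon,
#' reverse-complements on the minus strand, skips the first coding exon's
#' frame offset, and translates with the standard code. The trailing stop is
#' dropped; an internal stop truncates the translation and is flagged.
#' Ambiguous bases translate to `X`.
#'
#' @param models Gene-model tibble (coding; `cds_start < cds_end`).
#' @param genome Named character vector.
#' @return A tibble with `name`, `protein`, `internal_stop`.
#' @export
translate_cds <- function(models, genome) {
  if (any(models$cds_start >= models$cds_end)) {
    stop_majorref("NO_CDS", "translate_cds called on transcript(s) with empty CDS")
  }
  rows <- map(seq_len(nrow(models)), function(i) {
    es <- models$exon_starts[[i]]; ee <- models$exon_ends[[i]]
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    ov <- pmin(ee, ce) > pmax(es, cs)
    cds <- paste(map2_chr(pmax(es, cs)[ov], pmin(ee, ce)[ov],
                          ~ genome_slice(genome, models$chrom[i], .x, .y)),
                 collapse = "")
    cds <- toupper(cds)
    if (models$strand[i] == "-") cds <- revcomp(cds)
    frames <- models$exon_frames[[i]]
    coding_order <- if (models$strand[i] == "-") rev(which(ov)) else which(ov)
    offset <- if (length(coding_order) > 0) frames[coding_order[1]] else 0L
    if (is.na(offset) || offset < 0) offset <- 0L
    tr <- translate_nt(substr(cds, offset + 1L, nchar(cds)))
    tibble(name = models$name[i], protein = tr$protein, internal_stop = tr$internal_stop)
  })
  bind_rows(rows)
}

#' Translation-based sanity check of an annotation against reference sequences
#'
#' Extracts every transcript from the genome via its gene model and compares
#' it (exact, case-insensitive) with the reference mRNA set; translates every
#' coding model and compares with the reference protein set (terminal stop
#' ignored). Transcripts absent from the reference sets are `SKIPPED`;
#' percentages are over non-skipped transcripts.
#'
#' @param models Gene-model tibble.
#' @param genome Named character vector.
#' @param mrna_set,protein_set Named character vectors keyed by transcript id
#'   (e.g. from [read_genome()] on a FASTA).
#' @return A `sanity_report`: list with `summary` (n, match counts,
#'   percentages — `NA` when nothing comparable) and `per_transcript` (status
#'   `MATCH` / `MISMATCH` / `SKIPPED` with reason).
#' @export
sanity_check <- function(models, genome, mrna_set, protein_set) {
  n <- nrow(models)
  per <- vector("list", n)
  ext <- if (n > 0) extract_transcripts(models, genome) else tibble(name = character(), mrna = character())
  for (i in seq_len(n)) {
    nm <- models$name[i]
    coding <- models$cds_start[i] < models$cds_end[i]
    if (!nm %in% names(mrna_set) && !nm %in% names(protein_set)) {
      per[[i]] <- tibble(name = nm, mrna_status = "SKIPPED", protein_status = "SKIPPED",
                         reason = "absent from reference sets")
      next
    }
    mr_st <- if (nm %in% names(mrna_set)) {
      if (toupper(ext$mrna[i]) == toupper(mrna_set[[nm]])) "MATCH" else "MISMATCH"
    } else "SKIPPED"
    pr_st <- if (coding && nm %in% names(protein_set)) {
      got <- translate_cds(models[i, ], genome)$protein
      want <- sub("\\*$", "", toupper(protein_set[[nm]]))
      if (toupper(got) == want) "MATCH" else "MISMATCH"
    } else "SKIPPED"
    per[[i]] <- tibble(name = nm, mrna_status = mr_st, protein_status = pr_st,
                       reason = NA_character_)
  }
  per <- bind_rows(per)
  if (n == 0) per <- tibble(name = character(), mrna_status = character(),
                            protein_status = character(), reason = character())
  n_mrna <- sum(per$mrna_status != "SKIPPED")
  n_prot <- sum(per$protein_status != "SKIPPED")
  summary <- tibble(
    n_transcripts = n,
    mrna_compared = n_mrna,
    protein_compared = n_prot,
    mrna_exact_matches = sum(per$mrna_status == "MATCH"),
    protein_exact_matches = sum(per$protein_status == "MATCH"),
    mrna_match_pct = if (n_mrna > 0) 100 * sum(per$mrna_status == "MATCH") / n_mrna else NA_real_,
    protein_match_pct = if (n_prot > 0) 100 * sum(per$protein_status == "MATCH") / n_prot else NA_real_
  )
  structure(list(summary = summary, per_transcript = per), class = "sanity_report")
}

#' @export
print.sanity_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<sanity_report> %d transcript(s); mRNA match %s%%, protein match %s%%\n",
              s$n_transcripts,
              ifelse(is.na(s$mrna_match_pct), "NA", format(round(s$mrna_match_pct, 2))),
              ifelse(is.na(s$protein_match_pct), "NA", format(round(s$protein_match_pct, 2)))))
  invisible(x)
}

#' Migrate a gene annotation onto the normalized assembly
#'
#' The full annotation pipeline: liftover of all gene models, collapse of
#' spurious small introns, frame recomputation, and (when reference mRNA /
#' protein sets are supplied) a translation sanity check. Models whose
#' translation still mismatches after repair are labelled `UNFIXED` but kept
#' unchanged in the output.
#'
#' @param models Gene-model tibble on the old assembly.
#' @param map A `coord_map`.
#' @param genome The new (normalized) genome.
#' @param mrna_set,protein_set Optional named reference sequence sets.
#' @param min_intron Intron-collapse threshold, see
#'   [collapse_spurious_introns()].
#' @return A list with `models` (migrated tibble plus `status` column),
#'   `report` (a `sanity_report`, or `NULL`) and `unmapped` (names of models
#'   that could not be lifted).
#' @export
migrate_annotation <- function(models, map, genome,
                               mrna_set = NULL, protein_set = NULL,
                               min_intron = 0) {
  lifted <- lift_gene_models(models, map, direction = "old2new")
  unmapped <- attr(lifted, "unmapped_models")
  out <- lifted %>%
    collapse_spurious_introns(min_intron = min_intron) %>%
    recompute_frames()
  report <- NULL
  out$status <- "MIGRATED"
  if (!is.null(mrna_set) || !is.null(protein_set)) {
    report <- sanity_check(out, genome,
                           mrna_set %||% character(0),
                           protein_set %||% character(0))
    bad <- report$per_transcript$mrna_status == "MISMATCH" |
      report$per_transcript$protein_status == "MISMATCH"
    out$status[bad] <- "UNFIXED"
  }
  out <- select(out, -dplyr::starts_with(".src_"))
  list(models = out, report = report, unmapped = unmapped)
}
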