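#' Apply a non-overlapping edit set to a genome
#'
#' Replaces every edit's REF span with its ALT text, handling SNPs, MNPs,
#' insertions, deletions and complex substitutions natively, and returns the
#' edited genome together with a complete edit log carrying old- and
#' new-assembly coordinates for every edit. Edits are first reduced to "pure"
#' form (the shared anchor base of indels stripped) so that substitutions
#' replace in place and indels are pure gaps — the canonical block structure
#' the chain builder relies on.
#'
#' Replacement text is uppercased; soft-masked case outside edits is preserved
#' unless `uppercase_all = TRUE`.
#'
#' @param genome Named character vector (see [read_genome()]).
#' @param edits Edit tibble (`chrom`, `pos` 1-based, `ref`, `alt`, optionally
#'   `af`, `class`), non-overlapping; `ref` must match the genome
#'   (case-insensitively) at `pos`.
#' @param uppercase_all Uppercase the entire output genome.
#' @return A list with `genome` (edited, named character) and `log`
#'   (an [edit_log] object).
#' @export
apply_edits <- function(genome, edits, uppercase_all = FALSE) {
  edits <- as_tibble(edits)
  if (!"af" %in% names(edits)) edits$af <- NA_real_
  if (!"class" %in% names(edits)) edits$class <- NA_character_
  bad <- setdiff(unique(edits$chrom), names(genome))
  if (length(bad) > 0) {
    stop_majorref("UNKNOWN_CHROM", paste0("edits reference unknown chromosome(s): ",
                                          paste(bad, collapse = ", ")))
  }
  old_len <- vapply(genome, nchar, 0L)
  new_genome <- genome
  log_rows <- list()
  for (ch in names(genome)) {
    e <- edits %>% filter(.data$chrom == ch) %>% arrange(.data$pos)
    if (nrow(e) == 0) next
    # pure form: strip indel anchors
    pure <- pmap(list(e$pos, e$ref, e$alt), strip_anchor)
    p <- tibble(
      old_start = map_int(pure, ~ as.integer(.x$pos - 1L)),
      ref = map_chr(pure, "ref"),
      alt = map_chr(pure, "alt"),
      af = e$af, class = e$class
    ) %>% mutate(old_end = .data$old_start + nchar(.data$ref)) %>%
      arrange(.data$old_start, .data$old_end)
    if (any(p$old_end > old_len[[ch]])) {
      stop_majorref("OUT_OF_BOUNDS", sprintf("edit beyond end of %s", ch))
    }
    if (nrow(p) > 1 && any(p$old_start[-1] < p$old_end[-nrow(p)])) {
      i <- which(p$old_start[-1] < p$old_end[-nrow(p)])[1]
      stop_majorref("OVERLAPPING_EDITS",
                    sprintf("edits overlap on %s near position %d", ch, p$old_start[i + 1] + 1L))
    }
    seq <- genome[[ch]]
    slices <- substr(rep(seq, nrow(p)), p$old_start + 1L, p$old_end)
    mism <- which(toupper(slices) != toupper(p$ref) & nchar(p$ref) > 0)
    if (length(mism) > 0) {
      i <- mism[1]
      stop_majorref("REF_MISMATCH",
                    sprintf("edit %s:%d expects REF '%s' but genome has '%s'",
                            ch, p$old_start[i] + 1L, p$ref[i], slices[i]))
    }
    # assemble: untouched segment before each edit, then the ALT text
    seg_starts <- c(0L, p$old_end)
    seg_ends <- c(p$old_start, old_len[[ch]])
    segs <- substr(rep(seq, length(seg_starts)), seg_starts + 1L, seg_ends)
    pieces <- character(2 * nrow(p) + 1)
    pieces[seq(1, length(pieces), by = 2)] <- segs
    pieces[seq(2, length(pieces), by = 2)] <- toupper(p$alt)
    new_genome[[ch]] <- paste(pieces, collapse = "")
    delta <- nchar(p$alt) - nchar(p$ref)
    offset <- cumsum(dplyr::lag(delta, default = 0L))
    log_rows[[ch]] <- tibble(
      chrom = ch,
      old_start = p$old_start, old_end = p$old_end,
      new_start = p$old_start + offset,
      new_end = p$old_start + offset + nchar(p$alt),
      ref = p$ref, alt = toupper(p$alt), delta = delta,
      af = p$af, class = p$class
    )
  }
  if (uppercase_all) new_genome <- toupper(new_genome)
  log <- new_edit_log(bind_rows(log_rows), old_len,
                      vapply(new_genome, nchar, 0L))
  list(genome = new_genome, log = log)
}

#' Edit log constructor
#'
#' An `edit_log` records every applied replacement with its 0-based half-open
#' spans on both assemblies, plus the old and new chromosome lengths. It is the
#' single source from which the coordinate map and chain file are derived.
#'
#' @param edits Tibble with columns `chrom`, `old_start`, `old_end`,
#'   `new_start`, `new_end`, `ref`, `alt`, `delta`, `af`, `class`.
#' @param old_len,new_len Named integer vectors of chromosome lengths.
#' @return An `edit_log` object.
#' @export
new_edit_log <- function(edits, old_len, new_len) {
  if (nrow(edits) == 0) {
    edits <- tibble(chrom = character(), old_start = integer(), old_end = integer(),
                    new_start = integer(), new_end = integer(), ref = character(),
                    alt = character(), delta = integer(), af = double(), class = character())
  }
  structure(list(edits = as_tibble(edits),
                 old_len = old_len, new_len = new_len),
            class = "edit_log")
}

#' @export
print.edit_log <- function(x, ...) {
  cat(sprintf("<edit_log> %d edits on %d chromosome(s); net length change %+d bp\n",
              nrow(x$edits), length(x$old_len), sum(x$new_len) - sum(x$old_len)))
  print(x$edits, ...)
  invisible(x)
}

#' Write / read an edit log as TSV
#'
#' Chromosome lengths travel in `##old_length` / `##new_length` header lines so
#' the log is self-contained.
#'
#' @param log An `edit_log`.
#' @param path File path.
#' @return `path` (write) or an `edit_log` (read).
#' @export
write_edit_log <- function(log, path) {
  hdr <- c(
    sprintf("##old_length=%s:%d", names(log$old_len), log$old_len),
    sprintf("##new_length=%s:%d", names(log$new_len), log$new_len),
    paste0("#", paste(names(log$edits), collapse = "\t"))
  )
  body <- do.call(paste, c(as.list(log$edits), sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_edit_log
#' @export
read_edit_log <- function(path) {
  lines <- readLines(path)
  parse_len <- function(tag) {
    m <- lines[startsWith(lines, tag)]
    kv <- sub(tag, "", m, fixed = TRUE)
    parts <- strsplit(kv, ":", fixed = TRUE)
    stats::setNames(as.integer(map_chr(parts, 2)), map_chr(parts, 1))
  }
  old_len <- parse_len("##old_length=")
  new_len <- parse_len("##new_length=")
  body <- lines[!startsWith(lines, "##")]
  cols <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  if (length(body) > 1) {
    edits <- readr::read_tsv(I(body[-1]), col_names = cols, show_col_types = FALSE,
                             col_types = readr::cols(
                               chrom = "c", ref = "c", alt = "c", class = "c",
                               .default = readr::col_guess()))
    edits <- edits %>% mutate(across(c("old_start", "old_end", "new_start",
                                       "new_end", "delta"), as.integer),
                              across(c("ref", "alt"), ~ tidyr::replace_na(.x, "")))
  } else {
    edits <- tibble()
  }
  new_edit_log(edits, old_len, new_len)
}

#' Verify an applied edit set
#'
#' Re-checks, edit by edit, that the new genome carries each ALT at its logged
#' new span, the old genome carries each REF at its old span, and that every
#' inter-edit segment is identical between the two genomes.
#'
#' @param new_genome,old_genome Named character vectors.
#' @param log The [edit_log] produced by [apply_edits()].
#' @return A list with `pass` (logical) and `failures` (tibble naming the first
#'   and any further discrepancies).
#' @export
verify_edits <- function(new_genome, log, old_genome) {
  fails <- list()
  e <- log$edits
  for (ch in names(log$old_len)) {
    ec <- e %>% filter(.data$chrom == ch)
    oldseq <- toupper(old_genome[[ch]])
    newseq <- toupper(new_genome[[ch]])
    for (i in seq_len(nrow(ec))) {
      got_new <- substr(newseq, ec$new_start[i] + 1L, ec$new_end[i])
      got_old <- substr(oldseq, ec$old_start[i] + 1L, ec$old_end[i])
      if (got_new != toupper(ec$alt[i])) {
        fails[[length(fails) + 1]] <- tibble(chrom = ch, check = "alt_span",
                                             at = ec$new_start[i],
                                             expected = ec$alt[i], found = got_new)
      }
      if (got_old != toupper(ec$ref[i])) {
        fails[[length(fails) + 1]] <- tibble(chrom = ch, check = "ref_span",
                                             at = ec$old_start[i],
                                             expected = ec$ref[i], found = got_old)
      }
    }
    seg_old_s <- c(0L, ec$old_end); seg_old_e <- c(ec$old_start, log$old_len[[ch]])
    seg_new_s <- c(0L, ec$new_end); seg_new_e <- c(ec$new_start, log$new_len[[ch]])
    for (i in seq_along(seg_old_s)) {
      a <- substr(oldseq, seg_old_s[i] + 1L, seg_old_e[i])
      b <- substr(newseq, seg_new_s[i] + 1L, seg_new_e[i])
      if (a != b) {
        fails[[length(fails) + 1]] <- tibble(chrom = ch, check = "segment",
                                             at = seg_old_s[i],
                                             expected = substr(a, 1, 40),
                                             found = substr(b, 1, 40))
      }
    }
  }
  failures <- bind_rows(fails)
  list(pass = nrow(failures) == 0,
       failures = if (nrow(failures) == 0)
         tibble(chrom = character(), check = character(), at = integer(),
                expected = character(), found = character())
       else failures)
}
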