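#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_chr map2_chr map_int map_dbl map_lgl pmap imap keep
#' @importFrom stringr str_sub str_length str_detect str_split fixed
NULL

# classed conditions so callers can test on error identity
stop_majorref <- function(class, message, ...) {
  abort(message, class = c(paste0("majorref_", tolower(class)), "majorref_error"), ...)
}

is_symbolic_allele <- function(alt) {
  grepl("^<.*>$", alt) | grepl("[\\[\\]]", alt) | alt == "*"
}

#' Reduce a REF/ALT pair to its minimal VCF representation
#'
#' Trims the common suffix, then the common prefix, of a REF/ALT allele pair.
#' When either allele would become empty a single left anchor base is retained
#' and the position advanced accordingly (standard VCF minimal representation).
#'
#' @param pos 1-based position of the untrimmed pair.
#' @param ref,alt Allele strings.
#' @return A list with elements `pos`, `ref`, `alt`.
#' @examples
#' minimize_allele(5, "CAT", "CGT")  # pos 6, A > G
#' @export
minimize_allele <- function(pos, ref, alt) {
  r <- ref; a <- alt
  # suffix trim
  while (nchar(r) > 1 && nchar(a) > 1 &&
         substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
    r <- substr(r, 1, nchar(r) - 1)
    a <- substr(a, 1, nchar(a) - 1)
  }
  # prefix trim with anchor retention
  while (nchar(r) > 1 && nchar(a) > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
    r <- substr(r, 2, nchar(r))
    a <- substr(a, 2, nchar(a))
    pos <- pos + 1
  }
  list(pos = pos, ref = r, alt = a)
}

# Strip the shared leading anchor base of a minimal indel, yielding the "pure"
# edit (possibly empty ref or alt) used internally by the editor and chain
# builder. Substitutions (equal length) pass through unchanged.
strip_anchor <- function(pos, ref, alt) {
  if (nchar(ref) != nchar(alt) && nchar(ref) >= 1 && nchar(alt) >= 1 &&
      substr(ref, 1, 1) == substr(alt, 1, 1)) {
    list(pos = pos + 1, ref = substr(ref, 2, nchar(ref)), alt = substr(alt, 2, nchar(alt)))
  } else {
    list(pos = pos, ref = ref, alt = alt)
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

# translate a nucleotide string (already stranded) to protein; N -> X,
# translation truncated at first internal stop (flagged), trailing stop removed
translate_nt <- function(nt) {
  nt <- toupper(nt)
  n <- (nchar(nt) %/% 3) * 3
  if (n < 3) return(list(protein = "", internal_stop = FALSE))
  aa <- suppressWarnings(as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n)), if.fuzzy.codon = "solve"
  )))
  internal_stop <- FALSE
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    if (stop_at < nchar(aa)) internal_stop <- TRUE
    aa <- substr(aa, 1, stop_at - 1)
  }
  list(protein = aa, internal_stop = internal_stop)
}
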