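#' Read a genome FASTA into a named character vector
#'
#' Sequences are kept as-is, so soft-masked (lowercase) runs survive the round
#' trip. Headers are truncated at the first whitespace to obtain sequence names.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @return Named character vector, one element per sequence.
#' @export
read_genome <- function(path) {
  s <- Biostrings::readBStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width (default 60).
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 60) {
  s <- Biostrings::BStringSet(genome)
  Biostrings::writeXStringSet(s, path, width = width)
  invisible(path)
}

genome_slice <- function(genome, chrom, start0, end0) {
  # 0-based half-open slice
  if (!chrom %in% names(genome)) {
    stop_majorref("UNKNOWN_CHROM", paste0("chromosome not in genome: ", chrom))
  }
  substr(genome[[chrom]], start0 + 1, end0)
}
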