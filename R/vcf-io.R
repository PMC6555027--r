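#' Read a population VCF into a tidy variant table
#'
#' Parses a VCF 4.x file (plain or bgzip) with [vcfR::read.vcfR()] and returns
#' one row per record with the alternate alleles and their population allele
#' frequencies as list-columns. Frequencies are taken from the INFO `AF` field
#' (comma-separated, one value per ALT); when `AF` is absent they are derived
#' from the genotype columns as alternate-allele count / called-allele count.
#' Records with neither are kept with `af_source = "none"` and `NA` frequencies
#' (downstream selection skips them with a warning and tallies them).
#'
#' @param path Path to the VCF.
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alts`
#'   (list of character), `alt_freqs` (list of numeric), `vclass`,
#'   `multiallelic`, `af_source`.
#' @seealso [select_major_alleles()], [classify_variant()]
#' @export
read_population_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(empty_population_tbl())
  alts <- str_split(fix[, "ALT"], fixed(","))
  alts[is.na(fix[, "ALT"])] <- list(character(0))
  af_raw <- tryCatch(vcfR::extract.info(v, element = "AF"),
                     error = function(e) rep(NA_character_, n))
  if (is.null(af_raw)) af_raw <- rep(NA_character_, n)
  alt_freqs <- map2(af_raw, alts, function(a, al) {
    if (is.na(a)) return(rep(NA_real_, length(al)))
    f <- suppressWarnings(as.numeric(strsplit(a, ",", fixed = TRUE)[[1]]))
    if (length(f) != length(al)) f <- rep(NA_real_, length(al))
    f
  })
  af_source <- ifelse(!is.na(af_raw), "info", "none")

  # genotype-derived fallback for records without INFO AF
  need_gt <- which(af_source == "none")
  if (length(need_gt) > 0 && !is.null(v@gt) && ncol(v@gt) > 1) {
    gt <- vcfR::extract.gt(v, element = "GT")
    for (i in need_gt) {
      g <- gt[i, ]
      al <- unlist(strsplit(g[!is.na(g)], "[/|]"))
      al <- al[al != "."]
      if (length(al) > 0) {
        k <- length(alts[[i]])
        alt_freqs[[i]] <- vapply(seq_len(k), function(j) sum(al == as.character(j)) / length(al), 0)
        af_source[i] <- "genotypes"
      }
    }
  }

  tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alts = alts,
    alt_freqs = alt_freqs,
    vclass = map2_chr(fix[, "REF"], alts, classify_variant),
    multiallelic = lengths(alts) > 1,
    af_source = af_source
  )
}

empty_population_tbl <- function() {
  tibble(
    chrom = character(), pos = integer(), id = character(), ref = character(),
    alts = list(), alt_freqs = list(), vclass = character(),
    multiallelic = logical(), af_source = character()
  )
}

#' Read an individual call set VCF into a tidy table
#'
#' Multi-allelic records are expanded to one row per ALT allele. QUAL is taken
#' from the QUAL column; read depth from INFO `DP` (falling back to the first
#' sample's FORMAT `DP`). Missing values become `NA`.
#'
#' @param path Path to the VCF.
#' @return A tibble with columns `chrom`, `pos`, `id`, `ref`, `alt`, `qual`,
#'   `dp`.
#' @export
read_callset_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), id = character(),
                  ref = character(), alt = character(), qual = double(), dp = double()))
  }
  dp <- tryCatch(suppressWarnings(as.numeric(vcfR::extract.info(v, element = "DP"))),
                 error = function(e) rep(NA_real_, nrow(fix)))
  if (is.null(dp) || all(is.na(dp))) {
    dp2 <- tryCatch(suppressWarnings(as.numeric(vcfR::extract.gt(v, element = "DP")[, 1])),
                    error = function(e) NULL)
    if (!is.null(dp2)) dp <- dp2
  }
  out <- tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
    ref = fix[, "REF"],
    alt = str_split(fix[, "ALT"], fixed(",")),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    dp = dp
  )
  tidyr::unnest(out, "alt")
}

#' Write a tidy variant table as a plain-text VCF
#'
#' Serialises a variant tibble (either population records with `alts` /
#' `alt_freqs` list-columns, or single-ALT records with `alt` and optional
#' `af`, `qual`, `dp`) as an uncompressed VCF 4.2 file. Only the INFO keys
#' present in the data (`AF`, `DP`, `VC`) are emitted.
#'
#' @param records Variant tibble.
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, contigs = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=majorref",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), as.integer(contigs)),
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Alternate allele frequency">',
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=VC,Number=1,Type=String,Description="Variant class">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  n <- nrow(records)
  if (n == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  alt_col <- if ("alts" %in% names(records)) {
    map_chr(records$alts, paste, collapse = ",")
  } else records$alt
  info <- rep("", n)
  add_info <- function(info, piece) ifelse(piece == "", info,
                                           ifelse(info == "", piece, paste0(info, ";", piece)))
  if ("alt_freqs" %in% names(records)) {
    af <- map_chr(records$alt_freqs, function(f) {
      if (all(is.na(f))) "" else paste0("AF=", paste(format(f, trim = TRUE, scientific = FALSE), collapse = ","))
    })
    info <- add_info(info, af)
  } else if ("af" %in% names(records)) {
    info <- add_info(info, ifelse(is.na(records$af), "",
                                  paste0("AF=", format(records$af, trim = TRUE, scientific = FALSE))))
  }
  if ("dp" %in% names(records)) {
    info <- add_info(info, ifelse(is.na(records$dp), "", paste0("DP=", as.integer(records$dp))))
  }
  vc <- records[["vclass"]] %||% records[["class"]]
  if (!is.null(vc)) info <- add_info(info, ifelse(is.na(vc), "", paste0("VC=", vc)))
  info[info == ""] <- "."
  qual <- if ("qual" %in% names(records)) {
    ifelse(is.na(records$qual), ".", format(records$qual, trim = TRUE))
  } else rep(".", n)
  id <- records[["id"]] %||% rep(".", n)
  body <- paste(records$chrom, records$pos, id, records$ref, alt_col,
                qual, ".", info, sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
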