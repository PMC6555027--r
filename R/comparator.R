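#' Filter low-quality calls
#'
#' Keeps records with `qual > min_qual` and `dp > min_dp` (both strict).
#' Missing depth or quality fails the filter.
#'
#' @param calls Call tibble with `qual` and `dp` columns.
#' @param min_qual,min_dp Strict lower bounds (defaults 10 and 3).
#' @return The filtered tibble.
#' @export
filter_calls <- function(calls, min_qual = 10, min_dp = 3) {
  calls %>% filter(!is.na(.data$qual), !is.na(.data$dp),
                   .data$qual > min_qual, .data$dp > min_dp)
}

# single-record normalization: suffix trim, prefix trim to anchor, then
# left-align indels while the upstream genome base permits
normalize_one <- function(genome, chrom, pos, ref, alt) {
  got <- genome_slice(genome, chrom, pos - 1L, pos - 1L + nchar(ref))
  if (toupper(got) != toupper(ref)) {
    stop_majorref("REF_MISMATCH",
                  sprintf("record %s:%d REF '%s' does not match genome '%s'",
                          chrom, pos, ref, got))
  }
  r <- toupper(ref); a <- toupper(alt)
  if (r == a) return(list(pos = pos, ref = r, alt = a))
  repeat {
    nr <- nchar(r); na <- nchar(a)
    last_eq <- nr > 0 && na > 0 && substr(r, nr, nr) == substr(a, na, na)
    if (last_eq && nr > 1 && na > 1) {
      r <- substr(r, 1, nr - 1); a <- substr(a, 1, na - 1)
    } else if (last_eq && pos > 1L) {
      # trimming would empty an allele: shift left through the genome
      r <- substr(r, 1, nr - 1); a <- substr(a, 1, na - 1)
      b <- toupper(genome_slice(genome, chrom, pos - 2L, pos - 1L))
      r <- paste0(b, r); a <- paste0(b, a)
      pos <- pos - 1L
    } else if (!last_eq && nr > 1 && na > 1 && substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r)); a <- substr(a, 2, nchar(a))
      pos <- pos + 1L
    } else break
  }
  list(pos = pos, ref = r, alt = a)
}

#' Normalize variant records against a genome
#'
#' Produces the canonical minimal, left-aligned representation of every
#' record: the common suffix is trimmed, the common prefix trimmed to the
#' anchor base, and indels are shifted left through repeat/homopolymer context
#' as far as the flanking sequence permits. Idempotent. A REF allele that does
#' not match the genome raises `REF_MISMATCH`.
#'
#' @param calls Call tibble (`chrom`, `pos`, `ref`, `alt`, ...).
#' @param genome Named character vector the calls were made against.
#' @param on_mismatch `"error"` (default) aborts when a REF allele disagrees
#'   with the genome; `"keep"` minimizes such records without left-alignment
#'   and keeps them — the expected situation for records lifted from another
#'   assembly, whose REF text is deliberately not rewritten.
#' @return The tibble with `pos`, `ref`, `alt` rewritten, sorted.
#' @export
normalize_variants <- function(calls, genome, on_mismatch = c("error", "keep")) {
  on_mismatch <- match.arg(on_mismatch)
  if (nrow(calls) == 0) return(calls)
  norm <- pmap(list(calls$chrom, calls$pos, calls$ref, calls$alt),
               function(ch, p, r, a) {
                 if (on_mismatch == "keep") {
                   got <- genome_slice(genome, ch, p - 1L, p - 1L + nchar(r))
                   if (toupper(got) != toupper(r)) {
                     return(minimize_allele(p, toupper(r), toupper(a)))
                   }
                 }
                 normalize_one(genome, ch, p, r, a)
               })
  calls$pos <- map_int(norm, ~ as.integer(.x$pos))
  calls$ref <- map_chr(norm, "ref")
  calls$alt <- map_chr(norm, "alt")
  arrange(calls, .data$chrom, .data$pos)
}

# unit-cost global alignment with traceback preference: deletion (gap in ALT)
# over substitution over insertion on ties; returns aligned character vectors
nw_align <- function(ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  n <- length(r); m <- length(a)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    D[i + 1, j + 1] <- min(D[i, j] + (r[i] != a[j]),
                           D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  }
  ar <- character(0); aa <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1L) {
      ar <- c(r[i], ar); aa <- c("-", aa); i <- i - 1
    } else if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + (r[i] != a[j])) {
      ar <- c(r[i], ar); aa <- c(a[j], aa); i <- i - 1; j <- j - 1
    } else {
      ar <- c("-", ar); aa <- c(a[j], aa); j <- j - 1
    }
  }
  list(ref = ar, alt = aa)
}

decompose_one <- function(chrom, pos, ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (ref == alt) return(NULL)
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    rs <- strsplit(ref, "")[[1]]; as_ <- strsplit(alt, "")[[1]]
    d <- which(rs != as_)
    return(tibble(chrom = chrom, pos = pos + d - 1L, ref = rs[d], alt = as_[d],
                  vclass = "SNP"))
  }
  if ((nr == 1 || na == 1) && substr(ref, 1, 1) == substr(alt, 1, 1)) {
    return(tibble(chrom = chrom, pos = pos, ref = ref, alt = alt, vclass = "INDEL"))
  }
  al <- nw_align(ref, alt)
  out <- list()
  anchor_pos <- NA_integer_; anchor_char <- NA_character_
  rp <- pos - 1L
  k <- 1
  ncol_ <- length(al$ref)
  while (k <= ncol_) {
    rc <- al$ref[k]; ac <- al$alt[k]
    if (rc != "-" && ac != "-") {
      rp <- rp + 1L
      if (rc != ac) {
        out[[length(out) + 1]] <- tibble(chrom = chrom, pos = rp, ref = rc,
                                         alt = ac, vclass = "SNP")
      }
      anchor_pos <- rp; anchor_char <- ac
      k <- k + 1
    } else if (ac == "-") {  # deletion run
      del <- character(0); start_rp <- rp + 1L
      while (k <= ncol_ && al$alt[k] == "-") {
        rp <- rp + 1L; del <- c(del, al$ref[k]); k <- k + 1
      }
      if (!is.na(anchor_pos)) {
        out[[length(out) + 1]] <- tibble(
          chrom = chrom, pos = anchor_pos,
          ref = paste0(anchor_char, paste(del, collapse = "")),
          alt = anchor_char, vclass = "INDEL")
      } else {  # gap at the very start: suffix-anchor on the next column
        nxt <- if (k <= ncol_) al$alt[k] else al$ref[length(al$ref)]
        out[[length(out) + 1]] <- tibble(
          chrom = chrom, pos = start_rp,
          ref = paste0(paste(del, collapse = ""), nxt),
          alt = nxt, vclass = "INDEL")
      }
    } else {  # insertion run
      ins <- character(0)
      while (k <= ncol_ && al$ref[k] == "-") {
        ins <- c(ins, al$alt[k]); k <- k + 1
      }
      if (is.na(anchor_pos)) { anchor_pos <- pos; anchor_char <- substr(ref, 1, 1) }
      out[[length(out) + 1]] <- tibble(
        chrom = chrom, pos = anchor_pos, ref = anchor_char,
        alt = paste0(anchor_char, paste(ins, collapse = "")), vclass = "INDEL")
    }
  }
  bind_rows(out)
}

#' Decompose complex variants into allelic primitives
#'
#' Breaks every normalized record into simple components: equal-length
#' REF/ALT pairs become one SNP per differing base; complex substitutions are
#' decomposed along a unit-cost global alignment into their SNP components
#' plus one simple INDEL carrying the length difference (prefix-anchored on
#' the preceding aligned base); already-simple records pass through. The
#' decomposition conserves the unit-cost edit distance between REF and ALT.
#'
#' @param calls Normalized call tibble.
#' @return A tibble of primitive records with a `vclass` column
#'   (`SNP`/`INDEL`); other columns of the parent record are carried along.
#' @export
decompose_primitives <- function(calls) {
  if (nrow(calls) == 0) {
    return(mutate(calls, vclass = character(0)))
  }
  extra <- setdiff(names(calls), c("chrom", "pos", "ref", "alt", "vclass"))
  rows <- map(seq_len(nrow(calls)), function(i) {
    prim <- decompose_one(calls$chrom[i], calls$pos[i], calls$ref[i], calls$alt[i])
    if (is.null(prim) || nrow(prim) == 0) return(NULL)
    for (col in extra) prim[[col]] <- calls[[col]][i]
    prim
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), vclass = character())
  }
  arrange(out, .data$chrom, .data$pos)
}

# greedy one-to-one interval matching for indels: candidate pairs ordered by
# position distance then leftmost
match_indels <- function(a, b, window = 0) {
  if (nrow(a) == 0 || nrow(b) == 0) return(tibble(ia = integer(0), ib = integer(0)))
  pairs <- list()
  for (i in seq_len(nrow(a))) {
    s1 <- a$pos[i] - 1L - window; e1 <- a$pos[i] - 1L + nchar(a$ref[i]) + window
    j <- which(b$chrom == a$chrom[i] &
                 (b$pos - 1L) < e1 & s1 < (b$pos - 1L + nchar(b$ref)))
    if (length(j) > 0) {
      pairs[[length(pairs) + 1]] <- tibble(ia = i, ib = j,
                                           dist = abs(b$pos[j] - a$pos[i]))
    }
  }
  if (length(pairs) == 0) return(tibble(ia = integer(0), ib = integer(0)))
  cand <- bind_rows(pairs) %>% arrange(.data$dist, .data$ia, .data$ib)
  used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!used_a[cand$ia[k]] && !used_b[cand$ib[k]]) {
      keep[k] <- TRUE
      used_a[cand$ia[k]] <- TRUE
      used_b[cand$ib[k]] <- TRUE
    }
  }
  cand[keep, c("ia", "ib")]
}

#' Compare two variant call sets
#'
#' Both sets must be normalized, decomposed, sorted, and expressed in the same
#' coordinate frame (lift one of them first). In `"position"` mode a SNP is
#' common when the other set has a SNP at the same chromosome and position;
#' `"allele"` mode additionally requires the allele pair to match, where a
#' REF/ALT-swapped pair (`{ref, alt}` equal as an unordered pair — the same
#' heterozygous site called against references carrying different alleles)
#' counts as a match. INDELs are common when their REF intervals, padded by
#' `indel_window`, overlap; matching is one-to-one, greedy by nearest
#' position with leftmost tie-break.
#'
#' @param set_a,set_b Primitive call tibbles (`chrom`, `pos`, `ref`, `alt`,
#'   `vclass`).
#' @param mode `"position"` (default) or `"allele"`.
#' @param indel_window Padding (bp) for INDEL interval overlap. Default 0.
#' @param decimals Decimal places for the percentages. Default 2.
#' @return A `comparison_report`: tibble with one row per variant class
#'   (`total_a`, `total_b`, `common`, `unique_a`, `unique_b`, `fp_pct`,
#'   `fn_pct`).
#' @export
compare_sets <- function(set_a, set_b, mode = c("position", "allele"),
                         indel_window = 0, decimals = 2) {
  mode <- match.arg(mode)
  for (s in list(set_a, set_b)) {
    if (nrow(s) > 1) {
      by_chrom <- s %>% group_by(.data$chrom) %>%
        summarize(ok = !is.unsorted(.data$pos), .groups = "drop")
      if (!all(by_chrom$ok)) stop_majorref("SORT_REQUIRED", "input sets must be position-sorted")
    }
  }
  out <- list()
  for (cl in c("SNP", "INDEL")) {
    a <- set_a %>% filter(.data$vclass == cl)
    b <- set_b %>% filter(.data$vclass == cl)
    if (cl == "SNP") {
      key <- function(x) {
        if (mode == "allele") {
          pair <- map2_chr(x$ref, x$alt, ~ paste(sort(c(toupper(.x), toupper(.y))), collapse = "|"))
          paste(x$chrom, x$pos, pair, sep = ":")
        } else paste(x$chrom, x$pos, sep = ":")
      }
      ka <- key(a); kb <- key(b)
      tb <- table(kb)
      ta <- table(ka)
      shared <- intersect(names(ta), names(tb))
      common <- sum(pmin(ta[shared], tb[shared]))
    } else {
      common <- nrow(match_indels(a, b, window = indel_window))
    }
    counts <- tibble(vclass = cl, total_a = nrow(a), total_b = nrow(b),
                     common = as.integer(common),
                     unique_a = nrow(a) - as.integer(common),
                     unique_b = nrow(b) - as.integer(common))
    out[[cl]] <- bind_cols(counts, compute_fp_fn(counts, decimals = decimals))
  }
  structure(bind_rows(out), class = c("comparison_report", "tbl_df", "tbl", "data.frame"))
}

#' False-positive / false-negative percentages from comparison counts
#'
#' `fp_pct = 100 * unique_a / total_a` (calls present only in the first set)
#' and `fn_pct = 100 * unique_b / total_b` (calls present only in the second
#' set), rounded to `decimals`. Zero totals yield `NA`.
#'
#' @param counts Data frame with `total_a`, `unique_a`, `total_b`, `unique_b`
#'   (one or more rows).
#' @param decimals Decimal places (default 2).
#' @return A tibble with `fp_pct` and `fn_pct`.
#' @export
compute_fp_fn <- function(counts, decimals = 2) {
  tibble(
    fp_pct = ifelse(counts$total_a > 0,
                    round(100 * counts$unique_a / counts$total_a, decimals), NA_real_),
    fn_pct = ifelse(counts$total_b > 0,
                    round(100 * counts$unique_b / counts$total_b, decimals), NA_real_)
  )
}
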