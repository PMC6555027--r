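#' Build the coordinate map between the old and new assemblies
#'
#' Derives, from an edit log, the piecewise alignment between the source
#' (old) and edited (new) assemblies as ordered equal-length blocks in 0-based
#' half-open coordinates. Substitution edits (`delta == 0`) lie inside aligned
#' blocks (the alignment tolerates mismatches); every length-changing edit
#' breaks the blocks, its minimal inserted/deleted bases left unaligned.
#' Complex substitutions (both sides longer than one base, lengths differing)
#' are unaligned on both axes.
#'
#' @param log An [edit_log].
#' @return A `coord_map` object: blocks tibble (`chrom`, `new_start`,
#'   `new_end`, `old_start`, `old_end`) plus old/new chromosome lengths.
#' @export
build_map <- function(log) {
  rows <- list()
  for (ch in names(log$old_len)) {
    e <- log$edits %>% filter(.data$chrom == ch, .data$delta != 0 |
                                nchar(.data$ref) != nchar(.data$alt)) %>%
      arrange(.data$old_start)
    told <- 0L; tnew <- 0L
    blocks <- list()
    for (i in seq_len(nrow(e))) {
      size <- e$old_start[i] - told
      if (size > 0) {
        blocks[[length(blocks) + 1]] <-
          tibble(chrom = ch, new_start = tnew, new_end = tnew + size,
                 old_start = told, old_end = told + size)
      }
      told <- e$old_end[i]; tnew <- e$new_end[i]
    }
    size <- log$old_len[[ch]] - told
    if (size > 0) {
      blocks[[length(blocks) + 1]] <-
        tibble(chrom = ch, new_start = tnew, new_end = tnew + size,
               old_start = told, old_end = told + size)
    }
    rows[[ch]] <- bind_rows(blocks)
  }
  blocks <- bind_rows(rows)
  if (nrow(blocks) == 0) {
    blocks <- tibble(chrom = character(), new_start = integer(), new_end = integer(),
                     old_start = integer(), old_end = integer())
  }
  structure(list(blocks = blocks, old_len = log$old_len, new_len = log$new_len),
            class = "coord_map")
}

#' @export
print.coord_map <- function(x, ...) {
  cat(sprintf("<coord_map> %d aligned blocks over %d chromosome(s)\n",
              nrow(x$blocks), length(x$old_len)))
  print(x$blocks, ...)
  invisible(x)
}

#' Lift positions through a coordinate map
#'
#' Positions inside aligned blocks map by constant block offset; positions in
#' one-sided gaps (bases that exist only on the source assembly) are returned
#' as `UNMAPPED` with reason `INSERTED_IN_SOURCE`. Out-of-range positions
#' raise an `OUT_OF_BOUNDS` error.
#'
#' @param positions A data frame with columns `chrom` and `pos` (1-based).
#' @param map A `coord_map`.
#' @param direction `"new2old"` (default) or `"old2new"`.
#' @return The input tibble with columns `lifted_pos` (1-based, `NA` when
#'   unmapped), `status` (`"MAPPED"`/`"UNMAPPED"`) and `reason`.
#' @export
lift_positions <- function(positions, map, direction = c("new2old", "old2new")) {
  direction <- match.arg(direction)
  src <- if (direction == "new2old") "new" else "old"
  dst <- if (direction == "new2old") "old" else "new"
  src_len <- map[[paste0(src, "_len")]]
  positions <- as_tibble(positions)
  bad <- setdiff(unique(positions$chrom), names(src_len))
  if (length(bad) > 0) {
    stop_majorref("UNKNOWN_CHROM", paste0("unknown chromosome(s): ", paste(bad, collapse = ", ")))
  }
  oob <- positions$pos < 1L | positions$pos > src_len[positions$chrom]
  if (any(oob)) {
    i <- which(oob)[1]
    stop_majorref("OUT_OF_BOUNDS",
                  sprintf("position %s:%d outside source assembly", positions$chrom[i], positions$pos[i]))
  }
  out <- positions %>% mutate(lifted_pos = NA_integer_,
                              status = "UNMAPPED",
                              reason = "INSERTED_IN_SOURCE")
  for (ch in unique(positions$chrom)) {
    b <- map$blocks %>% filter(.data$chrom == ch)
    idx <- which(out$chrom == ch)
    if (nrow(b) == 0) next
    p0 <- out$pos[idx] - 1L
    k <- findInterval(p0, b[[paste0(src, "_start")]])
    inside <- k >= 1 & p0 < b[[paste0(src, "_end")]][pmax(k, 1L)]
    hit <- idx[inside]
    kk <- k[inside]
    out$lifted_pos[hit] <- as.integer(b[[paste0(dst, "_start")]][kk] +
                                        (p0[inside] - b[[paste0(src, "_start")]][kk]) + 1L)
    out$status[hit] <- "MAPPED"
    out$reason[hit] <- NA_character_
  }
  out$reason[out$status == "MAPPED"] <- NA_character_
  out
}

#' Build a UCSC chain file from an edit log
#'
#' One chain per chromosome, target = the new (normalized) assembly and query
#' = the old assembly (the convention of a `NewToOld.over.chain` used to lift
#' new-assembly coordinates back to the old frame). The body is the
#' `(size, dt, dq)` walk over the edit log: `dt` is the unaligned ALT length on
#' the target, `dq` the unaligned REF length on the query. Adjacent edits
#' produce consecutive triplets (intermediate block size 0), never merged
#' gaps. The score field, which chain parsers ignore, is the total number of
#' aligned bases.
#'
#' @param log An [edit_log].
#' @param swap Swap target and query (write the old-to-new chain instead).
#' @return A `chain_set`: a tibble with one row per chromosome (header fields
#'   and a `blocks` list-column of `(size, dt, dq)` tibbles whose final row has
#'   `NA` gaps).
#' @export
build_chain <- function(log, swap = FALSE) {
  rows <- list()
  id <- 0L
  for (ch in names(log$old_len)) {
    id <- id + 1L
    e <- log$edits %>% filter(.data$chrom == ch, .data$delta != 0 |
                                nchar(.data$ref) != nchar(.data$alt)) %>%
      arrange(.data$old_start)
    told <- 0L; tnew <- 0L
    size <- integer(0); dt <- integer(0); dq <- integer(0)
    for (i in seq_len(nrow(e))) {
      size <- c(size, e$new_start[i] - tnew)
      dt <- c(dt, e$new_end[i] - e$new_start[i])
      dq <- c(dq, e$old_end[i] - e$old_start[i])
      told <- e$old_end[i]; tnew <- e$new_end[i]
    }
    size <- c(size, log$new_len[[ch]] - tnew)
    blocks <- tibble(size = size, dt = c(dt, NA_integer_), dq = c(dq, NA_integer_))
    if (swap) blocks <- rename(blocks, dt = "dq", dq = "dt")[, c("size", "dt", "dq")]
    t_size <- if (swap) log$old_len[[ch]] else log$new_len[[ch]]
    q_size <- if (swap) log$new_len[[ch]] else log$old_len[[ch]]
    rows[[ch]] <- tibble(
      t_name = ch, t_size = as.integer(t_size), t_start = 0L, t_end = as.integer(t_size),
      q_name = ch, q_size = as.integer(q_size), q_start = 0L, q_end = as.integer(q_size),
      score = sum(size), id = id, blocks = list(blocks)
    )
  }
  structure(bind_rows(rows), class = c("chain_set", "tbl_df", "tbl", "data.frame"))
}

#' Write / read a UCSC chain file
#'
#' Standard dialect: header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id` (space-separated, strands always `+`), tab-separated
#' `size dt dq` triplets, a bare final size, and a blank line after each chain.
#'
#' @param chain A `chain_set`.
#' @param path File path.
#' @return `path` (write) or a `chain_set` (read).
#' @export
write_chain <- function(chain, path) {
  out <- character(0)
  for (i in seq_len(nrow(chain))) {
    h <- chain[i, ]
    out <- c(out, sprintf("chain %s %s %d + %d %d %s %d + %d %d %d",
                          format(h$score, scientific = FALSE, trim = TRUE),
                          h$t_name, h$t_size, h$t_start, h$t_end,
                          h$q_name, h$q_size, h$q_start, h$q_end, h$id))
    b <- h$blocks[[1]]
    n <- nrow(b)
    if (n > 1) {
      out <- c(out, paste(b$size[-n], b$dt[-n], b$dq[-n], sep = "\t"))
    }
    out <- c(out, as.character(b$size[n]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  rows <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "chain")) { i <- i + 1; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    body <- list()
    i <- i + 1
    repeat {
      if (i > length(lines) || !nzchar(trimws(lines[i]))) break
      v <- as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]])
      body[[length(body) + 1]] <- v
      i <- i + 1
    }
    last <- body[[length(body)]]
    trips <- body[-length(body)]
    blocks <- tibble(
      size = c(map_int(trips, 1), last[1]),
      dt = c(map_int(trips, 2), NA_integer_),
      dq = c(map_int(trips, 3), NA_integer_)
    )
    rows[[length(rows) + 1]] <- tibble(
      t_name = f[3], t_size = as.integer(f[4]), t_start = as.integer(f[6]),
      t_end = as.integer(f[7]), q_name = f[8], q_size = as.integer(f[9]),
      q_start = as.integer(f[11]), q_end = as.integer(f[12]),
      score = as.numeric(f[2]), id = as.integer(f[13]), blocks = list(blocks)
    )
  }
  structure(bind_rows(rows), class = c("chain_set", "tbl_df", "tbl", "data.frame"))
}

#' Convert a chain into a coordinate map by generic chain walking
#'
#' Walks each chain's `(size, dt, dq)` triplets with target and query cursors,
#' emitting one aligned block per non-empty size. This is the generic
#' chain-consumer route used to cross-validate the directly constructed
#' [build_map()] result.
#'
#' @param chain A `chain_set` whose target is the new assembly (the default
#'   produced by [build_chain()]).
#' @return A `coord_map`.
#' @export
map_from_chain <- function(chain) {
  rows <- list()
  new_len <- integer(0); old_len <- integer(0)
  for (i in seq_len(nrow(chain))) {
    h <- chain[i, ]
    b <- h$blocks[[1]]
    t <- h$t_start; q <- h$q_start
    blocks <- list()
    for (j in seq_len(nrow(b))) {
      if (b$size[j] > 0) {
        blocks[[length(blocks) + 1]] <-
          tibble(chrom = h$t_name, new_start = t, new_end = t + b$size[j],
                 old_start = q, old_end = q + b$size[j])
      }
      t <- t + b$size[j] + ifelse(is.na(b$dt[j]), 0L, b$dt[j])
      q <- q + b$size[j] + ifelse(is.na(b$dq[j]), 0L, b$dq[j])
    }
    rows[[i]] <- bind_rows(blocks)
    new_len[h$t_name] <- h$t_size
    old_len[h$q_name] <- h$q_size
  }
  blocks <- bind_rows(rows)
  if (nrow(blocks) == 0) {
    blocks <- tibble(chrom = character(), new_start = integer(), new_end = integer(),
                     old_start = integer(), old_end = integer())
  }
  structure(list(blocks = blocks, old_len = old_len, new_len = new_len),
            class = "coord_map")
}

#' Lift VCF records through a coordinate map
#'
#' Lifts POS only — REF/ALT text is intentionally left untouched, so lifted
#' records describe the same event in the other coordinate frame even where
#' the reference base differs between assemblies. A record is unmapped when
#' its anchor position falls in a one-sided gap; a deletion whose anchor maps
#' but whose REF span partially overlaps a gap is lifted and flagged
#' (`span_warning`).
#'
#' @param records Call tibble with `chrom`, `pos`, `ref`, `alt`, ... columns.
#' @param map A `coord_map`.
#' @param direction `"new2old"` or `"old2new"`.
#' @return A list with `lifted` (sorted tibble, `pos` replaced, plus
#'   `span_warning`) and `unmapped` (original records plus `reason`).
#' @export
lift_vcf <- function(records, map, direction = c("new2old", "old2new")) {
  direction <- match.arg(direction)
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(list(lifted = mutate(records, span_warning = logical(0)),
                unmapped = mutate(records, reason = character(0))))
  }
  anchors <- lift_positions(select(records, "chrom", "pos"), map, direction)
  span_warn <- rep(FALSE, nrow(records))
  long <- which(nchar(records$ref) > 1 & anchors$status == "MAPPED")
  if (length(long) > 0) {
    span_pos <- tibble(
      chrom = rep(records$chrom[long], nchar(records$ref[long]) - 1L),
      pos = unlist(map2(records$pos[long], nchar(records$ref[long]),
                        ~ seq(.x + 1L, .x + .y - 1L)))
    )
    # bases beyond the assembly end count as gap overlap, not an error
    src_len <- map[[if (direction == "new2old") "new_len" else "old_len"]]
    inb <- span_pos$pos <= src_len[span_pos$chrom]
    span_lift <- span_pos
    span_lift$status <- "UNMAPPED"
    if (any(inb)) span_lift$status[inb] <-
        lift_positions(span_pos[inb, ], map, direction)$status
    bad <- span_lift %>% mutate(row = rep(long, nchar(records$ref[long]) - 1L)) %>%
      filter(.data$status == "UNMAPPED")
    span_warn[unique(bad$row)] <- TRUE
  }
  ok <- anchors$status == "MAPPED"
  lifted <- records[ok, ]
  lifted$pos <- anchors$lifted_pos[ok]
  lifted$span_warning <- span_warn[ok]
  lifted <- arrange(lifted, .data$chrom, .data$pos)
  unmapped <- records[!ok, ]
  unmapped$reason <- anchors$reason[!ok]
  list(lifted = lifted, unmapped = unmapped)
}

#' Cross-validate map-based and chain-based liftover
#'
#' Lifts every supplied position both through the direct coordinate map and
#' through generic chain walking of the chain file, and returns the fraction
#' agreeing. Unmapped outcomes must agree too, and count toward concordance
#' only when both routes return the same status (and position, when mapped).
#' An empty position set is vacuously concordant (1).
#'
#' @param positions Data frame with `chrom`, `pos`.
#' @param map A `coord_map`.
#' @param chain A `chain_set` built over the same assemblies.
#' @param direction `"new2old"` or `"old2new"`.
#' @return A list with `concordance` (fraction in `[0, 1]`), `n`, and
#'   `mismatches` (tibble of disagreeing positions).
#' @export
concordance_check <- function(positions, map, chain,
                              direction = c("new2old", "old2new")) {
  direction <- match.arg(direction)
  positions <- as_tibble(positions)
  if (nrow(positions) == 0) {
    return(list(concordance = 1, n = 0L, mismatches = tibble()))
  }
  via_map <- lift_positions(positions, map, direction)
  via_chain <- lift_positions(positions, map_from_chain(chain), direction)
  agree <- via_map$status == via_chain$status &
    (via_map$status == "UNMAPPED" |
       (!is.na(via_map$lifted_pos) & !is.na(via_chain$lifted_pos) &
          via_map$lifted_pos == via_chain$lifted_pos))
  mism <- positions[!agree, ] %>%
    mutate(map_pos = via_map$lifted_pos[!agree], map_status = via_map$status[!agree],
           chain_pos = via_chain$lifted_pos[!agree], chain_status = via_chain$status[!agree])
  list(concordance = mean(agree), n = nrow(positions), mismatches = mism)
}
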