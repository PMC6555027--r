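#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_histogram facet_wrap
#'   labs position_dodge
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @method tidy selection_summary
#' @export
tidy.selection_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "selection_summary")
  attr(out, "dropped_conflicts") <- NULL
  attr(out, "no_frequency") <- NULL
  out
}

#' @method glance selection_summary
#' @export
glance.selection_summary <- function(x, ...) {
  tibble(n_records = sum(x$total), n_selected = sum(x$selected),
         n_multiallelic_selected = sum(x$selected_multiallelic),
         dropped_conflicts = attr(x, "dropped_conflicts") %||% 0L,
         no_frequency = attr(x, "no_frequency") %||% 0L)
}

#' @method autoplot selection_summary
#' @export
autoplot.selection_summary <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("total", "selected"), names_to = "set", values_to = "n")
  ggplot(d, aes(x = .data$vclass, y = .data$n, fill = .data$set)) +
    geom_col(position = position_dodge()) +
    ggplot2::scale_y_log10() +
    labs(x = "variant class", y = "records (log scale)",
         title = "Population records vs. selected major alleles")
}

#' @method tidy edit_log
#' @export
tidy.edit_log <- function(x, ...) x$edits

#' @method glance edit_log
#' @export
glance.edit_log <- function(x, ...) {
  tibble(n_edits = nrow(x$edits), n_chromosomes = length(x$old_len),
         net_delta = sum(x$new_len) - sum(x$old_len),
         n_insertions = sum(x$edits$delta > 0),
         n_deletions = sum(x$edits$delta < 0),
         n_substitutions = sum(x$edits$delta == 0))
}

#' @method autoplot edit_log
#' @export
autoplot.edit_log <- function(object, bins = 50, ...) {
  ggplot(object$edits, aes(x = .data$old_start, fill = .data$class)) +
    geom_histogram(bins = bins) +
    facet_wrap(~chrom, scales = "free_x") +
    labs(x = "position (source assembly)", y = "replaced alleles",
         title = "Distribution of replaced major alleles along the chromosomes")
}

#' @method tidy coord_map
#' @export
tidy.coord_map <- function(x, ...) x$blocks

#' @method glance coord_map
#' @export
glance.coord_map <- function(x, ...) {
  tibble(n_blocks = nrow(x$blocks),
         aligned_bases = sum(x$blocks$new_end - x$blocks$new_start),
         old_bases = sum(x$old_len), new_bases = sum(x$new_len))
}

#' @method tidy comparison_report
#' @export
tidy.comparison_report <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "comparison_report")
  out
}

#' @method glance comparison_report
#' @export
glance.comparison_report <- function(x, ...) {
  tibble(total_a = sum(x$total_a), total_b = sum(x$total_b),
         common = sum(x$common), unique_a = sum(x$unique_a),
         unique_b = sum(x$unique_b)) %>%
    bind_cols(compute_fp_fn(.))
}

#' @method autoplot comparison_report
#' @export
autoplot.comparison_report <- function(object, ...) {
  d <- tidy(object) %>%
    tidyr::pivot_longer(c("fp_pct", "fn_pct"), names_to = "measure", values_to = "pct")
  ggplot(d, aes(x = .data$vclass, y = .data$pct, fill = .data$measure)) +
    geom_col(position = position_dodge()) +
    labs(x = "variant class", y = "%",
         title = "False-positive / false-negative rates by class")
}

#' @method tidy sanity_report
#' @export
tidy.sanity_report <- function(x, ...) x$per_transcript

#' @method glance sanity_report
#' @export
glance.sanity_report <- function(x, ...) x$summary

#' @method autoplot sanity_report
#' @export
autoplot.sanity_report <- function(object, ...) {
  d <- object$summary %>%
    tidyr::pivot_longer(c("mrna_match_pct", "protein_match_pct"),
                        names_to = "level", values_to = "pct")
  ggplot(d, aes(x = .data$level, y = .data$pct)) +
    geom_col() +
    labs(y = "% exact matches", x = NULL,
         title = "Annotation sanity check against reference sequences")
}
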