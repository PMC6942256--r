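#' Per-taxon mean relative abundance within one condition
#'
#' @param x Long abundance tibble with `rel_abund` (see [to_relative()]).
#' @param condition Condition label present in the table.
#' @param center `"mean"` (default) or `"median"` across the condition's
#'   samples.
#' @return Tibble: taxon_id, the six ranks, mean_rel_abund.
#' @export
condition_means <- function(x, condition, center = c("mean", "median")) {
  center <- match.arg(center)
  validate_abund(x, relative = TRUE)
  if (!condition %in% x$condition) {
    stop("unknown condition: ", condition, call. = FALSE)
  }
  fun <- if (center == "mean") mean else median
  x |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("taxon_id", RANKS)))) |>
    dplyr::summarise(mean_rel_abund = fun(.data$rel_abund), .groups = "drop") |>
    dplyr::arrange(.data$taxon_id)
}

#' Fold change and direction class between two condition means
#'
#' f = (mean_a + eps) / (mean_b + eps); the reported fold is max(f, 1/f), so
#' it is always >= 1 and symmetric in its arguments. The direction is
#' `increased_in_a` or `increased_in_b` when the fold strictly exceeds
#' `threshold`, and `unchanged` otherwise (a fold of exactly `threshold`
#' counts as unchanged). Vectorised.
#'
#' @param mean_a,mean_b Non-negative mean relative abundances.
#' @param pseudocount Small proportion added to both means so absent taxa
#'   yield a bounded fold (default 1e-6).
#' @param threshold Fold beyond which a taxon is called changed (default 1.5,
#'   strict inequality).
#' @return Tibble with columns `fold` (>= 1) and `direction`.
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 1e-6, threshold = 1.5) {
  if (any(mean_a < 0) || any(mean_b < 0)) {
    stop("means must be non-negative", call. = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  f <- (mean_a + pseudocount) / (mean_b + pseudocount)
  fold <- pmax(f, 1 / f)
  direction <- dplyr::case_when(
    fold <= threshold ~ "unchanged",
    f > 1 ~ "increased_in_a",
    TRUE ~ "increased_in_b")
  tibble::tibble(fold = fold, direction = direction)
}

#' Fold-change classification of every taxon between two conditions
#'
#' Aggregates the table to the requested rank, computes each condition's mean
#' relative abundance per taxon, and classifies each taxon as increased in
#' a, increased in b, or unchanged by the strict fold threshold.
#'
#' @param x Long abundance tibble with `rel_abund`.
#' @param condition_a,condition_b Condition labels to contrast.
#' @param rank `"family"`, `"class"` or `"phylum"`.
#' @param fold_threshold Strict fold cut-off (default 1.5).
#' @param pseudocount See [fold_change()].
#' @param center Central tendency passed to [condition_means()].
#' @return Tibble of differential records: taxon, rank, phylum, condition_a,
#'   condition_b, mean_a, mean_b, fold, direction.
#' @export
differential_table <- function(x, condition_a, condition_b,
                               rank = c("family", "class", "phylum"),
                               fold_threshold = 1.5, pseudocount = 1e-6,
                               center = "mean") {
  rank <- match.arg(rank)
  validate_abund(x, relative = TRUE)
  agg <- aggregate_to_rank(x, rank)
  ma <- condition_means(agg, condition_a, center = center)
  mb <- condition_means(agg, condition_b, center = center)
  joined <- dplyr::inner_join(
    dplyr::rename(ma, mean_a = "mean_rel_abund"),
    dplyr::select(dplyr::rename(mb, mean_b = "mean_rel_abund"),
                  dplyr::all_of(c("taxon_id", "mean_b"))),
    by = "taxon_id")
  fc <- fold_change(joined$mean_a, joined$mean_b,
                    pseudocount = pseudocount, threshold = fold_threshold)
  tibble::tibble(
    taxon = joined$taxon_id,
    rank = rank,
    phylum = joined$phylum,
    condition_a = condition_a,
    condition_b = condition_b,
    mean_a = joined$mean_a,
    mean_b = joined$mean_b,
    fold = fc$fold,
    direction = fc$direction) |>
    dplyr::arrange(.data$taxon)
}

#' Most abundant families within one condition
#'
#' Ranks families by their mean relative abundance in the given condition and
#' keeps the top `k`. Ties at the boundary are broken lexicographically by
#' label so the result is deterministic. The `"unclassified"` family is
#' excluded.
#'
#' @param x Long abundance tibble with `rel_abund`.
#' @param condition Condition label.
#' @param k Number of families to keep (default 15).
#' @return Tibble: condition, family, mean_rel_abund, in descending abundance.
#' @export
top_abundant_families <- function(x, condition, k = 15) {
  stopifnot(k >= 1)
  agg <- aggregate_to_rank(x, "family")
  m <- condition_means(agg, condition)
  m |>
    dplyr::filter(.data$family != UNCLASSIFIED) |>
    dplyr::arrange(dplyr::desc(.data$mean_rel_abund), .data$taxon_id) |>
    head(k) |>
    dplyr::transmute(condition = !!condition, family = .data$taxon_id,
                     mean_rel_abund = .data$mean_rel_abund)
}

#' Plot a differential-abundance table
#'
#' Log2 fold changes signed toward condition a, coloured by direction class.
#'
#' @param diff Output of [differential_table()].
#' @return A ggplot object.
#' @export
plot_differential <- function(diff) {
  d <- diff |>
    dplyr::mutate(signed_log2 = ifelse(.data$mean_a >= .data$mean_b,
                                       log2(.data$fold), -log2(.data$fold)))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$taxon, .data$signed_log2),
    y = .data$signed_log2, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = sprintf("log2 fold (%s vs %s)", d$condition_a[1],
                              d$condition_b[1])) +
    ggplot2::theme_minimal()
}
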