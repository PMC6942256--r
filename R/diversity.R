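#' Shannon diversity of a count vector
#'
#' H = -sum(p_i log p_i) over taxa with positive counts, with
#' p_i = count_i / total. Natural log (nats) by default; pass `base = 2`
#' for bits.
#'
#' @param counts Non-negative numeric vector with at least one positive entry.
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Shannon entropy, a scalar >= 0 and <= log(richness).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("all-zero count vector", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' Observed richness of a count vector
#'
#' @param counts Non-negative numeric vector.
#' @return Number of strictly positive entries.
#' @export
richness <- function(counts) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  sum(counts > 0)
}

#' Expected richness in a rarefied subsample
#'
#' Analytic (hypergeometric) expectation of the number of taxa observed when
#' `depth` individuals are drawn without replacement from the pool described
#' by `counts`:
#' E(S_depth) = S - sum_i choose(N - N_i, depth) / choose(N, depth),
#' summed over taxa with N_i > 0. Evaluated via `lchoose` so large totals do
#' not overflow. Vectorised over `depth`.
#'
#' @param counts Non-negative integer vector.
#' @param depth Subsample size(s), integers in `[1, sum(counts)]`.
#' @return Expected richness, one value per depth.
#' @export
rarefaction_expected_richness <- function(counts, depth) {
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  n_i <- counts[counts > 0]
  n_total <- sum(n_i)
  if (any(depth < 1) || any(depth > n_total)) {
    stop("depth must lie in [1, total count]", call. = FALSE)
  }
  vapply(depth, function(d) {
    miss <- exp(lchoose(n_total - n_i, d) - lchoose(n_total, d))
    length(n_i) - sum(miss)
  }, numeric(1))
}

#' Per-sample richness and Shannon diversity
#'
#' @param x Long abundance tibble (counts).
#' @param base Logarithm base for Shannon (default natural log).
#' @return A tibble with sample_id, study_id, condition, richness, shannon.
#' @export
diversity_summary <- function(x, base = exp(1)) {
  validate_abund(x)
  x |>
    dplyr::group_by(.data$sample_id, .data$study_id, .data$condition) |>
    dplyr::summarise(richness = richness(.data$count),
                     shannon = shannon(.data$count, base = base),
                     .groups = "drop") |>
    dplyr::arrange(.data$sample_id)
}

#' Rarefaction curves for every sample
#'
#' Analytic expected richness on a grid of depths per sample. The default
#' grid is 20 depths evenly spaced from 1 to the sample total.
#'
#' @param x Long abundance tibble (counts).
#' @param depths Optional integer vector of depths applied to every sample
#'   (values above a sample's total are dropped for that sample).
#' @param n_depths Grid size when `depths` is `NULL`.
#' @return Long tibble: sample_id, depth, expected_richness.
#' @export
rarefaction_curve <- function(x, depths = NULL, n_depths = 20) {
  validate_abund(x)
  x |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::reframe({
      cts <- .data$count
      total <- sum(cts)
      d <- if (is.null(depths)) {
        unique(pmax(1, round(seq(1, total, length.out = n_depths))))
      } else {
        sort(unique(depths[depths <= total]))
      }
      tibble::tibble(
        depth = d,
        expected_richness = rarefaction_expected_richness(cts, d))
    }) |>
    dplyr::arrange(.data$sample_id, .data$depth)
}

#' Plot rarefaction curves
#'
#' @param curves Output of [rarefaction_curve()].
#' @return A ggplot object (one line per sample).
#' @export
plot_rarefaction <- function(curves) {
  ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$depth, y = .data$expected_richness, group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "subsample depth", y = "expected richness",
                  title = "Rarefaction curves") +
    ggplot2::theme_minimal()
}

#' Plot per-sample diversity by condition
#'
#' @param summary Output of [diversity_summary()].
#' @param metric `"shannon"` or `"richness"`.
#' @return A ggplot object.
#' @export
plot_diversity <- function(summary, metric = c("shannon", "richness")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(summary, ggplot2::aes(
    x = .data$condition, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
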