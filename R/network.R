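#' Pearson correlation test between two abundance vectors
#'
#' Sample Pearson coefficient with the two-sided p-value of
#' t = r * sqrt((n - 2) / (1 - r^2)) under a t distribution with n - 2
#' degrees of freedom (exact under bivariate normality). |r| = 1 yields
#' p = 0. A vector with zero variance cannot be tested: the pair is flagged
#' `untestable` with `r` and `p` set to `NA` — such pairs never become edges.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return One-row tibble: r, p, n, untestable.
#' @export
pearson_edge <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = n,
                          untestable = TRUE))
  }
  r <- cor(x, y)
  tibble::tibble(r = r, p = cor_pvalue(r, n), n = n, untestable = FALSE)
}

#' Two-sided p-value for a Pearson coefficient via the t transform
#'
#' @param r Pearson coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (>= 3).
#' @return Two-sided tail probability with n - 2 degrees of freedom;
#'   0 when |r| = 1.
#' @export
cor_pvalue <- function(r, n) {
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t_stat <- abs(r[ok]) * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
  p
}

new_coab_network <- function(nodes, edges, thresholds, n_samples,
                             untestable = character(0)) {
  structure(list(nodes = nodes, edges = edges, thresholds = thresholds,
                 n_samples = n_samples, untestable = untestable),
            class = "coab_network")
}

#' Build a family-family co-abundance network
#'
#' For every pair of eligible families, computes the Pearson correlation of
#' their relative abundances across all samples and connects the pair when
#' r strictly exceeds `r_min` AND the two-sided p-value is strictly below
#' `p_max` (defaults r > 0.3, p < 1e-10). Eligible families have a named
#' (non-"unclassified") phylum, appear with positive abundance in at least
#' `min_prevalence` samples, and have non-constant profiles. Correlations
#' pool all samples and studies; `stratify_by_study = TRUE` instead averages
#' per-study coefficients (studies with >= 3 samples) and computes the
#' p-value from that average at the pooled n, an approximation noted in the
#' documentation.
#'
#' @param x Long abundance tibble with `rel_abund`; aggregated to family rank
#'   internally if needed.
#' @param r_min Strict lower bound on r (default 0.3).
#' @param p_max Strict upper bound on p (default 1e-10).
#' @param min_prevalence Minimum number of samples with positive abundance
#'   (default 10).
#' @param include_unclassified Keep families whose label or phylum is
#'   "unclassified" (default `FALSE`).
#' @param stratify_by_study Average per-study correlations instead of pooling
#'   (default `FALSE`).
#' @return A `coab_network`: node tibble (family, phylum, mean_abundance,
#'   prevalence), edge tibble (family_u, family_v, r, p, n, intra_phylum),
#'   and the thresholds used.
#' @export
build_network <- function(x, r_min = 0.3, p_max = 1e-10, min_prevalence = 10,
                          include_unclassified = FALSE,
                          stratify_by_study = FALSE) {
  stopifnot(r_min >= -1, r_min <= 1, p_max > 0, p_max <= 1)
  validate_abund(x, relative = TRUE)
  fam <- if (all(x$taxon_id == x$family)) x else aggregate_to_rank(x, "family")

  n_samples <- dplyr::n_distinct(fam$sample_id)
  if (n_samples < 3) stop("need at least 3 samples", call. = FALSE)

  nodes <- fam |>
    dplyr::group_by(.data$family, .data$phylum) |>
    dplyr::summarise(mean_abundance = mean(.data$rel_abund),
                     prevalence = sum(.data$rel_abund > 0),
                     .groups = "drop")
  if (!include_unclassified) {
    nodes <- dplyr::filter(nodes, .data$family != UNCLASSIFIED,
                           .data$phylum != UNCLASSIFIED)
  }
  nodes <- nodes |>
    dplyr::filter(.data$prevalence >= min_prevalence) |>
    dplyr::arrange(.data$family)
  if (nrow(nodes) < 2) {
    stop("fewer than 2 eligible families after filtering", call. = FALSE)
  }

  mat <- fam |>
    dplyr::filter(.data$family %in% nodes$family) |>
    dplyr::select(dplyr::all_of(c("family", "sample_id", "rel_abund"))) |>
    tidyr::pivot_wider(names_from = "family", values_from = "rel_abund",
                       values_fill = 0) |>
    dplyr::arrange(.data$sample_id)
  sample_ids <- mat$sample_id
  m <- as.matrix(mat[, nodes$family, drop = FALSE])

  sds <- apply(m, 2, stats::sd)
  untestable <- nodes$family[sds == 0]
  testable <- nodes$family[sds > 0]
  edges <- tibble::tibble(family_u = character(0), family_v = character(0),
                          r = numeric(0), p = numeric(0), n = integer(0),
                          intra_phylum = logical(0))
  if (length(testable) >= 2) {
    mt <- m[, testable, drop = FALSE]
    if (stratify_by_study) {
      study_of <- fam |>
        dplyr::distinct(.data$sample_id, .data$study_id)
      study <- study_of$study_id[match(sample_ids, study_of$sample_id)]
      rs <- list()
      for (s in unique(study)) {
        idx <- which(study == s)
        if (length(idx) >= 3) {
          ok <- apply(mt[idx, , drop = FALSE], 2, stats::sd) > 0
          rmat_s <- matrix(NA_real_, ncol(mt), ncol(mt))
          rmat_s[ok, ok] <- cor(mt[idx, ok, drop = FALSE])
          rs[[s]] <- rmat_s
        }
      }
      if (length(rs) == 0) stop("no study with >= 3 samples", call. = FALSE)
      rmat <- apply(simplify2array(rs), c(1, 2), mean, na.rm = TRUE)
    } else {
      rmat <- cor(mt)
    }
    pair <- which(upper.tri(rmat), arr.ind = TRUE)
    r <- rmat[pair]
    keep <- !is.na(r) & r > r_min
    if (any(keep)) {
      pair <- pair[keep, , drop = FALSE]
      r <- r[keep]
      p <- cor_pvalue(r, nrow(mt))
      keep_p <- p < p_max
      pair <- pair[keep_p, , drop = FALSE]
      if (nrow(pair) > 0) {
        u <- testable[pair[, 1]]
        v <- testable[pair[, 2]]
        swap <- u > v
        tmp <- u[swap]; u[swap] <- v[swap]; v[swap] <- tmp
        phy <- setNames(nodes$phylum, nodes$family)
        edges <- tibble::tibble(
          family_u = u, family_v = v, r = r[keep_p], p = p[keep_p],
          n = nrow(mt), intra_phylum = phy[u] == phy[v]) |>
          dplyr::arrange(.data$family_u, .data$family_v)
      }
    }
  }
  new_coab_network(
    nodes, edges,
    thresholds = list(r_min = r_min, p_max = p_max,
                      min_prevalence = min_prevalence),
    n_samples = n_samples, untestable = untestable)
}

#' Fraction of edges whose endpoints share a phylum
#'
#' @param net A `coab_network` with at least one edge.
#' @return Scalar in `[0, 1]`.
#' @export
intra_phylum_fraction <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  if (nrow(net$edges) == 0) {
    stop("intra-phylum fraction is undefined for an empty edge set",
         call. = FALSE)
  }
  mean(net$edges$intra_phylum)
}

#' @export
print.coab_network <- function(x, ...) {
  cat("<coab_network> ", nrow(x$nodes), " families, ", nrow(x$edges),
      " edges (r > ", x$thresholds$r_min, ", p < ", x$thresholds$p_max,
      "), n = ", x$n_samples, " samples\n", sep = "")
  if (nrow(x$edges) > 0) {
    cat("  intra-phylum edge fraction: ",
        signif(intra_phylum_fraction(x), 3), "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy coab_network
#' @export
tidy.coab_network <- function(x, ...) x$edges

#' @method glance coab_network
#' @export
glance.coab_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    intra_phylum_fraction = if (nrow(x$edges) > 0)
      intra_phylum_fraction(x) else NA_real_,
    n_samples = x$n_samples,
    r_min = x$thresholds$r_min,
    p_max = x$thresholds$p_max)
}

#' Convert a co-abundance network to an igraph graph
#'
#' Node attributes: phylum, mean_abundance and any annotation columns (e.g.
#' direction); edge attributes: r, p.
#'
#' @param net A `coab_network`.
#' @return An undirected igraph object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "coab_network"))
  igraph::graph_from_data_frame(
    d = net$edges[, c("family_u", "family_v", "r", "p")],
    directed = FALSE,
    vertices = as.data.frame(net$nodes))
}

#' @method autoplot coab_network
#' @export
autoplot.coab_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  lay <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- object$nodes |>
    dplyr::mutate(x = lay[, 1], y = lay[, 2])
  ends <- igraph::as_edgelist(g)
  seg <- tibble::tibble(
    x = nodes$x[match(ends[, 1], nodes$family)],
    y = nodes$y[match(ends[, 1], nodes$family)],
    xend = nodes$x[match(ends[, 2], nodes$family)],
    yend = nodes$y[match(ends[, 2], nodes$family)],
    intra_phylum = object$edges$intra_phylum)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$intra_phylum),
      linewidth = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "black", `FALSE` = "grey60")) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$mean_abundance,
                   fill = .data$phylum),
      shape = 21) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "intra-phylum", fill = "phylum",
                  size = "mean abundance")
}

#' Write the edge list as TSV
#'
#' Columns: family_u, family_v, phylum_u, phylum_v, r, p, n, intra_phylum.
#'
#' @param net A `coab_network`.
#' @param path Output path.
#' @param header Optional comment line prepended to the file.
#' @return `path`, invisibly.
#' @export
write_edge_tsv <- function(net, path, header = NULL) {
  stopifnot(inherits(net, "coab_network"))
  phy <- setNames(net$nodes$phylum, net$nodes$family)
  out <- net$edges |>
    dplyr::mutate(phylum_u = unname(phy[.data$family_u]),
                  phylum_v = unname(phy[.data$family_v])) |>
    dplyr::select(dplyr::all_of(c("family_u", "family_v", "phylum_u",
                                  "phylum_v", "r", "p", "n", "intra_phylum")))
  if (!is.null(header)) {
    writeLines(header, path)
    readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(out, path, progress = FALSE)
  }
  invisible(path)
}

#' Write a co-abundance network as GraphML
#'
#' @param net A `coab_network`.
#' @param path Output path.
#' @param header Optional comment embedded after the XML declaration.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, header = NULL) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  if (!is.null(header)) {
    lines <- readLines(path)
    writeLines(c(lines[1], paste0("<!-- ", header, " -->"), lines[-1]), path)
  }
  invisible(path)
}
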