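#' Random-graph null for the intra-phylum edge fraction
#'
#' Under uniform placement of `n_edges` distinct edges among all unordered
#' node pairs, the expected intra-phylum fraction is
#' sum_p choose(n_p, 2) / choose(N, 2) over phyla p (independent of the edge
#' count). Monte-Carlo replicates draw `n_edges` pairs without replacement
#' and record the realised fraction; draws are seeded and reproducible. An
#' optional degree-preserving mode rewires the observed network instead
#' (requires `x` to be a `coab_network` with edges).
#'
#' @param x A `coab_network` (nodes, phyla, observed edges and fraction are
#'   taken from it) or a tibble of nodes with columns `family` and `phylum`.
#' @param n_edges Number of edges to place; defaults to the network's edge
#'   count when `x` is a network.
#' @param n_reps Number of Monte-Carlo replicates (default 1000).
#' @param seed Integer seed for the draws.
#' @param method `"uniform"` (default) or `"rewire"` (degree-preserving
#'   double-edge swaps via igraph).
#' @return A `coab_null`: observed fraction (NA when `x` is a bare node
#'   table), analytic expectation, Monte-Carlo draws, n_reps and seed.
#' @export
random_null <- function(x, n_edges = NULL, n_reps = 1000, seed = 1,
                        method = c("uniform", "rewire")) {
  method <- match.arg(method)
  stopifnot(n_reps >= 1)
  if (inherits(x, "coab_network")) {
    nodes <- x$nodes
    n_edges <- n_edges %||% nrow(x$edges)
    observed <- if (nrow(x$edges) > 0) intra_phylum_fraction(x) else NA_real_
  } else {
    nodes <- tibble::as_tibble(x)
    stopifnot(all(c("family", "phylum") %in% names(nodes)))
    observed <- NA_real_
    if (is.null(n_edges)) stop("n_edges required for a bare node table",
                               call. = FALSE)
  }
  n_nodes <- nrow(nodes)
  n_pairs <- choose(n_nodes, 2)
  if (n_edges > n_pairs) {
    stop("n_edges exceeds the number of node pairs", call. = FALSE)
  }
  sizes <- table(nodes$phylum)
  expected <- sum(choose(sizes, 2)) / n_pairs

  pairs <- combn(n_nodes, 2)
  intra <- nodes$phylum[pairs[1, ]] == nodes$phylum[pairs[2, ]]
  draws <- withr::with_seed(seed, {
    if (method == "uniform") {
      vapply(seq_len(n_reps), function(i) {
        mean(intra[sample.int(n_pairs, n_edges)])
      }, numeric(1))
    } else {
      if (!inherits(x, "coab_network") || nrow(x$edges) == 0) {
        stop("rewire method needs a coab_network with edges", call. = FALSE)
      }
      g <- as_igraph(x)
      phy <- setNames(nodes$phylum, nodes$family)
      vapply(seq_len(n_reps), function(i) {
        rg <- igraph::rewire(g, igraph::keeping_degseq(
          niter = 10 * n_edges))
        el <- igraph::as_edgelist(rg)
        mean(phy[el[, 1]] == phy[el[, 2]])
      }, numeric(1))
    }
  })
  structure(list(observed_fraction = observed,
                 expected_fraction_analytic = expected,
                 null_fractions = draws, n_reps = n_reps, seed = seed,
                 n_edges = n_edges, method = method),
            class = "coab_null")
}

#' @export
print.coab_null <- function(x, ...) {
  cat("<coab_null> ", x$n_reps, " reps (", x$method, "), ", x$n_edges,
      " edges\n  observed: ", signif(x$observed_fraction, 4),
      "  analytic: ", signif(x$expected_fraction_analytic, 4),
      "  MC mean: ", signif(mean(x$null_fractions), 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy coab_null
#' @export
tidy.coab_null <- function(x, ...) {
  tibble::tibble(rep = seq_len(x$n_reps), null_fraction = x$null_fractions)
}

#' @method glance coab_null
#' @export
glance.coab_null <- function(x, ...) {
  tibble::tibble(
    observed_fraction = x$observed_fraction,
    expected_fraction_analytic = x$expected_fraction_analytic,
    mc_mean = mean(x$null_fractions),
    mc_sd = stats::sd(x$null_fractions),
    mc_quantile_of_observed = if (is.na(x$observed_fraction)) NA_real_ else
      mean(x$null_fractions < x$observed_fraction),
    n_reps = x$n_reps,
    seed = x$seed)
}

#' @method autoplot coab_null
#' @export
autoplot.coab_null <- function(object, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$null_fraction)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$expected_fraction_analytic,
                        linetype = "dashed") +
    ggplot2::labs(x = "intra-phylum edge fraction (null draws)",
                  y = "replicates") +
    ggplot2::theme_minimal()
  if (!is.na(object$observed_fraction)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed_fraction,
                                 colour = "red")
  }
  p
}

#' Extract the condition-specific subnetwork
#'
#' Keeps an edge of the global network iff (a) at least one endpoint belongs
#' to the union of the most-abundant-family sets of the two contrasted
#' conditions and (b) at least one endpoint's abundance differs by more than
#' the fold threshold between the conditions (in either direction, per the
#' differential table). Nodes incident to a kept edge are annotated with the
#' direction class (for colouring) and the condition-b (typically healthy)
#' mean abundance (for sizing).
#'
#' @param net A `coab_network` built at family rank.
#' @param diff Differential table from [differential_table()] at family rank
#'   for (condition, healthy); must cover every network family.
#' @param abundant Families counted as "most abundant": a character vector,
#'   the output of [top_abundant_families()], or a list of such outputs
#'   (their union is used).
#' @param fold_threshold Strict fold cut-off (default 1.5). Endpoints with
#'   `direction != "unchanged"` in `diff` satisfy it by construction when
#'   `diff` was built at the same threshold.
#' @return A `coab_network` whose nodes carry `direction` and
#'   `healthy_abundance` annotations; edges are a subset of `net$edges`.
#' @export
extract_condition_subnetwork <- function(net, diff, abundant,
                                         fold_threshold = 1.5) {
  stopifnot(inherits(net, "coab_network"))
  if (is.list(abundant) && !is.data.frame(abundant)) {
    abundant <- unique(unlist(purrr::map(abundant, ~ .x$family)))
  } else if (is.data.frame(abundant)) {
    abundant <- unique(abundant$family)
  }
  unmatched <- setdiff(net$nodes$family, diff$taxon)
  if (length(unmatched) > 0) {
    stop("network families missing from the differential table: ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  changed <- diff$taxon[diff$fold > fold_threshold]
  keep <- (net$edges$family_u %in% abundant |
             net$edges$family_v %in% abundant) &
    (net$edges$family_u %in% changed | net$edges$family_v %in% changed)
  edges <- net$edges[keep, , drop = FALSE]
  node_keep <- union(edges$family_u, edges$family_v)
  nodes <- net$nodes |>
    dplyr::filter(.data$family %in% node_keep) |>
    dplyr::left_join(
      dplyr::select(diff, family = "taxon", "direction",
                    healthy_abundance = "mean_b"),
      by = "family") |>
    dplyr::arrange(.data$family)
  new_coab_network(nodes, edges,
                   thresholds = c(net$thresholds,
                                  list(fold_threshold = fold_threshold)),
                   n_samples = net$n_samples)
}
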