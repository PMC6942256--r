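#' Specification of a simulated multi-study cohort
#'
#' Fully parameterises a reproducible synthetic dataset: a phylum -> family
#' hierarchy, a latent-factor correlation structure (families within one
#' phylum share a latent factor, giving within-phylum log-scale correlation
#' `block_rho`; `between_rho` adds a global factor shared by all families),
#' per-family baseline log-abundances, log-normal dispersion, per-condition
#' fold effects on chosen families, and a sequencing-depth range. Counts are
#' drawn multinomially at a per-sample depth uniform in `depth_range`, so
#' downstream code must normalise — exactly as with real amplicon tables.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @param n_studies Number of studies.
#' @param samples_per_study Samples per study when `conditions` is `NULL`
#'   (all labelled "healthy").
#' @param conditions Named integer vector: samples per condition per study,
#'   e.g. `c(healthy = 100, CD = 100)`. Overrides `samples_per_study`.
#' @param phyla Tibble with columns `name`, `n_families`.
#' @param block_rho Within-phylum latent correlation in `[0, 1)`.
#' @param between_rho Between-phylum latent correlation in `[0, block_rho]`
#'   (default 0).
#' @param base_logmeans Baseline log-abundance per family; default an evenly
#'   spaced gradient from 2 to -2 (so softmax shares span roughly a 50-fold
#'   range, as in real family tables).
#' @param dispersion Log-normal sigma scaling the latent variation
#'   (default 1).
#' @param depth_range Min and max total counts per sample; default
#'   `c(6936, 100972)`, the depth range typical of 16S gut surveys.
#' @param condition_effects Named list: condition -> named numeric vector of
#'   fold multipliers per family (families not named get fold 1).
#' @return A `synthetic_spec` list, validated.
#' @export
synthetic_spec <- function(seed = 1, n_studies = 1, samples_per_study = 100,
                           conditions = NULL,
                           phyla = tibble::tibble(
                             name = c("Firmicutes", "Bacteroidetes",
                                      "Proteobacteria", "Actinobacteria"),
                             n_families = c(5, 5, 5, 5)),
                           block_rho = 0.8, between_rho = 0,
                           base_logmeans = NULL, dispersion = 1,
                           depth_range = c(6936, 100972),
                           condition_effects = list()) {
  phyla <- tibble::as_tibble(phyla)
  fail <- function(field) stop("invalid synthetic spec field: ", field,
                               call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1) fail("seed")
  if (n_studies < 1) fail("n_studies")
  if (!all(c("name", "n_families") %in% names(phyla)) ||
      any(phyla$n_families < 1)) fail("phyla")
  if (block_rho < 0 || block_rho >= 1) fail("block_rho")
  if (between_rho < 0 || between_rho > block_rho) fail("between_rho")
  if (dispersion <= 0) fail("dispersion")
  if (length(depth_range) != 2 || any(depth_range < 1) ||
      depth_range[1] > depth_range[2]) fail("depth_range")
  n_fam <- sum(phyla$n_families)
  families <- unlist(purrr::map2(phyla$name, phyla$n_families,
                                 ~ sprintf("%s_fam%02d", .x, seq_len(.y))))
  phylum_of <- rep(phyla$name, phyla$n_families)
  if (is.null(base_logmeans)) {
    base_logmeans <- seq(2, -2, length.out = n_fam)
  }
  if (length(base_logmeans) != n_fam) fail("base_logmeans")
  base_logmeans <- setNames(base_logmeans, families)
  if (is.null(conditions)) {
    if (samples_per_study < 1) fail("samples_per_study")
    conditions <- c(healthy = as.integer(samples_per_study))
  }
  if (is.null(names(conditions)) || any(conditions < 1)) fail("conditions")
  for (cond in names(condition_effects)) {
    eff <- condition_effects[[cond]]
    if (any(eff <= 0)) fail("condition_effects")
    if (!all(names(eff) %in% families)) {
      fail(paste0("condition_effects (unknown family: ",
                  paste(setdiff(names(eff), families), collapse = ", "), ")"))
    }
  }
  structure(list(seed = seed, n_studies = n_studies,
                 conditions = conditions, phyla = phyla,
                 families = families, phylum_of = phylum_of,
                 block_rho = block_rho, between_rho = between_rho,
                 base_logmeans = base_logmeans, dispersion = dispersion,
                 depth_range = depth_range,
                 condition_effects = condition_effects),
            class = "synthetic_spec")
}

spec_ground_truth <- function(spec) {
  planted_edges <- tibble::tibble(family_u = character(0),
                                  family_v = character(0))
  if (spec$block_rho > spec$between_rho) {
    blocks <- split(spec$families, spec$phylum_of)
    planted_edges <- purrr::map_dfr(blocks, function(fams) {
      if (length(fams) < 2) return(NULL)
      pr <- t(combn(sort(fams), 2))
      tibble::tibble(family_u = pr[, 1], family_v = pr[, 2])
    }) |>
      dplyr::arrange(.data$family_u, .data$family_v)
  }
  dirs <- purrr::map_dfr(names(spec$condition_effects), function(cond) {
    eff <- spec$condition_effects[[cond]]
    full <- setNames(rep(1, length(spec$families)), spec$families)
    full[names(eff)] <- eff
    tibble::tibble(
      condition = cond,
      family = spec$families,
      fold = unname(full),
      direction = dplyr::case_when(full > 1 ~ "increased",
                                   full < 1 ~ "decreased",
                                   TRUE ~ "unchanged"))
  })
  list(planted_edges = planted_edges, planted_directions = dirs)
}

#' Generate a synthetic multi-study abundance dataset
#'
#' Per sample: one standard-normal latent factor per phylum (plus an optional
#' global factor); each family's log-abundance is its baseline plus the
#' log fold effect of the sample's condition plus
#' `dispersion * (sqrt(between_rho) * g + sqrt(block_rho - between_rho) * z_phylum
#' + sqrt(1 - block_rho) * noise)`. Log-abundances are exponentiated,
#' normalised to proportions, and counts drawn multinomially at a depth
#' uniform in `depth_range`. With `asv_level = TRUE` each family is split
#' into 1-30 ASVs with Dirichlet(1) weights.
#'
#' @param spec A [synthetic_spec()].
#' @param asv_level Emit ASV-level rows instead of family-level rows.
#' @return A list: `table` (long abundance tibble) and `truth` (tibbles
#'   `planted_edges`, `planted_directions`).
#' @export
generate_dataset <- function(spec, asv_level = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_fam <- length(spec$families)
  phyla <- spec$phyla$name
  phy_idx <- match(spec$phylum_of, phyla)
  per_study <- sum(spec$conditions)
  n_samples <- spec$n_studies * per_study
  cond_per_study <- rep(names(spec$conditions), spec$conditions)

  sample_meta <- tibble::tibble(
    sample_id = sprintf("S%05d", seq_len(n_samples)),
    study_id = rep(sprintf("study%03d", seq_len(spec$n_studies)),
                   each = per_study),
    condition = rep(cond_per_study, times = spec$n_studies))

  logfold <- matrix(0, n_samples, n_fam)
  for (cond in names(spec$condition_effects)) {
    eff <- spec$condition_effects[[cond]]
    rows <- sample_meta$condition == cond
    logfold[rows, match(names(eff), spec$families)] <-
      rep(log(eff), each = sum(rows))
  }

  counts <- withr::with_seed(spec$seed, {
    g <- rnorm(n_samples)
    z <- matrix(rnorm(n_samples * length(phyla)), n_samples)
    eps <- matrix(rnorm(n_samples * n_fam), n_samples)
    latent <- sqrt(spec$between_rho) * g +
      sqrt(spec$block_rho - spec$between_rho) * z[, phy_idx, drop = FALSE] +
      sqrt(1 - spec$block_rho) * eps
    log_a <- matrix(spec$base_logmeans, n_samples, n_fam, byrow = TRUE) +
      logfold + spec$dispersion * latent
    w <- exp(log_a)
    p <- w / rowSums(w)
    depths <- floor(runif(n_samples, spec$depth_range[1],
                          spec$depth_range[2] + 1))
    cnt <- matrix(0L, n_fam, n_samples,
                  dimnames = list(spec$families, sample_meta$sample_id))
    for (j in seq_len(n_samples)) {
      cnt[, j] <- rmultinom(1, size = depths[j], prob = p[j, ])
    }
    if (!asv_level) {
      cnt
    } else {
      n_asv <- sample(1:30, n_fam, replace = TRUE)
      asv_rows <- list()
      k <- 0L
      for (i in seq_len(n_fam)) {
        wts <- -log(runif(n_asv[i])) # Dirichlet(1) via normalised exponentials
        wts <- wts / sum(wts)
        split_counts <- vapply(seq_len(n_samples), function(j) {
          if (cnt[i, j] == 0) integer(n_asv[i]) else
            rmultinom(1, cnt[i, j], wts)[, 1]
        }, integer(n_asv[i]))
        split_counts <- matrix(split_counts, nrow = n_asv[i])
        rownames(split_counts) <- sprintf("ASV_%s_%03d", spec$families[i],
                                          seq_len(n_asv[i]))
        asv_rows[[i]] <- split_counts
        k <- k + n_asv[i]
      }
      out <- do.call(rbind, asv_rows)
      colnames(out) <- sample_meta$sample_id
      attr(out, "family_of") <- rep(spec$families, n_asv)
      out
    }
  })

  fam_of_row <- attr(counts, "family_of") %||% rownames(counts)
  phy_of_row <- spec$phylum_of[match(fam_of_row, spec$families)]
  tax <- tibble::tibble(
    taxon_id = rownames(counts),
    kingdom = "Bacteria",
    phylum = phy_of_row,
    class = UNCLASSIFIED, order = UNCLASSIFIED,
    family = fam_of_row,
    genus = UNCLASSIFIED)
  tax$lineage <- format_lineage(tax, "silva")

  long <- dplyr::bind_cols(tax, tibble::as_tibble(counts)) |>
    tidyr::pivot_longer(dplyr::all_of(sample_meta$sample_id),
                        names_to = "sample_id", values_to = "count") |>
    dplyr::left_join(sample_meta, by = "sample_id") |>
    dplyr::select(dplyr::all_of(abund_cols()))
  validate_abund(long)
  list(table = long, truth = spec_ground_truth(spec), spec = spec)
}

#' Preset IBD-like cohort with planted fold effects
#'
#' Three conditions (CD, UC, healthy) over a 4-phylum, 20-family community
#' (Firmicutes 8, Bacteroidetes 4, Proteobacteria 5, Actinobacteria 3
#' families) with within-phylum latent correlation 0.8. Planted effects echo
#' the imbalance magnitudes reported for IBD cohorts: in CD one Bacteroidetes
#' family is decreased 2.4-fold and one Proteobacteria family increased
#' 3.8-fold; in UC a different Proteobacteria family is decreased 3.4-fold.
#' The planted families sit at low baseline abundance (about 1-2% of the
#' community) so that compositional closure perturbs the realised
#' relative-abundance folds by only a few percent.
#'
#' @param seed Integer seed.
#' @param n_per_condition Samples per condition (>= 2).
#' @return As [generate_dataset()]: list with `table`, `truth`, `spec`.
#' @export
generate_ibd_cohort <- function(seed = 1, n_per_condition = 200) {
  stopifnot(n_per_condition >= 2)
  phyla <- tibble::tibble(
    name = c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria"),
    n_families = c(8, 4, 5, 3))
  n_fam <- sum(phyla$n_families)
  # gradient within each phylum, planted families near the low end
  base <- unlist(purrr::map(phyla$n_families,
                            ~ seq(1.5, -1.5, length.out = .x)))
  spec <- synthetic_spec(
    seed = seed,
    conditions = c(CD = n_per_condition, UC = n_per_condition,
                   healthy = n_per_condition),
    phyla = phyla,
    block_rho = 0.8,
    base_logmeans = base,
    dispersion = 1,
    condition_effects = list(
      CD = c(Bacteroidetes_fam04 = 1 / 2.4, Proteobacteria_fam05 = 3.8),
      UC = c(Proteobacteria_fam04 = 1 / 3.4)))
  generate_dataset(spec)
}

#' Write a ground-truth object as TSVs next to a dataset
#'
#' @param truth The `truth` element of [generate_dataset()] output.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths of the written files, invisibly.
#' @export
write_ground_truth <- function(truth, dir, prefix = "truth") {
  edge_path <- file.path(dir, paste0(prefix, "_planted_edges.tsv"))
  dir_path <- file.path(dir, paste0(prefix, "_planted_directions.tsv"))
  readr::write_tsv(truth$planted_edges, edge_path, progress = FALSE)
  readr::write_tsv(truth$planted_directions, dir_path, progress = FALSE)
  invisible(c(edge_path, dir_path))
}
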