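# Small in-code fixtures shared across test files.

# Minimal hand-written long abundance tibble: 3 taxa x 2 samples.
tiny_table <- function() {
  tidyr::expand_grid(
    tibble::tibble(
      taxon_id = c("ASV1", "ASV2", "ASV3"),
      kingdom = "Bacteria",
      phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
      class = "unclassified", order = "unclassified",
      family = c("Lachnospiraceae", "Ruminococcaceae", "Bacteroidaceae"),
      genus = "unclassified"),
    tibble::tibble(
      sample_id = c("s1", "s2"),
      study_id = "studyA",
      condition = c("CD", "healthy"))) |>
    dplyr::mutate(
      lineage = paste("Bacteria", phylum, class, order, family, genus,
                      sep = ";"),
      count = c(3, 5, 2, 8, 1, 1)) |>
    dplyr::select(taxon_id, kingdom, phylum, class, order, family, genus,
                  lineage, sample_id, study_id, condition, count)
}

# Random table with fuzzed lineages and counts; deterministic per seed.
random_table <- function(seed, n_taxa = 20, n_samples = 6, n_families = 6,
                         n_phyla = 3, study_id = "studyR") {
  withr::with_seed(seed, {
    phyla <- paste0("Phy", seq_len(n_phyla))
    fams <- paste0("Fam", seq_len(n_families))
    fam_of <- sample(fams, n_taxa, replace = TRUE)
    phy_of_fam <- setNames(sample(phyla, n_families, replace = TRUE), fams)
    tax <- tibble::tibble(
      taxon_id = sprintf("T%03d", seq_len(n_taxa)),
      kingdom = "Bacteria",
      phylum = phy_of_fam[fam_of],
      class = "unclassified", order = "unclassified",
      family = fam_of,
      genus = "unclassified")
    tax$lineage <- paste(tax$kingdom, tax$phylum, tax$class, tax$order,
                         tax$family, tax$genus, sep = ";")
    counts <- matrix(rpois(n_taxa * n_samples, lambda = 20), n_taxa)
    counts[1, ] <- counts[1, ] + 1  # guard against zero-total samples
    colnames(counts) <- sprintf("s%02d", seq_len(n_samples))
    dplyr::bind_cols(tax, tibble::as_tibble(counts)) |>
      tidyr::pivot_longer(dplyr::starts_with("s0"), names_to = "sample_id",
                          values_to = "count") |>
      dplyr::mutate(study_id = study_id, condition = "other") |>
      dplyr::select(dplyr::all_of(c("taxon_id", "kingdom", "phylum", "class",
                                    "order", "family", "genus", "lineage",
                                    "sample_id", "study_id", "condition",
                                    "count")))
  })
}

# Independent brute-force Pearson r and two-sided t-test p, written from the
# covariance formula so it shares no code with the package path.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * min(pt(t_stat, n - 2), pt(t_stat, n - 2, lower.tail = FALSE))
  }
  list(r = r, p = p)
}

# Assemble a coab_network by hand for enumeration tests.
manual_network <- function(nodes, edges) {
  phy <- setNames(nodes$phylum, nodes$family)
  edges <- edges |>
    dplyr::mutate(intra_phylum = unname(phy[family_u] == phy[family_v]))
  structure(list(nodes = nodes, edges = edges,
                 thresholds = list(r_min = 0.3, p_max = 1e-10,
                                   min_prevalence = 0),
                 n_samples = NA_integer_, untestable = character(0)),
            class = "coab_network")
}
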