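test_that("pearson_edge matches hand-derived values and flags degenerate input", {
  perfect <- pearson_edge(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$r, 1)
  expect_equal(perfect$p, 0)
  expect_equal(pearson_edge(c(1, 2, 3), c(3, 2, 1))$r, -1)

  e <- pearson_edge(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(e$r, 0.8, tolerance = 1e-12)
  t_stat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(t_stat, 1.8856, tolerance = 1e-4)
  expect_equal(e$p, 2 * pt(t_stat, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(pearson_edge(1:4, 1:3), "length mismatch")
  expect_error(pearson_edge(1:2, 2:1), "at least 3")
  flat <- pearson_edge(rep(1, 5), 1:5)
  expect_true(flat$untestable)
  expect_true(is.na(flat$r))
})

test_that("pearson_edge agrees with brute force and cor.test on fuzzed pairs", {
  for (seed in 1:100) {
    n <- withr::with_seed(seed, sample(5:200, 1))
    xy <- withr::with_seed(seed + 1000, matrix(rnorm(2 * n), ncol = 2))
    e <- pearson_edge(xy[, 1], xy[, 2])
    o <- oracle_pearson(xy[, 1], xy[, 2])
    expect_equal(e$r, o$r, tolerance = 1e-12)
    expect_equal(e$p, o$p, tolerance = 1e-10)
    if (seed <= 10) {
      ct <- cor.test(xy[, 1], xy[, 2])
      expect_equal(e$r, unname(ct$estimate), tolerance = 1e-12)
      expect_equal(e$p, ct$p.value, tolerance = 1e-10)
    }
  }
})

test_that("r is invariant under positive affine rescaling of either input", {
  for (seed in 1:10) {
    xy <- withr::with_seed(seed, matrix(rnorm(40), ncol = 2))
    r0 <- pearson_edge(xy[, 1], xy[, 2])$r
    r1 <- pearson_edge(3.7 * xy[, 1] + 2, xy[, 2])$r
    r2 <- pearson_edge(xy[, 1], 0.01 * xy[, 2] - 5)$r
    expect_lt(abs(r1 - r0), 1e-12)
    expect_lt(abs(r2 - r0), 1e-12)
  }
})

test_that("build_network applies strict thresholds and prevalence filtering", {
  # a planted latent factor drives two families; a third is independent
  n <- 2000
  tbl <- withr::with_seed(5, {
    z <- rnorm(n)
    a <- exp(0.9 * z + sqrt(1 - 0.81) * rnorm(n))
    b <- exp(0.9 * z + sqrt(1 - 0.81) * rnorm(n))
    c_ <- exp(rnorm(n))
    base <- exp(rnorm(n)) + 2
    tidyr::expand_grid(
      fam = c("FamA", "FamB", "FamC", "FamD"),
      sample_id = sprintf("s%04d", 1:n)) |>
      dplyr::mutate(
        kingdom = "Bacteria",
        phylum = c(FamA = "P1", FamB = "P1", FamC = "P2", FamD = "P2")[fam],
        class = "unclassified", order = "unclassified",
        family = fam, genus = "unclassified",
        taxon_id = fam,
        lineage = paste("Bacteria", phylum, family, sep = ";"),
        study_id = "s", condition = "other",
        count = dplyr::case_when(
          fam == "FamA" ~ a[match(sample_id, sprintf("s%04d", 1:n))],
          fam == "FamB" ~ b[match(sample_id, sprintf("s%04d", 1:n))],
          fam == "FamC" ~ c_[match(sample_id, sprintf("s%04d", 1:n))],
          TRUE ~ base[match(sample_id, sprintf("s%04d", 1:n))])) |>
      dplyr::select(taxon_id, kingdom, phylum, class, order, family, genus,
                    lineage, sample_id, study_id, condition, count)
  })
  rel <- to_relative(tbl)
  net <- build_network(rel)
  expect_true(any(net$edges$family_u == "FamA" &
                    net$edges$family_v == "FamB"))
  expect_false(any(net$edges$family_u == "FamC" |
                     net$edges$family_v == "FamC"))
  # boundary: r exactly at r_min is excluded
  e_ab <- net$edges[net$edges$family_u == "FamA", ]
  net_strict <- build_network(rel, r_min = e_ab$r[1])
  expect_false(any(net_strict$edges$family_u == "FamA" &
                     net_strict$edges$family_v == "FamB"))
  expect_error(build_network(rel, min_prevalence = n + 1), "eligible")
})

test_that("build_network is invariant to sample and taxon order", {
  ds <- generate_dataset(synthetic_spec(seed = 21, samples_per_study = 120))
  rel <- to_relative(ds$table)
  net1 <- build_network(rel, min_prevalence = 5)
  shuffled <- withr::with_seed(1, rel[sample(nrow(rel)), ])
  net2 <- build_network(shuffled, min_prevalence = 5)
  expect_equal(net2$edges, net1$edges)
  expect_equal(net2$nodes, net1$nodes)
})

test_that("intra-phylum fraction equals enumeration on a hand-built graph", {
  nodes <- tibble::tibble(family = c("A1", "A2", "B1"),
                          phylum = c("P", "P", "Q"),
                          mean_abundance = 0.3, prevalence = 10L)
  edges <- tibble::tibble(family_u = c("A1", "A1"),
                          family_v = c("A2", "B1"),
                          r = 0.5, p = 1e-12, n = 20L)
  net <- manual_network(nodes, edges)
  expect_equal(intra_phylum_fraction(net), 0.5)
  # all same phylum -> 1
  nodes2 <- dplyr::mutate(nodes, phylum = "P")
  expect_equal(intra_phylum_fraction(manual_network(nodes2, edges)), 1.0)
  # empty edge set is an error
  empty <- manual_network(nodes, edges[0, ])
  expect_error(intra_phylum_fraction(empty), "undefined")
  # fuzzed networks vs brute-force scan
  for (seed in 1:10) {
    nn <- withr::with_seed(seed, {
      tibble::tibble(family = sprintf("F%02d", 1:12),
                     phylum = sample(c("P", "Q", "R"), 12, replace = TRUE),
                     mean_abundance = 0.1, prevalence = 10L)
    })
    pairs <- t(combn(nn$family, 2))
    pick <- withr::with_seed(seed + 50, sample(nrow(pairs), 15))
    ee <- tibble::tibble(family_u = pairs[pick, 1],
                         family_v = pairs[pick, 2],
                         r = 0.5, p = 0, n = 30L)
    netf <- manual_network(nn, ee)
    phy <- setNames(nn$phylum, nn$family)
    brute <- mean(phy[ee$family_u] == phy[ee$family_v])
    expect_equal(intra_phylum_fraction(netf), brute)
  }
})

test_that("random null matches pair enumeration and converges", {
  nodes <- tibble::tibble(family = sprintf("F%d", 1:5),
                          phylum = c("P", "P", "P", "Q", "Q"))
  # phylum sizes {3,2}: 4 intra pairs of 10 -> 0.4
  nul <- random_null(nodes, n_edges = 4, n_reps = 10000, seed = 7)
  expect_equal(nul$expected_fraction_analytic, 0.4)
  expect_lt(abs(mean(nul$null_fractions) - 0.4), 0.01)
  # single phylum -> expectation 1 regardless of edge count
  one <- dplyr::mutate(nodes, phylum = "P")
  expect_equal(random_null(one, n_edges = 3, n_reps = 10,
                           seed = 1)$expected_fraction_analytic, 1.0)
  expect_error(random_null(nodes, n_edges = 11, n_reps = 5, seed = 1),
               "exceeds")
  # reproducibility under a fixed seed
  again <- random_null(nodes, n_edges = 4, n_reps = 100, seed = 7)
  expect_equal(again$null_fractions, nul$null_fractions[1:100])
})

test_that("subnetwork extraction applies the abundant-and-changed rule", {
  nodes <- tibble::tibble(family = c("F1", "F2", "F3"),
                          phylum = "P", mean_abundance = 0.3,
                          prevalence = 10L)
  edges <- tibble::tibble(family_u = c("F1", "F2"),
                          family_v = c("F2", "F3"),
                          r = 0.6, p = 1e-15, n = 50L)
  net <- manual_network(nodes, edges)
  diff <- tibble::tibble(
    taxon = c("F1", "F2", "F3"), rank = "family", phylum = "P",
    condition_a = "CD", condition_b = "healthy",
    mean_a = c(0.4, 0.2, 0.2), mean_b = c(0.2, 0.2, 0.2),
    fold = c(2, 1, 1),
    direction = c("increased_in_a", "unchanged", "unchanged"))
  sub <- extract_condition_subnetwork(net, diff, abundant = "F1")
  expect_equal(nrow(sub$edges), 1)
  expect_equal(sub$edges$family_u, "F1")
  expect_setequal(sub$nodes$family, c("F1", "F2"))
  expect_equal(sub$nodes$direction[sub$nodes$family == "F1"],
               "increased_in_a")
  expect_equal(sub$nodes$healthy_abundance[sub$nodes$family == "F1"], 0.2)

  # nothing beyond the fold threshold -> empty subnetwork
  flat <- dplyr::mutate(diff, fold = 1, direction = "unchanged")
  sub0 <- extract_condition_subnetwork(net, flat, abundant = c("F1", "F2"))
  expect_equal(nrow(sub0$edges), 0)

  # unmatched labels are reported
  expect_error(extract_condition_subnetwork(net, diff[-2, ], abundant = "F1"),
               "F2")
})

test_that("subnetwork edges are a subset of the network and match a brute-force filter", {
  ds <- generate_ibd_cohort(seed = 3, n_per_condition = 150)
  rel <- to_relative(ds$table)
  net <- build_network(rel)
  diff <- differential_table(rel, "CD", "healthy")
  ab <- list(top_abundant_families(rel, "CD", k = 15),
             top_abundant_families(rel, "healthy", k = 15))
  sub <- extract_condition_subnetwork(net, diff, ab)
  key <- function(e) paste(e$family_u, e$family_v)
  expect_true(all(key(sub$edges) %in% key(net$edges)))
  # independent filter over the full edge list
  ab_set <- unique(c(ab[[1]]$family, ab[[2]]$family))
  ch_set <- diff$taxon[diff$fold > 1.5]
  brute <- net$edges[
    (net$edges$family_u %in% ab_set | net$edges$family_v %in% ab_set) &
      (net$edges$family_u %in% ch_set | net$edges$family_v %in% ch_set), ]
  expect_equal(key(sub$edges), key(brute))
  # annotations never alter topology
  expect_equal(sub$edges$r, brute$r)
})

test_that("network exports, tidiers and autoplot work end to end", {
  ds <- generate_ibd_cohort(seed = 2, n_per_condition = 60)
  rel <- to_relative(ds$table)
  net <- build_network(rel)
  expect_s3_class(tidy(net), "tbl_df")
  g <- glance(net)
  expect_equal(g$n_nodes, nrow(net$nodes))
  expect_s3_class(autoplot(net), "ggplot")
  expect_s3_class(autoplot(random_null(net, n_reps = 50, seed = 1)),
                  "ggplot")

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_edge_tsv(net, tsv, header = "# test header")
  first <- readLines(tsv, n = 1)
  expect_match(first, "^# test header")
  back <- readr::read_tsv(tsv, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(back), nrow(net$edges))
  expect_true(all(c("phylum_u", "phylum_v", "intra_phylum") %in% names(back)))

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml, header = "hdr")
  gr <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(gr), nrow(net$nodes))
  expect_equal(igraph::gsize(gr), nrow(net$edges))
  expect_true(any(grepl("<!--", readLines(gml))))
})
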