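#' Assemble and validate a pipeline configuration
#'
#' Either reads a YAML file or takes a named list. Recognised fields:
#' `abundance_path`, `metadata_path`, `dialect` (input mode) OR `simulate`
#' (list with `seed`, `n_per_condition`); plus `rank`, `r_min`, `p_max`,
#' `min_prevalence`, `fold_threshold`, `top_k`, `null_reps`, `seed`,
#' `out_dir`, `conditions` (the two disease conditions contrasted against
#' `healthy_label`). Unset fields take the defaults below.
#'
#' @param config A named list or a path to a YAML file.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    abundance_path = NULL, metadata_path = NULL, dialect = "prefix",
    simulate = NULL, rank = "family", r_min = 0.3, p_max = 1e-10,
    min_prevalence = 10, fold_threshold = 1.5, top_k = 15,
    null_reps = 1000, seed = 1, out_dir = ".",
    conditions = c("CD", "UC"), healthy_label = "healthy")
  cfg <- utils::modifyList(defaults, config)
  if (cfg$r_min < -1 || cfg$r_min > 1) stop("r_min must lie in [-1, 1]",
                                            call. = FALSE)
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max must lie in (0, 1]",
                                            call. = FALSE)
  if (cfg$fold_threshold < 1) stop("fold_threshold must be >= 1",
                                   call. = FALSE)
  if (cfg$top_k < 1 || cfg$min_prevalence < 0 || cfg$null_reps < 1) {
    stop("top_k, min_prevalence and null_reps must be positive",
         call. = FALSE)
  }
  if (is.null(cfg$simulate) && is.null(cfg$abundance_path)) {
    stop("config needs either abundance_path or simulate", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[coabnet] %-12s %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full co-abundance analysis pipeline
#'
#' Sequences the stages end to end: load (or simulate) the abundance table,
#' aggregate to family rank, normalise, per-sample diversity, differential
#' tables for each disease condition vs healthy, the global co-abundance
#' network, the random null, per-condition subnetworks, and a plain-text
#' summary. Every output file carries a header with the tool version, a
#' config hash, and the seed. On any stage failure the partially written
#' outputs are removed and the error names the stage.
#'
#' @param config A [pipeline_config()], a named list, or a YAML path.
#' @return Named character vector of the written file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    pipeline_config(config)
  hdr <- output_header(seed = cfg$seed, config = unclass(cfg))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  written <- character(0)
  note <- function(path) { written <<- c(written, path); path }

  run <- function() {
    dataset <- stage("load", {
      if (!is.null(cfg$simulate)) {
        generate_ibd_cohort(
          seed = cfg$simulate$seed %||% cfg$seed,
          n_per_condition = cfg$simulate$n_per_condition %||% 200)
      } else {
        list(table = parse_abundance_table(cfg$abundance_path,
                                           dialect = cfg$dialect,
                                           metadata = cfg$metadata_path),
             truth = NULL)
      }
    })
    tbl <- dataset$table
    fam <- stage("aggregate", aggregate_to_rank(tbl, cfg$rank))
    rel <- stage("normalise", to_relative(fam))

    stage("diversity", {
      div <- diversity_summary(tbl)
      writeLines(hdr, note(out("diversity.tsv")))
      readr::write_tsv(div, out("diversity.tsv"), append = TRUE,
                       col_names = TRUE, progress = FALSE)
    })

    diffs <- stage("diffabund", {
      purrr::map(setNames(cfg$conditions, cfg$conditions), function(cond) {
        d <- differential_table(rel, cond, cfg$healthy_label,
                                rank = cfg$rank,
                                fold_threshold = cfg$fold_threshold)
        path <- note(out(sprintf("diffabund_%s_vs_%s.tsv", cond,
                                 cfg$healthy_label)))
        writeLines(hdr, path)
        readr::write_tsv(d, path, append = TRUE, col_names = TRUE,
                         progress = FALSE)
        d
      })
    })

    net <- stage("network", build_network(
      rel, r_min = cfg$r_min, p_max = cfg$p_max,
      min_prevalence = cfg$min_prevalence))
    stage("network-out", {
      write_edge_tsv(net, note(out("network_edges.tsv")), header = hdr)
      write_graphml(net, note(out("network.graphml")), header = hdr)
    })

    null <- stage("null", random_null(net, n_reps = cfg$null_reps,
                                      seed = cfg$seed))
    stage("null-out", {
      path <- note(out("null_summary.tsv"))
      writeLines(hdr, path)
      readr::write_tsv(glance(null), path, append = TRUE, col_names = TRUE,
                       progress = FALSE)
    })

    stage("subnetwork", {
      for (cond in cfg$conditions) {
        abund <- list(top_abundant_families(rel, cond, k = cfg$top_k),
                      top_abundant_families(rel, cfg$healthy_label,
                                            k = cfg$top_k))
        sub <- extract_condition_subnetwork(
          net, diffs[[cond]], abund, fold_threshold = cfg$fold_threshold)
        write_graphml(sub, note(out(sprintf("subnetwork_%s.graphml", cond))),
                      header = hdr)
      }
    })

    stage("summary", {
      phylum_counts <- net$nodes |>
        dplyr::count(.data$phylum, name = "n_families") |>
        dplyr::arrange(dplyr::desc(.data$n_families))
      lines <- c(
        hdr,
        sprintf("families (nodes): %d", nrow(net$nodes)),
        sprintf("edges: %d", nrow(net$edges)),
        sprintf("observed intra-phylum fraction: %s",
                if (nrow(net$edges) > 0)
                  format(intra_phylum_fraction(net), digits = 4) else "NA"),
        sprintf("expected intra-phylum fraction (random): %s",
                format(null$expected_fraction_analytic, digits = 4)),
        "families per phylum:",
        sprintf("  %s: %d", phylum_counts$phylum,
                phylum_counts$n_families))
      writeLines(lines, note(out("summary.txt")))
    })
    invisible(setNames(written, basename(written)))
  }

  tryCatch(run(), error = function(e) {
    unlink(written)
    stop(conditionMessage(e), call. = FALSE)
  })
}
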