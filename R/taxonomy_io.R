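#' Parse taxonomy lineage strings
#'
#' Splits lineage annotations into the six ranks kingdom..genus. Three
#' dialects are understood:
#' \describe{
#'   \item{prefix}{Greengenes-style `k__Bacteria;p__Firmicutes;...` with
#'     single-letter rank prefixes; order of fields is irrelevant.}
#'   \item{silva}{positional `Bacteria;Firmicutes;Clostridia;...`, read as
#'     kingdom, phylum, class, order, family, genus in that order.}
#'   \item{plain}{ranks already split into separate fields; here `x` is
#'     interpreted positionally like `silva`.}
#' }
#' Empty or missing ranks become the sentinel `"unclassified"`.
#'
#' @param x Character vector of lineage strings.
#' @param dialect One of `"prefix"`, `"silva"`, `"plain"`.
#' @return A tibble with columns kingdom, phylum, class, order, family,
#'   genus and the original string as `lineage`.
#' @export
parse_lineage <- function(x, dialect = c("prefix", "silva", "plain")) {
  dialect <- match.arg(dialect)
  parts <- stringr::str_split(x, ";")
  prefix_map <- c(k = "kingdom", p = "phylum", c = "class",
                  o = "order", f = "family", g = "genus")
  rows <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    out <- setNames(rep(UNCLASSIFIED, 6), RANKS)
    if (dialect == "prefix") {
      pref <- stringr::str_match(p, "^([kpcofg])__(.*)$")
      for (i in seq_along(p)) {
        if (!is.na(pref[i, 1])) {
          rank <- prefix_map[[pref[i, 2]]]
          if (nzchar(pref[i, 3])) out[[rank]] <- pref[i, 3]
        } else if (nzchar(p[i]) && i <= 6) {
          # tolerate bare labels (e.g. a lone kingdom) positionally
          if (out[[RANKS[i]]] == UNCLASSIFIED) out[[RANKS[i]]] <- p[i]
        }
      }
    } else {
      keep <- seq_len(min(length(p), 6))
      filled <- p[keep]
      filled[!nzchar(filled)] <- UNCLASSIFIED
      out[RANKS[keep]] <- filled
    }
    out
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$lineage <- as.character(x)
  out
}

format_lineage <- function(tbl, dialect) {
  if (dialect == "prefix") {
    pref <- c("k__", "p__", "c__", "o__", "f__", "g__")
    vals <- purrr::map2(pref, RANKS, function(p, r) {
      v <- tbl[[r]]
      paste0(p, ifelse(v == UNCLASSIFIED, "", v))
    })
    do.call(paste, c(vals, sep = ";"))
  } else {
    do.call(paste, c(unname(as.list(tbl[RANKS])), sep = ";"))
  }
}

#' Read a lineage-annotated abundance table
#'
#' Reads a TSV whose header row carries sample ids, whose first column is the
#' taxon id, and whose taxonomy occupies either a single lineage column
#' (dialects `prefix` and `silva`) or six already-split rank columns
#' (dialect `plain`; a BIOM-TSV `#OTU ID` first header is accepted).
#' Remaining columns are per-sample counts. The result is the package's
#' universal currency: a long tibble with one row per taxon x sample carrying
#' the parsed ranks, raw lineage, sample metadata and count.
#'
#' @param path Path to the abundance TSV.
#' @param dialect Lineage dialect, see [parse_lineage()].
#' @param metadata Optional sample metadata: a path to a TSV with columns
#'   sample_id, study_id, condition, or a data frame with those columns.
#'   Samples without metadata get `study_id = "unknown"`,
#'   `condition = "other"`.
#' @return A long abundance tibble with columns `taxon_id`, the six ranks,
#'   `lineage`, `sample_id`, `study_id`, `condition`, `count`.
#' @export
parse_abundance_table <- function(path, dialect = c("prefix", "silva", "plain"),
                                  metadata = NULL) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, comment = "#",
                         name_repair = "minimal")
  if (dialect == "plain") {
    n_tax_cols <- 7L
    if (ncol(raw) < n_tax_cols + 1) {
      stop("plain-dialect table needs taxon id, six rank columns and at least one sample",
           call. = FALSE)
    }
    tax <- raw[, 2:7]
    names(tax) <- RANKS
    for (r in RANKS) {
      tax[[r]][is.na(tax[[r]]) | !nzchar(tax[[r]])] <- UNCLASSIFIED
    }
    tax$lineage <- format_lineage(tax, "silva")
    sample_cols <- names(raw)[-(1:7)]
  } else {
    if (ncol(raw) < 3) {
      stop("abundance table needs taxon id, lineage and at least one sample column",
           call. = FALSE)
    }
    tax <- parse_lineage(dplyr::coalesce(raw[[2]], ""), dialect)
    sample_cols <- names(raw)[-(1:2)]
  }
  if (anyDuplicated(sample_cols) > 0) {
    stop("duplicate sample id in header: ",
         sample_cols[duplicated(sample_cols)][1], call. = FALSE)
  }
  taxon_id <- raw[[1]]
  if (anyDuplicated(taxon_id) > 0) {
    stop("duplicate taxon id: ", taxon_id[duplicated(taxon_id)][1],
         call. = FALSE)
  }
  counts <- raw[, sample_cols, drop = FALSE]
  for (j in seq_along(sample_cols)) {
    v <- suppressWarnings(as.numeric(counts[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("malformed count at line ", bad[1] + 1L, ", sample ",
           sample_cols[j], call. = FALSE)
    }
    if (any(v < 0)) {
      stop("negative count at line ", which(v < 0)[1] + 1L, ", sample ",
           sample_cols[j], call. = FALSE)
    }
    counts[[j]] <- v
  }
  wide <- dplyr::bind_cols(tibble::tibble(taxon_id = taxon_id), tax, counts)
  long <- tidyr::pivot_longer(wide, dplyr::all_of(sample_cols),
                              names_to = "sample_id", values_to = "count")

  meta <- normalise_metadata(metadata, unique(long$sample_id))
  long <- dplyr::left_join(long, meta, by = "sample_id") |>
    dplyr::select(dplyr::all_of(abund_cols()))
  validate_abund(long)
  long
}

normalise_metadata <- function(metadata, sample_ids) {
  if (is.null(metadata)) {
    return(tibble::tibble(sample_id = sample_ids, study_id = "unknown",
                          condition = "other"))
  }
  meta <- if (is.character(metadata)) read_sample_metadata(metadata) else
    tibble::as_tibble(metadata)
  need <- c("sample_id", "study_id", "condition")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns sample_id, study_id, condition",
         call. = FALSE)
  }
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing) > 0) {
    meta <- dplyr::bind_rows(meta, tibble::tibble(
      sample_id = missing, study_id = "unknown", condition = "other"))
  }
  dplyr::distinct(meta[meta$sample_id %in% sample_ids, need])
}

#' Read a sample metadata TSV (sample_id, study_id, condition)
#' @param path Path to the TSV.
#' @return A tibble with the three metadata columns.
#' @export
read_sample_metadata <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE, comment = "#")
}

#' Write an abundance table (and optional metadata) back to TSV
#'
#' Inverse of [parse_abundance_table()]: the written file re-read with the
#' same dialect reproduces the table field by field.
#'
#' @param x Long abundance tibble.
#' @param path Output TSV path.
#' @param dialect Lineage dialect to emit.
#' @param metadata_path Optional path for the sample metadata TSV.
#' @param header Optional comment line written before the table.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path,
                                  dialect = c("prefix", "silva", "plain"),
                                  metadata_path = NULL, header = NULL) {
  dialect <- match.arg(dialect)
  validate_abund(x)
  if (dialect == "plain") {
    wide <- x |>
      dplyr::select(dplyr::all_of(c("taxon_id", RANKS, "sample_id", "count"))) |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                         values_fill = 0)
  } else {
    lin <- if (dialect == "prefix") format_lineage(x, "prefix") else
      format_lineage(x, "silva")
    wide <- x |>
      dplyr::mutate(lineage = lin) |>
      dplyr::select(dplyr::all_of(c("taxon_id", "lineage", "sample_id", "count"))) |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                         values_fill = 0)
  }
  if (!is.null(header)) {
    writeLines(header, path)
    readr::write_tsv(wide, path, append = TRUE, col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_tsv(wide, path, progress = FALSE)
  }
  if (!is.null(metadata_path)) {
    meta <- dplyr::distinct(x, .data$sample_id, .data$study_id, .data$condition)
    readr::write_tsv(meta, metadata_path, progress = FALSE)
  }
  invisible(path)
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums counts over all taxa sharing the same label at the chosen rank
#' (including the `"unclassified"` pool). Per-sample totals are conserved.
#' Ranks above the target keep the dominant (highest total count, ties
#' lexicographic) lineage among the members; ranks below become
#' `"unclassified"`.
#'
#' @param x Long abundance tibble.
#' @param rank One of `"phylum"`, `"class"`, `"family"`.
#' @return A long abundance tibble whose `taxon_id` is the rank label.
#' @export
aggregate_to_rank <- function(x, rank = c("family", "class", "phylum")) {
  rank <- match.arg(rank)
  validate_abund(x)
  has_rel <- "rel_abund" %in% names(x)
  above <- RANKS[seq_len(match(rank, RANKS) - 1)]
  agg <- x |>
    dplyr::group_by(.data[[rank]], .data$sample_id, .data$study_id,
                    .data$condition) |>
    dplyr::summarise(
      count = sum(.data$count),
      dplyr::across(dplyr::any_of("rel_abund"), sum),
      .groups = "drop")
  # dominant parent lineage per label
  parents <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(rank, above)))) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(c(rank, above)))) |>
    dplyr::group_by(.data[[rank]]) |>
    dplyr::slice_max(.data$total, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-"total")
  out <- agg |>
    dplyr::left_join(parents, by = rank) |>
    dplyr::mutate(taxon_id = .data[[rank]])
  below <- setdiff(RANKS, c(above, rank))
  for (r in below) out[[r]] <- UNCLASSIFIED
  out$lineage <- format_lineage(out, "silva")
  out <- dplyr::select(out, dplyr::all_of(abund_cols(has_rel))) |>
    dplyr::arrange(.data$taxon_id, .data$sample_id)
  validate_abund(out, relative = has_rel)
  out
}

#' Convert counts to per-sample relative abundance
#'
#' Adds a `rel_abund` column: each count divided by its sample total, so
#' every sample's proportions sum to 1. Errors on zero-total samples.
#'
#' @param x Long abundance tibble.
#' @return The table with a `rel_abund` column.
#' @export
to_relative <- function(x) {
  validate_abund(x)
  out <- x |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(rel_abund = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  validate_abund(out, relative = TRUE)
  out
}

#' Merge abundance tables from several studies
#'
#' Prefixes each sample id with its study id (`study__sample`), takes the
#' union of taxa (label identity at the table's rank), and fills missing
#' taxon x sample entries with zero counts. Per-sample totals are conserved.
#'
#' @param tables A list of long abundance tibbles.
#' @param prefix_samples Prefix sample ids with study ids (default `TRUE`).
#' @return A single merged long abundance tibble.
#' @export
merge_studies <- function(tables, prefix_samples = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 1)
  purrr::walk(tables, validate_abund)
  tables <- purrr::map(tables, function(t) {
    if (prefix_samples) {
      t$sample_id <- paste(t$study_id, t$sample_id, sep = "__")
    }
    t
  })
  ids <- purrr::map(tables, ~ unique(.x$sample_id))
  all_ids <- unlist(ids)
  if (anyDuplicated(all_ids) > 0) {
    stop("colliding sample ids across studies after prefixing: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "),
         call. = FALSE)
  }
  merged <- dplyr::bind_rows(purrr::map(tables, ~ .x[abund_cols()]))
  # taxon identity across studies is the label: reconcile divergent lineage
  # annotations for the same id to the lexicographically first one
  lineage_map <- merged |>
    dplyr::distinct(dplyr::across(dplyr::all_of(c("taxon_id", RANKS, "lineage")))) |>
    dplyr::arrange(.data$taxon_id, .data$lineage) |>
    dplyr::distinct(.data$taxon_id, .keep_all = TRUE)
  merged <- merged |>
    dplyr::select(-dplyr::all_of(c(RANKS, "lineage"))) |>
    dplyr::left_join(lineage_map, by = "taxon_id") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c("taxon_id", RANKS, "lineage"))),
      tidyr::nesting(!!!rlang::syms(c("sample_id", "study_id", "condition"))),
      fill = list(count = 0)) |>
    dplyr::select(dplyr::all_of(abund_cols())) |>
    dplyr::arrange(.data$taxon_id, .data$sample_id)
  validate_abund(merged)
  merged
}
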