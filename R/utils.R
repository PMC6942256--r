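#' @keywords internal
RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' @keywords internal
UNCLASSIFIED <- "unclassified"

abund_cols <- function(relative = FALSE) {
  c("taxon_id", RANKS, "lineage", "sample_id", "study_id", "condition",
    "count", if (relative) "rel_abund")
}

#' Validate a long abundance tibble
#'
#' Checks the invariants of the package's universal data structure: one row
#' per taxon x sample, non-negative counts, no duplicated taxon within a
#' sample, consistent per-sample metadata, and strictly positive per-sample
#' totals. Called internally by every operation; exported so scripts can
#' validate tables they assemble by hand.
#'
#' @param x A long abundance tibble (see [parse_abundance_table()]).
#' @param relative If `TRUE`, additionally require a `rel_abund` column whose
#'   per-sample sums are 1 within 1e-9 and whose values lie in `[0, 1]`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_abund <- function(x, relative = FALSE) {
  need <- abund_cols(relative)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("abundance table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) stop("abundance table is empty", call. = FALSE)
  if (any(!is.finite(x$count)) || any(x$count < 0)) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  dup <- x |>
    dplyr::count(.data$taxon_id, .data$sample_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicated taxon x sample rows, e.g. ", dup$taxon_id[1], " in ",
         dup$sample_id[1], call. = FALSE)
  }
  meta <- x |> dplyr::distinct(.data$sample_id, .data$study_id, .data$condition)
  if (anyDuplicated(meta$sample_id) > 0) {
    stop("sample_id maps to more than one (study_id, condition) pair",
         call. = FALSE)
  }
  totals <- x |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  if (any(totals$total <= 0)) {
    bad <- totals$sample_id[totals$total <= 0]
    stop("samples with zero total count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (relative) {
    if (any(x$rel_abund < 0 | x$rel_abund > 1)) {
      stop("rel_abund values must lie in [0, 1]", call. = FALSE)
    }
    sums <- x |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(s = sum(.data$rel_abund), .groups = "drop")
    if (any(abs(sums$s - 1) > 1e-9)) {
      stop("per-sample relative abundances do not sum to 1", call. = FALSE)
    }
  }
  invisible(x)
}

# 32-bit FNV-1a over a character scalar; used to stamp output files with a
# short fingerprint of the configuration. Arithmetic kept exact in doubles by
# splitting the 32-bit state before multiplying.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 2^32
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}

output_header <- function(seed = NA, config = NULL) {
  paste0("# coabnet ", as.character(packageVersion("coabnet")),
         "; seed=", seed,
         "; config_hash=", if (is.null(config)) "none" else config_hash(config))
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
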