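#' Read and write expression tables
#'
#' The canonical on-disk format is TSV (UTF-8): a header row of sample ids,
#' first column `gene_id`, numeric non-negative body. Files ending in `.gz`
#' are read/written compressed transparently. Batch labels travel in a
#' separate two-column label TSV (see [read_labels_tsv()]) or are supplied
#' directly.
#'
#' @param path File path (plain or `.gz`).
#' @param unit Abundance unit tag, `"TPM-like"` or `"counts"`.
#' @param batch Named character vector `sample_id -> batch`, or single label.
#' @return [read_expression_tsv()] returns an [expr_tbl()];
#'   [write_expression_tsv()] returns `path` invisibly.
#' @export
read_expression_tsv <- function(path, unit = c("TPM-like", "counts"),
                                batch = "batch1") {
  unit <- match.arg(unit)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  samples <- names(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- which(is.na(vals) | !is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "invalid expression value in '%s' at row %d (gene '%s'), column '%s'",
      path, bad[1L, 1L], raw[[1L]][bad[1L, 1L]], samples[bad[1L, 2L]]
    ))
  }
  expr_tbl(raw, batch = batch, unit = unit)
}

#' @rdname read_expression_tsv
#' @param x An `expr_tbl`.
#' @export
write_expression_tsv <- function(x, path) {
  validate_expr_tbl(x)
  readr::write_tsv(as_tibble(unclass_expr(x)), path, progress = FALSE)
  invisible(path)
}

unclass_expr <- function(x) {
  attr(x, "batch") <- NULL
  attr(x, "unit") <- NULL
  class(x) <- class(tibble())
  x
}

#' Read and write sample label tables
#'
#' Two-column TSV `sample_id`, `label`; used both for cohort/batch membership
#' and for subtype labels.
#'
#' @param path File path.
#' @return A tibble with columns `sample_id`, `label` (both character).
#' @export
read_labels_tsv <- function(path) {
  out <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  names(out)[1:2] <- c("sample_id", "label")
  if (anyDuplicated(out$sample_id)) abort("duplicated sample ids in label file")
  out
}

#' @rdname read_labels_tsv
#' @param labels Tibble with columns `sample_id`, `label`.
#' @export
write_labels_tsv <- function(labels, path) {
  readr::write_tsv(labels[, c("sample_id", "label")], path, progress = FALSE)
  invisible(path)
}

#' Read a directed DEG list
#'
#' TSV with columns `gene_id`, `direction` (+1 / -1), optional `fdr`.
#'
#' @param path File path.
#' @param universe_size Number of background genes commonly measured in the
#'   dataset the list was called from; stored as attribute `universe_size`.
#' @return Tibble with columns `gene_id`, `direction`, and `fdr` if present.
#' @export
read_deg_tsv <- function(path, universe_size = NULL) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  validate_deg_list(out, universe_size = universe_size)
}

#' @rdname read_deg_tsv
#' @param deg A DEG tibble.
#' @export
write_deg_tsv <- function(deg, path) {
  readr::write_tsv(deg, path, progress = FALSE)
  invisible(path)
}

validate_deg_list <- function(deg, universe_size = NULL) {
  deg <- as_tibble(deg)
  if (!all(c("gene_id", "direction") %in% names(deg))) {
    abort("DEG list needs columns gene_id and direction")
  }
  if (!all(deg$direction %in% c(-1, 1))) abort("directions must be +1 or -1")
  if (anyDuplicated(deg$gene_id)) abort("duplicated gene ids in DEG list")
  us <- universe_size %||% attr(deg, "universe_size")
  if (!is.null(us)) {
    if (us < nrow(deg)) abort("universe_size smaller than the DEG list")
    attr(deg, "universe_size") <- as.integer(us)
  }
  deg
}

BIOMARKER_SCHEMA_VERSION <- 1L

#' Serialize a classifier ensemble
#'
#' A versioned JSON schema listing, per subtype, the ordered
#' (`gene_hi`, `gene_lo`) pairs of its biomarker, plus the order in which
#' the biomarkers are applied at classification time. Round trips are
#' lossless.
#'
#' @param ensemble A [reo_ensemble()].
#' @param path Output file path.
#' @return `path` invisibly; [read_biomarker()] returns a `reo_ensemble`.
#' @export
write_biomarker <- function(ensemble, path) {
  ensemble <- validate_reo_ensemble(ensemble)
  payload <- list(
    schema_version = BIOMARKER_SCHEMA_VERSION,
    application_order = ensemble$application_order,
    biomarkers = lapply(ensemble$biomarkers, function(b) {
      list(subtype = b$subtype,
           pairs = as.data.frame(b$pairs[, c("gene_hi", "gene_lo")]))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_biomarker
#' @export
read_biomarker <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  ver <- payload$schema_version
  if (is.null(ver) || ver != BIOMARKER_SCHEMA_VERSION) {
    abort(sprintf("unknown biomarker schema version: %s",
                  ver %||% "<missing>"))
  }
  bms <- lapply(payload$biomarkers, function(b) {
    reo_biomarker(as_tibble(b$pairs), subtype = b$subtype)
  })
  reo_ensemble(bms, application_order = payload$application_order)
}
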