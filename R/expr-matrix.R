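#' Expression tables
#'
#' An `expr_tbl` is the package's carrier for a non-negative gene-by-sample
#' abundance matrix: a wide tibble whose first column is `gene_id` and whose
#' remaining columns are samples, with two attributes riding along —
#' `unit` (`"TPM-like"` or `"counts"`) and `batch`, a named character vector
#' mapping every sample id to its cohort/batch label.
#'
#' Invariants enforced by [expr_tbl()] / [validate_expr_tbl()]:
#' no duplicated gene or sample ids, all values finite and `>= 0`, and a
#' batch label for every sample.
#'
#' @param x A data frame whose first column holds gene ids (character) and
#'   whose remaining columns are numeric sample columns, or a numeric matrix
#'   with rownames (genes) and colnames (samples).
#' @param batch Named character vector `sample_id -> batch label`, or a single
#'   label recycled to all samples.
#' @param unit Abundance unit tag, `"TPM-like"` (default) or `"counts"`.
#' @return A tibble of subclass `expr_tbl`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' x <- expr_tbl(m, batch = "cohortA")
#' expr_values(x)
#' @export
expr_tbl <- function(x, batch = "batch1", unit = c("TPM-like", "counts")) {
  unit <- match.arg(unit)
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs gene rownames and sample colnames")
    }
    if (anyDuplicated(colnames(x))) abort("duplicated sample ids")
    x <- dplyr::bind_cols(
      tibble(gene_id = rownames(x)),
      as_tibble(x, .name_repair = "minimal")
    )
  }
  x <- as_tibble(x, .name_repair = "minimal")
  if (anyDuplicated(names(x)[-1L])) abort("duplicated sample ids")
  if (ncol(x) < 2L) abort("need a gene_id column plus at least one sample column")
  names(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  samples <- names(x)[-1L]
  if (length(batch) == 1L && is.null(names(batch))) {
    batch <- setNames(rep(as.character(batch), length(samples)), samples)
  }
  out <- structure(x,
    class = c("expr_tbl", class(tibble())),
    unit = unit, batch = batch[samples]
  )
  validate_expr_tbl(out)
}

#' @rdname expr_tbl
#' @export
validate_expr_tbl <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1L] == "gene_id")
  samples <- sample_ids(x)
  if (anyDuplicated(x$gene_id)) {
    abort(paste0("duplicated gene ids: ",
                 paste(unique(x$gene_id[duplicated(x$gene_id)]), collapse = ", ")))
  }
  if (anyDuplicated(samples)) abort("duplicated sample ids")
  vals <- expr_values(x)
  bad <- which(!is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "non-finite or negative value at gene '%s', sample '%s'",
      x$gene_id[bad[1L, 1L]], samples[bad[1L, 2L]]
    ))
  }
  b <- attr(x, "batch")
  if (is.null(b) || !all(samples %in% names(b)) || anyNA(b[samples])) {
    abort("batch label missing for some samples")
  }
  x
}

#' @rdname expr_tbl
#' @export
expr_values <- function(x) {
  m <- as.matrix(x[, -1L, drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric expression values")
  rownames(m) <- x$gene_id
  m
}

#' @rdname expr_tbl
#' @export
sample_ids <- function(x) names(x)[-1L]

#' @rdname expr_tbl
#' @export
gene_ids <- function(x) x$gene_id

#' @rdname expr_tbl
#' @export
sample_batches <- function(x) attr(x, "batch")[sample_ids(x)]

# rebuild an expr_tbl from a matrix, keeping metadata of `template`
new_expr_tbl_like <- function(values, template,
                              batch = NULL, unit = NULL) {
  expr_tbl(values,
    batch = batch %||% attr(template, "batch"),
    unit = unit %||% attr(template, "unit")
  )
}

#' @export
print.expr_tbl <- function(x, ...) {
  cat(sprintf(
    "# expr_tbl: %d genes x %d samples [%s], batches: %s\n",
    nrow(x), ncol(x) - 1L, attr(x, "unit"),
    paste(unique(sample_batches(x)), collapse = ", ")
  ))
  NextMethod()
}
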