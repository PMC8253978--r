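#' Drop lowly expressed genes
#'
#' Keeps genes whose mean abundance across samples is strictly above
#' `threshold` (default 1, the usual TPM floor). Idempotent at a fixed
#' threshold.
#'
#' @param x An [expr_tbl()].
#' @param threshold Mean-abundance cutoff (strict).
#' @return The filtered [expr_tbl()]; samples unchanged.
#' @export
filter_expressed <- function(x, threshold = 1) {
  if (threshold < 0) abort("threshold must be >= 0")
  vals <- expr_values(x)
  keep <- rowMeans(vals) > threshold
  if (!any(keep)) {
    abort(sprintf(
      "no gene has mean abundance > %g; lower the threshold", threshold
    ))
  }
  new_expr_tbl_like(vals[keep, , drop = FALSE], x)
}

#' Gene variability scores
#'
#' Per-gene dispersion across samples. The default, `"mean"`, is the mean of
#' absolute deviations from the gene's mean — the reading of "MAD" this
#' pipeline standardizes on; `"median"` gives the usual median absolute
#' deviation (unscaled) for sensitivity checks. Computed on the natural
#' abundance scale.
#'
#' @param x An [expr_tbl()] with at least 2 samples.
#' @param method `"mean"` (default) or `"median"`.
#' @return Tibble `gene_id`, `score`, in the input gene order.
#' @export
mad_scores <- function(x, method = c("mean", "median")) {
  method <- match.arg(method)
  vals <- expr_values(x)
  if (ncol(vals) < 2L) abort("variability needs >= 2 samples")
  score <- switch(method,
    mean = rowMeans(abs(vals - rowMeans(vals))),
    median = apply(vals, 1L, function(v) stats::median(abs(v - stats::median(v))))
  )
  tibble(gene_id = rownames(vals), score = unname(score))
}

#' Select the most variable genes
#'
#' Ranks genes by descending variability score ([mad_scores()]) and keeps the
#' top `top_n`. Ties are broken lexicographically by `gene_id` so the ranking
#' is deterministic and invariant to sample order.
#'
#' @inheritParams mad_scores
#' @param top_n Number of genes to keep (default 1500).
#' @return Tibble `gene_id`, `score`, sorted by descending score.
#' @export
select_top_mad <- function(x, top_n = 1500L, method = c("mean", "median")) {
  scores <- mad_scores(x, method = method)
  if (top_n > nrow(scores)) abort("top_n exceeds the number of genes")
  dplyr::arrange(scores, dplyr::desc(.data$score), .data$gene_id)[seq_len(top_n), ]
}

#' Intersect per-cohort feature lists
#'
#' Set intersection of two or more gene lists, ordered by the first list.
#'
#' @param ... Gene lists: character vectors or tibbles with a `gene_id`
#'   column (e.g. [select_top_mad()] output).
#' @return Character vector of shared gene ids.
#' @export
intersect_features <- function(...) {
  lists <- lapply(list(...), function(l) {
    if (is.data.frame(l)) l$gene_id else as.character(l)
  })
  if (length(lists) < 2L) abort("need at least two gene lists")
  Reduce(intersect, lists)
}

#' Merge cohorts into one expression table
#'
#' Column-concatenates cohorts restricted to their shared genes (ordered as
#' in the first cohort). With `batch_center = TRUE`, per-gene per-batch means
#' are equalized in log2 space and the result re-exponentiated — a simple
#' centering stand-in for model-based batch correction, provided as plumbing;
#' REO features are unaffected by any per-sample monotone distortion either
#' way.
#'
#' @param cohorts List of [expr_tbl()] objects with disjoint sample ids.
#' @param batch_center Equalize per-gene batch means in log space?
#' @return A merged [expr_tbl()]; batch labels are carried over per cohort.
#' @export
merge_cohorts <- function(cohorts, batch_center = FALSE) {
  stopifnot(length(cohorts) >= 1L)
  shared <- Reduce(intersect, lapply(cohorts, gene_ids))
  if (length(shared) == 0L) abort("cohorts share no genes")
  mats <- lapply(cohorts, function(co) expr_values(co)[shared, , drop = FALSE])
  vals <- do.call(cbind, mats)
  batch <- do.call(c, unname(lapply(cohorts, sample_batches)))
  if (anyDuplicated(colnames(vals))) abort("duplicated sample ids across cohorts")
  if (batch_center && length(unique(batch)) > 1L) {
    pc <- if (min(vals) > 0) 0 else 0.5  # pseudocount only when zeros present
    lv <- log2(vals + pc)
    grand <- rowMeans(lv)
    for (b in unique(batch)) {
      cols <- which(unname(batch[colnames(vals)]) == b)
      lv[, cols] <- lv[, cols] - rowMeans(lv[, cols, drop = FALSE]) + grand
    }
    vals <- pmax(2^lv - pc, 0)
  }
  expr_tbl(vals, batch = batch, unit = attr(cohorts[[1L]], "unit"))
}

#' Stratified train/test split
#'
#' Splits labeled samples into train and test sets, stratified by label so
#' per-subtype proportions are preserved up to integer rounding. Disjoint and
#' exhaustive; deterministic under `seed`.
#'
#' @param labels Tibble with columns `sample_id`, `label`.
#' @param fraction Training fraction in (0, 1) (default 0.7).
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
split_train_test <- function(labels, fraction = 0.7, seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) abort("fraction must be in (0, 1)")
  counts <- table(labels$label)
  if (any(counts < 2L)) {
    abort(sprintf("subtype '%s' has < 2 samples; cannot split",
                  names(counts)[which(counts < 2L)[1L]]))
  }
  withr::with_seed(seed, {
    split <- lapply(split(labels$sample_id, labels$label), function(ids) {
      n <- length(ids)
      n_train <- min(max(round(fraction * n), 1L), n - 1L)
      train <- sample(ids, n_train)
      list(train = train, test = setdiff(ids, train))
    })
    list(
      train = unname(unlist(lapply(split, `[[`, "train"))),
      test = unname(unlist(lapply(split, `[[`, "test")))
    )
  })
}
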