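#' REO biomarkers and classifier ensembles
#'
#' A biomarker is an ordered, duplicate-free set of directed gene pairs
#' (`gene_hi`, `gene_lo`) attached to one subtype; a sample votes *for* the
#' subtype on each pair whose REO is `+1` (`gene_hi` above `gene_lo`), and
#' is called subtype-positive when strictly more than half of the pairs vote
#' for it (an exact half does not fire). An ensemble bundles one biomarker
#' per subtype plus the order in which they are applied at classification
#' time: the first biomarker whose majority fires assigns the label.
#'
#' @param pairs Tibble with columns `gene_hi`, `gene_lo`.
#' @param subtype Subtype label the biomarker detects.
#' @param f_score Optional training F-score to carry along.
#' @return `reo_biomarker()` returns an object of class `reo_biomarker`;
#'   `reo_ensemble()` an object of class `reo_ensemble`.
#' @export
reo_biomarker <- function(pairs, subtype, f_score = NULL) {
  pairs <- as_tibble(pairs)[, c("gene_hi", "gene_lo")]
  if (nrow(pairs) == 0L) abort("a biomarker needs at least one pair")
  if (any(pairs$gene_hi == pairs$gene_lo)) abort("a pair cannot repeat one gene")
  if (anyDuplicated(paste(pairs$gene_hi, pairs$gene_lo))) {
    abort("duplicated pair within a biomarker")
  }
  structure(list(subtype = as.character(subtype), pairs = pairs,
                 f_score = f_score),
            class = "reo_biomarker")
}

#' @rdname reo_biomarker
#' @param biomarkers List of `reo_biomarker` objects (one per subtype).
#' @param application_order Character vector of subtype labels; defaults to
#'   sorted subtype order.
#' @export
reo_ensemble <- function(biomarkers, application_order = NULL) {
  if (length(biomarkers) == 0L) abort("an ensemble needs at least one biomarker")
  subtypes <- vapply(biomarkers, function(b) b$subtype, "")
  names(biomarkers) <- subtypes
  application_order <- as.character(application_order %||% sort(subtypes))
  out <- structure(list(biomarkers = biomarkers,
                        application_order = application_order),
                   class = "reo_ensemble")
  validate_reo_ensemble(out)
}

validate_reo_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "reo_ensemble") || is.list(ensemble))
  subtypes <- names(ensemble$biomarkers)
  if (length(subtypes) == 0L) abort("empty ensemble")
  if (!setequal(ensemble$application_order, subtypes) ||
      length(ensemble$application_order) != length(subtypes)) {
    abort("application_order must be a permutation of the biomarker subtypes")
  }
  for (b in ensemble$biomarkers) {
    reo_biomarker(b$pairs, b$subtype, b$f_score) # re-validate
  }
  ensemble
}

#' @export
print.reo_biomarker <- function(x, ...) {
  cat(sprintf("# REO biomarker for subtype %s: %d pair(s)%s\n",
              x$subtype, nrow(x$pairs),
              if (is.null(x$f_score)) "" else sprintf(" (training F = %.4f)", x$f_score)))
  print(x$pairs, ...)
  invisible(x)
}

#' @export
print.reo_ensemble <- function(x, ...) {
  cat(sprintf("# REO classifier ensemble: %d biomarkers, applied in order %s\n",
              length(x$biomarkers), paste(x$application_order, collapse = " -> ")))
  for (b in x$biomarkers) cat(sprintf("  subtype %s: %d pair(s)\n", b$subtype, nrow(b$pairs)))
  invisible(x)
}

# votes of each pair (rows) in each sample (cols): sign(hi - lo)
reo_vote_matrix <- function(vals, pairs) {
  missing <- setdiff(unique(c(pairs$gene_hi, pairs$gene_lo)), rownames(vals))
  if (length(missing) > 0L) {
    abort(paste0("biomarker gene(s) absent from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  sign(vals[pairs$gene_hi, , drop = FALSE] - vals[pairs$gene_lo, , drop = FALSE])
}

# strict-majority positive call per sample
majority_call <- function(votes) {
  colSums(votes == 1) > nrow(votes) / 2
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)`, or 0 when both
#'   are 0.
#' @export
f_score <- function(precision, recall) {
  ifelse(precision + recall == 0, 0,
         2 * precision * recall / (precision + recall))
}

#' Evaluate a biomarker on labeled samples
#'
#' Calls each sample subtype-positive when strictly more than half of the
#' biomarker's pairs show REO `+1`, then scores the calls with this
#' pipeline's metric conventions: *precision* is the fraction of the
#' subtype's samples correctly identified (a sensitivity), *recall* is the
#' fraction of non-subtype samples correctly rejected (a specificity), and
#' the F-score is their harmonic mean. `standard_metrics = TRUE` instead
#' reports conventional precision `TP/(TP+FP)` and recall `TP/(TP+FN)`.
#'
#' @param x An [expr_tbl()].
#' @param pairs A `reo_biomarker` or a tibble `gene_hi`, `gene_lo`.
#' @param labels Tibble `sample_id`, `label`.
#' @param subtype Label treated as positive.
#' @param standard_metrics Use conventional precision/recall instead.
#' @return One-row tibble: `subtype`, `tp`, `fp`, `tn`, `fn`, `precision`,
#'   `recall`, `f_score`.
#' @export
evaluate_biomarker <- function(x, pairs, labels, subtype,
                               standard_metrics = FALSE) {
  if (inherits(pairs, "reo_biomarker")) pairs <- pairs$pairs
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0L) abort("no pairs to evaluate")
  vals <- expr_values(x)[, labels$sample_id, drop = FALSE]
  calls <- majority_call(reo_vote_matrix(vals, pairs))
  truth <- labels$label == subtype
  conf <- c(
    tp = sum(calls & truth), fp = sum(calls & !truth),
    tn = sum(!calls & !truth), fn = sum(!calls & truth)
  )
  metrics_from_confusion(conf, subtype, standard_metrics)
}

metrics_from_confusion <- function(conf, subtype, standard_metrics = FALSE) {
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warn(sprintf("%s has a zero denominator; reporting 0", what))
      return(0)
    }
    num / den
  }
  if (standard_metrics) {
    precision <- safe_ratio(conf[["tp"]], conf[["tp"]] + conf[["fp"]], "precision")
    recall <- safe_ratio(conf[["tp"]], conf[["tp"]] + conf[["fn"]], "recall")
  } else {
    precision <- safe_ratio(conf[["tp"]], conf[["tp"]] + conf[["fn"]], "precision")
    recall <- safe_ratio(conf[["tn"]], conf[["tn"]] + conf[["fp"]], "recall")
  }
  tibble(
    subtype = as.character(subtype),
    tp = conf[["tp"]], fp = conf[["fp"]], tn = conf[["tn"]], fn = conf[["fn"]],
    precision = precision, recall = recall,
    f_score = f_score(precision, recall)
  )
}

#' Greedy forward selection of a minimal pair set
#'
#' Seeds the biomarker with the single pair of highest F-score, then
#' repeatedly adds, among the remaining candidates, the pair whose tentative
#' inclusion yields the largest strict F-score improvement; stops when no
#' candidate strictly improves the F-score. Candidates are scanned in a
#' deterministic order — descending single-pair F, then ascending `p_value`
#' (when the candidate table carries one), then lexicographic pair id — so
#' ties resolve reproducibly.
#'
#' @param x An [expr_tbl()] (training samples).
#' @param candidates Tibble `gene_hi`, `gene_lo` (optionally `p_value`),
#'   e.g. from [find_subtype_specific_pairs()].
#' @param labels Tibble `sample_id`, `label`.
#' @param subtype Target subtype.
#' @return A `reo_biomarker` whose `f_score` is the achieved training F;
#'   attribute `trace` records the F after each accepted pair.
#' @export
forward_select <- function(x, candidates, labels, subtype) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0L) abort("empty candidate set")
  vals <- expr_values(x)[, labels$sample_id, drop = FALSE]
  votes_pos <- reo_vote_matrix(vals, candidates) == 1   # m x n logical
  truth <- labels$label == subtype
  n_pos <- sum(truth)
  n_neg <- sum(!truth)

  f_of_calls <- function(calls_mat) {
    # calls_mat: candidates x samples logical
    tp <- calls_mat %*% truth
    fp <- calls_mat %*% (!truth)
    precision <- if (n_pos == 0) rep(0, nrow(calls_mat)) else tp / n_pos
    recall <- if (n_neg == 0) rep(0, nrow(calls_mat)) else (n_neg - fp) / n_neg
    as.numeric(f_score(precision, recall))
  }

  f_single <- f_of_calls(votes_pos * 1 > 0.5)
  ord <- order(-f_single,
               if ("p_value" %in% names(candidates)) candidates$p_value else
                 rep(0, nrow(candidates)),
               candidates$gene_hi, candidates$gene_lo)
  votes_pos <- votes_pos[ord, , drop = FALSE]
  candidates <- candidates[ord, ]
  f_single <- f_single[ord]

  selected <- 1L
  pos_counts <- as.numeric(votes_pos[1L, ])
  best_f <- f_single[1L]
  trace <- best_f
  remaining <- setdiff(seq_len(nrow(candidates)), selected)
  while (length(remaining) > 0L) {
    size <- length(selected) + 1L
    tent <- sweep(votes_pos[remaining, , drop = FALSE], 2L, pos_counts, `+`)
    f_tent <- f_of_calls(tent > size / 2)
    i <- which.max(f_tent)  # first max = scan order tie-break
    if (f_tent[i] <= best_f) break
    pick <- remaining[i]
    selected <- c(selected, pick)
    pos_counts <- pos_counts + votes_pos[pick, ]
    best_f <- f_tent[i]
    trace <- c(trace, best_f)
    remaining <- setdiff(remaining, pick)
  }
  out <- reo_biomarker(candidates[selected, c("gene_hi", "gene_lo")],
                       subtype = subtype, f_score = best_f)
  attr(out, "trace") <- trace
  out
}

#' Classify samples with a biomarker ensemble
#'
#' Applies the ensemble's biomarkers in `application_order`; the first
#' biomarker whose strict majority fires assigns its subtype. Samples firing
#' no biomarker are labeled `"unassigned"`.
#'
#' @param x An [expr_tbl()] containing every biomarker gene.
#' @param ensemble A [reo_ensemble()].
#' @return Tibble `sample_id`, `label`.
#' @export
classify_samples <- function(x, ensemble) {
  ensemble <- validate_reo_ensemble(ensemble)
  vals <- expr_values(x)
  label <- rep(NA_character_, ncol(vals))
  for (s in ensemble$application_order) {
    calls <- majority_call(reo_vote_matrix(vals, ensemble$biomarkers[[s]]$pairs))
    label[is.na(label) & calls] <- s
  }
  tibble(sample_id = colnames(vals),
         label = ifelse(is.na(label), "unassigned", label))
}

#' @rdname classify_samples
#' @param sample Named numeric vector of one sample's expression values.
#' @export
classify_sample <- function(sample, ensemble) {
  ensemble <- validate_reo_ensemble(ensemble)
  vals <- matrix(sample, ncol = 1, dimnames = list(names(sample), "sample"))
  for (s in ensemble$application_order) {
    if (majority_call(reo_vote_matrix(vals, ensemble$biomarkers[[s]]$pairs))) {
      return(s)
    }
  }
  "unassigned"
}

#' Train a full REO classifier ensemble
#'
#' For each subtype: discover subtype-specific reversed pairs
#' ([find_subtype_specific_pairs()]) and distill them into a minimal
#' biomarker by [forward_select()].
#'
#' @inheritParams find_subtype_specific_pairs
#' @param subtypes Subtype labels to train (default: all labels present).
#' @param application_order Order of application (default: sorted subtypes).
#' @return A [reo_ensemble()].
#' @export
train_reo_ensemble <- function(x, labels, candidate_pairs,
                               fdr_threshold = 1e-7, p0 = 0.5,
                               subtypes = NULL, application_order = NULL) {
  subtypes <- subtypes %||% sort(unique(labels$label))
  biomarkers <- lapply(subtypes, function(s) {
    specific <- find_subtype_specific_pairs(
      x, labels, s, candidate_pairs,
      fdr_threshold = fdr_threshold, p0 = p0
    )
    if (nrow(specific) == 0L) {
      abort(sprintf("no subtype-specific pairs found for subtype %s", s))
    }
    cand <- dplyr::rename(specific, p_value = "fdr_subtype")[,
      c("gene_hi", "gene_lo", "p_value")]
    forward_select(x, cand, labels, s)
  })
  reo_ensemble(biomarkers, application_order = application_order)
}
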