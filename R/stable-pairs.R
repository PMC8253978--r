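#' Relative expression ordering of one gene pair in one sample
#'
#' The REO of genes `(gene_hi, gene_lo)` in a sample: `+1` if the sample
#' expresses `gene_hi` strictly above `gene_lo`, `-1` if strictly below, `0`
#' on an exact tie. Invariant under any strictly increasing transform of the
#' sample's values.
#'
#' @param sample Named numeric vector of one sample's expression values.
#' @param pair Character vector `c(gene_hi, gene_lo)` or a one-row tibble
#'   with columns `gene_hi`, `gene_lo`.
#' @return `+1`, `-1`, or `0`.
#' @export
reo <- function(sample, pair) {
  if (is.data.frame(pair)) pair <- c(pair$gene_hi[1L], pair$gene_lo[1L])
  missing <- setdiff(pair, names(sample))
  if (length(missing) > 0L) {
    abort(paste0("gene(s) absent from sample: ", paste(missing, collapse = ", ")))
  }
  sign(sample[[pair[1L]]] - sample[[pair[2L]]])
}

#' Upper-tail binomial probability of a stable REO pattern
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: the chance that at least `k` of
#' `n` samples show one fixed orientation of a gene pair when orientations
#' are coin flips (`p0 = 0.5` by default). Evaluated exactly in log space.
#'
#' @param n Number of informative (untied) samples.
#' @param k Count of the majority orientation.
#' @param p0 Null orientation probability, in (0, 1).
#' @return The tail probability; vectorized over `n` and `k`.
#' @export
stable_pair_pvalue <- function(n, k, p0 = 0.5) {
  if (any(p0 <= 0 | p0 >= 1)) abort("p0 must lie in (0, 1)")
  if (any(k < 0 | n < 0 | k > n)) abort("need 0 <= k <= n")
  mapply(function(n1, k1) {
    if (k1 == 0) return(1)
    i <- k1:n1
    min(exp(logsumexp(lchoose(n1, i) + i * log(p0) + (n1 - i) * log1p(-p0))), 1)
  }, n, k)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via `stats::p.adjust`), with input validation.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, clipped to 1, order-preserving in the ranks.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Enumerate candidate gene pairs
#'
#' All unordered pairs over a gene universe. Warns when the universe implies
#' more than 10^7 pairs.
#'
#' @param genes Character vector of gene ids (no duplicates).
#' @return Tibble `gene_a`, `gene_b` with `gene_a < gene_b`.
#' @export
all_gene_pairs <- function(genes) {
  genes <- sort(unique(as.character(genes)))
  n <- length(genes)
  if (n < 2L) abort("need at least two genes")
  n_pairs <- n * (n - 1) / 2
  if (n_pairs > 1e7) {
    warn(sprintf("pair universe has %.3g pairs; consider restricting the gene universe", n_pairs))
  }
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  tibble(gene_a = genes[idx[, 1L]], gene_b = genes[idx[, 2L]])
}

# orientation counts of candidate pairs within a set of samples;
# returns pos (gene_a > gene_b), neg, tie counts. Chunked to bound memory.
pair_orientation_counts <- function(vals, pairs, chunk = 20000L) {
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), rownames(vals))
  if (length(missing) > 0L) {
    abort(paste0("candidate-pair gene(s) absent from matrix: ",
                 paste(head(missing, 5L), collapse = ", ")))
  }
  m <- nrow(pairs)
  pos <- neg <- integer(m)
  for (start in seq(1L, m, by = chunk)) {
    sel <- start:min(start + chunk - 1L, m)
    d <- vals[pairs$gene_a[sel], , drop = FALSE] -
      vals[pairs$gene_b[sel], , drop = FALSE]
    pos[sel] <- rowSums(d > 0)
    neg[sel] <- rowSums(d < 0)
  }
  tibble(pos = pos, neg = neg, tie = ncol(vals) - pos - neg)
}

#' Detect significantly stable REO gene pairs in a sample group
#'
#' For every candidate pair, counts the majority orientation among the group
#' samples, tests it against a fair-coin null with [stable_pair_pvalue()],
#' adjusts across all tested pairs with [bh_adjust()], and keeps pairs with
#' `fdr < fdr_threshold`. By default exactly tied samples are dropped from
#' `n` (they support neither orientation); `ties = "count"` keeps them in
#' `n` as failures.
#'
#' @param x An [expr_tbl()].
#' @param candidate_pairs Tibble `gene_a`, `gene_b` (e.g. [all_gene_pairs()]).
#' @param sample_ids Samples forming the group (default: all samples).
#' @param fdr_threshold BH-FDR cutoff (default 1e-7).
#' @param p0 Null orientation probability.
#' @param ties `"drop"` (default) or `"count"`.
#' @return Tibble of retained pairs, oriented by their majority direction:
#'   `gene_hi`, `gene_lo`, `n`, `k`, `p_value`, `fdr`, sorted by `p_value`.
#'   Attribute `n_tested` records the BH family size.
#' @export
find_stable_pairs <- function(x, candidate_pairs, sample_ids = NULL,
                              fdr_threshold = 1e-7, p0 = 0.5,
                              ties = c("drop", "count")) {
  ties <- match.arg(ties)
  candidate_pairs <- normalize_pairs(candidate_pairs)
  if (nrow(candidate_pairs) == 0L) abort("empty candidate pair universe")
  vals <- expr_values(x)
  if (!is.null(sample_ids)) vals <- vals[, sample_ids, drop = FALSE]
  if (ncol(vals) < 24L) {
    warn(sprintf(
      "group has %d samples; even a unanimous pair cannot reach FDR < 1e-7 below 24",
      ncol(vals)
    ))
  }
  counts <- pair_orientation_counts(vals, candidate_pairs)
  n <- if (ties == "drop") counts$pos + counts$neg else rep(ncol(vals), nrow(counts))
  k <- pmax(counts$pos, counts$neg)
  p <- stable_pair_pvalue(n, k, p0 = p0)
  fdr <- bh_adjust(p)
  up <- counts$pos >= counts$neg
  out <- tibble(
    gene_hi = ifelse(up, candidate_pairs$gene_a, candidate_pairs$gene_b),
    gene_lo = ifelse(up, candidate_pairs$gene_b, candidate_pairs$gene_a),
    n = as.integer(n), k = as.integer(k), p_value = p, fdr = fdr
  )
  out <- dplyr::arrange(out[fdr < fdr_threshold, ], .data$p_value,
                        .data$gene_hi, .data$gene_lo)
  attr(out, "n_tested") <- nrow(candidate_pairs)
  out
}

normalize_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  if (all(c("gene_hi", "gene_lo") %in% names(pairs)) &&
      !all(c("gene_a", "gene_b") %in% names(pairs))) {
    pairs <- tibble(gene_a = pairs$gene_hi, gene_b = pairs$gene_lo)
  }
  if (!all(c("gene_a", "gene_b") %in% names(pairs))) {
    abort("candidate pairs need columns gene_a/gene_b (or gene_hi/gene_lo)")
  }
  if (any(pairs$gene_a == pairs$gene_b)) abort("a pair cannot repeat one gene")
  pairs
}

#' Subtype-specific reversed REO pairs
#'
#' A pair is subtype-specific when its REO is significantly stable one way
#' within the subtype's samples and significantly stable the *opposite* way
#' in all remaining samples pooled (both at BH-FDR < `fdr_threshold`, each
#' adjusted across the full candidate universe in its own group). Returned
#' pairs are oriented as seen in the subtype: `gene_hi` above `gene_lo`.
#'
#' @inheritParams find_stable_pairs
#' @param labels Tibble `sample_id`, `label` covering the matrix samples.
#' @param subtype The label defining the in-group.
#' @return Tibble `gene_hi`, `gene_lo` plus per-group statistics
#'   (`n_subtype`, `k_subtype`, `fdr_subtype`, `n_rest`, `k_rest`,
#'   `fdr_rest`).
#' @export
find_subtype_specific_pairs <- function(x, labels, subtype, candidate_pairs,
                                        fdr_threshold = 1e-7, p0 = 0.5,
                                        ties = c("drop", "count")) {
  ties <- match.arg(ties)
  in_ids <- labels$sample_id[labels$label == subtype]
  out_ids <- labels$sample_id[labels$label != subtype]
  if (length(in_ids) == 0L || length(out_ids) == 0L) {
    abort("both the subtype group and its complement must be non-empty")
  }
  stable_in <- find_stable_pairs(x, candidate_pairs, sample_ids = in_ids,
                                 fdr_threshold = fdr_threshold, p0 = p0, ties = ties)
  stable_out <- find_stable_pairs(x, candidate_pairs, sample_ids = out_ids,
                                  fdr_threshold = fdr_threshold, p0 = p0, ties = ties)
  # reversal: the subtype's (hi, lo) must be stable as (lo, hi) in the rest
  dplyr::inner_join(
    stable_in, stable_out,
    by = c(gene_hi = "gene_lo", gene_lo = "gene_hi"),
    suffix = c("_subtype", "_rest")
  ) |>
    dplyr::select(
      "gene_hi", "gene_lo", "n_subtype", "k_subtype", "fdr_subtype",
      "n_rest", "k_rest", "fdr_rest"
    )
}
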