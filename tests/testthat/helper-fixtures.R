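# shared fixtures and independent oracles, built in code at test time

make_expr <- function(values, batch = "batch1", unit = "TPM-like") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  expr_tbl(values, batch = batch, unit = unit)
}

random_expr <- function(n_genes = 20, n_samples = 8, seed = 1) {
  withr::with_seed(seed, {
    make_expr(matrix(rexp(n_genes * n_samples, rate = 0.1), n_genes, n_samples))
  })
}

small_synthetic <- function(seed = 7, effect = 2, genes = 300,
                            sizes = list(a = c(18, 18, 18), b = c(12, 12, 12)),
                            markers = 10) {
  generate_cohorts(synthetic_spec(
    n_genes = genes, samples_per_subtype = sizes,
    n_marker_genes_per_subtype = markers, effect_size = effect, seed = seed
  ))
}

named_labels <- function(labels_tbl) {
  setNames(labels_tbl$label, labels_tbl$sample_id)
}

# independent average-linkage cophenetic oracle: naive agglomeration keeping
# explicit member lists, O(n^3); used to check the hclust-based implementation
oracle_cophenetic_cor <- function(consensus) {
  D <- 1 - consensus
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  dmat <- D
  diag(dmat) <- Inf
  sizes <- rep(1, n)
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- c(NA, NA)
    bestd <- Inf
    for (i in idx) {
      for (j in idx) {
        if (i < j && dmat[i, j] < bestd) {
          bestd <- dmat[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- coph[b, a] <- bestd
    }
    # average linkage: size-weighted mean of distances to the merged cluster
    for (k in idx) {
      if (k != i && k != j) {
        dmat[i, k] <- dmat[k, i] <-
          (sizes[i] * dmat[i, k] + sizes[j] * dmat[j, k]) / (sizes[i] + sizes[j])
      }
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    dmat[j, ] <- dmat[, j] <- Inf
  }
  off <- upper.tri(D)
  cor(D[off], coph[off])
}

# exact binomial upper tail by direct summation (small n)
oracle_binom_tail <- function(n, k, p0 = 0.5) {
  if (k == 0) return(1)
  i <- k:n
  sum(choose(n, i) * p0^i * (1 - p0)^(n - i))
}

# exhaustive hypergeometric tail: enumerate all draws of size L1 from L
oracle_hyper_tail <- function(L, L1, L2, s) {
  if (s == 0) return(1)
  draws <- utils::combn(L, L1)
  in2 <- seq_len(L2) # wlog the first L2 elements form list 2
  mean(apply(draws, 2, function(d) sum(d %in% in2) >= s))
}

# stepwise replay of greedy forward selection (independent of the package's
# vectorized implementation)
oracle_forward_select <- function(x, candidates, labels, subtype) {
  eval_f <- function(pairs) {
    evaluate_biomarker(x, pairs, labels, subtype)$f_score
  }
  f1 <- vapply(seq_len(nrow(candidates)), function(i) {
    eval_f(candidates[i, ])
  }, 1)
  p <- if ("p_value" %in% names(candidates)) candidates$p_value else rep(0, nrow(candidates))
  ord <- order(-f1, p, candidates$gene_hi, candidates$gene_lo)
  candidates <- candidates[ord, ]
  sel <- 1L
  best <- eval_f(candidates[sel, ])
  repeat {
    rem <- setdiff(seq_len(nrow(candidates)), sel)
    if (length(rem) == 0) break
    fs <- vapply(rem, function(i) eval_f(candidates[c(sel, i), ]), 1)
    i <- which.max(fs)
    if (fs[i] <= best) break
    sel <- c(sel, rem[i])
    best <- fs[i]
  }
  list(pairs = candidates[sel, c("gene_hi", "gene_lo")], f = best)
}
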