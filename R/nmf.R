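#' Brunet-style non-negative matrix factorization
#'
#' Factorizes a non-negative matrix `V` (features x samples) as `V ~ W H` by
#' multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence `D(V || WH)`. `W`, `H` are initialized i.i.d. uniform(0, 1]
#' under `seed`; a 1e-12 epsilon guards every division. The run stops when
#' the sample partition induced by the dominant metagene of `H` has been
#' unchanged for `patience` consecutive checks (made every `check_every`
#' iterations) or at `max_iter`.
#'
#' @param V Non-negative numeric matrix (or [expr_tbl()]), features x samples.
#' @param rank Factorization rank; must be `< min(dim(V))`.
#' @param seed Integer seed for the initialization.
#' @param max_iter Iteration cap.
#' @param check_every,patience Connectivity-stability stopping rule.
#' @param eps Epsilon guard inside the updates.
#' @return An object of class `nmf_fit`: list with `W`, `H`, `divergence`
#'   (final KL), `trace` (KL at each check, non-increasing), `n_iter`,
#'   `converged`, `rank`, `seed`.
#' @export
nmf_factorize <- function(V, rank, seed = 1L, max_iter = 1000L,
                          check_every = 10L, patience = 10L, eps = 1e-12) {
  if (inherits(V, "expr_tbl")) V <- expr_values(V)
  stopifnot(is.matrix(V), is.numeric(V))
  if (any(!is.finite(V)) || any(V < 0)) abort("V must be finite and non-negative")
  if (rank >= min(dim(V))) abort("rank must be smaller than both dimensions of V")
  if (any(rowSums(V) == 0) || any(colSums(V) == 0)) {
    abort("V has all-zero rows or columns; filter before factorizing")
  }
  init <- withr::with_seed(seed, list(
    W = matrix(runif(nrow(V) * rank), nrow(V), rank),
    H = matrix(runif(rank * ncol(V)), rank, ncol(V))
  ))
  fit <- nmf_brunet_cpp(V, init$W, init$H, as.integer(max_iter),
                        as.integer(check_every), as.integer(patience), eps)
  colnames(fit$H) <- colnames(V)
  rownames(fit$W) <- rownames(V)
  fit$rank <- as.integer(rank)
  fit$seed <- as.integer(seed)
  structure(fit, class = "nmf_fit")
}

#' Cluster labels from one NMF run
#'
#' Brunet convention: each sample is assigned to the metagene with the
#' largest coefficient in its column of `H`; exact ties go to the lowest
#' index.
#'
#' @param fit An `nmf_fit`.
#' @return Named integer vector of labels in `1..rank`.
#' @export
run_labels <- function(fit) {
  h <- t(fit$H)
  lab <- max.col(h, ties.method = "first")
  names(lab) <- rownames(h)
  lab
}

#' Consensus clustering over repeated NMF runs
#'
#' Runs [nmf_factorize()] `n_runs` times (run `r` uses seed `seed + r`) and
#' records, for every sample pair, the fraction of runs in which the two
#' samples share a dominant metagene. The cophenetic correlation of the
#' consensus is computed with [cophenetic_coefficient()].
#'
#' @inheritParams nmf_factorize
#' @param n_runs Number of stochastic restarts (>= 2).
#' @param ... Passed on to [nmf_factorize()].
#' @return Object of class `consensus_result`: list with `rank`, `consensus`
#'   (symmetric sample x sample matrix in `[0, 1]`, unit diagonal), `n_runs`,
#'   `cophenetic`.
#' @export
run_consensus <- function(V, rank, n_runs = 200L, seed = 1L, ...) {
  if (inherits(V, "expr_tbl")) V <- expr_values(V)
  if (n_runs < 2L) abort("n_runs must be >= 2")
  n <- ncol(V)
  acc <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    lab <- run_labels(nmf_factorize(V, rank, seed = seed + r, ...))
    acc <- acc + outer(lab, lab, `==`)
  }
  consensus <- acc / n_runs
  dimnames(consensus) <- list(colnames(V), colnames(V))
  structure(
    list(rank = as.integer(rank), consensus = consensus,
         n_runs = as.integer(n_runs),
         cophenetic = cophenetic_coefficient(consensus)),
    class = "consensus_result"
  )
}

#' Cophenetic correlation of a consensus matrix
#'
#' Measures cluster stability: the Pearson correlation between the
#' off-diagonal consensus distances `D = 1 - consensus` and the cophenetic
#' distances of the average-linkage hierarchical tree built on `D`. Values
#' near 1 indicate that the consensus is close to ultrametric, i.e. stable
#' clusters.
#'
#' @param consensus Symmetric sample x sample matrix in `[0, 1]` with unit
#'   diagonal, or a `consensus_result`.
#' @return Correlation in `[-1, 1]`.
#' @export
cophenetic_coefficient <- function(consensus) {
  if (inherits(consensus, "consensus_result")) consensus <- consensus$consensus
  check_consensus(consensus)
  d <- as.dist(1 - consensus)
  if (length(d) < 3L) abort("need at least 3 samples")
  if (sd(d) == 0) abort("all off-diagonal consensus distances equal; cophenetic correlation undefined")
  coph <- cophenetic(hclust(d, method = "average"))
  if (sd(coph) == 0) {
    # tree collapses every merge to one height (e.g. perfect blocks at equal
    # separation is excluded above; a zero-spread tree with spread in d is not)
    abort("cophenetic distances are constant; correlation undefined")
  }
  cor(d, coph)
}

check_consensus <- function(consensus) {
  stopifnot(is.matrix(consensus), nrow(consensus) == ncol(consensus))
  if (max(abs(consensus - t(consensus))) > 1e-12) abort("consensus must be symmetric")
  if (any(consensus < 0 | consensus > 1)) abort("consensus entries must lie in [0, 1]")
  if (any(abs(diag(consensus) - 1) > 1e-12)) abort("consensus diagonal must be 1")
  invisible(consensus)
}

#' Select the cluster number from cophenetic profiles
#'
#' Picks the rank maximizing the mean cophenetic coefficient across cohorts;
#' exact ties resolve to the smallest rank.
#'
#' @param profiles Tibble with columns `cohort`, `rank`, `cophenetic`
#'   (all cohorts on the same rank grid), e.g. from [cluster_cohorts()].
#' @return The selected rank (integer).
#' @export
select_rank <- function(profiles) {
  if (is.null(profiles) || nrow(as_tibble(profiles)) == 0L) abort("empty cophenetic profiles")
  profiles <- as_tibble(profiles)
  grids <- lapply(split(profiles$rank, profiles$cohort), sort)
  if (length(unique(grids)) != 1L) abort("cohorts must share the rank grid")
  avg <- profiles |>
    dplyr::summarise(mean_coph = mean(.data$cophenetic), .by = "rank") |>
    dplyr::arrange(dplyr::desc(.data$mean_coph), .data$rank)
  as.integer(avg$rank[1L])
}

#' Final subtype labels from a consensus matrix
#'
#' Cuts the average-linkage tree of `1 - consensus` into `rank` clusters.
#' Cluster indices are reassigned in order of decreasing cluster size
#' (ties: first occurrence) so labels are deterministic.
#'
#' @param consensus A `consensus_result`.
#' @return Tibble `sample_id`, `label` (character `"1"..."rank"`).
#' @export
assign_final <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_result"))
  d <- as.dist(1 - consensus$consensus)
  raw <- cutree(hclust(d, method = "average"), k = consensus$rank)
  sizes <- table(raw)
  order_idx <- order(-as.integer(sizes), as.integer(names(sizes)))
  remap <- setNames(seq_along(order_idx), names(sizes)[order_idx])
  tibble(
    sample_id = names(raw),
    label = as.character(remap[as.character(raw)])
  )
}

#' Cluster several cohorts over a rank grid
#'
#' Convenience wrapper running [run_consensus()] per cohort and rank,
#' returning the cophenetic profile table expected by [select_rank()] plus
#' all consensus results.
#'
#' @param mats Named list of expression matrices (or [expr_tbl()]s), already
#'   restricted to the clustering features.
#' @param ranks Integer vector of candidate cluster numbers.
#' @param n_runs Stochastic restarts per (cohort, rank).
#' @param seed Master seed; run seeds are derived per cohort/rank/run.
#' @param ... Passed to [nmf_factorize()].
#' @return List with `profiles` (tibble `cohort`, `rank`, `cophenetic`) and
#'   `results` (`results[[cohort]][[as.character(rank)]]` is a
#'   `consensus_result`).
#' @export
cluster_cohorts <- function(mats, ranks = 2:8, n_runs = 200L, seed = 1L, ...) {
  stopifnot(length(mats) >= 1L, !is.null(names(mats)))
  results <- list()
  profiles <- list()
  offset <- 0L
  for (co in names(mats)) {
    results[[co]] <- list()
    for (k in ranks) {
      cr <- run_consensus(mats[[co]], rank = k, n_runs = n_runs,
                          seed = seed + offset, ...)
      results[[co]][[as.character(k)]] <- cr
      profiles[[length(profiles) + 1L]] <-
        tibble(cohort = co, rank = as.integer(k), cophenetic = cr$cophenetic)
      offset <- offset + n_runs + 1L
    }
  }
  list(profiles = dplyr::bind_rows(profiles), results = results)
}

#' Match subtype numbering across two cohorts
#'
#' Finds the one-to-one relabeling of cohort B's clusters that maximizes the
#' sum of Pearson correlations between cluster centroids (per-cluster means
#' of `log2(x + 1)` over the shared genes), by exhaustive search over all
#' `rank!` permutations.
#'
#' @param mat_a,mat_b Expression tables ([expr_tbl()]) of the two cohorts.
#' @param labels_a,labels_b Label tibbles (`sample_id`, `label`) of equal
#'   rank (same number of distinct labels).
#' @param shared_genes Genes used for the centroids (default: all shared).
#' @return List with `map` (named character: B's old label -> A's label) and
#'   `labels_b` (the relabeled tibble).
#' @export
match_subtypes_across_cohorts <- function(mat_a, labels_a, mat_b, labels_b,
                                          shared_genes = NULL) {
  la <- sort(unique(labels_a$label))
  lb <- sort(unique(labels_b$label))
  if (length(la) != length(lb)) abort("clusterings have different ranks")
  shared_genes <- shared_genes %||% intersect(gene_ids(mat_a), gene_ids(mat_b))
  centroid <- function(mat, labels, lev) {
    lv <- log2(expr_values(mat)[shared_genes, , drop = FALSE] + 1)
    vapply(lev, function(l) {
      rowMeans(lv[, labels$sample_id[labels$label == l], drop = FALSE])
    }, numeric(length(shared_genes)))
  }
  ca <- centroid(mat_a, labels_a, la)
  cb <- centroid(mat_b, labels_b, lb)
  cors <- cor(ca, cb) # rows: A clusters, cols: B clusters
  perms <- all_permutations(length(la))
  score <- vapply(perms, function(p) sum(cors[cbind(seq_along(p), p)]), 0)
  best <- perms[[which.max(score)]]
  map <- setNames(la, lb[best])   # B label (old) -> A label
  tibble_b <- labels_b
  tibble_b$label <- unname(map[labels_b$label])
  list(map = map, labels_b = tibble_b)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1L)) {
      rest <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}
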