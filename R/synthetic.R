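#' Parameterize a synthetic multi-cohort expression study
#'
#' Describes the simulated design every generator call draws from: a fixed
#' number of latent subtypes shared by two (or more) cohorts, subtype marker
#' genes shifted up by `effect_size` (log2) in their own subtype and down by
#' the same amount elsewhere, an equal-baseline partner gene for every marker
#' (together they form a planted subtype-specific reversed REO pair),
#' gene-wise per-cohort batch shifts, per-sample library-size scaling, and
#' log-normal within-group noise. Values are `2^(log2 baseline + shifts)`,
#' hence non-negative with a heavy right tail, mimicking TPM marginals.
#'
#' Defaults mirror a two-cohort renal-cancer style design with asymmetric
#' cohort sizes (roughly a large TCGA-like cohort and a smaller one).
#'
#' @param n_genes Total genes simulated.
#' @param samples_per_subtype Named list, one integer vector per cohort giving
#'   samples per subtype (length `n_subtypes`).
#' @param n_subtypes Number of latent subtypes.
#' @param n_marker_genes_per_subtype Marker genes per subtype; each also gets
#'   a partner gene, so `2 * n_marker_genes_per_subtype * n_subtypes` must
#'   not exceed `n_genes`.
#' @param effect_size Log2 shift of marker genes (+ in own subtype, - in the
#'   others).
#' @param batch_shift_sd SD of the gene-wise per-cohort log2 shift.
#' @param libsize_sd SD of the per-sample log2 scaling factor.
#' @param noise_sd SD of the per-value log2 noise.
#' @param baseline_log2_mean,baseline_log2_sd Law of gene baseline log2 means.
#' @param seed Integer master seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           samples_per_subtype = list(
                             cohort1 = c(52L, 78L, 46L),
                             cohort2 = c(21L, 42L, 37L)
                           ),
                           n_subtypes = 3L,
                           n_marker_genes_per_subtype = 50L,
                           effect_size = 2.0,
                           batch_shift_sd = 0.3,
                           libsize_sd = 0.3,
                           noise_sd = 0.5,
                           baseline_log2_mean = 5,
                           baseline_log2_sd = 2,
                           seed = 1L) {
  spec <- list(
    n_genes = as.integer(n_genes),
    samples_per_subtype = samples_per_subtype,
    n_subtypes = as.integer(n_subtypes),
    n_marker_genes_per_subtype = as.integer(n_marker_genes_per_subtype),
    effect_size = effect_size, batch_shift_sd = batch_shift_sd,
    libsize_sd = libsize_sd, noise_sd = noise_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd, seed = as.integer(seed)
  )
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  with(spec, {
    if (n_subtypes < 1L || n_genes < 1L) abort("n_genes and n_subtypes must be positive")
    if (n_marker_genes_per_subtype * n_subtypes > n_genes) {
      abort("marker genes exceed n_genes")
    }
    if (2L * n_marker_genes_per_subtype * n_subtypes > n_genes) {
      abort("marker + partner genes exceed n_genes; lower n_marker_genes_per_subtype")
    }
    if (effect_size < 0 || batch_shift_sd < 0 || libsize_sd < 0 || noise_sd <= 0) {
      abort("effect_size/batch_shift_sd/libsize_sd must be >= 0 and noise_sd > 0")
    }
    lens <- vapply(samples_per_subtype, length, 1L)
    if (!all(lens == n_subtypes)) abort("each cohort needs one size per subtype")
    if (any(unlist(samples_per_subtype) < 1L)) abort("sample counts must be positive")
  })
  spec
}

#' Generate labeled multi-cohort expression data
#'
#' Draws one expression table per cohort under a shared gene model (see
#' [synthetic_spec()]): same baselines, markers, and planted pairs across
#' cohorts; cohort-specific batch shifts, samples and noise. Deterministic
#' under `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_cohorts` with elements
#'   * `cohorts`: named list; each cohort has `matrix` (an [expr_tbl()]) and
#'     `true_labels` (tibble `sample_id`, `label`),
#'   * `planted_pairs`: tibble `subtype`, `gene_hi`, `gene_lo` — the
#'     marker/partner pairs whose REO reverses between a subtype and the rest,
#'   * `gene_roles`: tibble `gene_id`, `role`, `subtype`,
#'   * `spec`: the input spec.
#' @export
generate_cohorts <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  withr::with_seed(spec$seed, {
    ng <- spec$n_genes
    ns <- spec$n_subtypes
    nm <- spec$n_marker_genes_per_subtype
    genes <- sprintf("g%05d", seq_len(ng))
    mu <- rnorm(ng, spec$baseline_log2_mean, spec$baseline_log2_sd)

    idx <- sample.int(ng, 2L * nm * ns)
    marker_idx <- matrix(idx[seq_len(nm * ns)], nrow = nm)        # col = subtype
    partner_idx <- matrix(idx[nm * ns + seq_len(nm * ns)], nrow = nm)
    mu[partner_idx] <- mu[marker_idx]   # equal baselines: the planted reversal

    roles <- tibble(gene_id = genes, role = "background", subtype = NA_character_)
    for (s in seq_len(ns)) {
      roles$role[marker_idx[, s]] <- "marker"
      roles$subtype[marker_idx[, s]] <- as.character(s)
      roles$role[partner_idx[, s]] <- "partner"
      roles$subtype[partner_idx[, s]] <- as.character(s)
    }
    planted <- purrr::map_dfr(seq_len(ns), function(s) {
      tibble(subtype = as.character(s),
             gene_hi = genes[marker_idx[, s]],
             gene_lo = genes[partner_idx[, s]])
    })

    # gene x subtype log2 shift: markers up in own subtype, down elsewhere
    delta <- matrix(0, ng, ns)
    for (s in seq_len(ns)) {
      delta[marker_idx[, s], ] <- delta[marker_idx[, s], ] - spec$effect_size
      delta[marker_idx[, s], s] <- spec$effect_size
    }

    cohorts <- purrr::imap(spec$samples_per_subtype, function(sizes, cohort) {
      n_samp <- sum(sizes)
      labels <- rep(seq_len(ns), times = sizes)
      sample_id <- sprintf("%s_%03d", cohort, seq_len(n_samp))
      batch_shift <- rnorm(ng, 0, spec$batch_shift_sd)
      libsize <- rnorm(n_samp, 0, spec$libsize_sd)
      log2x <- mu + batch_shift +
        delta[, labels, drop = FALSE] +
        matrix(rnorm(ng * n_samp, 0, spec$noise_sd), ng, n_samp)
      log2x <- sweep(log2x, 2L, libsize, `+`)
      vals <- 2^log2x
      dimnames(vals) <- list(genes, sample_id)
      list(
        matrix = expr_tbl(vals, batch = cohort, unit = "TPM-like"),
        true_labels = tibble(sample_id = sample_id, label = as.character(labels))
      )
    })

    structure(
      list(cohorts = cohorts, planted_pairs = planted,
           gene_roles = roles, spec = spec),
      class = "synthetic_cohorts"
    )
  })
}

#' Construct a pair of directed DEG lists with known overlap structure
#'
#' Builds two directed gene lists over a background universe with exactly
#' `n_overlap` shared genes, of which exactly `n_consistent` carry the same
#' dysregulation direction in both lists. Useful for exercising
#' [concordance()] against known `k` and `s`.
#'
#' @param n_background Universe size `L` (genes commonly measured).
#' @param n1,n2 Sizes of the two lists.
#' @param n_overlap Number of shared genes `k`.
#' @param n_consistent Number of direction-consistent shared genes `s`.
#' @param seed Integer seed for the random directions.
#' @return List with elements `deg1`, `deg2` (tibbles `gene_id`, `direction`,
#'   attribute `universe_size`) and `universe_size`.
#' @export
generate_deg_lists <- function(n_background, n1, n2, n_overlap, n_consistent,
                               seed = 1L) {
  if (!(n_consistent <= n_overlap && n_overlap <= min(n1, n2) &&
        max(n1, n2) <= n_background)) {
    abort("need n_consistent <= n_overlap <= min(n1, n2) <= n_background")
  }
  if (n1 + n2 - n_overlap > n_background) {
    abort("n1 + n2 - n_overlap exceeds the background universe")
  }
  withr::with_seed(seed, {
    genes <- sprintf("bg%06d", seq_len(n_background))
    shared <- genes[seq_len(n_overlap)]
    only1 <- genes[n_overlap + seq_len(n1 - n_overlap)]
    only2 <- genes[n_overlap + (n1 - n_overlap) + seq_len(n2 - n_overlap)]
    dir1 <- sample(c(-1, 1), n1, replace = TRUE)
    deg1 <- tibble(gene_id = c(shared, only1), direction = dir1)
    dir2_shared <- deg1$direction[seq_len(n_overlap)]
    if (n_consistent < n_overlap) {
      flip <- (n_consistent + 1L):n_overlap
      dir2_shared[flip] <- -dir2_shared[flip]
    }
    deg2 <- tibble(
      gene_id = c(shared, only2),
      direction = c(dir2_shared, sample(c(-1, 1), n2 - n_overlap, replace = TRUE))
    )
    attr(deg1, "universe_size") <- as.integer(n_background)
    attr(deg2, "universe_size") <- as.integer(n_background)
    list(deg1 = deg1, deg2 = deg2, universe_size = as.integer(n_background))
  })
}

#' Apply a rank-preserving distortion to an expression table
#'
#' Produces perturbed copies of an expression table under transforms that
#' preserve, exactly, the within-sample ordering of gene values — the
#' invariance REO classifiers are built on.
#'
#' @param x An [expr_tbl()].
#' @param kind `"nonlinear"` (per-sample power map `x^gamma`, `gamma` drawn in
#'   `(0.5, 1.5)`), `"scale"` (per-sample positive scaling), or `"log1p"`
#'   (global `log(1 + x)`).
#' @param seed Integer seed for the per-sample draws.
#' @return An [expr_tbl()] with identical ids and within-sample gene ranks.
#' @export
monotone_distort <- function(x, kind = c("nonlinear", "scale", "log1p"),
                             seed = 1L) {
  kind <- match.arg(kind)
  vals <- expr_values(x)
  n <- ncol(vals)
  out <- withr::with_seed(seed, switch(kind,
    nonlinear = sweep_pow(vals, runif(n, 0.5, 1.5)),
    scale = sweep(vals, 2L, runif(n, 0.25, 4), `*`),
    log1p = log1p(vals)
  ))
  new_expr_tbl_like(out, x)
}

sweep_pow <- function(vals, gamma) {
  out <- vals
  for (j in seq_along(gamma)) out[, j] <- vals[, j]^gamma[j]
  out
}

#' Adjusted Rand index between two labelings
#'
#' Thin wrapper over `mclust::adjustedRandIndex`, matching labels by shared
#' names when both vectors are named.
#'
#' @param a,b Label vectors (optionally named by sample id).
#' @return The adjusted Rand index in `[-1, 1]`.
#' @export
ari <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]
    b <- b[common]
  }
  mclust::adjustedRandIndex(a, b)
}
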