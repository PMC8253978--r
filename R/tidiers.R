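#' Tidy a consensus clustering result
#'
#' @param x A `consensus_result` from [run_consensus()].
#' @param ... Unused.
#' @return Long tibble `sample_1`, `sample_2`, `consensus` over all ordered
#'   sample pairs.
#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, ...) {
  cons <- x$consensus
  tibble(
    sample_1 = rep(rownames(cons), times = ncol(cons)),
    sample_2 = rep(colnames(cons), each = nrow(cons)),
    consensus = as.numeric(cons)
  )
}

#' @rdname tidy.consensus_result
#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(rank = x$rank, n_runs = x$n_runs,
         n_samples = ncol(x$consensus), cophenetic = x$cophenetic)
}

#' Tidy an NMF fit
#'
#' @param x An `nmf_fit` from [nmf_factorize()].
#' @param matrix `"H"` (default) for per-sample metagene coefficients or
#'   `"W"` for per-gene loadings.
#' @param ... Unused.
#' @return Long tibble of coefficients.
#' @method tidy nmf_fit
#' @export
tidy.nmf_fit <- function(x, matrix = c("H", "W"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "H") {
    h <- x$H
    tibble(
      metagene = rep(seq_len(nrow(h)), times = ncol(h)),
      sample_id = rep(colnames(h) %||% as.character(seq_len(ncol(h))), each = nrow(h)),
      value = as.numeric(h)
    )
  } else {
    w <- x$W
    tibble(
      gene_id = rep(rownames(w) %||% as.character(seq_len(nrow(w))), times = ncol(w)),
      metagene = rep(seq_len(ncol(w)), each = nrow(w)),
      value = as.numeric(w)
    )
  }
}

#' @rdname tidy.nmf_fit
#' @method glance nmf_fit
#' @export
glance.nmf_fit <- function(x, ...) {
  tibble(rank = x$rank, divergence = x$divergence,
         n_iter = x$n_iter, converged = x$converged, seed = x$seed)
}

#' Tidy an REO classifier ensemble
#'
#' @param x A [reo_ensemble()].
#' @param ... Unused.
#' @return [tidy()]: tibble `subtype`, `position`, `gene_hi`, `gene_lo`;
#'   [glance()]: one row per biomarker with pair count and training F.
#' @method tidy reo_ensemble
#' @export
tidy.reo_ensemble <- function(x, ...) {
  purrr::map_dfr(x$biomarkers, function(b) {
    dplyr::mutate(b$pairs, subtype = b$subtype,
                  position = dplyr::row_number(),
                  .before = 1L)
  })
}

#' @rdname tidy.reo_ensemble
#' @method glance reo_ensemble
#' @export
glance.reo_ensemble <- function(x, ...) {
  purrr::map_dfr(x$biomarkers, function(b) {
    tibble(subtype = b$subtype, n_pairs = nrow(b$pairs),
           f_score = b$f_score %||% NA_real_)
  })
}

#' Consensus heatmap
#'
#' Heatmap of the consensus matrix with samples ordered by the
#' average-linkage tree of `1 - consensus` (the ordering used for rank
#' inspection).
#'
#' @param object A `consensus_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, ...) {
  ord <- hclust(as.dist(1 - object$consensus), method = "average")$order
  ids <- rownames(object$consensus)[ord]
  df <- tidy.consensus_result(object)
  df$sample_1 <- factor(df$sample_1, levels = ids)
  df$sample_2 <- factor(df$sample_2, levels = ids)
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_1, .data$sample_2,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "#08306B", high = "#A50F15",
                                 limits = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Consensus over %d runs, rank %d (cophenetic %.3f)",
                      object$n_runs, object$rank, object$cophenetic),
      x = NULL, y = NULL, fill = "co-cluster\nfrequency"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Cophenetic profile plot
#'
#' Cophenetic correlation against candidate rank, one line per cohort, with
#' the across-cohort mean highlighted — the display rank selection is read
#' from.
#'
#' @param profiles Tibble `cohort`, `rank`, `cophenetic` (from
#'   [cluster_cohorts()]).
#' @return A ggplot object.
#' @export
plot_cophenetic <- function(profiles) {
  profiles <- as_tibble(profiles)
  avg <- dplyr::summarise(profiles, cophenetic = mean(.data$cophenetic),
                          .by = "rank")
  ggplot2::ggplot(profiles,
                  ggplot2::aes(.data$rank, .data$cophenetic,
                               colour = .data$cohort)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = avg, ggplot2::aes(colour = NULL),
                       linewidth = 1.1, colour = "black") +
    ggplot2::scale_x_continuous(breaks = sort(unique(profiles$rank))) +
    ggplot2::labs(x = "number of clusters",
                  y = "cophenetic correlation",
                  title = "Cluster-number selection (black: cohort mean)") +
    ggplot2::theme_minimal()
}
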