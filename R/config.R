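#' Pipeline configuration
#'
#' Bundles the tunable thresholds of the pipeline with their conventional
#' defaults, validated once. Individual functions take these values as plain
#' arguments; the config object is a convenience for scripts and the CLI to
#' carry one validated set around.
#'
#' @param mad_top_n Genes kept per cohort by variability ranking.
#' @param expression_mean_threshold Mean-abundance floor for
#'   [filter_expressed()].
#' @param nmf_runs Stochastic NMF restarts per consensus.
#' @param rank_range Candidate cluster numbers.
#' @param stable_pair_fdr BH-FDR cutoff for stable REO pairs.
#' @param deg_fdr FDR cutoff expected of input DEG lists.
#' @param train_fraction Training fraction for [split_train_test()].
#' @param seed Master seed for every stochastic step.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mad_top_n = 1500L,
                            expression_mean_threshold = 1,
                            nmf_runs = 200L,
                            rank_range = 2:8,
                            stable_pair_fdr = 1e-7,
                            deg_fdr = 0.01,
                            train_fraction = 0.7,
                            seed = 1L) {
  if (mad_top_n < 1L || nmf_runs < 2L) {
    abort("mad_top_n must be positive and nmf_runs >= 2")
  }
  if (expression_mean_threshold <= 0 || stable_pair_fdr <= 0 || deg_fdr <= 0) {
    abort("thresholds must be strictly positive")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("train_fraction must lie in (0, 1)")
  }
  if (length(rank_range) < 1L || any(rank_range < 2L)) {
    abort("rank_range must contain integers >= 2")
  }
  structure(
    list(
      mad_top_n = as.integer(mad_top_n),
      expression_mean_threshold = expression_mean_threshold,
      nmf_runs = as.integer(nmf_runs),
      rank_range = as.integer(rank_range),
      stable_pair_fdr = stable_pair_fdr,
      deg_fdr = deg_fdr,
      train_fraction = train_fraction,
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}
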