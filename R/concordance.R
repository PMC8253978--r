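#' Cumulative hypergeometric tail for list-overlap consistency
#'
#' The probability of observing at least `s` consistent genes by chance when
#' a list of `L1` genes is drawn from a universe of `L` genes of which `L2`
#' are in the second list:
#' `P = 1 - sum_{i=0}^{s-1} C(L2, i) C(L - L2, L1 - i) / C(L, L1)`.
#' Evaluated as the complementary (upper) sum in log space, so tiny tails do
#' not cancel. Infeasible terms contribute zero; `s = 0` gives 1 and
#' `s > min(L1, L2)` gives 0.
#'
#' @param L Universe size (background genes commonly measured).
#' @param L1,L2 Sizes of the two lists.
#' @param s Tail threshold (number of consistent genes).
#' @return The tail probability in `[0, 1]`.
#' @export
hypergeom_tail <- function(L, L1, L2, s) {
  if (any(c(L, L1, L2, s) < 0)) abort("arguments must be non-negative")
  if (L1 > L || L2 > L) abort("list sizes cannot exceed the universe L")
  if (s == 0) return(1)
  hi <- min(L1, L2)
  if (s > hi) return(0)
  lo <- max(0, L1 - (L - L2)) # feasibility: cannot miss more than L - L2
  i <- max(s, lo):hi
  logp <- lchoose(L2, i) + lchoose(L - L2, L1 - i) - lchoose(L, L1)
  min(exp(logsumexp(logp)), 1)
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Concordance of two directed DEG lists
#'
#' Counts the overlap `k` of two differentially-expressed-gene lists and the
#' number `s` of overlapping genes dysregulated in the same direction. The
#' concordance score is `s / k`; significance is the cumulative
#' hypergeometric tail [hypergeom_tail()] at `s` over the shared background
#' universe `L`. Lists are "significantly overlapped" at `p < alpha`.
#'
#' @param deg1,deg2 Tibbles with columns `gene_id`, `direction` (+1/-1),
#'   e.g. from [read_deg_tsv()] or [generate_deg_lists()].
#' @param universe_size Background size `L`; defaults to the (equal)
#'   `universe_size` attributes of the two lists.
#' @param alpha Significance threshold on the tail probability.
#' @return A one-row tibble: `k`, `s`, `score`, `p_value`, `significant`,
#'   `L`, `L1`, `L2`.
#' @export
concordance <- function(deg1, deg2, universe_size = NULL, alpha = 0.05) {
  deg1 <- validate_deg_list(deg1)
  deg2 <- validate_deg_list(deg2)
  u1 <- attr(deg1, "universe_size")
  u2 <- attr(deg2, "universe_size")
  if (is.null(universe_size)) {
    if (is.null(u1) || is.null(u2)) abort("universe_size not given and not carried by the lists")
    if (u1 != u2) abort("the two lists carry different universe sizes")
    universe_size <- u1
  } else if (!is.null(u1) && !is.null(u2) && u1 != u2) {
    abort("the two lists carry different universe sizes")
  }
  L <- as.integer(universe_size)
  if (L < max(nrow(deg1), nrow(deg2))) abort("universe smaller than a list")
  shared <- dplyr::inner_join(deg1, deg2, by = "gene_id",
                              suffix = c("_1", "_2"))
  k <- nrow(shared)
  if (k == 0L) abort("the lists do not overlap; concordance score undefined")
  s <- sum(shared$direction_1 == shared$direction_2)
  p <- hypergeom_tail(L, nrow(deg1), nrow(deg2), s)
  tibble(
    k = k, s = s, score = s / k, p_value = p,
    significant = p < alpha,
    L = L, L1 = nrow(deg1), L2 = nrow(deg2)
  )
}
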