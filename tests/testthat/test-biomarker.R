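test_that("the F-score is the harmonic mean with the right fixed points", {
  expect_equal(f_score(0.5, 0.5), 0.5)
  expect_equal(f_score(1, 0), 0)
  expect_equal(f_score(0, 0), 0)
  p <- withr::with_seed(1, runif(20)); r <- withr::with_seed(2, runif(20))
  f <- f_score(p, r)
  expect_true(all(f >= pmin(p, r) - 1e-12 & f <= pmax(p, r) + 1e-12))
})

test_that("evaluation applies the strict-majority rule and sensitivity/specificity-style metrics", {
  # 2-pair biomarker: a sample is positive only when BOTH pairs vote +1
  vals <- rbind(
    A = c(9, 9, 9, 1, 1, 9),
    B = c(1, 1, 1, 9, 9, 1),
    C = c(8, 8, 2, 2, 2, 2),
    D = c(2, 2, 8, 8, 8, 8)
  )
  colnames(vals) <- sprintf("s%d", 1:6)
  x <- make_expr(vals)
  labels <- tibble::tibble(sample_id = colnames(vals),
                           label = c("1", "1", "1", "2", "2", "2"))
  pairs <- tibble::tibble(gene_hi = c("A", "C"), gene_lo = c("B", "D"))
  m <- evaluate_biomarker(x, pairs, labels, "1")
  # positives: s1, s2 (both pairs +1); s3 and s6 have only one +1 vote
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(2, 1, 0, 3))
  expect_equal(m$precision, 2 / 3)   # identified subtype samples / all subtype samples
  expect_equal(m$recall, 1)          # rejected non-subtype samples / all non-subtype
  expect_equal(m$f_score, f_score(2 / 3, 1))
  std <- evaluate_biomarker(x, pairs, labels, "1", standard_metrics = TRUE)
  expect_equal(std$precision, 1)     # TP / (TP + FP)
  expect_equal(std$recall, 2 / 3)    # TP / (TP + FN)
})

test_that("zero-denominator metrics degrade to 0 with a warning", {
  vals <- rbind(A = c(5, 5), B = c(1, 1))
  colnames(vals) <- c("s1", "s2")
  labels <- tibble::tibble(sample_id = c("s1", "s2"), label = c("1", "1"))
  expect_warning(
    m <- evaluate_biomarker(make_expr(vals),
                            tibble::tibble(gene_hi = "A", gene_lo = "B"),
                            labels, "1"),
    "zero denominator"
  )
  expect_equal(m$recall, 0)
})

test_that("forward selection replays the greedy procedure exactly", {
  for (s in 1:4) {
    sim <- withr::with_seed(s, {
      n <- 40
      vals <- matrix(rexp(16 * n, 0.2), 16, n,
                     dimnames = list(sprintf("G%02d", 1:16), sprintf("s%02d", 1:n)))
      labels <- tibble::tibble(sample_id = colnames(vals),
                               label = sample(c("1", "2"), n, replace = TRUE))
      list(x = make_expr(vals), labels = labels)
    })
    cand <- withr::with_seed(s + 100, {
      p <- all_gene_pairs(sprintf("G%02d", 1:16))
      p <- p[sample(nrow(p), 8), ]
      tibble::tibble(gene_hi = p$gene_a, gene_lo = p$gene_b)
    })
    got <- forward_select(sim$x, cand, sim$labels, "1")
    want <- oracle_forward_select(sim$x, cand, sim$labels, "1")
    expect_equal(got$pairs, tibble::as_tibble(want$pairs))
    expect_equal(got$f_score, want$f)
    # never below the best single candidate
    singles <- vapply(seq_len(nrow(cand)), function(i) {
      evaluate_biomarker(sim$x, cand[i, ], sim$labels, "1")$f_score
    }, 1)
    expect_gte(got$f_score, max(singles))
    # the recorded trace is strictly increasing
    expect_true(all(diff(attr(got, "trace")) > 0))
  }
})

test_that("a single candidate yields a one-pair biomarker", {
  vals <- rbind(A = c(9, 1, 9, 1), B = c(1, 9, 1, 9))
  colnames(vals) <- sprintf("s%d", 1:4)
  labels <- tibble::tibble(sample_id = colnames(vals),
                           label = c("1", "2", "1", "2"))
  bm <- forward_select(make_expr(vals),
                       tibble::tibble(gene_hi = "A", gene_lo = "B"),
                       labels, "1")
  expect_s3_class(bm, "reo_biomarker")
  expect_equal(nrow(bm$pairs), 1L)
  expect_equal(bm$f_score, 1)
  expect_error(forward_select(make_expr(vals),
                              tibble::tibble(gene_hi = character(),
                                             gene_lo = character()),
                              labels, "1"),
               "empty candidate")
})

test_that("classification applies biomarkers in order, first strict majority wins", {
  ens <- reo_ensemble(list(
    reo_biomarker(tibble::tibble(gene_hi = "A", gene_lo = "B"), "1"),
    reo_biomarker(tibble::tibble(gene_hi = c("C", "D", "E"),
                                 gene_lo = c("F", "G", "H")), "2")
  ), application_order = c("1", "2"))
  base <- c(A = 1, B = 2, C = 5, D = 5, E = 1, F = 1, G = 1, H = 5)
  # subtype-2 majority (2 of 3), subtype-1 pair negative
  expect_equal(classify_sample(base, ens), "2")
  # subtype-1 pair positive wins regardless of the rest
  s1 <- base; s1["A"] <- 3
  expect_equal(classify_sample(s1, ens), "1")
  # no majority anywhere -> unassigned (1 of 3 is not > half)
  un <- base; un["D"] <- 0.5
  expect_equal(classify_sample(un, ens), "unassigned")
  # exact half on an even-size biomarker does not fire
  even <- reo_ensemble(list(
    reo_biomarker(tibble::tibble(gene_hi = c("A", "C"), gene_lo = c("B", "D")), "9")
  ))
  half <- c(A = 2, B = 1, C = 1, D = 2)
  expect_equal(classify_sample(half, even), "unassigned")

  # matrix interface agrees with the per-sample one
  vals <- cbind(s1 = s1, s2 = base, s3 = un)
  out <- classify_samples(make_expr(vals), ens)
  expect_equal(out$label, c("1", "2", "unassigned"))
  expect_error(classify_samples(make_expr(vals[1:4, , drop = FALSE]), ens),
               "absent")
})

test_that("votes counted as 11 of 21 pairs constitute a strict majority", {
  genes_hi <- sprintf("H%02d", 1:21)
  genes_lo <- sprintf("L%02d", 1:21)
  ens <- reo_ensemble(list(
    reo_biomarker(tibble::tibble(gene_hi = "P", gene_lo = "Q"), "1"),
    reo_biomarker(tibble::tibble(gene_hi = genes_hi, gene_lo = genes_lo), "2")
  ), application_order = c("1", "2"))
  sample <- c(P = 1, Q = 2,
              setNames(c(rep(2, 11), rep(1, 10)), genes_hi),
              setNames(c(rep(1, 11), rep(2, 10)), genes_lo))
  expect_equal(classify_sample(sample, ens), "2")
  # 10 of 21 is not
  sample10 <- sample
  sample10[genes_hi[11]] <- 0.5
  expect_equal(classify_sample(sample10, ens), "unassigned")
})

test_that("classification is invariant under per-sample monotone distortion", {
  sim <- small_synthetic(seed = 23, genes = 150, markers = 8,
                         sizes = list(a = c(30, 30, 30)))
  x <- sim$cohorts$a$matrix
  labels <- sim$cohorts$a$true_labels
  genes <- unique(unlist(sim$planted_pairs[, c("gene_hi", "gene_lo")]))
  ens <- train_reo_ensemble(x, labels, all_gene_pairs(genes))
  ref <- classify_samples(x, ens)
  for (kind in c("nonlinear", "scale", "log1p")) {
    distorted <- monotone_distort(x, kind = kind, seed = 99)
    expect_identical(classify_samples(distorted, ens), ref)
  }
  # while a raw-value threshold rule is not invariant
  g <- ens$biomarkers[[1]]$pairs$gene_hi[1]
  threshold_calls <- expr_values(x)[g, ] > stats::median(expr_values(x)[g, ])
  shifted <- monotone_distort(x, kind = "scale", seed = 99)
  shifted_calls <- expr_values(shifted)[g, ] > stats::median(expr_values(x)[g, ])
  expect_false(identical(threshold_calls, shifted_calls))
})

test_that("swapping pair orientation and negating the vote is an involution", {
  ens <- ccrcc_reference_ensemble()
  genes <- unique(unlist(lapply(ens$biomarkers, function(b) unlist(b$pairs))))
  vals <- withr::with_seed(31, matrix(rexp(length(genes) * 12, 0.1),
                                      length(genes), 12,
                                      dimnames = list(genes, sprintf("s%02d", 1:12))))
  x <- make_expr(vals)
  ref <- classify_samples(x, ens)
  # same decision computed from the flipped orientation: majority of -1 votes
  flipped_call <- function(b) {
    swapped <- tibble::tibble(gene_hi = b$pairs$gene_lo, gene_lo = b$pairs$gene_hi)
    votes <- sign(vals[swapped$gene_hi, , drop = FALSE] -
                    vals[swapped$gene_lo, , drop = FALSE])
    colSums(votes == -1) > nrow(swapped) / 2
  }
  label <- rep(NA_character_, ncol(vals))
  for (s in ens$application_order) {
    fire <- flipped_call(ens$biomarkers[[s]])
    label[is.na(label) & fire] <- s
  }
  expect_equal(ifelse(is.na(label), "unassigned", label), ref$label)
})

test_that("ensemble validation catches inconsistent application orders", {
  b1 <- reo_biomarker(tibble::tibble(gene_hi = "A", gene_lo = "B"), "1")
  expect_error(reo_ensemble(list(b1), application_order = c("1", "2")),
               "permutation")
  expect_error(reo_ensemble(list(b1), application_order = "2"), "permutation")
})
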