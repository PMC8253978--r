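test_that("an exact rank-1 matrix is factorized to near-zero divergence", {
  V <- withr::with_seed(1, outer(runif(8, 0.5, 2), runif(5, 0.5, 2)))
  fit <- nmf_factorize(V, rank = 1, seed = 3, max_iter = 2000)
  expect_lte(fit$divergence, 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("the KL objective is non-increasing across recorded checks", {
  for (s in 1:5) {
    V <- withr::with_seed(s, matrix(rexp(30 * 12), 30, 12))
    fit <- nmf_factorize(V, rank = 3, seed = s, max_iter = 300)
    diffs <- diff(fit$trace)
    expect_true(all(diffs <= 1e-10 * (1 + abs(fit$trace[-length(fit$trace)]))))
  }
})

test_that("factorization rejects invalid inputs", {
  V <- matrix(1, 4, 3)
  expect_error(nmf_factorize(V, rank = 3), "smaller than")
  V0 <- matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE)
  expect_error(nmf_factorize(V0, rank = 1), "all-zero")
  Vn <- matrix(c(1, -1, 2, 3), 2, 2)
  expect_error(nmf_factorize(Vn, rank = 1), "non-negative")
})

test_that("run labels follow dominant-H with lowest-index ties", {
  fit <- structure(list(H = matrix(c(0.9, 0.1, 0.5, 0.5, 0.2, 0.8), 2, 3,
                                   dimnames = list(NULL, c("s1", "s2", "s3")))),
                   class = "nmf_fit")
  expect_equal(unname(run_labels(fit)), c(1, 1, 2))
  # consistent permutation of W and H rows permutes untied labels accordingly
  fit2 <- structure(list(H = matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2)[c(2, 1), ]),
                    class = "nmf_fit")
  expect_equal(unname(run_labels(fit2)), c(2, 1))
})

test_that("block-diagonal data yields block connectivity across many seeds", {
  V <- rbind(
    cbind(matrix(5, 2, 2), matrix(0, 2, 2)),
    cbind(matrix(0, 2, 2), matrix(7, 2, 2))
  ) + 0.01
  for (s in 1:20) {
    lab <- run_labels(nmf_factorize(V, rank = 2, seed = s, max_iter = 500))
    expect_equal(lab[1], lab[2])
    expect_equal(lab[3], lab[4])
    expect_false(lab[1] == lab[3])
  }
})

test_that("positive rescaling of V leaves run labels unchanged", {
  V <- withr::with_seed(2, matrix(rexp(40 * 10), 40, 10))
  l1 <- run_labels(nmf_factorize(V, rank = 2, seed = 4))
  l2 <- run_labels(nmf_factorize(100 * V, rank = 2, seed = 4))
  expect_equal(l1, l2)
})

test_that("consensus matrices satisfy their contract at every run count", {
  sim <- small_synthetic(seed = 4, genes = 100, markers = 6,
                         sizes = list(a = c(8, 8, 8)))
  V <- expr_values(sim$cohorts$a$matrix)
  for (n_runs in c(2L, 5L)) {
    cr <- run_consensus(V, rank = 2, n_runs = n_runs, seed = 1, patience = 3)
    cons <- cr$consensus
    expect_equal(cons, t(cons))
    expect_true(all(diag(cons) == 1))
    expect_true(all(cons >= 0 & cons <= 1))
    # entries are multiples of 1/n_runs
    expect_true(all(abs(cons * n_runs - round(cons * n_runs)) < 1e-12))
  }
})

test_that("perfectly separable blocks give a binary consensus and cophenetic 1", {
  V <- rbind(
    cbind(matrix(9, 3, 4), matrix(0.01, 3, 4)),
    cbind(matrix(0.01, 3, 4), matrix(9, 3, 4))
  )
  colnames(V) <- sprintf("s%d", 1:8)
  rownames(V) <- sprintf("g%d", 1:6)
  cr <- run_consensus(V, rank = 2, n_runs = 10, seed = 2, patience = 3)
  expect_true(all(cr$consensus %in% c(0, 1)))
  expect_equal(cr$cophenetic, 1.0)
  labs <- assign_final(cr)
  expect_length(unique(labs$label[1:4]), 1L)
  expect_length(unique(labs$label[5:8]), 1L)
  expect_false(labs$label[1] == labs$label[5])
})

test_that("cophenetic coefficient matches an independent average-linkage oracle", {
  cons <- matrix(c(1, .8, .2, .2,
                   .8, 1, .2, .2,
                   .2, .2, 1, .9,
                   .2, .2, .9, 1), 4, 4)
  expect_equal(cophenetic_coefficient(cons), oracle_cophenetic_cor(cons),
               tolerance = 1e-10)
  # degenerate: all off-diagonal distances equal
  flat <- matrix(0.5, 3, 3); diag(flat) <- 1
  expect_error(cophenetic_coefficient(flat), "undefined")
})

test_that("rank selection maximizes the across-cohort mean with low-rank ties", {
  p <- tibble::tibble(
    cohort = rep(c("A", "B"), each = 3),
    rank = rep(2:4, 2),
    cophenetic = c(.95, .99, .90, .93, .98, .91)
  )
  expect_equal(select_rank(p), 3L)
  single <- tibble::tibble(cohort = "A", rank = 2:4, cophenetic = c(.5, .4, .9))
  expect_equal(select_rank(single), 4L)
  tie <- tibble::tibble(cohort = "A", rank = 2:3, cophenetic = c(.9, .9))
  expect_equal(select_rank(tie), 2L)
  expect_error(select_rank(tibble::tibble()), "empty")
  bad <- tibble::tibble(cohort = c("A", "B"), rank = c(2, 3), cophenetic = c(.9, .9))
  expect_error(select_rank(bad), "share the rank grid")
})

test_that("final assignment is equivariant under sample permutation", {
  sim <- small_synthetic(seed = 10, genes = 120, markers = 8,
                         sizes = list(a = c(10, 10, 10)))
  V <- expr_values(sim$cohorts$a$matrix)
  cr <- run_consensus(V, rank = 3, n_runs = 10, seed = 3, patience = 3)
  labs <- named_labels(assign_final(cr))
  perm <- withr::with_seed(1, sample(ncol(V)))
  cr_p <- cr
  cr_p$consensus <- cr$consensus[perm, perm]
  labs_p <- named_labels(assign_final(cr_p))
  expect_equal(ari(labs, labs_p), 1) # same partition, possibly renamed
})

test_that("cross-cohort subtype matching recovers a planted permutation", {
  sim <- small_synthetic(seed = 6)
  a <- sim$cohorts$a
  # cohort B := cohort A with permuted label names
  perm_map <- c(`1` = "3", `2` = "1", `3` = "2")
  labels_b <- a$true_labels
  labels_b$label <- unname(perm_map[labels_b$label])
  m <- match_subtypes_across_cohorts(a$matrix, a$true_labels, a$matrix, labels_b)
  expect_equal(m$map[c("3", "1", "2")], c(`3` = "1", `1` = "2", `2` = "3"))
  expect_equal(m$labels_b$label, a$true_labels$label)
  # and across genuinely different cohorts sharing the marker structure
  b <- sim$cohorts$b
  m2 <- match_subtypes_across_cohorts(a$matrix, a$true_labels, b$matrix, b$true_labels)
  expect_equal(m2$labels_b$label, b$true_labels$label)

  two <- a$true_labels
  two$label[two$label == "3"] <- "2"
  expect_error(match_subtypes_across_cohorts(a$matrix, a$true_labels,
                                             a$matrix, two), "different ranks")
})
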