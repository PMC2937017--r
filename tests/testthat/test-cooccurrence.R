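test_that("score test reproduces the published worked example", {
  # 20q11 gain in 68/183, 19q12 gain in 50/183, both in 35: strong
  # positive co-occurrence, p < 0.0001
  ct <- counts_from_margins(35, 68, 50, 183)
  expect_equal(ct$n10, 33)
  expect_equal(ct$n01, 15)
  expect_equal(ct$n00, 100)
  st <- score_test(ct)
  expect_equal(st$direction, "positive")
  expect_lt(st$p, 1e-4)
  # oracle: brute-force Pearson chi-square on the printed margins
  expect_equal(st$z^2, 31.78, tolerance = 2e-4)
  expect_equal(st$z, 5.64, tolerance = 1e-3)
  expect_equal(st$p, 1.7e-8, tolerance = 0.02)
  # expected co-occurrence from the printed rounded marginals: 12%
  expect_equal(round(expected_cooccurrence(0.37, 0.33), 2), 0.12)
  expect_equal(expected_cooccurrence(0, 0.8), 0)
  expect_equal(expected_cooccurrence(0.5, 0.5), 0.25)
})

test_that("z is 0 at exact independence and NA at degenerate margins", {
  st <- score_test(counts_from_margins(25, 50, 50, 100))
  expect_equal(st$z, 0)
  expect_equal(st$p, 1)
  expect_equal(st$direction, "none")
  for (ct in list(counts_from_margins(0, 0, 50, 100),
                  counts_from_margins(50, 100, 50, 100))) {
    st <- score_test(ct)
    expect_false(st$testable)
    expect_true(is.na(st$z) && is.na(st$p))
  }
})

test_that("z^2 equals the textbook Pearson chi-square (oracle)", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(20:500, 1)
    nA <- sample(1:(n - 1), 1)
    nB <- sample(1:(n - 1), 1)
    n11 <- sample(max(0, nA + nB - n):min(nA, nB), 1)
    ct <- counts_from_margins(n11, nA, nB, n)
    st <- score_test(ct)
    tab <- matrix(c(ct$n11, ct$n10, ct$n01, ct$n00), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    chisq <- unname(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$statistic))
    # relative error < 1e-10, with an absolute floor for statistics
    # near 0 where the oracle's own summation noise dominates
    expect_lt(abs(st$z^2 - chisq), 1e-10 * max(1, chisq))
    # antisymmetry: swapping the roles of A and B changes nothing
    st2 <- score_test(counts_from_margins(n11, nB, nA, n))
    expect_equal(st2$z, st$z)
  }
})

test_that("BH adjustment matches the step-up formula and p.adjust", {
  # hand-applied step-up: [0.01, 0.02, 0.03] -> all 0.03
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.2), 0.2)               # m = 1: q = p
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
})

test_that("pair_associations ranks, corrects and flags properly", {
  set.seed(43)
  X <- matrix(rbinom(500 * 6, 1, 0.3), 500, 6,
              dimnames = list(NULL, paste0("R", 1:6)))
  X[, 2] <- X[, 1]            # identical columns dominate
  X[, 6] <- 0L                # degenerate margin
  res <- pair_associations(X)
  expect_equal(sort(c(res$a[1], res$b[1])), c("R1", "R2"))
  expect_equal(res$q[1], res$p[1] * sum(res$testable) /
                 1)  # top-ranked BH step
  untest <- res[!res$testable, ]
  expect_equal(nrow(untest), 5)
  expect_true(all(is.na(untest$q)))
  # single admissible pair: q = p
  one <- pair_associations(X[, 1:4],
                           data.frame(a = "R1", b = "R3"))
  expect_equal(one$q, one$p)
  # row permutation (sample relabelling) leaves statistics unchanged
  res2 <- pair_associations(X[sample(nrow(X)), ])
  expect_equal(res2$z, res$z)
  expect_equal(res2$q, res$q)
})

test_that("permutation test flags a perfect association", {
  set.seed(44)
  x <- rbinom(50, 1, 0.5)
  X <- cbind(A = x, B = x, C = rbinom(50, 1, 0.5))
  res <- permutation_test(X, B = 999, seed = 45)
  ab <- res[res$a == "A" & res$b == "B", ]
  expect_lte(ab$perm_p, 0.01)
  expect_lte(ab$perm_fdr, 0.05)
})

test_that("permutation p-values are calibrated under the null", {
  set.seed(46)
  X <- matrix(rbinom(60 * 12, 1, 0.4), 60, 12,
              dimnames = list(NULL, paste0("R", 1:12)))
  res <- permutation_test(X, B = 400, seed = 47)
  # null perm_p roughly uniform: mean near 0.5, few small values
  expect_gt(mean(res$perm_p), 0.40)
  expect_lt(mean(res$perm_p), 0.60)
  expect_lt(mean(res$perm_p <= 0.05), 0.2)
})

test_that("replication filter intersects selections with direction", {
  set.seed(48)
  sm <- simulate_matrix(800, 12, 4, or_range = c(4, 4),
                        freq_range = c(0.25, 0.4), seed = 49)
  X <- sm$X
  half1 <- X[seq(1, 800, 2), ]
  half2 <- X[seq(2, 800, 2), ]
  r1 <- pair_associations(half1)
  r2 <- pair_associations(half2)
  # identical result sets: intersection equals each selection
  self <- replicate_associations(r1, r1)
  expect_equal(nrow(self), nrow(selected_pairs(r1)))
  # split-cohort recovery: all 4 planted OR=4 pairs replicate at
  # n = 400 per half
  rep <- replicate_associations(r1, r2)
  keys <- cnassoc:::.pair_key(sm$planted$a, sm$planted$b)
  expect_true(all(keys %in% cnassoc:::.pair_key(rep$a, rep$b)))
  expect_true(all(rep$direction[cnassoc:::.pair_key(rep$a, rep$b)
                                %in% keys] == "positive"))
  # mismatched universes error
  expect_error(replicate_associations(r1, r2[-1, ]), "universes")
})

test_that("planted pairs are detected with high sensitivity at n=380", {
  # parameter recovery: OR >= 3, base frequencies 0.15-0.4, full cohort
  hits <- total <- 0
  for (r in 1:10) {
    sm <- simulate_matrix(380, 30, 10, or_range = c(3, 5),
                          freq_range = c(0.15, 0.4), seed = 4100 + r)
    sel <- selected_pairs(pair_associations(sm$X), 0.05)
    keys <- cnassoc:::.pair_key(sm$planted$a, sm$planted$b)
    hits <- hits + sum(keys %in% cnassoc:::.pair_key(sel$a, sel$b))
    total <- total + length(keys)
  }
  expect_gte(hits / total, 0.9)
})

test_that("method agreement is honest set arithmetic", {
  expect_equal(method_agreement(c("x", "y"), c("x", "y"))$jaccard, 1)
  expect_equal(method_agreement(character(), character())$jaccard, 1)
  expect_equal(method_agreement(c("x"), c("y"))$jaccard, 0)
  m <- method_agreement(c("1", "2", "3"), c("2", "3", "4"))
  expect_equal(m$jaccard, 0.5)
  expect_equal(m$frac_a, 2 / 3)
  expect_equal(m$n_common, 2)
})
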