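test_that("dissimilarity matches hand arithmetic and is a bounded metric-like score", {
  expect_identical(delta_dissimilarity(c(5, 3, 2), c(5, 3, 2)), 0)
  expect_identical(delta_dissimilarity(c(10, 0), c(0, 10)), 2)
  # heart-looping WT vs triple mutant frequencies:
  # |0.8843 - 0.3817| + |0.1157 - 0.2595| + |0 - 0.3588|
  expect_equal(delta_dissimilarity(c(107, 14, 0), c(50, 34, 47)), 1.0052,
               tolerance = 1e-4)

  set.seed(11)
  for (i in 1:50) {
    m <- sample(2:5, 1)
    a <- as.vector(rmultinom(1, sample(5:60, 1), runif(m)))
    b <- as.vector(rmultinom(1, sample(5:60, 1), runif(m)))
    d <- delta_dissimilarity(a, b)
    expect_gte(d, 0)
    expect_lte(d, 2)
    expect_identical(d, delta_dissimilarity(b, a))
    ta <- outcome_table("a", paste0("c", seq_len(m)), a)
    tb <- outcome_table("b", paste0("c", seq_len(m)), b)
    expect_identical(d, delta_dissimilarity(ta, tb))
  }
})

test_that("dissimilarity rejects mismatched or empty inputs", {
  expect_error(delta_dissimilarity(c(1, 2), c(1, 2, 3)), "categories")
  expect_error(delta_dissimilarity(c(0, 0), c(1, 2)), "positive total")
  wt <- outcome_table("WT", c("a", "b"), c(3, 4))
  mu <- outcome_table("mut", c("b", "a"), c(3, 4))
  expect_error(delta_dissimilarity(wt, mu), "order")
})

test_that("permutation test is exact on degenerate tables and reproducible", {
  r <- permutation_test(c(5, 5), c(5, 5), n_resamples = 500, seed = 1)
  expect_identical(r$p_value, 1)
  expect_false(r$is_lower_bound)

  r1 <- permutation_test(c(8, 2, 1), c(2, 7, 3), n_resamples = 4000, seed = 7)
  r2 <- permutation_test(c(8, 2, 1), c(2, 7, 3), n_resamples = 4000, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$exceedances, r2$exceedances)
  expect_identical(r1$is_lower_bound, r1$exceedances == 0L)

  expect_error(permutation_test(c(1, 2), c(1, 2), n_resamples = 0), "positive")
  expect_error(permutation_test(c(1, 2), c(1, 2, 3)), "categories")
})

test_that("Monte-Carlo permutation p agrees with full-enumeration oracle", {
  # microexample with disjoint support: all C(6,3) = 20 splits enumerable
  p_exact <- perm_exact_p(c(3, 0), c(0, 3))
  expect_equal(p_exact, 2 / 20) # only the two fully-separated splits reach delta = 2
  r <- permutation_test(c(3, 0), c(0, 3), n_resamples = 2000, seed = 3)
  se <- sqrt(p_exact * (1 - p_exact) / 2000)
  expect_lt(abs(r$p_value - p_exact), 3 * se + 1e-12)

  # Across every small table the Monte-Carlo exceedance count must be
  # statistically consistent with the enumerated p: the exact binomial
  # two-sided tail probability of the observed count stays above 1e-6
  # (a Bonferroni-aware bound for the ~4600 cases checked here; the
  # 3-standard-error claim is asserted on a fixed case set elsewhere).
  binom_tail <- function(x, size, prob) {
    min(stats::pbinom(x, size, prob), stats::pbinom(x - 1, size, prob,
                                                    lower.tail = FALSE))
  }
  # every 2-category table with pooled total <= 10
  case <- 0L
  for (na in 1:9) for (nb in 1:(10 - na)) {
    for (a1 in 0:na) for (b1 in 0:nb) {
      case <- case + 1L
      a <- c(a1, na - a1); b <- c(b1, nb - b1)
      pe <- perm_exact_p(a, b)
      r <- permutation_test(a, b, n_resamples = 2000, seed = case)
      expect_gt(binom_tail(r$exceedances, 2000, pe), 1e-6)
    }
  }

  # every 3-category table with pooled total <= 7
  for (na in 1:6) for (nb in 1:(7 - na)) {
    ca <- compositions(na, 3L)
    cb <- compositions(nb, 3L)
    for (i in seq_len(nrow(ca))) for (j in seq_len(nrow(cb))) {
      case <- case + 1L
      pe <- perm_exact_p(ca[i, ], cb[j, ])
      r <- permutation_test(ca[i, ], cb[j, ], n_resamples = 2000, seed = case)
      expect_gt(binom_tail(r$exceedances, 2000, pe), 1e-6)
    }
  }
})

test_that("count reconstruction inverts two-decimal percentage printing", {
  r <- reconstruct_counts(c(88.43, 11.57), known_total = 121)
  expect_identical(r$counts, c(107L, 14L))

  r2 <- reconstruct_counts(c(93.84, 4.79, 1.37))
  expect_identical(r2$total, 146L)
  expect_identical(r2$counts, c(137L, 7L, 2L))

  r3 <- reconstruct_counts(c(100, 0), known_total = 10)
  expect_identical(r3$counts, c(10L, 0L))

  # round-trip property: percentages printed from random counts reconstruct
  # to counts with identical two-decimal percentages
  set.seed(5)
  for (i in 1:25) {
    n <- sample(20:400, 1)
    k <- as.vector(rmultinom(1, n, runif(3)))
    pct <- round(100 * k / n, 2)
    if (abs(sum(pct) - 100) > 0.02) next # printing artefact out of contract
    rec <- reconstruct_counts(pct, known_total = n)
    expect_equal(round(100 * rec$counts / n, 2), pct)
  }

  expect_error(reconstruct_counts(c(60, 30)), "sum")
  expect_error(reconstruct_counts(c(74.21, 21.38, 4.41), known_total = 104),
               "no integer counts")

  # complement-derived final percentage: 4.41 = 100 - 74.21 - 21.38 exactly,
  # while the frequency itself prints as 4.40 (7/159); the strict window
  # over-shoots to an implausible N, the complement-aware window does not
  strict <- reconstruct_counts(c(74.21, 21.38, 4.41))
  expect_identical(strict$total, 725L)
  comp <- reconstruct_counts(c(74.21, 21.38, 4.41), complement_last = TRUE)
  expect_identical(comp$total, 159L)
  expect_identical(comp$counts, c(118L, 34L, 7L))
})

test_that("uniform-prior binomial posterior has the closed-form moments", {
  p0 <- binomial_posterior(0, 1)
  expect_identical(p0$mle, 0)
  expect_identical(c(p0$alpha_post, p0$beta_post), c(1L, 2L))
  expect_equal(p0$posterior_mean, 1 / 3)

  p1 <- binomial_posterior(119, 182)
  expect_equal(p1$mle, 0.6538, tolerance = 1e-4)
  expect_equal(p1$posterior_sd, 0.0350, tolerance = 1e-3)

  # shrinkage bound: |posterior mean - mle| <= 1/(n + 2)
  set.seed(2)
  for (i in 1:30) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    p <- binomial_posterior(k, n)
    expect_lte(abs(p$posterior_mean - p$mle), 1 / (n + 2) + 1e-12)
    expect_true(all(p$interval >= 0 & p$interval <= 1))
  }

  expect_error(binomial_posterior(5, 4), "k <= n")
  expect_error(binomial_posterior(0, 0), "k <= n")
})

test_that("Fisher exact p matches brute-force enumeration and fisher.test", {
  expect_identical(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2))$p_two_sided, 1)
  expect_equal(fisher_exact_two_sided(matrix(c(3, 1, 1, 3), 2))$p_two_sided, 34 / 70)

  # all 2x2 tables with total <= 12 and positive margins
  for (n in 2:12) {
    tabs <- compositions(n, 4L)
    for (i in seq_len(nrow(tabs))) {
      tab <- matrix(tabs[i, ], 2, 2, byrow = TRUE)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
      p <- fisher_exact_two_sided(tab)$p_two_sided
      expect_equal(p, fisher_brute_p(tab), tolerance = 1e-12)
      expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
      expect_equal(p, fisher_exact_two_sided(t(tab))$p_two_sided, tolerance = 1e-12)
    }
  }

  expect_error(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})
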