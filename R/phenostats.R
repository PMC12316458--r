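#' Dissimilarity between two multinomial outcome distributions
#'
#' Computes the dissimilarity
#' \deqn{\delta = \sum_c | k_{a,c}/N_a - k_{b,c}/N_b |,}
#' the sum over outcome categories of absolute differences between the two
#' empirical frequency vectors. This equals twice the total-variation
#' distance between the empirical distributions, so \eqn{\delta \in [0, 2]}:
#' 0 for identical distributions, 2 for disjoint support.
#'
#' @param counts_a,counts_b Non-negative integer count vectors over the same
#'   ordered categories, or `outcome_table` objects. Each must have a
#'   positive total.
#'
#' @return The dissimilarity, a single number in \[0, 2\].
#' @examples
#' delta_dissimilarity(c(107, 14, 0), c(50, 34, 47))
#' @seealso [permutation_test()]
#' @export
delta_dissimilarity <- function(counts_a, counts_b) {
  cc <- .check_comparable(counts_a, counts_b)
  na <- sum(cc$a)
  nb <- sum(cc$b)
  if (na < 1L || nb < 1L) stop("each condition needs a positive total count", call. = FALSE)
  sum(abs(cc$a / na - cc$b / nb))
}

#' Pooled-resplit permutation test for two multinomial outcome distributions
#'
#' Tests the null hypothesis that two conditions share the same multinomial
#' outcome distribution. The observed dissimilarity \eqn{\delta}
#' ([delta_dissimilarity()]) is compared against its permutation null: all
#' \eqn{N_a + N_b} observations are pooled and repeatedly re-split at random
#' (without replacement) into groups of the original sizes \eqn{N_a} and
#' \eqn{N_b}, recomputing the dissimilarity \eqn{\delta'} each time. The
#' p-value is the frequency of resamples with \eqn{\delta' \ge \delta}
#' (ties count as exceedances).
#'
#' Re-splitting pooled categorical observations without replacement is a
#' multivariate hypergeometric draw of the group-a category counts, which is
#' what the implementation samples (vectorised over resamples); this is
#' exact, not an approximation to the label-shuffling formulation.
#'
#' When no resample reaches \eqn{\delta}, the p-value is reported as a bound
#' `p < 1/K` via `is_lower_bound` rather than as 0.
#'
#' @param table_a,table_b `outcome_table` objects or bare count vectors over
#'   the same ordered categories.
#' @param n_resamples Number of random re-splits K (default 100000).
#' @param seed Integer seed; the result is reproducible for a fixed seed.
#'
#' @return An object of class `perm_test`: list with `delta_observed`,
#'   `n_resamples`, `exceedances`, `p_value` (= exceedances / K),
#'   `is_lower_bound` (TRUE iff exceedances is 0, in which case the honest
#'   report is p < 1/K), and `seed`.
#' @examples
#' wt <- outcome_table("WT", c("D", "mild", "S"), c(107, 14, 0))
#' het <- outcome_table("het", c("D", "mild", "S"), c(155, 26, 1))
#' permutation_test(wt, het, n_resamples = 10000, seed = 1)
#' @export
permutation_test <- function(table_a, table_b, n_resamples = 100000L, seed = 1L) {
  if (length(n_resamples) != 1L || !is.finite(n_resamples) || n_resamples < 1) {
    stop("`n_resamples` must be a positive integer", call. = FALSE)
  }
  n_resamples <- as.integer(n_resamples)
  cc <- .check_comparable(table_a, table_b)
  a <- cc$a
  b <- cc$b
  na <- sum(a)
  nb <- sum(b)
  if (na < 1L || nb < 1L) stop("each condition needs a positive total count", call. = FALSE)
  delta_obs <- sum(abs(a / na - b / nb))

  pool <- a + b
  m <- length(pool)
  set.seed(seed)
  # Sequential-conditional multivariate hypergeometric draw of the group-a
  # counts, vectorised across the K resamples.
  amat <- matrix(0, nrow = m, ncol = n_resamples)
  rem_draw <- rep.int(na, n_resamples)
  rem_tot <- na + nb
  for (c_i in seq_len(m - 1L)) {
    k_c <- stats::rhyper(n_resamples, pool[c_i], rem_tot - pool[c_i], rem_draw)
    amat[c_i, ] <- k_c
    rem_draw <- rem_draw - k_c
    rem_tot <- rem_tot - pool[c_i]
  }
  amat[m, ] <- rem_draw
  deltas <- colSums(abs(amat / na - (pool - amat) / nb))
  # ties delta' == delta count as exceedances; small slack guards float noise
  exceed <- sum(deltas >= delta_obs - 1e-12)

  structure(
    list(
      delta_observed = delta_obs,
      n_resamples = n_resamples,
      exceedances = exceed,
      p_value = exceed / n_resamples,
      is_lower_bound = exceed == 0L,
      seed = as.integer(seed),
      condition_a = if (inherits(table_a, "outcome_table")) table_a$condition else NA_character_,
      condition_b = if (inherits(table_b, "outcome_table")) table_b$condition else NA_character_
    ),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat("Pooled-resplit permutation test\n")
  if (!is.na(x$condition_a)) {
    cat("  conditions:", x$condition_a, "vs", x$condition_b, "\n")
  }
  cat(sprintf("  delta = %.4f,  K = %d,  exceedances = %d\n",
              x$delta_observed, x$n_resamples, x$exceedances))
  if (x$is_lower_bound) {
    cat(sprintf("  p < %g\n", 1 / x$n_resamples))
  } else {
    cat(sprintf("  p = %g\n", x$p_value))
  }
  invisible(x)
}

#' Reconstruct integer counts from printed percentages
#'
#' Published phenotype tables often print per-category percentages to two
#' decimals without the underlying counts. This searches for the smallest
#' total N (or validates a stated N) such that non-negative integers
#' \eqn{k_c} summing to N reproduce every printed percentage to within half
#' a unit in the last printed decimal, i.e.
#' \eqn{|100 k_c / N - p_c| < 0.005}.
#'
#' @param percentages Numeric vector of printed percentages (two decimals);
#'   must sum to 100 within 0.02.
#' @param max_total Largest total to consider (default 1000).
#' @param known_total Optional stated total N; when given, only that N is
#'   checked and an error is raised if it is inconsistent with the
#'   percentages.
#' @param complement_last Treat the final percentage as complement-derived:
#'   published tables sometimes print the last category as
#'   100 minus the other printed (already rounded) percentages instead of
#'   rounding its own frequency, so it accumulates the others' rounding
#'   error. When `TRUE`, the last category's tolerance is widened to half a
#'   unit per printed value (`0.005 * m`) while the others keep the strict
#'   window.
#'
#' @return List with `counts` (integer vector), `total` (the N used) and
#'   `percent_check` (the percentages implied by the counts).
#' @examples
#' reconstruct_counts(c(88.43, 11.57, 0), known_total = 121)
#' reconstruct_counts(c(93.84, 4.79, 1.37))
#' @export
reconstruct_counts <- function(percentages, max_total = 1000L, known_total = NULL,
                               complement_last = FALSE) {
  p <- as.numeric(percentages)
  m <- length(p)
  if (m < 1L || any(!is.finite(p)) || any(p < 0)) {
    stop("`percentages` must be non-negative finite numbers", call. = FALSE)
  }
  if (abs(sum(p) - 100) > 0.02) {
    stop(sprintf("percentages sum to %.4f, not 100 (+/- 0.02)", sum(p)), call. = FALSE)
  }
  if (max_total < m) stop("`max_total` smaller than the number of categories", call. = FALSE)
  tol_base <- 0.005 - 1e-9  # strict half-unit-in-last-decimal window
  tols <- rep(tol_base, m)
  if (complement_last) tols[m] <- 0.005 * m - 1e-9

  candidates <- if (is.null(known_total)) seq_len(max_total) else as.integer(known_total)
  best_miss <- Inf
  best_n <- NA_integer_
  for (n in candidates) {
    lo <- integer(m)
    hi <- integer(m)
    ok <- TRUE
    for (c_i in seq_len(m)) {
      ks <- round(p[c_i] * n / 100) + (-2L:2L)
      ks <- ks[ks >= 0 & ks <= n & abs(100 * ks / n - p[c_i]) < tols[c_i]]
      if (length(ks) == 0L) {
        miss <- min(abs(100 * (0:n) / n - p[c_i]))
        best_here <- miss
        if (best_here < best_miss) { best_miss <- best_here; best_n <- n }
        ok <- FALSE
        break
      }
      lo[c_i] <- min(ks)
      hi[c_i] <- max(ks)
    }
    if (!ok) next
    if (sum(lo) > n || sum(hi) < n) {
      miss <- min(abs(sum(lo) - n), abs(sum(hi) - n)) * 100 / n
      if (miss < best_miss) { best_miss <- miss; best_n <- n }
      next
    }
    # feasible: raise entries from their minima until the sum reaches n
    k <- as.integer(lo)
    slack <- n - sum(lo)
    for (c_i in seq_len(m)) {
      if (slack <= 0L) break
      bump <- min(hi[c_i] - lo[c_i], slack)
      k[c_i] <- k[c_i] + bump
      slack <- slack - bump
    }
    return(list(counts = k, total = as.integer(n),
                percent_check = round(100 * k / n, 2)))
  }
  if (!is.null(known_total)) {
    stop(sprintf(
      "no integer counts with total N = %d reproduce the printed percentages (closest miss %.4f%%)",
      known_total, best_miss), call. = FALSE)
  }
  stop(sprintf(
    "no consistent total N <= %d found (closest miss %.4f%% at N = %d)",
    max_total, best_miss, best_n), call. = FALSE)
}

#' Uniform-prior posterior for a binomial malformation probability
#'
#' Treats each scored embryo as a Bernoulli outcome (malformed vs normal)
#' with condition-specific probability q. With a uniform Beta(1, 1) prior,
#' observing k malformed out of n gives the posterior
#' \deqn{q \mid k, n \sim \mathrm{Beta}(k + 1,\; n - k + 1).}
#' The maximum-likelihood estimate is the empirical frequency k/n; the
#' posterior standard deviation provides the uncertainty interval
#' (mean +/- sd, clipped to \[0, 1\]).
#'
#' @param k Number of malformed outcomes (0 <= k <= n).
#' @param n Total number of scored outcomes (n >= 1).
#'
#' @return An object of class `binomial_posterior`: list with `k`, `n`,
#'   `mle`, `alpha_post`, `beta_post`, `posterior_mean`, `posterior_sd` and
#'   `interval` (length-2 vector).
#' @examples
#' binomial_posterior(119, 182)
#' @export
binomial_posterior <- function(k, n) {
  if (length(k) != 1L || length(n) != 1L || !is.finite(k) || !is.finite(n)) {
    stop("`k` and `n` must be single finite numbers", call. = FALSE)
  }
  if (n < 1 || k < 0 || k > n || abs(k - round(k)) > 1e-8 || abs(n - round(n)) > 1e-8) {
    stop("need integers 0 <= k <= n with n >= 1", call. = FALSE)
  }
  k <- as.integer(round(k)); n <- as.integer(round(n))
  a <- k + 1L
  b <- n - k + 1L
  post_mean <- a / (a + b)
  post_sd <- sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  interval <- pmin(pmax(post_mean + c(-1, 1) * post_sd, 0), 1)
  structure(
    list(
      k = k, n = n,
      mle = k / n,
      alpha_post = a, beta_post = b,
      posterior_mean = post_mean,
      posterior_sd = post_sd,
      interval = interval
    ),
    class = "binomial_posterior"
  )
}

#' @export
print.binomial_posterior <- function(x, ...) {
  cat(sprintf("Beta-binomial posterior: k = %d / n = %d\n", x$k, x$n))
  cat(sprintf("  MLE = %.4f (%.2f%%)\n", x$mle, 100 * x$mle))
  cat(sprintf("  posterior Beta(%d, %d): mean = %.4f, sd = %.4f\n",
              x$alpha_post, x$beta_post, x$posterior_mean, x$posterior_sd))
  cat(sprintf("  interval (mean +/- sd): [%.4f, %.4f]\n",
              x$interval[1], x$interval[2]))
  invisible(x)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value for independence in a 2x2 contingency table under
#' the point-probability convention: conditioning on the margins, the
#' p-value is the sum of hypergeometric probabilities of all tables whose
#' point probability does not exceed that of the observed table. No
#' asymptotic approximation is used.
#'
#' @param table 2x2 matrix (or length-4 vector, filled by row) of
#'   non-negative integer counts; both margins must be positive.
#'
#' @return An object of class `fisher_result`: list with `table` and
#'   `p_two_sided`.
#' @examples
#' fisher_exact_two_sided(matrix(c(188, 14, 63, 119), 2, byrow = TRUE))
#' @export
fisher_exact_two_sided <- function(table) {
  if (is.vector(table) && length(table) == 4L) {
    table <- matrix(table, nrow = 2L, byrow = TRUE)
  }
  if (!is.matrix(table) || !all(dim(table) == c(2L, 2L))) {
    stop("`table` must be a 2x2 matrix", call. = FALSE)
  }
  if (any(!is.finite(table)) || any(table < 0) ||
      any(abs(table - round(table)) > 1e-8)) {
    stop("`table` must hold non-negative integers", call. = FALSE)
  }
  tab <- matrix(as.integer(round(table)), 2L, 2L)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    stop("degenerate table: every row and column margin must be positive", call. = FALSE)
  }
  r1 <- sum(tab[1L, ])
  c1 <- sum(tab[, 1L])
  n <- sum(tab)
  supp <- max(0L, r1 + c1 - n):min(r1, c1)
  # log-scale point probabilities for numerical stability at large counts
  logp <- stats::dhyper(supp, c1, n - c1, r1, log = TRUE)
  logp_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1, log = TRUE)
  sel <- logp <= logp_obs + 1e-7
  p <- sum(exp(logp[sel]))
  structure(
    list(table = tab, p_two_sided = min(p, 1)),
    class = "fisher_result"
  )
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher exact test (two-sided, point-probability convention)\n")
  print(x$table)
  cat(sprintf("  p = %g\n", x$p_two_sided))
  invisible(x)
}
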