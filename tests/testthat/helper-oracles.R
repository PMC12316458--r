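# Independent brute-force oracles used to validate the fast implementations.

# Exact permutation p-value by full enumeration of every way to split the
# pooled category counts into groups of sizes Na and Nb. The group-a counts
# follow a multivariate hypergeometric law; each split's weight is a product
# of binomial coefficients over choose(N, Na).
perm_exact_p <- function(counts_a, counts_b) {
  na <- sum(counts_a)
  nb <- sum(counts_b)
  pool <- counts_a + counts_b
  m <- length(pool)
  delta_obs <- sum(abs(counts_a / na - counts_b / nb))

  splits <- list(integer(0))
  for (c_i in seq_len(m)) {
    splits <- unlist(lapply(splits, function(pref) {
      left <- na - sum(pref)
      lo <- max(0L, left - sum(pool[-seq_len(c_i)])) # can't overdraw later cats
      hi <- min(pool[c_i], left)
      if (hi < lo) return(list())
      lapply(lo:hi, function(k) c(pref, k))
    }), recursive = FALSE)
  }
  p <- 0
  total_lw <- lchoose(na + nb, na)
  for (a_split in splits) {
    if (sum(a_split) != na) next
    d <- sum(abs(a_split / na - (pool - a_split) / nb))
    if (d >= delta_obs - 1e-12) {
      p <- p + exp(sum(lchoose(pool, a_split)) - total_lw)
    }
  }
  min(max(p, 0), 1)
}

# Exact two-sided Fisher p by enumerating every 2x2 table with the observed
# margins and summing the point probabilities (computed directly from
# factorials, independently of dhyper) of tables no more probable than the
# observed one.
fisher_brute_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  n <- r1 + r2
  point_logp <- function(x) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(x) - lfactorial(r1 - x) -
      lfactorial(c1 - x) - lfactorial(r2 - c1 + x)
  }
  supp <- max(0L, c1 - r2):min(r1, c1)
  lps <- vapply(supp, point_logp, numeric(1))
  lobs <- point_logp(tab[1, 1])
  sum(exp(lps[lps <= lobs + 1e-7]))
}

# All ways to write total n as an ordered sum of m non-negative integers.
compositions <- function(n, m) {
  if (m == 1L) return(matrix(n, ncol = 1L))
  out <- list()
  for (k in 0:n) {
    rest <- compositions(n - k, m - 1L)
    out[[length(out) + 1L]] <- cbind(k, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}
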