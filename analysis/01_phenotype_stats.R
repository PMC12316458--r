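#!/usr/bin/env Rscript

# Left-right phenotype statistics from the published count tables.
#
# Reconstructs integer counts from the printed two-decimal percentages,
# cross-checks the printed header totals, runs the pooled-resplit
# permutation test on every genotype-vs-control comparison, and computes
# the uniform-prior posterior and Fisher tests for the DFC clustering
# outcomes. Outputs land in results/.

suppressPackageStartupMessages(library(lrflow))
dir.create("results", showWarnings = FALSE)
K <- 100000L

cat("== Heart looping outcomes (D-loop / mild-no-loop / S-loop) ==\n")
heart_pct <- list(
  WT            = list(pct = c(88.43, 11.57, 0),     printed_n = 121L),
  `metrn-/-`    = list(pct = c(61.19, 29.10, 8.21),  printed_n = 131L),
  `metrnla-/-`  = list(pct = c(28.85, 51.92, 19.23), printed_n = 104L),
  `metrnlb-/-`  = list(pct = c(74.21, 21.38, 4.41),  printed_n = 104L),
  triplMut      = list(pct = c(38.17, 25.95, 35.88), printed_n = 134L),
  `triplMut+/-` = list(pct = c(85.16, 14.29, 0.55),  printed_n = 182L)
)
# The metrn-/- row's percentages sum to 98.50: they were evidently computed
# against a denominator other than the true total. Recover counts by finding
# the denominator d for which every printed percentage is k/d to half-ULP,
# without constraining the percentages to sum to 100.
reconstruct_with_denominator <- function(pct, max_denom = 400L) {
  for (d in 2:max_denom) {
    k <- round(pct * d / 100)
    if (all(abs(100 * k / d - pct) < 0.005) && all(k >= 0)) {
      return(list(counts = as.integer(k), total = sum(as.integer(k)),
                  denominator = d))
    }
  }
  stop("no consistent denominator found")
}

heart <- list()
for (g in names(heart_pct)) {
  row <- heart_pct[[g]]
  if (abs(sum(row$pct) - 100) > 0.02) {
    rec <- reconstruct_with_denominator(row$pct)
    cat(sprintf("  %-13s percentages sum to %.2f%%: computed against denominator %d;\n",
                g, sum(row$pct), rec$denominator))
  } else {
    rec <- tryCatch(reconstruct_counts(row$pct), error = function(e) NULL)
    if (is.null(rec) || rec$total > 400L) {
      # last percentage likely derived as the complement of the others
      rec <- reconstruct_counts(row$pct, complement_last = TRUE)
    }
  }
  flag <- if (rec$total != row$printed_n) " <-- header N disagrees with percentages" else ""
  cat(sprintf("  %-13s printed N=%3d, percentage-consistent N=%3d, counts (%s)%s\n",
              g, row$printed_n, rec$total, paste(rec$counts, collapse = ", "), flag))
  heart[[g]] <- rec
}
cat("  (the metrn-/- and triplMut header totals appear swapped; metrnlb-/- is\n",
    "  consistent only with N=159, its last percentage being complement-derived)\n")

cat("\n== Permutation tests, K =", K, "==\n")
comparisons <- list(
  c("WT", "triplMut"), c("WT", "metrn-/-"), c("WT", "metrnla-/-"),
  c("WT", "metrnlb-/-"), c("WT", "triplMut+/-"), c("triplMut+/-", "metrnlb-/-")
)
perm_rows <- do.call(rbind, lapply(seq_along(comparisons), function(i) {
  cmp <- comparisons[[i]]
  r <- permutation_test(heart[[cmp[1]]]$counts, heart[[cmp[2]]]$counts,
                        n_resamples = K, seed = 1000L + i)
  p_txt <- if (r$is_lower_bound) sprintf("< %g", 1 / K) else sprintf("%g", r$p_value)
  cat(sprintf("  %-13s vs %-13s delta = %.4f  p %s\n", cmp[1], cmp[2],
              r$delta_observed, p_txt))
  data.frame(condition_a = cmp[1], condition_b = cmp[2],
             delta = r$delta_observed, n_resamples = K,
             exceedances = r$exceedances, p_value = r$p_value,
             is_lower_bound = r$is_lower_bound)
}))

cat("\n== Visceral organ positioning (asymmetry / symmetry / heterotaxy) ==\n")
wt_v <- reconstruct_counts(c(93.84, 4.79, 1.37))
mu_v <- reconstruct_counts(c(100 - 10.49 - 9.88, 10.49, 9.88))
cat(sprintf("  WT N=%d counts (%s); triplMut N=%d counts (%s)\n",
            wt_v$total, paste(wt_v$counts, collapse = ", "),
            mu_v$total, paste(mu_v$counts, collapse = ", ")))
rv <- permutation_test(wt_v$counts, mu_v$counts, n_resamples = K, seed = 2000L)
cat(sprintf("  WT vs triplMut: delta = %.4f, p = %g\n", rv$delta_observed, rv$p_value))
perm_rows <- rbind(perm_rows, data.frame(
  condition_a = "WT (visceral)", condition_b = "triplMut (visceral)",
  delta = rv$delta_observed, n_resamples = K, exceedances = rv$exceedances,
  p_value = rv$p_value, is_lower_bound = rv$is_lower_bound))
write.csv(perm_rows, "results/permutation_tests.csv", row.names = FALSE)

cat("\n== DFC clustering defects: posteriors and Fisher tests ==\n")
clust <- list(
  WT            = c(defect = 14L,  n = 202L),
  `metrn-/-`    = c(defect = 51L,  n = 140L),
  `metrnla-/-`  = c(defect = 130L, n = 245L),
  triplMut      = c(defect = 119L, n = 182L),
  `triplMut+/-` = c(defect = 25L,  n = 122L)  # printed N=140 is inconsistent;
                                              # 20.49/79.51 identify N=122
)
post_rows <- do.call(rbind, lapply(names(clust), function(g) {
  k <- clust[[g]]["defect"]; n <- clust[[g]]["n"]
  p <- binomial_posterior(k, n)
  cat(sprintf("  %-13s k/n = %3d/%3d  MLE %.4f  posterior %.4f +/- %.4f\n",
              g, k, n, p$mle, p$posterior_mean, p$posterior_sd))
  data.frame(genotype = g, k = p$k, n = p$n, mle = p$mle,
             posterior_mean = p$posterior_mean, posterior_sd = p$posterior_sd,
             lo = p$interval[1], hi = p$interval[2])
}))
write.csv(post_rows, "results/clustering_posteriors.csv", row.names = FALSE)

fisher_rows <- do.call(rbind, lapply(
  list(c("WT", "metrn-/-"), c("WT", "metrnla-/-"), c("WT", "triplMut"),
       c("triplMut", "triplMut+/-")),
  function(cmp) {
    a <- clust[[cmp[1]]]; b <- clust[[cmp[2]]]
    tab <- matrix(c(a["n"] - a["defect"], a["defect"],
                    b["n"] - b["defect"], b["defect"]), 2, byrow = TRUE)
    fr <- fisher_exact_two_sided(tab)
    cat(sprintf("  Fisher %-13s vs %-13s p = %.3g\n", cmp[1], cmp[2], fr$p_two_sided))
    data.frame(condition_a = cmp[1], condition_b = cmp[2],
               p_two_sided = fr$p_two_sided)
  }))
cat("  (computed on the pooled tables; the published per-comparison values\n",
    "  appear to derive from per-batch replicates and differ)\n")
write.csv(fisher_rows, "results/clustering_fisher.csv", row.names = FALSE)

cat("\nWrote results/permutation_tests.csv, results/clustering_posteriors.csv,",
    "results/clustering_fisher.csv\n")
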