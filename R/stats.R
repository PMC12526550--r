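# Paired statistical comparison of two detectors on a shared test set.

#' McNemar's test on discordant outcomes
#'
#' Compares two classifiers evaluated on the same items using only the
#' discordant counts: `b` items where A is correct and B wrong, `c` where A
#' is wrong and B correct. The default continuity-corrected chi-square
#' statistic is `(max(|b - c| - 1, 0))^2 / (b + c)` with 1 df; the exact
#' mode uses the two-sided binomial tail
#' `min(1, 2 P(X <= min(b, c)))`, `X ~ Binomial(b + c, 1/2)`.
#'
#' @param b,c Nonnegative discordant counts.
#' @param mode `"cc"` (continuity-corrected chi-square, default) or
#'   `"exact"` (binomial).
#' @return List with `statistic`, `p_value`, `mode`, `b`, `c`.
#' @examples
#' mcnemar(34, 13) # p ~ 0.0035
#' @export
mcnemar <- function(b, c, mode = c("cc", "exact")) {
  mode <- match.arg(mode)
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stop("`b` and `c` must be nonnegative integers")
  }
  if (b + c == 0) {
    warning("no discordant pairs; p = 1")
    return(list(statistic = 0, p_value = 1, mode = mode, b = b, c = c))
  }
  if (mode == "cc") {
    stat <- max(abs(b - c) - 1, 0)^2 / (b + c)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    k <- min(b, c)
    stat <- k
    p <- min(1, 2 * stats::pbinom(k, b + c, 0.5))
  }
  list(statistic = stat, p_value = p, mode = mode, b = b, c = c)
}

# Discordant counts from per-item correctness vectors.
discordant_counts <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) {
    stop("correctness vectors must have equal length")
  }
  list(b = sum(correct_a & !correct_b), c = sum(!correct_a & correct_b),
       n = length(correct_a))
}

#' Bootstrap confidence interval for an accuracy difference
#'
#' Resamples test-set indices with replacement; each replicate recomputes
#' `accuracy(A) - accuracy(B)` on the resampled items. Returns the observed
#' difference, the mean of the bootstrap replicates, and the percentile
#' interval, all in percentage points.
#'
#' @param correct_a,correct_b Logical per-item correctness of the two
#'   models on the same test items.
#' @param n_boot Number of replicates (default 10000).
#' @param level Confidence level in (0, 1), default 0.95.
#' @param seed Integer seed for reproducibility.
#' @return List with `diff` (observed, pct points), `boot_mean`, `ci`
#'   (length-2), `level`, `n_boot`.
#' @export
bootstrap_accuracy_diff <- function(correct_a, correct_b, n_boot = 10000L,
                                    level = 0.95, seed = NULL) {
  if (level <= 0 || level >= 1) stop("`level` must lie in (0, 1)")
  if (length(correct_a) != length(correct_b) || length(correct_a) < 1) {
    stop("correctness vectors must be non-empty and of equal length")
  }
  n <- length(correct_a)
  a <- as.logical(correct_a)
  b <- as.logical(correct_b)
  diffs <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      100 * (mean(a[idx]) - mean(b[idx]))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  list(diff = 100 * (mean(a) - mean(b)),
       boot_mean = mean(diffs),
       ci = unname(stats::quantile(diffs, c(alpha, 1 - alpha), type = 7)),
       level = level, n_boot = n_boot)
}

#' Paired comparison report for two detectors
#'
#' Convenience wrapper combining [mcnemar()] on the discordant image-level
#' outcomes with [bootstrap_accuracy_diff()].
#'
#' @param correct_a,correct_b Per-image correctness (predicted image-level
#'   label equals the ground-truth label) for the two models.
#' @param n_boot,level,seed Passed to [bootstrap_accuracy_diff()].
#' @return List mirroring a statistical-validation table: accuracies,
#'   discordant counts, McNemar statistic and p, bootstrap CI and flags.
#' @export
compare_models <- function(correct_a, correct_b, n_boot = 10000L,
                           level = 0.95, seed = NULL) {
  dc <- discordant_counts(correct_a, correct_b)
  mc <- mcnemar(dc$b, dc$c)
  bt <- bootstrap_accuracy_diff(correct_a, correct_b, n_boot = n_boot,
                                level = level, seed = seed)
  list(n = dc$n, acc_a = 100 * mean(correct_a), acc_b = 100 * mean(correct_b),
       b = dc$b, c = dc$c, mcnemar_statistic = mc$statistic,
       mcnemar_p = mc$p_value, diff = bt$diff, ci = bt$ci, level = level,
       significant_mcnemar = mc$p_value < 0.05,
       significant_bootstrap = bt$ci[1] > 0 || bt$ci[2] < 0)
}
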