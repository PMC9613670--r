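#' Labeled percentile data
#'
#' Evaluation operates on a data.frame with columns `epoch_id`,
#' `movement_type`, `clinician_label`, `percentile`. Entries labeled
#' `"unclear"` are dropped (only epochs with a clear case-note
#' determination enter group comparisons), as are excluded epochs
#' (`NA` percentile).
#'
#' @param data data.frame with the four columns above.
#' @return Validated data.frame (class `labeled_percentiles`).
#' @export
labeled_percentiles <- function(data) {
  need <- c("epoch_id", "movement_type", "clinician_label", "percentile")
  miss <- setdiff(need, names(data))
  assert_that(length(miss) == 0, "nmmap_validation_error",
              "missing column(s): %s", paste(miss, collapse = ", "))
  keep <- data$clinician_label %in% c("clin_plus", "clin_minus") &
    !is.na(data$percentile)
  data <- data[keep, , drop = FALSE]
  assert_that(all(data$percentile >= 0 & data$percentile <= 100),
              "nmmap_validation_error", "percentiles must lie in [0, 100]")
  assert_that(all(data$movement_type %in% .movement_levels),
              "nmmap_validation_error", "invalid movement_type")
  class(data) <- c("labeled_percentiles", "data.frame")
  data
}

#' Compare percentile distributions between clinician labels
#'
#' Tests whether the clin+ and clin- percentile distributions differ in
#' central tendency. Each group is first checked for normality with the
#' Lilliefors test; when both groups are consistent with normality the
#' two-sample t-test is used, otherwise the Wilcoxon rank-sum test. All
#' tests are two-tailed. Groups smaller than 5 skip the normality gate
#' (the Lilliefors statistic is undefined there) and use the rank-sum test.
#'
#' @param data a [labeled_percentiles()] data.frame.
#' @param movement `"active"` or `"passive"`.
#' @param normality_alpha alpha for the Lilliefors gate (default 0.05).
#' @return List: `test` ("t-test" or "wilcoxon"), `statistic`, `p_value`,
#'   `n_plus`, `n_minus`, `lilliefors_p` (length 2).
#' @export
compare_groups <- function(data, movement = c("passive", "active"),
                           normality_alpha = 0.05) {
  movement <- match.arg(movement)
  data <- labeled_percentiles(as.data.frame(data))
  d <- data[data$movement_type == movement, ]
  gp <- d$percentile[d$clinician_label == "clin_plus"]
  gm <- d$percentile[d$clinician_label == "clin_minus"]
  assert_that(length(gp) >= 3 && length(gm) >= 3, "nmmap_validation_error",
              "need at least 3 epochs per clinician group (have %d / %d)",
              length(gp), length(gm))
  lp <- c(NA_real_, NA_real_)
  normal <- FALSE
  if (length(gp) >= 5 && length(gm) >= 5 &&
      sd(gp) > 0 && sd(gm) > 0) {
    lp <- c(nortest::lillie.test(gp)$p.value,
            nortest::lillie.test(gm)$p.value)
    normal <- all(lp > normality_alpha)
  }
  if (normal) {
    tt <- t.test(gp, gm)
    list(test = "t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, n_plus = length(gp), n_minus = length(gm),
         lilliefors_p = lp)
  } else {
    wt <- suppressWarnings(wilcox.test(gp, gm))
    list(test = "wilcoxon", statistic = unname(wt$statistic),
         p_value = wt$p.value, n_plus = length(gp), n_minus = length(gm),
         lilliefors_p = lp)
  }
}

#' Harrell-Davis quantile estimator
#'
#' Weighted average of the order statistics with Beta((n+1)q, (n+1)(1-q))
#' weights; smoother and more efficient than the sample quantile for the
#' decile-by-decile comparisons of the shift function.
#'
#' @param x numeric sample.
#' @param q quantile in (0, 1).
#' @return Estimate of the q-th quantile.
#' @export
harrell_davis <- function(x, q) {
  n <- length(x)
  assert_that(n >= 2, "nmmap_validation_error", "need at least 2 values")
  i <- seq_len(n)
  a <- (n + 1) * q
  b <- (n + 1) * (1 - q)
  w <- pbeta(i / n, a, b) - pbeta((i - 1) / n, a, b)
  sum(w * sort(x))
}

#' Shift function between two samples
#'
#' Decile-by-decile comparison: Harrell-Davis estimates of the 1st-9th
#' deciles for each group, the per-decile differences `b - a`, and
#' percentile-bootstrap confidence intervals. Simultaneous coverage across
#' the nine deciles is controlled by Hochberg-adjusting the per-decile
#' bootstrap p-values; a decile is flagged significant when its adjusted
#' p-value is below `alpha`, and its interval is reported at the
#' corresponding step-down level.
#'
#' @param a,b numeric samples (each of size at least 10).
#' @param n_boot bootstrap resamples (default 1000).
#' @param alpha familywise alpha (default 0.05).
#' @param seed integer seed for the bootstrap.
#' @return data.frame with one row per decile: `decile`, `q_a`, `q_b`,
#'   `difference`, `ci_lo`, `ci_hi`, `p_adj`, `significant`.
#' @export
shift_function <- function(a, b, n_boot = 1000, alpha = 0.05, seed = 1L) {
  assert_that(length(a) >= 10 && length(b) >= 10, "nmmap_validation_error",
              "shift function needs at least 10 values per group")
  qs <- seq(0.1, 0.9, by = 0.1)
  qa <- vapply(qs, function(q) harrell_davis(a, q), 0)
  qb <- vapply(qs, function(q) harrell_davis(b, q), 0)
  diffs <- qb - qa
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      as_ <- sample(a, replace = TRUE)
      bs_ <- sample(b, replace = TRUE)
      vapply(qs, function(q) harrell_davis(bs_, q) - harrell_davis(as_, q), 0)
    }, numeric(length(qs)))
  })  # 9 x n_boot
  # two-sided bootstrap p: how extreme is 0 within the resampled differences
  p <- vapply(seq_along(qs), function(k) {
    pos <- mean(boot[k, ] > 0) + 0.5 * mean(boot[k, ] == 0)
    2 * min(pos, 1 - pos)
  }, 0)
  p <- pmax(p, 1 / n_boot)  # bootstrap resolution floor
  p_adj <- p.adjust(p, method = "hochberg")
  # per-decile CI at its Hochberg step level (alpha / rank from the top)
  denom <- length(qs) + 1 - rank(p, ties.method = "first")
  ci <- t(vapply(seq_along(qs), function(k) {
    lev <- alpha / denom[k]
    quantile(boot[k, ], c(lev / 2, 1 - lev / 2), names = FALSE)
  }, numeric(2)))
  data.frame(decile = qs, q_a = qa, q_b = qb, difference = diffs,
             ci_lo = ci[, 1], ci_hi = ci[, 2], p_adj = p_adj,
             significant = p_adj < alpha)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact p-value by hypergeometric enumeration: with margins fixed, the
#' two-tailed p is the total probability of all tables whose probability
#' does not exceed the observed table's (the conventional definition).
#' The odds ratio reported is the cross-product `ad / bc`, with a Haldane
#' 0.5-cell correction applied only when some cell is zero (this is the
#' descriptive odds ratio clinicians quote, not the conditional MLE).
#'
#' @param tab 2x2 integer matrix (rows: groups; columns: outcomes).
#' @return List: `p_value`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  assert_that(all(dim(tab) == c(2, 2)) && all(tab >= 0) &&
                all(tab == round(tab)), "nmmap_validation_error",
              "need a 2x2 table of non-negative counts")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b          # row 1 total
  n_ <- c_ + d        # row 2 total
  k <- a + c_         # column 1 total
  if (m == 0 || n_ == 0 || k == 0 || b + d == 0) {
    p <- 1            # degenerate margin: only one table possible
  } else {
    support <- max(0, k - n_):min(k, m)
    probs <- dhyper(support, m, n_, k)
    p_obs <- dhyper(a, m, n_, k)
    p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
    p <- min(1, p)
  }
  if (any(tab == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  list(p_value = p, odds_ratio = (a * d) / (b * c_))
}

#' Odds ratio from two rule-in proportions
#'
#' Cross-product odds ratio of two proportions:
#' `(p1 / (1 - p1)) / (p2 / (1 - p2))`. Rates of exactly 0 or 1 are
#' degenerate (use the count-based [fisher_exact_2x2()] path with its
#' Haldane correction instead).
#'
#' @param rate_plus,rate_minus proportions in (0, 1).
#' @return The odds ratio.
#' @examples
#' odds_ratio_from_rates(0.82, 0.25)  # ~13.7, rounds to 14
#' @export
odds_ratio_from_rates <- function(rate_plus, rate_minus) {
  assert_that(rate_plus > 0 && rate_plus < 1 &&
                rate_minus > 0 && rate_minus < 1,
              "nmmap_degenerate_error",
              "rates must lie strictly in (0, 1); use the count-based path")
  (rate_plus / (1 - rate_plus)) / (rate_minus / (1 - rate_minus))
}

#' Threshold separation between clinician groups
#'
#' Receiver-operator-like analysis: at every candidate percentile threshold
#' `t`, the proportion of each clinician group "ruled in" (percentile
#' `<= t`) is computed; the best threshold maximizes the clin+ minus clin-
#' difference (ties resolved to the smallest threshold, the most
#' conservative rule-in). A shuffled baseline is built by randomly
#' reassigning the clin labels `n_shuffle` times and averaging the
#' resulting clin+ curves; it converges to the pooled empirical CDF and
#' should fall between the two group curves. At the best threshold a 2x2
#' table (clin group x ruled in/out) is tested with the two-tailed Fisher
#' exact test and the cross-product odds ratio.
#'
#' @param data a [labeled_percentiles()] data.frame.
#' @param movement `"passive"` or `"active"`.
#' @param n_shuffle label shuffles for the baseline (default 1000).
#' @param seed integer seed for the shuffles.
#' @param grid_step additional threshold grid spacing (default 0.5).
#' @return An object of class `threshold_analysis`: `thresholds`,
#'   `curve_plus`, `curve_minus`, `curve_shuffled`, `best_threshold`,
#'   `max_difference`, `rate_plus`, `rate_minus`, `table_at_best`,
#'   `odds_ratio`, `fisher_p`.
#' @export
threshold_separation <- function(data, movement = c("passive", "active"),
                                 n_shuffle = 1000, seed = 1L,
                                 grid_step = 0.5) {
  movement <- match.arg(movement)
  data <- labeled_percentiles(as.data.frame(data))
  d <- data[data$movement_type == movement, ]
  pp <- d$percentile[d$clinician_label == "clin_plus"]
  pm <- d$percentile[d$clinician_label == "clin_minus"]
  assert_that(length(pp) > 0 && length(pm) > 0, "nmmap_validation_error",
              "both clinician labels must be present for movement '%s'",
              movement)
  thr <- sort(unique(c(d$percentile, seq(0, 100, by = grid_step))))
  cp <- vapply(thr, function(t) mean(pp <= t), 0)
  cm <- vapply(thr, function(t) mean(pm <= t), 0)
  best_i <- which.max(cp - cm)          # which.max takes the first maximum:
  best <- thr[best_i]                   # smallest threshold wins ties
  ruled_p <- sum(pp <= best)
  ruled_m <- sum(pm <= best)
  tab <- matrix(c(ruled_p, length(pp) - ruled_p,
                  ruled_m, length(pm) - ruled_m),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("clin_plus", "clin_minus"),
                                c("ruled_in", "ruled_out")))
  fe <- fisher_exact_2x2(tab)
  pooled <- c(pp, pm)
  labs <- rep(c(TRUE, FALSE), c(length(pp), length(pm)))
  shuf <- with_seed(seed, {
    acc <- numeric(length(thr))
    for (s in seq_len(n_shuffle)) {
      sl <- sample(labs)
      sp <- pooled[sl]
      acc <- acc + vapply(thr, function(t) mean(sp <= t), 0)
    }
    acc / n_shuffle
  })
  structure(list(movement = movement, thresholds = thr,
                 curve_plus = cp, curve_minus = cm, curve_shuffled = shuf,
                 best_threshold = best, max_difference = cp[best_i] - cm[best_i],
                 rate_plus = ruled_p / length(pp),
                 rate_minus = ruled_m / length(pm),
                 table_at_best = tab,
                 odds_ratio = fe$odds_ratio, fisher_p = fe$p_value,
                 n_plus = length(pp), n_minus = length(pm)),
            class = "threshold_analysis")
}

#' @export
print.threshold_analysis <- function(x, ...) {
  cat(sprintf("<threshold_analysis> %s movements (n+ = %d, n- = %d)\n",
              x$movement, x$n_plus, x$n_minus))
  cat(sprintf("  best threshold : percentile %.1f (group difference %.2f)\n",
              x$best_threshold, x$max_difference))
  cat(sprintf("  ruled in       : %.0f%% of clin+, %.0f%% of clin-\n",
              100 * x$rate_plus, 100 * x$rate_minus))
  cat(sprintf("  Fisher exact   : p = %.3g, odds ratio = %.2f\n",
              x$fisher_p, x$odds_ratio))
  invisible(x)
}

#' @export
plot.threshold_analysis <- function(x, ...) {
  plot(x$thresholds, x$curve_plus, type = "l", col = "forestgreen", lwd = 2,
       xlab = "percentile threshold", ylab = "proportion ruled in",
       main = sprintf("%s movements: threshold separation", x$movement),
       ylim = c(0, 1))
  lines(x$thresholds, x$curve_minus, col = "deeppink3", lwd = 2)
  lines(x$thresholds, x$curve_shuffled, col = "grey40", lty = 2)
  abline(v = x$best_threshold, col = "grey70")
  legend("bottomright", c("clin+", "clin-", "shuffled"),
         col = c("forestgreen", "deeppink3", "grey40"),
         lty = c(1, 1, 2), lwd = c(2, 2, 1), bty = "n")
  invisible(x)
}

#' Full evaluation of quantitative vs clinician assessments
#'
#' Runs the group comparison, shift function, and threshold separation for
#' each movement type present in the data.
#'
#' @param data a [labeled_percentiles()]-compatible data.frame.
#' @param n_shuffle,n_boot,seed analysis parameters.
#' @return An `nm_evaluation` object: a list with one entry per movement
#'   type, each containing `comparison`, `shift`, `thresholds`.
#' @export
nm_evaluate <- function(data, n_shuffle = 1000, n_boot = 1000, seed = 1L) {
  data <- labeled_percentiles(as.data.frame(data))
  out <- list()
  for (mv in intersect(.movement_levels, unique(data$movement_type))) {
    d <- data[data$movement_type == mv, ]
    pp <- d$percentile[d$clinician_label == "clin_plus"]
    pm <- d$percentile[d$clinician_label == "clin_minus"]
    cmp <- tryCatch(compare_groups(d, mv),
                    nmmap_validation_error = function(e) NULL)
    sh <- if (length(pp) >= 10 && length(pm) >= 10)
      shift_function(pp, pm, n_boot = n_boot, seed = derive_seed(seed, mv))
    else NULL
    ta <- tryCatch(threshold_separation(d, mv, n_shuffle = n_shuffle,
                                        seed = derive_seed(seed, paste0(mv, "_shuffle"))),
                   nmmap_validation_error = function(e) NULL)
    out[[mv]] <- list(comparison = cmp, shift = sh, thresholds = ta,
                      n = nrow(d))
  }
  assert_that(length(out) > 0, "nmmap_validation_error",
              "no evaluable epochs")
  class(out) <- "nm_evaluation"
  out
}

#' @export
print.nm_evaluation <- function(x, ...) {
  for (mv in names(x)) {
    e <- x[[mv]]
    cat(sprintf("== %s movements (n = %d) ==\n", mv, e$n))
    if (!is.null(e$comparison))
      cat(sprintf("  central tendency: %s, p = %.3g\n",
                  e$comparison$test, e$comparison$p_value))
    if (!is.null(e$shift))
      cat(sprintf("  shift function: %d/9 deciles differ\n",
                  sum(e$shift$significant)))
    if (!is.null(e$thresholds))
      print(e$thresholds)
  }
  invisible(x)
}
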