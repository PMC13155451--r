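#' Two-way ANOVA mean squares of a measurement table
#'
#' Row (subject), column (rater/occasion) and residual mean squares of an
#' `n x k` complete table, the building blocks of the absolute-agreement
#' intraclass correlation:
#' `MSR = k * sum((row mean - grand)^2) / (n - 1)`,
#' `MSC = n * sum((col mean - grand)^2) / (k - 1)`,
#' `MSE = residual SS / ((n - 1) * (k - 1))`.
#'
#' @param table Numeric `n x k` matrix (or data frame) with `n >= 3` rows
#'   and `k >= 2` columns, no missing cells.
#' @return List with `msr`, `msc`, `mse`, `n`, `k`.
#' @examples
#' two_way_anova_ms(matrix(c(1, 2, 3, 1, 2, 3), ncol = 2))
#' @export
two_way_anova_ms <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(!is.finite(m))) {
    stop("two_way_anova_ms: table must be numeric with no missing cells",
         call. = FALSE)
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("two_way_anova_ms: need at least 3 subjects (rows)",
                  call. = FALSE)
  if (k < 2) stop("two_way_anova_ms: need at least 2 repeats (columns)",
                  call. = FALSE)
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  msr <- k * sum((rm_ - grand)^2) / (n - 1)
  msc <- n * sum((cm_ - grand)^2) / (k - 1)
  resid <- m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + grand
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse, n = n, k = k)
}

#' Single-rater absolute-agreement intraclass correlation
#'
#' ICC(A,1) from the two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`.
#' The same arithmetic serves both the two-way random-effects and the
#' two-way mixed-effects model; the model label only changes the
#' interpretation and is recorded for reporting. The 95% confidence interval
#' uses the F-based method with a Satterthwaite approximation to the
#' denominator degrees of freedom; the p-value tests ICC > 0 via
#' `F = MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of freedom (one-sided).
#' An all-equal table has no subject variance to resolve and is reported as
#' not computable (`icc = NA`).
#'
#' @param table Numeric `n x k` matrix, `n >= 3`, `k >= 2`, complete.
#' @param model `"two_way_random"` (inter-observer design) or
#'   `"two_way_mixed"` (intra-observer and test-retest designs).
#' @param alpha Significance level for the `1 - alpha` confidence interval.
#' @return An object of class `icc_result`: list with `icc`, `ci_low`,
#'   `ci_high`, `f`, `df1`, `df2`, `p`, `koo_li_class`, `model`, `n`, `k`
#'   and `not_computable`.
#' @examples
#' icc_single_agreement(matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2))
#' @export
icc_single_agreement <- function(table,
                                 model = c("two_way_random",
                                           "two_way_mixed"),
                                 alpha = 0.05) {
  model <- match.arg(model)
  ms <- two_way_anova_ms(table)
  n <- ms$n; k <- ms$k
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)

  if (msr == 0 && mse == 0) {
    res <- list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                f = NA_real_, df1 = df1, df2 = df2, p = NA_real_,
                koo_li_class = NA_character_, model = model, n = n, k = k,
                not_computable = TRUE)
    class(res) <- "icc_result"
    return(res)
  }

  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- (msr - mse) / denom

  f <- if (mse > 0) msr / mse else Inf
  p <- if (mse > 0) {
    stats::pf(f, df1, df2, lower.tail = FALSE)
  } else if (msr > 0) 0 else NA_real_

  if (mse == 0 && msc == 0) {
    ci_low <- 1; ci_high <- 1
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v_num <- (a * msc + b * mse)^2
    v_den <- (a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1))
    v <- v_num / v_den
    # extreme Satterthwaite df degrade qf/qbeta accuracy; the limit is exact
    if (!is.finite(v) || v > 1e6) v <- Inf
    # near-zero df (strongly negative ICC at tiny n) makes qf emit a qbeta
    # convergence warning although the quantile is adequate for the
    # degenerate interval it produces
    fl <- suppressWarnings(stats::qf(1 - alpha / 2, df1, v))
    fu <- suppressWarnings(stats::qf(1 - alpha / 2, v, df1))
    ci_low <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    ci_high <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }

  res <- list(icc = icc, ci_low = ci_low, ci_high = ci_high, f = f,
              df1 = df1, df2 = df2, p = p,
              koo_li_class = classify_icc(icc), model = model, n = n, k = k,
              not_computable = FALSE)
  class(res) <- "icc_result"
  res
}

#' @export
print.icc_result <- function(x, ...) {
  if (isTRUE(x$not_computable)) {
    cat("ICC(A,1): not computable (no between- or within-subject variance)\n")
    return(invisible(x))
  }
  cat(sprintf("ICC(A,1) [%s] = %.3f (95%% CI %.3f-%.3f), %s\n", x$model,
              x$icc, x$ci_low, x$ci_high, x$koo_li_class))
  cat(sprintf("  F(%d, %d) = %.3f, one-sided p = %.4g, n = %d, k = %d\n",
              x$df1, round(x$df2), x$f, x$p, x$n, x$k))
  invisible(x)
}

#' Koo-Li reliability classification of an ICC
#'
#' Bands: below 0.50 poor, 0.50 to below 0.75 moderate, 0.75 to 0.90
#' (inclusive) good, above 0.90 excellent.
#'
#' @param icc ICC value, at most 1 (may be negative).
#' @return One of `"poor"`, `"moderate"`, `"good"`, `"excellent"` (NA for a
#'   missing ICC).
#' @examples
#' classify_icc(c(0.48, 0.75, 0.92))
#' @export
classify_icc <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) {
    stop("classify_icc: ICC cannot exceed 1", call. = FALSE)
  }
  out <- ifelse(is.na(icc), NA_character_,
                ifelse(icc < 0.50, "poor",
                       ifelse(icc < 0.75, "moderate",
                              ifelse(icc <= 0.90, "good", "excellent"))))
  out
}

#' Bland-Altman agreement analysis
#'
#' Differences are `comparison - baseline`. The bias is their mean, the
#' limits of agreement are `bias +/- 1.96 * SD` (sample SD, `n - 1`
#' denominator), and proportional bias is checked by regressing the
#' differences on the pairwise means (a funnel shape shows up as a non-zero
#' slope).
#'
#' @param baseline,comparison Numeric vectors of equal length >= 3.
#' @return An object of class `bland_altman_result`: list with `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `prop_bias_slope`, `prop_bias_p`,
#'   `n`.
#' @examples
#' bland_altman(c(10, 12, 14), c(11, 13, 15))
#' @export
bland_altman <- function(baseline, comparison) {
  if (length(baseline) != length(comparison)) {
    stop("bland_altman: baseline and comparison differ in length",
         call. = FALSE)
  }
  n <- length(baseline)
  if (n < 3) stop("bland_altman: need at least 3 pairs", call. = FALSE)
  d <- comparison - baseline
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  m <- (baseline + comparison) / 2
  if (stats::sd(m) > 0 && sd_diff > 0) {
    fit <- summary(stats::lm(d ~ m))$coefficients
    slope <- fit["m", "Estimate"]
    slope_p <- fit["m", "Pr(>|t|)"]
  } else {
    slope <- if (stats::sd(m) > 0) 0 else NA_real_
    slope_p <- NA_real_
  }
  structure(list(bias = bias, sd_diff = sd_diff,
                 loa_low = bias - 1.96 * sd_diff,
                 loa_high = bias + 1.96 * sd_diff,
                 prop_bias_slope = slope, prop_bias_p = slope_p, n = n),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.3f, LoA (%.3f, %.3f), n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  if (!is.na(x$prop_bias_slope)) {
    cat(sprintf("  proportional bias slope %.4f (p = %.3g)\n",
                x$prop_bias_slope, x$prop_bias_p))
  }
  invisible(x)
}

# Exact two-sided signed-rank p by dynamic programming over the exact
# distribution of the positive-rank sum across all 2^n sign assignments.
# Works with tied (average) ranks too: ranks are multiples of 0.5, so
# doubling them gives integer weights for the subset-sum convolution.
signed_rank_exact_p <- function(w, ranks) {
  weights <- as.integer(round(2 * ranks))
  maxsum <- sum(weights)
  counts <- numeric(maxsum + 1)  # counts[s + 1] = #sign vectors with sum s
  counts[1] <- 1
  for (r in weights) {
    counts <- counts + c(numeric(r), counts[seq_len(maxsum + 1 - r)])
  }
  w2 <- 2 * w
  total <- 2^length(ranks)
  p_le <- sum(counts[seq_len(floor(w2) + 1)]) / total
  p_ge <- sum(counts[(ceiling(w2) + 1):(maxsum + 1)]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired measurements
#'
#' Tests for a systematic difference between a comparison and a baseline
#' analysis arm. Zero differences are dropped (classical Wilcoxon
#' convention; `zero_method = "pratt"` keeps them in the ranking instead).
#' The two-sided p-value is exact -- the positive-rank-sum distribution over
#' all sign assignments, computed by convolution (ties enter through their
#' average ranks) -- whenever there are at most 25 non-zero differences;
#' otherwise a normal approximation with
#' tie and continuity corrections is used. If every difference is zero the
#' test is degenerate: `p = 1` with `flag = "all_zero"`.
#'
#' @param baseline,comparison Numeric vectors of equal length >= 3.
#' @param zero_method `"wilcox"` (drop zeros, default) or `"pratt"`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact p-value;
#'   default `NULL` picks exact when valid.
#' @return An object of class `wilcoxon_result`: list with `w` (positive
#'   rank sum), `p`, `n_effective`, `method`, `flag`.
#' @examples
#' wilcoxon_signed_rank(1:6, 1:6 + 1)  # p = 2/64
#' @export
wilcoxon_signed_rank <- function(baseline, comparison,
                                 zero_method = c("wilcox", "pratt"),
                                 exact = NULL) {
  zero_method <- match.arg(zero_method)
  if (length(baseline) != length(comparison)) {
    stop("wilcoxon_signed_rank: input lengths differ", call. = FALSE)
  }
  if (length(baseline) < 3) {
    stop("wilcoxon_signed_rank: need at least 3 pairs", call. = FALSE)
  }
  d <- comparison - baseline
  zeros <- d == 0
  if (all(zeros)) {
    return(structure(list(w = 0, p = 1, n_effective = 0L,
                          method = "degenerate", flag = "all_zero"),
                     class = "wilcoxon_result"))
  }
  if (zero_method == "wilcox") {
    d_rank <- d[!zeros]
    r <- rank(abs(d_rank))
    w <- sum(r[d_rank > 0])
    n_eff <- length(d_rank)
    n_dist <- n_eff
  } else {
    # Pratt: rank zeros with the rest, then drop their ranks from the sums
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    n_eff <- sum(!zeros)
    n_dist <- length(d)
  }
  use_exact <- if (is.null(exact)) {
    zero_method == "wilcox" && n_eff <= 25
  } else isTRUE(exact)
  if (use_exact && zero_method == "pratt") {
    warning("wilcoxon_signed_rank: exact p is not available with ",
            "zero_method = 'pratt'; using the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    p <- signed_rank_exact_p(w, rank(abs(d[!zeros])))
    method <- "exact"
  } else {
    rr <- if (zero_method == "wilcox") rank(abs(d[!zeros])) else rank(abs(d))
    mu <- n_dist * (n_dist + 1) / 4
    sig2 <- n_dist * (n_dist + 1) * (2 * n_dist + 1) / 24
    if (zero_method == "pratt" && any(zeros)) {
      nz <- sum(zeros)
      mu <- mu - nz * (nz + 1) / 4
      sig2 <- sig2 - nz * (nz + 1) * (2 * nz + 1) / 24
    }
    tab <- table(rr)
    sig2 <- sig2 - sum(tab^3 - tab) / 48
    z <- w - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sig2)  # continuity correction
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approx"
  }
  structure(list(w = w, p = min(1, p), n_effective = as.integer(n_eff),
                 method = method, flag = NA_character_),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %.1f, p = %.4g (%s, n_eff = %d)%s\n",
              x$w, x$p, x$method, x$n_effective,
              if (!is.na(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
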