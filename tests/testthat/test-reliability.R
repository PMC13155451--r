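test_that("two-way mean squares match hand algebra and shift invariance", {
  perfect <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  ms <- two_way_anova_ms(perfect)
  expect_equal(ms$msr, 2)
  expect_equal(ms$msc, 0)
  expect_equal(ms$mse, 0)

  tab <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2)
  ms2 <- two_way_anova_ms(tab)
  expect_equal(ms2$msr, 40 / 3)
  expect_equal(ms2$msc, 2)
  expect_equal(ms2$mse, 0)

  set.seed(5)
  m <- random_table(8)
  a <- two_way_anova_ms(m)
  b <- two_way_anova_ms(m + 17.3)
  expect_equal(unlist(a), unlist(b))

  expect_error(two_way_anova_ms(m[1:2, ]), "3 subjects")
  expect_error(two_way_anova_ms(cbind(m[, 1])), "2 repeats")
  m[2, 1] <- NA
  expect_error(two_way_anova_ms(m), "missing")
})

test_that("the worked agreement example gives ICC(A,1) = 40/43", {
  tab <- matrix(c(1, 3, 5, 7, 2, 4, 6, 8), ncol = 2)
  r <- icc_single_agreement(tab)
  expect_equal(r$icc, (40 / 3) / (40 / 3 + (2 / 4) * 2), tolerance = 1e-12)
  expect_equal(r$icc, 0.93023255813953, tolerance = 1e-10)
  expect_equal(r$koo_li_class, "excellent")
  expect_equal(r$df1, 3)
})

test_that("perfect agreement and degenerate tables are handled", {
  perfect <- matrix(c(1, 2, 3, 1, 2, 3), ncol = 2)
  r <- icc_single_agreement(perfect)
  expect_equal(r$icc, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_equal(r$p, 0)

  allsame <- matrix(5, 4, 2)
  r0 <- icc_single_agreement(allsame)
  expect_true(r0$not_computable)
  expect_true(is.na(r0$icc))
})

test_that("ICC(A,1) is affine invariant but penalizes rater offsets", {
  set.seed(21)
  m <- random_table(12)
  r <- icc_single_agreement(m)
  expect_equal(icc_single_agreement(m + 3.2)$icc, r$icc, tolerance = 1e-12)
  expect_equal(icc_single_agreement(m * 2.5)$icc, r$icc, tolerance = 1e-12)

  base <- matrix(rnorm(20, 10, 2), ncol = 1)
  iccs <- sapply(c(2, 1, 0.5, 0.1, 0.01), function(cc) {
    icc_single_agreement(cbind(base, base + cc))$icc
  })
  expect_true(all(iccs < 1))
  expect_true(all(diff(iccs) > 0))    # smaller offset, higher agreement
  expect_gt(iccs[5], 0.999)           # ICC -> 1 as the offset vanishes
})

test_that("ICC matches the aov-based oracle on many random tables", {
  set.seed(99)
  for (i in 1:300) {
    m <- random_table()
    ours <- icc_single_agreement(m)
    expect_equal(ours$icc, oracle_icc_a1(m), tolerance = 1e-8)
  }
})

test_that("ICC, CI and p agree with an established independent implementation", {
  # pingouin's ICC(A,1) (same image, via the command line) on a handful of
  # frozen tables; its CI is printed to 2 decimals
  skip_if(Sys.which("python") == "", "python not on PATH")
  set.seed(123)
  tabs <- lapply(1:12, function(i) random_table())
  long <- do.call(rbind, lapply(seq_along(tabs), function(i) {
    m <- tabs[[i]]
    data.frame(tab = i, subj = rep(seq_len(nrow(m)), 2),
               rater = rep(1:2, each = nrow(m)), y = c(m))
  }))
  csv <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".csv")
  utils::write.csv(long, csv, row.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, pandas as pd, pingouin as pg",
    "d = pd.read_csv(sys.argv[1])",
    "rows = []",
    "for i, g in d.groupby('tab'):",
    "    r = pg.intraclass_corr(data=g, targets='subj', raters='rater',",
    "                           ratings='y').set_index('Type').loc['ICC(A,1)']",
    "    rows.append([i, r['ICC'], r['CI95'][0], r['CI95'][1], r['pval']])",
    "pd.DataFrame(rows).to_csv(sys.argv[2], index=False, header=False)"),
    script)
  status <- system2("python", c(script, csv, out), stdout = FALSE,
                    stderr = FALSE)
  skip_if(status != 0, "pingouin unavailable")
  ref <- utils::read.csv(out, header = FALSE)
  for (i in seq_along(tabs)) {
    ours <- icc_single_agreement(tabs[[i]])
    expect_equal(ours$icc, ref$V2[i], tolerance = 1e-10)
    expect_lt(abs(ours$ci_low - ref$V3[i]), 0.0051)   # pingouin prints 2 dp
    expect_lt(abs(ours$ci_high - ref$V4[i]), 0.0051)
    expect_equal(ours$p, ref$V5[i], tolerance = 1e-8)
  }
})

test_that("Koo-Li classification uses the agreed boundary rule", {
  expect_identical(classify_icc(c(-0.2, 0.48, 0.499999)),
                   rep("poor", 3))
  expect_identical(classify_icc(c(0.50, 0.6, 0.7499)),
                   rep("moderate", 3))
  expect_identical(classify_icc(c(0.75, 0.85, 0.90)), rep("good", 3))
  expect_identical(classify_icc(c(0.901, 0.92, 1)), rep("excellent", 3))
  expect_error(classify_icc(1.2), "exceed")
})

test_that("Bland-Altman identities hold exactly", {
  r <- bland_altman(c(10, 12, 14), c(11, 13, 15))
  expect_equal(r$bias, 1)
  expect_equal(r$sd_diff, 0)
  expect_equal(c(r$loa_low, r$loa_high), c(1, 1))

  r2 <- bland_altman(c(5, 5, 5), c(4, 5, 6))  # d = (-1, 0, 1)
  expect_equal(r2$bias, 0)
  expect_equal(c(r2$loa_low, r2$loa_high), c(-1.96, 1.96))

  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n, 10, 3); y <- x + rnorm(n, 0.5, 1)
    r <- bland_altman(x, y)
    expect_identical(r$bias, mean(y - x))
    expect_equal((r$loa_low + r$loa_high) / 2, r$bias)
    expect_equal(r$loa_high - r$loa_low, 2 * 1.96 * sd(y - x))
    # proportional-bias slope against a longhand OLS fit
    d <- y - x; m <- (x + y) / 2
    expect_equal(r$prop_bias_slope,
                 sum((m - mean(m)) * (d - mean(d))) / sum((m - mean(m))^2),
                 tolerance = 1e-10)
  }
  expect_error(bland_altman(1:4, 1:5), "length")
})

test_that("printed-triplet consistency: bias is the LoA midpoint", {
  # reconstruct samples whose differences realize a given (bias, LoA) pair,
  # then check the reported bias equals the interval midpoint
  make_pair <- function(loa_low, loa_high, n = 29) {
    bias <- (loa_low + loa_high) / 2
    sdd <- (loa_high - loa_low) / (2 * 1.96)
    z <- qnorm(seq(0.05, 0.95, length.out = n))
    d <- bias + sdd * (z - mean(z)) / sd(z)
    x <- seq(10, 30, length.out = n)
    list(x = x, y = x + d)
  }
  cases <- list(c(-4.60, 2.21, -1.19),   # LV inter-observer peak strain
                c(-1.96, 1.28, -0.34),   # LV test-retest early uncoupling
                c(-10.93, 6.78, -2.07))  # RV inter-observer peak strain
  for (cs in cases) {
    p <- make_pair(cs[1], cs[2])
    r <- bland_altman(p$x, p$y)
    expect_equal(r$bias, (r$loa_low + r$loa_high) / 2, tolerance = 1e-12)
    expect_lte(abs(r$bias - cs[3]), 0.005 + 1e-9)
  }
})

test_that("Wilcoxon signed-rank matches enumeration and the base oracle", {
  r <- wilcoxon_signed_rank(1:6, 1:6 + 1)
  expect_equal(r$p, 2 / 64)
  expect_identical(r$method, "exact")
  expect_equal(r$w, 21)

  # sign symmetry
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5, 3.5)
  y <- x + c(0.4, -0.2, 0.9, 1.1, -0.3, 0.2, 0.6, -0.8)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               wilcoxon_signed_rank(y, x)$p)

  # identical vectors are flagged degenerate
  r0 <- wilcoxon_signed_rank(x, x)
  expect_equal(r0$p, 1)
  expect_identical(r0$flag, "all_zero")
  expect_equal(r0$n_effective, 0L)

  # untied cases against the exact base-R oracle
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:24, 1)
    a <- rnorm(n); b <- a + rnorm(n, 0.4)
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  }

  # large/tied cases against the tie-corrected normal approximation
  set.seed(15)
  for (i in 1:10) {
    n <- sample(30:60, 1)
    a <- rnorm(n); b <- a + round(rnorm(n, 0.3), 1)
    b[b == a] <- a[b == a] + 0.05
    ours <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(b, a, paired = TRUE, exact = FALSE,
                              correct = TRUE)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }

  expect_error(wilcoxon_signed_rank(1:5, 1:4), "length")
})
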