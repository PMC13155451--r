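make_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      coh <- generate_cohort(cohort_config(seed = 17, n_subjects = 8))
      cache <<- list(cohort = coh, pt = compute_parameter_table(coh))
    }
    cache
  }
})

test_that("the study report covers every chamber, parameter and design", {
  st <- make_report()
  rep <- run_study(st$pt)
  ag <- rep$agreement
  expect_equal(nrow(ag), 10 * 2 * 3)  # 10 parameters x 2 chambers x 3 designs
  grid <- expand.grid(parameter = strainloops:::loop_parameter_names(),
                      chamber = c("LV", "RV"),
                      design = c("intra", "inter", "retest"))
  expect_equal(nrow(merge(ag, grid)), nrow(grid))
  expect_true(all(!ag$not_computable))
  expect_identical(unique(ag$model[ag$design == "inter"]), "two_way_random")
  expect_identical(unique(ag$model[ag$design != "inter"]), "two_way_mixed")
  # medians: 4 arms x 2 chambers x 10 parameters
  expect_equal(nrow(rep$medians), 4 * 2 * 10)
  expect_true(all(rep$medians$q1 <= rep$medians$median + 1e-12))
})

test_that("end-to-end runs are deterministic", {
  coh1 <- generate_cohort(cohort_config(seed = 23, n_subjects = 4,
                                        chambers = "LV"))
  coh2 <- generate_cohort(cohort_config(seed = 23, n_subjects = 4,
                                        chambers = "LV"))
  r1 <- run_study(coh1)
  r2 <- run_study(coh2)
  expect_identical(r1$agreement, r2$agreement)
  expect_identical(r1$medians, r2$medians)
})

test_that("a zero-error cohort degenerates exactly as expected", {
  pop <- strainloops:::default_population()
  for (ch in c("LV", "RV")) {
    pop[[ch]]$u_early_mean <- 0; pop[[ch]]$u_early_sd <- 0
    pop[[ch]]$u_late_mean <- 0; pop[[ch]]$u_late_sd <- 0
  }
  cfg <- cohort_config(seed = 4, n_subjects = 5,
                       noise = variance_components(), sigma_hr = 0,
                       population = pop)
  rep <- run_study(generate_cohort(cfg))
  ag <- rep$agreement
  # identical arms: Wilcoxon degenerate at p = 1, ICC not computable or 1
  expect_true(all(ag$wilcoxon_p == 1))
  expect_true(all(ag$wilcoxon_flag == "all_zero"))
  expect_true(all(is.na(ag$icc) | ag$icc == 1))
  expect_true(all(abs(ag$bias) < 1e-12))
  # no uncoupling offsets and closed loops
  pt <- rep$parameters
  expect_lt(max(abs(pt$early_u)), 0.02)
  expect_lt(max(abs(pt$late_u)), 0.02)
  expect_lt(max(pt$loop_area), 0.5)
})

test_that("median/IQR summaries use type-7 quantiles", {
  expect_equal(summarize_median_iqr(1:5),
               c(median = 3, q1 = 2, q3 = 4))
  expect_equal(summarize_median_iqr(7),
               c(median = 7, q1 = 7, q3 = 7))
  set.seed(2)
  x <- rnorm(37)
  s <- summarize_median_iqr(x)
  xs <- sort(x)
  # longhand type-7: h = (n - 1) p + 1
  q <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(unname(s), c(q(0.5), q(0.25), q(0.75)))
  expect_error(summarize_median_iqr(numeric(0)), "empty")
})

test_that("matched-cycle sensitivity reproduces direct recomputation", {
  st <- make_report()
  sm <- sensitivity_matched_cycles(st$pt)
  expect_setequal(unique(sm$design), c("intra", "inter"))
  # oracle: recompute one cell directly from the parameter table
  row <- sm[sm$chamber == "LV" & sm$design == "intra" &
              sm$parameter == "ss", ]
  pairs <- strainloops:::design_pairs(st$pt, "LV", "ss", "intra")
  sub <- pairs[pairs$matched_cycle, ]
  if (nrow(sub) >= 3) {
    direct <- icc_single_agreement(cbind(sub$baseline, sub$comparison),
                                   model = "two_way_mixed")$icc
    expect_equal(row$icc_matched, direct)
    expect_equal(row$delta_icc, direct - row$icc_full)
  } else {
    expect_true(row$not_computable)
  }

  # all flags true -> delta exactly zero
  pt2 <- st$pt
  pt2$matched_cycle <- TRUE
  sm2 <- sensitivity_matched_cycles(pt2)
  expect_true(all(sm2$delta_icc == 0))
  # no matched cycles -> not computable
  pt3 <- st$pt
  pt3$matched_cycle <- FALSE
  sm3 <- sensitivity_matched_cycles(pt3)
  expect_true(all(sm3$not_computable))
})

test_that("heart-rate filtering drops only large between-scan differences", {
  st <- make_report()
  # equal heart rates -> nothing excluded, identical ICCs
  pt_eq <- st$pt
  pt_eq$hr <- 60
  sh <- sensitivity_hr_filter(pt_eq)
  expect_true(all(sh$n_excluded == 0))
  expect_equal(sh$icc_filtered, sh$icc_full)
  expect_true(all(sh$delta_icc == 0))

  # threshold 0 retains only subjects with exactly matching heart rates
  sh0 <- sensitivity_hr_filter(st$pt, threshold = 0)
  pairs <- strainloops:::design_pairs(st$pt, "LV", "ss", "retest")
  n_same <- sum(pairs$hr_base == pairs$hr_comp)
  expect_equal(unique(sh0$n_kept[sh0$chamber == "LV"]), n_same)

  # jittered heart rates vs direct recomputation
  sh1 <- sensitivity_hr_filter(st$pt, threshold = 0.10)
  keep <- abs(pairs$hr_comp - pairs$hr_base) / pairs$hr_base <= 0.10
  sub <- pairs[keep, ]
  row <- sh1[sh1$chamber == "LV" & sh1$parameter == "ss", ]
  if (nrow(sub) >= 3) {
    direct <- icc_single_agreement(cbind(sub$baseline, sub$comparison),
                                   model = "two_way_mixed")$icc
    expect_equal(row$icc_filtered, direct)
  } else {
    expect_true(row$not_computable)
  }
})

test_that("inflating scan variance degrades test-retest below intra reliability", {
  noisy <- cohort_config(seed = 41, n_subjects = 20, chambers = "LV",
                         noise = variance_components(
                           sigma2_scan = 0.30^2,
                           sigma2_observer = 0.03^2,
                           sigma2_analysis = 0.3^2))
  rep <- run_study(generate_cohort(noisy))
  ag <- rep$agreement
  icc_of <- function(d) ag$icc[ag$design == d & ag$parameter == "ss"]
  expect_lt(icc_of("retest"), icc_of("intra"))
})

test_that("mean-loop rendering is deterministic and respects arm content", {
  coh <- generate_cohort(cohort_config(seed = 6, n_subjects = 3,
                                       chambers = "LV"))
  p <- render_mean_loops(coh, c("baseline", "retest"), chamber = "LV")
  expect_s3_class(p, "ggplot")
  d1 <- ggplot2::ggplot_build(p)$data[[1]]
  d2 <- ggplot2::ggplot_build(
    render_mean_loops(coh, c("baseline", "retest"), chamber = "LV"))$data[[1]]
  expect_identical(d1, d2)
  expect_error(render_mean_loops(coh, c("baseline", "retest"),
                                 chamber = "RV"), "no cycles")

  # zero-error cohort: the two arm curves coincide
  cfg0 <- cohort_config(seed = 2, n_subjects = 2, chambers = "LV",
                        noise = variance_components(), sigma_hr = 0)
  p0 <- render_mean_loops(generate_cohort(cfg0), c("baseline", "retest"))
  dat <- ggplot2::ggplot_build(p0)$data[[1]]
  grp <- split(dat[c("x", "y")], dat$colour)
  expect_equal(grp[[1]]$y, grp[[2]]$y, tolerance = 1e-9)
})
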