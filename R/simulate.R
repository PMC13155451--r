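#' Simulate a single-cycle volume or area curve
#'
#' Generates one cardiac cycle of cavity size as a piecewise half-cosine:
#' ejection from EDV to ESV on `[0, t_es]`, early filling from ESV to
#' `ESV + f_df * (EDV - ESV)` on `(t_es, t_df]`, a diastasis plateau on
#' `(t_df, t_af]`, and atrial filling back to EDV on `(t_af, 1)`. Frames are
#' sampled at `t = (0:(n_frames - 1)) / n_frames`, so the first frame is
#' end-diastole (value `edv`) and the global minimum `esv` falls at frame
#' `round(t_es * n_frames) + 1` (1-based). The curve is continuous at every
#' segment joint.
#'
#' @param params A [physio_params()] object.
#' @param n_frames Number of frames over the cycle; at least 25 (>= 50 Hz at
#'   resting heart rates).
#' @return Numeric vector of length `n_frames` (mL or cm^2).
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' v <- simulate_volume_curve(p, 60)
#' c(v[1], min(v), which.min(v))
#' @export
simulate_volume_curve <- function(params, n_frames) {
  validate_physio_params(params)
  if (!(is.numeric(n_frames) && length(n_frames) == 1L && n_frames >= 25)) {
    stop("simulate_volume_curve: n_frames must be >= 25 (one cycle at ",
         ">= 50 Hz); got ", n_frames, call. = FALSE)
  }
  n <- as.integer(n_frames)
  t <- (seq_len(n) - 1L) / n
  edv <- params$edv; esv <- params$esv
  exc <- edv - esv
  v_df <- esv + params$f_df * exc  # diastasis plateau level

  v <- numeric(n)
  ej <- t <= params$t_es
  v[ej] <- esv + exc * (1 + cos(pi * t[ej] / params$t_es)) / 2
  ef <- t > params$t_es & t <= params$t_df
  v[ef] <- esv + (v_df - esv) *
    (1 - cos(pi * (t[ef] - params$t_es) / (params$t_df - params$t_es))) / 2
  dia <- t > params$t_df & t <= params$t_af
  v[dia] <- v_df
  af <- t > params$t_af
  v[af] <- v_df + (edv - v_df) *
    (1 - cos(pi * (t[af] - params$t_af) / (1 - params$t_af))) / 2
  v
}

# Cycle fraction at which half of the total refill volume has returned.
# With f_df > 0.5 the crossing happens during early filling, otherwise
# during atrial filling (f_df = 0.5 puts it exactly at the start of
# diastasis).
half_refill_time <- function(params) {
  with(params, {
    if (f_df > 0.5) {
      t_es + (t_df - t_es) / pi * acos(1 - 1 / f_df)
    } else if (f_df == 0.5) {
      t_df
    } else {
      t_af + (1 - t_af) / pi * acos(1 - 2 * (0.5 - f_df) / (1 - f_df))
    }
  })
}

# Raised-cosine ramp from 0 at a to 1 at b, clamped outside.
cosine_rise <- function(t, a, b) {
  out <- pmin(pmax((t - a) / (b - a), 0), 1)
  (1 - cos(pi * out)) / 2
}

#' Simulate the strain curve coupled to a volume curve
#'
#' The noiseless strain trace is linearly coupled to the cavity size:
#' `strain(t) = s * (V(t) - EDV)` with `s = -peak_strain / (EDV - ESV)`, so
#' strain starts at 0 at end-diastole and reaches `peak_strain` at
#' end-systole. During diastole an uncoupling offset is added:
#' `u_early` while less than half of the refill volume has returned and
#' `u_late` afterwards. With `taper > 0` the offset ramps up over a
#' raised-cosine onset of width `taper` (fraction of the diastolic
#' duration) after end-systole, crossfades from `u_early` to `u_late`
#' around the half-refill time, and ramps back down at the cycle end, so
#' strain is continuous and returns to 0. With `taper = 0` the windows are
#' hard indicators on the refilled-volume fraction.
#'
#' @param volume Volume/area trace from [simulate_volume_curve()] generated
#'   with the same `params`.
#' @param params The [physio_params()] used for the volume trace.
#' @return Numeric strain trace (%), same length as `volume`.
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' s <- simulate_strain_curve(simulate_volume_curve(p, 60), p)
#' c(s[1], min(s))
#' @export
simulate_strain_curve <- function(volume, params) {
  validate_physio_params(params)
  n <- length(volume)
  if (n < 25) {
    stop("simulate_strain_curve: volume trace too short (", n, " frames)",
         call. = FALSE)
  }
  if (abs(volume[1] - params$edv) > 1e-6 * params$edv) {
    stop("simulate_strain_curve: volume trace does not start at EDV; was it ",
         "generated with the same params?", call. = FALSE)
  }
  t <- (seq_len(n) - 1L) / n
  s <- -params$peak_strain / (params$edv - params$esv)
  eps <- s * (volume - params$edv)

  t_half <- half_refill_time(params)
  w <- params$taper * (1 - params$t_es)
  if (params$taper == 0) {
    # hard windows keyed on the refilled-volume fraction; diastole is
    # strictly after end-systole so the shared ES frame stays coupled
    phi <- (volume - params$esv) / (params$edv - params$esv)
    dia <- t > params$t_es
    w_early <- as.numeric(dia & phi < 0.5)
    w_late <- as.numeric(dia & phi >= 0.5)
  } else {
    # onset ramp after end-systole, raised-cosine crossfade centred on the
    # half-refill time, and a closing ramp so strain returns to 0 at the
    # cycle end
    onset <- cosine_rise(t, params$t_es, params$t_es + w)
    onset[t < params$t_es] <- 0
    xfade <- cosine_rise(t, t_half - w / 2, t_half + w / 2)
    closing <- 1 - cosine_rise(t, 1 - w, 1)
    w_early <- onset * (1 - xfade)
    w_late <- onset * xfade * closing
  }
  eps + params$u_early * w_early + params$u_late * w_late
}

# Smooth re-analysis noise: first 3 half-cycle sine harmonics with random
# normal amplitudes. The sine basis vanishes at both cycle ends (preserving
# strain(0) = 0) and carries expected pointwise variance sigma2.
analysis_noise <- function(n, sigma2, n_harmonics = 3L) {
  if (sigma2 <= 0) return(numeric(n))
  t <- (seq_len(n) - 1L) / n
  a <- stats::rnorm(n_harmonics, 0, sqrt(2 * sigma2 / n_harmonics))
  out <- numeric(n)
  for (h in seq_len(n_harmonics)) out <- out + a[h] * sin(pi * h * t)
  out
}

rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

# Attenuation of the internal uncoupling offsets through loop extraction:
# the tapered windows and the shared end-systolic grid point shrink the
# extracted early/late uncoupling relative to the generator offsets.
# Column j holds the extracted (early_u, late_u) for a unit u_j on the
# population-mean subject; generate_cohort inverts this matrix so that the
# *extracted* cohort medians match the configured population means.
uncoupling_attenuation <- function(pop, hr, frame_rate, chamber) {
  n_frames <- max(25L, as.integer(round(frame_rate * 60 / hr)))
  A <- matrix(0, 2, 2)
  for (j in 1:2) {
    pp <- physio_params(edv = pop$edv_mean,
                        esv = pop$edv_mean - pop$excursion_mean,
                        peak_strain = pop$ps_mean, hr = hr,
                        u_early = if (j == 1) 1 else 0,
                        u_late = if (j == 2) 1 else 0,
                        chamber = chamber)
    v <- simulate_volume_curve(pp, n_frames)
    cyc <- cardiac_cycle(simulate_strain_curve(v, pp), v, chamber,
                         frame_rate)
    un <- uncoupling(build_loop(cyc))
    A[, j] <- c(un$early_u, un$late_u)
  }
  A
}

#' Generate a synthetic reliability cohort
#'
#' Draws subject-level physiology from the configured population, then
#' populates exactly the four analysis arms of the reliability study:
#' baseline (scan 1, observer 1, analysis 1), intra-observer repeat (scan 1,
#' observer 1, analysis 2), inter-observer (scan 1, observer 2, analysis 1)
#' and test-retest (scan 2, observer 1, analysis 1). Scan 2 re-draws a
#' relative perturbation of EDV, systolic excursion, peak strain and heart
#' rate; each (subject, observer) pair carries a multiplicative strain bias;
#' every analysis cell adds an independent smooth low-frequency strain noise.
#' LV cells carry three apical views (A2C/A3C/A4C) sharing the subject's
#' volume curve but with independent analysis noise; RV cells carry a single
#' RV-focused four-chamber view. The same seed always reproduces the same
#' cohort.
#'
#' @param config A [cohort_config()] object.
#' @return An object of class `svl_cohort`: a list with `cycles` (named list
#'   of [cardiac_cycle()] objects), `index` (a data frame keying subject,
#'   scan, observer, analysis, chamber, view, heart rate and matched-cycle
#'   flag to each cycle) and the `config`.
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1, n_subjects = 3,
#'                                      chambers = "LV"))
#' nrow(coh$index)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  arms <- data.frame(scan = c(1L, 1L, 1L, 2L),
                     observer = c(1L, 1L, 2L, 1L),
                     analysis = c(1L, 2L, 1L, 1L),
                     arm = c("baseline", "intra", "inter", "retest"))
  noise <- config$noise
  sd_scan <- sqrt(noise$sigma2_scan)
  sd_obs <- sqrt(noise$sigma2_observer)
  attn <- lapply(stats::setNames(nm = config$chambers), function(ch) {
    uncoupling_attenuation(config$population[[ch]], config$hr_mean,
                           config$frame_rate, ch)
  })

  cycles <- list()
  index <- list()
  for (i in seq_len(config$n_subjects)) {
    hr1 <- rnorm_clamped(1, config$hr_mean, config$hr_sd, 35, 110)
    hr2 <- hr1 * (1 + stats::rnorm(1, 0, config$sigma_hr))
    hr2 <- min(max(hr2, 35), 110)
    obs_bias <- exp(stats::rnorm(2, 0, sd_obs))  # per observer, this subject
    matched <- stats::runif(2) < config$p_matched  # intra, inter repeats

    for (ch in config$chambers) {
      pop <- config$population[[ch]]
      edv1 <- rnorm_clamped(1, pop$edv_mean, pop$edv_sd,
                            0.5 * pop$edv_mean, 1.6 * pop$edv_mean)
      exc1 <- rnorm_clamped(1, pop$excursion_mean, pop$excursion_sd,
                            0.25 * edv1, 0.85 * edv1)
      ps1 <- min(stats::rnorm(1, pop$ps_mean, pop$ps_sd), -5)
      # draw the subject's measured-scale uncoupling, then map it back to
      # generator offsets through the extraction attenuation matrix
      u_meas <- c(stats::rnorm(1, pop$u_early_mean, pop$u_early_sd),
                  stats::rnorm(1, pop$u_late_mean, pop$u_late_sd))
      u_int <- as.numeric(solve(attn[[ch]], u_meas))
      u_e <- u_int[1]; u_l <- u_int[2]
      # between-scan physiological + acquisition perturbation
      d <- stats::rnorm(3, 0, sd_scan)
      edv2 <- max(edv1 * (1 + d[1]), 0.4 * pop$edv_mean)
      exc2 <- min(max(exc1 * (1 + d[2]), 0.25 * edv2), 0.85 * edv2)
      ps2 <- min(ps1 * (1 + d[3]), -5)

      views <- if (ch == "LV") c("A2C", "A3C", "A4C") else "RV4C"
      for (r in seq_len(nrow(arms))) {
        scan <- arms$scan[r]
        hr <- if (scan == 1L) hr1 else hr2
        pp <- physio_params(
          edv = if (scan == 1L) edv1 else edv2,
          esv = if (scan == 1L) edv1 - exc1 else edv2 - exc2,
          peak_strain = if (scan == 1L) ps1 else ps2,
          hr = hr, u_early = u_e, u_late = u_l, chamber = ch)
        n_frames <- max(25L, as.integer(round(config$frame_rate * 60 / hr)))
        vol <- simulate_volume_curve(pp, n_frames)
        base_strain <- simulate_strain_curve(vol, pp)
        bias <- obs_bias[arms$observer[r]]
        for (vw in views) {
          strain <- base_strain * bias +
            analysis_noise(n_frames, noise$sigma2_analysis)
          key <- sprintf("S%03d_T%d_O%d_A%d_%s_%s", i, scan,
                         arms$observer[r], arms$analysis[r], ch, vw)
          cycles[[key]] <- cardiac_cycle(strain = strain, size = vol,
                                         chamber = ch,
                                         frame_rate = n_frames * hr / 60)
          index[[length(index) + 1L]] <- data.frame(
            subject = i, scan = scan, observer = arms$observer[r],
            analysis = arms$analysis[r], chamber = ch, view = vw,
            key = key, hr = hr,
            matched_cycle = switch(arms$arm[r],
                                   baseline = TRUE, retest = TRUE,
                                   intra = matched[1], inter = matched[2]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(cycles = cycles, index = do.call(rbind, index),
                 config = config),
            class = "svl_cohort")
}

#' @export
print.svl_cohort <- function(x, ...) {
  cat("Synthetic strain-size loop cohort\n")
  cat("  subjects:", x$config$n_subjects,
      " chambers:", paste(x$config$chambers, collapse = "/"),
      " traces:", length(x$cycles), "\n")
  cat("  seed:", x$config$seed, "\n")
  invisible(x)
}

#' Generate a parameter-level measurement table
#'
#' Shortcut generator for reliability-design tables that bypasses the curve
#' pipeline: `y_ij = mu + b_i + r_j + e_ij` with independent zero-mean normal
#' components. The between-subject effect `b_i` always has variance
#' `sigma2_subject` and the cell error `e_ij` variance `sigma2_analysis`;
#' the column effect `r_j` has variance `sigma2_observer` in the inter
#' design, `sigma2_scan` in the retest design, and is absent in the intra
#' design.
#'
#' @param n Number of subjects (rows), >= 2.
#' @param k Number of repeats (columns), >= 2.
#' @param mu Population mean of the parameter.
#' @param vc A [variance_components()] object.
#' @param design `"intra"`, `"inter"` or `"retest"`.
#' @param seed Integer seed.
#' @return An `n x k` numeric matrix of class `measurement_table` with the
#'   design recorded in `attr(, "design")`.
#' @examples
#' m <- generate_measurement_table(6, 2, 10, variance_components(4, 0, 0, 1),
#'                                 "intra", seed = 1)
#' dim(m)
#' @export
generate_measurement_table <- function(n, k = 2, mu, vc,
                                       design = c("intra", "inter", "retest"),
                                       seed) {
  design <- match.arg(design)
  stopifnot(inherits(vc, "variance_components"))
  if (n < 2 || k < 2) {
    stop("generate_measurement_table: need n >= 2 and k >= 2", call. = FALSE)
  }
  if (!missing(seed)) set.seed(as.integer(seed))
  sd_col <- switch(design,
                   intra = 0,
                   inter = sqrt(vc$sigma2_observer),
                   retest = sqrt(vc$sigma2_scan))
  b <- stats::rnorm(n, 0, sqrt(vc$sigma2_subject))
  r <- stats::rnorm(k, 0, sd_col)
  e <- matrix(stats::rnorm(n * k, 0, sqrt(vc$sigma2_analysis)), n, k)
  y <- mu + b + e + matrix(r, n, k, byrow = TRUE)
  structure(y, design = design, mu = mu, class = c("measurement_table",
                                                   class(y)))
}

#' Population intraclass correlation implied by variance components
#'
#' Closed-form counterpart of the ICC estimated from a reliability design:
#' `sigma2_subject / (sigma2_subject + error)`, where the error variance is
#' `sigma2_analysis` for the intra design, plus `sigma2_observer` for inter,
#' plus `sigma2_scan` for retest.
#'
#' @inheritParams generate_measurement_table
#' @return A number in `[0, 1]`.
#' @examples
#' expected_icc(variance_components(4, 0, 0, 1), "intra")  # 0.8
#' @export
expected_icc <- function(vc, design = c("intra", "inter", "retest")) {
  design <- match.arg(design)
  stopifnot(inherits(vc, "variance_components"))
  err <- switch(design,
                intra = vc$sigma2_analysis,
                inter = vc$sigma2_analysis + vc$sigma2_observer,
                retest = vc$sigma2_analysis + vc$sigma2_scan)
  tot <- vc$sigma2_subject + err
  if (tot <= 0) {
    stop("expected_icc: all relevant variance components are zero; the ",
         "ratio is undefined", call. = FALSE)
  }
  vc$sigma2_subject / tot
}
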