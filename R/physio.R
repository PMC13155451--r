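#' Physiological parameters of a single cardiac cycle
#'
#' Bundles the landmark values that shape one simulated heartbeat: cavity size
#' at end-diastole and end-systole, the most negative longitudinal strain, the
#' heart rate, the timing of the cycle phases (as fractions of the cycle), and
#' the diastolic uncoupling offsets that lift the diastolic limb of the
#' strain-size loop away from the systolic limb.
#'
#' @param edv End-diastolic volume (mL, LV) or area (cm^2, RV). Must exceed
#'   `esv`.
#' @param esv End-systolic volume/area, same units as `edv`; must be positive.
#' @param peak_strain Most negative longitudinal strain of the cycle (%),
#'   strictly negative.
#' @param hr Heart rate in beats per minute.
#' @param t_es End-systole as a fraction of the cycle length.
#' @param t_df End of early (rapid) filling as a cycle fraction.
#' @param t_af Start of atrial filling as a cycle fraction.
#' @param f_df Fraction of the total refill completed at diastasis, in (0, 1].
#' @param u_early Early-diastolic uncoupling offset (%): strain offset added
#'   while less than half of the refill volume has returned.
#' @param u_late Late-diastolic uncoupling offset (%), applied after half the
#'   refill has returned.
#' @param taper Width of the raised-cosine ramps at the edges of the
#'   uncoupling windows, as a fraction of the diastolic duration. `0` gives
#'   hard (indicator) windows.
#' @param chamber `"LV"` or `"RV"`; decides units and downstream view
#'   handling.
#'
#' @return An object of class `physio_params` (a validated list).
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' p$edv - p$esv
#' @export
physio_params <- function(edv, esv, peak_strain, hr = 58,
                          t_es = 0.35, t_df = 0.55, t_af = 0.80,
                          f_df = 0.75, u_early = 0, u_late = 0,
                          taper = 0.05, chamber = c("LV", "RV")) {
  chamber <- match.arg(chamber)
  p <- list(edv = edv, esv = esv, peak_strain = peak_strain, hr = hr,
            t_es = t_es, t_df = t_df, t_af = t_af, f_df = f_df,
            u_early = u_early, u_late = u_late, taper = taper,
            chamber = chamber)
  validate_physio_params(p)
  class(p) <- "physio_params"
  p
}

validate_physio_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("edv", "esv", "peak_strain", "hr", "t_es", "t_df", "t_af",
              "f_df", "u_early", "u_late", "taper")) {
    if (!num1(p[[f]])) {
      stop("physio_params: field '", f, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (!(p$edv > p$esv && p$esv > 0)) {
    stop("physio_params: require edv > esv > 0 (got edv = ", p$edv,
         ", esv = ", p$esv, ")", call. = FALSE)
  }
  if (p$peak_strain >= 0) {
    stop("physio_params: peak_strain must be negative (longitudinal ",
         "shortening convention)", call. = FALSE)
  }
  if (!(p$t_es > 0 && p$t_es < p$t_df && p$t_df <= p$t_af && p$t_af < 1)) {
    stop("physio_params: require 0 < t_es < t_df <= t_af < 1", call. = FALSE)
  }
  if (!(p$f_df > 0 && p$f_df <= 1)) {
    stop("physio_params: f_df must lie in (0, 1]", call. = FALSE)
  }
  if (p$hr <= 0) stop("physio_params: hr must be positive", call. = FALSE)
  if (p$taper < 0 || p$taper >= 0.5) {
    stop("physio_params: taper must lie in [0, 0.5)", call. = FALSE)
  }
  invisible(p)
}

#' Variance components of the hierarchical measurement-error model
#'
#' The four variance components of the reliability design: between-subject
#' spread of a loop parameter, between-scan (acquisition plus short-term
#' physiology) variation, between-observer bias, and within-observer
#' re-analysis noise. For [generate_measurement_table()] and [expected_icc()]
#' all four are on the squared scale of the loop parameter itself. Inside
#' [generate_cohort()] the last three act as generator noise scales:
#' `sigma2_scan` is the variance of the *relative* between-scan perturbation
#' of EDV, systolic excursion and peak strain, `sigma2_observer` the variance
#' of the per (subject, observer) log-scale strain bias, and `sigma2_analysis`
#' the variance (%^2) of the additive smooth re-analysis strain noise.
#'
#' @param sigma2_subject Between-subject variance (parameter units squared).
#' @param sigma2_scan Between-scan variance.
#' @param sigma2_observer Between-observer bias variance.
#' @param sigma2_analysis Within-observer re-analysis variance.
#'
#' @return An object of class `variance_components`.
#' @examples
#' vc <- variance_components(4, 0, 0, 1)
#' expected_icc(vc, "intra")
#' @export
variance_components <- function(sigma2_subject = 0, sigma2_scan = 0,
                                sigma2_observer = 0, sigma2_analysis = 0) {
  vc <- list(sigma2_subject = sigma2_subject, sigma2_scan = sigma2_scan,
             sigma2_observer = sigma2_observer,
             sigma2_analysis = sigma2_analysis)
  for (f in names(vc)) {
    x <- vc[[f]]
    if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0)) {
      stop("variance_components: '", f, "' must be a single finite ",
           "non-negative number", call. = FALSE)
    }
  }
  class(vc) <- "variance_components"
  vc
}

# Population distributions behind the default cohort, calibrated to the
# published healthy-adult medians: LV systolic slope 0.27 %/mL with peak
# strain -18.4 % (so excursion = 18.4/0.27 ~ 68 mL), RV systolic slope
# 2.42 %/cm^2 with peak strain -22.5 % (excursion ~ 9.3 cm^2), and the RV
# uncoupling setpoints 2.78 % (early) and 1.29 % (late). Between-subject SDs
# approximate the printed IQRs via IQR/1.35 and are labelled approximate.
default_population <- function() {
  list(
    LV = list(edv_mean = 120, edv_sd = 15,
              excursion_mean = 68.15, excursion_sd = 10,
              ps_mean = -18.4, ps_sd = 2.5,
              u_early_mean = -0.39, u_early_sd = 0.6,
              u_late_mean = -0.01, u_late_sd = 0.5),
    RV = list(edv_mean = 24, edv_sd = 3,
              excursion_mean = 9.31, excursion_sd = 1.3,
              ps_mean = -22.54, ps_sd = 2.2,
              u_early_mean = 2.78, u_early_sd = 0.9,
              u_late_mean = 1.29, u_late_sd = 0.7)
  )
}

#' Configuration of a synthetic reliability cohort
#'
#' Describes the simulated study: number of subjects, acquisition frame rate,
#' chambers, population distributions of the physiological parameters, the
#' hierarchical noise model, and the seed of the pseudo-random stream. The
#' defaults emulate the published healthy cohort: 29 subjects, heart rate
#' 58 (SD 8) bpm, frame rate 58 Hz (>= 50 Hz), LV/RV loop parameters centred
#' on the reported medians.
#'
#' @param n_subjects Number of subjects (>= 2; default 29).
#' @param frame_rate Acquisition frame rate in Hz; must be >= 50.
#' @param chambers Chambers to simulate, subset of `c("LV", "RV")`.
#' @param hr_mean,hr_sd Population mean and SD of heart rate (bpm).
#' @param population Named list (`LV`, `RV`) of population means and SDs for
#'   the physiological parameters; see `strainloops:::default_population()`
#'   for the expected fields.
#' @param noise A [variance_components()] object holding the generator noise
#'   scales (see that help page for the unit conventions).
#' @param sigma_hr SD of the relative between-scan heart-rate difference.
#' @param p_matched Probability that a repeat analysis uses the same cardiac
#'   cycle as the baseline analysis (drives the matched-cycle sensitivity
#'   analysis).
#' @param seed Integer seed for the cohort's pseudo-random stream (mandatory).
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 1, n_subjects = 4, chambers = "LV")
#' cfg$n_subjects
#' @export
cohort_config <- function(seed, n_subjects = 29, frame_rate = 58,
                          chambers = c("LV", "RV"),
                          hr_mean = 58, hr_sd = 8,
                          population = default_population(),
                          noise = variance_components(
                            sigma2_scan = 0.12^2,
                            sigma2_observer = 0.06^2,
                            sigma2_analysis = 0.5^2),
                          sigma_hr = 0.085,
                          p_matched = 0.65) {
  if (missing(seed)) stop("cohort_config: a seed is mandatory", call. = FALSE)
  seed <- as.integer(seed)
  if (!is.finite(seed)) stop("cohort_config: seed must be an integer",
                             call. = FALSE)
  if (!(is.numeric(n_subjects) && n_subjects >= 2)) {
    stop("cohort_config: n_subjects must be >= 2", call. = FALSE)
  }
  if (!(is.numeric(frame_rate) && frame_rate >= 50)) {
    stop("cohort_config: frame_rate must be >= 50 Hz", call. = FALSE)
  }
  chambers <- match.arg(chambers, c("LV", "RV"), several.ok = TRUE)
  if (!inherits(noise, "variance_components")) {
    stop("cohort_config: noise must be a variance_components object",
         call. = FALSE)
  }
  if (!(p_matched >= 0 && p_matched <= 1)) {
    stop("cohort_config: p_matched must lie in [0, 1]", call. = FALSE)
  }
  structure(list(seed = seed, n_subjects = as.integer(n_subjects),
                 frame_rate = frame_rate, chambers = chambers,
                 hr_mean = hr_mean, hr_sd = hr_sd, population = population,
                 noise = noise, sigma_hr = sigma_hr, p_matched = p_matched),
            class = "cohort_config")
}

#' Read or write a cohort configuration as a YAML document
#'
#' The on-disk schema mirrors the arguments of [cohort_config()]; the
#' `noise` block holds the four variance components by name.
#'
#' @param path Path to a YAML file.
#' @param config A `cohort_config` object.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_cohort_config(cohort_config(seed = 7, n_subjects = 5), f)
#' read_cohort_config(f)$n_subjects
#' @export
read_cohort_config <- function(path) {
  doc <- yaml::read_yaml(path)
  allowed <- c("seed", "n_subjects", "frame_rate", "chambers", "hr_mean",
               "hr_sd", "population", "noise", "sigma_hr", "p_matched")
  bad <- setdiff(names(doc), allowed)
  if (length(bad)) {
    stop("read_cohort_config: unknown field(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.null(doc$noise)) doc$noise <- do.call(variance_components, doc$noise)
  do.call(cohort_config, doc)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  doc <- unclass(config)
  doc$noise <- unclass(doc$noise)
  yaml::write_yaml(doc, path)
  invisible(path)
}
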