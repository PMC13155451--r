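#' Peak strain of a cycle
#'
#' The most negative strain value over the whole cycle (global longitudinal
#' strain convention).
#'
#' @param cycle A [cardiac_cycle()].
#' @return Peak strain in %.
#' @export
peak_strain <- function(cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  min(cycle$strain)
}

# OLS slope of y on x via the covariance form; NA if x has no spread.
ols_slope <- function(x, y) {
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) return(NA_real_)
  sum((x - mx) * (y - mean(y))) / sxx
}

#' Systolic and early systolic slopes
#'
#' The systolic slope (SS) is the ordinary-least-squares slope of strain on
#' volume/area over the systolic frames from end-diastole to end-systole
#' inclusive. The early systolic slope (ESS) uses only the systolic frames
#' whose volume lies within the first `ess_fraction` of the EDV-to-ESV
#' excursion; if fewer than 3 frames qualify the window is widened to the 3
#' earliest systolic frames and flagged.
#'
#' @param cycle A [cardiac_cycle()].
#' @param ess_fraction Fraction of the excursion defining the early-systolic
#'   window (default 0.05).
#' @return List with `ss`, `ess` (both %/mL or %/cm^2) and `ess_widened`
#'   (logical flag).
#' @export
systolic_slopes <- function(cycle, ess_fraction = 0.05) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  es <- cycle$es_index
  if (es < 3L) {
    stop("systolic_slopes: fewer than 3 systolic frames", call. = FALSE)
  }
  v <- cycle$size[1:es]
  s <- cycle$strain[1:es]
  ss <- ols_slope(v, s)
  edv <- v[1L]; esv <- v[es]
  in_window <- v >= edv - ess_fraction * (edv - esv)
  widened <- sum(in_window) < 3L
  idx <- if (widened) 1:3 else which(in_window)
  list(ss = ss, ess = ols_slope(v[idx], s[idx]), ess_widened = widened)
}

#' Early and late diastolic slopes
#'
#' OLS slopes of the diastolic limb strain on grid volume over the
#' lower-volume half of the grid (early diastole, up to the split index) and
#' the upper half (late diastole, from the split index on).
#'
#' @param loop An [build_loop()] result.
#' @return List with `eds` and `lds` (%/mL or %/cm^2).
#' @export
diastolic_slopes <- function(loop) {
  stopifnot(inherits(loop, "svl_loop"))
  G <- length(loop$grid)
  sp <- loop$split_index
  if (sp < 3L || G - sp + 1L < 3L) {
    stop("diastolic_slopes: degenerate grid half (< 3 points)",
         call. = FALSE)
  }
  list(eds = ols_slope(loop$grid[1:sp], loop$dia_strain[1:sp]),
       lds = ols_slope(loop$grid[sp:G], loop$dia_strain[sp:G]))
}

#' Diastolic uncoupling of the loop limbs
#'
#' The pointwise limb difference `d(v) = dia_strain(v) - sys_strain(v)` on
#' the volume grid, summarized as the mean over the lower-volume half
#' (indices 1..split, traversed first during refill: early uncoupling), the
#' mean over the remaining upper half (late uncoupling), and the grid-wide
#' mean (total uncoupling). The sign convention is diastolic minus systolic,
#' so a diastolic limb lying above (less negative than) the systolic limb
#' gives positive uncoupling.
#'
#' @param loop A [build_loop()] result.
#' @return List with `early_u`, `late_u`, `total_u` (%).
#' @export
uncoupling <- function(loop) {
  stopifnot(inherits(loop, "svl_loop"))
  d <- loop$dia_strain - loop$sys_strain
  sp <- loop$split_index
  G <- length(d)
  list(early_u = mean(d[1:sp]),
       late_u = mean(d[(sp + 1L):G]),
       total_u = mean(d))
}

#' Loop area
#'
#' Absolute shoelace area of the closed polygon traced by the per-frame
#' (size, strain) points, closing from the last frame back to the first.
#'
#' @param cycle A [cardiac_cycle()].
#' @return Area in %*mL (LV) or %*cm^2 (RV).
#' @export
loop_area <- function(cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  x <- cycle$size; y <- cycle$strain
  n <- length(x)
  if (n < 3L) stop("loop_area: need at least 3 frames", call. = FALSE)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Peak strain to end-diastolic size ratio
#'
#' @param cycle A [cardiac_cycle()].
#' @return Ratio in %/mL or %/cm^2.
#' @export
ps_ed_ratio <- function(cycle) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  edv <- cycle$size[cycle$ed_index]
  if (edv <= 0) stop("ps_ed_ratio: end-diastolic size must be positive",
                     call. = FALSE)
  peak_strain(cycle) / edv
}

#' All ten loop-derived parameters of one cycle
#'
#' Composes the individual parameter operations: builds the loop geometry and
#' returns the four headline parameters (systolic slope, peak strain, early
#' and late diastolic uncoupling) together with the six supplementary ones
#' (early systolic slope, early and late diastolic slope, total uncoupling,
#' loop area, peak strain/end-diastolic size ratio).
#'
#' @param cycle A [cardiac_cycle()].
#' @param grid_size,dedrift Passed to [build_loop()].
#' @param ess_fraction Passed to [systolic_slopes()].
#' @return A one-row data frame with columns `ss`, `ess`, `ps`, `eds`,
#'   `lds`, `early_u`, `late_u`, `total_u`, `loop_area`, `ps_ed_ratio` and
#'   the flag `ess_widened`.
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' v <- simulate_volume_curve(p, 60)
#' compute_loop_parameters(cardiac_cycle(simulate_strain_curve(v, p), v,
#'                                       "LV", 58))
#' @export
compute_loop_parameters <- function(cycle, grid_size = 101L, dedrift = FALSE,
                                    ess_fraction = 0.05) {
  loop <- build_loop(cycle, grid_size = grid_size, dedrift = dedrift)
  sy <- systolic_slopes(cycle, ess_fraction = ess_fraction)
  di <- diastolic_slopes(loop)
  un <- uncoupling(loop)
  data.frame(ss = sy$ss, ess = sy$ess, ps = peak_strain(cycle),
             eds = di$eds, lds = di$lds,
             early_u = un$early_u, late_u = un$late_u,
             total_u = un$total_u, loop_area = loop_area(cycle),
             ps_ed_ratio = ps_ed_ratio(cycle),
             ess_widened = sy$ess_widened)
}

# canonical parameter order and display units
loop_parameter_names <- function() {
  c("ss", "ess", "ps", "eds", "lds", "early_u", "late_u", "total_u",
    "loop_area", "ps_ed_ratio")
}
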