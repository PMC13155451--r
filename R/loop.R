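#' Build the strain-size loop geometry from a cycle
#'
#' Splits the cycle into a systolic limb (frames from end-diastole to
#' end-systole, inclusive) and a diastolic limb (end-systole to the last
#' frame), and interpolates the strain of each limb onto a common grid of
#' `grid_size` uniformly spaced absolute volume/area values spanning
#' `[ESV, EDV]`. Within each limb, non-monotonic volume runs are collapsed by
#' sorting the limb by volume and averaging strain at duplicate volumes;
#' interpolation is linear with constant extrapolation at the grid ends. The
#' two limbs share the end-systolic point by construction.
#'
#' @param cycle A [cardiac_cycle()].
#' @param grid_size Number of grid points (default 101).
#' @param dedrift If `TRUE`, subtract a linear ramp removing the end-of-cycle
#'   strain residual before splitting the limbs, so the diastolic limb
#'   returns to 0 at EDV. Off by default (no drift compensation is applied
#'   unless requested).
#' @return An object of class `svl_loop`: list with `grid`, `sys_strain`,
#'   `dia_strain`, `edv`, `esv`, `split_index` (grid index at
#'   `ESV + 0.5 * (EDV - ESV)`), and `chamber`.
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' v <- simulate_volume_curve(p, 60)
#' lp <- build_loop(cardiac_cycle(simulate_strain_curve(v, p), v, "LV", 58))
#' range(lp$grid)
#' @export
build_loop <- function(cycle, grid_size = 101L, dedrift = FALSE) {
  stopifnot(inherits(cycle, "cardiac_cycle"))
  if (grid_size < 5) stop("build_loop: grid_size must be >= 5", call. = FALSE)
  strain <- cycle$strain
  n <- length(strain)
  if (isTRUE(dedrift)) {
    strain <- strain - strain[n] * (seq_len(n) - 1L) / (n - 1L)
  }
  es <- cycle$es_index
  edv <- cycle$size[1L]
  esv <- cycle$size[es]
  if ((edv - esv) < 0.01 * edv) {
    stop("build_loop: volume excursion ", signif(edv - esv, 3),
         " is below 1% of EDV; degenerate cycle", call. = FALSE)
  }
  grid <- seq(esv, edv, length.out = as.integer(grid_size))
  limb <- function(idx) {
    v <- cycle$size[idx]; s <- strain[idx]
    ord <- order(v)
    stats::approx(v[ord], s[ord], xout = grid, ties = mean, rule = 2)$y
  }
  sys_strain <- limb(1:es)
  dia_strain <- limb(es:n)
  split_index <- which.min(abs(grid - (esv + 0.5 * (edv - esv))))
  structure(list(grid = grid, sys_strain = sys_strain,
                 dia_strain = dia_strain, edv = edv, esv = esv,
                 split_index = as.integer(split_index),
                 chamber = cycle$chamber),
            class = "svl_loop")
}

#' @export
print.svl_loop <- function(x, ...) {
  cat(sprintf("svl_loop (%s): %d grid points on [%.1f, %.1f]\n",
              x$chamber, length(x$grid), x$esv, x$edv))
  invisible(x)
}
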