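#' Paired strain and size traces for one heartbeat
#'
#' A validated container for one cardiac cycle: per-frame longitudinal strain
#' (%) and cavity size (mL for LV, cm^2 for RV), with end-diastole at frame 1
#' by convention (traces are R-wave gated) and end-systole at the frame of
#' minimum size.
#'
#' @param strain Numeric strain trace (%); must start at 0 within 0.5
#'   percentage points (R-wave gating).
#' @param size Numeric volume/area trace, strictly positive, same length.
#' @param chamber `"LV"` or `"RV"`.
#' @param frame_rate Frames per second of the trace.
#' @return An object of class `cardiac_cycle` with fields `strain`, `size`,
#'   `chamber`, `ed_index` (always 1), `es_index`, `frame_rate`.
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' v <- simulate_volume_curve(p, 60)
#' cyc <- cardiac_cycle(simulate_strain_curve(v, p), v, "LV", 58)
#' cyc$es_index
#' @export
cardiac_cycle <- function(strain, size, chamber = c("LV", "RV"), frame_rate) {
  chamber <- match.arg(chamber)
  n <- length(size)
  if (length(strain) != n) {
    stop("cardiac_cycle: strain and size traces differ in length (",
         length(strain), " vs ", n, ")", call. = FALSE)
  }
  if (n < 25) {
    stop("cardiac_cycle: need at least 25 frames per cycle, got ", n,
         call. = FALSE)
  }
  if (!all(is.finite(strain)) || !all(is.finite(size))) {
    stop("cardiac_cycle: traces must be finite", call. = FALSE)
  }
  if (any(size <= 0)) {
    stop("cardiac_cycle: size must be positive everywhere", call. = FALSE)
  }
  if (abs(strain[1]) > 0.5) {
    stop("cardiac_cycle: strain at the end-diastolic frame is ",
         round(strain[1], 3), " %; traces must be R-wave gated ",
         "(|strain[1]| <= 0.5)", call. = FALSE)
  }
  if (!(is.numeric(frame_rate) && frame_rate > 0)) {
    stop("cardiac_cycle: frame_rate must be positive", call. = FALSE)
  }
  es <- detect_es_index(size)
  structure(list(strain = as.numeric(strain), size = as.numeric(size),
                 chamber = chamber, ed_index = 1L, es_index = es,
                 frame_rate = frame_rate),
            class = "cardiac_cycle")
}

#' @export
print.cardiac_cycle <- function(x, ...) {
  cat(sprintf("cardiac_cycle (%s): %d frames @ %.1f Hz, EDV/ESV %.1f/%.1f, ",
              x$chamber, length(x$size), x$frame_rate, x$size[1],
              x$size[x$es_index]),
      sprintf("peak strain %.2f %%\n", min(x$strain)), sep = "")
  invisible(x)
}

#' Locate the end-systolic frame on a size trace
#'
#' End-systole is the frame of the global size minimum (the volume/area
#' curve criterion); ties are broken by the earliest frame. A minimum at the
#' first or last frame indicates a trace that does not span one full R-wave
#' gated cycle and is rejected.
#'
#' @param size Numeric volume/area trace with at least 25 frames.
#' @return Integer frame index (1-based).
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' detect_es_index(simulate_volume_curve(p, 60))  # 22 (t_es * 60 frames + 1)
#' @export
detect_es_index <- function(size) {
  if (length(size) < 25) {
    stop("detect_es_index: need at least 25 frames, got ", length(size),
         call. = FALSE)
  }
  es <- which.min(size)  # earliest index on ties
  if (es == 1L || es == length(size)) {
    stop("detect_es_index: size minimum at frame ", es, " of ", length(size),
         "; degenerate cycle (trace does not cover one full cycle)",
         call. = FALSE)
  }
  es
}

# Resample a cycle onto m uniform points of normalized cycle time [0, 1].
resample_cycle <- function(cycle, m = 201L) {
  n <- length(cycle$size)
  tau <- (seq_len(n) - 1L) / (n - 1L)
  tt <- seq(0, 1, length.out = m)
  list(strain = stats::approx(tau, cycle$strain, xout = tt)$y,
       size = stats::approx(tau, cycle$size, xout = tt)$y)
}

#' Average LV apical views into one cycle
#'
#' Each view is resampled by linear interpolation onto 201 uniform points of
#' normalized cycle time (0-100%), then strain and volume are averaged
#' pointwise and end-systole is re-detected on the averaged volume curve.
#' This mirrors the derivation of averaged temporal LV global longitudinal
#' strain and volume from apical two-, three- and four-chamber recordings.
#'
#' @param cycles List of LV [cardiac_cycle()] objects (one per view).
#' @param min_views Minimum number of views required (default 2, matching
#'   the matched-cycle subset rule of at least two apical views).
#' @param m Number of resampled points (default 201).
#' @return A [cardiac_cycle()] of `m` frames.
#' @examples
#' p <- physio_params(edv = 120, esv = 50, peak_strain = -18)
#' v <- simulate_volume_curve(p, 60)
#' cyc <- cardiac_cycle(simulate_strain_curve(v, p), v, "LV", 58)
#' avg <- average_views(list(cyc, cyc))
#' length(avg$size)
#' @export
average_views <- function(cycles, min_views = 2L, m = 201L) {
  if (!length(cycles) || !all(vapply(cycles, inherits, TRUE, "cardiac_cycle"))) {
    stop("average_views: expected a list of cardiac_cycle objects",
         call. = FALSE)
  }
  if (length(cycles) < min_views) {
    stop("average_views: ", length(cycles), " view(s) supplied but at least ",
         min_views, " required", call. = FALSE)
  }
  chambers <- vapply(cycles, `[[`, "", "chamber")
  if (any(chambers != "LV")) {
    stop("average_views: all views must be LV apical views; got ",
         paste(unique(chambers), collapse = ", "), call. = FALSE)
  }
  res <- lapply(cycles, resample_cycle, m = m)
  strain <- rowMeans(vapply(res, `[[`, numeric(m), "strain"))
  size <- rowMeans(vapply(res, `[[`, numeric(m), "size"))
  # preserve the mean cycle duration in the output frame rate
  dur <- mean(vapply(cycles, function(cy) length(cy$size) / cy$frame_rate, 0))
  cardiac_cycle(strain = strain, size = size, chamber = "LV",
                frame_rate = m / dur)
}
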