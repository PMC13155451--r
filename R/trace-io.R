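#' Read a per-frame trace file
#'
#' Trace files hold exactly one R-wave gated cardiac cycle as comma-separated
#' values with a `time_ms,strain_pct,size` header, preceded by metadata
#' comment lines `#chamber=LV|RV` and `#view=A2C|A3C|A4C|RV4C` (optionally
#' `#hr=<bpm>`). Decimal point is `.`; the time column is milliseconds from
#' the end-diastolic frame, strictly increasing and uniformly spaced within
#' 10% of the median frame interval. At least 25 frames are required and the
#' size column must be positive everywhere.
#'
#' @param path Path to the trace file.
#' @return An object of class `svl_trace`: a data frame with columns
#'   `time_ms`, `strain_pct`, `size` and attributes `chamber`, `view` and
#'   (if present) `hr`.
#' @seealso [write_trace()], [as_cardiac_cycle()]
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop("read_trace: file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- tryCatch(
    utils::read.csv(text = body, header = TRUE, colClasses = "numeric"),
    error = function(e) stop("read_trace: ", path, ": cannot parse body (",
                             conditionMessage(e), ")", call. = FALSE))
  required <- c("time_ms", "strain_pct", "size")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("read_trace: ", path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  validate_trace_frames(df, path)
  chamber <- meta$chamber
  if (is.null(chamber) || !chamber %in% c("LV", "RV")) {
    stop("read_trace: ", path, ": missing or invalid '#chamber=' metadata",
         call. = FALSE)
  }
  view <- meta$view
  if (is.null(view) || !view %in% c("A2C", "A3C", "A4C", "RV4C")) {
    stop("read_trace: ", path, ": missing or invalid '#view=' metadata",
         call. = FALSE)
  }
  structure(df, chamber = chamber, view = view,
            hr = if (!is.null(meta$hr)) as.numeric(meta$hr) else NULL,
            class = c("svl_trace", "data.frame"))
}

validate_trace_frames <- function(df, path) {
  n <- nrow(df)
  if (n < 25) {
    stop("read_trace: ", path, ": only ", n, " frames; one cycle at ",
         ">= 50 Hz requires at least 25", call. = FALSE)
  }
  if (any(!is.finite(as.matrix(df)))) {
    stop("read_trace: ", path, ": non-finite values", call. = FALSE)
  }
  dt <- diff(df$time_ms)
  if (any(dt <= 0)) {
    stop("read_trace: ", path, ": time_ms not strictly increasing at row ",
         which(dt <= 0)[1] + 1, call. = FALSE)
  }
  med <- stats::median(dt)
  off <- which(abs(dt - med) > 0.1 * med)
  if (length(off)) {
    stop("read_trace: ", path, ": non-uniform sampling at frame ", off[1] + 1,
         " (interval ", signif(dt[off[1]], 4), " ms vs median ",
         signif(med, 4), " ms)", call. = FALSE)
  }
  if (any(df$size <= 0)) {
    stop("read_trace: ", path, ": size must be positive everywhere",
         call. = FALSE)
  }
  invisible(df)
}

#' Write a per-frame trace file
#'
#' Inverse of [read_trace()]; values are written with 6 decimals so a
#' write/read round trip preserves them to that precision.
#'
#' @param trace An `svl_trace`, or a [cardiac_cycle()] (then `view` must be
#'   given).
#' @param path Output path.
#' @param view View token, required when `trace` is a `cardiac_cycle`.
#' @param hr Optional heart rate (bpm) recorded as metadata.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, view = NULL, hr = NULL) {
  if (inherits(trace, "cardiac_cycle")) {
    if (is.null(view)) {
      stop("write_trace: 'view' is required when writing a cardiac_cycle",
           call. = FALSE)
    }
    df <- data.frame(
      time_ms = (seq_along(trace$size) - 1L) * 1000 / trace$frame_rate,
      strain_pct = trace$strain, size = trace$size)
    chamber <- trace$chamber
  } else if (inherits(trace, "svl_trace")) {
    df <- as.data.frame(trace)
    chamber <- attr(trace, "chamber")
    view <- if (is.null(view)) attr(trace, "view") else view
    if (is.null(hr)) hr <- attr(trace, "hr")
  } else {
    stop("write_trace: expected an svl_trace or cardiac_cycle", call. = FALSE)
  }
  if (!nrow(df)) stop("write_trace: empty trace rejected", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("#chamber=", chamber), paste0("#view=", view),
               if (!is.null(hr)) sprintf("#hr=%.4f", hr),
               "time_ms,strain_pct,size"), con)
  writeLines(sprintf("%.6f,%.6f,%.6f", df$time_ms, df$strain_pct, df$size),
             con)
  invisible(path)
}

#' Convert a parsed trace to a cardiac cycle
#'
#' @param trace An `svl_trace` from [read_trace()].
#' @return A [cardiac_cycle()].
#' @export
as_cardiac_cycle <- function(trace) {
  stopifnot(inherits(trace, "svl_trace"))
  dt <- stats::median(diff(trace$time_ms))
  cardiac_cycle(strain = trace$strain_pct, size = trace$size,
                chamber = attr(trace, "chamber"), frame_rate = 1000 / dt)
}

manifest_columns <- function() {
  c("subject", "scan", "observer", "analysis", "chamber", "view", "path",
    "hr", "matched_cycle")
}

#' Read and validate a study manifest
#'
#' The manifest is a comma-separated table with columns `subject`, `scan`,
#' `observer`, `analysis`, `chamber`, `view`, `path`, `hr`, `matched_cycle`
#' mapping every analysis arm to a trace file. Keys
#' `(subject, scan, observer, analysis, view)` must be unique; `scan`,
#' `observer` and `analysis` must be 1 or 2; chamber/view tokens must be
#' valid; referenced paths (relative to the manifest's directory) must
#' exist unless `check_paths = FALSE`.
#'
#' @param path Path to the manifest file.
#' @param check_paths Verify that every referenced trace file exists.
#' @return A data frame of class `study_manifest` with the trace paths
#'   resolved relative to the manifest location.
#' @export
read_study_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) {
    stop("read_study_manifest: file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(manifest_columns(), names(df))
  if (length(missing_cols)) {
    stop("read_study_manifest: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("scan", "observer", "analysis")) {
    if (!all(df[[col]] %in% c(1L, 2L))) {
      stop("read_study_manifest: column '", col, "' must be 1 or 2",
           call. = FALSE)
    }
  }
  if (!all(df$chamber %in% c("LV", "RV"))) {
    stop("read_study_manifest: unknown chamber token: ",
         paste(unique(setdiff(df$chamber, c("LV", "RV"))), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$view %in% c("A2C", "A3C", "A4C", "RV4C"))) {
    stop("read_study_manifest: unknown view token: ",
         paste(unique(setdiff(df$view, c("A2C", "A3C", "A4C", "RV4C"))),
               collapse = ", "), call. = FALSE)
  }
  key <- with(df, paste(subject, scan, observer, analysis, view))
  if (anyDuplicated(key)) {
    stop("read_study_manifest: duplicate (subject, scan, observer, ",
         "analysis, view) row: ", key[duplicated(key)][1], call. = FALSE)
  }
  df$matched_cycle <- as.logical(df$matched_cycle)
  root <- dirname(normalizePath(path))
  abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                file.path(root, df$path))
  if (check_paths) {
    gone <- !file.exists(abs)
    if (any(gone)) {
      stop("read_study_manifest: dangling trace path(s): ",
           paste(utils::head(df$path[gone], 3), collapse = ", "),
           call. = FALSE)
    }
  }
  df$path <- abs
  class(df) <- c("study_manifest", "data.frame")
  df
}

#' Write a synthetic cohort to trace files plus a manifest
#'
#' Materializes a [generate_cohort()] result as one trace file per
#' (subject, scan, observer, analysis, view) and a `manifest.csv` in
#' `dir`, suitable for [read_study_manifest()] and [run_study()].
#'
#' @param cohort An `svl_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "svl_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- cohort$index
  idx$path <- paste0(idx$key, ".csv")
  for (r in seq_len(nrow(idx))) {
    write_trace(cohort$cycles[[idx$key[r]]],
                file.path(dir, idx$path[r]),
                view = idx$view[r], hr = idx$hr[r])
  }
  out <- idx[manifest_columns()]
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(out, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load a manifest and its traces as a cohort-like object
#'
#' @param manifest_path Path to a manifest file.
#' @return An `svl_cohort`-classed list with `cycles` and `index` (no
#'   generator `config`).
#' @export
load_cohort <- function(manifest_path) {
  mf <- read_study_manifest(manifest_path)
  cycles <- list()
  key <- with(mf, sprintf("S%03d_T%d_O%d_A%d_%s_%s", subject, scan, observer,
                          analysis, chamber, view))
  for (r in seq_len(nrow(mf))) {
    cycles[[key[r]]] <- as_cardiac_cycle(read_trace(mf$path[r]))
  }
  idx <- mf
  idx$key <- key
  structure(list(cycles = cycles, index = as.data.frame(idx), config = NULL),
            class = "svl_cohort")
}
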