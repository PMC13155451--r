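#' Compute the loop-parameter table of a cohort
#'
#' For every (subject, scan, observer, analysis, chamber) cell of a cohort
#' or manifest, averages the LV apical views ([average_views()]) or takes
#' the single RV-focused view, builds the loop and extracts the ten loop
#' parameters. Rows are ordered deterministically by subject, chamber, scan,
#' observer, analysis.
#'
#' @param x An `svl_cohort` from [generate_cohort()] / [load_cohort()], or a
#'   manifest path.
#' @param min_views Minimum LV views per cell (passed to [average_views()]).
#' @param grid_size,dedrift,ess_fraction Passed to the parameter extraction.
#' @return A data frame with design columns (`subject`, `scan`, `observer`,
#'   `analysis`, `chamber`, `arm`, `hr`, `matched_cycle`) and one column per
#'   loop parameter.
#' @export
compute_parameter_table <- function(x, min_views = 2L, grid_size = 101L,
                                    dedrift = FALSE, ess_fraction = 0.05) {
  cohort <- if (inherits(x, "svl_cohort")) x else load_cohort(x)
  idx <- cohort$index
  cell_id <- with(idx, paste(subject, chamber, scan, observer, analysis,
                             sep = "|"))
  rows <- list()
  for (cid in unique(cell_id)) {
    sub <- idx[cell_id == cid, , drop = FALSE]
    cycles <- cohort$cycles[sub$key]
    cyc <- if (sub$chamber[1] == "LV") {
      average_views(cycles, min_views = min_views)
    } else {
      if (length(cycles) > 1) {
        average_views(cycles, min_views = 1L)  # unused in practice
      } else cycles[[1]]
    }
    pars <- compute_loop_parameters(cyc, grid_size = grid_size,
                                    dedrift = dedrift,
                                    ess_fraction = ess_fraction)
    rows[[cid]] <- cbind(
      data.frame(subject = sub$subject[1], scan = sub$scan[1],
                 observer = sub$observer[1], analysis = sub$analysis[1],
                 chamber = sub$chamber[1], hr = sub$hr[1],
                 matched_cycle = all(sub$matched_cycle)),
      pars)
  }
  out <- do.call(rbind, rows)
  out$arm <- arm_label(out$scan, out$observer, out$analysis)
  rownames(out) <- NULL
  out[order(out$subject, out$chamber, out$scan, out$observer, out$analysis), ]
}

arm_label <- function(scan, observer, analysis) {
  ifelse(scan == 2, "retest",
         ifelse(observer == 2, "inter",
                ifelse(analysis == 2, "intra", "baseline")))
}

design_model <- function(design) {
  switch(design, intra = "two_way_mixed", retest = "two_way_mixed",
         inter = "two_way_random",
         stop("unknown design: ", design, call. = FALSE))
}

# Baseline/comparison pairs for one chamber, parameter and design,
# merged by subject; returns a data frame with baseline/comparison columns.
design_pairs <- function(pt, chamber, param, design) {
  base <- pt[pt$chamber == chamber & pt$arm == "baseline", ]
  comp <- pt[pt$chamber == chamber & pt$arm == design, ]
  m <- merge(base[c("subject", "hr", param)],
             comp[c("subject", "hr", "matched_cycle", param)],
             by = "subject", suffixes = c("_base", "_comp"))
  data.frame(subject = m$subject,
             baseline = m[[paste0(param, "_base")]],
             comparison = m[[paste0(param, "_comp")]],
             hr_base = m$hr_base, hr_comp = m$hr_comp,
             matched_cycle = m$matched_cycle)
}

#' Median and interquartile range
#'
#' Quantiles by linear interpolation (the common type-7 convention).
#'
#' @param values Numeric vector with at least one value.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @examples
#' summarize_median_iqr(1:5)
#' @export
summarize_median_iqr <- function(values) {
  if (!length(values)) {
    stop("summarize_median_iqr: empty input", call. = FALSE)
  }
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Run the full reliability study
#'
#' Orchestrates the end-to-end analysis: loop parameters per analysis arm,
#' then for every chamber, parameter and design (intra-observer,
#' inter-observer, test-retest) the ICC(A,1) with its design-appropriate
#' model label (mixed for intra and retest, random for inter), the
#' Bland-Altman analysis and the Wilcoxon signed-rank test versus the
#' baseline arm (scan 1, observer 1, analysis 1), plus per-arm median/IQR
#' summaries and the matched-cycle and heart-rate sensitivity analyses.
#' Cells that cannot be computed (missing arms, degenerate tables) are
#' marked not computable rather than dropped.
#'
#' @param x An `svl_cohort`, a manifest path, or a parameter table from
#'   [compute_parameter_table()].
#' @param hr_threshold Relative heart-rate difference between scans above
#'   which a subject is excluded in the heart-rate sensitivity analysis.
#' @param ... Passed to [compute_parameter_table()].
#' @return An object of class `study_report`: list with `parameters` (the
#'   per-arm parameter table), `agreement` (ICC + Bland-Altman + Wilcoxon
#'   per chamber x parameter x design), `medians` (per-arm median/IQR with
#'   Wilcoxon flags vs baseline), `sensitivity_matched` and
#'   `sensitivity_hr`, and `excluded` (per-design count of subjects missing
#'   an arm).
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1, n_subjects = 6,
#'                                      chambers = "LV"))
#' rep <- run_study(coh)
#' head(rep$agreement[c("chamber", "parameter", "design", "icc")])
#' @export
run_study <- function(x, hr_threshold = 0.10, ...) {
  pt <- if (is.data.frame(x) && all(c("arm", "ss") %in% names(x))) x
        else compute_parameter_table(x, ...)
  params <- loop_parameter_names()
  chambers <- unique(pt$chamber)
  designs <- c("intra", "inter", "retest")

  agreement <- list()
  excluded <- list()
  for (ch in chambers) {
    n_base <- length(unique(pt$subject[pt$chamber == ch &
                                         pt$arm == "baseline"]))
    for (de in designs) {
      pairs0 <- design_pairs(pt, ch, params[1], de)
      excluded[[paste(ch, de)]] <- data.frame(
        chamber = ch, design = de, n_used = nrow(pairs0),
        n_excluded = n_base - nrow(pairs0))
      for (pa in params) {
        pairs <- design_pairs(pt, ch, pa, de)
        agreement[[paste(ch, de, pa)]] <-
          agreement_row(pairs, ch, pa, de)
      }
    }
  }
  agreement <- do.call(rbind, agreement)
  rownames(agreement) <- NULL

  medians <- list()
  for (ch in chambers) for (arm in c("baseline", designs)) {
    sub <- pt[pt$chamber == ch & pt$arm == arm, ]
    if (!nrow(sub)) next
    for (pa in params) {
      s <- summarize_median_iqr(sub[[pa]])
      wp <- NA_real_; wflag <- NA_character_
      if (arm != "baseline") {
        pairs <- design_pairs(pt, ch, pa, arm)
        if (nrow(pairs) >= 3) {
          wt <- wilcoxon_signed_rank(pairs$baseline, pairs$comparison)
          wp <- wt$p; wflag <- wt$flag
        }
      }
      medians[[paste(ch, arm, pa)]] <- data.frame(
        chamber = ch, arm = arm, parameter = pa,
        median = s[["median"]], q1 = s[["q1"]], q3 = s[["q3"]],
        wilcoxon_p = wp, significant = !is.na(wp) & wp < 0.05,
        wilcoxon_flag = wflag)
    }
  }
  medians <- do.call(rbind, medians)
  rownames(medians) <- NULL

  report <- structure(
    list(parameters = pt, agreement = agreement, medians = medians,
         excluded = do.call(rbind, excluded),
         sensitivity_matched = NULL, sensitivity_hr = NULL),
    class = "study_report")
  report$sensitivity_matched <- sensitivity_matched_cycles(pt, report)
  report$sensitivity_hr <- sensitivity_hr_filter(pt, report,
                                                 threshold = hr_threshold)
  report
}

agreement_row <- function(pairs, chamber, param, design) {
  out <- data.frame(chamber = chamber, parameter = param, design = design,
                    model = design_model(design), n = nrow(pairs),
                    icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    f = NA_real_, p = NA_real_,
                    koo_li_class = NA_character_,
                    bias = NA_real_, sd_diff = NA_real_,
                    loa_low = NA_real_, loa_high = NA_real_,
                    prop_bias_slope = NA_real_, prop_bias_p = NA_real_,
                    wilcoxon_p = NA_real_, wilcoxon_flag = NA_character_,
                    not_computable = TRUE)
  if (nrow(pairs) < 3) return(out)
  tab <- cbind(pairs$baseline, pairs$comparison)
  ir <- icc_single_agreement(tab, model = design_model(design))
  ba <- bland_altman(pairs$baseline, pairs$comparison)
  wt <- wilcoxon_signed_rank(pairs$baseline, pairs$comparison)
  out$icc <- ir$icc; out$ci_low <- ir$ci_low; out$ci_high <- ir$ci_high
  out$f <- ir$f; out$p <- ir$p; out$koo_li_class <- ir$koo_li_class
  out$bias <- ba$bias; out$sd_diff <- ba$sd_diff
  out$loa_low <- ba$loa_low; out$loa_high <- ba$loa_high
  out$prop_bias_slope <- ba$prop_bias_slope
  out$prop_bias_p <- ba$prop_bias_p
  out$wilcoxon_p <- wt$p; out$wilcoxon_flag <- wt$flag
  out$not_computable <- ir$not_computable
  out
}

#' Matched-cycle sensitivity analysis
#'
#' Recomputes the intra- and inter-observer ICCs on the subset of subjects
#' whose repeat analysis used the same cardiac cycle as the baseline
#' analysis (`matched_cycle` flag), and reports the change
#' `delta_icc = subset - full` plus any change in Koo-Li class. Subsets
#' smaller than 3 subjects are marked not computable.
#'
#' @param pt A parameter table from [compute_parameter_table()].
#' @param report Optional `study_report` providing the full-cohort ICCs
#'   (recomputed if omitted).
#' @return Data frame with full and subset ICCs, `delta_icc`, subset size
#'   and class-change flag per chamber x parameter x design.
#' @export
sensitivity_matched_cycles <- function(pt, report = NULL) {
  params <- loop_parameter_names()
  rows <- list()
  for (ch in unique(pt$chamber)) for (de in c("intra", "inter")) {
    for (pa in params) {
      pairs <- design_pairs(pt, ch, pa, de)
      full <- if (nrow(pairs) >= 3) {
        icc_single_agreement(cbind(pairs$baseline, pairs$comparison),
                             model = design_model(de))
      } else list(icc = NA_real_, koo_li_class = NA_character_)
      sub <- pairs[pairs$matched_cycle, , drop = FALSE]
      if (nrow(sub) >= 3) {
        ir <- icc_single_agreement(cbind(sub$baseline, sub$comparison),
                                   model = design_model(de))
        rows[[paste(ch, de, pa)]] <- data.frame(
          chamber = ch, design = de, parameter = pa,
          n_matched = nrow(sub), icc_full = full$icc, icc_matched = ir$icc,
          delta_icc = ir$icc - full$icc,
          class_full = full$koo_li_class, class_matched = ir$koo_li_class,
          class_changed = !identical(full$koo_li_class, ir$koo_li_class),
          not_computable = isTRUE(ir$not_computable))
      } else {
        rows[[paste(ch, de, pa)]] <- data.frame(
          chamber = ch, design = de, parameter = pa,
          n_matched = nrow(sub), icc_full = full$icc,
          icc_matched = NA_real_, delta_icc = NA_real_,
          class_full = full$koo_li_class, class_matched = NA_character_,
          class_changed = NA, not_computable = TRUE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heart-rate difference sensitivity analysis
#'
#' Recomputes the test-retest ICCs after excluding subjects whose heart rate
#' differed between the two scans by more than `threshold` (relative to the
#' first scan). Subjects with a missing heart rate are retained with a
#' warning.
#'
#' @param pt A parameter table from [compute_parameter_table()].
#' @param report Optional `study_report` (full ICCs recomputed if omitted).
#' @param threshold Relative heart-rate difference cutoff (default 0.10).
#' @return Data frame with full and filtered ICCs and the number excluded,
#'   per chamber x parameter.
#' @export
sensitivity_hr_filter <- function(pt, report = NULL, threshold = 0.10) {
  params <- loop_parameter_names()
  rows <- list()
  for (ch in unique(pt$chamber)) {
    for (pa in params) {
      pairs <- design_pairs(pt, ch, pa, "retest")
      full <- if (nrow(pairs) >= 3) {
        icc_single_agreement(cbind(pairs$baseline, pairs$comparison),
                             model = "two_way_mixed")
      } else list(icc = NA_real_)
      hr_missing <- is.na(pairs$hr_base) | is.na(pairs$hr_comp)
      if (any(hr_missing)) {
        warning("sensitivity_hr_filter: ", sum(hr_missing), " subject(s) ",
                "without per-scan heart rate retained")
      }
      rel <- abs(pairs$hr_comp - pairs$hr_base) / pairs$hr_base
      keep <- hr_missing | (rel <= threshold)
      sub <- pairs[keep, , drop = FALSE]
      ok <- nrow(sub) >= 3
      ir <- if (ok) {
        icc_single_agreement(cbind(sub$baseline, sub$comparison),
                             model = "two_way_mixed")
      } else list(icc = NA_real_, not_computable = TRUE)
      rows[[paste(ch, pa)]] <- data.frame(
        chamber = ch, parameter = pa, n_kept = nrow(sub),
        n_excluded = nrow(pairs) - nrow(sub),
        icc_full = full$icc, icc_filtered = ir$icc,
        delta_icc = ir$icc - full$icc,
        not_computable = !ok || isTRUE(ir$not_computable))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.study_report <- function(x, ...) {
  cat("Strain-size loop reliability report\n")
  cat("  chambers:", paste(unique(x$parameters$chamber), collapse = "/"),
      "  subjects:", length(unique(x$parameters$subject)), "\n\n")
  show <- x$agreement[x$agreement$parameter %in%
                        c("ss", "ps", "early_u", "late_u"),
                      c("chamber", "parameter", "design", "icc", "ci_low",
                        "ci_high", "p", "koo_li_class")]
  print(show, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Mean loops of two analysis arms
#'
#' Per-arm mean loop over subjects: each subject's (view-averaged) cycle is
#' resampled onto 201 points of normalized cycle time, strain and size are
#' averaged across subjects, and the mean loop is drawn with the systolic
#' phase as a continuous line and diastole dashed.
#'
#' @param cohort An `svl_cohort`.
#' @param arms Two arm labels among `"baseline"`, `"intra"`, `"inter"`,
#'   `"retest"` (default baseline vs retest).
#' @param chamber Chamber to plot.
#' @param file Optional path; if given the figure is saved there.
#' @return A `ggplot` object (invisibly if `file` is given).
#' @export
render_mean_loops <- function(cohort, arms = c("baseline", "retest"),
                              chamber = "LV", file = NULL) {
  stopifnot(inherits(cohort, "svl_cohort"), length(arms) == 2)
  idx <- cohort$index
  idx$arm <- arm_label(idx$scan, idx$observer, idx$analysis)
  dat <- list()
  for (arm in arms) {
    sub <- idx[idx$arm == arm & idx$chamber == chamber, , drop = FALSE]
    if (!nrow(sub)) stop("render_mean_loops: no cycles in arm '", arm, "'",
                         call. = FALSE)
    per_subj <- lapply(split(sub, sub$subject), function(s) {
      cycles <- cohort$cycles[s$key]
      cyc <- if (chamber == "LV" && length(cycles) > 1) {
        average_views(cycles)
      } else cycles[[1]]
      resample_cycle(cyc, 201L)
    })
    strain <- rowMeans(vapply(per_subj, `[[`, numeric(201), "strain"))
    size <- rowMeans(vapply(per_subj, `[[`, numeric(201), "size"))
    es <- which.min(size)
    dat[[arm]] <- data.frame(
      arm = arm, size = size, strain = strain,
      phase = rep(c("systole", "diastole"), c(es, 201 - es)))
  }
  dat <- do.call(rbind, dat)
  xlab <- if (chamber == "LV") "LV volume (mL)" else "RV area (cm²)"
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = size, y = strain,
                                         colour = arm, linetype = phase)) +
    ggplot2::geom_path(linewidth = 0.8) +
    ggplot2::scale_linetype_manual(values = c(systole = "solid",
                                              diastole = "dashed")) +
    ggplot2::labs(x = xlab, y = "Longitudinal strain (%)",
                  colour = "Arm", linetype = "Phase") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 4.5)
    return(invisible(p))
  }
  p
}
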