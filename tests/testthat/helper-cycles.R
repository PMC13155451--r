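# Shared fixtures: noiseless simulated cycles and random measurement tables.

lv_params <- function(...) {
  do.call(physio_params,
          utils::modifyList(list(edv = 120, esv = 50, peak_strain = -18,
                                 chamber = "LV"), list(...)))
}

noiseless_cycle <- function(params = lv_params(), n_frames = 60,
                            frame_rate = 58) {
  v <- simulate_volume_curve(params, n_frames)
  cardiac_cycle(simulate_strain_curve(v, params), v, params$chamber,
                frame_rate)
}

# Random complete n x 2 tables spanning a range of reliabilities.
random_table <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:40, 1)
  b <- stats::rnorm(n, 10, sqrt(stats::runif(1, 0.5, 4)))
  m <- matrix(b + stats::rnorm(2 * n, 0, stats::runif(1, 0.2, 1.5)), n, 2)
  sweep(m, 2, stats::rnorm(2, 0, stats::runif(1, 0, 1)), `+`)
}

# Independent oracle for ICC(A,1): mean squares from stats::aov, plugged
# into the agreement formulas coded here from scratch.
oracle_icc_a1 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = c(m),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
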