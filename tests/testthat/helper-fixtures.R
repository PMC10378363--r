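# Shared fixtures: all synthetic, generated in code at test time.

# A small, fast simulation world: 3 classes x 18 cells, all sites present,
# full 600-1800 grid at the default 1.2 cm^-1 dispersion.
small_sim_config <- function(...) {
  sim_config(n_cells = c("NFC" = 18L, "NIH/3T3" = 18L, "MBM-T" = 18L),
             site_counts = NULL, ...)
}

# Random valid spectrum on an irregular-but-monotone grid.
random_spectrum <- function(n = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- sort(stats::runif(n, 600, 1800))
  while (any(diff(w) == 0)) w <- sort(stats::runif(n, 600, 1800))
  raman_spectrum(w, stats::rnorm(n))
}

# Independent sliding least-squares Savitzky-Golay oracle: fits a
# polynomial by lm() in each centred window of the mirror-padded signal.
savgol_oracle <- function(y, window, polyorder) {
  n <- length(y)
  h <- (window - 1L) %/% 2L
  ypad <- c(y[(h + 1L):2L], y, y[(n - 1L):(n - h)])
  out <- numeric(n)
  for (i in seq_len(n)) {
    yw <- ypad[i:(i + 2L * h)]
    t <- -h:h
    fit <- stats::lm(yw ~ poly(t, polyorder, raw = TRUE))
    out[i] <- unname(stats::predict(fit, data.frame(t = 0)))
  }
  out
}

# Hand-arithmetic confusion-matrix metrics oracle (percentages, NA on
# zero denominators).
metrics_oracle <- function(TP, FN, FP, TN) {
  div <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  c(ACC = div(TP + TN, TP + FN + FP + TN), SE = div(TP, TP + FN),
    SP = div(TN, TN + FP), PPV = div(TP, TP + FP), NPV = div(TN, TN + FN))
}

# Brute-force plateau scan oracle.
select_oracle <- function(acc, tol) {
  best <- max(acc)
  for (i in seq_along(acc)) if (acc[i] >= best - tol) return(i)
}
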