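# Independent oracles and small constructed fixtures used across the suite.

# Exact two-sided rank-sum p-value by full enumeration of all C(n+m, n)
# assignments of the pooled ranks to the first group. Mirrors the
# conventional two-sided definition p = min(1, 2 * min(P(U <= u), P(U >= u)))
# where U is the Mann-Whitney statistic of the first group.
enumerate_ranksum_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(idx) {
    sum(ranks[idx]) - n * (n + 1) / 2
  })
  p_low <- mean(u_all <= u_obs + 1e-9)
  p_high <- mean(u_all >= u_obs - 1e-9)
  min(1, 2 * min(p_low, p_high))
}

# Exact conditional (Fisher) two-sided p-value for a 2x2 table by direct
# enumeration of the hypergeometric support.
enumerate_fisher_p <- function(tab) {
  a <- tab[1, 1]
  row1 <- sum(tab[1, ])
  col1 <- sum(tab[, 1])
  total <- sum(tab)
  support <- max(0, col1 + row1 - total):min(row1, col1)
  probs <- stats::dhyper(support, row1, total - row1, col1)
  p_obs <- stats::dhyper(a, row1, total - row1, col1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A flat trace at `baseline` with raised-cosine pulses added at the given
# onsets; a direct, noise-free construction independent of the simulator.
make_pulse_trace <- function(duration = 900, baseline = 5, fs = 100,
                             onsets = numeric(0), amplitude = 50,
                             width = 40, phase_label = "vehicle") {
  n <- round(duration * fs)
  tt <- (seq_len(n) - 1) / fs
  p <- rep(baseline, n)
  for (o in onsets) {
    sel <- tt >= o & tt <= o + width
    p[sel] <- p[sel] + amplitude * 0.5 * (1 - cos(2 * pi * (tt[sel] - o) / width))
  }
  cpmcassay:::new_pressure_trace(p, fs, phase_label, 0)
}

# Hand-built per-phase metrics table for one experiment, for decision-rule
# tests that need full control over the numbers.
make_metrics <- function(amplitude, tiq, concentrations = c(0.3, 3, 30)) {
  labels <- c("vehicle", paste0("conc", seq_along(concentrations)))
  data.frame(
    phase_index = seq_along(labels),
    concentration = c(0, concentrations),
    phase_label = labels,
    frequency = 6,
    ti_mean = 150,
    tiq = tiq,
    amplitude_mean = amplitude,
    auc = 6000,
    stringsAsFactors = FALSE
  )
}
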