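# small, fast study configurations used across tests

clean_config <- function(...) {
  sim_config(drift_amplitude = 0, cardiac_amplitude = 0, noise_sd = 0,
             missing_rate = 0, subject_jitter_sd = 0, ...)
}

tiny_trial <- function(label = "LF", seed = 101, config = clean_config()) {
  generate_trial(config, label, seed = seed)
}

# Jaccard index of two integer intervals given as c(start, end)
interval_jaccard <- function(a, b) {
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  un <- (a[2] - a[1] + 1) + (b[2] - b[1] + 1) - ov
  ov / un
}

rms <- function(x) sqrt(mean(x^2))

# independently coded oracles -------------------------------------------------

# CBSI equations coded literally, element by element
oracle_cbsi <- function(hb, hbo2) {
  n <- length(hb)
  sd_pop <- function(v) {
    m <- sum(v) / n
    sqrt(sum((v - m)^2) / n)
  }
  a <- sd_pop(hbo2) / sd_pop(hb)
  tns <- numeric(n); tfs <- numeric(n)
  for (i in seq_len(n)) {
    tns[i] <- (hbo2[i] + a * hb[i]) / 2
    tfs[i] <- (hbo2[i] - a * hb[i]) / 2
  }
  list(alpha = a, tns = tns, tfs = tfs)
}

oracle_dbsi <- function(hb, hbo2) {
  n <- length(hb)
  cms <- numeric(n); dms <- numeric(n)
  for (i in seq_len(n)) {
    cms[i] <- (hbo2[i] + hb[i]) / 2
    dms[i] <- (hbo2[i] - hb[i]) / 2
  }
  list(cms = cms, dms = dms)
}

# least-squares slope by explicitly solving the 2x2 normal equations
oracle_slope <- function(x, t) {
  X <- cbind(1, t)
  beta <- solve(t(X) %*% X, t(X) %*% x)
  beta[2]
}
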