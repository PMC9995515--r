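# Shared fixtures: small synthetic configurations and toy recordings built
# in code at test time.

small_montage <- function(k = 4) {
  c("C3", "C4", "Pz", "Oz", "Fz", "Cz")[seq_len(k)]
}

small_band_amplitude <- function(theta = c(never = 4, past = 4, smoker = 4),
                                 alpha = c(never = 5, past = 5, smoker = 5)) {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    never = c(4, theta[["never"]], alpha[["never"]], 2, 1),
    past = c(4, theta[["past"]], alpha[["past"]], 2, 1),
    smoker = c(4, theta[["smoker"]], alpha[["smoker"]], 2, 1)
  )
}

# A fast cohort: few channels, short recordings, no planted correlations.
# Overrides replace defaults wholesale (no recursive merging of tables).
small_config <- function(...) {
  overrides <- list(...)
  defaults <- list(
    n_per_group = c(never = 3, past = 3, smoker = 3),
    sample_rate = 128,
    duration = 8,
    montage = small_montage(4),
    band_amplitude = small_band_amplitude(),
    background_rms = 2,
    alpha_ec_gain = c(never = 1.3, past = 1.3, smoker = 1.3),
    alpha_shared_fraction = c(never = 0.2, past = 0.2, smoker = 0.2),
    planted_correlations = resteeg:::default_planted_correlations()[0, ],
    seed = 7
  )
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  do.call(effect_config, defaults)
}

# Recording holding a sum of sinusoids, identical on every channel.
sine_recording <- function(freqs, amps = rep(1, length(freqs)), fs = 128,
                           duration = 10, nch = 2, offset = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- offset + Reduce(`+`, Map(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  eeg_recording(
    data = matrix(rep(x, each = nch), nrow = nch),
    sample_rate = fs,
    channel_labels = paste0("ch", seq_len(nch)),
    subject_id = "sine"
  )
}

# Brute-force Kruskal-Wallis H from the rank-sum definition with tie
# correction (independent oracle).
kw_brute_force <- function(groups) {
  v <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(v)
  n <- length(v)
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(v)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exhaustive two-sided Mann-Whitney p-value by enumerating all group
# assignments (tie-free samples).
mw_enumerate_p <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(length(pool), n1)
  u_all <- apply(cmb, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}
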