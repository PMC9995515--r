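test_that("generation is bit-identical under a fixed seed", {
  cfg <- small_config()
  r1 <- generate_recording("past", "EC", cfg, 42)
  r2 <- generate_recording("past", "EC", cfg, 42)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording("past", "EC", cfg, 43)
  expect_false(identical(r1$data, r3$data))
  # conditions draw different signal noise but share subject parameters
  r4 <- generate_recording("past", "EO", cfg, 42)
  expect_false(identical(r1$data, r4$data))
})

test_that("whole-cohort generation is deterministic and counts recordings", {
  cfg <- small_config(n_per_group = c(never = 2, past = 2, smoker = 2), duration = 4)
  c1 <- generate_cohort(cfg)
  expect_length(c1$recordings, 12)
  c2 <- generate_cohort(cfg)
  expect_identical(
    lapply(c1$recordings, `[[`, "data"),
    lapply(c2$recordings, `[[`, "data")
  )
  expect_identical(c1$covariates, c2$covariates)
  expect_equal(nrow(c1$covariates), 6)
  expect_equal(nrow(c1$ground_truth$subjects), 6)
})

test_that("unknown labels and invalid configurations are rejected", {
  cfg <- small_config()
  expect_error(generate_recording("vaper", "EC", cfg, 1), class = "resteeg_error_unknown_label")
  expect_error(generate_recording("never", "open", cfg, 1), class = "resteeg_error_unknown_label")
  expect_error(small_config(duration = 3), class = "resteeg_error_invalid_input")
  expect_error(
    small_config(n_per_group = c(never = 1, past = 3, smoker = 3)),
    class = "resteeg_error_invalid_input"
  )
  expect_error(
    small_config(alpha_shared_fraction = c(never = 1.2, past = 0.2, smoker = 0.2)),
    class = "resteeg_error_invalid_input"
  )
  expect_error(
    small_config(alpha_ec_gain = c(never = 0.8, past = 1.2, smoker = 1.2)),
    class = "resteeg_error_invalid_input"
  )
})

test_that("a zeroed theta amplitude lowers relative theta at every channel", {
  amp <- small_band_amplitude(theta = c(never = 4, past = 0, smoker = 0))
  cfg <- small_config(
    n_per_group = c(never = 10, past = 10, smoker = 10),
    band_amplitude = amp
  )
  tables <- resteeg:::cohort_feature_tables(cfg)
  theta <- tables$features[tables$features$band == "theta" &
    tables$features$condition == "EC", ]
  by_ch <- theta |>
    dplyr::group_by(.data$channel, .data$group) |>
    dplyr::summarise(m = mean(.data$rel_power), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "m")
  expect_true(all(by_ch$past < by_ch$never))
  expect_true(all(by_ch$smoker < by_ch$never))
})

test_that("eyes-closed gain produces positive alpha reactivity and none elsewhere", {
  cfg <- small_config(
    n_per_group = c(never = 6, past = 6, smoker = 6),
    duration = 16,
    alpha_ec_gain = c(never = 1.5, past = 1.5, smoker = 1.5)
  )
  tables <- resteeg:::cohort_feature_tables(cfg)
  for (src in c("absolute", "relative")) {
    reac <- resteeg:::reactivity_table(tables$features, source = src)
    means <- tapply(reac$reactivity, reac$band, mean)
    expect_gt(means[["alpha"]], 0.25)
    if (src == "absolute") {
      for (b in c("delta", "gamma")) expect_lt(abs(means[[b]]), 0.12)
    }
  }
})

test_that("realized single-band RMS stays within 10% of the configured amplitude", {
  for (b in c("delta", "alpha", "gamma")) {
    amp_tbl <- tibble::tibble(
      band = eeg_bands()$band,
      never = ifelse(eeg_bands()$band == b, 5, 0),
      past = 0, smoker = 0
    )
    cfg <- small_config(
      duration = 60, band_amplitude = amp_tbl, background_rms = 0,
      subject_sdlog = 0, alpha_ec_gain = c(never = 1, past = 1, smoker = 1)
    )
    rec <- generate_recording("never", "EC", cfg, 17)
    # band-filtered variance: a measurement band slightly wider than the
    # component's own, so the measuring filter's edge droop does not bias
    # the estimate (the configuration has no other components)
    be <- eeg_bands()[eeg_bands()$band == b, ]
    filt <- eeg_bandpass(rec, max(0.7 * be$f_low, 0.3), min(1.3 * be$f_high, 63))
    got <- sqrt(mean(filt$data^2))
    expect_equal(got, 5, tolerance = 0.10)
  }
})

test_that("covariates honor group summaries, bounds, integer scales and missing rates", {
  cfg <- small_config(n_per_group = c(never = 220, past = 220, smoker = 220))
  cov <- generate_covariates(cfg, features = NULL, seed = 5)
  expect_equal(nrow(cov), 660)

  ftnd <- cov$ftnd[cov$group == "smoker"]
  expect_equal(mean(ftnd, na.rm = TRUE), 5.58, tolerance = 0.35)
  expect_true(all(ftnd >= 0 & ftnd <= 10, na.rm = TRUE))
  expect_true(all(is.na(cov$ftnd[cov$group == "never"])))

  qa <- cov$quit_attempts[cov$group == "past"]
  expect_true(all(qa == round(qa), na.rm = TRUE))
  expect_equal(mean(is.na(qa)), 10 / 28, tolerance = 0.12)
  expect_equal(mean(is.na(cov$age)), 0)

  # deterministic under the seed
  cov2 <- generate_covariates(cfg, features = NULL, seed = 5)
  expect_identical(cov, cov2)
})

test_that("planted correlations are recovered and validated", {
  cfg <- small_config(
    n_per_group = c(never = 16, past = 24, smoker = 24),
    duration = 16,
    band_amplitude = small_band_amplitude(theta = c(never = 5, past = 4.4, smoker = 4)),
    planted_correlations = tibble::tibble(
      covariate = c("ftnd", "qsu"),
      feature = c("rel_theta_ec", "rel_theta_ec"),
      r = c(-0.40, 0)
    )
  )
  tables <- resteeg:::cohort_feature_tables(cfg)
  feats <- resteeg:::summarise_subject_features(tables)
  cov <- generate_covariates(cfg, features = feats, seed = 2)
  merged <- dplyr::inner_join(feats, cov, by = c("subject", "group"))
  merged <- merged[merged$group %in% c("past", "smoker"), ]
  r_ftnd <- stats::cor(merged$rel_theta_ec, merged$ftnd, use = "complete.obs")
  expect_lt(abs(r_ftnd - (-0.40)), 0.25)
  r_qsu <- stats::cor(merged$rel_theta_ec, merged$qsu, use = "complete.obs")
  expect_lt(abs(r_qsu), 2 / sqrt(sum(stats::complete.cases(merged$qsu))) + 0.1)

  bad_r <- cfg
  bad_r$planted_correlations <- tibble::tibble(
    covariate = "ftnd", feature = "rel_theta_ec", r = 1.2
  )
  expect_error(
    generate_covariates(bad_r, features = feats, seed = 2),
    class = "resteeg_error_invalid_input"
  )
  bad_f <- cfg
  bad_f$planted_correlations <- tibble::tibble(
    covariate = "ftnd", feature = "not_a_feature", r = 0.3
  )
  expect_error(
    generate_covariates(bad_f, features = feats, seed = 2),
    class = "resteeg_error_unknown_label"
  )
  expect_error(
    generate_covariates(cfg, features = NULL, seed = 2),
    class = "resteeg_error_invalid_input"
  )
})

test_that("effect configurations round-trip through the plain-text format", {
  cfg <- small_config(spikes = tibble::tibble(
    subject = "never01", condition = "EC", epoch = 1L, amplitude = 300
  ))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_effect_config(cfg, path)
  back <- read_effect_config(path)
  expect_equal(back$n_per_group, cfg$n_per_group)
  expect_equal(back$montage, cfg$montage)
  expect_equal(back$band_amplitude, cfg$band_amplitude)
  expect_equal(back$alpha_shared_fraction, cfg$alpha_shared_fraction)
  expect_equal(back$seed, cfg$seed)
  r1 <- generate_recording("never", "EC", cfg, 8)
  r2 <- generate_recording("never", "EC", back, 8)
  expect_identical(r1$data, r2$data)
})
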