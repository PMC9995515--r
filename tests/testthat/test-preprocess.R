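test_that("band-pass keeps in-band tones, removes out-of-band power and DC", {
  fs <- 500
  rec60 <- sine_recording(60, fs = fs, duration = 30)
  out60 <- eeg_bandpass(rec60, 1, 50)
  expect_lt(
    sqrt(mean(out60$data[1, ]^2)) / sqrt(mean(rec60$data[1, ]^2)),
    0.10
  )

  rec10 <- sine_recording(10, fs = fs, duration = 30)
  out10 <- eeg_bandpass(rec10, 1, 50)
  expect_equal(
    sqrt(mean(out10$data[1, ]^2)), sqrt(mean(rec10$data[1, ]^2)),
    tolerance = 0.05
  )

  recdc <- sine_recording(10, fs = fs, duration = 30, offset = 100)
  outdc <- eeg_bandpass(recdc, 1, 50)
  expect_lt(abs(mean(outdc$data[1, ])), 1)

  # attenuation at least 20 dB (power) one octave beyond the band edges
  rec100 <- sine_recording(100, fs = fs, duration = 30)
  p_ratio <- mean(eeg_bandpass(rec100, 1, 50)$data[1, ]^2) / mean(rec100$data[1, ]^2)
  expect_lt(10 * log10(p_ratio), -20)
  rec05 <- sine_recording(0.5, fs = fs, duration = 30)
  p_ratio <- mean(eeg_bandpass(rec05, 1, 50)$data[1, ]^2) / mean(rec05$data[1, ]^2)
  expect_lt(10 * log10(p_ratio), -20)

  expect_error(eeg_bandpass(rec10, 50, 1), class = "resteeg_error_invalid_input")
  expect_error(eeg_bandpass(rec10, 0, 50), class = "resteeg_error_invalid_input")
  expect_error(eeg_bandpass(rec10, 1, 400), class = "resteeg_error_invalid_input")
})

test_that("common average reference zeroes the channel mean and is idempotent", {
  set.seed(5)
  rec <- eeg_recording(
    matrix(rnorm(4 * 1000, sd = 10), 4), 128, paste0("ch", 1:4)
  )
  ref <- rereference_car(rec)
  expect_lt(max(abs(colMeans(ref$data))), 1e-10)
  expect_equal(rereference_car(ref)$data, ref$data)

  # already zero-mean channels are unchanged
  bal <- eeg_recording(rbind(rep(1, 100), rep(-1, 100)), 128, c("a", "b"))
  expect_equal(rereference_car(bal)$data, bal$data)

  # identical channels cancel to zero
  same <- eeg_recording(matrix(rep(rnorm(100), each = 3), 3, byrow = FALSE), 128, letters[1:3])
  same$data <- matrix(rep(rnorm(100), times = 3), 3, byrow = TRUE)
  expect_lt(max(abs(rereference_car(same)$data)), 1e-12)

  single <- eeg_recording(matrix(rnorm(200), 1), 128, "a")
  expect_error(rereference_car(single), class = "resteeg_error_invalid_input")
})

test_that("epoching counts, trims and reconstructs exactly", {
  fs <- 128
  rec <- eeg_recording(matrix(rnorm(2 * 180 * fs), 2), fs, c("a", "b"))
  ep <- make_epochs(rec, 2)
  expect_equal(n_epochs(ep), 90)

  rec39 <- eeg_recording(matrix(rnorm(2 * 1950), 2), 500, c("a", "b"))
  expect_equal(n_epochs(make_epochs(rec39, 2)), 1)

  rec2 <- eeg_recording(matrix(rnorm(2 * 256), 2), 128, c("a", "b"))
  ep2 <- make_epochs(rec2, 2)
  expect_equal(n_epochs(ep2), 1)
  expect_equal(ep2$data[, , 1], rec2$data)

  # concatenating all epochs reconstructs the trimmed signal
  rec_odd <- eeg_recording(matrix(rnorm(2 * 700), 2), 128, c("a", "b"))
  ep_odd <- make_epochs(rec_odd, 2)
  rebuilt <- do.call(cbind, lapply(seq_len(n_epochs(ep_odd)), function(e) ep_odd$data[, , e]))
  expect_equal(rebuilt, rec_odd$data[, seq_len(512)])

  expect_error(make_epochs(rec2, 0), class = "resteeg_error_invalid_input")
  short <- eeg_recording(matrix(rnorm(2 * 100), 2), 128, c("a", "b"))
  expect_error(make_epochs(short, 2), class = "resteeg_error_invalid_input")
})

test_that("amplitude rejection flags exactly the offending epochs", {
  fs <- 128
  quiet <- eeg_recording(matrix(runif(2 * 10 * fs, -10, 10), 2), fs, c("a", "b"))
  ep <- reject_amplitude(make_epochs(quiet, 2), 75)
  expect_equal(rejected_epochs(ep), integer(0))
  expect_false(is_excluded(ep))

  spiked <- quiet
  spiked$data[1, 2 * (2 * fs) + 50] <- 200 # one sample inside epoch 3
  ep3 <- reject_amplitude(make_epochs(spiked, 2), 75)
  expect_equal(rejected_epochs(ep3), 3L)

  # all epochs above threshold flags the subject x condition as excluded
  loud <- eeg_recording(matrix(rnorm(2 * 8 * fs, sd = 100), 2), fs, c("a", "b"))
  expect_true(is_excluded(reject_amplitude(make_epochs(loud, 2), 75)))

  expect_error(reject_amplitude(ep, -5), class = "resteeg_error_invalid_input")
})

test_that("spikes injected by the generator are rejected at exactly the planted epochs", {
  spikes <- tibble::tibble(
    subject = c("smoker01", "smoker01", "never02"),
    condition = c("EC", "EC", "EO"),
    epoch = c(2L, 4L, 1L),
    amplitude = 400
  )
  cfg <- small_config(spikes = spikes)
  subs <- resteeg:::cohort_subjects(cfg)
  seed_s <- subs$subject_seed[subs$subject == "smoker01"]
  rec <- generate_recording("smoker", "EC", cfg, seed_s, subject_id = "smoker01")
  ep <- preprocess_recording(rec)
  expect_equal(rejected_epochs(ep), c(2L, 4L))

  seed_n <- subs$subject_seed[subs$subject == "never02"]
  rec2 <- generate_recording("never", "EO", cfg, seed_n, subject_id = "never02")
  expect_equal(rejected_epochs(preprocess_recording(rec2)), 1L)
  # the same subject's other condition is untouched
  rec3 <- generate_recording("never", "EC", cfg, seed_n, subject_id = "never02")
  expect_equal(rejected_epochs(preprocess_recording(rec3)), integer(0))
})

test_that("spectral-power outlier screen is per condition and needs 3 subjects per group", {
  # group sizes matching the study scale: the inclusive 3 SD rule only has
  # room to fire once n reaches about a dozen (|z| <= (n-1)/sqrt(n))
  base <- tidyr::expand_grid(
    subject = sprintf("s%02d", 1:40),
    condition = c("EC", "EO"),
    channel = c("C3", "C4"),
    band = eeg_bands()$band
  )
  base$group <- rep(c("never", "smoker"), each = nrow(base) / 2)
  base$abs_power <- 10

  mask <- exclude_power_outliers(base, 3)
  expect_true(all(mask$included))
  expect_true(all(mask$z == 0))

  # one subject at the group mean plus 10 within-group SDs, EC only:
  # excluded in EC, kept in EO
  set.seed(41)
  jitter_tbl <- tibble::tibble(
    subject = sprintf("s%02d", 1:40),
    mult = rnorm(40, 1, 0.02)
  )
  out <- dplyr::mutate(
    dplyr::left_join(base, jitter_tbl, by = "subject"),
    abs_power = .data$abs_power * .data$mult
  )
  never_ec <- out$group == "never" & out$condition == "EC"
  m <- mean(jitter_tbl$mult[1:20])
  s <- stats::sd(jitter_tbl$mult[1:20])
  out$abs_power[never_ec & out$subject == "s03"] <- 10 * (m + 10 * s)
  mask2 <- exclude_power_outliers(dplyr::select(out, -"mult"), 3)
  excl <- mask2[!mask2$included, ]
  expect_equal(excl$subject, "s03")
  expect_equal(excl$condition, "EC")
  expect_true(mask2$included[mask2$subject == "s03" & mask2$condition == "EO"])

  tiny <- base[base$subject %in% c("s01", "s02", "s21", "s22", "s23"), ]
  expect_error(exclude_power_outliers(tiny, 3), class = "resteeg_error_degenerate")
})

test_that("power outliers planted by the generator are recovered exactly", {
  cfg <- small_config(
    n_per_group = c(never = 4, past = 20, smoker = 4),
    power_outliers = tibble::tibble(
      subject = "past02", condition = "EC", scale = 3
    )
  )
  tables <- resteeg:::cohort_feature_tables(cfg)
  mask <- exclude_power_outliers(tables$features, 3)
  excl <- mask[!mask$included, ]
  expect_equal(excl$subject, "past02")
  expect_equal(excl$condition, "EC")
})
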