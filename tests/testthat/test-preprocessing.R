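test_that("parameter invariants are enforced", {
  expect_error(preprocess_params(smoothing_window = 8L), "smoothing_window")
  expect_error(preprocess_params(smoothing_polyorder = 9L,
                                 smoothing_window = 9L), "smoothing_polyorder")
  expect_error(preprocess_params(snr_low_threshold = 3, snr_pick_threshold = 3),
               "snr_low_threshold")
})

test_that("replicate averaging is idempotent, linear and order-invariant", {
  mz <- seq(1000, 1010, 0.05)
  sp <- mass_spectrum(mz, gauss_bump(mz, 1005, 50) + 1, "s")
  avg <- average_replicates(list(sp, sp, sp), resample_step = 0.05)
  expect_equal(stats::approx(avg$mz, avg$intensity, xout = mz[5:150])$y,
               sp$intensity[5:150], tolerance = 1e-9)

  zero <- mass_spectrum(mz, rep(0, length(mz)), "z")
  half <- average_replicates(list(sp, zero), resample_step = 0.05)
  expect_equal(half$intensity[10], sp$intensity[10] / 2, tolerance = 1e-9)

  set.seed(42)
  reps <- lapply(1:3, function(k)
    mass_spectrum(mz, pmax(10 + rnorm(length(mz)), 0), "r"))
  a <- average_replicates(reps)
  b <- average_replicates(rev(reps))
  expect_identical(a$intensity, b$intensity)

  disjoint <- mass_spectrum(mz + 100, sp$intensity, "d")
  expect_error(average_replicates(list(sp, disjoint)), "disjoint")
})

test_that("averaging three replicates shrinks noise by about sqrt(3)", {
  mz <- seq(1000, 1020, 0.02)
  ratios <- vapply(1:100, function(seed) {
    set.seed(seed)
    truth <- rep(20, length(mz))
    reps <- lapply(1:3, function(k)
      mass_spectrum(mz, truth + rnorm(length(mz)), "r"))
    avg <- average_replicates(reps)
    single_sd <- sd(reps[[1]]$intensity - truth)
    sd(avg$intensity - 20) / single_sd
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1 / sqrt(3)), 0.2 / sqrt(3))
})

test_that("smoothing reproduces low-order polynomials and reduces noise", {
  mz <- seq(1000, 1002, 0.02)
  const <- mass_spectrum(mz, rep(7, length(mz)), "c")
  expect_equal(smooth_spectrum(const)$intensity, const$intensity,
               tolerance = 1e-12)

  quad <- mass_spectrum(mz, 5 + 3 * (mz - 1000) + 2 * (mz - 1000)^2, "q")
  expect_equal(smooth_spectrum(quad)$intensity, quad$intensity,
               tolerance = 1e-9)

  set.seed(11)
  truth <- gauss_bump(mz, 1001, 30) + 5
  noisy <- mass_spectrum(mz, pmax(truth + rnorm(length(mz)), 0), "n")
  sm <- smooth_spectrum(noisy)
  expect_lt(sum((sm$intensity - truth)^2), sum((noisy$intensity - truth)^2))

  short <- mass_spectrum(1:5, rep(1, 5), "s")
  expect_error(smooth_spectrum(short), "shorter than")
})

test_that("baseline subtraction recovers peaks and removes pure baselines", {
  mz <- seq(1000, 1100, 0.02)
  peaks_only <- mass_spectrum(mz, gauss_bump(mz, 1030, 40) +
                                gauss_bump(mz, 1070, 25), "p")
  out <- subtract_baseline(peaks_only)
  expect_equal(out$intensity, peaks_only$intensity, tolerance = 1e-6)

  base <- 80 * exp(-(mz - 1000) / 50)
  with_base <- mass_spectrum(mz, peaks_only$intensity + base, "pb")
  out <- subtract_baseline(with_base)
  for (center in c(1030, 1070)) {
    apex_truth <- max(peaks_only$intensity[abs(mz - center) < 0.5])
    apex_est <- max(out$intensity[abs(mz - center) < 0.5])
    expect_lt(abs(apex_est - apex_truth) / apex_truth, 0.1)
  }

  pure <- mass_spectrum(mz, base, "b")
  expect_lt(max(subtract_baseline(pure)$intensity), 0.05 * max(base))

  zeroish <- mass_spectrum(mz, rep(0, length(mz)), "z")
  expect_equal(subtract_baseline(zeroish)$intensity, zeroish$intensity)
})

test_that("noise estimation is calibrated, scale-equivariant and peak-robust", {
  sp1 <- noise_spectrum(1, n = 20000, sigma = 1)
  est1 <- estimate_noise(sp1, 5)
  expect_gt(mean(est1 >= 0.8 & est1 <= 1.2), 0.95)
  expect_true(all(est1 > 0))

  sp2 <- noise_spectrum(1, n = 20000, sigma = 2, offset = 40)
  est2 <- estimate_noise(sp2, 5)
  expect_lt(abs(median(est2) / median(est1) - 2), 0.15)

  # a single huge peak leaves the estimate away from it untouched
  y <- sp1$intensity + gauss_bump(sp1$mz, 1200, 500)
  est_pk <- estimate_noise(mass_spectrum(sp1$mz, y, "pk"), 5)
  far <- abs(sp1$mz - 1200) > 10
  expect_lt(max(abs(est_pk[far] - est1[far]) / est1[far]), 0.1)

  # window wider than the spectrum: one global estimate
  small <- noise_spectrum(3, n = 50)
  expect_length(unique(estimate_noise(small, 1e6)), 1L)
})

test_that("peak picking finds planted peaks at accurate positions", {
  flat <- mass_spectrum(seq(1000, 1010, 0.02), rep(0, 501), "f")
  expect_equal(nrow(pick_peaks(flat)), 0L)

  set.seed(21)
  mz <- seq(1400, 1450, 0.02)
  y <- pmax(gauss_bump(mz, 1427, 20) + rnorm(length(mz)) + 10, 0)
  sp <- mass_spectrum(mz, y, "one")
  pl <- pick_peaks(subtract_baseline(smooth_spectrum(sp)),
                   noise = estimate_noise(sp, 5))
  strong <- pl[pl$snr >= 3, , drop = FALSE]
  expect_equal(nrow(strong), 1L)
  expect_lt(abs(strong$mz - 1427), 0.05)
})

test_that("peak picking equals the brute-force oracle on seeded spectra", {
  params <- preprocess_params()
  for (seed in 1:50) {
    set.seed(seed)
    n <- 1500
    mz <- seq(1000, by = 0.02, length.out = n)
    y <- 10 + rnorm(n)
    for (k in seq_len(sample(2:5, 1))) {
      y <- y + gauss_bump(mz, runif(1, 1002, 1028), runif(1, 4, 40))
    }
    sp <- mass_spectrum(mz, pmax(y, 0), paste0("o", seed))
    noise <- estimate_noise(sp, params$noise_window)
    got <- pick_peaks(sp, params, noise = noise)
    want <- oracle_pick_peaks(sp, params, noise)
    expect_equal(nrow(got), nrow(want))
    expect_true(all(abs(got$mz - want$mz) <= 0.02))   # parabolic refinement
    expect_equal(got$snr, want$snr, tolerance = 1e-12)
  }
})

test_that("raising either SNR threshold never adds peaks", {
  for (seed in 1:10) {
    set.seed(seed)
    mz <- seq(1000, by = 0.02, length.out = 2000)
    y <- pmax(10 + rnorm(2000) + gauss_bump(mz, 1010, 8) +
                gauss_bump(mz, 1025, 3), 0)
    sp <- mass_spectrum(mz, y, "m")
    noise <- estimate_noise(sp, 5)
    base <- pick_peaks(sp, preprocess_params(), noise = noise)
    higher_low <- pick_peaks(sp, preprocess_params(snr_low_threshold = 2.5),
                             noise = noise)
    expect_lte(nrow(higher_low), nrow(base))
    expect_true(all(vapply(higher_low$mz, function(m)
      any(abs(base$mz - m) < 1e-9), logical(1))))
    strong <- base[base$snr >= 4, , drop = FALSE]
    expect_lte(nrow(strong), nrow(base))
  }
})

test_that("close peaks are merged keeping the more intense", {
  mz <- seq(1000, 1002, 0.002)
  y <- gauss_bump(mz, 1000.9, 30, fwhm = 0.05) +
    gauss_bump(mz, 1001.05, 50, fwhm = 0.05) + 0.01
  sp <- mass_spectrum(mz, y, "merge")
  pl <- pick_peaks(sp, preprocess_params(min_peak_separation = 0.3),
                   noise = rep(1, length(mz)))
  expect_equal(nrow(pl), 1L)
  expect_lt(abs(pl$mz - 1001.05), 0.01)
})

test_that("linear recalibration corrects offsets and ppm drift", {
  refs <- c(1105, 1648, 2131, 2883)
  exact <- peak_list(refs, rep(10, 4), rep(10, 4), sample_id = "cal")
  out <- recalibrate(exact, refs)
  cal <- attr(out, "calibration")
  expect_lt(abs(cal$offset), 1e-9)
  expect_lt(abs(cal$slope - 1), 1e-9)

  shifted <- peak_list(refs + 0.15, rep(10, 4), rep(10, 4), sample_id = "s")
  out <- recalibrate(shifted, refs)
  expect_lt(max(abs(attr(out, "residuals"))), 0.01)
  expect_lt(max(abs(out$mz - refs)), 0.01)

  drifted <- peak_list(refs * (1 + 50e-6), rep(10, 4), rep(10, 4),
                       sample_id = "d")
  out <- recalibrate(drifted, refs)
  expect_lt(max(abs(attr(out, "residuals"))), 0.02)

  lone <- peak_list(1105, 10, 10, sample_id = "l")
  expect_warning(out <- recalibrate(lone, refs), "fewer than 2")
  expect_identical(out$mz, lone$mz)
})

test_that("consensus peak filter keeps peaks seen in enough replicates", {
  a <- peak_list(c(1105, 1427), c(10, 8), c(10, 8), sample_id = "r1")
  b <- peak_list(c(1105.05, 2131), c(11, 5), c(11, 5), sample_id = "r2")
  c3 <- peak_list(c(1104.95, 1427.04), c(9, 7), c(9, 7), sample_id = "r3")
  cons <- consensus_peaks(list(a, b, c3), min_votes = 2)
  expect_equal(nrow(cons), 2L)
  expect_true(all(abs(cons$mz - c(1105, 1427)) < 0.1))
})
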