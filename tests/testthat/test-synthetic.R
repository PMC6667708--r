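panel <- builtin_cervid_panel()

test_that("generation is deterministic under a fixed seed and leaves the RNG alone", {
  cfg <- synth_config(grid_range = c(1000, 1500), seed = 99)
  a <- generate_spectrum("Synthodon", mini_panel(), cfg)
  b <- generate_spectrum("Synthodon", mini_panel(), cfg)
  expect_identical(a$intensity, b$intensity)
  expect_identical(attr(a, "truth"), attr(b, "truth"))

  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_spectrum("Synthodon", mini_panel(), cfg))
  expect_identical(runif(1), before)

  expect_error(generate_spectrum("Moose", mini_panel(), cfg), "not in panel")
})

test_that("noiseless spectra place apexes at the panel masses", {
  cfg <- synth_config(noise_sigma = 0, baseline_amplitude = 0,
                      noise_floor = 0, seed = 1)
  sp <- generate_spectrum("White-Tailed Deer", panel, cfg)
  truth <- attr(sp, "truth")
  expect_true(all(c(3043, 3059) %in% truth$panel_mass))
  for (m in truth$panel_mass) {
    win <- which(abs(sp$mz - m) < 1)
    apex <- sp$mz[win[which.max(sp$intensity[win])]]
    expect_lte(abs(apex - m), cfg$grid_step)
  }
})

test_that("the miscalibration model shifts peaks as configured", {
  cfg <- synth_config(noise_sigma = 0, baseline_amplitude = 0, noise_floor = 0,
                      mass_error_offset = 0.1, mass_error_slope = 20,
                      grid_range = c(1000, 1500), seed = 1)
  sp <- generate_spectrum("Synthodon", mini_panel(), cfg)
  truth <- attr(sp, "truth")
  expect_equal(truth$observed_mass,
               truth$panel_mass * (1 + 20e-6) + 0.1, tolerance = 1e-12)
})

test_that("planted peaks reconcile with picked peaks at high SNR", {
  for (seed in 1:5) {
    cfg <- synth_config(seed = seed)
    sp <- generate_spectrum("Red Deer", panel, cfg)
    pl <- preprocess_spectrum(sp)
    truth <- attr(sp, "truth")
    for (m in truth$observed_mass) {
      expect_true(any(abs(pl$mz - m) <= 3 * cfg$grid_step))
    }
    # no spurious full-grade peaks: everything at pick SNR is a planted peak
    strong <- pl$mz[pl$snr >= 3]
    expect_true(all(vapply(strong, function(p)
      any(abs(truth$observed_mass - p) <= 3 * cfg$grid_step), logical(1))))
  }
})

test_that("HMWP attenuation follows its closed form and is monotone in tau", {
  mz <- seq(1800, 2800, 0.5)
  sp <- mass_spectrum(mz, rep(100, length(mz)), "flat")

  ident <- degrade_hmwp(sp, degradation_config("destructive"))
  expect_identical(ident$intensity, sp$intensity)

  huge_tau <- degrade_hmwp(sp, degradation_config("bag", tau = 1e12))
  expect_equal(huge_tau$intensity, sp$intensity, tolerance = 1e-6)

  d <- degradation_config("bag", onset_mz = 2000, tau = 500)
  out <- degrade_hmwp(sp, d)
  at <- which.min(abs(mz - 2500))
  expect_equal(out$intensity[at], 100 * exp(-1), tolerance = 1e-6)
  below <- mz <= 2000
  expect_identical(out$intensity[below], sp$intensity[below])

  taus <- c(100, 200, 500, 1000, 5000)
  prev <- degrade_hmwp(sp, degradation_config("bag", tau = taus[1]))$intensity
  for (t in taus[-1]) {
    cur <- degrade_hmwp(sp, degradation_config("bag", tau = t))$intensity
    expect_true(all(cur >= prev - 1e-12))
    prev <- cur
  }
})

test_that("contaminant injection updates spectra and truth records", {
  cfg <- synth_config(grid_range = c(850, 1500), seed = 4)
  sp <- generate_spectrum("Synthodon", mini_panel(), cfg)
  same <- inject_keratin(sp, numeric(), config = cfg)
  expect_identical(same$intensity, sp$intensity)

  with_ker <- inject_keratin(sp, c(1277.7, 1300.5, 1365.6), config = cfg)
  truth <- attr(with_ker, "truth")
  expect_equal(sum(truth$kind == "keratin"), 3L)
  expect_true(all(with_ker$intensity >= sp$intensity))

  expect_error(inject_keratin(sp, 5000, config = cfg), "outside")
  expect_error(inject_polymer_series(sp, 900, 44, n = 0, config = cfg),
               "n >= 1")

  with_poly <- inject_polymer_series(sp, 900, 44, n = 6, config = cfg)
  expect_equal(sum(attr(with_poly, "truth")$kind == "polymer"), 6L)
  # a single injected peak can never be a series
  one <- inject_polymer_series(sp, 900, 44, n = 1, config = cfg)
  expect_equal(sum(attr(one, "truth")$kind == "polymer"), 1L)
})

test_that("planted polymer series survive noise and are always detected", {
  hits <- 0L
  for (seed in 1:50) {
    cfg <- synth_config(grid_range = c(850, 1500), seed = seed)
    sp <- generate_spectrum("Synthodon", mini_panel(), cfg)
    sp <- inject_polymer_series(sp, 900, 44.05, n = 6, config = cfg)
    pl <- preprocess_spectrum(sp)
    series <- detect_polymer_series(pl)
    planted <- attr(sp, "truth")
    planted <- planted$observed_mass[planted$kind == "polymer"]
    found <- any(vapply(series, function(s)
      all(vapply(planted, function(m) any(abs(s$mz - m) < 0.1), logical(1))),
      logical(1)))
    hits <- hits + found
  }
  expect_equal(hits, 50L)
})

test_that("the artefact fixture carries the published identifications", {
  rec <- load_table1_fixture()
  artefacts <- rec[!rec$is_control, ]
  expect_equal(nrow(artefacts), 15L)
  expect_equal(sum(rec$is_control), 1L)

  dr21 <- rec[rec$sample_id == "DR-21s", ]
  expect_identical(dr21$destructive, "Bear")
  expect_identical(dr21$dna, "U. americanus")

  expect_equal(summarize_fixture(rec, method = "destructive",
                                 value_class = "tested"), 11L)
  expect_equal(summarize_fixture(rec, method = "destructive",
                                 value = "White-tailed deer"), 3L)
  expect_equal(summarize_fixture(rec, burnt = TRUE), 2L)
  expect_equal(summarize_fixture(rec[0, ]), 0L)

  # method-wise tables and input validation
  tab <- summarize_fixture(rec, method = "eraser")
  expect_equal(unname(tab["Human"]), 2L)
  expect_error(summarize_fixture(rec, method = "microwave"), "unknown method")

  bad <- rec
  bad$eraser[1] <- "???"
  expect_error(summarize_fixture(bad, method = "eraser"), "vocabulary")
})
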