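#' Synthetic spectrum configuration
#'
#' Generative parameters of the spectrum simulator.  Peaks are Gaussian
#' profiles at panel marker masses; the trace adds an exponentially
#' decaying chemical baseline, a constant noise floor and i.i.d. Gaussian
#' detector noise; peak positions can be perturbed by a linear
#' miscalibration model (constant offset plus ppm slope).
#'
#' @param peak_fwhm Peak full width at half maximum in Da (default 0.3).
#' @param peak_snr Target peak signal-to-noise: peak apex height is
#'   `peak_snr * noise_sigma` (default 20).
#' @param noise_sigma Detector noise sigma in arbitrary units (default 1).
#' @param noise_floor Constant intensity offset (default 5) keeping the
#'   noisy trace essentially non-negative; removed by baseline subtraction.
#' @param baseline_amplitude,baseline_decay Exponential baseline
#'   `amplitude * exp(-(mz - grid_min)/decay)` (defaults 5 and 600 Da).
#' @param mass_error_offset Constant mass shift in Da (default 0).
#' @param mass_error_slope Proportional mass drift in ppm (default 0).
#' @param grid_range m/z range `c(min, max)` in Da (default `c(800, 3600)`).
#' @param grid_step Grid step in Da (default 0.02).
#' @param seed Integer seed fixing all randomness (default 1).
#' @param deamidation If `TRUE`, each marker peak gains a +0.984 Da
#'   satellite at half height (off by default; a stress test for match
#'   tolerances, not panel logic).
#' @return A list of class `zooms_synth_config`.
#' @export
synth_config <- function(peak_fwhm = 0.3, peak_snr = 20, noise_sigma = 1.0,
                         noise_floor = 5, baseline_amplitude = 5,
                         baseline_decay = 600, mass_error_offset = 0,
                         mass_error_slope = 0, grid_range = c(800, 3600),
                         grid_step = 0.02, seed = 1L, deamidation = FALSE) {
  stopifnot(peak_fwhm > 0, peak_snr >= 0, noise_sigma >= 0, noise_floor >= 0,
            baseline_amplitude >= 0, baseline_decay > 0,
            length(grid_range) == 2L, grid_range[1] < grid_range[2],
            grid_step > 0, is.logical(deamidation))
  structure(
    list(peak_fwhm = peak_fwhm, peak_snr = peak_snr,
         noise_sigma = noise_sigma, noise_floor = noise_floor,
         baseline_amplitude = baseline_amplitude,
         baseline_decay = baseline_decay,
         mass_error_offset = mass_error_offset,
         mass_error_slope = mass_error_slope,
         grid_range = as.numeric(grid_range), grid_step = grid_step,
         seed = as.integer(seed), deamidation = deamidation),
    class = "zooms_synth_config"
  )
}

#' High-molecular-weight-peptide degradation configuration
#'
#' Non-destructive collagen recovery yields degraded spectra in which long
#' peptides are under-represented; the effect is modelled as a single
#' exponential attenuation above an onset mass: intensities at
#' `m/z > onset_mz` are multiplied by `exp(-(m/z - onset_mz)/tau)`.
#' Destructive acquisition applies no attenuation.
#'
#' @param mode One of `"destructive"` (identity), `"bag"` or `"eraser"`.
#' @param onset_mz Attenuation onset in Da (default 2000; the markers that
#'   suffer in practice sit at or above ~2800).
#' @param tau Attenuation scale in Da; defaults per mode (`Inf` for
#'   destructive, 400 for bag, 800 for eraser — bags degrade harder).
#' @return A list of class `zooms_degradation_config`.
#' @export
degradation_config <- function(mode = c("destructive", "bag", "eraser"),
                               onset_mz = 2000, tau = NULL) {
  mode <- match.arg(mode)
  if (is.null(tau)) {
    tau <- switch(mode, destructive = Inf, bag = 400, eraser = 800)
  }
  stopifnot(onset_mz > 0, tau > 0)
  structure(list(mode = mode, onset_mz = onset_mz, tau = tau),
            class = "zooms_degradation_config")
}

## peak apex height; with noise_sigma = 0 (noiseless spectra) unit noise
## is used as the height scale so peaks do not degenerate to zero
synth_amp <- function(config) {
  config$peak_snr * if (config$noise_sigma > 0) config$noise_sigma else 1
}

hmwp_factor <- function(mz, dconfig) {
  if (dconfig$mode == "destructive") return(rep(1, length(mz)))
  ifelse(mz > dconfig$onset_mz, exp(-(mz - dconfig$onset_mz) / dconfig$tau), 1)
}

## evaluate seeded expression without disturbing the caller's RNG stream
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## sum of Gaussian profiles, each evaluated only within +-6 sigma
add_gaussians <- function(grid, signal, masses, heights, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  for (k in seq_along(masses)) {
    lo <- findInterval(masses[k] - 6 * sigma, grid) + 1L
    hi <- findInterval(masses[k] + 6 * sigma, grid)
    if (hi < lo) next
    idx <- lo:hi
    signal[idx] <- signal[idx] +
      heights[k] * exp(-(grid[idx] - masses[k])^2 / (2 * sigma^2))
  }
  signal
}

truth_record <- function(marker_id, panel_mass, observed_mass, height, kind) {
  data.frame(marker_id = marker_id, panel_mass = panel_mass,
             observed_mass = observed_mass, height = height, kind = kind,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic marker spectrum for a taxon
#'
#' Plants Gaussian peaks at every marker mass the panel expects for the
#' taxon (both members of paired markers); `EXPECTED` and
#' `EXPECTED_DIAGNOSTIC` markers at full height `peak_snr * noise_sigma`,
#' `EXPECTED_UNCERTAIN` markers at half height.  Peak positions are
#' shifted by the miscalibration model; baseline, noise floor and i.i.d.
#' Gaussian noise are added on top, and the trace is clipped at zero.
#' An optional [degradation_config()] attenuates the *peptide signal*
#' above its onset before noise is added — analyte loss does not shrink
#' detector noise, which is what makes high-mass markers sink below the
#' SNR thresholds in degraded acquisitions.
#'
#' @param taxon_label A taxon of `panel`.
#' @param panel A marker panel (default the built-in cervid panel).
#' @param config A [synth_config()]; `config$seed` fixes all randomness.
#' @param degradation Optional [degradation_config()].
#' @return A [mass_spectrum()] with attribute `"truth"`: the planted peak
#'   table (marker id, panel mass, observed mass, height after
#'   degradation, kind).
#' @export
generate_spectrum <- function(taxon_label, panel = builtin_cervid_panel(),
                              config = synth_config(), degradation = NULL) {
  stopifnot(inherits(panel, "zooms_marker_panel"))
  if (!taxon_label %in% panel$taxa$taxon_label) {
    stop("taxon not in panel: ", taxon_label, "; available: ",
         paste(panel$taxa$taxon_label, collapse = ", "), call. = FALSE)
  }
  exp_states <- panel$expectations[taxon_label, ]
  ids <- names(exp_states)[exp_states != "ABSENT"]
  marker_id <- character(); panel_mass <- numeric(); height <- numeric()
  amp <- synth_amp(config)
  for (id in ids) {
    m <- marker_masses(panel, id)
    h <- if (exp_states[[id]] == "EXPECTED_UNCERTAIN") amp / 2 else amp
    marker_id <- c(marker_id, rep(id, length(m)))
    panel_mass <- c(panel_mass, m)
    height <- c(height, rep(h, length(m)))
  }
  if (config$deamidation) {
    marker_id <- c(marker_id, marker_id)
    height <- c(height, height / 2)
    panel_mass <- c(panel_mass, panel_mass + 0.984)
  }
  observed <- panel_mass * (1 + config$mass_error_slope * 1e-6) +
    config$mass_error_offset
  if (any(observed < config$grid_range[1] | observed > config$grid_range[2])) {
    stop("panel masses fall outside the synthetic grid range", call. = FALSE)
  }
  if (!is.null(degradation)) {
    stopifnot(inherits(degradation, "zooms_degradation_config"))
    height <- height * hmwp_factor(observed, degradation)
  }
  grid <- seq(config$grid_range[1], config$grid_range[2],
              by = config$grid_step)
  signal <- add_gaussians(grid, numeric(length(grid)), observed, height,
                          config$peak_fwhm)
  baseline <- config$baseline_amplitude *
    exp(-(grid - config$grid_range[1]) / config$baseline_decay)
  noise <- with_local_seed(config$seed,
                           stats::rnorm(length(grid), 0, config$noise_sigma))
  intensity <- pmax(signal + baseline + config$noise_floor + noise, 0)
  out <- mass_spectrum(grid, intensity, sample_id = taxon_label,
                       acquisition_label = if (is.null(degradation))
                         "synthetic" else paste0("synthetic-", degradation$mode))
  attr(out, "truth") <- truth_record(marker_id, panel_mass, observed, height,
                                     "marker")
  attr(out, "config") <- config
  out
}

#' Attenuate high-molecular-weight peptides
#'
#' Multiplies intensities at `m/z > onset_mz` by
#' `exp(-(m/z - onset_mz)/tau)`; intensities below the onset (and the
#' whole spectrum in destructive mode) are unchanged.  When degrading a
#' spectrum *before* detector noise is added — the physically meaningful
#' order — use the `degradation` argument of [generate_spectrum()].
#'
#' @param spectrum A [mass_spectrum()].
#' @param dconfig A [degradation_config()].
#' @return The attenuated [mass_spectrum()] (truth heights, if present,
#'   are attenuated consistently).
#' @export
degrade_hmwp <- function(spectrum, dconfig = degradation_config("bag")) {
  stopifnot(is_spectrum(spectrum), inherits(dconfig, "zooms_degradation_config"))
  out <- mass_spectrum(spectrum$mz,
                       spectrum$intensity * hmwp_factor(spectrum$mz, dconfig),
                       spectrum$sample_id, dconfig$mode)
  truth <- attr(spectrum, "truth")
  if (!is.null(truth)) {
    truth$height <- truth$height * hmwp_factor(truth$observed_mass, dconfig)
    attr(out, "truth") <- truth
  }
  attr(out, "config") <- attr(spectrum, "config")
  out
}

inject_gaussians <- function(spectrum, masses, heights, config, kind) {
  stopifnot(is_spectrum(spectrum))
  if (length(masses) == 0L) return(spectrum)
  stopifnot(length(heights) == length(masses))
  rng <- range(spectrum$mz)
  if (any(masses < rng[1] | masses > rng[2])) {
    stop("injected mass outside the spectrum grid", call. = FALSE)
  }
  intensity <- add_gaussians(spectrum$mz, spectrum$intensity, masses, heights,
                             config$peak_fwhm)
  out <- mass_spectrum(spectrum$mz, intensity, spectrum$sample_id,
                       spectrum$acquisition_label)
  attr(out, "truth") <- rbind(
    attr(spectrum, "truth"),
    truth_record(paste0(kind, seq_along(masses)), masses, masses, heights, kind)
  )
  attr(out, "config") <- attr(spectrum, "config")
  out
}

#' Inject keratin contaminant peaks
#'
#' Adds Gaussian peaks at the given keratin masses and records them in the
#' truth table (kind `"keratin"`), so contaminant-flagging round trips can
#' be checked against planted ground truth.
#'
#' @param spectrum A [mass_spectrum()].
#' @param masses Keratin m/z values; must lie inside the spectrum grid.
#' @param heights Peak heights; defaults to `peak_snr * noise_sigma` of
#'   `config`.
#' @param config A [synth_config()] providing the peak width.
#' @return The spectrum with added peaks and updated `"truth"` attribute.
#' @export
inject_keratin <- function(spectrum, masses, heights = NULL,
                           config = synth_config()) {
  if (is.null(heights)) {
    heights <- rep(synth_amp(config), length(masses))
  }
  inject_gaussians(spectrum, masses, heights, config, "keratin")
}

#' Inject an equally spaced polymer peak series
#'
#' Adds `n` Gaussian peaks at `start_mz + (0:(n-1)) * spacing` (truth kind
#' `"polymer"`), emulating plastic residues leaching from storage bags.
#'
#' @param spectrum A [mass_spectrum()].
#' @param start_mz First peak position (Da).
#' @param spacing Repeat spacing (Da).
#' @param n Number of peaks (>= 1).
#' @param height Peak height; defaults to `peak_snr * noise_sigma`.
#' @param config A [synth_config()] providing the peak width.
#' @return The spectrum with added peaks and updated `"truth"` attribute.
#' @export
inject_polymer_series <- function(spectrum, start_mz, spacing, n,
                                  height = NULL, config = synth_config()) {
  n <- as.integer(n)
  if (n < 1L) stop("polymer series needs n >= 1", call. = FALSE)
  stopifnot(spacing > 0)
  if (is.null(height)) height <- synth_amp(config)
  masses <- start_mz + (seq_len(n) - 1L) * spacing
  inject_gaussians(spectrum, masses, rep(height, n), config, "polymer")
}
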