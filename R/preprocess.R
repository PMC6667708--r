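#' Preprocessing parameters
#'
#' Bundles every knob of the raw-spectrum-to-peak-list stage.  The two SNR
#' thresholds operationalise the usual two-grade reading of a peptide mass
#' fingerprint: peaks at or above `snr_pick_threshold` are full-grade
#' evidence ("present"), peaks in `[snr_low_threshold, snr_pick_threshold)`
#' are the low-intensity "?" grade.
#'
#' @param smoothing_window Odd window length (points) of the Savitzky-Golay
#'   smoother; the default (15 points = 0.3 Da at the default grid step)
#'   matches the expected peptide peak FWHM.
#' @param smoothing_polyorder Polynomial order of the smoother; must be
#'   smaller than the window.
#' @param baseline_iterations Number of SNIP iterations, i.e. the maximum
#'   half-window (points) of the baseline estimator.
#' @param noise_window Width (Da) of the sliding window of the robust noise
#'   estimator.
#' @param snr_pick_threshold SNR at or above which a peak is full-grade
#'   (default 3.0, the conventional detection limit).
#' @param snr_low_threshold SNR at or above which a peak is retained at all;
#'   peaks between the two thresholds are low-grade (default 1.5).
#' @param min_peak_separation Minimum distance (Da) between reported peaks;
#'   closer peaks are merged keeping the more intense (default 0.3).
#' @param resample_step Grid step (Da) used when averaging replicates
#'   (default 0.02).
#' @return A list of class `zooms_preprocess_params`.
#' @export
preprocess_params <- function(smoothing_window = 15L,
                              smoothing_polyorder = 2L,
                              baseline_iterations = 100L,
                              noise_window = 5,
                              snr_pick_threshold = 3.0,
                              snr_low_threshold = 1.5,
                              min_peak_separation = 0.3,
                              resample_step = 0.02) {
  smoothing_window <- as.integer(smoothing_window)
  smoothing_polyorder <- as.integer(smoothing_polyorder)
  baseline_iterations <- as.integer(baseline_iterations)
  stopifnot(
    smoothing_window > 0L, smoothing_window %% 2L == 1L,
    smoothing_polyorder > 0L, smoothing_polyorder < smoothing_window,
    baseline_iterations > 0L,
    noise_window > 0, snr_pick_threshold > 0, snr_low_threshold > 0,
    min_peak_separation > 0, resample_step > 0
  )
  if (snr_low_threshold >= snr_pick_threshold) {
    stop("snr_low_threshold must be < snr_pick_threshold", call. = FALSE)
  }
  structure(
    list(smoothing_window = smoothing_window,
         smoothing_polyorder = smoothing_polyorder,
         baseline_iterations = baseline_iterations,
         noise_window = noise_window,
         snr_pick_threshold = snr_pick_threshold,
         snr_low_threshold = snr_low_threshold,
         min_peak_separation = min_peak_separation,
         resample_step = resample_step),
    class = "zooms_preprocess_params"
  )
}

#' Average replicate spectra on a common grid
#'
#' MALDI targets are typically spotted in triplicate; the replicate traces
#' are linearly interpolated onto a uniform grid covering the intersection
#' of their m/z ranges and averaged pointwise.  A single spectrum is
#' returned resampled, without averaging.
#'
#' @param spectra List of [mass_spectrum()] objects with overlapping ranges.
#' @param resample_step Grid step in Da.
#' @return A [mass_spectrum()] on the uniform grid; its `sample_id` is taken
#'   from the first replicate.
#' @export
average_replicates <- function(spectra, resample_step = 0.02) {
  if (is_spectrum(spectra)) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L, all(vapply(spectra, is_spectrum, logical(1))))
  lo <- max(vapply(spectra, function(s) min(s$mz), numeric(1)))
  hi <- min(vapply(spectra, function(s) max(s$mz), numeric(1)))
  if (hi - lo < resample_step) {
    stop("replicate m/z ranges are disjoint (or overlap < one grid step)",
         call. = FALSE)
  }
  grid <- seq(lo, hi, by = resample_step)
  acc <- matrix(0, nrow = length(grid), ncol = length(spectra))
  for (k in seq_along(spectra)) {
    acc[, k] <- stats::approx(spectra[[k]]$mz, spectra[[k]]$intensity,
                              xout = grid, rule = 2)$y
  }
  mass_spectrum(grid, rowMeans(acc),
                sample_id = spectra[[1]]$sample_id,
                acquisition_label = spectra[[1]]$acquisition_label)
}

#' Consensus peak filter across replicate peak lists
#'
#' Alternative to profile averaging: a peak is kept if a matching peak
#' (within `tolerance`) occurs in at least `min_votes` replicate lists; the
#' retained record is the most intense of the matching peaks.
#'
#' @param peaklists List of [peak_list()] objects.
#' @param min_votes Minimum number of replicates a peak must occur in
#'   (default 2).
#' @param tolerance Match tolerance in Da (default 0.2).
#' @return A [peak_list()].
#' @export
consensus_peaks <- function(peaklists, min_votes = 2L, tolerance = 0.2) {
  stopifnot(length(peaklists) >= 1L,
            all(vapply(peaklists, is_peaklist, logical(1))))
  all_pk <- do.call(rbind, lapply(seq_along(peaklists), function(k) {
    df <- as.data.frame(peaklists[[k]])
    if (nrow(df) > 0L) df$replicate <- k
    df
  }))
  if (is.null(all_pk) || nrow(all_pk) == 0L) return(peaklists[[1]])
  all_pk <- all_pk[order(all_pk$mz), , drop = FALSE]
  # single-linkage clusters along m/z
  cluster <- cumsum(c(1, diff(all_pk$mz) > tolerance))
  keep <- do.call(rbind, lapply(split(all_pk, cluster), function(cl) {
    if (length(unique(cl$replicate)) >= min_votes) {
      cl[which.max(cl$intensity), c("mz", "intensity", "snr", "flags")]
    }
  }))
  if (is.null(keep)) {
    return(rebuild_peaklist(peaklists[[1]], numeric(), numeric(), numeric(),
                            character()))
  }
  keep <- keep[order(keep$mz), , drop = FALSE]
  rebuild_peaklist(peaklists[[1]], keep$mz, keep$intensity, keep$snr, keep$flags)
}

#' Savitzky-Golay smoothing
#'
#' Least-squares polynomial smoothing: any trace that is itself a polynomial
#' of degree `<= smoothing_polyorder` is reproduced exactly (including at the
#' edges).  Small negative excursions created near zero are clipped.
#'
#' @param spectrum A [mass_spectrum()] longer than the smoothing window.
#' @param params A [preprocess_params()].
#' @return The smoothed [mass_spectrum()] on the same grid.
#' @export
smooth_spectrum <- function(spectrum, params = preprocess_params()) {
  stopifnot(is_spectrum(spectrum))
  if (length(spectrum$mz) <= params$smoothing_window) {
    stop("spectrum shorter than the smoothing window", call. = FALSE)
  }
  y <- signal::sgolayfilt(spectrum$intensity,
                          p = params$smoothing_polyorder,
                          n = params$smoothing_window)
  mass_spectrum(spectrum$mz, pmax(y, 0),
                spectrum$sample_id, spectrum$acquisition_label)
}

## SNIP baseline estimate: iteratively clip each point to the mean of its
## neighbours at growing half-window i = 1..k.  Peaks (narrow relative to k)
## are eroded away; what remains is the baseline.
snip_baseline <- function(y, iterations) {
  n <- length(y)
  b <- y
  idx <- seq_len(n)
  for (i in seq_len(min(iterations, n - 1L))) {
    left <- b[pmax(idx - i, 1L)]
    right <- b[pmin(idx + i, n)]
    b <- pmin(b, (left + right) / 2)
  }
  b
}

## odd sliding-window length in points for a window given in Da
window_points <- function(mz, window_da) {
  step <- if (length(mz) > 1L) stats::median(diff(mz)) else window_da
  w <- round(window_da / step)
  if (w %% 2 == 0) w <- w + 1
  max(w, 3L)
}

#' Subtract the baseline of a spectrum
#'
#' Iterative SNIP (statistics-sensitive non-linear iterative peak-clipping)
#' baseline estimation followed by subtraction.  Because the clipping
#' estimate tracks the *lower envelope* of a noisy trace — leaving the
#' residual sitting about one noise sigma above zero — the residual is
#' recentred by its running median (window `noise_window`, which is wide
#' relative to peptide peaks and therefore insensitive to them) before
#' clipping at zero.  A flat-zero spectrum is returned unchanged.
#'
#' @param spectrum A [mass_spectrum()].
#' @param params A [preprocess_params()]; `baseline_iterations` sets the
#'   maximum clipping half-window in grid points.
#' @return The baseline-subtracted [mass_spectrum()]; the estimated
#'   envelope is attached as attribute `"baseline"`.
#' @export
subtract_baseline <- function(spectrum, params = preprocess_params()) {
  stopifnot(is_spectrum(spectrum))
  b <- snip_baseline(spectrum$intensity, params$baseline_iterations)
  r <- spectrum$intensity - b
  n <- length(r)
  w <- window_points(spectrum$mz, params$noise_window)
  if (w < n) {
    r <- r - stats::runmed(r, w, endrule = "median")
  }
  out <- mass_spectrum(spectrum$mz, pmax(r, 0),
                       spectrum$sample_id, spectrum$acquisition_label)
  attr(out, "baseline") <- b
  out
}

#' Robust per-point noise level
#'
#' Sliding-window median absolute deviation about the running median,
#' scaled by 1.4826 to the sigma of a Gaussian.  Windows wider than the
#' spectrum fall back to a single global estimate.  The returned level is
#' strictly positive.
#'
#' @param spectrum A [mass_spectrum()].
#' @param noise_window Window width in Da.
#' @return Numeric vector of noise sigma estimates, one per spectrum point.
#' @export
estimate_noise <- function(spectrum, noise_window = 5) {
  stopifnot(is_spectrum(spectrum), noise_window > 0)
  y <- spectrum$intensity
  n <- length(y)
  step <- if (n > 1L) stats::median(diff(spectrum$mz)) else noise_window
  w <- round(noise_window / step)
  if (w %% 2 == 0) w <- w + 1
  floor_val <- max(max(y), 1) * 1e-12
  if (w >= n || n < 3L) {
    est <- stats::mad(y)        # global fallback (already sigma-scaled)
    return(rep(max(est, floor_val), n))
  }
  med <- stats::runmed(y, w, endrule = "median")
  dev <- abs(y - med)
  noise <- 1.4826 * stats::runmed(dev, w, endrule = "median")
  pmax(noise, floor_val)
}

## exported for oracle comparison in tests: candidate local maxima indices
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer())
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

## parabolic apex refinement through three points around index i
refine_apex <- function(mz, y, i) {
  if (i <= 1L || i >= length(y)) return(c(mz[i], y[i]))
  denom <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (denom >= 0) return(c(mz[i], y[i]))    # not locally concave
  delta <- 0.5 * (y[i - 1] - y[i + 1]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  step <- (mz[i + 1] - mz[i - 1]) / 2
  c(mz[i] + delta * step, y[i] - 0.25 * (y[i - 1] - y[i + 1]) * delta)
}

#' Pick peaks from a preprocessed spectrum
#'
#' Local maxima with SNR at or above `snr_low_threshold` are retained; peak
#' positions are refined by parabolic interpolation of the apex; peaks
#' closer than `min_peak_separation` are merged keeping the more intense
#' (ties broken towards lower m/z).  The SNR of every retained peak is
#' recorded so downstream marker matching can distinguish full-grade
#' (`>= snr_pick_threshold`) from low-grade evidence.
#'
#' @param spectrum A smoothed, baseline-subtracted [mass_spectrum()].
#' @param params A [preprocess_params()].
#' @param noise Optional per-point noise sigma (same length as the
#'   spectrum); estimated from `spectrum` itself when `NULL`.  The pipeline
#'   passes the noise of the unsmoothed trace here, so that smoothing does
#'   not silently inflate SNR.
#' @return A [peak_list()] with provenance recording the parameters used.
#' @export
pick_peaks <- function(spectrum, params = preprocess_params(), noise = NULL) {
  stopifnot(is_spectrum(spectrum))
  y <- spectrum$intensity
  if (is.null(noise)) noise <- estimate_noise(spectrum, params$noise_window)
  stopifnot(length(noise) == length(y))
  prov <- list(stage = "pick_peaks", params = unclass(params))
  cand <- local_maxima(y)
  cand <- cand[y[cand] > 0]
  snr <- y[cand] / noise[cand]
  keep <- snr >= params$snr_low_threshold
  cand <- cand[keep]; snr <- snr[keep]
  if (length(cand) == 0L) {
    return(peak_list(sample_id = spectrum$sample_id, provenance = prov,
                     min_separation = params$min_peak_separation))
  }
  # greedy merge on the grid apexes: take the most intense remaining peak
  # (ties towards lower m/z), discard everything within min_peak_separation
  ord <- order(-y[cand], spectrum$mz[cand])
  accepted <- integer()
  for (i in ord) {
    if (length(accepted) == 0L ||
        all(abs(spectrum$mz[cand[accepted]] - spectrum$mz[cand[i]]) >=
              params$min_peak_separation)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- accepted[order(spectrum$mz[cand[accepted]])]
  # parabolic refinement of the retained apexes (reporting only; merge
  # decisions are made on the grid so they are reproducible exactly)
  apex <- t(vapply(cand[accepted], function(i) refine_apex(spectrum$mz, y, i),
                   numeric(2)))
  # refinement moves each apex by at most half a grid step, so the
  # guaranteed separation is the merge threshold minus one step
  step <- stats::median(diff(spectrum$mz))
  peak_list(apex[, 1], apex[, 2], snr[accepted],
            sample_id = spectrum$sample_id, provenance = prov,
            min_separation = max(params$min_peak_separation - step, 0))
}

#' Linear mass recalibration against reference masses
#'
#' Matches the peak list against external calibrant masses (nearest peak
#' within `tolerance`) and fits a two-parameter linear correction
#' `m_true = offset + slope * m_observed` by least squares, which is then
#' applied to every peak.  With fewer than two matched references the peak
#' list is returned unchanged with a warning.
#'
#' @param peaklist A [peak_list()].
#' @param reference_masses Numeric vector of calibrant m/z values (Da).
#' @param tolerance Match tolerance in Da (default 0.5; calibration errors
#'   are usually larger than marker-match tolerances).
#' @return The recalibrated [peak_list()]; attributes `"calibration"`
#'   (offset, slope, n_matched) and `"residuals"` (Da, reference minus
#'   corrected mass) report the fit.
#' @export
recalibrate <- function(peaklist, reference_masses, tolerance = 0.5) {
  stopifnot(is_peaklist(peaklist), is.numeric(reference_masses))
  obs <- ref <- numeric()
  for (m in sort(reference_masses)) {
    if (nrow(peaklist) == 0L) break
    d <- abs(peaklist$mz - m)
    i <- which.min(d)
    if (d[i] <= tolerance) {
      obs <- c(obs, peaklist$mz[i]); ref <- c(ref, m)
    }
  }
  if (length(ref) < 2L) {
    warning("fewer than 2 reference masses matched; peak list left uncalibrated",
            call. = FALSE)
    attr(peaklist, "calibration") <- list(offset = 0, slope = 1,
                                          n_matched = length(ref),
                                          status = "skipped")
    return(peaklist)
  }
  fit <- stats::lm(ref ~ obs)
  co <- stats::coef(fit)
  new_mz <- co[[1]] + co[[2]] * peaklist$mz
  prov <- c(attr(peaklist, "provenance"),
            list(recalibration = list(offset = co[[1]], slope = co[[2]])))
  out <- rebuild_peaklist(peaklist, new_mz, peaklist$intensity, peaklist$snr,
                          peaklist$flags, provenance = prov)
  attr(out, "calibration") <- list(offset = co[[1]], slope = co[[2]],
                                   n_matched = length(ref), status = "fitted")
  attr(out, "residuals") <- ref - (co[[1]] + co[[2]] * obs)
  out
}

#' Full preprocessing of one sample
#'
#' Replicate averaging, Savitzky-Golay smoothing, SNIP baseline subtraction
#' and SNR-based peak picking in one call.  Noise is estimated on the
#' baseline-subtracted unsmoothed trace (smoothing suppresses the very
#' noise the SNR is measured against), while apex intensities are read from
#' the smoothed trace.
#'
#' @param spectra A [mass_spectrum()] or list of replicate spectra.
#' @param params A [preprocess_params()].
#' @return A [peak_list()].
#' @export
preprocess_spectrum <- function(spectra, params = preprocess_params()) {
  avg <- average_replicates(spectra, params$resample_step)
  sm <- smooth_spectrum(avg, params)
  bs <- subtract_baseline(sm, params)
  # noise from the *unsmoothed* trace: the running median inside
  # estimate_noise absorbs the slowly varying baseline, and no zero
  # clipping is involved that would bias the scale estimate low
  noise <- estimate_noise(avg, params$noise_window)
  pick_peaks(bs, params, noise = noise)
}
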