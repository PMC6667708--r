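# Small deterministic fixtures and independent brute-force oracles used
# across the suite.  Oracles deliberately re-derive results by exhaustive
# search, not by calling the implementation's internals.

noise_spectrum <- function(seed, n = 2000, mz0 = 1000, step = 0.02,
                           sigma = 1, offset = 20, sample_id = NULL) {
  set.seed(seed)
  mass_spectrum(mz0 + (seq_len(n) - 1) * step,
                pmax(offset + stats::rnorm(n, 0, sigma), 0),
                sample_id = if (is.null(sample_id)) paste0("noise", seed)
                else sample_id)
}

gauss_bump <- function(mz, center, height, fwhm = 0.3) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-(mz - center)^2 / (2 * s^2))
}

## exhaustive local-maximum scan + SNR threshold + iterative
## strongest-first merge; the reference for pick_peaks
oracle_pick_peaks <- function(spectrum, params, noise) {
  y <- spectrum$intensity
  mz <- spectrum$mz
  n <- length(y)
  cand <- integer()
  for (i in seq.int(2L, n - 1L)) {
    if (y[i] > y[i - 1] && y[i] >= y[i + 1] && y[i] > 0 &&
        y[i] / noise[i] >= params$snr_low_threshold) {
      cand <- c(cand, i)
    }
  }
  out <- data.frame(mz = numeric(), snr = numeric())
  remaining <- cand
  while (length(remaining) > 0L) {
    j <- remaining[which.max(y[remaining])]
    out <- rbind(out, data.frame(mz = mz[j], snr = y[j] / noise[j]))
    remaining <- remaining[abs(mz[remaining] - mz[j]) >=
                             params$min_peak_separation]
  }
  out[order(out$mz), , drop = FALSE]
}

## exhaustive depth-first enumeration of all maximal arithmetic
## progressions; the reference for detect_polymer_series
oracle_polymer_series <- function(mz, config) {
  n <- length(mz)
  tol <- config$polymer_spacing_tolerance
  rng <- config$polymer_spacing_range
  found <- list()
  valid <- function(idx) {
    g <- diff(mz[idx])
    m <- stats::median(g)
    m >= rng[1] && m <= rng[2] && all(abs(g - m) <= tol)
  }
  extend <- function(idx) {
    last <- idx[length(idx)]
    d1 <- mz[idx[2]] - mz[idx[1]]
    gaps <- mz - mz[last]
    js <- which(seq_len(n) > last & gaps >= rng[1] - tol &
                  gaps <= rng[2] + tol & abs(gaps - d1) <= 2 * tol)
    for (j in js) extend(c(idx, j))
    if (length(idx) >= config$polymer_min_length && valid(idx)) {
      found[[length(found) + 1L]] <<- idx
    }
  }
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        d <- mz[j] - mz[i]
        if (d >= rng[1] - tol && d <= rng[2] + tol) extend(c(i, j))
      }
    }
  }
  if (length(found) == 0L) return(list())
  keys <- vapply(found, paste, character(1), collapse = ",")
  found <- found[!duplicated(keys)]
  keep <- rep(TRUE, length(found))
  for (a in seq_along(found)) {
    for (b in seq_along(found)) {
      if (a != b && length(found[[a]]) < length(found[[b]]) &&
          all(found[[a]] %in% found[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  found[keep]
}

## random peak list with guaranteed minimum separation
random_peaklist <- function(seed, n = 25, lo = 800, hi = 1600,
                            min_sep = 0.3) {
  set.seed(seed)
  raw <- sort(stats::runif(3 * n, lo, hi))
  mz <- numeric()
  for (m in raw) {
    if (length(mz) == 0L || m - mz[length(mz)] >= min_sep + 0.1) {
      mz <- c(mz, m)
    }
  }
  mz <- mz[seq_len(min(n, length(mz)))]
  peak_list(mz, intensity = stats::runif(length(mz), 1, 100),
            snr = stats::runif(length(mz), 1.5, 30),
            sample_id = paste0("rand", seed), min_separation = min_sep)
}

## direct recomputation of the weighted marker score from the expectation
## matrix, used to cross-check score_taxa
oracle_scores <- function(obs, panel, params = classifier_params()) {
  st <- stats::setNames(obs$state, obs$marker_id)
  vapply(panel$taxa$taxon_label, function(tx) {
    e <- panel$expectations[tx, ]
    ids <- names(e)[e != "ABSENT"]
    w <- ifelse(e[ids] == "EXPECTED_UNCERTAIN", params$uncertain_weight, 1)
    fac <- c(PRESENT = 1, LOW = 0.5, ABSENT = 0)[st[ids]]
    sum(w * fac) / sum(w)
  }, numeric(1))
}

## peak list realising a taxon's full marker pattern; groups can be
## dropped entirely or planted at low-grade SNR
pattern_peaklist <- function(panel, taxon, snr = 10,
                             drop_groups = character(),
                             low_groups = character()) {
  e <- panel$expectations[taxon, ]
  ids <- names(e)[e != "ABSENT"]
  masses <- numeric(); snrs <- numeric()
  for (id in ids) {
    g <- panel$markers$group[match(id, panel$markers$marker_id)]
    if (g %in% drop_groups) next
    m <- marker_masses(panel, id)
    masses <- c(masses, m)
    snrs <- c(snrs, rep(if (g %in% low_groups) 2 else snr, length(m)))
  }
  o <- order(masses)
  peak_list(masses[o], intensity = pmax(snrs[o], 0.1), snr = snrs[o],
            sample_id = taxon)
}

## one-taxon panel whose markers all sit below 1500 Da, so synthetic
## spectra can use short (fast) grids
mini_panel <- local({
  cached <- NULL
  function() {
    if (!is.null(cached)) return(cached)
    dir <- tempfile("minipanel")
    dir.create(dir)
    writeLines(c("marker_id\tgroup\tmass_1\tmass_2\tannotation",
                 "P1\tP1\t1105\tNA\t",
                 "F\tF\t1250\t1266\t",
                 "B\tB\t1427\tNA\t"),
               file.path(dir, "markers.tsv"))
    writeLines(c("taxon\trank_group\tgroup_report_label\tP1\tF\tB",
                 "Synthodon\tSynthidae\tSynth\t+\t+\t+"),
               file.path(dir, "matrix.tsv"))
    cached <<- load_panel(dir)
    cached
  }
})

tier_rank <- function(tier) {
  match(tier, c("SPECIES", "PROBABLE", "HIGHER_RANK", "UNIDENTIFIED"))
}
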