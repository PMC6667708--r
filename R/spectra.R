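#' Construct a mass spectrum
#'
#' A `zooms_spectrum` is a profile-mode MALDI-ToF trace: a strictly ascending
#' m/z axis (Da, singly charged assumption) and a non-negative intensity
#' vector in arbitrary units, plus minimal acquisition metadata.
#'
#' @param mz Numeric vector of mass-to-charge values (Da), strictly ascending.
#' @param intensity Numeric vector of intensities (arbitrary units, >= 0),
#'   same length as `mz`.
#' @param sample_id Sample identifier.
#' @param acquisition_label Free-text acquisition label, e.g. `"bag"`,
#'   `"eraser"`, `"destructive"` or `"synthetic"`.
#' @return An object of class `zooms_spectrum`.
#' @export
mass_spectrum <- function(mz, intensity, sample_id = "", acquisition_label = "") {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) == 0L) {
    stop("spectrum must contain at least one point", call. = FALSE)
  }
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have the same length", call. = FALSE)
  }
  if (anyNA(mz) || anyNA(intensity)) {
    stop("mz and intensity must not contain NA", call. = FALSE)
  }
  if (any(diff(mz) <= 0)) {
    stop("mz must be strictly ascending", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("intensity must be non-negative everywhere", call. = FALSE)
  }
  structure(
    list(
      mz = mz,
      intensity = intensity,
      sample_id = as.character(sample_id)[1L],
      acquisition_label = as.character(acquisition_label)[1L]
    ),
    class = "zooms_spectrum"
  )
}

#' @export
print.zooms_spectrum <- function(x, ...) {
  cat(sprintf(
    "<zooms_spectrum> %s [%s]: %d points, m/z %.2f-%.2f, max intensity %.3g\n",
    x$sample_id, x$acquisition_label, length(x$mz),
    min(x$mz), max(x$mz), max(x$intensity)
  ))
  invisible(x)
}

#' @export
length.zooms_spectrum <- function(x) length(x$mz)

is_spectrum <- function(x) inherits(x, "zooms_spectrum")

## Sort by m/z, collapse exact duplicates (keeping max intensity), drop NA
## and negative-intensity points.  Used by readers, which must enforce the
## Spectrum invariants on whatever the file contains.
repair_spectrum_arrays <- function(mz, intensity) {
  keep <- !(is.na(mz) | is.na(intensity))
  n_na <- sum(!keep)
  mz <- mz[keep]; intensity <- intensity[keep]
  neg <- intensity < 0
  n_neg <- sum(neg)
  mz <- mz[!neg]; intensity <- intensity[!neg]
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (anyDuplicated(mz)) {
    intensity <- vapply(split(intensity, match(mz, unique(mz))), max, numeric(1))
    mz <- unique(mz)
  }
  if (n_neg > 0L) {
    warning(sprintf("dropped %d negative-intensity point(s)", n_neg), call. = FALSE)
  }
  if (n_na > 0L) {
    warning(sprintf("dropped %d NA point(s)", n_na), call. = FALSE)
  }
  list(mz = mz, intensity = intensity)
}

valid_peak_flags <- c("KERATIN", "POLYMER_SERIES")

normalize_flags <- function(flags) {
  vapply(flags, function(f) {
    if (is.na(f) || !nzchar(f)) return("")
    tok <- unlist(strsplit(f, ",", fixed = TRUE))
    tok <- unique(trimws(tok))
    tok <- tok[nzchar(tok)]
    bad <- setdiff(tok, valid_peak_flags)
    if (length(bad) > 0L) {
      stop("unknown peak flag(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    paste(sort(tok), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a peak list
#'
#' A `zooms_peaklist` holds the picked peaks of one sample: m/z, intensity,
#' signal-to-noise ratio and contaminant flags.  Flags (`KERATIN`,
#' `POLYMER_SERIES`) are annotations: flagged peaks keep their values.
#'
#' @param mz Numeric vector of peak m/z values (Da), strictly ascending.
#' @param intensity Positive peak intensities.
#' @param snr Non-negative signal-to-noise ratios.
#' @param flags Character vector of comma-joined flag tokens (`""` for none).
#' @param sample_id Sample identifier.
#' @param provenance Named list recording how the peaks were produced
#'   (smoothing / baseline / picking parameters).
#' @param min_separation Minimum allowed m/z distance (Da) between adjacent
#'   peaks; part of the peak-list invariant.
#' @return An object of classes `zooms_peaklist` and `data.frame` with
#'   columns `mz`, `intensity`, `snr`, `flags`.
#' @export
peak_list <- function(mz = numeric(), intensity = numeric(), snr = numeric(),
                      flags = character(), sample_id = "",
                      provenance = list(), min_separation = 0.3) {
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  snr <- as.numeric(snr)
  if (length(flags) == 0L) flags <- rep("", length(mz))
  flags <- normalize_flags(as.character(flags))
  n <- length(mz)
  if (length(intensity) != n || length(snr) != n || length(flags) != n) {
    stop("mz, intensity, snr and flags must have equal length", call. = FALSE)
  }
  if (n > 0L) {
    if (anyNA(mz) || anyNA(intensity) || anyNA(snr)) {
      stop("peak fields must not contain NA", call. = FALSE)
    }
    if (any(diff(mz) <= 0)) {
      stop("peak mz must be strictly ascending", call. = FALSE)
    }
    if (any(diff(mz) < min_separation)) {
      stop(sprintf("peaks closer than the minimum separation (%.3g Da)",
                   min_separation), call. = FALSE)
    }
    if (any(intensity <= 0)) stop("peak intensity must be > 0", call. = FALSE)
    if (any(snr < 0)) stop("peak snr must be >= 0", call. = FALSE)
  }
  out <- data.frame(mz = mz, intensity = intensity, snr = snr, flags = flags,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("zooms_peaklist", "data.frame"),
            sample_id = as.character(sample_id)[1L],
            provenance = provenance,
            min_separation = min_separation)
}

is_peaklist <- function(x) inherits(x, "zooms_peaklist")

#' @export
print.zooms_peaklist <- function(x, ...) {
  cat(sprintf("<zooms_peaklist> %s: %d peaks\n", attr(x, "sample_id"), nrow(x)))
  if (nrow(x) > 0L) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Test peaks for a contaminant flag
#'
#' @param peaklist A [peak_list()].
#' @param flag One of `"KERATIN"`, `"POLYMER_SERIES"`.
#' @return Logical vector, one element per peak.
#' @export
has_flag <- function(peaklist, flag) {
  flag <- match.arg(flag, valid_peak_flags)
  vapply(strsplit(peaklist$flags, ",", fixed = TRUE),
         function(tok) flag %in% tok, logical(1))
}

add_flag <- function(peaklist, idx, flag) {
  if (length(idx) == 0L) return(peaklist)
  flag <- match.arg(flag, valid_peak_flags)
  new <- peaklist$flags
  new[idx] <- ifelse(nzchar(new[idx]), paste(new[idx], flag, sep = ","), flag)
  peaklist$flags <- normalize_flags(new)
  peaklist
}

## keep peak-list attributes when subsetting / rebuilding
rebuild_peaklist <- function(template, mz, intensity, snr, flags,
                             provenance = attr(template, "provenance")) {
  peak_list(mz, intensity, snr, flags,
            sample_id = attr(template, "sample_id"),
            provenance = provenance,
            min_separation = attr(template, "min_separation"))
}

# ---------------------------------------------------------------------------
# file formats
# ---------------------------------------------------------------------------

num_fmt <- function(x) formatC(x, digits = 17, format = "g", width = -1)

#' Read a two-column (m/z, intensity) text spectrum
#'
#' Lines starting with `#` and blank lines are skipped.  The two columns may
#' be separated by whitespace or an explicit delimiter.
#'
#' @param path Path to the text file.
#' @param delimiter Column delimiter; `NULL` (default) splits on any
#'   whitespace run.
#' @param sample_id,acquisition_label Metadata for the returned spectrum;
#'   `sample_id` defaults to the file name without extension.
#' @return A [mass_spectrum()].
#' @export
read_xy_text <- function(path, delimiter = NULL, sample_id = NULL,
                         acquisition_label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) < 2L) {
    stop("spectrum file must contain at least 2 data points: ", path,
         call. = FALSE)
  }
  split_pat <- if (is.null(delimiter)) "\\s+" else delimiter
  mz <- numeric(length(keep)); it <- numeric(length(keep))
  for (k in seq_along(keep)) {
    fields <- strsplit(trimws(lines[keep[k]]), split_pat)[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stop(sprintf("non-numeric spectrum row at line %d of %s", keep[k], path),
           call. = FALSE)
    }
    mz[k] <- vals[1]; it[k] <- vals[2]
  }
  arr <- repair_spectrum_arrays(mz, it)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  mass_spectrum(arr$mz, arr$intensity, sample_id, acquisition_label)
}

#' Write a spectrum as two-column text
#'
#' Values are written with 17 significant digits so that a write/read cycle
#' round-trips bit-identically.
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output path.
#' @param delimiter Column delimiter (default single space).
#' @return `path`, invisibly.
#' @export
write_xy_text <- function(spectrum, path, delimiter = " ") {
  stopifnot(is_spectrum(spectrum))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# sample_id=%s acquisition=%s",
                     spectrum$sample_id, spectrum$acquisition_label), con)
  writeLines("# m/z intensity", con)
  writeLines(paste(num_fmt(spectrum$mz), num_fmt(spectrum$intensity),
                   sep = delimiter), con)
  invisible(path)
}

#' Read spectra from an mzML file
#'
#' Minimal, read-only mzML support: the m/z and intensity arrays of every
#' MS1 spectrum are extracted (via the `mzR` parser); all spectra in one
#' file share the file-derived `sample_id`.  Vendor raw formats and MS/MS
#' spectra are not supported.
#'
#' @param path Path to an mzML file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param acquisition_label Acquisition label attached to every spectrum.
#' @return A list of [mass_spectrum()] objects, one per mzML spectrum.
#' @export
read_mzml <- function(path, sample_id = NULL, acquisition_label = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e) {
                       stop("invalid mzML file '", path, "': ",
                            conditionMessage(e), call. = FALSE)
                     })
  on.exit(try(mzR::close(handle), silent = TRUE))
  pk <- tryCatch(mzR::peaks(handle),
                 error = function(e) {
                   stop("failed to decode spectra in '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (is.matrix(pk)) pk <- list(pk)
  if (length(pk) == 0L) stop("mzML file contains no spectra: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  lapply(pk, function(m) {
    arr <- repair_spectrum_arrays(m[, 1], m[, 2])
    mass_spectrum(arr$mz, arr$intensity, sample_id, acquisition_label)
  })
}

#' Write a peak list as TSV
#'
#' Tab-delimited, UTF-8, `.` decimal separator; columns `mz`, `intensity`,
#' `snr`, `flags` (comma-joined tokens).  Numeric fields carry 17
#' significant digits so the round trip through [read_peaklist()] is
#' lossless, field for field.
#'
#' @param peaklist A [peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(peaklist, path) {
  stopifnot(is_peaklist(peaklist))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("mz\tintensity\tsnr\tflags", con)
  if (nrow(peaklist) > 0L) {
    writeLines(paste(num_fmt(peaklist$mz), num_fmt(peaklist$intensity),
                     num_fmt(peaklist$snr), peaklist$flags, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a peak list from TSV
#'
#' @param path Path to a TSV written by [write_peaklist()] (columns `mz`,
#'   `intensity`, `snr`, `flags`).
#' @param sample_id Sample identifier; defaults to the file name.
#' @param min_separation Minimum peak separation (Da) enforced on read;
#'   peaks closer than this raise a validation error.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, sample_id = NULL, min_separation = 0.3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("numeric", "numeric", "numeric",
                                         "character"),
                          stringsAsFactors = FALSE, na.strings = NULL)
  need <- c("mz", "intensity", "snr", "flags")
  if (!identical(names(df), need)) {
    stop("peak-list TSV must have columns mz, intensity, snr, flags: ", path,
         call. = FALSE)
  }
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  peak_list(df$mz, df$intensity, df$snr, df$flags,
            sample_id = sample_id, min_separation = min_separation)
}
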