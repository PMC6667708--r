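#' Contaminant-filter configuration
#'
#' Non-destructive collagen recovery (storage bags, erasers) is prone to two
#' well-known contaminant classes: keratin peptides from skin/hair/nails,
#' whose tryptic masses are documented and can be flagged by lookup, and
#' plastic residues, which show up as series of equally spaced peaks at the
#' low-m/z end of the spectrum.
#'
#' @param keratin_masses Numeric vector of keratin peptide m/z values (Da).
#'   Defaults to the packaged list ([default_keratin_masses()]), which is
#'   user-replaceable.
#' @param keratin_tolerance Match tolerance in Da (default 0.2).
#' @param polymer_min_length Minimum number of members of a polymer series
#'   (default 5, must be >= 3).
#' @param polymer_spacing_range Allowed repeat spacing `c(min, max)` in Da
#'   (default `c(14, 80)`, spanning common polymer repeat units).
#' @param polymer_spacing_tolerance Maximum deviation (Da) of each gap from
#'   the series' median gap (default 0.1).
#' @param polymer_max_mz Only peaks below this m/z are considered for
#'   polymer series (default 1500; plastic residues sit at the low-mass end).
#' @return A list of class `zooms_contaminant_config`.
#' @export
contaminant_config <- function(keratin_masses = default_keratin_masses(),
                               keratin_tolerance = 0.2,
                               polymer_min_length = 5L,
                               polymer_spacing_range = c(14, 80),
                               polymer_spacing_tolerance = 0.1,
                               polymer_max_mz = 1500) {
  polymer_min_length <- as.integer(polymer_min_length)
  stopifnot(
    is.numeric(keratin_masses),
    keratin_tolerance > 0,
    polymer_min_length >= 3L,
    length(polymer_spacing_range) == 2L,
    polymer_spacing_range[1] > 0,
    polymer_spacing_range[1] < polymer_spacing_range[2],
    polymer_spacing_tolerance > 0,
    polymer_max_mz > 0
  )
  structure(
    list(keratin_masses = sort(as.numeric(keratin_masses)),
         keratin_tolerance = keratin_tolerance,
         polymer_min_length = polymer_min_length,
         polymer_spacing_range = as.numeric(polymer_spacing_range),
         polymer_spacing_tolerance = polymer_spacing_tolerance,
         polymer_max_mz = polymer_max_mz),
    class = "zooms_contaminant_config"
  )
}

#' Packaged keratin contaminant masses
#'
#' Commonly reported tryptic keratin peptide masses from standard
#' laboratory-contaminant lists, shipped as a versioned, user-replaceable
#' TSV (`extdata/keratin_masses.tsv`, columns `mass`, `peptide_label`,
#' `source`).  The list is a curation starting point, not an exhaustive
#' reference.
#'
#' @param path Optional path to an alternative keratin TSV.
#' @return Numeric vector of m/z values; the full table is attached as
#'   attribute `"table"`.
#' @export
default_keratin_masses <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "keratin_masses.tsv", package = "zoomsid",
                        mustWork = TRUE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot("mass" %in% names(df))
  out <- as.numeric(df$mass)
  attr(out, "table") <- df
  out
}

#' Flag peaks matching known keratin masses
#'
#' Every peak within `keratin_tolerance` of any listed keratin mass receives
#' the `KERATIN` flag.  Nothing is removed: flags are annotations, and the
#' classifier demotes keratin-flagged matches to low-grade evidence rather
#' than ignoring them.
#'
#' @param peaklist A [peak_list()].
#' @param config A [contaminant_config()].
#' @return The flagged [peak_list()].
#' @export
flag_keratin <- function(peaklist, config = contaminant_config()) {
  stopifnot(is_peaklist(peaklist))
  if (length(config$keratin_masses) == 0L || nrow(peaklist) == 0L) {
    return(peaklist)
  }
  hit <- vapply(peaklist$mz, function(m) {
    any(abs(config$keratin_masses - m) <= config$keratin_tolerance)
  }, logical(1))
  add_flag(peaklist, which(hit), "KERATIN")
}

## complete enumeration of candidate progressions, seeded from every
## ordered peak pair.  In any valid series every gap lies within the
## spacing tolerance of the median gap, so all gaps agree pairwise within
## twice the tolerance and the first gap lies within one tolerance of the
## spacing range: pruning on those two facts loses no valid chain.
find_series_candidates <- function(mz, config) {
  n <- length(mz)
  tol <- config$polymer_spacing_tolerance
  rng <- config$polymer_spacing_range
  out <- list()
  if (n < max(config$polymer_min_length, 2L)) return(out)
  dfs <- function(idx, g1) {
    last <- idx[length(idx)]
    gaps <- mz - mz[last]
    cand <- which(gaps >= max(rng[1] - tol, g1 - 2 * tol) &
                    gaps <= min(rng[2] + tol, g1 + 2 * tol) &
                    seq_len(n) > last)
    for (k in cand) dfs(c(idx, k), g1)
    if (length(idx) >= config$polymer_min_length) {
      out[[length(out) + 1L]] <<- idx
    }
  }
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- mz[j] - mz[i]
      if (d > rng[2] + tol) break
      if (d >= rng[1] - tol) dfs(c(i, j), d)
    }
  }
  out
}

series_is_valid <- function(mz, idx, config) {
  g <- diff(mz[idx])
  m <- stats::median(g)
  m >= config$polymer_spacing_range[1] &&
    m <= config$polymer_spacing_range[2] &&
    all(abs(g - m) <= config$polymer_spacing_tolerance)
}

## drop duplicates and any candidate whose index set is contained in another
keep_maximal_series <- function(cands) {
  if (length(cands) == 0L) return(cands)
  keys <- vapply(cands, function(x) paste(x, collapse = ","), character(1))
  cands <- cands[!duplicated(keys)]
  n <- length(cands)
  keep <- rep(TRUE, n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a != b && keep[a] &&
          length(cands[[a]]) < length(cands[[b]]) &&
          all(cands[[a]] %in% cands[[b]])) {
        keep[a] <- FALSE
        break
      }
    }
  }
  cands[keep]
}

#' Detect equally spaced polymer peak series
#'
#' Finds maximal arithmetic progressions among the peak m/z values below
#' `polymer_max_mz`: at least `polymer_min_length` members, median gap
#' inside `polymer_spacing_range`, every gap within
#' `polymer_spacing_tolerance` of the median gap.  Detection uses peak
#' positions only; intensities play no role.
#'
#' @param peaklist A [peak_list()].
#' @param config A [contaminant_config()].
#' @return A list of series, each a list with elements `indices` (into the
#'   peak list), `mz` (member positions) and `spacing` (median gap, Da).
#' @export
detect_polymer_series <- function(peaklist, config = contaminant_config()) {
  stopifnot(is_peaklist(peaklist))
  sub <- which(peaklist$mz < config$polymer_max_mz)
  mz <- peaklist$mz[sub]
  cands <- find_series_candidates(mz, config)
  cands <- Filter(function(idx) series_is_valid(mz, idx, config), cands)
  cands <- keep_maximal_series(cands)
  lapply(cands, function(idx) {
    list(indices = sub[idx],
         mz = peaklist$mz[sub[idx]],
         spacing = stats::median(diff(mz[idx])))
  })
}

#' Flag members of detected polymer series
#'
#' Runs [detect_polymer_series()] and applies the `POLYMER_SERIES` flag to
#' every member peak.
#'
#' @param peaklist A [peak_list()].
#' @param config A [contaminant_config()].
#' @return The flagged [peak_list()]; the series report is attached as
#'   attribute `"polymer_series"`.
#' @export
flag_polymer_series <- function(peaklist, config = contaminant_config()) {
  series <- detect_polymer_series(peaklist, config)
  idx <- unique(unlist(lapply(series, `[[`, "indices")))
  out <- add_flag(peaklist, idx, "POLYMER_SERIES")
  attr(out, "polymer_series") <- series
  out
}

#' Remove flagged peaks
#'
#' Drops every peak carrying at least one of the requested flags; all other
#' peaks are untouched.
#'
#' @param peaklist A [peak_list()].
#' @param which_flags Flags to remove, subset of
#'   `c("KERATIN", "POLYMER_SERIES")`.
#' @return The filtered [peak_list()] with attribute `"n_removed"`.
#' @export
remove_flagged <- function(peaklist,
                           which_flags = c("KERATIN", "POLYMER_SERIES")) {
  stopifnot(is_peaklist(peaklist))
  which_flags <- match.arg(which_flags, valid_peak_flags, several.ok = TRUE)
  drop <- Reduce(`|`, lapply(which_flags, function(f) has_flag(peaklist, f)),
                 accumulate = FALSE)
  if (is.null(drop)) drop <- rep(FALSE, nrow(peaklist))
  keep <- !drop
  out <- rebuild_peaklist(peaklist, peaklist$mz[keep], peaklist$intensity[keep],
                          peaklist$snr[keep], peaklist$flags[keep])
  attr(out, "n_removed") <- sum(drop)
  out
}
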