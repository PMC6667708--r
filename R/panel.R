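#' @name marker_panel
#' @title Collagen m/z marker panels
#'
#' @description
#' A marker panel couples a set of collagen peptide markers (one or two m/z
#' values each — where two values are given the presence of both is
#' required) with a per-taxon expectation matrix.  Expectation states:
#'
#' * `EXPECTED` (`+`): the marker is expected for the taxon.
#' * `EXPECTED_DIAGNOSTIC` (`d`): expected and species-specific within the
#'   panel (bold in the usual tabular rendering); a species-tier call
#'   requires every diagnostic marker to be fully present.
#' * `EXPECTED_UNCERTAIN` (`?`): expected but typically weak ("present but
#'   at low intensity"); contributes reduced weight in scoring.
#' * `ABSENT` (`-`): no peak expected.
#'
#' Markers sharing a `group` (e.g. the A variants at 1150+1166 vs
#' 1180+1196) are alternative mass variants of one biological peptide; each
#' variant is a separate marker row with its own expectations.
NULL

panel_states <- c("EXPECTED", "EXPECTED_DIAGNOSTIC", "EXPECTED_UNCERTAIN",
                  "ABSENT")
state_codes <- c("+" = "EXPECTED", "d" = "EXPECTED_DIAGNOSTIC",
                 "?" = "EXPECTED_UNCERTAIN", "-" = "ABSENT")

new_marker_panel <- function(markers, taxa, expectations,
                             name = "", version = "", source = "") {
  panel <- structure(
    list(markers = markers, taxa = taxa, expectations = expectations,
         name = name, version = version, source = source),
    class = "zooms_marker_panel"
  )
  check_panel(panel)
  panel
}

check_panel <- function(panel) {
  m <- panel$markers
  t <- panel$taxa
  e <- panel$expectations
  if (anyDuplicated(m$marker_id)) {
    stop("duplicate marker_id in panel", call. = FALSE)
  }
  if (anyDuplicated(t$taxon_label)) {
    stop("duplicate taxon_label in panel", call. = FALSE)
  }
  mass_key <- apply(cbind(m$mass_1, m$mass_2), 1,
                    function(r) paste(r[!is.na(r)], collapse = "+"))
  if (anyDuplicated(mass_key)) {
    stop("two markers share an identical mass set", call. = FALSE)
  }
  if (any(!is.na(m$mass_2) & m$mass_2 <= m$mass_1)) {
    stop("paired marker masses must be ascending", call. = FALSE)
  }
  if (!identical(colnames(e), m$marker_id)) {
    extra <- setdiff(colnames(e), m$marker_id)
    if (length(extra) > 0L) {
      stop("expectation matrix references undefined marker(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    stop("expectation matrix columns must match panel markers", call. = FALSE)
  }
  if (!identical(rownames(e), t$taxon_label)) {
    stop("expectation matrix rows must match panel taxa", call. = FALSE)
  }
  bad <- setdiff(unique(as.vector(e)), panel_states)
  if (length(bad) > 0L) {
    stop("unknown expectation state(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  no_expected <- rownames(e)[rowSums(e != "ABSENT") == 0L]
  if (length(no_expected) > 0L) {
    stop("taxa with no expected marker: ", paste(no_expected, collapse = ", "),
         call. = FALSE)
  }
  invisible(panel)
}

#' @export
print.zooms_marker_panel <- function(x, ...) {
  cat(sprintf("<zooms_marker_panel> %s (version %s): %d markers, %d taxa\n",
              x$name, x$version, nrow(x$markers), nrow(x$taxa)))
  invisible(x)
}

#' Masses of one panel marker
#'
#' @param panel A marker panel.
#' @param marker_id Marker identifier.
#' @return Numeric vector of one or two m/z values.
#' @export
marker_masses <- function(panel, marker_id) {
  i <- match(marker_id, panel$markers$marker_id)
  if (is.na(i)) stop("unknown marker: ", marker_id, call. = FALSE)
  m <- c(panel$markers$mass_1[i], panel$markers$mass_2[i])
  m[!is.na(m)]
}

#' Load a marker panel
#'
#' Accepts either a single JSON document or a TSV pair: `markers.tsv`
#' (columns `marker_id`, `group`, `mass_1`, `mass_2`, `annotation`) and
#' `matrix.tsv` (columns `taxon`, `rank_group`, `group_report_label`, then
#' one column per marker with codes `+`, `d`, `?`, `-`).  `path` may be a
#' directory containing the two TSV files, a `.json` file, or the
#' `markers.tsv` path with `matrix_path` given explicitly.
#'
#' @param path Panel path (see above).
#' @param matrix_path Optional explicit path of the matrix TSV.
#' @return A validated marker panel.
#' @export
load_panel <- function(path, matrix_path = NULL) {
  if (length(path) != 1L || !nzchar(path)) stop("invalid panel path", call. = FALSE)
  if (dir.exists(path)) {
    return(load_panel_tsv(file.path(path, "markers.tsv"),
                          file.path(path, "matrix.tsv")))
  }
  if (!file.exists(path)) stop("panel path not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    return(load_panel_json(path))
  }
  if (is.null(matrix_path)) {
    stop("TSV panels need both a markers file and a matrix file", call. = FALSE)
  }
  load_panel_tsv(path, matrix_path)
}

load_panel_tsv <- function(markers_path, matrix_path) {
  for (p in c(markers_path, matrix_path)) {
    if (!file.exists(p)) stop("panel file not found: ", p, call. = FALSE)
  }
  mk <- utils::read.delim(markers_path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA",
                          colClasses = c(marker_id = "character",
                                         group = "character",
                                         mass_1 = "numeric", mass_2 = "numeric",
                                         annotation = "character"))
  need <- c("marker_id", "group", "mass_1", "mass_2", "annotation")
  if (!all(need %in% names(mk))) {
    stop("markers.tsv must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  mx <- utils::read.delim(matrix_path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = NULL)
  meta_cols <- c("taxon", "rank_group", "group_report_label")
  if (!all(meta_cols %in% names(mx))) {
    stop("matrix.tsv must have columns ", paste(meta_cols, collapse = ", "),
         call. = FALSE)
  }
  marker_cols <- setdiff(names(mx), meta_cols)
  codes <- as.matrix(mx[, marker_cols, drop = FALSE])
  bad <- setdiff(unique(as.vector(codes)), names(state_codes))
  if (length(bad) > 0L) {
    stop("unknown expectation code(s) in matrix.tsv: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  e <- matrix(state_codes[as.vector(codes)], nrow = nrow(mx),
              dimnames = list(mx$taxon, marker_cols))
  orphan <- setdiff(marker_cols, mk$marker_id)
  if (length(orphan) > 0L) {
    stop("matrix.tsv references undefined marker(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(mk$marker_id, marker_cols)
  if (length(missing) > 0L) {
    stop("matrix.tsv lacks column(s) for marker(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  e <- e[, mk$marker_id, drop = FALSE]
  taxa <- data.frame(taxon_label = mx$taxon, rank_group = mx$rank_group,
                     group_report_label = mx$group_report_label,
                     stringsAsFactors = FALSE)
  mk$annotation[is.na(mk$annotation)] <- ""
  new_marker_panel(mk[, need], taxa, e,
                   name = attr_or(mx, "name", "panel"),
                   version = "", source = "")
}

attr_or <- function(x, name, default) {
  v <- attr(x, name)
  if (is.null(v)) default else v
}

load_panel_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mk <- do.call(rbind, lapply(doc$markers, function(m) {
    masses <- as.numeric(unlist(m$masses))
    data.frame(marker_id = m$marker_id,
               group = if (is.null(m$group)) m$marker_id else m$group,
               mass_1 = masses[1],
               mass_2 = if (length(masses) > 1L) masses[2] else NA_real_,
               annotation = if (is.null(m$annotation)) "" else m$annotation,
               stringsAsFactors = FALSE)
  }))
  taxa <- do.call(rbind, lapply(doc$taxa, function(t) {
    data.frame(taxon_label = t$taxon_label, rank_group = t$rank_group,
               group_report_label = t$group_report_label,
               stringsAsFactors = FALSE)
  }))
  e <- matrix("ABSENT", nrow = nrow(taxa), ncol = nrow(mk),
              dimnames = list(taxa$taxon_label, mk$marker_id))
  for (t in doc$taxa) {
    for (id in names(t$expectations)) {
      if (!id %in% mk$marker_id) {
        stop("taxon '", t$taxon_label,
             "' references undefined marker: ", id, call. = FALSE)
      }
      e[t$taxon_label, id] <- t$expectations[[id]]
    }
  }
  new_marker_panel(mk, taxa, e,
                   name = if (is.null(doc$name)) "panel" else doc$name,
                   version = if (is.null(doc$version)) "" else doc$version,
                   source = if (is.null(doc$source)) "" else doc$source)
}

#' Write a marker panel
#'
#' @param panel A marker panel.
#' @param path Output path: a directory (created if needed) for
#'   `format = "tsv"`, a file path for `format = "json"`.
#' @param format `"tsv"` (markers.tsv + matrix.tsv pair) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(panel$markers, file.path(path, "markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    codes <- matrix(names(state_codes)[match(as.vector(panel$expectations),
                                             state_codes)],
                    nrow = nrow(panel$expectations))
    mx <- cbind(data.frame(taxon = panel$taxa$taxon_label,
                           rank_group = panel$taxa$rank_group,
                           group_report_label = panel$taxa$group_report_label,
                           stringsAsFactors = FALSE),
                as.data.frame(codes, col.names = colnames(panel$expectations)))
    names(mx) <- c("taxon", "rank_group", "group_report_label",
                   colnames(panel$expectations))
    utils::write.table(mx, file.path(path, "matrix.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    doc <- list(
      name = panel$name, version = panel$version, source = panel$source,
      markers = lapply(seq_len(nrow(panel$markers)), function(i) {
        m <- panel$markers[i, ]
        list(marker_id = m$marker_id, group = m$group,
             masses = as.numeric(c(m$mass_1, m$mass_2)[!is.na(c(m$mass_1, m$mass_2))]),
             annotation = m$annotation)
      }),
      taxa = lapply(seq_len(nrow(panel$taxa)), function(i) {
        t <- panel$taxa[i, ]
        list(taxon_label = t$taxon_label, rank_group = t$rank_group,
             group_report_label = t$group_report_label,
             expectations = as.list(panel$expectations[t$taxon_label, ]))
      })
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' The built-in cervid marker panel
#'
#' The packaged five-species cervid panel (Roe Deer, Red Deer, Fallow Deer,
#' Caribou/Reindeer, White-Tailed Deer).  Twelve marker rows: the singleton
#' markers P1 (1105), B (1427), P2 (1648) and D (2131) expected for all
#' five taxa; the paired A variants 1150+1166 (roe) and 1180+1196 (the
#' others); C variants at 1550 and 1580; the paired F marker 2883+2899 for
#' all taxa; and the discriminating high-mass G variants 3017+3033
#' (red/fallow), 3043+3059 (roe/white-tailed) and 3093 (caribou/reindeer).
#' The panel transcription lives in `extdata/cervid_panel/` and can be
#' curated without touching code.
#'
#' @return A validated marker panel.
#' @export
builtin_cervid_panel <- function() {
  dir <- system.file("extdata", "cervid_panel", package = "zoomsid",
                     mustWork = TRUE)
  panel <- load_panel(dir)
  panel$name <- "cervid"
  panel$version <- "1"
  panel$source <- "packaged cervid reference panel"
  panel
}

#' Resolve a panel specifier
#'
#' `"builtin:cervid"` returns the packaged panel; anything else is treated
#' as a path for [load_panel()].
#'
#' @param panel A panel object, `"builtin:cervid"`, or a path.
#' @return A marker panel.
#' @export
resolve_panel <- function(panel) {
  if (inherits(panel, "zooms_marker_panel")) return(panel)
  if (identical(panel, "builtin:cervid")) return(builtin_cervid_panel())
  load_panel(panel)
}

#' Validate a panel and report discriminability
#'
#' Beyond the structural invariants (enforced on load), reports pairs of
#' taxa whose expectation vectors are identical: such taxa can only ever be
#' reported at their shared higher rank, never at species level.
#'
#' @param panel A marker panel.
#' @return A list with elements `ok` (logical), `indistinguishable_pairs`
#'   (data.frame with columns `taxon_a`, `taxon_b`, `group_report_label`)
#'   and `species_discriminable` (character vector of taxa not involved in
#'   any identical pair).
#' @export
validate_panel <- function(panel) {
  check_panel(panel)
  labs <- panel$taxa$taxon_label
  sig <- apply(panel$expectations, 1, paste, collapse = "|")
  pairs <- data.frame(taxon_a = character(), taxon_b = character(),
                      group_report_label = character(),
                      stringsAsFactors = FALSE)
  n <- length(labs)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) {
      for (b in seq.int(a + 1L, n)) {
        if (identical(sig[[a]], sig[[b]])) {
          pairs <- rbind(pairs, data.frame(
            taxon_a = labs[a], taxon_b = labs[b],
            group_report_label = panel$taxa$group_report_label[a],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(ok = TRUE,
       indistinguishable_pairs = pairs,
       species_discriminable = setdiff(labs, c(pairs$taxon_a, pairs$taxon_b)))
}
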