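#' Run configuration for the identification pipeline
#'
#' Bundles inputs and all parameter blocks of an end-to-end run.  Every
#' block is validated by its own constructor before any computation
#' starts.
#'
#' @param inputs Named list: sample id -> character vector of spectrum
#'   file paths (replicates of that sample), or an unnamed character
#'   vector (one sample per file, ids from file names).
#' @param format `"auto"` (by extension), `"xy"`, `"mzml"` or `"peaklist"`.
#' @param panel A panel object, `"builtin:cervid"`, or a panel path.
#' @param preprocess,contaminants,classifier Parameter blocks (lists are
#'   spliced into the respective constructors).
#' @param reference_masses Optional calibrant masses for recalibration.
#' @param output_dir Directory for per-sample JSON reports and the summary
#'   TSV; `NULL` disables file output.
#' @param seed Seed recorded in the provenance block (the identification
#'   pipeline itself is deterministic).
#' @return A list of class `zooms_run_config`.
#' @export
run_config <- function(inputs, format = c("auto", "xy", "mzml", "peaklist"),
                       panel = "builtin:cervid",
                       preprocess = preprocess_params(),
                       contaminants = contaminant_config(),
                       classifier = classifier_params(),
                       reference_masses = NULL,
                       output_dir = NULL, seed = NULL) {
  format <- match.arg(format)
  if (is.character(inputs)) {
    nm <- tools::file_path_sans_ext(basename(inputs))
    inputs <- stats::setNames(as.list(inputs), nm)
  }
  stopifnot(is.list(inputs), length(inputs) >= 1L,
            !is.null(names(inputs)), all(nzchar(names(inputs))))
  if (is.list(preprocess) && !inherits(preprocess, "zooms_preprocess_params")) {
    preprocess <- do.call(preprocess_params, preprocess)
  }
  if (is.list(contaminants) && !inherits(contaminants, "zooms_contaminant_config")) {
    contaminants <- do.call(contaminant_config, contaminants)
  }
  if (is.list(classifier) && !inherits(classifier, "zooms_classifier_params")) {
    classifier <- do.call(classifier_params, classifier)
  }
  structure(
    list(inputs = inputs, format = format, panel = panel,
         preprocess = preprocess, contaminants = contaminants,
         classifier = classifier, reference_masses = reference_masses,
         output_dir = output_dir, seed = seed),
    class = "zooms_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]: top-level keys
#' `inputs`, `format`, `panel`, `output_dir`, `seed`, `reference_masses`
#' and parameter blocks `preprocess`, `contaminants`, `classifier` whose
#' entries override the defaults of the corresponding constructors.
#'
#' @param path Path to a YAML file.
#' @return A `zooms_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  args <- list(
    inputs = if (is.list(doc$inputs)) lapply(doc$inputs, unlist) else
      unlist(doc$inputs),
    format = if (is.null(doc$format)) "auto" else doc$format,
    panel = if (is.null(doc$panel)) "builtin:cervid" else doc$panel,
    preprocess = if (is.null(doc$preprocess)) preprocess_params() else
      doc$preprocess,
    contaminants = if (is.null(doc$contaminants)) contaminant_config() else
      doc$contaminants,
    classifier = if (is.null(doc$classifier)) classifier_params() else
      doc$classifier,
    reference_masses = doc$reference_masses,
    output_dir = doc$output_dir,
    seed = doc$seed
  )
  do.call(run_config, args)
}

read_sample_spectra <- function(paths, format) {
  out <- list()
  for (p in paths) {
    fmt <- format
    if (fmt == "auto") {
      ext <- tolower(tools::file_ext(p))
      fmt <- if (ext == "mzml") "mzml" else "xy"
    }
    out <- c(out, switch(fmt,
      mzml = read_mzml(p),
      xy = list(read_xy_text(p)),
      stop("unsupported spectrum format: ", fmt, call. = FALSE)
    ))
  }
  out
}

#' Identify every sample of a run
#'
#' The per-sample pipeline: read (grouping replicates), average, smooth,
#' subtract baseline, pick peaks, optionally recalibrate, flag keratin and
#' polymer-series contaminants, match markers, score taxa, assign a tier.
#' An `UNIDENTIFIED` ("X") outcome is a result, not an error; only I/O and
#' configuration problems raise errors.  When `output_dir` is set, one
#' JSON report per sample and a `summary.tsv` are written; every report
#' embeds the resolved configuration and package version.
#'
#' @param config A [run_config()] (or a YAML path for [read_run_config()]).
#' @return Invisibly, the summary data.frame (columns `sample`, `label`,
#'   `tier`, `report_label`, `top_score`, `n_markers_present`); the full
#'   identification objects are attached as attribute `"identifications"`.
#' @export
run_identify <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "zooms_run_config"))
  panel <- resolve_panel(config$panel)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  }
  resolved <- list(
    package_version = as.character(utils::packageVersion("zoomsid")),
    panel = panel$name, format = config$format, seed = config$seed,
    preprocess = unclass(config$preprocess),
    contaminants = unclass(config$contaminants)[
      setdiff(names(unclass(config$contaminants)), "keratin_masses")],
    classifier = unclass(config$classifier)
  )
  rows <- list(); ids <- list()
  for (sample in names(config$inputs)) {
    paths <- config$inputs[[sample]]
    if (config$format == "peaklist") {
      pl <- read_peaklist(paths[1], sample_id = sample,
                          min_separation = config$preprocess$min_peak_separation)
    } else {
      spectra <- read_sample_spectra(paths, config$format)
      spectra <- lapply(spectra, function(s) { s$sample_id <- sample; s })
      pl <- preprocess_spectrum(spectra, config$preprocess)
    }
    if (!is.null(config$reference_masses)) {
      pl <- recalibrate(pl, config$reference_masses)
    }
    pl <- flag_keratin(pl, config$contaminants)
    pl <- flag_polymer_series(pl, config$contaminants)
    id <- identify_peaks(pl, panel, config$classifier,
                         snr_pick_threshold = config$preprocess$snr_pick_threshold,
                         snr_low_threshold = config$preprocess$snr_low_threshold)
    id$sample_id <- sample
    ids[[sample]] <- id
    rows[[sample]] <- data.frame(
      sample = sample, label = id$label, tier = id$tier,
      report_label = id$report_label,
      top_score = max(id$scores$score),
      n_markers_present = sum(id$evidence$state == "PRESENT"),
      stringsAsFactors = FALSE
    )
    if (!is.null(config$output_dir)) {
      doc <- jsonlite::fromJSON(explain_identification(id),
                                simplifyVector = FALSE)
      doc$config <- resolved
      jsonlite::write_json(doc, file.path(config$output_dir,
                                          paste0(sample, ".json")),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  if (!is.null(config$output_dir)) {
    utils::write.table(summary, file.path(config$output_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  attr(summary, "identifications") <- ids
  invisible(summary)
}

#' Simulate a spectrum to files
#'
#' Generates a synthetic spectrum for a panel taxon (optionally degraded,
#' with injected contaminants) and writes the trace as two-column text and
#' the planted ground truth as JSON.
#'
#' @param taxon Taxon label of `panel`.
#' @param out_prefix Output path prefix; writes `<prefix>.txt` and
#'   `<prefix>_truth.json`.
#' @param panel A marker panel or specifier.
#' @param config A [synth_config()].
#' @param degradation Optional [degradation_config()].
#' @param keratin_masses Optional keratin masses to inject.
#' @param polymer Optional list `list(start_mz=, spacing=, n=)` for a
#'   polymer series.
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(taxon, out_prefix, panel = "builtin:cervid",
                         config = synth_config(), degradation = NULL,
                         keratin_masses = NULL, polymer = NULL) {
  panel <- resolve_panel(panel)
  sp <- generate_spectrum(taxon, panel, config, degradation = degradation)
  if (!is.null(keratin_masses)) {
    sp <- inject_keratin(sp, keratin_masses, config = config)
  }
  if (!is.null(polymer)) {
    sp <- inject_polymer_series(sp, polymer$start_mz, polymer$spacing,
                                polymer$n, config = config)
  }
  spec_path <- paste0(out_prefix, ".txt")
  truth_path <- paste0(out_prefix, "_truth.json")
  write_xy_text(sp, spec_path)
  jsonlite::write_json(attr(sp, "truth"), truth_path, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(spectrum = spec_path, truth = truth_path))
}

#' Validate a panel file and print a discriminability report
#'
#' @param path Panel path or `"builtin:cervid"`.
#' @return The [validate_panel()] report, invisibly.
#' @export
run_panel_validate <- function(path) {
  panel <- resolve_panel(path)
  report <- validate_panel(panel)
  cat(sprintf("panel '%s': %d markers, %d taxa — structure OK\n",
              panel$name, nrow(panel$markers), nrow(panel$taxa)))
  if (nrow(report$indistinguishable_pairs) > 0L) {
    for (i in seq_len(nrow(report$indistinguishable_pairs))) {
      p <- report$indistinguishable_pairs[i, ]
      cat(sprintf(
        "warning: '%s' and '%s' share identical expectation vectors; %s\n",
        p$taxon_a, p$taxon_b,
        sprintf("reportable only as '%s'", p$group_report_label)))
    }
  } else {
    cat("all taxa are species-discriminable\n")
  }
  invisible(report)
}
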