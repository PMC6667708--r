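#' Classifier parameters
#'
#' Numeric thresholds of the tiered assignment.  The underlying reference
#' workflow is expert visual comparison of spectra against published marker
#' tables; these thresholds are a declared operationalisation of that
#' judgement, chosen so that a complete marker pattern yields a species-tier
#' call and patterns with degraded high-mass markers demote to probable /
#' higher-rank calls.  All values are configurable.
#'
#' @param match_tolerance Peak-to-marker match tolerance in Da (default 0.2).
#' @param species_score Minimum weighted score for a species-tier call
#'   (default 0.75).
#' @param probable_score Minimum score for a probable-tier call
#'   (default 0.5); must be below `species_score`.
#' @param min_markers Minimum number of markers observed (present or low
#'   grade) for any identification at all (default 3).
#' @param uncertain_weight Scoring weight of `EXPECTED_UNCERTAIN` markers
#'   (default 0.5).
#' @param strict_pairs If `TRUE`, a paired marker with only one of its two
#'   masses matched is scored `ABSENT` instead of `LOW`.
#' @return A list of class `zooms_classifier_params`.
#' @export
classifier_params <- function(match_tolerance = 0.2,
                              species_score = 0.75,
                              probable_score = 0.5,
                              min_markers = 3L,
                              uncertain_weight = 0.5,
                              strict_pairs = FALSE) {
  min_markers <- as.integer(min_markers)
  stopifnot(match_tolerance > 0, species_score <= 1,
            probable_score > 0, min_markers >= 0L,
            uncertain_weight > 0, uncertain_weight <= 1,
            is.logical(strict_pairs))
  if (probable_score >= species_score) {
    stop("probable_score must be < species_score", call. = FALSE)
  }
  structure(
    list(match_tolerance = match_tolerance, species_score = species_score,
         probable_score = probable_score, min_markers = min_markers,
         uncertain_weight = uncertain_weight, strict_pairs = strict_pairs),
    class = "zooms_classifier_params"
  )
}

marker_states <- c("PRESENT", "LOW", "ABSENT")
tier_levels <- c("SPECIES", "PROBABLE", "HIGHER_RANK", "UNIDENTIFIED")

## nearest peak to a mass within tolerance; ties broken by smaller |error|
## then lower m/z (order(d, mz) — peak lists are mz-sorted already).
match_one_mass <- function(peaklist, mass, tolerance) {
  if (nrow(peaklist) == 0L) return(NULL)
  d <- abs(peaklist$mz - mass)
  i <- order(d, peaklist$mz)[1]
  if (d[i] > tolerance) return(NULL)
  data.frame(panel_mass = mass,
             observed_mz = peaklist$mz[i],
             mass_error = peaklist$mz[i] - mass,
             snr = peaklist$snr[i],
             keratin = has_flag(peaklist, "KERATIN")[i],
             stringsAsFactors = FALSE)
}

#' Match a peak list against panel markers
#'
#' One observation per marker.  A marker is `PRESENT` when all of its
#' masses (both, for paired markers) are matched at full-grade SNR by
#' unflagged peaks; `LOW` when all masses are matched but at least one
#' match is low-grade or keratin-flagged, or when exactly one mass of a
#' pair is matched (`strict_pairs = FALSE`); `ABSENT` otherwise.
#'
#' @param peaklist A [peak_list()], ideally contaminant-flagged.
#' @param panel A marker panel.
#' @param params A [classifier_params()].
#' @param snr_pick_threshold,snr_low_threshold SNR grade boundaries; should
#'   match the values used at peak picking (defaults 3.0 and 1.5).
#' @return A data.frame of class `zooms_observations` with one row per
#'   marker (`marker_id`, `group`, `state`, `n_masses`, `n_matched`,
#'   `min_snr`, `keratin_hit`); the per-mass match table is attached as
#'   attribute `"matches"`.
#' @export
match_markers <- function(peaklist, panel, params = classifier_params(),
                          snr_pick_threshold = 3.0, snr_low_threshold = 1.5) {
  stopifnot(is_peaklist(peaklist), inherits(panel, "zooms_marker_panel"))
  rows <- list()
  matches <- list()
  for (i in seq_len(nrow(panel$markers))) {
    id <- panel$markers$marker_id[i]
    masses <- marker_masses(panel, id)
    hits <- lapply(masses, match_one_mass, peaklist = peaklist,
                   tolerance = params$match_tolerance)
    hit_df <- do.call(rbind, hits)
    n_matched <- length(Filter(Negate(is.null), hits))
    keratin_hit <- !is.null(hit_df) && any(hit_df$keratin)
    min_snr <- if (is.null(hit_df)) 0 else min(hit_df$snr)
    state <- if (n_matched == length(masses) && n_matched > 0L) {
      if (min_snr >= snr_pick_threshold && !keratin_hit) "PRESENT" else "LOW"
    } else if (n_matched > 0L && !params$strict_pairs) {
      "LOW"
    } else {
      "ABSENT"
    }
    rows[[i]] <- data.frame(marker_id = id, group = panel$markers$group[i],
                            state = state, n_masses = length(masses),
                            n_matched = n_matched, min_snr = min_snr,
                            keratin_hit = keratin_hit,
                            stringsAsFactors = FALSE)
    if (!is.null(hit_df)) {
      hit_df$marker_id <- id
      matches[[length(matches) + 1L]] <- hit_df
    }
  }
  obs <- do.call(rbind, rows)
  detail <- if (length(matches) > 0L) do.call(rbind, matches) else
    data.frame(panel_mass = numeric(), observed_mz = numeric(),
               mass_error = numeric(), snr = numeric(), keratin = logical(),
               marker_id = character(), stringsAsFactors = FALSE)
  structure(obs,
            class = c("zooms_observations", "data.frame"),
            matches = detail[, c("marker_id", "panel_mass", "observed_mz",
                                 "mass_error", "snr", "keratin")],
            sample_id = attr(peaklist, "sample_id"))
}

state_weight_factor <- function(state) {
  c(PRESENT = 1, LOW = 0.5, ABSENT = 0)[state]
}

#' Score every panel taxon against marker observations
#'
#' For each taxon: `score` is the weight of its expected markers observed,
#' divided by the total weight of its expected markers.  `EXPECTED` and
#' `EXPECTED_DIAGNOSTIC` markers weigh 1, `EXPECTED_UNCERTAIN` markers
#' weigh `uncertain_weight`; a marker observed `LOW` contributes half its
#' weight.  `penalty` flags taxa for which a marker expected absent was
#' observed present; `diagnostic_satisfied` requires every diagnostic
#' marker to be `PRESENT`.
#'
#' @param observations Output of [match_markers()].
#' @param panel The marker panel the observations were made against.
#' @param params A [classifier_params()].
#' @return A data.frame (class `zooms_scores`) with one row per taxon,
#'   ordered by taxon label, carrying attribute `"n_markers_observed"`
#'   (markers PRESENT or LOW, panel-wide).
#' @export
score_taxa <- function(observations, panel, params = classifier_params()) {
  stopifnot(inherits(observations, "zooms_observations"))
  if (!setequal(observations$marker_id, panel$markers$marker_id)) {
    stop("observations must cover every panel marker", call. = FALSE)
  }
  st <- stats::setNames(observations$state, observations$marker_id)
  rows <- lapply(seq_len(nrow(panel$taxa)), function(i) {
    taxon <- panel$taxa$taxon_label[i]
    exp_states <- panel$expectations[taxon, ]
    expected_ids <- names(exp_states)[exp_states != "ABSENT"]
    w <- ifelse(exp_states[expected_ids] == "EXPECTED_UNCERTAIN",
                params$uncertain_weight, 1)
    got <- state_weight_factor(st[expected_ids]) * w
    absent_ids <- names(exp_states)[exp_states == "ABSENT"]
    data.frame(
      taxon_label = taxon,
      rank_group = panel$taxa$rank_group[i],
      group_report_label = panel$taxa$group_report_label[i],
      score = sum(got) / sum(w),
      n_expected = length(expected_ids),
      n_present = sum(st[expected_ids] == "PRESENT"),
      n_low = sum(st[expected_ids] == "LOW"),
      diagnostic_satisfied = all(
        st[names(exp_states)[exp_states == "EXPECTED_DIAGNOSTIC"]] == "PRESENT"
      ),
      penalty = any(st[absent_ids] == "PRESENT"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$taxon_label), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("zooms_scores", "data.frame"),
            n_markers_observed = sum(observations$state != "ABSENT"),
            sample_id = attr(observations, "sample_id"))
}

#' Assign a taxon and confidence tier
#'
#' Decision rules, applied in order:
#' 1. top score below `probable_score`, or fewer than `min_markers` markers
#'    observed at all: `UNIDENTIFIED` ("X");
#' 2. unique top taxon with score `>= species_score` and all diagnostic
#'    markers fully present: `SPECIES`;
#' 3. unique top taxon with score `>= probable_score`: `PROBABLE`
#'    ("Probable <taxon>");
#' 4. tied top taxa (within 1e-9) sharing one rank group: `HIGHER_RANK`,
#'    reported under the group report label;
#' 5. ties spanning rank groups: `UNIDENTIFIED`, with an explanatory note.
#'
#' @param scores Output of [score_taxa()].
#' @param panel The marker panel.
#' @param params A [classifier_params()].
#' @param observations Optional [match_markers()] output, embedded as the
#'   evidence trail of the identification.
#' @return An object of class `zooms_identification`: fields `label`,
#'   `tier`, `report_label` (Table-style vocabulary, e.g. "Probable Bear"
#'   or "X"), `rule`, `scores`, `evidence`, `notes`.
#' @export
assign_taxon <- function(scores, panel, params = classifier_params(),
                         observations = NULL) {
  stopifnot(inherits(scores, "zooms_scores"))
  eps <- 1e-9
  n_obs <- attr(scores, "n_markers_observed")
  top_score <- max(scores$score)
  top <- scores[scores$score >= top_score - eps, , drop = FALSE]
  mk <- function(label, tier, report_label, rule, notes = "") {
    structure(
      list(label = label, tier = tier, report_label = report_label,
           rule = rule, scores = scores, evidence = observations,
           notes = notes, params = unclass(params),
           sample_id = attr(scores, "sample_id")),
      class = "zooms_identification"
    )
  }
  if (top_score < params$probable_score || n_obs < params$min_markers) {
    return(mk("X", "UNIDENTIFIED", "X", 1L,
              sprintf("top score %.3f, %d marker(s) observed", top_score, n_obs)))
  }
  if (nrow(top) == 1L) {
    if (top$score >= params$species_score && top$diagnostic_satisfied) {
      return(mk(top$taxon_label, "SPECIES", top$taxon_label, 2L))
    }
    return(mk(top$taxon_label, "PROBABLE",
              paste("Probable", top$taxon_label), 3L))
  }
  if (length(unique(top$rank_group)) == 1L &&
      length(unique(top$group_report_label)) == 1L) {
    return(mk(top$group_report_label[1], "HIGHER_RANK",
              top$group_report_label[1], 4L,
              sprintf("tie among: %s",
                      paste(sort(top$taxon_label), collapse = ", "))))
  }
  mk("X", "UNIDENTIFIED", "X", 5L,
     sprintf("tie across rank groups: %s",
             paste(sort(top$taxon_label), collapse = ", ")))
}

#' @export
print.zooms_identification <- function(x, ...) {
  cat(sprintf("<zooms_identification> %s: %s (tier %s, rule %d)\n",
              x$sample_id, x$report_label, x$tier, x$rule))
  invisible(x)
}

#' Explain an identification as a JSON report
#'
#' Serialises the full evidence trail: per-marker match table (panel mass,
#' observed m/z, mass error, SNR, state), per-taxon scores, the decision
#' rule that fired, and the classifier parameters.  Output is
#' deterministic: re-running on the same identification yields
#' byte-identical JSON.
#'
#' @param identification A [assign_taxon()] result.
#' @param pretty Pretty-print the JSON (default `TRUE`).
#' @return A JSON string (class `json`).
#' @export
explain_identification <- function(identification, pretty = TRUE) {
  stopifnot(inherits(identification, "zooms_identification"))
  ev <- identification$evidence
  doc <- list(
    sample_id = identification$sample_id,
    label = identification$label,
    tier = identification$tier,
    report_label = identification$report_label,
    rule_fired = identification$rule,
    notes = identification$notes,
    markers = if (is.null(ev)) list() else
      lapply(seq_len(nrow(ev)), function(i) {
        row <- ev[i, ]
        mm <- attr(ev, "matches")
        mm <- mm[mm$marker_id == row$marker_id, , drop = FALSE]
        list(marker_id = row$marker_id, group = row$group, state = row$state,
             matched = lapply(seq_len(nrow(mm)), function(j) {
               list(panel_mass = mm$panel_mass[j],
                    observed_mz = round(mm$observed_mz[j], 6),
                    mass_error = round(mm$mass_error[j], 6),
                    snr = round(mm$snr[j], 4),
                    keratin_flagged = mm$keratin[j])
             }))
      }),
    scores = lapply(seq_len(nrow(identification$scores)), function(i) {
      s <- identification$scores[i, ]
      list(taxon_label = s$taxon_label, rank_group = s$rank_group,
           score = round(s$score, 6),
           diagnostic_satisfied = s$diagnostic_satisfied,
           penalty = s$penalty)
    }),
    params = identification$params
  )
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = pretty, digits = NA)
}

#' Classify a peak list against a panel
#'
#' Convenience wrapper: [match_markers()], [score_taxa()], [assign_taxon()].
#'
#' @inheritParams match_markers
#' @return A `zooms_identification`.
#' @export
identify_peaks <- function(peaklist, panel, params = classifier_params(),
                           snr_pick_threshold = 3.0, snr_low_threshold = 1.5) {
  obs <- match_markers(peaklist, panel, params,
                       snr_pick_threshold, snr_low_threshold)
  scores <- score_taxa(obs, panel, params)
  assign_taxon(scores, panel, params, observations = obs)
}

#' Full pipeline on raw spectra
#'
#' Preprocessing (averaging, smoothing, baseline, picking), optional
#' recalibration, contaminant flagging, and tiered classification.
#'
#' @param spectra A [mass_spectrum()] or list of replicate spectra.
#' @param panel A marker panel (or `"builtin:cervid"` / a panel path).
#' @param preprocess A [preprocess_params()].
#' @param contaminants A [contaminant_config()].
#' @param classifier A [classifier_params()].
#' @param reference_masses Optional calibrant masses for [recalibrate()].
#' @return A `zooms_identification`; the contaminant-flagged peak list is
#'   attached as attribute `"peaklist"`.
#' @export
identify_spectrum <- function(spectra, panel = "builtin:cervid",
                              preprocess = preprocess_params(),
                              contaminants = contaminant_config(),
                              classifier = classifier_params(),
                              reference_masses = NULL) {
  panel <- resolve_panel(panel)
  pl <- preprocess_spectrum(spectra, preprocess)
  if (!is.null(reference_masses)) {
    pl <- recalibrate(pl, reference_masses)
  }
  pl <- flag_keratin(pl, contaminants)
  pl <- flag_polymer_series(pl, contaminants)
  id <- identify_peaks(pl, panel, classifier,
                       snr_pick_threshold = preprocess$snr_pick_threshold,
                       snr_low_threshold = preprocess$snr_low_threshold)
  attr(id, "peaklist") <- pl
  id
}
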