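panel <- builtin_cervid_panel()

test_that("paired markers require both masses for full presence", {
  pl <- peak_list(c(3043, 3059), c(10, 10), c(10, 10), sample_id = "pair")
  obs <- match_markers(pl, panel)
  expect_identical(obs$state[obs$marker_id == "G3043"], "PRESENT")

  one <- peak_list(3043, 10, 10, sample_id = "half")
  obs <- match_markers(one, panel)
  expect_identical(obs$state[obs$marker_id == "G3043"], "LOW")

  # strict mode flips one-of-two to ABSENT
  obs_strict <- match_markers(one, panel, classifier_params(strict_pairs = TRUE))
  expect_identical(obs_strict$state[obs_strict$marker_id == "G3043"], "ABSENT")
})

test_that("matching respects the mass tolerance boundary", {
  pl <- peak_list(1105.25, 10, 10, sample_id = "tol")
  obs <- match_markers(pl, panel, classifier_params(match_tolerance = 0.2))
  expect_identical(obs$state[obs$marker_id == "P1"], "ABSENT")
  obs <- match_markers(pl, panel, classifier_params(match_tolerance = 0.3))
  expect_identical(obs$state[obs$marker_id == "P1"], "PRESENT")
})

test_that("low-grade SNR and keratin flags demote marker evidence", {
  pl <- peak_list(1105, 10, 2.0, sample_id = "low")
  obs <- match_markers(pl, panel)
  expect_identical(obs$state[obs$marker_id == "P1"], "LOW")

  pl <- peak_list(1105, 10, 10, flags = "KERATIN", sample_id = "ker")
  obs <- match_markers(pl, panel)
  expect_identical(obs$state[obs$marker_id == "P1"], "LOW")
  expect_true(obs$keratin_hit[obs$marker_id == "P1"])
})

test_that("scores match a direct recomputation from the expectation matrix", {
  cases <- list(
    pattern_peaklist(panel, "White-Tailed Deer"),
    pattern_peaklist(panel, "White-Tailed Deer", drop_groups = "G"),
    pattern_peaklist(panel, "White-Tailed Deer", drop_groups = c("G", "C")),
    pattern_peaklist(panel, "Roe Deer", low_groups = "F"),
    pattern_peaklist(panel, "Caribou/Reindeer", drop_groups = c("A", "D")),
    peak_list(sample_id = "empty")
  )
  for (pl in cases) {
    obs <- match_markers(pl, panel)
    got <- score_taxa(obs, panel)
    want <- oracle_scores(obs, panel)
    expect_equal(stats::setNames(got$score, got$taxon_label),
                 want[got$taxon_label], tolerance = 1e-12)
  }
})

test_that("a full noiseless pattern scores 1.0 with diagnostics satisfied", {
  obs <- match_markers(pattern_peaklist(panel, "White-Tailed Deer"), panel)
  sc <- score_taxa(obs, panel)
  wtd <- sc[sc$taxon_label == "White-Tailed Deer", ]
  expect_equal(wtd$score, 1.0)
  expect_true(wtd$diagnostic_satisfied)
  expect_false(wtd$penalty)
  expect_true(all(sc$score[sc$taxon_label != "White-Tailed Deer"] < 1))

  empty_obs <- match_markers(peak_list(sample_id = "e"), panel)
  expect_true(all(score_taxa(empty_obs, panel)$score == 0))
})

test_that("tier assignment follows the decision rules in order", {
  # full pattern, high SNR: species call
  id <- identify_peaks(pattern_peaklist(panel, "White-Tailed Deer"), panel)
  expect_identical(id$label, "White-Tailed Deer")
  expect_identical(id$tier, "SPECIES")

  # G pair at low SNR: the storage-bag behaviour, demoted to probable
  id <- identify_peaks(pattern_peaklist(panel, "White-Tailed Deer",
                                        low_groups = "G"), panel)
  expect_identical(id$label, "White-Tailed Deer")
  expect_identical(id$tier, "PROBABLE")
  expect_identical(id$report_label, "Probable White-Tailed Deer")

  # G and C gone entirely: tie among the cervids, family-level call
  id <- identify_peaks(pattern_peaklist(panel, "White-Tailed Deer",
                                        drop_groups = c("G", "C")), panel)
  expect_identical(id$tier, "HIGHER_RANK")
  expect_identical(id$report_label, "Bovid/Cervid")

  # red and fallow share identical expectations: never a species call
  id <- identify_peaks(pattern_peaklist(panel, "Red Deer"), panel)
  expect_identical(id$tier, "HIGHER_RANK")
  expect_identical(id$report_label, "Bovid/Cervid")

  # nothing observed: X
  id <- identify_peaks(peak_list(sample_id = "none"), panel)
  expect_identical(id$label, "X")
  expect_identical(id$tier, "UNIDENTIFIED")

  # below min_markers even with a decent score: X
  few <- peak_list(c(1105, 1427), c(10, 10), c(10, 10), sample_id = "few")
  id <- identify_peaks(few, panel, classifier_params(min_markers = 3,
                                                     probable_score = 0.2))
  expect_identical(id$tier, "UNIDENTIFIED")
})

test_that("every discriminable taxon round-trips from its own pattern", {
  discriminable <- validate_panel(panel)$species_discriminable
  for (tx in panel$taxa$taxon_label) {
    id <- identify_peaks(pattern_peaklist(panel, tx), panel)
    if (tx %in% discriminable) {
      expect_identical(id$label, tx)
      expect_identical(id$tier, "SPECIES")
    } else {
      expect_identical(id$tier, "HIGHER_RANK")
    }
  }
})

test_that("increasing match tolerance never decreases any taxon's score", {
  for (seed in 1:10) {
    pl <- random_peaklist(seed, n = 30, lo = 1000, hi = 3200)
    prev <- rep(0, nrow(panel$taxa))
    for (tol in c(0.05, 0.2, 0.5, 1.0)) {
      obs <- match_markers(pl, panel, classifier_params(match_tolerance = tol))
      sc <- score_taxa(obs, panel)
      expect_true(all(sc$score >= prev - 1e-12))
      prev <- sc$score
    }
  }
})

test_that("classification does not depend on how the peak list was assembled", {
  pl <- pattern_peaklist(panel, "Caribou/Reindeer")
  set.seed(9)
  perm <- sample(nrow(pl))
  o <- order(pl$mz[perm])
  shuffled <- peak_list(pl$mz[perm][o], pl$intensity[perm][o],
                        pl$snr[perm][o], sample_id = "shuffled")
  a <- identify_peaks(pl, panel)
  b <- identify_peaks(shuffled, panel)
  expect_identical(a$label, b$label)
  expect_identical(a$tier, b$tier)
  expect_equal(a$scores$score, b$scores$score)
})

test_that("identification reports are stable, complete JSON", {
  id <- identify_peaks(pattern_peaklist(panel, "White-Tailed Deer"), panel)
  j1 <- explain_identification(id)
  j2 <- explain_identification(id)
  expect_identical(as.character(j1), as.character(j2))
  doc <- jsonlite::fromJSON(j1, simplifyVector = FALSE)
  expect_identical(doc$tier, "SPECIES")
  diag_states <- vapply(doc$markers, function(m)
    if (m$marker_id %in% c("C1580", "G3043")) m$state else NA_character_,
    character(1))
  expect_true(all(diag_states[!is.na(diag_states)] == "PRESENT"))

  id_x <- identify_peaks(peak_list(sample_id = "x"), panel)
  doc_x <- jsonlite::fromJSON(explain_identification(id_x),
                              simplifyVector = FALSE)
  expect_identical(doc_x$label, "X")
  expect_equal(doc_x$rule_fired, 1L)
})
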