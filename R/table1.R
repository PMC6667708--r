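#' Load the packaged bone-artefact identification fixture
#'
#' A transcription of the published identification table for the 15 worked
#' bone artefacts from the three St. Lawrence Iroquoian village sites: per
#' artefact, the result of each ZooMS acquisition method (original storage
#' bag, forced bag, PVC eraser, destructive) and the subsequent DNA
#' identification, plus burnt / tooth-pendant annotations.  The blank
#' control bag is included as a separate record with `is_control = TRUE`.
#'
#' Result strings use the controlled vocabulary: a taxon or group label
#' (e.g. `"Bear"`, `"Carnivora"`), `"Probable <taxon>"`, `"X"` (no
#' identification), `"N/T"` (method not tested), `"N/A"` (not applicable),
#' `"Fail"` (analysis failed).
#'
#' @return A data.frame with columns `sample_id`, `artefact_type`,
#'   `original_bag`, `forced_bag`, `eraser`, `destructive`, `dna`,
#'   `burnt`, `tooth_pendant`, `is_control`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_artefacts.tsv", package = "zoomsid",
                      mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = NULL,
                          colClasses = list(burnt = "logical",
                                            tooth_pendant = "logical",
                                            is_control = "logical"))
  validate_fixture_vocabulary(df)
  df
}

fixture_methods <- c("original_bag", "forced_bag", "eraser", "destructive",
                     "dna")
fixture_specials <- c("X", "N/T", "N/A", "Fail")

validate_fixture_vocabulary <- function(records) {
  need <- c("sample_id", "artefact_type", fixture_methods, "burnt",
            "tooth_pendant", "is_control")
  missing <- setdiff(need, names(records))
  if (length(missing) > 0L) {
    stop("fixture lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  taxon_pat <- "^(Probable )?[A-Z][A-Za-z./()' -]*$"
  for (m in fixture_methods) {
    vals <- records[[m]]
    ok <- vals %in% fixture_specials | grepl(taxon_pat, vals)
    if (!all(ok)) {
      stop("method '", m, "' contains value(s) outside the controlled ",
           "vocabulary: ", paste(unique(vals[!ok]), collapse = ", "),
           call. = FALSE)
    }
  }
  invisible(records)
}

#' Count fixture records under a declarative filter
#'
#' Filters the artefact records (control records are excluded unless
#' `include_control = TRUE`) and counts them.  Filters combine with AND:
#'
#' * `method` + `value`: records whose result for that method equals
#'   `value` exactly;
#' * `method` + `value_class`: `"tested"` (result is not `N/T`/`N/A`) or
#'   `"identified"` (tested, and not `X`/`Fail` either);
#' * `burnt`: records with the given burnt flag.
#'
#' With `method` given and neither `value` nor `value_class`, a named
#' table of result counts for that method is returned instead.
#'
#' @param records Fixture records from [load_table1_fixture()].
#' @param method One of `"original_bag"`, `"forced_bag"`, `"eraser"`,
#'   `"destructive"`, `"dna"`, or `NULL`.
#' @param value Exact result string to count.
#' @param value_class `"tested"` or `"identified"`.
#' @param burnt Logical filter on the burnt flag.
#' @param include_control Include control records (default `FALSE`).
#' @return An integer count, or a named table when only `method` is given.
#' @export
summarize_fixture <- function(records, method = NULL, value = NULL,
                              value_class = NULL, burnt = NULL,
                              include_control = FALSE) {
  validate_fixture_vocabulary(records)
  if (!include_control) records <- records[!records$is_control, , drop = FALSE]
  if (!is.null(method)) {
    if (!method %in% fixture_methods) {
      stop("unknown method '", method, "'; expected one of: ",
           paste(fixture_methods, collapse = ", "), call. = FALSE)
    }
    vals <- records[[method]]
    if (!is.null(value)) {
      records <- records[vals == value, , drop = FALSE]
    } else if (!is.null(value_class)) {
      value_class <- match.arg(value_class, c("tested", "identified"))
      tested <- !vals %in% c("N/T", "N/A")
      keep <- if (value_class == "tested") tested else
        tested & !vals %in% c("X", "Fail")
      records <- records[keep, , drop = FALSE]
    } else if (is.null(burnt)) {
      return(table(vals))
    }
  } else if (!is.null(value) || !is.null(value_class)) {
    stop("value/value_class filters require a method", call. = FALSE)
  }
  if (!is.null(burnt)) {
    records <- records[records$burnt == burnt, , drop = FALSE]
  }
  nrow(records)
}
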