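#' Published genus-wide numt survey tables
#'
#' Per-species summary of the published 11-species Drosophila numt survey
#' (assembly size in Mb, repeat content, numt count, average and total
#' numt length in bp), and the corresponding gross-rearrangement event
#' table ("events" and "distinct numts affected" per class). Bundled as
#' plain TSV fixtures; these printed values serve as inputs for
#' reproducing the survey's derived statistics (correlations, fractions,
#' rate inputs).
#'
#' @return `drosophilaNumtSurvey`: data.frame with one row per species.
#' @export
drosophilaNumtSurvey <- function() {
  read.delim(system.file("extdata", "drosophila_numt_survey.tsv",
                         package = "numtdyn", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' @rdname drosophilaNumtSurvey
#' @return `drosophilaRearrangementCounts`: data.frame of event and
#'   affected-numt counts per species and class.
#' @export
drosophilaRearrangementCounts <- function() {
  read.delim(system.file("extdata", "drosophila_rearrangements.tsv",
                         package = "numtdyn", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' @rdname drosophilaNumtSurvey
#' @return `drosophilaSurveyCounts`: list of the survey's printed scalar
#'   counts: total numts (302), numts with gross rearrangements (79),
#'   paralogous numts (93) in paralog sets (26), dated non-excluded
#'   insertions (266) split into terminal (238.7) and internal (27.3)
#'   density mass, intronic numts (24), repeat-adjacent numts (92) among
#'   testable (233) with background repeat fraction (0.15), numts excluded
#'   for short scaffolds (69) and for age windows reaching the deep split
#'   (36).
#' @export
drosophilaSurveyCounts <- function() {
  list(totalNumts = 302,
       rearrangedNumts = 79,
       paralogousNumts = 93,
       paralogSets = 26,
       datedInsertions = 266,
       terminalMass = 238.7,
       internalMass = 27.3,
       intronicNumts = 24,
       repeatAdjacentNumts = 92,
       repeatTestableNumts = 233,
       backgroundRepeatFraction = 0.15,
       shortScaffoldExcluded = 69,
       deepWindowExcluded = 36)
}
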