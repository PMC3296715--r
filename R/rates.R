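## Insertion, duplication and steady-state deletion rate estimation, plus
## correlation and report tables.

#' Density table of dated insertions
#'
#' Collects per-branch frequency-density masses from a set of placements,
#' dropping excluded numts (windows reaching the deep split). Masses of the
#' retained numts sum to the number of dated insertions. Supply
#' `eventOf` to count ortholog sets once: masses of copies sharing an
#' event are downweighted so each event contributes total mass 1.
#'
#' @param placements list of [PlacementResult-class].
#' @param eventOf optional named character: numtId -> event/ortholog-set id.
#' @return data.frame `numtId`, `branch`, `mass`, plus attribute
#'   `nDated` (number of dated, non-excluded insertions).
#' @export
insertionDensityTable <- function(placements, eventOf = NULL) {
  rows <- list()
  ids <- character(0)
  for (pl in placements) {
    if (pl@excluded) next
    ids <- c(ids, pl@numtId)
    tb <- pl@table[pl@table$density > 0, , drop = FALSE]
    if (nrow(tb)) {
      rows[[length(rows) + 1L]] <- data.frame(
        numtId = pl@numtId, branch = tb$branch, mass = tb$density,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
         else data.frame(numtId = character(), branch = character(),
                         mass = numeric(), stringsAsFactors = FALSE)
  if (!is.null(eventOf) && nrow(out)) {
    ev <- eventOf[out$numtId]
    copies <- table(eventOf[ids])
    out$mass <- out$mass / as.numeric(copies[ev])
  }
  attr(out, "nDated") <- if (is.null(eventOf)) length(ids)
                         else length(unique(eventOf[ids]))
  out
}

## total time (My) along the configured recent branch set, truncating each
## branch at the age cutoff
recentBranchTime <- function(ct, config) {
  br <- ct@branches
  sel <- br$branch %in% config@recentBranches
  if (!any(sel)) stop("no recent branches found on the tree")
  sum(pmin(br$parentAge[sel], config@recentBranchAgeCutoffMy) -
        br$childAge[sel])
}

#' Genus-average and per-branch numt insertion rate
#'
#' Insertion rate = N_i / T, where N_i is the density-weighted number of
#' insertions attributed to the configured recent branch set (branches
#' arising within the last ~20 My) and T the total time along those
#' branches (each truncated at the age cutoff). Insertions dated to a
#' window of several branches contribute fractional mass to each in
#' proportion to branch duration.
#'
#' @param density data.frame with columns `branch`, `mass` (e.g. from
#'   [insertionDensityTable()]).
#' @param ct the [CalibratedTree-class].
#' @param config a [PipelineConfig-class] (recent branch set and cutoff).
#' @return list: `rate` (insertions/My), `Ni`, `T`, `perBranch`
#'   (data.frame branch, mass, duration, rate over all branches with
#'   nonzero mass or in the recent set).
#' @export
insertionRate <- function(density, ct, config = pipelineConfig()) {
  br <- ct@branches
  sel <- br$branch %in% config@recentBranches
  if (!any(sel)) stop("empty recent branch set")
  Tt <- recentBranchTime(ct, config)
  massBy <- tapply(density$mass, density$branch, sum)
  mass <- setNames(rep(0, nrow(br)), br$branch)
  mass[names(massBy)] <- massBy
  Ni <- sum(mass[br$branch[sel]])
  perBranch <- data.frame(
    branch = br$branch, mass = as.numeric(mass[br$branch]),
    duration = br$duration, terminal = br$terminal,
    recent = sel, stringsAsFactors = FALSE)
  perBranch$rate <- perBranch$mass / perBranch$duration
  list(rate = Ni / Tt, Ni = Ni, T = Tt,
       perBranch = perBranch[perBranch$mass > 0 | perBranch$recent, ])
}

#' Numt duplication rate
#'
#' Rate = Dp / (N * T/2): `Dp` duplication events on the recent branch set
#' (one per paralog set in `"one_per_set"` mode, all duplicate copies in
#' `"total"` mode), `N` the average number of numts per genome, and T/2
#' half the total time along the branches, since the mean age of a
#' duplication is assumed to be roughly half its branch window.
#'
#' @param Dp number of duplication events (already counted in the chosen
#'   mode) or, if `paralogSetSizes` is given and `countMode = "total"`,
#'   recomputed as `sum(sizes - 1)`.
#' @param N average numts per genome (> 0).
#' @param ct the [CalibratedTree-class].
#' @param config a [PipelineConfig-class].
#' @param countMode `"one_per_set"` (default) or `"total"`.
#' @param paralogSetSizes optional integer vector of paralog set sizes.
#' @return list: `rate`, `Dp`, `N`, `Thalf`.
#' @export
duplicationRate <- function(Dp = NULL, N, ct, config = pipelineConfig(),
                            countMode = c("one_per_set", "total"),
                            paralogSetSizes = NULL) {
  countMode <- match.arg(countMode)
  if (!is.null(paralogSetSizes)) {
    Dp <- if (countMode == "one_per_set") length(paralogSetSizes)
          else sum(paralogSetSizes - 1L)
  }
  if (is.null(Dp)) stop("supply Dp or paralogSetSizes")
  if (N <= 0) stop("N (average numts per genome) must be > 0")
  Thalf <- recentBranchTime(ct, config) / 2
  list(rate = Dp / (N * Thalf), Dp = Dp, N = N, Thalf = Thalf)
}

#' Steady-state deletion rate and numt half-life
#'
#' Equates numt gain and loss under a constant-complement assumption:
#' deletion rate = gain rate / N; half-life = ln(2) / deletion rate.
#'
#' @param gainRate numt gains per My (insertions, or insertions plus
#'   duplications).
#' @param N average numts per genome (> 0).
#' @return list: `rate` (deletions/numt/My), `halfLife` (My; `Inf` when
#'   the gain rate is 0).
#' @export
deletionRateSteadyState <- function(gainRate, N) {
  if (N <= 0) stop("N must be > 0")
  if (gainRate < 0) stop("gain rate must be >= 0")
  rate <- gainRate / N
  list(rate = rate, halfLife = if (rate > 0) log(2) / rate else Inf)
}

#' Combined rate estimates object
#'
#' @param insertion result of [insertionRate()].
#' @param duplication result of [duplicationRate()].
#' @param deletion result of [deletionRateSteadyState()].
#' @return a [RateEstimates-class].
#' @export
rateEstimates <- function(insertion, duplication, deletion) {
  new("RateEstimates",
      insertionRate = insertion$rate,
      duplicationRate = duplication$rate,
      deletionRate = deletion$rate,
      halfLife = deletion$halfLife,
      perBranch = insertion$perBranch,
      inputs = list(Ni = insertion$Ni, T = insertion$T,
                    Dp = duplication$Dp, N = duplication$N,
                    Thalf = duplication$Thalf))
}

#' Pearson and Spearman correlations with t-approximation P values
#'
#' Pearson on raw values; Spearman as Pearson on average ranks (ties get
#' mean rank). Both P values are two-sided from the t approximation
#' t = r * sqrt((n-2)/(1-r^2)). Constant columns give an undefined
#' correlation, reported as NA.
#'
#' @param x,y numeric vectors (>= 3 complete pairs).
#' @return data.frame with rows `pearson`, `spearman`: `estimate`,
#'   `pValue`, `n`.
#' @export
correlationSuite <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  corP <- function(a, b) {
    if (var(a) == 0 || var(b) == 0) return(c(NA_real_, NA_real_))
    r <- cor(a, b)
    if (abs(r) >= 1) return(c(r, 0))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    c(r, 2 * pt(-abs(tstat), n - 2))
  }
  p1 <- corP(x, y)
  p2 <- corP(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  data.frame(row.names = c("pearson", "spearman"),
             estimate = c(p1[1], p2[1]), pValue = c(p1[2], p2[2]), n = n)
}

#' Fraction of dated insertions on terminal branches
#'
#' @param density density table ([insertionDensityTable()]).
#' @param ct the [CalibratedTree-class].
#' @return list: `terminalMass`, `internalMass`, `fraction` (percent of
#'   total mass on terminal branches).
#' @export
terminalInsertionFraction <- function(density, ct) {
  br <- ct@branches
  term <- setNames(br$terminal, br$branch)
  tm <- sum(density$mass[term[density$branch]])
  im <- sum(density$mass[!term[density$branch]])
  list(terminalMass = tm, internalMass = im,
       fraction = 100 * tm / (tm + im))
}

#' Per-species summary report tables
#'
#' Mirrors the survey's reporting: per-species numt counts, average and
#' total numt lengths (fragment-union basis, excluding interruptions and
#' internal duplications), a rearrangement-event table in
#' "events (affected numts)" form with totals, and per-branch insertion
#' rates when placements are supplied.
#'
#' @param numts list of [NumtAnnotation-class].
#' @param events rearrangement event data.frame
#'   ([classifyRearrangements()] output, any number of numts).
#' @param speciesOrder optional ordering of species rows.
#' @param insertion optional result of [insertionRate()] for the
#'   per-branch rate table.
#' @return list of data.frames: `perSpecies`, `rearrangements`,
#'   `perBranch` (NULL when no placements supplied).
#' @export
summaryReport <- function(numts, events = NULL, speciesOrder = NULL,
                          insertion = NULL) {
  sp <- vapply(numts, function(n) n@species, "")
  len <- vapply(numts, numtLength, 0)
  if (is.null(speciesOrder)) speciesOrder <- sort(unique(sp))
  perSpecies <- do.call(rbind, lapply(speciesOrder, function(s) {
    idx <- sp == s
    data.frame(species = s, nNumts = sum(idx),
               avgLengthBp = if (any(idx)) round(mean(len[idx])) else NA,
               totalContentBp = sum(len[idx]), stringsAsFactors = FALSE)
  }))
  types <- c("interruption", "deletion", "inversion", "internal_duplication")
  rearr <- NULL
  if (!is.null(events)) {
    id2sp <- setNames(sp, vapply(numts, function(n) n@numtId, ""))
    rearr <- do.call(rbind, lapply(speciesOrder, function(s) {
      row <- data.frame(species = s, stringsAsFactors = FALSE)
      for (ty in types) {
        ee <- events[events$type == ty &
                       id2sp[events$numtId] %in% s, , drop = FALSE]
        nEv <- nrow(ee); nNumt <- length(unique(ee$numtId))
        row[[paste0(ty, "Events")]] <- nEv
        row[[paste0(ty, "Numts")]] <- nNumt
        row[[ty]] <- if (nEv) sprintf("%d (%d)", nEv, nNumt) else "-"
      }
      row
    }))
    tot <- data.frame(species = "Total", stringsAsFactors = FALSE)
    for (ty in types) {
      ee <- events[events$type == ty, , drop = FALSE]
      tot[[paste0(ty, "Events")]] <- nrow(ee)
      tot[[paste0(ty, "Numts")]] <- length(unique(ee$numtId))
      tot[[ty]] <- sprintf("%d (%d)", nrow(ee),
                           length(unique(ee$numtId)))
    }
    rearr <- rbind(rearr, tot)
  }
  list(perSpecies = perSpecies, rearrangements = rearr,
       perBranch = if (!is.null(insertion)) insertion$perBranch else NULL)
}
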