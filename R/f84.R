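#' F84 substitution model parameters
#'
#' The F84 model allows unequal stationary base frequencies and a
#' transition/transversion bias, and is the model used by classic maximum
#' likelihood DNA phylogeny programs. Internally the model is parameterised
#' by two event intensities: a "transversion-type" intensity `b` that
#' proposes any base in proportion to its frequency, and a "transition-type"
#' intensity `a` that proposes a base within the same purine/pyrimidine
#' class. Both are scaled so that one unit of branch length equals one
#' expected substitution per site at stationarity.
#'
#' @param freqs named numeric vector of stationary frequencies (A, C, G, T);
#'   must be positive and sum to 1 (renormalised internally).
#' @param tsTv expected transition/transversion ratio (default 2.0, the
#'   conventional default of ML DNA phylogeny programs).
#' @return an [F84Params-class] object.
#' @examples
#' m <- f84Params(freqsFromAT(0.78), tsTv = 2)
#' rowSums(f84TransitionMatrix(m, 0.1))
#' @export
f84Params <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      tsTv = 2.0) {
  stopifnot(length(freqs) == 4L, all(freqs > 0), tsTv > 0)
  freqs <- freqs / sum(freqs)
  names(freqs) <- BASES
  piA <- freqs[["A"]]; piC <- freqs[["C"]]
  piG <- freqs[["G"]]; piT <- freqs[["T"]]
  piR <- piA + piG; piY <- piC + piT
  b <- 1
  tvRate <- 2 * b * piR * piY
  tsFromB <- 2 * b * (piA * piG + piC * piT)
  denom <- 2 * (piA * piG / piR + piC * piT / piY)
  a <- (tsTv * tvRate - tsFromB) / denom
  if (a < 0) {
    stop("tsTv ratio ", tsTv, " is below the minimum attainable for these ",
         "base frequencies")
  }
  total <- tvRate + tsFromB + a * denom
  new("F84Params", freqs = freqs, tsTv = tsTv,
      a = a / total, b = b / total)
}

#' F84 transition probability matrix
#'
#' @param model an [F84Params-class] object.
#' @param t branch length in expected substitutions per site (>= 0).
#' @return 4x4 row-stochastic matrix, rows/cols ordered A, C, G, T.
#' @export
f84TransitionMatrix <- function(model, t) {
  stopifnot(is(model, "F84Params"), t >= 0)
  p <- model@freqs
  a <- model@a; b <- model@b
  piClass <- c(p[["A"]] + p[["G"]], p[["C"]] + p[["T"]],
               p[["A"]] + p[["G"]], p[["C"]] + p[["T"]])[c(1, 2, 1, 2)]
  ## class of A,C,G,T: R,Y,R,Y
  cls <- c(1L, 2L, 1L, 2L)
  Pi <- c(p[["A"]] + p[["G"]], p[["C"]] + p[["T"]])
  e1 <- exp(-(a + b) * t)
  e2 <- exp(-b * t)
  P <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in 1:4) for (j in 1:4) {
    P[i, j] <- (1 - e2) * p[[j]] +
      (if (cls[i] == cls[j]) e2 * (1 - exp(-a * t)) * p[[j]] / Pi[cls[j]] else 0) +
      (if (i == j) e1 else 0)
  }
  P
}

#' Expected proportion of differing sites under F84
#'
#' Closed form for the expected p-distance between two sequences separated
#' by a total path length of `t` expected substitutions per site, used as an
#' independent check on sequence simulation.
#'
#' @inheritParams f84TransitionMatrix
#' @return expected pairwise difference per site.
#' @export
f84ExpectedPDistance <- function(model, t) {
  P <- f84TransitionMatrix(model, t)
  1 - sum(model@freqs * diag(P))
}

## Mutate an integer-coded sequence across a branch of length t (expected
## substitutions/site). Sites with NA (N) are left untouched.
evolveCodes <- function(code, model, t) {
  if (t <= 0) return(code)
  P <- f84TransitionMatrix(model, t)
  out <- code
  for (i in 1:4) {
    idx <- which(!is.na(code) & code == i)
    if (length(idx)) {
      out[idx] <- sample.int(4L, length(idx), replace = TRUE, prob = P[i, ])
    }
  }
  out
}
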