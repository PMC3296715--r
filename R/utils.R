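## Internal sequence utilities. Sequences are passed around either as
## Biostrings objects (I/O boundary) or as integer code vectors 1..4
## (A,C,G,T) with NA for N; masking state (lowercase) is carried separately.

BASES <- c("A", "C", "G", "T")

## data.table is used via :: only; enable native [.data.table semantics
.datatable.aware <- TRUE

## code points: A C G T N a c g t n
.CODE_MAP <- local({
  m <- rep(NA_integer_, 128L)
  m[utf8ToInt("A")] <- 1L; m[utf8ToInt("C")] <- 2L
  m[utf8ToInt("G")] <- 3L; m[utf8ToInt("T")] <- 4L
  m[utf8ToInt("a")] <- 1L; m[utf8ToInt("c")] <- 2L
  m[utf8ToInt("g")] <- 3L; m[utf8ToInt("t")] <- 4L
  m
})

## Decompose a DNA string into base codes (1..4, NA for N/n) and a mask
## flag per position (TRUE where lowercase).
seqToCodes <- function(x) {
  if (inherits(x, "XString")) x <- as.character(x)
  stopifnot(is.character(x), length(x) == 1L)
  ints <- utf8ToInt(x)
  bad <- ints > 127L | is.na(.CODE_MAP[ints]) &
    !(ints %in% utf8ToInt("Nn"))
  if (any(bad)) {
    stop("non-IUPAC character(s) at position(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  list(code = .CODE_MAP[ints], masked = ints >= 97L)
}

codesToSeq <- function(code, masked = NULL) {
  ch <- ifelse(is.na(code), utf8ToInt("N"), utf8ToInt("A") - 1L)
  off <- c(0L, 2L, 6L, 19L)   # A->A, C, G, T offsets from "A"
  ch[!is.na(code)] <- utf8ToInt("A") + off[code[!is.na(code)]]
  if (!is.null(masked)) ch[masked] <- ch[masked] + 32L
  intToUtf8(ch)
}

revcompCodes <- function(code) {
  out <- rev(code)
  ifelse(is.na(out), NA_integer_, 5L - out)
}

## Weighted sampling of bases for random sequence generation.
randomCodes <- function(n, freqs) {
  sample.int(4L, n, replace = TRUE, prob = freqs)
}

#' Base frequencies from an A+T fraction
#'
#' Symmetric composition with A = T and C = G, handy for specifying the
#' A+T-rich mitochondrial and nuclear backgrounds used across the package.
#'
#' @param at A+T fraction in (0, 1).
#' @return named numeric vector (A, C, G, T) summing to 1.
#' @examples
#' freqsFromAT(0.78)
#' @export
freqsFromAT <- function(at) {
  stopifnot(at > 0, at < 1)
  c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
}

empiricalFreqs <- function(code) {
  tab <- tabulate(code, nbins = 4L)
  if (sum(tab) == 0L) stop("sequence contains no unambiguous bases")
  f <- tab / sum(tab)
  ## guard against zero frequencies for likelihood work
  f <- pmax(f, 1e-4)
  f <- f / sum(f)
  names(f) <- BASES
  f
}

## 0-based half-open interval helpers (internal convention everywhere)
intervalWidth <- function(start, end) end - start

`%||%` <- function(a, b) if (is.null(a)) b else a
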