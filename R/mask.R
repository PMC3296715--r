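#' Entropy-based low-complexity masking
#'
#' Segments a DNA sequence into low-complexity regions by windowed Shannon
#' entropy, in the spirit of classic nucleotide complexity filters: windows
#' whose entropy is at or below `locut` bits trigger a candidate segment,
#' which is extended through any adjacent windows with entropy at or below
#' `hicut`. All residues covered by the selected windows are lowercased;
#' residue identity and sequence length are preserved, and masking is
#' idempotent. AT-rich mitochondrial genomes produce many spurious
#' similarity hits without this step.
#'
#' @param x a single character string of DNA (existing lowercase is kept
#'   masked), or a `DNAStringSet` from [loadSequences()] whose `mask`
#'   metadata column is then updated.
#' @param window window size in bases (>= 4).
#' @param locut trigger entropy threshold in bits.
#' @param hicut extension entropy threshold in bits (>= locut).
#' @return same type as `x`, with low-complexity runs masked.
#' @examples
#' maskLowComplexity(strrep("A", 30))
#' @export
maskLowComplexity <- function(x, window = 21, locut = 1.4, hicut = 1.6) {
  stopifnot(window >= 4, hicut >= locut)
  if (inherits(x, "DNAStringSet")) {
    masks <- lapply(seq_along(x), function(i) {
      s <- seqToCodes(as.character(x[[i]]))
      old <- S4Vectors::mcols(x)$mask[[i]]
      flag <- maskFlags(s$code, window, locut, hicut)
      if (length(old)) {
        pos <- unlist(lapply(seq_along(old), function(k)
          seq(IRanges::start(old)[k], IRanges::end(old)[k])))
        flag[pos] <- TRUE
      }
      IRanges::IRanges(flag)
    })
    S4Vectors::mcols(x)$mask <- IRanges::IRangesList(masks)
    return(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  s <- seqToCodes(x)
  flag <- maskFlags(s$code, window, locut, hicut) | s$masked
  codesToSeq(s$code, masked = flag)
}

## logical per-position mask from windowed entropy segmentation
maskFlags <- function(code, window, locut, hicut) {
  L <- length(code)
  flag <- logical(L)
  if (L < window) return(flag)
  H <- windowEntropy(code, window)
  ext <- H <= hicut
  trig <- H <= locut
  if (!any(trig)) return(flag)
  ## runs of extendable windows containing >= 1 trigger window
  r <- rle(ext)
  endIdx <- cumsum(r$lengths)
  startIdx <- endIdx - r$lengths + 1L
  for (k in which(r$values)) {
    i1 <- startIdx[k]; i2 <- endIdx[k]
    if (any(trig[i1:i2])) flag[i1:(i2 + window - 1L)] <- TRUE
  }
  flag
}

## Shannon entropy (bits) of each length-`window` window; NA bases ignored.
## Uses H = log2(n) - sum(c_i log2 c_i)/n with a lookup table over counts.
windowEntropy <- function(code, window) {
  L <- length(code)
  nw <- L - window + 1L
  nlogn <- c(0, seq_len(window) * log2(seq_len(window)))
  sumNlogN <- numeric(nw)
  tot <- integer(nw)
  for (b in 1:4) {
    v <- as.integer(!is.na(code) & code == b)
    cs <- c(0L, cumsum(v))
    cnt <- cs[(window + 1L):(L + 1L)] - cs[1:nw]
    sumNlogN <- sumNlogN + nlogn[cnt + 1L]
    tot <- tot + cnt
  }
  H <- log2(tot) - sumNlogN / tot
  H[tot == 0L] <- Inf
  H
}
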