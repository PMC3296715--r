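#' Load genome sequences from a FASTA file
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet] and validates it:
#' the file must be non-empty, record IDs (first whitespace-separated header
#' token) must be unique, and residues must be IUPAC DNA letters (N
#' allowed). Lowercase (masked) runs are preserved as per-sequence mask
#' ranges in `mcols(x)$mask`; masking never changes residue identity, only
#' case. A `topology` metadata column records linear/circular state.
#'
#' @param path readable FASTA file.
#' @param expectedTopology `"linear"` (nuclear scaffolds) or `"circular"`
#'   (mitochondrial genomes).
#' @return a `DNAStringSet` with metadata columns `topology` and `mask`
#'   (an `IRangesList` of masked runs, 1-based as is native to IRanges).
#' @export
loadSequences <- function(path, expectedTopology = c("linear", "circular")) {
  expectedTopology <- match.arg(expectedTopology)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids)) {
    stop("duplicated FASTA record ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(BiocGenerics::width(raw) == 0L)) {
    stop("zero-length FASTA record: ", ids[BiocGenerics::width(raw) == 0L][1])
  }
  chars <- as.character(raw)
  allowed <- strsplit("ACGTRYSWKMBDHVNacgtryswkmbdhvn", "")[[1]]
  masks <- vector("list", length(raw))
  for (i in seq_along(chars)) {
    v <- strsplit(chars[i], "")[[1]]
    bad <- !(v %in% allowed)
    if (any(bad)) {
      stop("non-IUPAC character '", v[which(bad)[1]], "' in record ", ids[i])
    }
    lower <- v %in% letters
    r <- IRanges::IRanges(lower)          # ranges of TRUE runs, 1-based
    masks[[i]] <- r
  }
  dna <- Biostrings::DNAStringSet(toupper(chars))
  names(dna) <- ids
  S4Vectors::mcols(dna)$topology <- rep(expectedTopology, length(dna))
  S4Vectors::mcols(dna)$mask <- IRanges::IRangesList(masks)
  dna
}

#' Retrieve a sequence as a character string with mask reapplied
#'
#' @param x DNAStringSet from [loadSequences()].
#' @param i record index or name.
#' @return character string with masked runs in lowercase.
#' @export
maskedChar <- function(x, i = 1L) {
  s <- as.character(x[[i]])
  m <- S4Vectors::mcols(x)$mask
  if (!is.null(m)) {
    idx <- if (is.character(i)) match(i, names(x)) else i
    r <- m[[idx]]
    if (length(r)) {
      v <- strsplit(s, "")[[1]]
      pos <- unlist(lapply(seq_along(r), function(k)
        seq(IRanges::start(r)[k], IRanges::end(r)[k])))
      v[pos] <- tolower(v[pos])
      s <- paste(v, collapse = "")
    }
  }
  s
}

#' Build a calibrated tree from an ape phylo object
#'
#' Branch lengths are interpreted as millions of years. The tree must be
#' rooted and ultrametric (all root-to-tip depths equal within `tol`);
#' node ages are depths below the root age, with leaves at age 0.
#'
#' @param phy a rooted `phylo` with branch lengths in My.
#' @param tol ultrametricity tolerance in My.
#' @return a [CalibratedTree-class] object.
#' @export
calibratedTree <- function(phy, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  tipDepth <- depth[seq_len(ntip)]
  spread <- max(tipDepth) - min(tipDepth)
  if (spread > tol) {
    stop(sprintf(paste0("tree is not ultrametric: leaf depth spread %.6g My",
                        " (min %.6g, max %.6g)"),
                 spread, min(tipDepth), max(tipDepth)))
  }
  rootAge <- max(depth)
  ages <- rootAge - depth
  ages[seq_len(ntip)] <- 0
  labs <- character(ntip + phy$Nnode)
  labs[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label) && all(nzchar(phy$node.label))) {
    labs[ntip + seq_len(phy$Nnode)] <- phy$node.label
  } else {
    labs[ntip + seq_len(phy$Nnode)] <- paste0("n", ntip + seq_len(phy$Nnode))
  }
  br <- data.frame(
    branch = labs[phy$edge[, 2]],
    parentAge = ages[phy$edge[, 1]],
    childAge = ages[phy$edge[, 2]],
    node = phy$edge[, 2],
    terminal = phy$edge[, 2] <= ntip,
    stringsAsFactors = FALSE)
  br$duration <- br$parentAge - br$childAge
  new("CalibratedTree", tree = phy, ages = ages, branches = br)
}

#' Load a calibrated (ultrametric) species tree from a newick file
#'
#' @param path newick file with branch lengths in My.
#' @param tol ultrametricity tolerance (My).
#' @return a [CalibratedTree-class].
#' @export
loadCalibratedTree <- function(path, tol = 1e-6) {
  phy <- ape::read.tree(path)
  if (is.null(phy)) stop("could not parse newick file: ", path)
  calibratedTree(phy, tol = tol)
}

#' The calibrated 11-species Drosophila tree used throughout the package
#'
#' Consensus genus topology with TimeTree-derived node ages (My) and an
#' Anopheles outgroup attached at 470 My. Bundled with the package as a
#' newick fixture.
#'
#' @param outgroup keep the Anopheles outgroup leaf (default TRUE).
#' @return a [CalibratedTree-class].
#' @examples
#' tr <- drosophilaTree()
#' branchTable(tr)
#' @export
drosophilaTree <- function(outgroup = TRUE) {
  path <- system.file("extdata", "drosophila_tree.nwk", package = "numtdyn",
                      mustWork = TRUE)
  ct <- loadCalibratedTree(path)
  if (!outgroup) {
    phy <- ape::drop.tip(ct@tree, "Agam")
    ct <- calibratedTree(phy)
  }
  ct
}

## ---- numt annotation serialization --------------------------------------

numtsToTable <- function(numts) {
  if (length(numts) == 0L) {
    return(data.frame(numtId = character(), species = character(),
                      scaffold = character(), fragIndex = integer(),
                      nucStart = integer(), nucEnd = integer(),
                      mitoStart = integer(), mitoEnd = integer(),
                      strand = character(), identity = numeric(),
                      originSpanning = logical(), numtLength = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(numts, function(n) {
    fr <- n@fragments
    data.frame(numtId = n@numtId, species = n@species,
               scaffold = n@scaffold, fragIndex = seq_len(nrow(fr)),
               nucStart = fr$nucStart, nucEnd = fr$nucEnd,
               mitoStart = fr$mitoStart, mitoEnd = fr$mitoEnd,
               strand = fr$strand, identity = fr$identity,
               originSpanning = fr$originSpanning,
               numtLength = n@numtLength, stringsAsFactors = FALSE)
  }))
}

tableToNumts <- function(tab) {
  if (nrow(tab) == 0L) return(list())
  lapply(split(tab, factor(tab$numtId, levels = unique(tab$numtId))),
         function(d) {
           d <- d[order(d$fragIndex), ]
           new("NumtAnnotation", numtId = d$numtId[1], species = d$species[1],
               scaffold = d$scaffold[1],
               fragments = data.frame(
                 nucStart = d$nucStart, nucEnd = d$nucEnd,
                 mitoStart = d$mitoStart, mitoEnd = d$mitoEnd,
                 strand = d$strand, identity = d$identity,
                 originSpanning = d$originSpanning, stringsAsFactors = FALSE),
               numtLength = d$numtLength[1])
         })
}

#' Write numt annotations to TSV, BED or GFF3
#'
#' Internal coordinates are 0-based half-open throughout the package and
#' are converted only here: BED keeps 0-based half-open starts/ends, GFF3
#' uses 1-based inclusive. The TSV format is lossless (per-fragment
#' mitochondrial origin intervals and strands) and round-trips exactly via
#' [readNumtAnnotations()].
#'
#' @param numts list of [NumtAnnotation-class] objects (may be empty).
#' @param path output file.
#' @param format one of `"TSV"`, `"BED"`, `"GFF3"`.
#' @param scaffoldLengths optional named vector of scaffold lengths used to
#'   validate that fragments lie within bounds.
#' @return `path`, invisibly.
#' @export
writeNumtAnnotations <- function(numts, path, format = c("TSV", "BED", "GFF3"),
                                 scaffoldLengths = NULL) {
  format <- match.arg(format)
  tab <- numtsToTable(numts)
  if (!is.null(scaffoldLengths) && nrow(tab)) {
    lim <- scaffoldLengths[tab$scaffold]
    bad <- is.na(lim) | tab$nucEnd > lim | tab$nucStart < 0
    if (any(bad)) {
      stop("fragment outside scaffold bounds for numt ",
           tab$numtId[which(bad)[1]])
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "TSV") {
    writeLines(paste(names(tab), collapse = "\t"), con)
    if (nrow(tab)) {
      write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  } else if (format == "BED") {
    writeLines("#chrom\tchromStart\tchromEnd\tname\tscore\tstrand", con)
    if (nrow(tab)) {
      writeLines(sprintf("%s\t%d\t%d\t%s.%d\t0\t%s", tab$scaffold,
                         tab$nucStart, tab$nucEnd, tab$numtId, tab$fragIndex,
                         tab$strand), con)
    }
  } else {
    writeLines("##gff-version 3", con)
    if (nrow(tab)) {
      for (id in unique(tab$numtId)) {
        d <- tab[tab$numtId == id, ]
        writeLines(sprintf(
          "%s\tnumtdyn\tnumt\t%d\t%d\t.\t.\t.\tID=%s;species=%s",
          d$scaffold[1], min(d$nucStart) + 1L, max(d$nucEnd), id,
          d$species[1]), con)
        writeLines(sprintf(
          paste0("%s\tnumtdyn\tnumt_fragment\t%d\t%d\t.\t%s\t.\t",
                 "ID=%s.%d;Parent=%s;mito_start=%d;mito_end=%d"),
          d$scaffold, d$nucStart + 1L, d$nucEnd, d$strand, id, d$fragIndex,
          id, d$mitoStart, d$mitoEnd), con)
      }
    }
  }
  invisible(path)
}

#' Read numt annotations from the lossless TSV format
#'
#' @param path TSV written by [writeNumtAnnotations()].
#' @return list of [NumtAnnotation-class] objects.
#' @export
readNumtAnnotations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tableToNumts(tab)
}

#' Convert between 0-based half-open and 1-based inclusive intervals
#'
#' `toGff(c(start, end))` maps a 0-based half-open interval to 1-based
#' inclusive; `fromGff` is its inverse. These are mutually inverse for all
#' intervals.
#'
#' @param interval numeric vector `c(start, end)`.
#' @return converted `c(start, end)`.
#' @export
toGff <- function(interval) c(interval[1] + 1, interval[2])

#' @rdname toGff
#' @export
fromGff <- function(interval) c(interval[1] - 1, interval[2])
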