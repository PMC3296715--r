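## Internal phylogenetic likelihood engine.
##
## Trees are held in a light edge-list structure ("ptree") that tolerates
## arbitrary node ids, which makes pendant-leaf attachment cheap (no
## renumbering):
##   list(edges   = m x 2 integer matrix (parent, child),
##        lengths = numeric m (expected substitutions/site),
##        root    = integer node id,
##        leaves  = named integer vector: label -> node id)

ptreeFromPhylo <- function(phy) {
  ntip <- length(phy$tip.label)
  list(edges = phy$edge, lengths = phy$edge.length,
       root = ntip + 1L,
       leaves = setNames(seq_len(ntip), phy$tip.label))
}

## Edge processing order: children before parents (decreasing child depth).
ptreeOrder <- function(pt) {
  maxId <- max(pt$edges)
  depth <- rep(NA_integer_, maxId)
  depth[pt$root] <- 0L
  repeat {
    known <- !is.na(depth[pt$edges[, 1]]) & is.na(depth[pt$edges[, 2]])
    if (!any(known)) break
    depth[pt$edges[known, 2]] <- depth[pt$edges[known, 1]] + 1L
  }
  order(depth[pt$edges[, 2]], decreasing = TRUE)
}

## Conditional-likelihood pruning over compressed site patterns.
## leafLike: named list label -> 4 x npat matrix.
## Returns list(patLogLik = per-pattern log-likelihood, logL = weighted sum)
pruneLogLik <- function(pt, leafLike, model, weights) {
  npat <- ncol(leafLike[[1]])
  maxId <- max(pt$edges)
  cond <- vector("list", maxId)
  for (lab in names(pt$leaves)) cond[[pt$leaves[[lab]]]] <- leafLike[[lab]]
  ord <- ptreeOrder(pt)
  for (e in ord) {
    p <- pt$edges[e, 1]; ch <- pt$edges[e, 2]
    P <- f84TransitionMatrix(model, pt$lengths[e])
    msg <- P %*% cond[[ch]]
    if (is.null(cond[[p]])) cond[[p]] <- msg else cond[[p]] <- cond[[p]] * msg
  }
  lik <- as.vector(model@freqs %*% cond[[pt$root]])
  patLog <- log(lik)
  list(patLogLik = patLog, logL = sum(patLog * weights))
}

## Compress an integer-coded alignment (rows = taxa) into site patterns.
alnPatterns <- function(codes) {
  stopifnot(is.matrix(codes), !is.null(rownames(codes)))
  if (ncol(codes) == 0L) stop("alignment has zero columns")
  if (any(is.na(codes))) stop("alignment contains N/gap after filtering")
  key <- apply(codes, 2, paste, collapse = ",")
  uk <- unique(key)
  idx <- match(key, uk)
  first <- match(uk, key)
  pat <- codes[, first, drop = FALSE]
  w <- tabulate(idx, nbins = length(uk))
  leafLike <- lapply(rownames(codes), function(r) {
    m <- matrix(0, 4, length(uk))
    m[cbind(pat[r, ], seq_len(ncol(m)))] <- 1
    m
  })
  names(leafLike) <- rownames(codes)
  list(leafLike = leafLike, weights = w, index = idx, npat = length(uk))
}

#' Log-likelihood of an alignment on a fixed tree under F84
#'
#' Felsenstein pruning with site independence and compressed site patterns.
#' Alignment columns must be gap- and N-free (use [projectAlignment()] to
#' produce such alignments); branch lengths are expected substitutions per
#' site.
#'
#' @param aln character matrix (rows = taxa, named) over A/C/G/T, or an
#'   integer-coded matrix (1..4).
#' @param tree `phylo` with edge lengths in expected substitutions/site;
#'   leaf labels must be a subset of alignment rows.
#' @param model an [F84Params-class].
#' @param perSite also return the per-column log-likelihood vector.
#' @return list with `logL` and, if requested, `siteLogLik`.
#' @examples
#' m <- f84Params()
#' aln <- matrix(c("A", "A"), 1, 2, dimnames = list("t1", NULL))
#' tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = "t1",
#'                      edge.length = 0, Nnode = 1L), class = "phylo")
#' treeLogLikelihood(aln, tr, m)$logL  # = 2 * log pi_A
#' @export
treeLogLikelihood <- function(aln, tree, model, perSite = FALSE) {
  codes <- alnToCodes(aln)
  miss <- setdiff(tree$tip.label, rownames(codes))
  if (length(miss)) stop("tree leaves missing from alignment: ",
                         paste(miss, collapse = ", "))
  codes <- codes[tree$tip.label, , drop = FALSE]
  pats <- alnPatterns(codes)
  pt <- ptreeFromPhylo(tree)
  if (length(tree$tip.label) == 1L) {
    ## single leaf: likelihood is the stationary probability of each base
    patLog <- log(model@freqs[codes[1, ]])
    res <- list(patLogLik = patLog, logL = sum(patLog))
    return(c(list(logL = res$logL),
             if (perSite) list(siteLogLik = as.numeric(patLog))))
  }
  res <- pruneLogLik(pt, pats$leafLike, model, pats$weights)
  out <- list(logL = res$logL)
  if (perSite) out$siteLogLik <- res$patLogLik[pats$index]
  out
}

alnToCodes <- function(aln) {
  if (is.matrix(aln) && is.character(aln)) {
    codes <- matrix(match(toupper(aln), BASES), nrow(aln), ncol(aln),
                    dimnames = dimnames(aln))
  } else if (is.matrix(aln) && is.numeric(aln)) {
    codes <- aln
    storage.mode(codes) <- "integer"
  } else {
    stop("alignment must be a character or integer matrix")
  }
  if (is.null(rownames(codes))) stop("alignment rows must be named")
  codes
}

## Attach a pendant leaf on edge `e` of a ptree. `frac` is the position of
## the new node measured from the CHILD end (0 = at child, 1 = at parent).
## Returns the new ptree plus indices of the mutable edges:
##   lower (parent->new), upper (new->child)  [note: lower/upper in age],
##   pendant (new->leaf).
ptreeAttach <- function(pt, e, frac, pendantLen, label) {
  p <- pt$edges[e, 1]; ch <- pt$edges[e, 2]
  len <- pt$lengths[e]
  newNode <- max(pt$edges) + 1L
  newLeaf <- newNode + 1L
  edges <- rbind(pt$edges[-e, , drop = FALSE],
                 c(p, newNode), c(newNode, ch), c(newNode, newLeaf))
  lengths <- c(pt$lengths[-e], len * (1 - frac), len * frac, pendantLen)
  m <- nrow(edges)
  leaves <- c(pt$leaves, setNames(newLeaf, label))
  list(edges = edges, lengths = lengths, root = pt$root, leaves = leaves,
       stemEdge = m - 2L, childEdge = m - 1L, pendantEdge = m)
}
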