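#' Poisson-corrected evolutionary distance
#'
#' `d = -ln(1 - p)` for an observed proportion `p` of differing sites:
#' the expected number of substitutions per site under a Poisson model
#' without back-substitution correction for the alphabet.
#'
#' @param p observed proportion of differing sites, in \[0, 1).
#' @return distance in substitutions/site.
#' @export
poissonDistance <- function(p) {
  if (any(p < 0)) stop("p must be >= 0")
  if (any(p >= 1)) stop("saturated distance: p must be < 1")
  -log(1 - p)
}

#' Pairwise distance matrix from an alignment
#'
#' Proportion of differing sites per pair (over columns where both rows
#' carry letters), optionally Poisson-corrected.
#'
#' @param aln aligned `AAStringSet` or [TrimmedAlignment-class].
#' @param correction `"jc"` (default; the 20-state Jukes-Cantor-type
#'   protein distance `d = -(19/20) ln(1 - (20/19) p)`, the
#'   model-consistent correction for uniform residue replacement),
#'   `"poisson"` (`-ln(1 - p)`) or `"raw"`.
#' @param truncate if TRUE, saturated proportions (p >= 1) are
#'   truncated just below 1 instead of raising an error (used by
#'   bootstrap resampling, where small replicates can saturate).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distanceMatrix <- function(aln, correction = c("jc", "poisson", "raw"),
                           truncate = FALSE) {
  correction <- match.arg(correction)
  if (is(aln, "TrimmedAlignment")) aln <- aln@alignment
  m <- alignmentMatrix(aln)
  rownames(m) <- names(aln)
  distFromMatrix(m, correction, truncate)
}

distFromMatrix <- function(m, correction, truncate) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  gap <- m == "-"
  for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    nc <- sum(ok)
    p <- if (nc == 0L) 0 else sum(m[i, ok] != m[j, ok]) / nc
    pmax_ <- if (correction == "jc") 19 / 20 else 1
    if (truncate && p >= pmax_) p <- pmax_ - 0.5 / max(nc, 1L)
    d[i, j] <- d[j, i] <- switch(correction,
      jc = {
        if (p >= 19 / 20) stop("saturated distance: p must be < 19/20")
        -(19 / 20) * log(1 - (20 / 19) * p)
      },
      poisson = poissonDistance(p),
      raw = p)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration. For an additive (tree-metric) input the
#' generating topology and branch lengths are recovered exactly. Ties
#' in the Q criterion are broken by the lexicographically smallest
#' taxon pair (each cluster represented by its smallest tip label), so
#' the result is independent of input order. Negative branch-length
#' estimates are clamped to zero with the deficit transferred to the
#' sister edge, preserving path lengths.
#'
#' @param dm symmetric non-negative distance matrix with zero diagonal
#'   and taxon dimnames.
#' @return rooted-binary `phylo` whose unrooted form is the NJ tree;
#'   the final NJ edge is split at its midpoint so all tip-to-tip path
#'   lengths equal those of the unrooted NJ tree.
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(dm))) stop("distance matrix needs taxon names")
  if (max(abs(dm - t(dm))) > 1e-12 || any(dm < 0) ||
      any(abs(diag(dm)) > 1e-12))
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  if (!all(is.finite(dm))) stop("distances must be finite")

  frag <- rownames(dm)           # newick fragment per active node
  rep_ <- rownames(dm)           # smallest tip label per cluster
  D <- dm
  fmt <- function(x) format(x, digits = 12, scientific = FALSE)
  while (nrow(D) > 2L) {
    k <- nrow(D)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    qmin <- min(Q)
    ties <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    if (nrow(ties) > 1L) {
      keys <- apply(ties, 1L, function(ij)
        paste(sort(c(rep_[ij[1L]], rep_[ij[2L]])), collapse = "\r"))
      ties <- ties[order(keys), , drop = FALSE]
    }
    i <- ties[1L, 1L]; j <- ties[1L, 2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (k - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newFrag <- paste0("(", frag[i], ":", fmt(li), ",",
                      frag[j], ":", fmt(lj), ")")
    newRep <- min(rep_[i], rep_[j])
    others <- setdiff(seq_len(k), c(i, j))
    newD <- (D[i, others] + D[j, others] - D[i, j]) / 2
    newD <- pmax(newD, 0)
    D <- rbind(cbind(D[others, others, drop = FALSE], newD),
               c(newD, 0))
    frag <- c(frag[others], newFrag)
    rep_ <- c(rep_[others], newRep)
    rownames(D) <- colnames(D) <- rep_
  }
  d12 <- D[1L, 2L]
  nwk <- paste0("(", frag[1L], ":", fmt(d12 / 2), ",",
                frag[2L], ":", fmt(d12 / 2), ");")
  tr <- ape::read.tree(text = nwk)
  tr$node.label <- NULL
  tr
}

#' Nonparametric bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes the NJ tree
#' per replicate, and reports for each internal branch of the original
#' tree the fraction of replicates whose tree contains the same
#' bipartition.
#'
#' @param aln aligned `AAStringSet` or [TrimmedAlignment-class] with at
#'   least 2 columns.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param correction distance correction passed to [distanceMatrix()].
#' @return a [SupportedTree-class]: the NJ tree from the full alignment
#'   with supports in \[0,1\] keyed by canonical splits.
#' @export
bootstrapSupport <- function(aln, replicates = 1000L, seed,
                             correction = "poisson") {
  if (replicates < 1L) stop("replicates must be >= 1")
  if (is(aln, "TrimmedAlignment")) aln <- aln@alignment
  m <- alignmentMatrix(aln)
  rownames(m) <- names(aln)
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  full <- neighborJoining(distFromMatrix(m, correction,
                                         truncate = TRUE))
  target <- canonicalSplits(full)
  counts <- setNames(numeric(length(unique(target))),
                     unique(unname(target)))
  withSeed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_ <- neighborJoining(distFromMatrix(m[, cols, drop = FALSE],
                                             correction,
                                             truncate = TRUE))
      hits <- intersect(names(counts), splitSet(rep_))
      counts[hits] <- counts[hits] + 1
    }
  })
  new("SupportedTree", tree = full, supports = counts / replicates)
}

#' Midpoint-root a gene tree
#'
#' Places the root at the midpoint of the longest tip-to-tip path.
#' Bootstrap supports, being keyed by (rooting-invariant) bipartitions,
#' carry over unchanged.
#'
#' @param x a `phylo` or [SupportedTree-class].
#' @return same class as the input, rooted at the midpoint.
#' @export
midpointRoot <- function(x) {
  if (is(x, "SupportedTree")) {
    tr <- phangorn::midpoint(x@tree, node.labels = "deleted")
    return(new("SupportedTree", tree = tr, supports = x@supports))
  }
  phangorn::midpoint(x, node.labels = "deleted")
}

#' Support value for a given tip-set bipartition
#'
#' @param st a [SupportedTree-class].
#' @param tips character vector: one side of the bipartition.
#' @return the bootstrap support, or `NA` if the tree does not contain
#'   that split.
#' @export
splitSupport <- function(st, tips) {
  alltips <- sort(st@tree$tip.label)
  side <- sort(tips)
  if (alltips[1L] %in% side) side <- setdiff(alltips, side)
  key <- paste(sort(side), collapse = "|")
  if (key %in% names(st@supports)) unname(st@supports[key]) else NA_real_
}

#' Write a supported tree as Newick with supports as node labels
#'
#' @param st a [SupportedTree-class].
#' @param path output path.
#' @export
writeSupportedTree <- function(st, path) {
  tr <- st@tree
  spl <- canonicalSplits(tr)
  ntip <- length(tr$tip.label)
  lab <- rep("", tr$Nnode)
  for (nd in names(spl)) {
    s <- st@supports[spl[nd]]
    if (!is.na(s))
      lab[as.integer(nd) - ntip] <- format(round(unname(s), 3))
  }
  tr$node.label <- lab
  ape::write.tree(tr, file = path)
  invisible(path)
}
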