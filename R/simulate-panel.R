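#' Simulate a species panel with supergroup structure
#'
#' Builds a rooted binary species tree in which every supergroup forms a
#' clade, emulating a taxon panel spanning the three domains of life
#' (e.g. 17 Bacteria, 6 Archaea, 7 Discoba, 2 Metamonada, 14 SAR,
#' 6 Archaeplastida and 36 Amorphea for an 88-taxon panel). The first
#' two supergroups in `counts` are placed as sister clades (the
#' prokaryote side when the canonical order is used); the remaining
#' supergroups descend along a ladder backbone. Within-clade topologies
#' and all branch lengths are drawn at random, deterministically for a
#' given seed.
#'
#' @param counts named integer vector: tips per supergroup (all >= 1).
#' @param seed integer seed; the same seed reproduces the same panel.
#' @return a [SpeciesPanel-class].
#' @examples
#' panel <- simulateSpeciesPanel(c(Bacteria = 4, Archaea = 2,
#'                                 SAR = 4, Amorphea = 6), seed = 1)
#' panel
#' @export
simulateSpeciesPanel <- function(counts, seed) {
  if (length(counts) == 0L || is.null(names(counts)))
    stop("counts must be a non-empty named vector")
  if (any(counts < 1)) stop("all supergroup counts must be >= 1")
  groups <- names(counts)
  counts <- setNames(as.integer(round(counts)), groups)

  withSeed(seed, {
    cladeNwk <- function(g, n) {
      labs <- sprintf("%s_%02d", g, seq_len(n))
      if (n == 1L) return(labs)   # stem added by the combiner
      tr <- ape::rtree(n, tip.label = labs,
                      br = function(k) runif(k, 0.05, 0.5))
      sub(";$", "", ape::write.tree(tr))
    }
    clades <- mapply(cladeNwk, groups, counts)
    stemLen <- function() sprintf("%.6f", runif(1, 0.1, 0.5))
    if (length(clades) == 1L) {
      nwk <- paste0("(", clades[1L], ");")
    } else if (length(clades) == 2L) {
      nwk <- paste0("(", clades[1L], ":", stemLen(), ",",
                    clades[2L], ":", stemLen(), ");")
    } else {
      # ladder over clades 3..k, then ((C1,C2), ladder) at the root
      k <- length(clades)
      lad <- paste0(clades[k], ":", stemLen())
      i <- k - 1L
      while (i >= 3L) {
        lad <- paste0("(", clades[i], ":", stemLen(), ",", lad,
                      "):", stemLen())
        i <- i - 1L
      }
      nwk <- paste0("((", clades[1L], ":", stemLen(), ",",
                    clades[2L], ":", stemLen(), "):", stemLen(), ",",
                    lad, ");")
    }
    tr <- ape::read.tree(text = nwk)
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
    sg <- setNames(sub("_[0-9]+$", "", tr$tip.label), tr$tip.label)
    new("SpeciesPanel", tree = tr, supergroup = sg)
  })
}

#' Read a species panel from a Newick tree and a species-map table
#'
#' @param newickPath path to a rooted Newick species tree.
#' @param mapPath path to a two-column TSV (`taxon`, `supergroup`).
#' @return a [SpeciesPanel-class].
#' @export
readSpeciesPanel <- function(newickPath, mapPath) {
  tr <- ape::read.tree(newickPath)
  if (is.null(tr$node.label) || !any(nzchar(tr$node.label)))
    tr$node.label <- paste0("n", seq_len(tr$Nnode))
  map <- readTsv(mapPath)
  if (!all(c("taxon", "supergroup") %in% names(map)))
    stop("species map needs 'taxon' and 'supergroup' columns")
  sg <- setNames(map$supergroup, map$taxon)
  new("SpeciesPanel", tree = tr, supergroup = sg)
}

#' Write a species panel to disk
#'
#' @param panel a [SpeciesPanel-class].
#' @param newickPath,mapPath output paths (Newick tree; taxon/supergroup
#'   TSV).
#' @return invisibly, the two paths.
#' @export
writeSpeciesPanel <- function(panel, newickPath, mapPath) {
  ape::write.tree(panel@tree, file = newickPath)
  writeTsv(data.frame(taxon = names(panel@supergroup),
                      supergroup = unname(panel@supergroup)), mapPath)
  invisible(c(newickPath, mapPath))
}

# For every node: the single supergroup of all tips below it, or NA if
# mixed. Tips are their own supergroup.
nodePurity <- function(panel) {
  tr <- panel@tree
  tu <- tipsUnder(tr)
  vapply(tu, function(tt) {
    g <- unique(unname(panel@supergroup[tr$tip.label[tt]]))
    if (length(g) == 1L) g else NA_character_
  }, character(1))
}

# MRCA node of each supergroup's tips.
supergroupMrca <- function(panel) {
  tr <- panel@tree
  sg <- panel@supergroup
  out <- integer(0)
  for (g in unique(unname(sg))) {
    tips <- match(names(sg)[sg == g], tr$tip.label)
    out[g] <- if (length(tips) == 1L) tips else ape::getMRCA(tr, tips)
  }
  out
}

#' Are two supergroups adjacent (sister clades) on the species tree?
#'
#' "Distantly related" donors for xenologue calls are supergroups that
#' are *not* sisters; this helper encodes that adjacency test.
#'
#' @param panel a [SpeciesPanel-class].
#' @return symmetric logical matrix over supergroups; `TRUE` marks
#'   sister (adjacent) supergroup clades.
#' @export
supergroupAdjacency <- function(panel) {
  mr <- supergroupMrca(panel)
  par <- parentVector(panel@tree)
  gs <- names(mr)
  adj <- matrix(FALSE, length(gs), length(gs), dimnames = list(gs, gs))
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (i == j) { adj[i, j] <- TRUE; next }
    adj[i, j] <- !is.na(par[mr[i]]) && !is.na(par[mr[j]]) &&
      par[mr[i]] == par[mr[j]]
  }
  adj
}
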