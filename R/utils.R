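#' @importFrom stats rexp rpois rnorm runif setNames
#' @importFrom utils combn read.delim write.table
NULL

# Evaluate expr with a local RNG seed, restoring global RNG state after.
# All stochastic operations in the package funnel through this, so there
# is no hidden global RNG dependence.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Node label helpers -------------------------------------------------------

# Label for any node (tip label for tips, node.label for internals).
nodeLabel <- function(tree, node) {
  if (length(node) == 0L) return(character(0))
  ntip <- length(tree$tip.label)
  out <- character(length(node))
  isTip <- node <= ntip
  out[isTip] <- tree$tip.label[node[isTip]]
  out[!isTip] <- tree$node.label[node[!isTip] - ntip]
  out
}

nodeNumber <- function(tree, label) {
  ntip <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  j <- match(label, tree$node.label)
  out <- ifelse(!is.na(i), i, j + ntip)
  if (anyNA(out)) stop("unknown node label: ",
                       paste(label[is.na(out)], collapse = ", "))
  out
}

# Parent lookup vector: parentOf[node] = parent node (NA at root).
parentVector <- function(tree) {
  p <- rep(NA_integer_, length(tree$tip.label) + tree$Nnode)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

# children of each node as a list
childrenList <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1]]] <- c(ch[[tree$edge[i, 1]]], tree$edge[i, 2])
  ch
}

# tips (numbers) descending from each node
tipsUnder <- function(tree) {
  ntip <- length(tree$tip.label)
  n <- ntip + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(ntip)) out[[i]] <- i
  # postorder: process edges so parents come after children
  for (i in rev(seq_len(nrow(tree$edge)))) {
    a <- tree$edge[i, 1]; b <- tree$edge[i, 2]
    out[[a]] <- c(out[[a]], out[[b]])
  }
  lapply(out, sort)
}

# Absolute time (distance from root) of every node.
nodeTimes <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  tt <- rep(NA_real_, n)
  root <- length(tree$tip.label) + 1L
  tt[root] <- 0
  # preorder over edges (ape trees from our builders are in cladewise order)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    a <- ord$edge[i, 1]; b <- ord$edge[i, 2]
    tt[b] <- tt[a] + ord$edge.length[i]
  }
  tt
}

# Canonical splits ----------------------------------------------------------

# Canonical string for the bipartition induced by each internal edge of an
# (un)rooted tree: the side NOT containing the alphabetically first tip,
# sorted and joined. Used to key bootstrap supports independent of rooting
# and of tip input order.
canonicalSplits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1L]
  tu <- tipsUnder(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  res <- character(0)
  for (node in (ntip + 1L):(ntip + tree$Nnode)) {
    if (node == root) next
    side <- tree$tip.label[tu[[node]]]
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > ntip - 2L) next  # trivial
    res[as.character(node)] <- paste(sort(side), collapse = "|")
  }
  res
}

# All non-trivial splits of a tree as a character set (unnamed, unique).
splitSet <- function(tree) unique(unname(canonicalSplits(tree)))

# Small IO helpers -----------------------------------------------------------

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}

randomAASeq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                 collapse = "")
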