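# Shared fixtures and independent oracles, built in code at test time.

smallPanel <- function(seed = 1) {
  simulateSpeciesPanel(c(Bacteria = 4, Archaea = 2, SAR = 4,
                         Amorphea = 6), seed = seed)
}

twoTipPanel <- function(seed = 3) simulateSpeciesPanel(c(A = 1, B = 1),
                                                       seed = seed)

randomAln <- function(nrow, ncol, gapProb = 0.3, xProb = 0.02) {
  chars <- c("A", "C", "D", "E", "F", "G", "-", "X")
  m <- matrix(sample(chars, nrow * ncol, replace = TRUE,
                     prob = c(rep((1 - gapProb - xProb) / 6, 6),
                              gapProb, xProb)),
              nrow, ncol)
  Biostrings::AAStringSet(setNames(apply(m, 1, paste, collapse = ""),
                                   paste0("s", seq_len(nrow))))
}

# brute-force per-column trimming oracle: literal re-statement of the
# 30%/10% rule with explicit pair enumeration
oracleTrim <- function(aln, minNongap = 0.30, minPairs = 0.10) {
  m <- do.call(rbind, strsplit(as.character(aln), ""))
  keep <- integer(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    letters <- col[col != "-"]
    if (length(letters) / length(col) < minNongap) next
    if (length(letters) < 2) next
    prs <- utils::combn(seq_along(letters), 2)
    tot <- ncol(prs)
    cons <- sum(apply(prs, 2, function(ij) {
      a <- letters[ij[1]]; b <- letters[ij[2]]
      a == b && a != "X"
    }))
    if (cons / tot >= minPairs) keep <- c(keep, j)
  }
  keep
}

# naive affine-gap Smith-Waterman oracle (gap of length L costs
# go + L * ge, matching the package's scoring convention)
oracleLocalScore <- function(a, b, scheme = scoringScheme()) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  go <- scheme$gapOpen; ge <- scheme$gapExtend
  S <- scheme$matrix
  M <- matrix(-Inf, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - go - ge, Ix[i - 1, j] - ge)
    Iy[i, j] <- max(M[i, j - 1] - go - ge, Iy[i, j - 1] - ge)
    M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                          Iy[i - 1, j - 1]) + S[A[i - 1], B[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

randomProtein <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K",
                 "M","F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

# independent greedy clustering oracle (longest first, ties by id)
oracleGreedyCluster <- function(records, cutoff, idFun) {
  ord <- order(-Biostrings::width(records), names(records))
  reps <- character(0)
  for (i in ord) {
    id <- names(records)[i]
    hit <- FALSE
    for (r in reps) {
      if (idFun(as.character(records[[i]]),
                as.character(records[[r]])) >= cutoff) {
        hit <- TRUE; break
      }
    }
    if (!hit) reps <- c(reps, id)
  }
  reps
}

# tip-set clades under the listed nodes
cladeTipSets <- function(tree, nodes) {
  lapply(nodes, function(v)
    if (v <= length(tree$tip.label)) tree$tip.label[v]
    else sort(ape::extract.clade(tree, v)$tip.label))
}

# surviving transferred tips recorded in a TrueHistory
transferredTips <- function(history, geneTree) {
  x <- unique(unlist(strsplit(
    history$recipientTips[history$kind == "transfer"], ",")))
  x[nzchar(x) & x %in% geneTree$tip.label]
}

# transfers the per-tip detector is specified to recover: exactly one
# surviving recipient tip, and not nested inside another transferred
# lineage (whose context the copy then shares)
detectableTransfers <- function(history, geneTree) {
  ev <- history[history$kind == "transfer" & nzchar(history$recipientTips), ,
                drop = FALSE]
  if (nrow(ev) == 0) return(character(0))
  tipsets <- strsplit(ev$recipientTips, ",")
  out <- character(0)
  for (k in seq_len(nrow(ev))) {
    tips <- tipsets[[k]]
    tips <- tips[tips %in% geneTree$tip.label]
    if (length(tips) != 1) next
    nested <- any(vapply(seq_len(nrow(ev)), function(j)
      j != k && all(tips %in% tipsets[[j]]), logical(1)))
    if (!nested) out <- c(out, tips)
  }
  unique(out)
}

# Dollo + lineage-specific-loss oracle on a presence pattern, by
# explicit clade enumeration over the species tree
oracleGainLosses <- function(stree, nativeTips, anyTips,
                             maxInternal = 1) {
  ntip <- length(stree$tip.label)
  allnodes <- seq_len(ntip + stree$Nnode)
  clade <- function(v) if (v <= ntip) stree$tip.label[v]
    else ape::extract.clade(stree, v)$tip.label
  if (length(nativeTips) == 0)
    return(list(gain = NA_character_, losses = character(0)))
  cover <- allnodes[vapply(allnodes, function(v)
    all(nativeTips %in% clade(v)), logical(1))]
  gain <- cover[which.min(vapply(cover, function(v)
    length(clade(v)), integer(1)))]
  gcl <- clade(gain)
  losses <- character(0)
  for (v in allnodes) {
    cl <- clade(v)
    if (v == gain || !all(cl %in% gcl)) next
    par <- stree$edge[stree$edge[, 2] == v, 1]
    if (length(par) == 0) next
    pcl <- clade(par)
    if (all(!cl %in% anyTips) && any(pcl %in% anyTips) &&
        (length(cl) - 1) <= maxInternal) {
      lab <- if (v <= ntip) stree$tip.label[v]
        else stree$node.label[v - ntip]
      losses <- c(losses, lab)
    }
  }
  list(gain = if (gain <= ntip) stree$tip.label[gain]
       else stree$node.label[gain - ntip],
       losses = losses)
}
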