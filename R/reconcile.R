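#' Derive the gene-tip to taxon map from tip identifiers
#'
#' Simulated (and pipeline) gene copies are named `taxon|gN`; this
#' recovers the taxon part.
#'
#' @param tips character vector of gene-tree tip labels.
#' @return named character vector tip -> taxon.
#' @export
tipMapFromIds <- function(tips) setNames(sub("\\|.*$", "", tips), tips)

#' Treat a tree as fully supported
#'
#' Wraps a tree (e.g. a true simulated gene tree) as a
#' [SupportedTree-class] with support 1 on every internal branch, for
#' use where downstream calls require bootstrap supports.
#'
#' @param tree a `phylo`.
#' @return a [SupportedTree-class].
#' @export
fullySupported <- function(tree) {
  spl <- unique(unname(canonicalSplits(tree)))
  new("SupportedTree", tree = tree,
      supports = setNames(rep(1, length(spl)), spl))
}

# ancestor path (node -> root) for every node of a tree
ancestorPaths <- function(tree) {
  par <- parentVector(tree)
  n <- length(par)
  lapply(seq_len(n), function(v) {
    path <- v
    while (!is.na(par[path[length(path)]]))
      path <- c(path, par[path[length(path)]])
    path
  })
}

#' LCA reconciliation of a gene tree with the species tree
#'
#' Maps every gene-tree node to the most recent common ancestor (on the
#' species tree) of the species of its descendant copies. An internal
#' node is labelled a duplication iff its species mapping equals that
#' of at least one child; otherwise it marks a speciation. Homologues
#' that diverged at a speciation node are orthologues; those diverged
#' at a duplication node are paralogues.
#'
#' @param geneTree rooted `phylo` over sequence ids.
#' @param panel a [SpeciesPanel-class].
#' @param tipMap named character mapping every gene tip to a species
#'   tip; defaults to the `taxon|copy` naming convention.
#' @param xenologs optional data.frame of xenologue calls (from
#'   [detectXenologs()]) stored with the result and used by
#'   [classifyPairs()].
#' @return a [ReconciliationResult-class].
#' @export
lcaReconcile <- function(geneTree, panel,
                         tipMap = tipMapFromIds(geneTree$tip.label),
                         xenologs = emptyXenologs()) {
  st <- panel@tree
  if (!all(geneTree$tip.label %in% names(tipMap)))
    stop("unmapped gene tips: ",
         paste(setdiff(geneTree$tip.label, names(tipMap)),
               collapse = ", "))
  taxa <- tipMap[geneTree$tip.label]
  if (!all(taxa %in% st$tip.label))
    stop("tip map points at unknown taxa: ",
         paste(setdiff(taxa, st$tip.label), collapse = ", "))

  paths <- ancestorPaths(st)
  depth <- vapply(paths, length, integer(1))  # root has depth 1
  mrca2 <- function(a, b) {
    while (a != b) {
      if (depth[a] <= depth[b]) b <- paths[[b]][2L]
      else a <- paths[[a]][2L]
    }
    a
  }

  ntipG <- length(geneTree$tip.label)
  nG <- ntipG + geneTree$Nnode
  mapping <- integer(nG)
  mapping[seq_len(ntipG)] <- match(taxa, st$tip.label)
  ch <- childrenList(geneTree)
  event <- character(0)
  # postorder: children before parents
  ord <- rev(ape::reorder.phylo(geneTree, "cladewise")$edge[, 2L])
  for (v in c(ord, ntipG + 1L)) {
    if (v <= ntipG) next
    kids <- ch[[v]]
    m <- mapping[kids[1L]]
    for (k in kids[-1L]) m <- mrca2(m, mapping[k])
    mapping[v] <- m
    event[as.character(v)] <-
      if (any(mapping[kids] == m)) "duplication" else "speciation"
  }
  event <- event[as.character((ntipG + 1L):nG)]
  new("ReconciliationResult", geneTree = geneTree, tipMap = tipMap,
      mapping = mapping, nodeEvent = event, xenologs = xenologs)
}

emptyXenologs <- function() {
  data.frame(tip = character(0), taxon = character(0),
             recipientSupergroup = character(0),
             donorSupergroup = character(0), support = numeric(0),
             stringsAsFactors = FALSE)
}

#' Classify every pair of gene copies
#'
#' For each pair of gene-tree tips the label is `paralog` if their
#' gene-tree LCA is a duplication node, `ortholog` if it is a
#' speciation node, and `xenolog` if either tip carries a xenologue
#' flag.
#'
#' @param recon a [ReconciliationResult-class].
#' @return data.frame with columns `tip1`, `tip2`, `relation`;
#'   `choose(n, 2)` rows.
#' @export
classifyPairs <- function(recon) {
  gt <- recon@geneTree
  tips <- gt$tip.label
  n <- length(tips)
  if (n < 2L)
    return(data.frame(tip1 = character(0), tip2 = character(0),
                      relation = character(0)))
  lca <- ape::mrca(gt)
  xen <- recon@xenologs$tip
  prs <- combn(n, 2L)
  relation <- vapply(seq_len(ncol(prs)), function(k) {
    i <- prs[1L, k]; j <- prs[2L, k]
    if (tips[i] %in% xen || tips[j] %in% xen) return("xenolog")
    ev <- recon@nodeEvent[as.character(lca[i, j])]
    if (identical(unname(ev), "duplication")) "paralog" else "ortholog"
  }, character(1))
  data.frame(tip1 = tips[prs[1L, ]], tip2 = tips[prs[2L, ]],
             relation = relation, stringsAsFactors = FALSE)
}

#' Detect xenologues (horizontal transfers) in a gene tree
#'
#' A tip is called a xenologue iff (a) it belongs to a different
#' supergroup than *all* other members of its smallest enclosing clade
#' of at least 3 tips, (b) that clade is supported at or above the
#' threshold, and (c) the donor supergroup (the majority supergroup of
#' the other members) is distantly related to the recipient's -- i.e.
#' the two supergroup clades are not sisters on the species tree.
#'
#' @param st a [SupportedTree-class] (rooted); use [fullySupported()]
#'   for trees whose topology is known without error.
#' @param panel a [SpeciesPanel-class].
#' @param tipMap named character gene tip -> taxon.
#' @param supportThreshold minimum clade support (default 0.8).
#' @return data.frame with columns `tip`, `taxon`,
#'   `recipientSupergroup`, `donorSupergroup`, `support`.
#' @export
detectXenologs <- function(st, panel,
                           tipMap = tipMapFromIds(st@tree$tip.label),
                           supportThreshold = 0.8) {
  if (!is(st, "SupportedTree"))
    stop("supports are required: pass a SupportedTree ",
         "(see bootstrapSupport() or fullySupported())")
  gt <- st@tree
  ntip <- length(gt$tip.label)
  if (ntip < 3L) return(emptyXenologs())
  sg <- panel@supergroup
  adj <- supergroupAdjacency(panel)
  par <- parentVector(gt)
  tu <- tipsUnder(gt)
  spl <- canonicalSplits(gt)
  alltips <- sort(gt$tip.label)

  cladeSupport <- function(node) {
    size <- length(tu[[node]])
    if (size >= ntip - 1L || node == ntip + 1L) return(1)  # trivial
    key <- spl[as.character(node)]
    if (is.na(key) || !(key %in% names(st@supports))) return(NA_real_)
    unname(st@supports[key])
  }

  # Detection runs to a fixpoint: once a tip is called, it is excluded
  # from every other tip's clade context and the scan repeats, so
  # stacked transfers into the same region are peeled off one by one.
  out <- emptyXenologs()
  excluded <- integer(0)
  repeat {
    found <- FALSE
    for (i in setdiff(seq_len(ntip), excluded)) {
      if (ntip - length(excluded) < 3L) break
      v <- par[i]
      while (!is.na(v) &&
             length(setdiff(tu[[v]], excluded)) < 3L) v <- par[v]
      if (is.na(v)) next
      members <- setdiff(setdiff(tu[[v]], excluded), i)
      gTip <- unname(sg[tipMap[gt$tip.label[i]]])
      gOthers <- unname(sg[tipMap[gt$tip.label[members]]])
      if (any(gOthers == gTip)) next
      cnt <- table(gOthers)
      donor <- names(cnt)[order(-cnt, names(cnt))][1L]  # majority donor
      if (adj[donor, gTip]) next              # adjacent: not distant
      supp <- cladeSupport(v)
      if (is.na(supp) || supp < supportThreshold) next
      out <- rbind(out, data.frame(
        tip = gt$tip.label[i], taxon = unname(tipMap[gt$tip.label[i]]),
        recipientSupergroup = gTip, donorSupergroup = donor,
        support = supp, stringsAsFactors = FALSE))
      excluded <- c(excluded, i)
      found <- TRUE
    }
    if (!found) break
  }
  out[order(out$tip), , drop = FALSE]
}

#' Reconcile one gene family against the species tree
#'
#' Convenience wrapper running the full per-family inference:
#' xenologues are detected first; flagged tips are pruned (their
#' removal restores taxonomic concordance) and the pruned tree is
#' LCA-reconciled, so transferred copies do not masquerade as ancient
#' duplications.
#'
#' @param st a [SupportedTree-class] (rooted gene tree with supports).
#' @param panel a [SpeciesPanel-class].
#' @param tipMap named character gene tip -> taxon.
#' @param supportThreshold xenologue support threshold.
#' @return list with elements `reconciliation`
#'   ([ReconciliationResult-class] of the pruned tree, or NULL if
#'   fewer than 2 tips remain), `xenologs` (data.frame), and
#'   `duplications` (duplication-node count).
#' @export
reconcileFamily <- function(st, panel,
                            tipMap = tipMapFromIds(st@tree$tip.label),
                            supportThreshold = 0.8) {
  xen <- detectXenologs(st, panel, tipMap, supportThreshold)
  gt <- st@tree
  keep <- setdiff(gt$tip.label, xen$tip)
  if (length(keep) < 2L)
    return(list(reconciliation = NULL, xenologs = xen,
                duplications = 0L))
  pruned <- if (length(keep) < length(gt$tip.label))
    ape::keep.tip(gt, keep) else gt
  recon <- lcaReconcile(pruned, panel, tipMap[keep], xenologs = xen)
  list(reconciliation = recon, xenologs = xen,
       duplications = sum(recon@nodeEvent == "duplication"))
}

#' Build the presence/absence landscape matrix
#'
#' One row per panel taxon (species-tree tip order), one column per
#' family: 0 = absent, 1 = present (at least one retained record),
#' 2 = xenolog-present (every retained record for that taxon is a
#' flagged horizontal acquisition).
#'
#' @param retained named list (one element per family) of named
#'   character vectors mapping retained record ids to taxa, or
#'   [GeneFamily-class] objects.
#' @param panel a [SpeciesPanel-class].
#' @param xenologTips named list (per family) of record ids flagged by
#'   [detectXenologs()].
#' @return a [PresenceAbsence-class].
#' @export
buildPresenceAbsence <- function(retained, panel,
                                 xenologTips = list()) {
  taxa <- panel@tree$tip.label
  fams <- names(retained)
  if (is.null(fams)) stop("retained must be a named list of families")
  mat <- matrix(0L, length(taxa), length(fams),
                dimnames = list(taxa, fams))
  for (f in fams) {
    recs <- retained[[f]]
    if (is(recs, "GeneFamily")) recs <- recs@species
    if (length(recs) == 0L) next
    if (!all(recs %in% taxa))
      stop("records with unknown taxa: ",
           paste(setdiff(unique(recs), taxa), collapse = ", "))
    xen <- xenologTips[[f]]
    for (tx in unique(recs)) {
      ids <- names(recs)[recs == tx]
      mat[tx, f] <- if (length(xen) && all(ids %in% xen)) 2L else 1L
    }
  }
  new("PresenceAbsence", mat = mat)
}

#' Infer gene gains and lineage-specific losses (Dollo parsimony)
#'
#' Per family, the gain is the single Dollo origin: the most recent
#' species-tree node covering all natively present taxa
#' (xenolog-present cells are excluded from gain placement, so a
#' transferred copy cannot drag a family's origin towards the root).
#' Candidate losses are the maximal uniformly-absent subtrees below the
#' gain (any presence, including xenolog presence, blocks an absence
#' call). Reported losses are restricted to lineage-specific ones:
#' absent subtrees containing at most `maxInternal` internal nodes
#' whose sister subtree retains the gene (terminal branches always
#' qualify). This guards against scoring patchy genome quality as deep
#' ancestral losses.
#'
#' @param pam a [PresenceAbsence-class].
#' @param panel a [SpeciesPanel-class].
#' @param maxInternal maximum internal-node count of an absent subtree
#'   still reported as a lineage-specific loss (default 1).
#' @return named list of [EventSummary-class], one per family. A family
#'   absent everywhere yields an empty summary (gain `NA`), not an
#'   error.
#' @export
inferGainsLosses <- function(pam, panel, maxInternal = 1L) {
  st <- panel@tree
  if (!setequal(rownames(pam@mat), st$tip.label))
    stop("matrix taxa must equal the species-tree tips")
  ntip <- length(st$tip.label)
  tu <- tipsUnder(st)
  par <- parentVector(st)
  # internal nodes under v = (#tips under v) - 1 for a binary subtree
  nInternalUnder <- vapply(tu, function(tt)
    max(length(tt) - 1L, 0L), integer(1))

  out <- list()
  for (f in colnames(pam@mat)) {
    cells <- pam@mat[st$tip.label, f]
    nativeTips <- which(cells == 1L)
    anyTips <- which(cells >= 1L)
    if (length(nativeTips) == 0L) {
      out[[f]] <- new("EventSummary", family = f,
                      gainBranch = NA_character_,
                      lossBranches = character(0),
                      candidateLosses = character(0),
                      duplications = 0L, xenologs = emptyXenologs())
      next
    }
    gain <- if (length(nativeTips) == 1L) nativeTips else
      ape::getMRCA(st, nativeTips)
    inGain <- tu[[gain]]
    absent <- vapply(tu, function(tt)
      length(intersect(tt, anyTips)) == 0L, logical(1))
    cand <- which(absent & !is.na(par) & !absent[pmax(par, 1L)])
    # restrict to branches inside the gain subtree
    cand <- cand[vapply(cand, function(v)
      all(tu[[v]] %in% inGain) && v != gain, logical(1))]
    candLab <- nodeLabel(st, cand)
    keep <- cand[nInternalUnder[cand] <= maxInternal]
    out[[f]] <- new("EventSummary", family = f,
                    gainBranch = nodeLabel(st, gain),
                    lossBranches = nodeLabel(st, keep),
                    candidateLosses = candLab,
                    duplications = 0L, xenologs = emptyXenologs())
  }
  out
}

#' Write the landscape matrix as TSV
#'
#' Taxa x families, values 0/1/2 for absent/present/xenolog-present.
#'
#' @param pam a [PresenceAbsence-class].
#' @param path output path.
#' @export
writePresenceAbsence <- function(pam, path) {
  df <- data.frame(taxon = rownames(pam@mat), pam@mat,
                   check.names = FALSE)
  writeTsv(df, path)
}

# duplication + loss cost of a rooted gene tree against the species tree
dlCost <- function(geneTree, panel, tipMap) {
  st <- panel@tree
  taxa <- tipMap[geneTree$tip.label]
  paths <- ancestorPaths(st)
  depth <- vapply(paths, length, integer(1))
  mrca2 <- function(a, b) {
    while (a != b) {
      if (depth[a] <= depth[b]) b <- paths[[b]][2L]
      else a <- paths[[a]][2L]
    }
    a
  }
  ntipG <- length(geneTree$tip.label)
  mapping <- integer(ntipG + geneTree$Nnode)
  mapping[seq_len(ntipG)] <- match(taxa, st$tip.label)
  ch <- childrenList(geneTree)
  isDup <- logical(ntipG + geneTree$Nnode)
  ord <- rev(ape::reorder.phylo(geneTree, "cladewise")$edge[, 2L])
  for (v in c(ord, ntipG + 1L)) {
    if (v <= ntipG) next
    kids <- ch[[v]]
    m <- mapping[kids[1L]]
    for (k in kids[-1L]) m <- mrca2(m, mapping[k])
    mapping[v] <- m
    isDup[v] <- any(mapping[kids] == m)
  }
  dups <- sum(isDup)
  losses <- 0L
  for (e in seq_len(nrow(geneTree$edge))) {
    u <- geneTree$edge[e, 1L]; v <- geneTree$edge[e, 2L]
    p <- depth[mapping[v]] - depth[mapping[u]]
    losses <- losses + max(if (isDup[u]) p else p - 1L, 0L)
  }
  c(dups = dups, losses = losses)
}

#' Root a gene tree by minimizing the reconciliation cost
#'
#' Tries every branch of the unrooted gene tree as a root position and
#' keeps the rooting with the smallest duplication + loss
#' reconciliation cost against the species tree (ties broken by fewer
#' duplications, then by a deterministic branch order). This is the
#' standard rooting for gene-tree/species-tree reconciliation when the
#' true root is unknown; [midpointRoot()] remains available as the
#' rate-based alternative.
#'
#' @param st a [SupportedTree-class] (supports, keyed by bipartitions,
#'   are rooting-invariant and carry over).
#' @param panel a [SpeciesPanel-class].
#' @param tipMap named character gene tip -> taxon.
#' @return a [SupportedTree-class] rooted at the minimum-cost branch.
#' @export
rootByReconciliation <- function(st, panel,
                                 tipMap = tipMapFromIds(st@tree$tip.label)) {
  utr <- ape::unroot(st@tree)
  ntip <- length(utr$tip.label)
  tu <- tipsUnder(utr)
  sides <- lapply(seq_len(ntip), function(i) utr$tip.label[i])
  for (v in (ntip + 2L):(ntip + utr$Nnode)) {
    s <- utr$tip.label[tu[[v]]]
    if (length(s) >= 1L && length(s) <= ntip - 1L)
      sides[[length(sides) + 1L]] <- s
  }
  best <- NULL; bestCost <- c(Inf, Inf)
  for (s in sides) {
    cand <- tryCatch(
      ape::root(utr, outgroup = s, resolve.root = TRUE),
      error = function(e) NULL)
    if (is.null(cand) || !ape::is.rooted(cand)) next
    cost <- dlCost(cand, panel, tipMap)
    tot <- sum(cost)
    if (tot < sum(bestCost) - 1e-9 ||
        (tot == sum(bestCost) && cost["dups"] < bestCost["dups"])) {
      bestCost <- cost; best <- cand
    }
  }
  if (is.null(best)) best <- midpointRoot(st)@tree
  new("SupportedTree", tree = best, supports = st@supports)
}
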