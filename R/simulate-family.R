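#' Parameters for the gene-family evolution simulator
#'
#' Rates are per unit branch length of the species tree (branch lengths
#' double as time in the simulator). Transfers draw a contemporaneous
#' recipient branch; with `transferScope = "distant"` donors and
#' recipients are restricted to branches lying within a single
#' supergroup, the two supergroups non-sister on the species tree, and
#' the recipient terminal — the configuration the xenologue detector is
#' specified to recover (a single foreign tip inside a distant clade).
#'
#' @param dup duplication rate (events per unit branch length).
#' @param loss loss rate.
#' @param transfer horizontal-transfer rate.
#' @param rootCopies gene copies at the species root (the single gain).
#' @param seqLength protein length for sequence evolution.
#' @param subRate substitution rate (expected replacement events per
#'   site per unit branch length).
#' @param motifs list of `list(pattern=, pos=)` conserved motif inserts
#'   held invariant during evolution (1-based positions).
#' @param transferScope `"any"` or `"distant"` (see Details).
#' @return a list of class `EvolParams`.
#' @export
evolParams <- function(dup = 0, loss = 0, transfer = 0, rootCopies = 1L,
                       seqLength = 200L, subRate = 0.1,
                       motifs = list(), transferScope = c("any", "distant")) {
  transferScope <- match.arg(transferScope)
  if (any(c(dup, loss, transfer, subRate) < 0))
    stop("all rates must be >= 0")
  if (rootCopies < 1L) stop("rootCopies must be >= 1")
  for (m in motifs) {
    if (m$pos < 1L || m$pos + nchar(m$pattern) - 1L > seqLength)
      stop("motif insert out of sequence range")
  }
  structure(list(dup = dup, loss = loss, transfer = transfer,
                 rootCopies = as.integer(rootCopies),
                 seqLength = as.integer(seqLength), subRate = subRate,
                 motifs = motifs, transferScope = transferScope),
            class = "EvolParams")
}

#' Simulate one gene family along a species tree
#'
#' Runs a branchwise birth-death-transfer process from a single gain at
#' the species root: along every branch each gene copy experiences
#' exponential waiting times to duplication, loss or transfer; at
#' speciation nodes copies pass into both daughter branches; transferred
#' copies continue on a contemporaneous recipient branch. Returns the
#' surviving tip copies, the true gene tree (internal nodes tagged
#' `spec`/`dup`/`xfer`), and the complete event history.
#'
#' Sequences are not evolved here; see [evolveSequences()].
#'
#' @param panel a [SpeciesPanel-class].
#' @param params an [evolParams()] object.
#' @param seed integer seed.
#' @param familyId family identifier for the output records.
#' @return a [SimulatedFamily-class]. When every copy is lost the family
#'   is empty and `geneTree(x)` is `NULL`, but the gain and losses are
#'   still recorded in the history.
#' @export
simulateFamily <- function(panel, params, seed, familyId = "fam1") {
  stopifnot(inherits(params, "EvolParams"))
  tr <- panel@tree
  ntip <- length(tr$tip.label)
  tt <- nodeTimes(tr)
  ch <- childrenList(tr)
  par <- parentVector(tr)
  root <- ntip + 1L
  purity <- nodePurity(panel)
  adj <- supergroupAdjacency(panel)
  rates <- c(dup = params$dup, loss = params$loss, xfer = params$transfer)
  totRate <- sum(rates)

  withSeed(seed, {
    env <- new.env()
    env$events <- list()
    env$tipCount <- setNames(integer(ntip), tr$tip.label)
    env$nodeIdx <- c(spec = 0L, dup = 0L, xfer = 0L)

    recordEvent <- function(kind, branch, donor = NA, recipient = NA,
                            time = NA, recipientTips = "") {
      env$events[[length(env$events) + 1L]] <-
        data.frame(kind = kind, branch = branch, donor = donor,
                   recipient = recipient, time = time,
                   recipientTips = recipientTips,
                   stringsAsFactors = FALSE)
    }

    # branches alive at absolute time t, excluding branch `not`
    aliveBranches <- function(t, not) {
      cand <- which(!is.na(par) & tt[par] <= t & tt > t)
      setdiff(cand, not)
    }
    eligibleRecipients <- function(t, donor) {
      cand <- aliveBranches(t, donor)
      if (params$transferScope == "distant") {
        dg <- purity[donor]
        if (is.na(dg)) return(integer(0))
        cand <- cand[cand <= ntip]            # terminal recipients only
        keep <- vapply(cand, function(b) {
          rg <- purity[b]
          !is.na(rg) && rg != dg && !adj[dg, rg]
        }, logical(1))
        cand <- cand[keep]
      }
      cand
    }

    mkLabel <- function(kind) {
      env$nodeIdx[kind] <- env$nodeIdx[kind] + 1L
      paste0(kind, env$nodeIdx[kind])
    }
    mkNode <- function(kind, time, kids) {
      kids <- kids[!vapply(kids, is.null, logical(1))]
      if (length(kids) == 0L) return(NULL)
      if (length(kids) == 1L) return(kids[[1L]])
      list(tip = FALSE, event = kind, label = mkLabel(kind),
           time = time, kids = kids)
    }
    collectTips <- function(node) {
      if (is.null(node)) return(character(0))
      if (node$tip) return(node$label)
      unlist(lapply(node$kids, collectTips))
    }

    simAtNode <- function(node) {
      if (node <= ntip) {
        taxon <- tr$tip.label[node]
        env$tipCount[taxon] <- env$tipCount[taxon] + 1L
        return(list(tip = TRUE, label = paste0(taxon, "|g",
                                               env$tipCount[taxon]),
                    time = tt[node], taxon = taxon))
      }
      mkNode("spec", tt[node],
             lapply(ch[[node]], function(b) simBranch(b, tt[node])))
    }

    simBranch <- function(b, t0) {
      tEnd <- tt[b]
      t <- t0
      repeat {
        if (totRate == 0) return(simAtNode(b))
        w <- rexp(1, totRate)
        if (t + w >= tEnd) return(simAtNode(b))
        t <- t + w
        kind <- sample(names(rates), 1L, prob = rates)
        if (kind == "loss") {
          recordEvent("loss", nodeLabel(tr, b), time = t)
          return(NULL)
        }
        if (kind == "dup") {
          recordEvent("duplication", nodeLabel(tr, b), time = t)
          return(mkNode("dup", t,
                        list(simBranch(b, t), simBranch(b, t))))
        }
        # transfer
        rec <- eligibleRecipients(t, b)
        if (length(rec) == 0L) next   # no contemporaneous recipient
        r <- if (length(rec) == 1L) rec else sample(rec, 1L)
        transferred <- simBranch(r, t)
        recordEvent("transfer", nodeLabel(tr, b),
                    donor = nodeLabel(tr, b),
                    recipient = nodeLabel(tr, r), time = t,
                    recipientTips = paste(collectTips(transferred),
                                          collapse = ","))
        return(mkNode("xfer", t, list(simBranch(b, t), transferred)))
      }
    }

    recordEvent("gain", nodeLabel(tr, root), time = 0)
    lineages <- lapply(seq_len(params$rootCopies), function(i) {
      simAtNode(root)
    })
    geneRoot <- if (params$rootCopies == 1L) {
      lineages[[1L]]
    } else {
      mkNode("dup", 0, lineages)
    }

    geneTree <- structToPhylo(geneRoot)
    tipIds <- collectTips(geneRoot)
    seqs <- Biostrings::AAStringSet(setNames(rep("", length(tipIds)),
                                             tipIds))
    # placeholder sequences: evolveSequences() fills them in
    species <- setNames(sub("\\|.*$", "", tipIds), tipIds)
    fam <- new("GeneFamily", sequences = seqs, species = species,
               family = familyId)
    hist <- do.call(rbind, env$events)
    new("SimulatedFamily", family = fam, history = hist,
        geneTree = geneTree)
  })
}

# Convert the recursive node structure to an ape phylo (NULL if extinct;
# a single surviving copy yields a 1-tip, 1-node tree).
structToPhylo <- function(node) {
  if (is.null(node)) return(NULL)
  nwkOf <- function(nd) {
    if (nd$tip) return(nd$label)
    kids <- vapply(nd$kids, function(k) {
      paste0(nwkOf(k), ":", format(max(k$time - nd$time, 0),
                                   digits = 10, scientific = FALSE))
    }, character(1))
    paste0("(", paste(kids, collapse = ","), ")", nd$label)
  }
  if (node$tip) {
    txt <- paste0("(", node$label, ":",
                  format(node$time, digits = 10, scientific = FALSE),
                  ")gain1;")
  } else {
    txt <- paste0(nwkOf(node), ";")
  }
  ape::read.tree(text = txt)
}

#' Evolve protein sequences along the true gene tree
#'
#' The root sequence is uniform-random over the 20 amino acids with the
#' configured motif inserts written in; each gene-tree branch then
#' applies a Poisson number of replacement events per site (rate =
#' `subRate` x branch length), each replacing the residue with one of
#' the other 19 letters uniformly. Motif-insert columns are held
#' invariant. Under this uniform-replacement chain two tips separated by
#' path length `t` differ at an expected proportion
#' `(19/20) * (1 - exp(-(20/19) * t))` of sites.
#'
#' @param sim a [SimulatedFamily-class] from [simulateFamily()].
#' @param params the [evolParams()] used (sequence length, substitution
#'   rate, motif inserts).
#' @param seed integer seed.
#' @return the [SimulatedFamily-class] with sequences filled in.
#' @export
evolveSequences <- function(sim, params, seed) {
  stopifnot(is(sim, "SimulatedFamily"), inherits(params, "EvolParams"))
  gt <- sim@geneTree
  if (is.null(gt)) return(sim)
  L <- params$seqLength
  motifCols <- integer(0)
  motifChar <- character(0)
  for (m in params$motifs) {
    idx <- seq(m$pos, m$pos + nchar(m$pattern) - 1L)
    if (max(idx) > L) stop("motif insert out of sequence range")
    motifCols <- c(motifCols, idx)
    motifChar <- c(motifChar, strsplit(m$pattern, "")[[1L]])
  }
  free <- setdiff(seq_len(L), motifCols)

  withSeed(seed, {
    rootSeq <- sample(AA20, L, replace = TRUE)
    rootSeq[motifCols] <- motifChar
    ntip <- length(gt$tip.label)
    nnode <- ntip + gt$Nnode
    seqsAt <- vector("list", nnode)
    seqsAt[[ntip + 1L]] <- rootSeq
    ord <- ape::reorder.phylo(gt, "cladewise")
    for (i in seq_len(nrow(ord$edge))) {
      a <- ord$edge[i, 1L]; b <- ord$edge[i, 2L]
      t <- ord$edge.length[i] * params$subRate
      s <- seqsAt[[a]]
      if (t > 0 && length(free)) {
        k <- rpois(length(free), t)
        hit <- which(k > 0L)
        for (j in hit) {
          site <- free[j]
          cur <- s[site]
          for (rep in seq_len(k[j]))
            cur <- sample(AA20[AA20 != cur], 1L)
          s[site] <- cur
        }
      }
      seqsAt[[b]] <- s
    }
    tipSeqs <- vapply(seq_len(ntip),
                      function(i) paste(seqsAt[[i]], collapse = ""),
                      character(1))
    seqs <- Biostrings::AAStringSet(setNames(tipSeqs, gt$tip.label))
    fam <- sim@family
    fam@sequences <- seqs
    fam@species <- setNames(sub("\\|.*$", "", gt$tip.label),
                            gt$tip.label)
    initialize(sim, family = fam)
  })
}
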