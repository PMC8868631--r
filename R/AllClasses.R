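#' @import methods
#' @importFrom Biostrings AAStringSet width
NULL

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

SUPERGROUPS <- c("Bacteria", "Archaea", "Discoba", "Metamonada",
                 "SAR", "Archaeplastida", "Amorphea")

#' Species panel: a rooted species tree with supergroup labels
#'
#' Container for a rooted (binary) species tree over a panel of taxa,
#' each tip carrying exactly one supergroup label (e.g. Bacteria,
#' Archaea, Discoba, Metamonada, SAR, Archaeplastida, Amorphea).
#' Branch lengths are in expected substitutions per site; for the
#' simulator they double as time.
#'
#' @slot tree an [ape::phylo] object, rooted, with non-negative branch
#'   lengths and labelled internal nodes.
#' @slot supergroup named character vector mapping every tip label to
#'   its supergroup.
#' @export
setClass("SpeciesPanel",
         representation(tree = "ANY", supergroup = "character"))

setValidity("SpeciesPanel", function(object) {
  tr <- object@tree
  if (!inherits(tr, "phylo")) return("tree must be a 'phylo' object")
  if (!ape::is.rooted(tr)) return("species tree must be rooted")
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    return("branch lengths must be present and >= 0")
  sg <- object@supergroup
  if (is.null(names(sg)) || !setequal(names(sg), tr$tip.label))
    return("supergroup must be named by exactly the tree's tip labels")
  if (anyNA(sg)) return("supergroup labels must not be NA")
  TRUE
})

#' Gene family: homologous protein records with species assignments
#'
#' @slot sequences an [Biostrings::AAStringSet] of protein sequences,
#'   uniquely named.
#' @slot species named character vector mapping each sequence id to its
#'   taxon (a tip of the species panel).
#' @slot family single family identifier.
#' @export
setClass("GeneFamily",
         representation(sequences = "ANY", species = "character",
                        family = "character"))

setValidity("GeneFamily", function(object) {
  s <- object@sequences
  if (!is(s, "AAStringSet")) return("sequences must be an AAStringSet")
  ids <- names(s)
  if (length(s) && (is.null(ids) || anyDuplicated(ids)))
    return("sequences must have unique names")
  if (length(s) && !setequal(names(object@species), ids))
    return("species must be named by exactly the sequence ids")
  if (length(object@family) != 1L) return("family must be length 1")
  TRUE
})

#' Simulated gene family with its true evolutionary history
#'
#' Produced by [simulateFamily()]: a [GeneFamily-class] whose true gene
#' tree and true event history (gain, duplications, losses, transfers)
#' are known, so downstream inference can be scored against ground
#' truth.
#'
#' @slot family the [GeneFamily-class] at the tips.
#' @slot history data.frame of events with columns `kind` (gain,
#'   duplication, loss, transfer), `branch` (species-tree branch,
#'   identified by its child node label), `donor`, `recipient`
#'   (transfers only) and `time` (absolute time from the root).
#' @slot geneTree the true gene tree (`phylo`), or `NULL` when every
#'   copy was lost.
#' @export
setClass("SimulatedFamily",
         representation(family = "GeneFamily", history = "data.frame",
                        geneTree = "ANY"))

setValidity("SimulatedFamily", function(object) {
  h <- object@history
  need <- c("kind", "branch", "donor", "recipient", "time")
  if (!all(need %in% names(h))) return("history lacks required columns")
  if (sum(h$kind == "gain") != 1L)
    return("history must contain exactly one gain event")
  gt <- object@geneTree
  if (!is.null(gt)) {
    if (!inherits(gt, "phylo")) return("geneTree must be phylo or NULL")
    if (!setequal(gt$tip.label, names(object@family@sequences)))
      return("gene-tree tips must match family sequence ids 1:1")
  }
  TRUE
})

#' Trimmed multiple alignment
#'
#' An alignment restricted to the columns that survive the
#' column-retention rule of [trimColumns()] (at least 30% non-gap
#' letters and at least 10% conserved letter pairs, by default),
#' together with the indices of the retained columns in the source
#' alignment.
#'
#' @slot alignment [Biostrings::AAStringSet], all rows equal width
#'   (the retained columns only).
#' @slot retained integer vector of retained column indices (1-based,
#'   strictly increasing) into the source alignment.
#' @slot sourceWidth width of the source alignment.
#' @export
setClass("TrimmedAlignment",
         representation(alignment = "ANY", retained = "integer",
                        sourceWidth = "integer"))

setValidity("TrimmedAlignment", function(object) {
  a <- object@alignment
  if (!is(a, "AAStringSet")) return("alignment must be an AAStringSet")
  if (length(unique(width(a))) > 1L) return("rows must have equal width")
  r <- object@retained
  if (length(r) && any(diff(r) <= 0L))
    return("retained indices must be strictly increasing")
  if (length(r) && (min(r) < 1L || max(r) > object@sourceWidth))
    return("retained indices out of source range")
  if (length(r) != (if (length(a)) unique(width(a)) else 0L))
    return("retained length must equal trimmed width")
  TRUE
})

#' Gene tree with per-branch bootstrap support
#'
#' @slot tree an [ape::phylo]; may be rooted or unrooted.
#' @slot supports numeric in \[0,1\], named by canonical split strings
#'   (see internal `canonicalSplits()`), one per internal branch.
#' @export
setClass("SupportedTree",
         representation(tree = "ANY", supports = "numeric"))

setValidity("SupportedTree", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be phylo")
  s <- object@supports
  if (length(s) && (any(s < 0) || any(s > 1)))
    return("supports must lie in [0, 1]")
  if (length(s) && is.null(names(s)))
    return("supports must be named by canonical splits")
  TRUE
})

#' Gene-tree/species-tree reconciliation result
#'
#' @slot geneTree rooted gene tree (`phylo`).
#' @slot tipMap named character, gene tip id -> species taxon.
#' @slot mapping integer vector: for every gene-tree node (tips then
#'   internals, ape numbering) the species-tree node it maps to.
#' @slot nodeEvent character vector labelling every gene-tree internal
#'   node `"speciation"` or `"duplication"`, named by node number.
#' @slot xenologs data.frame of xenologue calls (columns `tip`,
#'   `taxon`, `recipientSupergroup`, `donorSupergroup`, `support`).
#' @export
setClass("ReconciliationResult",
         representation(geneTree = "ANY", tipMap = "character",
                        mapping = "integer", nodeEvent = "character",
                        xenologs = "data.frame"))

setValidity("ReconciliationResult", function(object) {
  gt <- object@geneTree
  if (!inherits(gt, "phylo")) return("geneTree must be phylo")
  if (length(object@nodeEvent) != gt$Nnode)
    return("one event label per internal node required")
  if (!all(object@nodeEvent %in% c("speciation", "duplication")))
    return("node events must be speciation or duplication")
  TRUE
})

#' Presence/absence landscape matrix
#'
#' Taxa-by-family matrix of the landscape ("which component exists
#' where"): 0 = absent, 1 = present, 2 = xenolog-present (present via
#' horizontal transfer).
#'
#' @slot mat integer matrix, rows = taxa in species-tree order,
#'   columns = gene families.
#' @export
setClass("PresenceAbsence", representation(mat = "matrix"))

setValidity("PresenceAbsence", function(object) {
  m <- object@mat
  if (!all(m %in% c(0L, 1L, 2L))) return("cells must be 0, 1 or 2")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("matrix must carry taxon and family names")
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    return("row/column labels must be unique")
  TRUE
})

#' Per-family gain/loss/duplication/transfer summary
#'
#' @slot family family id.
#' @slot gainBranch species-tree branch (child-node label) carrying the
#'   Dollo gain, or `NA` for an empty family.
#' @slot lossBranches character vector of lineage-specific loss
#'   branches (child-node labels).
#' @slot candidateLosses all Dollo candidate loss branches before the
#'   lineage-specific restriction.
#' @slot duplications duplication-node count from reconciliation.
#' @slot xenologs data.frame of xenologue calls.
#' @export
setClass("EventSummary",
         representation(family = "character", gainBranch = "character",
                        lossBranches = "character",
                        candidateLosses = "character",
                        duplications = "integer",
                        xenologs = "data.frame"))

#' Ordered C-alpha trace of one protein chain
#'
#' @slot chain chain identifier.
#' @slot resno author residue numbers (integer).
#' @slot resname three-letter residue names.
#' @slot coords n x 3 numeric matrix of CA coordinates in Angstrom.
#' @export
setClass("CaTrace",
         representation(chain = "character", resno = "integer",
                        resname = "character", coords = "matrix"))

setValidity("CaTrace", function(object) {
  n <- nrow(object@coords)
  if (n < 3L) return("a CA trace needs at least 3 residues")
  if (ncol(object@coords) != 3L) return("coords must be n x 3")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@resno) != n || length(object@resname) != n)
    return("resno/resname must match coordinate rows")
  TRUE
})

#' Result of an optimal rigid superposition
#'
#' @slot rotation 3 x 3 orthonormal rotation matrix, determinant +1.
#' @slot translation length-3 translation vector (applied after
#'   rotation to map trace `b` onto trace `a`).
#' @slot rmsd root-mean-square deviation (Angstrom) over retained pairs.
#' @slot nPairs number of atom pairs retained after outlier rejection.
#' @slot nStart number of corresponding pairs before rejection.
#' @slot cycles rejection/refit cycles actually run.
#' @export
setClass("SuperpositionResult",
         representation(rotation = "matrix", translation = "numeric",
                        rmsd = "numeric", nPairs = "integer",
                        nStart = "integer", cycles = "integer"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    return("rotation must be orthonormal")
  if (abs(det(R) - 1) > 1e-6) return("rotation must have determinant +1")
  if (object@rmsd < 0) return("rmsd must be >= 0")
  if (object@nPairs > object@nStart)
    return("retained pairs cannot exceed initial correspondence")
  TRUE
})
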