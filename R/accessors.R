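#' @name accessors
#' @title Accessors for m6APhylo classes
#' @description Slot accessors; user code should use these rather than
#'   `@`.
#' @param x an object of the documented class.
NULL

#' @rdname accessors
#' @export
setGeneric("speciesTree", function(x) standardGeneric("speciesTree"))
#' @rdname accessors
#' @export
setMethod("speciesTree", "SpeciesPanel", function(x) x@tree)

#' @rdname accessors
#' @export
setGeneric("supergroups", function(x) standardGeneric("supergroups"))
#' @rdname accessors
#' @export
setMethod("supergroups", "SpeciesPanel", function(x) x@supergroup)

#' @rdname accessors
#' @export
setGeneric("proteinSequences",
           function(x) standardGeneric("proteinSequences"))
#' @rdname accessors
#' @export
setMethod("proteinSequences", "GeneFamily", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("proteinSequences", "SimulatedFamily",
          function(x) x@family@sequences)

#' @rdname accessors
#' @export
setGeneric("speciesMap", function(x) standardGeneric("speciesMap"))
#' @rdname accessors
#' @export
setMethod("speciesMap", "GeneFamily", function(x) x@species)
#' @rdname accessors
#' @export
setMethod("speciesMap", "SimulatedFamily", function(x) x@family@species)

#' @rdname accessors
#' @export
setGeneric("geneTree", function(x) standardGeneric("geneTree"))
#' @rdname accessors
#' @export
setMethod("geneTree", "SimulatedFamily", function(x) x@geneTree)
#' @rdname accessors
#' @export
setMethod("geneTree", "SupportedTree", function(x) x@tree)

#' @rdname accessors
#' @export
setGeneric("trueHistory", function(x) standardGeneric("trueHistory"))
#' @rdname accessors
#' @export
setMethod("trueHistory", "SimulatedFamily", function(x) x@history)

#' @rdname accessors
#' @export
setGeneric("supports", function(x) standardGeneric("supports"))
#' @rdname accessors
#' @export
setMethod("supports", "SupportedTree", function(x) x@supports)

#' @rdname accessors
#' @export
setGeneric("retainedColumns",
           function(x) standardGeneric("retainedColumns"))
#' @rdname accessors
#' @export
setMethod("retainedColumns", "TrimmedAlignment", function(x) x@retained)

#' @rdname accessors
#' @export
setGeneric("alignedSequences",
           function(x) standardGeneric("alignedSequences"))
#' @rdname accessors
#' @export
setMethod("alignedSequences", "TrimmedAlignment",
          function(x) x@alignment)

#' @rdname accessors
#' @export
setGeneric("nodeEvents", function(x) standardGeneric("nodeEvents"))
#' @rdname accessors
#' @export
setMethod("nodeEvents", "ReconciliationResult", function(x) x@nodeEvent)

#' @rdname accessors
#' @export
setGeneric("xenologCalls", function(x) standardGeneric("xenologCalls"))
#' @rdname accessors
#' @export
setMethod("xenologCalls", "ReconciliationResult",
          function(x) x@xenologs)
#' @rdname accessors
#' @export
setMethod("xenologCalls", "EventSummary", function(x) x@xenologs)

#' @rdname accessors
#' @export
setGeneric("pamMatrix", function(x) standardGeneric("pamMatrix"))
#' @rdname accessors
#' @export
setMethod("pamMatrix", "PresenceAbsence", function(x) x@mat)

#' @rdname accessors
#' @export
setGeneric("gainBranch", function(x) standardGeneric("gainBranch"))
#' @rdname accessors
#' @export
setMethod("gainBranch", "EventSummary", function(x) x@gainBranch)

#' @rdname accessors
#' @export
setGeneric("lossBranches", function(x) standardGeneric("lossBranches"))
#' @rdname accessors
#' @export
setMethod("lossBranches", "EventSummary", function(x) x@lossBranches)

#' @rdname accessors
#' @export
setGeneric("rmsd", function(x) standardGeneric("rmsd"))
#' @rdname accessors
#' @export
setMethod("rmsd", "SuperpositionResult", function(x) x@rmsd)

#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setMethod("caCoords", "CaTrace", function(x) x@coords)

# show methods ---------------------------------------------------------

setMethod("show", "SpeciesPanel", function(object) {
  sg <- table(object@supergroup)
  cat("SpeciesPanel:", length(object@tree$tip.label), "taxa,",
      length(sg), "supergroups\n")
  cat(paste0("  ", names(sg), ": ", as.integer(sg), collapse = "\n"),
      "\n")
})

setMethod("show", "GeneFamily", function(object) {
  cat("GeneFamily '", object@family, "': ", length(object@sequences),
      " sequences over ", length(unique(object@species)), " taxa\n",
      sep = "")
})

setMethod("show", "SimulatedFamily", function(object) {
  show(object@family)
  ev <- table(object@history$kind)
  cat("  true history:",
      paste(names(ev), as.integer(ev), collapse = ", "), "\n")
})

setMethod("show", "TrimmedAlignment", function(object) {
  cat("TrimmedAlignment:", length(object@alignment), "rows,",
      length(object@retained), "of", object@sourceWidth,
      "columns retained\n")
})

setMethod("show", "SupportedTree", function(object) {
  cat("SupportedTree:", length(object@tree$tip.label), "tips,",
      length(object@supports), "supported splits",
      if (length(object@supports))
        sprintf("(min %.2f, max %.2f)", min(object@supports),
                max(object@supports)) else "", "\n")
})

setMethod("show", "ReconciliationResult", function(object) {
  ev <- table(object@nodeEvent)
  cat("ReconciliationResult:",
      length(object@geneTree$tip.label), "gene copies;",
      paste(names(ev), as.integer(ev), collapse = ", "),
      if (nrow(object@xenologs)) paste0("; ", nrow(object@xenologs),
                                        " xenolog(s)") else "", "\n")
})

setMethod("show", "PresenceAbsence", function(object) {
  cat("PresenceAbsence:", nrow(object@mat), "taxa x",
      ncol(object@mat), "families;",
      sum(object@mat == 1L), "present,",
      sum(object@mat == 2L), "xenolog-present\n")
})

setMethod("show", "EventSummary", function(object) {
  cat("EventSummary '", object@family, "': gain at ",
      object@gainBranch, "; ", length(object@lossBranches),
      " lineage-specific loss(es); ", object@duplications,
      " duplication(s); ", nrow(object@xenologs), " xenolog(s)\n",
      sep = "")
})

setMethod("show", "CaTrace", function(object) {
  cat("CaTrace chain ", object@chain, ": ", nrow(object@coords),
      " CA atoms\n", sep = "")
})

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf(
    "SuperpositionResult: RMSD %.3f A over %d/%d pairs (%d cycle(s))\n",
    object@rmsd, object@nPairs, object@nStart, object@cycles))
})
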