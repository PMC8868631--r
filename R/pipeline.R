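#' Assemble and validate a pipeline configuration
#'
#' Declarative configuration for [runPipeline()]. All thresholds carry
#' the screening defaults of the analysis: E-value cutoff 0.05,
#' redundancy identity 0.98, column retention 0.30/0.10, 1000 bootstrap
#' replicates, xenologue support 0.8. A seed is mandatory because the
#' simulation and bootstrap stages are stochastic.
#'
#' @param outputDir run directory for artifacts.
#' @param seed integer seed driving every stochastic stage.
#' @param panelCounts named vector of tips per supergroup for the
#'   simulated panel (ignored when `speciesTreePath` is given).
#' @param speciesTreePath,speciesMapPath optional paths to a Newick
#'   species tree and a taxon/supergroup TSV for a user panel.
#' @param nFamilies number of gene families to simulate.
#' @param nDecoys unrelated random sequences added to each family's
#'   search database.
#' @param dup,loss,transfer simulator event rates.
#' @param seqLength,subRate sequence simulation parameters.
#' @param motifs motif inserts for the simulator (also the required
#'   domain patterns of the screen).
#' @param eCutoff,identityCutoff,minNongap,minConservedPairs,bootstrap,xenologSupport
#'   stage thresholds.
#' @param pdbPaths optional named character vector of PDB files (one
#'   chain each, `name=path:chain`) for the structure stage.
#' @return validated config list (class `PipelineConfig`).
#' @export
pipelineConfig <- function(outputDir, seed,
                           panelCounts = c(Bacteria = 4, Archaea = 2,
                                           SAR = 4, Amorphea = 6),
                           speciesTreePath = NULL,
                           speciesMapPath = NULL,
                           nFamilies = 5L, nDecoys = 10L,
                           dup = 0.1, loss = 0.1, transfer = 0.05,
                           seqLength = 200L, subRate = 0.3,
                           motifs = list(list(pattern = "DPPW",
                                              pos = 50L)),
                           eCutoff = 0.05, identityCutoff = 0.98,
                           minNongap = 0.30, minConservedPairs = 0.10,
                           bootstrap = 1000L, xenologSupport = 0.8) {
  cfg <- list(outputDir = outputDir, seed = as.integer(seed),
              panelCounts = panelCounts,
              speciesTreePath = speciesTreePath,
              speciesMapPath = speciesMapPath,
              nFamilies = as.integer(nFamilies),
              nDecoys = as.integer(nDecoys), dup = dup, loss = loss,
              transfer = transfer, seqLength = as.integer(seqLength),
              subRate = subRate, motifs = motifs, eCutoff = eCutoff,
              identityCutoff = identityCutoff, minNongap = minNongap,
              minConservedPairs = minConservedPairs,
              bootstrap = as.integer(bootstrap),
              xenologSupport = xenologSupport)
  validatePipelineConfig(cfg)
  structure(cfg, class = "PipelineConfig")
}

validatePipelineConfig <- function(cfg) {
  inUnit <- function(x) is.numeric(x) && x > 0 && x <= 1
  if (!inUnit(cfg$identityCutoff))
    stop("identityCutoff must lie in (0, 1]")
  if (!inUnit(cfg$minNongap) || !inUnit(cfg$minConservedPairs))
    stop("trim thresholds must lie in (0, 1]")
  if (!inUnit(cfg$xenologSupport))
    stop("xenologSupport must lie in (0, 1]")
  if (cfg$eCutoff <= 0) stop("eCutoff must be > 0")
  if (cfg$bootstrap < 1L) stop("bootstrap replicates must be >= 1")
  if (is.null(cfg$seed) || is.na(cfg$seed))
    stop("a seed is required: the pipeline has stochastic stages")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Keys map one-to-one onto [pipelineConfig()] arguments; missing keys
#' take the documented defaults.
#'
#' @param path YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$panelCounts)) y$panelCounts <- unlist(y$panelCounts)
  do.call(pipelineConfig, y)
}

#' Validate a species panel (map + tree agreement, supergroup counts)
#'
#' @param speciesMapPath TSV with columns `taxon`, `supergroup`.
#' @param newickPath rooted Newick species tree.
#' @return list with `counts` (per supergroup), `total`, and the
#'   [SpeciesPanel-class]. Errors name any taxon present in one input
#'   but not the other.
#' @export
validatePanel <- function(speciesMapPath, newickPath) {
  map <- readTsv(speciesMapPath)
  if (nrow(map) == 0L) stop("species map is empty")
  if (!all(c("taxon", "supergroup") %in% names(map)))
    stop("species map needs 'taxon' and 'supergroup' columns")
  tr <- ape::read.tree(newickPath)
  onlyMap <- setdiff(map$taxon, tr$tip.label)
  onlyTree <- setdiff(tr$tip.label, map$taxon)
  if (length(onlyMap) || length(onlyTree))
    stop("taxon sets disagree; only in map: [",
         paste(onlyMap, collapse = ", "), "]; only in tree: [",
         paste(onlyTree, collapse = ", "), "]")
  panel <- readSpeciesPanel(newickPath, speciesMapPath)
  counts <- table(map$supergroup)
  list(counts = setNames(as.integer(counts), names(counts)),
       total = nrow(map), panel = panel)
}

#' Run the full evolutionary-tracing pipeline on simulated families
#'
#' Executes the stages in analysis order -- simulate (or ingest a
#' panel), screen homologues, cluster redundancy, filter by domain,
#' align, trim, build bootstrap NJ trees, reconcile (duplications,
#' xenologues), assemble the presence/absence landscape and infer
#' gains/losses, scan motifs -- writing every artifact plus a manifest
#' with checksums into the run directory. Identical config and seed
#' reproduce identical artifact bytes.
#'
#' @param cfg a [pipelineConfig()].
#' @return invisibly, a list with the run directory, the landscape
#'   [PresenceAbsence-class], per-family event summaries and the
#'   manifest path.
#' @export
runPipeline <- function(cfg) {
  validatePipelineConfig(cfg)
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(...) file.path(cfg$outputDir, ...)
  artifacts <- character(0)
  emit <- function(path) { artifacts <<- c(artifacts, path); path }

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e)))
  }

  panel <- stage("panel", {
    p <- if (!is.null(cfg$speciesTreePath))
      readSpeciesPanel(cfg$speciesTreePath, cfg$speciesMapPath)
    else simulateSpeciesPanel(cfg$panelCounts, seed = cfg$seed)
    writeSpeciesPanel(p, emit(outp("species_tree.nwk")),
                      emit(outp("species_map.tsv")))
    p
  })

  params <- evolParams(dup = cfg$dup, loss = cfg$loss,
                       transfer = cfg$transfer,
                       seqLength = cfg$seqLength,
                       subRate = cfg$subRate, motifs = cfg$motifs,
                       transferScope = "distant")
  requiredMotifs <- lapply(seq_len(cfg$nFamilies), function(i)
    vapply(cfg$motifs, `[[`, character(1), "pattern"))
  names(requiredMotifs) <- sprintf("fam%02d", seq_len(cfg$nFamilies))

  retained <- list(); xenTips <- list(); summaries <- list()
  allHits <- list(); motifRows <- list()
  for (i in seq_len(cfg$nFamilies)) {
    fid <- sprintf("fam%02d", i)
    sim <- stage(paste0(fid, ":simulate"), {
      s <- simulateFamily(panel, params, seed = cfg$seed + 13L * i,
                          familyId = fid)
      evolveSequences(s, params, seed = cfg$seed + 13L * i + 1L)
    })
    writeTsv(trueHistory(sim), emit(outp(paste0(fid, "_history.tsv"))))
    if (!is.null(geneTree(sim)))
      ape::write.tree(geneTree(sim),
                      file = emit(outp(paste0(fid, "_true_tree.nwk"))))
    seqs <- proteinSequences(sim)
    if (length(seqs) == 0L) {
      retained[[fid]] <- setNames(character(0), character(0))
      next
    }
    Biostrings::writeXStringSet(seqs, emit(outp(paste0(fid, ".fa"))))

    kept <- stage(paste0(fid, ":screen"), {
      decoys <- withSeed(cfg$seed + 977L * i, {
        Biostrings::AAStringSet(setNames(
          vapply(seq_len(cfg$nDecoys), function(k)
            randomAASeq(cfg$seqLength), character(1)),
          sprintf("decoy%02d", seq_len(cfg$nDecoys))))
      })
      db <- c(seqs, decoys)
      hits <- screenHomologs(seqs[1L], db, eCutoff = cfg$eCutoff)
      writeHitTable(hits, emit(outp(paste0(fid, "_hits.tsv"))))
      allHits[[fid]] <- hits
      message("  hits: ", nrow(hits), "/", length(db))
      surv <- db[names(db) %in% hits$subject]
      reps <- clusterRedundant(surv, cfg$identityCutoff)
      message("  after clustering: ", length(reps))
      out <- filterByDomain(reps, fid, requiredMotifs)
      message("  after domain filter: ", length(out))
      out
    })
    if (length(kept) == 0L) {
      retained[[fid]] <- setNames(character(0), character(0))
      next
    }
    retained[[fid]] <- setNames(sub("\\|.*$", "", names(kept)),
                                names(kept))

    hitsDf <- do.call(rbind, lapply(names(kept), function(id) {
      h4 <- scanMotif(as.character(kept[[id]]), motifIV())
      if (nrow(h4)) cbind(sequence = id, family = fid, h4) else NULL
    }))
    if (!is.null(hitsDf)) motifRows[[fid]] <- hitsDf

    if (length(kept) >= 3L) {
      st <- stage(paste0(fid, ":tree"), {
        aln <- if (length(unique(Biostrings::width(kept))) == 1L)
          kept else buildMsa(kept)
        trimmed <- trimColumns(aln, cfg$minNongap,
                               cfg$minConservedPairs)
        writeRetainedColumns(
          trimmed, emit(outp(paste0(fid, "_retained_cols.tsv"))))
        Biostrings::writeXStringSet(
          alignedSequences(trimmed),
          emit(outp(paste0(fid, "_trimmed.fa"))))
        boot <- bootstrapSupport(trimmed, replicates = cfg$bootstrap,
                                 seed = cfg$seed + 331L * i)
        rooted <- midpointRoot(boot)
        writeSupportedTree(rooted,
                           emit(outp(paste0(fid, "_tree.nwk"))))
        rooted
      })
      rec <- stage(paste0(fid, ":reconcile"),
                   reconcileFamily(st, panel,
                                   supportThreshold = cfg$xenologSupport))
      xenTips[[fid]] <- rec$xenologs$tip
      summaries[[fid]] <- rec
    }
  }

  pam <- stage("landscape", {
    p <- buildPresenceAbsence(retained, panel, xenTips)
    writePresenceAbsence(p, emit(outp("landscape.tsv")))
    p
  })
  events <- stage("gains_losses", {
    ev <- inferGainsLosses(pam, panel)
    for (fid in names(ev)) {
      if (!is.null(summaries[[fid]]))
        ev[[fid]]@duplications <- summaries[[fid]]$duplications
      if (!is.null(xenTips[[fid]]) && length(xenTips[[fid]]))
        ev[[fid]]@xenologs <- summaries[[fid]]$xenologs
    }
    df <- do.call(rbind, lapply(ev, function(e) data.frame(
      family = e@family, gain = e@gainBranch,
      losses = paste(e@lossBranches, collapse = ","),
      duplications = e@duplications,
      xenologs = nrow(e@xenologs))))
    writeTsv(df, emit(outp("events.tsv")))
    ev
  })
  if (length(motifRows))
    writeMotifHits(do.call(rbind, motifRows),
                   emit(outp("motif_hits.tsv")))

  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE)
  attr(manifest, "seed") <- cfg$seed
  manifestPath <- outp("manifest.tsv")
  writeTsv(cbind(manifest, seed = cfg$seed), manifestPath)
  message("pipeline complete: ", length(artifacts), " artifacts")
  invisible(list(dir = cfg$outputDir, landscape = pam,
                 events = events, manifest = manifestPath))
}
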