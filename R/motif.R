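#' Define a catalytic motif pattern
#'
#' A motif is a position-wise allowed-residue pattern (e.g. methylation
#' catalysis motif IV, `[DNSH]PP[WFY]`) plus optional literal variants
#' that match even when they fall outside the consensus (e.g. the EPPV
#' motif of E. coli Dam).
#'
#' @param name motif name.
#' @param positions list of character vectors: allowed residues per
#'   position; or a single bracket-expression string like
#'   `"[DNSH]PP[WFY]"`.
#' @param variants character vector of literal variant strings.
#' @return a list of class `MotifPattern`.
#' @export
motifPattern <- function(name, positions, variants = character(0)) {
  if (is.character(positions) && length(positions) == 1L) {
    toks <- regmatches(positions,
                       gregexpr("\\[[A-Z]+\\]|[A-Z]", positions))[[1L]]
    positions <- lapply(toks, function(tk)
      strsplit(gsub("\\[|\\]", "", tk), "")[[1L]])
  }
  if (length(positions) == 0L) stop("motif needs at least one position")
  if (any(vapply(positions, length, integer(1)) == 0L))
    stop("every position needs at least one allowed residue")
  structure(list(name = name, positions = positions,
                 variants = toupper(variants)),
            class = "MotifPattern")
}

motifRegex <- function(pattern) {
  core <- paste(vapply(pattern$positions, function(p)
    if (length(p) == 1L) p else paste0("[", paste(p, collapse = ""), "]"),
    character(1)), collapse = "")
  alts <- c(core, pattern$variants)
  paste0("(", paste(unique(alts), collapse = "|"), ")")
}

#' Scan a sequence for a motif
#'
#' Reports all non-overlapping matches of the pattern or any registered
#' variant, left to right.
#'
#' @param seq amino-acid string.
#' @param pattern a [motifPattern()].
#' @return data.frame with columns `motif`, `variant` (the matched
#'   substring), `start` (1-based), `match`.
#' @export
scanMotif <- function(seq, pattern) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("sequence must be non-empty")
  m <- gregexpr(motifRegex(pattern), seq)[[1L]]
  if (m[1L] == -1L)
    return(data.frame(motif = character(0), variant = character(0),
                      start = integer(0), match = character(0),
                      stringsAsFactors = FALSE))
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  hits <- substring(seq, starts, starts + lens - 1L)
  data.frame(motif = pattern$name, variant = hits, start = starts,
             match = hits, stringsAsFactors = FALSE)
}

#' Default motif definitions
#'
#' `motifIV`: the Rossmann-fold MTase methylation-catalysis motif
#' (D/N/S/H-PP-W/F/Y) with the Dam-type EPPV and the NI/LPY variants
#' registered. `motifI`: a glycine-rich AdoMet-binding consensus
#' ((A/G)-x-(A/G)-x-(A/G)); the literature reasons about motif I by
#' order rather than by an exact consensus, so this is deliberately
#' config-overridable.
#'
#' @return a [motifPattern()].
#' @export
motifIV <- function() {
  motifPattern("motifIV", "[DNSH]PP[WFY]",
               variants = c("EPPV", "NIPY", "NLPY"))
}

#' @rdname motifIV
#' @export
motifI <- function() {
  motifPattern("motifI", list(c("A", "G"), AA20, c("A", "G"), AA20,
                              c("A", "G")))
}

#' Classify a Rossmann-fold MTase by motif order
#'
#' Class alpha MTases carry the AdoMet-binding motif I before the
#' catalytic motif IV (order I-IV); class beta MTases carry them in the
#' reverse order (IV-I). If either motif is absent the class is
#' unknown.
#'
#' @param seq amino-acid string.
#' @param motif_I,motif_IV [motifPattern()] objects.
#' @return `"alpha"`, `"beta"` or `"unknown"`.
#' @export
classifyMtaseClass <- function(seq, motif_I = motifI(),
                               motif_IV = motifIV()) {
  h1 <- scanMotif(seq, motif_I)
  h4 <- scanMotif(seq, motif_IV)
  if (nrow(h1) == 0L || nrow(h4) == 0L) return("unknown")
  if (h1$start[1L] < h4$start[1L]) "alpha" else "beta"
}

#' Assign a motif-IV hit to an evolutionary group
#'
#' Group I N6mA MTases (RlmJ, TrmM, METTL5, N6AMT1, RlmF, METTL16)
#' carry NPPF/NPPY; Group II (ZCCHC4, ErmAM, RsmA, DIMT1L, TFB2M) carry
#' NIPY/NLPY; Group III is PCIF1, whose NPPF is distinguished from
#' Group I by family identity (its function, not its sequence, sets it
#' apart), hence the family hint.
#'
#' @param hit one row of a [scanMotif()] result (or a variant string).
#' @param familyHint optional family id (e.g. `"PCIF1"`).
#' @return `"I"`, `"II"`, `"III"` or `"none"`.
#' @export
classifyMtaseGroup <- function(hit, familyHint = NULL) {
  v <- if (is.data.frame(hit)) hit$variant[1L] else as.character(hit)
  if (v %in% c("NPPF", "NPPY")) {
    if (!is.null(familyHint) && identical(familyHint, "PCIF1") &&
        v == "NPPF") return("III")
    return("I")
  }
  if (v %in% c("NIPY", "NLPY")) return("II")
  "none"
}

#' Check ALKB-family catalytic sites
#'
#' The ALKB dioxygenase double-stranded beta-helix fold binds Fe(2+)
#' through an H-x-D pair plus a distal H (HXD...H), and the
#' alpha-ketoglutarate cofactor through N, Y, R, R in sequence order.
#' Exact spacings vary by family, so the windows are configuration
#' values.
#'
#' @param seq amino-acid string.
#' @param feSpacing integer c(min, max): allowed gap (residues) between
#'   the D of HxD and the distal H.
#' @param akgSpacing list of three c(min, max) windows for the N->Y,
#'   Y->R and R->R gaps.
#' @return list with `feSite`, `akgSite` (logicals) and `positions`.
#' @export
checkAlkbhSites <- function(seq, feSpacing = c(10L, 150L),
                            akgSpacing = list(c(1L, 120L), c(1L, 120L),
                                              c(1L, 120L))) {
  seq <- toupper(as.character(seq))
  if (!nzchar(seq)) stop("sequence must be non-empty")
  chars <- strsplit(seq, "")[[1L]]
  fePos <- NULL
  hxd <- gregexpr("H.D", seq)[[1L]]
  if (hxd[1L] != -1L) {
    for (s in as.integer(hxd)) {
      dPos <- s + 2L
      hDist <- which(chars == "H")
      ok <- hDist[hDist - dPos >= feSpacing[1L] &
                  hDist - dPos <= feSpacing[2L]]
      if (length(ok)) { fePos <- c(HxD = s, distalH = ok[1L]); break }
    }
  }
  # depth-first search for any N -> Y -> R -> R chain whose successive
  # gaps respect the windows
  need <- c("N", "Y", "R", "R")
  searchChain <- function(k, cur) {
    lo <- if (k == 1L) 1L else cur + akgSpacing[[k - 1L]][1L]
    hi <- if (k == 1L) nchar(seq) else cur + akgSpacing[[k - 1L]][2L]
    idx <- which(chars == need[k])
    idx <- idx[idx >= lo & idx <= min(hi, nchar(seq))]
    for (p in idx) {
      if (k == length(need)) return(p)
      rest <- searchChain(k + 1L, p)
      if (!is.null(rest)) return(c(p, rest))
    }
    NULL
  }
  chain <- searchChain(1L, 0L)
  akgPos <- if (!is.null(chain)) setNames(chain, c("N", "Y", "R1", "R2"))
  list(feSite = !is.null(fePos), akgSite = !is.null(chain),
       positions = list(fe = fePos, akg = akgPos))
}

#' Check the YTH aromatic cage in an alignment
#'
#' The YTH domain (and its McrB-N and MJECL36 relatives) recognizes the
#' methylated base through three hydrophobic cage residues. For every
#' sequence, reports whether all three cage columns hold residues from
#' the allowed set; a gap at any cage column fails. L is allowed by
#' default because one cage position is aliphatic in some prokaryotic
#' homologues.
#'
#' @param aln aligned `AAStringSet`.
#' @param cageColumns exactly three column indices (1-based).
#' @param allowed permitted cage residues (default F, W, Y, L).
#' @return named logical vector, one per sequence.
#' @export
checkAromaticCage <- function(aln, cageColumns,
                              allowed = c("F", "W", "Y", "L")) {
  if (length(cageColumns) != 3L) stop("exactly 3 cage columns required")
  m <- alignmentMatrix(aln)
  if (any(cageColumns < 1L) || any(cageColumns > ncol(m)))
    stop("cage column out of alignment range")
  res <- apply(m[, cageColumns, drop = FALSE], 1L,
               function(r) all(r %in% allowed))
  setNames(as.logical(res), names(aln))
}

#' Write motif hits as TSV
#'
#' @param hits data.frame with a `sequence` id column plus
#'   [scanMotif()] columns.
#' @param path output path.
#' @export
writeMotifHits <- function(hits, path) writeTsv(hits, path)
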