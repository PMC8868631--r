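#' Extract the C-alpha trace of one chain from a PDB file
#'
#' Reads ATOM records (author numbering) via `bio3d::read.pdb`, keeps
#' the CA atoms of the requested chain in file order, and resolves
#' alternate locations to their first occurrence.
#'
#' @param pdb path to a PDB coordinate file, or the file content as a
#'   single string containing newlines.
#' @param chain chain identifier.
#' @return a [CaTrace-class].
#' @export
parseStructure <- function(pdb, chain) {
  path <- pdb
  if (length(pdb) == 1L && grepl("\n", pdb)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(strsplit(pdb, "\n")[[1L]], path)
  }
  p <- bio3d::read.pdb(path, verbose = FALSE)
  at <- p$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!chain %in% at$chain)
    stop("chain '", chain, "' not present in the structure")
  at <- at[at$chain == chain, , drop = FALSE]
  ins <- if ("insert" %in% names(at)) {
    iv <- at$insert; iv[is.na(iv)] <- ""; iv
  } else rep("", nrow(at))
  at <- at[!duplicated(paste(at$resno, ins)), , drop = FALSE]  # altlocs
  if (nrow(at) < 3L)
    stop("fewer than 3 CA atoms in chain '", chain, "'")
  new("CaTrace", chain = chain, resno = as.integer(at$resno),
      resname = as.character(at$resid),
      coords = cbind(at$x, at$y, at$z))
}

# one-letter residue sequence of a trace (unknown residues become X)
traceSequence <- function(trace) {
  one <- AA1[trace@resname]
  one[is.na(one)] <- "X"
  paste(one, collapse = "")
}

# Optimal least-squares rotation/translation (Kabsch) mapping point set
# Q onto P (both n x 3). Reflections are forbidden: the determinant
# correction enforces det(R) = +1.
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Qc, Pc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cp - R %*% cq))
}

# aligned (non-gap, non-X-free) residue index pairs from a global
# sequence alignment of the two traces' residue sequences
alignTraces <- function(a, b, scheme) {
  sa <- traceSequence(a); sb <- traceSequence(b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "global", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gapOpen, gapExtension = scheme$gapExtend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  i <- 0L; j <- 0L
  pairs <- matrix(integer(0), ncol = 2L)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") i <- i + 1L
    if (pb[k] != "-") j <- j + 1L
    if (pa[k] != "-" && pb[k] != "-")
      pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

#' Superpose two CA traces with iterative outlier rejection
#'
#' Residue correspondence comes from a global sequence alignment of
#' the two chains (aligned non-gap pairs only); the optimal
#' least-squares rotation (Kabsch, reflections forbidden) is fitted on
#' the corresponding CA pairs, then up to `maxCycles` rejection cycles
#' drop pairs deviating by more than `rejectSigma` standard deviations
#' of the current per-pair deviations and refit. RMSD is reported over
#' the retained pairs; each cycle is monotone non-increasing in RMSD.
#'
#' @param a,b [CaTrace-class] objects (>= 3 residues each).
#' @param scheme a [scoringScheme()] for the correspondence alignment.
#' @param maxCycles maximum rejection/refit cycles (default 5).
#' @param rejectSigma rejection threshold in standard deviations of the
#'   per-pair deviation (default 2.0).
#' @return a [SuperpositionResult-class].
#' @export
superpose <- function(a, b, scheme = scoringScheme(), maxCycles = 5L,
                      rejectSigma = 2.0) {
  pairs <- alignTraces(a, b, scheme)
  if (nrow(pairs) < 3L)
    stop("fewer than 3 corresponding residue pairs")
  nStart <- nrow(pairs)
  keep <- seq_len(nStart)
  cycles <- 0L
  repeat {
    P <- a@coords[pairs[keep, 1L], , drop = FALSE]
    Q <- b@coords[pairs[keep, 2L], , drop = FALSE]
    fit <- kabsch(P, Q)
    dev <- sqrt(rowSums((P - (Q %*% t(fit$R) +
      matrix(fit$t, nrow(Q), 3L, byrow = TRUE)))^2))
    rmsd <- sqrt(mean(dev^2))
    if (cycles >= maxCycles) break
    s <- stats::sd(dev)
    # numerically exact fits have nothing to reject
    if (!is.finite(s) || s < 1e-9 || max(dev) < 1e-8) break
    drop_ <- dev > rejectSigma * s
    if (!any(drop_)) break
    if (sum(!drop_) < 3L) {
      # rejection never reduces the correspondence below 3 pairs:
      # keep the 3 best-fitting pairs instead
      if (length(keep) <= 3L) break
      keep <- keep[order(dev)[seq_len(3L)]]
    } else {
      keep <- keep[!drop_]
    }
    cycles <- cycles + 1L
  }
  new("SuperpositionResult", rotation = fit$R, translation = fit$t,
      rmsd = rmsd, nPairs = length(keep), nStart = nStart,
      cycles = cycles)
}

#' Pairwise RMSD matrix over a set of CA traces
#'
#' All pairwise superpositions via [superpose()]; the matrix is
#' symmetric with a zero diagonal (RMSD(a,b) = RMSD(b,a)).
#'
#' @param traces named list of [CaTrace-class] objects (>= 2).
#' @param scheme,maxCycles,rejectSigma passed to [superpose()].
#' @return symmetric numeric matrix of RMSD in Angstrom.
#' @export
rmsdMatrix <- function(traces, scheme = scoringScheme(),
                       maxCycles = 5L, rejectSigma = 2.0) {
  n <- length(traces)
  if (n < 2L) stop("need at least 2 traces")
  nm <- names(traces)
  if (is.null(nm)) nm <- paste0("trace", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    r <- superpose(traces[[i]], traces[[j]], scheme, maxCycles,
                   rejectSigma)@rmsd
    m[i, j] <- m[j, i] <- r
  }
  m
}

#' Apply a superposition to a trace
#'
#' Maps trace `b` into the frame of trace `a` using a fitted
#' [SuperpositionResult-class].
#'
#' @param trace a [CaTrace-class].
#' @param fit a [SuperpositionResult-class].
#' @return the transformed [CaTrace-class].
#' @export
transformTrace <- function(trace, fit) {
  co <- trace@coords %*% t(fit@rotation) +
    matrix(fit@translation, nrow(trace@coords), 3L, byrow = TRUE)
  initialize(trace, coords = co)
}
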