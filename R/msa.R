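#' Progressive multiple alignment of a gene family
#'
#' Thin, deterministic wrapper around the MAFFT progressive aligner
#' (guide tree from pairwise distances, then profile-profile alignment
#' with affine gaps). Row order follows the input; ungapping any row
#' reproduces its input sequence exactly.
#'
#' @param records named `AAStringSet` with at least two sequences.
#' @param scheme a [scoringScheme()] (accepted for interface symmetry;
#'   the aligner uses its own BLOSUM62-based scoring).
#' @return aligned `AAStringSet` (all rows equal width, gap `-`).
#' @export
buildMsa <- function(records, scheme = scoringScheme()) {
  if (length(records) < 2L) stop("need at least 2 records to align")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(records, fin)
  status <- system2("mafft", c("--quiet", "--retree", "2",
                               "--maxiterate", "0", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aln <- Biostrings::readAAStringSet(fout)
  aln <- Biostrings::AAStringSet(toupper(aln))
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln[names(records)]
}

alignmentMatrix <- function(aln) {
  if (length(unique(Biostrings::width(aln))) > 1L)
    stop("alignment rows must have equal width")
  do.call(rbind, strsplit(as.character(aln), ""))
}

# per-column retention test for the 30%/10% rule; exported logic lives
# in trimColumns(); this operates on a character column
columnKept <- function(col, minNongap, minConservedPairs, conserved,
                       posMatrix) {
  n <- length(col)
  letters <- col[col != "-"]
  if (length(letters) / n < minNongap) return(FALSE)
  if (length(letters) < 2L) return(FALSE)  # no pairs: fails by convention
  tot <- choose(length(letters), 2L)
  informative <- letters[letters != "X"]   # X never certifies conservation
  if (conserved == "identity") {
    cons <- sum(choose(table(informative), 2L))
  } else {
    cons <- 0
    if (length(informative) >= 2L) {
      prs <- combn(informative, 2L)
      cons <- sum(posMatrix[cbind(prs[1L, ], prs[2L, ])] > 0)
    }
  }
  cons / tot >= minConservedPairs
}

#' Trim alignment columns by the 30%/10% retention rule
#'
#' A column is retained iff (a) at least `minNongap` of its rows are
#' non-gap letters, and (b) at least `minConservedPairs` of the letter
#' pairs in the column are conserved. Both thresholds are inclusive
#' ("at least"). A column with fewer than two letters has no pairs and
#' fails criterion (b) by convention. `X` counts as a letter for (a)
#' but never as a member of a conserved pair. "Conserved" defaults to
#' identical residues; `conserved = "positive"` instead accepts any
#' pair with a positive substitution-matrix score.
#'
#' @param aln aligned `AAStringSet` (>= 2 rows).
#' @param minNongap minimum non-gap fraction (default 0.30).
#' @param minConservedPairs minimum conserved-pair fraction
#'   (default 0.10).
#' @param conserved `"identity"` (default) or `"positive"`.
#' @param scheme a [scoringScheme()]; supplies the matrix for
#'   `conserved = "positive"`.
#' @return a [TrimmedAlignment-class]; retained column indices are
#'   1-based into the source alignment, order preserved.
#' @export
trimColumns <- function(aln, minNongap = 0.30, minConservedPairs = 0.10,
                        conserved = c("identity", "positive"),
                        scheme = scoringScheme()) {
  conserved <- match.arg(conserved)
  if (length(aln) < 2L) stop("alignment needs at least 2 rows")
  m <- alignmentMatrix(aln)
  keep <- which(vapply(seq_len(ncol(m)), function(j) {
    columnKept(m[, j], minNongap, minConservedPairs, conserved,
               scheme$matrix)
  }, logical(1)))
  trimmed <- if (length(keep)) {
    Biostrings::AAStringSet(apply(m[, keep, drop = FALSE], 1L, paste,
                                  collapse = ""))
  } else {
    Biostrings::AAStringSet(setNames(rep("", nrow(m)), rownames(m)))
  }
  names(trimmed) <- names(aln)
  new("TrimmedAlignment", alignment = trimmed,
      retained = as.integer(keep), sourceWidth = ncol(m))
}

#' Write the retained-column index list of a trimmed alignment
#'
#' One-column TSV (`column`, 1-based source indices) for provenance.
#'
#' @param trimmed a [TrimmedAlignment-class].
#' @param path output path.
#' @export
writeRetainedColumns <- function(trimmed, path) {
  writeTsv(data.frame(column = trimmed@retained), path)
}
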