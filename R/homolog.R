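#' Scoring scheme for sequence comparison and E-value estimation
#'
#' Bundles the substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw local-alignment
#' scores to E-values (`E = K * m * n * exp(-lambda * S)`). Default
#' Karlin-Altschul values are the canonical ungapped BLOSUM62 estimates.
#'
#' @param matrix substitution matrix name or numeric matrix
#'   (default BLOSUM62).
#' @param gapOpen,gapExtend positive gap penalties; a gap of length L
#'   costs `gapOpen + L * gapExtend`.
#' @param K,lambda Karlin-Altschul parameters (> 0).
#' @return a list of class `ScoringScheme`.
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gapOpen = 10,
                          gapExtend = 4, K = 0.13, lambda = 0.3176) {
  if (gapOpen <= 0 || gapExtend <= 0) stop("gap penalties must be > 0")
  if (K <= 0 || lambda <= 0) stop("K and lambda must be > 0")
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(ls(e)[1L], envir = e)
  }
  structure(list(matrix = matrix, gapOpen = gapOpen,
                 gapExtend = gapExtend, K = K, lambda = lambda),
            class = "ScoringScheme")
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gaps (via
#' `Biostrings::pairwiseAlignment`). Scores are floored at zero: when no
#' positive-scoring alignment exists the empty alignment (score 0,
#' identity 0) is reported.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @param scheme a [scoringScheme()].
#' @return list with `score`, `identity` (percent, over aligned
#'   columns), and 1-based span coordinates `qstart`, `qend`, `sstart`,
#'   `send` (NA for the empty alignment).
#' @export
localAlign <- function(a, b, scheme = scoringScheme()) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gapOpen, gapExtension = scheme$gapExtend)
  sc <- Biostrings::score(al)
  if (sc <= 0)
    return(list(score = 0, identity = 0, qstart = NA_integer_,
                qend = NA_integer_, sstart = NA_integer_,
                send = NA_integer_))
  p <- Biostrings::pattern(al); s <- Biostrings::subject(al)
  list(score = sc, identity = Biostrings::pid(al, type = "PID1"),
       qstart = Biostrings::start(p), qend = Biostrings::end(p),
       sstart = Biostrings::start(s), send = Biostrings::end(s))
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of distinct
#' local alignments with score >= S between a random query of length m
#' and a database of total length n.
#'
#' @param score raw alignment score (matrix units, >= 0).
#' @param m query length; `n` database length (both >= 1).
#' @param n database length.
#' @param scheme a [scoringScheme()] supplying K and lambda.
#' @return the E-value (> 0, strictly decreasing in score).
#' @export
estimateEvalue <- function(score, m, n, scheme = scoringScheme()) {
  stopifnot(score >= 0, m >= 1, n >= 1)
  scheme$K * m * n * exp(-scheme$lambda * score)
}

#' Screen a database for homologues of query proteins
#'
#' Aligns every query against every database record, converts scores to
#' Karlin-Altschul E-values (n = total database residue count) and
#' keeps subjects with E below the cutoff against at least one query;
#' per subject the best (lowest-E) hit is reported.
#'
#' @param queries,database named `AAStringSet` objects (non-empty).
#' @param eCutoff E-value cutoff (default 0.05; hits must be strictly
#'   below it).
#' @param scheme a [scoringScheme()].
#' @return data.frame hit table with columns `query`, `subject`,
#'   `score`, `evalue`, `pident`, `qstart`, `qend`, `sstart`, `send`
#'   (1-based inclusive coordinates).
#' @export
screenHomologs <- function(queries, database, eCutoff = 0.05,
                           scheme = scoringScheme()) {
  if (length(queries) == 0L || length(database) == 0L)
    stop("queries and database must be non-empty")
  nDb <- sum(Biostrings::width(database))
  rows <- list()
  for (qi in seq_along(queries)) {
    q <- as.character(queries[[qi]])
    for (si in seq_along(database)) {
      h <- localAlign(q, as.character(database[[si]]), scheme)
      e <- estimateEvalue(h$score, nchar(q), nDb, scheme)
      if (e < eCutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = names(queries)[qi], subject = names(database)[si],
          score = h$score, evalue = e, pident = h$identity,
          qstart = h$qstart, qend = h$qend, sstart = h$sstart,
          send = h$send, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(query = character(0), subject = character(0),
                      score = numeric(0), evalue = numeric(0),
                      pident = numeric(0), qstart = integer(0),
                      qend = integer(0), sstart = integer(0),
                      send = integer(0)))
  tab <- do.call(rbind, rows)
  # pool hits per subject: keep the best E-value
  tab <- tab[order(tab$subject, tab$evalue), ]
  tab <- tab[!duplicated(tab$subject), ]
  tab[order(tab$evalue), , drop = FALSE]
}

# identity fraction between two sequences: identical residues in the
# global alignment divided by the length of the shorter sequence (the
# convention of greedy incremental clustering tools)
identityFraction <- function(a, b, scheme = scoringScheme()) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gapOpen, gapExtension = scheme$gapExtend)
  Biostrings::nmatch(al) / min(nchar(a), nchar(b))
}

#' Remove redundant sequences by greedy identity clustering
#'
#' Greedy longest-first clustering: records are visited by decreasing
#' length (ties broken by lexicographic id); each record joins the
#' first existing cluster whose representative it matches at or above
#' the identity cutoff, otherwise it founds a new cluster. Identity is
#' identical residues over the shorter sequence length. Clustering the
#' representatives again changes nothing (idempotence).
#'
#' @param records named `AAStringSet`.
#' @param identityCutoff fraction in (0, 1]; default 0.98.
#' @param scheme a [scoringScheme()].
#' @return `AAStringSet` of cluster representatives, in processing
#'   order (deterministic).
#' @export
clusterRedundant <- function(records, identityCutoff = 0.98,
                             scheme = scoringScheme()) {
  if (length(records) == 0L) stop("records must be non-empty")
  ord <- order(-Biostrings::width(records), names(records))
  reps <- integer(0)
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      idf <- identityFraction(as.character(records[[i]]),
                              as.character(records[[r]]), scheme)
      if (idf >= identityCutoff) { placed <- TRUE; break }
    }
    if (!placed) reps <- c(reps, i)
  }
  records[reps]
}

#' Filter records by required domain/motif content
#'
#' A record is retained iff every required motif pattern for its family
#' matches its sequence, or its family is in the bypass set (families
#' whose diagnostic domain is legitimately absent in some species, the
#' ZC3H13-type exception).
#'
#' @param records named `AAStringSet`.
#' @param family family id of the records (single value) or named
#'   character vector per record.
#' @param requiredMotifs named list: family id -> character vector of
#'   regular-expression patterns (e.g. `"[DNSH]PP[WFY]"`).
#' @param bypassFamilies character vector of family ids exempt from the
#'   filter.
#' @return the retained `AAStringSet`.
#' @export
filterByDomain <- function(records, family, requiredMotifs = list(),
                           bypassFamilies = character()) {
  fam <- if (length(family) == 1L)
    setNames(rep(family, length(records)), names(records))
  else family[names(records)]
  keep <- vapply(seq_along(records), function(i) {
    f <- fam[i]
    if (f %in% bypassFamilies) return(TRUE)
    pats <- requiredMotifs[[f]]
    if (is.null(pats))
      stop("family '", f, "' has neither required motifs nor bypass")
    all(vapply(pats, grepl, logical(1),
               x = as.character(records[[i]])))
  }, logical(1))
  records[keep]
}

#' Write a hit table as tab-delimited text
#'
#' Columns query, subject, score, evalue, pident, qstart, qend, sstart,
#' send; 1-based inclusive coordinates, matching tabular search-output
#' conventions.
#'
#' @param hits data.frame from [screenHomologs()].
#' @param path output path.
#' @export
writeHitTable <- function(hits, path) writeTsv(hits, path)
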