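#' Local alignment score between two proteins
#'
#' Smith-Waterman best local alignment score under a fixed identity-flavoured
#' scheme: match +2, mismatch -1, and affine gaps where a gap of length k
#' costs 5 + k (open 5, extend 1 per residue). The score is symmetric.
#'
#' @param a,b amino-acid sequences (character scalars).
#' @return integer alignment score (>= 0; unrelated sequences floor at 0).
#' @examples
#' scorePair("MKR", "MKR")  # 6
#' scorePair("MKR", "WWW")  # 0
#' @export
scorePair <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  .swScore(a, b)
}

#' All-pairs local alignment scores
#'
#' @param queries,targets named character vectors of sequences.
#' @return integer matrix of scores; rows queries, cols targets.
#' @export
scoreMatrix <- function(queries, targets) {
  validateSequenceRecords(queries)
  validateSequenceRecords(targets)
  m <- .swScoreMatrix(unname(queries), unname(targets))
  dimnames(m) <- list(names(queries), names(targets))
  m
}

#' Best hit of every query in a target proteome
#'
#' For each query the single best-scoring target is reported; ties are broken
#' by the lexicographically smallest target id.
#'
#' @param queries,targets named character vectors of protein sequences, or a
#'   precomputed score matrix via `scores`.
#' @param scores optional score matrix (rows queries, cols targets) to avoid
#'   recomputation.
#' @return hit table data.frame (`query`, `subject`, `score`).
#' @export
bestHits <- function(queries = NULL, targets = NULL, scores = NULL) {
  if (is.null(scores)) {
    if (!length(queries) || !length(targets)) stop("both proteomes required")
    scores <- scoreMatrix(queries, targets)
  }
  tnames <- colnames(scores)
  ord <- order(tnames)  # ties resolved toward smallest id
  best <- apply(scores[, ord, drop = FALSE], 1L, which.max)
  hitTable(data.frame(
    query = rownames(scores),
    subject = tnames[ord][best],
    score = scores[cbind(seq_len(nrow(scores)), ord[best])],
    stringsAsFactors = FALSE
  ))
}

#' Mutual (reciprocal) best hits from two directed hit tables
#'
#' A pair (a, b) is mutual iff b is a's best hit and a is b's best hit.
#'
#' @param ab hit table of A-queries against B.
#' @param ba hit table of B-queries against A.
#' @return data.frame of pairs (`gene_a` from A, `gene_b` from B).
#' @export
mutualBestHits <- function(ab, ba) {
  ab <- hitTable(ab); ba <- hitTable(ba)
  back <- stats::setNames(ba$subject, ba$query)
  keep <- !is.na(back[ab$subject]) & back[ab$subject] == ab$query
  out <- data.frame(gene_a = ab$query[keep], gene_b = ab$subject[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Reciprocal best hits between two proteomes
#'
#' Computes the score matrix once (scores are symmetric) and intersects best
#' hits in both directions.
#'
#' @param protA,protB named character vectors of protein sequences.
#' @return data.frame of RBH pairs (`gene_a`, `gene_b`).
#' @export
reciprocalBestHits <- function(protA, protB) {
  s <- scoreMatrix(protA, protB)
  ab <- bestHits(scores = s)
  ba <- bestHits(scores = t(s))
  mutualBestHits(ab, ba)
}

#' Build orthogroups from reciprocal-best-hit pairs
#'
#' Orthogroups are the connected components of the cross-species RBH graph.
#' Singleton genes (no RBH) are excluded from orthogroups but retained in
#' the species map. With at most one gene copy per species (as the simulator
#' guarantees) components coincide with strict ortholog groups.
#'
#' @param pairsList data.frame of RBH pairs (`gene_a`, `gene_b`), or a list
#'   of such data.frames (one per species pair).
#' @param speciesOf named character vector mapping every gene (including
#'   RBH-less singletons) to its species.
#' @return an [OrthologySet-class].
#' @export
buildOrthogroups <- function(pairsList, speciesOf) {
  if (is.data.frame(pairsList)) pairsList <- list(pairsList)
  pairs <- do.call(rbind, lapply(pairsList, function(p) {
    stopifnot(all(c("gene_a", "gene_b") %in% names(p)))
    p[, c("gene_a", "gene_b")]
  }))
  if (is.null(pairs))
    pairs <- data.frame(gene_a = character(0), gene_b = character(0))
  if (nrow(pairs)) {
    swap <- pairs$gene_a > pairs$gene_b
    tmp <- pairs$gene_a[swap]
    pairs$gene_a[swap] <- pairs$gene_b[swap]
    pairs$gene_b[swap] <- tmp
    pairs <- unique(pairs)
    miss <- setdiff(c(pairs$gene_a, pairs$gene_b), names(speciesOf))
    if (length(miss)) stop("gene without species assignment: ", miss[[1L]])
  }
  og <- list()
  if (nrow(pairs)) {
    g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
    comp <- igraph::components(g)
    members <- split(names(comp$membership), comp$membership)
    members <- lapply(members, function(x) sort(x))
    members <- members[order(vapply(members, `[[`, character(1), 1L))]
    names(members) <- sprintf("OG%04d", seq_along(members))
    og <- members
  }
  new("OrthologySet", rbhPairs = pairs, orthogroups = og,
      speciesOf = speciesOf)
}

#' Presence/absence matrix from orthogroups
#'
#' One column per orthogroup; a cell is 1 iff the taxon contributes at least
#' one member gene. Columns that would be unobservable in comparative data --
#' all-absent or present in exactly one taxon -- are removed before export,
#' matching the ascertainment correction applied at inference time; removal
#' counts are recorded as attributes `droppedAbsent` / `droppedSingleton`
#' and logged.
#'
#' @param ortho an [OrthologySet-class].
#' @param taxa character vector of taxa (matrix row order).
#' @return a filtered [PresenceAbsenceMatrix-class].
#' @export
matrixFromOrthogroups <- function(ortho, taxa) {
  stopifnot(is(ortho, "OrthologySet"))
  og <- orthogroups(ortho)
  sp <- speciesOf(ortho)
  m <- matrix(0L, length(taxa), length(og),
              dimnames = list(taxa, names(og)))
  for (i in seq_along(og)) {
    present <- unique(sp[og[[i]]])
    m[intersect(present, taxa), i] <- 1L
  }
  filterObservable(presenceAbsenceMatrix(m))
}

#' Drop unobservable presence/absence columns
#'
#' Removes all-absent and singleton-presence gene families, the two classes
#' of characters that cannot enter a comparative presence/absence matrix and
#' that the corrected likelihood conditions away.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @return the filtered matrix, with attributes `droppedAbsent` and
#'   `droppedSingleton` on the contained matrix recording removal counts.
#' @export
filterObservable <- function(pam) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  m <- paMatrix(pam)
  cs <- colSums(m)
  nAbsent <- sum(cs == 0L)
  nSingle <- sum(cs == 1L)
  if (nAbsent + nSingle > 0)
    message(sprintf("dropped %d all-absent and %d singleton-presence families",
                    nAbsent, nSingle))
  m <- m[, cs >= 2L, drop = FALSE]
  out <- presenceAbsenceMatrix(m)
  attr(out@mat, "droppedAbsent") <- nAbsent
  attr(out@mat, "droppedSingleton") <- nSingle
  out
}
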