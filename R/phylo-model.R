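#' Transition probability matrix of the reversible two-state model
#'
#' Closed form for the gain/loss chain with stationary frequencies
#' (pi0, pi1) and rate normalised so branch length t is the expected number
#' of changes per character: P(t) = Pi + exp(-t / beta) (I - Pi), with
#' beta = 2 pi0 pi1 and Pi the matrix with rows (pi0, pi1).
#'
#' @param model a [BinaryModel-class].
#' @param t branch length (>= 0).
#' @return 2x2 stochastic matrix, states ordered (absent, present).
#' @examples
#' transitionMatrix(binaryModel(0.6), 0)      # identity
#' transitionMatrix(binaryModel(0.6), 1e6)    # rows -> (0.4, 0.6)
#' @export
transitionMatrix <- function(model, t) {
  stopifnot(is(model, "BinaryModel"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("branch length t must be a single value >= 0")
  pi1 <- model@pi1
  pi0 <- 1 - pi1
  beta <- 2 * pi0 * pi1
  e <- exp(-t / beta)
  P <- matrix(c(pi0 + e * pi1, pi1 - e * pi1,
                pi0 - e * pi0, pi1 + e * pi0),
              2L, 2L, byrow = TRUE,
              dimnames = list(c("0", "1"), c("0", "1")))
  P
}

# postorder edge arrays for the C++ pruning kernel
.treeArrays <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree needs branch lengths")
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, blen = po$edge.length,
       nTip = length(tree$tip.label), tips = tree$tip.label)
}

#' Probability of one leaf presence/absence pattern
#'
#' Felsenstein pruning under the reversible two-state model, with the root
#' weighted by the stationary frequencies; by reversibility (pulley
#' principle) the value does not depend on root placement.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param model a [BinaryModel-class].
#' @param pattern 0/1 vector; if named, names must be the tree's tip labels,
#'   otherwise it is taken in `tree$tip.label` order.
#' @return the pattern probability.
#' @examples
#' tr <- parseNewick("(A:0,B:0);")
#' patternLikelihood(tr, binaryModel(0.3), c(A = 1, B = 1))  # = 0.3
#' @export
patternLikelihood <- function(tree, model, pattern) {
  stopifnot(is(model, "BinaryModel"))
  ta <- .treeArrays(tree)
  if (!is.null(names(pattern))) {
    if (!setequal(names(pattern), ta$tips))
      stop("pattern names must match tree tips")
    pattern <- pattern[ta$tips]
  }
  if (length(pattern) != ta$nTip)
    stop("pattern length must equal the number of leaves")
  if (!all(pattern %in% c(0, 1))) stop("pattern must be 0/1")
  pm <- matrix(as.integer(pattern), 1L)
  exp(.patternLogProb(ta$edge, ta$blen, ta$nTip, model@pi1, pm))
}

#' Pattern counts of a presence/absence matrix
#'
#' Collapses the matrix columns (gene families) into unique leaf-state
#' patterns with multiplicities: the sufficient statistic for the likelihood.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @return list with `taxa`, `patterns` (unique patterns as a k x ntaxa 0/1
#'   matrix), and `counts` (integer multiplicities summing to the number of
#'   families).
#' @export
patternCounts <- function(pam) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  m <- paMatrix(pam)
  keys <- apply(m, 2L, paste, collapse = "")
  tab <- table(keys)
  pats <- do.call(rbind, lapply(strsplit(names(tab), ""), as.integer))
  colnames(pats) <- rownames(m)
  list(taxa = rownames(m), patterns = pats,
       counts = as.integer(tab))
}

.checkObservable <- function(counts) {
  rs <- rowSums(counts$patterns)
  if (any(rs == 0L))
    stop("counts contain an all-absent pattern; filter with filterObservable()")
  if (any(rs == 1L))
    stop("counts contain a singleton-presence pattern; filter with filterObservable()")
  invisible(counts)
}

# align pattern columns to a tree's tip order
.alignCounts <- function(counts, tips) {
  if (!setequal(counts$taxa, tips)) stop("taxa of counts and tree differ")
  counts$patterns <- counts$patterns[, tips, drop = FALSE]
  counts$taxa <- tips
  counts
}

#' Ascertainment-corrected log-likelihood
#'
#' Log-likelihood of observable presence/absence patterns, conditioning each
#' character on being observable at all: all-absent and singleton-presence
#' patterns can never enter a comparative matrix, so every pattern
#' probability is renormalised by
#' 1 - P(all absent) - sum over taxa of P(only that taxon present).
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param model a [BinaryModel-class].
#' @param counts pattern counts from [patternCounts()]; must contain only
#'   observable patterns.
#' @return the corrected log-likelihood (0 for 2 taxa, where (1,1) is the
#'   only observable pattern).
#' @export
correctedLogLik <- function(tree, model, counts) {
  stopifnot(is(model, "BinaryModel"))
  .checkObservable(counts)
  ta <- .treeArrays(tree)
  counts <- .alignCounts(counts, ta$tips)
  .correctedLogLik(ta$edge, ta$blen, ta$nTip, model@pi1,
                   counts$patterns, as.numeric(counts$counts))
}
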