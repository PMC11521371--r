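#' @useDynLib GenomeEvoKit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Binary gene presence/absence matrix
#'
#' An S4 container for a taxa-by-gene-family binary character matrix, the
#' substrate of gene-content phylogenetics. Rows are taxa, columns are gene
#' families (orthogroups); a cell is 1 if the taxon retains at least one
#' member of the family and 0 otherwise.
#'
#' @slot mat integer matrix of 0/1 with unique rownames (taxa) and unique
#'   colnames (family ids).
#' @seealso [presenceAbsenceMatrix()], [patternCounts()],
#'   [matrixFromOrthogroups()]
#' @export
setClass("PresenceAbsenceMatrix", representation(mat = "matrix"))

setValidity("PresenceAbsenceMatrix", function(object) {
  m <- object@mat
  if (!is.matrix(m) || !is.numeric(m))
    return("'mat' must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("matrix must carry taxon rownames and family colnames")
  if (anyDuplicated(rownames(m)))
    return("duplicate taxon labels")
  if (anyDuplicated(colnames(m)))
    return("duplicate family ids")
  if (!all(m %in% c(0L, 1L)))
    return("all cells must be exactly 0 or 1")
  TRUE
})

#' Construct a PresenceAbsenceMatrix
#'
#' @param mat numeric/integer matrix of 0 and 1 with taxon rownames and
#'   family colnames.
#' @return A [PresenceAbsenceMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 1, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("A", "B"), c("f1", "f2", "f3")))
#' presenceAbsenceMatrix(m)
#' @export
presenceAbsenceMatrix <- function(mat) {
  storage.mode(mat) <- "integer"
  new("PresenceAbsenceMatrix", mat = mat)
}

#' Time-reversible two-state gene content model
#'
#' The reversible (gain/loss) two-state continuous-time Markov model for
#' presence/absence characters, parameterised by the stationary presence
#' frequency `pi1` (absence frequency is `1 - pi1`). Rates are scaled so that
#' branch lengths are expected numbers of state changes per character.
#'
#' @slot pi1 numeric in (0, 1), stationary frequency of the "present" state.
#' @seealso [binaryModel()], [transitionMatrix()], [correctedLogLik()]
#' @export
setClass("BinaryModel", representation(pi1 = "numeric"))

setValidity("BinaryModel", function(object) {
  p <- object@pi1
  if (length(p) != 1L || !is.finite(p) || p <= 0 || p >= 1)
    return("'pi1' must be a single value strictly between 0 and 1")
  TRUE
})

#' Construct a BinaryModel
#'
#' @param pi1 stationary presence frequency, strictly in (0, 1).
#' @return A [BinaryModel-class] object.
#' @examples
#' binaryModel(0.6)
#' @export
binaryModel <- function(pi1) new("BinaryModel", pi1 = pi1)

#' Orthology relations across proteomes
#'
#' Holds reciprocal-best-hit (RBH) pairs, orthogroups (connected components
#' of the RBH graph; singleton genes are excluded from orthogroups but kept
#' in the species map), and the gene-to-species assignment.
#'
#' @slot rbhPairs data.frame with columns `gene_a`, `gene_b`; unordered pairs
#'   stored with `gene_a < gene_b` lexicographically.
#' @slot orthogroups named list of character vectors; names are orthogroup
#'   ids, elements are member gene ids.
#' @slot speciesOf named character vector mapping every gene id to its
#'   species.
#' @seealso [buildOrthogroups()], [matrixFromOrthogroups()]
#' @export
setClass("OrthologySet",
         representation(rbhPairs = "data.frame", orthogroups = "list",
                        speciesOf = "character"))

setValidity("OrthologySet", function(object) {
  p <- object@rbhPairs
  if (!all(c("gene_a", "gene_b") %in% names(p)))
    return("rbhPairs needs columns gene_a, gene_b")
  genes <- unlist(object@orthogroups, use.names = FALSE)
  if (anyDuplicated(genes))
    return("orthogroups must be pairwise disjoint")
  if (nrow(p) && !all(c(p$gene_a, p$gene_b) %in% names(object@speciesOf)))
    return("every RBH gene must appear in speciesOf")
  if (length(genes) && !all(genes %in% names(object@speciesOf)))
    return("every orthogroup member must appear in speciesOf")
  TRUE
})

#' Ancestral linkage group assignment of query chromosomes
#'
#' Result of testing every (query chromosome, reference ALG) pair for
#' enrichment of shared orthologs: the full test table, the significant
#' composition per query chromosome, and the histogram of composition sizes
#' (how many chromosomes derive from 1, 2, 3, ... ALGs).
#'
#' @slot table data.frame with columns `query_chrom`, `ref_alg`, `shared`,
#'   `p`, `p_adj`, `in_composition`.
#' @slot composition named list: query chromosome -> character vector of
#'   significantly enriched reference ALGs.
#' @slot alpha significance level used on BH-adjusted p-values.
#' @slot minShared minimum shared-ortholog count required for membership.
#' @seealso [classifyALGComposition()]
#' @export
setClass("ALGAssignment",
         representation(table = "data.frame", composition = "list",
                        alpha = "numeric", minShared = "numeric"))

#' @describeIn PresenceAbsenceMatrix-class number of taxa and families
#' @param x,object a `PresenceAbsenceMatrix`
#' @export
setMethod("dim", "PresenceAbsenceMatrix", function(x) dim(x@mat))

setMethod("show", "PresenceAbsenceMatrix", function(object) {
  cat(sprintf("PresenceAbsenceMatrix: %d taxa x %d families (%.1f%% present)\n",
              nrow(object@mat), ncol(object@mat), 100 * mean(object@mat)))
  invisible(object)
})

setMethod("show", "BinaryModel", function(object) {
  cat(sprintf("BinaryModel (reversible two-state): pi1 = %.4f\n", object@pi1))
  invisible(object)
})

setMethod("show", "OrthologySet", function(object) {
  cat(sprintf("OrthologySet: %d RBH pairs, %d orthogroups, %d genes in %d species\n",
              nrow(object@rbhPairs), length(object@orthogroups),
              length(object@speciesOf), length(unique(object@speciesOf))))
  invisible(object)
})

setMethod("show", "ALGAssignment", function(object) {
  h <- compositionSizes(object)
  cat(sprintf("ALGAssignment: %d query chromosomes (alpha = %g, min shared = %g)\n",
              length(object@composition), object@alpha, object@minShared))
  cat("  composition sizes:",
      paste(sprintf("%s ALG(s): %d", names(h), h), collapse = ", "), "\n")
  invisible(object)
})
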