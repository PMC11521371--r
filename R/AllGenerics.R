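#' Taxon labels of a container
#' @param x object carrying taxa
#' @return character vector of taxon labels.
#' @export
setGeneric("taxonNames", function(x) standardGeneric("taxonNames"))

#' Gene-family (orthogroup) identifiers of a container
#' @param x object carrying gene families
#' @return character vector of family ids.
#' @export
setGeneric("familyNames", function(x) standardGeneric("familyNames"))

#' Underlying binary matrix
#' @param x object wrapping a 0/1 matrix
#' @return integer matrix (taxa x families).
#' @export
setGeneric("paMatrix", function(x) standardGeneric("paMatrix"))

#' Reciprocal best hit pairs
#' @param x an orthology container
#' @return data.frame of unordered gene pairs.
#' @export
setGeneric("rbhPairs", function(x) standardGeneric("rbhPairs"))

#' Orthogroup membership
#' @param x an orthology container
#' @return named list of gene-id vectors.
#' @export
setGeneric("orthogroups", function(x) standardGeneric("orthogroups"))

#' Species assignment of genes
#' @param x an orthology container
#' @return named character vector gene -> species.
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))

#' Per-chromosome ALG composition
#' @param x an assignment object
#' @return named list: query chromosome -> enriched reference ALGs.
#' @export
setGeneric("composition", function(x) standardGeneric("composition"))

#' Histogram of ALG composition sizes
#'
#' Tabulates, over query chromosomes, how many derive from exactly 1, 2, 3,
#' ... reference ALGs (chromosomes with empty composition are tabulated
#' under "0").
#' @param x an assignment object
#' @return named integer vector, names are composition sizes.
#' @export
setGeneric("compositionSizes", function(x) standardGeneric("compositionSizes"))

#' @rdname taxonNames
#' @export
setMethod("taxonNames", "PresenceAbsenceMatrix", function(x) rownames(x@mat))

#' @rdname familyNames
#' @export
setMethod("familyNames", "PresenceAbsenceMatrix", function(x) colnames(x@mat))

#' @rdname paMatrix
#' @export
setMethod("paMatrix", "PresenceAbsenceMatrix", function(x) x@mat)

#' @rdname rbhPairs
#' @export
setMethod("rbhPairs", "OrthologySet", function(x) x@rbhPairs)

#' @rdname orthogroups
#' @export
setMethod("orthogroups", "OrthologySet", function(x) x@orthogroups)

#' @rdname speciesOf
#' @export
setMethod("speciesOf", "OrthologySet", function(x) x@speciesOf)

#' @rdname composition
#' @export
setMethod("composition", "ALGAssignment", function(x) x@composition)

#' @rdname compositionSizes
#' @export
setMethod("compositionSizes", "ALGAssignment", function(x) {
  sizes <- vapply(x@composition, length, integer(1))
  tab <- table(factor(sizes, levels = 0:max(c(sizes, 1))))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
})

#' Test table of an ALG assignment
#' @param x an [ALGAssignment-class]
#' @return the per-(chromosome, ALG) data.frame of shared counts and p-values.
#' @export
assignmentTable <- function(x) {
  stopifnot(is(x, "ALGAssignment"))
  x@table
}
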