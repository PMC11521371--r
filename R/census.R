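#' Ancestral (urbilaterian-style) gene-family census
#'
#' A family observed in at least one ingroup taxon AND at least one outgroup
#' taxon must (barring transfer and convergence) have existed in the
#' ingroup's last common ancestor. The census returns that ancestral family
#' set and, per ingroup taxon, how many ancestral families it retains --
#' missing ones must have been lost along that lineage.
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param ingroup,outgroup disjoint, non-empty character vectors of taxa.
#' @return list: `ancestralFamilies` (character vector), `retention` (named
#'   integer vector over ingroup taxa), `ingroupMean`.
#' @examples
#' m <- presenceAbsenceMatrix(matrix(c(1L,1L,0L, 1L,0L,1L, 1L,0L,0L), 3,
#'        byrow = TRUE, dimnames = list(c("in1","in2","out"),
#'                                      c("f1","f2","f3"))))
#' urbilaterianCensus(m, c("in1","in2"), "out")
#' @export
urbilaterianCensus <- function(pam, ingroup, outgroup) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  if (!length(ingroup) || !length(outgroup))
    stop("ingroup and outgroup must be non-empty")
  if (length(intersect(ingroup, outgroup)))
    stop("ingroup and outgroup overlap")
  m <- paMatrix(pam)
  miss <- setdiff(c(ingroup, outgroup), rownames(m))
  if (length(miss)) stop("taxon not in matrix: ", miss[[1L]])
  inAny <- colSums(m[ingroup, , drop = FALSE]) >= 1L
  outAny <- colSums(m[outgroup, , drop = FALSE]) >= 1L
  anc <- colnames(m)[inAny & outAny]
  retention <- vapply(ingroup, function(tx) sum(m[tx, anc]), numeric(1))
  list(ancestralFamilies = anc,
       retention = retention,
       ingroupMean = mean(retention))
}

#' Phylostratigraphic age of an orthogroup
#'
#' Assigns an orthogroup to the most recent common ancestor (on a reference
#' species tree) of the focal taxon and the most distantly related taxon
#' sharing the orthogroup; orthogroups confined to the focal taxon are
#' "species-specific".
#'
#' @param members character vector of taxa represented in the orthogroup;
#'   must include `focal`.
#' @param refTree an [ape::phylo] reference tree whose tips cover `members`;
#'   internal node labels, if absent, are generated as `node<k>`.
#' @param focal the focal taxon.
#' @return the node label of the assigned stratum, or "species-specific".
#' @export
assignPhylostratum <- function(members, refTree, focal) {
  if (!length(members)) stop("orthogroup composition is empty")
  if (!focal %in% members) stop("focal taxon not in the orthogroup")
  miss <- setdiff(members, refTree$tip.label)
  if (length(miss)) stop("taxon not in reference tree: ", miss[[1L]])
  if (is.null(refTree$node.label))
    refTree$node.label <- sprintf("node%d", seq_len(refTree$Nnode))
  others <- setdiff(members, focal)
  if (!length(others)) return("species-specific")
  nTip <- length(refTree$tip.label)
  depth <- .nodeDepths(refTree)
  best <- NULL
  for (tx in others) {
    mrca <- ape::getMRCA(refTree, c(focal, tx))
    if (is.null(best) || depth[mrca] < depth[best]) best <- mrca
  }
  refTree$node.label[best - nTip]
}

# node depths: edges from the root
.nodeDepths <- function(tree) {
  nTip <- length(tree$tip.label)
  depth <- integer(nTip + tree$Nnode)
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(edges)))
    depth[edges[i, 2L]] <- depth[edges[i, 1L]] + 1L
  depth
}
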