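#' Study-condition presets for the simulator
#'
#' Bundles the default conditions under which the pipeline is exercised and
#' validated.
#'
#' `"bilaterian"` emulates a gene-content study of 8 ingroup plus 2 outgroup
#' taxa: families gained at the root, lost at 0.15 per branch, with one
#' deeply nested ingroup lineage (taxon A, an acoel-like fast loser) losing
#' at 5x that rate; 2000 families; protein substitution probability 0.05 per
#' site per branch. The karyotype component has 24 ancestral linkage groups
#' of 40 genes, derived into 18 chromosomes by the rearrangement history of
#' [xenoturbellaKaryotypeHistory()] with within-chromosome shuffle 0.2. The
#' precursor component plants 20 positives among 80 backgrounds.
#'
#' `"compact"` is the same design at reduced size (6 taxa: 4 ingroup + 2
#' outgroup, exhaustive-searchable; 2000 families) used for topology-recovery
#' and fast-loser-artifact experiments.
#'
#' @param name preset name.
#' @return list of simulator settings; `treeNewick` fixes the true topology
#'   (branch lengths are drawn at simulation time), `fastTaxon` and
#'   `fastLossProb` define the fast-losing lineage.
#' @export
simulationPreset <- function(name = c("bilaterian", "compact")) {
  name <- match.arg(name)
  base <- list(
    lossProb = 0.15,
    fastMultiplier = 5,
    rootPresenceProb = 1,
    nFamilies = 2000L,
    substitutionProb = 0.05,
    nAlg = 24L,
    genesPerAlg = 40L,
    karyotype = xenoturbellaKaryotypeHistory(),
    shuffleFrac = 0.2,
    precursorCount = 20L,
    backgroundCount = 80L,
    blRange = c(0.05, 0.3)
  )
  if (name == "bilaterian") {
    base$treeNewick <- "((((((((A,B),C),D),E),F),G),H),(O1,O2));"
    base$fastTaxon <- "A"
  } else {
    base$treeNewick <- "((((A,B),C),D),(O1,O2));"
    base$fastTaxon <- "A"
  }
  base$fastLossProb <- min(base$fastMultiplier * base$lossProb, 1)
  base
}

#' Simulate gene content under a preset
#'
#' Draws branch lengths, runs gene gain/loss (optionally with the preset's
#' fast-losing lineage), and filters the matrix to observable families.
#'
#' @param preset list from [simulationPreset()].
#' @param fastLoss apply the preset's 5x loss rate to the fast taxon?
#' @param nFamilies override for the number of families.
#' @return list: `tree` (true tree with drawn branch lengths), `pam`
#'   (observable presence/absence matrix), `raw` (unfiltered simulation
#'   output of [evolveGeneContent()]).
#' @export
simulatePresetContent <- function(preset = simulationPreset(),
                                  fastLoss = FALSE, nFamilies = NULL) {
  tree <- parseNewick(preset$treeNewick)
  tree$edge.length <- stats::runif(nrow(tree$edge), preset$blRange[1L],
                                   preset$blRange[2L])
  overrides <- NULL
  if (fastLoss)
    overrides <- stats::setNames(preset$fastLossProb, preset$fastTaxon)
  raw <- evolveGeneContent(
    tree,
    nFamilies = if (is.null(nFamilies)) preset$nFamilies else nFamilies,
    rootPresenceProb = preset$rootPresenceProb,
    lossProb = preset$lossProb,
    lossOverrides = overrides
  )
  pam <- suppressMessages(filterObservable(raw$pam))
  list(tree = tree, pam = pam, raw = raw)
}

#' Rootward displacement of a taxon's attachment point
#'
#' Roots both trees with the given outgroup and compares the depth (edges
#' from the root) of the node where `taxon` attaches. A negative value means
#' the taxon attaches closer to the root than in the reference tree -- the
#' signature artifact of a fast-losing lineage being pulled towards the
#' outgroup.
#'
#' @param tree estimated tree (rooted or unrooted).
#' @param refTree true tree.
#' @param taxon the focal tip.
#' @param outgroup tips used to root both trees.
#' @return integer: estimated depth minus true depth.
#' @export
attachmentDepthShift <- function(tree, refTree, taxon, outgroup) {
  depthOf <- function(tr) {
    tr <- ape::unroot(tr)
    rooted <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    nTip <- length(rooted$tip.label)
    d <- .nodeDepths(rooted)
    tipIdx <- match(taxon, rooted$tip.label)
    parent <- rooted$edge[rooted$edge[, 2L] == tipIdx, 1L]
    d[parent]
  }
  depthOf(tree) - depthOf(refTree)
}
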