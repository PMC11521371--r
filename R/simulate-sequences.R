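#' Simulate divergent protein sequences along a tree
#'
#' One root protein per family (length uniform in `lengthRange`, residues
#' i.i.d. uniform over the 20 amino acids) evolves along every edge: each
#' site substitutes to a uniformly chosen *different* residue with
#' probability `substitutionProb` per branch. A species' proteome contains
#' exactly the families present in its row of the presence matrix, with ids
#' `<species>_<family>`.
#'
#' @param tree an [ape::phylo] tree.
#' @param pam a [PresenceAbsenceMatrix-class] over the tree's tips (typically
#'   from [evolveGeneContent()]).
#' @param substitutionProb per-site, per-branch substitution probability.
#' @param lengthRange integer range for root protein lengths.
#' @return named list of per-species named character vectors (FASTA-ready,
#'   see [writeFasta()]).
#' @examples
#' set.seed(1)
#' tr <- simulateTree(3, "caterpillar")
#' sim <- evolveGeneContent(tr, 5, lossProb = 0)
#' prot <- evolveSequences(tr, sim$pam, substitutionProb = 0.02)
#' names(prot)
#' @export
evolveSequences <- function(tree, pam, substitutionProb = 0.05,
                            lengthRange = c(120L, 400L)) {
  stopifnot(inherits(tree, "phylo"), is(pam, "PresenceAbsenceMatrix"))
  .checkProb(substitutionProb, "substitutionProb")
  m <- paMatrix(pam)
  if (!setequal(rownames(m), tree$tip.label))
    stop("matrix taxa must match tree tips")
  fams <- colnames(m)
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  edges <- ape::reorder.phylo(tree, "cladewise")$edge
  lenVals <- seq.int(lengthRange[1L], lengthRange[2L])
  # index into the candidate vector: sample(x) on a length-1 x would
  # misbehave as sample.int(x)
  lens <- lenVals[sample.int(length(lenVals), length(fams), replace = TRUE)]
  # per family: integer site matrix over nodes, root down
  out <- lapply(tree$tip.label, function(sp) character(0))
  names(out) <- tree$tip.label
  root <- nTip + 1L
  for (f in seq_along(fams)) {
    L <- lens[f]
    seqs <- matrix(0L, nNode, L)
    seqs[root, ] <- sample.int(20L, L, replace = TRUE)
    for (i in seq_len(nrow(edges))) {
      p <- edges[i, 1L]; ch <- edges[i, 2L]
      s <- seqs[p, ]
      hit <- which(stats::runif(L) < substitutionProb)
      if (length(hit)) {
        # uniform over the 19 other residues
        shift <- sample.int(19L, length(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1L + shift) %% 20L) + 1L
      }
      seqs[ch, ] <- s
    }
    for (ti in seq_len(nTip)) {
      sp <- tree$tip.label[ti]
      if (m[sp, f] == 1L) {
        nm <- paste0(sp, "_", fams[f])
        out[[sp]][nm] <- paste(AA_ALPHABET20[seqs[ti, ]], collapse = "")
      }
    }
  }
  out
}
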