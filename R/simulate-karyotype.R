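#' Simulate ALG-structured karyotypes
#'
#' Builds a reference species that keeps one chromosome per ancestral linkage
#' group (ALG) with genes in ALG order, and a derived species whose karyotype
#' applies a rearrangement history: fusions (member ALGs concatenated onto one
#' chromosome) and optional fissions (one ALG split into two chromosomes,
#' each still deriving from that single ALG). A within-chromosome shuffle
#' fraction then permutes that fraction of gene positions on every derived
#' chromosome. Gene positions are 0-based ordinals.
#'
#' @param nAlg number of ancestral linkage groups (default 24, the number of
#'   ancestral bilaterian linkage units).
#' @param genesPerAlg genes per ALG.
#' @param fusions list of character vectors of ALG ids fused (in order) onto
#'   a single derived chromosome; sets must be disjoint.
#' @param fissions character vector of ALG ids each split into two derived
#'   chromosomes (first half / second half); disjoint from `fusions`.
#' @param shuffleFrac fraction (0..1) of gene positions randomly permuted
#'   within each derived chromosome.
#' @param refSpecies,derivedSpecies species names used in ids and maps.
#' @return list with `refMap` and `derivedMap` (chromosome-map data.frames,
#'   see [chromosomeMap()]), and `truth`: `algOfGene` (named by base gene
#'   id), `derivedComposition` (chromosome -> ALG id set), `truePairs`
#'   (data.frame of cross-species ortholog ids), `baseIds`.
#' @examples
#' set.seed(1)
#' k <- simulateKaryotype(nAlg = 4, genesPerAlg = 5,
#'                        fusions = list(c("ALG01", "ALG02")))
#' length(unique(k$derivedMap$chromosome))  # 3 chromosomes
#' @export
simulateKaryotype <- function(nAlg = 24L, genesPerAlg = 40L,
                              fusions = list(), fissions = character(0),
                              shuffleFrac = 0,
                              refSpecies = "ref", derivedSpecies = "qry") {
  if (nAlg < 1) stop("nAlg must be >= 1")
  .checkProb(shuffleFrac, "shuffleFrac")
  algIds <- sprintf("ALG%02d", seq_len(nAlg))
  inFusion <- unlist(fusions, use.names = FALSE)
  unknown <- setdiff(c(inFusion, fissions), algIds)
  if (length(unknown)) stop("fusion/fission references unknown ALG: ",
                            unknown[[1L]])
  if (anyDuplicated(c(inFusion, fissions)))
    stop("fusion/fission ALG sets must be disjoint")

  nGenes <- nAlg * genesPerAlg
  baseIds <- sprintf("g%04d", seq_len(nGenes))
  algOfGene <- rep(algIds, each = genesPerAlg)
  names(algOfGene) <- baseIds
  genesByAlg <- split(baseIds, algOfGene)[algIds]

  refMap <- data.frame(
    gene_id = paste0(refSpecies, "_", baseIds),
    species = refSpecies,
    chromosome = algOfGene,
    position_index = rep(seq_len(genesPerAlg) - 1L, times = nAlg),
    stringsAsFactors = FALSE
  )

  # derived chromosomes: untouched ALGs, fission halves, fused blocks
  blocks <- list()     # chromosome gene vectors, in order
  compo <- list()      # chromosome -> ALG set
  for (alg in setdiff(algIds, c(inFusion, fissions))) {
    blocks[[length(blocks) + 1L]] <- genesByAlg[[alg]]
    compo[[length(compo) + 1L]] <- alg
  }
  for (alg in fissions) {
    g <- genesByAlg[[alg]]
    half <- ceiling(length(g) / 2)
    blocks[[length(blocks) + 1L]] <- g[seq_len(half)]
    compo[[length(compo) + 1L]] <- alg
    blocks[[length(blocks) + 1L]] <- g[seq.int(half + 1L, length(g))]
    compo[[length(compo) + 1L]] <- alg
  }
  for (fu in fusions) {
    blocks[[length(blocks) + 1L]] <- unlist(genesByAlg[fu], use.names = FALSE)
    compo[[length(compo) + 1L]] <- fu
  }
  chromNames <- sprintf("chr%02d", seq_along(blocks))
  names(compo) <- chromNames

  derRows <- lapply(seq_along(blocks), function(i) {
    g <- blocks[[i]]
    pos <- seq_along(g) - 1L
    if (shuffleFrac > 0 && length(g) > 1L) {
      k <- round(shuffleFrac * length(g))
      if (k >= 2L) {
        sel <- sample(seq_along(g), k)
        pos[sel] <- pos[sample(sel)]
      }
    }
    data.frame(gene_id = paste0(derivedSpecies, "_", g),
               species = derivedSpecies,
               chromosome = chromNames[i],
               position_index = pos,
               stringsAsFactors = FALSE)
  })
  derivedMap <- do.call(rbind, derRows)

  truePairs <- data.frame(
    gene_a = paste0(refSpecies, "_", baseIds),
    gene_b = paste0(derivedSpecies, "_", baseIds),
    stringsAsFactors = FALSE
  )
  list(refMap = chromosomeMap(refMap),
       derivedMap = chromosomeMap(derivedMap),
       truth = list(algOfGene = algOfGene, derivedComposition = compo,
                    truePairs = truePairs, baseIds = baseIds))
}

#' Simulate a full two-species macrosynteny scenario
#'
#' Couples [simulateKaryotype()] with sequence evolution: every gene gets a
#' root protein that diverges independently along the two terminal branches
#' with `substitutionProb` per site per branch, giving proteomes on which
#' reciprocal-best-hit orthology is non-trivial but recoverable.
#'
#' @inheritParams simulateKaryotype
#' @param substitutionProb per-site, per-branch substitution probability.
#' @param lengthRange root protein length range.
#' @return as [simulateKaryotype()], plus `proteomes`: named list of two
#'   named character vectors (reference and derived proteome).
#' @export
simulateSynteny <- function(nAlg = 24L, genesPerAlg = 40L,
                            fusions = list(), fissions = character(0),
                            shuffleFrac = 0, substitutionProb = 0.05,
                            lengthRange = c(120L, 400L),
                            refSpecies = "ref", derivedSpecies = "qry") {
  k <- simulateKaryotype(nAlg, genesPerAlg, fusions, fissions, shuffleFrac,
                         refSpecies, derivedSpecies)
  nGenes <- length(k$truth$baseIds)
  m <- matrix(1L, 2L, nGenes,
              dimnames = list(c(refSpecies, derivedSpecies), k$truth$baseIds))
  tr <- ape::read.tree(text = sprintf("(%s:1,%s:1);", refSpecies,
                                      derivedSpecies))
  prot <- evolveSequences(tr, presenceAbsenceMatrix(m),
                          substitutionProb = substitutionProb,
                          lengthRange = lengthRange)
  k$proteomes <- prot
  k
}

#' The fusion/fission history of the focal xenoturbellid karyotype scenario
#'
#' Rearrangement preset deriving an 18-chromosome karyotype from 24 ALGs:
#' 10 ALGs stay whole, one ALG is split over two chromosomes (so 12
#' chromosomes derive from a single ALG), 5 chromosomes are pairwise fusions
#' and 1 chromosome is a triple fusion, i.e. a composition-size histogram of
#' 12/5/1.
#'
#' @return list with elements `fusions` (list of ALG-id vectors) and
#'   `fissions` (character vector).
#' @export
xenoturbellaKaryotypeHistory <- function() {
  list(
    fusions = list(c("ALG12", "ALG13"), c("ALG14", "ALG15"),
                   c("ALG16", "ALG17"), c("ALG18", "ALG19"),
                   c("ALG20", "ALG21"), c("ALG22", "ALG23", "ALG24")),
    fissions = "ALG11"
  )
}
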