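#' Search tree topologies under the corrected likelihood
#'
#' Exhaustive mode evaluates every unrooted binary topology (feasible up to 7
#' taxa: 105 trees for 6 taxa, 945 for 7) and returns the maximum-likelihood
#' tree, ties broken by the lexicographically smallest canonical Newick
#' string. NNI mode hill-climbs by nearest-neighbour interchanges from a
#' neighbour-joining start on pattern-mismatch distances, with optional
#' random restarts; the result never has lower likelihood than its start.
#'
#' @param counts pattern counts from [patternCounts()].
#' @param mode `"exhaustive"` or `"nni"`.
#' @param relTol per-topology fit tolerance (see [fitBinaryModel()]).
#' @param restarts extra random NNI starts (nni mode).
#' @param maxSweeps per-fit sweep cap.
#' @return list: `tree` (fitted), `model`, `loglik`, `evaluated` (number of
#'   topologies fitted), `startLoglik` (nni mode).
#' @export
searchTopology <- function(counts, mode = c("exhaustive", "nni"),
                           relTol = 1e-6, restarts = 0L, maxSweeps = 60L) {
  mode <- match.arg(mode)
  taxa <- counts$taxa
  n <- length(taxa)
  if (mode == "exhaustive") {
    if (n > 7L) stop("exhaustive search supports at most 7 taxa")
    topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = taxa)
    best <- NULL
    for (k in seq_along(topos)) {
      # index via [[ so compressed multiPhylo tip labels are restored;
      # screening fits may hit the sweep cap, which is fine for ranking
      fit <- suppressWarnings(fitBinaryModel(topos[[k]], counts,
                                             relTol = relTol,
                                             maxSweeps = maxSweeps))
      fit$canon <- canonicalTopology(fit$tree)
      if (is.null(best) || fit$loglik > best$loglik + 1e-12 ||
          (abs(fit$loglik - best$loglik) <= 1e-12 && fit$canon < best$canon))
        best <- fit
    }
    # clean refit of the winning topology at a tight tolerance
    refit <- fitBinaryModel(best$tree, counts, relTol = 1e-8,
                            maxSweeps = 2000L)
    refit$canon <- best$canon
    refit$evaluated <- length(topos)
    return(refit)
  }
  # NNI hill climb
  starts <- list(.njStart(counts))
  if (restarts > 0L)
    for (i in seq_len(restarts))
      starts[[i + 1L]] <- ape::rtopology(n, rooted = FALSE, tip.label = taxa)
  best <- NULL
  evaluated <- 0L
  for (start in starts) {
    cur <- suppressWarnings(fitBinaryModel(start, counts, relTol = relTol,
                                           maxSweeps = maxSweeps))
    startLL <- cur$loglik
    evaluated <- evaluated + 1L
    repeat {
      nb <- .nniNeighbors(cur$tree)
      improved <- FALSE
      for (tr in nb) {
        fit <- suppressWarnings(fitBinaryModel(tr, counts, relTol = relTol,
                                               maxSweeps = maxSweeps))
        evaluated <- evaluated + 1L
        if (fit$loglik > cur$loglik + 1e-9) {
          cur <- fit
          improved <- TRUE
          break
        }
      }
      if (!improved) break
    }
    cur$startLoglik <- startLL
    if (is.null(best) || cur$loglik > best$loglik) best <- cur
  }
  refit <- fitBinaryModel(best$tree, counts, relTol = 1e-8, maxSweeps = 2000L)
  refit$startLoglik <- best$startLoglik
  refit$canon <- canonicalTopology(refit$tree)
  refit$evaluated <- evaluated
  refit
}

# neighbour-joining start on weighted pattern-mismatch distances
.njStart <- function(counts) {
  taxa <- counts$taxa
  n <- length(taxa)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  tot <- sum(counts$counts)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    mis <- sum(counts$counts *
                 (counts$patterns[, i] != counts$patterns[, j])) / tot
    d[i, j] <- d[j, i] <- mis
  }
  ape::unroot(ape::nj(stats::as.dist(d)))
}

# all distinct unrooted NNI neighbours of a binary tree
.nniNeighbors <- function(tree) {
  nb <- list()
  seen <- character(0)
  nTip <- length(tree$tip.label)
  intEdges <- which(tree$edge[, 2L] > nTip)
  for (i in intEdges) {
    u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    vKids <- which(tree$edge[, 1L] == v)
    uKids <- setdiff(which(tree$edge[, 1L] == u), i)
    for (a in vKids) for (b in uKids) {
      tr <- .swapSubtrees(tree, a, b)
      key <- canonicalTopology(tr)
      if (!key %in% seen) {
        seen <- c(seen, key)
        nb[[length(nb) + 1L]] <- tr
      }
    }
  }
  nb
}

# exchange the subtrees hanging off edge rows a and b
.swapSubtrees <- function(tree, a, b) {
  tr <- tree
  ca <- tr$edge[a, 2L]
  tr$edge[a, 2L] <- tr$edge[b, 2L]
  tr$edge[b, 2L] <- ca
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

# one uniformly chosen random NNI move (used as the MCMC topology proposal)
.randomNNI <- function(tree) {
  nTip <- length(tree$tip.label)
  intEdges <- which(tree$edge[, 2L] > nTip)
  i <- intEdges[sample.int(length(intEdges), 1L)]
  u <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
  vKids <- which(tree$edge[, 1L] == v)
  uKids <- setdiff(which(tree$edge[, 1L] == u), i)
  a <- vKids[sample.int(length(vKids), 1L)]
  b <- uKids[sample.int(length(uKids), 1L)]
  .swapSubtrees(tree, a, b)
}
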