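#' MCMC over trees, branch lengths and pi1
#'
#' Exploratory Metropolis-Hastings sampler under the corrected likelihood
#' with flat priors: topology moves by random nearest-neighbour interchange,
#' branch lengths by multiplicative proposals (Hastings ratio b'/b), pi1 by a
#' reflected uniform window. Intended for consensus summaries and run
#' comparison, not as a replica of any particular Bayesian implementation.
#'
#' @param counts pattern counts from [patternCounts()].
#' @param iterations number of MCMC iterations.
#' @param sampleEvery thinning interval for stored trees.
#' @param startTree optional starting topology (default: NJ start).
#' @param blWindow multiplicative branch proposal scale.
#' @param piWindow reflected-window half-width for pi1.
#' @param maxBl branch length bound.
#' @return list: `trees` (multiPhylo of thinned samples), `pi1` and `loglik`
#'   traces (thinned), `acceptance` (per move type), `warnings`.
#' @export
mcmcTrees <- function(counts, iterations = 5000L, sampleEvery = 10L,
                      startTree = NULL, blWindow = 0.5, piWindow = 0.05,
                      maxBl = 20) {
  if (iterations < sampleEvery) stop("iterations must exceed sampleEvery")
  tree <- if (is.null(startTree)) .njStart(counts) else startTree
  tree$edge.length <- rep(0.1, nrow(tree$edge))
  ta <- .treeArrays(tree)
  counts <- .alignCounts(counts, ta$tips)
  pi1 <- min(max(sum(counts$patterns * counts$counts) /
                   (ncol(counts$patterns) * sum(counts$counts)), 0.01), 0.99)
  ll <- function(tr, p) {
    a <- .treeArrays(tr)
    .correctedLogLik(a$edge, a$blen, a$nTip, p, counts$patterns,
                     as.numeric(counts$counts))
  }
  cur <- ll(tree, pi1)
  trees <- vector("list", iterations %/% sampleEvery)
  piTrace <- numeric(length(trees))
  llTrace <- numeric(length(trees))
  acc <- c(topology = 0, blen = 0, pi1 = 0)
  tries <- c(topology = 0, blen = 0, pi1 = 0)
  accWindow <- 0L
  k <- 0L
  for (it in seq_len(iterations)) {
    move <- sample(c("topology", "blen", "pi1"), 1L,
                   prob = c(0.3, 0.5, 0.2))
    tries[move] <- tries[move] + 1L
    if (move == "topology") {
      cand <- .randomNNI(tree)
      newLL <- ll(cand, pi1)
      if (log(stats::runif(1)) < newLL - cur) {
        tree <- cand; cur <- newLL
        acc[move] <- acc[move] + 1L; accWindow <- accWindow + 1L
      }
    } else if (move == "blen") {
      i <- sample.int(nrow(tree$edge), 1L)
      old <- tree$edge.length[i]
      prop <- old * exp(blWindow * (stats::runif(1) - 0.5))
      if (prop <= maxBl) {
        cand <- tree
        cand$edge.length[i] <- prop
        newLL <- ll(cand, pi1)
        # multiplicative proposal: Hastings ratio prop/old
        if (log(stats::runif(1)) < newLL - cur + log(prop / old)) {
          tree <- cand; cur <- newLL
          acc[move] <- acc[move] + 1L; accWindow <- accWindow + 1L
        }
      }
    } else {
      prop <- pi1 + piWindow * (2 * stats::runif(1) - 1)
      if (prop <= 0) prop <- -prop          # reflect at 0
      if (prop >= 1) prop <- 2 - prop       # reflect at 1
      newLL <- ll(tree, prop)
      if (log(stats::runif(1)) < newLL - cur) {
        pi1 <- prop; cur <- newLL
        acc[move] <- acc[move] + 1L; accWindow <- accWindow + 1L
      }
    }
    if (it %% sampleEvery == 0L) {
      k <- k + 1L
      trees[[k]] <- tree
      piTrace[k] <- pi1
      llTrace[k] <- cur
    }
    if (it %% 1000L == 0L) {
      if (accWindow == 0L)
        warning("zero acceptance over the last 1000 iterations")
      accWindow <- 0L
    }
  }
  class(trees) <- "multiPhylo"
  list(trees = trees, pi1 = piTrace, loglik = llTrace,
       acceptance = ifelse(tries > 0, acc / tries, NA))
}

#' Majority-rule consensus of sampled trees
#'
#' Strict >50% majority rule over post-burnin samples: the consensus contains
#' exactly the clades appearing in more than half of the samples (which are
#' mutually compatible by construction).
#'
#' @param trees a `multiPhylo` sample.
#' @param burnin fraction of initial samples discarded.
#' @return an [ape::phylo] consensus tree (topology only).
#' @export
majorityConsensus <- function(trees, burnin = 0.25) {
  stopifnot(inherits(trees, "multiPhylo") || is.list(trees))
  n <- length(trees)
  keep <- trees[seq.int(floor(burnin * n) + 1L, n)]
  class(keep) <- "multiPhylo"
  # p slightly above 0.5 so clades at exactly 50% are excluded
  ape::consensus(keep, p = 0.5000001)
}

#' Clade (split) frequencies of a tree sample
#'
#' Frequencies of non-trivial bipartitions, keyed by the sorted tip labels of
#' the side not containing the alphabetically first tip.
#'
#' @param trees a list/multiPhylo of trees over the same tips.
#' @param burnin fraction of initial samples discarded.
#' @return named numeric vector of frequencies in (0, 1].
#' @export
cladeFrequencies <- function(trees, burnin = 0) {
  n <- length(trees)
  keep <- trees[seq.int(floor(burnin * n) + 1L, n)]
  ref <- sort(keep[[1L]]$tip.label)[1L]
  tab <- new.env()
  for (tr in keep) {
    for (key in .splitKeys(tr, ref)) {
      cnt <- get0(key, envir = tab, ifnotfound = 0)
      assign(key, cnt + 1, envir = tab)
    }
  }
  keys <- ls(tab)
  out <- vapply(keys, get, numeric(1), envir = tab) / length(keep)
  out
}

# non-trivial splits of an unrooted tree as canonical keys
.splitKeys <- function(tree, refTip) {
  tr <- ape::unroot(tree)
  nTip <- length(tr$tip.label)
  tips <- tr$tip.label
  keys <- character(0)
  desc <- .descendantTips(tr)
  for (i in which(tr$edge[, 2L] > nTip)) {
    side <- desc[[tr$edge[i, 2L]]]
    if (refTip %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= nTip - 2L)
      keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

.descendantTips <- function(tree) {
  nTip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  out <- vector("list", nTip + tree$Nnode)
  for (i in seq_len(nTip)) out[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Compare clade frequencies between two MCMC runs
#'
#' The convergence diagnostic used with independent runs: the maximum
#' absolute difference in clade frequency over all splits observed in either
#' run.
#'
#' @param run1,run2 results of [mcmcTrees()] (or plain tree lists).
#' @param burnin fraction discarded from each run.
#' @return list: `maxDiscrepancy`, `frequencies` (two-column matrix).
#' @export
compareRuns <- function(run1, run2, burnin = 0.25) {
  t1 <- if (is.list(run1) && !is.null(run1$trees)) run1$trees else run1
  t2 <- if (is.list(run2) && !is.null(run2$trees)) run2$trees else run2
  f1 <- cladeFrequencies(t1, burnin)
  f2 <- cladeFrequencies(t2, burnin)
  keys <- union(names(f1), names(f2))
  m <- cbind(run1 = ifelse(keys %in% names(f1), f1[keys], 0),
             run2 = ifelse(keys %in% names(f2), f2[keys], 0))
  rownames(m) <- keys
  list(maxDiscrepancy = if (length(keys)) max(abs(m[, 1] - m[, 2])) else 0,
       frequencies = m)
}
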