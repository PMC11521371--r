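# Independent pure-R oracles. Each deliberately uses a different algorithm
# from the package implementation it checks.

# ---- Smith-Waterman with affine gaps: full three-matrix DP ----------------
oracleSW <- function(a, b, match = 2, mismatch = -1, open = 5, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in a (consuming b)
  F <- matrix(NEG, n + 1, m + 1)  # gap in b (consuming a)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(E[i + 1, j] - ext, H[i + 1, j] - open - ext)
    F[i + 1, j + 1] <- max(F[i, j + 1] - ext, H[i, j + 1] - open - ext)
    s <- H[i, j] + if (A[i] == B[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, s, E[i + 1, j + 1], F[i + 1, j + 1])
    best <- max(best, H[i + 1, j + 1])
  }
  as.integer(best)
}

# ---- pattern probability by exhaustive internal-state enumeration ---------
oracleTransMat <- function(t, pi1) {
  pi0 <- 1 - pi1
  beta <- 2 * pi0 * pi1
  e <- exp(-t / beta)
  matrix(c(pi0 + e * pi1, pi1 - e * pi1,
           pi0 - e * pi0, pi1 + e * pi0), 2, 2, byrow = TRUE)
}

# pattern: named 0/1 vector over tips of `tree`
oraclePatternProb <- function(tree, pi1, pattern) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  internal <- (nTip + 1):nNode
  edges <- tree$edge
  Ps <- lapply(seq_len(nrow(edges)),
               function(i) oracleTransMat(tree$edge.length[i], pi1))
  states <- rep(NA_integer_, nNode)
  states[seq_len(nTip)] <- pattern[tree$tip.label]
  total <- 0
  combos <- expand.grid(rep(list(0:1), length(internal)))
  for (r in seq_len(nrow(combos))) {
    states[internal] <- as.integer(combos[r, ])
    pr <- if (states[nTip + 1] == 1) pi1 else 1 - pi1  # root prior
    for (i in seq_len(nrow(edges)))
      pr <- pr * Ps[[i]][states[edges[i, 1]] + 1, states[edges[i, 2]] + 1]
    total <- total + pr
  }
  total
}

oracleCorrectedLogLik <- function(tree, pi1, patterns, counts) {
  n <- ncol(patterns)
  tips <- tree$tip.label
  lp <- apply(patterns, 1, function(p)
    log(oraclePatternProb(tree, pi1, stats::setNames(p, colnames(patterns)))))
  bad <- oraclePatternProb(tree, pi1, stats::setNames(rep(0L, n), tips))
  for (i in seq_len(n)) {
    s <- rep(0L, n); s[i] <- 1L
    bad <- bad + oraclePatternProb(tree, pi1, stats::setNames(s, tips))
  }
  sum(counts * lp) - sum(counts) * log(1 - bad)
}

# ---- hypergeometric upper tail by explicit enumeration --------------------
oracleHyperTail <- function(x, rowTotal, colTotal, total) {
  if (x == 0) return(1)
  ks <- x:min(rowTotal, colTotal)
  sum(exp(lchoose(rowTotal, ks) + lchoose(total - rowTotal, colTotal - ks) -
            lchoose(total, colTotal)))
}

# ---- union-find for orthogroup components ---------------------------------
oracleComponents <- function(pairs) {
  ids <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs$gene_a[k]); rb <- find(pairs$gene_b[k])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(ids, find, character(1))
  comps <- split(ids, roots)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[[`, character(1), 1L))]
  names(comps) <- NULL
  comps
}

# ---- scanner: recursive block-decomposition existence oracle ---------------
# blocks: list of elements "RR", c("x", min, max), "G", "Z"
oracleBlocks <- function(patternId) {
  RR <- "RR"; G <- "G"; Z <- "Z"
  sp <- function(lo, hi) list("x", lo, hi)
  switch(patternId,
    P1 = list(RR, sp(3, 36), RR, sp(3, 36), RR, sp(3, 36), RR),
    P2 = list(RR, sp(2, 35), Z, RR, sp(2, 35), Z, RR),
    P3 = list(RR, sp(2, 35), G, RR, sp(2, 35), G, RR),
    P4 = list(RR, sp(1, 34), Z, G, RR, sp(1, 34), Z, G, RR),
    stop("unknown pattern ", patternId))
}

# does blocks[k..] match s starting exactly at pos (1-based), with Z bound to
# zc (NA if unbound)? memoised on (pos, k, zc)
oracleMatchFrom <- function(chars, pos, blocks, k, zc, memo) {
  if (k > length(blocks)) return(TRUE)
  key <- paste(pos, k, ifelse(is.na(zc), "-", zc))
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  n <- length(chars)
  b <- blocks[[k]]
  res <- FALSE
  if (identical(b, "RR")) {
    if (pos + 1 <= n && chars[pos] %in% c("K", "R") &&
        chars[pos + 1] %in% c("K", "R"))
      res <- oracleMatchFrom(chars, pos + 2, blocks, k + 1, zc, memo)
  } else if (identical(b, "G")) {
    if (pos <= n && chars[pos] == "G")
      res <- oracleMatchFrom(chars, pos + 1, blocks, k + 1, zc, memo)
  } else if (identical(b, "Z")) {
    if (pos <= n) {
      if (is.na(zc)) {
        res <- oracleMatchFrom(chars, pos + 1, blocks, k + 1, chars[pos], memo)
      } else if (chars[pos] == zc) {
        res <- oracleMatchFrom(chars, pos + 1, blocks, k + 1, zc, memo)
      }
    }
  } else {  # spacer
    for (len in b[[2]]:b[[3]]) {
      if (pos + len - 1 > n) break
      if (oracleMatchFrom(chars, pos + len, blocks, k + 1, zc, memo)) {
        res <- TRUE
        break
      }
    }
  }
  memo[[key]] <- res
  res
}

oracleScan <- function(seq, patternId) {
  chars <- strsplit(seq, "")[[1]]
  blocks <- oracleBlocks(patternId)
  # the memo key (pos, block, Z-binding) is independent of the start
  # position, so one memo serves every anchoring attempt
  memo <- new.env(parent = emptyenv())
  for (start in seq_along(chars)) {
    if (oracleMatchFrom(chars, start, blocks, 1L, NA_character_, memo))
      return(TRUE)
  }
  FALSE
}

# ---- misc ------------------------------------------------------------------
randomProtein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                 "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

randomBinaryTree <- function(nTip, blRange = c(0.05, 0.5)) {
  tr <- ape::rtree(nTip, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), blRange[1], blRange[2])
  tr
}
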