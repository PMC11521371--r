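test_that("transition matrices are stochastic, reversible and correct at 0", {
  set.seed(40)
  for (r in 1:20) {
    pi1 <- stats::runif(1, 0.05, 0.95)
    t <- stats::runif(1, 0, 3)
    P <- transitionMatrix(binaryModel(pi1), t)
    expect_equal(unname(rowSums(P)), c(1, 1), tolerance = 1e-12)
    # detailed balance: pi0 P01 = pi1 P10
    expect_equal((1 - pi1) * P["0", "1"], pi1 * P["1", "0"],
                 tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
  expect_equal(unname(transitionMatrix(binaryModel(0.3), 0)), diag(2),
               tolerance = 1e-12)
  expect_error(transitionMatrix(binaryModel(0.3), -1))
})

test_that("pruning equals exhaustive state enumeration on small trees", {
  set.seed(41)
  for (r in 1:30) {
    n <- sample(3:5, 1)
    tr <- randomBinaryTree(n)
    pi1 <- stats::runif(1, 0.1, 0.9)
    pattern <- stats::setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    got <- patternLikelihood(tr, binaryModel(pi1), pattern)
    want <- oraclePatternProb(tr, pi1, pattern)
    expect_lt(abs(got - want), 1e-12)
  }
})

test_that("likelihood respects the pulley principle (root invariance)", {
  set.seed(42)
  for (r in 1:10) {
    tr <- randomBinaryTree(5)
    pi1 <- stats::runif(1, 0.2, 0.8)
    pattern <- stats::setNames(sample(0:1, 5, replace = TRUE), tr$tip.label)
    base <- patternLikelihood(tr, binaryModel(pi1), pattern)
    for (out in sample(tr$tip.label, 2)) {
      rerooted <- ape::unroot(ape::root(tr, outgroup = out,
                                        resolve.root = TRUE))
      expect_equal(patternLikelihood(rerooted, binaryModel(pi1), pattern),
                   base, tolerance = 1e-10)
    }
  }
})

test_that("pattern counts tabulate the matrix faithfully", {
  m <- matrix(c(1L, 1L, 0L, 1L,
                1L, 1L, 0L, 0L,
                0L, 1L, 1L, 1L), 3, 4, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), paste0("f", 1:4)))
  cnt <- patternCounts(presenceAbsenceMatrix(m))
  expect_identical(cnt$taxa, c("a", "b", "c"))
  expect_equal(sum(cnt$counts), 4)
  # column f1 = (1,1,0) appears once; f2 = (1,1,1) once; etc.
  key <- apply(cnt$patterns, 1, paste, collapse = "")
  expect_identical(sort(rep(key, cnt$counts)),
                   sort(unname(apply(m, 2, paste, collapse = ""))))
})

test_that("corrected likelihood rejects unobservable patterns", {
  m <- matrix(c(0L, 1L,
                0L, 1L,
                0L, 1L), 3, 2, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("f1", "f2")))
  cnt <- patternCounts(presenceAbsenceMatrix(m))
  tr <- randomBinaryTree(3)
  tr$tip.label <- c("a", "b", "c")
  expect_error(correctedLogLik(tr, binaryModel(0.5), cnt),
               "filterObservable")
})

test_that("corrected likelihood equals the enumeration oracle", {
  set.seed(43)
  for (r in 1:5) {
    n <- 4
    tr <- randomBinaryTree(n)
    sim <- evolveGeneContent(tr, 60, lossProb = 0.3)
    pam <- suppressMessages(filterObservable(sim$pam))
    if (ncol(paMatrix(pam)) == 0) next
    cnt <- patternCounts(pam)
    pi1 <- stats::runif(1, 0.2, 0.8)
    got <- correctedLogLik(tr, binaryModel(pi1), cnt)
    pats <- cnt$patterns
    colnames(pats) <- cnt$taxa
    want <- oracleCorrectedLogLik(tr, pi1, pats, cnt$counts)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("fitting improves the likelihood and is deterministic", {
  set.seed(44)
  tr <- simulateTree(5)
  sim <- evolveGeneContent(tr, 500, lossProb = 0.2)
  pam <- suppressMessages(filterObservable(sim$pam))
  cnt <- patternCounts(pam)
  fit1 <- fitBinaryModel(tr, cnt)
  fit2 <- fitBinaryModel(tr, cnt)
  expect_identical(fit1$loglik, fit2$loglik)
  expect_identical(fit1$model@pi1, fit2$model@pi1)
  # fitted likelihood beats arbitrary parameter settings
  expect_gt(fit1$loglik, correctedLogLik(tr, binaryModel(0.5), cnt))
  expect_true(fit1$converged)
  expect_error(fitBinaryModel(parseNewick("(a:1,b:1);"), cnt),
               "at least 3")
})

test_that("maximum-likelihood fit recovers parameters from CTMC data", {
  # simulate from the reversible model itself (not the Dollo simulator),
  # conditioned on observability, then refit on the true topology
  set.seed(45)
  pi1 <- 0.65
  tr <- parseNewick("((a:0.4,b:0.4):0.3,(c:0.4,d:0.4):0.3);")
  tr <- ape::unroot(tr)
  nFam <- 4000
  tips <- tr$tip.label
  po <- ape::reorder.phylo(tr, "postorder")
  sampleOne <- function() {
    repeat {
      st <- integer(length(tips) + tr$Nnode)
      root <- length(tips) + 1L
      st[root] <- stats::rbinom(1, 1, pi1)
      for (i in rev(seq_len(nrow(po$edge)))) {
        p <- po$edge[i, 1]; ch <- po$edge[i, 2]
        P <- transitionMatrix(binaryModel(pi1), po$edge.length[i])
        st[ch] <- stats::rbinom(1, 1, P[st[p] + 1, 2])
      }
      leaf <- st[seq_along(tips)]
      if (sum(leaf) >= 2) return(leaf)
    }
  }
  m <- t(replicate(nFam, sampleOne()))
  dimnames(m) <- list(NULL, tips)
  m <- m[, tips]
  pam <- presenceAbsenceMatrix(
    matrix(as.integer(t(m)), length(tips), nFam,
           dimnames = list(tips, sprintf("f%04d", seq_len(nFam)))))
  cnt <- patternCounts(pam)
  fit <- fitBinaryModel(tr, cnt)
  # the maximum must not fall below the generating parameters
  expect_gte(fit$loglik, correctedLogLik(tr, binaryModel(pi1), cnt) - 1e-6)
  # parameters trade off along a ridge (a near-pure-loss corner can mimic
  # the conditioned distribution on few taxa), so test the identifiable
  # object: the conditional pattern distribution itself
  pats <- as.matrix(expand.grid(rep(list(0:1), length(tips))))
  colnames(pats) <- tips
  pats <- pats[rowSums(pats) >= 2, , drop = FALSE]
  condProbs <- function(tree, model) {
    pr <- apply(pats, 1, function(p)
      patternLikelihood(tree, model, stats::setNames(p, tips)))
    pr / sum(pr)
  }
  expect_lt(max(abs(condProbs(fit$tree, fit$model) -
                      condProbs(tr, binaryModel(pi1)))), 0.01)
})

test_that("exhaustive search caps at 7 taxa and evaluates all topologies", {
  set.seed(46)
  tr <- simulateTree(4)
  sim <- evolveGeneContent(tr, 300, lossProb = 0.25)
  pam <- suppressMessages(filterObservable(sim$pam))
  cnt <- patternCounts(pam)
  res <- searchTopology(cnt, mode = "exhaustive")
  expect_identical(res$evaluated, 3L)  # 3 unrooted topologies on 4 taxa
  expect_identical(res$canon, canonicalTopology(tr))
  big <- cnt
  big$taxa <- paste0("t", 1:8)
  expect_error(searchTopology(big, mode = "exhaustive"), "at most 7")
})

test_that("NNI search never ends below its start likelihood", {
  set.seed(47)
  tr <- simulateTree(7)
  sim <- evolveGeneContent(tr, 1500, lossProb = 0.2)
  pam <- suppressMessages(filterObservable(sim$pam))
  cnt <- patternCounts(pam)
  res <- searchTopology(cnt, mode = "nni")
  expect_gte(res$loglik, res$startLoglik - 1e-6)
  expect_identical(res$canon, canonicalTopology(tr))
})

test_that("MCMC machinery produces sane samples and summaries", {
  set.seed(48)
  tr <- simulateTree(5)
  sim <- evolveGeneContent(tr, 300, lossProb = 0.2)
  pam <- suppressMessages(filterObservable(sim$pam))
  cnt <- patternCounts(pam)
  run1 <- mcmcTrees(cnt, iterations = 1500L, sampleEvery = 5L)
  expect_length(run1$trees, 300)
  expect_true(all(run1$pi1 > 0 & run1$pi1 < 1))
  expect_true(all(is.finite(run1$loglik)))
  cons <- majorityConsensus(run1$trees)
  expect_s3_class(cons, "phylo")
  run2 <- mcmcTrees(cnt, iterations = 1500L, sampleEvery = 5L)
  cmpr <- compareRuns(run1, run2)
  expect_gte(cmpr$maxDiscrepancy, 0)
  expect_lte(cmpr$maxDiscrepancy, 1)
  # identical runs have discrepancy exactly zero
  self <- compareRuns(run1, run1)
  expect_identical(self$maxDiscrepancy, 0)
})

test_that("clade frequencies count splits correctly", {
  trees <- list(parseNewick("((A:1,B:1):1,(C:1,D:1):1);"),
                parseNewick("((A:1,B:1):1,(C:1,D:1):1);"),
                parseNewick("((A:1,C:1):1,(B:1,D:1):1);"))
  f <- cladeFrequencies(trees)
  expect_equal(unname(f[["C|D"]]), 2 / 3)
  expect_equal(unname(f[["B|D"]]), 1 / 3)
})

test_that("urbilaterian census counts ancestral families and retention", {
  m <- matrix(c(1L, 1L, 0L, 1L,
                1L, 0L, 1L, 0L,
                1L, 1L, 0L, 0L,
                0L, 1L, 1L, 0L), 4, 4, byrow = TRUE,
              dimnames = list(c("in1", "in2", "out1", "out2"),
                              paste0("f", 1:4)))
  cc <- urbilaterianCensus(presenceAbsenceMatrix(m), c("in1", "in2"),
                           c("out1", "out2"))
  # ancestral: present in >=1 ingroup AND >=1 outgroup: f1, f2, f3
  expect_identical(cc$ancestralFamilies, c("f1", "f2", "f3"))
  expect_identical(unname(cc$retention), c(2, 2))
  expect_equal(cc$ingroupMean, 2)
  expect_error(urbilaterianCensus(presenceAbsenceMatrix(m), "in1", "in1"),
               "overlap")
})

test_that("fast loser retains fewer ancestral families in the census", {
  set.seed(49)
  preset <- simulationPreset("compact")
  sim <- suppressMessages(simulatePresetContent(preset, fastLoss = TRUE))
  cc <- urbilaterianCensus(sim$pam, c("A", "B", "C", "D"), c("O1", "O2"))
  others <- cc$retention[c("B", "C", "D")]
  expect_lt(cc$retention[["A"]], min(others))
})

test_that("phylostratum assignment picks the deepest sharing ancestor", {
  ref <- parseNewick("(((A:1,B:1)n1:1,C:1)n2:1,D:1)root;")
  ref$node.label <- c("root", "n2", "n1")
  expect_identical(assignPhylostratum(c("A", "B"), ref, "A"), "n1")
  expect_identical(assignPhylostratum(c("A", "C"), ref, "A"), "n2")
  expect_identical(assignPhylostratum(c("A", "B", "D"), ref, "A"), "root")
  expect_identical(assignPhylostratum("A", ref, "A"), "species-specific")
  expect_error(assignPhylostratum(c("A", "Z"), ref, "A"), "reference tree")
})
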