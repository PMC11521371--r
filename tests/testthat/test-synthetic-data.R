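test_that("simulateTree produces the requested shapes and labels", {
  set.seed(10)
  cat4 <- simulateTree(4, shape = "caterpillar")
  expect_identical(sort(cat4$tip.label), LETTERS[1:4])
  expect_identical(canonicalTopology(cat4),
                   canonicalTopology(parseNewick("(((A:1,B:1):1,C:1):1,D:1);")))
  bal4 <- simulateTree(4, shape = "balanced")
  expect_identical(canonicalTopology(bal4),
                   canonicalTopology(parseNewick("((A:1,B:1):1,(C:1,D:1):1);")))
  lab <- simulateTree(5, labels = c("v", "w", "x", "y", "z"))
  expect_identical(sort(lab$tip.label), c("v", "w", "x", "y", "z"))
  rnd <- simulateTree(30)
  expect_length(rnd$tip.label, 30)
  expect_true(all(rnd$edge.length >= 0.05 & rnd$edge.length <= 0.3))
  expect_error(simulateTree(2))
})

test_that("gene content evolution is Dollo-like without gain", {
  set.seed(11)
  tr <- simulateTree(6)
  sim <- evolveGeneContent(tr, 400, lossProb = 0.3)
  states <- sim$truth$nodeStates
  edges <- sim$truth$tree$edge
  # no regain: a child can never be present where its parent is absent
  for (i in seq_len(nrow(edges)))
    expect_true(all(states[edges[i, 2], ] <= states[edges[i, 1], ]))
  # leaf rows of the truth equal the emitted matrix
  m <- paMatrix(sim$pam)
  for (tx in rownames(m))
    expect_identical(unname(m[tx, ]),
                     unname(states[match(tx, sim$truth$tree$tip.label), ]))
})

test_that("content simulation boundary parameters behave", {
  set.seed(12)
  tr <- simulateTree(4)
  all0 <- evolveGeneContent(tr, 50, rootPresenceProb = 0, lossProb = 0.2)
  expect_true(all(paMatrix(all0$pam) == 0L))
  noLoss <- evolveGeneContent(tr, 50, lossProb = 0)
  expect_true(all(paMatrix(noLoss$pam) == 1L))
  expect_error(evolveGeneContent(tr, 50, lossProb = 1.5))
})

test_that("per-tip loss overrides hit only that terminal branch", {
  set.seed(13)
  tr <- simulateTree(5)
  sim <- evolveGeneContent(tr, 300, lossProb = 0,
                           lossOverrides = c(A = 1))
  m <- paMatrix(sim$pam)
  expect_true(all(m["A", ] == 0L))
  expect_true(all(m[setdiff(rownames(m), "A"), ] == 1L))
})

test_that("sequences are emitted exactly for present families", {
  set.seed(14)
  tr <- simulateTree(4)
  sim <- evolveGeneContent(tr, 60, lossProb = 0.3)
  seqs <- evolveSequences(tr, sim$pam, substitutionProb = 0.05)
  m <- paMatrix(sim$pam)
  for (tx in rownames(m)) {
    expected <- paste0(tx, "_", colnames(m)[m[tx, ] == 1L])
    expect_identical(sort(names(seqs[[tx]])), sort(expected))
  }
  lens <- nchar(unlist(seqs))
  expect_true(all(lens >= 120 & lens <= 400))
})

test_that("zero substitution probability gives identical orthologs", {
  set.seed(15)
  tr <- simulateTree(4)
  sim <- evolveGeneContent(tr, 30, lossProb = 0)
  seqs <- evolveSequences(tr, sim$pam, substitutionProb = 0)
  fam <- colnames(paMatrix(sim$pam))[1]
  byTaxon <- vapply(rownames(paMatrix(sim$pam)),
                    function(tx) seqs[[tx]][[paste0(tx, "_", fam)]],
                    character(1))
  expect_length(unique(byTaxon), 1L)
})

test_that("pairwise identity between sister tips matches the site model", {
  # two tips, one branch each at prob p: P(site identical) = (1-p)^2 + p^2/19
  set.seed(16)
  p <- 0.1
  tr <- parseNewick("(s1:1,s2:1);")
  pam <- presenceAbsenceMatrix(matrix(1L, 2, 40,
    dimnames = list(c("s1", "s2"), sprintf("f%02d", 1:40))))
  seqs <- evolveSequences(tr, pam, substitutionProb = p,
                          lengthRange = c(300L, 300L))
  a <- strsplit(unname(seqs$s1), "")
  b <- strsplit(unname(seqs$s2), "")
  same <- sum(mapply(function(x, y) sum(x == y), a, b))
  total <- 40 * 300
  expected <- (1 - p)^2 + p^2 / 19
  se <- sqrt(expected * (1 - expected) / total)
  expect_lt(abs(same / total - expected), 5 * se)
})

test_that("karyotype simulation records a consistent truth", {
  set.seed(17)
  kar <- simulateKaryotype(nAlg = 6, genesPerAlg = 10,
                           fusions = list(c("ALG03", "ALG04")),
                           fissions = "ALG05", shuffleFrac = 0)
  expect_equal(nrow(kar$refMap), 60)
  expect_setequal(unique(kar$refMap$chromosome), sprintf("ALG%02d", 1:6))
  # 3 unfused + 2 fission halves + 1 fused = 6 derived chromosomes
  expect_length(unique(kar$derivedMap$chromosome), 6)
  sizes <- lengths(kar$truth$derivedComposition)
  expect_equal(sort(unname(sizes)), c(1, 1, 1, 1, 1, 2))
  # every derived gene descends from the recorded ALG
  alg <- kar$truth$algOfGene
  byPair <- kar$truth$truePairs
  expect_equal(nrow(byPair), 60)
  # with shuffle 0 the within-block order is preserved
  d <- kar$derivedMap[kar$derivedMap$chromosome ==
                        kar$derivedMap$chromosome[1], ]
  expect_identical(d$position_index[order(d$position_index)],
                   d$position_index)
  expect_error(simulateKaryotype(4, 5, fusions = list(c("ALG04", "ALG09"))),
               "unknown ALG")
})

test_that("fusion blocks concatenate their ALGs and fissions split one", {
  set.seed(18)
  kar <- simulateKaryotype(nAlg = 4, genesPerAlg = 8,
                           fusions = list(c("ALG01", "ALG02")),
                           fissions = "ALG03", shuffleFrac = 0)
  comp <- kar$truth$derivedComposition
  fused <- names(comp)[lengths(comp) == 2]
  expect_length(fused, 1)
  genesOnFused <- kar$derivedMap$gene_id[kar$derivedMap$chromosome == fused]
  srcAlg <- unique(kar$truth$algOfGene[sub("^qry_", "", genesOnFused)])
  expect_setequal(srcAlg, c("ALG01", "ALG02"))
  expect_length(genesOnFused, 16)
  # fission halves jointly carry all ALG03 genes, no others
  halves <- names(comp)[vapply(comp, function(x)
    identical(x, "ALG03"), logical(1))]
  expect_length(halves, 2)
  genesOnHalves <- kar$derivedMap$gene_id[
    kar$derivedMap$chromosome %in% halves]
  expect_setequal(
    unique(kar$truth$algOfGene[sub("^qry_", "", genesOnHalves)]), "ALG03")
  expect_length(genesOnHalves, 8)
})

test_that("the preset fusion history yields 18 chromosomes sized 12/5/1", {
  set.seed(19)
  h <- xenoturbellaKaryotypeHistory()
  kar <- simulateKaryotype(nAlg = 24, genesPerAlg = 4, fusions = h$fusions,
                           fissions = h$fissions, shuffleFrac = 0.2)
  comp <- kar$truth$derivedComposition
  expect_length(comp, 18)
  expect_equal(unname(table(lengths(comp))), c(12L, 5L, 1L),
               ignore_attr = TRUE)
})

test_that("planted precursors match and negatives do not", {
  set.seed(20)
  pl <- plantPrecursors(8, 30)
  expect_length(pl$fasta, 38)
  expect_length(pl$positiveIds, 8)
  for (id in pl$positiveIds) {
    hits <- scanSequence(pl$fasta[[id]], neuropeptidePatterns())
    expect_gt(nrow(hits), 0)
  }
  negatives <- setdiff(names(pl$fasta), pl$positiveIds)
  for (id in negatives) {
    hits <- scanSequence(pl$fasta[[id]], neuropeptidePatterns())
    expect_identical(nrow(hits), 0L)
  }
})
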