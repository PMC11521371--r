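pats <- neuropeptidePatterns()

test_that("printed-pattern examples match as documented", {
  r1 <- scanSequence("RRAAARRAAARRAAARR", pats)
  expect_true("P1" %in% r1$pattern)
  expect_identical(r1$witness[r1$pattern == "P1"], "RRAAARRAAARRAAARR")

  r2 <- scanSequence("RRAAQRRAAQRR", pats)
  expect_true("P2" %in% r2$pattern)
  expect_identical(r2$z[r2$pattern == "P2"], "Q")
  r2bad <- scanSequence("RRAAQRRAAWRR", pats)
  expect_false("P2" %in% r2bad$pattern)

  r4 <- scanSequence("KKAQGKRAQGRK", pats)
  expect_true("P4" %in% r4$pattern)
  expect_identical(r4$z[r4$pattern == "P4"], "Q")
})

test_that("witness spans are 0-based half-open and re-match the pattern", {
  s <- "MMMMRRAAARRAAARRAAARRWW"
  r <- scanSequence(s, pats)
  row <- r[r$pattern == "P1", ]
  expect_identical(row$start, 4L)
  expect_identical(substr(s, row$start + 1, row$end), row$witness)
  expect_true(oracleScan(row$witness, "P1"))
})

test_that("witnesses are leftmost then shortest", {
  # two P1 matches; the left one must win even though a later one exists
  s <- paste0("RRAAARRAAARRAAARR", "XXXX", "RRCCCRRCCCRRCCCRR")
  r <- scanSequence(s, pats)
  expect_identical(r$start[r$pattern == "P1"], 0L)
  # minimality: no proper prefix of the witness is itself an anchored match
  w <- r$witness[r$pattern == "P1"]
  anchored <- function(s, pid) {
    # anchored at both ends: blocks must consume the whole string
    chars <- strsplit(s, "")[[1]]
    blocks <- oracleBlocks(pid)
    rec <- function(pos, k, zc) {
      if (k > length(blocks)) return(pos == length(chars) + 1)
      b <- blocks[[k]]
      if (identical(b, "RR")) {
        pos + 1 <= length(chars) && chars[pos] %in% c("K", "R") &&
          chars[pos + 1] %in% c("K", "R") && rec(pos + 2, k + 1, zc)
      } else if (identical(b, "G")) {
        pos <= length(chars) && chars[pos] == "G" && rec(pos + 1, k + 1, zc)
      } else if (identical(b, "Z")) {
        if (pos > length(chars)) return(FALSE)
        if (is.na(zc)) rec(pos + 1, k + 1, chars[pos])
        else chars[pos] == zc && rec(pos + 1, k + 1, zc)
      } else {
        any(vapply(b[[2]]:b[[3]], function(len)
          pos + len - 1 <= length(chars) && rec(pos + len, k + 1, zc),
          logical(1)))
      }
    }
    rec(1L, 1L, NA_character_)
  }
  for (cut in 1:(nchar(w) - 1))
    expect_false(anchored(substr(w, 1, nchar(w) - cut), "P1"))
  expect_true(anchored(w, "P1"))
})

test_that("any P3 match with spacers in bounds also matches P2 with Z=G", {
  set.seed(60)
  for (r in 1:50) {
    sp1 <- randomProtein(sample(2:35, 1),
                         alphabet = setdiff(strsplit(
                           "ACDEFHILMNPQSTVWY", "")[[1]], "G"))
    sp2 <- randomProtein(sample(2:35, 1),
                         alphabet = setdiff(strsplit(
                           "ACDEFHILMNPQSTVWY", "")[[1]], "G"))
    s <- paste0("RR", sp1, "G", "RR", sp2, "G", "RR")
    hits <- scanSequence(s, pats)$pattern
    expect_true("P3" %in% hits)
    expect_true("P2" %in% hits)
  }
})

test_that("scanner existence decisions equal the decomposition oracle", {
  set.seed(61)
  # enriched alphabet so dibasic blocks actually occur at these lengths
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "K", "R", "K",
                "R", "G")
  for (len in c(20, 40, 60)) {
    for (r in 1:120) {
      s <- randomProtein(len, alphabet = alphabet)
      hits <- scanSequence(s, pats)$pattern
      for (pid in c("P1", "P2", "P3", "P4"))
        expect_identical(pid %in% hits, oracleScan(s, pid))
    }
  }
})

test_that("length filter is strict at 600", {
  seqs <- c(a = paste(rep("A", 599), collapse = ""),
            b = paste(rep("A", 600), collapse = ""),
            c = "MKR")
  kept <- lengthFilter(seqs)
  expect_identical(names(kept), c("a", "c"))
  expect_length(lengthFilter(character(0)), 0)
})

test_that("E-value ratio filter implements the decision table", {
  prot <- paste0("p", 1:5)
  nr <- data.frame(query = c("p1", "p2", "p4", "p5"),
                   subject = "x",
                   score = c(1e-100, 1e-20, 1e-10, 0),
                   stringsAsFactors = FALSE)
  cur <- data.frame(query = c("p1", "p2", "p3", "p4", "p5"),
                    subject = "y",
                    score = c(1e-10, 1e-30, 1e-8, 0, 0),
                    stringsAsFactors = FALSE)
  expect_warning(rec <- evalueRatioFilter(prot, nr, cur),
                 "both best E-values are 0")
  expect_identical(rec$decision[rec$protein_id == "p1"], "discard")
  expect_identical(rec$decision[rec$protein_id == "p2"], "keep")
  expect_identical(rec$decision[rec$protein_id == "p3"], "no_nr_hit")
  # curated 0, nr > 0: ratio +Inf, keep
  expect_identical(rec$decision[rec$protein_id == "p4"], "keep")
  expect_identical(rec$ratio[rec$protein_id == "p4"], Inf)
  badNr <- nr; badNr$score[1] <- -1
  expect_error(evalueRatioFilter(prot, badNr, cur), "negative")
})

test_that("missing curated hit keeps the protein with a flag", {
  prot <- "p1"
  nr <- data.frame(query = "p1", subject = "x", score = 1e-50,
                   stringsAsFactors = FALSE)
  cur <- data.frame(query = character(0), subject = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  rec <- evalueRatioFilter(prot, nr, cur)
  expect_identical(rec$decision, "no_curated_hit")
})

test_that("cleavage products split at dibasic sites and flag amidation", {
  p1 <- cleavageProducts("RRAAARRAAARRAAARR", "P1", pats)
  expect_identical(p1$peptide, c("AAA", "AAA", "AAA"))
  expect_false(any(p1$amidation))
  p3 <- cleavageProducts("RRAAGRRAAGRR", "P3", pats)
  expect_identical(p3$peptide, c("AAG", "AAG"))
  expect_identical(p3$mature, c("AA", "AA"))
  expect_true(all(p3$amidation))
  # conservation: interleaving dibasic blocks and products rebuilds witness
  w <- "RRAAGRRAAGRR"
  rebuilt <- paste0("RR", p3$peptide[1], "RR", p3$peptide[2], "RR")
  expect_identical(rebuilt, w)
})

test_that("the full screen keeps planted positives and drops negatives", {
  set.seed(62)
  pl <- plantPrecursors(6, 25)
  rep1 <- runPrecursorScreen(pl$fasta)
  expect_setequal(unique(rep1$protein_id), pl$positiveIds)
  expect_true(all(rep1$decision == "not_validated"))
  # idempotence: re-screening the survivors reproduces the same set
  rep2 <- runPrecursorScreen(pl$fasta[unique(rep1$protein_id)])
  expect_setequal(unique(rep2$protein_id), unique(rep1$protein_id))
})

test_that("screen applies the length filter after scanning", {
  set.seed(63)
  pl <- plantPrecursors(1, 0)
  long <- paste0(pl$fasta[[1]],
                 paste(rep("A", 600 - nchar(pl$fasta[[1]]) + 1),
                       collapse = ""))
  seqs <- c(pl$fasta, stats::setNames(long, "toolong"))
  rep <- runPrecursorScreen(seqs)
  expect_false("toolong" %in% rep$protein_id)
  expect_true(pl$positiveIds %in% rep$protein_id)
})
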