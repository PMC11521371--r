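NONBASIC_ALPHABET <- setdiff(AA_ALPHABET20, c("K", "R"))

#' Plant neuropeptide-like precursors among background proteins
#'
#' Positives instantiate one of the four repeat patterns (see
#' [neuropeptidePatterns()]): dibasic blocks drawn over \{K, R\}, spacers
#' drawn over the non-basic alphabet (so no spurious dibasic pair can blur
#' the planted decomposition), Z drawn once per sequence, all embedded in
#' random flanks; positives are shorter than 600 residues by construction.
#' Negatives are random sequences rejection-sampled against the scanner:
#' a candidate matching any pattern is redrawn.
#'
#' @param precursorCount number of planted positives.
#' @param backgroundCount number of rejection-sampled negatives.
#' @param flankRange length range of the random flanks around a positive.
#' @param negLengthRange length range of negatives.
#' @param patterns pattern set from [neuropeptidePatterns()].
#' @param maxTries rejection-sampling cap per negative.
#' @return list with `fasta` (named character vector), `positiveIds`,
#'   `truth` (data.frame id/pattern for positives).
#' @examples
#' set.seed(1)
#' pp <- plantPrecursors(3, 5)
#' all(pp$positiveIds %in% names(pp$fasta))
#' @export
plantPrecursors <- function(precursorCount, backgroundCount,
                            flankRange = c(5L, 30L),
                            negLengthRange = c(60L, 300L),
                            patterns = neuropeptidePatterns(),
                            maxTries = 1000L) {
  if (precursorCount < 0 || backgroundCount < 0)
    stop("counts must be non-negative")
  fasta <- character(0)
  truth <- data.frame(id = character(0), pattern = character(0),
                      stringsAsFactors = FALSE)
  if (precursorCount > 0) {
    pids <- sample(names(patterns), precursorCount, replace = TRUE)
    for (i in seq_len(precursorCount)) {
      id <- sprintf("prec%03d", i)
      core <- .instantiatePattern(patterns[[pids[i]]])
      flank <- function() paste(sample(NONBASIC_ALPHABET,
                                       sample(seq.int(flankRange[1L],
                                                      flankRange[2L]), 1L),
                                       replace = TRUE), collapse = "")
      fasta[id] <- paste0(flank(), core, flank())
      truth <- rbind(truth, data.frame(id = id, pattern = pids[i],
                                       stringsAsFactors = FALSE))
    }
  }
  for (i in seq_len(backgroundCount)) {
    id <- sprintf("bg%03d", i)
    for (try in seq_len(maxTries)) {
      L <- sample(seq.int(negLengthRange[1L], negLengthRange[2L]), 1L)
      s <- paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
      if (nrow(scanSequence(s, patterns)) == 0L) break
      s <- NULL
    }
    if (is.null(s)) stop("failed to sample a pattern-free negative")
    fasta[id] <- s
  }
  list(fasta = fasta, positiveIds = truth$id, truth = truth)
}

.instantiatePattern <- function(p) {
  z <- sample(NONBASIC_ALPHABET, 1L)
  parts <- vapply(p$blocks, function(b) {
    switch(b$type,
      DIBASIC = paste(sample(c("K", "R"), 2L, replace = TRUE),
                      collapse = ""),
      SPACER = paste(sample(NONBASIC_ALPHABET,
                            sample(seq.int(b$min, b$max), 1L),
                            replace = TRUE), collapse = ""),
      Z = z,
      G = "G")
  }, character(1))
  paste(parts, collapse = "")
}
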