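AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

#' Read a protein FASTA file
#'
#' Reads amino-acid sequences and enforces the contracts the downstream
#' pipeline relies on: unique, non-empty ids; non-empty sequences; only the
#' 20 standard amino-acid letters. Wrapped lines are concatenated; record
#' order is preserved.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences (names are record ids).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "MK", "RW", ">b", "ACD"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- names(aa)
  # keep only the first whitespace-delimited token, as ids must be tokens
  ids <- sub("\\s.*$", "", ids)
  seqs <- as.character(aa)
  names(seqs) <- ids
  validateSequenceRecords(seqs)
  seqs
}

#' Validate a set of protein sequence records
#'
#' Checks that every record has a non-empty unique id, a non-empty sequence,
#' and only standard amino-acid letters.
#'
#' @param seqs named character vector of amino-acid sequences.
#' @return `seqs`, invisibly; errors describe the first offending record.
#' @export
validateSequenceRecords <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must carry a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate id ", dup[[1L]])
  empty <- ids[!nzchar(seqs)]
  if (length(empty)) stop("empty sequence for id ", empty[[1L]])
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    bad <- which(!ch %in% AA_ALPHABET20)
    if (length(bad))
      stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                   ch[bad[1L]], bad[1L], ids[[i]]))
  }
  invisible(seqs)
}

#' Write protein sequences as FASTA
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path, width = 70L) {
  validateSequenceRecords(seqs)
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}
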