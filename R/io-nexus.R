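NEXUS_RESERVED <- "[\\s()\\[\\]{}/\\\\,;:=*'\"`<>]"

#' Write a presence/absence matrix as NEXUS restriction data
#'
#' Emits a NEXUS DATA block with `datatype=restriction`, the convention for
#' binary gene presence/absence characters in Bayesian phylogenetic software.
#' The output round-trips bit-identically through [readNexusRestriction()].
#'
#' @param pam a [PresenceAbsenceMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @examples
#' m <- presenceAbsenceMatrix(matrix(c(1L,0L,1L,1L,1L,0L), 2, byrow = TRUE,
#'        dimnames = list(c("t1","t2"), c("f1","f2","f3"))))
#' f <- tempfile(fileext = ".nex")
#' writeNexusRestriction(m, f)
#' identical(paMatrix(readNexusRestriction(f)), paMatrix(m))
#' @export
writeNexusRestriction <- function(pam, path) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  validObject(pam)
  m <- pam@mat
  taxa <- rownames(m)
  bad <- grepl(NEXUS_RESERVED, taxa, perl = TRUE)
  if (any(bad))
    stop("taxon label contains NEXUS-reserved characters: ", taxa[bad][1L])
  rows <- apply(m, 1L, paste, collapse = "")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "#NEXUS",
    "begin data;",
    sprintf("dimensions ntax=%d nchar=%d;", nrow(m), ncol(m)),
    "format datatype=restriction missing=? gap=-;",
    "matrix"
  ), con)
  writeLines(sprintf("%s %s", taxa, rows), con)
  writeLines(c(";", "end;"), con)
  invisible(path)
}

#' Read NEXUS restriction data into a presence/absence matrix
#'
#' Parses the dialect written by [writeNexusRestriction()] (a single DATA
#' block with one-line taxon rows of 0/1 characters). Family ids are not part
#' of the NEXUS format and are regenerated as `c1..cN`, unless supplied.
#'
#' @param path path to a NEXUS file.
#' @param familyIds optional character vector of column ids (length NCHAR).
#' @return A [PresenceAbsenceMatrix-class].
#' @export
readNexusRestriction <- function(path, familyIds = NULL) {
  lines <- readLines(path, warn = FALSE)
  low <- tolower(trimws(lines))
  if (!length(low) || low[1L] != "#nexus") stop("not a NEXUS file: ", path)
  dimLine <- grep("^dimensions", low)
  if (!length(dimLine)) stop("no dimensions statement found")
  ntax <- as.integer(sub(".*ntax=([0-9]+).*", "\\1", low[dimLine[1L]]))
  nchar_ <- as.integer(sub(".*nchar=([0-9]+).*", "\\1", low[dimLine[1L]]))
  fmtLine <- grep("^format", low)
  if (!length(fmtLine) || !grepl("datatype=restriction", low[fmtLine[1L]]))
    stop("expected format datatype=restriction")
  mstart <- grep("^matrix$", low)
  if (!length(mstart)) stop("no matrix statement found")
  body <- character(0)
  for (i in seq(mstart[1L] + 1L, length(lines))) {
    tl <- trimws(lines[[i]])
    if (tl == ";" || tolower(tl) == "end;") break
    if (nzchar(tl)) body <- c(body, tl)
  }
  if (length(body) != ntax)
    stop(sprintf("expected %d taxon rows, found %d", ntax, length(body)))
  parts <- strsplit(body, "\\s+")
  taxa <- vapply(parts, `[[`, character(1), 1L)
  rows <- vapply(parts, function(p) paste(p[-1L], collapse = ""), character(1))
  if (any(nchar(rows) != nchar_))
    stop("row length does not match nchar")
  if (any(!grepl("^[01]+$", rows)))
    stop("restriction rows must contain only 0 and 1")
  m <- do.call(rbind, lapply(strsplit(rows, ""), as.integer))
  if (is.null(familyIds)) familyIds <- sprintf("c%d", seq_len(nchar_))
  dimnames(m) <- list(taxa, familyIds)
  presenceAbsenceMatrix(m)
}

#' Write a presence/absence matrix as TSV
#'
#' @param pam a [PresenceAbsenceMatrix-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeMatrixTSV <- function(pam, path) {
  stopifnot(is(pam, "PresenceAbsenceMatrix"))
  df <- data.frame(taxon = rownames(pam@mat), pam@mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV presence/absence matrix written by [writeMatrixTSV()]
#' @param path input path
#' @return A [PresenceAbsenceMatrix-class]
#' @export
readMatrixTSV <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  presenceAbsenceMatrix(m)
}
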