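#' Validate a gene-to-chromosome map
#'
#' A chromosome map is a BED-like table assigning every gene of one species
#' to a chromosome and a 0-based ordinal position on it.
#'
#' @param map data.frame with columns `gene_id`, `species`, `chromosome`,
#'   `position_index`.
#' @return the validated data.frame (invisibly usable).
#' @export
chromosomeMap <- function(map) {
  need <- c("gene_id", "species", "chromosome", "position_index")
  if (!all(need %in% names(map)))
    stop("chromosome map needs columns: ", paste(need, collapse = ", "))
  map <- map[, need]
  map$gene_id <- as.character(map$gene_id)
  map$species <- as.character(map$species)
  map$chromosome <- as.character(map$chromosome)
  map$position_index <- as.integer(map$position_index)
  for (sp in unique(map$species)) {
    sub <- map[map$species == sp, ]
    d <- sub$gene_id[duplicated(sub$gene_id)]
    if (length(d)) stop("duplicate gene_id within species ", sp, ": ", d[[1L]])
    byChrom <- split(sub$position_index, sub$chromosome)
    for (ch in names(byChrom))
      if (anyDuplicated(byChrom[[ch]]))
        stop("duplicate position_index on chromosome ", ch, " of ", sp)
  }
  if (any(map$position_index < 0)) stop("position_index must be >= 0")
  map
}

#' Read / write chromosome-map TSVs
#' @param path file path
#' @return data.frame with the chromosome-map columns
#' @export
readChromosomeMap <- function(path) {
  chromosomeMap(utils::read.table(path, sep = "\t", header = TRUE,
                                  colClasses = "character"))
}

#' @rdname readChromosomeMap
#' @param map a chromosome-map data.frame
#' @export
writeChromosomeMap <- function(map, path) {
  map <- chromosomeMap(map)
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate and normalise a hit table
#'
#' Hit tables carry pairwise similarity results with columns `query`,
#' `subject` and `score` (alignment score, or an E-value for the neuropeptide
#' validation tables).
#'
#' @param hits data.frame with columns `query`, `subject`, `score`.
#' @return normalised data.frame.
#' @export
hitTable <- function(hits) {
  need <- c("query", "subject", "score")
  if (!all(need %in% names(hits)))
    stop("hit table needs columns: ", paste(need, collapse = ", "))
  hits <- hits[, need]
  hits$query <- as.character(hits$query)
  hits$subject <- as.character(hits$subject)
  hits$score <- as.numeric(hits$score)
  if (any(!is.finite(hits$score))) stop("hit scores must be finite")
  if (anyDuplicated(hits[, c("query", "subject")]))
    stop("duplicate (query, subject) row in hit table")
  hits
}

#' Read / write hit-table TSVs
#' @param path file path
#' @return data.frame with columns query, subject, score
#' @export
readHitTable <- function(path) {
  hitTable(utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE))
}

#' @rdname readHitTable
#' @param hits a hit-table data.frame
#' @export
writeHitTable <- function(hits, path) {
  hits <- hitTable(hits)
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write orthogroups as TSV (orthogroup_id, gene_id, species)
#' @param ortho an [OrthologySet-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeOrthogroupTSV <- function(ortho, path) {
  stopifnot(is(ortho, "OrthologySet"))
  og <- orthogroups(ortho)
  df <- data.frame(
    orthogroup_id = rep(names(og), lengths(og)),
    gene_id = unlist(og, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  df$species <- speciesOf(ortho)[df$gene_id]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
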