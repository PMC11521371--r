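#' Shared-ortholog contingency table between two karyotypes
#'
#' Counts, for every (chromosome of species A, chromosome of species B) pair,
#' the reciprocal-best-hit ortholog pairs whose members lie on those
#' chromosomes.
#'
#' @param mapA,mapB chromosome maps (see [chromosomeMap()]) of the two
#'   species.
#' @param pairs data.frame of ortholog pairs with `gene_a` (in `mapA`) and
#'   `gene_b` (in `mapB`).
#' @return list: `table` (integer matrix, rows = A chromosomes, cols = B
#'   chromosomes), `rowTotals`, `colTotals`, `total`.
#' @export
sharedOrthologCounts <- function(mapA, mapB, pairs) {
  mapA <- chromosomeMap(mapA); mapB <- chromosomeMap(mapB)
  chromA <- stats::setNames(mapA$chromosome, mapA$gene_id)
  chromB <- stats::setNames(mapB$chromosome, mapB$gene_id)
  missA <- setdiff(pairs$gene_a, names(chromA))
  if (length(missA)) stop("gene missing from map A: ", missA[[1L]])
  missB <- setdiff(pairs$gene_b, names(chromB))
  if (length(missB)) stop("gene missing from map B: ", missB[[1L]])
  chrsA <- sort(unique(mapA$chromosome))
  chrsB <- sort(unique(mapB$chromosome))
  tab <- matrix(0L, length(chrsA), length(chrsB),
                dimnames = list(chrsA, chrsB))
  if (nrow(pairs)) {
    cross <- table(factor(chromA[pairs$gene_a], levels = chrsA),
                   factor(chromB[pairs$gene_b], levels = chrsB))
    tab <- tab + unclass(cross)
  }
  storage.mode(tab) <- "integer"
  list(table = tab, rowTotals = rowSums(tab), colTotals = colSums(tab),
       total = sum(tab))
}

#' One-sided Fisher (hypergeometric tail) enrichment p-values
#'
#' For each cell, the upper-tail probability of observing at least the seen
#' number of shared orthologs given the table margins -- the one-sided Fisher
#' exact test for enrichment, computed in log space via the hypergeometric
#' distribution. A zero cell has p = 1 exactly (the tail includes 0).
#'
#' @param counts result of [sharedOrthologCounts()] (or a bare integer
#'   matrix).
#' @return matrix of p-values with the same dimnames as the input table.
#' @export
fisherEnrichment <- function(counts) {
  tab <- if (is.list(counts)) counts$table else counts
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  rt <- rowSums(tab); ct <- colSums(tab); N <- sum(tab)
  p <- tab * 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    x <- tab[i, j]
    if (x > min(rt[i], ct[j]))
      stop("cell exceeds its margins")
    if (x == 0L) {
      p[i, j] <- 1
    } else {
      # P(X >= x), X ~ Hypergeometric(white = rt[i], black = N - rt[i],
      # drawn = ct[j]); log-space tail from phyper
      p[i, j] <- exp(stats::phyper(x - 1, rt[i], N - rt[i], ct[j],
                                   lower.tail = FALSE, log.p = TRUE))
    }
  }
  p
}

#' Classify chromosome compositions from enrichment tests
#'
#' Benjamini-Hochberg adjustment across all (query chromosome, reference ALG)
#' cells; a reference ALG enters a query chromosome's composition iff its
#' adjusted p-value is below `alpha` AND the shared-ortholog count reaches
#' `minShared`. Rows of the table are the query chromosomes, columns the
#' reference ALGs (the reference species' unfused chromosomes act as ALG
#' proxies).
#'
#' @param counts result of [sharedOrthologCounts()] with query chromosomes as
#'   rows.
#' @param p matrix of raw p-values from [fisherEnrichment()] (computed if
#'   omitted).
#' @param alpha significance level on adjusted p-values (in (0, 1)).
#' @param minShared minimum shared-ortholog count.
#' @return an [ALGAssignment-class].
#' @export
classifyALGComposition <- function(counts, p = NULL, alpha = 0.05,
                                   minShared = 5L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tab <- if (is.list(counts)) counts$table else counts
  if (is.null(p)) p <- fisherEnrichment(tab)
  stopifnot(identical(dim(p), dim(tab)))
  padj <- matrix(stats::p.adjust(as.vector(p), method = "BH"),
                 nrow(p), ncol(p), dimnames = dimnames(p))
  df <- data.frame(
    query_chrom = rep(rownames(tab), times = ncol(tab)),
    ref_alg = rep(colnames(tab), each = nrow(tab)),
    shared = as.vector(tab),
    p = as.vector(p),
    p_adj = as.vector(padj),
    stringsAsFactors = FALSE
  )
  df$in_composition <- df$p_adj < alpha & df$shared >= minShared
  compo <- lapply(rownames(tab), function(q) {
    sub <- df[df$query_chrom == q & df$in_composition, ]
    sort(sub$ref_alg)
  })
  names(compo) <- rownames(tab)
  new("ALGAssignment", table = df, composition = compo,
      alpha = alpha, minShared = as.numeric(minShared))
}

#' Oxford dotplot coordinates
#'
#' One point per ortholog pair at the global ordinal positions of its two
#' members, chromosomes concatenated in sorted order; chromosome boundary
#' offsets are returned for plotting gridlines.
#'
#' @inheritParams sharedOrthologCounts
#' @return list: `points` (data.frame gene_a, gene_b, chrom_a, chrom_b, x,
#'   y), `boundariesA`, `boundariesB` (named cumulative offsets).
#' @export
dotplotPoints <- function(mapA, mapB, pairs) {
  mapA <- chromosomeMap(mapA); mapB <- chromosomeMap(mapB)
  globalIndex <- function(map) {
    chrs <- sort(unique(map$chromosome))
    sizes <- vapply(chrs, function(ch) sum(map$chromosome == ch), numeric(1))
    offs <- stats::setNames(cumsum(c(0, sizes[-length(sizes)])), chrs)
    idx <- offs[map$chromosome] + map$position_index
    list(index = stats::setNames(idx, map$gene_id),
         chrom = stats::setNames(map$chromosome, map$gene_id),
         boundaries = stats::setNames(cumsum(sizes), chrs))
  }
  gA <- globalIndex(mapA); gB <- globalIndex(mapB)
  missA <- setdiff(pairs$gene_a, names(gA$index))
  if (length(missA)) stop("gene missing from map A: ", missA[[1L]])
  missB <- setdiff(pairs$gene_b, names(gB$index))
  if (length(missB)) stop("gene missing from map B: ", missB[[1L]])
  pts <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    chrom_a = unname(gA$chrom[pairs$gene_a]),
    chrom_b = unname(gB$chrom[pairs$gene_b]),
    x = unname(gA$index[pairs$gene_a]),
    y = unname(gB$index[pairs$gene_b]),
    stringsAsFactors = FALSE
  )
  list(points = pts, boundariesA = gA$boundaries,
       boundariesB = gB$boundaries)
}

#' Plot an Oxford dotplot
#'
#' @param dp result of [dotplotPoints()].
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `dp`.
#' @export
plotOxfordDotplot <- function(dp, ...) {
  graphics::plot(dp$points$x, dp$points$y, pch = 20, cex = 0.4,
                 xlab = "ortholog index, species A",
                 ylab = "ortholog index, species B", ...)
  graphics::abline(v = dp$boundariesA, h = dp$boundariesB,
                   col = "grey80", lty = 3)
  invisible(dp)
}
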