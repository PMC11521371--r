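#' Simulate a species tree
#'
#' Generates a binary tree of a requested shape with branch lengths drawn
#' uniformly from `blRange`. Randomness comes from the session RNG; seed it
#' once per analysis (the CLI and scripts do this) for reproducibility.
#'
#' @param nTaxa number of leaves (>= 3).
#' @param shape one of `"balanced"`, `"caterpillar"`, `"random"`.
#' @param blRange length-2 numeric range for uniform branch lengths.
#' @param labels optional leaf labels; defaults to `A`, `B`, ... for up to 26
#'   taxa, `t01`, `t02`, ... otherwise.
#' @return an [ape::phylo] tree, rooted, binary, with `edge.length`.
#' @examples
#' set.seed(1)
#' writeNewick(simulateTree(4, "balanced"))
#' @export
simulateTree <- function(nTaxa, shape = c("balanced", "caterpillar", "random"),
                         blRange = c(0.05, 0.3), labels = NULL) {
  shape <- match.arg(shape)
  if (nTaxa < 3) stop("nTaxa must be >= 3")
  if (is.null(labels)) {
    labels <- if (nTaxa <= 26) LETTERS[seq_len(nTaxa)]
              else sprintf("t%02d", seq_len(nTaxa))
  }
  if (length(labels) != nTaxa) stop("need exactly nTaxa labels")
  newick <- switch(shape,
    balanced = .balancedNewick(labels),
    caterpillar = .caterpillarNewick(labels),
    random = .randomTopologyNewick(labels)
  )
  tr <- ape::read.tree(text = paste0(newick, ";"))
  tr$edge.length <- stats::runif(nrow(tr$edge), blRange[1L], blRange[2L])
  tr
}

.balancedNewick <- function(labels) {
  n <- length(labels)
  if (n == 1L) return(labels)
  k <- ceiling(n / 2)
  paste0("(", .balancedNewick(labels[seq_len(k)]), ",",
         .balancedNewick(labels[(k + 1L):n]), ")")
}

.caterpillarNewick <- function(labels) {
  out <- paste0("(", labels[1L], ",", labels[2L], ")")
  for (lab in labels[-(1:2)]) out <- paste0("(", out, ",", lab, ")")
  out
}

# random rooted binary topology by sequential random sister attachment
.randomTopologyNewick <- function(labels) {
  nodes <- as.list(labels)
  while (length(nodes) > 1L) {
    i <- sample.int(length(nodes), 2L)
    merged <- paste0("(", nodes[[i[1L]]], ",", nodes[[i[2L]]], ")")
    nodes <- c(nodes[-i], merged)
  }
  nodes[[1L]]
}
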