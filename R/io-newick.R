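#' Parse a Newick tree
#'
#' Thin validating wrapper around [ape::read.tree()]. Leaf labels must be
#' unique; unbalanced parentheses are a hard error. Edges without branch
#' lengths default to 0 (reported via a message). Internal node labels and
#' quoted labels are outside the supported dialect and are dropped.
#'
#' @param text a Newick string (with or without trailing semicolon).
#' @return an [ape::phylo] tree with `edge.length` set.
#' @examples
#' tr <- parseNewick("((A:1,B:1):0.5,C:2);")
#' tr$tip.label
#' @export
parseNewick <- function(text) {
  text <- trimws(text)
  if (!grepl(";\\s*$", text)) text <- paste0(text, ";")
  opens <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  closes <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (opens != closes) stop("unbalanced parentheses in Newick string")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick string")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup)) stop("duplicate leaf ", dup[[1L]])
  if (is.null(tr$edge.length)) {
    message("no branch lengths in Newick input; defaulting all to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  } else if (anyNA(tr$edge.length)) {
    message(sum(is.na(tr$edge.length)),
            " missing branch length(s) defaulted to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr$node.label <- NULL
  tr
}

# smallest descendant leaf label per node; used for canonical child ordering
.minLeaf <- function(tree) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  out <- character(n + m)
  out[seq_len(n)] <- tree$tip.label
  # process edges child-before-parent (postorder)
  po <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; c <- po$edge[i, 2L]
    if (!nzchar(out[p]) || out[c] < out[p]) out[p] <- out[c]
  }
  out
}

#' Serialize a tree as canonical Newick
#'
#' Children of every node are ordered by their smallest descendant leaf
#' label, so topologically identical rooted trees serialize identically.
#' Branch lengths are written as plain decimal floats; internal node labels
#' are never emitted.
#'
#' @param tree an [ape::phylo] object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string ending in ";".
#' @examples
#' writeNewick(parseNewick("((B:1,A:1):0.5,C:2);"))
#' @export
writeNewick <- function(tree, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  haveLen <- !is.null(tree$edge.length)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  minleaf <- .minLeaf(tree)
  fmt <- function(x) formatC(x, digits = digits, format = "fg", flag = "#")
  rec <- function(node, edgeIdx) {
    if (node <= n) {
      lab <- tree$tip.label[node]
    } else {
      ki <- kids[[as.character(node)]]
      ki <- ki[order(minleaf[tree$edge[ki, 2L]])]
      lab <- paste0("(", paste(vapply(ki, function(i)
        rec(tree$edge[i, 2L], i), character(1)), collapse = ","), ")")
    }
    if (!is.na(edgeIdx) && haveLen)
      lab <- paste0(lab, ":", sub("\\.$", "", fmt(tree$edge.length[edgeIdx])))
    lab
  }
  root <- n + 1L
  paste0(rec(root, NA_integer_), ";")
}

#' Canonical Newick form of unrooted tree topology
#'
#' Strips branch lengths, unroots, and serializes canonically; equal strings
#' imply (and are implied by) equal unrooted topologies. Used for
#' deterministic tie-breaking in tree search.
#'
#' @param tree an [ape::phylo] object.
#' @return a Newick string without branch lengths.
#' @export
canonicalTopology <- function(tree) {
  tr <- ape::unroot(tree)
  # re-root the unrooted (trifurcating-root) representation at the internal
  # node adjacent to the globally smallest leaf, making the form unique
  small <- sort(tr$tip.label)[1L]
  tr2 <- ape::root(tr, outgroup = small, resolve.root = FALSE)
  tr2$edge.length <- NULL
  writeNewick(tr2)
}

#' Topological identity of two unrooted trees
#' @param a,b [ape::phylo] trees over the same leaf set
#' @return logical
#' @export
sameTopology <- function(a, b) {
  identical(canonicalTopology(a), canonicalTopology(b))
}
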