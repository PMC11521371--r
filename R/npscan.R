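#' Neuropeptide precursor repeat patterns
#'
#' The four dibasic-repeat patterns used to screen proteomes for candidate
#' neuropeptide precursors. In block notation (DIBASIC = two residues each in
#' \{K, R\}; x(a,b) = a..b arbitrary residues, K/R allowed; Z = one residue,
#' identical at every Z position of a match; G = glycine):
#'
#' * P1: DIBASIC x(3,36) DIBASIC x(3,36) DIBASIC x(3,36) DIBASIC
#' * P2: DIBASIC x(2,35) Z DIBASIC x(2,35) Z DIBASIC
#' * P3: DIBASIC x(2,35) G DIBASIC x(2,35) G DIBASIC
#' * P4: DIBASIC x(1,34) Z G DIBASIC x(1,34) Z G DIBASIC
#'
#' Every P3 match is also a P2 match with Z = G (pattern subsumption).
#'
#' @return named list of pattern objects (id, block list, compiled regexes,
#'   minimal/maximal witness lengths).
#' @export
neuropeptidePatterns <- function() {
  D <- list(type = "DIBASIC")
  S <- function(a, b) list(type = "SPACER", min = a, max = b)
  Z <- list(type = "Z")
  G <- list(type = "G")
  specs <- list(
    P1 = list(D, S(3, 36), D, S(3, 36), D, S(3, 36), D),
    P2 = list(D, S(2, 35), Z, D, S(2, 35), Z, D),
    P3 = list(D, S(2, 35), G, D, S(2, 35), G, D),
    P4 = list(D, S(1, 34), Z, G, D, S(1, 34), Z, G, D)
  )
  lapply(names(specs), function(id) {
    blocks <- specs[[id]]
    compilePattern(id, blocks)
  }) |> stats::setNames(names(specs))
}

# build lazy-quantifier PCRE with one capture group per block; the first Z
# block captures, later Z blocks backreference it
compilePattern <- function(id, blocks) {
  pieces <- character(length(blocks))
  zGroup <- NA_integer_
  minLen <- 0L; maxLen <- 0L
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    pieces[i] <- switch(b$type,
      DIBASIC = "([KR][KR])",
      SPACER = sprintf("(.{%d,%d}?)", b$min, b$max),
      G = "(G)",
      Z = if (is.na(zGroup)) "(.)" else sprintf("(\\%d)", zGroup)
    )
    if (b$type == "Z" && is.na(zGroup)) zGroup <- i
    minLen <- minLen + switch(b$type, DIBASIC = 2L, SPACER = b$min, 1L)
    maxLen <- maxLen + switch(b$type, DIBASIC = 2L, SPACER = b$max, 1L)
  }
  list(id = id, blocks = blocks,
       regex = paste(pieces, collapse = ""),
       anchored = paste0("^", paste(pieces, collapse = ""), "$"),
       zGroup = zGroup, minLen = minLen, maxLen = maxLen)
}

#' Scan one protein sequence for precursor repeat patterns
#'
#' For each pattern, reports whether any block decomposition exists in the
#' sequence, together with one witness span: the leftmost possible start,
#' then the shortest end at that start. Spacer positions may contain any
#' residue including K and R; the Z residue is enforced identical within a
#' match.
#'
#' @param seq one amino-acid sequence (character scalar).
#' @param patterns pattern set from [neuropeptidePatterns()].
#' @return data.frame with one row per matching pattern: `pattern`, `start`,
#'   `end` (0-based half-open), `witness`, `z` (NA when the pattern has no Z
#'   block). Zero rows when nothing matches.
#' @examples
#' scanSequence("RRAAARRAAARRAAARR")
#' scanSequence("RRAAQRRAAQRR")$z
#' @export
scanSequence <- function(seq, patterns = neuropeptidePatterns()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  rows <- lapply(patterns, function(p) {
    hit <- regexpr(p$regex, seq, perl = TRUE)
    if (hit == -1L) return(NULL)
    s <- as.integer(hit)  # 1-based leftmost start
    eMax <- min(n, s + p$maxLen - 1L)
    e <- NA_integer_
    for (cand in seq.int(s + p$minLen - 1L, eMax)) {
      if (grepl(p$anchored, substr(seq, s, cand), perl = TRUE)) {
        e <- cand
        break
      }
    }
    if (is.na(e)) {
      # regex matched but only with an end beyond eMax bound; cannot happen
      # given maxLen is the exact maximal witness length
      stop("internal error: witness end not found for ", p$id)
    }
    witness <- substr(seq, s, e)
    z <- NA_character_
    if (!is.na(p$zGroup)) {
      m <- regexpr(p$anchored, witness, perl = TRUE)
      cs <- attr(m, "capture.start")[1L, ]
      z <- substr(witness, cs[p$zGroup], cs[p$zGroup])
    }
    data.frame(pattern = p$id, start = s - 1L, end = e,
               witness = witness, z = z, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pattern = character(0), start = integer(0),
                      end = integer(0), witness = character(0),
                      z = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Keep precursor candidates under a length cutoff
#'
#' @param seqs named character vector of sequences.
#' @param maxLen exclusive length bound; sequences with fewer than `maxLen`
#'   residues are kept (default 600).
#' @return the kept subset of `seqs`.
#' @export
lengthFilter <- function(seqs, maxLen = 600L) {
  seqs[nchar(seqs) < maxLen]
}

#' E-value-ratio validation of precursor candidates
#'
#' Compares each protein's best hit against a general database (nr) with its
#' best hit against a curated neuropeptide set: candidates whose ratio
#' best(nr E-value) / best(curated E-value) falls below `threshold` look far
#' more like a known non-neuropeptide protein and are discarded. Proteins
#' without an nr hit are kept (flag `no_nr_hit`); proteins without a curated
#' hit are kept and flagged `no_curated_hit` for downstream evidence.
#'
#' @param proteins character vector of protein ids to validate.
#' @param nrHits,curatedHits hit tables (see [hitTable()]) whose `score`
#'   column holds E-values (>= 0).
#' @param threshold discard ratio bound (default 1e-40).
#' @return data.frame: `protein_id`, `nr_evalue`, `curated_evalue`, `ratio`,
#'   `decision` in keep / discard / no_nr_hit / no_curated_hit.
#' @export
evalueRatioFilter <- function(proteins, nrHits, curatedHits,
                              threshold = 1e-40) {
  nrHits <- hitTable(nrHits); curatedHits <- hitTable(curatedHits)
  if (any(nrHits$score < 0) || any(curatedHits$score < 0))
    stop("E-values must be non-negative")
  bestOf <- function(h) {
    if (!nrow(h)) return(numeric(0))
    vapply(split(h$score, h$query), min, numeric(1))
  }
  bestNr <- bestOf(nrHits); bestCur <- bestOf(curatedHits)
  out <- data.frame(protein_id = proteins,
                    nr_evalue = unname(bestNr[proteins]),
                    curated_evalue = unname(bestCur[proteins]),
                    stringsAsFactors = FALSE)
  ratio <- rep(NA_real_, nrow(out))
  decision <- character(nrow(out))
  for (i in seq_len(nrow(out))) {
    nr <- out$nr_evalue[i]; cur <- out$curated_evalue[i]
    if (is.na(nr)) {
      decision[i] <- "no_nr_hit"
    } else if (is.na(cur)) {
      decision[i] <- "no_curated_hit"
    } else if (cur == 0) {
      if (nr == 0) {
        warning("both best E-values are 0 for ", out$protein_id[i],
                "; keeping")
        ratio[i] <- NaN
      } else {
        ratio[i] <- Inf
      }
      decision[i] <- "keep"
    } else {
      ratio[i] <- nr / cur
      decision[i] <- if (ratio[i] < threshold) "discard" else "keep"
    }
  }
  out$ratio <- ratio
  out$decision <- decision
  out
}

#' Cleavage products of a precursor pattern witness
#'
#' Splits a witness at its dibasic blocks (the prohormone-convertase sites).
#' Every inter-dibasic segment is a candidate peptide; a segment ending in
#' glycine is an amidation candidate and its mature form is reported with
#' the substrate G removed.
#'
#' @param witness the witness substring of a match.
#' @param patternId which pattern the witness matched (P1..P4).
#' @param patterns pattern set from [neuropeptidePatterns()].
#' @return data.frame: `peptide` (raw segment), `mature`, `amidation`.
#' @examples
#' cleavageProducts("RRAAGRRAAGRR", "P3")
#' @export
cleavageProducts <- function(witness, patternId,
                             patterns = neuropeptidePatterns()) {
  p <- patterns[[patternId]]
  if (is.null(p)) stop("unknown pattern id: ", patternId)
  m <- regexpr(p$anchored, witness, perl = TRUE)
  if (m == -1L) stop("witness does not match pattern ", patternId)
  cs <- attr(m, "capture.start")[1L, ]
  cl <- attr(m, "capture.length")[1L, ]
  caps <- substring(witness, cs, cs + cl - 1L)
  types <- vapply(p$blocks, `[[`, character(1), "type")
  # concatenate consecutive non-dibasic captures into inter-dibasic segments
  segs <- character(0); cur <- NULL
  for (i in seq_along(types)) {
    if (types[i] == "DIBASIC") {
      if (!is.null(cur)) { segs <- c(segs, cur); cur <- NULL }
    } else {
      cur <- paste0(if (is.null(cur)) "" else cur, caps[i])
    }
  }
  amid <- endsWith(segs, "G")
  data.frame(peptide = segs,
             mature = ifelse(amid, substr(segs, 1L, nchar(segs) - 1L), segs),
             amidation = amid, stringsAsFactors = FALSE)
}

#' Run the full precursor screen on a proteome
#'
#' Pipeline: pattern scan over all proteins, length filter on candidates
#' (< `maxLen` residues), then E-value-ratio validation when hit tables are
#' supplied (otherwise candidates are flagged `not_validated`).
#'
#' @param seqs named character vector of protein sequences.
#' @param nrHits,curatedHits optional hit tables with E-values (see
#'   [evalueRatioFilter()]); supply both or neither.
#' @param threshold E-value-ratio discard bound.
#' @param maxLen exclusive candidate length bound.
#' @param patterns pattern set.
#' @return data.frame with one row per surviving protein: `protein_id`,
#'   `length`, `patterns` (comma-separated ids), `witness` and `z` of the
#'   first matching pattern, `products` (;-separated mature peptides),
#'   `nr_evalue`, `curated_evalue`, `ratio`, `decision`.
#' @export
runPrecursorScreen <- function(seqs, nrHits = NULL, curatedHits = NULL,
                               threshold = 1e-40, maxLen = 600L,
                               patterns = neuropeptidePatterns()) {
  validateSequenceRecords(seqs)
  if (xor(is.null(nrHits), is.null(curatedHits)))
    stop("supply both hit tables or neither")
  hits <- lapply(seqs, scanSequence, patterns = patterns)
  matched <- names(hits)[vapply(hits, nrow, integer(1)) > 0L]
  cand <- lengthFilter(seqs[matched], maxLen)
  if (!length(cand))
    return(data.frame(protein_id = character(0), length = integer(0),
                      patterns = character(0), witness = character(0),
                      z = character(0), products = character(0),
                      nr_evalue = numeric(0), curated_evalue = numeric(0),
                      ratio = numeric(0), decision = character(0),
                      stringsAsFactors = FALSE))
  ids <- names(cand)
  rows <- lapply(ids, function(id) {
    h <- hits[[id]]
    prods <- cleavageProducts(h$witness[1L], h$pattern[1L], patterns)
    data.frame(protein_id = id, length = nchar(cand[[id]]),
               patterns = paste(h$pattern, collapse = ","),
               witness = h$witness[1L], z = h$z[1L],
               products = paste(prods$mature, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (is.null(nrHits)) {
    report$nr_evalue <- NA_real_
    report$curated_evalue <- NA_real_
    report$ratio <- NA_real_
    report$decision <- "not_validated"
  } else {
    val <- evalueRatioFilter(ids, nrHits, curatedHits, threshold)
    report <- cbind(report,
                    val[match(ids, val$protein_id),
                        c("nr_evalue", "curated_evalue", "ratio", "decision")])
    report <- report[report$decision != "discard", , drop = FALSE]
  }
  rownames(report) <- NULL
  report
}
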