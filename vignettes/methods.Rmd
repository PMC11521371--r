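---
title: "Methods behind GenomeEvoKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind GenomeEvoKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenomeEvoKit)
```

This vignette explains the statistical and algorithmic choices behind the
package's four analysis layers — gene-content phylogenetics, orthology,
macrosynteny classification and the neuropeptide precursor screen — and the
simulator that provides ground truth for all of them. It is a rationale
document; the README shows a worked pipeline run.

## Gene-content phylogenetics

### The model

Gene presence/absence across species is modelled as a two-state reversible
continuous-time Markov chain with stationary distribution
$(\pi_0, \pi_1)$. The transition matrix over a branch of length $t$ is

$$P(t) = \Pi + e^{-t/\beta}\,(I - \Pi), \qquad \beta = 2\pi_0\pi_1,$$

where $\Pi$ has rows equal to the stationary distribution. The scaling
$\beta$ makes a branch length of 1 equal one expected change per gene at
stationarity. Because the chain is reversible and the root prior is the
stationary distribution, the likelihood is invariant under re-rooting (the
pulley principle), so trees are treated as unrooted throughout;
`canonicalTopology()` reduces any rooted representation to a canonical
unrooted Newick string for comparison.

### Ascertainment correction

A presence/absence matrix assembled from orthology detection can never
contain a family absent in every species, and families present in exactly
one species are indistinguishable from annotation artifacts and are
conventionally excluded. `filterObservable()` removes both classes, and
`correctedLogLik()` conditions the likelihood on observability: each pattern
probability is divided by one minus the total probability of the excluded
patterns. Patterns with a single *absence* are retained — they are genuine
shared-loss signal, and excluding them would discard most of the information
about terminal branches. The module tests verify that corrected
probabilities of the observable patterns sum to one.

### Fitting, and what is identifiable

`fitBinaryModel()` maximises the corrected likelihood by coordinate ascent:
golden-section moves on $\pi_1$ and on each branch length, plus two ridge
moves — a global rescaling of all branches, and a joint move that changes
$\pi_1$ while rescaling branches so that $t/\beta$ is held fixed. The joint
move exists because $\pi_1$ and the overall tree scale are strongly
correlated: $\beta$ couples the rate scaling to the stationary
distribution, and plain per-branch updates zigzag along this ridge. Every
move is accepted only if it does not lower the incumbent likelihood, which
guarantees monotone convergence.

A practical caveat: on few taxa, the conditioned likelihood surface has a
competitive mode at the near-pure-loss corner ($\pi_1 \to 0$ with short
branches along the ridge), because a Dollo-like model can closely mimic the
conditional distribution of observable patterns. The *parameters* are
therefore weakly identified even when the *distribution* is fit well. Users
interested in interpretable parameters should work with many taxa; users
interested in topology are unaffected, because topology comparison uses the
maximised likelihood, not the parameter values.

### Topology search

`searchTopology()` offers exhaustive enumeration of all unrooted topologies
(capped at 7 taxa; 945 topologies) and a nearest-neighbour-interchange
hill-climb from a neighbour-joining start for larger problems. Candidate
topologies are screened with a loose fit and the winner is refit cleanly at
tight tolerance. `mcmcTrees()` provides a Bayesian check: a
Metropolis-Hastings sampler over (topology, branch lengths, $\pi_1$) with
NNI, multiplicative branch-length and reflected-$\pi_1$ proposals, plus
`majorityConsensus()` and `compareRuns()` (maximum clade-frequency
discrepancy between independent runs) for convergence assessment.

### Unequal loss rates and where a fast-losing lineage goes

A lineage that loses genes much faster than its relatives is the binary
analogue of a long-branch taxon, and it reproducibly triggers the classical
artifact: in simulations with one ingroup lineage at five-fold loss, the
maximum-likelihood placement of that lineage moves rootward of its true
position in the majority of replicates, while at equal loss it is placed
correctly. `attachmentDepthShift()` quantifies where a focal taxon attaches
relative to the true tree so that this behaviour can be measured rather
than assumed, and `urbilaterianCensus()` reports ancestral-family retention
per ingroup taxon, where a fast loser is also visible directly as depressed
retention.

A related and less obvious consequence of fitting the reversible model to
loss-only data deserves emphasis. The reversible model is unrooted and its
root prior is the stationary distribution, so the conditional distribution
implied by a *rooted* pure-loss process (family present at the root, lost
along branches, never regained) lies strictly outside the reversible
family. The maximised reversible likelihood compensates by invoking regains
near the root to explain blocks of shared absence, and at that optimum a
discriminating internal edge can collapse to zero length — leaving the true
topology and a nearest-neighbour alternative with *identical* maximised
likelihood. In our simulations with uniform per-branch loss, exhaustive
corrected-ML search recovers the generating 6-taxon topology in roughly
half of replicates for exactly this reason, even with thousands of
families; the failure is a property of the model/process mismatch, not of
the optimizer (an independent optimizer reproduces the same optimum, and
the generating Dollo process scores far above anything the reversible
family can reach on the same data). Users analysing loss-dominated data
should therefore treat topology ties and near-zero internal edges as a
diagnostic for this regime rather than evidence of resolution.

## Orthology

Pairwise scores are local alignments (Smith–Waterman) with affine gaps:
match +2, mismatch −1, a gap of length $k$ costs $5 + k$. The kernel is a
single-pass Gotoh formulation in C++. `bestHits()` breaks score ties by
lexicographically smallest target id, which makes results independent of
input order; `mutualBestHits()` intersects the two directions, and
`orthogroups()` takes connected components of the resulting graph. With no
sequence divergence, reciprocal best hits recover the true pairing exactly;
the module tests also check the DP kernel against an independent pure-R
three-matrix oracle.

## Macrosynteny classification

`sharedOrthologCounts()` cross-tabulates ortholog pairs by (query
chromosome, reference chromosome/ALG). `fisherEnrichment()` computes, for
every cell, the one-sided hypergeometric upper-tail probability of sharing
at least the observed number of orthologs given the margins (a cell with
zero shared genes has $p = 1$ exactly). `classifyALGComposition()` applies
Benjamini–Hochberg control across all cells and calls a (chromosome, ALG)
association significant when the adjusted $p$ is below `alpha` *and* the
raw shared count reaches `minShared` — the second condition guards against
tiny-but-significant overlaps in sparse tables. A chromosome's composition
is the set of ALGs it is significantly associated with;
`compositionSizes()` tabulates composition sizes, including zero for
chromosomes with no significant ALG.

One subtlety matters for interpreting composition-size histograms: a
*fission* of one ALG produces two chromosomes that each derive from exactly
that one ALG, so fission products are counted in the size-1 class alongside
never-fused chromosomes. In the packaged 24-ALG history
(`xenoturbellaKaryotypeHistory()`: ten ALGs untouched, one ALG split in two,
five pairwise fusions and one triple fusion) this yields 18 chromosomes with
the histogram 12 singles, 5 doubles, 1 triple.

## Neuropeptide precursor screen

`scanSequence()` searches protein sequences for repeating
prohormone-convertase cleavage architectures: dibasic sites (`KK`, `KR`,
`RK`, `RR`) separated by spacers, optionally with a conserved residue
(backreferenced `Z`) and/or an amidation glycine immediately before each
internal dibasic. Spacer length bounds are inclusive on both ends. Matches
report a *witness*: the leftmost match, and at the leftmost start the
shortest one, with 0-based half-open coordinates — so a witness is
reproducible and can be decomposed by `cleavageProducts()` into candidate
peptides, with trailing-glycine segments flagged as amidation candidates.
Candidate *proteins* are restricted to fewer than 600 residues
(`lengthFilter()`), applied to the input of the screen; the scan itself is
length-agnostic. `evalueRatioFilter()` validates candidates against two hit
tables: a candidate whose best general-database E-value is vastly smaller
than its best curated-neuropeptide E-value (ratio below the threshold) is
discarded as a known non-neuropeptide protein; candidates with no
general-database hit are kept (`no_nr_hit`), and candidates with no curated
hit are kept but flagged (`no_curated_hit`) rather than discarded, since an
empty curated database row is absence of evidence, not evidence of absence.

## The simulator

Ground truth for every layer comes from `simulateTree()`,
`evolveGeneContent()`, `evolveSequences()`, `simulateKaryotype()` /
`simulateSynteny()` and `plantPrecursors()`.

Gene content evolves by pure loss from a present root (no regain), with a
**per-branch** loss probability: each gene present at the parent is lost
along a branch with probability `lossProb`, regardless of branch length.
This is deliberately *not* the inference model — fitting a reversible model
to Dollo-generated data is the realistic misspecification test — and it has
a consequence worth stating: every internal edge induces, in expectation,
`lossProb` × (families present) shared losses, so internal edges are well
supported even at modest loss probabilities. Per-tip `lossOverrides` create
fast-losing lineages by raising the loss probability of single terminal
branches.

Protein sequences evolve by per-site, per-branch substitution to a uniformly
chosen different residue. Karyotypes are built from a reference species with
unfused ALGs and a derived species whose chromosomes follow a declared
fusion/fission history, with within-chromosome shuffling; the returned truth
records the ALG of every gene, the true ortholog pairs and the true
composition of every derived chromosome. `plantPrecursors()` embeds known
pattern witnesses in random backgrounds and records which sequences are
positives.

Every simulator consumes R's global random-number stream only, so a single
`set.seed()` makes any pipeline — including the command-line interface
`runPipelineCLI()` — bit-identical across reruns.
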