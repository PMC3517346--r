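---
title: "Methods: homology search, family clustering and phylogenomics of the polyamine oxidase family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology search, family clustering and phylogenomics of the polyamine oxidase family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paofam)
```

## The scientific problem

Vertebrates carry two specialised polyamine oxidases — spermine oxidase
(SMO) and acetylpolyamine oxidase (APAO) — where yeast and invertebrates
carry one broad-specificity PAO. Establishing that SMO and APAO are
paralogs born of a single duplication on the vertebrate stem, that each
subfamily then tracked organismal speciation, and that placental mammals
later added a long SMO splice isoform, requires a chain of standard but
error-prone computational steps: homology search, filtering, family
clustering, multiple alignment, conservation scoring, tree building and
gene-tree/species-tree reconciliation. `paofam` implements that chain as a
set of small, separately testable stages, together with a sequence-evolution
simulator that provides ground truth for every one of them.

## Homology search

`local_align()` computes exact affine-gap Smith–Waterman alignments. A gap
of length $L$ costs `gap_open` $+ (L-1)\cdot$ `gap_extend` (defaults 11/1
with BLOSUM62). After the optimal local alignment is reported, its aligned
spans are masked in both sequences — masked residues score $-\infty$ and
cannot be traversed at all — and the search repeats, so successive hits for
one pair occupy disjoint spans in both coordinate systems. This replaces a
heuristic BLASTP search with an exact computation: slower per pair, but the
result is reproducible and directly checkable against an independently
coded dynamic program, which the test suite does on hundreds of random
pairs. Externally produced BLAST tabular hits can be injected through
`read_blast_tab()` when a heuristic search is preferred.

Raw scores are converted to bitscores and E-values by the Karlin–Altschul
transform, $S' = (\lambda S - \ln K)/\ln 2$ and $E = mn\,2^{-S'}$. The
$\lambda = 0.267$, $K = 0.041$ defaults are the widely used gapped
BLOSUM62-11-1 constants; both are plain parameters of `scoring_scheme()`.
E-value magnitudes under exact Smith–Waterman are therefore interpretable in
the usual BLAST sense, and the default all-vs-all cutoff of $10^{-10}$
matches the workflow the package reproduces.

Coordinates are 0-based half-open internally (in the C++ kernels) and
1-based inclusive in every R-facing table, which keeps the TSV outputs in
the convention bioinformatics readers expect.

## Hit chaining

When a pair has several local hits, `chain_hits()` selects the subset that
is pairwise non-overlapping in *both* the query and the subject coordinates
and maximises total aligned length (query-span residues + subject-span
residues), by exact depth-first search with an upper-bound prune (hard cap:
64 hits per pair). Two readings of "longest alignable regions" were
possible — maximise hit count or total length; total length is used because
the chained coverage feeds the 50%-of-length filter downstream. Ties are
broken by higher summed raw score, then by the lexicographically smallest
hit-index set, so results are deterministic. Intervals that merely touch do
not overlap. No collinearity constraint is imposed — hits may appear in a
different order on query and subject — because domain shuffling is exactly
the signal one does not want to discard silently; `require_collinear = TRUE`
switches the constraint on. The chained combination is thereafter treated as
one composite hit: pooled identity $\sum \mathrm{id} / \sum \mathrm{cols}$
and summed bitscore.

## Filtering, reciprocal hits, and single-linkage families

`apply_filters()` keeps a chained ordered pair when combined identity
$\ge 0.30$, combined bitscore $\ge 50$, and the aligned residues cover
$\ge 50\%$ of *both* sequence lengths, excluding self-pairs. All thresholds
are inclusive ("at least" semantics); identity and coverage are computed
from the chained composite, not from the best single hit. A pair of
sequences is a two-way hit when both directions pass, and
`single_linkage_families()` merges whole families whenever any two members
share a two-way hit, repeating until stable — equivalently, connected
components of the two-way-hit graph, implemented with union-find and
verified against a breadth-first-search oracle on random graphs. Output
order and family numbering are deterministic (families numbered by their
smallest member id).

Because every threshold only removes edges, raising any of them can split
but never merge families; the suite checks this monotonicity on a fixed
simulated data set.

## Multiple alignment and conservation

`progressive_align()` is a deliberately basic progressive aligner: pairwise
global alignments give $1 - \mathrm{identity}$ distances, `hclust`/UPGMA
provides the guide tree, and profiles are merged by profile–profile affine
alignment under sum-of-pairs scoring (gap columns carry no residue mass).
It is a surrogate for an external aligner such as ClustalW, not a
reproduction of one — which is why aligned FASTA and Clustal `.aln` imports
are first-class (`read_alignment()`). On simulated families at the package's
study conditions the surrogate reproduces the simulator's true column
homology essentially exactly (the suite bounds the pairwise-distance
discrepancy against the truth alignment).

Column conservation is the majority-residue fraction, with gaps counted as
mismatches in the denominator by default; a column is flagged at
$\ge 0.90$. Both choices mirror how "conserved in at least 90% of the
sequences" is conventionally counted; the published wording varies between
"at least" and "more than" 90%, so the strictly-greater variant is exposed
as `strict_gt = TRUE` rather than silently chosen, and
`gaps_in_denominator = FALSE` switches to scoring over non-gap rows only.
Consensus sequences take the most frequent non-gap residue per column
(alphabetic tie-break) and drop columns where the gap state is strictly the
most frequent. `map_active_sites()` resolves residue panels (e.g. the mouse
SMO panel Trp80, His82, …, Thr528, packaged in `inst/extdata/`) through the
reference row's numbering and errors on any reference/panel mismatch, so a
frame shift in the alignment cannot silently misreport conservation.

## Phylogeny

`protein_distance()` computes the mismatch fraction over columns where
neither row is gapped, with Poisson ($-\ln(1-p)$) or Kimura
($-\ln(1-p-p^2/5)$) correction. `neighbor_joining()` is the standard
Saitou–Nei agglomeration with two determinism rules: Q-criterion ties break
to the smallest index pair, and negative branch estimates are clamped to
zero with the deficit moved to the sibling edge. On additive matrices the
algorithm recovers the generating tree exactly (topology and lengths), which
the suite verifies over hundreds of random trees with branch lengths in
[0.01, 1].

Maximum-likelihood and Bayesian tree inference are intentionally out of
scope: the claims this pipeline supports are topology-level (monophyly of
subfamilies; placement of one duplication), NJ on simulated data tests them
directly, and externally computed trees can be imported as Newick at any
point. Bootstrap support (`bootstrap_support()`) resamples alignment columns
with replacement, rebuilds distance + NJ per replicate, and reports the
fraction of replicates containing each internal-edge bipartition, attached
to the full-data tree as node labels. Rooting places the root at the
midpoint of the outgroup's pendant edge (yeast plays this role in the real
data); bootstrap supports are rooting-invariant and carried over.

## Reconciliation

`reconcile()` maps every gene-tree node to the species-tree LCA of its
descendant taxa; a node is a duplication when it maps to the same species
node as at least one child, otherwise a speciation. Leaf pairs whose LCA is
a duplication are paralogs, all others orthologs. This is the minimal
formalisation of reading a gene-family phylogeny by eye: no loss costs, no
transfers, no model comparison. Where the underlying biology is genuinely
ambiguous — e.g. whether the two amphioxus PAO copies reflect a
chordate-wide or a lineage-specific duplication — the tool reports the
mapped species branch of each duplication node and makes no call.

## The isoform analysis

The long-isoform survey ships as a verbatim 25-row table; a record carries
the long isoform unless its label reads "no isoform", which yields the
published 22-vs-3 census (the three non-carriers being the two marsupials
and the platypus). One listed label ("isoform 1" for the Sumatran orangutan)
is ambiguous in the source; the fixture stores the label verbatim and the
census rule is explicit, so the reading is auditable rather than baked in.
`parsimony_gain()` places the gain of a binary presence character by Fitch
parsimony; among equally parsimonious labelings it prefers absence at the
root and keeps the parent's state whenever allowed, which dates each change
to the latest compatible branch — so presence confined to one clade yields a
single gain on that clade's stem. The event count is verified against an
exhaustive labeling oracle on small trees. `domain_conservation()` averages
column conservation over designated blocks (the NDA/NDB analogs) per clade,
quantifying the placental-versus-other contrast.

## The simulator and what passing tests mean

`simulate_family()` evolves a root protein along the gene tree implied by a
species tree plus a duplication scenario. Design choices:

* **Substitution process.** Continuous-time Markov chain built from an
  empirical exchangeability matrix and stationary frequencies, normalised to
  one expected substitution per site per unit branch length and simulated
  exactly by its jump chain. The default matrix is JTT, resolved at run time
  from phangorn's packaged model table; any PAML-layout `.dat` file can be
  substituted (`read_exchange_matrix()`), so the matrix is data, not code.
* **Rate heterogeneity (I+G).** Each site draws rate 0 with probability
  `p_invariant`, otherwise Gamma(α, mean 1); defaults α = 1,
  I = 0.2 — mid-range values for protein families of this depth. Rates are
  drawn once per site and inherited, as in the standard I+G model.
* **Constrained columns.** A configurable set of root columns has rate
  multiplier 0 and is never hit by indels, globally or per post-duplication
  subfamily (`locus_constraints`), emulating active-site residues that are
  conserved family-wide or in only one subfamily (the SMO-specific
  Glu216/Ser218 pocket pattern).
* **Indels.** Single-residue insertions/deletions at `indel_rate`
  events/site/unit length (default 0.01 — enough to exercise gap handling
  without dominating alignments), applied after the branch's substitutions;
  the true column homology is tracked throughout and returned as the truth
  alignment.
* **Duplication and losses.** The duplication sits at the midpoint of the
  stem edge of a designated clade; per-taxon, per-locus retention models
  secondary losses (the single PAO copy of a sea-squirt-like taxon).
* **Extra exon.** A 40-residue block appended after a configurable anchor
  (default: the C-terminus), evolving under the same process at a reduced
  rate (default multiplier 0.3) within the carrier clade only — the exon-VIa
  analog, sized to match a short alignable domain block.
* **Determinism.** One master seed; every stochastic draw flows from R's
  RNG seeded once, so identical inputs give byte-identical FASTA/TSV
  outputs.

The default alignment length for tree-building experiments is 400–500
sites, typical of PAO-family proteins' alignable core and large enough for
bootstrap supports to be informative at the simulated divergences.

What the simulator does *not* emulate: codon structure and selection
(dN/dS), domain-level rate variation, alignment-length heterogeneity from
large structural indels, compositional drift across lineages, and database
artefacts (truncated or chimeric predicted proteins). Tests passing on
simulated families therefore certify the *algorithms* — that chaining is
optimal, clustering equals connected components, NJ is consistent,
reconciliation recovers a planted duplication — not that real database
sequences will be as well-behaved.

## Study conditions used by the verification suite

The end-to-end checks simulate two unrelated families over the same
six-taxon-plus-outgroup species tree (ingroup root-to-tip ≈ 0.2
substitutions/site, duplication stem 0.4, outgroup 0.6 + 0.6). These depths
put within-subfamily identity near 60–65% and cross-subfamily identity near
45–50% — comfortably above the 30%/50% filter thresholds within a family,
and far below any chance similarity between the two unrelated families — so
the correct outcome under default thresholds is exactly two families, which
is what the adjusted-Rand-index check asserts. Bootstrap monophyly of the
two subfamilies is checked at 100 replicates (a desk-scale stand-in for the
500 used on the real data). The planted-conservation closed loop instead
uses a deep tree (pairwise divergence ≈ 2–4 substitutions/site, no
invariant sites, α = 20) so that every unconstrained column almost surely
varies and the ≥ 90% flag isolates exactly the planted columns. The
reconciliation check runs 200 random single-duplication scenarios on true
gene trees, isolating the reconciliation step from tree-estimation error.

## Numerical and degenerate-input conventions

Distance corrections error outside their domain ($p \ge 1$ for Poisson,
$1 - p - p^2/5 \le 0$ for Kimura) rather than returning `NaN`. Pairs with no
shared ungapped columns are an error, not a silent zero. A single-sequence
"alignment" is returned unchanged with a warning. The hit-chaining cap (64
hits/pair) errors loudly instead of degrading to a heuristic. Sequences may
contain `X`, which scores zero against everything; any other non-standard
letter is rejected at parse time. All TSV artifacts carry headers and are
read back by the same module that wrote them, which the pipeline tests
assert file-by-file.

## Known limitations

The progressive aligner has no iterative refinement and will fall behind
dedicated MSA tools on distant or gappy real families — import paths exist
precisely for that case. NJ is a surrogate for likelihood methods: adequate
for deep, well-separated splits, weaker near short internal edges.
Reconciliation assumes a rooted, binary gene tree and does not penalise
losses, so a badly estimated gene tree inflates duplication counts (the
pipeline roots with the outgroup before reconciling, and the simulator's
true trees quantify how much of any error is tree estimation rather than
reconciliation). The Karlin–Altschul constants are not re-estimated per
scoring scheme; for non-default matrices the user should supply matching
λ and K.
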