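---
title: "Methods: ortholog inference, profiling and pattern discovery in icortho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ortholog inference, profiling and pattern discovery in icortho}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icortho)
```

`icortho` chains six analysis stages — similarity search, graph-based
ortholog inference, annotation-quality validation, phylogenetic profiling,
conserved-pattern discovery and pore-domain calling — and ships the
synthetic-cohort generator that makes all of them testable against known
ground truth. This vignette documents the models, the tunable parameters,
the numerical choices, and what the synthetic tests do and do not
demonstrate about real data.

## Similarity search and E-values

Pairwise similarity is the optimal Smith–Waterman local alignment under
affine gaps (a gap of length $L$ costs `gap_open` $+ L\cdot$`gap_extend`;
defaults 11/1 with BLOSUM62). Raw scores are converted with
Karlin–Altschul statistics,

$$E = K\,m\,n\,e^{-\lambda S},$$

where $m$ is the query length and $n$ the total residue count of the
searched proteome set (the convention of standard search tools). The
default constants are the usual gapped BLOSUM62 pair
($\lambda = 0.267$, $K = 0.041$); an ungapped pair
($\lambda = 0.318$, $K = 0.134$) is available via
`scoring_scheme(gapped = FALSE)`. Inside `search_all()` E-values are
floored at the smallest positive double so that underflowed perfect hits
still behave monotonically under any cutoff. The aligner is checked
exactly, over hundreds of random short pairs, against a from-scratch
Gotoh dynamic program kept in the test suite.

The hit-table contract (query, subject, proteome, raw score, bitscore,
E-value, matched intervals; ordered by bitscore, then E-value, then
subject id) is deliberately minimal so that a wrapper around an external
search tool can substitute for the internal aligner at corpus scale
without touching the orthology stage.

## Ortholog inference

The inference is reference-centric and runs twice per query set: once
with full-length sequences, once with the pore-domain subsequence
(`domain_start`–`domain_end`). Stages:

1. **Forward search** at `e_forward_max` (default `1e-5`).
2. **Reciprocal confirmation**: for each (query, proteome) the forward top
   hit is aligned back against the reference set *in the same mode*;
   the pair survives only if the reverse best hit is the original query
   (mutual top) with reverse E-value at most `e_reciprocal_max`.
3. **Graph clustering**: retained pairs form an undirected graph with
   edge weights $\min(-\log_{10} E_{\text{forward}}, 200)$; a
   Markov-flow clustering (expansion 2, inflation 1.5, column-normalised,
   deterministic sorted node order) partitions the graph and pairs whose
   endpoints fall in different clusters are removed. Self-loops are set
   to each node's maximum incident weight: with loops much smaller than
   the edge weights, expansion on star-shaped RBH graphs oscillates
   between the two sides of the near-bipartite structure instead of
   converging to one attractor.
4. **Evidence intersection**: only (ic, target) pairs found in *both*
   modes are kept (`evidence = "both"`), carrying the per-mode maximum
   E-values as the conservative summary.
5. **Relationship labelling**: within a proteome a pair is `one-to-one`
   iff its ic has exactly one target there and that target maps back to
   exactly one ic; any multiplicity makes all involved pairs
   `co-ortholog`.

Two reciprocal-threshold profiles exist and must be chosen explicitly.
The `"paper"` profile keeps the documented full-scale threshold
(`1e-200`), which is meaningful for multi-hundred-residue alignments
against proteome-scale search spaces. The `"desk"` profile uses `1e-3`:
synthetic sequences of a few hundred residues cannot reach E-values
anywhere near `1e-200`, and the stringency of the reciprocal step is
carried by the mutual-top requirement rather than the threshold. Both
values are recorded in the run manifest.

The ground-truth generator defines orthology by reconciliation: a
cross-species pair is orthologous iff its gene-tree LCA is a speciation
node, and it is `one-to-one` iff each member is the other's only ortholog
in its organism. This operational co-ortholog definition matches the
labelling rule above and is verified against an independent
species-overlap reconciliation in the tests.

## Validation

Validation is a short-circuit three-step filter. Reviewed entries pass at
step 1. Unreviewed entries with protein-, transcript- or
homology-level existence evidence pass at step 2. The remainder
(Predicted/Uncertain) must pass **all five** sequence-QC checks — the
conjunction is deliberate, and the sequence-version check is treated as
disqualifying on its own, the strict reading of "pass all the checks".
The length bounds ([30, 5000] aa) are the documented ones; the other
three checks are named but not quantified upstream, so the package fixes
reproducible defaults, all exposed in `qc_config()`:

| check | rule | default |
|---|---|---|
| non-standard residues | fraction outside the 20-letter alphabet | ≤ 0.05 |
| compositional bias | sliding 20-residue windows with Shannon entropy < 2.2 bits | < 50% of windows |
| sequence version | `sequenceVersion` | ≤ 100 |
| cross-references | `crossRefCount` | ≥ 1 |

Date-based recency checks are not implemented (no date field is in
scope). The defect generator plants each defect past these exact
thresholds and routes defected records to step 3 (Unreviewed +
Predicted/Uncertain), so the planted `is_valid` label is precisely the
verdict a correct validator must produce; the short-circuit order is
asserted separately (a Reviewed record with a planted length defect must
still pass).

## Profiling, clustering, enrichment

The profile matrix is three-state per (ic, organism): 0 absent,
1 one-to-one, 2 co-ortholog (co-orthology dominates). The family-by-
lineage percentage is

$$P_{fl} = 100\cdot\frac{O_{fl}}{N_l\,S_f},$$

with $O_{fl}$ counting **distinct nonzero cells**, not co-ortholog
multiplicity — the bounded reading that keeps $P_{fl} \le 100$ and makes
the quantity a percentage; the three-state matrix is kept for display.

Clustering binarises presence (state ≠ 0), restricts to eukaryote
organisms (prokaryotic profiles are too sparse to be informative), and
cuts a Ward/Euclidean agglomeration into `k` flat clusters; `k` defaults
to 9 and is a parameter, not estimated from data. The agglomeration is
implemented in the package with the Lance–Williams recurrence and a fully
deterministic tie-break (merge the pair with lexicographically smallest
original row indices): binary profile rows produce tied linkage values
routinely, and `stats::hclust` does not specify its tie order. On
tie-free data the result coincides with `hclust(method = "ward.D2")`
(asserted in the tests); on all data it equals an exhaustive
agglomeration oracle that recomputes within-cluster variance from scratch.

Enrichment is a generic annotation test, not an ontology client: for each
term, $p = P(X \ge k)$ under the hypergeometric null, Benjamini–Hochberg
adjusted across the terms of one cluster, retaining $q <$ `fdr_max`
(default 0.01). Ontology-graph propagation is out of scope; term
annotations are a user-supplied table.

## Pattern discovery

The pattern stage is a transparent surrogate for Bayesian pattern-
partitioning classifiers, with the same inputs and outputs (alignment +
partition in, ranked pattern positions out) but simple, fully documented
statistics; results are comparable in kind, not numerically identical to
any external tool. Per column, with $x$ of $m$ foreground and $y$ of $n$
background residues matching a candidate set $R$, the score is the
pseudocounted binomial log-likelihood ratio

$$S = x\log\frac{\hat p}{\hat q} + (m-x)\log\frac{1-\hat p}{1-\hat q},
\qquad \hat p = \frac{x+\alpha}{m+2\alpha},\ \hat q = \frac{y+\alpha}{n+2\alpha},$$

maximised over a fixed library of candidate sets: the 20 singletons plus
the conservative groups ILVM, FYW, KR, DE, ST, NQ (small enough that the
search stays exhaustive). Only foreground-enriched sets
($\hat p > \hat q$) are eligible, so a column whose signal is background
conservation is never reported as a foreground pattern. Gaps are excluded
from counts; columns with more than 50% foreground gaps are skipped and
listed.

Significance is an empirical permutation p-value over `n_perm` (default
1000) random relabelings of the partition, with mid-p counting:

$$p = \frac{0.5 + \#\{S_{\text{perm}} > S_{\text{obs}}\} + 0.5\,\#\{S_{\text{perm}} = S_{\text{obs}}\}}{n_{\text{perm}} + 1}.$$

Scores built from integer counts are discrete, so the conventional
$(1 + \#\{\ge\})/(n+1)$ estimator is systematically conservative under
ties; mid-p is the standard correction for discrete permutation tests and
is what keeps the selection rate at `p_max` calibrated under the null
(a property the acceptance suite checks at 0.01 ± 3 standard errors over
4 000 null columns).

Family-shared analysis contrasts the whole family against a background
composition — by default the alignment-wide residue composition, with the
family size as its pseudo-count mass — because the natural contrast set
(other channel families) is not part of the input; the null distribution
comes from columns drawn i.i.d. from that composition. A retained
position must additionally reach modal-residue frequency `c_min`
(default 0.7) within *every* subfamily. Positions are mapped to reference
numbering as residue letter + count of non-gap reference positions up to
the column; columns gapped in the reference are flagged unlabelled.

Sequence weighting is uniform in this version — a known limitation, since
deep ortholog sets are phylogenetically redundant and a heavily sampled
clade can dominate the counts.

## Pore-domain calling

Transmembrane interval sets from different sources are merged by
precedence — literature > database annotation > predictors (pooled) >
structure-derived — encoding sequential verification rather than voting.
Within the chosen set, overlapping intervals are unioned; intramembrane
segments extend the span but are not counted as TMs. The domain call is
`start = min(starts)`, `end = max(ends)`, and `length = end − start`: the
span-difference convention of the source annotation tables (Aquaporin-1:
228 − 8 = 220), one less than the inclusive residue count — callers
expecting inclusive lengths should add 1. Unit classification is total:
pore domain present → pore-containing; absent with complex evidence →
auxiliary; otherwise excluded.

## The synthetic cohort: what it emulates, and what it does not

The generator emulates the features the pipeline's correctness depends
on: lineage-labelled species trees; gene families with duplication/loss
(hence true co-orthologs and absences); sequences whose pore domain
evolves more slowly than its flanks (independent per-site replacement,
$P(\text{change}) = 1 - e^{-r\,t}$, flat target distribution over the 19
alternatives — chosen to keep the oracle analytic); metadata defects
planted past the exact validator thresholds; and alignments with planted
family-shared and subfamily-specific columns flipped with probability
`noise`.

It does **not** emulate realistic substitution matrices, indels (columns
equal positions by construction, which is what makes pattern truth
exact), rate heterogeneity beyond the domain/flank split, genuinely
ambiguous annotation metadata, or the 1,596-proteome corpus scale.
Passing tests therefore demonstrate algorithmic correctness against the
stated models — not that the thresholds are optimal for real proteomes,
nor that corpus-scale results are reproduced. Headline corpus numbers
(hundreds of curated channels, tens of thousands of relationships)
depend on the full proteome collection and external search tools and are
out of scope by design.

Default study conditions, used by the tests and the acceptance script:
8 taxa across four lineages, 12 families, no duplication or loss,
branch scale 0.1 substitutions/site, 240-residue proteins with an
80-residue domain at rate 0.3 vs flanks at 1.0; patterned alignments of
4 subfamilies × 50 sequences × 100 columns at noise 0.1; null
calibration over 20 × 200 i.i.d. columns with 1000 permutations. These
sizes make every stage's behaviour measurable in minutes on one CPU
while leaving the signal regimes (divergence, noise, defect rates)
non-trivial.

## Numerical and degenerate-input choices

* Seeds: every generator is a pure function of (arguments, seed); a
  master seed fans out to per-stage child seeds via a deterministic
  string hash (`derive_seed()`), all below $2^{31}$.
* Markov-flow clustering: convergence tolerance `1e-6` on the max
  absolute change, at most 200 iterations, clusters read off the
  converged matrix's non-zero support (threshold `1e-8`).
* Ward heights are reported on the Euclidean (`ward.D2`) scale.
* `local_align()` returns score 0 with `NA` intervals when no
  positive-scoring alignment exists; empty sequences and non-alphabet
  characters are errors, `X` is accepted and scored by the matrix.
* A single-taxon species tree, empty pair tables, empty candidate sets
  and empty enrichment term maps all return typed empty results rather
  than errors; empty universes, empty member sets and ragged alignments
  are errors.
* Pipeline tables are written with 10 significant digits and empty
  strings (never literal `"NA"`) for missing cells, so byte-identical
  reruns are achievable and asserted via the MD5 manifest.
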