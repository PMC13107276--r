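---
title: "Methods: quantifying plastome degradation and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying plastome degradation and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(plastevol)
```

This vignette is the package's own account of the models and procedures it
implements, the assumptions behind them, and the choices made where the
design was genuinely open. The quantitative behaviour referred to here is
exactly what the test suite and `scripts/acceptance.R` compute; nothing
below reports a number that those do not reproduce.

## The biological setting

Plastomes of plants that relax or abandon photosynthesis degrade along a
well-known trajectory: the *ndh* genes (subunits of the plastid NADH
dehydrogenase-like complex) are pseudogenized or lost first, genome length
and GC content decline, repeats and foreign-looking insertions accumulate,
inverted-repeat (IR) boundaries wander, and purifying selection on the
remaining protein genes weakens. The package measures each of these axes
from assembled genomes and derived data (codon alignments, strand-specific
fragment counts, pileups); it deliberately does not assemble reads, build
alignments or infer trees — those are upstream tools' jobs, and the
package consumes their outputs.

## Coordinates and containers

All coordinates are 1-based inclusive, the convention of the IRanges /
Biostrings ecosystem the package is built on; GenBank and GFF3 (1-based)
are read and written directly, and BED output is converted to 0-based
half-open at the boundary. Circular genomes are stored linearised at the
conventional LSC start; a feature wrapping the origin is represented as
two rows sharing a `wrap` flag.

## Inverted-repeat detection

`detect_inverted_repeat()` seeds exact 21-mers between the genome and its
reverse complement, extends ungapped along each diagonal (match +1,
mismatch −3, X-drop 100), and keeps the longest pair of disjoint segments
of at least `min_len` (default 1000 bp — plastid IRs are tens of kb;
anything shorter is a dispersed repeat, not the IR) at identity at least
`min_identity` (default 0.99; the two IR copies are homogenised by gene
conversion and are essentially identical in real plastomes). Ties on
length break by identity, then leftmost position. The single-copy stretch
between the two copies is SSC if it is the shorter one; the IR copy
preceding it in the linearised record is IRb. The non-redundant length is
the total length minus one IR copy. A genome shorter than `2 * min_len`
warns and reports `has_ir = FALSE` rather than failing: IR loss is a real
biological outcome, not an error.

Because extension is ungapped and exact-scoring, a planted IR flanked by
a chance complementary base is *correctly* reported one base longer; the
synthetic generator therefore pins the SSC termini to `A` so that planted
coordinates equal detected coordinates exactly.

## Coverage-based gene classification

Each reference CDS is located in the target genome by the same
seed-and-extend engine (word 11); if no anchor of at least `min_anchor`
(50 bp) exists anywhere, the gene is *lost*. Otherwise candidate ORFs
(ATG to in-frame stop, both strands, `orf_scan()`) overlapping the locus
are aligned to the reference CDS with a global Needleman–Wunsch alignment
(match +1, mismatch −1, gap open −5, gap extend −1; an L-base gap costs
5 + (L − 1)). Coverage is the fraction of reference bases aligned to
query bases. The decision rule is inclusive at the threshold: coverage
≥ 0.70 → *intact*, below → *pseudogene*. Because coverage can never
exceed len(candidate)/len(reference), candidates are scanned in
decreasing length and the scan stops as soon as no remaining ORF could
beat the best coverage — the reported maximum is exact, not heuristic.

Two deliberate refinements:

* **Override list.** Genes whose shortened CDS is a normal autotroph
  variant can be annotated intact below threshold when present with
  coverage at least 0.5. The shipped list contains only `psbI`;
  it is a parameter, not a constant.
* **The coordinated *ndh* rule** (`apply_ndh_cascade()`): if any *ndh*
  gene is pseudogenized or lost, all eleven are downgraded (intact →
  pseudogene; lost stays lost), because the NDH complex does not assemble
  when any subunit is missing. Coverage values are kept as evidence,
  `cascade_applied` marks calls changed by the rule, and the operation is
  idempotent.

The synthetic generator plants truncations in the 0.35–0.62 coverage
range. This is not cosmetic: a premature stop at fraction *c* leaves a
downstream in-frame fragment of roughly 1 − *c*, which itself becomes a
candidate ORF; keeping *c* ≥ 0.35 ensures neither fragment approaches the
0.70 decision boundary, so planted truth and classifier output are
comparable without a grey zone (the recovery tests additionally require
planted coverages outside [0.68, 0.72]).

## Short repeats, E-values and the content slope

`find_short_repeats()` self-aligns the IR-reduced genome (one IR copy —
otherwise the IR itself would swamp the repeat landscape) with word size
7, ungapped X-drop extension at +1/−2, and scores hits by the
Karlin–Altschul expectation E = K·m·n·e^(−λS) with λ = 1.33, K = 0.62 —
the canonical ungapped parameters for +1/−2 nucleotide scoring, so scores
and E-values are mutually consistent. Hits of 500 bp or more are
discarded (they belong to the large-repeat class), the self-diagonal is
excluded, and mirrored inverted pairs are deduplicated keeping the pair
with the smaller first coordinate. Gapped extension is deliberately
omitted: at word size 7 the short-repeat class is dominated by ungapped
matches, and the exhaustive small-sequence oracle in the tests stays
exact.

`repeat_content_curve()` computes one hit set at the loosest threshold
and filters per threshold, which makes content (merged footprint over
IR-reduced length) monotone in E by construction — the monotonicity
assertion in the tests then checks the merging, not the search.
`content_slope()` is ordinary least squares of content on log10(E) with a
t-based 95% CI; the slope measures how much low-similarity repeat
sequence a genome accumulates as the threshold relaxes, and is
comparable *between* genomes analysed with the same engine. Absolute
E-values are implementation-relative (the original study's search-tool
settings are not fully specified), which is why all repeat comparisons in
this package are property- and contrast-based rather than absolute.

## Homology maps, indels, species-specific fragments

`homology_intervals()` applies the same engine across genomes (word 7,
anchors below `min_anchor` = 30 bp dropped as seed-level noise, anchors
merged across gaps of up to 25 bp). Insertions are the complement of the
homology footprint on the query, deletions the complement on the
reference; contents divide by query length and reference length
respectively. Fragments shorter than `min_fragment` (30 bp) are dropped —
at word size 7 anything smaller is indistinguishable from alignment
noise. `species_specific_fragments()` takes the complement of the *union*
of homology footprints against every comparator (equivalently, the
intersection of pairwise complements — an identity the tests assert) and
annotates each fragment with overlapping genes and IR membership, because
lineage-specific insertions concentrating in the IR (typically within
*ycf1*) are a diagnostic pattern of structurally dynamic plastomes.

## Expression and RNA editing

FPKM is computed exactly as fragments × 10⁶ / (total fragments × length
in kb), with the total counted over both strands; the conservation
identity Σ FPKM·len_kb = 10⁶ holds to 10⁻⁹ whenever the features
partition all mapped fragments, and is asserted. Clustering is UPGMA on
Euclidean distances via `stats::hclust`, exported as Newick through
`ape`.

The editing caller requires, at a candidate position (reference C with T
variants, or reference G with A variants — the two orientations of
plastid C-to-U editing): coverage ≥ 60, variant fraction ≥ 0.10, a
one-sided binomial tail P(X ≥ x | n, ε) ≤ 10⁻⁶ against the sequencing
error rate ε (default 0.001), and — only when one strand carries more
than 65% of the variant reads — a two-sided Fisher exact test of variant
versus total reads by strand with p ≥ 10⁻⁵ (significantly biased sites
are rejected; genuine editing affects the transcript, not one sequencing
strand). The bias rule is stated ambiguously in common tool
documentation; this package resolves it as "the filter only engages above
65% imbalance, and then rejects significant bias", which is the reading
that keeps balanced high-efficiency sites callable. Efficiency is the
variant fraction. Silent/non-silent status translates the affected codon
under the standard genetic code, mirroring the substitution into the
sense strand for minus-strand genes.

With these thresholds and ε = 0.001, a false call needs both ≥ 10%
variant fraction and a binomial tail below 10⁻⁶ at coverage ≥ 60 — the
expected number of false calls across a 150 kb genome is far below one,
and the acceptance suite verifies zero calls on a simulated null pileup
of that size. Sensitivity: the generator plants efficiencies in the
0.3–0.9 range at coverages of 150–400×, the regime plastid transcripts
actually occupy; there each planted site clears every threshold with
margin and the suite requires 100% recall. At the exact corner
(efficiency 0.10, coverage 60) recall is limited by binomial sampling of
the variant count itself, not by the caller — a site drawing 5 of 60
variant reads is below the frequency rule by definition.

## The MG94 selection machinery

The codon model is MG94-type on the 61 sense codons: rate(i→j) = 0 unless
the codons differ at one nucleotide, otherwise s(a,b)·π_j·(ω if
nonsynonymous), with HKY exchangeabilities (κ estimated; full GTR
supported in the likelihood core) and F3×4 codon frequencies computed
empirically from the alignment, never optimised. Likelihoods come from
Felsenstein pruning with per-node rescaling; transition matrices use the
symmetrised eigendecomposition of the reversible generator.

**Rate normalisation (an important convention).** All rate matrices
within one model evaluation share the normalisation constant of the
*background* process: branch lengths are expected substitutions per codon
for a background site, and a branch or site class at a different ω
evolves proportionally faster or slower (the raw rate is linear in ω).
Self-normalising every matrix instead would make ω affect only the
*composition* of substitutions, not their number — which silently
destroys most of the branch-site signal and changes the meaning of Δω.
The simulator uses the identical convention, so recovery tests are
internally consistent.

**Branch models and the classification.** M0 (one ω), b_neut (foreground
ω fixed at 1) and b_free (foreground free) are fitted by box-constrained
L-BFGS-B on log parameters, ω ∈ [10⁻⁴, 20]; κ is estimated jointly with ω
under M0 and then held fixed, and branch lengths are taken from the input
tree (optionally rescaled once under M0 via `optimize_blen = TRUE`) and
held fixed across models, so the models remain nested in the ω
parameters alone. b_free starts from the M0 estimate and falls back to a
grid of starts (ω ∈ {0.1, 0.3, 0.5, 1, 2}) whenever its likelihood drops
below a nested null — the nesting inequalities are asserted in the tests.
LRTs use 2Δℓ against χ² with df equal to the difference in free
parameter counts, with small negative statistics clamped to zero; no
boundary mixture correction is applied (the plain LRT is the convention
this classification follows). A gene is *Relaxed* when b_free vs M0 is
significant (p < 0.05) and ω_fg > ω_bg, *Strengthened* when ω_fg < ω_bg,
and additionally *under relaxed selection* when the foreground does not
deviate from neutrality (b_free vs b_neut p ≥ 0.05). Genes with any
estimated ω ≥ 10 or ≤ 0.001, or any non-converged fit, are excluded from
interpretation. On the package's default simulation scenario (below) the
b_free-vs-M0 test is calibrated — the acceptance suite requires a
null rejection rate in [3%, 8%] at α = 0.05 over 500 replicates — and
has ≥ 80% power at ω_bg = 0.2 vs ω_fg = 0.8 with 500 codons.

**Branch-site test.** Model A (classes 0, 1, 2a, 2b; ω2 ≥ 1 free on the
foreground) against its null (ω2 = 1), df = 1. Class proportions use the
standard parameterisation p2a = p2·p0/(p0+p1), p2b = p2·p1/(p0+p1), fitted
through a softmax transform. Site identification uses empirical Bayes at
the MLEs (NEB) with posterior ≥ 0.95 — full Bayes Empirical Bayes
integration over parameter priors is out of scope, and NEB at these data
sizes is the standard fallback; the posterior threshold is kept at 0.95.
The selected-site ratio (sites / protein length) is binned as <0.25%,
0.25–0.50%, or — a case representable in simulation though not in the
original study's bins — >0.50%.

**Pairwise rates.** `ng86_rates()` implements Nei–Gojobori (1986)
counting: synonymous site fractions per codon (changes to stops counted
nonsynonymous), differences averaged with equal weight over all minimal
substitution pathways that avoid stops (all-path fallback when every
pathway is blocked), Jukes–Cantor correction d = −(3/4)·log(1 − 4p/3)
with a saturation flag at p ≥ 3/4. The full 61×61 pathway table is
verified against an independent enumeration oracle. `pairwise_mg94()`
provides the ML counterpart (2-taxon MG94, joint t and ω), with dN and dS
derived by partitioning the fitted substitution flux. `hky85_distance()`
covers non-coding regions (joint ML of distance and κ, empirical base
frequencies). `branch_rate_regression()` regresses dS on dN across
branches (both directions are reported, since which axis a published
slope refers to is not always recoverable) and reports excluded branches
by their own dS/dN ratio.

## The synthetic-data generator

`make_plastome()` assembles LSC + IRb + SSC + IRa (IRa the exact reverse
complement of IRb) with the default layout 84/25/18 kb and genome GC
0.38 — typical autotroph plastome values — and a gene roster mirroring
the real gene classes, including the two *ndh* clusters
(*ndhJ–ndhK–ndhC* in the LSC; *ndhH–ndhA–ndhI–ndhG–ndhE–psaC–ndhD* in
the SSC), *ndhB* and the rRNAs in the IR, and the junction genes
(*rps19* at JLB, *rpl2*/*trnH* inside the IR). Degradations are planted
per plan: premature stops truncating to a target coverage, internal
deletions (forced to frameshift), whole-gene removals; inversions
reverse-complement a span of the SSC; insertions are foreign blocks at a
distinct GC, accepted only when they share no ≥ 20 bp anchor with the
host — at the word sizes and `min_fragment` the homology analyses use,
that guarantees non-homology (avoiding *all* shared 7-mers is
combinatorially impossible for realistic lengths and is not what any
consuming analysis measures). Truth records planted statuses both raw
and post-cascade, IR coordinates, insertions and repeats; identical seed
and configuration give byte-identical output.

`simulate_codon_alignment()` draws root codons from the F3×4-style
stationary distribution and evolves them branch by branch, with optional
site classes for branch-site scenarios. The default selection tree
(`default_selection_tree()`) is a balanced ultrametric 8-taxon tree of
depth 0.5 substitutions per codon (every edge 0.125) with one terminal
foreground branch — deep enough for calibrated LRTs, small enough that a
full power experiment runs in minutes. `simulate_counts()` inverts the
FPKM formula for expected counts and draws negative binomial
(Poisson at dispersion 0). `simulate_pileup()` draws coverage uniformly
(default 150–400×), splits it binomially between strands, applies uniform
errors at ε, and plants variant reads at the requested efficiency and
strand bias.

**What the generator does not emulate** — and therefore what passing
tests do not demonstrate about real data: sequencing-error profiles
beyond uniform ε, mapping artefacts, paralogy and nuclear plastid-like
sequences (NUPTs), alignment/cleaning errors in codon alignments,
among-site rate variation beyond the discrete branch-site classes,
context-dependent mutation, and real tRNA structure. The pipeline's
statistical behaviour on real plastomes inherits whatever upstream
assembly, annotation and alignment quality provide.

## Problem sizes

The shipped experiments are sized for a single core: recovery and power
use 8 taxa × 500 codons (50 genes), type-I calibration 500 replicates of
100 codons, gene-status recovery 20 genomes of ≈ 29 kb with a 21-gene
roster, repeat oracles ten 2 kb sequences, editing specificity one
150 kb null pileup. The analysis scripts use a seven-genome panel of
≈ 32 kb genomes (14/7/11 kb regions). These are the package's chosen
study conditions; the underlying operations scale linearly (pruning,
pileup calling) or near-quadratically in seed density (the repeat
engine) and handle full-size ~150 kb plastomes in minutes per genome.

## Known limitations

* The repeat/homology engine is ungapped; diverged repeats whose best
  alignment requires indels are fragmented into adjacent hits (partly
  healed by interval merging).
* NEB, not full BEB, identifies branch-site selected sites; posterior
  probabilities are conditional on the MLEs and mildly anti-conservative
  at small sample sizes.
* Branch lengths are not re-optimised per model; if the input tree's
  lengths are poor, all models share the distortion (by design, so LRTs
  compare ω structures only).
* The Mann–Whitney exact p-value uses a rank-sum counting recursion that
  is exact with ties, but the Hodges–Lehmann CI follows the standard
  no-ties construction (`stats::wilcox.test`); with heavy ties the CI is
  approximate.
* `classify_genome()` assumes the reference CDS set is trustworthy; it
  will happily measure coverage against a wrong reference.
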