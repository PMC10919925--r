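---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytonuclear)
```

# The scientific setting

Allopolyploid species carry two diverged parental genome sets
(subgenomes) in one nucleus, but their plastids and mitochondria descend
from a single, maternally inherited cytoplasm. Nuclear genes whose
products function inside the organelles — and especially genes whose
products join chimeric enzyme complexes with organelle-encoded subunits —
are therefore expected to experience asymmetric selection between the
maternal and the paternal subgenome. The triangle-of-U configuration
(three diploids A, B, C with A and C sister to each other, and
allotetraploids sharing the B genome but with opposite maternal donors)
is the natural experiment: if cytonuclear selection dominates, signals
should track the *maternal* subgenome across crosses; if intrinsic
subgenome properties dominate, they should track the *B genome*
regardless of which parent contributed it.

`cytonuclear` implements the analysis battery for that question:
organelle variant typing and donor inference, retention bias across
functional categories, two gene-conversion detectors, counting-based
dN/dS comparisons, and homoeolog expression-bias classification, together
with a fully labelled synthetic data generator used to validate each
detector.

# Codon-level primitives

All detectors work on gapped, codon-framed alignments
(`codon_alignment`) whose rows carry genome, role (diploid parent /
subgenome / outgroup / allopolyploid organelle) and parent-of-origin
metadata, parsed from `geneID|genome|role|origin` FASTA headers.

**Pairwise identity** is the fraction of identical columns among columns
where both sequences are ungapped and unambiguous. Columns containing
`-` or `N` in either sequence never contribute, so a local alignment gap
cannot masquerade as divergence.

**Synonymous/nonsynonymous classification** uses the standard genetic
code only: a substitution is synonymous iff both codons are sense codons
encoding the same amino acid. Substitutions creating (or removing) stop
codons are nonsynonymous.

**Counting-based dN/dS.** The estimator is the classical
counting scheme: per codon, each position contributes the fraction of its
three possible mutations that are synonymous (so every sense codon
contributes exactly 3 sites split between the two classes); site totals
of a pair are the average over the two sequences. Differences between
codons that differ at $k$ positions are averaged over all $k!$ orderings
of minimal mutational pathways; pathways crossing a stop codon are
discarded unless every pathway does, in which case all are weighted
equally and stop-crossing steps count as nonsynonymous. Proportions
$p_S, p_N$ are corrected with the Jukes–Cantor formula
$d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$ and $\omega = d_N/d_S$.
Codons containing gaps, `N`, or a stop in *either* sequence are excluded
pairwise, not globally. When $p \ge 3/4$ the distance is flagged
saturated and $\omega$ is undefined, as it is when $d_S = 0$.

This counting estimator is a deliberately self-contained stand-in for
maximum-likelihood codon models: it is exactly testable against a
brute-force pathway-enumeration oracle (the test suite does this for all
sense codons and for random codon pairs to $10^{-9}$), symmetric in its
arguments by construction, and adequate at the low divergences the
triangle spans. It does not model transition/transversion bias or codon
frequencies; an external ML estimator can be substituted upstream of the
`rate_estimate` container without touching the rest of the pipeline.

**dS filter.** Ortholog groups whose $d_S$ exceeds a cutoff are treated
as alignment artefacts and dropped. The cutoff is a configuration
parameter (`ds_cutoff`, default 2.0 substitutions/site) echoed in the run
log; there is no universally correct value, and the default is
deliberately permissive — at triangle-of-U depths genuine $d_S$ is an
order of magnitude smaller.

**Subgenome rate comparison.** For each cross, $\omega$ is estimated for
the maternal and the paternal subgenome copy of every ortholog group
against the *outgroup* sequence (full-depth divergence, so both copies
are measured over the same tree depth), concatenated per functional
category after dS filtering, and compared as
$\log_2(\omega_P/\omega_M)$. Ratios are undefined (excluded, with a
reason code) when either $\omega$ is zero, undefined or saturated.

# Organelle variant typing and donor inference

For each organelle protein-coding gene the allopolyploid sequence is
compared column-by-column with the candidate genomes (both parents plus
any further diploid in the scheme). A column counts as:

* **genome-like** when the allopolyploid matches exactly one candidate
  genome and differs from all others;
* **private** when it differs from every candidate — regardless of
  whether the candidates differ among themselves, since private
  mutations arise after hybridization at arbitrary positions;
* **non-diagnostic** (skipped, tallied) when two or more candidates share
  the allopolyploid's state.

A genome represented by several varieties must be internally concordant
at the column; discordant or gapped columns are skipped and counted.
Effects are classified by substituting the alternative state into the
allopolyploid's own codon context; when several variant columns fall in
one codon the effect is averaged over mutational pathways, so counts can
be fractional in that rare case.

The donor call takes the candidate with the largest genome-like count;
support is its share of all genome-like variants. Two guards make the
call "ambiguous": support below `donor_support_threshold` (default 0.8)
and a private fraction of all variants at or above 0.4 — the pattern of a
complex or unresolved origin, where no extant candidate explains the
cytoplasm.

# Retention bias across functional categories

Nuclear genes are binned into 8 categories by organelle targeting and
interaction strength: `Other` (non-targeted), `Dual` (dual-targeted), and
per compartment targeted-only (`pt_tar`/`mt_tar`), interacting-without-
complex (`pt_int`/`mt_int`) and enzyme-complex members
(`pt_com`/`mt_com`). Categories transfer to study genes through reference
orthologs; conflicts resolve by interaction strength
(complex > interacting > targeted > Dual > Other), and an equal-strength
plastid/mitochondrial tie resolves to `Dual`.

Per category, $r_M$ is the fraction of ortholog groups (with a
maternal-parent gene) that retain a maternal-subgenome copy, $r_P$ the
paternal analogue, and the bias is $r_M - r_P$. Ortholog groups that lost
*both* copies are excluded from both denominators: retention is measured
relative to parental presence, and a doubly lost group carries no
information about asymmetry. Each category is compared to `Other` with a
two-sided Fisher exact test on the 2×2 table of
(maternal-only-lost, paternal-only-lost) counts. The exact test was
chosen because several categories are small (tens of groups); its slight
conservatism is the acceptable cost, and the test-suite calibration check
(500 null replicates at realistic margins) verifies the type-I error sits
at the nominal 5% level.

# The quartet conversion rule

Each high-quality ortholog group contributes four focal sequences:
maternal parent, paternal parent, and the two subgenome copies. Four
identities are computed on jointly ungapped columns — o1 (maternal copy
vs maternal parent), o2 (paternal copy vs paternal parent), h1 (the
homoeolog pair) and h2 (paternal copy vs maternal parent) — and the
decision tree is:

1. both orthologous identities strictly exceed both homoeologous ones →
   **no conversion**;
2. h1 strictly exceeds both orthologous identities → **directional**: the
   copy whose own-parent identity dropped is the converted one
   (o1 < o2 → P→M, o1 > o2 → M→P, tie → reciprocal/unknown);
3. h1 and h2 both exceed both orthologous identities →
   **reciprocal/unknown**;
4. anything else → no conversion with a `weak-signal` flag.

Two numerical choices matter. First, the tolerance `epsilon` defaults to
0 with *strict* inequalities, so exact ties fall through to the
conservative outcome rather than being broken arbitrarily — reproducible
and bias-free. Second, a quartet whose parents differ at fewer than
`min_diag` comparable sites (default 3) is always `reciprocal_or_unknown`
with an `insufficient divergence` flag: with one or two informative
sites, a direction call would be a coin flip.

The rule's domain of sensitivity deserves emphasis. The directional
branch requires the homoeolog pair to be *more* similar than both
ortholog pairs. An unconverted copy is nearly identical to its parent, so
this only happens when the exchanged tract spans essentially the whole
gene and the conversion postdates some homoeolog-specific divergence.
Partial tracts leave the unconverted majority of the gene in control of
the identities and are classified no-conversion — the detector
systematically *underestimates* conversion, which is why the test suite
asserts that detection is non-decreasing in tract length rather than
claiming sensitivity to short tracts, and why direction accuracy and
false-positive rate (not recall) are the guaranteed quantities.

Directional calls aggregate per category into the conversion summary
with the directional percentage `round(100 · M→P / P→M)` and pooled rows
for plastid-targeted, mitochondria-targeted and all organelle-targeted
categories excluding `Dual`.

# Site-level conversion scanning

Inside a gene-family clade whose topology matches the species tree
(clade eligibility is the caller's responsibility; the scanner consumes
clade membership, it does not infer trees), a **diagnostic site** is a
column where every variety of one parental genome shares a state, every
variety of the other shares a different state, and no parental sequence
is gapped or ambiguous. A homoeolog carrying the *other* parent's state
at a diagnostic site is one conversion event; direction follows from the
homoeolog's subgenome of origin (maternal copy carrying the paternal
state → P→M), and the effect is classified in the homoeolog's codon
context with the two parental states swapped at the focal position.
Homoeolog states matching neither parent are new mutations: tallied
separately, never called. Both homoeologs are scanned independently; a
column converted in both directions is emitted as two events flagged
reciprocal. Coordinates are 0-based internally and 1-based in reports.

Family tables sum diagnostic-SNP counts and direction-by-effect event
counts per family plus an exact column-wise `Total` row; the maternally
biased total (M→P synonymous + nonsynonymous) is the headline statistic.

# Expression bias

Replicate FPKM values are averaged per homoeolog; with pseudocount
$c$ (default 0.1) the statistic is
$\log_2\frac{\bar x_P + c}{\bar x_M + c}$. Pairs with both means under
the expression floor (default 1 FPKM) are `not_expressed`; otherwise
$|\text{log2FC}| \ge 1$ is biased toward the larger side, with the
boundary value counting as biased (documented and tested). This is a
deterministic stand-in for negative-binomial differential testing: no
dispersion estimation, no shrinkage, no p-values per gene — appropriate
for the ratio-threshold classification it feeds, and exactly testable.
Per-category summaries exclude `not_expressed` pairs from all
denominators and attach a Fisher exact p-value on biased counts versus
`Other` (the package's convention; the choice of test for this summary
was open).

# The synthetic triangle generator

`simulate_triangle()` emits a fully labelled dataset under the tree
((A,C),B,outgroup) with two allotetraploids: AB (maternal A × paternal B)
and BC (maternal B × paternal C) — opposite maternal donors for the
shared B genome, the configuration that lets the pipeline separate
cytonuclear effects from subgenome identity.

**Sequence model.** Ancestral genes are random stop-free codon strings.
Along each branch every site substitutes to a uniformly chosen different
base with the Jukes–Cantor probability $\tfrac{3}{4}(1-e^{-4t/3})$;
proposals that create stop codons are always rejected, and nonsynonymous
proposals are kept with a per-category acceptance probability — the
minimal mechanism that makes synonymous/nonsynonymous truth trackable and
gives each functional category a realized $\omega$ near its acceptance
value (stronger purifying selection for complex members than for
non-targeted genes). This is deliberately not a realistic codon model:
no transition bias, no rate heterogeneity, no indels. Passing tests on
simulated data therefore demonstrate correctness of the bookkeeping and
decision rules, not robustness to alignment error or model violation on
real data.

**Default study conditions** (chosen once, as a plausible triangle-of-U
regime, and not revisited):

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 270 OGs across 8 categories | genome-wide set, desk scale |
| `codons_per_gene` | 120 | typical exon-set length |
| `branch_lengths` | outgroup 0.12; B 0.03; AC 0.015; A, C 0.015 | B splits first, A–C sister; ~6% A–B silent-site divergence |
| `nonsyn_acceptance` | 0.5 (Other) … 0.2 (complex members) | purifying-selection gradient |
| `variety_divergence` | 0.002 | two varieties per diploid, exercising concordance logic |
| `post_hybrid_divergence` | 0.005 | young polyploids (10⁴-yr scale) |
| `quartet_conversion_rate` | 0.15 / OG | with `direction_bias` 0.6 toward P→M |
| `tract_fraction` | 1.0 | whole-gene homoeologous exchange — the regime the quartet rule detects |
| `site_conversion_rate` | 0.05 / diagnostic site / homoeolog | clade-level single-site events |
| `loss_prob` | maternal 0.08, paternal 0.12 | mild maternal retention bias |
| `organelle_private_rate` | 0.002 / site | rare post-hybridization organelle mutations |
| expression | lognormal(3, 1.2), 20% biased by 2 log2 units, 5% replicate CV | clear biased/unbiased separation |

Two timing conventions are part of the model, not knobs tuned to tests:
tract conversions are applied *after* post-hybridization divergence
(recent events — older whole-gene exchanges converge to ties the strict
rule deliberately refuses to call), and clade homoeologs carry no
post-conversion mutations by default (`clade_post_hybrid_divergence` = 0;
site conversion modelled as the most recent event). Raising the latter
layers noise onto the site scanner and degrades recall, which
`evaluate_recovery()` reports — that degradation is the realistic caveat,
and the noise-free default is what makes precision/recall = 1 a
meaningful correctness check rather than a claim about real data.
Similarly, emitted varieties never concordantly disagree with their
genome's canonical state (intra-genome polymorphism is discordant only),
so a diagnostic state always represents its genome.

Everything is a deterministic function of the seed; the test suite checks
byte-identical reruns of the written dataset and pipeline reports.

**What the generator does not emulate:** recombination, transposable
elements, epigenetic silencing, indels and alignment error, expression
count noise (FPKM is drawn, not derived from reads), heteroplasmy, and
gene-tree/species-tree discordance (discordant clades are an input flag,
not an emergent property).

# Problem sizes and runtime conventions

The shipped defaults run the full simulate–analyse–score cycle on 270
ortholog groups, 12 clade families and 30 organelle genes in well under a
minute on one core; the retention-recovery check uses 2,000
single-category ortholog groups of 12 codons (retention depends only on
presence/absence, so short genes suffice); the Fisher calibration uses
500 null replicates of two 1,000-group cohorts at 20% loss. These sizes
were chosen so that every stochastic assertion sits several standard
errors away from its threshold under the configured conditions.

# Known limitations

* The quartet rule cannot see sub-gene tracts or old whole-gene
  exchanges (ties at `epsilon = 0`); its counts are lower bounds, and the
  directional ratio can be distorted if tract-length distributions differ
  between directions.
* The counting dN/dS estimator ignores transition/transversion bias and
  codon usage; at high divergence it saturates rather than extrapolating.
* Donor inference assumes the true donor (or a close relative) is among
  the candidates; a missing donor manifests as a private-heavy ambiguous
  call, not as an error.
* The expression classifier is threshold-based and unreplicated in
  spirit: it does not control false discovery across genes.
* Category transfer trusts the reference annotation; genes absent from
  the ortholog map silently become `Other` (logged), which dilutes — never
  inflates — organelle-targeted signals.
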