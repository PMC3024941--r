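---
title: "Recoding ambiguous alignment regions as ordered integers: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recoding ambiguous alignment regions as ordered integers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(picsord)
```

## The problem

Multiple sequence alignments of length-variable markers (ribosomal ITS,
mtSSU and similar) routinely contain stretches where indel variability
admits many equal-cost alignments.  Treating the columns of such
*ambiguous regions* as positional homologies is unsafe, but excluding
them discards phylogenetic signal.  `picsord` takes the middle road: it
replaces each ambiguous region by a small set of ordered integer
characters that summarize the pairwise distances among the region's
(unaligned) sequences, and merges these characters with the untouched
DNA partition for downstream ML/MP/Bayesian analysis.

The pipeline per region is:

1. extract each OTU's ungapped residues within the region;
2. compute an OTU-by-OTU distance or cost-score matrix
   (`region_matrix()`);
3. ordinate it with principal coordinates analysis, keeping only axes
   with positive eigenvalues (`pcoa()`);
4. rescale the coordinates by the maximum axis range and round them to
   k-state integer codes (`rescale_scores()`, `to_codes()`), dropping
   invariant columns (`drop_invariant()`).

Because PCoA is deterministic in the input distances, identical region
sequences always map to identical code rows — the property that rules
out stress-minimizing ordinations (NMS), whose iterative optimization
can scatter identical objects.

## Distance engines

**identity** — each pair is globally aligned under unit costs (match 0,
mismatch 1, gap of length $k$ costs $1 + k$); identity is the fraction
of aligned non-gapped site pairs with equal residues over the shorter
raw sequence length, and the distance is one minus identity.  Because
tied optimal alignments can differ in match count and the dynamic
program breaks ties positionally, the pair is put in canonical
(lexicographic) order first, which makes the distance exactly symmetric.

**cost** — user-specified substitution costs (match/transition/
transversion) with log-affine gap costs
$C_k = a + b\,k + c\,\ln k$, the family that interpolates between
affine ($c = 0$) and logarithmic ($b = 0$) gap models.  With the
default unit scheme this reproduces INAASE-style cost scores.

**zeta** — substitution costs are Kimura 2-parameter *log-odds* at a
reference divergence $d$ (default 0.5 expected substitutions/site) with
transition:transversion event ratio 2:

$$\mathrm{cost}(x,y) = -\log\!\big(4\,P_{xy}(d)\big),$$

so matches score negative (about $-0.95$ by default) and transversions
about $+1.26$.  Gap costs are the negative log-probability of an indel
event (rate 0.15 per substitution by default) with a zeta power-law
length, $P(k) \propto k^{-z}$, $z = 1.6$:

$$C_k = \big(-\log r + \log \zeta(z)\big) + z \ln k .$$

The log-odds form matters: with *free end gaps* (terminal gap runs cost
0, the right choice when region ends need not be homologous, as in
ITS1/ITS2), a model whose costs are all non-negative is degenerate —
the "alignment" consisting of two terminal gaps and no aligned columns
always has cost 0.  Rewarding matches removes the degeneracy, exactly
as log-likelihood scoring does.  Free end gaps default to on for the
zeta engine and off for the plain cost engine, which warns if they are
combined with a non-negative match cost.

Cost scores are converted to distances by self-normalization,
$d_{ij} = c_{ij} - (c_{ii} + c_{jj})/2$, which zeroes the diagonal and
makes identical sequences exactly distance 0; a negligible negative
residue (the scores are not metric) is clipped to 0.  Distances from
*empty* region sequences follow a fixed convention: identity engine 1.0
against anything non-empty, cost engines the forced-gap cost
$C_{L}$ of the non-empty partner (deliberately *without* the free-end
discount, which would otherwise place empty sequences at distance 0
from everything); two empty sequences are at distance 0.

The aligner itself is a three-state dynamic program (substitution /
gap-in-a / gap-in-b) in C++ that charges each maximal gap run once at
its full length, enumerating run lengths exhaustively —
$O(nm(n+m))$.  Region sequences are at most a few hundred residues, so
correctness was preferred over the candidate-list tricks needed for
chromosome-scale inputs; an exhaustive path-enumeration oracle guards
the implementation in the tests.

## Ordination

`pcoa()` applies Gower double-centering
$B = -\tfrac12 J (D \circ D) J$ and a symmetric eigendecomposition.
Axes are kept iff their eigenvalue exceeds $10^{-8} \lambda_{\max}$ —
symmetric solvers emit noise-scale eigenvalues for rank-deficient $B$,
and "positive" must not include them.  No Lingoes/Cailliez correction
is offered: correcting inflates the number of non-zero axes beyond the
number of distinct sequence patterns and distorts the configuration,
so negative axes are simply discarded.

Eigenvector signs are arbitrary in any solver, but the codes must be
reproducible, so each axis is reflected to make its largest-magnitude
loading positive (ties broken by lowest OTU index); a reflection only
reverses codes within an axis (0↔9) and preserves inter-OTU code
differences.  Axes with tied eigenvalues are ordered by their first
differing coordinate.

## Encoding

Per axis, $S_{\min}$ and the range are computed; all axes share the
*maximum* range as denominator:

$$S_{\text{rescaled}} = \frac{S_{\mathrm{OTU}} - S_{\min}}{S_{\mathrm{Range(max)}}}$$

so the widest axis spans exactly $[0, 1]$ and narrower axes are
compressed towards 0 — the encoding is proportional to the spread each
axis carries.  Codes are then

$$\mathrm{INT} = \mathrm{round}\big(S_{\text{rescaled}} (k - 0.01) - 0.495\big),$$

which for the default $k = 10$ is exactly "multiply by 9.99, subtract
0.495, round", yielding ordered states 0–9 in nearly equal pre-rounding
intervals.  The same formula generalizes to any $k$ in 2–64 (RAxML
accepts up to 32 multi-state symbols; the NEXUS writer path covers
33–64).  Rounding is *half away from zero*: exact .5 boundaries are
measure-zero on real data, but a reproducible rule is required and the
language default (round-half-even) would silently shift codes.

Rescaling minima are computed over retained axes only.  Axis variance
fractions are written as a sidecar (and optionally a NEXUS `WTSET`) but
never baked into the codes; weighting showed no marked effect and is
only plausibly useful for unordered/GTR treatment of the codes.

## Region delimitation

`delimit_regions()` operationalizes the manual flank rule: slide a
5-column window; a window is conserved iff it is gap-free in every OTU
and the maximum pairwise window cost (0.5 per transition, 1 per
transversion, `N` wildcard) is at most 2.0.  Maximal spans not covered
by any conserved window are candidates; a candidate is reported iff its
per-OTU ungapped lengths differ by at least `min_len_var` (default 3 —
"highly length-variable" made operational; exposed as a flag).  Regions
may abut the alignment ends, and regions separated by a single
conserved window are not merged.  A likelihood criterion for motif
conservation is sometimes mentioned alongside this rule; only the
operational threshold rule is implemented here.

## The simulator

`evolve()` emulates the published simulation design at desk scale: five
partitions with root lengths 400/400/100/100/200, substitution-rate
multipliers 1/2/2/3/2, indels only in partitions 3–5 at 1 insertion and
2 deletions per 20 substitutions, lengths from a discrete power law
with slope 1.6 truncated at 30 (50 for partition 5).  Substitutions
follow K2P transition probabilities along each branch (the original
study used GTR+Γ with parameters estimated from unpublished data; K2P
with a configurable ts:tv ratio is the reproducible stand-in).  Indel
event counts are Poisson with mean proportional to the branch's
expected substitution load; positions are uniform; inserted sites get
fresh identities so the true alignment is assembled exactly from the
recorded homology.  Substitutions are applied before the branch's
indels rather than interleaved event-by-event — a simplification that
leaves per-branch expectations intact.

What the generator does *not* emulate: among-site rate heterogeneity,
base-composition bias, selection, alignment error in the unambiguous
partitions, and rate variation along lineages.  Tests passing on these
simulations show that the pipeline recovers signal a distance-based
method can see under a homogeneous substitution process; they do not
certify performance on real data with model misspecification.

The guide tree for the recovery experiment is a 12-leaf birth–death
tree scaled to height 0.25 expected substitutions per site (at rate
multiplier 1) — a moderate, ITS-like divergence; the original 30-OTU
guide phylogeny is not published.  The test suite runs 20 replicates
and compares mean relative Robinson–Foulds distances of
neighbor-joining trees (true tree as reference) with partitions 3–5
either excluded or encoded; distances are pooled per character (DNA
mismatch counts plus per-column L1 code differences scaled to $[0,1]$,
over the total character count).  Neighbor-joining on pooled distances
replaces the original RAxML ML searches: external ML engines are out of
scope, and the comparative sign — encoding recovers at least as much
topology as exclusion — is the assertable claim at this scale, not the
absolute RF values.

## Numerical and interface choices

* Eigenvalue tolerance $10^{-8}$ relative to $\lambda_{\max}$;
  all-zero distance matrices yield zero axes and an empty code matrix;
  such regions are dropped from the output with a warning, leaving the
  DNA partition untouched.
* The DNA partition is the input alignment with region columns removed
  — never re-aligned, never recoded.
* User-facing coordinates are 1-based inclusive columns; conversion to
  0-based arithmetic happens only inside the accessors.
* `?` normalizes to `N`, `.` to `-` on input; `N` scores as a match in
  the distance engines and as a wildcard in window scoring (the
  conservative choice for conservedness).
* PHYLIP output uses relaxed names by default (strict 10-character mode
  behind a flag); multi-state codes render 0–9 then A–V, the RAxML
  convention.
* Every run parameter, per-region axis count and variance fraction is
  recorded in the JSON manifest written by `write_mixed()` —
  reproducibility hinges on parameter disclosure, since the method's
  defaults are otherwise buried in external tools.

## Known limitations

* The cubic aligner is comfortable for regions up to a few hundred
  residues and alignments of hundreds of OTUs, but pairwise cost grows
  quadratically in OTU count; very large datasets should expect
  minutes, not seconds.
* Cost-score matrices are not metric; PCoA tolerates this (negative
  axes are dropped), but strongly non-metric inputs can leave a larger
  share of variance on discarded axes.
* Codes are abstract summaries of distance space: they support
  tree inference, not ancestral-state interpretation at the region.
* Protein sequences pass through the I/O layer, but the distance
  models are DNA-centric (transition/transversion structure).
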