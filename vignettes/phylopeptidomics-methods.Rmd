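---
title: "Phylopeptidomic signatures: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylopeptidomic signatures: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylopep)
```

## The quantification problem

Shotgun metaproteomics identifies peptides, not organisms. A tryptic
peptide is usually present in the proteomes of many taxa, and the fraction
of an organism's peptidome shared with a neighbor grows as their
phylogenetic distance shrinks. Estimators built on taxon-specific peptides
therefore degrade exactly where quantification matters most — among closely
related, densely sequenced organisms — while estimators that count every
match inflate each organism by its neighbors' shared signal.

`phylopep` instead treats the sharing itself as the signal. Every MS/MS
spectrum is assigned to all taxa reachable through its matched peptides'
proteins (a *taxon-to-spectrum match*, TSM, with no parsimony filtering),
and the resulting per-taxon TSM counts are viewed as a function of each
taxon's phylogenetic distance to the organisms actually present.

## The signature model

An organism present at TSM-scale abundance $N$ contributes to a taxon at
distance $x$ an expected count

$$y(x) = N\left(A\,e^{-x/a} + (1-A)\,e^{-x/b}\right),$$

a bi-exponential decay with a fast short-range term ($a$) and a slow tail
($b$), mixed by the repartition coefficient $A$. At $x=0$ the organism
receives its full $N$; the two decay scales reflect the empirical shape of
TSM-versus-distance profiles on a log axis, which is bilinear rather than
linear. $A$ depends on the depth of the MS/MS acquisition and must remain
adjustable per dataset.

A community's observed profile is modeled as the sum of one signature per
reference organism, and the abundances are recovered by minimizing the
sum of squared errors between observed and modeled counts over all panel
taxa. Because the deconvolution removes each organism's leakage into its
neighbors, fitted abundances can be summed upward across taxonomic ranks
without double counting.

### Parameters, defaults and bounds

| parameter | meaning | default (start) | bounds | units |
|---|---|---|---|---|
| $N_k$ | abundance of reference $k$ | its observed TSM count | $[0,\,5N_0]$ | spectra |
| $A_k$ | repartition between decays | 0.45 | $\pm 0.05$ | — |
| $a_k$ | fast decay constant | 0.013 | $\pm 0.001$ | distance |
| $b_k$ | slow decay constant | 0.082 | $\pm 0.001$ | distance |

The distance unit is fractional sequence dissimilarity of concatenated
marker-gene supervectors, $d = 1 - \mathrm{PI}/100$ with PI the percent
identity; on this scale the default decay constants mean the fast term
halves roughly every 0.9% of sequence divergence. The narrow boxes around
$a$, $b$ and $A$ encode that the decay shape is a property of the
acquisition, not of the mixture; $N$ is the genuinely free quantity.

### The optimizer contract

`fit_signatures()` uses bounded L-BFGS-B (`stats::optim`) with an analytic
gradient. Parameters are normalized during the search by the correction
factors $1/A_0$, $1/a_0$, $1/b_0$ and $1/100$ (the last applying to $N$,
the only parameter otherwise far from unit scale), implemented through
`parscale`. Termination uses a relative objective-decrease tolerance of
0.01 (`factr` $=$ 0.01/machine epsilon); on the scaled, well-conditioned
problems the fit typically converges in well under 200 gradient
evaluations. The start point is deterministic (the defaults above), so
identical inputs always produce identical fits. Restarting from a fitted
parameter vector cannot increase the objective, which the test suite
asserts.

Degenerate inputs: a profile with all-zero counts is an error (no MS/MS
attribution); references closer than $10^{-3}$ in distance trigger a
collinearity warning because their signatures become numerically
indistinguishable and only the *sum* of their $N$ is identified; a
reference observed at zero TSMs is pinned at $N=0$ (its box collapses),
which keeps absent organisms honest in dilution end points.

## TSM counting rules

* A spectrum contributes at most once to a taxon's TSM count, however many
  of its peptides map there; PSM counts (spectrum–peptide pairs) and
  distinct peptide counts are tracked separately.
* Validation keeps PSMs with expectation value strictly below the
  threshold (default 0.1) and allows several PSMs per spectrum.
* Contaminant accessions are stripped before mapping; records left with
  only contaminant evidence are dropped.
* Rollup to the seven canonical ranks (species … superkingdom)
  re-deduplicates spectra and peptides at every rank. Taxa absent from the
  taxonomy are pooled into a synthetic `unplaced` bin rather than silently
  dropped.
* A peptide is *specific* to taxon $t$ at rank $r$ when its full taxon set
  resolves to $t$ and nothing else at $r$. Two strict conventions apply:
  a set member that does not resolve at $r$ (including `unplaced`) makes
  the peptide non-specific there — the unresolved organism is still a
  distinct organism; and a spectrum is a *specific TSM* of $t$ only when
  every one of its peptides is specific to $t$. Both are the conservative
  readings; the alternative (at-least-one-peptide) rule would only inflate
  specific counts.

## Distances

Two build paths produce the same container (`distance_matrix`, symmetric,
zero diagonal, finite):

1. **Patristic**: leaf-to-leaf branch-length sums on a newick tree, via
   `ape`. Raw by default; optional rescaling to $[0,1]$.
2. **Supervector PIM**: per-taxon marker (COG) sequences are recruited by
   validated homology hits (e-value $<$ 0.001, identity $>$ 45%, coverage
   $>$ 0.94, all strict; best hit by lowest e-value, ties by identity;
   missing markers filled from the reference and flagged, taxa with more
   than 10 missing markers excluded), concatenated, aligned to a
   pre-aligned reference profile by an external aligner (the package
   consumes aligned FASTA; it does not re-implement MUSCLE/CLUSTAL), and
   masked. Percent identity is computed over gap-free column pairs
   (CLUSTAL convention) and converted to $d = 1-\mathrm{PI}/100$.

The identity-to-distance transform is a package convention: the fitted
decay constants ($a \approx 0.013$, $b \approx 0.082$) are only meaningful
on a fractional-dissimilarity axis, so that scale is normative throughout.
No tree-based smoothing (ML/NJ/UPGMA) is applied to the PIM distances; the
fit consumes them raw, and property tests deliberately run on arbitrary
symmetric matrices as well as ultrametric ones.

The conservation mask is *gblocks-like*, not Gblocks: a column is
conserved when its modal non-gap residue is held by strictly more than
half (default) of the block's sequences — gaps count in the denominator
but never disqualify a column by themselves; runs of more than 8
non-conserved columns split blocks; blocks with fewer than 2 conserved
columns are dropped; the final mask keeps conserved columns of surviving
blocks, and per-superkingdom masks are combined by union. Only these
parameters are specified for the original masking step, so this
reimplementation is normative for the package.

## The simulator

`random_distance_panel()` draws a random coalescent (ultrametric) tree and
rescales its cophenetic distances into a chosen spread (default
$[0.005, 0.4]$ — from just below the fast-decay scale out to deep
inter-phylum distances, the range over which real profiles carry signal).
References are picked for maximal mutual separation so that mixtures are
identifiable. `simulate_tsm_profile()` evaluates the mixture expectation
and, with `noise = "poisson"`, draws integer counts — spectral counts are
event counts, and Poisson is the standard minimal noise model for them;
no published noise model exists for TSM counts, so this is an assumption.
`simulate_mixture_series()` reproduces a two-organism dilution design
(nine ratios from 1:0 to 0:1, default total 3000 TSMs, matching the scale
of a single-organism LC-MS/MS run's validated spectra), and
`synthetic_peptidome()` generates toy peptidomes whose pairwise sharing
probability decays with distance, enabling end-to-end tests from the PSM
level.

What the simulator does *not* emulate: peptide detectability and
ionization efficiency, spectrum-level ambiguity (each synthetic spectrum
carries one peptide), database incompleteness, and inter-replicate
biological variation. Passing recovery tests therefore demonstrate the
*deconvolution's* correctness under the model's own statistical
assumptions — not end-to-end accuracy on real samples, which additionally
depends on database coverage and distance quality.

### Recovery performance, as computed by this package

With the test-suite problem sizes (panel 60, total 3000 TSMs, Poisson
noise, 25 seeds × 9 ratios — sizes chosen to mirror a realistic
single-run spectral depth while keeping the suite fast), the
deconvolution recovers mixture ratios with a mean absolute error well
under 3 percentage points and identity-line $R^2$ above 0.98; noiseless
profiles are recovered to within 0.1% with objective indistinguishable
from zero. The acceptance script recomputes these numbers at run time.

## Estimators and metrics

`relative_ratios()` (fitted $N_k$, the method's output) is compared
against three deliberately biased baselines: raw total-TSM ratios,
specific-peptide ratios, and the protein-centric two-unique-peptide
spectral-count estimator. Accuracy is summarized by `mape()` — the mean
*absolute* error in percentage points, not relative error (estimating 62%
where 91% was expected contributes 29 points) — and `linearity()`, which
reports both the OLS slope/$R^2$ and the $R^2$ to the identity line.

Mock-community arithmetic: with one genome copy per cell, cell-count
ratios are DNA fraction over genome size, normalized; the cell-volume
biomass proxy is the unnormalized product of cell-count ratio and mean
cell volume (kept unnormalized deliberately — the printed reference values
sum to over 100% — with `normalize = TRUE` as the opt-in variant); and
signature biomass shares normalize the fitted TSM quantities.

## Known limitations

* Reference organisms must be named a priori; there is no automatic
  reference discovery.
* Quantification quality degrades when references sit closer than the
  distance resolution (collinear signatures) or when the panel is small
  relative to the number of free parameters; both conditions warn.
* The raw-PSM input is a generic TSV schema; proprietary search-engine
  container formats must be exported upstream.
* XIC/intensity-based quantification is out of scope; TSMs are spectral
  counts.
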