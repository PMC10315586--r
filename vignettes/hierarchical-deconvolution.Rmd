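---
title: "Hierarchical reference-based deconvolution of brain methylation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical reference-based deconvolution of brain methylation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hibed)
```

## The problem

Bulk brain tissue is a mixture of cell types whose DNA methylation profiles
differ strongly; any bulk methylation association study is therefore
confounded by cellular composition. Reference-based deconvolution estimates
the mixing proportions $\pi$ of known cell types from a bulk beta-value
profile $y$ by constrained least squares against purified reference
profiles $X$:

$$\hat\pi = \arg\min_{\pi}\ \lVert y - X\pi\rVert^2
\quad\text{s.t.}\quad \pi \ge 0,\ \textstyle\sum_i \pi_i \le 1 .$$

Seven brain cell types are resolved here — GABAergic (GABA) and
glutamatergic (GLU) neurons, astrocytes, microglia, oligodendrocytes,
endothelial and stromal cells — but they are not resolved in one step.
Cell types within a lineage are far more similar to each other than to
other lineages, so a single flat reference matrix conflates two very
different scales of signal. Instead the types are organised in a two-layer
hierarchy:

* **Layer 1**: three groups — neuronal, glial, endothelial/stromal;
* **Layer 2A**: endothelial vs stromal; **Layer 2B**: astrocyte, microglia,
  oligodendrocyte; **Layer 2C**: GABA vs GLU.

Each node gets its own marker-CpG sub-library, and deconvolution proceeds
in three steps: (1) the Layer-1 library estimates group proportions
(whatever mass the references cannot explain is reported as `unknown`);
(2) each Layer-2 library estimates proportions among its group's types,
renormalised to conditional proportions summing to one; (3) leaf
proportions are the conditional estimates weighted by their group's
Layer-1 proportion, so leaves always sum exactly to their group total.

## Marker selection

At each node, candidate markers are scored one-vs-rest per child class:
the effect is the mean beta difference between the class and the pooled
rest, and its standard error uses an empirical-Bayes moderated variance —
per-probe residual variances are shrunk toward a scaled inverse-chi-square
prior fitted across probes (`limma::squeezeVar`), the standard remedy when
each class holds only a handful of purified samples. Per class, the top
`n_per_type` probes by moderated $t$ are kept in each direction
(hypermethylated and hypomethylated, `mode = "hybrid"`, the default), and
the node's library is the deduplicated union with the per-class mean beta
profiles as reference columns. Ranking uses a stable sort with probe-ID
tie-break, so library construction involves no randomness at all.

Candidate library designs can be compared with the dispersion separability
criterion (`compute_dsc()`): the ratio of between-class to within-class
dispersion of the purified samples over the probe set, higher being better
separation.

Two consequences of one-vs-rest scoring are worth knowing. First, at a
two-class node the contrast is exactly antisymmetric — class A's
hypermethylated ranking *is* class B's hypomethylated ranking — so the four
selection lists of a two-class node collapse to at most $2\,n$
distinct probes. Second, at realistic selection depths (the default
`n_per_type = 50`) the ranked lists reach beyond the strongest markers;
extra probes contribute little discrimination but are harmless to the
constrained fit.

## The constrained projection

`cp_qp()` solves the quadratic program above exactly by enumerating KKT
active sets: every subset of the non-negativity constraints, with and
without the sum bound, yields a small equality-constrained linear system;
the feasible candidate with the lowest objective is the global optimum of
this convex problem. With at most seven cell types plus nuisance columns
this is at most a few hundred solves of systems no larger than 9×9 —
microseconds per sample — and the enumeration order makes ties fully
deterministic; singular systems fall back to the minimum-norm solution.
Tests verify the solver against exhaustive grid search over the simplex.

Numerical conventions: negative round-off is clipped to zero after
solving; feasibility tolerances are $10^{-9}$; probes missing for a given
bulk sample are dropped from that sample's fit only, with a warning below
80% coverage of a node's library and an error below 50%.

### Why Layer-2 fits carry context columns

A subtle bias lurks in the naive three-step scheme. The Layer-2B library
is built to discriminate glial types *from each other*; fitted to a bulk
profile, its columns must also absorb the non-glial part of the signal,
which at those probes looks like a baseline profile roughly equidistant
from all child columns. Because the sum constraint lets the children soak
up that mass, the conditional proportions are pulled toward uniform — on
synthetic mixtures this costs about four percentage points of RMSE.
`build_hibed_library()` therefore attaches to each Layer-2 sub-library the
pooled mean profiles of the *other* Layer-1 groups over the node's probes.
These context columns enter the node's QP as nuisance components under the
same sum constraint and are discarded afterwards: out-of-group mass lands
on them, and the children are estimated essentially unbiased. The
conditional-times-group weighting itself is unchanged.

The Layer-2 renormalisation has one degenerate case — an all-zero child
solution (no mass of that group at all). The conditional is then undefined;
the implementation falls back to uniform conditional proportions with a
warning, which is immaterial because it is subsequently multiplied by a
(near-)zero group proportion.

## The synthetic reference and mixture framework

Real purified panels (flow-sorted nuclei profiled on Illumina arrays) are
emulated by `make_synthetic_reference()`: each probe draws a baseline beta
uniformly from `baseline_beta_range` (default 0.15–0.85); disjoint probe
blocks per group and per leaf are shifted by `delta_beta_group` (default
0.5) or `delta_beta_leaf` (default 0.4) in that class's samples, half of
each block upward and half downward; i.i.d. Gaussian noise
(`noise_sd = 0.02`) is added and values are clipped to $[0,1]$. Marker
baselines are rescaled into the sub-range where the shift cannot saturate
at 0 or 1, mirroring the bimodal unmethylated-to-methylated character of
real cell-type markers and keeping the designed effect size undistorted.
The defaults (2000 probes, 5 samples per type, 20 marker probes per class)
keep the full pipeline comfortably under a minute while leaving ~80% of
probes uninformative, so selection is non-trivial.

Validation mixtures follow the in-silico design used for benchmarking:
per mixture, seven Uniform(0,1) draws are normalised to proportions
(`sample_mixture_proportions()`, a gradient of proportions per type across
50 mixtures); per cell type, 3 of the 5 purified samples are drawn without
replacement and averaged into a mean-profile matrix, and the bulk profile
is that matrix times the designed proportion vector
(`build_mixture_matrix()`). Per-type, per-probe standard deviations across
the drawn samples are returned as metadata so users can optionally inject
matched noise; the default adds none, because the benchmark's purpose is
to isolate estimator error from simulated noise. Drawing 3 of 5 samples
keeps genuine sampling variability between the mixtures and the library
(which averages all 5).

What the generator does *not* emulate: probe-chemistry artifacts
(Infinium type I/II), batch effects, normalisation residue, age or disease
shifts within a cell type, or correlated (co-methylated) probes. Passing
tests on this generator therefore demonstrate correctness of the
estimator and selection machinery under the designed signal structure, not
performance on any particular real cohort.

## Evaluation

`evaluate_proportions()` scores predictions per cell type by Pearson $r$
(with $R^2 = r^2$, matching the field's reporting convention), RMSE and
MAE in proportion units, plus unweighted averages across types; the
`unknown` column is excluded since designed mixtures carry no unknown
mass. A cell type with constant true proportions has no defined
correlation and is dropped from the $R^2$ average with a warning.
Downstream summaries: glia-to-neuron ratio
$(\text{astro}+\text{micro}+\text{oligo})/(\text{GABA}+\text{GLU})$,
GABA/GLU ratio, and the composition of the glial compartment — each with
`NaN` sentinels and warnings where the denominator vanishes.

On the default synthetic conditions (seed 42, 50 mixtures), layer-2
deconvolution recovers the designed proportions with average
$R^2 \approx 0.999$ and average RMSE $\approx 0.2$ percentage points; the
test suite recomputes these numbers rather than asserting stored copies.

## Problem sizes and determinism

The shipped tests and the acceptance script run everything at the scale
above: 2000 probes, 35 reference samples, 50 mixtures, grid-search solver
oracles at step 0.005 on up to 10 probes and 3 types. All randomness flows
through explicit seeds (`withr::with_seed`), so the whole
simulate → build → deconvolve → evaluate chain is byte-reproducible; the
exactness tests build bulks as exact linear combinations of sub-library
mean matrices, node block by node block, which is the construction under
which sub-$10^{-6}$ recovery is the correct expectation at both layers.

## Known limitations

* Proportion estimates are only as good as the reference: cell types
  absent from the hierarchy surface either as `unknown` (Layer 1,
  `sum_mode = "le_one"`) or leak into related columns.
* The library builder requires complete (no-missing) reference betas for
  the probes it considers; probes with any missingness are dropped before
  selection.
* Two-class nodes cannot distinguish "A-hyper" from "B-hypo" markers (the
  contrast is one-dimensional); interpret per-class marker lists of
  two-leaf groups accordingly.
* WGBS data must be mapped into array probe space upstream; IDAT parsing
  and normalisation are out of scope.
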