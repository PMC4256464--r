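---
title: "Quantifying immunogold labelling over membrane compartments"
author: "goldstereo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immunogold labelling over membrane compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goldstereo)
```

## The measurement problem

On-section immunogold labelling of thawed cryo-sections marks a protein
with 10 nm colloidal gold particles that can be counted on electron
micrographs. Deciding *where* the protein lives — plasma membrane, nuclear
envelope, tubulovesicular endo-membranes, or the tiny double-membrane
mitosomes of microsporidian meronts — requires three corrections that raw
gold counts do not make:

1. **Membrane abundance.** A compartment with more membrane in the section
   collects more gold at equal labelling intensity. Counts must be
   normalised to membrane profile *length*, which is estimated
   stereologically rather than traced.
2. **Nonspecific binding.** Antisera stick nonspecifically. A parallel
   incubation with antiserum pre-mixed with its immunising peptide (the
   inhibition control) measures the nonspecific component, which is then
   subtracted.
3. **Replication.** Labelling intensity varies between experiments;
   results are summarised as the mean over replicate experiments with its
   standard error.

The package implements this pipeline — and a synthetic annotation
generator with known ground truth, so that every estimator can be tested
by parameter recovery.

## Membrane length by intersection counting

A square test-line lattice of spacing $d$ is dropped on each micrograph
with uniform random offset in $[0,d)^2$ *and* uniform random rotation in
$[0,\pi/2)$. If the membrane profiles of a compartment cross the lattice
lines $I$ times, the classical stereological relation between boundary
length per area and intersections per test-line length
($B_A = \frac{\pi}{2} I_L$, with test-line length per area $2/d$ for a
square lattice) gives the design-unbiased estimator

$$\hat L = \frac{\pi}{4}\, d\, I .$$

Randomising the rotation, not just the translation, is what makes the
estimator unbiased for *anisotropic* membranes (a straight membrane
crossing the field would otherwise be over- or under-counted depending on
its orientation relative to the lattice). The acquisition protocol this
mirrors used spacings of 262, 618 or 914 nm for the plasma membrane and
nuclear envelope and 914 nm or 1.54 µm for endo-membranes; the package
defaults to the finest alternative of each pair
(`defaultSpacingMap()`), and the mapping is configurable per compartment.

Two numerical conventions are fixed so the count is deterministic and
testable: a segment endpoint lying exactly on a lattice line counts as one
intersection, and a segment exactly collinear with a lattice line
contributes zero. Both are measure-zero events under random placement, so
any fixed convention leaves the estimator unbiased.

```{r stereology}
grid <- makeGrid(262, seed = 1L)
scene <- makeScene(SceneParams(seed = 1L))
I <- countIntersections(profiles(scene), grid)
I
estimateLength(I[["plasma_membrane"]], 262)   # nm; truth below
trueLengthNm(scene)[["plasma_membrane"]]
```

Mitosome membranes are deliberately *not* length-estimated: at 50–300 nm
across, a single organelle profile crosses a 262 nm lattice zero or one
time, so per-compartment length estimates would be dominated by counting
noise. Mitosome labelling is therefore carried as counts (see below).

## Membrane association of gold

A particle is membrane-associated when it lies less than one particle
width from a membrane profile. For 10 nm gold the package reads this as an
edge-to-membrane gap under one diameter, i.e. a centre-to-line distance
below radius + diameter = 15 nm; because "width" could equally be measured
from the particle centre (threshold 10 nm), the threshold is exposed as
`assocDistNm` rather than hard-coded. The inequality is strict, matching
"less than". A particle within threshold of several profiles goes to the
nearest; exact distance ties (a measure-zero event) are broken by
lexicographic compartment name, a deterministic and testable convention.

Densities are pooled **within** an experiment by ratio of sums,
$D = \sum N \big/ \sum \hat L$, never by averaging per-micrograph ratios:
$\hat L$ is itself a noisy estimate and micrographs with little membrane
would otherwise contribute wildly unstable ratios with equal weight.

## Specificity correction and the specific distribution

Per experiment and compartment, with native density $D(0)$ and
inhibition-control density $D(-)$:

$$D(sp) = D(0) - D(-), \qquad
  F(sp) = \frac{D(sp)}{D(0)}, \qquad
  N_g(sp) = F(sp) \times N(0).$$

Design choices where the procedure leaves room:

* **Negative values.** $D(sp)$ and raw $F(sp)$ can be negative (the
  control induced signal over a compartment); both are reported as-is in
  the density table. For the distribution $N_g(sp)$ — a frequency
  distribution, hence non-negative — the clamped
  $F(sp) \in [0,1]$ is used by default; `clamp = FALSE` switches to the
  raw fraction for diagnostics.
* **$D(0) = 0$.** $F(sp)$ is defined as 0 (no label, no specific label)
  rather than undefined, and flagged, so empty compartments do not poison
  reports.
* **Per-compartment fractions.** $F(sp)$ is computed per compartment,
  since densities are compared per compartment; a section-wide scalar mode
  (`fspMode = "section_wide"`, one fraction from total gold over total
  estimated length applied to all compartments) is provided without
  asserting it is preferable.
* **Mitosomes.** With no length estimate, the mitosome fraction is
  computed from per-micrograph count rates, $N/m$ native vs inhibited —
  valid because both conditions of an experiment have equal sampling
  effort, and recorded in the `fsp_basis` column. Mitosome counts come
  from the comprehensive-scan sampling stream when one is present and are
  never pooled with the systematic-uniform-random (SUR) stream.
* **Compute order.** Densities are pooled within an experiment, the
  specificity statistics computed per experiment, and only then averaged
  (mean ± SEM, $n-1$ variance) across the (by default 3) experiments.
  Pooling conditions across experiments first would let a strong
  experiment dominate the ratio statistics.

## What the synthetic generator emulates — and what it does not

`makeScene()` draws one meront-like section into a square field (default
3 µm): a closed star-convex plasma-membrane blob (characteristic radius
1 µm, random low-order Fourier roughness), one nuclear envelope
(0.45 × the cell radius, offset from centre), open random-walk
endo-membrane tubules, and elliptical mitosomes with axes uniform in
50–300 nm. The shapes are qualitative stand-ins: section profiles are
described in the literature only as smooth, convoluted or tubulovesicular,
with no coordinates, so the generator aims for realistic length scales and
per-compartment membrane amounts rather than morphological fidelity.

`placeGold()` lays specific gold as a Poisson process along each membrane
at $\lambda_c$ gold/µm, displaced off the line by a centred normal
(default SD 8 nm — real gold never sits exactly on the membrane because
the antibody bridge and section geometry displace it; the default sits
below the 15 nm association threshold so most specific gold is
recoverable, and it is configurable). Background gold is a uniform spatial
Poisson process. The default intensity, $\beta = 100/3$ gold/µm², is
chosen so that the expected *membrane-associated* background density is
$\beta \times 2 \times 0.015\,\text{µm} = 1$ gold/µm at the default
threshold — a control density of about 1 gold/µm, against a default
specific plasma-membrane signal of 5 gold/µm with complete inhibition
($\rho = 1$). The default study design is 3 experiments × 18 micrographs
per condition, the midpoint of the 16–20 micrographs per sample of the
acquisition protocol it emulates.

Simulated features the tests therefore *do* exercise: Poisson counting
noise, stereological estimation noise, background contamination near
membranes, imperfect particle–membrane association, replicate
variability. Features of real data they do **not** exercise: segmentation
and annotation error, section compression and membrane obliquity,
clustered (non-Poisson) antibody binding, antibody-specific background
structure, and partial inhibition that varies by epitope. Passing
recovery tests shows the estimators are correct under the stated model,
not that any particular biological dataset is well described by it.

```{r recovery}
study <- simulateStudy(SceneParams(), LabellingModel(),
                       nExperiments = 3L, micrographsPerCondition = 6L,
                       seed = 7L)
quant <- quantifyAnnotations(study$annotations, seed = 8L)
spec <- specificityAnalysis(quant)
aggregateSpecificity(spec, "Ngsp")
```

## Numerical and degenerate-input conventions

* Identical seeds and parameters reproduce scenes, studies and pipeline
  outputs bit for bit; all randomness flows through explicit seeds and the
  caller's RNG state is left untouched.
* Density is **undefined** (`NA`), not zero, when the estimated length is
  zero — a zero would fake a measured absence of labelling.
* Degenerate geometry (single-point polylines, nonpositive spacings,
  negative counts, min > max ranges) is rejected with parameter errors,
  not silently repaired.
* Annotations are stored in nm in JSON at full double precision
  (17 significant digits), so write→read round-trips are exact; the pixel
  size `nm_per_px` is provenance metadata only.
* Missing inhibition-control data aborts the pipeline: specificity is
  meaningless without the paired control.

## Problem sizes used by the test suite

The suite validates the geometry kernels against brute-force oracles (200
random polyline/grid instances; 500 random point/polyline distances),
checks estimator unbiasedness on a circle (r = 1 µm) and a 5 µm segment
over 10,000 random grid placements (mean within 1%), and runs full
parameter-recovery studies at protocol scale — 3 × 18 × 2 micrographs —
over 20 seeds for the recovery pattern (specific plasma-membrane density
recovered within 20%, mitosome share of specific gold below 5%) and 50
seeds for the null control (mean raw $F(sp)$ within ±0.1 of 0). These
sizes give Monte-Carlo standard errors comfortably below the asserted
tolerances while keeping the suite quick on a single CPU.

## Known limitations

* 2-D only: membrane profile length per section, no surface-area-per-
  volume stereology.
* Particles arrive as coordinates; there is no detection from images.
* The association rule uses the particle centre; edge-based distance is
  available only through the threshold parameter.
* The mitosome count-rate fraction assumes equal micrograph counts per
  condition within an experiment — true of the simulated design, and of
  the emulated protocol only approximately (16–20 per sample).
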