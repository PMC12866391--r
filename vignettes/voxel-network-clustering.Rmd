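---
title: "Digital-biopsy voxel network clustering of dynamic PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-biopsy voxel network clustering of dynamic PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinclust)
library(dplyr)
```

## The analysis problem

Static PET signal intensity often cannot separate malignant from benign
tracer-avid lesions: in FAPI imaging of the pancreas, carcinomas,
inflammatory lesions and post-surgical reactive tissue all take up the
tracer. What differs is the *kinetics* — malignant tissue accumulates
tracer slowly and holds it (late peak, slow washout), while inflammatory
and reactive tissue peak early and clear quickly. kinclust implements a
data-driven way to exploit this: sample standardized "digital biopsies"
from a dynamic scan, correlate every voxel's time–activity curve (TAC)
with every other voxel's, reduce the correlation network, and let Markov
clustering (MCL) partition the voxels into kinetically coherent groups.
No kinetic model is fitted and no tissue identity is used during
clustering; labels are masked beforehand and restored only for
interpretation.

## Pipeline and model

1. **Homogenization and SUV.** Images are resampled to a 1 × 1 × 4 mm
   grid (trilinear, cell-centred) and scaled to standardized uptake
   values, `SUV = conc / (dose / body weight)`.
2. **Digital biopsy.** Each volume of interest is a 10 × 10 × 3 voxel
   block — exactly 300 voxels, 10 × 10 × 12 mm, the only near-cubic
   integer block of that size at this grid anisotropy. Blocks that
   would cross the image boundary are an error, never clipped. Lesions
   can be gated on a tumor-to-background ratio against the aortic blood
   pool of at least 1.5 in the final frame (boundary inclusive).
3. **Correlation network.** Pearson correlation of raw SUV TACs over
   frames, an edge wherever r ≥ `r_min`. Pearson's affine invariance is
   load-bearing: curves from different scans can be combined without
   any inter-scan intensity normalization.
4. **k-nearest-neighbour reduction.** Each node ranks its edges by
   weight (descending, ties to the smaller neighbour index); an edge
   survives if it is in the top *k* of **either** endpoint (union
   semantics). Components smaller than `min_component_size` are then
   dropped.
5. **Markov clustering.** Standard MCL on the weighted adjacency with
   unit self-loops: column-normalize, square (expansion), raise
   entrywise to the `granularity` exponent and renormalize (inflation),
   prune entries below `prune_eps`, repeat to convergence. Clusters are
   read off the attractors of the limit matrix; a node attracted to
   several attractor systems goes to the one holding most of its column
   mass (ties to the lowest cluster id).

Defaults follow the two published settings: single-scan networks use
`r_min = 0.7` (range 0.7–0.78), `k = 9` (range 7–12), granularity 1.2,
minimum component size 10; combined multi-scan lesion networks use 0.95,
25, 1.3 and 100. `granularity` is the MCL inflation exponent — the name
follows the visual-analytics tool this workflow was designed around.

### Numerical choices

* `prune_eps = 1e-4`, the canonical MCL pruning cutoff; `max_iter =
  200`; convergence when the largest entry change drops below `1e-6`.
  MCL on symmetric flows can enter an exact period-two limit cycle
  (a pair of states mapping to each other); the iteration detects this
  and treats it as converged, interpreting the current matrix.
* MCL flow never crosses connected components, so the implementation
  iterates per component, re-checking after every iteration whether
  pruning has disconnected a block (it typically severs weak
  inter-tissue bridges within the first dozen iterations). Blocks of up
  to 2000 nodes iterate as dense BLAS matrices through a small compiled
  kernel; larger blocks stay sparse. Both paths share identical
  pruning/normalization semantics, and the test suite checks the
  production implementation against an independent dense reference
  iteration on small graphs.
* Zero-variance (flat) TACs cannot be correlated; those voxels are
  excluded with a message and reported as dropped, rather than
  propagating `NaN`.
* Time to peak is the midpoint of the first frame attaining the
  maximum (ties break early). Static SUV parameters average frames
  whose midpoints fall inside the 40–60 min window; partial-overlap
  proration was rejected for simplicity.
* Frame-wise dispersion of cluster TACs uses the population SD
  (divisor *n*); cohort summary tables use the sample SD (divisor
  *n* − 1), the biomedical convention. Each is stated where used.

## The synthetic phantom

No patient scans are distributable, so validation runs on a
ground-truthed synthetic generator. A phantom is a set of axis-aligned
300-voxel tissue blocks on the homogenization grid, each with a
Bateman-type kinetic model

$$u(t) = b + A\,(e^{-\lambda_{out} t} - e^{-\lambda_{in} t}),$$

the simplest curve with one interior peak and separately tunable uptake
and washout. Noise-free frame values are exact duration-weighted means
of \(u\) over each frame interval, and voxel noise is zero-mean Gaussian
with SD `noise_scale * sqrt(max(value, eps) / duration_min)` — variance
grows with signal and shrinks with frame duration, the structure that
matters for correlation analysis. Values are not clipped at zero. The
default acquisition is the 28-frame, 60-min clinical schedule whose
durations step from 30 s to 10 min (12 × 30, 6 × 60, 4 × 120, 4 × 300,
2 × 600 s).

The default tissue classes are synthetic archetypes chosen to reproduce
the qualitative kinetic contrasts of the clinical setting, and they are
deliberately idealized:

```{r kinetics}
tissue_kinetics()
```

* **malignant**: slow accumulation, peak ≈ 22.6 min, ~25% washout by
  60 min; **inflammatory**: peak ≈ 5.5 min, ~93% washout;
  **reactive**: even earlier peak and near-complete washout. These
  reproduce the orderings time-to-peak(malignant) >
  time-to-peak(inflammatory) ≥ time-to-peak(reactive) and washout
  (reactive) > (inflammatory) > (malignant).
* **kidney, liver, blood** are early-transit classes (peak within the
  first two minutes, fast clearance) and **muscle/fat** are near-noise
  background tissues whose late SUV sits below every pathologic class.

Two idealizations deserve emphasis. First, the control classes were
placed in a kinetic niche (early transit) chosen for *separability*
from both lesion archetypes, not for organ-level realism — clinically,
kidneys retain FAPI tracers late, whereas the phantom's kidneys clear.
Second, within a tissue block all voxels share one true curve;
real tissue has spatial kinetic dispersion and spatially correlated
reconstruction noise, neither of which is simulated. Passing tests
therefore demonstrate that the pipeline recovers kinetic structure that
is present, not that clinical scans will be this clean. The default
`noise_scale = 0.2` makes lesion-class voxels correlate within class at
roughly r ≈ 0.95 and across classes below the 0.7 threshold, while
muscle and fat are noise-dominated and largely excluded by the
threshold — at this noise level the correlation threshold behaves like
the published workflow's "as many nodes as possible" trade-off.

Intralesional heterogeneity is modelled by mixing 1–3 kinetic
subpopulations per lesion (`lesion_subpopulations()`): the default
second subpopulation is a faster-clearing subclone (peak ≈ 9.5 min,
~84% washout) whose curve correlates only ≈ 0.45 with the parent class,
so the network resolves the two as separate clusters.

`default_phantom_spec()` (one malignant + one inflammatory lesion +
five controls), `two_kidney_phantom_spec()` (paired kidneys for
coclustering) and `cohort_phantom_spec()` (4 single-subpopulation + 6
two-subpopulation lesions + controls) encode the standard study
conditions; everything is reproducible from the phantom specification's seed.

## Readouts

`cluster_report()` assembles the cluster-level statistics: per-cluster
size, source-VOI composition (fractions sum to 1) and purity (largest
single-VOI fraction); averaged cluster TACs ± SD; per-VOI retained
fraction and cluster count; and pairwise VOI coclustering fractions.
A cluster "counts" for a VOI when it holds at least `min_frac = 0.10`
of that VOI's retained voxels — the threshold is this package's
explicit operationalisation of clusters-per-VOI counting (the published
description does not define one); 10% suppresses stray-voxel counts
while allowing the observed 1–3 range. Group comparisons use a
hand-implemented Mann–Whitney U (exact enumeration for tie-free samples
with n₁ + n₂ ≤ 12, else the tie- and continuity-corrected normal
approximation); a Welch t test is provided as a labelled alternative,
and no multiple-testing correction is applied (a documented
limitation).

## Validation scales

The validation suite and `scripts/acceptance.R` use: 20 phantom
replicates of the 7-VOI reference scan (2100 voxels each) for the
purity readout; 20 replicates of the 15-block lesion cohort (10
pipeline runs each, ~1800 voxels per run) for the clusters-per-VOI
readout; and 20 two-kidney phantoms for coclustering. These sizes give
stable statistics while keeping a full run in the tens of minutes on a
single core.

## Known limitations

* Image-based motion correction is not implemented; the phantom is
  motion-free. Clinical reuse would need registration upstream.
* The reactive-tissue archetype overlaps kinetically with the
  early-transit controls; it is not part of the default validation
  phantoms.
* Low-uptake tissues (muscle, fat) are mostly excluded by the 0.7
  correlation threshold at the default noise level; their micro-cluster
  structure is noise, not biology.
* DICOM ingestion, scanner reconstruction effects (PSF, TOF,
  partial-volume) and CT co-registration are out of scope; inputs are
  NIfTI volumes assumed decay-corrected.
* The package stops at descriptive cluster separation, as the study
  design does: no classifier and no outcome linkage.

## A worked run

```{r pipeline, eval = FALSE}
spec <- default_phantom_spec(seed = 1)
ph <- generate_phantom(spec)
img <- to_suv(ph$image)
biopsies <- place_biopsies(img, ph$centers)
tacs <- extract_tacs(img, biopsies)
clustering <- cluster_voxels(tacs, individual_defaults())
report <- cluster_report(clustering, tacs,
                         pathologic = c("malignant", "inflammatory"))
glance(report)
autoplot(report)
```

`run_individual()` wraps the same steps (plus masking, optional TBR
gating and artifact export with a provenance log) behind a single
config, and `run_combined()` builds the cross-scan lesion network.
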