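# kinclust

Data-driven clustering of dynamic PET voxels by their tracer kinetics.

Fibroblast-activation-protein inhibitor (FAPI) PET lights up pancreatic
carcinomas, pancreatitis and post-surgical reactive tissue alike, so
static uptake (SUVmax/SUVmean) often cannot tell them apart. Their
time–activity curves (TACs) differ, though: malignant tissue
accumulates tracer slowly and retains it, benign pathologies peak early
and wash out. kinclust implements a digital-biopsy workflow that turns
this into an observer-independent analysis, for imaging scientists
working with dynamic PET:

1. sample standardized **digital biopsies** — 10 × 10 × 3-voxel blocks
   (exactly 300 voxels, 10 × 10 × 12 mm on the 1 × 1 × 4 mm
   homogenization grid) — from lesions and control tissues;
2. build a **voxel correlation network**: nodes are voxels, edges
   connect TACs with Pearson *r* ≥ *r*<sub>min</sub>, reduced by
   *k*-nearest-neighbour filtering (union semantics) and a minimum
   component size;
3. partition it with **Markov clustering** (MCL): alternate expansion
   (matrix squaring) and inflation (entrywise power *g*, the
   "granularity") of the column-stochastic transition matrix until the
   flow localizes into clusters;
4. summarise **cluster purity**, clusters per volume of interest,
   averaged cluster TACs and coclustering, and compare groups with a
   Mann–Whitney U test.

Default parameters follow the published clinical settings: single-scan
networks use *r*<sub>min</sub> = 0.7, *k* = 9, granularity 1.2, minimum
component size 10; combined multi-scan lesion networks use 0.95, 25,
1.3 and 100. Labels are masked before clustering and unmasked for
interpretation.

Because no patient scans can ship with the package, it includes a
ground-truthed **synthetic dynamic-PET phantom generator**: Bateman
kinetics per tissue class (malignant, inflammatory, reactive, kidney,
liver, blood, muscle, fat, plus intralesional subpopulations),
the 28-frame 60-min acquisition schedule (30 s → 10 min frames),
exact frame averaging, and frame-duration-scaled Gaussian noise.

## A worked example

```r
library(kinclust)
library(dplyr)

spec <- default_phantom_spec(seed = 1)      # 2 lesions + 5 control tissues
ph <- generate_phantom(spec)
img <- to_suv(ph$image)
biopsies <- place_biopsies(img, ph$centers) # 300 voxels per VOI
tacs <- extract_tacs(img, biopsies)         # 2100 x 28 TAC matrix
clustering <- cluster_voxels(tacs, individual_defaults())
report <- cluster_report(clustering, tacs,
                         pathologic = c("malignant", "inflammatory"))
tidy(report) |> arrange(desc(size)) |> head(4)
#> # A tibble: 4 × 4
#>   cluster  size majority_voi purity
#>     <int> <int> <chr>         <dbl>
#> 1       3   640 kidney        0.469
#> 2       7   451 blood         0.636
#> 3       1   300 malignant     1
#> 4       2   300 inflammatory  1
```

Both lesions are recovered as perfectly pure 300-voxel clusters —
voxels grouped by kinetics alone, with labels masked during clustering.
The early-transit control tissues (kidney, liver, blood) share similar
kinetics by design and merge into mixed control clusters, which is
irrelevant to lesion readouts. `autoplot(report)` draws the averaged
cluster TACs (malignant clusters keep a sustained late signal, benign
ones decay), `plot_composition(report)` the per-cluster source-VOI
bars.

Group comparison of, say, lesion SUVmax values uses the package's exact
Mann–Whitney U:

```r
mann_whitney_u(c(14.2, 9.8, 11.5, 16.0), c(8.1, 6.9, 10.2, 7.4),
               c("malignant", "benign"))
#>   group1    group2    n1    n2     u p_value method            alpha
#> 1 malignant benign     4     4    15  0.0571 exact enumeration  0.05
```

`run_individual()` / `run_combined()` wrap the whole pipeline
(masking, optional tumor-to-background gating at TBR ≥ 1.5, artifact
export with provenance) behind a single config list. See the vignette
`vignettes/voxel-network-clustering.Rmd` for the model, the phantom's
assumptions and the numerical choices.

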