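# linkscape

Linkage maps, segregation distortion regions and recombination landscapes
for full-sib mapping populations of outcrossing plants.

## The problem

In outcrossing species with long generation times — conifers are the
archetype — quantitative genetics runs on SNP-based linkage maps built
from two kinds of full-sib family: an **outbred cross** of two
heterozygous parents, analysed under the two-way pseudo-testcross
strategy (markers heterozygous in one parent segregate 1:1 and yield
separate maternal and paternal maps), and a **selfed F2** of a single
hybrid, in which every informative marker segregates 1:2:1 and recessive
deleterious alleles are exposed by inbreeding. Comparing the two designs
answers questions a single family cannot:

* **Where are the embryo-viability loci?** A cluster of markers with
  distorted segregation in the selfed F2, but clean in the same genomic
  region of both outbred parental maps, marks a deleterious allele
  revealed by inbreeding. Distortion restricted to one parental (gametic)
  map instead points to prezygotic (gametic) selection.
* **Is recombination genetically variable?** Map lengths and pairwise
  recombination fractions for shared markers can be compared between the
  genotypes in which meiosis occurred, and marker-density profiles along
  each map expose recombination coldspots (marker pile-ups) and hotspots
  (marker deserts) that may or may not be shared between genotypes.

linkscape implements this entire workflow, driven by a forward meiosis
simulator so every stage is testable against a known truth without any
external data.

## Methods at the core

* **Simulator**: gametes drawn per linkage group as a Poisson
  count–location process (no interference; gamma-renewal interference
  optional) on a modifier-warped distance scale, so local hot/coldspots
  and genome-wide rate differences can be planted; offspring survive an
  optional viability locus with class fitness *w<sub>c</sub>* (survivor
  shares *p<sub>c</sub>w<sub>c</sub>* / Σ *p<sub>k</sub>w<sub>k</sub>*);
  genotyping error and missingness on top.
* **Segregation**: per-marker Pearson χ² against 1:1 or 1:2:1 (*P* ≤
  0.01, no continuity or multiplicity correction), clustering of
  distorted markers into SDRs in map order, inbred/outbred contrast via
  anchor-marker projection, validation in an independent cohort, stage
  classification and grandparental-origin tracing of the deficient
  allele.
* **Two-point mapping**: θ̂ = *R/n* with LOD = *n* log₁₀2 + *R* log₁₀θ̂ +
  (*n−R*) log₁₀(1−θ̂) for testcross pairs; EM over the 3×3 table for
  codominant F2 pairs; Kosambi distances *d* = ¼ ln((1+2θ)/(1−2θ));
  LOD ≥ 3 grouping, greedy + 2-opt ordering, accessory-marker attachment
  by maximal two-point LOD; same-contig call comparisons as a
  genotyping-error estimate.
* **Coverage**: observed length G₀ (with gap adjustment), expected length
  G<sub>e</sub> = Σ L<sub>i</sub>(m<sub>i</sub>+1)/(m<sub>i</sub>−1),
  observed coverage 100·G₀/G<sub>e</sub>, expected coverage by the Bishop
  formula.
* **Landscape**: Sheather–Jones plug-in bandwidth per linkage group,
  1-cM sliding windows, Poisson(λ) thresholds for hot/coldspot calling,
  cross-map interval matching with Venn counts and Jaccard indices.
* **Comparison**: paired Wilcoxon signed rank on recombination fractions
  of shared non-distorted markers, per-pair Z-tests, marker-distribution
  χ², collinearity checks.

## Worked example

Plant a fully lethal recessive at 30 cM of LG02, genotype 69 selfed
offspring, build the map, detect and validate the SDR, and trace the
deficient allele:

```r
library(linkscape)
tm <- grid_true_map(n_lg = 2, length_cM = 60, spacing_cM = 6,
                    viability_locus = list(lg = "LG02", pos_cM = 30,
                                           fitness = c("11"=1, "12"=1, "22"=0)))
cd <- cross_design("F2_SELF", list(parent = f2_parent(tm)), 69, seed = 42,
                   grandparents = c("Landes", "Corsica"))
gm <- simulate_cross(cd, tm)
map <- build_map(gm)
seg <- seg_test_all(gm, alpha = 0.01)
sdr <- detect_sdr(map, seg[seg$marker_id %in% map$marker_id, ])
sdr$regions[, c("lg", "start_cM", "end_cM", "n_distorted")]
#>     lg start_cM   end_cM n_distorted
#> 1 LG02   28.576 61.62793           8
```

Eight linked markers around the planted locus are distorted and cluster
into one SDR. A second, larger cohort confirms it and names the origin:

```r
val <- simulate_cross(cross_design("F2_SELF", list(parent = f2_parent(tm)),
                                   380, seed = 43,
                                   grandparents = c("Landes", "Corsica")), tm)
v <- validate_sdr(sdr$regions[1, ], val)
v$status
#> [1] "validated"
transmission_origin(val, strsplit(v$members, ",")[[1]])[c("deficit_class", "origin")]
#> $deficit_class
#> [1] "B"
#> $origin
#> [1] "Corsica"
```

The homozygote class carrying the second grandparent's haplotype is in
deficit — the planted semi-lethal is correctly traced to the "Corsica"
grandparent. Map coverage statistics come from the same map object:

```r
coverage_stats(map, X = 30)
#> coverage_stats: G0 = 124 cM, Ge = 148 cM, Co = 83%, Ce = 0.982
#>   R = 2 chromosomes, N = 22 framework loci, X = 30 cM, 5.6 cM/locus
```

(A 22-marker toy map leaves real coverage gaps — hence 83%. Study-scale
maps in the package checks reach the high-90s, as real saturated maps
do.)

`run_pipeline(default_config(), out_dir = "out")` runs every stage —
simulate both designs, map, SDR detection/validation, coverage,
landscape, comparison — and writes the TSV report bundle. The same
pipeline is scriptable from a shell via `exec/linkscape`
(`simulate`, `run`, `map`, `segdist`, `coverage`, `landscape`, `qc`).

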