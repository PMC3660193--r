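---
title: "Models and methods behind linkscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind linkscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkscape)
```

linkscape analyses SNP-based linkage maps from full-sib families of
outcrossing plants, with a forward meiosis simulator as its backbone so
that every statistical stage — segregation-distortion detection, map
construction, coverage estimation, recombination-landscape calling and
between-map comparison — can be exercised against a known truth. This
vignette explains the models, the tunable parameters and the numerical
choices, and states what the simulation-based checks do and do not
demonstrate about real data.

## The meiosis simulator

### Crossover model

Each gamete is drawn per linkage group as a count–location process: the
number of crossovers is Poisson with mean equal to the effective length
in Morgans, and locations are uniform — equivalent to a no-interference
(Haldane) model. This choice is deliberate: it admits closed-form oracles
(for two markers $d$ cM apart, $\theta = \frac12(1-e^{-d/50})$), and none
of the downstream analyses condition on interference. A gamma-renewal
chiasma process (shape `interference_nu`, thinned 1/2) is exposed for
users who want positive interference, but it is off by default.

Local recombination-rate variation is modelled by piecewise-constant
multiplier tracks per parent: a multiplier $m$ over an interval stretches
(or shrinks) its effective genetic length $m$-fold. Crossovers are placed
uniformly on the warped scale and mapped back, so a multiplier of 0.25
over 20 cM behaves exactly like a 5 cM stretch of baseline genome — that
is how hotspots and coldspots of recombination are planted.

Because distances are simulated under Haldane but downstream maps use the
Kosambi function (the field's convention), estimated map lengths differ
from the simulated truth by the map-function mismatch (a few percent at
typical marker spacing). Tests therefore compare recombination fractions,
not centimorgans, against truth, and length checks use the
Kosambi-transformed truth.

### Mating designs and genotype codes

Two designs are supported. `F2_SELF` selfs a single heterozygous F1
(every informative marker segregates 1:2:1; codes `A/H/B/U`), with
haplotype 1 inherited from the first grandparent by convention — this
phase bookkeeping is what lets `transmission_origin()` name the
grandparental source of a deficient allele. `CP` crosses two distinct,
partially heterozygous parents and is analysed under the two-way
pseudo-testcross strategy: markers heterozygous in one parent only
segregate 1:1 (JoinMap-style codes `lm/ll`, `nn/np`) and give separate
maternal and paternal maps; markers heterozygous in both segregate
1:2:1 (`hh/hk/kk`) and enter maps as accessory markers.

### Viability selection

An optional embryo-viability locus assigns a fitness in $[0,1]$ to each
genotype class (by haplotype origin: `"11"`, `"12"`, `"22"`). Each
conceived offspring survives with the fitness of its class at that locus;
rejection sampling continues until the requested number of survivors is
reached. Survivor shares follow $p_c w_c / \sum_k p_k w_k$, which is the
mechanism that produces clustered segregation distortion around the locus
upon inbreeding. The selection coefficient of a semi-lethal allele is a
free parameter: the demo configuration uses fitness 0.1 for the
affected homozygote (a strongly semi-lethal allele), while the
simulation-recovery checks use full lethality, the cleanest case.

### Noise model and defaults

Genotyping error is a symmetric random substitution among the legal codes
of the marker's segregation type, applied per call with probability
`error_rate`; missingness masks calls at `missing_rate`. Defaults are
0.0017 (the 0.17% discordance measured between same-contig SNPs on
high-quality Infinium arrays) and 0.02. All randomness flows from a
single root seed stored in the `cross_design`, so a run is reproducible
byte for byte.

The simulator emulates Mendelian transmission, linkage, viability
selection, local rate variation, genotyping error and missingness. It
does **not** emulate segregation-ratio distortion from scoring bias,
paralogous loci, null alleles, or non-random missingness — so passing
recovery tests show the statistics work under the stated model, not that
real-data artefacts cannot mimic distortion; that is precisely why the
validation-cohort step exists.

## Segregation distortion and SDRs

Each marker is tested by Pearson chi-square against its Mendelian ratio
(1:1 or 1:2:1) with no continuity correction and **no multiple-testing
adjustment**, at $\alpha = 0.01$ — the field's convention. With ~1000
markers, ~10 false flags are expected; the package's position is that
clustering plus independent validation, not a multiplicity correction, is
the right filter here, but users should be aware of the issue. A warning
(not an error) is emitted when any expected count drops below 5.

`detect_sdr()` scans markers in map order: a tested non-distorted marker
breaks a run; an untested marker is skipped as long as consecutive
distorted members stay within `max_gap_cM` (default 10). Runs of at least
`min_cluster` (default 3) markers become SDR candidates; shorter runs are
reported as singletons. The defaults are our operationalization of a
qualitative notion of "cluster": 3 is the smallest run length that is
unlikely to arise from independent 1% false positives, and both knobs are
exposed.

The inbred/outbred contrast (`contrast_pedigrees()`) projects each F2 SDR
onto the two outbred parental maps through shared anchor markers
(piecewise-linear interpolation between anchors, constant extrapolation
beyond the terminal ones) and keeps only regions with no distorted marker
on either parental map — the signature of a deleterious allele revealed
by inbreeding rather than a locus under gametic selection.
`validate_sdr()` re-tests member markers in an independent larger cohort
and calls the region validated when a **majority** remain distorted; the
criterion is deliberately conservative because single-marker re-tests at
$\alpha=0.01$ would let one lucky marker validate a spurious region.
`classify_stage()` encodes the standard logic: distortion on one parental
(gametic) map only is prezygotic; distortion in zygotic ratios, or
mirrored on both parental maps, is postzygotic.

`transmission_origin()` pools genotype counts across SDR member markers
before testing. Tightly linked markers are near-replicates of one test,
so pooling changes power little while keeping the type-I rate near
nominal; the deficit class and its grandparental origin are reported only
when the pooled chi-square is significant.

## Two-point mapping

For testcross pairs the recombination fraction is the mismatch count over
pairwise-complete individuals, with the orientation chosen so that
$\hat\theta \le 0.5$ (reported as coupling/repulsion), and
$\mathrm{LOD} = n\log_{10}2 + R\log_{10}\hat\theta +
(n-R)\log_{10}(1-\hat\theta)$, evaluated with the $0\log 0 = 0$
convention at the boundaries (continuity of the likelihood). For
codominant F2 pairs the MLE comes from an EM over the 3×3 genotype table
(the double heterozygote being the ambiguous class), run under both
phases with the better-supported one kept; it matches a fine grid search
of the likelihood to $10^{-4}$.

Grouping is the transitive closure of pairs with LOD ≥ 3. Ordering is a
transparent heuristic, not a reimplementation of regression mapping:
greedy chain extension from the tightest-linked pair, refined by 2-opt
segment reversals minimizing the sum of adjacent recombination fractions;
positions are cumulative Kosambi distances. Output orientation is fixed
lexicographically, since whole-group reversal is unidentifiable. Accessory
markers (1:2:1 in a CP family, or low-support markers) attach to the
framework marker with maximal two-point LOD, ties broken toward the
smaller distance; the attachment distance and LOD are recorded in the map
table. One marker per contig (the most complete, by default) enters the
framework. Acceptance of the ordering heuristic is truth recovery on
simulations — exact order at ≥2 cM spacing with 500 offspring — not
concordance with any particular mapping program.

Genotyping error inflates maps: at 1 cM marker spacing an error rate of
0.17% adds roughly 0.3 cM per interval. This is a property of two-point
estimation generally, not of this implementation; error-free simulations
recover map length within 10%.

## Genome length and coverage

Observed length $G_0$ is the sum of linkage-group spans plus an explicit
gap adjustment for chromosomes split into subgroups. Expected length uses
the marker-count inflation $G_e = \sum_i L_i\,(m_i+1)/(m_i-1)$ over
framework markers; observed coverage is $100\,G_0/G_e$. Expected coverage
uses the Bishop et al. formula
$$C_e = 1 - \Big[\tfrac{2R}{N+1}\big((1-\tfrac{X}{2G_e})^{N+1} -
(1-\tfrac{X}{G_e})^{N+1}\big) + (1-\tfrac{RX}{G_e})(1-\tfrac{X}{G_e})^{N}\Big],$$
clamped to $[0,1]$. Published renderings of this expression are often
typographically mangled; the implementation was validated against its
structural limits ($X=0 \Rightarrow C_e=0$; $N\to\infty \Rightarrow
C_e\to 1$) and an independent re-evaluation. $X$ — the largest accepted
gap between adjacent markers at the chosen LOD support — is a required
explicit input, since published analyses rarely state which support level
produced their $X$. Marker density divides $G_0$ by **all** mapped
markers (framework plus accessory), which is the convention under which
published density figures reconcile.

## Recombination landscape

Marker density along a map is profiled by sliding a window of width $h$
(one bandwidth) in 1 cM steps, anchored at position 0; the final partial
window is dropped so every count shares the same window area and the
Poisson rate stays comparable. $h$ is the Sheather–Jones direct plug-in
bandwidth for a Gaussian kernel, computed per linkage group per map; with
fewer than 5 markers (or degenerate positions) the code falls back to
Silverman's rule and finally a 1 cM floor, with warnings.

Thresholds come from the Poisson null: with $\lambda$ the mean markers
per window over the whole map (not per linkage group, where expected
counts get too small), the coldspot threshold $k_{\mathrm{cold}}$ is the
smallest count whose pooled upper tail is observed in significant excess
over $N_w P(X \ge k)$ by a one-cell chi-square at $\alpha$, and the
hotspot threshold $k_{\mathrm{hot}}$ is the largest count whose pooled
lower tail is in significant excess. "Remains significant" is procedural
in the source methods; the one-cell chi-square on the pooled tail is our
formalization. One guard was added after null calibration: a candidate
tail must have expected count ≥ 5 (Cochran's rule) — without it, a single
extreme window in the far tail (expected ≈ 0.1) passes the chi-square and
the false-threshold rate on homogeneous maps exceeds the nominal level.
Interval calling merges maximal runs of threshold-passing windows into
`[first start, last start + h)`, never across a failing window.

Cross-map comparison projects intervals through shared anchors
(piecewise-linear, constant extrapolation), matches same-kind intervals
whose projected spans overlap, merges matches into clusters, and reports
per-kind counts of map-specific, two-map and all-map clusters plus a
Jaccard index $m/(|A|+|B|-m)$ per map pair. Linkage groups with fewer
than two shared anchors are excluded with a warning.

## Comparing recombination between genotypes

Paired comparisons use all within-linkage-group two-point recombination
fractions for markers common to two populations and distorted in neither
(distortion biases recombination estimates). The genome-wide and per-LG
tests are Wilcoxon signed rank with continuity correction, zero
differences dropped, exact distribution below 20 informative pairs (ties
force the approximation). Per-pair differences use
$Z = (\theta_1-\theta_2)\big/\sqrt{\theta_1(1-\theta_1)/n_1 +
\theta_2(1-\theta_2)/n_2}$ with $n_1, n_2$ the **mean** informative
meioses per map — a map-wide constant, matching the classical usage —
though per-pair counts can be supplied. No multiplicity correction is
applied across pairs, mirroring standard practice; the per-pair tests are
descriptive highlights under the genome-wide Wilcoxon umbrella. Note that
at large true $\theta$ both estimators are biased (the cap at 0.5), so
paired tests between *estimator types* on distant pairs can reject even
under equal recombination — comparisons are most meaningful within a
linkage group at moderate distances, and the planted-effect checks use
exactly that regime.

## Problem sizes used in the checks

The packaged checks run at the scale of a realistic SNP-array study:
discovery cohorts of 69 (selfed F2) and 83 (outbred CP) offspring, a
validation cohort of 380, linkage groups of 100–120 cM carrying markers
every 1–5 cM, 500 offspring for landscape and ordering recovery, and
10,000 offspring for estimator-bias measurement. Monte-Carlo replicate
counts (8–100 depending on the check) were chosen so that pass/fail
bands sit several binomial standard errors from their thresholds.

## Known limitations

* Ordering is two-point only; no multipoint likelihood, no consensus
  maps across populations.
* The CP design assumes known marker phase within the simulator; real CP
  data require phase inference, which `rf_testcross()` handles per pair
  but the map assembly does not revisit globally.
* Mixed-type linkage (1:1 vs 1:2:1 pairs) is used only for accessory
  attachment, where it is weakly informative by nature.
* The landscape thresholds assume exchangeable windows; per-LG bandwidth
  differences make the pooled $\lambda$ an approximation (inherited from
  the method it formalizes).
* No QTL mapping, no physical-genome extrapolation, no sequence-level
  hotspot analysis.
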