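---
title: "Models and methods behind dropcult"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dropcult}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropcult)
```

`dropcult` packages the computational side of droplet-based anaerobic
cultivation: scoring colonies in droplet images, making sort decisions,
doing the encapsulation arithmetic, filtering dead-DNA carryover out of ASV
count tables, and summarizing cultivation bias with standard community
ecology. This vignette explains each model, the tunable parameters and their
defaults, the numerical choices, and — importantly — what the synthetic
generators can and cannot demonstrate.

## Poisson encapsulation

Cells suspended at density $\rho$ (cells/mL), diluted $D$-fold and
partitioned into droplets of volume $V$ (pL) land in any given droplet as a
Poisson count with mean $\lambda = (\rho/D)\,V \cdot 10^{-9}$ (the single
place where the mL ↔ pL conversion happens). `poisson_occupancy()` reports
$p_0 = e^{-\lambda}$, $p_1 = \lambda e^{-\lambda}$ and the multiple-occupancy
remainder. `occupancy_range()` evaluates $p_1$ at the extremes
(density mean − sd, smallest volume) and (mean + sd, largest volume); with
the default stool-aliquot parameters (1.5 ± 1.0 × 10⁸ cells/mL, 200×,
65–115 pL) the range is 1.6–12.5%, i.e. roughly 2–12% of droplets start
with exactly one live cell. `droplet_count()` floors the emulsion/droplet
volume ratio (partial droplets do not exist) and `plating_density()`
converts a per-µm² plating density to cells/mm² after dilution.

`plates_for_isolation()` answers "how many dilution plates until every
target population has probability ≥ c of appearing at least once?" under
independent multinomial colony sampling: the smallest $n$ with
$\prod_i \left(1 - (1-p_i)^{n\,m}\right) \ge c$ for $m$ colonies per plate.
This is a generic model, solved by direct scan in log space; it is not
calibrated to any particular experiment.

## Synthetic droplet imaging

`render_frame()` draws what the sorter's camera sees: a darker oil
background (intensity 70), a droplet with a 3 px bright rim (220) and a
lighter aqueous interior (150), and the colony as a cluster of dark granular
spots (granule cores 45–70) scattered around a jittered centre, followed by
additive Gaussian noise (default SD 2) and clipping to 8 bits. Frames
default to 672 × 360 px, the native size of a commodity high-frame-rate
camera. Ground truth (droplet edges, colony pixel mask) is returned with
each frame. The class defaults are 0 / 20 / 500 granules for
empty / sparse / dense.

This is deliberately not an optics simulation: no refraction, no motion
blur, no oil-phase artifacts. The renderer's only job is to give the texture
pipeline the contrast structure that separates the three classes, and its
appearance parameters (rim contrast, granule darkness, scatter width) were
calibrated once, by eye and by class separability, and then frozen. Colonies
are confined near the droplet centre (scatter within the ~60×80 px region
the scorer analyzes) so patch-level and frame-level renders share one
texture scale.

## The Wavelet OD

The score reconstructs a proprietary texture routine from its published
parameters; the contract that matters downstream is that the score is
bounded in $[0,1]$ and increases with colony density. Per detected droplet:

1. **Edge detection** (`detect_droplet()`): on the channel centerline row,
   lightly smoothed, bands above a rim-level threshold
   (background + 0.6 × peak contrast) are rim candidates; consecutive bands
   enclosing a brighter-than-oil interior are paired, and the pair nearest
   the sorting junction wins. Bands touching the frame border mean an
   incomplete droplet: no detection (a normal outcome, not an error).
   A blank frame (rim contrast < 30 intensity units) is also no-detection.
2. **ROI extraction** (`extract_roi()`): a patch of target size 60 × 80 px
   centred between the edges, shrunk proportionally for narrow droplets and
   refused below 15 px (the window size).
3. **Texture features** (`wavelet_texture_vector()`): for each 15 × 15 px
   window (step 5, row-major): take the undecimated biorthogonal-3.1
   subband "LLH" — one level of low-pass along both axes, then a
   second-level high-pass along the horizontal axis with the à-trous
   (zero-upsampled) filter, periodic extension; quantize the subband into
   15 equal-width gray levels over its observed range; build the
   co-occurrence matrix at displacement (3,3); emit one element per window:
   the subband standard deviation times the normalized co-occurrence
   contrast $\sum_{ij} P_{ij}\,((i-j)/(G-1))^2$.
4. **Score** (`wavelet_od()`): the fraction of elements with magnitude
   above `nonzero_tolerance`.

Numerical choices worth knowing:

* *Why amplitude-weight the contrast?* Equal-width quantization over the
  observed per-window range is scale-free, so pure sensor noise would
  quantize to full range and masquerade as texture. Multiplying by the
  subband SD restores an intensity scale, letting one tolerance separate
  noise from colony granularity.
* *Flat-window guard*: windows whose subband range is below `1e-6` are
  emitted as exactly 0, so constant patches can never acquire phantom
  texture from float round-off.
* *Tolerance default 0.8* (8-bit intensity units): calibrated once on the
  synthetic fixtures so that noise-only windows (SD 2) score zero while
  granule texture does not, then frozen. On the default fixtures the class
  means are ≈ 0.00 (empty), ≈ 0.32 (sparse), ≈ 0.86 (dense).
* The "LLH" letters admit more than one reading; the path above (level-1
  low/low, level-2 horizontal high) is this package's normative definition,
  and every stage (family, subband, window, step, levels, displacement,
  tolerance) is swappable through `texture_config()`.
* A single-pixel checkerboard is pure Nyquist frequency and is annihilated
  exactly by the level-1 low-pass stage — the correct "maximally textured"
  probe for this subband is block structure at scale ≥ 2 px.

Sorting (`classify_od()`, `sort_stream()`) applies the empirically
identified gate: scores in $[0.3, 0.7]$ (inclusive on both ends — the
boundary convention is documented rather than silent) are slow-growers and
kept; below is empty, above is dense. The false-positive bound
`false_positive_bound()` is the odds ratio
$\varepsilon \le f^{un}(1-f^s)/[f^s(1-f^{un})]$; defining the empirical
false-positive rate as (kept non-slow)/(all non-slow), the bound holds with
equality when no slow droplet is missed and strictly dominates otherwise,
which the simulator tests verify run by run.

## Synthetic communities

`community_spec()` fixes the study conditions for the sequencing-side
modules. Defaults, chosen once as desk-scale versions of a stool cultivation
run, and the reasoning:

| parameter | default | why |
|---|---|---|
| `n_taxa` | 150 | order of detected ASVs in one stool sample |
| `lognormal_sigma` | 1.5 | heavy-tailed rank-abundance; most taxa < 1% |
| `growth_rate` | lognormal, median 0.35 h⁻¹, sdlog 0.45 | doubling times ~1–7 h |
| `growth_success_prob` | Beta(0.35, 0.35) per taxon | U-shaped culturability: a taxon is mostly either unculturable in a medium or grows reliably |
| `culture_time` | 24 h | one-day droplet cultivation |
| `occupancy_lam` | 0.1 | inside the 2–12% single-occupancy operating band |
| `n_droplets` | 10⁴ | desk scale (real runs use millions); see limits below |
| `carrying_capacity` | 500 cells | picoliter-volume cap per founder |
| `carryover_fraction` | 0.2 | planted dead-DNA read fraction |
| `read_depth` | 10⁵ | typical amplicon library |

Droplet cultivation seeds Poisson(λ) cells per droplet multinomially from
the stool profile; each founder grows *independently* (no competition) to
$\min(K, e^{rt})$ with its taxon's success probability. Plate cultivation is
the minimal shared-resource competition model: grown abundance
$\propto$ stool × success × $e^{rt}$, so fast growers dominate
exponentially. Sorting keeps droplets whose total colony biomass falls in a
window; the sub-capacity window $[1, K/2]$ is the size-space analogue of the
0.3–0.7 OD gate. Carryover mixes at the *read* level —
$(1-f)\cdot\text{grown} + f\cdot\text{stool}$ — matching the premise that
dead inoculum DNA contributes reads in proportion to stool composition;
sequencing is a single multinomial draw at fixed depth. All randomness runs
through per-stage child seeds of one spec seed; reruns are bit-identical.

## Carryover filtering

For each cultured sample the filter first fits the dead/nonviable fraction
$p_{nv}$ on ASVs whose sample proportion is at least `fold_threshold` (10)
times below their stool proportion: the least-squares slope through the
origin of sample vs. stool proportions on that qualifying set (a
median-of-ratios alternative sits behind `method = "ratio"`). Each detected
ASV then gets a 90% MLE confidence interval for its proportion on the logit
scale, $\theta = \ln p/(1-p)$: maximum at $\hat\theta = \ln x/(n-x)$,
observed information $n\hat p(1-\hat p)$, interval
$\hat\theta \pm z/\sqrt{n\hat p(1-\hat p)}$ with $z = 1.645$, transformed
back to counts. The ASV is discarded when the interval's lower count is
below its carryover expectation $p_{nv}\, q_k\, n$. Conventions at the
boundaries: $x = 0$ means absent (no interval); $x = n$ takes a continuity
correction $x - 0.5$ for the lower limit and an upper limit of 1; ASVs
absent from stool have threshold 0 and are always retained (carryover
cannot explain them). No multiple-testing correction is applied across
ASVs — deliberately, and documented rather than silently added, since the
filter is calibrated as a per-ASV rule.

Two structural properties of this filter deserve emphasis. First, the
origin-slope estimate can never exceed $1/\text{fold}$: every qualifying
point has ratio ≤ 1/fold by definition, so a true carryover fraction above
that cap (e.g. 0.2 with fold 10) is unrecoverable — the estimator is
consistent only in the regime $p_{nv} \lesssim 1/\text{fold}$, which is also
the regime where treating 10×-depleted ASVs as "pure carryover" is coherent
in the first place. The package reproduces this faithfully rather than
redefining the rule. Second, the logit-Wald interval at small $p$ is
slightly conservative: at $(n = 1000, p = 0.01)$ its exact coverage is
92.3%, not 90% — the tests assert the empirical coverage around that exact
value, computed independently from the binomial pmf.

## Ecology conventions

Shannon diversity uses the natural log (no base is standard; the choice is
free and documented). Rank-abundance ties break lexicographically by ASV id.
Amplification calls use the 1% cutoff on both sides: a stool-rare ASV
(< 1%) is amplified when its cultured relative abundance exceeds 1%.
Bray–Curtis, UPGMA clustering, KS and Mann-Whitney tests delegate to
`vegan`, `stats::hclust`, `stats::ks.test` and `stats::wilcox.test`; the
package's own Bray–Curtis formula is cross-checked against `vegan::vegdist`
in the tests. Dendrograms serialize to Newick via `ape`. The pipeline
(`run_pipeline()`) computes ecology on the *filtered* table, since the
metrics should describe organisms that grew.

## What the synthetic tests do and do not show

The generators reproduce the statistical *structure* the methods assume —
lognormal rank abundance, Poisson loading, capacity-limited isolated growth
vs. exponential competition, read-level carryover, multinomial sequencing —
not any particular stool. Passing tests therefore show the algorithms are
correct and the qualitative claims (droplets track stool more closely than
plates; low-size sorting enriches slow taxa; carryover-level ASVs are
removed) hold under those assumptions; they say nothing about taxonomy,
phylogeny, real growth-rate distributions, or co-encapsulation dynamics
(none of which are modeled).

Known limitations:

* **Founder sampling at desk scale.** At 10⁴ droplets and λ = 0.1 only a
  few hundred colonies grow, and a size-gated keep pool holds ~10–15
  distinct taxa. The *count* of rare taxa amplified above 1% by sorting is
  then dominated by which taxa happen to be seeded, and the sorted-vs-
  unsorted comparison of that count is near a tie at this scale (at 10⁵
  droplets the direction favors sorting, as it does in a real run with
  millions of droplets). The share of slow-growing taxa, by contrast,
  increases under sorting robustly at any scale.
* The plate model has no spatial structure, lag phases or interactions
  beyond shared exponential competition.
* The imaging model's classes are calibrated to be separable; it cannot
  quantify real-camera misclassification rates.
* Problem sizes in the test-suite experiments (e.g. 100 seeded runs of
  3000–10⁴ droplets, 10⁴ binomial draws for interval coverage) are the
  package's chosen desk-scale defaults, stated here so results are read at
  the right scale.
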