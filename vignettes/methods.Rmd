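---
title: "Methods: multispectral leaf-color phenotyping and pseudo-testcross QTL mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral leaf-color phenotyping and pseudo-testcross QTL mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures it
implements, the assumptions behind them, and the design choices made where
the design was genuinely open.

# Phenotyping model

## Input contract

A plant observation is a co-registered stack of nine grayscale planes at
445, 500, 532, 550, 568, 676, 680, 700 and 800 nm (10 nm bandwidth each).
Integer images are rescaled to `[0, 1]` by `value / (2^bitdepth − 1)` at
ingestion; all later arithmetic is on that relative-intensity scale. Two
assumptions are made and not checked computationally: the planes are
*co-registered* (the imaging rig holds the pot and camera fixed, so no
alignment step exists), and gray values are *relative*, not calibrated
reflectances. The second assumption is harmless downstream because the
sum-to-one standardization removes any global scale; whether day-to-day
illumination differences are truly multiplicative — the implicit assumption
behind standardizing at all — cannot be tested from the data and is simply
inherited by every standardized trait.

## Segmentation

A pixel is plant iff `I(800) > I(680)`, strictly; ties are background.
Healthy mesophyll scatters NIR strongly while absorbing red, whereas soil
and pots do not show that inversion. The strict inequality is deliberate:
it makes an all-constant image segment to an empty mask rather than an
arbitrary one. No morphological cleanup is applied by default because the
rule operates per pixel in the source method; on synthetic scenes the rule
is exact by construction, and on real images stray pixels are tolerated by
the median that follows.

## Spectra and indices

The phenotype unit is the vector of per-band *medians* over the mask (even
pixel counts use the mean of the two middle values — the standard
convention; the method description is silent), rescaled to proportions
`p_w = r_w / Σ r` that sum to 1 within 1e−12. The fifteen vegetation
indices are evaluated on those proportions exactly as published, including
the reciprocal forms (`ARI = 1/p550 − 1/p700`, `CRI1`, `CRI2`) and the EVI
`+1` constant applied on the proportion scale. That is a
faithful-reproduction choice, not a radiometric one: on proportions the
non-ratio indices (CARI, MCARI, ARI, CRI1, CRI2) take different absolute
values than they would on calibrated reflectance, but a shared illumination
factor leaves every between-plant ranking unchanged, and ranks are what the
genetic analysis consumes. A zero denominator makes that single index `NaN`
with a warning instead of aborting, so one degenerate plant cannot kill a
population run.

## Multivariate traits

PCA of the nine proportions is *covariance* PCA (the inputs are already
commensurable; correlation PCA is available via `scale.`). The PC1 sign is
fixed so the 676 nm loading is positive — high PC1 always means
redder/browner leaves — and the remaining components get a
largest-loading-positive convention so results are platform-stable. The
27-trait table is cover area, nine proportions, PC1, PC2, and the fifteen
indices. Interannual correlations and the PC1-versus-cover-area correlation
are Pearson (the conventional "R value"; Spearman is available). Quantile
representatives use type-7 quantiles with ties broken to the lower plant
id, making selections deterministic.

PCA is fit per image set (i.e. per capture date); pooling two years into
one decomposition is possible by concatenating tables, but per-date fits
are the default because the two dates are separate illumination regimes.

# Genetic model

## Pseudo-testcross maps

Both parents are outbred heterozygotes, so no marker class segregates in
both parents informatively at once. Markers with parent genotypes H/A build
the P1 map, A/H the P2 map; H/H and A/A markers are excluded, as are
markers whose F1 segregation rejects 1:1 by chi-square at `alpha = 0.001`
(distorted markers create pseudo-linkage; the threshold is conservative so
only strong distortion is removed).

Two-point estimation scores both phases — in a two-class testcross a
recombination event is a genotype *difference* in coupling and a *match* in
repulsion — and keeps the phase with `r ≤ 0.5`. Estimates need at least 10
pairwise-complete individuals; missing genotypes are handled
pairwise-complete with no imputation at this stage. Grouping is
single-linkage transitive closure at `r ≤ 0.35` and `LOD ≥ 3`, common
defaults where the source is silent. Ordering is exact (exhaustive over
`k!/2` orders) up to 8 markers and greedy nearest-neighbour plus 2-opt
beyond; orientation is normalized lexicographically. Phases are then
propagated along the order so each marker carries a flip flag relative to
the group's reference orientation — essential for the probability model
below when real (mixed-phase) data are mapped. Haldane is the default map
function, matching the default of the standard mapping software; Kosambi is
selectable everywhere.

Mean marker spacing is reported as `total length / (markers − groups)`,
i.e. the mean adjacent interval.

## Genotype probabilities

Each linkage group is a two-state Markov chain along the chromosome; the
transition probability across `d` cM is the inverse map function of `d`.
Conditional probabilities of the heterozygous state at every grid point
(2 cM step, marker positions always included) given all observed markers on
the group come from the forward–backward algorithm with genotyping-error
rate 0 — at a typed marker the posterior is a point mass on the observed
class. Individuals untyped on a whole group get 0.5 everywhere, with a
warning.

## Scans, CIM, thresholds

Haley–Knott regression at each grid point regresses the trait on the single
genotype-probability column (testcross: `P(A) = 1 − P(H)`, so one
regressor), with `LOD = (n/2) log10(RSS0/RSS1)`. At a fully typed marker
this reduces algebraically to `−(n/2) log10(1 − R²)` of the simple 0/1
regression, which the tests verify to 1e−10. Singular positions (constant
probability) score 0 with a warning; a phenotype fully absorbed by the null
model scans flat at 0.

Composite interval mapping forward-selects up to 3 marker cofactors by
model R² on the observed genotypes, then drops any cofactor lying on the
scanned group within 30 cM of the scan position. The window parameter is
stated without units in the source method ("window size 30") and is read as
30 cM of exclusion distance. Cofactor covariate values are the
marker-position probabilities — equal to the observed genotype where typed
and its conditional expectation where missing — so missing cofactor calls
do not shrink the sample. With zero cofactors CIM is bit-identical to the
plain scan.

Permutation thresholds shuffle the trait over individuals with genotypes
fixed, rerun the full scan — for CIM including cofactor reselection, which
is slower but gives a valid null — and take type-7 empirical quantiles of
the genome-wide maximum LOD at 5% and 10%. Thresholds are computed per
trait, and a seed is required for reproducibility. Cofactor-free scans use
a closed-form vectorized path (`LOD = −(n/2) log10(1 − ρ²)` over all
position-permutation pairs) that the tests check against explicit rescans.
QTL calls collapse each contiguous supra-threshold run to its argmax, one
peak per run per group; peaks clearing only the 10% threshold are labelled
marginal.

## Genotype classes

Given two QTLs, each F1 is labelled by its genotypes at the two nearest
markers (first letter = first QTL), giving classes AA/AH/HA/HH. A one-way
ANOVA plus Tukey HSD at `alpha = 0.01` compares the trait across classes;
the compact letter display is computed by insert-and-absorb on the Tukey
p-value matrix, with the highest-mean class getting letter `a`. Classes
with fewer than two members are dropped with a warning.

# What the synthetic generators emulate

The imaged study system this package targets deposited no raw data, so the
generators define the study conditions the tests run under.

`generate_scene` draws a disk or blob of plant pixels over background, each
from a nine-band Gaussian profile truncated to `[0, 1]`. The default
*green_leaf* profile peaks at 550 nm with strong 800 nm; *dormant_leaf*
depresses the green bands and elevates 676–700 nm — the reflectance shape
of anthocyanin-rich overwintering foliage (anthocyanins absorb around
510–550 nm); *background* is a flat soil spectrum whose NIR sits well below
its red (0.10 vs 0.22), a 6-sigma margin at the default 0.02 pixel noise so
the segmentation rule behaves as cleanly as it did on the real pot-and-soil
scenes. Rasterization is fixed — pixel centres at half-integer offsets from
the image centre, strict `x² + y² < r²` — so area oracles are exact
(e.g. radius 16 in 64×64 gives 812 pixels).

`simulate_pseudo_testcross` defaults to the study scale: 94 F1s, two
linkage groups per parent, eight markers per group at 10 cM. Haplotypes
follow the chain implied by the chosen map function, so markers segregate
1:1 and realized recombination matches the map in expectation (tested by
Monte Carlo at n = 2000). Phase flips are optional (`phase = "random"`)
and drawn after the genetic states, so the latent genetics under one seed
is identical across phase regimes. QTL effects act through the nearest
marker's latent state — exactly recoverable by design — with noise scaled
to an explicit SD or a target heritability.

`render_population_images` closes the loop: a *color* QTL on a P2 group
sets each plant's green/dormant mixture weight (A = 0.30, H = 0.70,
plant-level SD 0.10) and its disk radius (A = 10 px, H = 13 px, SD 1), so
greener genotypes are also larger — reproducing the negative
PC1-versus-cover-area relationship of spring dormancy breaking; a *NIR*
QTL on a P1 group scales the 800 nm mean (A = 0.90, H = 1.15, SD 0.05),
driving the NDVI/SR/EVI family. These magnitudes were fixed once, chosen
to match a system whose genotype classes are visibly distinct, and are not
tuned per test.

What the generators do **not** model: shadows, specular highlights,
multi-plant scenes, registration error, radiometric calibration,
genotyping error, segregation-distorted regions, and map fragmentation
(real maps of this kind split into many more groups than chromosomes).
Passing tests therefore demonstrate correctness of the algorithms under
clean study-scale conditions, not robustness to every artifact of field
imaging or RAD genotyping.

# Numerical choices

- Standardization tolerance 1e−12 on the unit sum; degenerate (all-zero)
  spectra are an error.
- `estimate_rf` limit case `R = 0` uses `LOD = n log10 2` exactly.
- Adjacent recombination fractions of 0.5 or above inside an ordered group
  (possible for weakly supported transitive links) are clamped just below
  0.5 with a warning rather than breaking the group.
- Forward–backward is normalized per step to avoid underflow; posteriors
  are exact at typed markers.
- `RSS1` is floored at `RSS0 × 1e−12`, capping any single-position LOD at
  `6n`, to keep near-perfect fits finite.
- Thresholds use type-7 quantiles; ties in representative selection and
  group numbering break lexicographically; seeds are plain `set.seed`
  integers consumed at function entry.

# Problem sizes in the test suite

Simulation-backed tests run at the study scale (n = 94, two groups per
parent, eight markers at 10 cM) with 20–40 seeds per property, permutation
tests at 150–1000 permutations, the null-calibration experiment at 200
replicates × 200 permutations, and the end-to-end image-to-QTL property at
20 seeds × 200 permutations over eight traits. These sizes were chosen to
give stable pass/fail behaviour for the stated tolerances.

# Known limitations

- Multipoint maximum-likelihood ordering, consensus (integrated) maps,
  multiple-QTL models, epistasis scans and QTL confidence intervals are out
  of scope; the two parental maps are scanned separately and concatenated.
- Markers heterozygous in both parents (3:1 class) are excluded rather than
  mapped, keeping the design a pure pseudo-testcross.
- The CIM window interpretation (30 cM exclusion distance on the scanned
  group) is one reading of an under-specified setting; the parameter is
  exposed for users who prefer another.
- JPEG input is accepted for compatibility but lossy; TIFF is preferred.
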