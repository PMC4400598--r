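---
title: "Quantifying oriented granulosa-cell division and the ovarian follicle census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oriented granulosa-cell division and the ovarian follicle census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcorient)
```

## The measurement

During early folliculogenesis the granulosa cells surrounding the oocyte
divide in an oriented manner: the mitotic spindle tends to align with the
axis running from the oocyte centre through the dividing cell towards the
basal lamina, so that division produces a proximal and a distal daughter and
stacks new concentric layers around the growing oocyte. Loss of that
orientation is a candidate mechanism for folliculogenesis failure, so the
quantity of interest is the acute angle $\theta$ between two undirected axes
measured in a 2-D histological section:

* the **oocyte–basal-membrane axis**: the line through the oocyte centre and
  the centre of the mitotic granulosa cell (extended, it meets the basal
  lamina; the lamina polygon itself only participates in validity checks,
  because two centres already fix the line);
* the **spindle axis**: for an anaphase cell, the line joining the centroids
  of the two separating chromatid masses; for a metaphase cell, the
  perpendicular to the metaphase plate, the plate being the line through the
  annotated chromatin landmarks.

With unit direction vectors $d_1, d_2$,

$$\theta = \arccos\,\lvert d_1 \cdot d_2 \rvert \in [0^\circ, 90^\circ].$$

The absolute value folds the angle: an axis has no sign, so $\alpha$ and
$180^\circ - \alpha$ are the same measurement. The source data for this
pipeline report medians and a "random distribution" null that are consistent
with the $[0^\circ, 90^\circ]$ range, but do not state the folding
explicitly; folding via the absolute dot product is this package's
inference, recorded here as such. All angle input is unit-agnostic in
coordinates (pixels or µm) and always reported in degrees.

For a metaphase plate annotated with more than two points, the plate line is
the first principal axis of the landmark scatter (orthogonal, total-least-
squares regression). A chromatin band has no privileged endpoints, so
orthogonal regression — which minimises perpendicular distance and is
rotation-equivariant — is the right fit; with exactly two points it reduces
to the line through both.

Degenerate cells (coincident centres, coincident chromatid centroids, a
collapsed plate) are skipped with a logged, counted report; a hard error is
reserved for violations of the section's own invariants (oocyte centre
outside the lamina, a cell centre inside the oocyte disc). Coincidence is
declared below `1e-9` coordinate units, and unit vectors are normalised to
within `1e-12`.

## Testing against the "random" null

The null hypothesis of unoriented division is that $\theta$ is uniform on
$[0^\circ, 90^\circ]$. Angles are normalised to $u = \theta / 90 \in [0,1]$
and tested with the one-sample Kolmogorov–Smirnov statistic

$$D_n = \max_i \left\{ \tfrac{i}{n} - u_{(i)},\; u_{(i)} - \tfrac{i-1}{n} \right\}.$$

Two p-value routes are implemented:

* **asymptotic**: $p = 2 \sum_{k \ge 1} (-1)^{k-1} e^{-2 k^2 n D^2}$,
  truncated when a term falls below $10^{-16}$ of the running sum and
  clamped to $[0,1]$. With $D = 0.5582$ and $n = 41$ (the concentrated,
  wild-type-like configuration at its published sample size) this evaluates
  to $1.602 \times 10^{-11}$.
* **exact** (Durbin's recursion in the Marsaglia–Tsang–Wang matrix form),
  supported for $n \le 1000$ and used by default for $n \le 140$. The two
  routes converge as $n$ grows, but the asymptotic error is $O(1/\sqrt n)$:
  about $0.017$ at $n = 100$ near $D = 0.1$, below $0.005$ only around
  $n \approx 1000$. Small-sample work should therefore use the exact route;
  the asymptotic one is kept because it is the form under which the
  published statistic is interpretable.

A **two-sample mode** is also provided: a seeded uniform sample of equal
size is drawn and compared with the two-sample $D$ at effective size
$nm/(n+m)$. The reason is an ambiguity in the source statistics: the
published mutant-like value ($p = 0.6416$ at $D = 0.1876$, $n = 31$) is not
reproduced by the one-sample asymptotic formula ($\approx 0.225$) but is
close to the two-sample reading ($\approx 0.646$). Rather than guess, both
modes are implemented, the one-sample mode is the default, and the
two-sample p is reported alongside in the stats output. Neither mode is
ever silently substituted for the other.

Group comparison uses the **Mann–Whitney** test with the convention
$U = \#\{(x, y): y < x\} + \tfrac{1}{2}\#\text{ties}$ (the rank-sum of $x$
minus $n_1(n_1+1)/2$). The exact null distribution (count recursion over
rank assignments) is used when both samples are at most 12 with no ties;
otherwise a normal approximation with continuity and tie correction. The
accompanying shift estimate is the **Hodges–Lehmann** estimator — the median
of all $n_1 n_2$ pairwise differences $y - x$ — with the distribution-free
confidence interval read from the ordered pairwise differences at the
normal-approximation rank cutoff (95% by default). The published "difference
of the two populations ... with a 95% confidence interval" names no method;
the Hodges–Lehmann interval is the standard companion of the Mann–Whitney
test and is used here under that explicitly flagged assumption. No
multiple-testing correction is applied anywhere: each comparison is a single
planned test, matching the source design.

```{r ks-example}
theta_wt <- sample_angles(angle_model("folded_normal", 0, 16.5), 41, seed = 11)
theta_mu <- sample_angles(angle_model("uniform"), 31, seed = 12)
test_against_random(angle_dataset("wild-type-like", theta_wt))
test_against_random(angle_dataset("mutant-like", theta_mu))
mann_whitney(angle_dataset("wt", theta_wt), angle_dataset("mu", theta_mu))
```

## The follicle census

The census procedure classifies every follicle observed on one-in-five
4-µm serial sections into a maturation stage and reports raw per-ovary
counts. The Pedersen–Peters types map to stages (types 1–3 primordial, 4–5
primary, 6 secondary, 7 antral, 8 preovulatory) but carry no numeric
criteria, so the classifier operationalises them through features a
histologist actually annotates:

| stage | criterion |
|---|---|
| primordial | one flattened granulosa layer, no antrum |
| primary | one cuboidal/mixed layer, no antrum |
| secondary | ≥ 2 layers, no antrum |
| antral | multiple small antral cavities |
| preovulatory | single large antrum |

This feature convention is a package decision, isolated in
`classify_follicle()` so alternative criteria can be swapped in. A
single-layer follicle with an antrum is a contradiction and errors.
Counts are raw sums over the sampled sections — no Abercrombie or
fractionator correction — because the procedure being reproduced plots the
total number of follicles in the sections examined; `sampling_fraction` is
carried in the output so users can rescale. Section sampling is
deterministic: indices congruent to a configurable offset modulo 5. Group
comparisons are per-stage Welch t-tests on per-ovary counts, requiring at
least two ovaries per group.

Fertility records (litters per mating pair and mean litter size over a
6-month assay) are summarised as group mean ± s.d. with two-tailed Welch
t-tests against the control group — one p-value per measure, since litter
count and litter size are separate published comparisons.

## What the synthetic generator emulates

`build_study()` produces every input the pipeline consumes, with the truth
recorded next to the data. Its defaults are the study conditions of the
source design:

* **Angles** — a wild-type-like group of 41 mitotic cells drawn from a
  folded normal with mode 0° and σ = 16.5°, and a mutant-like group of 31
  cells drawn uniformly on [0°, 90°]. The folded normal is a modelling
  choice, not a published claim: the source reports only a concentrated
  distribution with median 11.1°, and σ = 16.5° makes the half-normal
  median $\sigma \,\Phi^{-1}(0.75) \approx 11.1^\circ$. Note that a uniform
  sample on [0°, 90°] has population median 45°; the published mutant
  median of 24.2° is a feature of the unpublished raw sample, not of the
  uniform null it was statistically indistinguishable from, and is not a
  target of the generator.
* **Geometry** — each planted angle becomes a cell at a random azimuth
  midway between a circular oocyte (radius 20 µm) and a circular basal
  lamina (radius 50 µm), with landmarks constructed so the noiseless
  forward pass recovers the planted angle to 1e-9°. Landmark jitter, when
  requested, is applied to the landmark *points* (s.d. =
  separation · tan(noise)/√2, a small-angle design giving the recovered
  angle roughly the requested angular s.d.), so noise propagates through
  exactly the geometry code that real annotations would use.
* **Census** — 4 ovaries per group, 100 sections per ovary, per-section
  per-stage Poisson rates with a 5-fold reduction in the mutant-like group
  (the published scale of the primary-follicle deficit). Rates are set so
  sampled per-ovary primary counts sit near 50 (wild-type-like) versus 10
  (mutant-like). The truth file stores the realised per-stage counts on the
  sampled sections, so the census stage can be checked for exact equality.
* **Fertility** — 5 pairs per group; control means 5.6 litters/pair and
  litter size 7.11 versus 5.0 and 4.60 (the published assay totals:
  28 litters / 199 offspring versus 25 / 115 over five pairs each), litter
  counts Poisson, litter sizes Gaussian with s.d. 1.0.

Identical configurations (including the seed) produce byte-identical file
bundles; every stochastic routine takes an explicit seed (default 1729)
recorded in the outputs and manifests.

What the generator does **not** emulate: pixel-level images (annotations are
taken as given points — there is no segmentation to validate), 3-D follicle
shape and section obliquity, atretic follicles, observer disagreement in
landmark placement, and any dynamics of folliculogenesis. Tests passing on
synthetic data therefore validate the measurement and inference machinery,
not the upstream annotation quality of real sections.

## Numerical choices and verification sizes

* Exact KS p-values are cross-checked against an independent reference
  implementation; the statistic is checked against a brute-force supremum
  over a $10^6$-point grid augmented with the sample's jump points.
* Type-I calibration of the uniformity test is verified by simulation at
  the published mutant-like sample size ($n = 31$, 2000 replicates,
  exact p, α = 0.05); power is verified at the wild-type-like configuration
  (folded normal σ = 16.5°, $n = 41$, 500 replicates, α = 0.001). These
  replicate counts keep the full suite under a minute while bounding the
  Monte-Carlo error on a 5% rate to about ±0.5% (one s.e.).
* Mann–Whitney exact p-values are verified against full enumeration of all
  rank assignments for every size pair up to 6×6.
* The even-sample median and the Hodges–Lehmann estimator are exact order
  statistics; translation equivariance of the shift holds to floating-point
  rounding (asserted at 1e-12).
* Ties in the annotation of angles are legitimate (rounded protractor
  values); the rank machinery handles them by midranks with the tie-corrected
  variance.

## Known limitations

* The angle is measured in the section plane; spindles tilted out of plane
  project onto it, which real studies mitigate by selecting clearly in-plane
  mitotic figures. The pipeline inherits whatever selection the annotator
  applied.
* The one-sample/two-sample ambiguity described above means one published
  p-value cannot be attributed to a unique procedure; both are reported.
* The census classifier encodes one reasonable operationalisation of the
  Pedersen–Peters types; laboratories using oocyte-diameter cutoffs or
  different layer conventions should replace `classify_follicle()`.
* Raw sampled counts are not whole-ovary estimates; comparisons between
  groups censused with the same sampling fraction are unaffected.
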