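# gcorient

Quantification of oriented mitotic division of granulosa cells around the
oocyte, and the companion ovarian follicle census.

## The problem

In the growing ovarian follicle, the somatic granulosa cells proliferate
around the oocyte and stack into concentric layers. Histological studies of
this process score, for each mitotic granulosa cell in a section, the acute
angle θ between two axes: the **oocyte–basal-membrane axis** (the line
through the oocyte centre and the dividing cell's centre, extended to the
basal lamina) and the **spindle axis** (for anaphase, the direction of the
separating chromatid masses; for metaphase, the perpendicular to the
metaphase plate). With unit directions d₁, d₂,

    θ = arccos |d₁ · d₂| ∈ [0°, 90°].

Small θ means the cell divides perpendicular to the oocyte surface,
generating proximal and distal daughters. Whether a genotype's θ
distribution is "oriented" is tested against the uniform ("random") null on
[0°, 90°] with the one-sample Kolmogorov–Smirnov test on θ/90; genotypes are
compared with the Mann–Whitney test and the Hodges–Lehmann shift estimate
with its distribution-free 95% CI. The same studies count follicles by
maturation stage (Pedersen–Peters types mapped to
primordial/primary/secondary/antral/preovulatory) on one-in-five 4-µm serial
sections, and summarise fertility of mating pairs.

This package implements that entire measurement and inference chain from
point annotations (no image processing — annotations are taken as given
coordinates), plus a seeded synthetic-study generator that plants known
angles, census counts and fertility records so every stage can be verified
against ground truth. It is aimed at groups quantifying division-plane
orientation in follicle sections — or any radially organised epithelium —
who want the statistics reproducible from the raw annotation table.

## Worked example

```r
library(gcorient)

# two synthetic genotype groups at the published sample sizes
theta_wt <- sample_angles(angle_model("folded_normal", 0, 16.5), 41, seed = 11)
theta_mu <- sample_angles(angle_model("uniform"), 31, seed = 12)

test_against_random(angle_dataset("wild-type-like", theta_wt))
#> Kolmogorov-Smirnov (one_sample_uniform, exact): D = 0.7000, p = 9.992e-16, n = 41
test_against_random(angle_dataset("mutant-like", theta_mu))
#> Kolmogorov-Smirnov (one_sample_uniform, exact): D = 0.2198, p = 0.08528, n = 31
mann_whitney(angle_dataset("wt", theta_wt), angle_dataset("mu", theta_mu))
#> Mann-Whitney (normal_approximation): U = 253, p = 1.397e-05 (n1 = 41, n2 = 31)
#> medians 10.819 vs 33.862; Hodges-Lehmann shift 19.400 [95% CI 10.343, 30.767]
```

The concentrated group (median 10.8°) rejects the uniform null decisively;
the uniform group (median 33.9°) does not (p = 0.085 at n = 31). The
Mann–Whitney comparison reports the shift between the groups: the
mutant-like angles sit 19.4° higher, with the 95% Hodges–Lehmann interval
[10.3°, 30.8°]. As a fixed-input check of the p-value machinery,
`kolmogorov_p_asymptotic(0.5582, 41)` returns `1.602e-11`.

## The analysis workflow

The numbered scripts under `analysis/` run the full pipeline on a simulated
study and write everything under `results/run/`:

```sh
Rscript analysis/01_simulate.R           # annotations, census, fertility + truth.json
Rscript analysis/02_angles.R             # per-cell theta -> angles.csv
Rscript analysis/03_orientation_stats.R  # KS vs random, Mann-Whitney + HL -> stats.json/tsv
Rscript analysis/04_census.R             # per-ovary stage counts + Welch comparison
Rscript analysis/05_fertility.R          # litters / litter size summaries
Rscript analysis/06_report.R             # Markdown report with embedded manifests
```

Each stage writes a manifest (seeds, input digests, record and skip counts);
the report re-verifies the digests and flags tampered inputs. All
computation lives in the package functions, so the scripts are thin,
narrative drivers.

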