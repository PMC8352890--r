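# imcorr

Correlative intima–media gene-expression analysis for discovering
flow-induced vascular-remodeling signals.

## The problem

When blood flow through an artery changes persistently, the vessel
remodels. The endothelial cells of the **intima** sense the wall shear
stress (WSS) directly; the smooth muscle cells of the **media** carry
out the structural remodeling. Whatever links the two must be a
transmittable signal. Given paired RNA-seq of laser-microdissected
intima and media from the same arterial locations under different flow
conditions — the reference design is 2 tissues × 2 locations (straight
basilar segment *BA*, basilar terminus *BT*) × 2 conditions
(carotid-ligated vs sham) × 2 animals = 16 samples — `imcorr` asks: which
intimal genes respond to WSS, co-vary with many medial genes across the
8 matched sample slots, and encode extracellular products that could
physically carry the signal?

The package is aimed at vascular biologists and computational
collaborators who start from a gene-level count matrix (alignment and
counting are upstream, out of scope) plus per-sample mean WSS values
from CFD.

## The method

For each compartment and location, flow-modulated genes are detected
with an exact-style conditional negative-binomial test. For gene counts
summed within the ligated (A) and sham (B) groups, conditional on the
total *S = s<sub>A</sub> + s<sub>B</sub>*, the two-sided p-value is

> p = Σ<sub>a : P(a) ≤ P(s_A)</sub> P(a),&nbsp;&nbsp;
> P(a) = NB(a; n<sub>A</sub>μ, φ/n<sub>A</sub>) ·
> NB(S−a; n<sub>B</sub>μ, φ/n<sub>B</sub>) / Z,

with a qCML common dispersion and df-weighted gene-wise shrinkage, and
BH correction (DEG ⇔ detectable ∧ q < 0.05; detectable ⇔ max group-mean
RPKM > 1). The core screen then computes, for every (intimal DEG,
medial DEG) pair, the Pearson correlation *r* over the 8 matched slots
with p from *t = r√(n−2)/√(1−r²)* on n−2 df, and keeps pairs with
|r| > 0.9 **and** p < 10⁻⁴. Per intimal gene, medial correlates are
tallied (total = positive + negative, by construction); intimal DEGs
with extracellular products and > 200 correlates become signal
candidates. Candidate correlate sets are tested for GO
over-representation (hypergeometric, BH per query), pooled by term
occurrence across queries (> 50% rule), and reduced by greedy semantic
similarity (SimRel or Lin, cutoff C = 0.90). Finally each candidate's
intimal expression vs local WSS is classified as *linear_increasing*
(r ≥ 0.8, positive slope), *plateau*, or *peaked_decline* (maximum
below 40 Pa, ≤ 10% of peak above 50 Pa).

A fully tested synthetic-data generator (`generate_dataset()`) plants
signal genes with known dose–response shapes, log-coupled medial
responders, tissue markers, and media-into-intima contamination, and
serializes the ground truth — so the whole pipeline is validated by
recovery, calibration, and determinism tests rather than by eye.

## Worked example

```r
library(imcorr)

sim <- simulation_config(n_background_genes = 2000,
                         responders_per_signal = 20)
cfg <- run_config(simulation = sim, output_dir = "imcorr_demo",
                  min_correlates = 50, seed = 1)
report <- run_all(cfg)

report$deg_counts
#>   comparison n_deg n_up n_down
#> 1  intima.BA   380  175    205
#> 2  intima.BT   394  182    212
#> 3   media.BA   378  180    198
#> 4   media.BT   379  174    205

unlist(report$pair_counts)
#>   n_pos   n_neg n_total
#>   46064      85   46149

head(report$candidates)
#>   intimal_gene direction_under_flow n_total n_pos n_neg product_class
#> 1      SIGUP01                   up     156   156     0      cytokine
#> 2      SIGUP02                   up     156   156     0 growth factor
#> 3      SIGUP03                   up     156   156     0     peptidase
#> 4      SIGUP04                   up     156   156     0        enzyme
#> 5      SIGUP05                   up     156   156     0         other
#> 6      SIGDN01                 down     144   144     0 growth factor

head(unlist(report$dose_classes))
#>             SIGUP01             SIGUP02             SIGUP03
#> "linear_increasing" "linear_increasing" "linear_increasing"
#>             SIGUP04             SIGUP05             SIGDN01
#> "linear_increasing" "linear_increasing"    "peaked_decline"
```

Reading this: each of the four ligated-vs-sham comparisons calls a few
hundred DEGs (planted responders plus their contamination echo in the
intima); 46,149 intima–media pairs pass the correlation screen, almost
all positive on the RPKM scale (reciprocally coupled responders are
penalized by linear-scale Pearson — see the methods vignette); the
planted up-signals surface as extracellular candidates with ~156 medial
correlates each and are classified `linear_increasing`, while
down-signals come out `peaked_decline`. `report$enriched_terms` lists
the planted medial response modules that exceed the > 50% occurrence
rule per (direction × sign) stratum. All stage tables (`pairs.tsv`,
`candidates.tsv`, `dose_response.tsv`, …) and `report.json` are written
to `output_dir`; reruns with the same config and seed are
byte-identical.

A thin CLI wrapper lives at `inst/cli/imcorr.R`
(`Rscript imcorr.R simulate|run-all …`).

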