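# ppfequant

Computerised quantification of pleuroparenchymal fibroelastosis (PPFE) on
thoracic CT, with the downstream prognostic analyses used in idiopathic
pulmonary fibrosis (IPF) cohorts.

PPFE is an upper-lobe-predominant fibrosis of the visceral pleura and
subpleural lung. In IPF it marks out patients with faster forced vital
capacity (FVC) decline and worse survival, largely independently of the
usual interstitial-severity measures, which makes an objective extent score
valuable for prognosis and trial stratification. This package is aimed at
quantitative-imaging and clinical-research groups who want that score and
its statistical pipeline as tested, reusable code.

## What it computes

**The computerised PPFE score (cPPFE).** For each axial slice the visceral
pleural surface is represented by the most peripheral 3 pixels of the lung
cross-section (the mask minus its three-fold 4-connected erosion),
restricted to the *upper zone* — from the carina to 5 mm below the lung
apex. Shell voxels at or above a dense-tissue threshold (default −200 HU)
are classified PPFE-like after small-component suppression, and

```
cPPFE = 100 · (dense shell voxels) / (shell voxels),   pooled over both lungs.
```

The score is set to 0% for scans where the radiologist saw no PPFE, and
dichotomised at a cutpoint (2.5% by default, inclusive).

**The prognostic pipeline.** Lobar visual PPFE grades (0–3 per lobe, the
lingula as a sixth lobe) with presence / 3-category / 7-point derivations;
LME-predicted 1-year FVC decline, `100·(FVC_baseline − FVC_predicted,1y) /
FVC_baseline`, from a random-intercept-and-slope mixed model; Cox and
gamma-frailty Cox mortality models with Schoenfeld checks and bootstrapped
concordance; Kaplan–Meier medians with Dorey–Korn-style confidence
intervals and log-rank tests; 2-year sensitivity/specificity/PPV/NPV with
censored-before-horizon exclusion; paired DeLong comparisons of ROC areas.

**Generators with known truth.** CT lung phantoms whose pleural lesion
coverage is exactly countable on a label grid, and synthetic cohorts with
known trajectory and hazard parameters — so every stage of the pipeline is
testable without access to clinical data.

## Worked example

Generate a phantom with 25% pleural lesion coverage, run the full imaging
chain, and compare with the counted ground truth:

```r
library(ppfequant)

spec <- phantom_with_coverage(phantom_spec(seed = 7), 25)
ph <- generate_phantom(spec)
round(ph$truth$true_cppfe_percent, 2)
#> [1] 25.25

mask   <- segment_lungs(ph$volume)
carina <- detect_carina(ph$volume, lung_mask = mask)
zone   <- upper_zone(mask, carina, ph$volume$spacing)
res    <- gate_by_radiologist(compute_cppfe(ph$volume, mask, zone),
                              vppfe_present = TRUE)
res
#> <cppfe_result> 24.61% of 5047 upper-zone shell voxels dense
#>   gated 24.61%, positive at cutpoint 2.5%
```

The counted truth is 25.25% of the upper-zone pleural shell; the pipeline
measures 24.61% — a 0.6-point error, typical of the 0.5–1 point mean
absolute error across the 0–40% coverage range. The "positive at cutpoint
2.5%" flag is the dichotomised score used by the survival analyses.

The `analysis/` directory holds the full narrative workflow as numbered
scripts (run them in order from the repository root):

```sh
Rscript analysis/01_simulate_phantoms.R    # phantom set + ground truth
Rscript analysis/02_quantify_cppfe.R       # cPPFE vs truth table
Rscript analysis/03_simulate_cohorts.R     # derivation/validation cohorts
Rscript analysis/04_fvc_decline.R          # decline mixed model + regressions
Rscript analysis/05_survival_analysis.R    # Cox, KM, 2-year metrics, AUC
```

Each prints what it found and writes its tables under `results/`. On the
shipped seeds, for example, the survival script reports a three-group
log-rank chi-squared of 20.2 (p = 4e-05) with median survival 1.85 years in
the cPPFE ≥ 2.5% group against 5.81 years with no PPFE, and a combined
C-index of 0.718 (bootstrap 95% CI 0.681–0.761).

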