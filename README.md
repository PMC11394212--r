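# binbat — automated bin-based basophil activation test analysis

The basophil activation test (BAT) is a whole-blood ex vivo assay for
allergy diagnostics: basophils are exposed to an allergen (or an
anti-IgE positive control), and their degranulation is read out by flow
cytometry as the fraction of CD63-positive basophils. Manual gating of
the rare basophil population (~0.5% of leukocytes) is the main source
of irreproducibility in routine BAT use. `binbat` implements a fully
automated, bin-based analysis of BAT data for clinical cytometrists and
method developers:

- **Event I/O** — FCS 3.0/3.1 (list mode, float or integer) and CSV
  event tables, with a logical channel map (FSC-A, FSC-H, SSC, FcεRIα,
  CD63, CD32, optionally CD123/HLA-DR/CCR3/CRTH2).
- **Pregating** — singlet selection via a robust FSC-H ~ FSC-A line
  (Theil–Sen fit, residual band of ±4 MAD) and scatter floors that
  remove debris and thrombocytes.
- **Bin statistics (PRI)** — the transformed SSC × FcεRIα plane is
  partitioned into bins of width 0.2 (half-open `[low, high)`), and
  per-bin statistics of a third marker *z* are computed: event count,
  density, frequency of z⁺ cells (strictly above threshold), mean
  signal intensity of all cells (MSI) and of only z⁺ cells (MSI⁺),
  colored blue→red by per-sample min–max scaling.
- **Automated basophil identification** — a grid search over quantile
  candidates places the SSC and FcεRIα thresholds so that the
  upper-left quadrant holds a plausible basophil fraction with maximal
  CD32⁺ purity; basophils are SSC-low / FcεRIα-high / CD32⁺.
- **Threshold calibration** — on the donor's *unstimulated* sample the
  CD63 threshold is set so that 1% of basophils are positive
  (nearest-rank 99th percentile) and the CD32 threshold so that the
  basophil-quadrant "red percentage" is 70%. The frozen threshold set
  is applied verbatim to every other sample of the donor.
- **Results and QC** — per-sample basophil counts, CD63⁺% and CD32⁺%,
  responder status and allergen calls, with quality-control flags
  (LOW_EVENTS, LOW_BASOPHILS, THRESHOLD_OUT_OF_RANGE,
  CALIBRATION_FAILED, EMPTY_QUADRANT, DEGENERATE_Z); blocking flags
  suppress activation calls.
- **Cohort statistics** — Wilcoxon matched-pairs signed rank (exact
  sign enumeration for n ≤ 12, tie-corrected normal approximation
  otherwise), Pearson agreement, Q3 + 1.5·IQR outlier flagging.
- **Synthetic data** — a ground-truth whole-blood generator
  (granulocyte-dominant composition, rare basophils with correlated
  FcεRIα/CD32, condition-dependent CD63 activation, CD63↔CD32
  anticorrelation on activated cells, allergic CD32 baseline shift,
  doublets/debris/thrombocytes) used by the entire test suite.

## Worked example

```r
library(binbat)

cfg <- bat_config()                       # channel map, transforms, cutoffs
prof <- synthetic_profile(allergic = TRUE)
exp <- generate_experiment(prof, n_events = 50000, seed = 7)
res <- analyze_experiment(lapply(exp, function(s) s[c("events", "meta")]), cfg)
res
```

```
<experiment_result> donor D1: RESPONDER
  D1_UNSTIM_                   n_gated= 44779 n_baso=  224 CD63+%=0.89 CD32+%=69.64
  D1_POS_CTRL_                 n_gated= 44605 n_baso=  218 CD63+%=39.91 CD32+%=52.75
  D1_ALLERGEN_allergen1        n_gated= 44706 n_baso=  198 CD63+%=31.31 CD32+%=58.08
  allergen allergen1: POSITIVE
```

Reading the output: ~45 000 events per sample survive pregating, ~0.5%
of them are identified as basophils. In the unstimulated sample the
CD63⁺ fraction is 0.89% — the calibrated ~1% convention (nearest-rank
granularity at 224 events) — and the CD32 red percentage is 69.6%, the
calibrated 70% rule. Under anti-IgE the CD63⁺ fraction rises to ~40%,
so the donor is a responder (cutoff 10%), and the allergen sample at
~31% exceeds both the 5% absolute cutoff and 2× the unstimulated
baseline, giving a POSITIVE call. CD32⁺% drops in stimulated samples —
activated basophils down-regulate CD32.

A command-line interface wraps the same pipeline
(`inst/scripts/binbat`): `simulate`, `analyze` (a directory of FCS/CSV
files with a `manifest.csv`), `report` and `plot` (SVG bin plots).

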