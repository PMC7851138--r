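# pdtexture

Texture markers of Parkinson's disease (PD) progression in deep grey-matter
structures on T1-weighted MRI.

Volumetric atrophy measures change late in PD, which limits their value as
progression markers. This package implements the alternative: quantify the
*organisation* of the T1 signal inside the nuclei of the nigrostriatal
pathway — substantia nigra (SN), putamen, caudate nucleus, thalamus and
sub-thalamic nucleus (STN) — and test whether those texture features
separate healthy controls from early- and late-stage PD patients and track
motor severity. It is written for imaging researchers who have
intensity images plus structure label masks (NIfTI) and a clinical table,
and for methodologists who want a fully synthetic, seeded test bed for this
class of radiomics pipeline.

## What it computes

Per structure (each hemisphere separately, then averaged):

- **First-order features** of the ROI histogram: mean, SD (population
  moments), skewness E[((X−μ)/σ)³], non-excess kurtosis E[((X−μ)/σ)⁴].
- **Co-occurrence (GLCM) features**: intensities quantized to G = 64 levels,
  ordered voxel pairs at distance d = 1 in four in-plane directions
  (θ = 0°, 45°, 90°, 135°) pooled per axial slice into one symmetrized,
  normalized matrix P(i,j); from it homogeneity ΣP², contrast Σ(i−j)²P,
  entropy −ΣP log P, correlation (Σ ijP − μxμy)/(σxσy), sum of squares
  Σ(i−μ)²P, sum average Σ k·P_{x+y}(k), sum variance
  Σ (k−sumA)²·P_{x+y}(k), and inverse difference moment ΣP/(1+(i−j)²).
- **ROI volumetry**: voxel-count volumes in cm³ and their ratio to total
  intracranial volume.

Cohort inference chain: per-(structure, feature) one-way ANOVA (p < 0.05) →
pairwise Welch t tests, Benjamini–Hochberg within structure, flag at
q < 0.02 → multinomial LASSO over the three groups (5-fold stratified CV,
1-SE rule) → ROC (Mann–Whitney AUC, Youden operating point) for early- vs
late-stage discrimination → Spearman correlations with MDS-UPDRS III,
Hoehn–Yahr and MDS-UPDRS total, FDR-corrected.

A seeded synthetic cohort generator (`cohort_config()`, `generate_cohort()`)
produces NIfTI images, label masks and clinical scores in which within-ROI
texture heterogeneity decreases monotonically from controls to late-stage
patients and motor scores rise as heterogeneity falls — the structure the
chain is designed to detect — so the whole pipeline runs and is tested
without any patient data.

## Worked example

The `analysis/` scripts run the study end to end:

```sh
Rscript analysis/01_simulate.R   # 60-subject cohort -> scratch/runs/cohort
Rscript analysis/02_extract.R    # features.csv, volumes.csv -> results/
Rscript analysis/03_analyze.R    # inference chain -> results/analysis
Rscript analysis/04_report.R     # figures -> results/figures
```

Step 1 prints the group structure of the simulated cohort:

```
Simulating cohort: 60 subjects on a 40x48x44 grid
Group sizes: CTRL=20, earlyPD=20, latePD=20
Mean MDS-UPDRS III by group:
   CTRL earlyPD  latePD
   26.7    33.9    43.2
```

Motor scores rise with stage because the generator links them negatively to
texture heterogeneity. Step 3 then recovers exactly that structure from the
voxel data:

```
ANOVA-significant (structure, feature) pairs: 45 of 60
Pairwise flags at q < 0.02: 122
LASSO-selected markers:
  SN.kurtosis, SN.homogeneity, STN.sumA, putamen.homogeneity,
  putamen.contrast, putamen.correlation, caudate.correlation,
  caudate.sumV, thalamus.correlation, thalamus.sumSQR, thalamus.sumV
Early- vs late-stage ROC of selected markers:
                feature   auc specificity sensitivity
1           SN.kurtosis 0.442        0.10        0.95
2        SN.homogeneity 0.992        1.00        0.95
...
Volume ANOVA minimum p across structures: 0.67
```

Reading these numbers: variance-like markers (sumV, sumSQR, contrast,
entropy) fall with disease stage, so their early-vs-late AUC is printed
below 0.5 — orientation is fixed (late-stage positive) and never flipped —
while homogeneity, which rises as texture flattens, discriminates at
AUC ≈ 0.99. The Spearman table shows the variance-family markers correlating
negatively with all three clinical scores (e.g. thalamus sumV vs MDS-UPDRS
total: ρ = −0.97), and the volume ANOVA finds nothing — the generator puts
the disease signal in texture, not in structure size.

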