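# aifpvc — conservation-of-activity partial volume correction for dynamic PET input functions

Kinetic modelling of dynamic PET (dPET) needs an arterial input function
(AIF), and in most body sites the AIF must be read off a small artery
(internal iliac, carotid: 5–10 mm) whose diameter is comparable to the
scanner's spatial resolution (4–7 mm FWHM). Partial volume effects (PVE)
then spill most of the vessel's signal into its surroundings, the measured
AIF is depressed by tens of percent, and every fitted rate constant
downstream is biased.

`aifpvc` implements and validates a correction family built on
conservation of activity (CoA): a calibrated PET image does not lose
counts to blur, so the signal spilled out of a vessel can be collected in
an enlarged region and reassigned to the vessel's true volume.

With `C` mean concentrations (kBq/cc) and `V` volumes (cc), `A` the true
artery region, `SO` an enlarged "spill-out" region assumed to contain all
blurred vessel signal, `BKG` a background ring just outside it, and `V` a
companion vein sharing the spill-out region:

* no background:
  `C_A^corr = C_SO · V_SO / V_A`
* with background:
  `C_A^corr = (C_SO · V_SO − C_BKG · (V_SO − V_A)) / V_A`
* artery + vein in one spill-out region, apportioned by the
  image-derived signals:
  `C_A^corr = [C_SO · V_SO − C_BKG · (V_SO − V_A − V_V)] / V_A ×
  (C_A V_A) / (C_A V_A + C_V V_V)`
  (and symmetrically for the vein).

All corrections act frame by frame on mean-ROI readouts — no single-voxel
SUVmax, no deconvolution, no vendor PSF machinery — so they apply to any
PET-CT (or PET-MR) system.

The package also provides:

* a **digital flow phantom**: cylindrical flow tubes (25.4 / 12.7 / 9.5 /
  6.35 mm ID arteries plus a 6.35 mm vein) carrying a common well-mixed
  chamber input function inside a uniform background compartment, rendered
  as a 4-D image with Gaussian PSF blur, 15 × 20 s frames, and optional
  frame-duration-dependent noise — so every claim is testable against
  known ground truth;
* nested cylindrical **ROI extraction** with fractional voxel occupancy;
* **metrics**: rectangle-rule AUC, temporal bin averaging of fine
  reference curves, decay correction, ground-truth AUC from delivered
  activity and flow, HU↔kBq/cc scaling, percent error / improvement;
* a classical **recovery-coefficient comparator** (`C_A / RC`) that
  reproduces the known failure of background-blind linear corrections;
* an **irreversible two-tissue compartment model** (K1, k2, k3; optional
  blood volume fraction) with forward simulation and bounded multi-start
  nonlinear least-squares fitting, to quantify how AIF correction changes
  fitted parameters.

## Worked example

A single correction is one line — a 9.5 mm tube ROI (V_A = 1.418 cc), its
+1.5 cm spill-out region (V_SO = 24.53 cc), a measured spill-out mean of
4.1 kBq/cc over a 1.4 kBq/cc background:

```r
library(aifpvc)
coa_correct_background(c_so = 4.1, v_so = 24.53, v_a = 1.418, c_bkg = 1.4)
#> [1] 48.10733
```

The full validation experiment — simulate the default phantom, extract
all regions, apply every correction, compare against ground truth:

```r
res <- run_validation_experiment(default_run_config())
print(res)
```

```
Phantom validation summary
  ground-truth AUC: 2200.0 kBq.s/cc
  improvement_pts = |auc_err_pct(uncorrected)| - |auc_err_pct(method)| in percentage points

      tube diameter_mm                    method auc_kBq_s_cc gt_auc_kBq_s_cc peak_kBq_cc gt_peak_kBq_cc auc_err_pct
 tube_25.4       25.40               uncorrected         1914            2200       34.99          41.43   -13.00000
 tube_25.4       25.40            coa_background         2201            2200       41.45          41.43     0.05582
 tube_25.4       25.40                        rc         2276            2200       41.62          41.43     3.47100
 tube_12.7       12.70               uncorrected         1634            2200       28.70          41.43   -25.72000
 tube_12.7       12.70            coa_background         2199            2200       41.41          41.43    -0.03896
 tube_12.7       12.70                        rc         2380            2200       41.81          41.43     8.19100
  tube_9.5        9.50               uncorrected         1453            2200       24.62          41.43   -33.97000
  tube_9.5        9.50            coa_background         2199            2200       41.39          41.43    -0.06290
  tube_9.5        9.50                        rc         2468            2200       41.83          41.43    12.18000
 tube_6.35        6.35               uncorrected         1163            2200       18.11          41.43   -47.13000
 tube_6.35        6.35           coa_artery_vein         2235            2200       41.06          41.43     1.58900
 tube_6.35        6.35 coa_background_misapplied         3973            2200       71.97          41.43    80.60000
 tube_6.35        6.35                        rc         2761            2200       43.00          41.43    25.52000
 vein_6.35        6.35           coa_artery_vein         2158            2200       37.82          37.95    -1.89900
```

Reading the table: uncorrected AUC losses grow from −13% (25.4 mm) to
−47% (6.35 mm) as the tube shrinks relative to the 6 mm PSF; the CoA
corrections recover AUC to well under 1% for isolated tubes and to ~2%
for the paired artery/vein; applying the single-vessel equation to the
paired tubes ("misapplied") overcorrects by +81% because the vein's
signal is wrongly assigned to the artery; and the recovery-coefficient
comparator overshoots AUC because it inflates the sub-background tail
frames.

A command-line wrapper (`inst/cli/aifpvc`) exposes the same pipeline as
`simulate`, `extract`, `correct`, `fit`, `report` and `validate`
subcommands over NIfTI/CSV/YAML files.

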