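# mechcycle

Tools for two linked questions in early enzyme-inhibitor characterisation,
built around α-amylase inhibitors from plant extracts:

1. **Mechanism** — given docking-derived equilibrium constants for the four
   complexes E·S (K1), E·I (Ka), EI·S (K4) and ES·I (Kb, estimated directly
   by multi-ligand simultaneous docking), does the thermodynamic cycle close?
   Closure forces `Kb = K4·Ka/K1`; agreement between the direct and
   cycle-predicted Kb (fold ratio ≤ a threshold, default 1.5) is the
   signature of **noncompetitive** inhibition, while competitive and
   uncompetitive inhibitors break the cycle (they cannot be told apart by
   this test).
2. **Potency** — starch–iodine α-amylase assay analysis: absorbance →
   activity units `(E_B1 − E_S)/E_B1 × 800` → percent inhibition
   `(B − A)/B × 100` → IC50 by maximum-likelihood probit regression on
   log10(concentration) → molar Ki via the Cheng–Prusoff family
   (noncompetitive: Ki = IC50; competitive: IC50/(1+S/Km); uncompetitive:
   IC50/(1+Km/S)), plus `Ki = exp(ΔG/RT)` conversions for docking energies.

Group-level in vivo endpoints (blood glucose, amylase activity) are handled
with one-way ANOVA and Fisher LSD post-hoc, implemented from first
principles. Synthetic-data generators (labelled docking sets, Michaelis–
Menten kinetics based assay plates, Gaussian group measurements) provide
every pipeline input with known ground truth for end-to-end recovery tests.

For whom: computational chemists triaging docking hits, and assay analysts
who want a deterministic, scriptable IC50/Ki pipeline with explicit rules
where the source literature judged "≈ vs ≠" by eye.

## Worked example

```r
library(mechcycle)

# --- mechanism: classify the packaged four-ligand reference set ---
classify_batch(load_docking_fixture())
#>              ligand_id kb_pred_uM kb_direct_uM      fold                      verdict
#> 1              Betulin   29.99521        23.36     1.284               noncompetitive
#> 2       Betulinic acid  144.56760       149.13     1.032               noncompetitive
#> 3 Bisdemethoxycurcumin   39.54877        83.49     2.111 competitive_or_uncompetitive
#> 4             Curcumin    0.04367       841.04 19259.035 competitive_or_uncompetitive

# --- potency: replicate IC50s and the molar Ki they imply ---
summ <- ic50_replicate_summary(load_ic50_fixture()$ic50_mg_ml)
sprintf("mean IC50 %.4f mg/mL, SEM %.4f (n=%d)", summ$mean_ic50, summ$sem, summ$n)
#> "mean IC50 0.1433 mg/mL, SEM 0.0220 (n=6)"
betulin <- compound_spec("Betulin", 442.72)
ic50_to_ki(mass_to_molar(0.14, betulin), "noncompetitive")
#> 316.227  # uM; the reference analysis reports 314 uM for this conversion

# --- closed loop: simulate a plate with known truth and recover it ---
ki <- mass_to_molar(0.14, betulin)      # noncompetitive => IC50 = Ki = 316.2 uM
kc <- kinetics_config(true_ki = ki, mode = "noncompetitive",
                      noise_sd_abs = 0.01, n_replicates = 6, seed = 42)
plate <- generate_assay_plate(kc)
pts <- plate_dose_response(plate)
fits <- lapply(split(pts, pts$replicate_id), fit_probit)
ic50_replicate_summary(unname(fits))$mean_ic50
#> 0.1381  # mg/mL, within 2% of the true 0.14 at this seed
```

Reading the classification: `fold` is max/min of the direct and
cycle-predicted Kb. Betulin's cycle closes to within 1.28-fold (consistent
binding to both E and ES → noncompetitive); curcumin's direct constant is
four orders of magnitude off the prediction (the ES·I edge of the cycle is
not a real equilibrium for a competitive binder).

## Command line

An executable is installed under `exec/`:

```sh
mechcycle classify --in docking.csv --threshold 1.5 --out results.csv
mechcycle assay --plate plate.csv --out fit.json
mechcycle ic50 --in dose.csv --out fit.json
mechcycle stats --in groups.csv --alpha 0.01
mechcycle simulate docking|assay|groups --seed 42 --out file.csv
mechcycle reproduce            # fixture-driven report; exit 3 if checks fail
```

Exit codes: 0 success, 2 validation error, 3 failed reproduction check.

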