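# Four-ligand constant sets typed in code, independent of the CSV fixture.
# Columns: K1, Ka, K4, Kb_direct (uM), reported cycle prediction, verdict.
table4_sets <- function() {
  rows <- list(
    list(id = "Betulin",              K1 = 427180, Ka = 13.66,  K4 = 938020, Kb = 23.36,
         pred = 29.99,  mode = "noncompetitive"),
    list(id = "Betulinic acid",       K1 = 493240, Ka = 75.66,  K4 = 942460, Kb = 149.13,
         pred = 144.26, mode = "noncompetitive"),
    list(id = "Bisdemethoxycurcumin", K1 = 791530, Ka = 45.86,  K4 = 682600, Kb = 83.49,
         pred = 39.55,  mode = "competitive_or_uncompetitive"),
    list(id = "Curcumin",             K1 = 791530, Ka = 260.62, K4 = 132.63, Kb = 841.04,
         pred = 0.044,  mode = "competitive_or_uncompetitive")
  )
  sets <- lapply(rows, function(r) {
    binding_constant_set(r$id, "Maltose", "alpha-amylase",
                         K1 = r$K1, Ka = r$Ka, K4 = r$K4, Kb_direct = r$Kb)
  })
  attr(sets, "reported_pred") <- vapply(rows, `[[`, numeric(1), "pred")
  attr(sets, "reported_mode") <- vapply(rows, `[[`, character(1), "mode")
  sets
}

# Exact probit curve points (the generating-curve oracle for fit_probit).
probit_curve_points <- function(intercept, slope, concentrations) {
  data.frame(
    concentration = concentrations,
    percent_inhibition = 100 * pnorm(intercept + slope * log10(concentrations))
  )
}

# Plate -> replicate probit fits -> IC50 summary, the full assay pipeline.
run_assay_pipeline <- function(plate) {
  points <- plate_dose_response(plate)
  fits <- lapply(split(points, points$replicate_id), fit_probit)
  ic50_replicate_summary(unname(fits))
}
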