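#' Thermodynamic settings for free-energy / inhibition-constant conversions
#'
#' Container for the gas constant and absolute temperature used when
#' interconverting binding free energies and inhibition constants via
#' \eqn{K_i = \exp(\Delta G / RT)}. The defaults are the AutoDock convention:
#' R = 1.98719e-3 kcal mol^-1 K^-1 at T = 298.15 K, which reproduces published
#' docking (deltaG, Ki) pairs to within the rounding of the printed energies.
#'
#' @param gas_constant_R Gas constant, kcal mol^-1 K^-1. Must be > 0.
#' @param temperature_T Absolute temperature, kelvin. Must be > 0.
#' @return An object of class `thermo_settings`.
#' @examples
#' s <- thermo_settings()
#' deltaG_to_ki(-6.66, s) # ~13.1 uM
#' @export
thermo_settings <- function(gas_constant_R = 1.98719e-3, temperature_T = 298.15) {
  if (!is.numeric(gas_constant_R) || length(gas_constant_R) != 1L ||
      !is.finite(gas_constant_R) || gas_constant_R <= 0) {
    stop("`gas_constant_R` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(temperature_T) || length(temperature_T) != 1L ||
      !is.finite(temperature_T) || temperature_T <= 0) {
    stop("`temperature_T` must be a single positive finite number", call. = FALSE)
  }
  structure(
    list(gas_constant_R = gas_constant_R, temperature_T = temperature_T),
    class = "thermo_settings"
  )
}

#' Compound descriptor for mass/molar conversions
#'
#' @param name Compound name.
#' @param molecular_weight Molecular weight, g/mol. Must be > 0.
#' @param mass_fraction_in_extract Mass fraction of the compound in the crude
#'   extract, dimensionless in \[0, 1\]. Defaults to 1 (pure compound).
#' @return An object of class `compound_spec`.
#' @examples
#' betulin <- compound_spec("Betulin", 442.72, mass_fraction_in_extract = 0.0696)
#' @export
compound_spec <- function(name, molecular_weight, mass_fraction_in_extract = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1L ||
      !is.finite(molecular_weight) || molecular_weight <= 0) {
    stop("`molecular_weight` must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(mass_fraction_in_extract) || length(mass_fraction_in_extract) != 1L ||
      !is.finite(mass_fraction_in_extract) ||
      mass_fraction_in_extract < 0 || mass_fraction_in_extract > 1) {
    stop("`mass_fraction_in_extract` must be a number in [0, 1]", call. = FALSE)
  }
  structure(
    list(name = name, molecular_weight = molecular_weight,
         mass_fraction_in_extract = mass_fraction_in_extract),
    class = "compound_spec"
  )
}

#' Convert a binding free energy to an inhibition constant
#'
#' Evaluates \eqn{K_i[\mathrm{M}] = \exp(\Delta G / RT)} and returns the result
#' in micromolar. Vectorised over `e_binding`. Strictly increasing in the
#' binding energy: more negative energies (tighter binding) give smaller Ki.
#'
#' @param e_binding Binding free energy, kcal/mol (typically negative).
#' @param settings A [thermo_settings()] object.
#' @return Inhibition constant(s) in micromolar.
#' @examples
#' deltaG_to_ki(-6.66) # ~13.1 uM
#' deltaG_to_ki(0)     # 1e6 uM = 1 M
#' @export
deltaG_to_ki <- function(e_binding, settings = thermo_settings()) {
  stopifnot(inherits(settings, "thermo_settings"))
  if (!is.numeric(e_binding) || length(e_binding) == 0L || any(!is.finite(e_binding))) {
    stop("`e_binding` must be finite numeric (kcal/mol)", call. = FALSE)
  }
  rt <- settings$gas_constant_R * settings$temperature_T
  exp(e_binding / rt) * 1e6
}

#' Convert an inhibition constant to a binding free energy
#'
#' Exact inverse of [deltaG_to_ki()]: \eqn{\Delta G = RT \ln(K_i[\mathrm{M}])}.
#' Vectorised over `ki_uM`.
#'
#' @param ki_uM Inhibition constant(s), micromolar. Must be > 0.
#' @inheritParams deltaG_to_ki
#' @return Binding free energy in kcal/mol.
#' @examples
#' ki_to_deltaG(13.12) # ~ -6.66 kcal/mol
#' @export
ki_to_deltaG <- function(ki_uM, settings = thermo_settings()) {
  stopifnot(inherits(settings, "thermo_settings"))
  if (!is.numeric(ki_uM) || length(ki_uM) == 0L || any(!is.finite(ki_uM)) || any(ki_uM <= 0)) {
    stop("`ki_uM` must be positive finite numeric (uM)", call. = FALSE)
  }
  rt <- settings$gas_constant_R * settings$temperature_T
  rt * log(ki_uM / 1e6)
}

#' Convert a mass concentration to a molar concentration
#'
#' \eqn{\mu M = c \cdot f / MW \cdot 10^6} where c is in mg/mL, MW in g/mol and
#' f is the compound's mass fraction in the extract (applied only when
#' `use_mass_fraction = TRUE`). With the flag off, the whole measured mass is
#' attributed to the compound -- the convention used when an extract IC50 is
#' quoted directly as a molar constant of its active principle.
#'
#' @param conc_mg_per_mL Mass concentration(s), mg/mL. Must be >= 0.
#' @param compound A [compound_spec()] object.
#' @param use_mass_fraction Apply the compound's mass fraction in the extract?
#' @return Molar concentration(s) in micromolar.
#' @examples
#' betulin <- compound_spec("Betulin", 442.72)
#' mass_to_molar(0.14, betulin) # ~316.2 uM
#' @export
mass_to_molar <- function(conc_mg_per_mL, compound, use_mass_fraction = FALSE) {
  stopifnot(inherits(compound, "compound_spec"))
  if (!is.numeric(conc_mg_per_mL) || length(conc_mg_per_mL) == 0L ||
      any(!is.finite(conc_mg_per_mL)) || any(conc_mg_per_mL < 0)) {
    stop("`conc_mg_per_mL` must be non-negative finite numeric", call. = FALSE)
  }
  f <- if (isTRUE(use_mass_fraction)) compound$mass_fraction_in_extract else 1
  conc_mg_per_mL * f / compound$molecular_weight * 1e6
}

#' Convert an IC50 to an inhibition constant (Cheng-Prusoff family)
#'
#' Mode-specific conversion of a half-maximal inhibitory concentration to an
#' inhibition constant:
#' \itemize{
#'   \item noncompetitive: \eqn{K_i = IC_{50}} (pure noncompetitive identity);
#'   \item competitive: \eqn{K_i = IC_{50} / (1 + S/K_m)};
#'   \item uncompetitive: \eqn{K_i = IC_{50} / (1 + K_m/S)}.
#' }
#' Competitive and uncompetitive modes require the substrate concentration and
#' Michaelis constant at which the IC50 was measured.
#'
#' @param ic50_uM IC50, micromolar. Must be > 0.
#' @param mode One of `"noncompetitive"`, `"competitive"`, `"uncompetitive"`.
#' @param substrate_conc Substrate concentration S (same units as `km`).
#' @param km Michaelis constant (same units as `substrate_conc`).
#' @return Ki in micromolar.
#' @examples
#' ic50_to_ki(316.2, "noncompetitive")            # 316.2
#' ic50_to_ki(100, "competitive", substrate_conc = 2, km = 2) # 50
#' @export
ic50_to_ki <- function(ic50_uM,
                       mode = c("noncompetitive", "competitive", "uncompetitive"),
                       substrate_conc = NULL, km = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(ic50_uM) || length(ic50_uM) == 0L ||
      any(!is.finite(ic50_uM)) || any(ic50_uM <= 0)) {
    stop("`ic50_uM` must be positive finite numeric", call. = FALSE)
  }
  if (mode == "noncompetitive") return(ic50_uM)
  if (is.null(substrate_conc) || is.null(km)) {
    stop(sprintf(paste0("mode '%s' requires both `substrate_conc` and `km` ",
                        "(the IC50 depends on the substrate level in this mode)"),
                 mode), call. = FALSE)
  }
  if (!is.numeric(substrate_conc) || any(substrate_conc <= 0) ||
      !is.numeric(km) || any(km <= 0)) {
    stop("`substrate_conc` and `km` must be positive", call. = FALSE)
  }
  switch(mode,
    competitive   = ic50_uM / (1 + substrate_conc / km),
    uncompetitive = ic50_uM / (1 + km / substrate_conc)
  )
}
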