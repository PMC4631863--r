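# Run expr with a locally seeded RNG, restoring the caller's RNG state after.
# Makes every generator a pure function of its config (seed included).
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Configuration for synthetic docking-constant sets
#'
#' Ground-truth generator config for the thermodynamic-cycle classifier: each
#' generated set has its three free-energy-cycle constants drawn log-uniformly
#' and its direct ternary constant displaced from the cycle prediction by a
#' known fold factor. Default scale ranges echo published docking magnitudes:
#' substrate constants K1, K4 of order 1e5-1e6 uM, inhibitor constants Ka of
#' order 10-300 uM.
#'
#' @param n_sets Number of sets, >= 1.
#' @param fold_factors Positive true Kb_direct/Kb_pred ratios, recycled to
#'   `n_sets`.
#' @param k1_range,ka_range,k4_range Two-element positive ranges (uM) sampled
#'   log-uniformly.
#' @param label_threshold Fold threshold used to attach the true label
#'   (noncompetitive iff fold <= threshold). Default 1.5, the classifier
#'   default.
#' @param seed RNG seed.
#' @return An object of class `docking_set_config`.
#' @export
docking_set_config <- function(n_sets, fold_factors = 1,
                               k1_range = c(1e5, 1e6),
                               ka_range = c(10, 300),
                               k4_range = c(1e5, 1e6),
                               label_threshold = 1.5,
                               seed = 1L) {
  if (!is.numeric(n_sets) || length(n_sets) != 1L || n_sets < 1) {
    stop("`n_sets` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(fold_factors) || any(!is.finite(fold_factors)) || any(fold_factors <= 0)) {
    stop("`fold_factors` must be positive and finite", call. = FALSE)
  }
  for (nm in c("k1_range", "ka_range", "k4_range")) {
    r <- get(nm)
    if (!is.numeric(r) || length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop(sprintf("`%s` must be an increasing pair of positive numbers", nm), call. = FALSE)
    }
  }
  structure(list(n_sets = as.integer(n_sets), fold_factors = fold_factors,
                 k1_range = k1_range, ka_range = ka_range, k4_range = k4_range,
                 label_threshold = label_threshold, seed = seed),
            class = "docking_set_config")
}

.runif_log <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))

#' Generate labelled docking-constant sets
#'
#' Draws K1, Ka, K4 log-uniformly within the configured ranges, computes the
#' cycle prediction Kb = K4*Ka/K1, and sets Kb_direct = Kb_pred * fold (the
#' fold is inverted with probability 1/2, so discrepancies are symmetric on
#' the log scale). The true fold and label travel with each set as attributes
#' `true_fold` and `true_label`, enabling exact-recovery tests of the
#' classifier. Reproducible: the same config (same seed) gives identical
#' output.
#'
#' @param config A [docking_set_config()].
#' @return List of [binding_constant_set()] objects, each carrying
#'   `true_fold` and `true_label` attributes.
#' @export
generate_docking_sets <- function(config) {
  stopifnot(inherits(config, "docking_set_config"))
  n <- config$n_sets
  folds <- rep_len(config$fold_factors, n)
  .with_seed(config$seed, {
    k1 <- .runif_log(n, config$k1_range)
    ka <- .runif_log(n, config$ka_range)
    k4 <- .runif_log(n, config$k4_range)
    invert <- stats::runif(n) < 0.5
    lapply(seq_len(n), function(i) {
      kb_pred <- k4[i] * ka[i] / k1[i]
      fold <- folds[i]
      kb_direct <- if (invert[i]) kb_pred / fold else kb_pred * fold
      s <- binding_constant_set(
        ligand_id = sprintf("synthetic_ligand_%03d", i),
        substrate_id = "synthetic_substrate",
        target_id = "synthetic_target",
        K1 = k1[i], Ka = ka[i], K4 = k4[i], Kb_direct = kb_direct)
      attr(s, "true_fold") <- fold
      attr(s, "true_label") <- if (fold <= config$label_threshold) {
        "noncompetitive"
      } else {
        "competitive_or_uncompetitive"
      }
      s
    })
  })
}

#' Default assay concentration ladder (mg/mL)
#'
#' Six log-spaced extract concentrations spanning 0.016 to 1.6 mg/mL, the
#' range over which the starch-iodine assay runs from weak (~7\%) to
#' near-complete (~94\%) inhibition.
#' @return Numeric vector of six concentrations.
#' @export
default_concentration_ladder <- function() {
  round(10^seq(log10(0.016), log10(1.6), length.out = 6), 4)
}

#' Configuration for kinetics-based synthetic assay plates
#'
#' The generator emulates the fixed-incubation starch-iodine assay with a
#' linear-in-time Michaelis-Menten digestion model: the fraction of starch
#' digested in `incubation_min` minutes is \eqn{v t / s_0} with
#' \eqn{v = V_{max,eff} s_0 / (K_{m,eff} + s_0)}, where the inhibitor rescales
#' Vmax and/or Km according to its mode:
#' noncompetitive \eqn{V_{max}/(1 + I/K_i)}; competitive
#' \eqn{K_m (1 + I/K_i)}; uncompetitive both scaled by \eqn{1/(1 + I/K_i)}.
#' The sample absorbance is `blank_abs * (1 - digested)` plus Gaussian read
#' noise. For noncompetitive inhibition the implied IC50 equals Ki exactly
#' (in molar), the identity the downstream pipeline must recover.
#'
#' Defaults: 0.4 mg/mL starch (40 mg/dL), 7.5 min incubation, Km set equal to
#' s0 absent any measured value, Vmax 0.075 mg/mL/min (~70\% digestion with no
#' inhibitor), blank OD 0.8, read noise 0.01 OD, 6 replicates.
#'
#' @param true_ki True inhibition constant, uM. May be `Inf` (no inhibition).
#' @param mode One of "noncompetitive", "competitive", "uncompetitive".
#' @param inhibitor_mw Inhibitor molecular weight, g/mol (converts the mg/mL
#'   ladder to molar concentrations).
#' @param vmax Maximal digestion rate, mg/mL/min.
#' @param km Michaelis constant, mg/mL starch.
#' @param s0 Initial starch, mg/mL.
#' @param incubation_min Incubation time, minutes.
#' @param concentrations Inhibitor ladder, mg/mL (zero-concentration controls
#'   are always added).
#' @param noise_sd_abs Gaussian read noise SD, OD units.
#' @param blank_abs Blank absorbance, OD.
#' @param n_replicates Replicates per plate.
#' @param seed RNG seed.
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(true_ki, mode = c("noncompetitive", "competitive", "uncompetitive"),
                            inhibitor_mw = 442.72,
                            vmax = 0.075, km = 0.4, s0 = 0.4, incubation_min = 7.5,
                            concentrations = default_concentration_ladder(),
                            noise_sd_abs = 0.01, blank_abs = 0.8,
                            n_replicates = 6L, seed = 1L) {
  mode <- match.arg(mode)
  if (!is.numeric(true_ki) || length(true_ki) != 1L || is.na(true_ki) || true_ki <= 0) {
    stop("`true_ki` must be positive (uM); Inf means no inhibition", call. = FALSE)
  }
  for (nm in c("inhibitor_mw", "vmax", "km", "s0", "incubation_min", "blank_abs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single positive finite number", nm), call. = FALSE)
    }
  }
  if (!is.numeric(noise_sd_abs) || noise_sd_abs < 0) {
    stop("`noise_sd_abs` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(concentrations) || length(concentrations) == 0L ||
      any(concentrations <= 0)) {
    stop("`concentrations` must be a non-empty vector of positive mg/mL values",
         call. = FALSE)
  }
  f0 <- vmax * incubation_min / (km + s0)
  if (f0 > 1) {
    stop(sprintf(paste0("uninhibited digested fraction vmax*t/(km+s0) = %.3g exceeds 1; ",
                        "reduce vmax or incubation_min"), f0), call. = FALSE)
  }
  structure(list(true_ki = true_ki, mode = mode, inhibitor_mw = inhibitor_mw,
                 vmax = vmax, km = km, s0 = s0, incubation_min = incubation_min,
                 concentrations = concentrations, noise_sd_abs = noise_sd_abs,
                 blank_abs = blank_abs, n_replicates = as.integer(n_replicates),
                 seed = seed),
            class = "kinetics_config")
}

# Expected digested starch fraction at inhibitor concentration conc (mg/mL).
.digested_fraction <- function(config, conc) {
  i_uM <- conc / config$inhibitor_mw * 1e6
  r <- if (is.infinite(config$true_ki)) rep(0, length(conc)) else i_uM / config$true_ki
  vmax_eff <- switch(config$mode,
    noncompetitive = config$vmax / (1 + r),
    competitive = rep(config$vmax, length(conc)),
    uncompetitive = config$vmax / (1 + r))
  km_eff <- switch(config$mode,
    noncompetitive = rep(config$km, length(conc)),
    competitive = config$km * (1 + r),
    uncompetitive = config$km / (1 + r))
  pmin(pmax(vmax_eff * config$incubation_min / (km_eff + config$s0), 0), 1)
}

#' Generate a synthetic starch-iodine assay plate
#'
#' One row per well: each replicate gets a zero-concentration control well plus
#' one well per ladder concentration. Expected sample absorbance rises with
#' inhibitor concentration (less starch digested); Gaussian read noise is
#' added to the sample channel and readings are floored at 0 OD.
#'
#' @param config A [kinetics_config()].
#' @return data.frame with columns `replicate_id`, `concentration`, `eb1`,
#'   `es`; attribute `truth` records the generating config.
#' @export
generate_assay_plate <- function(config) {
  stopifnot(inherits(config, "kinetics_config"))
  concs <- c(0, config$concentrations)
  .with_seed(config$seed, {
    out <- do.call(rbind, lapply(seq_len(config$n_replicates), function(r) {
      frac <- .digested_fraction(config, concs)
      es_expect <- config$blank_abs * (1 - frac)
      es <- pmax(es_expect + stats::rnorm(length(concs), 0, config$noise_sd_abs), 0)
      data.frame(replicate_id = sprintf("R%d", r),
                 concentration = concs,
                 eb1 = config$blank_abs,
                 es = es,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    attr(out, "truth") <- config
    out
  })
}

#' Generate probit-curve dose-response replicates
#'
#' Direct generator on the percent-inhibition scale: the mean response at
#' concentration c is \eqn{100\,\Phi(\beta_1 (\log_{10} c - \log_{10} IC_{50}))}
#' with Gaussian noise in percentage points added per point. With the default
#' slope 1.5 probit units per decade, the six-point 0.016-1.6 mg/mL ladder
#' spans roughly 8\% to 94\% inhibition.
#'
#' @param true_ic50 True IC50, mg/mL.
#' @param slope Probit slope per log10 concentration. Default 1.5.
#' @param concentrations Ladder, mg/mL.
#' @param noise_sd_pct Gaussian noise SD in percentage points.
#' @param n_replicates Number of replicate series.
#' @param seed RNG seed.
#' @return data.frame with `replicate_id`, `concentration`,
#'   `percent_inhibition`.
#' @export
generate_dose_response <- function(true_ic50, slope = 1.5,
                                   concentrations = default_concentration_ladder(),
                                   noise_sd_pct = 3, n_replicates = 6L, seed = 1L) {
  if (!is.numeric(true_ic50) || true_ic50 <= 0) stop("`true_ic50` must be > 0", call. = FALSE)
  if (any(concentrations <= 0)) stop("`concentrations` must be positive", call. = FALSE)
  mean_pct <- 100 * stats::pnorm(slope * (log10(concentrations) - log10(true_ic50)))
  .with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      data.frame(replicate_id = sprintf("R%d", r),
                 concentration = concentrations,
                 percent_inhibition = mean_pct +
                   stats::rnorm(length(concentrations), 0, noise_sd_pct),
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate Gaussian group measurements
#'
#' Seeded Normal draws per group, truncated at 0 (physiological measurements
#' cannot be negative; negative draws are redrawn, a mild deviation from
#' exact normality that matters only when mean/sd is small).
#'
#' @param means Named numeric vector of group means (names become group
#'   labels).
#' @param sds Group SDs, recycled to `length(means)`. Must be >= 0.
#' @param n Observations per group, >= 2.
#' @param seed RNG seed.
#' @param timepoint Optional timepoint label attached to every group.
#' @return List of [group_data()] objects.
#' @export
generate_groups <- function(means, sds, n = 6L, seed = 1L, timepoint = NA_character_) {
  if (!is.numeric(means) || length(means) == 0L || is.null(names(means)) ||
      any(!nzchar(names(means)))) {
    stop("`means` must be a named numeric vector", call. = FALSE)
  }
  sds <- rep_len(sds, length(means))
  if (any(!is.finite(sds)) || any(sds < 0)) stop("`sds` must be >= 0", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  .with_seed(seed, {
    lapply(seq_along(means), function(i) {
      v <- stats::rnorm(n, means[i], sds[i])
      while (any(v < 0)) {
        v[v < 0] <- stats::rnorm(sum(v < 0), means[i], sds[i])
      }
      group_data(names(means)[i], v, timepoint = timepoint)
    })
  })
}
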