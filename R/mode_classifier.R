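#' Binding-constant set for one enzyme / substrate / inhibitor triple
#'
#' Holds the four equilibrium constants of the enzyme-substrate-inhibitor
#' thermodynamic cycle:
#' \itemize{
#'   \item K1: E + S = ES (substrate binding to free enzyme);
#'   \item Ka: E + I = EI (inhibitor binding to free enzyme);
#'   \item K4: EI + S = EIS (substrate binding to the enzyme-inhibitor complex);
#'   \item Kb_direct: ES + I = ESI, estimated directly (e.g. by multi-ligand
#'     simultaneous docking) rather than from the cycle.
#' }
#' All constants are carried in micromolar. Only ratios and products of the
#' four enter the cycle test, so the association-vs-dissociation convention
#' cancels as long as the set is self-consistent.
#'
#' @param ligand_id,substrate_id,target_id Non-empty identifier strings.
#' @param K1,Ka,K4,Kb_direct Positive equilibrium constants, micromolar.
#' @param e_binding_EI Optional binding free energy of the EI complex, kcal/mol.
#' @return An object of class `binding_constant_set`.
#' @examples
#' bcs <- binding_constant_set("Betulin", "Maltose", "amylase",
#'                             K1 = 427180, Ka = 13.66, K4 = 938020,
#'                             Kb_direct = 23.36)
#' predicted_kb(bcs) # ~29.99
#' @export
binding_constant_set <- function(ligand_id, substrate_id, target_id,
                                 K1, Ka, K4, Kb_direct, e_binding_EI = NA_real_) {
  for (nm in c("ligand_id", "substrate_id", "target_id")) {
    v <- get(nm)
    if (!is.character(v) || length(v) != 1L || is.na(v) || !nzchar(v)) {
      stop(sprintf("`%s` must be a non-empty string", nm), call. = FALSE)
    }
  }
  for (nm in c("K1", "Ka", "K4", "Kb_direct")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("equilibrium constant `%s` must be a single positive finite number (uM)", nm),
           call. = FALSE)
    }
  }
  structure(
    list(ligand_id = ligand_id, substrate_id = substrate_id, target_id = target_id,
         K1 = K1, Ka = Ka, K4 = K4, Kb_direct = Kb_direct,
         e_binding_EI = e_binding_EI),
    class = "binding_constant_set"
  )
}

#' Cycle-predicted ternary-complex constant
#'
#' Closure of the thermodynamic cycle E/ES/EI/EIS forces the ES + I = ESI
#' constant to equal \eqn{K_b = K_4 K_a / K_1}. The result is homogeneous of
#' degree 0 in (K1, K4) scaled together and degree 1 in Ka.
#'
#' @param set A [binding_constant_set()].
#' @return Predicted Kb in micromolar.
#' @export
predicted_kb <- function(set) {
  stopifnot(inherits(set, "binding_constant_set"))
  set$K4 * set$Ka / set$K1
}

#' Fold discrepancy between two positive constants
#'
#' The max/min ratio, always >= 1 and symmetric in its arguments. This makes
#' the qualitative "approximately equal vs different" judgement on the directly
#' estimated and cycle-predicted Kb operational.
#'
#' @param kb_direct,kb_predicted Positive constants (micromolar).
#' @return Dimensionless fold ratio >= 1. Vectorised.
#' @examples
#' fold_discrepancy(23.36, 29.99) # ~1.284
#' @export
fold_discrepancy <- function(kb_direct, kb_predicted) {
  if (!is.numeric(kb_direct) || !is.numeric(kb_predicted) ||
      any(!is.finite(kb_direct)) || any(!is.finite(kb_predicted)) ||
      any(kb_direct <= 0) || any(kb_predicted <= 0)) {
    stop("both constants must be positive and finite", call. = FALSE)
  }
  pmax(kb_direct, kb_predicted) / pmin(kb_direct, kb_predicted)
}

#' Classify the inhibition mode of one ligand by cycle consistency
#'
#' A noncompetitive inhibitor binds free enzyme and the enzyme-substrate
#' complex alike, so all four cycle constants exist and the directly estimated
#' Kb must agree with the cycle prediction K4*Ka/K1. Competitive and
#' uncompetitive inhibitors lack one edge of the cycle, so the two estimates
#' diverge. The verdict is `"noncompetitive"` iff the fold discrepancy is at
#' most `threshold` (ties classify as noncompetitive: approximate equality is
#' the affirmative claim). The test cannot separate competitive from
#' uncompetitive inhibition; those collapse into one verdict.
#'
#' @param set A [binding_constant_set()].
#' @param threshold Fold-discrepancy threshold, > 1. Default 1.5.
#' @return An object of class `inhibition_mode_result`: a list with
#'   `ligand_id`, `kb_predicted`, `kb_direct`, `fold_discrepancy`,
#'   `threshold_used` and `verdict` (one of `"noncompetitive"`,
#'   `"competitive_or_uncompetitive"`).
#' @export
classify_mode <- function(set, threshold = 1.5) {
  stopifnot(inherits(set, "binding_constant_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 1) {
    stop("`threshold` must be a single number > 1", call. = FALSE)
  }
  kb_pred <- predicted_kb(set)
  fold <- fold_discrepancy(set$Kb_direct, kb_pred)
  verdict <- if (fold <= threshold) "noncompetitive" else "competitive_or_uncompetitive"
  structure(
    list(ligand_id = set$ligand_id,
         kb_predicted = kb_pred,
         kb_direct = set$Kb_direct,
         fold_discrepancy = fold,
         threshold_used = threshold,
         verdict = verdict),
    class = "inhibition_mode_result"
  )
}

#' @export
print.inhibition_mode_result <- function(x, ...) {
  cat(sprintf("%s: Kb_pred %.4g uM vs Kb_direct %.4g uM (fold %.4g, threshold %.3g) -> %s\n",
              x$ligand_id, x$kb_predicted, x$kb_direct,
              x$fold_discrepancy, x$threshold_used, x$verdict))
  invisible(x)
}

#' Classify a batch of ligands
#'
#' Applies [classify_mode()] to each set, preserving input order. Ligand ids
#' must be unique. Verdict counts are attached as the `"summary"` attribute.
#'
#' @param sets Non-empty list of [binding_constant_set()] objects.
#' @inheritParams classify_mode
#' @return A data.frame with one row per ligand: `ligand_id`, `kb_pred_uM`,
#'   `kb_direct_uM`, `fold`, `verdict`; attribute `summary` holds the verdict
#'   table and attribute `results` the full `inhibition_mode_result` list.
#' @export
classify_batch <- function(sets, threshold = 1.5) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop("`sets` must be a non-empty list of binding_constant_set objects", call. = FALSE)
  }
  ok <- vapply(sets, inherits, logical(1), "binding_constant_set")
  if (!all(ok)) stop("all elements of `sets` must be binding_constant_set objects", call. = FALSE)
  ids <- vapply(sets, `[[`, character(1), "ligand_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate ligand_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  results <- lapply(sets, classify_mode, threshold = threshold)
  out <- data.frame(
    ligand_id = ids,
    kb_pred_uM = vapply(results, `[[`, numeric(1), "kb_predicted"),
    kb_direct_uM = vapply(results, `[[`, numeric(1), "kb_direct"),
    fold = vapply(results, `[[`, numeric(1), "fold_discrepancy"),
    verdict = vapply(results, `[[`, character(1), "verdict"),
    stringsAsFactors = FALSE
  )
  attr(out, "summary") <- table(factor(out$verdict,
    levels = c("noncompetitive", "competitive_or_uncompetitive")))
  attr(out, "results") <- results
  out
}
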