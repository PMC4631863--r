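#' Amylase activity units from starch-iodine absorbances
#'
#' Remaining starch forms a blue iodine complex; its absorbance at 581 nm
#' drops as amylase digests the starch. One arbitrary activity unit is defined
#' by \eqn{(E_{B1} - E_S)/E_{B1} \times 800}, where `eb1` is the blank (no
#' enzyme) absorbance and `es` the sample absorbance. Units are 0 when the
#' sample equals the blank and 800 when all starch is digested (`es` = 0).
#' A sample reading above its blank yields negative units; these are passed
#' through but flagged with a warning (read noise or pipetting artefact).
#'
#' @param readings Either a data.frame of plate readings with columns
#'   `replicate_id`, `concentration`, `eb1`, `es`, or a numeric vector of
#'   blank absorbances (with `es` supplied).
#' @param es Sample absorbances when `readings` is numeric.
#' @return If given a data.frame: the same frame with `activity_units` and
#'   logical `flagged` columns appended. If given numerics: a numeric vector
#'   of activity units.
#' @examples
#' activity_units(0.8, 0.4)     # 400
#' activity_units(0.611, 0.302) # ~404.6
#' @export
activity_units <- function(readings, es = NULL) {
  if (is.data.frame(readings)) {
    need <- c("replicate_id", "concentration", "eb1", "es")
    miss <- setdiff(need, names(readings))
    if (length(miss)) {
      stop("plate readings missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
    }
    units <- activity_units(readings$eb1, readings$es)
    out <- readings
    out$activity_units <- units
    out$flagged <- units < 0
    return(out)
  }
  eb1 <- readings
  if (!is.numeric(eb1) || !is.numeric(es) || length(es) == 0L) {
    stop("supply numeric `eb1` and `es` absorbances or a readings data.frame", call. = FALSE)
  }
  if (any(!is.finite(eb1)) || any(eb1 <= 0)) {
    stop("blank absorbance `eb1` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(es)) || any(es < 0)) {
    stop("sample absorbance `es` must be non-negative and finite", call. = FALSE)
  }
  units <- (eb1 - es) / eb1 * 800
  if (any(units < 0)) {
    warning(sprintf("%d reading(s) with es > eb1 produce negative activity units (flagged)",
                    sum(units < 0)), call. = FALSE)
  }
  units
}

#' Percent inhibition from paired activity measurements
#'
#' \eqn{(B - A)/B \times 100} where A is the enzyme activity with the test
#' solution and B the activity without it: 0\% when the inhibitor has no
#' effect, 100\% at complete inhibition, negative when the test solution
#' activates the enzyme (passed through with a warning). The alternative sign
#' convention \eqn{(A - B)/B \times 100}, which is negative for inhibitors, is
#' available via `printed_form = TRUE` for compatibility with sources that
#' quote the formula that way.
#'
#' @param activity_with_inhibitor Activity A, arbitrary units.
#' @param activity_without Activity B of the uninhibited control, > 0.
#' @param printed_form Use the (A-B)/B sign convention instead.
#' @return Percent inhibition, vectorised.
#' @examples
#' percent_inhibition(228.3, 404.6) # ~43.58
#' @export
percent_inhibition <- function(activity_with_inhibitor, activity_without,
                               printed_form = FALSE) {
  a <- activity_with_inhibitor
  b <- activity_without
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) || any(!is.finite(b))) {
    stop("activities must be finite numeric", call. = FALSE)
  }
  if (any(b <= 0)) {
    stop("`activity_without` (uninhibited control) must be positive", call. = FALSE)
  }
  pct <- if (isTRUE(printed_form)) (a - b) / b * 100 else (b - a) / b * 100
  if (!printed_form && any(pct < 0)) {
    warning(sprintf("%d point(s) show negative inhibition (activation); passed through",
                    sum(pct < 0)), call. = FALSE)
  }
  pct
}

#' Dose-response points from a plate of readings
#'
#' Per replicate, the mean activity of the concentration-0 wells is the
#' uninhibited control B; each positive concentration's activity becomes a
#' percent-inhibition point against that control. The 800-unit scale and the
#' blank cancel in the composition, so the result depends only on the
#' absorbances.
#'
#' @param readings Plate data.frame: `replicate_id`, `concentration`, `eb1`, `es`.
#' @return data.frame with `replicate_id`, `concentration`, `percent_inhibition`.
#' @export
plate_dose_response <- function(readings) {
  acts <- activity_units(readings)
  out <- do.call(rbind, lapply(split(acts, acts$replicate_id), function(d) {
    ctrl <- d$activity_units[d$concentration == 0]
    if (length(ctrl) == 0L) {
      stop(sprintf("replicate '%s' has no concentration-0 control wells",
                   d$replicate_id[1]), call. = FALSE)
    }
    dd <- d[d$concentration > 0, , drop = FALSE]
    data.frame(
      replicate_id = dd$replicate_id,
      concentration = dd$concentration,
      percent_inhibition = percent_inhibition(dd$activity_units, mean(ctrl)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(match(out$replicate_id, unique(readings$replicate_id)), out$concentration), ,
      drop = FALSE]
}

# Quasi-binomial deviance on clipped proportions; the IRLS objective.
.probit_deviance <- function(p, mu) {
  2 * sum(p * log(p / mu) + (1 - p) * log((1 - p) / (1 - mu)))
}

#' Probit dose-response regression
#'
#' Classical Finney probit analysis: maximum-likelihood probit regression of
#' the inhibition proportion on log10(concentration), fitted by iteratively
#' reweighted least squares initialised from ordinary least squares on
#' probit-transformed proportions. Deterministic; at most 100 iterations with
#' a 1e-10 deviance tolerance. Proportions are clipped to
#' \[1e-6, 1 - 1e-6\] so that 0\% and 100\% observations are admissible.
#' The IC50 is read off where the fitted probit crosses zero:
#' \eqn{IC_{50} = 10^{-\beta_0/\beta_1}}.
#'
#' Degenerate inputs (all-identical proportions, complete separation) return a
#' fit with `converged = FALSE` and a diagnostic rather than an error.
#'
#' @param points data.frame with columns `concentration` (> 0, mg/mL) and
#'   `percent_inhibition`. At least 3 points over at least 2 distinct
#'   concentrations.
#' @return An object of class `probit_fit`: list with `intercept`, `slope`
#'   (probit units per log10 concentration), `ic50`, `se_ic50`,
#'   `standard_errors` (named, for the two coefficients), `converged`,
#'   `iterations`, `n_points`, `extrapolated` (IC50 outside the tested
#'   concentration range) and `diagnostic`.
#' @examples
#' pts <- data.frame(concentration = c(0.05, 0.1, 0.2, 0.4),
#'                   percent_inhibition = 100 * pnorm(1.5 * log10(c(0.05, 0.1, 0.2, 0.4) / 0.14)))
#' fit_probit(pts)$ic50 # 0.14
#' @export
fit_probit <- function(points) {
  if (!is.data.frame(points) ||
      !all(c("concentration", "percent_inhibition") %in% names(points))) {
    stop("`points` must be a data.frame with columns concentration, percent_inhibition",
         call. = FALSE)
  }
  conc <- points$concentration
  pct <- points$percent_inhibition
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all concentrations must be positive and finite", call. = FALSE)
  }
  if (nrow(points) < 3L || length(unique(conc)) < 2L) {
    stop("need at least 3 points over at least 2 distinct concentrations", call. = FALSE)
  }
  eps <- 1e-6
  p <- pmin(pmax(pct / 100, eps), 1 - eps)
  x <- log10(conc)
  n <- length(p)

  fail <- function(msg, b = c(NA_real_, NA_real_), it = 0L) {
    structure(list(
      intercept = b[1], slope = b[2], ic50 = NA_real_, se_ic50 = NA_real_,
      standard_errors = c(intercept = NA_real_, slope = NA_real_),
      converged = FALSE, iterations = it, n_points = n,
      extrapolated = NA, diagnostic = msg), class = "probit_fit")
  }

  if (length(unique(p)) == 1L) {
    return(fail("all inhibition proportions identical; slope not estimable"))
  }

  # OLS on the probit scale for starting values
  X <- cbind(`(Intercept)` = 1, x = x)
  b <- tryCatch(qr.solve(X, stats::qnorm(p)), error = function(e) NULL)
  if (is.null(b) || any(!is.finite(b))) return(fail("singular design in initialisation"))

  dev_old <- Inf
  converged <- FALSE
  it <- 0L
  W <- rep(1, n)
  while (it < 100L) {
    it <- it + 1L
    eta <- drop(X %*% b)
    mu <- pmin(pmax(stats::pnorm(eta), eps / 10), 1 - eps / 10)
    phi <- pmax(stats::dnorm(eta), .Machine$double.xmin)
    W <- phi^2 / (mu * (1 - mu))
    z <- eta + (p - mu) / phi
    fit <- tryCatch(stats::lm.wfit(X, z, W), error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$coefficients))) {
      return(fail("IRLS step failed (separation or degenerate weights)", b, it))
    }
    b <- fit$coefficients
    dev <- .probit_deviance(p, pmin(pmax(stats::pnorm(drop(X %*% b)), eps / 10), 1 - eps / 10))
    if (!is.finite(dev)) return(fail("non-finite deviance (separation)", b, it))
    if (abs(dev - dev_old) < 1e-10) { converged <- TRUE; break }
    dev_old <- dev
  }

  info <- crossprod(X, W * X)
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(cov), 0))
  names(se) <- c("intercept", "slope")

  b0 <- unname(b[1]); b1 <- unname(b[2])
  ic50 <- if (is.finite(b1) && b1 != 0) 10^(-b0 / b1) else NA_real_
  se_ic50 <- NA_real_
  if (is.finite(ic50) && all(is.finite(cov))) {
    ln10 <- log(10)
    grad <- c(-ln10 * ic50 / b1, ln10 * ic50 * b0 / b1^2)
    v <- drop(t(grad) %*% cov %*% grad)
    if (is.finite(v) && v >= 0) se_ic50 <- sqrt(v)
  }
  extrap <- if (is.finite(ic50)) (ic50 < min(conc) || ic50 > max(conc)) else NA

  structure(list(
    intercept = b0, slope = b1, ic50 = ic50, se_ic50 = se_ic50,
    standard_errors = se, converged = converged, iterations = it,
    n_points = n, extrapolated = extrap,
    diagnostic = if (converged) "" else "maximum iterations reached"),
    class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("probit fit (%d points): intercept %.4g, slope %.4g, IC50 %.4g%s%s\n",
              x$n_points, x$intercept, x$slope, x$ic50,
              if (isTRUE(x$extrapolated)) " [extrapolated]" else "",
              if (x$converged) "" else sprintf(" [NOT converged: %s]", x$diagnostic)))
  invisible(x)
}

#' Replicate IC50 summary
#'
#' Mean and SEM (= SD / sqrt(n)) of the converged replicate IC50s.
#' Non-converged fits are excluded and counted. A single converged replicate
#' reports SEM 0 with a flag. Either a list of [fit_probit()] results or a
#' bare numeric vector of per-replicate IC50s is accepted.
#'
#' @param fits List of `probit_fit` objects, or numeric IC50s.
#' @return List with `mean_ic50`, `sem`, `ic50s` (per converged replicate),
#'   `n`, `n_excluded`, `single_replicate` flag.
#' @examples
#' ic50_replicate_summary(c(0.15, 0.24, 0.11, 0.08, 0.14, 0.14))$mean_ic50 # ~0.1433
#' @export
ic50_replicate_summary <- function(fits) {
  if (is.numeric(fits)) {
    ic50s <- fits[is.finite(fits)]
    n_excluded <- sum(!is.finite(fits))
  } else if (is.list(fits) && all(vapply(fits, inherits, logical(1), "probit_fit"))) {
    conv <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$ic50), logical(1))
    ic50s <- vapply(fits[conv], `[[`, numeric(1), "ic50")
    n_excluded <- sum(!conv)
  } else {
    stop("`fits` must be a list of probit_fit objects or a numeric vector", call. = FALSE)
  }
  if (length(ic50s) == 0L) {
    stop("no converged replicate fits to summarise", call. = FALSE)
  }
  single <- length(ic50s) == 1L
  list(
    mean_ic50 = mean(ic50s),
    sem = if (single) 0 else stats::sd(ic50s) / sqrt(length(ic50s)),
    ic50s = ic50s,
    n = length(ic50s),
    n_excluded = n_excluded,
    single_replicate = single
  )
}
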