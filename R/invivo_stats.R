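#' Named group of measurements
#'
#' @param group_label Non-empty group name (e.g. "control", "diabetic_control").
#' @param values Numeric measurements (mg/dL or activity units).
#' @param timepoint Optional timepoint label (e.g. "day0", "week2").
#' @return An object of class `group_data`.
#' @export
group_data <- function(group_label, values, timepoint = NA_character_) {
  if (!is.character(group_label) || length(group_label) != 1L || !nzchar(group_label)) {
    stop("`group_label` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    stop("`values` must be non-empty finite numeric", call. = FALSE)
  }
  structure(list(group_label = group_label, values = as.numeric(values),
                 timepoint = timepoint),
            class = "group_data")
}

#' Group summary: mean, sample SD, n
#'
#' @param group A [group_data()] object.
#' @return List with `group_label`, `mean`, `sd` (n-1 denominator; 0 for a
#'   single observation), `n`.
#' @export
group_summary <- function(group) {
  stopifnot(inherits(group, "group_data"))
  v <- group$values
  list(group_label = group$group_label,
       mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else 0,
       n = length(v))
}

#' One-way analysis of variance
#'
#' Fixed-effects one-way ANOVA from the standard sums of squares:
#' F = MS_between / MS_within with df (k-1, N-k); the p-value is the upper
#' tail of the F distribution (computed via the regularized incomplete beta
#' function). When both the between- and within-group variation are exactly
#' zero (all observations identical) F is defined as 0 with p = 1 and the
#' result is flagged degenerate.
#'
#' @param groups List of at least two [group_data()] objects, each with n >= 2.
#' @return An object of class `anova_result`: `f_statistic`, `df_between`,
#'   `df_within`, `p_value`, `ms_error`, `group_means`, `group_ns`,
#'   `degenerate` flag.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      !all(vapply(groups, inherits, logical(1), "group_data"))) {
    stop("`groups` must be a list of >= 2 group_data objects", call. = FALSE)
  }
  ns <- vapply(groups, function(g) length(g$values), integer(1))
  if (any(ns < 2L)) stop("every group needs n >= 2 for variance-based tests", call. = FALSE)
  labels <- vapply(groups, `[[`, character(1), "group_label")
  means <- vapply(groups, function(g) mean(g$values), numeric(1))
  all_values <- unlist(lapply(groups, `[[`, "values"))
  grand <- mean(all_values)
  k <- length(groups)
  N <- sum(ns)
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g$values - mean(g$values))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  degenerate <- FALSE
  if (ms_w == 0 && ms_b == 0) {
    f <- 0; p <- 1; degenerate <- TRUE
  } else if (ms_w == 0) {
    f <- Inf; p <- 0
  } else {
    f <- ms_b / ms_w
    p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(
    f_statistic = f, df_between = df_b, df_within = df_w,
    p_value = p, ms_error = ms_w,
    group_means = stats::setNames(means, labels),
    group_ns = stats::setNames(ns, labels),
    degenerate = degenerate), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Fisher least-significant-difference post-hoc comparisons
#'
#' For each group pair (i, j) the least significant difference is
#' \eqn{LSD = t_{1-\alpha/2,\,df_w} \sqrt{MS_e (1/n_i + 1/n_j)}}; a pair
#' differs when |mean_i - mean_j| exceeds it. This is the unadjusted pairwise
#' rule, identical to a pooled-variance t-test at level alpha with MS_error as
#' the pooled variance. With `protect = TRUE` (the textbook protected-LSD
#' procedure) the pairwise flags are additionally gated on the omnibus F being
#' significant at `alpha`; the raw pairwise decision is always reported in
#' `significant_unprotected`.
#'
#' @param anova An [one_way_anova()] result computed on `groups`.
#' @param groups The same list of [group_data()] objects.
#' @param alpha Significance level in (0, 1). Default 0.01.
#' @param protect Gate pairwise flags on the omnibus test?
#' @return data.frame with one row per unordered pair: `group_i`, `group_j`,
#'   `mean_difference`, `lsd_threshold`, `significant`,
#'   `significant_unprotected`; attribute `omnibus_significant`.
#' @export
lsd_posthoc <- function(anova, groups, alpha = 0.01, protect = TRUE) {
  stopifnot(inherits(anova, "anova_result"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  }
  labels <- names(anova$group_means)
  got <- vapply(groups, `[[`, character(1), "group_label")
  if (!identical(sort(labels), sort(got))) {
    stop("`groups` do not match the groups the ANOVA was computed on", call. = FALSE)
  }
  tcrit <- stats::qt(1 - alpha / 2, anova$df_within)
  omnibus <- anova$p_value < alpha
  k <- length(labels)
  pairs <- utils::combn(k, 2)
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff_ij <- anova$group_means[i] - anova$group_means[j]
    lsd <- tcrit * sqrt(anova$ms_error * (1 / anova$group_ns[i] + 1 / anova$group_ns[j]))
    sig_raw <- abs(diff_ij) > lsd
    data.frame(group_i = labels[i], group_j = labels[j],
               mean_difference = unname(diff_ij),
               lsd_threshold = unname(lsd),
               significant = unname(if (protect) sig_raw && omnibus else sig_raw),
               significant_unprotected = unname(sig_raw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omnibus_significant") <- omnibus
  attr(out, "alpha") <- alpha
  out
}
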