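test_that("activity_units follows the 800-unit starch-iodine definition", {
  expect_equal(activity_units(0.8, 0.4), 400)
  expect_equal(activity_units(0.55, 0.55), 0)
  expect_equal(activity_units(0.611, 0.302), 404.5826513911621, tolerance = 1e-12)
  expect_equal(activity_units(0.7, 0), 800)
  # affine and decreasing in es
  es <- seq(0, 0.8, by = 0.1)
  u <- activity_units(rep(0.8, length(es)), es)
  expect_equal(diff(u), rep(-100, length(es) - 1))
  expect_error(activity_units(0, 0.1), "eb1")
  expect_warning(u2 <- activity_units(0.5, 0.6), "negative")
  expect_lt(u2, 0)
})

test_that("activity_units on a plate data.frame appends units and flags", {
  plate <- data.frame(replicate_id = "R1", concentration = c(0, 0.1),
                      eb1 = 0.8, es = c(0.3, 0.82))
  out <- suppressWarnings(activity_units(plate))
  expect_equal(out$activity_units[1], 500)
  expect_identical(out$flagged, c(FALSE, TRUE))
  expect_error(activity_units(data.frame(eb1 = 1)), "missing column")
})

test_that("percent_inhibition uses the positive-for-inhibitors convention", {
  expect_equal(percent_inhibition(300, 300), 0)
  expect_equal(percent_inhibition(0, 300), 100)
  expect_equal(percent_inhibition(228.3, 404.6), 43.57390014829461, tolerance = 1e-12)
  # the literal printed form flips the sign
  expect_equal(percent_inhibition(228.3, 404.6, printed_form = TRUE),
               -43.57390014829461, tolerance = 1e-12)
  expect_error(percent_inhibition(1, 0), "positive")
  expect_warning(percent_inhibition(350, 300), "activation")
})

test_that("blank and 800-scale cancel composing units into inhibition", {
  # inhibition% = (es_sample - es_control)/(eb1 - es_control) * 100
  set.seed(5)
  for (i in 1:10) {
    eb1 <- runif(1, 0.5, 1)
    es_ctrl <- runif(1, 0.05, eb1 - 0.1)
    es_smp <- runif(1, es_ctrl, eb1)
    got <- percent_inhibition(activity_units(eb1, es_smp), activity_units(eb1, es_ctrl))
    expect_equal(got, (es_smp - es_ctrl) / (eb1 - es_ctrl) * 100, tolerance = 1e-10)
  }
})

test_that("plate_dose_response references each replicate to its own control", {
  cfg <- kinetics_config(true_ki = 316.2, mode = "noncompetitive",
                         noise_sd_abs = 0, seed = 1L, n_replicates = 2L)
  plate <- generate_assay_plate(cfg)
  pts <- plate_dose_response(plate)
  expect_identical(names(pts), c("replicate_id", "concentration", "percent_inhibition"))
  expect_equal(nrow(pts), 2L * length(cfg$concentrations))
  expect_true(all(pts$concentration > 0))
  # noiseless noncompetitive plate: inhibition = I/(I + Ki) exactly
  i_uM <- pts$concentration / cfg$inhibitor_mw * 1e6
  expect_equal(pts$percent_inhibition, 100 * i_uM / (i_uM + cfg$true_ki),
               tolerance = 1e-9)
  expect_error(plate_dose_response(plate[plate$concentration > 0, ]), "control")
})

test_that("fit_probit recovers the generating curve exactly on noiseless data", {
  ladder <- default_concentration_ladder()
  cases <- list(c(b0 = 1.281, b1 = 1.5), c(b0 = -0.5, b1 = 0.8), c(b0 = 2, b1 = 3))
  for (cs in cases) {
    pts <- probit_curve_points(cs["b0"], cs["b1"], ladder)
    fit <- fit_probit(pts)
    expect_true(fit$converged)
    expect_equal(fit$intercept, unname(cs["b0"]), tolerance = 1e-6)
    expect_equal(fit$slope, unname(cs["b1"]), tolerance = 1e-6)
    expect_equal(fit$ic50, 10^(-cs[["b0"]] / cs[["b1"]]), tolerance = 1e-6)
  }
})

test_that("fit_probit pins the IC50 at the symmetric midpoint", {
  cstar <- 0.2
  pts <- data.frame(concentration = c(cstar / 10, cstar, cstar * 10),
                    percent_inhibition = 100 * pnorm(c(-1, 0, 1)))
  fit <- fit_probit(pts)
  expect_equal(fit$ic50, cstar, tolerance = 1e-8)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
})

test_that("fit_probit IC50 is equivariant under concentration rescaling", {
  pts <- generate_dose_response(0.14, seed = 9L, n_replicates = 1L)
  f1 <- fit_probit(pts)
  pts2 <- pts
  pts2$concentration <- pts$concentration * 50
  f2 <- fit_probit(pts2)
  expect_equal(f2$ic50, 50 * f1$ic50, tolerance = 1e-8)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-8)
})

test_that("fit_probit degenerates gracefully, never raising", {
  ladder <- default_concentration_ladder()
  flat <- data.frame(concentration = ladder, percent_inhibition = 40)
  f <- fit_probit(flat)
  expect_false(f$converged)
  expect_match(f$diagnostic, "identical")
  sep <- data.frame(concentration = ladder,
                    percent_inhibition = c(0, 0, 0, 100, 100, 100))
  expect_no_error(fs <- fit_probit(sep))
  expect_error(fit_probit(flat[1:2, ]), "at least 3 points")
  expect_error(fit_probit(data.frame(concentration = c(1, 1, 1),
                                     percent_inhibition = c(10, 20, 30))),
               "distinct")
  expect_error(fit_probit(data.frame(concentration = c(-1, 1, 2),
                                     percent_inhibition = c(1, 2, 3))), "positive")
})

test_that("six noisy replicates at the standard ladder recover IC50 within 15%", {
  pts <- generate_dose_response(true_ic50 = 0.14, slope = 1.5, noise_sd_pct = 3,
                                n_replicates = 6L, seed = 42L)
  fits <- lapply(split(pts, pts$replicate_id), fit_probit)
  summ <- ic50_replicate_summary(unname(fits))
  expect_equal(summ$n, 6L)
  expect_lt(abs(summ$mean_ic50 - 0.14) / 0.14, 0.15)
})

test_that("probit recovery is calibrated over 200 simulated replicates", {
  true_ic50 <- 0.14
  res <- vapply(1:200, function(i) {
    pts <- generate_dose_response(true_ic50, slope = 1.5, noise_sd_pct = 3,
                                  n_replicates = 1L, seed = 1000L + i)
    f <- fit_probit(pts)
    c(f$ic50, f$se_ic50, as.numeric(f$converged))
  }, numeric(3))
  conv <- res[3, ] == 1
  expect_gt(mean(conv), 0.95)
  rel_err <- abs(res[1, conv] - true_ic50) / true_ic50
  expect_lt(median(rel_err), 0.10)
  covered <- abs(res[1, conv] - true_ic50) <= 2 * res[2, conv]
  expect_gte(mean(covered), 0.80)
})

test_that("ic50_replicate_summary gives mean and SEM of converged fits", {
  # the six published replicate IC50s
  s <- ic50_replicate_summary(c(0.15, 0.24, 0.11, 0.08, 0.14, 0.14))
  expect_equal(s$mean_ic50, 0.14333333333333334, tolerance = 1e-12)
  expect_equal(s$sem, 0.022010098692292236, tolerance = 1e-9)
  expect_equal(round(s$mean_ic50, 2), 0.14)
  s1 <- ic50_replicate_summary(0.2)
  expect_true(s1$single_replicate)
  expect_equal(s1$sem, 0)
  expect_equal(ic50_replicate_summary(rep(0.3, 6))$sem, 0)
  # non-converged fits are excluded and counted
  good <- fit_probit(probit_curve_points(1.281, 1.5, default_concentration_ladder()))
  bad <- fit_probit(data.frame(concentration = c(0.1, 0.2, 0.4),
                               percent_inhibition = 40))
  s2 <- ic50_replicate_summary(list(good, bad))
  expect_equal(s2$n, 1L)
  expect_equal(s2$n_excluded, 1L)
  expect_error(ic50_replicate_summary(list(bad)), "no converged")
})
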