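protocol_steps <- c(400, 200, 50, 150, 300, 400, 500, 600, 700, 800, 1200)

# noiseless curve at the stepped protocol, via the coupled operating point
noiseless_curve <- function(params = c4_params(120, 45), gs_scale = 1) {
  cfg <- sim_config(noise_cv_a = 0, noise_cv_gs = 0)
  eff <- genotype_effects()[1, ]
  eff$gs_scale <- gs_scale
  sim_aci_curve(eff, params, cfg)
}

test_that("validate_protocol accepts the stepped sequence and warns on deviations", {
  curve <- data.frame(ca_sample = protocol_steps, a_n = 40)
  expect_silent(ok <- validate_protocol(curve))
  expect_true(ok)
  expect_warning(validate_protocol(curve[1:10, ]), "missing")
  expect_error(validate_protocol(curve[0, ]), "empty")
  drift <- data.frame(ca_sample = protocol_steps,
                      a_n = c(40, 40, 8, 30, 38, 30, 43, 43, 43, 43, 43))
  expect_warning(validate_protocol(drift), "drifted")
})

test_that("initial_guess lands near the truth and degrades gracefully", {
  curve <- noiseless_curve()
  g <- initial_guess(curve, kp = 80, rd = 2)
  expect_lt(abs(g$vpmax - 120) / 120, 0.25)
  expect_lt(abs(g$vmax - 45) / 45, 0.25)
  flat <- data.frame(ci = c(100, 200, 300), a_n = c(43, 43, 43))
  gf <- initial_guess(flat, kp = 80, rd = 2)
  expect_equal(gf$vpmax, 2 * gf$vmax)  # zero-slope fallback
  expect_error(initial_guess(data.frame(ci = 1:2, a_n = 1:2)), "at least 3")
})

test_that("noiseless curves are recovered to machine-level accuracy", {
  curve <- noiseless_curve()
  fit <- fit_aci(curve)
  expect_lt(abs(fit$params$vpmax - 120) / 120, 1e-6)
  expect_lt(abs(fit$params$vmax - 45) / 45, 1e-6)
  expect_lt(abs(fit$params$rd - 2), 1e-6)
  expect_lt(fit$rss, 1e-12)
  expect_true(fit$converged)
  expect_true(fit$identifiable_vmax)
})

test_that("a constant shift in a_n is absorbed entirely by rd", {
  curve <- noiseless_curve()
  shifted <- curve
  shifted$a_n <- shifted$a_n + 1
  f0 <- fit_aci(curve)
  f1 <- fit_aci(shifted)
  expect_lt(abs(f1$params$rd - (f0$params$rd - 1)), 1e-6)
  expect_lt(abs(f1$params$vpmax - f0$params$vpmax) / f0$params$vpmax, 1e-6)
  expect_lt(abs(f1$params$vmax - f0$params$vmax) / f0$params$vmax, 1e-6)
})

test_that("saturation never observed flags vmax as unidentifiable", {
  p <- c4_params(120, 45, 80, 2)
  curve <- data.frame(ci = c(20, 30, 40), a_n = predict_a(c(20, 30, 40), p))
  fit <- suppressWarnings(fit_aci(curve))
  expect_false(fit$identifiable_vmax)
  # vpmax is still well determined by the sub-inflection branch
  expect_lt(abs(fit$params$vpmax - 120) / 120, 1e-4)
})

test_that("fit is invariant to the ordering of points", {
  set.seed(11)
  curve <- noiseless_curve()
  curve$a_n <- curve$a_n * (1 + rnorm(nrow(curve), 0, 0.02))
  f1 <- fit_aci(curve)
  f2 <- fit_aci(curve[sample(nrow(curve)), ])
  expect_equal(f1$params$vpmax, f2$params$vpmax)
  expect_equal(f1$params$vmax, f2$params$vmax)
  expect_equal(f1$rss, f2$rss)
})

test_that("freeing rd never increases the residual sum of squares", {
  set.seed(13)
  for (i in 1:5) {
    curve <- noiseless_curve()
    curve$a_n <- curve$a_n * (1 + rnorm(nrow(curve), 0, 0.03))
    f_fixed <- fit_aci(curve, fit_config(free = c("vpmax", "vmax"), rd = 2))
    f_free <- fit_aci(curve, fit_config(free = c("vpmax", "vmax", "rd"), rd = 2))
    expect_lte(f_free$rss, f_fixed$rss + 1e-10)
  }
})

test_that("exact recovery holds across random parameter draws", {
  set.seed(21)
  draws <- random_c4_params(50, ratio_range = c(1.5, 4))
  cfg <- sim_config(noise_cv_a = 0, noise_cv_gs = 0)
  eff <- genotype_effects()[1, ]
  for (p in draws) {
    curve <- sim_aci_curve(eff, p, cfg)
    # rd fixed at truth: with one sub-inflection point and rd free the
    # noiseless problem can admit a family of exact fits
    fit <- fit_aci(curve, fit_config(free = c("vpmax", "vmax"),
                                     kp = p$kp, rd = p$rd))
    expect_lt(abs(fit$params$vpmax - p$vpmax) / p$vpmax, 1e-6)
    expect_lt(abs(fit$params$vmax - p$vmax) / p$vmax, 1e-6)
  }
})

test_that("mean_curve_with_se aggregates replicate fits pointwise", {
  p44 <- c4_params(120, 44, 80, 2)
  p46 <- c4_params(120, 46, 80, 2)
  mk_fit <- function(p) {
    ci <- c(5, 10, 20, 35, 60, 150, 400, 900)
    fit_aci(data.frame(ci = ci, a_n = predict_a(ci, p)),
            fit_config(kp = 80, rd = 2))
  }
  f44 <- mk_fit(p44)
  f46 <- mk_fit(p46)
  out <- mean_curve_with_se(list(f44, f46), ci_grid = c(10, 900))
  # saturated ci: predictions 42 and 44 -> mean 43, SE = sd/sqrt(2) = 1
  expect_equal(out$a_mean[2], 43, tolerance = 1e-6)
  expect_equal(out$a_se[2], 1, tolerance = 1e-6)
  same <- mean_curve_with_se(list(f44, f44), ci_grid = c(10, 900))
  expect_equal(same$a_se, c(0, 0), tolerance = 1e-9)
  expect_warning(single <- mean_curve_with_se(list(f44), ci_grid = 10),
                 "single fit")
  expect_equal(single$a_se, 0)
  expect_error(mean_curve_with_se(list()), "no fits")
})

test_that("fit_aci_curves returns one tidy row per plant", {
  set.seed(31)
  cfg <- sim_config(n_plants = 2, noise_cv_a = 0.02)
  panel <- sim_aci_panel(genotype_effects()[1:2, ], c4_params(120, 45), cfg)
  fits <- fit_aci_curves(panel)
  expect_equal(nrow(fits), 4)
  expect_true(all(c("vpmax", "vmax", "rss", "identifiable_vmax") %in% names(fits)))
  expect_s3_class(fits$fit[[1]], "aci_fit")
  td <- tidy(fits$fit[[1]])
  expect_equal(td$term, c("vpmax", "vmax", "kp", "rd"))
  expect_true(td$fixed[td$term == "kp"])
  gl <- glance(fits$fit[[1]])
  expect_equal(gl$n_points, 11L)
})
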