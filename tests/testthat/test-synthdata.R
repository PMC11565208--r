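test_that("noiseless simulated curves satisfy supply = demand at every step", {
  cfg <- sim_config(noise_cv_a = 0, noise_cv_gs = 0)
  eff <- genotype_effects()[1, ]
  p <- c4_params(120, 45)
  curve <- sim_aci_curve(eff, p, cfg)
  gs_co2 <- gs_h2o_to_co2(curve$gs[1])
  supply <- gs_co2 * (curve$ca_sample - curve$ci)
  expect_equal(supply, curve$a_n, tolerance = 1e-8)
  expect_equal(curve$a_n, predict_a(curve$ci, p), tolerance = 1e-8)
})

test_that("the same seed reproduces simulated tables bit for bit", {
  cfg <- sim_config(n_plants = 3)
  set.seed(101)
  a <- sim_aci_panel(genotype_effects(), c4_params(120, 45), cfg)
  set.seed(101)
  b <- sim_aci_panel(genotype_effects(), c4_params(120, 45), cfg)
  expect_identical(a, b)
  set.seed(102)
  s1 <- sim_stomatal_fields(genotype_effects(), n_plants = 2)
  set.seed(102)
  s2 <- sim_stomatal_fields(genotype_effects(), n_plants = 2)
  expect_identical(s1, s2)
})

test_that("a gs-scaled panel recovers the imposed conductance ratio", {
  set.seed(103)
  cfg <- sim_config(n_plants = 10, noise_cv_gs = 0.05, noise_cv_a = 0.02)
  effects <- genotype_effects()[1, ]
  low <- effects
  low$name <- "low"
  low$gs_scale <- 0.68
  panel <- sim_aci_panel(dplyr::bind_rows(effects, low),
                         c4_params(120, 45), cfg)
  gs_plant <- panel |>
    dplyr::distinct(.data$plant_id, .data$genotype, .data$gs)
  m <- tapply(gs_plant$gs, gs_plant$genotype, mean)
  ratio <- m[["low"]] / m[["WT"]]
  # 3 SE of the ratio under 5% CV and n = 10 per group
  se_ratio <- 0.68 * 0.05 * sqrt(2 / 10)
  expect_lt(abs(ratio - 0.68), 3 * se_ratio)
})

test_that("field counts are Poisson with mean density times area", {
  set.seed(104)
  eff <- genotype_effects()[1, ]
  eff$sd_abaxial <- 50
  eff$sd_adaxial <- 30
  st <- sim_stomatal_fields(eff, n_plants = 1250, leaf_positions = 6,
                            n_fields = 4)
  ab <- st$counts$count[st$counts$surface == "abaxial"]
  expect_equal(length(ab), 5000)
  expect_lt(abs(mean(ab) - 32), 3 * sqrt(32 / length(ab)))
  ad <- st$counts$count[st$counts$surface == "adaxial"]
  expect_lt(mean(ad), mean(ab))
})

test_that("the bucket model conserves water and responds to gs scaling", {
  eff <- genotype_effects()[1, ]
  eff$leaf_area_scale <- 1
  zero <- eff
  zero$name <- "closed"
  zero$gs_scale <- 0
  dd0 <- sim_drydown(zero, drydown_config(noise_cv = 0), n_pots = 1)
  expect_equal(unique(dd0$masses$mass), dd0$refs$saturated_mass)
  dd <- sim_drydown(eff, drydown_config(noise_cv = 0.1), n_pots = 2)
  for (pot in unique(dd$masses$pot_id)) {
    m <- dd$masses$mass[dd$masses$pot_id == pot]
    expect_equal(sum(-diff(m)), m[1] - m[length(m)])
  }
})

test_that("a low-gs genotype reaches the limiting FTSW threshold later", {
  eff_hi <- genotype_effects()[1, ]
  eff_hi$leaf_area_scale <- 1
  eff_lo <- eff_hi
  eff_lo$name <- "low"
  eff_lo$gs_scale <- 0.7
  cfg <- drydown_config(noise_cv = 0)
  dd <- sim_drydown(dplyr::bind_rows(eff_hi, eff_lo), cfg, n_pots = 1)
  swc <- rswc_series(dd$masses, dd$refs)
  wt <- swc[swc$genotype == "WT", ]
  lo <- swc[swc$genotype == "low", ]
  thresh_day <- function(s) min(s$day[s$rswc / 100 < cfg$ftsw_threshold])
  expect_gt(thresh_day(lo), thresh_day(wt))
  until_wt <- wt$day[which(wt$rswc <= 1e-6)][1]
  if (is.na(until_wt)) until_wt <- max(wt$day)
  days <- 1:until_wt
  expect_true(all(lo$rswc[lo$day %in% days] >= wt$rswc[wt$day %in% days]))
})

test_that("reducing gs drives SL upward only past the inflection", {
  p <- c4_params(120, 45)
  cfg <- sim_config(noise_cv_a = 0, noise_cv_gs = 0)
  scales <- seq(1, 0.15, length.out = 25)
  sl <- vapply(scales, function(s) {
    gs_co2 <- gs_h2o_to_co2(cfg$gs_base * s)
    op <- solve_operating_point(gs_co2, cfg$ambient_ca, p)
    stomatal_limitation(op, p, cfg$ambient_ca)$sl
  }, numeric(1))
  expect_true(all(diff(sl) >= -1e-12))
  ci_star <- inflection_ci(p)
  above <- vapply(scales, function(s) {
    gs_co2 <- gs_h2o_to_co2(cfg$gs_base * s)
    solve_operating_point(gs_co2, cfg$ambient_ca, p)$ci_op >= ci_star
  }, logical(1))
  expect_true(all(sl[above] == 0))
  expect_true(all(sl[!above] > 0))
})

test_that("group Vpmax scaling survives the full simulate-then-fit loop", {
  set.seed(107)
  cfg <- sim_config(n_plants = 10, noise_cv_a = 0.02, noise_cv_gs = 0.05)
  wt <- genotype_effects()[1, ]
  lo <- wt
  lo$name <- "low"
  lo$vpmax_scale <- 0.68
  panel <- sim_aci_panel(dplyr::bind_rows(wt, lo), c4_params(120, 45), cfg)
  fits <- fit_aci_curves(panel)
  m <- tapply(fits$vpmax, fits$genotype, mean)
  expect_lt(abs(m[["low"]] / m[["WT"]] - 0.68) / 0.68, 0.05)
})

test_that("simulated leaf areas scale with the genotype leaf_area_scale", {
  set.seed(109)
  la <- sim_leaf_area(genotype_effects(), n_plants = 15)
  areas <- total_leaf_area(la)
  m <- tapply(areas$total_area, areas$genotype, mean)
  expect_lt(m[["epf_strong"]], m[["WT"]])
})
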