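#' Default genotype effect panel
#'
#' Multiplicative effect sizes for a wild type and two engineered
#' low-stomatal-density lines, patterned on a constitutively expressed
#' stomatal-development repressor: a strong line ("epf_strong", gs -32%,
#' Vpmax -32%, Vmax -20%, stomatal density -43%/-61% abaxial/adaxial) and a
#' moderate line ("epf_moderate", gs -18%, Vpmax -21%, density -30%/-36%).
#' These are generator configuration, not estimates; change them to emulate
#' other panels.
#'
#' Baseline stomatal densities default to 120 (abaxial) and 75 (adaxial)
#' stomata mm^-2, with the abaxial surface always denser.
#'
#' @return Tibble with columns `name`, `gs_scale`, `vpmax_scale`,
#'   `vmax_scale`, `sd_abaxial`, `sd_adaxial`, `leaf_area_scale`,
#'   `complex_scale`.
#' @export
genotype_effects <- function() {
  tibble::tibble(
    name = c("WT", "epf_strong", "epf_moderate"),
    gs_scale = c(1.00, 0.68, 0.82),
    vpmax_scale = c(1.00, 0.68, 0.79),
    vmax_scale = c(1.00, 0.80, 1.00),
    sd_abaxial = c(120, 120 * 0.57, 120 * 0.70),
    sd_adaxial = c(75, 75 * 0.39, 75 * 0.64),
    leaf_area_scale = c(1.00, 0.90, 0.95),
    complex_scale = c(1.00, 1.10, 1.05)
  )
}

#' Simulation configuration for synthetic gas exchange
#'
#' @param n_plants Replicate plants per genotype (default 10).
#' @param noise_cv_a Coefficient of variation of multiplicative Gaussian
#'   noise on recorded assimilation (default 0.02).
#' @param noise_cv_gs CV of multiplicative noise on per-plant stomatal
#'   conductance (default 0.05).
#' @param ca_steps Cuvette CO2 step protocol, µmol mol^-1 (default the
#'   11-step sequence 400, 200, 50, 150, 300, 400, 500, 600, 700, 800, 1200).
#' @param ambient_ca Ambient CO2 for operating points, µmol mol^-1.
#' @param gs_base Baseline light-saturated stomatal conductance to water
#'   vapour of the wild type, mol m^-2 s^-1 (default 0.30, placing the WT
#'   operating ci/ca near 0.4, above the A/ci inflection).
#' @param leaf_temp,rh,ppfd Cuvette conditions recorded as metadata
#'   (defaults 27 degC, 65%, 1800 µmol m^-2 s^-1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_plants = 10, noise_cv_a = 0.02, noise_cv_gs = 0.05,
                       ca_steps = c(400, 200, 50, 150, 300, 400, 500, 600,
                                    700, 800, 1200),
                       ambient_ca = 400, gs_base = 0.30,
                       leaf_temp = 27, rh = 65, ppfd = 1800) {
  stopifnot(n_plants >= 1, noise_cv_a >= 0, noise_cv_gs >= 0,
            all(ca_steps > 0), ambient_ca > 0, gs_base > 0)
  structure(
    list(n_plants = as.integer(n_plants), noise_cv_a = noise_cv_a,
         noise_cv_gs = noise_cv_gs, ca_steps = ca_steps,
         ambient_ca = ambient_ca, gs_base = gs_base,
         leaf_temp = leaf_temp, rh = rh, ppfd = ppfd),
    class = "sim_config"
  )
}

#' Dry-down (bucket model) configuration
#'
#' @param available_water0 Plant-available water at saturation, g
#'   (default 3000, a large greenhouse pot).
#' @param potential_use Potential daily water use at unit
#'   `gs_scale * leaf_area_scale`, g day^-1 (default 500, which exhausts the
#'   default bucket in about 6 days for the wild type).
#' @param ftsw_threshold Fraction of transpirable soil water below which
#'   relative transpiration declines linearly to 0 (default 0.4).
#' @param n_days Length of the withholding period, days (default 9).
#' @param noise_cv CV of multiplicative lognormal noise on daily decrements
#'   (default 0.05; set 0 for a deterministic run).
#' @param tare_plus_drysoil,plant_mass Reference masses, g.
#' @return An object of class `drydown_config`.
#' @export
drydown_config <- function(available_water0 = 3000, potential_use = 500,
                           ftsw_threshold = 0.4, n_days = 9, noise_cv = 0.05,
                           tare_plus_drysoil = 8000, plant_mass = 150) {
  stopifnot(available_water0 > 0, potential_use >= 0,
            ftsw_threshold > 0, ftsw_threshold < 1, n_days >= 1, noise_cv >= 0)
  structure(
    list(available_water0 = available_water0, potential_use = potential_use,
         ftsw_threshold = ftsw_threshold, n_days = as.integer(n_days),
         noise_cv = noise_cv, tare_plus_drysoil = tare_plus_drysoil,
         plant_mass = plant_mass),
    class = "drydown_config"
  )
}

# multiplicative lognormal noise with mean 1 and the requested CV
.lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate one A/ci response curve
#'
#' For each CO2 step the operating point is solved by coupling the
#' genotype-scaled demand curve with diffusive supply at the plant's
#' stomatal conductance (held constant across steps within a curve, as the
#' fit only uses the (A, ci) pairs), then the recorded assimilation gets
#' multiplicative Gaussian noise. With all noise at zero every recorded
#' point satisfies supply = demand exactly.
#'
#' @param effect One row of [genotype_effects()] (data frame or list).
#' @param base_params Baseline [c4_params()] scaled by the effect.
#' @param config A [sim_config()].
#' @param plant_id Identifier recorded on every row.
#' @param gs_plant Optional pre-drawn plant-level gs (mol H2O m^-2 s^-1);
#'   default draws one multiplicative deviate around
#'   `gs_base * effect$gs_scale`.
#' @return Tibble of `ACiObservation` rows: `plant_id`, `genotype`,
#'   `step_index`, `ca_sample`, `a_n`, `gs`, `ci`, `leaf_temp`, `rh`, `ppfd`.
#' @export
sim_aci_curve <- function(effect, base_params = c4_params(120, 45),
                          config = sim_config(), plant_id = "plant_1",
                          gs_plant = NULL) {
  effect <- as.list(effect)
  params <- c4_params(
    vpmax = base_params$vpmax * effect$vpmax_scale,
    vmax = base_params$vmax * effect$vmax_scale,
    kp = base_params$kp,
    rd = base_params$rd
  )
  if (is.null(gs_plant)) {
    gs_plant <- config$gs_base * effect$gs_scale *
      .lognoise(1, config$noise_cv_gs)
  }
  gs_co2 <- gs_h2o_to_co2(gs_plant)
  steps <- config$ca_steps
  op <- purrr::map_dfr(steps, function(ca) {
    solve_operating_point(gs_co2, ca, params)
  })
  a_noise <- 1 + stats::rnorm(length(steps), 0, config$noise_cv_a)
  tibble::tibble(
    plant_id = plant_id,
    genotype = effect$name,
    step_index = seq_along(steps),
    ca_sample = steps,
    a_n = op$a_op * a_noise,
    gs = gs_plant,
    ci = op$ci_op,
    leaf_temp = config$leaf_temp,
    rh = config$rh,
    ppfd = config$ppfd
  )
}

#' Simulate a gas-exchange panel across genotypes
#'
#' Replicate plants per genotype, each one curve via [sim_aci_curve()].
#'
#' @param effects Tibble of genotype effects ([genotype_effects()]).
#' @inheritParams sim_aci_curve
#' @return Tibble of all curves stacked.
#' @export
sim_aci_panel <- function(effects = genotype_effects(),
                          base_params = c4_params(120, 45),
                          config = sim_config()) {
  purrr::map_dfr(seq_len(nrow(effects)), function(i) {
    eff <- effects[i, ]
    purrr::map_dfr(seq_len(config$n_plants), function(p) {
      sim_aci_curve(eff, base_params, config,
                    plant_id = sprintf("%s_%02d", eff$name, p))
    })
  })
}

#' Simulate a gravimetric dry-down with a bucket model
#'
#' Each pot starts saturated (FTSW = 1, the full plant-available bucket).
#' Daily transpiration is `potential_use * gs_scale * leaf_area_scale`
#' scaled by relative transpiration — 1 while FTSW is above
#' `ftsw_threshold`, declining linearly to 0 below it — with multiplicative
#' lognormal noise, and never exceeding the water remaining. Pot masses are
#' reconstructed from the decrements, so cumulative daily water use equals
#' initial minus final mass exactly.
#'
#' @param effects Tibble of genotype effects.
#' @param ddconfig A [drydown_config()].
#' @param n_pots Pots per genotype.
#' @return List of two tibbles: `masses` (`pot_id`, `genotype`, `day`,
#'   `mass`) and `refs` (`pot_id`, `tare_plus_drysoil`, `plant_mass`,
#'   `saturated_mass`).
#' @export
sim_drydown <- function(effects = genotype_effects(),
                        ddconfig = drydown_config(), n_pots = 10) {
  res <- purrr::map(seq_len(nrow(effects)), function(i) {
    eff <- effects[i, ]
    purrr::map(seq_len(n_pots), function(p) {
      pot_id <- sprintf("%s_pot%02d", eff$name, p)
      avail <- ddconfig$available_water0
      sat <- ddconfig$tare_plus_drysoil + ddconfig$plant_mass + avail
      pot_use <- ddconfig$potential_use * eff$gs_scale * eff$leaf_area_scale
      remaining <- avail
      mass <- numeric(ddconfig$n_days + 1)
      mass[1] <- sat
      for (d in seq_len(ddconfig$n_days)) {
        ftsw <- remaining / avail
        rel <- min(1, ftsw / ddconfig$ftsw_threshold)
        dec <- pot_use * rel * .lognoise(1, ddconfig$noise_cv)
        dec <- min(dec, remaining)
        remaining <- remaining - dec
        mass[d + 1] <- mass[d] - dec
      }
      list(
        masses = tibble::tibble(pot_id = pot_id, genotype = eff$name,
                                day = 0:ddconfig$n_days, mass = mass),
        refs = tibble::tibble(pot_id = pot_id,
                              tare_plus_drysoil = ddconfig$tare_plus_drysoil,
                              plant_mass = ddconfig$plant_mass,
                              saturated_mass = sat)
      )
    })
  })
  flat <- purrr::flatten(res)
  list(
    masses = purrr::map_dfr(flat, "masses"),
    refs = purrr::map_dfr(flat, "refs")
  )
}

#' Simulate stomatal field counts and complex measurements
#'
#' Field-of-view counts are Poisson with mean `density x field_area` for the
#' surface-specific density of each genotype (abaxial denser than adaxial by
#' default); four fields per plant x leaf position x surface. Complex widths
#' and lengths are zero-truncated Gaussians scaled by the genotype's
#' `complex_scale`, six complexes per plant.
#'
#' @param effects Tibble of genotype effects.
#' @param n_plants Plants per genotype.
#' @param leaf_positions Leaf positions scanned (default 4, 5, 6).
#' @param n_fields Fields of view per transect (default 4).
#' @param field_area Field-of-view area, mm^2 (default 0.64).
#' @param n_complexes Complexes measured per plant (default 6).
#' @param width_mean,length_mean,size_sd Gaussian parameters for complex
#'   size, µm.
#' @return List of tibbles `counts` and `complexes` in the schemas read by
#'   [density_from_counts()] and [complex_size_summary()].
#' @export
sim_stomatal_fields <- function(effects = genotype_effects(), n_plants = 10,
                                leaf_positions = c(4, 5, 6), n_fields = 4,
                                field_area = 0.64, n_complexes = 6,
                                width_mean = 30, length_mean = 40,
                                size_sd = 2.5) {
  stopifnot(all(effects$sd_abaxial > 0), all(effects$sd_adaxial > 0))
  rtruncnorm0 <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
    x
  }
  counts <- purrr::map_dfr(seq_len(nrow(effects)), function(i) {
    eff <- effects[i, ]
    tidyr::expand_grid(
      plant = seq_len(n_plants),
      leaf_position = leaf_positions,
      surface = c("abaxial", "adaxial"),
      field_index = seq_len(n_fields)
    ) |>
      dplyr::mutate(
        plant_id = sprintf("%s_%02d", eff$name, .data$plant),
        genotype = eff$name,
        field_area = field_area,
        count = stats::rpois(
          dplyr::n(),
          ifelse(.data$surface == "abaxial", eff$sd_abaxial, eff$sd_adaxial) *
            field_area
        )
      ) |>
      dplyr::select("plant_id", "genotype", "leaf_position", "surface",
                    "field_index", "count", "field_area")
  })
  complexes <- purrr::map_dfr(seq_len(nrow(effects)), function(i) {
    eff <- effects[i, ]
    purrr::map_dfr(seq_len(n_plants), function(p) {
      tibble::tibble(
        plant_id = sprintf("%s_%02d", eff$name, p),
        genotype = eff$name,
        width = rtruncnorm0(n_complexes, width_mean * eff$complex_scale, size_sd),
        length = rtruncnorm0(n_complexes, length_mean * eff$complex_scale, size_sd)
      )
    })
  })
  list(counts = counts, complexes = complexes)
}

#' Simulate per-leaf width/length records for leaf-area estimation
#'
#' @param effects Tibble of genotype effects.
#' @param n_plants Plants per genotype.
#' @param n_leaves Leaves per plant (default 8).
#' @param width_mean,length_mean Leaf dimensions, cm; areas scale with the
#'   genotype's `leaf_area_scale`.
#' @param cv Multiplicative CV on each dimension.
#' @return Tibble with `plant_id`, `genotype`, `leaf_index`, `width`,
#'   `length` (cm).
#' @export
sim_leaf_area <- function(effects = genotype_effects(), n_plants = 10,
                          n_leaves = 8, width_mean = 7, length_mean = 75,
                          cv = 0.1) {
  purrr::map_dfr(seq_len(nrow(effects)), function(i) {
    eff <- effects[i, ]
    purrr::map_dfr(seq_len(n_plants), function(p) {
      s <- sqrt(eff$leaf_area_scale)  # split the area effect across both axes
      tibble::tibble(
        plant_id = sprintf("%s_%02d", eff$name, p),
        genotype = eff$name,
        leaf_index = seq_len(n_leaves),
        width = width_mean * s * .lognoise(n_leaves, cv),
        length = length_mean * s * .lognoise(n_leaves, cv)
      )
    })
  })
}
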