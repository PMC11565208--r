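#' Simulate a full synthetic phenotyping experiment to disk
#'
#' Generates the four input tables the analysis stages read — gas-exchange
#' curves, pot-mass series plus references, stomatal counts and complex
#' measurements, and per-leaf dimensions — and writes them as CSVs with a
#' JSON manifest recording the seed and parameters, sufficient to reproduce
#' the files bit for bit.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving every random draw.
#' @param effects Tibble of genotype effects ([genotype_effects()]).
#' @param base_params Baseline [c4_params()].
#' @param config A [sim_config()].
#' @param ddconfig A [drydown_config()].
#' @return Invisibly, the manifest list.
#' @export
simulate_experiment <- function(out_dir, seed = 1,
                                effects = genotype_effects(),
                                base_params = c4_params(120, 45),
                                config = sim_config(),
                                ddconfig = drydown_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed))
  gas <- sim_aci_panel(effects, base_params, config)
  dd <- sim_drydown(effects, ddconfig, n_pots = config$n_plants)
  st <- sim_stomatal_fields(effects, n_plants = config$n_plants)
  la <- sim_leaf_area(effects, n_plants = config$n_plants)

  readr::write_csv(gas, file.path(out_dir, "gas_exchange.csv"))
  readr::write_csv(dd$masses, file.path(out_dir, "pot_mass.csv"))
  readr::write_csv(dd$refs, file.path(out_dir, "pot_reference.csv"))
  readr::write_csv(st$counts, file.path(out_dir, "stomatal_counts.csv"))
  readr::write_csv(st$complexes, file.path(out_dir, "stomatal_complexes.csv"))
  readr::write_csv(la, file.path(out_dir, "leaf_area.csv"))

  manifest <- list(
    seed = as.integer(seed),
    genotypes = effects$name,
    base_params = unclass(base_params),
    sim_config = unclass(config),
    drydown_config = unclass(ddconfig),
    files = c("gas_exchange.csv", "pot_mass.csv", "pot_reference.csv",
              "stomatal_counts.csv", "stomatal_complexes.csv",
              "leaf_area.csv"),
    package_version = as.character(utils::packageVersion("c4wue"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

.read_if_exists <- function(path) {
  if (file.exists(path)) readr::read_csv(path, show_col_types = FALSE) else NULL
}

#' Run the full analysis pipeline on an experiment directory
#'
#' Reads the CSVs written by [simulate_experiment()] (or equivalently
#' formatted measured data), then runs: per-plant A/ci fits; operating
#' points, stomatal limitation and iWUE at ambient CO2; water budgets (rSWC
#' and daily water use with per-day Tukey flags); stomatal density
#' summaries with a genotype x surface factorial ANOVA; leaf areas; and
#' genotype least-squares means for the key gas-exchange traits. Results
#' are written as per-stage CSVs plus a plain-text report. Stages whose
#' input files are missing are skipped with a warning.
#'
#' Plants whose curves never reach the saturated branch are flagged
#' (`identifiable_vmax = FALSE`) and excluded from Vmax group means.
#'
#' @param input_dir Directory of input CSVs.
#' @param out_dir Output directory (created if missing).
#' @param ambient_ca Ambient CO2 for operating points, µmol mol^-1.
#' @param fitcfg A [fit_config()] (carries the kp and rd constants).
#' @param alpha Significance level for Tukey flags.
#' @return Invisibly, a list of the per-stage result tables.
#' @export
analyze_experiment <- function(input_dir, out_dir, ambient_ca = 400,
                               fitcfg = fit_config(), alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  report <- c("c4wue analysis report", strrep("=", 60))

  gas <- .read_if_exists(file.path(input_dir, "gas_exchange.csv"))
  if (!is.null(gas)) {
    fits <- fit_aci_curves(gas, fitcfg)
    results$fits <- dplyr::select(fits, -"fit")
    readr::write_csv(results$fits, file.path(out_dir, "fits.csv"))

    ambient <- gas |>
      dplyr::filter(abs(.data$ca_sample - ambient_ca) <= 0.05 * ambient_ca) |>
      dplyr::group_by(.data$plant_id) |>
      dplyr::summarise(ci_op = mean(.data$ci), a_obs = mean(.data$a_n),
                       gs = mean(.data$gs), .groups = "drop")
    lim <- fits |>
      dplyr::inner_join(ambient, by = "plant_id") |>
      dplyr::mutate(summ = purrr::pmap(
        list(.data$fit, .data$ci_op, .data$gs),
        function(f, ci_op, gs) {
          stomatal_limitation(ci_op, f$params, ca = ambient_ca, gs = gs)
        })) |>
      tidyr::unnest("summ", names_sep = ".") |>
      dplyr::transmute(
        plant_id = .data$plant_id, genotype = .data$genotype,
        sl = .data$summ.sl, ci_inflection = .data$summ.ci_inflection,
        ci_op = .data$summ.ci_op, a_op = .data$summ.a_op,
        above_inflection = .data$summ.above_inflection,
        iwue = .data$summ.iwue, gs = .data$gs, a_obs = .data$a_obs,
        identifiable_vmax = .data$identifiable_vmax
      )
    results$limitation <- lim
    readr::write_csv(lim, file.path(out_dir, "limitation.csv"))

    n_flag <- sum(!fits$identifiable_vmax)
    report <- c(report, "", "A/ci fits", strrep("-", 40),
                sprintf("%d curve(s) fitted; %d flagged with unidentifiable Vmax%s",
                        nrow(fits), n_flag,
                        if (n_flag) " (excluded from Vmax means)" else ""))
    if (length(unique(fits$genotype)) >= 2) {
      vp_ls <- lsmeans_se(fits, "vpmax", "genotype")
      vm_ok <- dplyr::filter(fits, .data$identifiable_vmax)
      results$genotype_means <- vp_ls
      report <- c(report, "", "Vpmax least-squares means:",
                  utils::capture.output(print(as.data.frame(vp_ls))))
      if (length(unique(vm_ok$genotype)) >= 2) {
        vm_ls <- lsmeans_se(vm_ok, "vmax", "genotype")
        report <- c(report, "", "Vmax least-squares means (identifiable fits):",
                    utils::capture.output(print(as.data.frame(vm_ls))))
      }
      sl_by_gen <- lim |>
        dplyr::group_by(.data$genotype) |>
        dplyr::summarise(sl_mean = mean(.data$sl), iwue_mean = mean(.data$iwue),
                         .groups = "drop")
      report <- c(report, "", "Stomatal limitation and iWUE by genotype:",
                  utils::capture.output(print(as.data.frame(sl_by_gen))))
      iw <- lsmeans_se(lim, "iwue", "genotype")
      report <- c(report, "", "iWUE least-squares means:",
                  utils::capture.output(print(as.data.frame(iw))))
    }
  } else {
    warning("gas_exchange.csv missing: gas-exchange stage skipped", call. = FALSE)
  }

  masses <- .read_if_exists(file.path(input_dir, "pot_mass.csv"))
  refs <- .read_if_exists(file.path(input_dir, "pot_reference.csv"))
  if (!is.null(masses) && !is.null(refs)) {
    swc <- rswc_series(masses, refs)
    results$soil_water <- swc
    readr::write_csv(swc, file.path(out_dir, "soil_water.csv"))
    day_flags <- per_day_tukey(dplyr::filter(swc, .data$day > 0),
                               "rswc", "genotype", alpha = alpha)
    results$rswc_tukey <- day_flags
    readr::write_csv(day_flags, file.path(out_dir, "rswc_tukey_by_day.csv"))
    sig_days <- day_flags |>
      dplyr::filter(.data$significant) |>
      dplyr::group_by(.data$group1, .data$group2) |>
      dplyr::summarise(days = paste(sort(unique(.data$day)), collapse = ", "),
                       .groups = "drop")
    report <- c(report, "", "Dry-down water budget", strrep("-", 40),
                sprintf("%d pots over %d days", length(unique(swc$pot_id)),
                        max(swc$day)),
                "Days with significant rSWC differences (Tukey, per day):",
                utils::capture.output(print(as.data.frame(sig_days))))
  } else {
    warning("pot_mass.csv or pot_reference.csv missing: water stage skipped",
            call. = FALSE)
  }

  counts <- .read_if_exists(file.path(input_dir, "stomatal_counts.csv"))
  if (!is.null(counts)) {
    dens <- density_from_counts(counts)
    results$stomatal_density <- dens
    readr::write_csv(dens, file.path(out_dir, "stomatal_density.csv"))
    tab <- surface_contrast_table(dens)
    if (nlevels(tab$genotype) >= 2) {
      aov2 <- two_way_anova(tab, "density", "genotype", "surface")
      results$density_anova <- aov2
      readr::write_csv(aov2, file.path(out_dir, "density_anova.csv"))
      report <- c(report, "", "Stomatal density", strrep("-", 40),
                  "Two-way ANOVA (genotype x surface, Type III):",
                  utils::capture.output(print(as.data.frame(aov2))))
    }
  } else {
    warning("stomatal_counts.csv missing: stomatal stage skipped", call. = FALSE)
  }

  cmpx <- .read_if_exists(file.path(input_dir, "stomatal_complexes.csv"))
  if (!is.null(cmpx)) {
    results$complex_sizes <- complex_size_summary(cmpx)
    readr::write_csv(results$complex_sizes,
                     file.path(out_dir, "complex_sizes.csv"))
  }

  la <- .read_if_exists(file.path(input_dir, "leaf_area.csv"))
  if (!is.null(la)) {
    results$leaf_area <- total_leaf_area(la)
    readr::write_csv(results$leaf_area, file.path(out_dir, "leaf_area.csv"))
  }

  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(results)
}

#' Stomatal-conductance reduction scenario
#'
#' Quantifies how much a fractional reduction in stomatal conductance
#' increases stomatal limitation: solves the coupled operating point at
#' `gs_co2` and at `gs_co2 * (1 - reduction)` and reports SL at both, their
#' difference, and the operating ci values. While both operating points stay
#' on the CO2-saturated branch (above the A/ci inflection), the change in SL
#' is exactly zero — the leaf can trade conductance for water savings at no
#' assimilation cost.
#'
#' @param params A [c4_params()] object.
#' @param ca Ambient CO2, µmol mol^-1.
#' @param gs_co2 Initial stomatal conductance to CO2, mol m^-2 s^-1.
#'   Alternatively supply `target_ci` to derive it.
#' @param target_ci If given, `gs_co2` is chosen so the initial operating ci
#'   equals this value (`gs_co2 = A(target_ci) / (ca - target_ci)`).
#' @param reduction Fractional reduction in conductance, in (0, 1); 0 allowed
#'   (trivial no-change scenario).
#' @return One-row tibble: `gs_co2`, `ci_before`, `ci_after`, `sl_before`,
#'   `sl_after`, `delta_sl` (fractions, not percent).
#' @examples
#' sl_scenario(c4_params(120, 45), ca = 400, target_ci = 160, reduction = 0.2)
#' @export
sl_scenario <- function(params, ca = 400, gs_co2 = NULL, target_ci = NULL,
                        reduction = 0.2) {
  params <- as_c4_params(params)
  if (reduction < 0 || reduction >= 1) {
    stop("`reduction` must be in [0, 1)", call. = FALSE)
  }
  if (is.null(gs_co2)) {
    if (is.null(target_ci)) stop("supply `gs_co2` or `target_ci`", call. = FALSE)
    if (target_ci <= 0 || target_ci >= ca) {
      stop("`target_ci` must lie in (0, ca)", call. = FALSE)
    }
    a_target <- predict_a(target_ci, params)
    if (a_target <= 0) {
      stop("assimilation non-positive at `target_ci`; no physical conductance",
           call. = FALSE)
    }
    gs_co2 <- a_target / (ca - target_ci)
  }
  op1 <- solve_operating_point(gs_co2, ca, params)
  op2 <- solve_operating_point(gs_co2 * (1 - reduction), ca, params)
  if (!op1$positive || !op2$positive) {
    stop("operating point at or below compensation; SL scenario undefined",
         call. = FALSE)
  }
  sl1 <- stomatal_limitation(op1, params, ca)
  sl2 <- stomatal_limitation(op2, params, ca)
  tibble::tibble(
    gs_co2 = gs_co2,
    ci_before = op1$ci_op, ci_after = op2$ci_op,
    sl_before = sl1$sl, sl_after = sl2$sl,
    delta_sl = sl2$sl - sl1$sl
  )
}
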