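#' Relative soil water content over a dry-down
#'
#' Converts a per-pot daily mass series into percentage relative soil water
#' content (rSWC), referencing each pot's tare-plus-dry-soil mass, a
#' constant plant-mass estimate from the destructive harvest at the start of
#' water withholding, and the saturated mass (~100% rSWC):
#' \deqn{rSWC(d) = 100 \frac{m(d) - m_{tare+dry} - m_{plant}}
#'   {m_{sat} - m_{tare+dry} - m_{plant}}}
#' Values outside \[0, 100\] are clamped with a warning. Daily water use
#' (mass decrement, g day^-1) is attached per day; see [daily_water_use()].
#'
#' @param masses Data frame with columns `pot_id`, `genotype`, `day`
#'   (integer, day 0 required), `mass` (g); one or more pots.
#' @param refs Data frame with columns `pot_id`, `tare_plus_drysoil`,
#'   `plant_mass`, `saturated_mass` (g).
#' @return Tibble with one row per pot x day: `rswc` (%), `water_use`
#'   (g day^-1, NA on day 0).
#' @export
rswc_series <- function(masses, refs) {
  stopifnot(all(c("pot_id", "genotype", "day", "mass") %in% names(masses)),
            all(c("pot_id", "tare_plus_drysoil", "plant_mass", "saturated_mass")
                %in% names(refs)))
  bad_ref <- refs$saturated_mass <= refs$tare_plus_drysoil + refs$plant_mass
  if (any(bad_ref)) {
    stop("invalid reference: saturated mass must exceed tare + dry soil + plant",
         call. = FALSE)
  }
  out <- masses |>
    dplyr::inner_join(refs, by = "pot_id") |>
    dplyr::group_by(.data$pot_id, .data$genotype) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      if (df$day[1] != 0) {
        stop(sprintf("pot %s: day 0 reference weighing missing", key$pot_id),
             call. = FALSE)
      }
      if (any(diff(df$day) <= 0)) {
        stop(sprintf("pot %s: days must be strictly increasing", key$pot_id),
             call. = FALSE)
      }
      dry <- df$tare_plus_drysoil[1] + df$plant_mass[1]
      avail <- df$saturated_mass[1] - dry
      rswc <- 100 * (df$mass - dry) / avail
      if (any(rswc < 0 | rswc > 100)) {
        warning(sprintf("pot %s: rSWC outside [0, 100] clamped", key$pot_id),
                call. = FALSE)
        rswc <- pmin(pmax(rswc, 0), 100)
      }
      wu <- c(NA_real_, -diff(df$mass) / diff(df$day))
      if (any(wu < 0, na.rm = TRUE)) {
        warning(sprintf("pot %s: mass increased between days; water use clamped to 0",
                        key$pot_id), call. = FALSE)
        wu <- pmax(wu, 0)
      }
      tibble::tibble(day = df$day, mass = df$mass, rswc = rswc, water_use = wu)
    }) |>
    dplyr::ungroup()
  out
}

#' Daily water use from a pot mass series
#'
#' The day-to-day mass decrement, `mass(t-1) - mass(t)`, in g day^-1
#' (normalised by the day gap when weighings are not strictly daily).
#' Mass increases (unmodelled watering events or weighing error) are clamped
#' to 0 with a warning, so the series is never negative.
#'
#' @param masses Data frame with columns `pot_id`, `genotype`, `day`, `mass`
#'   (one or more pots, >= 2 days each).
#' @return Tibble with one row per pot per day after the first:
#'   `water_use` (g day^-1).
#' @export
daily_water_use <- function(masses) {
  stopifnot(all(c("pot_id", "day", "mass") %in% names(masses)))
  if (!"genotype" %in% names(masses)) masses$genotype <- NA_character_
  masses |>
    dplyr::group_by(.data$pot_id, .data$genotype) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) {
        stop(sprintf("pot %s: need at least 2 days to compute water use",
                     key$pot_id), call. = FALSE)
      }
      if (any(diff(df$day) <= 0)) {
        stop(sprintf("pot %s: days must be strictly increasing", key$pot_id),
             call. = FALSE)
      }
      wu <- -diff(df$mass) / diff(df$day)
      if (any(wu < 0)) {
        warning(sprintf("pot %s: mass increased between days; water use clamped to 0",
                        key$pot_id), call. = FALSE)
        wu <- pmax(wu, 0)
      }
      tibble::tibble(day = df$day[-1], water_use = wu)
    }) |>
    dplyr::ungroup()
}

#' Whole-plant leaf area from per-leaf width and length
#'
#' Non-destructive leaf-area estimate: the sum over leaves of width times
#' length, with no shape-correction factor. An empty leaf list gives area 0.
#'
#' @param leaves Data frame with columns `width` and `length` (cm), and
#'   optionally `plant_id`/`genotype` for grouped totals.
#' @return If `plant_id` is present, a tibble of per-plant `total_area`
#'   (cm^2); otherwise a single number.
#' @export
total_leaf_area <- function(leaves) {
  stopifnot(all(c("width", "length") %in% names(leaves)))
  if (nrow(leaves) == 0) {
    return(if ("plant_id" %in% names(leaves)) {
      tibble::tibble(plant_id = character(), genotype = character(),
                     total_area = numeric())
    } else 0)
  }
  if (any(leaves$width <= 0) || any(leaves$length <= 0)) {
    stop("leaf widths and lengths must be positive", call. = FALSE)
  }
  if ("plant_id" %in% names(leaves)) {
    if (!"genotype" %in% names(leaves)) leaves$genotype <- NA_character_
    leaves |>
      dplyr::group_by(.data$plant_id, .data$genotype) |>
      dplyr::summarise(total_area = sum(.data$width * .data$length),
                       .groups = "drop")
  } else {
    sum(leaves$width * leaves$length)
  }
}
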