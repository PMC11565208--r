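#' Stomatal density from field-of-view counts
#'
#' Converts raw stomata counts per microscope field of view (800 x 800 µm,
#' i.e. 0.64 mm^2, by default) into densities and averages the four fields
#' of a transect into one value per plant x leaf position x surface — the
#' subsample averaging used before any statistics, so each replicate plant
#' contributes a single observation.
#'
#' @param counts Data frame with columns `plant_id`, `genotype`,
#'   `leaf_position`, `surface`, `count`, and optionally `field_area`
#'   (mm^2; filled with `field_area` argument when absent).
#' @param field_area Default field-of-view area, mm^2.
#' @return Tibble with one row per plant x leaf position x surface:
#'   `density` (stomata mm^-2) and `n_fields`.
#' @export
density_from_counts <- function(counts, field_area = 0.64) {
  if (is.null(counts) || nrow(counts) == 0) {
    stop("no field counts supplied", call. = FALSE)
  }
  stopifnot(all(c("plant_id", "genotype", "leaf_position", "surface", "count")
                %in% names(counts)))
  if (!"field_area" %in% names(counts)) counts$field_area <- field_area
  if (any(counts$count < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(counts$field_area <= 0)) stop("field_area must be positive", call. = FALSE)
  counts |>
    dplyr::group_by(.data$plant_id, .data$genotype, .data$leaf_position,
                    .data$surface) |>
    dplyr::summarise(
      density = mean(.data$count / .data$field_area),
      n_fields = dplyr::n(),
      .groups = "drop"
    )
}

#' Per-plant stomatal complex size summary
#'
#' Averages the width and length of the randomly selected stomatal complexes
#' (six per plant in the measurement protocol) into per-plant means. Widths
#' exceeding lengths are kept but trigger a warning, since length is the
#' major axis by convention and such records usually indicate an orientation
#' mix-up.
#'
#' @param measures Data frame with columns `plant_id`, `genotype`, `width`,
#'   `length` (µm).
#' @return Tibble with one row per plant: `mean_width`, `mean_length`,
#'   `n_complexes`.
#' @export
complex_size_summary <- function(measures) {
  if (is.null(measures) || nrow(measures) == 0) {
    stop("no complex measurements supplied", call. = FALSE)
  }
  stopifnot(all(c("plant_id", "genotype", "width", "length") %in% names(measures)))
  if (any(measures$width <= 0) || any(measures$length <= 0)) {
    stop("widths and lengths must be positive", call. = FALSE)
  }
  if (any(measures$width > measures$length)) {
    warning("some complexes have width > length; check orientation convention",
            call. = FALSE)
  }
  measures |>
    dplyr::group_by(.data$plant_id, .data$genotype) |>
    dplyr::summarise(
      mean_width = mean(.data$width),
      mean_length = mean(.data$length),
      n_complexes = dplyr::n(),
      .groups = "drop"
    )
}

#' Long-format density table for factorial analysis
#'
#' Reshapes per-plant stomatal summaries into the long table consumed by the
#' statistical layer: one density row per plant, keyed by genotype, leaf
#' position, and surface, ready for a two-way ANOVA with interaction or for
#' surface contrasts.
#'
#' @param summaries Output of [density_from_counts()].
#' @return Tibble with columns `plant_id`, `genotype`, `leaf_position`,
#'   `surface`, `density`, with the factor columns coerced to factors.
#' @export
surface_contrast_table <- function(summaries) {
  stopifnot(all(c("plant_id", "genotype", "leaf_position", "surface", "density")
                %in% names(summaries)))
  summaries |>
    dplyr::transmute(
      plant_id = .data$plant_id,
      genotype = factor(.data$genotype),
      leaf_position = factor(.data$leaf_position),
      surface = factor(.data$surface),
      density = .data$density
    ) |>
    tibble::as_tibble()
}
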