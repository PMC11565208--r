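#' C4 photosynthesis model parameters
#'
#' Bundles the parameters of the reduced enzyme-limited C4 A/ci model
#' \deqn{A(c_i) = \min\left(\frac{V_{pmax} c_i}{c_i + K_p},\; V_{max}\right) - R_d}
#' where `vpmax` is the apparent maximum PEPC carboxylation rate (the initial
#' slope of the A/ci curve is `vpmax / kp` at low ci), `vmax` the CO2-saturated
#' asymptote of the curve, `kp` the Michaelis constant of PEPC for CO2, and
#' `rd` day respiration. Mesophyll CO2 is taken equal to the intercellular
#' mole fraction ci, so the model has no mesophyll-conductance term; the two
#' branches meet at a sharp inflection point (see [inflection_ci()]).
#'
#' @param vpmax Apparent maximum PEPC carboxylation rate, µmol m^-2 s^-1.
#' @param vmax CO2-saturated asymptote of the A/ci curve, µmol m^-2 s^-1.
#' @param kp Michaelis constant of PEPC for CO2, µmol mol^-1. Default 80,
#'   a typical C4 literature value.
#' @param rd Day respiration, µmol m^-2 s^-1 (>= 0). Default 2.
#' @return An object of class `c4_params` (a named list).
#' @examples
#' p <- c4_params(vpmax = 120, vmax = 45)
#' predict_a(c(40, 80, 400), p)
#' @export
c4_params <- function(vpmax, vmax, kp = 80, rd = 2) {
  stopifnot(is.numeric(vpmax), is.numeric(vmax), is.numeric(kp), is.numeric(rd))
  if (vpmax <= 0) stop("`vpmax` must be positive", call. = FALSE)
  if (vmax <= 0) stop("`vmax` must be positive", call. = FALSE)
  if (kp <= 0) stop("`kp` must be positive", call. = FALSE)
  if (rd < 0) stop("`rd` must be non-negative", call. = FALSE)
  structure(
    list(vpmax = as.numeric(vpmax), vmax = as.numeric(vmax),
         kp = as.numeric(kp), rd = as.numeric(rd)),
    class = "c4_params"
  )
}

#' @export
print.c4_params <- function(x, ...) {
  cat(sprintf(
    "<c4_params> vpmax = %.4g, vmax = %.4g, kp = %.4g, rd = %.4g (umol m-2 s-1 / umol mol-1)\n",
    x$vpmax, x$vmax, x$kp, x$rd
  ))
  invisible(x)
}

as_c4_params <- function(x) {
  if (inherits(x, "c4_params")) return(x)
  c4_params(x[["vpmax"]], x[["vmax"]], x[["kp"]], x[["rd"]])
}

#' Predict net CO2 assimilation from intercellular CO2
#'
#' Forward (demand) side of the C4 model: the PEPC-limited hyperbola at low
#' ci and the flat CO2-saturated branch at high ci, minus day respiration.
#' The function is continuous, non-decreasing in `ci`, and exactly equal to
#' `vmax - rd` for all ci at or above the inflection point.
#'
#' @param ci Intercellular CO2 mole fraction(s), µmol mol^-1 (>= 0).
#' @param params A [c4_params()] object.
#' @return Net assimilation, µmol m^-2 s^-1, same length as `ci`.
#' @seealso [inflection_ci()], [solve_operating_point()]
#' @export
predict_a <- function(ci, params) {
  params <- as_c4_params(params)
  if (any(!is.finite(ci)) || any(ci < 0)) {
    stop("`ci` must be finite and non-negative", call. = FALSE)
  }
  pepc <- params$vpmax * ci / (ci + params$kp)
  pmin(pepc, params$vmax) - params$rd
}

#' Intercellular CO2 at the A/ci inflection point
#'
#' The ci at which the PEPC-limited branch meets the saturated asymptote,
#' i.e. the solution of `vpmax * ci / (ci + kp) = vmax`:
#' `ci* = vmax * kp / (vpmax - vmax)`. Only finite when `vpmax > vmax`.
#'
#' @inheritParams predict_a
#' @return ci*, µmol mol^-1.
#' @export
inflection_ci <- function(params) {
  params <- as_c4_params(params)
  if (params$vpmax <= params$vmax) {
    stop("no finite inflection: vpmax must exceed vmax", call. = FALSE)
  }
  params$vmax * params$kp / (params$vpmax - params$vmax)
}

#' Solve the stomatal supply-demand operating point
#'
#' Finds the (ci, A) pair at which CO2 demand by photosynthesis,
#' `predict_a(ci)`, equals diffusive supply through stomata,
#' `gs_co2 * (ca - ci)`. Demand is non-decreasing and supply strictly
#' decreasing in ci, so the crossing is unique. This is the leaf's operating
#' point at ambient CO2 under its actual stomatal conductance.
#'
#' `gs_co2` is the stomatal conductance to CO2; divide a water-vapour
#' conductance by 1.6 (see [gs_h2o_to_co2()]).
#'
#' @param gs_co2 Stomatal conductance to CO2, mol m^-2 s^-1 (> 0).
#' @param ca Ambient (cuvette sample) CO2, µmol mol^-1 (> 0).
#' @inheritParams predict_a
#' @param tol Absolute residual tolerance on |supply - demand|.
#' @return A one-row tibble with `ci_op`, `a_op`, `source` (`"solved"`), and
#'   `positive` (FALSE when the solution sits at or below the CO2
#'   compensation level, i.e. `a_op <= 0`).
#' @examples
#' solve_operating_point(0.125, 400, c4_params(120, 45))
#' @export
solve_operating_point <- function(gs_co2, ca, params, tol = 1e-10) {
  params <- as_c4_params(params)
  stopifnot(length(gs_co2) == 1, length(ca) == 1)
  if (!is.finite(gs_co2) || gs_co2 <= 0) stop("`gs_co2` must be positive", call. = FALSE)
  if (!is.finite(ca) || ca <= 0) stop("`ca` must be positive", call. = FALSE)

  # saturated branch admits a closed form: A = vmax - rd, ci = ca - A/gs
  a_sat <- params$vmax - params$rd
  ci_sat <- ca - a_sat / gs_co2
  on_sat <- params$vpmax > params$vmax &&
    ci_sat >= inflection_ci(params) && ci_sat > 0
  if (on_sat) {
    ci_op <- ci_sat
    a_op <- a_sat
  } else {
    f <- function(ci) gs_co2 * (ca - ci) - predict_a(ci, params)
    upper <- max(ca, ca + (params$rd + params$vmax) / gs_co2)
    root <- stats::uniroot(f, lower = 1e-12, upper = upper,
                           extendInt = "downX", tol = min(tol, 1e-12))
    # polish by bisection until the residual meets the requested tolerance
    lo <- max(root$root - 10 * root$estim.prec, 1e-12)
    hi <- root$root + 10 * root$estim.prec
    for (i in seq_len(200)) {
      mid <- (lo + hi) / 2
      if (abs(f(mid)) <= tol || (hi - lo) < 1e-14) break
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    ci_op <- mid
    a_op <- predict_a(ci_op, params)
  }
  tibble::tibble(
    ci_op = ci_op,
    a_op = a_op,
    source = "solved",
    positive = a_op > 0
  )
}

#' Convert water-vapour stomatal conductance to CO2 conductance
#'
#' Divides by 1.6, the ratio of diffusivities of water vapour and CO2 in air.
#' Gas-exchange systems report gs for water vapour; the supply function in
#' [solve_operating_point()] needs the CO2 conductance.
#'
#' @param gs_h2o Stomatal conductance to water vapour, mol m^-2 s^-1.
#' @return Stomatal conductance to CO2, mol m^-2 s^-1.
#' @export
gs_h2o_to_co2 <- function(gs_h2o) gs_h2o / 1.6

#' Stomatal limitation and related summaries at an operating point
#'
#' Stomatal limitation (SL) is the fractional shortfall of assimilation at
#' the operating point relative to a theoretical leaf with no diffusive
#' resistance to CO2 entry (ci equal to the atmospheric ca):
#' `SL = (A(ca) - A(ci_op)) / A(ca)`. Both A values are evaluated on the
#' fitted model curve, so measurement noise cannot drive SL negative; the
#' only way to obtain a negative value is `ci_op > ca`, in which case SL is
#' clipped to 0 with a warning.
#'
#' @param ci_op Operating-point intercellular CO2, µmol mol^-1. Either a
#'   number or a one-row tibble from [solve_operating_point()].
#' @inheritParams solve_operating_point
#' @param gs Optional stomatal conductance to water vapour at the operating
#'   point; when supplied, intrinsic water-use efficiency `A/gs` is filled in.
#' @return A one-row tibble: `sl`, `ci_inflection`, `ci_op`, `a_op`,
#'   `above_inflection`, `iwue` (NA unless `gs` given).
#' @export
stomatal_limitation <- function(ci_op, params, ca, gs = NULL) {
  params <- as_c4_params(params)
  if (is.data.frame(ci_op)) ci_op <- ci_op$ci_op
  stopifnot(length(ci_op) == 1, length(ca) == 1)
  if (ci_op <= 0) stop("`ci_op` must be positive", call. = FALSE)
  a_ca <- predict_a(ca, params)
  if (a_ca <= 0) {
    stop("SL undefined at or below compensation: predicted A at ci = ca is not positive",
         call. = FALSE)
  }
  a_op <- predict_a(ci_op, params)
  sl <- (a_ca - a_op) / a_ca
  if (ci_op > ca && sl < 0) {
    warning("operating ci exceeds ca; clipping SL to 0", call. = FALSE)
    sl <- 0
  }
  ci_star <- if (params$vpmax > params$vmax) inflection_ci(params) else Inf
  tibble::tibble(
    sl = sl,
    ci_inflection = ci_star,
    ci_op = ci_op,
    a_op = a_op,
    above_inflection = ci_op >= ci_star,
    iwue = if (is.null(gs)) NA_real_ else iwue(a_op, gs)
  )
}

#' Intrinsic water-use efficiency
#'
#' The ratio of net CO2 assimilation to stomatal conductance to water vapour,
#' `A_N / g_s`, in µmol CO2 per mol H2O. Higher values mean more carbon fixed
#' per unit of water-vapour conductance.
#'
#' @param a_n Net assimilation, µmol m^-2 s^-1.
#' @param gs Stomatal conductance to water vapour, mol m^-2 s^-1 (> 0).
#' @return iWUE, µmol mol^-1; vectorised.
#' @export
iwue <- function(a_n, gs) {
  if (any(!is.finite(gs)) || any(gs <= 0)) {
    stop("`gs` must be positive", call. = FALSE)
  }
  a_n / gs
}
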