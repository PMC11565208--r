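#' Fit configuration for A/ci curve estimation
#'
#' Controls which parameters are free, the fixed-constant values used for
#' parameters that are not, and the multistart/convergence behaviour of
#' [fit_aci()].
#'
#' @param free Character vector of free parameters; `"vpmax"` and `"vmax"`
#'   are always free, `"rd"` optionally so. Default all three.
#' @param kp Fixed Michaelis constant of PEPC for CO2, µmol mol^-1.
#' @param rd Day respiration used when `"rd"` is not free, µmol m^-2 s^-1.
#' @param multistart Number of deterministic perturbation starts around the
#'   initial guess (>= 1). Starts are a fixed grid of scale factors, so fits
#'   are reproducible without any random draws.
#' @param tol Relative tolerance on the residual sum of squares used to
#'   declare convergence.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(free = c("vpmax", "vmax", "rd"), kp = 80, rd = 2,
                       multistart = 5, tol = 1e-10) {
  free <- match.arg(free, c("vpmax", "vmax", "rd"), several.ok = TRUE)
  if (!all(c("vpmax", "vmax") %in% free)) {
    stop("`vpmax` and `vmax` must always be free", call. = FALSE)
  }
  stopifnot(kp > 0, rd >= 0, multistart >= 1, tol > 0)
  structure(
    list(free = free, kp = kp, rd = rd,
         multistart = as.integer(multistart), tol = tol),
    class = "fit_config"
  )
}

# parameter box constraints used by fit_aci
.aci_bounds <- list(
  vpmax = c(1e-6, 500),
  vmax = c(1e-6, 200),
  rd = c(0, 10)
)

#' Check a measured A/ci curve against the stepped-CO2 protocol
#'
#' The measurement protocol steps the cuvette CO2 through
#' 400, 200, 50, 150, 300, 400, 500, 600, 700, 800, 1200 µmol mol^-1 after
#' full induction at 400. This validates the recorded `ca_sample` sequence
#' against that protocol (5% per-step tolerance), warns on missing or extra
#' steps, and flags drift when net assimilation at the second 400 step
#' differs from the first by more than 10%.
#'
#' @param curve Data frame of one curve, ordered by step, with at least
#'   `ca_sample` and `a_n` columns.
#' @param steps Reference protocol, µmol mol^-1.
#' @param tol_step Relative tolerance per step.
#' @return `TRUE` (invisibly `FALSE` when the sequence does not match);
#'   problems are signalled as warnings so curves are never discarded here.
#' @export
validate_protocol <- function(curve,
                              steps = c(400, 200, 50, 150, 300, 400, 500,
                                        600, 700, 800, 1200),
                              tol_step = 0.05) {
  if (is.null(curve) || nrow(curve) == 0) {
    stop("empty curve: no CO2 steps to validate", call. = FALSE)
  }
  ca <- curve$ca_sample
  ok <- TRUE
  n <- min(length(ca), length(steps))
  mism <- abs(ca[seq_len(n)] - steps[seq_len(n)]) > tol_step * steps[seq_len(n)]
  if (any(mism)) {
    ok <- FALSE
    warning(sprintf("CO2 steps deviate >%g%% from the protocol at positions: %s",
                    100 * tol_step, paste(which(mism), collapse = ", ")),
            call. = FALSE)
  }
  if (length(ca) < length(steps)) {
    ok <- FALSE
    warning(sprintf("curve has %d of %d protocol steps (missing steps)",
                    length(ca), length(steps)), call. = FALSE)
  } else if (length(ca) > length(steps)) {
    warning(sprintf("curve has %d extra step(s) beyond the protocol",
                    length(ca) - length(steps)), call. = FALSE)
  }
  # drift check between the two 400 steps (induction stability)
  i400 <- which(abs(ca - 400) <= tol_step * 400)
  if (length(i400) >= 2 && !is.null(curve$a_n)) {
    a1 <- curve$a_n[i400[1]]
    a2 <- curve$a_n[i400[2]]
    if (is.finite(a1) && a1 != 0 && abs(a2 - a1) > 0.1 * abs(a1)) {
      warning(sprintf(
        "assimilation drifted %.1f%% between repeated 400 steps",
        100 * (a2 - a1) / a1), call. = FALSE)
    }
  }
  invisible(ok)
}

#' Initial parameter guess for an A/ci fit
#'
#' `vmax0` is the maximum observed assimilation plus respiration; `vpmax0`
#' comes from the slope between the two lowest-ci points, inverted through
#' the PEPC hyperbola at the fixed `kp` (the slope between ci1 and ci2 on the
#' hyperbola is `vpmax * kp / ((ci1 + kp)(ci2 + kp))`). A non-positive slope
#' falls back to `vpmax0 = 2 * vmax0`.
#'
#' @param curve Data frame with `ci` and `a_n` columns (>= 3 points).
#' @param kp,rd Fixed constants used in the inversion.
#' @return A [c4_params()] object.
#' @export
initial_guess <- function(curve, kp = 80, rd = 2) {
  if (nrow(curve) < 3) stop("need at least 3 points for an initial guess", call. = FALSE)
  ord <- order(curve$ci)
  ci <- curve$ci[ord]
  a <- curve$a_n[ord]
  vmax0 <- max(a) + rd
  if (vmax0 <= 0) vmax0 <- 1
  slope <- (a[2] - a[1]) / (ci[2] - ci[1])
  if (is.finite(slope) && slope > 0) {
    vpmax0 <- slope * (ci[1] + kp) * (ci[2] + kp) / kp
  } else {
    vpmax0 <- 2 * vmax0
  }
  clamp <- function(x, b) min(max(x, b[1]), b[2])
  c4_params(
    vpmax = clamp(vpmax0, .aci_bounds$vpmax),
    vmax = clamp(vmax0, .aci_bounds$vmax),
    kp = kp,
    rd = clamp(rd, .aci_bounds$rd)
  )
}

# Residual sum of squares of the piecewise model on a curve.
.aci_rss <- function(par, ci, a, kp) {
  pred <- pmin(par[["vpmax"]] * ci / (ci + kp), par[["vmax"]]) - par[["rd"]]
  sum((a - pred)^2)
}

# One conditional linear least-squares pass: given a branch assignment
# (PEPC-limited vs saturated), the model is linear in (vpmax, vmax, rd).
# Iterating assignment -> LLS converges to a local optimum of the piecewise
# objective; exact on noiseless data.
.aci_lls_iterate <- function(start, ci, a, kp, free_rd, rd_fixed, max_iter = 100) {
  x <- ci / (ci + kp)
  vpmax <- start$vpmax
  vmax <- start$vmax
  rd <- if (free_rd) start$rd else rd_fixed
  prev_assign <- NULL
  clamp <- function(v, b) min(max(v, b[1]), b[2])
  for (iter in seq_len(max_iter)) {
    branch1 <- vpmax * x < vmax
    if (!any(branch1)) branch1[which.min(ci)] <- TRUE  # keep vpmax estimable
    cols <- list(ifelse(branch1, x, 0), ifelse(branch1, 0, 1))
    if (free_rd) cols <- c(cols, list(rep(-1, length(ci))))
    X <- do.call(cbind, cols)
    y <- if (free_rd) a else a + rd_fixed
    est_vmax <- any(!branch1)
    if (!est_vmax) X <- X[, -2, drop = FALSE]
    beta <- tryCatch(qr.solve(X, y), error = function(e) NULL)
    if (is.null(beta)) break
    k <- 1
    vpmax <- clamp(beta[k], .aci_bounds$vpmax); k <- k + 1
    if (est_vmax) { vmax <- clamp(beta[k], .aci_bounds$vmax); k <- k + 1 }
    if (free_rd) rd <- clamp(beta[k], .aci_bounds$rd)
    if (!est_vmax) vmax <- clamp(max(vpmax * x) + 1e-9, .aci_bounds$vmax)
    if (!is.null(prev_assign) && identical(branch1, prev_assign)) break
    prev_assign <- branch1
  }
  par <- c(vpmax = vpmax, vmax = vmax, rd = rd)
  list(par = par, rss = .aci_rss(par, ci, a, kp))
}

#' Fit the C4 A/ci model to one response curve
#'
#' Least-squares estimation of `vpmax` and `vmax` (and optionally `rd`) with
#' `kp` fixed, by minimising \eqn{\sum (a_n - A(c_i))^2} over the piecewise
#' model of [predict_a()]. Because the model is linear in the parameters once
#' each point is assigned to the PEPC-limited or saturated branch, the fit
#' alternates branch assignment with exact linear least squares, from a
#' deterministic grid of multistart perturbations around [initial_guess()],
#' followed by a Nelder-Mead polish of the best candidate. Repeated CO2
#' steps (the protocol measures 400 twice) are retained as data points, and
#' the result does not depend on the ordering of the points.
#'
#' `identifiable_vmax` is `FALSE` when fewer than two points lie on the
#' saturated branch of the fitted curve (the observed ci effectively never
#' cross the inflection); `vmax` is then only a lower bound and is excluded
#' from group summaries downstream.
#'
#' @param curve Data frame with `ci` and `a_n` columns for a single curve.
#' @param config A [fit_config()].
#' @return An object of class `aci_fit`: list with `params` ([c4_params()]),
#'   `rss`, `n_points`, `converged`, `identifiable_vmax`, `residuals`,
#'   `config`, and the fitted `curve`.
#' @examples
#' p <- c4_params(120, 45)
#' ci <- c(7, 20, 35, 60, 120, 250, 500, 900)
#' fit <- fit_aci(data.frame(ci = ci, a_n = predict_a(ci, p)))
#' tidy(fit)
#' @export
fit_aci <- function(curve, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  curve <- curve[is.finite(curve$ci) & is.finite(curve$a_n), , drop = FALSE]
  if (nrow(curve) < 3) stop("need at least 3 valid points to fit", call. = FALSE)
  if (nrow(curve) < 4) {
    warning("fewer than 4 points: fit is minimally determined", call. = FALSE)
  }
  ord <- order(curve$ci, curve$a_n)  # order-invariance
  ci <- curve$ci[ord]
  a <- curve$a_n[ord]
  free_rd <- "rd" %in% config$free
  kp <- config$kp

  g <- initial_guess(curve, kp = kp, rd = config$rd)
  # fixed perturbation-factor grid (no RNG): scales on (vpmax, vmax)
  scales <- list(c(1, 1), c(0.6, 0.9), c(1.8, 1.1), c(3, 1), c(0.4, 0.7),
                 c(1.2, 0.8), c(2.2, 0.95), c(0.8, 1.2))
  scales <- scales[seq_len(min(config$multistart, length(scales)))]
  clamp <- function(v, b) min(max(v, b[1]), b[2])
  cands <- lapply(scales, function(s) {
    start <- list(vpmax = clamp(g$vpmax * s[1], .aci_bounds$vpmax),
                  vmax = clamp(g$vmax * s[2], .aci_bounds$vmax),
                  rd = g$rd)
    .aci_lls_iterate(start, ci, a, kp, free_rd, config$rd)
  })
  best <- cands[[which.min(vapply(cands, `[[`, numeric(1), "rss"))]]

  # Nelder-Mead polish on the raw piecewise objective
  par0 <- best$par
  if (!free_rd) par0 <- par0[c("vpmax", "vmax")]
  obj <- function(p) {
    full <- c(vpmax = clamp(p[1], .aci_bounds$vpmax),
              vmax = clamp(p[2], .aci_bounds$vmax),
              rd = if (free_rd) clamp(p[3], .aci_bounds$rd) else config$rd)
    .aci_rss(full, ci, a, kp)
  }
  opt <- stats::optim(unname(par0), obj, method = "Nelder-Mead",
                      control = list(reltol = config$tol, maxit = 2000))
  polished <- c(vpmax = clamp(opt$par[1], .aci_bounds$vpmax),
                vmax = clamp(opt$par[2], .aci_bounds$vmax),
                rd = if (free_rd) clamp(opt$par[3], .aci_bounds$rd) else config$rd)
  rss_polished <- .aci_rss(polished, ci, a, kp)
  if (rss_polished < best$rss) {
    # re-run the exact LLS pass from the polished point
    best <- .aci_lls_iterate(as.list(polished), ci, a, kp, free_rd, config$rd)
    if (rss_polished < best$rss) best <- list(par = polished, rss = rss_polished)
  }

  par <- best$par
  params <- c4_params(par[["vpmax"]], par[["vmax"]], kp, par[["rd"]])
  pred <- predict_a(ci, params)
  sat <- params$vpmax * ci / (ci + kp) >= params$vmax
  # a single saturated point can be a noise artefact of the kink placement;
  # require the asymptote to be supported by at least two points
  identifiable <- sum(sat) >= 2 && params$vpmax > params$vmax
  structure(
    list(
      params = params,
      rss = best$rss,
      n_points = length(ci),
      converged = opt$convergence == 0,
      identifiable_vmax = identifiable,
      residuals = a - pred,
      config = config,
      curve = tibble::tibble(ci = ci, a_n = a, fitted = pred)
    ),
    class = "aci_fit"
  )
}

#' @export
print.aci_fit <- function(x, ...) {
  cat(sprintf(
    "<aci_fit> n = %d, vpmax = %.3f, vmax = %.3f%s, rd = %.3f, rss = %.4g%s\n",
    x$n_points, x$params$vpmax, x$params$vmax,
    if (x$identifiable_vmax) "" else " (not identifiable)",
    x$params$rd, x$rss,
    if (x$converged) "" else " [not converged]"
  ))
  invisible(x)
}

#' Fit A/ci curves for every plant in a gas-exchange table
#'
#' Applies [fit_aci()] per `plant_id` and returns one row per plant with the
#' estimates, fit diagnostics, and the fit object in a list column.
#'
#' @param data Gas-exchange table with columns `plant_id`, `genotype`, `ci`,
#'   `a_n` (extra columns are ignored for fitting).
#' @inheritParams fit_aci
#' @return A tibble with columns `plant_id`, `genotype`, `vpmax`, `vmax`,
#'   `rd`, `kp`, `rss`, `n_points`, `converged`, `identifiable_vmax`, `fit`.
#' @export
fit_aci_curves <- function(data, config = fit_config()) {
  stopifnot(all(c("plant_id", "ci", "a_n") %in% names(data)))
  if (!"genotype" %in% names(data)) data$genotype <- NA_character_
  data |>
    dplyr::group_by(.data$plant_id, .data$genotype) |>
    tidyr::nest() |>
    dplyr::ungroup() |>
    dplyr::mutate(fit = purrr::map(.data$data, fit_aci, config = config)) |>
    dplyr::mutate(
      vpmax = purrr::map_dbl(.data$fit, ~ .x$params$vpmax),
      vmax = purrr::map_dbl(.data$fit, ~ .x$params$vmax),
      rd = purrr::map_dbl(.data$fit, ~ .x$params$rd),
      kp = purrr::map_dbl(.data$fit, ~ .x$params$kp),
      rss = purrr::map_dbl(.data$fit, "rss"),
      n_points = purrr::map_int(.data$fit, "n_points"),
      converged = purrr::map_lgl(.data$fit, "converged"),
      identifiable_vmax = purrr::map_lgl(.data$fit, "identifiable_vmax")
    ) |>
    dplyr::select(-"data")
}

#' Pointwise mean fitted curve with standard errors
#'
#' Evaluates each replicate fit on a common ci grid and returns the
#' pointwise mean and standard error of the predicted assimilation, the
#' quantities drawn as the mean fit line and its shaded SE band.
#'
#' @param fits List of `aci_fit` objects (or a [fit_aci_curves()] tibble with
#'   a `fit` column).
#' @param ci_grid Numeric vector of ci values, µmol mol^-1.
#' @return Tibble with `ci`, `a_mean`, `a_se`, `n`. With a single fit the SE
#'   is reported as 0 with a warning.
#' @export
mean_curve_with_se <- function(fits, ci_grid = seq(0, 1200, by = 10)) {
  if (is.data.frame(fits)) fits <- fits$fit
  if (length(fits) == 0) stop("no fits supplied", call. = FALSE)
  preds <- vapply(fits, function(f) predict_a(ci_grid, f$params),
                  numeric(length(ci_grid)))
  preds <- matrix(preds, nrow = length(ci_grid))
  n <- length(fits)
  if (n == 1) {
    warning("single fit: SE undefined, reported as 0", call. = FALSE)
    se <- rep(0, length(ci_grid))
  } else {
    se <- apply(preds, 1, stats::sd) / sqrt(n)
  }
  tibble::tibble(
    ci = ci_grid,
    a_mean = rowMeans(preds),
    a_se = se,
    n = n
  )
}
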