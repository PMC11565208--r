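#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an A/ci fit into one row per parameter
#'
#' @param x An `aci_fit` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `fixed` (TRUE for constants that
#'   were not free in the fit).
#' @method tidy aci_fit
#' @export
tidy.aci_fit <- function(x, ...) {
  free <- x$config$free
  tibble::tibble(
    term = c("vpmax", "vmax", "kp", "rd"),
    estimate = c(x$params$vpmax, x$params$vmax, x$params$kp, x$params$rd),
    fixed = !c("vpmax", "vmax", "kp", "rd") %in% free
  )
}

#' One-row summary of an A/ci fit
#'
#' @param x An `aci_fit` object.
#' @param ... Unused.
#' @return Tibble with `rss`, `sigma` (residual SD), `n_points`,
#'   `converged`, `identifiable_vmax`.
#' @method glance aci_fit
#' @export
glance.aci_fit <- function(x, ...) {
  n_free <- length(x$config$free)
  tibble::tibble(
    rss = x$rss,
    sigma = sqrt(x$rss / max(x$n_points - n_free, 1)),
    n_points = x$n_points,
    converged = x$converged,
    identifiable_vmax = x$identifiable_vmax
  )
}

#' Tidy a Tukey HSD result into one row per comparison
#'
#' @param x A `tukey_hsd` object.
#' @param ... Unused.
#' @return The comparisons tibble (`group1`, `group2`, `diff`, `q`, `p.adj`,
#'   `significant`).
#' @method tidy tukey_hsd
#' @export
tidy.tukey_hsd <- function(x, ...) x$comparisons

#' One-row summary of a Tukey HSD result
#'
#' @param x A `tukey_hsd` object.
#' @param ... Unused.
#' @return Tibble with `n_groups`, `ms_within`, `df_resid`, `alpha`,
#'   `n_significant`.
#' @method glance tukey_hsd
#' @export
glance.tukey_hsd <- function(x, ...) {
  tibble::tibble(
    n_groups = nrow(x$groups),
    ms_within = x$ms_within,
    df_resid = x$df_resid,
    alpha = x$alpha,
    n_significant = sum(x$comparisons$significant)
  )
}
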