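#' Average technical subsamples into one value per replicate plant
#'
#' Where several subsamples are measured within a replicate plant (e.g. four
#' fields of view per leaf), the plain mean over subsamples is taken and the
#' per-plant average becomes the single input row for every downstream
#' statistical test, regardless of subsample count.
#'
#' @param data Data frame of raw rows.
#' @param response Name of the response column (string).
#' @param keys Character vector of columns identifying the replicate plant
#'   and any within-plant cell (e.g. `c("plant_id", "genotype", "surface")`).
#' @return Tibble with one row per unique key combination and the averaged
#'   response.
#' @export
average_subsamples <- function(data, response, keys) {
  stopifnot(response %in% names(data), all(keys %in% names(data)))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      "{response}" := mean(.data[[response]]),
      .groups = "drop"
    )
}

.check_factor <- function(data, response, factor, min_levels = 2) {
  stopifnot(response %in% names(data), factor %in% names(data))
  f <- as.factor(data[[factor]])
  tab <- table(f)
  if (any(tab == 0)) {
    stop(sprintf("factor `%s` has level(s) with no observations: %s", factor,
                 paste(names(tab)[tab == 0], collapse = ", ")), call. = FALSE)
  }
  if (nlevels(f) < min_levels) {
    stop(sprintf("factor `%s` needs at least %d levels", factor, min_levels),
         call. = FALSE)
  }
  f
}

#' One-way analysis of variance
#'
#' Classical one-way decomposition via `lm()`, returned as a tidy table with
#' one row per term (factor and residuals).
#'
#' @param data Data frame.
#' @param response,factor Column names (strings).
#' @return Tibble with columns `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value`.
#' @export
one_way_anova <- function(data, response, factor) {
  f <- .check_factor(data, response, factor)
  d <- data.frame(y = data[[response]], g = droplevels(f))
  if (nrow(d) - nlevels(d$g) < 1) {
    stop("residual degrees of freedom must be at least 1", call. = FALSE)
  }
  a <- stats::anova(stats::lm(y ~ g, data = d))
  tibble::tibble(
    term = c(factor, "Residuals"),
    df = a$Df,
    sumsq = a$`Sum Sq`,
    meansq = a$`Mean Sq`,
    statistic = a$`F value`,
    p.value = a$`Pr(>F)`
  )
}

#' Two-way factorial analysis of variance
#'
#' Fully factorial two-way ANOVA with optional interaction. Effects are
#' sum-to-zero coded and tested with partial (Type-III) sums of squares, so
#' unbalanced tables are handled; on balanced data the partial SS coincide
#' with the classical sequential decomposition term by term.
#'
#' @param data Data frame.
#' @param response,factor_a,factor_b Column names (strings).
#' @param interaction Include the A:B interaction term (default TRUE).
#' @return Tibble with columns `term`, `df`, `sumsq`, `meansq`, `statistic`,
#'   `p.value`.
#' @export
two_way_anova <- function(data, response, factor_a, factor_b,
                          interaction = TRUE) {
  fa <- .check_factor(data, response, factor_a)
  fb <- .check_factor(data, response, factor_b)
  d <- data.frame(y = data[[response]], A = droplevels(fa), B = droplevels(fb))
  if (interaction) {
    cells <- table(d$A, d$B)
    if (any(cells == 0)) {
      stop("empty cell(s) in the A x B design: interaction not estimable",
           call. = FALSE)
    }
  }
  form <- if (interaction) y ~ A * B else y ~ A + B
  # partial (Type-III) SS with sum-to-zero coding: for each term, the rise in
  # RSS when that term's columns are dropped from the full design matrix
  mm <- stats::model.matrix(form, d,
                            contrasts.arg = list(A = "contr.sum",
                                                 B = "contr.sum"))
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(form), "term.labels")
  fit_full <- stats::lm.fit(mm, d$y)
  rss_full <- sum(fit_full$residuals^2)
  df_resid <- nrow(d) - ncol(mm)
  if (df_resid < 1) stop("residual degrees of freedom must be at least 1", call. = FALSE)
  mse <- rss_full / df_resid
  rows <- purrr::map_dfr(seq_along(labels), function(ti) {
    reduced <- stats::lm.fit(mm[, asgn != ti, drop = FALSE], d$y)
    ss <- max(sum(reduced$residuals^2) - rss_full, 0)
    df_t <- sum(asgn == ti)
    tibble::tibble(term = labels[ti], df = df_t, sumsq = ss,
                   meansq = ss / df_t, statistic = (ss / df_t) / mse)
  })
  term_map <- c(A = factor_a, B = factor_b,
                `A:B` = paste0(factor_a, ":", factor_b))
  rows$term <- unname(term_map[rows$term])
  rows$p.value <- stats::pf(rows$statistic, rows$df, df_resid,
                            lower.tail = FALSE)
  dplyr::bind_rows(
    rows,
    tibble::tibble(term = "Residuals", df = df_resid, sumsq = rss_full,
                   meansq = mse, statistic = NA_real_, p.value = NA_real_)
  )
}

#' Repeated-measures (split-plot-in-time) analysis of variance
#'
#' Univariate repeated-measures ANOVA for a design with one between-subjects
#' factor (e.g. genotype) and one within-subjects factor (e.g. day of the
#' dry-down). The between factor is tested against the subject-within-group
#' mean square; the within factor and the interaction are tested against the
#' residual. Every subject must be observed at every within level.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param between,within Factor column names (strings).
#' @param subject Subject identifier column name.
#' @return Tibble with columns `term`, `stratum`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`.
#' @export
repeated_measures_anova <- function(data, response, between, within, subject) {
  fb <- .check_factor(data, response, between)
  fw <- .check_factor(data, response, within)
  stopifnot(subject %in% names(data))
  d <- data.frame(
    y = data[[response]],
    B = droplevels(fb),
    W = droplevels(fw),
    S = factor(data[[subject]])
  )
  grid <- table(d$S, d$W)
  if (any(grid != 1)) {
    stop("incomplete design: every subject must be observed exactly once at every within level",
         call. = FALSE)
  }
  m <- stats::aov(y ~ B * W + Error(S), data = d)
  s <- summary(m)
  sub <- as.data.frame(s[["Error: S"]][[1]])
  wit <- as.data.frame(s[["Error: Within"]][[1]])
  row_tbl <- function(tab, stratum) {
    tibble::tibble(
      term = trimws(rownames(tab)),
      stratum = stratum,
      df = tab$Df,
      sumsq = tab$`Sum Sq`,
      meansq = tab$`Mean Sq`,
      statistic = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
      p.value = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_
    )
  }
  out <- dplyr::bind_rows(row_tbl(sub, "subject"), row_tbl(wit, "within"))
  out$term <- sub("^B:W$", paste0(between, ":", within),
                  sub("^W$", within, sub("^B$", between, out$term)))
  out
}

#' Tukey honestly-significant-difference test
#'
#' All pairwise comparisons after a one-way ANOVA. For groups i and j the
#' studentized-range statistic is
#' \deqn{q = |\bar y_i - \bar y_j| / \sqrt{\frac{MS_W}{2}(1/n_i + 1/n_j)}}
#' with the adjusted p-value from the studentized-range distribution
#' (`ptukey`) at the number of groups and the residual df. A compact-letter
#' display is built greedily from the pairwise significance matrix: groups
#' sharing a letter are not significantly different at `alpha`.
#'
#' @inheritParams one_way_anova
#' @param alpha Familywise significance level for flags and letters.
#' @return An object of class `tukey_hsd`: list with `comparisons` (tibble:
#'   `group1`, `group2`, `diff`, `q`, `p.adj`, `significant`), `groups`
#'   (tibble: `group`, `mean`, `n`, `letters`), `ms_within`, `df_resid`,
#'   `alpha`.
#' @export
tukey_hsd <- function(data, response, factor, alpha = 0.05) {
  f <- .check_factor(data, response, factor)
  y <- data[[response]]
  g <- droplevels(f)
  k <- nlevels(g)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  df_resid <- length(y) - k
  if (df_resid < 1) stop("residual degrees of freedom must be at least 1", call. = FALSE)
  msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_resid
  pairs <- utils::combn(levels(g), 2)
  comp <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    diff <- means[[g1]] - means[[g2]]
    se <- sqrt(msw / 2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    q <- if (se > 0) abs(diff) / se else if (diff == 0) 0 else Inf
    p <- stats::ptukey(q, nmeans = k, df = df_resid, lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, diff = diff, q = q, p.adj = p,
                   significant = p < alpha)
  })
  letters_tbl <- .letter_display(levels(g), means, comp)
  letters_tbl$n <- as.integer(ns[letters_tbl$group])
  structure(
    list(comparisons = comp,
         groups = letters_tbl[, c("group", "mean", "n", "letters")],
         ms_within = msw, df_resid = df_resid, alpha = alpha),
    class = "tukey_hsd"
  )
}

# Greedy compact-letter display: order groups by descending mean, find
# maximal runs with no significant internal pair, letter the non-nested runs.
.letter_display <- function(groups, means, comp) {
  ord <- order(-unlist(means[groups]))
  gs <- groups[ord]
  k <- length(gs)
  sig <- matrix(FALSE, k, k, dimnames = list(gs, gs))
  for (i in seq_len(nrow(comp))) {
    if (comp$significant[i]) {
      sig[comp$group1[i], comp$group2[i]] <- TRUE
      sig[comp$group2[i], comp$group1[i]] <- TRUE
    }
  }
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !any(sig[gs[i:(j + 1)], gs[i:(j + 1)]])) j <- j + 1
    runs[[length(runs) + 1]] <- i:j
  }
  # drop runs nested inside an earlier run
  keep <- vapply(seq_along(runs), function(r) {
    !any(vapply(runs[-r], function(o) all(runs[[r]] %in% o), logical(1)))
  }, logical(1))
  runs <- runs[keep]
  lab <- stats::setNames(rep("", k), gs)
  for (r in seq_along(runs)) {
    lab[runs[[r]]] <- paste0(lab[runs[[r]]], letters[r])
  }
  tibble::tibble(group = gs, mean = unlist(means[gs]), letters = unname(lab))
}

#' @export
print.tukey_hsd <- function(x, ...) {
  cat(sprintf("<tukey_hsd> %d groups, MSW = %.4g, df = %d, alpha = %g\n",
              nrow(x$groups), x$ms_within, x$df_resid, x$alpha))
  print(x$groups)
  invisible(x)
}

#' Least-squares means with standard errors
#'
#' Least-squares (model-adjusted) means per cell of the requested factors,
#' from a sum-to-zero-coded linear model containing all requested factors
#' and their interactions. On balanced designs these equal raw cell/marginal
#' means; on unbalanced designs a marginal lsmean is the unweighted average
#' of cell means, not the raw marginal mean.
#'
#' @param data Data frame.
#' @param response Response column name.
#' @param specs Character vector of factor column names to report means for
#'   (one entry gives marginal means of that factor from the full model).
#' @param model_factors Factors to include in the model; defaults to `specs`.
#' @return Tibble with the factor columns plus `lsmean`, `se`, `df`.
#' @export
lsmeans_se <- function(data, response, specs, model_factors = specs) {
  stopifnot(response %in% names(data), all(specs %in% names(data)),
            all(specs %in% model_factors))
  d <- data.frame(y = data[[response]])
  for (v in model_factors) d[[v]] <- factor(data[[v]])
  form <- stats::as.formula(paste("y ~", paste(model_factors, collapse = " * ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(model_factors)),
                           model_factors)
  m <- stats::lm(form, data = d, contrasts = contr)
  # emmeans notes that marginal means average over interactions; that is
  # exactly the convention wanted here, so the note is suppressed
  em <- suppressMessages(emmeans::emmeans(m, specs = specs))
  out <- tibble::as_tibble(as.data.frame(em))
  names(out)[names(out) == "emmean"] <- "lsmean"
  names(out)[names(out) == "SE"] <- "se"
  if (any(!is.finite(out$lsmean))) {
    stop("inestimable cell(s) in the requested least-squares means", call. = FALSE)
  }
  out[, c(specs, "lsmean", "se", "df")]
}

#' Planned contrast on group least-squares means
#'
#' Tests a linear contrast \eqn{\sum_i w_i \bar y_i} over the levels of one
#' factor, with the SE propagated from the residual mean square:
#' \eqn{SE = \sqrt{MS_W \sum_i w_i^2 / n_i}}; two-sided t test on the
#' residual df. Weights must sum to zero.
#'
#' @inheritParams one_way_anova
#' @param weights Numeric contrast weights, either named by factor level or
#'   in sorted level order; must sum to (numerically) zero.
#' @return One-row tibble: `estimate`, `se`, `statistic`, `df`, `p.value`.
#' @export
planned_contrast <- function(data, response, factor, weights) {
  f <- .check_factor(data, response, factor)
  g <- droplevels(f)
  y <- data[[response]]
  lev <- levels(g)
  if (!is.null(names(weights))) {
    if (!setequal(names(weights), lev)) {
      stop("contrast weight names must match the factor levels", call. = FALSE)
    }
    w <- weights[lev]
  } else {
    if (length(weights) != length(lev)) {
      stop("need one weight per factor level", call. = FALSE)
    }
    w <- stats::setNames(weights, lev)
  }
  if (abs(sum(w)) > 1e-8) stop("contrast weights must sum to zero", call. = FALSE)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  df_resid <- length(y) - length(lev)
  if (df_resid < 1) stop("residual degrees of freedom must be at least 1", call. = FALSE)
  msw <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_resid
  est <- sum(w * means[lev])
  se <- sqrt(msw * sum(w^2 / ns[lev]))
  t <- est / se
  tibble::tibble(
    estimate = est, se = se, statistic = t, df = df_resid,
    p.value = 2 * stats::pt(abs(t), df_resid, lower.tail = FALSE)
  )
}

#' Per-day group comparisons over a dry-down
#'
#' Runs an independent one-way ANOVA plus Tukey HSD on each day of a time
#' series and flags, per day and genotype pair, whether the groups differ at
#' `alpha`. No across-day multiplicity correction is applied (each day is an
#' independent family).
#'
#' @param data Data frame with a `day` column plus the response and factor.
#' @inheritParams one_way_anova
#' @param alpha Significance level per day.
#' @return Tibble with one row per day x pair: `day`, `group1`, `group2`,
#'   `diff`, `p.adj`, `significant`.
#' @export
per_day_tukey <- function(data, response, factor, alpha = 0.05) {
  stopifnot("day" %in% names(data))
  data |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(df, key) {
      tk <- tukey_hsd(df, response, factor, alpha = alpha)
      tk$comparisons[, c("group1", "group2", "diff", "p.adj", "significant")]
    }) |>
    dplyr::ungroup()
}
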