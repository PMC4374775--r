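#' Classify a double-reciprocal intersection pattern
#'
#' Fits a straight line to 1/v versus 1/S for each series (each fixed level
#' of the co-substrate) and classifies the family of the pattern:
#'
#' * `parallel` — a common-slope model is not rejected against per-series
#'   slopes (F-test at `parallel_alpha`);
#' * `intersecting_on_S_axis` — the series share a common intersection
#'   point whose ordinate is compatible with zero (the visual "intersects
#'   on the 1/S axis" judgement made quantitative);
#' * `intersecting_left_above` / `intersecting_left_below` — common
#'   intersection off the axis, by the sign of its ordinate;
#' * `ambiguous` — a common intersection point is rejected against
#'   unconstrained per-series lines, so no family is forced.
#'
#' A rapid-equilibrium random-order mechanism intersects on the 1/S axis at
#' x = -1/Ka; a ping-pong mechanism gives parallel lines; an ordered
#' mechanism with Kia != Ka intersects off-axis.
#'
#' Because reciprocal transformation makes constant-relative-error
#' velocities strongly heteroscedastic, all regressions are weighted by
#' v^2 (so the tests are calibrated for relative measurement error, the
#' usual error structure of coupled-assay velocities). The common-point
#' "pencil of lines" 1/v = y0 + m_k (1/S - x0) is fitted by least squares
#' with y0 free and with y0 fixed at 0; on-axis is called when the y0 = 0
#' constraint is not rejected (F-test at `axis_alpha`). On noiseless data
#' the tests are degenerate and deterministic tolerances take over:
#' relative slope spread below 1e-6 is parallel, and |y0| below `axis_tol`
#' times the smallest fitted 1/v intercept is on-axis.
#'
#' @param data Data frame with the varied-substrate concentration, the fixed
#'   co-substrate concentration and the velocity `v`.
#' @param varied Name of the varied-substrate column (default `"a"`).
#' @param fixed Name of the co-substrate column defining the series
#'   (default `"b"`).
#' @param axis_tol Deterministic relative tolerance for "on the 1/S axis"
#'   (default 0.05, of the smallest fitted 1/v intercept).
#' @param parallel_alpha Significance level of the common-slope F-test
#'   (default 0.01); slopes that fail to reject equality are parallel.
#' @param axis_alpha Significance level of the y0 = 0 F-test (default
#'   0.05).
#' @param ambiguity_alpha Significance level at which lack of fit of the
#'   common-point model downgrades the call to ambiguous (default 1e-3).
#' @return A `pk_pattern` object: `family`, `intersection` (common point
#'   x0, y0), `dispersion` (weighted spread of the pairwise
#'   intersections, as a diagnostic), per-series `lines`, and the settings
#'   used.
#' @examples
#' d <- make_velocity_dataset("random_re",
#'        params = c(vmax = 183, ka = 0.38, kb = 0.16),
#'        design = design_initial_velocity(), noise = noise_model(scale = 0))
#' double_reciprocal_pattern(d)  # intersecting_on_S_axis, x ~ -1/0.38
#' @export
double_reciprocal_pattern <- function(data, varied = "a", fixed = "b",
                                      axis_tol = 0.05, parallel_alpha = 0.01,
                                      axis_alpha = 0.05,
                                      ambiguity_alpha = 1e-3) {
  data <- tibble::as_tibble(data)
  if (!all(c(varied, fixed, "v") %in% names(data))) {
    abort(paste0("`data` needs columns ", varied, ", ", fixed, ", v"))
  }
  if (any(data$v <= 0)) abort("velocities must be positive in reciprocal space")
  series_f <- factor(data[[fixed]])
  if (nlevels(series_f) < 3) abort("need >= 3 series at distinct co-substrate levels")
  series <- split(data, series_f)
  if (any(vapply(series, function(d) dplyr::n_distinct(d[[varied]]), 1L) < 4)) {
    abort("each series needs >= 4 distinct varied-substrate levels")
  }

  y <- 1 / data$v
  x <- 1 / data[[varied]]
  w <- data$v^2
  k <- nlevels(series_f)
  n <- length(y)

  lines <- purrr::map_dfr(series, function(d) {
    fit <- lm(I(1 / d$v) ~ I(1 / d[[varied]]), weights = d$v^2)
    cf <- suppressWarnings(summary(fit))$coefficients
    tibble::tibble(
      level = d[[fixed]][1],
      intercept = cf[1, 1], slope = cf[2, 1],
      intercept_se = cf[1, 2], slope_se = cf[2, 2]
    )
  })

  settings <- list(axis_tol = axis_tol, parallel_alpha = parallel_alpha,
                   axis_alpha = axis_alpha, ambiguity_alpha = ambiguity_alpha)

  wrss <- function(res) sum(w * res^2)
  fit_sep <- lm(y ~ series_f * x, weights = w)
  rss_sep <- wrss(fit_sep$residuals)
  df_sep <- n - 2 * k
  scale0 <- wrss(y - stats::weighted.mean(y, w))
  noiseless <- rss_sep <= 1e-12 * scale0

  # parallel -----------------------------------------------------------------
  rel_spread <- sd(lines$slope) / max(abs(mean(lines$slope)), .Machine$double.eps)
  if (noiseless) {
    if (rel_spread < 1e-6) {
      return(new_pk_pattern("parallel", c(NA, NA), c(NA, NA), lines, settings))
    }
  } else {
    fit_par <- lm(y ~ series_f + x, weights = w)
    f_par <- ((wrss(fit_par$residuals) - rss_sep) / (k - 1)) / (rss_sep / df_sep)
    if (stats::pf(f_par, k - 1, df_sep, lower.tail = FALSE) > parallel_alpha) {
      return(new_pk_pattern("parallel", c(NA, NA), c(NA, NA), lines, settings))
    }
  }

  # pairwise intersections (diagnostic centroid/dispersion) -------------------
  pairs <- utils::combn(nrow(lines), 2)
  dm <- lines$slope[pairs[1, ]] - lines$slope[pairs[2, ]]
  xi <- (lines$intercept[pairs[2, ]] - lines$intercept[pairs[1, ]]) / dm
  yi <- lines$slope[pairs[1, ]] * xi + lines$intercept[pairs[1, ]]
  wp <- abs(dm)
  cx <- sum(wp * xi) / sum(wp)
  cy <- sum(wp * yi) / sum(wp)
  dx <- sqrt(sum(wp * (xi - cx)^2) / sum(wp))
  dy <- sqrt(sum(wp * (yi - cy)^2) / sum(wp))

  # pencil of lines through a common point ------------------------------------
  pencil <- function(fix_y0) {
    np <- k + 2 - fix_y0
    par0 <- c(x0 = cx, y0 = if (fix_y0) NULL else cy,
              setNames(lines$slope, paste0("m", seq_len(k))))
    res_fn <- function(p) {
      x0 <- p[1]
      y0 <- if (fix_y0) 0 else p[2]
      m <- p[(3 - fix_y0):length(p)][as.integer(series_f)]
      sqrt(w) * (y - (y0 + m * (x - x0)))
    }
    fit <- minpack.lm::nls.lm(par0, fn = res_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                           maxiter = 400))
    list(rss = fit$deviance, par = fit$par, np = np)
  }
  pen <- pencil(FALSE)
  x0 <- pen$par[["x0"]]; y0 <- pen$par[["y0"]]

  if (noiseless) {
    # exact data: no common point -> ambiguous; otherwise threshold on y0
    if (pen$rss > 1e-9 * scale0) {
      return(new_pk_pattern("ambiguous", c(cx, cy), c(dx, dy), lines, settings))
    }
    on_axis <- abs(y0) < axis_tol * min(abs(lines$intercept))
  } else {
    f_lof <- ((pen$rss - rss_sep) / (2 * k - pen$np)) / (rss_sep / df_sep)
    if (k > 3 &&
        stats::pf(f_lof, 2 * k - pen$np, df_sep, lower.tail = FALSE) <
          ambiguity_alpha) {
      return(new_pk_pattern("ambiguous", c(cx, cy), c(dx, dy), lines, settings))
    }
    pen0 <- pencil(TRUE)
    f_axis <- (pen0$rss - pen$rss) / (pen$rss / (n - pen$np))
    on_axis <- stats::pf(f_axis, 1, n - pen$np, lower.tail = FALSE) > axis_alpha
  }
  family <- if (on_axis) "intersecting_on_S_axis" else
    if (y0 > 0) "intersecting_left_above" else "intersecting_left_below"
  new_pk_pattern(family, c(x0, y0), c(dx, dy), lines, settings)
}

new_pk_pattern <- function(family, intersection, dispersion, lines, settings) {
  structure(list(
    family = family,
    intersection = setNames(intersection, c("x", "y")),
    dispersion = setNames(dispersion, c("x", "y")),
    lines = lines, settings = settings
  ), class = "pk_pattern")
}

#' @export
print.pk_pattern <- function(x, ...) {
  cat("<pk_pattern>", x$family, "\n")
  if (!is.na(x$intersection["x"])) {
    cat(sprintf("  intersection centroid (%.4g, %.4g), dispersion (%.3g, %.3g)\n",
                x$intersection["x"], x$intersection["y"],
                x$dispersion["x"], x$dispersion["y"]))
  }
  invisible(x)
}

#' Classify a dead-end inhibition pattern
#'
#' Combines the model-selection verdict of [fit_inhibition_series()] with
#' the classical linear replots: for each inhibitor level a 1/v-vs-1/S line
#' is fitted, and the slopes and intercepts of those lines are regressed on
#' the inhibitor concentration. A significant slope replot means the
#' inhibitor raises the apparent Km/V (slope effect); a significant
#' intercept replot means it lowers the apparent Vmax (intercept effect).
#' Cleland's reading: slope effect only = competitive (C); intercept only =
#' uncompetitive (UC); both with alpha = 1 = noncompetitive (NC); both with
#' alpha != 1 = mixed (MT). An inhibitor with neither effect yields a
#' no-inhibition call (`"none"`), not UC. When the replot reading and the
#' model selection disagree, the model-selection kind is retained and the
#' call is flagged inconsistent (with a warning).
#'
#' @param fit A `pk_inhibition_fit` from [fit_inhibition_series()].
#' @param effect_alpha Significance level of the replot slope t-tests
#'   (default 0.05).
#' @return A `pk_inhibition_call`: `kind` (C/NC/MT/UC/none), `slope_effect`,
#'   `intercept_effect`, `alpha_flag`, `consistent`, and the `replots`
#'   regressions.
#' @export
classify_inhibition <- function(fit, effect_alpha = 0.05) {
  if (!inherits(fit, "pk_inhibition_fit")) {
    abort("`fit` must come from fit_inhibition_series()")
  }
  if (!fit$best$converged) abort("inhibition fit did not converge")
  data <- fit$best$data

  replots <- purrr::map_dfr(split(data, data$i), function(d) {
    lf <- lm(I(1 / d$v) ~ I(1 / d$s))
    tibble::tibble(i = d$i[1], slope = coef(lf)[2], intercept = coef(lf)[1])
  })
  p_of <- function(y) {
    if (sd(y) < 1e-12 * max(abs(y), .Machine$double.eps)) return(1)
    lf <- suppressWarnings(summary(lm(y ~ replots$i)))$coefficients
    p <- if (nrow(lf) < 2) 1 else lf[2, 4]
    if (is.na(p)) 1 else p
  }
  slope_effect <- p_of(replots$slope) < effect_alpha
  intercept_effect <- p_of(replots$intercept) < effect_alpha

  replot_kind <- if (!slope_effect && !intercept_effect) "none" else
    if (slope_effect && !intercept_effect) "C" else
    if (!slope_effect && intercept_effect) "UC" else
    if (fit$alpha_flag == "alpha=1") "NC" else "MT"

  model_kind <- c(competitive = "C", noncompetitive = "NC",
                  mixed = "MT", uncompetitive = "UC")[[fit$kind]]

  if (replot_kind == "none") {
    kind <- "none"
    consistent <- TRUE
  } else {
    consistent <- replot_kind == model_kind
    kind <- model_kind
    if (!consistent) {
      warn(paste0("replot reading (", replot_kind,
                  ") disagrees with model selection (", model_kind,
                  "); keeping the model-selection call"))
    }
  }

  structure(list(
    kind = kind, slope_effect = slope_effect,
    intercept_effect = intercept_effect, alpha_flag = fit$alpha_flag,
    consistent = consistent, replots = replots
  ), class = "pk_inhibition_call")
}

#' @export
print.pk_inhibition_call <- function(x, ...) {
  cat("<pk_inhibition_call>", x$kind,
      "| slope effect:", x$slope_effect,
      "| intercept effect:", x$intercept_effect,
      "| alpha:", x$alpha_flag,
      if (!x$consistent) "| INCONSISTENT" else "", "\n")
  invisible(x)
}

#' Infer the kinetic mechanism from pattern and inhibition evidence
#'
#' Decision table over Cleland's diagnostics for a bi-bi reaction:
#'
#' * parallel double-reciprocal pattern => ping-pong;
#' * intersecting pattern where every dead-end analog is competitive against
#'   its own substrate and noncompetitive or mixed against the co-substrate
#'   => rapid-equilibrium random order (both substrates bind independently);
#' * a dead-end analog of one substrate appearing *uncompetitive* against
#'   the other => ordered, with the uncompetitively-inhibited (varied)
#'   substrate binding first;
#' * anything else (including an empty evidence list — an intersecting
#'   pattern alone cannot distinguish ordered steady state from random rapid
#'   equilibrium) => ambiguous, with the evidence retained.
#'
#' @param pattern A `pk_pattern` from [double_reciprocal_pattern()].
#' @param inhibitions Data frame of inhibition evidence with columns
#'   `inhibitor`, `varied` (substrate the pattern was measured against),
#'   `analog_of` (substrate the inhibitor mimics) and `kind`
#'   (C/NC/MT/UC/none); or a list of `pk_inhibition_call` objects plus the
#'   same metadata in columns.
#' @return A `pk_mechanism`: `mechanism` (one of
#'   `rapid_equilibrium_random`, `ordered`, `ping_pong`, `ambiguous`),
#'   `evidence`, `notes`.
#' @export
infer_mechanism <- function(pattern, inhibitions = NULL) {
  if (!inherits(pattern, "pk_pattern")) {
    abort("`pattern` must come from double_reciprocal_pattern()")
  }
  ev <- if (is.null(inhibitions)) {
    tibble::tibble(inhibitor = character(), varied = character(),
                   analog_of = character(), kind = character())
  } else tibble::as_tibble(inhibitions)

  notes <- character()
  mech <- "ambiguous"

  if (pattern$family == "parallel") {
    mech <- "ping_pong"
    notes <- c(notes, "parallel double-reciprocal pattern")
  } else if (pattern$family == "ambiguous") {
    notes <- c(notes, "intersection pattern too dispersed to classify")
  } else if (nrow(ev) == 0) {
    notes <- c(notes,
      "intersecting pattern alone cannot separate ordered steady state from random rapid equilibrium; dead-end inhibition evidence required")
  } else {
    uc <- ev$kind == "UC" & ev$varied != ev$analog_of
    own <- ev$varied == ev$analog_of
    if (any(uc)) {
      mech <- "ordered"
      first <- ev$varied[uc][1]
      notes <- c(notes, paste0(
        "analog of ", ev$analog_of[uc][1], " uncompetitive vs ", first,
        ": ", first, " binds first"))
    } else if (all(ev$kind[own] == "C") && any(own) &&
               all(ev$kind[!own] %in% c("NC", "MT"))) {
      mech <- "rapid_equilibrium_random"
      notes <- c(notes,
        "each analog competitive vs its own substrate, noncompetitive/mixed vs the co-substrate")
      if (pattern$family != "intersecting_on_S_axis") {
        notes <- c(notes, paste0("pattern family ", pattern$family,
          " (off-axis) noted; inhibition evidence dominates"))
      }
    } else {
      notes <- c(notes, "inhibition patterns match no canonical bi-bi signature")
    }
  }

  structure(list(mechanism = mech, pattern = pattern$family, evidence = ev,
                 notes = notes), class = "pk_mechanism")
}

#' @export
print.pk_mechanism <- function(x, ...) {
  cat("<pk_mechanism>", x$mechanism, "| pattern:", x$pattern, "\n")
  if (nrow(x$evidence)) print(x$evidence)
  for (n in x$notes) cat("  -", n, "\n")
  invisible(x)
}
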