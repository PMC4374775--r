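#' Globally fit a rate law to an initial-velocity dataset
#'
#' Weighted nonlinear least squares over the complete dataset (all series at
#' once), as done when a bisubstrate grid is fitted to a single rate
#' equation rather than series by series. Minimisation is
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) with box bounds, repeated
#' from `n_starts` starting points (the data-driven heuristic plus seeded
#' log-uniform draws over the bounds) to guard against the local minima that
#' the Hill and mixed-inhibition surfaces exhibit at small n; the best
#' converged solution is kept.
#'
#' @param data Data frame of observations. Required columns depend on the
#'   model: `a`, `b`, `v` for `"random_re"`; `s`, `v` for `"hill"` and
#'   `"michaelis"`; `s`, `i`, `v` for the inhibition models. Concentrations
#'   mM, `v` in velocity units.
#' @param model Model name; one of `"random_re"`, `"hill"`, `"michaelis"`,
#'   `"competitive"`, `"noncompetitive"`, `"mixed"`, `"uncompetitive"`.
#' @param init Optional named vector of starting values (replaces the
#'   heuristic first start).
#' @param bounds Optional list with named vectors `lower` and/or `upper`
#'   overriding the data-driven defaults.
#' @param weights `"none"` (unweighted least squares on v, the default) or
#'   `"relative"` (residuals scaled by the observed velocity).
#' @param n_starts Number of starts (default 8).
#' @param seed Seed for the random starts (and the bootstrap).
#' @param boot Number of residual-bootstrap resamples for bootstrap standard
#'   errors (default 0 = off; the Gauss-Newton errors are always reported).
#' @return A `pk_fit` object with elements `model`, `estimates`, `stderr`
#'   (Gauss-Newton standard errors from the Jacobian at the optimum), `rss`,
#'   `n_obs`, `converged`, `aicc`, plus the data and fitted values.
#'   [tidy()], [glance()] and [augment()] methods are provided.
#' @examples
#' d <- make_velocity_dataset("random_re",
#'        params = c(vmax = 183, ka = 0.38, kb = 0.16),
#'        design = design_initial_velocity(), noise = noise_model(scale = 0))
#' fit_global(d, "random_re")
#' @export
fit_global <- function(data, model, init = NULL, bounds = NULL,
                       weights = c("none", "relative"), n_starts = 8,
                       seed = 1, boot = 0) {
  weights <- match.arg(weights)
  spec <- model_spec(model)
  data <- tibble::as_tibble(data)
  miss <- setdiff(spec$cols, names(data))
  if (length(miss)) {
    abort(paste0("model `", model, "` needs column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(data$v < 0)) abort("negative velocities in `data`")
  spec$check(data)

  bnd <- spec$bounds(data)
  if (!is.null(bounds$lower)) bnd$lower[names(bounds$lower)] <- bounds$lower
  if (!is.null(bounds$upper)) bnd$upper[names(bounds$upper)] <- bounds$upper

  wts <- if (weights == "relative") ifelse(data$v > 0, 1 / data$v, 1) else
    rep(1, nrow(data))
  resid_fn <- function(p) {
    p <- setNames(pmin(pmax(p, bnd$lower), bnd$upper), spec$params)
    (data$v - spec$rate(data, p)) * wts
  }

  starts <- list(if (is.null(init)) spec$init(data) else
    init[spec$params])
  if (n_starts > 1) {
    rng <- local({
      set.seed(seed)
      lapply(seq_len(n_starts - 1), function(k) {
        exp(runif(length(spec$params), log(bnd$lower), log(pmin(bnd$upper, 1e8))))
      })
    })
    starts <- c(starts, lapply(rng, setNames, spec$params))
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = pmin(pmax(st, bnd$lower), bnd$upper), fn = resid_fn,
        lower = bnd$lower, upper = bnd$upper,
        control = minpack.lm::nls.lm.control(
          ftol = 1e-14, ptol = 1e-14, gtol = 1e-14, maxiter = 500)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) abort("optimisation failed from every start")

  est <- setNames(as.numeric(best$par), spec$params)
  rss <- sum((data$v - spec$rate(data, est))^2)
  # model comparison must score the same objective the fit minimised
  wrss <- sum(((data$v - spec$rate(data, est)) * wts)^2)
  n <- nrow(data)
  p <- length(est)
  converged <- best$info %in% 1:4

  # Gauss-Newton standard errors from a central-difference Jacobian
  jac <- jacobian_fd(function(q) spec$rate(data, setNames(q, spec$params)), est)
  stderr <- rep(NA_real_, p)
  if (n > p) {
    sigma2 <- sum(((data$v - spec$rate(data, est)) * wts)^2) / (n - p)
    jw <- jac * wts
    cv <- tryCatch(solve(crossprod(jw)) * sigma2, error = function(e) NULL)
    if (!is.null(cv)) stderr <- sqrt(pmax(diag(cv), 0))
  }
  names(stderr) <- spec$params

  stderr_boot <- NULL
  if (boot > 0) {
    fitted0 <- spec$rate(data, est)
    resid0 <- data$v - fitted0
    bs <- with_seed(seed + 1L, {
      vapply(seq_len(boot), function(b) {
        db <- data
        db$v <- pmax(fitted0 + sample(resid0, length(resid0), replace = TRUE), 0)
        rb <- tryCatch(
          minpack.lm::nls.lm(
            par = est, fn = function(p) {
              p <- setNames(pmin(pmax(p, bnd$lower), bnd$upper), spec$params)
              (db$v - spec$rate(db, p)) * wts
            },
            lower = bnd$lower, upper = bnd$upper,
            control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(rb)) rep(NA_real_, p) else as.numeric(rb$par)
      }, numeric(p))
    })
    stderr_boot <- setNames(apply(bs, 1, sd, na.rm = TRUE), spec$params)
  }

  structure(list(
    model = model, estimates = est, stderr = stderr,
    stderr_boot = stderr_boot, rss = rss,
    n_obs = n, converged = converged, aicc = aicc(wrss, n, p),
    weights = weights, data = data,
    fitted = spec$rate(data, est), n_starts = n_starts, seed = seed,
    info = best$info, message = best$message
  ), class = "pk_fit")
}

aicc <- function(rss, n, p) {
  k <- p + 1 # + residual variance
  aic <- n * log(rss / n) + 2 * k
  if (n - k - 1 > 0) aic + 2 * k * (k + 1) / (n - k - 1) else Inf
}

jacobian_fd <- function(f, x, rel = 1e-6) {
  f0 <- f(x)
  out <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- rel * max(abs(x[j]), 1e-8)
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    out[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  out
}

#' Fit and compare the dead-end inhibition models on one series
#'
#' Globally fits each candidate inhibition law to a varied-substrate x
#' inhibitor grid, ranks the fits by the small-sample corrected information
#' criterion (AICc), and summarises the evidence about the interaction
#' factor alpha from the mixed-law fit. A difference of less than 2 AICc
#' units between the best and second-best candidate is reported as
#' `ambiguous = TRUE` rather than silently resolved.
#'
#' @param data Data frame with columns `s`, `i`, `v`; at least 3 distinct
#'   inhibitor levels including 0.
#' @param candidates Inhibition kinds to compare (default all four).
#' @param ... Passed on to [fit_global()] (weights, n_starts, seed, bounds).
#' @return A `pk_inhibition_fit` list: `best` (the winning [fit_global()]
#'   object), `kind`, `alpha_flag` (`"alpha<1"`, `"alpha=1"` or `"alpha>1"`,
#'   judged at 2 standard errors from the mixed fit), `ambiguous`, and
#'   `comparison` (tibble of AICc per candidate).
#' @export
fit_inhibition_series <- function(data,
                                  candidates = c("competitive",
                                                 "noncompetitive", "mixed",
                                                 "uncompetitive"), ...) {
  data <- tibble::as_tibble(data)
  candidates <- match.arg(candidates, several.ok = TRUE)
  if (!all(c("s", "i", "v") %in% names(data))) {
    abort("`data` needs columns s, i, v")
  }
  if (dplyr::n_distinct(data$i) < 3 || !any(data$i == 0)) {
    abort("need >= 3 inhibitor levels including 0")
  }
  fits <- lapply(setNames(candidates, candidates), function(k)
    fit_global(data, k, ...))
  cmp <- tibble::tibble(
    kind = candidates,
    n_par = vapply(fits, function(f) length(f$estimates), integer(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)),
    rss = vapply(fits, function(f) f$rss, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  ) |> dplyr::arrange(.data$aicc)
  # within the delta-AICc < 2 band the most parsimonious candidate wins
  # (the mixed law nests the simpler ones, so raw AICc alone would overfit)
  band <- cmp$aicc - cmp$aicc[1] < 2
  best_kind <- cmp$kind[band][order(cmp$n_par[band])][1]
  ambiguous <- sum(band & cmp$n_par == min(cmp$n_par[band])) > 1

  alpha_flag <- NA_character_
  if ("mixed" %in% candidates) {
    mf <- fits[["mixed"]]
    a <- mf$estimates["alpha"]
    se <- mf$stderr["alpha"]
    if (!is.finite(se)) se <- 0
    alpha_flag <- if (a + 2 * se < 1) "alpha<1" else
      if (a - 2 * se > 1) "alpha>1" else "alpha=1"
  }

  structure(list(
    best = fits[[best_kind]], kind = best_kind, alpha_flag = alpha_flag,
    ambiguous = ambiguous, comparison = cmp, fits = fits
  ), class = "pk_inhibition_fit")
}

# broom-style accessors ------------------------------------------------------

#' @export
tidy.pk_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = as.numeric(x$estimates),
    std.error = as.numeric(x$stderr)
  )
}

#' @export
glance.pk_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, rss = x$rss, n_obs = x$n_obs,
    sigma = sqrt(x$rss / max(x$n_obs - length(x$estimates), 1)),
    AICc = x$aicc, converged = x$converged
  )
}

#' @export
augment.pk_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = .data$v - x$fitted)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("<pk_fit> model:", x$model,
      sprintf("| rss %.4g | n %d | AICc %.2f | %s\n", x$rss, x$n_obs, x$aicc,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.pk_inhibition_fit <- function(x, ...) tidy(x$best)

#' @export
glance.pk_inhibition_fit <- function(x, ...) {
  dplyr::mutate(glance(x$best), kind = x$kind, alpha_flag = x$alpha_flag,
                ambiguous = x$ambiguous)
}

#' @export
print.pk_inhibition_fit <- function(x, ...) {
  cat("<pk_inhibition_fit> kind:", x$kind,
      "| alpha:", x$alpha_flag,
      if (x$ambiguous) "| AMBIGUOUS (delta-AICc < 2)" else "", "\n")
  print(x$comparison)
  invisible(x)
}
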