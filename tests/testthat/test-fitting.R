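test_that("global fit recovers generating parameters exactly from noiseless data", {
  d <- make_velocity_dataset("random_re", table1_mg,
                             design_initial_velocity(),
                             noise = noise_model(scale = 0))
  f <- fit_global(d, "random_re")
  expect_true(f$converged)
  expect_equal(unname(f$estimates["vmax"]), 183, tolerance = 1e-8)
  expect_equal(unname(f$estimates["ka"]), 0.38, tolerance = 1e-8)
  expect_equal(unname(f$estimates["kb"]), 0.16, tolerance = 1e-8)

  # competitive-inhibition grid with the published oxalate Ki
  app <- apparent_mm(table1_mg, b = 2)
  di <- make_velocity_dataset("competitive",
                              c(v = app[["v"]], km = app[["km"]], ki = 0.05),
                              design_inhibition("oxalate_vs_pep"),
                              noise = noise_model(scale = 0))
  fi <- fit_global(di, "competitive")
  expect_equal(unname(fi$estimates["ki"]), 0.05, tolerance = 1e-8)

  # Hill parameters for the Mn2+ saturation column
  dh <- make_velocity_dataset("hill", c(vmax = 41, k05 = 0.02, n = 1.6),
    design = tibble::tibble(s = 0.02 * c(0.2, 0.5, 1, 2, 4, 10)),
    noise = noise_model(scale = 0))
  fh <- fit_global(dh, "hill")
  expect_equal(unname(fh$estimates), c(41, 0.02, 1.6), tolerance = 1e-7)
})

test_that("degenerate designs raise identifiability errors, never silent misfits", {
  d <- tibble::tibble(a = rep(0.5, 6), b = rep(c(0.1, 0.2, 0.4), 2),
                      v = rep(c(30, 40, 50), 2))
  expect_error(fit_global(d, "random_re"), "identifiable")
  d2 <- tibble::tibble(s = c(0.1, 0.2, 0.5), i = 0, v = c(10, 20, 30))
  expect_error(fit_global(d2, "competitive"), "inhibition information")
  expect_error(fit_inhibition_series(d2), "inhibitor levels")
  expect_error(fit_global(d, "no_such_model"), "unknown model")
})

test_that("fit is invariant to row order and equivariant under velocity rescaling", {
  d <- make_velocity_dataset("random_re", table1_mg,
                             design_initial_velocity(),
                             noise = noise_model(scale = 0.05), seed = 11)
  f1 <- fit_global(d, "random_re", n_starts = 2)
  f2 <- fit_global(d[sample.int(nrow(d)), ], "random_re", n_starts = 2)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  d3 <- dplyr::mutate(d, v = v * 1000)   # unit change of v
  f3 <- fit_global(d3, "random_re", n_starts = 2)
  expect_equal(unname(f3$estimates["vmax"]) / 1000,
               unname(f1$estimates["vmax"]), tolerance = 1e-6)
  expect_equal(f3$estimates[c("ka", "kb")], f1$estimates[c("ka", "kb")],
               tolerance = 1e-6)
})

test_that("reported rss equals direct recomputation at the estimates", {
  d <- make_velocity_dataset("random_re", table1_mg,
                             design_initial_velocity(),
                             noise = noise_model(scale = 0.05), seed = 3)
  f <- fit_global(d, "random_re", n_starts = 2)
  vhat <- rate_random_re(d$a, d$b, f$estimates["vmax"], f$estimates["ka"],
                         f$estimates["kb"])
  expect_equal(f$rss, sum((d$v - vhat)^2), tolerance = 1e-10)
  expect_equal(augment(f)$.fitted, vhat)
  td <- tidy(f)
  expect_named(td, c("term", "estimate", "std.error"))
  expect_true(all(td$std.error >= 0))
  expect_equal(glance(f)$n_obs, nrow(d))

  # bootstrap standard errors agree with the Gauss-Newton ones in magnitude
  fb <- fit_global(d, "random_re", n_starts = 1, boot = 40)
  expect_true(all(fb$stderr_boot > 0))
  expect_true(all(fb$stderr_boot / f$stderr > 0.3 &
                    fb$stderr_boot / f$stderr < 3))
})

test_that("inhibition model selection identifies the generating kind", {
  app <- apparent_mm(table1_mg, b = 2)
  # competitive generator, 5% noise: correct kind in >= 95% of 200 replicates
  # (relative-error weighting matches the error structure of the velocities)
  hits <- vapply(1:200, function(k) {
    d <- make_velocity_dataset("competitive",
                               c(v = app[["v"]], km = app[["km"]], ki = 0.05),
                               design_inhibition("oxalate_vs_pep"),
                               noise = noise_model(scale = 0.05), seed = 2000 + k)
    fit_inhibition_series(d, n_starts = 2, weights = "relative")$kind ==
      "competitive"
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # mixed generator with alpha = 0.5 flags alpha < 1
  dm <- make_velocity_dataset("mixed",
    c(v = app[["v"]], km = app[["km"]], ki = 35, alpha = 0.5),
    design_inhibition("amp_vs_pep"), noise = noise_model(scale = 0))
  fm <- fit_inhibition_series(dm, n_starts = 4)
  expect_equal(fm$kind, "mixed")
  expect_equal(fm$alpha_flag, "alpha<1")
  expect_equal(unname(fm$best$estimates["ki"]), 35, tolerance = 1e-5)
})

test_that("parameter estimates are nearly unbiased at 5% noise", {
  # reduced-size check of estimator consistency (the full-scale version runs
  # with the acceptance suite): 100 seeded replicate datasets, 5 replicates
  est <- vapply(1:100, function(k) {
    d <- make_velocity_dataset("random_re", table1_mg,
                               design_initial_velocity(), replicates = 5,
                               noise = noise_model(scale = 0.05), seed = 5000 + k)
    fit_global(d, "random_re", n_starts = 1)$estimates
  }, numeric(3))
  bias <- rowMeans(est) / table1_mg - 1
  expect_lt(max(abs(bias)), 0.02)
})
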