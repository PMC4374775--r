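test_that("noiseless patterns are recovered for all three mechanism families", {
  des <- design_initial_velocity()
  # exhaustive over a small parameter grid per family
  grid <- tidyr::expand_grid(vmax = c(50, 183), ka = c(0.2, 0.38),
                             kb = c(0.16, 0.5))
  for (r in seq_len(nrow(grid))) {
    p <- unlist(grid[r, ])
    d <- make_velocity_dataset("random_re", p, des, noise_model(scale = 0))
    pat <- double_reciprocal_pattern(d)
    expect_equal(pat$family, "intersecting_on_S_axis")
    expect_equal(unname(pat$intersection["x"]), -1 / p["ka"],
                 ignore_attr = TRUE, tolerance = 1e-6)

    dp <- make_velocity_dataset("ping_pong", p, des, noise_model(scale = 0))
    expect_equal(double_reciprocal_pattern(dp)$family, "parallel")

    do <- make_velocity_dataset("ordered", c(p, kia = 5 * p[["ka"]]), des,
                                noise_model(scale = 0))
    po <- double_reciprocal_pattern(do)
    expect_equal(po$family, "intersecting_left_above")
    # analytic common point of the ordered pattern: (-1/Kia, (1-Ka/Kia)/V)
    expect_equal(unname(po$intersection["x"]), -1 / (5 * p[["ka"]]),
                 tolerance = 1e-6)
    expect_equal(unname(po$intersection["y"]), (1 - 1 / 5) / p[["vmax"]],
                 tolerance = 1e-6)
    # ordered with Kia = Ka degenerates to the on-axis pattern
    dq <- make_velocity_dataset("ordered", c(p, kia = p[["ka"]]), des,
                                noise_model(scale = 0))
    expect_equal(double_reciprocal_pattern(dq)$family, "intersecting_on_S_axis")
  }
})

test_that("pattern family is invariant to series relabelling and velocity scaling", {
  d <- make_velocity_dataset("random_re", table1_mg, design_initial_velocity(),
                             noise_model(scale = 0.05), seed = 21)
  p0 <- double_reciprocal_pattern(d)
  p1 <- double_reciprocal_pattern(d[rev(seq_len(nrow(d))), ])
  expect_equal(p0$family, p1$family)
  p2 <- double_reciprocal_pattern(dplyr::mutate(d, v = v * 7.3))
  expect_equal(p0$family, p2$family)
  expect_equal(p0$intersection["x"], p2$intersection["x"], tolerance = 1e-6)
})

test_that("pattern classification demands an adequate design", {
  d <- make_velocity_dataset("random_re", table1_mg,
    tidyr::expand_grid(a = c(0.1, 0.3, 0.6, 1.2), b = c(0.1, 0.3)),
    noise_model(scale = 0))
  expect_error(double_reciprocal_pattern(d), ">= 3 series")
  d2 <- make_velocity_dataset("random_re", table1_mg,
    tidyr::expand_grid(a = c(0.1, 0.3, 0.6), b = c(0.1, 0.2, 0.3)),
    noise_model(scale = 0))
  expect_error(double_reciprocal_pattern(d2), ">= 4 distinct")
})

test_that("replot classification reads C, MT and flat inhibitors correctly", {
  app <- apparent_mm(table1_mg, b = 2)
  # oxalate-style: competitive vs its own substrate
  dc <- make_velocity_dataset("competitive",
    c(v = app[["v"]], km = app[["km"]], ki = 0.05),
    design_inhibition("oxalate_vs_pep"), noise_model(scale = 0))
  call_c <- classify_inhibition(fit_inhibition_series(dc, n_starts = 2))
  expect_equal(call_c$kind, "C")
  expect_true(call_c$slope_effect)
  expect_false(call_c$intercept_effect)

  # AMP-style: mixed with alpha < 1 vs the co-substrate
  dm <- make_velocity_dataset("mixed",
    c(v = app[["v"]], km = app[["km"]], ki = 35, alpha = 0.5),
    design_inhibition("amp_vs_pep"), noise_model(scale = 0))
  call_m <- classify_inhibition(fit_inhibition_series(dm, n_starts = 4))
  expect_equal(call_m$kind, "MT")
  expect_equal(call_m$alpha_flag, "alpha<1")
  expect_true(call_m$slope_effect && call_m$intercept_effect)

  # an inhibitor with no effect is a no-inhibition call, not UC
  flat <- tidyr::expand_grid(s = c(0.05, 0.1, 0.2, 0.5, 1),
                             i = c(0, 1, 2, 4)) |>
    dplyr::mutate(v = 100 * s / (0.4 + s))
  call_0 <- classify_inhibition(fit_inhibition_series(flat, n_starts = 2))
  expect_equal(call_0$kind, "none")
})

test_that("the mechanism decision table reproduces Cleland's diagnostics", {
  des <- design_initial_velocity()
  pat_axis <- double_reciprocal_pattern(
    make_velocity_dataset("random_re", table1_mg, des, noise_model(scale = 0)))
  pat_par <- double_reciprocal_pattern(
    make_velocity_dataset("ping_pong", table1_mg, des, noise_model(scale = 0)))

  # the full dead-end evidence set of a random rapid-equilibrium enzyme:
  # each analog competitive vs its own substrate, NC/MT vs the co-substrate
  ev <- tibble::tibble(
    inhibitor = c("oxalate", "oxalate", "AMP", "AMP"),
    varied   = c("pep", "adp", "pep", "adp"),
    analog_of = c("pep", "pep", "adp", "adp"),
    kind = c("C", "NC", "MT", "C"))
  m <- infer_mechanism(pat_axis, ev)
  expect_equal(m$mechanism, "rapid_equilibrium_random")

  # a competitive analog of B appearing uncompetitive vs A implies order
  ev_ord <- tibble::tibble(inhibitor = "ib", varied = c("a", "b"),
                           analog_of = "b", kind = c("UC", "C"))
  m_ord <- infer_mechanism(pat_axis, ev_ord)
  expect_equal(m_ord$mechanism, "ordered")
  expect_match(paste(m_ord$notes, collapse = " "), "a binds first")

  expect_equal(infer_mechanism(pat_par)$mechanism, "ping_pong")
  expect_equal(infer_mechanism(pat_axis)$mechanism, "ambiguous")
  ev_odd <- tibble::tibble(inhibitor = "x", varied = "pep",
                           analog_of = "pep", kind = "NC")
  expect_equal(infer_mechanism(pat_axis, ev_odd)$mechanism, "ambiguous")
})
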