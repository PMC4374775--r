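#' Rapid-equilibrium random-order bisubstrate rate law
#'
#' Initial velocity of a bi-bi reaction in which both substrates bind
#' independently and binding equilibria are fast relative to catalysis:
#' \deqn{v = \frac{V_{max}\,A\,B}{K_a K_b + K_a B + K_b A + A B}}
#' For pyruvate kinase, A is the PEP trianion and B the ADP-metal complex.
#' The denominator factorises as \eqn{(K_a + A)(K_b + B)}, so in double
#' reciprocal space all fixed-B lines share the point \eqn{(-1/K_a, 0)}:
#' the pattern intersects *on* the 1/S axis.
#'
#' @param a,b Substrate concentrations (mM), vectorised.
#' @param vmax Maximal specific activity (umol min^-1 mg^-1).
#' @param ka,kb Michaelis constants for A and B (mM).
#' @return Velocity, same units as `vmax`.
#' @examples
#' rate_random_re(0.38, 0.16, vmax = 183, ka = 0.38, kb = 0.16)  # vmax/4
#' @export
rate_random_re <- function(a, b, vmax, ka, kb) {
  check_nonneg(a, "a"); check_nonneg(b, "b")
  check_pos(vmax, "vmax"); check_pos(ka, "ka"); check_pos(kb, "kb")
  vmax * a * b / ((ka + a) * (kb + b))
}

#' Hill rate law
#'
#' \deqn{v = \frac{V_{max} S^n}{K_{0.5}^n + S^n}} with half-saturation
#' constant `k05` and Hill coefficient `n` (cooperativity; n = 1 recovers
#' Michaelis-Menten).
#'
#' @param s Substrate concentration (mM), vectorised.
#' @param vmax Maximal velocity.
#' @param k05 Half-saturation constant K0.5 (mM).
#' @param n Hill coefficient (> 0).
#' @return Velocity.
#' @examples
#' rate_hill(0.02, vmax = 41, k05 = 0.02, n = 1.6)  # vmax/2
#' @export
rate_hill <- function(s, vmax, k05, n) {
  check_nonneg(s, "s")
  check_pos(vmax, "vmax"); check_pos(k05, "k05"); check_pos(n, "n")
  sn <- (s / k05)^n
  vmax * sn / (1 + sn)
}

#' Dead-end inhibition rate laws
#'
#' Michaelis-Menten velocity in the presence of a dead-end inhibitor at
#' concentration `i`:
#' * competitive (`"competitive"`): \eqn{v = V S / (K_m(1 + I/K_i) + S)}
#' * noncompetitive / mixed (`"noncompetitive"`, `"mixed"`):
#'   \eqn{v = V S / (K_m(1 + I/K_i) + S(1 + I/(\alpha K_i)))}, with
#'   \eqn{\alpha = 1} for noncompetitive and \eqn{\alpha \ne 1} (typically
#'   < 1) for mixed
#' * uncompetitive (`"uncompetitive"`): \eqn{v = V S /(K_m + S(1 + I/K_i))}
#'   — included for completeness of Cleland's pattern set; the slope of the
#'   double-reciprocal line is unaffected.
#'
#' @param s,i Substrate and inhibitor concentrations (mM), vectorised.
#' @param v Maximal velocity.
#' @param km Michaelis constant (mM).
#' @param ki Inhibition constant (mM).
#' @param alpha Interaction factor for the mixed law; fixed to 1 for
#'   noncompetitive, ignored for competitive and uncompetitive.
#' @param kind One of `"competitive"`, `"noncompetitive"`, `"mixed"`,
#'   `"uncompetitive"`.
#' @return Velocity; equals `v * s / (km + s)` whenever `i = 0`.
#' @examples
#' rate_inhibited(1, 0.05, v = 100, km = 0.4, ki = 0.05, kind = "competitive")
#' @export
rate_inhibited <- function(s, i, v, km, ki, alpha = 1,
                           kind = c("competitive", "noncompetitive",
                                    "mixed", "uncompetitive")) {
  kind <- match.arg(kind)
  check_nonneg(s, "s"); check_nonneg(i, "i")
  check_pos(v, "v"); check_pos(km, "km"); check_pos(ki, "ki")
  if (kind == "noncompetitive") alpha <- 1
  if (kind %in% c("noncompetitive", "mixed")) check_pos(alpha, "alpha")
  switch(kind,
    competitive   = v * s / (km * (1 + i / ki) + s),
    noncompetitive = ,
    mixed         = v * s / (km * (1 + i / ki) + s * (1 + i / (alpha * ki))),
    uncompetitive = v * s / (km + s * (1 + i / ki))
  )
}

#' Turnover number and specificity constants from a specific activity
#'
#' Converts a maximal specific activity (umol min^-1 mg^-1) into a turnover
#' number kcat (s^-1) using the molar mass of the catalytic unit, and forms
#' log10 specificity constants kcat/Km (M^-1 s^-1) for any supplied Michaelis
#' constants. The default basis is the homotetramer: pyruvate kinases are
#' homotetramers and the tetramer basis (4 x 51,340 Da for the T. pendens
#' monomer) is the one that reproduces the published turnover number of this
#' enzyme; set `n_subunits = 1` for a per-monomer basis.
#'
#' kcat = Vmax (mol s^-1 g^-1) x mass (g mol^-1); with Vmax in
#' umol min^-1 mg^-1 this is `vmax * mass_da * n_subunits / (60 * 1000)`.
#'
#' @param vmax_specific Maximal specific activity, umol min^-1 mg^-1.
#' @param subunit_mass Monomer molar mass, Da.
#' @param n_subunits Subunits per catalytic unit (default 4, tetramer).
#' @param km Optional named numeric vector of Michaelis constants (mM) for
#'   which log10(kcat/Km) is reported.
#' @return A tibble with `kcat` (s^-1) and, per supplied Km, columns
#'   `log_kcat_km_<name>` (log10 of M^-1 s^-1).
#' @examples
#' catalytic_constants(183, 51340, km = c(pep = 0.38, adp_mg = 0.16))
#' @export
catalytic_constants <- function(vmax_specific, subunit_mass, n_subunits = 4,
                                km = NULL) {
  check_nonneg(vmax_specific, "vmax_specific")
  check_pos(subunit_mass, "subunit_mass")
  check_pos(n_subunits, "n_subunits")
  kcat <- vmax_specific * subunit_mass * n_subunits / 60 / 1e3 # s^-1
  out <- tibble::tibble(kcat = kcat)
  if (!is.null(km)) {
    check_pos(km, "km")
    nm <- names(km)
    if (is.null(nm)) nm <- paste0("km", seq_along(km))
    for (j in seq_along(km)) {
      # Km mM -> M
      out[[paste0("log_kcat_km_", nm[j])]] <-
        unname(log10(kcat / (km[[j]] * 1e-3)))
    }
  }
  out
}
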