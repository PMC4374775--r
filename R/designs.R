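#' Published kinetic constants for the T. pendens pyruvate kinase
#'
#' The kinetic constants reported for TpPK at 45 C, pH 6.0, without
#' monovalent cations, as fitted to the rapid-equilibrium random-order rate
#' law (Mg2+ series) and the Hill equation (Mn2+ series). These are used as
#' the generating parameters of the synthetic study conditions and as
#' benchmarks in worked examples.
#'
#' @return A tibble with columns `cation`, `parameter`, `value`, `sd`,
#'   `units`. Parameters: `vmax` (umol min^-1 mg^-1), `km_pep`, `km_adp`
#'   (Michaelis constants, mM; Mg2+ series), `k05_pep`, `k05_adp`,
#'   `k05_cation` (half-saturation constants, mM), `n_pep`, `n_adp`,
#'   `n_cation` (Hill coefficients). The monomer molar mass is 51,340 Da and
#'   the enzyme is a homotetramer.
#' @export
tppk_constants <- function() {
  tibble::tribble(
    ~cation, ~parameter,   ~value, ~sd,   ~units,
    "Mg",    "vmax",        183,    8,     "umol/min/mg",
    "Mg",    "km_pep",      0.38,   0.03,  "mM",
    "Mg",    "km_adp",      0.16,   0.01,  "mM",
    "Mg",    "k05_cation",  5.0,    0.28,  "mM",
    "Mg",    "n_cation",    1.8,    0.4,   "",
    "Mn",    "vmax",        41,     1.9,   "umol/min/mg",
    "Mn",    "k05_pep",     1.0,    0.1,   "mM",
    "Mn",    "n_pep",       1.2,    0.1,   "",
    "Mn",    "k05_adp",     0.2,    0.02,  "mM",
    "Mn",    "n_adp",       1.2,    0.3,   "",
    "Mn",    "k05_cation",  0.02,   0.001, "mM",
    "Mn",    "n_cation",    1.6,    0.2,   ""
  )
}

#' Published dead-end inhibition constants for TpPK
#'
#' Oxalate (dead-end analog of the PEP trianion) and AMP (dead-end analog of
#' ADP-Mg), with the inhibition-pattern calls made against each varied
#' substrate: oxalate is competitive (C) versus PEP and noncompetitive (NC)
#' versus ADP-Mg; AMP is mixed with alpha < 1 (MT) versus PEP and competitive
#' versus ADP-Mg.
#'
#' @return A tibble with columns `inhibitor`, `analog_of`, `ki`, `sd`
#'   (mM), `pattern_vs_pep`, `pattern_vs_adp`.
#' @export
tppk_inhibition_constants <- function() {
  tibble::tribble(
    ~inhibitor, ~analog_of, ~ki,  ~sd,   ~pattern_vs_pep, ~pattern_vs_adp,
    "oxalate",  "pep",      0.05, 0.002, "C",             "NC",
    "AMP",      "adp",      35,   1.2,   "MT",            "C"
  )
}

# published assay concentration grids ---------------------------------------

iv_pep_levels <- c(0.031, 0.14, 0.34, 0.69, 1.30)
iv_adp_levels <- c(0.084, 0.12, 0.16, 0.37, 0.67)

#' Initial-velocity concentration designs
#'
#' The bisubstrate initial-velocity grids used to characterise TpPK: one
#' substrate varied over its published level set at each fixed level of the
#' other, free Mg2+ held at 30 mM. `varied = "pep"` varies the PEP trianion
#' (0.031-1.30 mM) across five fixed ADP-Mg levels (0.084-0.67 mM);
#' `varied = "adp"` is the transpose. The same five-level sets serve as the
#' fixed levels of the co-substrate, the published design being symmetric.
#'
#' @param varied Which substrate is varied: `"pep"` or `"adp"`.
#' @return A tibble with columns `a` (PEP3-, mM), `b` (ADP-Mg, mM) and a
#'   `varied` attribute, one row per grid point.
#' @export
design_initial_velocity <- function(varied = c("pep", "adp")) {
  varied <- match.arg(varied)
  grid <- tidyr::expand_grid(a = iv_pep_levels, b = iv_adp_levels)
  attr(grid, "varied") <- if (varied == "pep") "a" else "b"
  grid
}

#' Dead-end inhibition concentration designs
#'
#' The four published inhibition grids: varied substrate levels crossed with
#' fixed inhibitor levels, the co-substrate held saturating.
#' * `"oxalate_vs_pep"`: PEP 0.054-1.1 mM, oxalate 0-0.040 mM (ADP 2 mM)
#' * `"oxalate_vs_adp"`: ADP-Mg 0.045-0.90 mM, oxalate 0-0.040 mM
#' * `"amp_vs_pep"`: PEP 0.15-1.5 mM, AMP 0-16 mM
#' * `"amp_vs_adp"`: ADP-Mg 0.045-0.90 mM, AMP 0-20 mM
#'
#' @param which One of the four design names above.
#' @return A tibble with columns `s` (varied substrate, mM) and `i`
#'   (inhibitor, mM), one row per grid point.
#' @export
design_inhibition <- function(which = c("oxalate_vs_pep", "oxalate_vs_adp",
                                        "amp_vs_pep", "amp_vs_adp")) {
  which <- match.arg(which)
  levels <- switch(which,
    oxalate_vs_pep = list(s = c(0.054, 0.077, 0.10, 0.22, 1.1),
                          i = c(0, 0.010, 0.020, 0.030, 0.040)),
    oxalate_vs_adp = list(s = c(0.045, 0.063, 0.090, 0.18, 0.90),
                          i = c(0, 0.010, 0.020, 0.030, 0.040)),
    amp_vs_pep     = list(s = c(0.15, 0.30, 0.55, 0.77, 1.5),
                          i = c(0, 4, 8, 12, 16)),
    amp_vs_adp     = list(s = c(0.045, 0.063, 0.090, 0.18, 0.90),
                          i = c(0, 8, 12, 16, 20))
  )
  tidyr::expand_grid(s = levels$s, i = levels$i)
}
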