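#' Speciate a 1:1 metal-ligand binding system
#'
#' Solves the single-site binding equilibrium M + L <-> ML for the complex,
#' free-metal and free-ligand concentrations given the analytical totals and
#' the dissociation constant. This is the bookkeeping used to convert total
#' added Mg2+ (or Mn2+) and ADP into the ADP-metal complex and free divalent
#' cation concentrations that the rate laws take as substrates.
#'
#' The complex concentration is the physical root of
#' \deqn{c^2 - c\,(M_t + L_t + K_d) + M_t L_t = 0}
#' evaluated in the cancellation-free form
#' \eqn{c = 2 M_t L_t / (S + \sqrt{S^2 - 4 M_t L_t})} with
#' \eqn{S = M_t + L_t + K_d}, which stays accurate when \eqn{K_d} is orders of
#' magnitude below the totals (assay conditions span roughly 0.02-30 mM).
#'
#' Only the 1:1 equilibrium is modelled; competing equilibria (protonation of
#' ADP, other ligands) are out of scope. The dissociation constants for
#' ADP-Mg and ADP-Mn are not universal constants and must be supplied; see
#' [kd_defaults()] for the documented literature defaults.
#'
#' @param systems Data frame with columns `total_metal`, `total_ligand`, `kd`
#'   (all mM; one row per system), or nothing if the three scalars are given.
#' @param total_metal,total_ligand,kd Scalar shortcuts used when `systems` is
#'   missing.
#'
#' @return A tibble with columns `total_metal`, `total_ligand`, `kd`,
#'   `complex`, `free_metal`, `free_ligand` (mM). Mass conservation and the
#'   mass-action law hold to ~1e-10 relative.
#'
#' @examples
#' speciate(total_metal = 1, total_ligand = 1, kd = 1)   # complex = (3 - sqrt(5))/2
#' speciate(tibble::tibble(total_metal = 30.16, total_ligand = 0.1613,
#'                         kd = kd_defaults()$adp_mg))
#' @export
speciate <- function(systems = NULL, total_metal = NULL, total_ligand = NULL,
                     kd = NULL) {
  if (is.null(systems)) {
    systems <- tibble::tibble(
      total_metal = total_metal, total_ligand = total_ligand, kd = kd
    )
  }
  systems <- tibble::as_tibble(systems)
  for (fld in c("total_metal", "total_ligand", "kd")) {
    if (!fld %in% names(systems)) abort(paste0("missing column `", fld, "`"))
  }
  check_nonneg(systems$total_metal, "total_metal")
  check_nonneg(systems$total_ligand, "total_ligand")
  check_pos(systems$kd, "kd")

  m <- systems$total_metal
  l <- systems$total_ligand
  kd <- systems$kd
  s <- m + l + kd
  disc <- s^2 - 4 * m * l
  # disc >= kd^2 > 0 analytically; clamp defends against rounding
  cplx <- 2 * m * l / (s + sqrt(pmax(disc, 0)))
  dplyr::mutate(
    systems,
    complex = cplx,
    free_metal = m - cplx,
    free_ligand = l - cplx
  )
}

#' Totals that realise target free-metal and complex concentrations
#'
#' Inverse of [speciate()]: experimental designs fix the *free* divalent
#' cation (e.g. 30 mM free Mg2+) and the metal-nucleotide *complex* at chosen
#' levels, and the experimenter must know which totals to pipette. Closed
#' form: `total_metal = free_metal + complex`;
#' `total_ligand = complex + kd * complex / free_metal`.
#'
#' @param targets Data frame with columns `free_metal`, `complex`, `kd`, or
#'   nothing if scalars are given.
#' @param free_metal,complex,kd Scalar shortcuts.
#' @return A tibble of `total_metal`, `total_ligand`, `kd` rows that
#'   [speciate()] maps back onto the targets (round-trip residual < 1e-10
#'   relative).
#' @examples
#' totals_for_design(free_metal = 30, complex = 0.16, kd = 0.25)
#' @export
totals_for_design <- function(targets = NULL, free_metal = NULL,
                              complex = NULL, kd = NULL) {
  if (is.null(targets)) {
    targets <- tibble::tibble(free_metal = free_metal, complex = complex, kd = kd)
  }
  targets <- tibble::as_tibble(targets)
  check_nonneg(targets$free_metal, "free_metal")
  check_nonneg(targets$complex, "complex")
  check_pos(targets$kd, "kd")
  if (any(targets$complex > 0 & targets$free_metal == 0)) {
    abort("a nonzero `complex` target with zero `free_metal` needs infinite ligand")
  }
  free_ligand <- ifelse(targets$complex == 0, 0,
                        targets$kd * targets$complex / targets$free_metal)
  tibble::tibble(
    total_metal = targets$free_metal + targets$complex,
    total_ligand = targets$complex + free_ligand,
    kd = targets$kd
  )
}

#' Ionized (trianionic) phosphoenolpyruvate concentration
#'
#' Henderson-Hasselbalch fraction of the catalytically active PEP trianion:
#' `total_pep / (1 + 10^(pk - ph))`. The enolic phosphate of PEP titrates
#' with pK 6.3, so at the assay pH of 6.0 only ~33% of total PEP is the
#' active species.
#'
#' @param total_pep Total PEP concentration (mM), vectorised.
#' @param ph Assay pH.
#' @param pk Acid dissociation pK of the PEP phosphate (default 6.3).
#' @return Ionized PEP concentration(s), mM.
#' @examples
#' ionized_pep(1, ph = 6.0)         # 0.3339
#' ionized_pep(1, ph = 6.3)         # exactly half
#' @export
ionized_pep <- function(total_pep, ph, pk = 6.3) {
  check_nonneg(total_pep, "total_pep")
  total_pep / (1 + 10^(pk - ph))
}

#' Default metal-ADP dissociation constants
#'
#' The assay-condition calculations need Kd values for the ADP-Mg and ADP-Mn
#' complexes, which are medium-dependent and are treated here as
#' configuration, not constants of nature. Defaults are literature stability
#' constants at near-neutral pH (association ~4e3 M^-1 for Mg-ADP and
#' ~2.2e4 M^-1 for Mn-ADP), i.e. Kd 0.25 mM and 0.045 mM. Override them
#' whenever condition-specific values are available.
#'
#' @return Named list with elements `adp_mg` and `adp_mn` (mM).
#' @export
kd_defaults <- function() {
  list(adp_mg = 0.25, adp_mn = 0.045)
}
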