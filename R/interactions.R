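# Noncovalent-interaction detectors. All return one tibble row per detected
# interaction with the geometry that defines it, mirroring the columns of a
# contact table (partners, distance, angle, class).

ring_atoms <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "NE1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

#' Detect aromatic pi-pi pairs
#'
#' For every pair of aromatic residues whose ring centroids (mass centre of
#' the ring atoms) lie within `max_centroid_dist`, reports the
#' centroid-centroid distance and the acute angle between the best-fit ring
#' planes (least-squares plane through the ring atoms; 0 deg = stacked,
#' 90 deg = edge-to-face). Residues with incomplete rings are skipped with a
#' warning. Each pair is reported once, ordered by residue number.
#'
#' @param s A `pk_structure`.
#' @param chain Restrict to one chain (default: all chains, pairs within a
#'   chain only).
#' @param residues Optional residue numbers to restrict to.
#' @param max_centroid_dist Centroid distance cutoff, Angstrom (default 7).
#' @return Tibble: `kind`, `chain`, `res1`, `resid1`, `res2`, `resid2`,
#'   `distance` (A), `angle` (deg, in \[0, 90\]).
#' @export
pi_pi_pairs <- function(s, chain = NULL, residues = NULL,
                        max_centroid_dist = 7.0) {
  at <- s$atoms
  if (!is.null(chain)) at <- dplyr::filter(at, .data$chain %in% !!chain)
  at <- dplyr::filter(at, .data$resid %in% names(ring_atoms))
  if (!is.null(residues)) at <- dplyr::filter(at, .data$resno %in% residues)
  if (!nrow(at)) return(empty_interactions(angle = TRUE))

  rings <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid) |>
    dplyr::group_map(function(d, key) {
      want <- ring_atoms[[key$resid]]
      d <- d[d$elety %in% want, ]
      if (nrow(d) < length(want)) {
        warn(paste0("incomplete aromatic ring ", key$resid, key$resno,
                    " (chain ", key$chain, "); skipped"))
        return(NULL)
      }
      xyz <- coords_of(d)
      ctr <- colMeans(xyz)
      sv <- svd(sweep(xyz, 2, ctr))
      list(chain = key$chain, resno = key$resno, resid = key$resid,
           centroid = ctr, normal = sv$v[, 3])
    }) |> purrr::compact()
  if (length(rings) < 2) return(empty_interactions(angle = TRUE))

  out <- list()
  for (i in seq_len(length(rings) - 1)) {
    for (j in seq(i + 1, length(rings))) {
      ri <- rings[[i]]; rj <- rings[[j]]
      if (ri$chain != rj$chain) next
      d <- sqrt(sum((ri$centroid - rj$centroid)^2))
      if (d > max_centroid_dist) next
      cosang <- abs(sum(ri$normal * rj$normal))
      ang <- acos(pmin(cosang, 1)) * 180 / pi
      out[[length(out) + 1]] <- tibble::tibble(
        kind = "pi_pi", chain = ri$chain,
        res1 = min(ri$resno, rj$resno), res2 = max(ri$resno, rj$resno),
        resid1 = if (ri$resno <= rj$resno) ri$resid else rj$resid,
        resid2 = if (ri$resno <= rj$resno) rj$resid else ri$resid,
        distance = d, angle = ang
      )
    }
  }
  if (!length(out)) return(empty_interactions(angle = TRUE))
  dplyr::arrange(dplyr::bind_rows(out), .data$chain, .data$res1, .data$res2)
}

empty_interactions <- function(angle = FALSE) {
  out <- tibble::tibble(kind = character(), chain = character(),
                        res1 = numeric(), res2 = numeric(),
                        resid1 = character(), resid2 = character(),
                        distance = numeric())
  if (angle) out$angle <- numeric()
  out
}

salt_basic <- list(ARG = c("NH1", "NH2", "NE"), LYS = "NZ",
                   HIS = c("ND1", "NE2"))
salt_acidic <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect salt bridges
#'
#' Pairs a basic nitrogen (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2) with an
#' acidic carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2, or any C-terminal
#' OXT) within `cutoff`. One record per residue pair, at the minimum atom
#' distance, naming the atoms that realise it.
#'
#' @param s A `pk_structure`.
#' @param cutoff Distance cutoff, Angstrom (default 4.0).
#' @param chain Optional chain restriction.
#' @return Tibble: `kind`, `chain1`, `res1`, `resid1`, `atom1` (basic N),
#'   `chain2`, `res2`, `resid2`, `atom2` (acidic O), `distance`.
#' @export
salt_bridges <- function(s, cutoff = 4.0, chain = NULL) {
  at <- s$atoms
  if (!is.null(chain)) at <- dplyr::filter(at, .data$chain %in% !!chain)
  pick <- function(defs) {
    keep <- mapply(function(res, nm) at$resid == res & at$elety %in% nm,
                   names(defs), defs, SIMPLIFY = FALSE)
    at[Reduce(`|`, keep), ]
  }
  basic <- pick(salt_basic)
  acidic <- dplyr::bind_rows(pick(salt_acidic),
                             dplyr::filter(at, .data$elety == "OXT"))
  if (!nrow(basic) || !nrow(acidic)) {
    return(pair_records_empty())
  }
  dm <- cross_dist(coords_of(basic), coords_of(acidic))
  idx <- which(dm <= cutoff, arr.ind = TRUE)
  if (!nrow(idx)) return(pair_records_empty())
  recs <- tibble::tibble(
    kind = "salt_bridge",
    chain1 = basic$chain[idx[, 1]], res1 = basic$resno[idx[, 1]],
    resid1 = basic$resid[idx[, 1]], atom1 = basic$elety[idx[, 1]],
    chain2 = acidic$chain[idx[, 2]], res2 = acidic$resno[idx[, 2]],
    resid2 = acidic$resid[idx[, 2]], atom2 = acidic$elety[idx[, 2]],
    distance = dm[idx]
  )
  recs |>
    dplyr::filter(!(.data$chain1 == .data$chain2 & .data$res1 == .data$res2)) |>
    dplyr::group_by(.data$chain1, .data$res1, .data$chain2, .data$res2) |>
    dplyr::slice_min(.data$distance, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain1, .data$res1, .data$res2)
}

pair_records_empty <- function() {
  tibble::tibble(kind = character(), chain1 = character(), res1 = numeric(),
                 resid1 = character(), atom1 = character(),
                 chain2 = character(), res2 = numeric(), resid2 = character(),
                 atom2 = character(), distance = numeric())
}

#' Detect hydrogen bonds by the heavy-atom criterion
#'
#' Reports every N/O/S heavy-atom pair within `d_a_cutoff` as a putative
#' donor-acceptor pair (crystal structures without hydrogens give no
#' donor/acceptor orientation, so the criterion is symmetric). Pairs within
#' the same residue, and backbone-backbone pairs of sequence-adjacent
#' residues (covalently connected through the peptide bond), are excluded.
#'
#' @param s A `pk_structure`.
#' @param d_a_cutoff Donor-acceptor distance cutoff, Angstrom (default 3.4).
#' @param chain Optional chain restriction.
#' @return Tibble with one row per atom pair (same columns as
#'   [salt_bridges()]).
#' @export
hbonds <- function(s, d_a_cutoff = 3.4, chain = NULL) {
  at <- s$atoms
  if (!is.null(chain)) at <- dplyr::filter(at, .data$chain %in% !!chain)
  da <- dplyr::filter(at, .data$elesy %in% c("N", "O", "S"))
  if (nrow(da) < 2) return(pair_records_empty())
  dm <- cross_dist(coords_of(da), coords_of(da))
  idx <- which(dm <= d_a_cutoff & upper.tri(dm), arr.ind = TRUE)
  if (!nrow(idx)) return(pair_records_empty())
  i <- idx[, 1]; j <- idx[, 2]
  same_res <- da$chain[i] == da$chain[j] & da$resno[i] == da$resno[j]
  backbone <- c("N", "O", "OXT")
  adj_bb <- da$chain[i] == da$chain[j] &
    abs(da$resno[i] - da$resno[j]) == 1 &
    da$elety[i] %in% backbone & da$elety[j] %in% backbone
  keep <- !same_res & !adj_bb
  if (!any(keep)) return(pair_records_empty())
  i <- i[keep]; j <- j[keep]
  tibble::tibble(
    kind = "hbond",
    chain1 = da$chain[i], res1 = da$resno[i], resid1 = da$resid[i],
    atom1 = da$elety[i],
    chain2 = da$chain[j], res2 = da$resno[j], resid2 = da$resid[j],
    atom2 = da$elety[j],
    distance = dm[cbind(i, j)]
  ) |> dplyr::arrange(.data$chain1, .data$res1, .data$res2)
}

#' Domain-domain interface contacts with polar/hydrophobic classification
#'
#' Enumerates inter-domain atom pairs and classifies each contact the way
#' LigPlot/Dimplot's interface module does: `Polar` when both atoms are
#' nitrogen or oxygen and the distance is at most `polar_cutoff` (3.35 A);
#' `Hydrophobic` when at least one atom is carbon and the distance is at
#' most `nonpolar_cutoff` (3.90 A). Residues in `exclude` (e.g. hinge
#' regions between the domains) are removed before pairing.
#'
#' @param s A `pk_structure`.
#' @param dom_a,dom_b `pk_domain` definitions (see [domain_definition()],
#'   [pk_domains()]); must not overlap.
#' @param chain Chain to analyse (default: each chain separately).
#' @param exclude Optional `pk_domain` or numeric residue numbers removed
#'   from both sides before pairing.
#' @param polar_cutoff,nonpolar_cutoff Distance cutoffs, Angstrom.
#' @return Tibble: `kind`, `chain`, `res1`/`resid1`/`atom1` (domain-A side),
#'   `res2`/`resid2`/`atom2` (domain-B side), `distance`, `contact_class`.
#' @export
interface_contacts <- function(s, dom_a, dom_b, chain = NULL, exclude = NULL,
                               polar_cutoff = 3.35, nonpolar_cutoff = 3.90) {
  ra <- domain_resnos(dom_a)
  rb <- domain_resnos(dom_b)
  if (length(intersect(ra, rb))) abort("domain definitions overlap")
  if (!is.null(exclude)) {
    ex <- if (inherits(exclude, "pk_domain")) domain_resnos(exclude) else exclude
    ra <- setdiff(ra, ex); rb <- setdiff(rb, ex)
  }
  at <- s$atoms
  if (!is.null(chain)) at <- dplyr::filter(at, .data$chain %in% !!chain)
  out <- purrr::map_dfr(split(at, at$chain), function(ac) {
    aa <- dplyr::filter(ac, .data$resno %in% ra, .data$type == "ATOM")
    ab <- dplyr::filter(ac, .data$resno %in% rb, .data$type == "ATOM")
    if (!nrow(aa) || !nrow(ab)) return(NULL)
    dm <- cross_dist(coords_of(aa), coords_of(ab))
    idx <- which(dm <= max(polar_cutoff, nonpolar_cutoff), arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    i <- idx[, 1]; j <- idx[, 2]
    d <- dm[idx]
    both_no <- aa$elesy[i] %in% c("N", "O") & ab$elesy[j] %in% c("N", "O")
    any_c <- aa$elesy[i] == "C" | ab$elesy[j] == "C"
    cls <- dplyr::case_when(
      both_no & d <= polar_cutoff ~ "Polar",
      any_c & d <= nonpolar_cutoff ~ "Hydrophobic",
      TRUE ~ NA_character_
    )
    keep <- !is.na(cls)
    if (!any(keep)) return(NULL)
    tibble::tibble(
      kind = "interface_contact", chain = ac$chain[1],
      res1 = aa$resno[i][keep], resid1 = aa$resid[i][keep],
      atom1 = aa$elety[i][keep],
      res2 = ab$resno[j][keep], resid2 = ab$resid[j][keep],
      atom2 = ab$elety[j][keep],
      distance = d[keep], contact_class = cls[keep]
    )
  })
  if (!nrow(out)) {
    return(tibble::tibble(kind = character(), chain = character(),
                          res1 = numeric(), resid1 = character(),
                          atom1 = character(), res2 = numeric(),
                          resid2 = character(), atom2 = character(),
                          distance = numeric(), contact_class = character()))
  }
  dplyr::arrange(out, .data$chain, .data$res1, .data$res2, .data$distance)
}
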