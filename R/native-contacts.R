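#' Native Calpha contact map of a reference structure
#'
#' All Calpha pairs within `cutoff` whose residues are at least
#' `min_seq_sep` apart in sequence (same chain), optionally restricted to a
#' domain. Residues present in the structure but lacking a Calpha atom are
#' skipped with a warning.
#'
#' @param reference A `pk_structure`.
#' @param cutoff Calpha-Calpha distance cutoff, Angstrom (default 8).
#' @param min_seq_sep Minimum residue separation |j - i| (default 3).
#' @param selection Optional `pk_domain` or residue numbers to restrict to.
#' @param chain Optional chain restriction.
#' @return A `pk_contacts` object: tibble `pairs` (`chain`, `i`, `j`,
#'   `native_distance`), the ordered reference Calpha table `ca` used for
#'   frame matching, and the settings.
#' @export
native_contact_map <- function(reference, cutoff = 8.0, min_seq_sep = 3,
                               selection = NULL, chain = NULL) {
  at <- reference$atoms
  if (!is.null(chain)) at <- dplyr::filter(at, .data$chain %in% !!chain)
  at <- dplyr::filter(at, .data$type == "ATOM")
  if (!is.null(selection)) {
    sel <- if (inherits(selection, "pk_domain")) domain_resnos(selection) else selection
    at <- dplyr::filter(at, .data$resno %in% sel)
  }
  res <- dplyr::distinct(at, .data$chain, .data$resno)
  ca <- dplyr::filter(at, .data$elety == "CA") |>
    dplyr::arrange(.data$chain, .data$resno)
  missing <- dplyr::anti_join(res, ca, by = c("chain", "resno"))
  if (nrow(missing)) {
    warn(paste0(nrow(missing), " selected residue(s) lack a CA atom; skipped"))
  }

  pairs <- if (nrow(ca) >= 2 && cutoff > 0) {
    dm <- cross_dist(coords_of(ca), coords_of(ca))
    idx <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
    if (nrow(idx)) {
      ri <- idx[, 1]; rj <- idx[, 2]
      keep <- ca$chain[ri] == ca$chain[rj] &
        abs(ca$resno[rj] - ca$resno[ri]) >= min_seq_sep
      tibble::tibble(
        chain = ca$chain[ri][keep], i = ca$resno[ri][keep],
        j = ca$resno[rj][keep], native_distance = dm[idx][keep],
        ai = ri[keep], aj = rj[keep]
      )
    } else tibble::tibble(chain = character(), i = numeric(), j = numeric(),
                          native_distance = numeric(), ai = integer(),
                          aj = integer())
  } else tibble::tibble(chain = character(), i = numeric(), j = numeric(),
                        native_distance = numeric(), ai = integer(),
                        aj = integer())

  structure(list(pairs = pairs, ca = ca,
                 settings = list(cutoff = cutoff, min_seq_sep = min_seq_sep)),
            class = "pk_contacts")
}

#' @export
print.pk_contacts <- function(x, ...) {
  cat("<pk_contacts>", nrow(x$pairs), "native contacts over", nrow(x$ca),
      "CA atoms | cutoff", x$settings$cutoff, "A | min separation",
      x$settings$min_seq_sep, "\n")
  invisible(x)
}

#' Fraction of native contacts per trajectory frame
#'
#' For each frame, Q = the fraction of the reference contact pairs whose
#' Calpha distance is at most `tolerance_factor` times the native distance.
#' Frame atoms must be ordered as the reference Calpha table of the contact
#' map (`contacts$ca`).
#'
#' @param traj A `pk_trajectory` (from [make_trajectory()] or
#'   [read_trajectory()]): list with `coords`, a list of n_atoms x 3
#'   matrices, and optional `time`.
#' @param contacts A `pk_contacts` from [native_contact_map()].
#' @param tolerance_factor Retention tolerance on the native distance
#'   (default 1.2).
#' @return A `pk_qseries` tibble: `frame`, `time`, `q` in \[0, 1\].
#' @export
q_trajectory <- function(traj, contacts, tolerance_factor = 1.2) {
  if (!inherits(contacts, "pk_contacts")) {
    abort("`contacts` must come from native_contact_map()")
  }
  frames <- traj$coords
  n_ref <- nrow(contacts$ca)
  if (!length(frames)) abort("trajectory has no frames")
  if (any(vapply(frames, nrow, 1L) != n_ref)) {
    abort(paste0("frame size does not match the ", n_ref,
                 "-atom reference selection"))
  }
  if (!nrow(contacts$pairs)) abort("contact set is empty")
  ai <- contacts$pairs$ai
  aj <- contacts$pairs$aj
  lim <- tolerance_factor * contacts$pairs$native_distance
  q <- vapply(frames, function(m) {
    d <- sqrt(rowSums((m[ai, , drop = FALSE] - m[aj, , drop = FALSE])^2))
    mean(d <= lim)
  }, numeric(1))
  tm <- if (!is.null(traj$time)) traj$time else seq_along(frames)
  out <- tibble::tibble(frame = seq_along(frames), time = tm, q = q)
  class(out) <- c("pk_qseries", class(out))
  attr(out, "tolerance_factor") <- tolerance_factor
  out
}

#' Read a Calpha coordinate trajectory
#'
#' Two plain-text formats: a multi-MODEL PDB (each MODEL a frame; Calpha
#' atoms extracted in chain/residue order), or a bare xyz table (`natoms`
#' on the first line, then `natoms` rows of `x y z` per frame).
#'
#' @param path Input file.
#' @param format `"pdb"` or `"xyz"`.
#' @return A `pk_trajectory`: list of per-frame coordinate matrices plus
#'   `time` (frame index).
#' @export
read_trajectory <- function(path, format = c("pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    ca_idx <- which(pdb$atom$elety == "CA")
    ord <- ca_idx[order(pdb$atom$chain[ca_idx], pdb$atom$resno[ca_idx])]
    nf <- nrow(pdb$xyz)
    coords <- lapply(seq_len(nf), function(f) {
      m <- matrix(pdb$xyz[f, ], ncol = 3, byrow = TRUE)
      m[ord, , drop = FALSE]
    })
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    n <- as.integer(lines[1])
    body <- matrix(as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+"))),
                   ncol = 3, byrow = TRUE)
    if (nrow(body) %% n != 0) abort("xyz trajectory length is not a multiple of natoms")
    coords <- lapply(seq_len(nrow(body) / n), function(f) {
      body[((f - 1) * n + 1):(f * n), , drop = FALSE]
    })
  }
  structure(list(coords = coords, time = seq_along(coords)),
            class = "pk_trajectory")
}

#' Write a Calpha trajectory as a multi-MODEL PDB
#'
#' @param traj A `pk_trajectory`.
#' @param ca Reference Calpha atom table (chain, resno, resid) giving the
#'   atom identities; defaults to sequential alanines on chain A.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, ca = NULL) {
  n <- nrow(traj$coords[[1]])
  if (is.null(ca)) {
    ca <- tibble::tibble(chain = "A", resno = seq_len(n), resid = "ALA")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$coords)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- traj$coords[[f]]
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(n), ca$resid, ca$chain, ca$resno, m[, 1], m[, 2], m[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
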