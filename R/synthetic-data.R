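# Seeded generators for every input the pipeline consumes: kinetics tables
# with a prescribed noise model, idealised-geometry structure fixtures,
# contact-breaking trajectories, and alignments with planted column
# frequencies. All are bit-reproducible functions of (spec, seed).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Measurement noise model for synthetic velocities
#'
#' @param kind `"gaussian_relative"` (sd = scale x true velocity, the
#'   default, matching the visual scatter of published initial-velocity
#'   data) or `"gaussian_absolute"` (sd = scale, in velocity units).
#' @param scale Noise scale, >= 0 (default 0.05, i.e. 5% relative).
#' @return A `pk_noise` list.
#' @export
noise_model <- function(kind = c("gaussian_relative", "gaussian_absolute"),
                        scale = 0.05) {
  kind <- match.arg(kind)
  check_nonneg(scale, "scale")
  structure(list(kind = kind, scale = scale), class = "pk_noise")
}

# simplified bisubstrate laws used as mechanism-classifier oracles
rate_ordered <- function(a, b, vmax, ka, kb, kia) {
  vmax * a * b / (kia * kb + kb * a + ka * b + a * b)
}
rate_ping_pong <- function(a, b, vmax, ka, kb) {
  vmax * a * b / (ka * b + kb * a + a * b)
}

generator_rate <- function(model, design, params) {
  p <- params
  switch(model,
    ordered = rate_ordered(design$a, design$b, p[["vmax"]], p[["ka"]],
                           p[["kb"]], p[["kia"]]),
    ping_pong = rate_ping_pong(design$a, design$b, p[["vmax"]], p[["ka"]],
                               p[["kb"]]),
    {
      spec <- model_spec(model)
      spec$rate(design, setNames(as.numeric(p[spec$params]), spec$params))
    }
  )
}

#' Generate a synthetic initial-velocity dataset
#'
#' Evaluates a rate law on a concentration design and adds seeded Gaussian
#' noise (truncated at zero — velocities are non-negative; the slight
#' upward bias this causes at low velocity is documented). In addition to
#' the fit models, the generator knows the simplified `"ordered"` (needs a
#' `kia` parameter) and `"ping_pong"` bisubstrate laws used as oracles for
#' the pattern classifier.
#'
#' @param model Model name (see [fit_global()], plus `"ordered"` and
#'   `"ping_pong"`).
#' @param params Named parameter vector for the model.
#' @param design Data frame of concentrations (`a`, `b` or `s`, `i` or
#'   `s`), e.g. from [design_initial_velocity()] / [design_inhibition()].
#' @param noise A [noise_model()] (default 5% relative Gaussian).
#' @param replicates Replicate measurements per grid point (default 1).
#' @param seed RNG seed.
#' @return A tibble: the design columns, `replicate`, `v`, with generator
#'   settings in the `meta` attribute and the varied axis in `varied`.
#' @examples
#' make_velocity_dataset("hill", c(vmax = 41, k05 = 0.02, n = 1.6),
#'   design = tibble::tibble(s = c(0.005, 0.01, 0.02, 0.05, 0.2)),
#'   noise = noise_model(scale = 0), replicates = 2)
#' @export
make_velocity_dataset <- function(model, params, design,
                                  noise = noise_model(), replicates = 1,
                                  seed = 1) {
  design <- tibble::as_tibble(design)
  varied <- attr(design, "varied")
  out <- tidyr::expand_grid(design, replicate = seq_len(replicates))
  mu <- generator_rate(model, out, params)
  if (any(!is.finite(mu) | mu < 0)) abort("rate law produced invalid velocities")
  eps <- with_seed(seed, switch(noise$kind,
    gaussian_relative = rnorm(length(mu), 0, noise$scale) * mu,
    gaussian_absolute = rnorm(length(mu), 0, noise$scale)
  ))
  out$v <- pmax(mu + eps, 0)
  attr(out, "varied") <- varied
  attr(out, "meta") <- list(model = model, params = params, noise = noise,
                            replicates = replicates, seed = seed)
  out
}

# fixture-structure group constructors ---------------------------------------

#' Building blocks for idealised structure fixtures
#'
#' Group constructors consumed by [make_fixture_structure()]:
#' * `phe_ring(center, normal)` — a phenylalanine ring as a regular hexagon
#'   of carbons (bond length 1.39 A) centred at `center`, perpendicular to
#'   `normal`;
#' * `lys_glu_pair(at, distance, direction)` — Lys NZ at `at` and Glu
#'   OE1 `distance` away along `direction` (a salt-bridge pair);
#' * `backbone_hbond(at, distance, direction)` — a backbone carbonyl O and
#'   an amide N `distance` apart on non-adjacent residues;
#' * `ca_chain(n, spacing, start, direction)` — `n` collinear Calpha atoms.
#'
#' @param center,at,start 3-vectors, Angstrom.
#' @param normal,direction 3-vectors (normalised internally).
#' @param distance Pair distance, Angstrom.
#' @param n Number of residues.
#' @param spacing Calpha spacing, Angstrom (default 3.8).
#' @return A group spec list for [make_fixture_structure()].
#' @name fixture_groups
NULL

#' @rdname fixture_groups
#' @export
phe_ring <- function(center, normal = c(0, 0, 1)) {
  list(type = "phe_ring", center = center, normal = normal / sqrt(sum(normal^2)))
}

#' @rdname fixture_groups
#' @export
lys_glu_pair <- function(at = c(0, 0, 0), distance = 3.0,
                         direction = c(1, 0, 0)) {
  list(type = "lys_glu_pair", at = at, distance = distance,
       direction = direction / sqrt(sum(direction^2)))
}

#' @rdname fixture_groups
#' @export
backbone_hbond <- function(at = c(0, 0, 0), distance = 2.9,
                           direction = c(1, 0, 0)) {
  list(type = "backbone_hbond", at = at, distance = distance,
       direction = direction / sqrt(sum(direction^2)))
}

#' @rdname fixture_groups
#' @export
ca_chain <- function(n, spacing = 3.8, start = c(0, 0, 0),
                     direction = c(1, 0, 0)) {
  list(type = "ca_chain", n = n, spacing = spacing, start = start,
       direction = direction / sqrt(sum(direction^2)))
}

orthobasis <- function(normal) {
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * normal) * normal
  u <- u / sqrt(sum(u^2))
  v <- c(normal[2] * u[3] - normal[3] * u[2],
         normal[3] * u[1] - normal[1] * u[3],
         normal[1] * u[2] - normal[2] * u[1])
  list(u = u, v = v)
}

#' Build an idealised-geometry structure fixture
#'
#' Places the requested groups (see [fixture_groups]) as residues of chain
#' A with ideal geometry, separated by at least 4 in residue numbering so
#' no pair is treated as covalently adjacent. Placements whose atoms from
#' different groups come within 2 A of each other are rejected as clashing.
#'
#' @param groups List of group specs.
#' @return A `pk_structure` with known, analytically prescribed geometry.
#' @examples
#' s <- make_fixture_structure(list(
#'   phe_ring(c(0, 0, 0)), phe_ring(c(0, 0, 4)),
#'   lys_glu_pair(at = c(30, 0, 0), distance = 3.0)))
#' pi_pi_pairs(s)     # 4.0 A, 0 deg
#' salt_bridges(s)    # one bridge at 3.0 A
#' @export
make_fixture_structure <- function(groups) {
  resno <- 1
  rows <- list()
  group_id <- integer()
  add <- function(resid, elety, xyz, rn) {
    tibble::tibble(chain = "A", resno = rn, insert = "", resid = resid,
                   elety = elety, elesy = element_from_name(elety),
                   x = xyz[1], y = xyz[2], z = xyz[3], o = 1, type = "ATOM")
  }
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    new <- switch(g$type,
      phe_ring = {
        b <- orthobasis(g$normal)
        ang <- (0:5) * pi / 3
        nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
        purrr::map2_dfr(ang, nm, function(a, name) {
          p <- g$center + 1.39 * (cos(a) * b$u + sin(a) * b$v)
          add("PHE", name, p, resno)
        })
      },
      lys_glu_pair = {
        o1 <- g$at + g$distance * g$direction
        perp <- orthobasis(g$direction)$u
        dplyr::bind_rows(
          add("LYS", "CA", g$at - 2.5 * perp, resno),
          add("LYS", "NZ", g$at, resno),
          add("GLU", "CA", o1 + 2.5 * perp, resno + 4),
          add("GLU", "OE1", o1, resno + 4),
          add("GLU", "OE2", o1 + 1.1 * perp, resno + 4)
        )
      },
      backbone_hbond = {
        n1 <- g$at + g$distance * g$direction
        perp <- orthobasis(g$direction)$u
        dplyr::bind_rows(
          add("ALA", "CA", g$at - 2.4 * perp, resno),
          add("ALA", "C", g$at - 1.23 * perp, resno),
          add("ALA", "O", g$at, resno),
          add("GLY", "CA", n1 + 1.5 * perp, resno + 4),
          add("GLY", "N", n1, resno + 4)
        )
      },
      ca_chain = {
        purrr::map_dfr(seq_len(g$n), function(k) {
          add("GLY", "CA", g$start + (k - 1) * g$spacing * g$direction,
              resno + (k - 1))
        })
      },
      abort(paste0("unknown fixture group type `", g$type, "`"))
    )
    resno <- max(new$resno) + 5
    group_id <- c(group_id, rep(gi, nrow(new)))
    rows[[gi]] <- new
  }
  atoms <- dplyr::bind_rows(rows)
  if (length(unique(group_id)) > 1) {
    xyz <- coords_of(atoms)
    dm <- cross_dist(xyz, xyz)
    inter <- outer(group_id, group_id, "!=")
    if (any(dm[inter] < 2.0)) abort("overlapping placements: groups clash (< 2 A)")
  }
  structure(list(atoms = atoms, source = "<fixture>"), class = "pk_structure")
}

#' Generate a trajectory that breaks native contacts on schedule
#'
#' Starting from the Calpha selection of a reference structure, emits one
#' frame per schedule entry in which the prescribed fraction of the native
#' contacts is broken: contacts are put in a seeded random order once, the
#' first `ceil(fraction * n)` are broken in each frame (so a monotone
#' schedule breaks contacts irreversibly), and a contact is broken by
#' displacing its second partner far beyond the retention tolerance. When
#' each atom takes part in at most one contact (as in the paired fixtures
#' built with [ca_chain()] clusters), [q_trajectory()] on the result
#' reproduces `1 - schedule` exactly to one-contact resolution.
#'
#' @param reference A `pk_structure`.
#' @param schedule Numeric vector in \[0, 1\]: fraction of contacts broken
#'   per frame. Empty schedule = a single unperturbed frame.
#' @param seed Seed for the breaking order.
#' @param contacts Optional precomputed [native_contact_map()]; defaults to
#'   the map of `reference` with default settings.
#' @param displacement How far a broken partner is moved, Angstrom.
#' @return A `pk_trajectory` whose frames match `contacts$ca`.
#' @export
make_trajectory <- function(reference, schedule = numeric(), seed = 1,
                            contacts = NULL, displacement = 50) {
  if (any(schedule < 0 | schedule > 1)) abort("schedule must lie in [0, 1]")
  if (is.null(contacts)) contacts <- native_contact_map(reference)
  base <- coords_of(contacts$ca)
  nc <- nrow(contacts$pairs)
  if (!length(schedule)) {
    return(structure(list(coords = list(base), time = 1),
                     class = "pk_trajectory"))
  }
  if (nc == 0) abort("reference has no native contacts to break")
  ord <- with_seed(seed, sample.int(nc))
  coords <- lapply(schedule, function(fr) {
    m <- base
    nb <- ceiling(fr * nc - 1e-9)
    if (nb > 0) {
      atoms <- unique(contacts$pairs$aj[ord[seq_len(nb)]])
      m[atoms, 3] <- m[atoms, 3] + displacement
    }
    m
  })
  structure(list(coords = coords, time = seq_along(schedule)),
            class = "pk_trajectory")
}

#' Generate a multiple alignment with planted column frequencies
#'
#' Builds `n_sequences` aligned rows in which specified reference positions
#' carry prescribed residue frequencies and all other positions are a
#' constant background. Frequencies are realised by exact largest-remainder
#' allocation of counts followed by a seeded shuffle, so the realised
#' column composition matches the specification as closely as `n` allows
#' (and converges to it exactly as `n` grows). Optional reference-gap
#' columns insert `-` into the reference row (other rows get a residue),
#' exercising gap-aware position mapping.
#'
#' @param n_sequences Total number of sequences, reference row included.
#' @param column_spec Named list: names are reference positions, values are
#'   named frequency vectors over residues (may include `"-"`); each must
#'   sum to 1.
#' @param length Ungapped reference length (default: past the last
#'   specified position).
#' @param reference_gaps Alignment columns (after insertion) at which the
#'   reference has a gap.
#' @param seed RNG seed.
#' @param reference_id Name of the reference row (default `"ref"`).
#' @return Named character vector of aligned sequences, reference first.
#' @examples
#' aln <- make_alignment(10, list(`5` = c(E = 0.7, K = 0.3)))
#' column_profile(aln, "ref", 5)
#' @export
make_alignment <- function(n_sequences, column_spec, length = NULL,
                           reference_gaps = integer(), seed = 1,
                           reference_id = "ref") {
  pos <- as.integer(names(column_spec))
  if (any(is.na(pos))) abort("column_spec names must be reference positions")
  for (fq in column_spec) {
    if (abs(sum(fq) - 1) > 1e-8) abort("column frequencies must sum to 1")
  }
  L <- if (is.null(length)) max(pos) + 2 else length
  if (any(pos > L)) abort("specified position beyond alignment length")

  # row 1 is the reference; planted frequencies are realised across all rows
  # (the reference is part of the alignment the logo is computed on) by
  # exact largest-remainder allocation, then a seeded shuffle
  base <- matrix("A", nrow = n_sequences, ncol = L)
  with_seed(seed, {
    for (k in seq_along(pos)) {
      fq <- column_spec[[k]]
      counts <- floor(fq * n_sequences)
      rem <- n_sequences - sum(counts)
      if (rem > 0) {
        frac <- fq * n_sequences - counts
        top <- order(frac, decreasing = TRUE)[seq_len(rem)]
        counts[top] <- counts[top] + 1
      }
      col <- sample(rep(names(fq), counts))
      if (col[1] == "-") { # the reference row cannot carry a planted gap
        sw <- which(col != "-")[1]
        if (is.na(sw)) abort("column spec is all-gap; reference needs a residue")
        col[c(1, sw)] <- col[c(sw, 1)]
      }
      base[, pos[k]] <- col
    }
  })

  # insert reference-gap columns: reference '-', other rows a residue
  ncol_out <- L + base::length(reference_gaps)
  keep <- setdiff(seq_len(ncol_out), reference_gaps)
  out <- matrix("G", nrow = n_sequences, ncol = ncol_out)
  out[, keep] <- base
  out[1, ] <- "-"
  out[1, keep] <- base[1, ]

  seqs <- apply(out, 1, paste, collapse = "")
  names(seqs) <- c(reference_id,
                   if (n_sequences > 1) paste0("seq", seq_len(n_sequences - 1)))
  seqs
}

#' Write an alignment to FASTA
#'
#' @param alignment Named character vector of aligned sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment), path)
  invisible(path)
}
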