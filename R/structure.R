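#' Read a PDB structure into an atom table
#'
#' Parses ATOM/HETATM records (via [bio3d::read.pdb()]) into a tidy atom
#' tibble. Alternate locations are resolved by keeping, per
#' (chain, residue, atom name), the record with the highest occupancy,
#' breaking ties in favour of altloc 'A'. Author residue numbering
#' (1-based) and insertion codes are preserved. Missing element symbols are
#' derived from the atom name.
#'
#' @param x Path to a PDB file, or a character vector of PDB-format lines.
#' @return A `pk_structure`: list with `atoms` (tibble: `chain`, `resno`,
#'   `insert`, `resid`, `elety` (atom name), `elesy` (element), `x`, `y`,
#'   `z`, `o`) and `source`.
#' @export
read_structure <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) &&
      grepl("\\.(pdb|ent)$", x, ignore.case = TRUE)) {
    if (!file.exists(x)) abort(paste0("PDB file not found: ", x))
    src <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    src <- basename(x)
    lines <- readLines(x, warn = FALSE)
  } else {
    src <- "<text>"
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  rec <- grepl("^(ATOM  |HETATM)", lines)
  bad <- which(rec & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38))))))
  if (length(bad)) {
    abort(paste0("malformed fixed-width PDB record at line ", bad[1], ": ",
                 substr(lines[bad[1]], 1, 30), "..."))
  }
  if (!any(rec)) abort("no ATOM/HETATM records found")

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- suppressWarnings(bio3d::read.pdb(tmp, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- tibble::as_tibble(pdb$atom)

  at$elesy <- ifelse(is.na(at$elesy) | at$elesy == "",
                     element_from_name(at$elety), trimws(at$elesy))
  at$chain <- ifelse(is.na(at$chain), " ", at$chain)
  at$insert <- ifelse(is.na(at$insert), "", at$insert)
  at$alt <- ifelse(is.na(at$alt), "", at$alt)
  at$o <- ifelse(is.na(at$o), 1, at$o)
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    abort("non-finite coordinates in PDB input")
  }

  atoms <- at |>
    dplyr::arrange(dplyr::desc(.data$o),
                   match(.data$alt, c("", "A"), nomatch = 3L)) |>
    dplyr::distinct(.data$chain, .data$resno, .data$insert, .data$elety,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$chain, .data$resno, .data$insert, .data$eleno) |>
    dplyr::select("chain", "resno", "insert", "resid", "elety", "elesy",
                  "x", "y", "z", "o", "type")

  structure(list(atoms = atoms, source = src), class = "pk_structure")
}

element_from_name <- function(name) {
  n <- sub("^[0-9]*", "", trimws(name))
  substr(n, 1, 1)
}

#' Write a structure back to PDB format
#'
#' @param s A `pk_structure`.
#' @param path Output file; omit to get the PDB text invisibly.
#' @return The PDB lines, invisibly.
#' @export
write_structure <- function(s, path = NULL) {
  at <- s$atoms
  tmp <- if (is.null(path)) tempfile(fileext = ".pdb") else path
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = if ("type" %in% names(at)) at$type else rep("ATOM", nrow(at)),
    resno = at$resno, resid = at$resid, eleno = seq_len(nrow(at)),
    elety = at$elety, chain = at$chain, insert = at$insert,
    o = at$o, b = rep(0, nrow(at)), elesy = at$elesy
  )
  out <- readLines(tmp, warn = FALSE)
  if (is.null(path)) unlink(tmp)
  invisible(out)
}

#' @export
print.pk_structure <- function(x, ...) {
  cat("<pk_structure>", x$source, "|", nrow(x$atoms), "atoms |",
      dplyr::n_distinct(x$atoms$chain), "chain(s) |",
      nrow(dplyr::distinct(x$atoms, .data$chain, .data$resno, .data$insert)),
      "residues\n")
  invisible(x)
}

#' Define a domain as residue intervals
#'
#' @param name Domain label.
#' @param ranges List of inclusive `c(start, end)` residue intervals, or a
#'   string like `"1-65,165-334"` (author numbering).
#' @return A `pk_domain` with non-overlapping, sorted intervals.
#' @examples
#' domain_definition("B", "66-164")
#' @export
domain_definition <- function(name, ranges) {
  if (is.character(ranges)) {
    parts <- strsplit(ranges, ",", fixed = TRUE)[[1]]
    ranges <- lapply(parts, function(p) {
      se <- as.numeric(strsplit(trimws(p), "-", fixed = TRUE)[[1]])
      if (length(se) == 1) c(se, se) else se
    })
  }
  m <- do.call(rbind, lapply(ranges, function(r) {
    if (length(r) != 2 || any(!is.finite(r)) || r[2] < r[1]) {
      abort("each range must be c(start, end) with end >= start")
    }
    r
  }))
  m <- m[order(m[, 1]), , drop = FALSE]
  if (nrow(m) > 1 && any(m[-1, 1] <= m[-nrow(m), 2])) {
    abort(paste0("overlapping intervals in domain `", name, "`"))
  }
  structure(list(name = name, ranges = m), class = "pk_domain")
}

domain_resnos <- function(dom) {
  unlist(lapply(seq_len(nrow(dom$ranges)), function(k)
    seq(dom$ranges[k, 1], dom$ranges[k, 2])))
}

#' @export
print.pk_domain <- function(x, ...) {
  cat("<pk_domain>", x$name, ":",
      paste(apply(x$ranges, 1, paste, collapse = "-"), collapse = ", "), "\n")
  invisible(x)
}

#' Published A/B domain boundaries of three pyruvate kinases
#'
#' Lid (B) and body (A) domain intervals in author numbering: TpPK B 66-164,
#' A 1-65 + 165-334; PaPK B 81-177, A 1-80 + 178-346; RMPK B 116-223,
#' A 43-115 + 224-387.
#'
#' @param protein `"TpPK"`, `"PaPK"` or `"RMPK"`.
#' @return List with `pk_domain` elements `A` and `B`.
#' @export
pk_domains <- function(protein = c("TpPK", "PaPK", "RMPK")) {
  protein <- match.arg(protein)
  switch(protein,
    TpPK = list(A = domain_definition("A", "1-65,165-334"),
                B = domain_definition("B", "66-164")),
    PaPK = list(A = domain_definition("A", "1-80,178-346"),
                B = domain_definition("B", "81-177")),
    RMPK = list(A = domain_definition("A", "43-115,224-387"),
                B = domain_definition("B", "116-223"))
  )
}

# geometry helpers -----------------------------------------------------------

cross_dist <- function(m1, m2) {
  # m1: n x 3, m2: m x 3 -> n x m euclidean distances
  sq1 <- rowSums(m1^2)
  sq2 <- rowSums(m2^2)
  d2 <- outer(sq1, sq2, "+") - 2 * tcrossprod(m1, m2)
  sqrt(pmax(d2, 0))
}

coords_of <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])
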