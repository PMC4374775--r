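# Column conservation and covariation at reference-numbered positions of a
# multiple sequence alignment (the computation behind sequence-logo stacks).

as_alignment <- function(x) {
  if (inherits(x, "AAStringSet") || inherits(x, "BStringSet")) {
    x <- as.character(x)
  } else if (is.character(x) && length(x) == 1 && !grepl("\n", x) &&
             file.exists(x)) {
    x <- as.character(Biostrings::readAAStringSet(x))
  }
  if (!is.character(x) || is.null(names(x))) {
    abort("alignment must be a FASTA path, an AAStringSet, or a named character vector")
  }
  x <- toupper(chartr(".", "-", x))
  if (dplyr::n_distinct(nchar(x)) != 1) {
    abort("alignment rows have unequal lengths")
  }
  x
}

# alignment column holding reference position p (1-based, gap-aware)
ref_columns <- function(refseq, positions) {
  chars <- strsplit(refseq, "")[[1]]
  cum <- cumsum(chars != "-")
  vapply(positions, function(p) {
    if (p < 1 || p > max(cum)) {
      abort(paste0("position ", p, " is beyond the reference length ", max(cum)))
    }
    match(p, cum)
  }, integer(1))
}

#' Residue frequencies at reference-numbered alignment positions
#'
#' Locates, for each requested position of the reference sequence, the
#' alignment column holding it (counting non-gap reference characters
#' through the reference's own gaps) and tabulates the relative frequency
#' of every residue (and of the gap character) across all sequences — the
#' numbers a sequence-logo stack displays.
#'
#' @param alignment FASTA file path, `AAStringSet`, or named character
#'   vector of aligned sequences. `-` and `.` are gaps; case-insensitive.
#' @param reference_id Name of the reference sequence.
#' @param positions Reference-sequence positions (1-based, ungapped).
#' @return A `pk_profile` tibble: `position`, `column` (alignment column),
#'   `residue`, `frequency` (sums to 1 per position over residues + gap),
#'   with attributes `reference` and `n_sequences`.
#' @examples
#' aln <- c(ref = "MK-VL", s2 = "MKAVL", s3 = "MKAIL")
#' column_profile(aln, "ref", positions = 3)  # column 4: V 2/3, I 1/3
#' @export
column_profile <- function(alignment, reference_id, positions) {
  aln <- as_alignment(alignment)
  if (!reference_id %in% names(aln)) {
    abort(paste0("reference sequence `", reference_id, "` not in alignment"))
  }
  cols <- ref_columns(aln[[reference_id]], positions)
  mat <- do.call(rbind, strsplit(aln, ""))
  out <- purrr::map2_dfr(positions, cols, function(p, cl) {
    tab <- table(mat[, cl]) / nrow(mat)
    tibble::tibble(position = p, column = cl,
                   residue = names(tab), frequency = as.numeric(tab))
  })
  attr(out, "reference") <- reference_id
  attr(out, "n_sequences") <- length(aln)
  class(out) <- c("pk_profile", class(out))
  out
}

#' Covariation fraction at reference-numbered positions
#'
#' Among the sequences carrying a given anchor residue at an anchor
#' position, the fraction that simultaneously satisfy every partner
#' constraint (a position plus an allowed residue set). This is the
#' statistic behind statements like "Leu113/Gln114 and a hydrophobic
#' residue at 120 are covariant in 77% of the PKs that contain Lys117".
#'
#' @param alignment As in [column_profile()].
#' @param reference_id Reference sequence name (positions are numbered on
#'   it).
#' @param anchor List `list(position =, residue =)`.
#' @param partners List of `list(position =, residues =)` constraints
#'   (residues = allowed set).
#' @return A one-row tibble: `n_anchor`, `n_match`, `fraction`.
#' @export
covariation <- function(alignment, reference_id, anchor, partners) {
  aln <- as_alignment(alignment)
  if (!reference_id %in% names(aln)) {
    abort(paste0("reference sequence `", reference_id, "` not in alignment"))
  }
  pos <- c(anchor$position, vapply(partners, `[[`, numeric(1), "position"))
  cols <- ref_columns(aln[[reference_id]], pos)
  mat <- do.call(rbind, strsplit(aln, ""))
  in_anchor <- mat[, cols[1]] == toupper(anchor$residue)
  n_anchor <- sum(in_anchor)
  if (n_anchor == 0) {
    abort("anchor matched by zero sequences; covariation fraction is undefined")
  }
  ok <- rep(TRUE, nrow(mat))
  for (k in seq_along(partners)) {
    ok <- ok & mat[, cols[k + 1]] %in% toupper(partners[[k]]$residues)
  }
  n_match <- sum(in_anchor & ok)
  tibble::tibble(n_anchor = n_anchor, n_match = n_match,
                 fraction = n_match / n_anchor)
}
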