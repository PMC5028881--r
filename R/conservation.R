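check_alignment <- function(alignment) {
  if (!is.character(alignment) || length(alignment) == 0L) {
    ph1_error("alignment must be a non-empty named character vector of rows",
              "ph1_alignment_error")
  }
  if (is.null(names(alignment)) || any(!nzchar(names(alignment)))) {
    ph1_error("alignment rows must be named by sequence id", "ph1_alignment_error")
  }
  if (anyDuplicated(names(alignment))) {
    ph1_error("duplicate sequence ids in alignment", "ph1_alignment_error")
  }
  w <- nchar(alignment)
  if (length(unique(w)) != 1L) {
    ph1_error(sprintf("ragged alignment: row widths %s", paste(unique(w), collapse = ", ")),
              "ph1_alignment_error")
  }
  invisible(alignment)
}

#' Map a protein position to its alignment column
#'
#' Alignment rows may contain gaps (`-`); residue `prot_pos` of the
#' reference sequence (1-based, gaps not counted) sits in some alignment
#' column, which is what per-column conservation is computed over.
#'
#' @param alignment named character vector of equal-length aligned rows.
#' @param reference_id name of the reference row.
#' @param prot_pos 1-based residue position in the ungapped reference.
#' @return the 0-based alignment column index.
#' @export
map_position_to_column <- function(alignment, reference_id, prot_pos) {
  check_alignment(alignment)
  if (!reference_id %in% names(alignment)) {
    ph1_error(sprintf("reference id '%s' not in alignment", reference_id),
              "ph1_alignment_error")
  }
  stopifnot(is.numeric(prot_pos), length(prot_pos) == 1L, prot_pos >= 1)
  chars <- strsplit(alignment[[reference_id]], "", fixed = TRUE)[[1]]
  nongap <- cumsum(chars != "-")
  hit <- which(nongap == prot_pos & chars != "-")
  if (length(hit) == 0L) {
    ph1_error(sprintf("position %d beyond reference length %d", prot_pos,
                      max(nongap)), "ph1_range_error")
  }
  hit[1L] - 1L
}

#' Count conserved species at a protein position
#'
#' Conservation is the number of alignment rows (the reference included)
#' whose residue at the mapped column equals the reference residue,
#' case-insensitive; gap characters never count as conserved. Because the
#' reference matches itself, the count is at least 1.
#'
#' @inheritParams map_position_to_column
#' @return a `ph1_conservation` list: `prot_pos`, `n_conserved`,
#'   `n_species`, `column_index` (0-based), `ref_residue`.
#' @export
conservation_count <- function(alignment, reference_id, prot_pos) {
  col0 <- map_position_to_column(alignment, reference_id, prot_pos)
  col <- toupper(substr(alignment, col0 + 1L, col0 + 1L))
  ref_res <- toupper(substr(alignment[[reference_id]], col0 + 1L, col0 + 1L))
  structure(
    list(prot_pos = as.integer(prot_pos),
         n_conserved = sum(col == ref_res & col != "-"),
         n_species = length(alignment),
         column_index = col0,
         ref_residue = ref_res),
    class = "ph1_conservation")
}

#' Conservation points of the pathogenicity rubric
#'
#' For the standard 8-species homolog panel: conserved in all 8 species
#' scores 5 points, 6-7 species 4 points, 4-5 species 3 points, 1-3 species
#' 1 point. With `mode = "proportional"` the bins generalize to fractions
#' (>= 100% -> 5, >= 75% -> 4, >= 50% -> 3, else 1) for panels of other
#' sizes; this extrapolates the published 8-species rubric and warns.
#'
#' @param n_conserved number of species (reference included) matching the
#'   reference residue; must be in `[1, n_species]`.
#' @param n_species panel size (default 8).
#' @param mode `"strict8"` (default; requires `n_species == 8`) or
#'   `"proportional"`.
#' @return integer points in {1, 3, 4, 5}.
#' @export
msa_points <- function(n_conserved, n_species = 8L, mode = c("strict8", "proportional")) {
  mode <- match.arg(mode)
  stopifnot(length(n_conserved) == 1L, length(n_species) == 1L)
  n_conserved <- as.integer(n_conserved)
  n_species <- as.integer(n_species)
  if (is.na(n_conserved) || n_conserved < 1L || n_conserved > n_species) {
    ph1_error(sprintf("n_conserved = %s out of range [1, %d]", n_conserved, n_species),
              "ph1_range_error")
  }
  if (mode == "strict8") {
    if (n_species != 8L) {
      ph1_error("strict8 mode requires an 8-species panel; use mode = 'proportional'",
                "ph1_range_error")
    }
    if (n_conserved == 8L) 5L
    else if (n_conserved >= 6L) 4L
    else if (n_conserved >= 4L) 3L
    else 1L
  } else {
    warning("proportional conservation bins extrapolate the published 8-species rubric")
    frac <- n_conserved / n_species
    if (frac >= 1) 5L else if (frac >= 0.75) 4L else if (frac >= 0.5) 3L else 1L
  }
}
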