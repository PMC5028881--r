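#' Classify a total rubric score
#'
#' Total score >= 8 means high pathogenicity, 6-7 moderate, <= 5 probably
#' non-pathogenic (polymorphism-like). The published rubric lists 8 in both
#' the high and moderate bands; high takes precedence here (the band is
#' stated ">= 8 high" first, and the worked study example calls a 9 "high"
#' while only a 6 is exemplified as moderate). A total of exactly 8 is
#' reported on the INFO channel so the boundary remains auditable.
#'
#' @param total integer total score in `[2, 10]` (the attainable range:
#'   both sub-scores are at least 1, at most 5).
#' @return `"high"`, `"moderate"` or `"probably_nonpathogenic"`.
#' @export
classify_total <- function(total) {
  stopifnot(is.numeric(total), length(total) == 1L)
  if (is.na(total) || total != as.integer(total) || total < 2 || total > 10) {
    ph1_error(sprintf("total score %s outside the attainable range [2, 10]", total),
              "ph1_range_error")
  }
  if (total == 8) ph1_info("total score exactly 8: overlapping band, classified high")
  if (total >= 8) "high" else if (total >= 6) "moderate" else "probably_nonpathogenic"
}

#' Score a missense variant with the combined Grantham + conservation rubric
#'
#' Computes the Grantham distance of the substitution, bins it
#' ([grantham_points()]), counts cross-species conservation of the
#' reference residue in the homolog alignment ([conservation_count()]),
#' bins that ([msa_points()]), and sums the two sub-scores into a total
#' that is classified by [classify_total()]. Only missense variants are
#' scoreable: nonsense changes such as p.R333* are null alleles, presumed
#' deleterious, and are rejected with a pointer to that convention.
#'
#' The reference residue found in the alignment at `prot_pos` must equal
#' the variant's stated reference residue; a mismatch aborts with both
#' residues named, which guards against off-by-one coordinate errors.
#'
#' @param variant a `ph1_variant` of kind `"missense"` (or a label string,
#'   which is parsed first).
#' @param alignment named character vector of aligned homolog rows.
#' @param reference_id name of the reference (human) row.
#' @param mode conservation binning mode, see [msa_points()].
#' @return a `ph1_scorecard`: `variant`, `grantham_distance`,
#'   `grantham_points`, `n_conserved`, `n_species`, `msa_points`, `total`,
#'   `pathogenicity_class`.
#' @examples
#' aln <- simulate_msa(msa_spec(length = 60, planted_conservation = c(`49` = 8),
#'                              reference_residues = c(`49` = "M"), seed = 1))
#' score_variant("p.M49L", aln, "homo_sapiens")
#' @export
score_variant <- function(variant, alignment, reference_id,
                          mode = c("strict8", "proportional")) {
  mode <- match.arg(mode)
  if (is.character(variant)) variant <- parse_variant(variant)
  stopifnot(inherits(variant, "ph1_variant"))
  if (identical(variant$kind, "nonsense")) {
    ph1_error(sprintf(
      "'%s' is a nonsense change: a null allele, presumed deleterious; the rubric scores missense substitutions only",
      variant$label), "ph1_not_missense_error")
  }
  if (!identical(variant$kind, "missense")) {
    ph1_error(sprintf("'%s' (kind '%s') is not a missense variant; the rubric scores missense substitutions only",
                      variant$label, variant$kind), "ph1_not_missense_error")
  }
  cons <- conservation_count(alignment, reference_id, variant$prot_pos)
  if (!identical(cons$ref_residue, variant$prot_ref)) {
    ph1_error(sprintf(
      "reference residue mismatch at position %d: variant states %s, alignment has %s",
      variant$prot_pos, variant$prot_ref, cons$ref_residue),
      "ph1_reference_mismatch_error")
  }
  gd <- grantham_distance(variant$prot_ref, variant$prot_alt)
  gp <- grantham_points(gd, variant$prot_ref, variant$prot_alt)
  mp <- msa_points(cons$n_conserved, cons$n_species, mode = mode)
  total <- gp + mp
  structure(
    list(variant = variant,
         grantham_distance = gd,
         grantham_points = gp,
         n_conserved = cons$n_conserved,
         n_species = cons$n_species,
         msa_points = mp,
         total = as.integer(total),
         pathogenicity_class = classify_total(total)),
    class = "ph1_scorecard")
}

#' @export
print.ph1_scorecard <- function(x, ...) {
  cat(sprintf("<ph1_scorecard> %s\n", x$variant$label))
  cat(sprintf("  Grantham %d (%d pts), conservation %d/%d (%d pts)\n",
              x$grantham_distance, x$grantham_points,
              x$n_conserved, x$n_species, x$msa_points))
  cat(sprintf("  total %d -> %s\n", x$total, x$pathogenicity_class))
  invisible(x)
}

#' @export
as.data.frame.ph1_scorecard <- function(x, ...) {
  data.frame(variant = x$variant$label,
             grantham = x$grantham_distance,
             grantham_pts = x$grantham_points,
             conserved = sprintf("%d/%d", x$n_conserved, x$n_species),
             msa_pts = x$msa_points,
             total = x$total,
             class = x$pathogenicity_class,
             stringsAsFactors = FALSE)
}

#' Score several variants and tabulate the scorecards
#'
#' @param variants list of `ph1_variant` objects or character labels.
#' @inheritParams score_variant
#' @return a data.frame with columns `variant`, `grantham`, `grantham_pts`,
#'   `conserved`, `msa_pts`, `total`, `class`.
#' @export
score_variants <- function(variants, alignment, reference_id,
                           mode = c("strict8", "proportional")) {
  mode <- match.arg(mode)
  rows <- lapply(variants, function(v)
    as.data.frame(score_variant(v, alignment, reference_id, mode = mode)))
  do.call(rbind, rows)
}

#' Write scorecards as TSV or JSON
#'
#' @param scorecards a data.frame from [score_variants()] or a list of
#'   `ph1_scorecard` objects.
#' @param path output path; format chosen by extension (`.json` for JSON,
#'   anything else TSV).
#' @return the path, invisibly.
#' @export
write_scorecards <- function(scorecards, path) {
  if (!is.data.frame(scorecards)) {
    scorecards <- do.call(rbind, lapply(scorecards, as.data.frame))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(scorecards, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write.table(scorecards, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
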