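#' Run configuration for the end-to-end workflow
#'
#' The defaults reproduce the published study analysis: the strict
#' 8-species conservation rubric and the classic 186-coefficient MDRD
#' equation.
#'
#' @param reference_id reference row id in the alignment.
#' @param n_species expected homolog panel size.
#' @param msa_mode `"strict8"` or `"proportional"` (see [msa_points()]).
#' @param mdrd_variant `"classic186"` or `"idms175"` (see [egfr_mdrd()]).
#' @param output_dir directory for report files, or `NULL` to skip writing.
#' @param seed seed for any simulation feeding the run.
#' @return a `ph1_config`.
#' @export
ph1_config <- function(reference_id = "homo_sapiens", n_species = 8L,
                       msa_mode = c("strict8", "proportional"),
                       mdrd_variant = c("classic186", "idms175"),
                       output_dir = NULL, seed = 1L) {
  structure(list(reference_id = reference_id, n_species = as.integer(n_species),
                 msa_mode = match.arg(msa_mode),
                 mdrd_variant = match.arg(mdrd_variant),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "ph1_config")
}

#' Run the full PH1 family workflow
#'
#' Composes the stages on prepared inputs: parse and score the missense
#' variants against the homolog alignment, check Mendelian consistency,
#' phase the family's variants and test autosomal-recessive
#' co-segregation, estimate control-cohort allele frequencies, and compute
#' the clinical metrics (MDRD eGFR, OCR flag, diagnostic rule). The run is
#' deterministic for fixed inputs. If `config$output_dir` is set, a JSON
#' bundle (`report.json`) and a text summary (`summary.txt`) are written
#' there.
#'
#' @param variants list of `ph1_variant` objects or labels; only missense
#'   entries are scored, others are reported as unscored (nonsense changes
#'   are null alleles, presumed deleterious).
#' @param alignment named character vector of aligned homolog rows.
#' @param ped a `ph1_pedigree`, or `NULL` to skip the family stages.
#' @param cohort control genotype table (see [allele_frequency()]), or
#'   `NULL`.
#' @param clinical named list of `ph1_clinical_record`, or `NULL`.
#' @param config a [ph1_config()].
#' @return a `ph1_report` bundle (list with elements `scorecards`,
#'   `unscored`, `mendelian`, `phase`, `segregation`, `maf`, `clinical`,
#'   `config`), invisibly when written to disk.
#' @export
run_ph1_pipeline <- function(variants, alignment, ped = NULL, cohort = NULL,
                             clinical = NULL, config = ph1_config()) {
  stopifnot(inherits(config, "ph1_config"))
  if (length(variants) == 0L) {
    ph1_error("no variants supplied", "ph1_usage_error")
  }
  variants <- lapply(variants, function(v)
    if (is.character(v)) parse_variant(v) else v)
  is_missense <- vapply(variants, function(v) identical(v$kind, "missense"),
                        logical(1))
  scorecards <- if (any(is_missense)) {
    score_variants(variants[is_missense], alignment, config$reference_id,
                   mode = config$msa_mode)
  } else NULL
  unscored <- data.frame(
    variant = vapply(variants[!is_missense], function(v) v$label, character(1)),
    kind = vapply(variants[!is_missense], function(v) v$kind, character(1)),
    note = vapply(variants[!is_missense], function(v) {
      if (identical(v$kind, "nonsense")) "null allele, presumed deleterious"
      else "not scoreable by the missense rubric"
    }, character(1)),
    stringsAsFactors = FALSE)

  mendelian <- NULL; phase <- NULL; segregation <- NULL
  if (!is.null(ped)) {
    mendelian <- check_mendelian(ped)
    phase <- phase_variants(ped)
    if (identical(phase$status, "resolved")) {
      segregation <- cosegregation_test(ped, phase)
    }
  }

  maf <- NULL
  if (!is.null(cohort) && ncol(as.matrix(cohort)) > 0L) {
    labs <- colnames(as.matrix(cohort))
    maf <- data.frame(variant = labs,
                      maf = vapply(labs, function(v) allele_frequency(cohort, v),
                                   numeric(1)),
                      stringsAsFactors = FALSE)
  }

  clin_tab <- NULL
  if (!is.null(clinical) && length(clinical)) {
    clin_tab <- do.call(rbind, lapply(names(clinical), function(id) {
      r <- clinical[[id]]
      data.frame(id = id, sex = r$sex, age_years = r$age_years,
                 scr_umol_per_l = r$scr_umol_per_l,
                 egfr_ml_min = round(egfr_mdrd(r$scr_umol_per_l, r$age_years,
                                               r$sex, config$mdrd_variant), 1),
                 ocr = r$ocr_mmol_per_mmol,
                 ocr_flag = if (is.na(r$ocr_mmol_per_mmol)) NA_character_
                            else ocr_flag(r$ocr_mmol_per_mmol),
                 diagnosis = diagnose_ph1(r),
                 stringsAsFactors = FALSE)
    }))
  }

  bundle <- structure(
    list(scorecards = scorecards, unscored = unscored, mendelian = mendelian,
         phase = phase, segregation = segregation, maf = maf,
         clinical = clin_tab, config = config),
    class = "ph1_report")

  if (!is.null(config$output_dir)) {
    write_report(bundle, config$output_dir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a workflow report bundle
#'
#' @param bundle a `ph1_report` from [run_ph1_pipeline()].
#' @param dir output directory (created if absent); writes `report.json`
#'   and `summary.txt`.
#' @return the directory, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ph1_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    scorecards = bundle$scorecards,
    unscored = bundle$unscored,
    mendelian_violations = bundle$mendelian,
    phase = if (!is.null(bundle$phase)) list(
      status = bundle$phase$status,
      haplotypes = bundle$phase$haplotypes,
      supporting_individuals = bundle$phase$supporting_individuals),
    segregation = if (!is.null(bundle$segregation)) list(
      model = bundle$segregation$model,
      n_affected_biallelic = bundle$segregation$n_affected_biallelic,
      n_carriers = bundle$segregation$n_carriers,
      n_noncarriers = bundle$segregation$n_noncarriers,
      n_untyped = bundle$segregation$n_untyped,
      violations = bundle$segregation$violations),
    maf = bundle$maf,
    clinical = bundle$clinical,
    config = unclass(bundle$config))
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines(utils::capture.output(print(bundle)), con)
  invisible(dir)
}

#' @export
print.ph1_report <- function(x, ...) {
  cat("== PH1 family workflow report ==\n")
  if (!is.null(x$scorecards)) {
    cat("\n-- Missense pathogenicity scorecards --\n")
    print(x$scorecards, row.names = FALSE)
  }
  if (!is.null(x$unscored) && nrow(x$unscored)) {
    cat("\n-- Unscored variants --\n")
    print(x$unscored, row.names = FALSE)
  }
  if (!is.null(x$mendelian)) {
    cat(sprintf("\n-- Mendelian check: %d violation(s) --\n", nrow(x$mendelian)))
    if (nrow(x$mendelian)) print(x$mendelian, row.names = FALSE)
  }
  if (!is.null(x$phase)) { cat("\n"); print(x$phase) }
  if (!is.null(x$segregation)) { cat("\n"); print(x$segregation) }
  if (!is.null(x$maf)) {
    cat("\n-- Control-cohort allele frequencies --\n")
    print(x$maf, row.names = FALSE)
  }
  if (!is.null(x$clinical)) {
    cat("\n-- Clinical metrics --\n")
    print(x$clinical, row.names = FALSE)
  }
  invisible(x)
}
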