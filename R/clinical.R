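#' MDRD estimated glomerular filtration rate
#'
#' The 4-variable MDRD study equation from serum creatinine, age and sex.
#' Creatinine in umol/L is converted to mg/dL (divide by 88.4). The
#' default is the original equation, eGFR = 186 x Scr^-1.154 x age^-0.203,
#' multiplied by 0.742 for females; `variant = "idms175"` selects the
#' IDMS-traceable re-expression with coefficient 175. The ethnicity factor
#' is not applied. Values are returned at full precision; clinical reports
#' conventionally round to 1 decimal.
#'
#' @param scr_umol_per_l serum creatinine, umol/L (> 0). Vectorized.
#' @param age_years age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param variant `"classic186"` (default) or `"idms175"`.
#' @return eGFR in ml/min (per 1.73 m^2 body surface area).
#' @examples
#' round(egfr_mdrd(1044, 52, "female"), 1) # 3.6
#' @export
egfr_mdrd <- function(scr_umol_per_l, age_years, sex,
                      variant = c("classic186", "idms175")) {
  variant <- match.arg(variant)
  n <- max(length(scr_umol_per_l), length(age_years), length(sex))
  scr_umol_per_l <- rep_len(scr_umol_per_l, n)
  age_years <- rep_len(age_years, n)
  sex <- rep_len(sex, n)
  if (any(!sex %in% c("male", "female"))) {
    ph1_error("sex must be 'male' or 'female'", "ph1_clinical_error")
  }
  if (any(!is.finite(scr_umol_per_l)) || any(scr_umol_per_l <= 0) ||
      any(!is.finite(age_years)) || any(age_years <= 0)) {
    ph1_error("serum creatinine and age must be positive", "ph1_clinical_error")
  }
  coef <- if (variant == "classic186") 186 else 175
  scr_mg_dl <- scr_umol_per_l / 88.4
  egfr <- coef * scr_mg_dl^-1.154 * age_years^-0.203
  egfr[sex == "female"] <- egfr[sex == "female"] * 0.742
  egfr
}

#' Flag an abnormal urinary oxalate-to-creatinine ratio
#'
#' The random urine oxalate-to-creatinine ratio (OCR, mmol/mmol; the ratio
#' is dimensionless so mol/mol is identical) is abnormal in adults when
#' strictly greater than 0.04; 0.04 itself is the upper normal limit.
#'
#' @param ocr non-negative OCR value(s).
#' @return `"normal"` or `"abnormal"` per element.
#' @export
ocr_flag <- function(ocr) {
  if (any(!is.finite(ocr)) || any(ocr < 0)) {
    ph1_error("OCR must be non-negative", "ph1_clinical_error")
  }
  ifelse(ocr > 0.04, "abnormal", "normal")
}

#' Pyridoxine responsiveness from paired OCR measurements
#'
#' Responsiveness to vitamin B6 is a reduction of more than 30% (strict)
#' in the random urinary oxalate-to-creatinine ratio.
#'
#' @param ocr_before OCR before pyridoxine (> 0).
#' @param ocr_after OCR on treatment (>= 0).
#' @return list with `percent_reduction` and logical `responsive`.
#' @examples
#' pyridoxine_response(0.35, 0.20) # ~42.9%, responsive
#' @export
pyridoxine_response <- function(ocr_before, ocr_after) {
  stopifnot(length(ocr_before) == 1L, length(ocr_after) == 1L)
  if (!is.finite(ocr_before) || ocr_before <= 0) {
    ph1_error("baseline OCR must be positive", "ph1_clinical_error")
  }
  if (!is.finite(ocr_after) || ocr_after < 0) {
    ph1_error("on-treatment OCR must be non-negative", "ph1_clinical_error")
  }
  pct <- 100 * (ocr_before - ocr_after) / ocr_before
  list(percent_reduction = pct, responsive = pct > 30)
}

#' Construct a per-patient clinical record
#'
#' @param scr_umol_per_l serum creatinine, umol/L (> 0).
#' @param age_years age in years (> 0).
#' @param sex `"male"` or `"female"`.
#' @param ocr_mmol_per_mmol random urinary oxalate-to-creatinine ratio, or
#'   `NA` if not measured.
#' @param has_nephrolithiasis,has_nephrocalcinosis stone / diffuse renal
#'   calcification flags.
#' @param biallelic_pathogenic `TRUE`/`FALSE`/`NA`: pathogenic mutations on
#'   both *AGXT* alleles.
#' @param agt_activity_deficient `TRUE`/`FALSE`/`NA`: loss of AGT catalytic
#'   activity in liver tissue (the enzymology prong is accepted only as a
#'   boolean; no quantitative cutoff is defined).
#' @return a `ph1_clinical_record`.
#' @export
clinical_record <- function(scr_umol_per_l, age_years, sex,
                            ocr_mmol_per_mmol = NA_real_,
                            has_nephrolithiasis = FALSE,
                            has_nephrocalcinosis = FALSE,
                            biallelic_pathogenic = NA,
                            agt_activity_deficient = NA) {
  if (!is.finite(scr_umol_per_l) || scr_umol_per_l <= 0 ||
      !is.finite(age_years) || age_years <= 0) {
    ph1_error("serum creatinine and age must be positive", "ph1_clinical_error")
  }
  if (!sex %in% c("male", "female")) {
    ph1_error("sex must be 'male' or 'female'", "ph1_clinical_error")
  }
  if (!is.na(ocr_mmol_per_mmol) && ocr_mmol_per_mmol < 0) {
    ph1_error("OCR must be non-negative", "ph1_clinical_error")
  }
  structure(list(scr_umol_per_l = scr_umol_per_l, age_years = age_years,
                 sex = sex, ocr_mmol_per_mmol = ocr_mmol_per_mmol,
                 has_nephrolithiasis = isTRUE(has_nephrolithiasis),
                 has_nephrocalcinosis = isTRUE(has_nephrocalcinosis),
                 biallelic_pathogenic = biallelic_pathogenic,
                 agt_activity_deficient = agt_activity_deficient),
            class = "ph1_clinical_record")
}

#' Apply the adult PH1 diagnostic rule set
#'
#' An adult meets the criteria when the stone prong holds -- bilateral
#' nephrocalcinosis or recurrent urolithiasis -- together with at least one
#' confirmatory condition: abnormal random OCR (> 0.04), deficient AGT
#' catalytic activity in liver tissue, or pathogenic mutations on both
#' *AGXT* alleles. If the stone prong holds but all three confirmatory
#' fields are unknown, the verdict is `insufficient_data`.
#'
#' @param record a `ph1_clinical_record`.
#' @return `"meets_criteria"`, `"does_not_meet"` or `"insufficient_data"`.
#' @export
diagnose_ph1 <- function(record) {
  stopifnot(inherits(record, "ph1_clinical_record"))
  prong1 <- record$has_nephrolithiasis || record$has_nephrocalcinosis
  if (!prong1) return("does_not_meet")
  ocr_ab <- if (is.na(record$ocr_mmol_per_mmol)) NA else
    record$ocr_mmol_per_mmol > 0.04
  confirm <- c(ocr_ab,
               record$agt_activity_deficient,
               record$biallelic_pathogenic)
  if (any(confirm %in% TRUE)) return("meets_criteria")
  if (all(is.na(confirm))) return("insufficient_data")
  "does_not_meet"
}

#' Read clinical records from CSV
#'
#' Columns: `id, sex, age_years, scr_umol_per_l, ocr_mmol_per_mmol,
#' has_nephrolithiasis, has_nephrocalcinosis` and optionally
#' `biallelic_pathogenic, agt_activity_deficient` (logical; empty cells are
#' unknown).
#'
#' @param path CSV file.
#' @return a named list of `ph1_clinical_record`.
#' @export
read_clinical_csv <- function(path) {
  if (!file.exists(path)) ph1_error(sprintf("no such file: %s", path), "ph1_io_error")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "sex", "age_years", "scr_umol_per_l")
  if (!all(need %in% names(tab))) {
    ph1_error(sprintf("clinical CSV needs columns: %s", paste(need, collapse = ", ")),
              "ph1_io_error")
  }
  get_or <- function(col, default) if (col %in% names(tab)) tab[[col]] else
    rep(default, nrow(tab))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    clinical_record(
      scr_umol_per_l = tab$scr_umol_per_l[i],
      age_years = tab$age_years[i],
      sex = tab$sex[i],
      ocr_mmol_per_mmol = get_or("ocr_mmol_per_mmol", NA_real_)[i],
      has_nephrolithiasis = isTRUE(get_or("has_nephrolithiasis", FALSE)[i]),
      has_nephrocalcinosis = isTRUE(get_or("has_nephrocalcinosis", FALSE)[i]),
      biallelic_pathogenic = get_or("biallelic_pathogenic", NA)[i],
      agt_activity_deficient = get_or("agt_activity_deficient", NA)[i])
  })
  names(out) <- tab$id
  out
}
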