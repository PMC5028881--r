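#' Read / write an aligned protein FASTA
#'
#' Rows must be equal length (gap character `-`) with unique ids; the
#' reader enforces both. I/O goes through Biostrings.
#'
#' @param path FASTA file.
#' @param alignment for the writer, a named character vector of rows.
#' @return `read_alignment()`: named character vector of aligned rows.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) ph1_error(sprintf("no such file: %s", path), "ph1_io_error")
  seqs <- tryCatch(Biostrings::readAAStringSet(path),
                   error = function(e) ph1_error(
                     sprintf("cannot read FASTA '%s': %s", path, conditionMessage(e)),
                     "ph1_io_error"))
  if (length(seqs) == 0L) ph1_error(sprintf("empty FASTA: %s", path), "ph1_io_error")
  rows <- as.character(seqs)
  # keep only the first whitespace-delimited token of each header
  names(rows) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  check_alignment(rows)
}

#' @rdname read_alignment
#' @export
write_alignment <- function(alignment, path) {
  check_alignment(alignment)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(alignment), path, width = 80L)
  invisible(path)
}

# PED dialect: a "#VARIANTS lab1 lab2 ..." header line, then rows of
# family id, individual id, father, mother, sex (1=male, 2=female,
# 0=unknown), affection (1=unaffected, 2=affected, 0=unknown), and two
# allele columns per variant coded 1=ref, 2=alt, 0=missing.

#' Read / write the PED-dialect genotype file
#'
#' @param path PED file. The variant order is declared in a leading
#'   `#VARIANTS` comment line.
#' @param ped for the writer, a `ph1_pedigree`.
#' @return `read_pedigree()`: a `ph1_pedigree`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) ph1_error(sprintf("no such file: %s", path), "ph1_io_error")
  lines <- readLines(path)
  hdr <- grep("^#VARIANTS\\b", lines, value = TRUE)
  if (length(hdr) != 1L) {
    ph1_error("PED file needs exactly one '#VARIANTS' header line", "ph1_io_error")
  }
  vars <- strsplit(trimws(sub("^#VARIANTS", "", hdr)), "\\s+")[[1]]
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(body), "\\s+")
  want <- 6L + 2L * length(vars)
  bad <- which(lengths(fields) != want)
  if (length(bad)) {
    ph1_error(sprintf("PED row %d has %d fields, expected %d (6 + 2 per variant)",
                      bad[1], lengths(fields)[bad[1]], want), "ph1_io_error")
  }
  tab <- do.call(rbind, fields)
  sex_code <- tab[, 5]
  aff_code <- tab[, 6]
  if (!all(sex_code %in% c("0", "1", "2"))) {
    ph1_error("PED sex codes must be 0 (unknown), 1 (male) or 2 (female)",
              "ph1_io_error")
  }
  if (!all(aff_code %in% c("0", "1", "2"))) {
    ph1_error("PED affection codes must be 0 (unknown), 1 (unaffected) or 2 (affected)",
              "ph1_io_error")
  }
  members <- data.frame(
    id = tab[, 2], family_id = tab[, 1],
    father_id = ifelse(tab[, 3] == "0", NA_character_, tab[, 3]),
    mother_id = ifelse(tab[, 4] == "0", NA_character_, tab[, 4]),
    sex = c("0" = "unknown", "1" = "male", "2" = "female")[sex_code],
    affected = c("0" = "unknown", "1" = "unaffected", "2" = "affected")[aff_code],
    stringsAsFactors = FALSE)
  G <- matrix(NA_integer_, nrow(members), length(vars),
              dimnames = list(members$id, vars))
  for (k in seq_along(vars)) {
    a1 <- tab[, 6L + 2L * k - 1L]
    a2 <- tab[, 6L + 2L * k]
    if (!all(c(a1, a2) %in% c("0", "1", "2"))) {
      ph1_error(sprintf("allele codes for '%s' must be 0 (missing), 1 (ref) or 2 (alt)",
                        vars[k]), "ph1_io_error")
    }
    miss <- a1 == "0" | a2 == "0"
    dose <- (a1 == "2") + (a2 == "2")
    dose[miss] <- NA_integer_
    G[, k] <- as.integer(dose)
  }
  pedigree(members, G)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "ph1_pedigree"))
  vars <- ped$variant_labels
  sex_code <- c(male = "1", female = "2", unknown = "0")[ped$members$sex]
  aff_code <- c(unaffected = "1", affected = "2", unknown = "0")[ped$members$affected]
  allele_cols <- lapply(vars, function(v) {
    g <- ped$genotypes[, v]
    a1 <- ifelse(is.na(g), "0", ifelse(g == 2L, "2", "1"))
    a2 <- ifelse(is.na(g), "0", ifelse(g >= 1L, "2", "1"))
    cbind(a1, a2)
  })
  rows <- cbind(ped$members$family_id, ped$members$id,
                ifelse(is.na(ped$members$father_id), "0", ped$members$father_id),
                ifelse(is.na(ped$members$mother_id), "0", ped$members$mother_id),
                sex_code, aff_code, do.call(cbind, allele_cols))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#VARIANTS", paste(vars, collapse = " ")), con)
  writeLines(apply(rows, 1L, paste, collapse = " "), con)
  invisible(path)
}
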