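#' @importFrom utils read.delim write.table read.csv write.csv
NULL

# One- and three-letter amino-acid code tables. The stop symbol is stored
# canonically as "*".
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL",
         `*` = "TER")

ph1_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ph1_error", "error", "condition")))
}

# Normalize an amino-acid token (1- or 3-letter, any case, stop as * or X
# or Ter) to the canonical one-letter code; NULL if unrecognized.
normalize_aa <- function(tok) {
  tok <- toupper(tok)
  if (tok %in% c("*", "X", "TER")) return("*")
  if (nchar(tok) == 1L && tok %in% AA1) return(tok)
  if (nchar(tok) == 3L) {
    hit <- names(AA3)[AA3 == tok]
    if (length(hit) == 1L) return(hit)
  }
  NULL
}

new_variant <- function(kind, label, cdna_pos = NA_integer_, cdna_ref = NA_character_,
                        cdna_alt = NA_character_, prot_pos = NA_integer_,
                        prot_ref = NA_character_, prot_alt = NA_character_) {
  structure(
    list(kind = kind, label = label,
         cdna_pos = cdna_pos, cdna_ref = cdna_ref, cdna_alt = cdna_alt,
         prot_pos = prot_pos, prot_ref = prot_ref, prot_alt = prot_alt),
    class = "ph1_variant")
}

parse_protein_part <- function(tok, label) {
  # e.g. M49L, Met49Leu, R333*, R333X, P11L
  m <- regmatches(tok, regexec("^([A-Za-z*]{1,3})([0-9]+)([A-Za-z*]{1,3})$", tok))[[1]]
  if (length(m) != 4L) {
    ph1_error(sprintf("cannot parse protein change '%s' in '%s'", tok, label),
              "ph1_parse_error")
  }
  ref <- normalize_aa(m[2])
  pos <- as.integer(m[3])
  alt <- normalize_aa(m[4])
  if (is.null(ref) || is.null(alt)) {
    ph1_error(sprintf("unknown amino-acid code in '%s' ('%s')", tok, label),
              "ph1_parse_error")
  }
  if (ref == "*") {
    ph1_error(sprintf("reference residue cannot be a stop in '%s'", label),
              "ph1_parse_error")
  }
  if (pos < 1L) ph1_error(sprintf("non-positive protein position in '%s'", label),
                          "ph1_parse_error")
  if (identical(ref, alt)) {
    ph1_error(sprintf("'%s' is synonymous (%s -> %s); not scoreable", label, ref, alt),
              "ph1_synonymous_error")
  }
  list(pos = pos, ref = ref, alt = alt,
       kind = if (alt == "*") "nonsense" else "missense")
}

parse_cdna_part <- function(tok, label) {
  # substitution: 145A>C (spaces around '>' tolerated); duplication: 33dupC / 33dup
  tok <- gsub("\\s+", "", tok)
  m <- regmatches(tok, regexec("^([0-9]+)([ACGTacgt])>([ACGTacgt])$", tok))[[1]]
  if (length(m) == 4L) {
    pos <- as.integer(m[2])
    if (pos < 1L) ph1_error(sprintf("non-positive cDNA position in '%s'", label),
                            "ph1_parse_error")
    if (toupper(m[3]) == toupper(m[4])) {
      ph1_error(sprintf("'%s' is a synonymous nucleotide change", label),
                "ph1_synonymous_error")
    }
    return(list(pos = pos, ref = toupper(m[3]), alt = toupper(m[4]),
                kind = "substitution"))
  }
  m <- regmatches(tok, regexec("^([0-9]+)dup([ACGTacgt]?)$", tok))[[1]]
  if (length(m) == 3L) {
    pos <- as.integer(m[2])
    if (pos < 1L) ph1_error(sprintf("non-positive cDNA position in '%s'", label),
                            "ph1_parse_error")
    return(list(pos = pos, ref = if (nzchar(m[3])) toupper(m[3]) else NA_character_,
                alt = NA_character_, kind = "duplication"))
  }
  ph1_error(sprintf("cannot parse cDNA change '%s' in '%s'", tok, label),
            "ph1_parse_error")
}

#' Parse an HGVS-like variant label
#'
#' Accepts the notation dialects used in clinical PH1 reports: protein
#' changes (`"p.M49L"`, `"p.Met49Leu"`, bare `"P11L"`, `"p.R333*"` with the
#' stop written `*`, `X` or `Ter`), cDNA substitutions with optional spaces
#' around the `>` (`"c.145A > C"`), cDNA duplications (`"c.33dupC"`), paired
#' notation (`"p.M49L (c.145A > C)"`), and the intron-1 74-bp duplication tag
#' of the *AGXT* minor allele (`"IVS1+74bp"`), which is represented as a
#' haplotype marker of kind `"other"` rather than a sequence edit.
#'
#' cDNA positions are 1-based from the A of the initiator ATG, protein
#' positions 1-based from the initiator Met, so a paired label must satisfy
#' `cdna_pos` in `[3*prot_pos - 2, 3*prot_pos]`; violations are rejected.
#'
#' @param label a single non-empty variant string.
#' @return an object of class `ph1_variant`: a list with fields `kind`
#'   (`"missense"`, `"nonsense"`, `"duplication"` or `"other"`), `label`
#'   (normalized), `cdna_pos`, `cdna_ref`, `cdna_alt`, `prot_pos`,
#'   `prot_ref`, `prot_alt` (missing fields are `NA`).
#' @examples
#' parse_variant("p.M49L")
#' parse_variant("p.N72I (c.215A > T)")
#' parse_variant("c.33dupC")
#' @seealso [format_variant()] for the inverse operation.
#' @export
parse_variant <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) || !nzchar(trimws(label))) {
    ph1_error("variant label must be a single non-empty string", "ph1_parse_error")
  }
  raw <- trimws(label)

  # intron-1 74-bp duplication marker of the AGXT minor allele
  if (grepl("^IVS *(1|I) *\\+ *74 *bp$", raw, ignore.case = TRUE)) {
    return(new_variant("other", "IVS1+74bp"))
  }

  # split paired notation "A (B)"
  paired <- regmatches(raw, regexec("^([^()]+)\\(([^()]+)\\)$", raw))[[1]]
  parts <- if (length(paired) == 3L) trimws(paired[2:3]) else raw

  prot <- NULL; cdna <- NULL
  for (part in parts) {
    p <- trimws(part)
    if (grepl("^p\\.", p, ignore.case = TRUE)) {
      prot <- parse_protein_part(sub("^p\\.", "", p, ignore.case = TRUE), raw)
    } else if (grepl("^c\\.", p, ignore.case = TRUE)) {
      cdna <- parse_cdna_part(sub("^c\\.", "", p, ignore.case = TRUE), raw)
    } else if (grepl("^[A-Za-z]", p) && grepl("[0-9]", p)) {
      # bare protein shorthand like "P11L" or "I340M"
      prot <- parse_protein_part(p, raw)
    } else {
      ph1_error(sprintf("unrecognized token '%s' in '%s'", p, raw), "ph1_parse_error")
    }
  }

  if (!is.null(prot) && !is.null(cdna)) {
    if (cdna$kind != "substitution") {
      ph1_error(sprintf("paired protein/cDNA notation requires a substitution: '%s'", raw),
                "ph1_parse_error")
    }
    lo <- 3L * prot$pos - 2L
    hi <- 3L * prot$pos
    if (cdna$pos < lo || cdna$pos > hi) {
      ph1_error(sprintf(
        "cDNA position %d inconsistent with protein position %d (codon spans %d-%d) in '%s'",
        cdna$pos, prot$pos, lo, hi, raw), "ph1_consistency_error")
    }
    v <- new_variant(prot$kind, label = NA_character_,
                     cdna_pos = cdna$pos, cdna_ref = cdna$ref, cdna_alt = cdna$alt,
                     prot_pos = prot$pos, prot_ref = prot$ref, prot_alt = prot$alt)
  } else if (!is.null(prot)) {
    v <- new_variant(prot$kind, label = NA_character_,
                     prot_pos = prot$pos, prot_ref = prot$ref, prot_alt = prot$alt)
  } else if (!is.null(cdna)) {
    kind <- if (cdna$kind == "duplication") "duplication" else "other"
    v <- new_variant(kind, label = NA_character_,
                     cdna_pos = cdna$pos, cdna_ref = cdna$ref, cdna_alt = cdna$alt)
  } else {
    ph1_error(sprintf("cannot parse '%s'", raw), "ph1_parse_error")
  }
  v$label <- format_variant(v)
  v
}

#' Format a parsed variant back to normalized notation
#'
#' The output is the compact dialect (`"p.M49L (c.145A>C)"`); re-parsing it
#' yields an identical `ph1_variant`.
#'
#' @param variant a `ph1_variant`.
#' @return a single string.
#' @export
format_variant <- function(variant) {
  stopifnot(inherits(variant, "ph1_variant"))
  if (identical(variant$kind, "other") && is.na(variant$cdna_pos) &&
      is.na(variant$prot_pos)) {
    return("IVS1+74bp")
  }
  prot <- if (!is.na(variant$prot_pos)) {
    sprintf("p.%s%d%s", variant$prot_ref, variant$prot_pos, variant$prot_alt)
  } else NULL
  cdna <- if (!is.na(variant$cdna_pos)) {
    if (identical(variant$kind, "duplication")) {
      sprintf("c.%ddup%s", variant$cdna_pos,
              if (is.na(variant$cdna_ref)) "" else variant$cdna_ref)
    } else {
      sprintf("c.%d%s>%s", variant$cdna_pos, variant$cdna_ref, variant$cdna_alt)
    }
  } else NULL
  if (!is.null(prot) && !is.null(cdna)) sprintf("%s (%s)", prot, cdna)
  else if (!is.null(prot)) prot
  else cdna
}

#' @export
print.ph1_variant <- function(x, ...) {
  cat(sprintf("<ph1_variant> %s [%s]\n", x$label, x$kind))
  invisible(x)
}

#' Construct an AGXT haplotype label
#'
#' The study vocabulary for the three *AGXT* haplotypes segregating in a PH1
#' family: `AGT_MA` is the normal major allele (no mutation, no intron-1
#' 74-bp duplication), `AGT_Ma` the mutated major allele, and `AGT_Mi` the
#' mutated minor allele, which by definition carries the IVS1+74bp tag.
#'
#' @param name one of `"AGT_MA"`, `"AGT_Ma"`, `"AGT_Mi"`.
#' @param carried_variants character vector of variant labels on the
#'   haplotype.
#' @param carries_ivs1_74bp does the haplotype carry the intron-1 74-bp
#'   duplication? Defaults to `TRUE` for `AGT_Mi`, `FALSE` otherwise.
#' @return an object of class `ph1_haplotype`.
#' @export
agxt_haplotype <- function(name = c("AGT_MA", "AGT_Ma", "AGT_Mi"),
                           carried_variants = character(0),
                           carries_ivs1_74bp = identical(name, "AGT_Mi")) {
  name <- match.arg(name)
  carried_variants <- as.character(carried_variants)
  if (name == "AGT_MA" && (length(carried_variants) > 0L || isTRUE(carries_ivs1_74bp))) {
    ph1_error("AGT_MA is the normal major allele: no mutations, no IVS1+74bp",
              "ph1_haplotype_error")
  }
  if (name == "AGT_Mi" && !isTRUE(carries_ivs1_74bp)) {
    ph1_error("AGT_Mi is defined by the IVS1+74bp duplication", "ph1_haplotype_error")
  }
  structure(list(name = name, carried_variants = carried_variants,
                 carries_ivs1_74bp = isTRUE(carries_ivs1_74bp)),
            class = "ph1_haplotype")
}

#' Read / write a variants table
#'
#' Tab-separated table with columns `label`, `kind`, `cdna`, `protein`, one
#' variant per row; lines starting with `#` are skipped. `read_variants_tsv()`
#' re-parses the `label` column so the returned list carries fully populated
#' `ph1_variant` objects.
#'
#' @param path file path.
#' @param variants for the writer, a list of `ph1_variant` objects.
#' @return `read_variants_tsv()`: a named list of `ph1_variant` (names are
#'   the normalized labels). `write_variants_tsv()`: the path, invisibly.
#' @export
read_variants_tsv <- function(path) {
  if (!file.exists(path)) ph1_error(sprintf("no such file: %s", path), "ph1_io_error")
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"label" %in% names(tab)) {
    ph1_error("variants TSV must have a 'label' column", "ph1_io_error")
  }
  out <- lapply(tab$label, parse_variant)
  names(out) <- vapply(out, function(v) v$label, character(1))
  out
}

#' @rdname read_variants_tsv
#' @export
write_variants_tsv <- function(variants, path) {
  stopifnot(all(vapply(variants, inherits, logical(1), "ph1_variant")))
  tab <- data.frame(
    label = vapply(variants, function(v) v$label, character(1)),
    kind = vapply(variants, function(v) v$kind, character(1)),
    cdna = vapply(variants, function(v) {
      if (is.na(v$cdna_pos)) NA_character_ else {
        if (identical(v$kind, "duplication")) {
          sprintf("c.%ddup%s", v$cdna_pos, if (is.na(v$cdna_ref)) "" else v$cdna_ref)
        } else sprintf("c.%d%s>%s", v$cdna_pos, v$cdna_ref, v$cdna_alt)
      }
    }, character(1)),
    protein = vapply(variants, function(v) {
      if (is.na(v$prot_pos)) NA_character_
      else sprintf("p.%s%d%s", v$prot_ref, v$prot_pos, v$prot_alt)
    }, character(1)),
    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
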