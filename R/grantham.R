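# The published Grantham (1974) amino-acid chemical-distance matrix,
# embedded as integer constants. Residue order follows the original table.
# Anchors checked against the PH1 rubric: Met-Leu = 15, Asn-Ile = 149.
grantham_order <- c("S","R","L","P","T","A","V","G","I","F",
                    "Y","C","H","Q","N","K","D","E","M","W")

grantham_upper <- list(
  S = c(110,145, 74, 58, 99,124, 56,142,155,144,112, 89, 68, 46,121, 65, 80,135,177),
  R = c(102,103, 71,112, 96,125, 97, 97, 77,180, 29, 43, 86, 26, 96, 54, 91,101),
  L = c( 98, 92, 96, 32,138,  5, 22, 36,198, 99,113,153,107,172,138, 15, 61),
  P = c( 38, 27, 68, 42, 95,114,110,169, 77, 76, 91,103,108, 93, 87,147),
  T = c( 58, 69, 59, 89,103, 92,149, 47, 42, 65, 78, 85, 65, 81,128),
  A = c( 64, 60, 94,113,112,195, 86, 91,111,106,126,107, 84,148),
  V = c(109, 29, 50, 55,192, 84, 96,133, 97,152,121, 21, 88),
  G = c(135,153,147,159, 98, 87, 80,127, 94, 98,127,184),
  I = c( 21, 33,198, 94,109,149,102,168,134, 10, 61),
  F = c( 22,205,100,116,158,102,177,140, 28, 40),
  Y = c(194, 83, 99,143, 85,160,122, 36, 37),
  C = c(174,154,139,202,154,170,196,215),
  H = c( 24, 68, 32, 81, 40, 87,115),
  Q = c( 46, 53, 61, 29,101,130),
  N = c( 94, 23, 42,142,174),
  K = c(101, 56, 95,110),
  D = c( 45,160,181),
  E = c(126,152),
  M = c( 67))

build_grantham <- function() {
  aa <- grantham_order
  m <- matrix(0L, 20L, 20L, dimnames = list(aa, aa))
  for (i in 1:19) {
    row <- grantham_upper[[aa[i]]]
    for (j in (i + 1L):20L) {
      m[i, j] <- row[j - i]
      m[j, i] <- m[i, j]
    }
  }
  m[sort(aa), sort(aa)]
}

.grantham <- build_grantham()

#' The Grantham amino-acid distance matrix
#'
#' The symmetric 20x20 physicochemical distance matrix of Grantham (1974),
#' combining side-chain composition, polarity and molecular volume; larger
#' values mean more radical substitutions (range 5 for Leu-Ile to 215 for
#' Cys-Trp, mean approximately 100).
#'
#' @return an integer matrix with one-letter amino-acid dimnames.
#' @export
grantham_matrix <- function() .grantham

#' Grantham distance between two amino acids
#'
#' @param ref,alt one-letter (or three-letter) codes of the reference and
#'   substituted residue. They must differ: the distance of a synonymous
#'   "substitution" is not defined by the rubric.
#' @return the integer distance; symmetric in its arguments.
#' @examples
#' grantham_distance("M", "L") # 15
#' grantham_distance("N", "I") # 149
#' @export
grantham_distance <- function(ref, alt) {
  r <- normalize_aa(ref)
  a <- normalize_aa(alt)
  if (is.null(r) || is.null(a) || r == "*" || a == "*") {
    ph1_error(sprintf("not a standard amino acid: '%s' / '%s'", ref, alt),
              "ph1_residue_error")
  }
  if (r == a) {
    ph1_error(sprintf("synonymous pair (%s, %s): Grantham distance undefined", r, a),
              "ph1_synonymous_error")
  }
  .grantham[r, a]
}

#' Grantham-bin points of the pathogenicity rubric
#'
#' Maps a Grantham distance to rubric points: distance below 60 scores 1
#' point, 60.0-78.3 scores 2, 78.4-93.4 scores 3, above 93.4 scores 4, and
#' any substitution involving cysteine scores 5 regardless of distance
#' (cysteine's disulfide chemistry makes every exchange radical). The
#' printed bins leave the open interval (78.3, 78.4) uncovered; no integer
#' distance falls there, but a value in the gap maps to 3 points with a
#' warning rather than failing.
#'
#' @param distance non-negative Grantham distance.
#' @param ref,alt the residues of the substitution (needed for the cysteine
#'   override).
#' @return integer points in 1..5.
#' @export
grantham_points <- function(distance, ref, alt) {
  stopifnot(is.numeric(distance), length(distance) == 1L, distance >= 0)
  r <- normalize_aa(ref)
  a <- normalize_aa(alt)
  if (is.null(r) || is.null(a)) {
    ph1_error(sprintf("not a standard amino acid: '%s' / '%s'", ref, alt),
              "ph1_residue_error")
  }
  if (r == "C" || a == "C") return(5L)
  if (distance == 60) ph1_info("Grantham distance exactly 60.0 (2-point bin boundary)")
  if (distance < 60) 1L
  else if (distance <= 78.3) 2L
  else if (distance < 78.4) {
    warning("Grantham distance in the uncovered bin gap (78.3, 78.4); scoring 3 points")
    3L
  }
  else if (distance <= 93.4) 3L
  else 4L
}
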