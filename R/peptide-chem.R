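# Molecular masses of peptides with noncanonical residues (Aib) and
# terminal caps, from elemental composition.

# IUPAC 2021 standard atomic weights and monoisotopic masses.
.elem_avg <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
.elem_mono <- c(H = 1.00782503, C = 12, N = 14.00307401,
                O = 15.99491462, S = 31.97207117)

# Residue (= amino acid minus water) elemental formulas; AIB is
# 2-aminoisobutyric acid, residue formula C4H7NO.
.res_formula <- list(
  G = c(C = 2, H = 3, N = 1, O = 1),
  A = c(C = 3, H = 5, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  V = c(C = 5, H = 9, N = 1, O = 1),
  T = c(C = 4, H = 7, N = 1, O = 2),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  K = c(C = 6, H = 12, N = 2, O = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1),
  AIB = c(C = 4, H = 7, N = 1, O = 1))

#' Parse a peptide sequence string
#'
#' Accepts strings like \code{"Ac-CTGHSGN\{Aib\}SEI-NH2"}: an optional
#' \code{Ac-} (acetyl) or \code{H-} (free amine) prefix, one-letter codes
#' with noncanonical residues in braces, and an optional \code{-NH2}
#' (C-terminal amide) or \code{-OH} (free acid) suffix.
#'
#' @param seq sequence string
#' @return list with \code{residues} (character vector of codes),
#'   \code{n_cap} ("free" or "acetyl"), \code{c_cap} ("free_acid" or
#'   "amide")
#' @export
parse_peptide <- function(seq) {
  s <- trimws(seq)
  n_cap <- "free"; c_cap <- "free_acid"
  if (grepl("^Ac-", s)) { n_cap <- "acetyl"; s <- sub("^Ac-", "", s) }
  else if (grepl("^H-", s)) s <- sub("^H-", "", s)
  if (grepl("-NH2$", s)) { c_cap <- "amide"; s <- sub("-NH2$", "", s) }
  else if (grepl("-OH$", s)) s <- sub("-OH$", "", s)
  toks <- regmatches(s, gregexpr("\\{[^}]+\\}|[A-Za-z]", s))[[1]]
  if (!length(toks)) stop("parse_peptide: empty sequence")
  residues <- toupper(gsub("[{}]", "", toks))
  unknown <- setdiff(residues, names(.res_formula))
  if (length(unknown))
    stop("parse_peptide: unknown residue code(s): ",
         paste(unknown, collapse = ", "))
  list(residues = residues, n_cap = n_cap, c_cap = c_cap)
}

peptide_formula <- function(p) {
  if (is.character(p)) p <- parse_peptide(p)
  f <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (r in p$residues) {
    rf <- .res_formula[[r]]
    f[names(rf)] <- f[names(rf)] + rf
  }
  f[c("H", "O")] <- f[c("H", "O")] + c(2, 1)         # + H2O for the chain
  if (p$n_cap == "acetyl") f[c("C", "H", "O")] <- f[c("C", "H", "O")] +
    c(2, 2, 1)                                       # +C2H2O
  if (p$c_cap == "amide") {                          # -OH +NH2
    f["O"] <- f["O"] - 1
    f[c("N", "H")] <- f[c("N", "H")] + 1
  }
  f
}

#' Average molecular mass of a peptide
#'
#' Sum of residue masses plus one water, with cap corrections (acetyl
#' +C2H2O, C-terminal amide -O +NH), using IUPAC 2021 standard atomic
#' weights.
#'
#' @param seq sequence string (see \code{\link{parse_peptide}}) or a
#'   parsed peptide list
#' @return mass in atomic mass units
#' @examples
#' average_mass("G")                        # free glycine, 75.07
#' average_mass("Ac-CTGHSGN{AIB}SEI-NH2")   # undecapeptide with Aib
#' @export
average_mass <- function(seq) {
  f <- peptide_formula(seq)
  sum(f * .elem_avg[names(f)])
}

#' Monoisotopic molecular mass of a peptide
#'
#' As \code{\link{average_mass}} but with monoisotopic atomic masses
#' (lightest-isotope composition), for comparison with MALDI-TOF peaks.
#'
#' @inheritParams average_mass
#' @return mass in atomic mass units
#' @export
monoisotopic_mass <- function(seq) {
  f <- peptide_formula(seq)
  sum(f * .elem_mono[names(f)])
}
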