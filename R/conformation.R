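# Conformational characterization of mined motifs: backbone and side-chain
# torsions, rotamer classes, i->i+4 hydrogen bonds, alpha-turn typing,
# metal-site geometry and Lambda/Delta configuration.

#' Backbone and side-chain torsion profile of a motif
#'
#' Computes phi/psi for the three interior residues (i+1, i+2, i+3) of the
#' five-residue window and chi1 for the coordinating Cys (N-CA-CB-SG) and
#' His (N-CA-CB-CG).
#'
#' @param m a \code{zt_motif}
#' @param s the \code{zt_structure} the motif was mined from
#' @return list of class \code{zt_torsions} with elements \code{phi1},
#'   \code{psi1}, \code{phi2}, \code{psi2}, \code{phi3}, \code{psi3}
#'   (interior residues, degrees), \code{chi1_cys}, \code{chi1_his}
#' @export
torsion_profile <- function(m, s) {
  g <- function(resno, elety) {
    p <- atom_xyz(s, m$chain, resno, elety)
    if (is.null(p)) stop("torsion_profile: missing atom ", elety,
                         " in residue ", resno, " of ", m$structure_id)
    p
  }
  i <- m$start
  phi <- function(r) dihedral(g(r - 1, "C"), g(r, "N"), g(r, "CA"), g(r, "C"))
  psi <- function(r) dihedral(g(r, "N"), g(r, "CA"), g(r, "C"), g(r + 1, "N"))
  out <- list(phi1 = phi(i + 1), psi1 = psi(i + 1),
              phi2 = phi(i + 2), psi2 = psi(i + 2),
              phi3 = phi(i + 3), psi3 = psi(i + 3),
              chi1_cys = dihedral(g(i, "N"), g(i, "CA"),
                                  g(i, "CB"), g(i, "SG")),
              chi1_his = dihedral(g(i + 3, "N"), g(i + 3, "CA"),
                                  g(i + 3, "CB"), g(i + 3, "CG")))
  structure(out, class = "zt_torsions")
}

#' Classify a chi1 value into the three staggered rotamer wells
#'
#' Bins: g+ for chi1 in [0, 120), g- for chi1 in (-120, 0), trans
#' otherwise.  These boundaries reproduce the conventional labels for all
#' observed survey values (72 g+, 179 trans, -58 g-, 93 g+, -175 trans).
#'
#' @param chi1 angle in degrees in (-180, 180] (vectorized)
#' @return character vector over \{"g+", "g-", "trans"\}
#' @export
rotamer_class <- function(chi1) {
  chi1 <- wrap_angle(chi1)
  ifelse(chi1 >= 0 & chi1 < 120, "g+",
         ifelse(chi1 > -120 & chi1 < 0, "g-", "trans"))
}

#' Test for the i -> i+4 hydrogen bond closing an alpha-turn
#'
#' True when the carbonyl O of residue i and the amide N of residue i+4
#' are within 3.5 A with angle C=O...N >= 90 degrees; when the i+4 amide
#' hydrogen is defined (residue not Pro) it is built geometrically and the
#' N-H...O angle must additionally be >= 120 degrees.
#'
#' @param m a \code{zt_motif}
#' @param s the parent structure
#' @param max_dist O...N distance cutoff in Angstrom
#' @return logical
#' @export
hbond_i_i4 <- function(m, s, max_dist = 3.5) {
  i <- m$start
  O <- atom_xyz(s, m$chain, i, "O")
  C <- atom_xyz(s, m$chain, i, "C")
  N4 <- atom_xyz(s, m$chain, i + 4L, "N")
  if (is.null(O) || is.null(C) || is.null(N4)) return(NA)
  d <- sqrt(sum((N4 - O)^2))
  if (d > max_dist) return(FALSE)
  if (vangle(C, O, N4) < 90) return(FALSE)
  res4 <- residue_name(s, m$chain, i + 4L)
  if (!is.na(res4) && res4 != "PRO") {
    CA4 <- atom_xyz(s, m$chain, i + 4L, "CA")
    C3 <- atom_xyz(s, m$chain, i + 3L, "C")
    if (!is.null(CA4) && !is.null(C3)) {
      H <- amide_h(N4, CA4, C3)
      if (vangle(N4, H, O) < 120) return(FALSE)
    }
  }
  TRUE
}

# Geometric amide hydrogen: on N, in the peptide plane, N-H = 1.01 A,
# along the external bisector of C(prev)-N-CA (anti to the carbonyl O).
amide_h <- function(N, CA, C_prev) {
  u <- N - C_prev; u <- u / sqrt(sum(u^2))
  v <- N - CA; v <- v / sqrt(sum(v^2))
  w <- u + v
  N + 1.01 * w / sqrt(sum(w^2))
}

#' Classify an alpha-turn torsion profile
#'
#' Labels a profile as the right-handed alpha-turn type (IaRS) when each
#' of the six interior backbone torsions lies within \code{tol} of the
#' template (default: the largest-cluster mean torsions of the survey),
#' using circular differences.
#'
#' @param t a \code{zt_torsions}
#' @param template numeric length-6 vector (phi1, psi1, phi2, psi2, phi3,
#'   psi3)
#' @param tol per-angle tolerance in degrees
#' @return \code{"IaRS"} or \code{"other"}
#' @export
classify_alpha_turn <- function(t, template = c(-59, -37, -65, -47, -79, -21),
                                tol = 40) {
  v <- c(t$phi1, t$psi1, t$phi2, t$psi2, t$phi3, t$psi3)
  if (all(mapply(circ_diff, v, template) <= tol)) "IaRS" else "other"
}

#' Geometry of a four-coordinate metal site
#'
#' @param zn_xyz metal position (3-vector)
#' @param ligand_xyz 4 x 3 matrix of donor-atom coordinates
#' @return list with \code{bond_lengths} (4), \code{angles} (6, degrees),
#'   and \code{tetrahedricity} (mean absolute deviation of the six
#'   donor-metal-donor angles from 109.47 degrees)
#' @export
site_geometry <- function(zn_xyz, ligand_xyz) {
  ligand_xyz <- as.matrix(ligand_xyz)
  if (nrow(ligand_xyz) != 4)
    stop("site_geometry: exactly four ligand atoms required, got ",
         nrow(ligand_xyz))
  bl <- sqrt(rowSums(sweep(ligand_xyz, 2, zn_xyz)^2))
  pairs <- utils::combn(4, 2)
  ang <- apply(pairs, 2, function(p)
    vangle(ligand_xyz[p[1], ], zn_xyz, ligand_xyz[p[2], ]))
  list(bond_lengths = bl, angles = ang,
       tetrahedricity = mean(abs(ang - 109.47)))
}

# Sign convention calibrated so that the reconstructed reference dimers of
# the survey (all reported Lambda) evaluate to Lambda; the mirror image of
# any site then necessarily evaluates to Delta.
.lambda_sign <- -1

#' Lambda/Delta configuration of a two-pair metal site
#'
#' The handedness of a four-coordinate site whose donors come in two pairs,
#' one pair per motif copy.  With u1, u2 the unit vectors along each pair
#' and d the unit vector between pair midpoints, the sign of
#' d . (u1 x u2) determines the label; reflection of the site flips it.
#'
#' @param pair1,pair2 2 x 3 matrices; each row a donor-atom coordinate, in
#'   consistent order (coordinating atom of motif position 1 first, then
#'   position 4)
#' @return \code{"Lambda"}, \code{"Delta"}, or \code{"undefined"} for
#'   degenerate (parallel-axis) arrangements
#' @export
lambda_delta <- function(pair1, pair2) {
  pair1 <- as.matrix(pair1); pair2 <- as.matrix(pair2)
  u1 <- pair1[2, ] - pair1[1, ]
  u2 <- pair2[2, ] - pair2[1, ]
  u1 <- u1 / sqrt(sum(u1^2)); u2 <- u2 / sqrt(sum(u2^2))
  d <- colMeans(pair2) - colMeans(pair1)
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) return("undefined")
  d <- d / nd
  s <- sum(d * cross3(u1, u2))
  if (abs(s) < 1e-9) return("undefined")
  if (sign(s) == .lambda_sign) "Lambda" else "Delta"
}

#' Solve the Karplus equation for phi
#'
#' Finds all backbone phi values whose predicted three-bond J coupling
#' J(phi) = A cos^2(theta) + B cos(theta) + C, theta = phi + offset,
#' matches the observed coupling, by dense grid search plus root
#' refinement.
#'
#' @param J observed coupling in Hz
#' @param coeffs numeric (A, B, C); A > 0
#' @param theta_offset offset in degrees relating theta to phi (the common
#'   HN-Ha convention uses theta = phi - 60)
#' @param tol match tolerance in Hz
#' @return numeric vector of phi solutions in (-180, 180] (possibly empty)
#' @export
karplus_phi_solutions <- function(J, coeffs = c(6.4, -1.4, 1.9),
                                  theta_offset = -60, tol = 0.05) {
  A <- coeffs[1]; B <- coeffs[2]; C <- coeffs[3]
  stopifnot(A > 0)
  f <- function(phi) {
    ct <- cos((phi + theta_offset) * pi / 180)
    A * ct^2 + B * ct + C - J
  }
  grid <- seq(-180, 180, by = 0.25)
  fv <- f(grid)
  roots <- numeric(0)
  for (k in seq_len(length(grid) - 1)) {
    if (is.finite(fv[k]) && is.finite(fv[k + 1]) &&
        fv[k] * fv[k + 1] <= 0 && !(fv[k] == 0 && fv[k + 1] == 0)) {
      r <- uniroot(f, c(grid[k], grid[k + 1]), tol = 1e-10)$root
      roots <- c(roots, r)
    }
  }
  # tangential solutions (extrema touching zero)
  touch <- grid[abs(fv) < tol & c(TRUE, diff(sign(diff(fv))) != 0, TRUE)]
  roots <- wrap_angle(c(roots, touch))
  roots <- roots[abs(f(roots)) <= tol]
  roots <- sort(unique(round(roots, 4)))
  if (!length(roots)) return(numeric(0))
  keep <- c(TRUE, diff(roots) > 0.5)
  roots[keep]
}

#' Torsion table for a motif set
#'
#' @param motifs list of \code{zt_motif}
#' @param structures named list of \code{zt_structure}, keyed by id
#' @return data.frame with torsions, rotamer classes and turn type per motif
#' @export
torsion_table <- function(motifs, structures) {
  rows <- lapply(motifs, function(m) {
    s <- structures[[m$structure_id]]
    if (is.null(s)) stop("torsion_table: no structure for ", m$structure_id)
    t <- torsion_profile(m, s)
    data.frame(structure_id = m$structure_id, chain = m$chain,
               start = m$start, sequence = m$sequence,
               phi1 = t$phi1, psi1 = t$psi1, phi2 = t$phi2, psi2 = t$psi2,
               phi3 = t$phi3, psi3 = t$psi3,
               chi1_cys = t$chi1_cys, chi1_his = t$chi1_his,
               rotamer_cys = rotamer_class(t$chi1_cys),
               rotamer_his = rotamer_class(t$chi1_his),
               turn_type = classify_alpha_turn(t),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
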