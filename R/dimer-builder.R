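# Detection of pseudo-symmetric zinc-sharing segment pairs, idealized
# C2-symmetric homodimer construction, hydrogen placement and the
# inter-/intra-chain distance report used to discriminate dimer topologies.

# Zinc-binding five-residue segments C-X1-X2-(C|H)-X3 at one site: the
# position-1 Cys S-gamma and the position-4 donor (His ring N or Cys
# S-gamma) must both be ligands of the site's zinc.
zinc_segments <- function(s, site) {
  lig <- site$ligands
  cys <- lig[lig$type == "cys_sg", , drop = FALSE]
  segs <- list()
  for (ci in seq_len(nrow(cys))) {
    chain <- cys$chain[ci]; i0 <- cys$resno[ci]
    resn <- vapply(i0:(i0 + 4L), function(r) residue_name(s, chain, r),
                   character(1))
    if (any(is.na(resn)) || !(resn[4] %in% c("HIS", "CYS"))) next
    p4 <- i0 + 3L
    donor <- if (resn[4] == "HIS") {
      hl <- lig[lig$type == "his_n" & lig$chain == chain & lig$resno == p4, ,
                drop = FALSE]
      if (!nrow(hl)) next
      hl$elety[which.min(hl$dist)]
    } else {
      cl <- lig[lig$type == "cys_sg" & lig$chain == chain & lig$resno == p4, ,
                drop = FALSE]
      if (!nrow(cl)) next
      "SG"
    }
    g <- function(r, a) atom_xyz(s, chain, r, a)
    chi1_1 <- tryCatch(dihedral(g(i0, "N"), g(i0, "CA"), g(i0, "CB"),
                                g(i0, "SG")), error = function(e) NA)
    a4 <- if (resn[4] == "HIS") "CG" else "SG"
    chi1_4 <- tryCatch(dihedral(g(p4, "N"), g(p4, "CA"), g(p4, "CB"),
                                g(p4, a4)), error = function(e) NA)
    if (is.na(chi1_1) || is.na(chi1_4)) next
    seq5 <- paste(vapply(resn, function(r)
      if (r %in% names(.aa1)) .aa1[[r]] else "X", character(1)), collapse = "")
    segs[[length(segs) + 1L]] <- list(
      chain = chain, start = i0, sequence = seq5, res4 = resn[4],
      donor_atom = donor, chi1_1 = chi1_1, chi1_4 = chi1_4,
      rot1 = rotamer_class(chi1_1), rot4 = rotamer_class(chi1_4))
  }
  segs
}

#' Find pseudo-symmetric zinc-sharing segment pairs
#'
#' Two five-residue zinc-binding segments (C-X1-X2-H-X3 or C-X1-X2-C-X3)
#' on the same zinc form a pseudo-symmetric pair when the chi1 rotamer
#' classes of the corresponding coordinating residues match (position 1
#' with position 1, position 4 with position 4).
#'
#' @param s a \code{zt_structure}
#' @param sites zinc sites (default mined from \code{s})
#' @return list of pairs, each a list with \code{site}, \code{segment_a}
#'   (His-containing if any), \code{segment_b} and \code{rotamer_match}
#' @export
find_pseudosymmetric_pairs <- function(s, sites = find_zinc_sites(s)) {
  pairs <- list()
  for (site in sites) {
    segs <- zinc_segments(s, site)
    if (length(segs) < 2) next
    for (i in seq_len(length(segs) - 1)) {
      for (j in (i + 1):length(segs)) {
        a <- segs[[i]]; b <- segs[[j]]
        match14 <- c(pos1 = a$rot1 == b$rot1, pos4 = a$rot4 == b$rot4)
        if (!all(match14)) next
        # orient the pair so that a His-containing segment, if any, is A
        if (a$res4 != "HIS" && b$res4 == "HIS") { tmp <- a; a <- b; b <- tmp }
        pairs[[length(pairs) + 1L]] <- list(
          structure_id = s$id, site = site, segment_a = a, segment_b = b,
          rotamer_match = match14)
      }
    }
  }
  pairs
}

# Matched superposition coordinate sets for two segments: backbone
# N, CA, C, CB of the five residues (CB skipped where absent on either
# side, e.g. Gly) plus the coordinating atoms of positions 1 and 4.
segment_fit_sets <- function(s, seg_a, seg_b) {
  A <- NULL; B <- NULL
  for (k in 0:4) {
    for (a in c("N", "CA", "C", "CB")) {
      pa <- atom_xyz(s, seg_a$chain, seg_a$start + k, a)
      pb <- atom_xyz(s, seg_b$chain, seg_b$start + k, a)
      if (is.null(pa) || is.null(pb)) next
      A <- rbind(A, pa); B <- rbind(B, pb)
    }
  }
  pa <- atom_xyz(s, seg_a$chain, seg_a$start, "SG")
  pb <- atom_xyz(s, seg_b$chain, seg_b$start, "SG")
  if (!is.null(pa) && !is.null(pb)) { A <- rbind(A, pa); B <- rbind(B, pb) }
  pa <- atom_xyz(s, seg_a$chain, seg_a$start + 3L, seg_a$donor_atom)
  pb <- atom_xyz(s, seg_b$chain, seg_b$start + 3L, seg_b$donor_atom)
  if (!is.null(pa) && !is.null(pb)) { A <- rbind(A, pa); B <- rbind(B, pb) }
  list(A = A, B = B)
}

# Atom table of one five-residue segment (all heavy atoms) from a structure.
segment_atoms <- function(s, chain, start) {
  at <- s$atoms
  sel <- at$chain == chain & at$resno >= start & at$resno <= start + 4L &
    at$insert == "" & !at$het
  at[sel, , drop = FALSE]
}

make_dimer <- function(s, seg_a, axis, zn, source, rmsd_pair = NA,
                       observed_b = NULL) {
  R <- rotation_about_axis(axis, 180)
  atA <- segment_atoms(s, seg_a$chain, seg_a$start)
  xyzA <- as.matrix(atA[, c("x", "y", "z")])
  xyzB <- sweep(sweep(xyzA, 2, zn) %*% t(R), 2, zn, `+`)
  atB <- atA
  atB[, c("x", "y", "z")] <- xyzB
  atA$chain <- "A"; atB$chain <- "B"
  znrow <- data.frame(chain = "A", resno = max(atA$resno) + 100L,
                      insert = "", resid = "ZN", elety = "ZN", elesy = "ZN",
                      x = zn[1], y = zn[2], z = zn[3], o = 1, het = TRUE,
                      stringsAsFactors = FALSE)
  dimer_s <- zt_structure(paste0(s$id, "_dimer"), rbind(atA, atB, znrow))
  his_no <- seg_a$start + 3L
  # chirality from the two (position-1 donor -> position-4 donor) pairs
  d1A <- atom_xyz(dimer_s, "A", seg_a$start, "SG")
  d4A <- atom_xyz(dimer_s, "A", his_no,
                  if (seg_a$res4 == "HIS") seg_a$donor_atom else "SG")
  d1B <- atom_xyz(dimer_s, "B", seg_a$start, "SG")
  d4B <- atom_xyz(dimer_s, "B", his_no,
                  if (seg_a$res4 == "HIS") seg_a$donor_atom else "SG")
  chirality <- lambda_delta(rbind(d1A, d4A), rbind(d1B, d4B))
  geom <- site_geometry(zn, rbind(d1A, d4A, d1B, d4B))
  report <- dimer_distances(dimer_s, seg_a)
  report$s_zn <- sqrt(sum((d1A - zn)^2))
  report$n_zn <- sqrt(sum((d4A - zn)^2))
  if (!is.null(observed_b)) report <- c(report, observed_b)
  # clash check: inter-chain heavy atoms closer than 2.4 A (flagged only;
  # loose contacts are tolerated in these minimal models)
  dmin <- min(sqrt(outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) -
                     2 * xyzA %*% t(xyzB)))
  structure(list(structure = dimer_s, axis = axis, zn = zn,
                 rotation = R, source = source, chirality = chirality,
                 tetrahedricity = geom$tetrahedricity,
                 report = report, rmsd_pair = rmsd_pair,
                 clash = is.finite(dmin) && dmin < 2.4,
                 segment = seg_a),
            class = "zt_dimer")
}

# Inter- and intra-chain hydrogen distances of the His at position 4:
# ring HE1 of one chain vs the backbone amide H of the His of the other.
dimer_distances <- function(dimer_s, seg_a) {
  if (seg_a$res4 != "HIS") return(list())
  his_no <- seg_a$start + 3L
  h <- lapply(c("A", "B"), function(ch) {
    list(he1 = place_hydrogens(dimer_s, ch, his_no, "his_he1")$HE1,
         hn = place_hydrogens(dimer_s, ch, his_no, "amide")$H)
  })
  names(h) <- c("A", "B")
  list(his_he1_A_to_hn_B = sqrt(sum((h$A$he1 - h$B$hn)^2)),
       his_he1_B_to_hn_A = sqrt(sum((h$B$he1 - h$A$hn)^2)),
       intra_he1_hn_A = sqrt(sum((h$A$he1 - h$A$hn)^2)),
       intra_he1_hn_B = sqrt(sum((h$B$he1 - h$B$hn)^2)))
}

#' Idealize a pseudo-symmetric pair into an exact C2 homodimer
#'
#' The best-fit rigid transform mapping segment A onto segment B
#' (backbone + C-beta + coordinating atoms) is computed; its rotation is
#' projected to the nearest exact 180-degree rotation (axis direction
#' kept, angle forced to 180) and the axis is translated through the
#' zinc.  Chain B of the model is that operation applied to chain A, so
#' the result is exactly C2-symmetric with the zinc on the axis.
#'
#' @param pair a pair from \code{\link{find_pseudosymmetric_pairs}}
#' @param s the parent structure
#' @param max_rmsd refuse pairs whose superposition RMSD exceeds this
#'   (default 2.5 A: beyond that the pair is not pseudo-symmetric)
#' @return object of class \code{zt_dimer}
#' @export
idealize_c2 <- function(pair, s, max_rmsd = 2.5) {
  sets <- segment_fit_sets(s, pair$segment_a, pair$segment_b)
  fit <- kabsch_superpose(sets$B, sets$A)   # maps segment A onto segment B
  if (fit$rmsd > max_rmsd)
    stop("idealize_c2: pair superposition RMSD ", round(fit$rmsd, 2),
         " A exceeds ", max_rmsd, " A; not pseudo-symmetric")
  aa <- rotation_axis_angle(fit$rotation)
  zn <- pair$site$zn_xyz
  obs <- list(observed_pair_rmsd = fit$rmsd)
  if (pair$segment_a$res4 == "HIS" && pair$segment_b$res4 == "HIS") {
    # distances measured on the native (non-idealized) pair
    he1a <- place_hydrogens(s, pair$segment_a$chain,
                            pair$segment_a$start + 3L, "his_he1")$HE1
    hnb <- place_hydrogens(s, pair$segment_b$chain,
                           pair$segment_b$start + 3L, "amide")$H
    obs$observed_he1_hn <- sqrt(sum((he1a - hnb)^2))
  }
  make_dimer(s, pair$segment_a, aa$axis, zn, "idealized_from_pair",
             rmsd_pair = fit$rmsd, observed_b = obs)
}

#' Build a C2-symmetric dimer from a single motif
#'
#' Completes the tetrahedral metal site of one zinc-bound C-X1-X2-H-X3
#' motif by a two-fold rotation: the C2 axis through the zinc is chosen
#' to minimize the tetrahedricity of the four-donor set \{S, N, R(S),
#' R(N)\} (2-degree grid over axis orientations plus local refinement;
#' near-degenerate optima are resolved toward the least-clashing dimer).
#' Chain A atoms are never moved; chain B is the exact rotated copy.
#'
#' Exactly two enantiomeric near-optimal completions (Lambda and Delta)
#' generally exist; by default the sterically most open one is returned,
#' and \code{chirality} selects a specific handedness instead, as when a
#' model must match the configuration observed in natural dimers.
#'
#' @param m a \code{zt_motif}
#' @param s the parent structure
#' @param max_tetrahedricity abort when no axis achieves a completed-site
#'   tetrahedricity below this (degrees)
#' @param chirality \code{"auto"} (steric tie-break), \code{"Lambda"} or
#'   \code{"Delta"}
#' @return object of class \code{zt_dimer}
#' @export
build_c2_dimer_from_motif <- function(m, s, max_tetrahedricity = 30,
                                      chirality = c("auto", "Lambda",
                                                    "Delta")) {
  chirality <- match.arg(chirality)
  zn <- m$zn_xyz
  Sxyz <- atom_xyz(s, m$chain, m$start, "SG")
  Nxyz <- atom_xyz(s, m$chain, m$start + 3L, m$his_binding_atom)
  if (is.null(Sxyz) || is.null(Nxyz))
    stop("build_c2_dimer_from_motif: motif lacks S or N donor atoms")
  u <- Sxyz - zn; v <- Nxyz - zn
  lu <- sqrt(sum(u^2)); lv <- sqrt(sum(v^2))
  ang_uv <- vangle(Sxyz, zn, Nxyz)
  score <- function(par) {
    th <- par[1]; ph <- par[2]
    a <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    Ru <- 2 * sum(a * u) * a - u
    Rv <- 2 * sum(a * v) * a - v
    angs <- c(ang_uv,
              vangle(zn + u, zn, zn + Ru), vangle(zn + u, zn, zn + Rv),
              vangle(zn + v, zn, zn + Ru), vangle(zn + v, zn, zn + Rv),
              vangle(zn + Ru, zn, zn + Rv))
    mean(abs(angs - 109.47))
  }
  grid_th <- seq(0, pi / 2, by = 2 * pi / 180)
  grid_ph <- seq(0, 2 * pi, by = 2 * pi / 180)
  best <- NULL
  vals <- matrix(NA_real_, length(grid_th), length(grid_ph))
  for (i in seq_along(grid_th)) for (j in seq_along(grid_ph))
    vals[i, j] <- score(c(grid_th[i], grid_ph[j]))
  vmin <- min(vals)
  # refine every near-optimal grid point; keep distinct local optima
  cand_idx <- which(vals <= vmin + 1, arr.ind = TRUE)
  cands <- list()
  for (r in seq_len(nrow(cand_idx))) {
    p0 <- c(grid_th[cand_idx[r, 1]], grid_ph[cand_idx[r, 2]])
    op <- optim(p0, score, method = "Nelder-Mead",
                control = list(reltol = 1e-12))
    a <- c(sin(op$par[1]) * cos(op$par[2]),
           sin(op$par[1]) * sin(op$par[2]), cos(op$par[1]))
    cands[[length(cands) + 1L]] <- list(axis = a, value = op$value)
  }
  vbest <- min(vapply(cands, `[[`, numeric(1), "value"))
  if (vbest > max_tetrahedricity)
    stop("build_c2_dimer_from_motif: no axis reaches tetrahedricity < ",
         max_tetrahedricity, " deg (best ", round(vbest, 1), ")")
  cands <- Filter(function(cc) cc$value <= vbest + 1, cands)
  cand_label <- vapply(cands, function(cc) {
    RS <- zn + 2 * sum(cc$axis * u) * cc$axis - u
    RN <- zn + 2 * sum(cc$axis * v) * cc$axis - v
    lambda_delta(rbind(Sxyz, Nxyz), rbind(RS, RN))
  }, character(1))
  if (chirality != "auto") {
    sel <- cand_label == chirality
    if (!any(sel))
      stop("build_c2_dimer_from_motif: no near-optimal axis with ",
           chirality, " configuration")
    cands <- cands[sel]
  }
  # among near-degenerate axes prefer the sterically open dimer
  atA <- segment_atoms(s, m$chain, m$start)
  xyzA <- as.matrix(atA[, c("x", "y", "z")])
  open_score <- function(a) {
    R <- rotation_about_axis(a, 180)
    xyzB <- sweep(sweep(xyzA, 2, zn) %*% t(R), 2, zn, `+`)
    d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), `+`) -
      2 * xyzA %*% t(xyzB)
    sqrt(max(0, min(d2)))
  }
  opens <- vapply(cands, function(cc) open_score(cc$axis), numeric(1))
  axis <- cands[[which.max(opens)]]$axis
  seg <- list(chain = m$chain, start = m$start, sequence = m$sequence,
              res4 = "HIS", donor_atom = m$his_binding_atom)
  make_dimer(s, seg, axis, zn, "idealized_from_motif")
}

#' @export
print.zt_dimer <- function(x, ...) {
  cat("<zt_dimer>", x$structure$id, "(", x$source, ")\n")
  cat("  chirality:", x$chirality,
      " tetrahedricity:", round(x$tetrahedricity, 2), "deg",
      if (x$clash) " [clash flagged]" else "", "\n")
  if (!is.null(x$report$his_he1_A_to_hn_B))
    cat(sprintf("  inter-chain He1(A)-HN(B): %.2f A, intra: %.2f A\n",
                x$report$his_he1_A_to_hn_B, x$report$intra_he1_hn_A))
  invisible(x)
}

#' Place standard hydrogens needed for the NOE-distance report
#'
#' Crystal structures lack hydrogens; the ring HE1 and backbone amide H
#' are built from standard geometry: HE1 on CE1 in the imidazole plane
#' along the external bisector of ND1-CE1-NE2 at 1.08 A; the amide H on N
#' in the peptide plane at 1.01 A, anti to the carbonyl O of the
#' preceding residue.
#'
#' @param s a \code{zt_structure}
#' @param chain,resno residue to protonate
#' @param kind \code{"his_he1"} or \code{"amide"}
#' @return named list of added hydrogen positions
#' @export
place_hydrogens <- function(s, chain, resno, kind = c("his_he1", "amide")) {
  kind <- match.arg(kind)
  if (kind == "his_he1") {
    nd1 <- atom_xyz(s, chain, resno, "ND1")
    ce1 <- atom_xyz(s, chain, resno, "CE1")
    ne2 <- atom_xyz(s, chain, resno, "NE2")
    if (is.null(nd1) || is.null(ce1) || is.null(ne2))
      stop("place_hydrogens: missing imidazole ring atom on residue ", resno)
    u <- ce1 - nd1; u <- u / sqrt(sum(u^2))
    v <- ce1 - ne2; v <- v / sqrt(sum(v^2))
    w <- u + v
    list(HE1 = ce1 + 1.08 * w / sqrt(sum(w^2)))
  } else {
    N <- atom_xyz(s, chain, resno, "N")
    CA <- atom_xyz(s, chain, resno, "CA")
    Cp <- atom_xyz(s, chain, resno - 1L, "C")
    if (is.null(N) || is.null(CA) || is.null(Cp))
      stop("place_hydrogens: missing backbone atoms around residue ", resno)
    list(H = amide_h(N, CA, Cp))
  }
}
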