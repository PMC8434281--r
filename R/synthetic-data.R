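# Synthetic structure generator: builds CXXHX-type peptide motifs from
# internal coordinates at prescribed backbone and side-chain torsions, with
# optional idealized zinc placement, Gaussian coordinate noise and decoys.

# Canonical covalent geometry (bond lengths A, angles degrees).  Backbone
# values are standard Engh-Huber-type parameters; side-chain and imidazole
# ring values follow ideal residue geometry from the chemical component
# dictionary.  The L-amino-acid branch is fixed by the improper torsion
# N-C-CA-CB = +120 degrees.
.geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.530, b_cb_sg = 1.814, b_cb_cg = 1.510,
  b_cg_nd1 = 1.351, b_cg_cd2 = 1.338, b_nd1_ce1 = 1.337,
  b_cd2_ne2 = 1.374,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8,
  a_c_ca_cb = 110.1, a_ca_cb_sg = 113.8, a_ca_cb_cg = 113.0,
  a_cb_cg_nd1 = 122.7, a_cb_cg_cd2 = 129.9,
  a_cg_nd1_ce1 = 107.9, a_cg_cd2_ne2 = 105.3,
  improper_cb = 120.0,
  d_s_zn = 2.34, d_n_zn = 2.05
)

#' Specify a synthetic CXXHX-type motif
#'
#' Describes a five-residue peptide to be built at prescribed torsions.
#' Backbone phi/psi are given for all five positions (phi of the first
#' residue has no meaning and is ignored; terminal defaults are ordinary
#' helical/extended values).  chi1 applies to Cys and His side chains at any
#' position; for other residue types only the C-beta is placed.
#'
#' @param sequence 5-character string of one-letter codes, e.g. "CPFHP"
#' @param phi,psi numeric length-5 vectors, degrees in (-180, 180]
#' @param chi1 numeric length-5 vector of side-chain chi1 values, degrees
#'   (used only at Cys/His positions)
#' @param zn \code{"ideal"} to place a zinc coordinated by the position-1
#'   Cys S-gamma (2.34 A) and the position-4 His N-delta1 or Cys S-gamma,
#'   \code{"none"} for no metal, or \code{"decoy"} for a zinc placed 8 A
#'   away from the site (non-coordinating)
#' @param noise_sd Gaussian coordinate noise SD in Angstrom, applied last
#' @param seed integer seed used for the noise draw (NULL = no seeding)
#' @return a list of class \code{zt_motif_spec}
#' @export
motif_spec <- function(sequence, phi, psi, chi1 = rep(180, 5),
                       zn = c("ideal", "none", "decoy"),
                       noise_sd = 0, seed = NULL) {
  zn <- match.arg(zn)
  stopifnot(nchar(sequence) == 5, length(phi) == 5, length(psi) == 5,
            length(chi1) == 5, noise_sd >= 0)
  structure(list(sequence = toupper(sequence), phi = wrap_angle(phi),
                 psi = wrap_angle(psi), chi1 = wrap_angle(chi1),
                 zn = zn, noise_sd = noise_sd, seed = seed),
            class = "zt_motif_spec")
}

#' Build a synthetic motif structure from a spec
#'
#' Constructs the peptide residue by residue from canonical internal
#' geometry (omega fixed at 180 degrees) at the spec's torsions, places
#' Cys/His side chains at the requested chi1, optionally adds an idealized
#' zinc, and applies seeded Gaussian coordinate noise last.  If any two
#' non-bonded atoms fall within 1.2 A before noise the returned structure
#' carries attribute \code{clash = TRUE}.
#'
#' @param spec a \code{zt_motif_spec}
#' @param id identifier for the resulting structure
#' @param chain chain identifier
#' @param start author number of the first residue
#' @return a \code{zt_structure} (resolution set to 1.5 A so synthetic
#'   entries pass the default resolution filter)
#' @export
build_motif_structure <- function(spec, id = "synth", chain = "A", start = 1L) {
  g <- .geom
  seq1 <- strsplit(spec$sequence, "")[[1]]
  if (!all(seq1 %in% names(.aa3)))
    stop("build_motif_structure: unknown residue code in ", spec$sequence)
  n <- 5L
  # backbone
  N <- CA <- C <- O <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$b_n_ca, 0, 0)
  th <- g$a_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + g$b_ca_c * c(cos(pi - th), sin(pi - th), 0)
  for (i in 1:n) {
    if (i < n) {
      N[[i + 1]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                               g$b_c_n, g$a_ca_c_n, spec$psi[i])
      CA[[i + 1]] <- place_atom(CA[[i]], C[[i]], N[[i + 1]],
                                g$b_n_ca, g$a_c_n_ca, 180)
      C[[i + 1]] <- place_atom(C[[i]], N[[i + 1]], CA[[i + 1]],
                               g$b_ca_c, g$a_n_ca_c, spec$phi[i + 1])
    }
    # carbonyl O anti to the next amide N (psi + 180)
    O[[i]] <- place_atom(N[[i]], CA[[i]], C[[i]],
                         g$b_c_o, g$a_ca_c_o, spec$psi[i] + 180)
  }
  rows <- list()
  add <- function(resno, resid, elety, elesy, xyz, het = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      chain = chain, resno = resno, insert = "", resid = resid,
      elety = elety, elesy = elesy, x = xyz[1], y = xyz[2], z = xyz[3],
      o = 1, het = het, stringsAsFactors = FALSE)
  }
  side <- vector("list", n)
  for (i in 1:n) {
    rn <- start + i - 1L
    r3 <- .aa3[[seq1[i]]]
    add(rn, r3, "N", "N", N[[i]])
    add(rn, r3, "CA", "C", CA[[i]])
    add(rn, r3, "C", "C", C[[i]])
    add(rn, r3, "O", "O", O[[i]])
    if (seq1[i] != "G") {
      CB <- place_atom(N[[i]], C[[i]], CA[[i]],
                       g$b_ca_cb, g$a_c_ca_cb, g$improper_cb)
      add(rn, r3, "CB", "C", CB)
      if (seq1[i] == "C") {
        SG <- place_atom(N[[i]], CA[[i]], CB,
                         g$b_cb_sg, g$a_ca_cb_sg, spec$chi1[i])
        add(rn, r3, "SG", "S", SG)
        side[[i]] <- list(CB = CB, SG = SG)
      } else if (seq1[i] == "H") {
        side[[i]] <- list(CB = CB, place = local({
          CBi <- CB; Ni <- N[[i]]; CAi <- CA[[i]]; chi1i <- spec$chi1[i]
          function(chi2) {
            CG <- place_atom(Ni, CAi, CBi, g$b_cb_cg, g$a_ca_cb_cg, chi1i)
            ND1 <- place_atom(CAi, CBi, CG, g$b_cg_nd1, g$a_cb_cg_nd1, chi2)
            CD2 <- place_atom(CAi, CBi, CG, g$b_cg_cd2, g$a_cb_cg_cd2,
                              chi2 + 180)
            CE1 <- place_atom(CBi, CG, ND1, g$b_nd1_ce1, g$a_cg_nd1_ce1, 180)
            NE2 <- place_atom(CBi, CG, CD2, g$b_cd2_ne2, g$a_cg_cd2_ne2, 180)
            list(CG = CG, ND1 = ND1, CD2 = CD2, CE1 = CE1, NE2 = NE2)
          }
        }))
      } else {
        side[[i]] <- list(CB = CB)
      }
    }
  }
  # His rings: default chi2 = 180; when an ideal zinc is requested and the
  # ring must coordinate, chi2 is tuned so that the donor N approaches the
  # geometry of a tetrahedral S/N zinc site (d(SG, N-donor) near 3.58 A).
  zn_xyz <- NULL
  his_pos <- which(seq1 == "H")
  coord4 <- spec$zn == "ideal" && seq1[1] == "C" && seq1[4] %in% c("H", "C")
  for (i in his_pos) {
    chi2 <- 180
    if (coord4 && i == 4L && !is.null(side[[1]]$SG)) {
      sg <- side[[1]]$SG
      target <- sqrt(g$d_s_zn^2 + g$d_n_zn^2 -
                       2 * g$d_s_zn * g$d_n_zn * cos(109.47 * pi / 180))
      dfun <- function(x) sqrt(sum((side[[i]]$place(x)$ND1 - sg)^2)) - target
      # d(chi2) is sinusoidal, so the target is crossed at most twice per
      # turn; the ascending crossing is taken, which selects one ring
      # orientation consistently across near-identical motifs
      grid <- seq(-180, 180, by = 1)
      fv <- vapply(grid, dfun, numeric(1))
      chi2 <- NA_real_
      for (k2 in seq_len(length(grid) - 1)) {
        if (fv[k2] <= 0 && fv[k2 + 1] > 0) {
          chi2 <- uniroot(dfun, c(grid[k2], grid[k2 + 1]), tol = 1e-9)$root
          break
        }
      }
      if (is.na(chi2)) chi2 <- grid[which.min(abs(fv))]
    }
    ring <- side[[i]]$place(chi2)
    rn <- start + i - 1L
    for (nm in names(ring))
      add(rn, "HIS", nm, substr(nm, 1, 1), ring[[nm]])
    side[[i]] <- c(side[[i]][c("CB")], ring)
  }
  atoms <- do.call(rbind, rows)
  # zinc placement
  if (spec$zn != "none" && seq1[1] == "C") {
    sg <- side[[1]]$SG
    cb <- side[[1]]$CB
    if (spec$zn == "decoy") {
      zn_xyz <- sg + 8 * (sg - cb) / sqrt(sum((sg - cb)^2))
    } else if (coord4) {
      donor <- if (seq1[4] == "H") side[[4]]$ND1 else side[[4]]$SG
      rd <- if (seq1[4] == "H") g$d_n_zn else g$d_s_zn
      allxyz <- as.matrix(atoms[, c("x", "y", "z")])
      notdonor <- rowSums(sweep(allxyz, 2, sg)^2) > 1e-12 &
        rowSums(sweep(allxyz, 2, donor)^2) > 1e-12
      zn_xyz <- .two_sphere_point(sg, g$d_s_zn, donor, rd,
                                  ref = allxyz[notdonor, , drop = FALSE])
    } else {
      zn_xyz <- sg + g$d_s_zn * (sg - cb) / sqrt(sum((sg - cb)^2))
    }
  }
  if (!is.null(zn_xyz)) {
    znrow <- data.frame(chain = chain, resno = start + 100L, insert = "",
                        resid = "ZN", elety = "ZN", elesy = "ZN",
                        x = zn_xyz[1], y = zn_xyz[2], z = zn_xyz[3],
                        o = 1, het = TRUE, stringsAsFactors = FALSE)
    atoms <- rbind(atoms, znrow)
  }
  clash <- .has_clash(atoms)
  if (spec$noise_sd > 0) {
    if (!is.null(spec$seed)) set.seed(spec$seed)
    m <- nrow(atoms)
    atoms$x <- atoms$x + rnorm(m, 0, spec$noise_sd)
    atoms$y <- atoms$y + rnorm(m, 0, spec$noise_sd)
    atoms$z <- atoms$z + rnorm(m, 0, spec$noise_sd)
  }
  s <- zt_structure(id = id, atoms = atoms, resolution = 1.5,
                    method = "SYNTHETIC")
  attr(s, "clash") <- clash
  attr(s, "spec") <- spec
  s
}

# Point at distance r1 from c1 and r2 from c2 (sphere intersection).  On
# the intersection circle the unique point farthest from the reference
# centroid is taken: it points away from the peptide body, and (unlike an
# argmax over individual atom distances) it varies continuously with the
# input coordinates, so near-identical motifs get near-identical metal
# positions.  Falls back to the closest-approach point when the spheres
# do not intersect.
.two_sphere_point <- function(c1, r1, c2, r2, ref) {
  d <- sqrt(sum((c2 - c1)^2))
  u <- (c2 - c1) / d
  if (d > r1 + r2 || d < abs(r1 - r2)) {
    return(c1 + r1 * u)
  }
  a <- (d^2 + r1^2 - r2^2) / (2 * d)
  h <- sqrt(max(0, r1^2 - a^2))
  center <- c1 + a * u
  g0 <- colMeans(ref)
  # project the away-from-centroid direction onto the circle plane
  w <- (center - g0)
  w <- w - sum(w * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-9) {
    w <- cross3(u, c(1, 0, 0))
    if (sum(w^2) < 1e-6) w <- cross3(u, c(0, 1, 0))
    nw <- sqrt(sum(w^2))
  }
  p <- center + h * w / nw
  if (min(sqrt(rowSums(sweep(ref, 2, p)^2))) >= 2.0) return(p)
  # crowded pocket: fall back to the clearance-maximizing circle point
  e1 <- w / nw
  e2 <- cross3(u, e1)
  ang <- seq(0, 2 * pi, length.out = 181)[-181]
  best <- p; bestscore <- -Inf
  for (t in ang) {
    q <- center + h * (cos(t) * e1 + sin(t) * e2)
    score <- min(sqrt(rowSums(sweep(ref, 2, q)^2)))
    if (score > bestscore) { bestscore <- score; best <- q }
  }
  best
}

.has_clash <- function(atoms, cutoff = 1.2) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  m <- nrow(xyz)
  if (m < 2) return(FALSE)
  dm <- as.matrix(stats::dist(xyz))
  # ignore pairs adjacent in the build order (covalently bonded neighbours)
  near <- abs(row(dm) - col(dm)) > 2 & dm < cutoff & upper.tri(dm)
  any(near)
}

#' Reference cluster torsion table
#'
#' The bundled per-cluster average dihedral angles (and SDs) of the
#' zinc-bound CXXHX alpha-turn survey: four clusters of sizes 86, 16, 13
#' and 11, plus three singleton outliers (129 sites in total).  Used as
#' the default population for the synthetic benchmark generator.
#'
#' @return data.frame with cluster id, size, six backbone torsion means,
#'   chi1 means for Cys and His, and the corresponding SDs
#' @export
cluster_torsion_table <- function() {
  read.delim(system.file("extdata", "cxxhx_cluster_torsions.tsv",
                         package = "zincturn"),
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Motif spec at the mean torsions of a reference cluster
#'
#' Maps one row of \code{\link{cluster_torsion_table}} (interior-residue
#' torsions phi/psi i+1..i+3 and the two chi1 values) onto a buildable
#' five-residue spec.  Terminal torsions are not part of the reference
#' table; the defaults place residue i in an extended conformation
#' (psi = 120) so that, as in the observed sites, the Cys thiolate and the
#' His imidazole converge on a common metal position.
#'
#' @param row one-row data.frame with columns \code{phi1..psi3},
#'   \code{chi1_cys}, \code{chi1_his}
#' @param sequence 5-letter sequence (C at 1, H at 4)
#' @param psi_i,phi_i4,psi_i4 terminal torsion defaults
#' @param ... passed to \code{\link{motif_spec}} (zn, noise_sd, seed)
#' @return a \code{zt_motif_spec}
#' @export
cluster_motif_spec <- function(row, sequence = "CAAHG", psi_i = 120,
                               phi_i4 = -120, psi_i4 = 140, ...) {
  motif_spec(sequence,
             phi = c(-100, row$phi1, row$phi2, row$phi3, phi_i4),
             psi = c(psi_i, row$psi1, row$psi2, row$psi3, psi_i4),
             chi1 = c(row$chi1_cys, 180, 180, row$chi1_his, 180), ...)
}

#' Generate a synthetic benchmark set of motif structures
#'
#' Emulates the population structure of the mined database: for each row of
#' the cluster table, \code{size} structures are drawn with every torsion
#' jittered around the cluster means (independent Gaussian,
#' SD \code{torsion_sd}), plus isotropic coordinate noise, plus optional
#' decoys that must be rejected by mining.  All randomness derives from
#' \code{seed}.
#'
#' @param clusters cluster definition table, default
#'   \code{cluster_torsion_table()}
#' @param decoys number of decoy structures (non-coordinating zinc,
#'   wrong Cys/His spacing, extended backbone), cycled over the three types
#' @param torsion_sd per-angle torsion jitter SD in degrees (within the
#'   reported per-cluster spreads, small enough that planted membership is
#'   recoverable)
#' @param noise_sd coordinate noise SD in Angstrom (emulating coordinate
#'   uncertainty of good crystal structures)
#' @param seed integer seed
#' @param sequences optional character vector of 5-letter sequences to cycle
#'   over (default generic "CAAHG")
#' @return list with \code{structures} (named list of \code{zt_structure})
#'   and \code{truth} (data.frame: id, cluster label, decoy type)
#' @export
make_benchmark_set <- function(clusters = cluster_torsion_table(),
                               decoys = 0, torsion_sd = 2.5,
                               noise_sd = 0.02, seed = 1,
                               sequences = "CAAHG") {
  set.seed(seed)
  structures <- list()
  truth <- list()
  k <- 0L
  for (ci in seq_len(nrow(clusters))) {
    row <- clusters[ci, ]
    for (j in seq_len(row$size)) {
      k <- k + 1L
      id <- sprintf("bench%03d", k)
      jit <- function(mean) wrap_angle(mean + rnorm(1, 0, torsion_sd))
      phi <- c(-100, jit(row$phi1), jit(row$phi2), jit(row$phi3), -120)
      psi <- c(120, jit(row$psi1), jit(row$psi2), jit(row$psi3), 140)
      chi1 <- rep(180, 5)
      chi1[1] <- jit(row$chi1_cys)
      chi1[4] <- jit(row$chi1_his)
      sq <- sequences[(k - 1L) %% length(sequences) + 1L]
      spec <- motif_spec(sq, phi, psi, chi1, zn = "ideal",
                         noise_sd = noise_sd, seed = seed + k)
      structures[[id]] <- build_motif_structure(spec, id = id, start = 10L)
      truth[[k]] <- data.frame(id = id, cluster = row$cluster,
                               decoy = "none", stringsAsFactors = FALSE)
    }
  }
  if (decoys > 0) {
    types <- c("nozinc", "spacing", "extended")
    for (j in seq_len(decoys)) {
      k <- k + 1L
      id <- sprintf("decoy%03d", j)
      type <- types[(j - 1L) %% 3L + 1L]
      spec <- switch(type,
        nozinc = motif_spec("CAAHG", c(-100, -59, -65, -79, -120),
                            c(120, -37, -47, -21, 140),
                            chi1 = c(72, 180, 180, -75, 180), zn = "decoy"),
        spacing = motif_spec("CAHGA", c(-100, -59, -65, -79, -120),
                             c(120, -37, -47, -21, 140),
                             chi1 = c(72, 180, 180, 180, 180), zn = "ideal"),
        extended = motif_spec("CAAHG", c(-100, -120, -120, -120, -120),
                              c(130, 130, 130, 130, 130),
                              chi1 = c(72, 180, 180, -75, 180), zn = "ideal"))
      structures[[id]] <- build_motif_structure(spec, id = id, start = 10L)
      truth[[k]] <- data.frame(id = id, cluster = NA_integer_,
                               decoy = type, stringsAsFactors = FALSE)
    }
  }
  list(structures = structures, truth = do.call(rbind, truth))
}

#' Simulate a titration dataset
#'
#' Generates direct metal-binding, competition-displacement or pH-titration
#' data with the experimental designs of the self-assembly study as
#' defaults: direct Co(II) titration into 8.0e-4 M peptide over 0-2.5
#' equivalents; Zn(II)/Cd(II) competition against 3.5 equivalents of Co(II)
#' at 1.0e-3 M peptide; a two-state pH transition with midpoint 7.1.
#' Additive i.i.d. Gaussian noise is applied to the observed values.
#'
#' @param kind \code{"direct"}, \code{"competition"} or \code{"ph"}
#' @param params named list overriding the default generator parameters
#'   (direct: \code{P_t}, \code{K_D}, \code{n}, \code{equivalents};
#'   competition: \code{P_t}, \code{M1_t}, \code{K_D1}, \code{K_ex},
#'   \code{equivalents}; ph: \code{midpoint}, \code{hill}, \code{low},
#'   \code{high}, \code{ph_range})
#' @param noise_sd additive noise SD on the observable
#' @param seed integer seed
#' @param n_points number of titration points
#' @return data.frame of (\code{titrant_total_M} or \code{ph},
#'   \code{observed}), with the generating truth in attribute \code{truth}
#' @export
make_titration <- function(kind = c("direct", "competition", "ph"),
                           params = list(), noise_sd = 0.02, seed = 1,
                           n_points = 26) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "direct") {
    p <- utils::modifyList(list(P_t = 8.0e-4, K_D = 85e-6, n = 2,
                                equivalents = 2.5), params)
    M <- seq(0, p$equivalents * p$P_t, length.out = n_points)
    y <- vapply(M, function(m)
      if (m == 0) 0 else solve_single(p$P_t, m, p$K_D, p$n)$Y, numeric(1))
    out <- data.frame(titrant_total_M = M,
                      observed = y + rnorm(n_points, 0, noise_sd))
  } else if (kind == "competition") {
    p <- utils::modifyList(list(P_t = 1.0e-3, M1_t = 3.5e-3, K_D1 = 85e-6,
                                K_ex = (85 / 5.6)^2, equivalents = 5),
                           params)
    M2 <- seq(0, p$equivalents * p$P_t, length.out = n_points)
    y <- vapply(M2, function(m)
      solve_competition(p$P_t, p$M1_t, m, p$K_D1, p$K_ex)$Y1, numeric(1))
    out <- data.frame(titrant_total_M = M2,
                      observed = y + rnorm(n_points, 0, noise_sd))
  } else {
    p <- utils::modifyList(list(midpoint = 7.1, hill = 1, low = 0, high = 1,
                                ph_range = c(3.8, 9.2)), params)
    ph <- seq(p$ph_range[1], p$ph_range[2], length.out = n_points)
    y <- p$low + (p$high - p$low) / (1 + 10^(p$hill * (p$midpoint - ph)))
    out <- data.frame(ph = ph, observed = y + rnorm(n_points, 0, noise_sd))
  }
  attr(out, "truth") <- c(list(kind = kind, noise_sd = noise_sd, seed = seed),
                          p)
  out
}
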