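test_that("builder-to-profile round trip recovers every torsion within 0.5 deg", {
  tab <- cluster_torsion_table()
  for (k in seq_len(nrow(tab))) {
    r <- tab[k, ]
    s <- cluster_fixtures()[[k]]
    m <- find_cxxhx_motifs(s)[[1]]
    t <- torsion_profile(m, s)
    want <- c(r$phi1, r$psi1, r$phi2, r$psi2, r$phi3, r$psi3,
              r$chi1_cys, r$chi1_his)
    got <- c(t$phi1, t$psi1, t$phi2, t$psi2, t$phi3, t$psi3,
             t$chi1_cys, t$chi1_his)
    expect_lt(max(abs(wrap_angle(got - want))), 0.5)
  }
})

test_that("mirror inversion negates every torsion", {
  s <- cluster_fixtures()[[1]]
  m <- find_cxxhx_motifs(s)[[1]]
  t0 <- unlist(torsion_profile(m, s))
  sm <- s
  sm$atoms$z <- -sm$atoms$z
  mm <- find_cxxhx_motifs(sm)[[1]]
  t1 <- unlist(torsion_profile(mm, sm))
  expect_equal(unname(wrap_angle(t1 + t0)), rep(0, 8), tolerance = 1e-6)
})

test_that("rotamer bins reproduce conventional labels and partition the circle", {
  expect_equal(rotamer_class(72), "g+")
  expect_equal(rotamer_class(93), "g+")
  expect_equal(rotamer_class(179), "trans")
  expect_equal(rotamer_class(-175), "trans")
  expect_equal(rotamer_class(-58), "g-")
  expect_equal(rotamer_class(-75), "g-")
  # no gaps, no overlaps over a fine grid of the whole circle
  grid <- seq(-179.75, 180, by = 0.25)
  lab <- rotamer_class(grid)
  expect_true(all(lab %in% c("g+", "g-", "trans")))
  expect_equal(sum(lab == "g+") + sum(lab == "g-") + sum(lab == "trans"),
               length(grid))
  # boundary assignments are deterministic
  expect_equal(rotamer_class(c(0, 120, -120, 180)),
               c("g+", "trans", "trans", "trans"))
})

test_that("i->i+4 hydrogen bond criterion responds to distance and Pro", {
  # ideal alpha-turn fixture: cluster 1 carries the canonical H-bond
  s <- cluster_fixtures()[[1]]
  m <- find_cxxhx_motifs(s)[[1]]
  expect_true(hbond_i_i4(m, s))
  # pull residue i+4 away: bond must vanish
  far <- s
  i5 <- far$atoms$resno == m$start + 4L
  far$atoms$x[i5] <- far$atoms$x[i5] + 5
  expect_false(hbond_i_i4(m, far))
  # Pro at i+4 is judged on distance/C=O angle only (no amide H gate)
  sp <- build_motif_structure(
    cluster_motif_spec(cluster_torsion_table()[1, ], sequence = "CAAHP",
                       zn = "ideal"), id = "pro5")
  mp <- find_cxxhx_motifs(sp)[[1]]
  expect_true(hbond_i_i4(mp, sp))
})

test_that("alpha-turn classification accepts cluster means and rejects extended", {
  # clusters 1-3 fall inside the default +/-40 degree window around the
  # largest-cluster template; cluster 4's psi(i+3) (78 vs -21) is the
  # documented special case outside it
  for (k in 1:3) {
    s <- cluster_fixtures()[[k]]
    t <- torsion_profile(find_cxxhx_motifs(s)[[1]], s)
    expect_equal(classify_alpha_turn(t), "IaRS")
  }
  ext <- list(phi1 = -120, psi1 = 130, phi2 = -120, psi2 = 130,
              phi3 = -120, psi3 = 130)
  expect_equal(classify_alpha_turn(ext), "other")
  shifted <- list(phi1 = -59 + 39, psi1 = -37 + 39, phi2 = -65 + 39,
                  psi2 = -47 + 39, phi3 = -79 + 39, psi3 = -21 + 39)
  expect_equal(classify_alpha_turn(shifted), "IaRS")
})

test_that("site geometry reports tetrahedral and square-planar signatures", {
  zn <- c(0, 0, 0)
  tet <- 2.3 * rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                     c(-1, -1, 1)) / sqrt(3)
  g <- site_geometry(zn, tet)
  expect_equal(g$bond_lengths, rep(2.3, 4), tolerance = 1e-9)
  expect_equal(g$angles, rep(109.47, 6), tolerance = 0.01)
  expect_lt(g$tetrahedricity, 0.01)
  sq <- 2.3 * rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0))
  gs <- site_geometry(zn, sq)
  expect_equal(sort(round(gs$angles)), c(90, 90, 90, 90, 180, 180))
  # direct oracle: (4*|90-109.47| + 2*|180-109.47|)/6
  expect_equal(gs$tetrahedricity,
               (4 * abs(90 - 109.47) + 2 * abs(180 - 109.47)) / 6,
               tolerance = 1e-3)
  expect_error(site_geometry(zn, tet[1:3, ]), "four ligand")
})

test_that("metal-site chirality flips under reflection and degenerates to undefined", {
  p1 <- rbind(c(2.3, 0, 0.5), c(0, 2.1, -0.4))
  p2 <- rbind(c(-2.2, 0.3, 0.6), c(0.1, -2.0, -0.7))
  lab <- lambda_delta(p1, p2)
  expect_true(lab %in% c("Lambda", "Delta"))
  m1 <- p1; m1[, 3] <- -m1[, 3]
  m2 <- p2; m2[, 3] <- -m2[, 3]
  expect_false(lambda_delta(m1, m2) == lab)
  # parallel pair axes are degenerate
  q1 <- rbind(c(0, 0, 0), c(1, 0, 0))
  q2 <- rbind(c(0, 1, 0), c(1, 1, 0))
  expect_equal(lambda_delta(q1, q2), "undefined")
})

test_that("Karplus inversion finds grid-verified phi solutions", {
  # J = A + |B| + C + 1 exceeds the curve maximum: no solution
  expect_length(karplus_phi_solutions(6.4 + 1.4 + 1.9 + 1), 0)
  # J = 9.7 Hz with the default coefficients: phi = -120 among solutions
  sol <- karplus_phi_solutions(9.7, c(6.4, -1.4, 1.9), -60)
  expect_true(any(abs(sol - (-120)) < 0.1))
  # every returned solution reproduces J; grid oracle finds no extras
  J <- 7.3
  sol <- karplus_phi_solutions(J, c(6.4, -1.4, 1.9), -60)
  f <- function(phi) {
    ct <- cos((phi - 60) * pi / 180)
    6.4 * ct^2 - 1.4 * ct + 1.9
  }
  expect_true(all(abs(vapply(sol, f, numeric(1)) - J) <= 0.05))
  grid <- seq(-180, 180, by = 0.01)
  hits <- grid[abs(f(grid) - J) < 0.005]
  expect_true(all(vapply(hits, function(h) min(abs(sol - h)) < 0.5,
                         logical(1))))
  # solutions are symmetric about the offset axis (cosine parity)
  refl <- sort(wrap_angle(2 * 60 - sol))
  expect_equal(sort(sol), refl, tolerance = 1e-3)
})
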