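# shared fixture: Lambda-selected C2 dimer built from the reconstructed
# outlier-5-like motif (trans/g+ rotamer subset)
dimer_fixture <- function() cached("dimer5", function() {
  tab <- cluster_torsion_table()
  s <- build_motif_structure(
    cluster_motif_spec(tab[5, ], sequence = "CPFHP", zn = "ideal"),
    id = "synth2au3", start = 35L)
  m <- find_cxxhx_motifs(s)[[1]]
  list(s = s, m = m,
       dimer = build_c2_dimer_from_motif(m, s, chirality = "Lambda"))
})

test_that("single-motif C2 completion yields an exact symmetric tetrahedral site", {
  d <- dimer_fixture()$dimer
  expect_lt(d$tetrahedricity, 1)
  # chain B is exactly the stored rotation of chain A
  at <- d$structure$atoms
  A <- as.matrix(at[at$chain == "A" & !at$het, c("x", "y", "z")])
  B <- as.matrix(at[at$chain == "B", c("x", "y", "z")])
  Bpred <- sweep(sweep(A, 2, d$zn) %*% t(d$rotation), 2, d$zn, `+`)
  expect_lt(max(abs(B - Bpred)), 1e-9)
  # the rotation is a proper 180-degree rotation and the zinc sits on the axis
  aa <- zincturn:::rotation_axis_angle(d$rotation)
  expect_equal(aa$angle, 180, tolerance = 1e-6)
  expect_equal(det(d$rotation), 1, tolerance = 1e-9)
  # chain A atoms equal the source motif atoms (never moved)
  src <- zincturn:::segment_atoms(dimer_fixture()$s, "A", 35L)
  expect_equal(A, as.matrix(src[, c("x", "y", "z")]), ignore_attr = TRUE)
  # ligand-zinc distances preserved exactly in the copy
  expect_equal(d$report$s_zn, 2.34, tolerance = 1e-6)
  sB <- zincturn:::atom_xyz(d$structure, "B", 35L, "SG")
  expect_equal(sqrt(sum((sB - d$zn)^2)), d$report$s_zn, tolerance = 1e-9)
})

test_that("distance report is chain-symmetric for idealized dimers", {
  r <- dimer_fixture()$dimer$report
  expect_equal(r$his_he1_A_to_hn_B, r$his_he1_B_to_hn_A, tolerance = 1e-3)
  expect_equal(r$intra_he1_hn_A, r$intra_he1_hn_B, tolerance = 1e-3)
  # the intra-residue He1/HN separation of an imidazole is around 6 A
  expect_gt(r$intra_he1_hn_A, 4.5)
  expect_lt(r$intra_he1_hn_A, 7)
})

test_that("dimer chirality is selectable and flips under mirror inversion", {
  fx <- dimer_fixture()
  dL <- build_c2_dimer_from_motif(fx$m, fx$s, chirality = "Lambda")
  dD <- build_c2_dimer_from_motif(fx$m, fx$s, chirality = "Delta")
  expect_equal(dL$chirality, "Lambda")
  expect_equal(dD$chirality, "Delta")
  sm <- fx$s
  sm$atoms$z <- -sm$atoms$z
  mm <- find_cxxhx_motifs(sm)[[1]]
  d0 <- build_c2_dimer_from_motif(fx$m, fx$s)
  d1 <- build_c2_dimer_from_motif(mm, sm)
  expect_true(d0$chirality %in% c("Lambda", "Delta"))
  expect_false(d1$chirality == d0$chirality)
})

test_that("pseudo-symmetric pair detection requires matching rotamer classes", {
  d <- dimer_fixture()$dimer
  pairs <- find_pseudosymmetric_pairs(d$structure)
  expect_length(pairs, 1)
  expect_true(all(pairs[[1]]$rotamer_match))
  # break the symmetry: flip the chain-B Cys chi1 into another rotamer well
  s2 <- d$structure
  sgB <- which(s2$atoms$chain == "B" & s2$atoms$elety == "SG")
  cbB <- which(s2$atoms$chain == "B" & s2$atoms$elety == "CB" &
                 s2$atoms$resno == 35L)
  caB <- which(s2$atoms$chain == "B" & s2$atoms$elety == "CA" &
                 s2$atoms$resno == 35L)
  nB <- which(s2$atoms$chain == "B" & s2$atoms$elety == "N" &
                s2$atoms$resno == 35L)
  xyz <- function(i) as.numeric(s2$atoms[i, c("x", "y", "z")])
  s2$atoms[sgB, c("x", "y", "z")] <-
    as.list(place_atom(xyz(nB), xyz(caB), xyz(cbB), 1.81, 114, 60))
  expect_length(find_pseudosymmetric_pairs(s2), 0)
})

test_that("idealizing an already exact C2 pair is a fixed point", {
  d <- dimer_fixture()$dimer
  pair <- find_pseudosymmetric_pairs(d$structure)[[1]]
  ideal <- idealize_c2(pair, d$structure)
  expect_lt(ideal$rmsd_pair, 1e-9)
  atB0 <- d$structure$atoms[d$structure$atoms$chain == "B", ]
  atB1 <- ideal$structure$atoms[ideal$structure$atoms$chain == "B", ]
  expect_lt(max(abs(as.matrix(atB0[, c("x", "y", "z")]) -
                      as.matrix(atB1[, c("x", "y", "z")]))), 1e-6)
  # far-from-symmetric pairs are refused
  skewed <- d$structure
  bidx <- skewed$atoms$chain == "B"
  skewed$atoms$x[bidx] <- skewed$atoms$x[bidx] + 4
  pair2 <- find_pseudosymmetric_pairs(skewed)
  if (length(pair2))
    expect_error(idealize_c2(pair2[[1]], skewed, max_rmsd = 0.5),
                 "not pseudo-symmetric")
})

test_that("hydrogen placement is planar, standard-length and equivariant", {
  fx <- dimer_fixture()
  s <- fx$s
  h <- place_hydrogens(s, "A", 38L, "his_he1")$HE1
  nd1 <- zincturn:::atom_xyz(s, "A", 38L, "ND1")
  ce1 <- zincturn:::atom_xyz(s, "A", 38L, "CE1")
  ne2 <- zincturn:::atom_xyz(s, "A", 38L, "NE2")
  cg <- zincturn:::atom_xyz(s, "A", 38L, "CG")
  expect_equal(sqrt(sum((h - ce1)^2)), 1.08, tolerance = 1e-6)
  # coplanar with the ring plane spanned at ND1
  nrm <- zincturn:::cross3(ce1 - nd1, cg - nd1)
  nrm <- nrm / sqrt(sum(nrm^2))
  expect_lt(abs(sum((h - ce1) * nrm)), 1e-3)
  amide <- place_hydrogens(s, "A", 38L, "amide")$H
  n38 <- zincturn:::atom_xyz(s, "A", 38L, "N")
  expect_equal(sqrt(sum((amide - n38)^2)), 1.01, tolerance = 1e-6)
  # translation equivariance
  st <- s
  st$atoms$x <- st$atoms$x + 11.5
  h2 <- place_hydrogens(st, "A", 38L, "his_he1")$HE1
  expect_equal(h2, h + c(11.5, 0, 0), tolerance = 1e-9)
  expect_error(place_hydrogens(s, "A", 36L, "his_he1"), "ring atom")
})
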