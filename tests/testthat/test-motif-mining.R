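test_that("planted ideal motifs are mined with the constructed bond lengths", {
  for (s in cluster_fixtures()) {
    sites <- find_zinc_sites(s)
    expect_length(sites, 1)
    lig <- sites[[1]]$ligands
    expect_equal(lig$dist, sort(lig$dist))
    expect_equal(lig$dist[lig$type == "cys_sg"], 2.34, tolerance = 1e-3)
    motifs <- find_cxxhx_motifs(s, sites)
    expect_length(motifs, 1)
    m <- motifs[[1]]
    expect_equal(m$his_binding_atom, "ND1")
    expect_equal(m$s_zn_distance, 2.34, tolerance = 1e-3)
    expect_equal(m$n_zn_distance, 2.05, tolerance = 1e-3)
    expect_true(alpha_turn_filter(m))
  }
})

test_that("decoys are rejected: far zinc, wrong spacing, extended backbone", {
  bench <- small_benchmark()
  decoy_ids <- bench$truth$id[bench$truth$decoy != "none"]
  expect_length(decoy_ids, 6)
  for (id in decoy_ids) {
    s <- bench$structures[[id]]
    motifs <- find_cxxhx_motifs(s)
    motifs <- motifs[vapply(motifs, alpha_turn_filter, logical(1))]
    expect_length(motifs, 0)
  }
})

test_that("mining recall on planted non-decoy structures is complete", {
  bench <- small_benchmark()
  planted <- bench$truth$id[bench$truth$decoy == "none"]
  mined <- vapply(planted, function(id) {
    length(find_cxxhx_motifs(bench$structures[[id]]))
  }, integer(1))
  expect_true(all(mined == 1))
})

test_that("zinc sites without ligands inside the cutoff are not reported", {
  s <- cluster_fixtures()[[1]]
  # displace the zinc 8 A away from everything
  zn_i <- which(s$atoms$resid == "ZN")
  dir <- c(1, 1, 1) / sqrt(3)
  far <- as.numeric(s$atoms[zn_i, c("x", "y", "z")]) + 20 * dir
  s$atoms[zn_i, c("x", "y", "z")] <- as.list(far)
  expect_length(find_zinc_sites(s, cutoff = 3.0), 0)
})

test_that("two independent zinc sites give two disjoint site records", {
  s1 <- cluster_fixtures()[[1]]
  s2 <- cluster_fixtures()[[2]]
  shifted <- s2$atoms
  shifted$x <- shifted$x + 50
  shifted$resno <- shifted$resno + 50L
  merged <- zt_structure("twosites", rbind(s1$atoms, shifted),
                         resolution = 1.5)
  sites <- find_zinc_sites(merged)
  expect_length(sites, 2)
  r1 <- sites[[1]]$ligands$resno
  r2 <- sites[[2]]$ligands$resno
  expect_length(intersect(r1, r2), 0)
  expect_length(find_cxxhx_motifs(merged, sites), 2)
})

test_that("alpha-turn filter boundary is inclusive at 7 A", {
  m <- list(ca_distance_i_i4 = 6.5, structure_id = "x", chain = "A",
            start = 1L)
  expect_true(alpha_turn_filter(m))
  m$ca_distance_i_i4 <- 7.0
  expect_true(alpha_turn_filter(m))
  m$ca_distance_i_i4 <- 7.5
  expect_false(alpha_turn_filter(m))
  m$ca_distance_i_i4 <- NULL
  expect_error(alpha_turn_filter(m), "missing")
})

test_that("sequence deduplication keeps one lexicographic representative", {
  mk <- function(id, chain, start, seqs) {
    structure(list(structure_id = id, chain = chain, start = start,
                   sequence = seqs), class = "zt_motif")
  }
  motifs <- list(mk("4ijd", "B", 216L, "CAAHG"),
                 mk("4ijd", "A", 216L, "CAAHG"),
                 mk("2au3", "A", 35L, "CPFHP"))
  u <- deduplicate_sequences(motifs)
  expect_length(u, 2)
  caahg <- u[[which(vapply(u, `[[`, character(1), "sequence") == "CAAHG")]]
  expect_equal(caahg$chain, "A")
  expect_length(deduplicate_sequences(list()), 0)
  # set-size oracle: many motifs, known number of distinct sequences
  set.seed(5)
  seq_pool <- sequences_from_occurrences(reference_occurrences())
  motifs <- lapply(1:129, function(i)
    mk(sprintf("e%03d", i), "A", 1L, seq_pool[(i - 1L) %% 44L + 1L]))
  expect_length(deduplicate_sequences(motifs), 44)
})

test_that("mining is idempotent on its own detected structures", {
  s <- cluster_fixtures()[[3]]
  m1 <- find_cxxhx_motifs(s)
  m2 <- find_cxxhx_motifs(s)
  expect_identical(motif_table(m1), motif_table(m2))
})
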