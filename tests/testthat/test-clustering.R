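test_that("pairwise RMSD matrix is symmetric, zero-diagonal, order-invariant", {
  bench <- small_benchmark()
  ids <- bench$truth$id[bench$truth$decoy == "none"][1:6]
  motifs <- lapply(ids, function(id)
    find_cxxhx_motifs(bench$structures[[id]])[[1]])
  D <- pairwise_rmsd(motifs, bench$structures)
  expect_equal(diag(D), rep(0, 6))
  expect_lt(max(abs(D - t(D))), 1e-9)
  perm <- c(3, 1, 6, 2, 5, 4)
  D2 <- pairwise_rmsd(motifs[perm], bench$structures)
  expect_equal(D2, D[perm, perm], tolerance = 1e-9)
  expect_equal(pairwise_rmsd(motifs[1], bench$structures),
               matrix(0, 1, 1))
})

test_that("noisy copies of one motif have RMSD near the Monte-Carlo expectation", {
  spec <- cluster_motif_spec(cluster_torsion_table()[1, ], zn = "ideal")
  mk <- function(seed) {
    sp <- spec
    sp$noise_sd <- 0.1
    sp$seed <- seed
    build_motif_structure(sp, id = paste0("noisy", seed))
  }
  structures <- setNames(lapply(1:8, mk), paste0("noisy", 1:8))
  motifs <- lapply(structures, function(s) find_cxxhx_motifs(s)[[1]])
  D <- pairwise_rmsd(motifs, structures)
  off <- D[upper.tri(D)]
  # two independent isotropic 0.1 A jitters: per-atom displacement RMS
  # sqrt(3 * 2 * 0.1^2) = 0.245, shrunk by the 6 fitted rigid-body
  # parameters (factor sqrt(1 - 7/(3n)) with n = 18 subset atoms)
  expected <- sqrt(3 * 2 * 0.1^2) * sqrt(1 - 7 / (3 * 18))
  expect_gt(mean(off), 0.8 * expected)
  expect_lt(mean(off), 1.2 * expected)
})

test_that("GROMOS clustering reproduces the worked example and edge cases", {
  D <- matrix(10, 5, 5); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.2
  D[2, 3] <- D[3, 2] <- 0.2
  D[1, 3] <- D[3, 1] <- 0.35
  D[4, 5] <- D[5, 4] <- 0.3
  cl <- gromos_cluster(D, cutoff = 0.4)
  expect_length(cl$clusters, 2)
  expect_equal(cl$clusters[[1]]$centroid, 1)     # item 1: 2 neighbors, tie rule
  expect_setequal(cl$clusters[[1]]$members, 1:3)
  expect_equal(cl$clusters[[2]]$centroid, 4)
  expect_setequal(cl$clusters[[2]]$members, 4:5)
  expect_length(cl$outliers, 0)
  # all isolated -> all outliers
  D2 <- matrix(5, 4, 4); diag(D2) <- 0
  cl2 <- gromos_cluster(D2, 0.4)
  expect_length(cl2$clusters, 0)
  expect_equal(cl2$outliers, 1:4)
  cl3 <- gromos_cluster(matrix(0, 1, 1), 0.4)
  expect_equal(cl3$outliers, 1L)
})

test_that("clustering equals brute-force enumeration on random small instances", {
  set.seed(99)
  for (trial in 1:500) {
    n <- sample(2:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0, 1)
    d <- d + t(d)
    cutoff <- runif(1, 0.1, 0.9)
    got <- gromos_cluster(d, cutoff)
    ref <- oracle_gromos(d, cutoff)
    got_members <- lapply(got$clusters, function(cl) sort(cl$members))
    # same partition (reference does not order by size)
    expect_setequal(lapply(got_members, paste, collapse = ","),
                    lapply(ref$clusters, paste, collapse = ","))
    expect_equal(got$outliers, ref$outliers)
    # partition property
    all_items <- c(unlist(got_members), got$outliers)
    expect_equal(sort(all_items), 1:n)
  }
})

test_that("cluster summary uses circular means and recovers planted torsions", {
  # wraparound: chi1 values straddling the 180 boundary
  cl <- structure(list(clusters = list(list(centroid = 1L, members = 1:2)),
                       outliers = 3L, cutoff = 0.4, n = 3L),
                  class = "zt_clustering")
  tors <- data.frame(phi1 = c(-60, -60, -60), psi1 = c(-40, -40, -40),
                     phi2 = c(-65, -65, -65), psi2 = c(-45, -45, -45),
                     phi3 = c(-80, -80, -80), psi3 = c(-20, -20, -20),
                     chi1_cys = c(175, -179, 60), chi1_his = c(-60, -60, -60))
  sm <- cluster_summary(cl, tors)
  expect_equal(sm$mean_chi1_cys[1], 178)
  expect_equal(sm$size, c(2, 1))
  expect_equal(sm$sd_phi1[2], 0)      # singleton: SD 0, mean its own value
  expect_equal(sm$mean_chi1_cys[2], 60)

  # recovery: cluster-2 means planted with 5 deg jitter come back within 2
  tab <- cluster_torsion_table()[2, , drop = FALSE]
  tab$size <- 12
  bench <- make_benchmark_set(tab, torsion_sd = 5, noise_sd = 0, seed = 8)
  rep <- run_pipeline(pipeline_config(bench$structures, max_resolution = NA,
                                      cluster_cutoff = 1.0))
  sm2 <- rep$cluster_summary[1, ]
  expect_lt(circ_diff(sm2$mean_phi1, tab$phi1), 2)
  expect_lt(circ_diff(sm2$mean_chi1_cys, tab$chi1_cys), 2)
  expect_lt(circ_diff(sm2$mean_chi1_his, tab$chi1_his), 2)
})
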