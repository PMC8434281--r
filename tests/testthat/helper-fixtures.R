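# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# one ideal motif per reference cluster, exact mean torsions, no noise
cluster_fixtures <- function() cached("clusters", function() {
  tab <- cluster_torsion_table()
  lapply(seq_len(nrow(tab)), function(k)
    build_motif_structure(cluster_motif_spec(tab[k, ], zn = "ideal"),
                          id = paste0("cmean", k)))
})

# scaled-down benchmark population (same shape, smaller sizes) + decoys
small_benchmark <- function() cached("small_bench", function() {
  tab <- cluster_torsion_table()
  tab$size <- c(10, 6, 5, 4, 1, 1, 1)
  make_benchmark_set(tab, decoys = 6, seed = 101)
})

# full-size benchmark emulating the mined database population (86,16,13,11
# + 3 singletons); built once and shared between the pipeline and
# acceptance tests
full_benchmark <- function() cached("full_bench", function()
  make_benchmark_set(decoys = 0, seed = 20))

full_benchmark_report <- function() cached("full_report", function()
  run_pipeline(pipeline_config(full_benchmark()$structures,
                               max_resolution = NA)))

# independent dihedral oracle: normal-vector atan2 form, written separately
# from the implementation under test
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  cosv <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, cosv))) * 180 / pi
  # clockwise-positive convention: looking along b2, a positive torsion
  # carries the far bond to the -normal side
  if (sum(n1 * b3) > 0) ang <- -ang
  if (ang <= -180) ang <- ang + 360
  ang
}

# brute-force GROMOS reference: literal restatement of the algorithm using
# explicit neighbor recounting over the surviving index set
oracle_gromos <- function(D, cutoff) {
  n <- nrow(D)
  alive <- rep(TRUE, n)
  clusters <- list(); outliers <- integer(0)
  while (any(alive)) {
    idx <- which(alive)
    nb <- sapply(idx, function(i) sum(D[i, idx] <= cutoff) - 1L)
    center <- idx[which.max(nb)]
    mem <- idx[D[center, idx] <= cutoff]
    if (length(mem) == 1L) outliers <- c(outliers, center)
    else clusters[[length(clusters) + 1L]] <- sort(mem)
    alive[mem] <- FALSE
  }
  list(clusters = clusters, outliers = sort(outliers))
}

# random rigid rotation (QR-based, determinant +1)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
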