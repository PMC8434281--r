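# RMSD-based clustering of mined motifs: pair-fitted superposition on a
# fixed atom subset and the GROMOS greedy neighbor-count algorithm.

#' Default 18-atom subset for motif superposition
#'
#' Backbone N, CA, C of the five motif residues (15 atoms) plus the Cys
#' S-gamma, the His N-delta1 and the zinc: the subset spans the backbone
#' conformation, both coordinating side chains and the metal.  The exact
#' subset used in the original survey is not published; this reconstruction
#' is configurable wherever a subset is accepted.
#'
#' @return data.frame with columns \code{relpos} (0..4, or NA for the
#'   zinc) and \code{elety}
#' @export
default_atom_subset <- function() {
  data.frame(
    relpos = c(rep(0:4, each = 3), 0L, 3L, NA),
    elety = c(rep(c("N", "CA", "C"), 5), "SG", "ND1", "ZN"),
    stringsAsFactors = FALSE)
}

# Coordinates of the subset atoms for one motif, as an n x 3 matrix.
subset_coords <- function(m, s, subset = default_atom_subset()) {
  xyz <- matrix(NA_real_, nrow(subset), 3)
  for (k in seq_len(nrow(subset))) {
    if (subset$elety[k] == "ZN" && is.na(subset$relpos[k])) {
      xyz[k, ] <- m$zn_xyz
    } else {
      p <- atom_xyz(s, m$chain, m$start + subset$relpos[k], subset$elety[k])
      if (is.null(p))
        stop("subset atom ", subset$elety[k], " (position ",
             subset$relpos[k], ") unresolvable on motif ",
             m$structure_id, "_", m$chain, " ", m$start)
      xyz[k, ] <- p
    }
  }
  xyz
}

#' Pairwise superposition RMSD matrix over a motif set
#'
#' Each pair of motifs is superposed (Kabsch least squares) on the atom
#' subset before the RMSD is taken, matching pair-fitted conformational
#' clustering practice.
#'
#' @param motifs list of \code{zt_motif}
#' @param structures named list of parent structures keyed by id
#' @param subset atom subset specification, default
#'   \code{\link{default_atom_subset}}
#' @return symmetric matrix of RMSD values in Angstrom, zero diagonal
#' @export
pairwise_rmsd <- function(motifs, structures, subset = default_atom_subset()) {
  n <- length(motifs)
  coords <- lapply(motifs, function(m)
    subset_coords(m, structures[[m$structure_id]], subset))
  D <- matrix(0, n, n)
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
    }
  }
  D
}

#' GROMOS neighbor-count clustering
#'
#' Iteratively takes the element with the most neighbors within the cutoff
#' as a cluster center, forms the cluster from it and its neighbors,
#' removes them, and repeats.  Ties on the neighbor count are broken by the
#' lowest input index.  Singleton clusters are reported as outliers.
#'
#' @param D symmetric distance matrix (Angstrom)
#' @param cutoff neighbor cutoff in Angstrom (0.4 A = the survey's 0.04 nm)
#' @return list of class \code{zt_clustering} with \code{clusters} (list
#'   of \code{list(centroid, members)} using input indices, ordered by
#'   decreasing size), \code{outliers} (integer vector) and \code{cutoff}
#' @export
gromos_cluster <- function(D, cutoff = 0.4) {
  D <- as.matrix(D)
  stopifnot(nrow(D) == ncol(D))
  n <- nrow(D)
  remaining <- seq_len(n)
  clusters <- list()
  outliers <- integer(0)
  while (length(remaining) > 0) {
    sub <- D[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff) - 1L
    center_local <- which.max(counts)          # which.max takes first on ties
    center <- remaining[center_local]
    members <- remaining[sub[center_local, ] <= cutoff]
    if (length(members) == 1L) {
      outliers <- c(outliers, center)
    } else {
      clusters[[length(clusters) + 1L]] <-
        list(centroid = center, members = members)
    }
    remaining <- setdiff(remaining, members)
  }
  if (length(clusters)) {
    sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
    clusters <- clusters[order(-sizes, vapply(clusters, `[[`, integer(1),
                                              "centroid"))]
  }
  structure(list(clusters = clusters, outliers = sort(outliers),
                 cutoff = cutoff, n = n), class = "zt_clustering")
}

#' @export
print.zt_clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat("<zt_clustering>", x$n, "items, cutoff", x$cutoff, "A\n")
  cat("  clusters:", paste(sizes, collapse = ", "),
      " outliers:", length(x$outliers), "\n")
  invisible(x)
}

#' Cluster assignment vector from a clustering
#'
#' @param cl a \code{zt_clustering}
#' @return integer vector: cluster rank (1 = largest) per item, with
#'   outliers given unique negative labels
#' @export
cluster_assignments <- function(cl) {
  lab <- integer(cl$n)
  for (k in seq_along(cl$clusters)) lab[cl$clusters[[k]]$members] <- k
  for (j in seq_along(cl$outliers)) lab[cl$outliers[j]] <- -j
  lab
}

#' Per-cluster circular torsion summary
#'
#' Circular means and circular SDs of each torsion angle per cluster
#' (outliers are reported as singleton rows), with cluster sizes.
#'
#' @param cl a \code{zt_clustering}
#' @param torsions data.frame from \code{\link{torsion_table}}, rows in
#'   the same order as the clustered motifs
#' @return data.frame: one row per cluster/outlier, columns \code{cluster},
#'   \code{size}, then mean and SD per angle
#' @export
cluster_summary <- function(cl, torsions) {
  stopifnot(nrow(torsions) == cl$n)
  angle_cols <- c("phi1", "psi1", "phi2", "psi2", "phi3", "psi3",
                  "chi1_cys", "chi1_his")
  groups <- c(lapply(cl$clusters, `[[`, "members"),
              as.list(cl$outliers))
  labels <- c(seq_along(cl$clusters),
              if (length(cl$outliers))
                paste0("outlier", seq_along(cl$outliers)) else character(0))
  rows <- mapply(function(members, label) {
    out <- data.frame(cluster = as.character(label),
                      size = length(members), stringsAsFactors = FALSE)
    for (a in angle_cols) {
      v <- torsions[[a]][members]
      out[[paste0("mean_", a)]] <- circ_mean(v)
      out[[paste0("sd_", a)]] <- circ_sd(v)
    }
    out
  }, groups, labels, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}
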