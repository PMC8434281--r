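#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by four points using the standard
#' IUPAC sign convention: looking from \code{p2} toward \code{p3}, a
#' clockwise rotation of the far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (coordinates in Angstrom).
#' @return Angle in degrees in the half-open interval (-180, 180].
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)) # 180
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))  # 0
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b2^2) < 1e-12 || sum(b1^2) < 1e-12 || sum(b3^2) < 1e-12)
    stop("dihedral: coincident consecutive points")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16)
    stop("dihedral: collinear points give an undefined torsion")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Wrap an angle in degrees into (-180, 180]
#' @param x angle(s) in degrees
#' @return wrapped angle(s)
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Angle at vertex b of three points, degrees
#' @param a,b,c numeric 3-vectors
#' @return angle a-b-c in degrees in (0, 180)
#' @export
vangle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cs <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  cs <- max(-1, min(1, cs))
  acos(cs) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three placed atoms a, b, c, returns the position of a new atom
#' bonded to c with the given bond length, angle b-c-new and torsion
#' a-b-c-new.
#'
#' @param a,b,c numeric 3-vectors, previously placed atoms
#' @param bond bond length c-new in Angstrom
#' @param angle angle b-c-new in degrees
#' @param torsion torsion a-b-c-new in degrees (IUPAC sign convention)
#' @return numeric 3-vector
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- -torsion * pi / 180
  d2 <- c(bond * cos(pi - ang),
          bond * sin(pi - ang) * cos(tor),
          bond * sin(pi - ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("place_atom: collinear reference atoms")
  n <- n / nn
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  c + as.vector(rot %*% d2)
}

#' Circular mean of angles in degrees
#' @param x numeric vector of angles, degrees
#' @return mean direction in degrees in (-180, 180]
#' @export
circ_mean <- function(x) {
  r <- x * pi / 180
  wrap_angle(atan2(mean(sin(r)), mean(cos(r))) * 180 / pi)
}

#' Circular standard deviation of angles in degrees
#'
#' Uses the standard definition sqrt(-2 log Rbar), converted to degrees.
#' For tightly grouped angles this agrees with the linear SD of the
#' unwrapped values.
#'
#' @param x numeric vector of angles, degrees
#' @return circular SD in degrees
#' @export
circ_sd <- function(x) {
  if (length(x) < 2) return(0)
  r <- x * pi / 180
  rbar <- sqrt(mean(sin(r))^2 + mean(cos(r))^2)
  rbar <- min(1, rbar)
  sqrt(-2 * log(rbar)) * 180 / pi
}

#' Smallest absolute circular difference between two angles, degrees
#' @param a,b angles in degrees
#' @return absolute difference in [0, 180]
#' @export
circ_diff <- function(a, b) abs(wrap_angle(a - b))

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' matched point sets, mapping \code{Y} onto \code{X}.
#'
#' @param X,Y n x 3 matrices of matched coordinates (n >= 3).
#' @return list with \code{rotation} (3 x 3, determinant +1),
#'   \code{translation} (3-vector; the fit is \code{Y \%*\% t(R) + t}),
#'   and \code{rmsd} in Angstrom.
#' @export
kabsch_superpose <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == 3, ncol(Y) == 3, nrow(X) == nrow(Y), nrow(X) >= 3)
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx)
  Yc <- sweep(Y, 2, cy)
  H <- t(Yc) %*% Xc
  sv <- svd(H)
  if (sv$d[2] < 1e-10)
    stop("kabsch_superpose: degenerate (rank-deficient) point sets")
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  fit <- Yc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Xc)^2)))
  translation <- cx - as.vector(R %*% cy)
  list(rotation = R, translation = translation, rmsd = rmsd)
}

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix
#' @param rotation 3 x 3 rotation matrix
#' @param translation 3-vector
#' @return transformed n x 3 matrix
#' @export
apply_transform <- function(xyz, rotation, translation) {
  sweep(as.matrix(xyz) %*% t(rotation), 2, translation, `+`)
}

# Axis-angle decomposition of a rotation matrix.  Returns unit axis and
# angle in degrees; for angles near 180 the axis is recovered from R + I.
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  cs <- max(-1, min(1, (tr - 1) / 2))
  theta <- acos(cs)
  if (theta < 1e-8) return(list(axis = c(0, 0, 1), angle = 0))
  if (abs(theta - pi) > 1e-6) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(theta))
  } else {
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    ax <- B[, i] / sqrt(B[i, i])
  }
  list(axis = ax / sqrt(sum(ax^2)), angle = theta * 180 / pi)
}

# Rotation matrix for a rotation of `angle` degrees about unit `axis`.
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two labelings agree (same/different
#' cluster).  Used to score recovery of planted cluster structure.
#'
#' @param a,b vectors of cluster labels of equal length
#' @return Rand index in [0, 1]
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  agree <- 0
  for (i in seq_len(n - 1)) {
    sa <- a[i] == a[(i + 1):n]
    sb <- b[i] == b[(i + 1):n]
    agree <- agree + sum(sa == sb)
  }
  agree / (n * (n - 1) / 2)
}
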