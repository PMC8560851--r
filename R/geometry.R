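# Small 3D vector helpers. All coordinates are in Angstrom, right-handed axes.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Bond angle at B for atoms A-B-C, in degrees
#' @param a,b,c numeric 3-vectors (Angstrom).
#' @return angle in degrees in [0, 180].
#' @keywords internal
bond_angle <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Dihedral angle for atoms A-B-C-D, in degrees
#'
#' Standard atan2 formulation; the sign follows the right-hand rule about the
#' B->C axis. Returns values in (-180, 180].
#' @param a,b,c,d numeric 3-vectors (Angstrom).
#' @return dihedral in degrees.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(y, x))
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Positions atom D given three reference atoms A, B, C so that |C-D| = bond,
#' angle(B,C,D) = angle and dihedral(A,B,C,D) = dihedral.
#'
#' @param a,b,c reference positions (numeric 3-vectors, Angstrom).
#' @param bond bond length C-D in Angstrom.
#' @param angle bond angle B-C-D in degrees.
#' @param dihedral dihedral A-B-C-D in degrees.
#' @return numeric 3-vector, the position of D.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- deg2rad(angle); ph <- deg2rad(dihedral)
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), -bond * sin(th) * sin(ph))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

#' Least-squares rigid-body superposition (Kabsch/SVD)
#'
#' Computes the proper rotation and translation minimising the RMSD between a
#' mobile point set and a reference point set. The SVD formulation with
#' reflection correction is used, so the returned rotation always has
#' determinant +1 (no mirroring), matching the behaviour of the classic
#' structure-superposition algorithms used for anchor fitting.
#'
#' @param mobile n x 3 matrix of points to move.
#' @param reference n x 3 matrix of target points (same row order).
#' @return list with elements \code{R} (3x3 rotation), \code{t} (translation,
#'   so that transformed points are \code{mobile \%*\% t(R) + t}), and
#'   \code{rmsd} (post-fit residual, Angstrom). Class \code{"rigid_transform"}.
#' @examples
#' p <- matrix(rnorm(30), ncol = 3)
#' tr <- superpose(p, p)
#' tr$rmsd # 0
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L)
    stop("mobile and reference must be n x 3 matrices of equal size")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  m0 <- sweep(mobile, 2L, cm); r0 <- sweep(reference, 2L, cr)
  # collinearity guard: rank of the centred mobile set must be >= 2
  if (sum(svd(m0)$d > 1e-8 * max(1, vnorm(m0))) < 2L)
    stop("degenerate (collinear) point set")
  H <- t(m0) %*% r0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  moved <- m0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - r0)^2)))
  tr <- list(R = R, t = as.numeric(cr - R %*% cm), rmsd = rmsd)
  class(tr) <- "rigid_transform"
  tr
}

#' Apply a rigid transform to a coordinate matrix
#' @param transform a \code{rigid_transform} from [superpose()].
#' @param x n x 3 coordinate matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(transform, x) {
  x <- as.matrix(x)
  sweep(x %*% t(transform$R), 2L, transform$t, "+")
}

#' Pairwise-count of inter-set atom contacts
#'
#' Counts (i, j) pairs with distance <= cutoff between two heavy-atom
#' coordinate sets. Used for the antibody-antigen contact definition
#' (default cutoff 4.5 Angstrom elsewhere in the package).
#' @param x,y coordinate matrices (n x 3, m x 3).
#' @param cutoff distance cutoff in Angstrom.
#' @return integer count.
#' @keywords internal
count_pairs_within <- function(x, y, cutoff) {
  if (nrow(x) == 0L || nrow(y) == 0L) return(0L)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * (x %*% t(y))
  sum(d2 <= cutoff^2 + 1e-12)
}

# squared-distance matrix between two coordinate sets
dist2_mat <- function(x, y) {
  outer(rowSums(x^2), rowSums(y^2), "+") - 2 * (x %*% t(y))
}
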