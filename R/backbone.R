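# Backbone construction, dihedral extraction and cyclic-coordinate-descent
# (CCD) loop closure. A loop segment under (re)construction is represented as
# an m x 3 matrix of N, CA, C atoms in chain order: 3 rows per rebuilt residue
# followed by 3 rows for the projected C-side anchor residue (N, CA, C). The
# anchor triplet is compared against its fixed target position to measure the
# closure gap.

# ideal backbone geometry (Engh-Huber-like averages)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
  ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
  ang_ca_c_o = 120.8, omega = 180
)

#' Build a peptide backbone segment from internal coordinates
#'
#' Extends a chain from three seed atoms (N, CA, C of the residue preceding
#' the segment) using ideal bond lengths/angles and the supplied dihedrals.
#' Residue i of the segment is generated by (omega_i, phi_i, psi_i): psi of
#' the previous residue places N_i, omega_i places CA_i, phi_i places C_i.
#'
#' @param seed 3 x 3 matrix: N, CA, C coordinates of the preceding residue.
#' @param psi_prev psi dihedral of the preceding residue (places N_1), degrees.
#' @param phi,psi numeric vectors (length k) of segment dihedrals, degrees.
#' @param omega numeric vector (length k) of omega dihedrals (default trans).
#' @return (3k) x 3 matrix of N, CA, C rows per segment residue.
#' @keywords internal
build_bb_segment <- function(seed, psi_prev, phi, psi, omega = NULL) {
  k <- length(phi)
  stopifnot(length(psi) == k)
  if (is.null(omega)) omega <- rep(BB_GEOM$omega, k)
  out <- matrix(0, nrow = 3L * k, ncol = 3L)
  a <- seed[1L, ]; b <- seed[2L, ]; c3 <- seed[3L, ]
  psi_cur <- psi_prev
  for (i in seq_len(k)) {
    n_i <- place_atom(a, b, c3, BB_GEOM$c_n, BB_GEOM$ang_ca_c_n, psi_cur)
    ca_i <- place_atom(b, c3, n_i, BB_GEOM$n_ca, BB_GEOM$ang_c_n_ca, omega[i])
    c_i <- place_atom(c3, n_i, ca_i, BB_GEOM$ca_c, BB_GEOM$ang_n_ca_c, phi[i])
    out[3L * i - 2L, ] <- n_i
    out[3L * i - 1L, ] <- ca_i
    out[3L * i, ] <- c_i
    a <- n_i; b <- ca_i; c3 <- c_i
    psi_cur <- psi[i]
  }
  out
}

#' Extract phi/psi dihedrals from a backbone chain matrix
#' @param bb m x 3 matrix of N, CA, C rows in chain order (m multiple of 3).
#' @return list with vectors \code{phi}, \code{psi}; first phi and last psi
#'   are NA (undefined without flanking atoms).
#' @keywords internal
bb_dihedrals <- function(bb) {
  nres <- nrow(bb) / 3L
  phi <- psi <- rep(NA_real_, nres)
  for (i in seq_len(nres)) {
    N <- bb[3L * i - 2L, ]; CA <- bb[3L * i - 1L, ]; C <- bb[3L * i, ]
    if (i > 1L) phi[i] <- dihedral_angle(bb[3L * (i - 1L), ], N, CA, C)
    if (i < nres) psi[i] <- dihedral_angle(N, CA, C, bb[3L * i + 1L, ])
  }
  list(phi = phi, psi = psi)
}

# Rodrigues rotation of a point block about a unit axis through `origin`
rotate_about_axis <- function(x, origin, axis, theta) {
  x1 <- x[, 1L] - origin[1L]; x2 <- x[, 2L] - origin[2L]; x3 <- x[, 3L] - origin[3L]
  ct <- cos(theta); st <- sin(theta)
  a1 <- axis[1L]; a2 <- axis[2L]; a3 <- axis[3L]
  dotp <- x1 * a1 + x2 * a2 + x3 * a3
  k <- dotp * (1 - ct)
  cbind(x1 * ct + (a2 * x3 - a3 * x2) * st + k * a1 + origin[1L],
        x2 * ct + (a3 * x1 - a1 * x3) * st + k * a2 + origin[2L],
        x3 * ct + (a1 * x2 - a2 * x1) * st + k * a3 + origin[3L],
        deparse.level = 0L)
}

# closure gap: rmsd of the trailing anchor triplet vs its fixed target
closure_gap_of <- function(bb, target) {
  m <- nrow(bb)
  mob <- bb[(m - 2L):m, , drop = FALSE]
  sqrt(mean(rowSums((mob - target)^2)))
}

#' Close a loop onto its C-side anchor by cyclic coordinate descent
#'
#' Iterates over the rotatable phi/psi axes of the selected residues; for each
#' axis the closed-form optimal rotation angle (maximising the alignment of
#' the rebuilt anchor triplet with its fixed target) is applied to all
#' downstream atoms. Omega angles are never rotated, so trans-peptide
#' geometry is preserved.
#'
#' @param bb (3k + 3) x 3 backbone matrix (k loop residues + anchor triplet).
#' @param rotatable integer indices (1-based residues within the matrix,
#'   excluding the anchor residue) whose phi/psi may rotate.
#' @param target 3 x 3 fixed anchor coordinates (N, CA, C).
#' @param tol stop when the closure gap (rmsd over the anchor triplet) falls
#'   below this value, Angstrom.
#' @param max_pass maximum CCD sweeps.
#' @return list(bb = closed matrix, gap = final closure gap).
#' @keywords internal
ccd_close <- function(bb, rotatable, target, tol = 0.05, max_pass = 60L,
                      pre_axes = NULL) {
  m <- nrow(bb)
  end_idx <- (m - 2L):m
  gap <- closure_gap_of(bb, target)
  opt_rot <- function(p1, p2) {
    u <- p2 - p1
    nu <- vnorm(u)
    if (nu < 1e-9) return(NULL)
    u <- u / nu
    aa <- 0; bbq <- 0
    for (j in seq_len(3L)) {
      M <- bb[end_idx[j], ]
      r <- M - p2
      rpar <- sum(r * u) * u
      rho <- r - rpar
      f <- target[j, ] - p2 - rpar
      aa <- aa + sum(f * rho)
      bbq <- bbq + sum(f * vcross(u, rho))
    }
    list(u = u, theta = atan2(bbq, aa))
  }
  for (pass in seq_len(max_pass)) {
    if (gap <= tol) break
    # optional fixed axes upstream of the rebuilt residues (e.g. the psi of
    # the last fixed stem residue): rotate the whole segment
    for (pa in pre_axes) {
      o <- opt_rot(pa$p1, pa$p2)
      if (is.null(o) || abs(o$theta) < 1e-10) next
      bb <- rotate_about_axis(bb, pa$p2, o$u, o$theta)
    }
    for (i in rotatable) {
      for (ax in 1:2) {
        # phi axis: N_i -> CA_i (moves C_i onward); psi: CA_i -> C_i (moves next N onward)
        if (ax == 1L) {
          p1 <- bb[3L * i - 2L, ]; p2 <- bb[3L * i - 1L, ]; from <- 3L * i
        } else {
          p1 <- bb[3L * i - 1L, ]; p2 <- bb[3L * i, ]; from <- 3L * i + 1L
        }
        if (from > m) next
        o <- opt_rot(p1, p2)
        if (is.null(o) || abs(o$theta) < 1e-10) next
        rows <- from:m
        bb[rows, ] <- rotate_about_axis(bb[rows, , drop = FALSE], p2, o$u, o$theta)
      }
    }
    gap_new <- closure_gap_of(bb, target)
    if (gap - gap_new < 1e-6 && gap_new > tol) { gap <- gap_new; break }
    gap <- gap_new
  }
  list(bb = bb, gap = gap)
}

# place a backbone carbonyl O given CA, C of a residue and the next N
place_bb_O <- function(ca, c3, n_next) {
  place_atom(n_next, ca, c3, BB_GEOM$c_o, BB_GEOM$ang_ca_c_o, 180)
}
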