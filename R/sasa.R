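# Shrake-Rupley solvent-accessible surface area. Implemented in-package
# (validated in the tests against the closed-form two-sphere buried-area
# expression); supports computing only a subset of atoms, which lets the
# interaction score restrict itself to interface atoms.

# quasi-uniform unit sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param radii per-atom van der Waals radii.
#' @param probe probe radius (default water, 1.4 Angstrom).
#' @param n_points test points per atom sphere.
#' @param subset optional integer indices: compute SASA only for these atoms
#'   (occlusion still considers all atoms).
#' @return numeric vector of per-atom areas (Angstrom^2); zero-filled outside
#'   \code{subset} when given.
#' @export
shrake_rupley <- function(xyz, radii, probe = 1.4, n_points = 92L,
                          subset = NULL) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  if (is.null(subset)) subset <- seq_len(n)
  pts <- sphere_points(n_points)
  rs <- radii + probe
  out <- numeric(n)
  maxr <- max(rs)
  for (i in subset) {
    ri <- rs[i]
    d2 <- rowSums(sweep(xyz, 2L, xyz[i, ])^2)
    nb <- which(d2 < (ri + maxr)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < ri + rs[nb]]
    sp <- sweep(pts * ri, 2L, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        if (!any(free)) break
        dj <- rowSums(sweep(sp[free, , drop = FALSE], 2L, xyz[j, ])^2)
        free[free] <- dj >= rs[j]^2
      }
      acc <- sum(free)
    } else acc <- n_points
    out[i] <- 4 * pi * ri^2 * acc / n_points
  }
  out
}

# per-atom SASA of a complex (heavy atoms), optionally on a row subset
cx_sasa <- function(cx, rows = NULL, subset = NULL, n_points = 92L) {
  xyz <- cx_coords(cx, rows)
  at <- if (is.null(rows)) cx$atoms else cx$atoms[rows, , drop = FALSE]
  shrake_rupley(xyz, vdw_radius(at$elem), subset = subset,
                n_points = n_points)
}
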