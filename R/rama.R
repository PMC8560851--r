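# Ramachandran classification and phi/psi propensity sampling.
#
# A 5-degree raster over the (phi, psi) torus is built in code from
# rectangular favoured-region definitions (beta/extended, right-handed
# alpha, left-handed alpha), then dilated twice to produce the classical
# four-class map: core -> allowed (core + 20 deg) -> generous (allowed +
# 20 deg) -> disallowed. Separate maps are kept for glycine (point-symmetric
# about the origin) and proline (phi restricted to about -110..-40).

RAMA_STEP <- 5L
RAMA_N <- 360L %/% RAMA_STEP

rama_cell <- function(angle) {
  # map angle (degrees) to cell index 1..RAMA_N; cells cover [-180, 180)
  a <- ((angle + 180) %% 360)
  pmin(RAMA_N, floor(a / RAMA_STEP) + 1L)
}

.rama_rect <- function(m, phi_lo, phi_hi, psi_lo, psi_hi) {
  ctr <- seq(-180 + RAMA_STEP / 2, 180 - RAMA_STEP / 2, by = RAMA_STEP)
  pi_in <- ctr >= phi_lo & ctr <= phi_hi
  ps_in <- ctr >= psi_lo & ctr <= psi_hi
  m[pi_in, ps_in] <- TRUE
  m
}

# one 8-neighbourhood dilation step on the torus
.dilate1 <- function(m) {
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    shifted <- m[(seq_len(RAMA_N) - 1L - di) %% RAMA_N + 1L,
                 (seq_len(RAMA_N) - 1L - dj) %% RAMA_N + 1L]
    out <- out | shifted
  }
  out
}

.dilate <- function(m, k) { for (i in seq_len(k)) m <- .dilate1(m); m }

.rama_env <- new.env(parent = emptyenv())

rama_maps <- function() {
  if (!is.null(.rama_env$maps)) return(.rama_env$maps)
  empty <- matrix(FALSE, RAMA_N, RAMA_N)
  core_gen <- .rama_rect(empty, -170, -50, 95, 180)
  core_gen <- .rama_rect(core_gen, -170, -50, -180, -170)
  core_gen <- .rama_rect(core_gen, -140, -45, -70, -10)
  core_gen <- .rama_rect(core_gen, 45, 65, 25, 60)
  core_gly <- core_gen | core_gen[RAMA_N:1, RAMA_N:1]
  ctr <- seq(-180 + RAMA_STEP / 2, 180 - RAMA_STEP / 2, by = RAMA_STEP)
  pro_phi <- ctr >= -115 & ctr <= -40
  core_pro <- core_gen
  core_pro[!pro_phi, ] <- FALSE
  mk <- function(core) {
    allowed <- .dilate(core, 4L)
    generous <- .dilate(allowed, 4L)
    cls <- matrix("disallowed", RAMA_N, RAMA_N)
    cls[generous] <- "generous"
    cls[allowed] <- "allowed"
    cls[core] <- "core"
    cls
  }
  .rama_env$maps <- list(general = mk(core_gen), GLY = mk(core_gly),
                         PRO = mk(core_pro))
  .rama_env$maps
}

rama_type <- function(resid) {
  ifelse(resid == "GLY", "GLY", ifelse(resid == "PRO", "PRO", "general"))
}

#' Classify backbone dihedrals on the Ramachandran map
#'
#' @param phi,psi numeric vectors, degrees.
#' @param resid 3-letter residue names (selects the glycine/proline maps).
#' @return character vector: "core", "allowed", "generous" or "disallowed".
#' @export
rama_classify <- function(phi, psi, resid) {
  maps <- rama_maps()
  ty <- rama_type(resid)
  vapply(seq_along(phi), function(i) {
    maps[[ty[i]]][rama_cell(phi[i]), rama_cell(psi[i])]
  }, "")
}

RAMA_CLASS_WEIGHT <- c(core = 1, allowed = 0.3, generous = 0.05,
                       disallowed = 0.001)

# per-class propensity used as a pseudo-energy term and as sampling weight
rama_propensity <- function(phi, psi, resid) {
  unname(RAMA_CLASS_WEIGHT[rama_classify(phi, psi, resid)])
}

# sample n (phi, psi) pairs for a residue type from the class-weighted raster
sample_phipsi <- function(n, resid) {
  maps <- rama_maps()
  m <- maps[[rama_type(resid)]]
  w <- RAMA_CLASS_WEIGHT[m]
  idx <- sample.int(length(m), n, replace = TRUE, prob = w)
  i <- (idx - 1L) %% RAMA_N + 1L
  j <- (idx - 1L) %/% RAMA_N + 1L
  ctr <- seq(-180 + RAMA_STEP / 2, 180 - RAMA_STEP / 2, by = RAMA_STEP)
  jit <- function(k) stats::runif(k, -RAMA_STEP / 2, RAMA_STEP / 2)
  cbind(phi = ctr[i] + jit(n), psi = ctr[j] + jit(n))
}
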