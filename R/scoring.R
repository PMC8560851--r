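# Two-track conformer scoring: a total-energy score (internal strain +
# interface terms; the stability-aware track) and an interaction-only
# binding score in the solvated-interaction-energy (SIE) style, plus
# Boltzmann-weighted ensemble averaging driven by the total energy.

#' Total energy of a complex, centred on its H3 loop
#'
#' Sum of intra-loop bonded strain (bond/angle/omega deviations), loop-self
#' and loop-environment Lennard-Jones, screened Coulomb with a distance-
#' dependent dielectric (eps = 4r), a geometric hydrogen-bond well, and a
#' backbone phi/psi propensity term. This is the same functional minimised
#' by the loop minimiser, so refinement stages are energetically coherent.
#'
#' @param cx an [abcomplex()].
#' @param loop_rows atom rows of the loop (default: annotated H3).
#' @return scalar energy (kcal/mol-like units).
#' @export
total_energy <- function(cx, loop_rows = NULL) {
  if (is.null(loop_rows)) {
    reg <- atom_region(cx)
    loop_rows <- which(!is.na(reg) & reg == "H3")
  }
  obj <- make_objective(cx, loop_rows, mode = "full", bb_restraint = 0)
  e <- obj$fn(obj$x0)
  # backbone propensity over loop residues with defined dihedrals
  rt <- residue_table(cx)
  reg <- atom_region(cx)
  lr <- unique(atom_keys(cx)[loop_rows])
  ri <- match(lr, res_key(rt$chain, rt$label))
  pr <- 0
  for (r in ri) {
    if (is.na(r) || r <= 1L || r >= nrow(rt)) next
    if (rt$chain[r - 1L] != rt$chain[r] || rt$chain[r + 1L] != rt$chain[r]) next
    prev <- residue_backbone(cx, rt$chain[r - 1L], rt$label[r - 1L])
    this <- residue_backbone(cx, rt$chain[r], rt$label[r])
    nxt <- residue_backbone(cx, rt$chain[r + 1L], rt$label[r + 1L])
    if (is.null(prev$C) || is.null(nxt$N)) next
    phi <- dihedral_angle(prev$C, this$N, this$CA, this$C)
    psi <- dihedral_angle(this$N, this$CA, this$C, nxt$N)
    pr <- pr - FF$rama_weight * log(rama_propensity(phi, psi, rt$resid[r]))
  }
  e + pr
}

#' Default SIE-style coefficients
#'
#' The published solvated-interaction-energy parameterisation lineage:
#' global scaling alpha, interior dielectric Din, molecular-surface
#' coefficient gamma and constant C; beta_rf scales the Born-style
#' charge-desolvation approximation used here.
#' @param alpha,Din,gamma,C,beta_rf numeric coefficients.
#' @return named list.
#' @export
sie_params <- function(alpha = 0.1048, Din = 2.25, gamma = 0.0129,
                       C = -2.89, beta_rf = 0.06) {
  list(alpha = alpha, Din = Din, gamma = gamma, C = C, beta_rf = beta_rf)
}

#' Interaction (binding) energy of the antibody-antigen interface
#'
#' SIE-style two-body score over the interface defined by the ANTIGEN
#' annotation: alpha * (E_vdW + E_Coulomb(eps = Din) + reaction-field
#' desolvation approximation + gamma * dSASA) + C. The desolvation term is a
#' Born-style penalty proportional to the buried area of charged atoms;
#' dSASA (<= 0) is the solvent-accessible area lost on binding, computed by
#' Shrake-Rupley restricted to interface atoms.
#'
#' @param cx an [abcomplex()].
#' @param params coefficients from [sie_params()].
#' @return scalar energy (kcal/mol-like scale).
#' @export
interaction_energy <- function(cx, params = sie_params()) {
  reg <- atom_region(cx)
  ag <- which(!is.na(reg) & reg == "ANTIGEN")
  ab <- which(!is.na(reg) & reg != "ANTIGEN")
  if (!length(ag)) stop("annotation lacks an ANTIGEN region")
  at <- cx$atoms
  xyz <- cx_coords(cx)
  d2 <- dist2_mat(xyz[ab, , drop = FALSE], xyz[ag, , drop = FALSE])

  # vdW + Coulomb over cross pairs within 10 A
  hit <- which(d2 <= 100, arr.ind = TRUE)
  e_vdw <- 0; e_coul <- 0
  if (nrow(hit)) {
    i <- ab[hit[, 1L]]; j <- ag[hit[, 2L]]
    d <- pmax(sqrt(d2[hit]), 0.5)
    rm <- FF$lj_scale * (vdw_radius(at$elem[i]) + vdw_radius(at$elem[j]))
    x6 <- (rm / d)^6
    e_vdw <- FF$lj_eps * sum(x6^2 - 2 * x6)
    q <- atom_charge(at$resid, at$elety)
    # interior dielectric scaled by distance: the d^2 denominator stands in
    # for the solvent screening that a full reaction-field treatment would
    # provide at longer range
    e_coul <- FF$coul_const * sum(q[i] * q[j] / (params$Din * d^2))
  }

  # interface atoms: any cross-pair within contact + probe reach
  reach <- 2 * 1.4 + 3.5
  iface_ab <- ab[apply(d2, 1L, min) <= reach^2]
  iface_ag <- ag[apply(d2, 2L, min) <= reach^2]
  iface <- c(iface_ab, iface_ag)
  if (length(iface)) {
    sasa_cx <- cx_sasa(cx, subset = iface)
    sasa_ab <- cx_sasa(cx, rows = ab,
                       subset = match(iface_ab, ab))
    sasa_ag <- cx_sasa(cx, rows = ag,
                       subset = match(iface_ag, ag))
    free_sasa <- numeric(nrow(at))
    free_sasa[ab] <- sasa_ab
    free_sasa[ag] <- sasa_ag
    dsasa_atom <- sasa_cx[iface] - free_sasa[iface]   # <= 0 when buried
    dsasa <- sum(dsasa_atom)
    q <- atom_charge(at$resid, at$elety)
    buried <- pmax(0, -dsasa_atom)
    e_rf <- params$beta_rf * sum(q[iface]^2 * buried)
  } else {
    dsasa <- 0; e_rf <- 0
  }
  params$alpha * (e_vdw + e_coul + e_rf + params$gamma * dsasa) + params$C
}

#' Boltzmann-weighted average
#'
#' Weighted mean of \code{values} with weights proportional to
#' exp(-(E - min(E)) / kT) taken from \code{weight_energies} (the shift
#' makes the exponentials overflow-safe; the average is invariant under it).
#' As kT -> 0 this selects the value at the minimum weight energy; as
#' kT -> Inf it tends to the arithmetic mean.
#'
#' @param values numeric vector to average.
#' @param weight_energies numeric vector of weighting energies (same length).
#' @param kT temperature factor in energy units (> 0).
#' @return scalar weighted average.
#' @export
boltzmann_average <- function(values, weight_energies, kT = 1) {
  if (!length(values)) stop("empty input")
  stopifnot(length(values) == length(weight_energies), kT > 0)
  w <- exp(-(weight_energies - min(weight_energies)) / kT)
  sum(values * w) / sum(w)
}

#' Score a final loop ensemble
#'
#' Computes the Boltzmann-averaged total energy and interaction energy of a
#' refined ensemble. Interaction energies are evaluated on conformers that
#' are first energy-minimised with the H3 heavy atoms harmonically
#' restrained (1 kcal/mol/A^2) in a fixed environment; the total energies of
#' the refined conformers provide the Boltzmann weights for both averages.
#'
#' @param ens a \code{loop_ensemble} at the final stage.
#' @param kT Boltzmann temperature factor (energy units).
#' @param prescore_maxit iteration budget of the pre-score minimisation.
#' @param params SIE-style coefficients.
#' @return a one-row data.frame (ScoreRecord): candidate_id, h3_length,
#'   avg_total, avg_interaction, n_conformers.
#' @export
score_ensemble <- function(ens, kT = 1, prescore_maxit = 80L,
                           params = sie_params()) {
  if (!length(ens$conformers)) stop("empty ensemble")
  tot <- vapply(ens$conformers, function(cf) cf$total_energy, 0)
  inter <- vapply(seq_along(ens$conformers), function(i) {
    cxi <- instantiate_conformer(ens, i)
    reg <- atom_region(cxi)
    loop <- which(!is.na(reg) & reg == "H3")
    cxi <- minimize_cartesian(cxi, loop, mode = "full", bb_restraint = 1,
                              sc_restraint = 1, maxit = prescore_maxit)
    interaction_energy(cxi, params = params)
  }, 0)
  data.frame(candidate_id = ens$candidate_id,
             h3_length = nchar(ens$sequence),
             avg_total = boltzmann_average(tot, tot, kT),
             avg_interaction = boltzmann_average(inter, tot, kT),
             n_conformers = length(tot),
             stringsAsFactors = FALSE)
}
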