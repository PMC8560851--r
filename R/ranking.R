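# Length-stratified consensus Z-scores, the -1.5 selection cutoff, and the
# post-ranking filter cascade (Ramachandran check, hydrogen-bond screen,
# codified curation rules).

dense_rank <- function(x) match(x, sort(unique(x)))

#' Length-stratified consensus Z-scores
#'
#' Scoring functions favour longer loops (more atoms), so Z-scores are
#' computed independently within each H3 length stratum: z = (score -
#' stratum median) / (1.4826 * stratum MAD). The composite is the mean of
#' the total-energy and interaction-energy Z-scores. Ranks (dense, ties
#' share the smaller rank) are assigned across the whole pool for each raw
#' score and for the composite Z after merging strata. Candidates alone in
#' their stratum are flagged unscorable.
#'
#' @param records data.frame with candidate_id, h3_length, avg_total,
#'   avg_interaction (a ScoreRecord table).
#' @param dispersion "mad" (robust, default) or "sd".
#' @return data.frame of ZRecords: z_total, z_interaction, z_composite,
#'   rank_total, rank_interaction, rank_composite, scorable.
#' @export
stratified_z <- function(records, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  stopifnot(all(c("candidate_id", "h3_length", "avg_total",
                  "avg_interaction") %in% names(records)))
  n <- nrow(records)
  zt <- zi <- rep(NA_real_, n)
  scorable <- rep(FALSE, n)
  for (len in unique(records$h3_length)) {
    idx <- which(records$h3_length == len)
    if (length(idx) < 2L) next
    scorable[idx] <- TRUE
    for (col in c("avg_total", "avg_interaction")) {
      x <- records[[col]][idx]
      ctr <- stats::median(x)
      sc <- if (dispersion == "mad") stats::mad(x) else stats::sd(x)
      if (!is.finite(sc) || sc == 0) sc <- stats::sd(x)
      if (!is.finite(sc) || sc == 0) sc <- 1
      z <- (x - ctr) / sc
      if (col == "avg_total") zt[idx] <- z else zi[idx] <- z
    }
  }
  zc <- (zt + zi) / 2
  out <- data.frame(candidate_id = records$candidate_id,
                    h3_length = records$h3_length,
                    z_total = zt, z_interaction = zi, z_composite = zc,
                    rank_total = dense_rank(records$avg_total),
                    rank_interaction = dense_rank(records$avg_interaction),
                    rank_composite = NA_integer_,
                    scorable = scorable, stringsAsFactors = FALSE)
  ok <- which(scorable)
  out$rank_composite[ok] <- dense_rank(zc[ok])
  out
}

#' Apply the composite Z-score selection cutoff
#'
#' @param zrecords output of [stratified_z()].
#' @param cutoff composite Z threshold (default -1.5; <= passes).
#' @return character vector of candidate ids meeting the cutoff.
#' @export
apply_cutoff <- function(zrecords, cutoff = -1.5) {
  if (!nrow(zrecords)) return(character(0))
  zrecords$candidate_id[zrecords$scorable &
                          !is.na(zrecords$z_composite) &
                          zrecords$z_composite <= cutoff]
}

#' Ramachandran check of the extracted loop segment
#'
#' Classifies the backbone dihedrals of residues 92 through 103 (the loop
#' plus one flanking residue each side) against the bundled
#' core/allowed/generous/disallowed raster; the check fails if any residue
#' falls in the disallowed class. Residues with undefined phi or psi
#' (termini) are skipped.
#'
#' @param cx an [abcomplex()].
#' @return list with \code{pass} and \code{offenders} (chain/label/resid
#'   rows of disallowed residues).
#' @export
ramachandran_check <- function(cx) {
  labs <- c("92", cx$h3_map, "103")
  hch <- cx$heavy_chain
  rt <- residue_table(cx)
  ri <- match(res_key(hch, labs), res_key(rt$chain, rt$label))
  offenders <- list()
  for (j in seq_along(labs)) {
    r <- ri[j]
    if (is.na(r) || r <= 1L || r >= nrow(rt)) next
    if (rt$chain[r - 1L] != hch || rt$chain[r + 1L] != hch) next
    prev <- residue_backbone(cx, hch, rt$label[r - 1L])
    this <- residue_backbone(cx, hch, rt$label[r])
    nxt <- residue_backbone(cx, hch, rt$label[r + 1L])
    if (is.null(prev$C) || is.null(this$N) || is.null(this$CA) ||
        is.null(this$C) || is.null(nxt$N))
      stop("missing backbone atoms at residue ", labs[j])
    phi <- dihedral_angle(prev$C, this$N, this$CA, this$C)
    psi <- dihedral_angle(this$N, this$CA, this$C, nxt$N)
    cls <- rama_classify(phi, psi, rt$resid[r])
    if (cls == "disallowed")
      offenders[[length(offenders) + 1L]] <-
        data.frame(chain = hch, label = labs[j], resid = rt$resid[r],
                   phi = phi, psi = psi, stringsAsFactors = FALSE)
  }
  offenders <- if (length(offenders)) do.call(rbind, offenders)
  else data.frame(chain = character(0), label = character(0),
                  resid = character(0), phi = numeric(0), psi = numeric(0))
  list(pass = nrow(offenders) == 0L, offenders = offenders)
}

# intermolecular hydrogen-bond energy and unsatisfied-buried-polar flaw
# count across the antibody-antigen interface (heavy-atom geometry with
# implicit hydrogens: distance well at 2.9 A modulated by the angle at the
# donor's antecedent atom)
hb_terms <- function(cx) {
  at <- cx$atoms
  reg <- atom_region(cx)
  ag <- which(!is.na(reg) & reg == "ANTIGEN")
  ab <- which(!is.na(reg) & reg != "ANTIGEN")
  role <- hb_role(at$resid, at$elety)
  xyz <- cx_coords(cx)
  keys <- atom_keys(cx)

  antecedent <- function(i) {
    rws <- setdiff(which(keys == keys[i]), i)
    if (!length(rws)) return(NULL)
    d <- sqrt(rowSums(sweep(xyz[rws, , drop = FALSE], 2L, xyz[i, ])^2))
    cand <- rws[d < 1.9]
    if (!length(cand)) return(rws[which.min(d)])
    cand[which.min(d[d < 1.9])]
  }
  pair_energy <- function(don, acc) {
    e <- 0
    if (!length(don) || !length(acc)) return(list(e = 0, partner = logical(0)))
    d2 <- dist2_mat(xyz[don, , drop = FALSE], xyz[acc, , drop = FALSE])
    hit <- which(d2 >= 2.2^2 & d2 <= 3.6^2, arr.ind = TRUE)
    if (!nrow(hit)) return(list(e = 0, hits = hit))
    for (h in seq_len(nrow(hit))) {
      i <- don[hit[h, 1L]]; j <- acc[hit[h, 2L]]
      d <- sqrt(d2[hit[h, 1L], hit[h, 2L]])
      antei <- antecedent(i)
      angf <- 1
      if (!is.null(antei)) {
        ang <- bond_angle(xyz[antei, ], xyz[i, ], xyz[j, ])
        angf <- exp(-((ang - 115) / 40)^2)
      }
      e <- e - FF$hb_depth * exp(-0.5 * ((d - FF$hb_d0) / FF$hb_sigma)^2) * angf
    }
    list(e = e, hits = hit)
  }
  don_ab <- ab[role[ab] %in% c("donor", "both")]
  acc_ab <- ab[role[ab] %in% c("acceptor", "both")]
  don_ag <- ag[role[ag] %in% c("donor", "both")]
  acc_ag <- ag[role[ag] %in% c("acceptor", "both")]
  e1 <- pair_energy(don_ab, acc_ag)
  e2 <- pair_energy(don_ag, acc_ab)
  hb_energy <- e1$e + e2$e

  # flaw: buried interface polar atoms with no counterpart within 3.5 A
  polar <- which(role != "none")
  d2x <- dist2_mat(xyz[ab, , drop = FALSE], xyz[ag, , drop = FALSE])
  iface_ab <- ab[apply(d2x, 1L, min) <= 6.3^2]
  iface_ag <- ag[apply(d2x, 2L, min) <= 6.3^2]
  iface_polar <- intersect(c(iface_ab, iface_ag), polar)
  flaw <- 0
  if (length(iface_polar)) {
    sasa <- cx_sasa(cx, subset = iface_polar)
    for (i in iface_polar) {
      if (sasa[i] >= 5) next
      counterpart <- if (role[i] %in% c("donor", "both"))
        polar[hb_role(at$resid, at$elety)[polar] %in% c("acceptor", "both")]
      else polar[hb_role(at$resid, at$elety)[polar] %in% c("donor", "both")]
      counterpart <- setdiff(counterpart, which(keys == keys[i]))
      if (!length(counterpart)) { flaw <- flaw + 1; next }
      dmin <- min(dist2_mat(xyz[i, , drop = FALSE],
                            xyz[counterpart, , drop = FALSE]))
      if (dmin > 3.5^2) flaw <- flaw + 1
    }
  }
  list(hb_energy = hb_energy, hb_flaw = flaw)
}

#' Hydrogen-bond screen against the parental complex
#'
#' A candidate passes when neither its intermolecular hydrogen-bond energy
#' nor its buried-unsatisfied-polar flaw count is worse than the parental
#' value by more than \code{tolerance} (two independent one-sided tests).
#'
#' @param candidate,parent [abcomplex()] objects.
#' @param tolerance allowed degradation (energy units / flaw counts).
#' @return list: pass, hb_energy, hb_flaw, parent_hb_energy, parent_hb_flaw.
#' @export
hb_screen <- function(candidate, parent, tolerance = 1) {
  hc <- hb_terms(candidate)
  hp <- hb_terms(parent)
  list(pass = hc$hb_energy <= hp$hb_energy + tolerance &&
         hc$hb_flaw <= hp$hb_flaw + tolerance,
       hb_energy = hc$hb_energy, hb_flaw = hc$hb_flaw,
       parent_hb_energy = hp$hb_energy, parent_hb_flaw = hp$hb_flaw)
}

# antigen residues contacted by the H3 loop (4.5 A heavy-atom rule)
h3_epitope_residues <- function(cx, cutoff = 4.5) {
  reg <- atom_region(cx)
  loop <- which(!is.na(reg) & reg == "H3")
  ag <- which(!is.na(reg) & reg == "ANTIGEN")
  if (!length(loop) || !length(ag)) return(character(0))
  d2 <- dist2_mat(cx_coords(cx, loop), cx_coords(cx, ag))
  hit <- unique(ag[which(apply(d2, 2L, min) <= cutoff^2)])
  unique(atom_keys(cx)[hit])
}

# minimum guanidinium-N to carboxylate-O distance between loop positions 2
# and L-1, or NA when the complex lacks the Arg/Asp pair
stem_saltbridge_dist <- function(cx) {
  s <- strsplit(h3_sequence(cx), "")[[1L]]
  L <- length(s)
  if (L < 3L || s[2L] != "R" || s[L - 1L] != "D") return(NA_real_)
  hch <- cx$heavy_chain
  argrows <- atom_rows(cx, hch, cx$h3_map[2L])
  asprows <- atom_rows(cx, hch, cx$h3_map[L - 1L])
  gN <- argrows[cx$atoms$elety[argrows] %in% c("NE", "NH1", "NH2")]
  cO <- asprows[cx$atoms$elety[asprows] %in% c("OD1", "OD2")]
  if (!length(gN) || !length(cO)) return(NA_real_)
  sqrt(min(dist2_mat(cx_coords(cx, gN), cx_coords(cx, cO))))
}

# "atom key + name" identifiers of charged side-chain atoms near the loop
# that are buried (SASA < 5 A^2) without an opposite charge within 4.5 A
buried_charge_violations <- function(cx) {
  at <- cx$atoms
  reg <- atom_region(cx)
  loop <- which(!is.na(reg) & reg == "H3")
  charged <- which(is_charged_sc_atom(at$resid, at$elety))
  if (!length(charged) || !length(loop)) return(character(0))
  d2 <- dist2_mat(cx_coords(cx, charged), cx_coords(cx, loop))
  near <- charged[apply(d2, 1L, min) <= 6^2]
  if (!length(near)) return(character(0))
  sasa <- cx_sasa(cx, subset = near)
  sign_of <- charge_sign_sc(at$resid)
  out <- character(0)
  for (i in near) {
    if (sasa[i] >= 5) next
    opp <- charged[sign_of[charged] == -sign_of[i]]
    ok <- length(opp) &&
      min(dist2_mat(cx_coords(cx, i), cx_coords(cx, opp))) <= 4.5^2
    if (!ok) out <- c(out, paste(atom_keys(cx)[i], at$elety[i]))
  }
  out
}

#' Codified curation checks
#'
#' Three automated stand-ins for visual inspection, each judged against the
#' parental complex: (a) epitope retention - the fraction of antigen
#' residues contacted by the parental H3 that the candidate H3 also
#' contacts must reach \code{shared_threshold}; (b) when the parental loop
#' exhibits the stem salt bridge (Arg at loop position 2 within 4 Angstrom
#' of Asp at position L-1), a candidate carrying the same Arg/Asp pair must
#' maintain it; (c) the grafted loop must not newly bury a charged
#' side-chain atom (SASA < 5 A^2) that lacks an opposite charge within 4.5
#' Angstrom - buried charges already present in the parent do not count
#' against the candidate.
#'
#' @param candidate,parent [abcomplex()] objects.
#' @param shared_threshold minimum shared-epitope fraction (default 0.25).
#' @return list of flags and diagnostics; overall \code{pass}.
#' @export
curation_checks <- function(candidate, parent, shared_threshold = 0.25) {
  reasons <- character(0)
  # (a) shared epitope
  pe <- h3_epitope_residues(parent)
  ce <- h3_epitope_residues(candidate)
  shared <- if (length(pe)) length(intersect(pe, ce)) / length(pe) else 1
  pass_epitope <- shared >= shared_threshold
  if (!pass_epitope)
    reasons <- c(reasons, sprintf("shared epitope fraction %.2f < %.2f",
                                  shared, shared_threshold))
  # (b) stem salt bridge, active when the parent exhibits it
  pass_salt <- TRUE
  pd <- stem_saltbridge_dist(parent)
  if (!is.na(pd) && pd <= 4.0) {
    cd <- stem_saltbridge_dist(candidate)
    if (!is.na(cd) && cd > 4.0) {
      pass_salt <- FALSE
      reasons <- c(reasons, sprintf(
        "Arg(2)-Asp(L-1) salt bridge broken (%.1f A)", cd))
    }
  }
  # (c) charges newly buried by the grafted loop
  viol_c <- buried_charge_violations(candidate)
  viol_p <- buried_charge_violations(parent)
  new_viol <- setdiff(viol_c, viol_p)
  pass_buried <- length(new_viol) == 0L
  if (!pass_buried)
    reasons <- c(reasons, paste0("buried unpaired charge at ", new_viol))
  list(pass = pass_epitope && pass_salt && pass_buried,
       pass_epitope = pass_epitope, shared_fraction = shared,
       pass_saltbridge = pass_salt, pass_buried_charge = pass_buried,
       reasons = reasons)
}

#' Run the full selection cascade
#'
#' Z-cutoff, then Ramachandran check, hydrogen-bond screen and curation
#' checks, each evaluated on the candidate's best total-energy conformer.
#' The report lists every candidate (ordered by composite Z) with
#' per-filter outcomes and reasons; \code{selected} is true when all pass.
#'
#' @param zrecords [stratified_z()] output.
#' @param best_complexes named list of [abcomplex()]s (best conformer per
#'   candidate id).
#' @param parent parental [abcomplex()].
#' @param cutoff composite Z cutoff.
#' @param hb_tolerance hydrogen-bond screen tolerance.
#' @param shared_threshold curation epitope threshold.
#' @return data.frame selection report.
#' @export
select_candidates <- function(zrecords, best_complexes, parent,
                              cutoff = -1.5, hb_tolerance = 1,
                              shared_threshold = 0.25) {
  zr <- zrecords[order(zrecords$z_composite), , drop = FALSE]
  pass_ids <- apply_cutoff(zrecords, cutoff)
  rows <- lapply(seq_len(nrow(zr)), function(i) {
    id <- zr$candidate_id[i]
    passed_z <- id %in% pass_ids
    passed_rama <- passed_hb <- passed_cur <- NA
    reasons <- character(0)
    if (!passed_z) reasons <- "composite Z above cutoff"
    cxi <- best_complexes[[id]]
    if (passed_z && !is.null(cxi)) {
      rc <- ramachandran_check(cxi)
      passed_rama <- rc$pass
      if (!rc$pass)
        reasons <- c(reasons, paste0("disallowed backbone at ",
                                     paste(rc$offenders$label, collapse = ",")))
      hb <- hb_screen(cxi, parent, tolerance = hb_tolerance)
      passed_hb <- hb$pass
      if (!hb$pass) reasons <- c(reasons, "hydrogen-bond screen failed")
      cu <- curation_checks(cxi, parent, shared_threshold = shared_threshold)
      passed_cur <- cu$pass
      reasons <- c(reasons, cu$reasons)
    }
    data.frame(candidate_id = id, h3_length = zr$h3_length[i],
               z_total = zr$z_total[i], z_interaction = zr$z_interaction[i],
               z_composite = zr$z_composite[i],
               rank = zr$rank_composite[i],
               passed_z = passed_z,
               passed_rama = passed_rama, passed_hb = passed_hb,
               passed_curation = passed_cur,
               selected = isTRUE(passed_z) && isTRUE(passed_rama) &&
                 isTRUE(passed_hb) && isTRUE(passed_cur),
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
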