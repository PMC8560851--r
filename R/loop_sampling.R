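# Hierarchical H3 loop ensemble generation: propensity-guided dihedral
# sampling of the loop tip with cyclic-coordinate-descent closure, contact
# potential culling, antigen-contact filtering, restrained minimisation,
# per-stem retention and perturb-and-reclose refinement with
# retention-window merging across stems.

CLOSURE_TOL <- 0.5   # Angstrom, maximum accepted closure gap
CLASH_FACTOR <- 0.6  # fraction of summed vdW radii counted as a hard clash

#' Loop tip window for a given H3 length
#'
#' Under the internal convention (position 1 <-> residue 93, position L <->
#' residue 102): length 6 samples the whole loop; length 7 has no tip (the
#' grafted conformation passes through); length 8 samples positions
#' 2..L-2; length 9 positions 3..L-2; length 10 and longer positions
#' 3..L-3, so at least a 5-residue stretch is searched for loops of 8+.
#'
#' @param h3_length integer >= 6.
#' @return list with \code{start}, \code{end} (1-based, inclusive) and
#'   \code{empty} flag.
#' @export
tip_window <- function(h3_length) {
  L <- as.integer(h3_length)
  if (L < 6L) stop("H3 length must be at least 6")
  if (L == 6L) w <- c(1L, L)
  else if (L == 7L) return(list(start = NA_integer_, end = NA_integer_,
                                empty = TRUE))
  else if (L == 8L) w <- c(2L, L - 2L)
  else if (L == 9L) w <- c(3L, L - 2L)
  else w <- c(3L, L - 3L)
  list(start = w[1L], end = w[2L], empty = FALSE)
}

# atom rows of the H3 loop of a complex, in residue order
loop_rows_of <- function(cx) {
  atom_rows(cx, cx$heavy_chain, cx$h3_map)
}

new_loop_ensemble <- function(candidate_id, sequence, bases, conformers,
                              stage = "initial") {
  ens <- list(candidate_id = candidate_id, sequence = sequence,
              bases = bases, conformers = conformers, stage = stage)
  class(ens) <- "loop_ensemble"
  ens
}

#' @export
print.loop_ensemble <- function(x, ...) {
  cat("loop_ensemble", x$candidate_id, "stage", x$stage, "with",
      length(x$conformers), "conformers,", length(x$bases), "stem base(s)\n")
  invisible(x)
}

#' Materialise conformer i of an ensemble as a full complex
#' @param ens a \code{loop_ensemble}.
#' @param i conformer index.
#' @return an [abcomplex()] with the conformer's loop coordinates.
#' @export
instantiate_conformer <- function(ens, i) {
  cf <- ens$conformers[[i]]
  base <- ens$bases[[cf$stem]]
  set_cx_coords(base, loop_rows_of(base), cf$xyz)
}

# conformer record
new_conformer <- function(stem, xyz, closure_gap, phi = NULL, psi = NULL) {
  list(stem = stem, xyz = xyz, closure_gap = closure_gap,
       phi = phi, psi = psi, stat_energy = NA_real_,
       min_energy = NA_real_, total_energy = NA_real_,
       contact_count = NA_integer_)
}

# measured backbone dihedrals of the loop + psi of the preceding flank
loop_dihedrals <- function(cx) {
  lab <- c("92", cx$h3_map, "103")
  bb <- lapply(lab, function(l) residue_backbone(cx, cx$heavy_chain, l))
  n <- length(lab)
  phi <- psi <- omg <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      phi[i] <- dihedral_angle(bb[[i - 1L]]$C, bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C)
      omg[i] <- dihedral_angle(bb[[i - 1L]]$CA, bb[[i - 1L]]$C, bb[[i]]$N, bb[[i]]$CA)
    }
    if (i < n) psi[i] <- dihedral_angle(bb[[i]]$N, bb[[i]]$CA, bb[[i]]$C, bb[[i + 1L]]$N)
  }
  list(lab = lab, phi = phi, psi = psi, omega = omg, bb = bb)
}

# Rebuild loop residues seg_start..seg_end (1-based loop positions) with the
# given dihedrals and close onto the first fixed residue after the segment.
# Returns NULL on failure, else the updated complex and the closure gap.
rebuild_segment <- function(cx, seg, phi, psi, max_pass = 40L) {
  L <- h3_length(cx)
  dh <- loop_dihedrals(cx)           # index i in dh = loop position i (+1 offset: dh[1] = residue 92)
  a <- seg[1L]; e <- seg[2L]
  # seed: N, CA, C of the residue before the segment (92 for a = 1)
  seedbb <- dh$bb[[a]]               # dh index a = loop position a-1... (dh[1]=92)
  seed <- rbind(seedbb$N, seedbb$CA, seedbb$C)
  k <- e - a + 1L
  # dihedrals for rebuilt residues: supplied for a..e, original beyond
  phis <- phi
  psis <- psi
  # anchor projection residue: first fixed residue after segment
  anchor_pos <- e + 1L               # loop position (or flank 103 when e = L)
  anchor_lab <- if (anchor_pos <= L) cx$h3_map[anchor_pos] else "103"
  anchor_bb <- residue_backbone(cx, cx$heavy_chain, anchor_lab)
  target <- rbind(anchor_bb$N, anchor_bb$CA, anchor_bb$C)
  # projection dihedrals (re-used from current geometry)
  proj_phi <- dh$phi[[anchor_pos + 1L]]
  omegas <- dh$omega[(a + 1L):(anchor_pos + 1L)]
  omegas[is.na(omegas)] <- 180
  bb <- build_bb_segment(seed, psi_prev = dh$psi[[a]],
                         phi = c(phis, proj_phi),
                         psi = c(psis, 0),
                         omega = omegas)
  # psi_prev of seed is overridden: the first rebuilt N is placed by the
  # *sampled* psi of the preceding residue only when the segment starts
  # inside the loop; here we keep the measured value, matching a fixed
  # N-side stem.
  cl <- ccd_close(bb, rotatable = seq_len(k), target = target,
                  tol = 0.04, max_pass = max_pass)
  list(bb = cl$bb, gap = cl$gap, k = k)
}

# write rebuilt backbone into the complex and redo O atoms + side chains
apply_rebuilt_backbone <- function(cx, seg, bb) {
  L <- h3_length(cx)
  a <- seg[1L]; e <- seg[2L]
  hch <- cx$heavy_chain
  for (i in seq_len(e - a + 1L)) {
    pos <- a + i - 1L
    lab <- cx$h3_map[pos]
    rows <- atom_rows(cx, hch, lab)
    N <- bb[3L * i - 2L, ]; CA <- bb[3L * i - 1L, ]; C <- bb[3L * i, ]
    n_next <- if (3L * i + 1L <= nrow(bb)) bb[3L * i + 1L, ] else NULL
    for (rw in rows) {
      el <- cx$atoms$elety[rw]
      if (el == "N") cx$atoms[rw, c("x", "y", "z")] <- N
      else if (el == "CA") cx$atoms[rw, c("x", "y", "z")] <- CA
      else if (el == "C") cx$atoms[rw, c("x", "y", "z")] <- C
      else if (el == "O" && !is.null(n_next))
        cx$atoms[rw, c("x", "y", "z")] <- place_bb_O(CA, C, n_next)
    }
  }
  # O of the residue just before the anchor points at the fixed anchor N
  anchor_pos <- e + 1L
  anchor_lab <- if (anchor_pos <= L) cx$h3_map[anchor_pos] else "103"
  abb <- residue_backbone(cx, hch, anchor_lab)
  lastlab <- cx$h3_map[e]
  lrows <- atom_rows(cx, hch, lastlab)
  lbb <- residue_backbone(cx, hch, lastlab)
  oi <- lrows[cx$atoms$elety[lrows] == "O"]
  if (length(oi))
    cx$atoms[oi, c("x", "y", "z")] <- place_bb_O(lbb$CA, lbb$C, abb$N)
  cx
}

# hard-clash test of rebuilt segment backbone against the fixed environment
segment_clashes <- function(cx, seg, bb) {
  a <- seg[1L]; e <- seg[2L]
  labs <- cx$h3_map[max(1L, a - 1L):min(h3_length(cx), e + 1L)]
  ex_rows <- atom_rows(cx, cx$heavy_chain, labs)
  env <- setdiff(seq_len(nrow(cx$atoms)), ex_rows)
  exyz <- cx_coords(cx, env)
  erad <- vdw_radius(cx$atoms$elem[env])
  pts <- bb[seq_len(3L * (e - a + 1L)), , drop = FALSE]
  prad <- rep(c(vdw_radius("N"), vdw_radius("C"), vdw_radius("C")), e - a + 1L)
  d2 <- dist2_mat(pts, exyz)
  lim <- CLASH_FACTOR * outer(prad, erad, "+")
  any(d2 < lim^2)
}

#' Sample loop-tip conformations for a grafted candidate
#'
#' Draws phi/psi for the tip residues from residue-type-conditioned
#' Ramachandran propensity maps, closes the tip onto the fixed C-side stem
#' by CCD, rejects conformations with closure gap above 0.5 Angstrom or a
#' hard backbone clash, and rebuilds tip side chains at clash-minimal
#' rotamers. Deterministic under \code{seed}. A length-7 loop has no tip:
#' the grafted conformation passes through as a single-member ensemble.
#'
#' @param graft a \code{graft_result}.
#' @param n_samples conformations to generate (default 5000).
#' @param seed RNG seed.
#' @param candidate_id identifier carried by the ensemble.
#' @param max_tries retry budget multiplier.
#' @return a \code{loop_ensemble} at stage "initial".
#' @export
sample_tip <- function(graft, n_samples = 5000L, seed = 1L,
                       candidate_id = "candidate", max_tries = 25L) {
  base <- graft$complex
  L <- h3_length(base)
  stem <- graft$stem_of_origin
  bases <- stats::setNames(list(base), stem)
  seqs <- h3_sequence(base)
  tw <- tip_window(L)
  lrows <- loop_rows_of(base)
  if (tw$empty) {
    dh <- loop_dihedrals(base)
    junction <- abs(vnorm(dh$bb[[L + 1L]]$C - dh$bb[[L + 2L]]$N) - BB_GEOM$c_n)
    cf <- new_conformer(stem, cx_coords(base, lrows), junction,
                        phi = dh$phi[1L + seq_len(L)],
                        psi = dh$psi[1L + seq_len(L)])
    return(new_loop_ensemble(candidate_id, seqs, bases, list(cf), "initial"))
  }
  seg <- c(tw$start, tw$end)
  k <- tw$end - tw$start + 1L
  res3 <- aa_three(strsplit(seqs, "")[[1L]])[seg[1L]:seg[2L]]
  sc_res <- data.frame(chain = base$heavy_chain,
                       label = base$h3_map[seg[1L]:seg[2L]],
                       stringsAsFactors = FALSE)
  with_seed(seed, {
    out <- vector("list", n_samples)
    made <- 0L; tries <- 0L
    budget <- max_tries * n_samples
    while (made < n_samples && tries < budget) {
      tries <- tries + 1L
      pp <- t(vapply(res3, function(r) sample_phipsi(1L, r)[1L, ], numeric(2)))
      rb <- rebuild_segment(base, seg, pp[, 1L], pp[, 2L])
      if (rb$gap > CLOSURE_TOL) next
      if (segment_clashes(base, seg, rb$bb)) next
      cxi <- apply_rebuilt_backbone(base, seg, rb$bb)
      cxi <- place_side_chains(cxi, sc_res)
      made <- made + 1L
      dh <- loop_dihedrals(cxi)
      out[[made]] <- new_conformer(stem, cx_coords(cxi, loop_rows_of(cxi)),
                                   rb$gap,
                                   phi = dh$phi[1L + seq_len(L)],
                                   psi = dh$psi[1L + seq_len(L)])
    }
    if (made < max(1L, ceiling(0.01 * tries)))
      stop("loop closure success rate below 1%: graft geometrically infeasible")
    if (made < n_samples) out <- out[seq_len(made)]
    new_loop_ensemble(candidate_id, seqs, bases, out, "initial")
  })
}

#' H3-antigen contact count of a complex
#' @param cx an [abcomplex()].
#' @param cutoff contact distance, Angstrom.
#' @return integer count of loop-antigen heavy-atom pairs within the cutoff.
#' @export
h3_antigen_contacts <- function(cx, cutoff = 4.5) {
  reg <- atom_region(cx)
  contact_count(cx_coords(cx, which(!is.na(reg) & reg == "H3")),
                cx_coords(cx, which(!is.na(reg) & reg == "ANTIGEN")),
                cutoff)
}

#' Antibody-antigen heavy-atom contact count
#'
#' Number of (loop atom, antigen atom) pairs within the cutoff.
#' @param loop_xyz n x 3 heavy-atom coordinates (e.g. an H3 conformation).
#' @param antigen_xyz m x 3 heavy-atom coordinates.
#' @param cutoff contact distance, Angstrom (default 4.5).
#' @return integer pair count.
#' @export
contact_count <- function(loop_xyz, antigen_xyz, cutoff = 4.5) {
  count_pairs_within(as.matrix(loop_xyz), as.matrix(antigen_xyz), cutoff)
}

# fill contact counts for all conformers
ensure_contacts <- function(ens, cutoff = 4.5) {
  for (i in seq_along(ens$conformers)) {
    if (!is.na(ens$conformers[[i]]$contact_count)) next
    base <- ens$bases[[ens$conformers[[i]]$stem]]
    reg <- atom_region(base)
    ag <- cx_coords(base, which(!is.na(reg) & reg == "ANTIGEN"))
    ens$conformers[[i]]$contact_count <-
      contact_count(ens$conformers[[i]]$xyz, ag, cutoff)
  }
  ens
}

#' Cull an initial ensemble with the statistical potential
#'
#' The first \code{keep_rescore} conformations (generation order) are scored
#' with [stat_potential()] and re-ranked; the best \code{keep_top} are
#' retained. With fewer conformations than \code{keep_top} everything is
#' kept with a warning.
#'
#' @param ens ensemble at stage "initial".
#' @param keep_rescore how many leading conformers to rescore (default 1000).
#' @param keep_top how many to keep after re-ranking (default 250).
#' @return ensemble at stage "culled".
#' @export
cull_ensemble <- function(ens, keep_rescore = 1000L, keep_top = 250L) {
  stopifnot(inherits(ens, "loop_ensemble"))
  if (ens$stage != "initial") stop("cull_ensemble expects an initial ensemble")
  n <- length(ens$conformers)
  m <- min(n, keep_rescore)
  idx <- seq_len(m)
  for (i in idx) {
    cxi <- instantiate_conformer(ens, i)
    ens$conformers[[i]]$stat_energy <- stat_potential(cxi)
  }
  sc <- vapply(ens$conformers[idx], function(cf) cf$stat_energy, 0)
  if (m <= keep_top) {
    if (m < keep_top)
      warning("only ", m, " conformations available; keeping all")
    keep <- idx[order(sc)]
  } else keep <- idx[order(sc)][seq_len(keep_top)]
  ens$conformers <- ens$conformers[keep]
  ens$stage <- "culled"
  ens
}

#' Filter an ensemble by minimum antigen contacts
#'
#' The threshold is the median contact count of the reference population
#' (the rescored head of the initial ensemble, by default); conformations
#' with fewer contacts than the median are removed.
#'
#' @param ens ensemble to filter.
#' @param reference_population ensemble supplying the median threshold.
#' @param cutoff contact distance, Angstrom.
#' @return filtered ensemble (stage unchanged) with attribute
#'   \code{removed_fraction}.
#' @export
contact_filter <- function(ens, reference_population, cutoff = 4.5) {
  if (!length(reference_population$conformers))
    stop("empty reference population")
  reference_population <- ensure_contacts(reference_population, cutoff)
  thr <- stats::median(vapply(reference_population$conformers,
                              function(cf) as.numeric(cf$contact_count), 0))
  ens <- ensure_contacts(ens, cutoff)
  cc <- vapply(ens$conformers, function(cf) as.numeric(cf$contact_count), 0)
  keep <- cc >= thr
  removed <- mean(!keep)
  ens$conformers <- ens$conformers[keep]
  attr(ens, "removed_fraction") <- removed
  attr(ens, "contact_threshold") <- thr
  ens
}

#' Minimise one loop conformation in a fixed environment
#'
#' Internal force-field descent (bonded + Lennard-Jones + screened Coulomb
#' with eps = 4r + hydrogen-bond well) over the H3 atoms; all other atoms
#' fixed; energy non-increasing.
#'
#' @param cx complex carrying the conformation.
#' @param maxit iteration budget.
#' @return minimised complex with attribute \code{min_value}.
#' @export
minimize_loop <- function(cx, maxit = 150L) {
  minimize_cartesian(cx, loop_rows_of(cx), mode = "full", maxit = maxit)
}

#' Minimise every conformer of an ensemble
#' @param ens ensemble (typically after the contact filter).
#' @param maxit per-conformer iteration budget.
#' @return ensemble with updated coordinates and \code{min_energy}, stage
#'   "minimized".
#' @export
minimize_ensemble <- function(ens, maxit = 150L) {
  for (i in seq_along(ens$conformers)) {
    cxi <- instantiate_conformer(ens, i)
    cxi <- minimize_loop(cxi, maxit = maxit)
    ens$conformers[[i]]$xyz <- cx_coords(cxi, loop_rows_of(cxi))
    ens$conformers[[i]]$min_energy <- attr(cxi, "min_value")
  }
  ens$stage <- "minimized"
  ens
}

#' Retain the best conformers per stem
#'
#' Keeps the \code{keep} best conformers (minimised energy) within each
#' stem's ensemble and concatenates across stems: energies from different
#' stems sit in different reference frames, so cross-stem comparison is
#' deferred to the refinement stage.
#'
#' @param ens_by_stem list of minimised ensembles (one per stem) for the
#'   same candidate.
#' @param keep conformers kept per stem (default 100).
#' @return merged ensemble, stage "minimized".
#' @export
retain_per_stem <- function(ens_by_stem, keep = 100L) {
  stopifnot(length(ens_by_stem) >= 1L)
  bases <- list(); confs <- list()
  for (ens in ens_by_stem) {
    bases[names(ens$bases)] <- ens$bases
    en <- vapply(ens$conformers, function(cf) cf$min_energy, 0)
    keep_i <- order(en)[seq_len(min(keep, length(en)))]
    confs <- c(confs, ens$conformers[keep_i])
  }
  first <- ens_by_stem[[1L]]
  new_loop_ensemble(first$candidate_id, first$sequence, bases, confs,
                    "minimized")
}

# total energies for all conformers lacking one
ensure_total_energy <- function(ens) {
  for (i in seq_along(ens$conformers)) {
    if (!is.na(ens$conformers[[i]]$total_energy)) next
    cxi <- instantiate_conformer(ens, i)
    ens$conformers[[i]]$total_energy <- total_energy(cxi)
  }
  ens
}

# one perturb-and-reclose expansion of conformer i over the full loop
expand_conformer <- function(ens, i, sigma = 8) {
  cf <- ens$conformers[[i]]
  base <- ens$bases[[cf$stem]]
  cxi <- set_cx_coords(base, loop_rows_of(base), cf$xyz)
  L <- h3_length(cxi)
  seg <- c(1L, L)
  dh <- loop_dihedrals(cxi)
  phi <- dh$phi[1L + seq_len(L)] + stats::rnorm(L, 0, sigma)
  psi <- dh$psi[1L + seq_len(L)] + stats::rnorm(L, 0, sigma)
  rb <- rebuild_segment(cxi, seg, phi, psi)
  if (rb$gap > CLOSURE_TOL || segment_clashes(cxi, seg, rb$bb)) return(NULL)
  cxn <- apply_rebuilt_backbone(cxi, seg, rb$bb)
  cxn <- place_side_chains(cxn, data.frame(chain = cxn$heavy_chain,
                                           label = cxn$h3_map,
                                           stringsAsFactors = FALSE))
  dh2 <- loop_dihedrals(cxn)
  cf2 <- new_conformer(cf$stem, cx_coords(cxn, loop_rows_of(cxn)), rb$gap,
                       phi = dh2$phi[1L + seq_len(L)],
                       psi = dh2$psi[1L + seq_len(L)])
  cf2$total_energy <- total_energy(cxn)
  cf2
}

#' Archive an ensemble as a multi-model PDB with a TSV sidecar
#'
#' Writes the loop heavy atoms of every conformer as successive MODEL
#' blocks of \code{<candidate_id>.pdb} and a sidecar table
#' \code{<candidate_id>.tsv} with columns conformer_id, stem, stage,
#' stat_energy, total_energy, contact_count, closure_gap.
#'
#' @param ens a \code{loop_ensemble}.
#' @param dir output directory.
#' @return invisibly, the PDB path.
#' @export
write_ensemble <- function(ens, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb_path <- file.path(dir, paste0(ens$candidate_id, ".pdb"))
  con <- file(pdb_path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  for (i in seq_along(ens$conformers)) {
    cf <- ens$conformers[[i]]
    base <- ens$bases[[cf$stem]]
    rows <- loop_rows_of(base)
    a <- base$atoms[rows, , drop = FALSE]
    bio3d::write.pdb(file = tmp, xyz = as.numeric(t(cf$xyz)),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain,
                     insert = ifelse(a$insert == "", NA, a$insert),
                     o = a$o, b = rep(0, nrow(a)))
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(grep("^(ATOM|HETATM|TER)", readLines(tmp), value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  side <- data.frame(
    conformer_id = seq_along(ens$conformers),
    stem = vapply(ens$conformers, function(cf) cf$stem, ""),
    stage = ens$stage,
    stat_energy = vapply(ens$conformers, function(cf) cf$stat_energy, 0),
    total_energy = vapply(ens$conformers, function(cf) cf$total_energy, 0),
    contact_count = vapply(ens$conformers,
                           function(cf) as.numeric(cf$contact_count), 0),
    closure_gap = vapply(ens$conformers, function(cf) cf$closure_gap, 0))
  utils::write.table(side, file.path(dir, paste0(ens$candidate_id, ".tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(pdb_path)
}

#' Refine an ensemble by perturb-and-reclose expansion
#'
#' Stage 1: every conformer spawns \code{stage1_expansions} perturbed,
#' re-closed variants of the full loop scored by [total_energy()]; the pool
#' (incumbents included) is merged across stems and truncated to the
#' retention window above the best score. Stage 2 repeats with
#' \code{stage2_expansions}. Deterministic under \code{seed}.
#'
#' @param ens merged per-stem ensemble.
#' @param stage1_expansions,stage2_expansions expansions per conformer.
#' @param window retention window above the best total energy (energy units).
#' @param seed RNG seed.
#' @param sigma dihedral perturbation, degrees.
#' @return ensemble at stage "final", conformers sorted by total energy.
#' @export
refine_ensemble <- function(ens, stage1_expansions = 5L,
                            stage2_expansions = 25L, window = 5,
                            seed = 1L, sigma = 8) {
  with_seed(seed + 17L, {
    ens <- ensure_total_energy(ens)
    for (stage in 1:2) {
      nexp <- if (stage == 1L) stage1_expansions else stage2_expansions
      pool <- ens$conformers
      for (i in seq_along(ens$conformers)) {
        for (k in seq_len(nexp)) {
          cf2 <- expand_conformer(ens, i, sigma = sigma)
          if (!is.null(cf2)) pool[[length(pool) + 1L]] <- cf2
        }
      }
      en <- vapply(pool, function(cf) cf$total_energy, 0)
      keep <- en <= min(en) + window
      pool <- pool[keep][order(en[keep])]
      ens$conformers <- pool
      ens$stage <- if (stage == 1L) "refined" else "final"
    }
    ens
  })
}
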