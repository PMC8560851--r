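# Post-hoc analyses: per-region RMSD/BRMSD after framework superposition,
# sequence identity/similarity, dissociation-constant fold tables, and the
# retrospective grafting of crystal loop conformations into the parental
# complex.

RMSD_REGIONS <- c("H1", "H2", "H3", "L1", "L2", "L3", "FR", "ANTIGEN")

# matched atom rows between two complexes by (chain, residue label, atom)
matched_rows <- function(a, b, rows_a, rows_b) {
  ka <- paste(atom_keys(a)[rows_a], a$atoms$elety[rows_a])
  kb <- paste(atom_keys(b)[rows_b], b$atoms$elety[rows_b])
  common <- intersect(ka, kb)
  list(a = rows_a[match(common, ka)], b = rows_b[match(common, kb)])
}

#' Per-region RMSD and backbone RMSD between two complexes
#'
#' A rigid fit is computed on the framework (FR) backbone atoms only; with
#' that single superposition applied, heavy-atom RMSD and backbone-only
#' BRMSD are reported per region without refitting. Correspondence is by
#' chain + residue label + atom name within each region; a region absent
#' from either structure yields NA. H3 cells are only defined when both
#' loops have the same length (cross-length comparison is refused).
#'
#' @param model,reference [abcomplex()] objects sharing annotation
#'   vocabulary.
#' @return data.frame with region, rmsd_heavy, brmsd_backbone, n_atoms.
#' @export
per_region_rmsd <- function(model, reference) {
  regm <- atom_region(model); regr <- atom_region(reference)
  frm <- which(!is.na(regm) & regm == "FR" &
                 model$atoms$elety %in% BACKBONE_ATOMS)
  frr <- which(!is.na(regr) & regr == "FR" &
                 reference$atoms$elety %in% BACKBONE_ATOMS)
  mm <- matched_rows(model, reference, frm, frr)
  if (length(mm$a) < 3L) stop("insufficient matched framework backbone atoms")
  tr <- superpose(cx_coords(model, mm$a), cx_coords(reference, mm$b))
  mxyz <- apply_transform(tr, cx_coords(model))

  out <- lapply(RMSD_REGIONS, function(rg) {
    rm_ <- which(!is.na(regm) & regm == rg)
    rr <- which(!is.na(regr) & regr == rg)
    if (!length(rm_) || !length(rr))
      return(data.frame(region = rg, rmsd_heavy = NA_real_,
                        brmsd_backbone = NA_real_, n_atoms = 0L))
    if (rg == "H3" &&
        length(unique(atom_keys(model)[rm_])) !=
        length(unique(atom_keys(reference)[rr])))
      return(data.frame(region = rg, rmsd_heavy = NA_real_,
                        brmsd_backbone = NA_real_, n_atoms = 0L))
    mh <- matched_rows(model, reference, rm_, rr)
    if (!length(mh$a))
      return(data.frame(region = rg, rmsd_heavy = NA_real_,
                        brmsd_backbone = NA_real_, n_atoms = 0L))
    dev2 <- rowSums((mxyz[mh$a, , drop = FALSE] -
                       cx_coords(reference, mh$b))^2)
    bb <- model$atoms$elety[mh$a] %in% BACKBONE_ATOMS
    data.frame(region = rg,
               rmsd_heavy = sqrt(mean(dev2)),
               brmsd_backbone = if (any(bb)) sqrt(mean(dev2[bb])) else NA_real_,
               n_atoms = length(dev2))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Global sequence identity and similarity (percent)
#'
#' Needleman-Wunsch global alignment with BLOSUM62 and affine gaps;
#' identity is the fraction of identical aligned (non-gap) pairs,
#' similarity the fraction of aligned pairs with a positive substitution
#' score. Both are reported to the whole percent.
#'
#' @param a,b amino-acid strings.
#' @return named numeric vector: identity, similarity.
#' @export
seq_identity_similarity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  al <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                      Biostrings::AAString(b),
                                      substitutionMatrix = "BLOSUM62",
                                      gapOpening = 10, gapExtension = 0.5,
                                      type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1L]]
  keep <- p != "-" & s != "-"
  p <- p[keep]; s <- s[keep]
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  idy <- round(100 * mean(p == s))
  sim <- round(100 * mean(B62[cbind(p, s)] > 0))
  c(identity = idy, similarity = sim)
}

#' Dissociation-constant fold table
#'
#' Fold improvements relative to the parental antibody and to the minimal-H3
#' baseline: fold_vs_parent = Kd(parent)/Kd(design), fold_vs_baseline =
#' Kd(baseline)/Kd(design). Folds above 1 mean the design binds more
#' tightly than the comparator.
#'
#' @param records data.frame with columns id, kd_nm (nanomolar).
#' @param parent_id,baseline_id row ids of the comparators.
#' @return records with fold_vs_parent and fold_vs_baseline columns.
#' @export
kd_fold_table <- function(records, parent_id = "parent",
                          baseline_id = "minH3") {
  stopifnot(all(c("id", "kd_nm") %in% names(records)))
  if (any(records$kd_nm <= 0)) stop("Kd values must be positive")
  kp <- records$kd_nm[records$id == parent_id]
  kb <- records$kd_nm[records$id == baseline_id]
  if (!length(kp) || !length(kb)) stop("parent or baseline id missing")
  records$fold_vs_parent <- kp / records$kd_nm
  records$fold_vs_baseline <- kb / records$kd_nm
  records
}

#' Count designs whose H3 adds affinity over the baseline
#'
#' Number of designs (excluding the parent and the baseline construct) with
#' Kd strictly below the baseline Kd.
#'
#' @param records data.frame with id, kd_nm.
#' @param baseline_id,parent_id comparator row ids.
#' @return integer count.
#' @export
favorable_h3_count <- function(records, baseline_id = "minH3",
                               parent_id = "parent") {
  kb <- records$kd_nm[records$id == baseline_id]
  if (!length(kb)) stop("baseline id missing")
  designs <- records[!records$id %in% c(baseline_id, parent_id), , drop = FALSE]
  sum(designs$kd_nm < kb)
}

#' Single-structure scores of a complex
#'
#' The loop is energy-minimised with its heavy atoms harmonically
#' restrained (1 kcal/mol/A^2) in a fixed environment, then the total
#' energy and the interaction energy are evaluated. Used both for scoring
#' retrospective grafts and for the parental reference values.
#'
#' @param cx an [abcomplex()].
#' @param maxit minimisation budget.
#' @param params SIE-style coefficients.
#' @return named numeric: total_energy, interaction_energy.
#' @export
single_structure_scores <- function(cx, maxit = 120L, params = sie_params()) {
  loop <- loop_rows_of(cx)
  cx <- minimize_cartesian(cx, loop, mode = "full", bb_restraint = 1,
                           sc_restraint = 1, maxit = maxit)
  c(total_energy = total_energy(cx),
    interaction_energy = interaction_energy(cx, params = params))
}

#' Per-length median/scale table from a screen's score records
#'
#' @param records ScoreRecord data.frame.
#' @param dispersion robust ("mad") or "sd".
#' @return data.frame: h3_length, med_total, scale_total, med_interaction,
#'   scale_interaction.
#' @export
score_medians <- function(records, dispersion = c("mad", "sd")) {
  dispersion <- match.arg(dispersion)
  disp <- function(x) {
    sc <- if (dispersion == "mad") stats::mad(x) else stats::sd(x)
    if (!is.finite(sc) || sc == 0) sc <- stats::sd(x)
    if (!is.finite(sc) || sc == 0) sc <- 1
    sc
  }
  out <- lapply(split(records, records$h3_length), function(d)
    data.frame(h3_length = d$h3_length[1L],
               med_total = stats::median(d$avg_total),
               scale_total = disp(d$avg_total),
               med_interaction = stats::median(d$avg_interaction),
               scale_interaction = disp(d$avg_interaction)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Retrospective graft of a crystal loop conformation
#'
#' Superposes a design's crystal structure onto the parental complex via the
#' framework backbone, transplants the design's H3 loop into the parent,
#' copies the design-crystal rotamer for any environment side chain that
#' clashes with the incoming loop, minimises the loop in the fixed
#' environment, and scores the single structure. Z-scores come from the
#' per-length medians stored during the original screen.
#'
#' @param parent parental [abcomplex()].
#' @param design_crystal design co-crystal [abcomplex()].
#' @param stored_medians [score_medians()] table from the screen.
#' @param maxit minimisation budget.
#' @param params SIE-style coefficients.
#' @return list: total_energy, interaction_energy, z_composite, z_total,
#'   z_interaction, replaced_side_chains, unresolved_clashes.
#' @export
retrospective_graft <- function(parent, design_crystal, stored_medians,
                                maxit = 120L, params = sie_params()) {
  # framework superposition of the design onto the parent
  regd <- atom_region(design_crystal); regp <- atom_region(parent)
  frd <- which(!is.na(regd) & regd == "FR" &
                 design_crystal$atoms$elety %in% BACKBONE_ATOMS)
  frp <- which(!is.na(regp) & regp == "FR" &
                 parent$atoms$elety %in% BACKBONE_ATOMS)
  mm <- matched_rows(design_crystal, parent, frd, frp)
  tr <- superpose(cx_coords(design_crystal, mm$a), cx_coords(parent, mm$b))
  dxyz <- apply_transform(tr, cx_coords(design_crystal))
  design <- set_cx_coords(design_crystal, seq_len(nrow(design_crystal$atoms)),
                          dxyz)

  # transplant the design's H3 block into the parent
  hch <- parent$heavy_chain
  loop_block <- design$atoms[loop_rows_of(design), , drop = FALSE]
  loop_block$chain <- hch
  at <- parent$atoms
  key <- atom_keys(parent)
  old_keys <- res_key(hch, parent$h3_map)
  in_loop <- key %in% old_keys
  first <- which(in_loop)[1L]
  atoms <- rbind(at[seq_len(first - 1L), , drop = FALSE], loop_block,
                 at[setdiff(which(!in_loop), seq_len(first - 1L)), , drop = FALSE])
  rownames(atoms) <- NULL
  ann <- parent$annotation
  ann <- ann[!(ann$chain == hch & ann$res_label %in% parent$h3_map), , drop = FALSE]
  ann <- rbind(ann, data.frame(chain = hch,
                               res_label = design$h3_map,
                               region = "H3", stringsAsFactors = FALSE))
  grafted <- abcomplex(atoms, ann, parent$models_dropped)

  # environment side chains clashing with the loop -> copy design rotamer
  loop <- loop_rows_of(grafted)
  lxyz <- cx_coords(grafted, loop)
  lrad <- vdw_radius(grafted$atoms$elem[loop])
  env <- setdiff(seq_len(nrow(grafted$atoms)), loop)
  sc_env <- env[!grafted$atoms$elety[env] %in% BACKBONE_ATOMS]
  replaced <- character(0); unresolved <- character(0)
  if (length(sc_env)) {
    d2 <- dist2_mat(cx_coords(grafted, sc_env), lxyz)
    lim <- CLASH_FACTOR * outer(vdw_radius(grafted$atoms$elem[sc_env]), lrad, "+")
    bad <- sc_env[apply(d2 < lim^2, 1L, any)]
    for (k in unique(atom_keys(grafted)[bad])) {
      ch <- sub("\\|.*", "", k); lab <- sub(".*\\|", "", k)
      drows <- atom_rows(design, ch, lab)
      grows <- atom_rows(grafted, ch, lab)
      if (!length(drows)) { unresolved <- c(unresolved, k); next }
      dsub <- design$atoms[drows, , drop = FALSE]
      ok <- TRUE
      for (rw in grows) {
        el <- grafted$atoms$elety[rw]
        if (el %in% BACKBONE_ATOMS) next
        di <- which(dsub$elety == el)[1L]
        if (is.na(di)) { ok <- FALSE; next }
        grafted$atoms[rw, c("x", "y", "z")] <-
          dsub[di, c("x", "y", "z")]
      }
      replaced <- c(replaced, k)
      if (!ok) unresolved <- c(unresolved, k)
    }
  }

  sc <- single_structure_scores(grafted, maxit = maxit, params = params)
  L <- h3_length(grafted)
  med <- stored_medians[stored_medians$h3_length == L, , drop = FALSE]
  if (!nrow(med)) stop("no stored medians for H3 length ", L)
  z_tot <- (sc[["total_energy"]] - med$med_total) / med$scale_total
  z_int <- (sc[["interaction_energy"]] - med$med_interaction) /
    med$scale_interaction
  list(total_energy = sc[["total_energy"]],
       interaction_energy = sc[["interaction_energy"]],
       z_total = z_tot, z_interaction = z_int,
       z_composite = (z_tot + z_int) / 2,
       replaced_side_chains = replaced,
       unresolved_clashes = unresolved,
       complex = grafted)
}
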