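# Grafting: superpose a stem template onto the parental anchors, transplant
# the 90-105 graft region, rebuild side chains at clash-minimal rotamers and
# regularise the new geometry with the internal force field (backbone
# restrained, environment fixed, antigen ignored).

#' Graft a stem template into a parental complex
#'
#' The template is fitted on the six anchor CA atoms (residues 90-92 and
#' 103-105), its backbone for residues 90-105 replaces the parental graft
#' region, the H3 sequence is mutated to \code{h3_sequence} (flanks keep the
#' parental identities) and side chains are rebuilt with
#' [place_side_chains()]. Antigen and framework atoms outside 90-105 are
#' untouched (bitwise).
#'
#' @param parent an [abcomplex()].
#' @param template a \code{stem_template} of matching length.
#' @param h3_sequence candidate H3 (one-letter), nchar == template length.
#' @param regularize_after logical; run [regularize_region()] on the graft.
#' @return list of class \code{"graft_result"}: \code{complex},
#'   \code{anchor_rmsd} (Angstrom over the 6 anchor CAs),
#'   \code{stem_of_origin}.
#' @export
graft_stem <- function(parent, template, h3_sequence,
                       regularize_after = TRUE) {
  stopifnot(inherits(parent, "abcomplex"), inherits(template, "stem_template"))
  L <- nchar(h3_sequence)
  if (template$h3_length != L)
    stop("template length ", template$h3_length,
         " does not match sequence length ", L)
  hch <- parent$heavy_chain
  anchor_labs <- c(H3_FLANK_N, H3_FLANK_C)

  # anchor CA coordinates
  panch <- t(vapply(anchor_labs, function(lab) {
    bb <- residue_backbone(parent, hch, lab)
    if (is.null(bb$CA)) stop("anchor CA missing for residue ", lab)
    bb$CA
  }, numeric(3)))
  tanch <- t(vapply(anchor_labs, function(lab) {
    i <- which(template$atoms$label == lab & template$atoms$elety == "CA")[1L]
    if (is.na(i)) stop("template anchor CA missing for residue ", lab)
    as.numeric(template$atoms[i, c("x", "y", "z")])
  }, numeric(3)))
  tr <- superpose(tanch, panch)

  # transformed template backbone
  txyz <- apply_transform(tr, as.matrix(template$atoms[, c("x", "y", "z")]))
  tmpl <- template$atoms
  tmpl[, c("x", "y", "z")] <- txyz

  # graft-region sequence: parental flank identities + candidate H3
  new_h3_labs <- h3_labels(L)
  flank_resid <- vapply(anchor_labs, function(lab) {
    parent$atoms$resid[atom_rows(parent, hch, lab)][1L]
  }, "")
  lab_order <- c(H3_FLANK_N, new_h3_labs, H3_FLANK_C)
  res3 <- c(flank_resid[1:3], aa_three(strsplit(h3_sequence, "")[[1L]]),
            flank_resid[4:6])
  names(res3) <- lab_order

  graft_rows <- lapply(lab_order, function(lab) {
    sub <- tmpl[tmpl$label == lab & tmpl$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    if (nrow(sub) < 4L) stop("template residue ", lab, " lacks backbone atoms")
    sl <- split_label(lab)
    data.frame(chain = hch, resno = sl$resno, insert = sl$insert,
               resid = res3[[lab]], elety = sub$elety,
               elem = element_of(sub$elety),
               x = sub$x, y = sub$y, z = sub$z, o = 1,
               stringsAsFactors = FALSE)
  })
  graft_block <- do.call(rbind, graft_rows)

  # splice: heavy-chain rows before 90 / after 105 are kept verbatim
  at <- parent$atoms
  key <- atom_keys(parent)
  old_labs <- c(H3_FLANK_N, parent$h3_map, H3_FLANK_C)
  old_keys <- res_key(hch, old_labs)
  in_graft <- key %in% old_keys
  first_graft <- which(in_graft)[1L]
  pre <- at[seq_len(first_graft - 1L), , drop = FALSE]
  post <- at[setdiff(which(!in_graft), seq_len(first_graft - 1L)), , drop = FALSE]
  atoms <- rbind(pre, graft_block, post)
  rownames(atoms) <- NULL

  # annotation: replace H3 rows, keep everything else
  ann <- parent$annotation
  ann <- ann[!(ann$chain == hch & ann$res_label %in% parent$h3_map), , drop = FALSE]
  ann <- rbind(ann, data.frame(chain = hch, res_label = new_h3_labs,
                               region = "H3", stringsAsFactors = FALSE))
  out <- abcomplex(atoms, ann, parent$models_dropped)

  # rebuild graft-region side chains (GLY backbone from the template carries
  # no side chains; flanks regain their parental identities)
  out <- place_side_chains(out, data.frame(chain = hch, label = lab_order,
                                           stringsAsFactors = FALSE))
  if (regularize_after)
    out <- regularize_region(out, data.frame(chain = hch, label = lab_order,
                                             stringsAsFactors = FALSE))
  res <- list(complex = out, anchor_rmsd = tr$rmsd,
              stem_of_origin = template$cluster_id, transform = tr)
  class(res) <- "graft_result"
  res
}

#' @export
print.graft_result <- function(x, ...) {
  cat("graft_result: stem", x$stem_of_origin, "anchor rmsd",
      round(x$anchor_rmsd, 3), "A, H3", h3_sequence(x$complex), "\n")
  invisible(x)
}

# drop all side-chain atoms of the given residues
strip_side_chains <- function(cx, residues) {
  keys <- res_key(residues$chain, residues$label)
  drop <- which(atom_keys(cx) %in% keys &
                  !cx$atoms$elety %in% BACKBONE_ATOMS)
  if (length(drop)) {
    cx$atoms <- cx$atoms[-drop, , drop = FALSE]
    rownames(cx$atoms) <- NULL
    cx <- abcomplex(cx$atoms, cx$annotation, cx$models_dropped)
  }
  cx
}

#' Rebuild side chains at clash-minimal rotamers
#'
#' For each residue (in order) every rotamer of a small backbone-independent
#' library is built at ideal geometry; the rotamer with the fewest heavy-atom
#' clashes (non-bonded pair closer than 0.6 x the sum of van der Waals radii)
#' against the current structure is kept (greedy, ties to the most frequent
#' rotamer). Glycine gets no atoms, alanine exactly a CB.
#'
#' @param cx an [abcomplex()].
#' @param residues data.frame with columns chain, label.
#' @param clash_factor clash threshold as a fraction of summed vdW radii.
#' @return the updated complex.
#' @export
place_side_chains <- function(cx, residues, clash_factor = 0.6) {
  for (r in seq_len(nrow(residues))) {
    ch <- residues$chain[r]; lab <- residues$label[r]
    rows <- atom_rows(cx, ch, lab)
    if (!length(rows)) stop("residue ", ch, "|", lab, " not found")
    resid <- cx$atoms$resid[rows][1L]
    if (!resid %in% names(ROTAMERS)) stop("unknown residue type ", resid)
    bbrows <- rows[cx$atoms$elety[rows] %in% BACKBONE_ATOMS]
    scrows <- setdiff(rows, bbrows)
    # strip existing side chain
    if (length(scrows)) cx$atoms <- cx$atoms[-scrows, , drop = FALSE]
    rownames(cx$atoms) <- NULL
    if (resid == "GLY") next
    rows <- atom_rows(cx, ch, lab)
    bb <- residue_backbone(cx, ch, lab)
    if (is.null(bb$N) || is.null(bb$CA) || is.null(bb$C))
      stop("incomplete backbone for residue ", ch, "|", lab)
    other <- setdiff(seq_len(nrow(cx$atoms)), rows)
    oxyz <- cx_coords(cx, other)
    orad <- vdw_radius(cx$atoms$elem[other])
    rot <- ROTAMERS[[resid]]
    nrot <- nrow(rot)
    best <- NULL; best_clash <- Inf
    for (k in seq_len(nrot)) {
      chi <- if (ncol(rot)) rot[k, ] else numeric(0)
      sc <- build_sidechain(resid, bb, chi)
      rad <- vdw_radius(element_of(rownames(sc)))
      d <- sqrt(dist2_mat(sc, oxyz))
      lim <- clash_factor * outer(rad, orad, "+")
      ncl <- sum(d < lim)
      if (ncl < best_clash) { best <- sc; best_clash <- ncl }
      if (best_clash == 0L) break
    }
    sl <- split_label(lab)
    newrows <- data.frame(chain = ch, resno = sl$resno, insert = sl$insert,
                          resid = resid, elety = rownames(best),
                          elem = element_of(rownames(best)),
                          x = best[, 1L], y = best[, 2L], z = best[, 3L],
                          o = 1, stringsAsFactors = FALSE)
    last <- max(rows)
    at <- cx$atoms
    cx$atoms <- rbind(at[seq_len(last), , drop = FALSE], newrows,
                      if (last < nrow(at)) at[(last + 1L):nrow(at), , drop = FALSE])
    rownames(cx$atoms) <- NULL
  }
  # re-derive maps (atom rows changed)
  abcomplex(cx$atoms, cx$annotation, cx$models_dropped)
}

#' Regularise the geometry of a region
#'
#' Gradient-based descent on bonded terms (bond, angle, omega planarity)
#' plus soft-sphere repulsion, with harmonic restraints on the region's
#' backbone atoms; every atom outside the region is fixed. The antigen is
#' excluded from the nonbonded environment so that loop geometry is restored
#' without being deflected by interface contacts.
#'
#' @param cx an [abcomplex()].
#' @param residues data.frame chain/label defining the free region.
#' @param ca_restraint harmonic constant on backbone atoms (kcal/mol/A^2).
#' @param maxit iteration budget.
#' @param include_antigen include antigen atoms in the repulsion environment.
#' @return the regularised complex.
#' @export
regularize_region <- function(cx, residues, ca_restraint = 5, maxit = 500L,
                              include_antigen = FALSE) {
  keys <- res_key(residues$chain, residues$label)
  free <- which(atom_keys(cx) %in% keys)
  if (!length(free)) return(cx)
  if (!include_antigen) {
    reg <- atom_region(cx)
    drop <- which(!is.na(reg) & reg == "ANTIGEN")
    # exclude antigen by treating it as absent: subset complex, minimise,
    # then copy coordinates back
    if (length(drop)) {
      keep <- setdiff(seq_len(nrow(cx$atoms)), drop)
      sub_atoms <- cx$atoms[keep, , drop = FALSE]
      ann <- cx$annotation
      sub <- abcomplex(sub_atoms, ann[ann$region != "ANTIGEN", , drop = FALSE],
                       cx$models_dropped)
      sub_free <- match(free, keep)
      sub <- minimize_cartesian(sub, sub_free, mode = "soft",
                                bb_restraint = ca_restraint, maxit = maxit)
      cx <- set_cx_coords(cx, free, cx_coords(sub, sub_free))
      return(cx)
    }
  }
  minimize_cartesian(cx, free, mode = "soft", bb_restraint = ca_restraint,
                     maxit = maxit)
}
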