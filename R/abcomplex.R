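# Annotated antibody-antigen complex container ("abcomplex") and PDB-backed
# input/output. Atomic data live in a flat data.frame (one row per heavy
# atom); regions (FR, H1..H3, L1..L3, ANTIGEN) come from a user-supplied
# annotation table; the H3 loop is addressed through an explicit index map
# between sequence position and residue label.

REGION_LEVELS <- c("FR", "H1", "H2", "H3", "L1", "L2", "L3", "ANTIGEN")

#' Residue labels for an H3 loop of length L (internal numbering convention)
#'
#' Position 1 maps to residue 93 of the heavy chain and position L to residue
#' 102; the penultimate position maps to 101. Loops longer than 10 residues
#' use insertion codes at position 100 (100A, 100B, ...). Loops shorter than
#' 10 leave a numbering gap before 101; labels are identifiers, not indices.
#'
#' @param len H3 length (>= 4).
#' @return character vector of residue labels, length \code{len}.
#' @export
h3_labels <- function(len) {
  if (len < 4L) stop("H3 length must be at least 4")
  n_head <- len - 2L
  head <- as.character(seq(93L, length.out = min(n_head, 8L)))
  if (n_head > 8L) head <- c(head, paste0("100", LETTERS[seq_len(n_head - 8L)]))
  c(head, "101", "102")
}

H3_FLANK_N <- c("90", "91", "92")
H3_FLANK_C <- c("103", "104", "105")

res_label <- function(resno, insert) {
  ins <- ifelse(is.na(insert), "", insert)
  paste0(resno, ins)
}

split_label <- function(label) {
  resno <- as.integer(sub("[A-Za-z]*$", "", label))
  insert <- sub("^[0-9]*", "", label)
  list(resno = resno, insert = insert)
}

res_key <- function(chain, label) paste(chain, label, sep = "|")

#' Construct an annotated antibody-antigen complex
#'
#' @param atoms data.frame with columns chain, resno, insert, resid, elety,
#'   elem, x, y, z, o (one row per heavy atom, file order).
#' @param annotation data.frame with columns chain, res_label, region; region
#'   vocabulary is FR, H1, H2, H3, L1, L2, L3, ANTIGEN.
#' @param models_dropped count of extra coordinate models discarded on read.
#' @return object of class \code{"abcomplex"} with the H3 index map
#'   (\code{h3_map}: residue labels in loop order) and graft flank labels.
#' @export
abcomplex <- function(atoms, annotation, models_dropped = 0L) {
  stopifnot(is.data.frame(atoms), is.data.frame(annotation))
  need <- c("chain", "resno", "insert", "resid", "elety", "elem", "x", "y", "z", "o")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks columns: ", paste(miss, collapse = ","))
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates")
  annotation$region <- toupper(annotation$region)
  bad <- setdiff(unique(annotation$region), REGION_LEVELS)
  if (length(bad)) stop("unknown region label(s): ", paste(bad, collapse = ","))
  if (anyDuplicated(res_key(annotation$chain, annotation$res_label)))
    stop("annotation maps a residue to more than one region")

  h3 <- annotation[annotation$region == "H3", , drop = FALSE]
  if (nrow(h3) == 0L) stop("annotation contains no H3 residues")
  if (length(unique(h3$chain)) > 1L)
    stop("H3 annotated on more than one chain")
  hchain <- h3$chain[1L]

  akey <- res_key(atoms$chain, res_label(atoms$resno, atoms$insert))
  ankey <- res_key(annotation$chain, annotation$res_label)
  absent <- setdiff(ankey, akey)
  if (length(absent))
    stop("annotated residue(s) absent from coordinates: ",
         paste(absent, collapse = ", "))

  # H3 residues in chain (file) order; must be contiguous on the heavy chain
  chain_res <- unique(akey[atoms$chain == hchain])
  h3key <- res_key(h3$chain, h3$res_label)
  pos <- match(h3key, chain_res)
  pos <- sort(pos)
  if (any(diff(pos) != 1L))
    stop("H3 residues are not a contiguous stretch on chain ", hchain)
  h3_map <- sub("^.*\\|", "", chain_res[pos])

  cx <- list(atoms = atoms, annotation = annotation,
             heavy_chain = hchain, h3_map = h3_map,
             graft_flank = list(n = H3_FLANK_N, c = H3_FLANK_C),
             models_dropped = as.integer(models_dropped),
             disulfides = NULL, caps = NULL)
  class(cx) <- "abcomplex"
  cx
}

#' @export
print.abcomplex <- function(x, ...) {
  cat("abcomplex:", nrow(x$atoms), "atoms,",
      length(unique(res_key(x$atoms$chain, res_label(x$atoms$resno, x$atoms$insert)))),
      "residues; H3 length", length(x$h3_map),
      "on chain", x$heavy_chain, "\n")
  invisible(x)
}

#' H3 length of a complex
#' @param cx an \code{abcomplex}.
#' @return integer loop length (IMGT H3 length).
#' @export
h3_length <- function(cx) length(cx$h3_map)

#' H3 amino-acid sequence of a complex (one-letter)
#' @param cx an \code{abcomplex}.
#' @return character scalar.
#' @export
h3_sequence <- function(cx) {
  res <- vapply(cx$h3_map, function(lab) {
    sel <- atom_rows(cx, cx$heavy_chain, lab)
    cx$atoms$resid[sel][1L]
  }, "")
  paste(aa_one(res), collapse = "")
}

# per-atom residue keys
atom_keys <- function(cx) res_key(cx$atoms$chain, res_label(cx$atoms$resno, cx$atoms$insert))

# per-atom region (NA for unannotated, e.g. removed heteroatoms)
atom_region <- function(cx) {
  ankey <- res_key(cx$annotation$chain, cx$annotation$res_label)
  cx$annotation$region[match(atom_keys(cx), ankey)]
}

atom_rows <- function(cx, chain, label) {
  which(cx$atoms$chain == chain &
          res_label(cx$atoms$resno, cx$atoms$insert) %in% label)
}

cx_coords <- function(cx, rows = NULL) {
  a <- cx$atoms
  if (!is.null(rows)) a <- a[rows, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

set_cx_coords <- function(cx, rows, xyz) {
  cx$atoms$x[rows] <- xyz[, 1L]
  cx$atoms$y[rows] <- xyz[, 2L]
  cx$atoms$z[rows] <- xyz[, 3L]
  cx
}

# backbone atom positions of one residue as a named list
residue_backbone <- function(cx, chain, label) {
  rows <- atom_rows(cx, chain, label)
  a <- cx$atoms[rows, , drop = FALSE]
  out <- lapply(c("N", "CA", "C", "O"), function(nm) {
    i <- which(a$elety == nm)[1L]
    if (is.na(i)) return(NULL)
    c(a$x[i], a$y[i], a$z[i])
  })
  names(out) <- c("N", "CA", "C", "O")
  out
}

# residue table: one row per residue in atom order
residue_table <- function(cx) {
  key <- atom_keys(cx)
  first <- !duplicated(key)
  data.frame(chain = cx$atoms$chain[first],
             label = res_label(cx$atoms$resno, cx$atoms$insert)[first],
             resid = cx$atoms$resid[first],
             region = atom_region(cx)[first],
             stringsAsFactors = FALSE)
}

WATER_RESIDS <- c("HOH", "WAT", "DOD", "H2O")
ION_RESIDS <- c("NA", "K", "MG", "CA", "ZN", "FE", "FE2", "MN", "CU", "NI",
                "CO", "CD", "CL", "BR", "F", "I", "IOD")

#' Read an annotated antibody-antigen complex from PDB
#'
#' Parses coordinates with \pkg{bio3d} and attaches a region annotation.
#' Multi-model files contribute only their first model; alternate locations
#' keep the highest-occupancy copy (ties broken by altloc identifier order);
#' hydrogens are dropped (the package is heavy-atom based).
#'
#' @param pdb_source path to a PDB file.
#' @param annotation_source path to a tab-separated table with columns
#'   \code{chain}, \code{residue_label}, \code{region}, or an equivalent
#'   data.frame.
#' @return an [abcomplex()].
#' @export
read_structure <- function(pdb_source, annotation_source) {
  pdb <- bio3d::read.pdb(pdb_source, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  nmodels <- max(1L, sum(grepl("^MODEL", readLines(pdb_source, warn = FALSE))))
  a$insert[is.na(a$insert)] <- ""
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  elem <- element_of(a$elety)
  keep <- elem != "H"
  a <- a[keep, , drop = FALSE]; elem <- elem[keep]
  # altloc resolution: highest occupancy, ties by altloc identifier order
  akey <- paste(a$chain, a$resno, a$insert, a$elety)
  ord <- order(akey, -a$o, a$alt)
  a <- a[ord, , drop = FALSE][!duplicated(akey[ord]), , drop = FALSE]
  a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  elem <- element_of(a$elety)

  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, elety = a$elety, elem = elem,
                      x = a$x, y = a$y, z = a$z, o = a$o,
                      stringsAsFactors = FALSE)

  ann <- annotation_source
  if (!is.data.frame(ann)) {
    ann <- utils::read.table(annotation_source, header = TRUE, sep = "\t",
                             colClasses = "character")
  }
  names(ann) <- tolower(names(ann))
  if ("residue_label" %in% names(ann))
    names(ann)[names(ann) == "residue_label"] <- "res_label"
  abcomplex(atoms, ann[, c("chain", "res_label", "region")],
            models_dropped = nmodels - 1L)
}

#' Prepare a complex for modelling
#'
#' Removes waters, metal and halide ions; records disulfide bridges
#' (SG-SG < 2.5 Angstrom); completes missing side-chain heavy atoms at ideal
#' internal coordinates without repacking existing atoms; flags chain breaks
#' (C(i)-N(i+1) > 2.0 Angstrom) and chain termini with neutral cap markers
#' (flags, not extra atoms). Idempotent.
#'
#' @param cx an [abcomplex()].
#' @return list with elements \code{complex} (prepared) and \code{report}
#'   (counts: copies_removed, waters_ions_removed, chain_breaks_capped,
#'   missing_sidechains_completed).
#' @export
prepare_complex <- function(cx) {
  stopifnot(inherits(cx, "abcomplex"))
  atoms <- cx$atoms
  drop <- atoms$resid %in% WATER_RESIDS |
    (atoms$resid %in% ION_RESIDS & !atoms$elety %in% c("CA", "CD"))
  # metal CA/CD het-residues (calcium/cadmium) are single-atom residues whose
  # residue name equals the atom name; protein CA/CD atoms never are
  drop <- drop | (atoms$resid %in% c("CA", "CD") & atoms$elety == atoms$resid)
  n_removed <- length(unique(atom_keys(cx)[drop]))
  atoms <- atoms[!drop, , drop = FALSE]
  cx2 <- abcomplex(atoms, cx$annotation, cx$models_dropped)

  # disulfides
  sg <- which(atoms$resid == "CYS" & atoms$elety == "SG")
  ss <- NULL
  if (length(sg) >= 2L) {
    xyz <- cx_coords(cx2, sg)
    d2 <- dist2_mat(xyz, xyz)
    pair <- which(upper.tri(d2) & d2 < 2.5^2, arr.ind = TRUE)
    if (nrow(pair))
      ss <- data.frame(key1 = atom_keys(cx2)[sg[pair[, 1L]]],
                       key2 = atom_keys(cx2)[sg[pair[, 2L]]],
                       dist = sqrt(d2[pair]), stringsAsFactors = FALSE)
  }
  cx2$disulfides <- ss

  # complete missing side-chain atoms (ideal geometry, default chi, no repack)
  rt <- residue_table(cx2)
  n_completed <- 0L
  for (i in seq_len(nrow(rt))) {
    if (!rt$resid[i] %in% names(SC_TOPO_BY_RES) && rt$resid[i] != "GLY") next
    rows <- atom_rows(cx2, rt$chain[i], rt$label[i])
    have <- cx2$atoms$elety[rows]
    want <- expected_atoms(rt$resid[i])
    missing <- setdiff(want, have)
    missing <- setdiff(missing, BACKBONE_ATOMS) # backbone not rebuilt here
    if (!length(missing)) next
    bb <- residue_backbone(cx2, rt$chain[i], rt$label[i])
    if (is.null(bb$N) || is.null(bb$CA) || is.null(bb$C)) next
    sc <- build_sidechain(rt$resid[i], bb)
    add <- sc[rownames(sc) %in% missing, , drop = FALSE]
    if (!nrow(add)) next
    newrows <- data.frame(chain = rt$chain[i],
                          resno = split_label(rt$label[i])$resno,
                          insert = split_label(rt$label[i])$insert,
                          resid = rt$resid[i], elety = rownames(add),
                          elem = element_of(rownames(add)),
                          x = add[, 1L], y = add[, 2L], z = add[, 3L], o = 1,
                          stringsAsFactors = FALSE)
    at <- cx2$atoms
    last <- max(rows)
    cx2$atoms <- rbind(at[seq_len(last), , drop = FALSE], newrows,
                       if (last < nrow(at)) at[(last + 1L):nrow(at), , drop = FALSE])
    rownames(cx2$atoms) <- NULL
    n_completed <- n_completed + 1L
  }

  # chain breaks: C(i)-N(i+1) > 2.0 A within a chain -> neutral cap flags
  rt <- residue_table(cx2)
  caps <- NULL
  n_breaks <- 0L
  for (ch in unique(rt$chain)) {
    sub <- rt[rt$chain == ch, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (j in seq_len(nrow(sub) - 1L)) {
      b1 <- residue_backbone(cx2, ch, sub$label[j])
      b2 <- residue_backbone(cx2, ch, sub$label[j + 1L])
      if (is.null(b1$C) || is.null(b2$N)) next
      if (vnorm(b1$C - b2$N) > 2.0) {
        n_breaks <- n_breaks + 1L
        caps <- rbind(caps, data.frame(
          chain = ch, label = c(sub$label[j], sub$label[j + 1L]),
          cap = c("C_neutral", "N_neutral"), stringsAsFactors = FALSE))
      }
    }
  }
  cx2$caps <- caps

  report <- list(copies_removed = cx2$models_dropped,
                 waters_ions_removed = n_removed,
                 chain_breaks_capped = n_breaks,
                 missing_sidechains_completed = n_completed)
  list(complex = cx2, report = report)
}

#' Write a complex to a PDB file
#'
#' Serialises through \pkg{bio3d}; coordinates are written at the standard
#' 3-decimal fixed width and insertion codes/chain identifiers round-trip.
#'
#' @param cx an [abcomplex()].
#' @param target output file path.
#' @return invisibly, the path.
#' @export
write_structure <- function(cx, target) {
  stopifnot(inherits(cx, "abcomplex"))
  a <- cx$atoms
  if (any(nchar(a$resid) > 3L)) stop("residue name exceeds PDB field width")
  if (any(nchar(a$elety) > 4L)) stop("atom name exceeds PDB field width")
  xyz <- as.numeric(t(cx_coords(cx)))
  bio3d::write.pdb(file = target, xyz = xyz, resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety, chain = a$chain,
                   insert = ifelse(a$insert == "", NA, a$insert),
                   o = a$o, b = rep(0, nrow(a)))
  invisible(target)
}
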