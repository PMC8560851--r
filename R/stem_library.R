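# Stem-template library: backbone fragments that anchor H3 grafting. A
# template covers residues 90-105 under the internal numbering; its stem
# residues come from a cluster representative and the remaining loop is
# completed as poly-glycine closed onto the C-side stem. Sequence-to-stem
# matching uses a BLOSUM62 position profile over the 7 canonical stem
# positions (first 3 + last 4 of the H3).

#' Split an H3 sequence into its shortened stem parts
#'
#' The grafting stems are shortened to the first 2 and last 3 residues of
#' the H3 so that the structurally variable inner stem ends can be sampled.
#'
#' @param h3_sequence one-letter amino-acid string, length >= 6.
#' @return list with \code{n_stem} (2 residues) and \code{c_stem} (3).
#' @examples
#' stem_parts("SRWGGDGFYAMDY") # SR / MDY
#' @export
stem_parts <- function(h3_sequence) {
  L <- nchar(h3_sequence)
  if (L < 6L) stop("H3 sequence must have at least 6 residues")
  list(n_stem = substr(h3_sequence, 1L, 2L),
       c_stem = substr(h3_sequence, L - 2L, L))
}

# canonical (North-style) stem positions: first 3 and last 4
north_stem_positions <- function(L) c(1L, 2L, 3L, L - 3L, L - 2L, L - 1L, L)

north_stem_seq <- function(h3_sequence) {
  L <- nchar(h3_sequence)
  paste(strsplit(h3_sequence, "")[[1L]][north_stem_positions(L)], collapse = "")
}

TEMPLATE_LENGTH_RANGE <- c(7L, 30L)

new_stem_template <- function(cluster_id, h3_length, atoms, stem_seq,
                              source_tag = "synthetic") {
  tpl <- list(cluster_id = cluster_id, h3_length = as.integer(h3_length),
              atoms = atoms, stem_seq = stem_seq, source_tag = source_tag)
  class(tpl) <- "stem_template"
  tpl
}

#' @export
print.stem_template <- function(x, ...) {
  cat("stem_template", x$cluster_id, "length", x$h3_length,
      "stem", x$stem_seq, "(", x$source_tag, ")\n")
  invisible(x)
}

# backbone block extractor: residues `labels` of the heavy chain as a
# data.frame(label, elety, resid, x, y, z) with N, CA, C, O per residue
extract_bb_block <- function(cx, labels) {
  rows <- atom_rows(cx, cx$heavy_chain, labels)
  a <- cx$atoms[rows, , drop = FALSE]
  a <- a[a$elety %in% BACKBONE_ATOMS, , drop = FALSE]
  data.frame(label = res_label(a$resno, a$insert), elety = a$elety,
             resid = a$resid, x = a$x, y = a$y, z = a$z,
             stringsAsFactors = FALSE)
}

block_xyz <- function(block, label, elety) {
  i <- which(block$label == label & block$elety == elety)[1L]
  if (is.na(i)) stop("missing backbone atom ", elety, " in residue ", label)
  c(block$x[i], block$y[i], block$z[i])
}

#' Build a stem template of a given H3 length
#'
#' Starting from a cluster representative's stem geometry (N-side block:
#' residues 90-92 plus the first two H3 residues; C-side block: last three
#' H3 residues plus 103-105), the inner loop is completed as poly-glycine:
#' an extended placement grown from the N-side stem and closed onto the
#' C-side stem by cyclic coordinate descent.
#'
#' @param cluster_backbone list with \code{n_block}, \code{c_block}
#'   (backbone data.frames as produced by the fixture/stem extractors),
#'   \code{stem_seq} (7-residue canonical stem sequence) and
#'   \code{cluster_id}.
#' @param target_length desired H3 length, 7 to 30.
#' @return a \code{stem_template}.
#' @export
build_template <- function(cluster_backbone, target_length) {
  target_length <- as.integer(target_length)
  if (target_length < TEMPLATE_LENGTH_RANGE[1L] ||
      target_length > TEMPLATE_LENGTH_RANGE[2L])
    stop("template length must be in 7..30 (got ", target_length, ")")
  L <- target_length
  lab <- h3_labels(L)
  nb <- cluster_backbone$n_block
  cb <- cluster_backbone$c_block
  # relabel blocks onto the target-length convention
  nlabs_src <- unique(nb$label)            # 90 91 92 s1 s2
  clabs_src <- unique(cb$label)            # sL-2 sL-1 sL 103 104 105
  stopifnot(length(nlabs_src) == 5L, length(clabs_src) == 6L)
  nb$label <- c("90", "91", "92", lab[1L], lab[2L])[match(nb$label, nlabs_src)]
  cb$label <- c(lab[L - 2L], lab[L - 1L], lab[L], "103", "104", "105")[
    match(cb$label, clabs_src)]

  # grow L-5 glycines from s2 in extended conformation, close onto s[L-2]
  k <- L - 5L
  seed <- rbind(block_xyz(nb, lab[2L], "N"), block_xyz(nb, lab[2L], "CA"),
                block_xyz(nb, lab[2L], "C"))
  target <- rbind(block_xyz(cb, lab[L - 2L], "N"),
                  block_xyz(cb, lab[L - 2L], "CA"),
                  block_xyz(cb, lab[L - 2L], "C"))
  starts <- expand.grid(phi = c(-135, -75, -60, 60, -100),
                        psi = c(150, 0, -40, 60), psi0 = c(135, -30, 60))
  pre <- list(list(p1 = seed[2L, ], p2 = seed[3L, ]))  # psi axis of s2
  best <- NULL
  for (si in seq_len(nrow(starts))) {
    bb <- build_bb_segment(seed, psi_prev = starts$psi0[si],
                           phi = rep(starts$phi[si], k + 1L),
                           psi = rep(starts$psi[si], k + 1L))
    # last generated triplet is the anchor projection of s[L-2]
    cl <- ccd_close(bb, rotatable = seq_len(k), target = target,
                    pre_axes = pre)
    if (is.null(best) || cl$gap < best$gap) best <- cl
    if (best$gap <= 0.05) break
  }
  bb <- best$bb
  # assemble template backbone: N block, glycines (with O), C block
  rows <- list()
  rows[[1L]] <- nb
  for (i in seq_len(k)) {
    N <- bb[3L * i - 2L, ]; CA <- bb[3L * i - 1L, ]; C <- bb[3L * i, ]
    n_next <- bb[3L * i + 1L, ]
    O <- place_bb_O(CA, C, n_next)
    rows[[i + 1L]] <- data.frame(label = lab[2L + i],
                                 elety = c("N", "CA", "C", "O"), resid = "GLY",
                                 x = c(N[1L], CA[1L], C[1L], O[1L]),
                                 y = c(N[2L], CA[2L], C[2L], O[2L]),
                                 z = c(N[3L], CA[3L], C[3L], O[3L]),
                                 stringsAsFactors = FALSE)
  }
  rows[[k + 2L]] <- cb
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  # re-orient the O of s2 towards the rebuilt N of the first glycine
  o_i <- which(atoms$label == lab[2L] & atoms$elety == "O")
  O2 <- place_bb_O(block_xyz(nb, lab[2L], "CA"), block_xyz(nb, lab[2L], "C"),
                   bb[1L, ])
  atoms[o_i, c("x", "y", "z")] <- O2
  attr(atoms, "closure_gap") <- best$gap
  new_stem_template(cluster_backbone$cluster_id, L, atoms,
                    cluster_backbone$stem_seq,
                    source_tag = cluster_backbone$source_tag %||% "synthetic")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the graft-region backbone of a complex as an exact stem template
#'
#' Unlike [build_template()], the full 90-105 backbone is copied verbatim
#' (no poly-glycine completion), so grafting this template with the parental
#' sequence reproduces the parental loop.
#'
#' @param cx an [abcomplex()].
#' @param cluster_id template identifier.
#' @return a \code{stem_template} of the complex's own H3 length.
#' @export
template_from_complex <- function(cx, cluster_id = "self") {
  lab <- c("90", "91", "92", cx$h3_map, "103", "104", "105")
  atoms <- extract_bb_block(cx, lab)
  new_stem_template(cluster_id, h3_length(cx), atoms,
                    north_stem_seq(h3_sequence(cx)), source_tag = "complex")
}

#' Match an H3 sequence against a stem-template library
#'
#' Templates of matching length are scored with a position-specific BLOSUM62
#' log-odds profile over the 7 canonical stem positions; every template
#' within \code{retention_window} score units of the best match is retained.
#'
#' @param h3_sequence one-letter string.
#' @param library list of \code{stem_template}s.
#' @param retention_window score window below the best match (default 1.7).
#' @return data.frame with columns cluster_id, alignment_score, retained,
#'   plus the matched templates in \code{attr(, "templates")}.
#' @export
match_stems <- function(h3_sequence, library, retention_window = 1.7) {
  if (!length(library)) stop("empty stem library")
  L <- nchar(h3_sequence)
  same <- Filter(function(t) t$h3_length == L, library)
  if (!length(same))
    stop("no stem template of length ", L, " in library")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B62 <- get("BLOSUM62", envir = environment())
  q <- strsplit(north_stem_seq(h3_sequence), "")[[1L]]
  score <- vapply(same, function(t) {
    s <- strsplit(t$stem_seq, "")[[1L]]
    sum(B62[cbind(q, s)])
  }, 0)
  retained <- (max(score) - score) <= retention_window
  out <- data.frame(cluster_id = vapply(same, `[[`, "", "cluster_id"),
                    alignment_score = score, retained = retained,
                    stringsAsFactors = FALSE)
  attr(out, "templates") <- same
  out
}

#' Write / read a stem-template library directory
#'
#' The on-disk format is a directory of PDB fragments (backbone of residues
#' 90-105 on chain H) plus a tab-separated manifest \code{stems.tsv} with
#' columns \code{cluster_id}, \code{length}, \code{file}, \code{stem_seq},
#' \code{source_tag}.
#'
#' @param library list of \code{stem_template}s.
#' @param dir directory path.
#' @return invisibly, the directory (write) or the template list (read).
#' @export
write_stem_library <- function(library, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(library), function(i) {
    tpl <- library[[i]]
    fn <- sprintf("%s_L%02d.pdb", tpl$cluster_id, tpl$h3_length)
    a <- tpl$atoms
    sl <- split_label(a$label)
    bio3d::write.pdb(file = file.path(dir, fn),
                     xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = sl$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = rep("H", nrow(a)),
                     insert = ifelse(sl$insert == "", NA, sl$insert),
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)))
    data.frame(cluster_id = tpl$cluster_id, length = tpl$h3_length,
               file = fn, stem_seq = tpl$stem_seq,
               source_tag = tpl$source_tag, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), file.path(dir, "stems.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_stem_library
#' @export
read_stem_library <- function(dir) {
  man <- utils::read.table(file.path(dir, "stems.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    pdb <- bio3d::read.pdb(file.path(dir, man$file[i]), verbose = FALSE)
    a <- pdb$atom
    a$insert[is.na(a$insert)] <- ""
    a <- a[a$elety %in% BACKBONE_ATOMS, , drop = FALSE]
    atoms <- data.frame(label = res_label(a$resno, a$insert),
                        elety = a$elety, resid = a$resid,
                        x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    new_stem_template(man$cluster_id[i], man$length[i], atoms,
                      man$stem_seq[i], source_tag = man$source_tag[i])
  })
}

#' Build the default synthetic stem library from a parental complex
#'
#' Cluster 1 is the parental stem geometry itself; additional clusters are
#' produced by small rigid perturbations of the C-side stem block (rotation
#' about the anchor axis) together with alternative germline-like stem
#' sequences. Templates are generated for every requested H3 length.
#'
#' @param parent an [abcomplex()].
#' @param lengths integer vector of H3 lengths to cover.
#' @param n_clusters number of stem clusters (1..4).
#' @param seed RNG seed for the perturbations.
#' @return list of \code{stem_template}s.
#' @export
default_stem_library <- function(parent, lengths = 7:16, n_clusters = 2L,
                                 seed = 1L) {
  stopifnot(inherits(parent, "abcomplex"), n_clusters >= 1L, n_clusters <= 4L)
  L0 <- h3_length(parent)
  lab0 <- parent$h3_map
  n_block <- extract_bb_block(parent, c("90", "91", "92", lab0[1:2]))
  c_block <- extract_bb_block(parent, c(lab0[(L0 - 2L):L0], "103", "104", "105"))
  pseq <- h3_sequence(parent)
  stems <- c(north_stem_seq(pseq), "ARGGFDY", "AKGGMDV", "GRSYFDF")
  alt_rot <- c(0, 12, -12, 20)
  with_seed(seed, {
    lib <- list()
    for (ci in seq_len(n_clusters)) {
      cb <- c_block
      if (alt_rot[ci] != 0) {
        # rotate the C-side block about the axis joining the two anchor CAs
        p1 <- block_xyz(n_block, "91", "CA")
        p2 <- block_xyz(cb, "104", "CA")
        ax <- vunit(p2 - p1)
        xyz <- as.matrix(cb[, c("x", "y", "z")])
        xyz <- rotate_about_axis(xyz, p2, ax, deg2rad(alt_rot[ci]))
        cb[, c("x", "y", "z")] <- xyz
      }
      cbb <- list(cluster_id = paste0("C", ci), n_block = n_block,
                  c_block = cb, stem_seq = stems[ci],
                  source_tag = if (ci == 1L) "parent" else "synthetic")
      for (L in lengths) {
        tpl <- build_template(cbb, L)
        lib[[length(lib) + 1L]] <- tpl
      }
    }
    lib
  })
}
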