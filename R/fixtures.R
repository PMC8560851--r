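# Synthetic inputs: a toy antibody-antigen complex with annotated regions, an
# H3 sequence library with the composition of human germline-derived loops,
# and synthetic score tables reproducing the length bias of binding scoring
# functions. All generators are bit-reproducible under the configured seed.

PARENT_H3 <- "SRWGGDGFYAMDY"

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixture specification
#'
#' Parameters controlling the synthetic fixture generators. Defaults emulate
#' the screened H3 library regime: loop lengths 7-16, a positive
#' score-per-residue length bias and unit score noise.
#'
#' @param seed integer RNG seed.
#' @param h3_length_range integer pair within [6, 30].
#' @param library_size number of generated sequences (>= 1).
#' @param length_bias_slope score units gained per extra residue in synthetic
#'   score tables (positive slope means longer loops score better).
#' @param noise_sd score noise standard deviation (>= 0).
#' @return list of class \code{"fixture_spec"}.
#' @export
fixture_spec <- function(seed = 1L, h3_length_range = c(7L, 16L),
                         library_size = 50L, length_bias_slope = 1,
                         noise_sd = 1) {
  stopifnot(length(h3_length_range) == 2L,
            h3_length_range[1L] >= 6L, h3_length_range[2L] <= 30L,
            h3_length_range[1L] <= h3_length_range[2L],
            library_size >= 1L, noise_sd >= 0)
  out <- list(seed = as.integer(seed),
              h3_length_range = as.integer(h3_length_range),
              library_size = as.integer(library_size),
              length_bias_slope = length_bias_slope, noise_sd = noise_sd)
  class(out) <- "fixture_spec"
  out
}

# Build atoms rows for one chain from per-residue dihedrals. Backbone from
# ideal internal coordinates; O anti to the next nitrogen; side chains at the
# default rotamer.
build_peptide_atoms <- function(chain, labels, seq1, phi, psi,
                                seed_mat = NULL) {
  n <- length(labels)
  stopifnot(length(phi) == n, length(psi) == n, nchar(seq1) == n)
  res3 <- aa_three(strsplit(seq1, "")[[1L]])
  if (is.null(seed_mat))
    seed_mat <- rbind(c(0, 0, 0), c(1.458, 0, 0),
                      c(1.458 + 1.525 * cos(deg2rad(180 - 111.2)),
                        1.525 * sin(deg2rad(180 - 111.2)), 0))
  bb <- build_bb_segment(seed_mat, psi_prev = 140, phi = phi, psi = psi)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    N <- bb[3L * i - 2L, ]; CA <- bb[3L * i - 1L, ]; C <- bb[3L * i, ]
    O <- place_atom(N, CA, C, BB_GEOM$c_o, BB_GEOM$ang_ca_c_o, psi[i] + 180)
    sc <- build_sidechain(res3[i], list(N = N, CA = CA, C = C))
    nm <- c("N", "CA", "C", "O", rownames(sc))
    xyz <- rbind(N, CA, C, O, sc)
    lab <- split_label(labels[i])
    rows[[i]] <- data.frame(chain = chain, resno = lab$resno,
                            insert = lab$insert, resid = res3[i], elety = nm,
                            elem = element_of(nm),
                            x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], o = 1,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a toy antibody-antigen complex
#'
#' Builds a small antibody-like scaffold: a heavy-chain segment carrying the
#' graft site (framework strands, flank residues 90-92/103-105 and a
#' contiguous H3 at residues 93-102 under the internal numbering), a
#' light-chain beta-hairpin, and a rigid convex helical "antigen" placed so
#' that the parental H3 makes at least 5 heavy-atom contacts at 4.5 Angstrom.
#' Deterministic under \code{spec$seed}.
#'
#' @param spec a [fixture_spec()].
#' @param parent_h3 parental H3 sequence (default SRWGGDGFYAMDY, length 13).
#' @return an [abcomplex()].
#' @export
make_toy_complex <- function(spec = fixture_spec(), parent_h3 = PARENT_H3) {
  with_seed(spec$seed, {
    L <- nchar(parent_h3)
    h3lab <- h3_labels(L)
    hlabs <- c(as.character(80:92), h3lab, as.character(103:115))
    hseq <- paste0("EVQLVESGGGLVQ", parent_h3, "WGQGTLVTVSSAS")
    stopifnot(nchar(hseq) == length(hlabs))
    nH <- length(hlabs)
    # hairpin: strand out, type-I' turn at the middle of the H3, strand
    # back (keeps the 90-92/103-105 anchor bases ~10 A apart, the typical
    # H3 base span, so grafted loops of length 7+ can bridge them)
    phi <- rep(-139, nH); psi <- rep(135, nH)
    i3 <- 13L + seq_len(L)
    half <- floor(L / 2)
    phi[i3] <- c(rep(-139, half), 60, 90, rep(-139, L - half - 2L))
    psi[i3] <- c(rep(135, half), 30, 0, rep(135, L - half - 2L))
    strand3 <- setdiff(seq_len(L), c(half + 1L, half + 2L))
    phi[i3][strand3] <- phi[i3][strand3] + stats::runif(length(strand3), -3, 3)
    psi[i3][strand3] <- psi[i3][strand3] + stats::runif(length(strand3), -3, 3)
    heavy <- build_peptide_atoms("H", hlabs, hseq, phi, psi)

    hxyz <- as.matrix(heavy[, c("x", "y", "z")])
    h3rows <- heavy$resno >= 93 & heavy$resno <= 102
    turn_lab <- h3lab[c(half + 1L, half + 2L)]
    tiprows <- res_label(heavy$resno, heavy$insert) %in% turn_lab &
      heavy$elety == "CA"
    tip <- colMeans(hxyz[tiprows, , drop = FALSE])
    fr_ctr <- colMeans(hxyz[!h3rows & heavy$elety == "CA", , drop = FALSE])
    dirv <- vunit(tip - fr_ctr)

    # light chain: a hairpin on the far side of the framework from the H3
    llabs <- as.character(1:20)
    lseq <- "DIQMTQSPSSLSASVGDRVT"
    lphi <- c(rep(-125, 9), -60, -90, rep(-125, 9)) + stats::runif(20, -3, 3)
    lpsi <- c(rep(135, 9), -30, 0, rep(135, 9)) + stats::runif(20, -3, 3)
    light <- build_peptide_atoms("L", llabs, lseq, lphi, lpsi)
    lxyz <- as.matrix(light[, c("x", "y", "z")])
    lxyz <- sweep(lxyz, 2L, colMeans(lxyz))
    target <- fr_ctr - 18 * dirv
    lxyz <- sweep(lxyz, 2L, target, "+")
    away <- vunit(target - fr_ctr)
    for (k in 1:60) {
      d2 <- dist2_mat(lxyz, hxyz)
      if (sqrt(min(d2)) >= 3.6) break
      lxyz <- sweep(lxyz, 2L, away, "+")
    }
    light[, c("x", "y", "z")] <- lxyz

    # rigid convex antigen: a 24-residue helix, axis perpendicular to the
    # approach direction, slid toward the H3 tip until just in contact
    # small/polar residues only: helix side chains stay clash-free at the
    # default rotamer while still offering HB donors/acceptors and charges
    aseq <- "ASTNADSVATNSKDSTVANSADST"
    aphi <- rep(-57, 24); apsi <- rep(-47, 24)
    anti <- build_peptide_atoms("A", as.character(1:24), aseq, aphi, apsi)
    axyz <- as.matrix(anti[, c("x", "y", "z")])
    axyz <- sweep(axyz, 2L, colMeans(axyz))
    ax <- svd(axyz)$v[, 1L]                      # helix principal axis
    perp <- vcross(dirv, c(0, 0, 1))
    if (vnorm(perp) < 1e-6) perp <- vcross(dirv, c(0, 1, 0))
    perp <- vunit(perp)
    rot <- rotation_between(ax, perp)
    axyz <- axyz %*% t(rot)
    abxyz <- rbind(hxyz, lxyz)
    h3xyz <- hxyz[h3rows, , drop = FALSE]
    # engage the loop at the deepest sterically clean approach (close
    # heavy-atom pairs no nearer than a hydrogen-bond distance) and present
    # the antigen face most complementary to the parental loop, emulating a
    # cognate epitope: over rotations of the helix about its own axis, pick
    # the (rotation, depth) with the best quick interface score
    h3at <- heavy[h3rows, , drop = FALSE]
    abat <- rbind(heavy, light)
    qab <- atom_charge(abat$resid, abat$elety)
    qag <- atom_charge(anti$resid, anti$elety)
    rab <- vdw_radius(abat$elem); rag <- vdw_radius(anti$elem)
    iface_score <- function(cand) {
      d2 <- dist2_mat(abxyz, cand)
      hit <- which(d2 <= 64, arr.ind = TRUE)
      if (!nrow(hit)) return(0)
      d <- pmax(sqrt(d2[hit]), 0.8)
      rm <- 0.95 * (rab[hit[, 1L]] + rag[hit[, 2L]])
      x6 <- (rm / d)^6
      sum(0.15 * (x6^2 - 2 * x6)) +
        sum(332 * qab[hit[, 1L]] * qag[hit[, 2L]] / (2.25 * d^2))
    }
    best <- NULL
    for (rot in seq(0, 330, by = 30)) {
      cxyz <- rotate_about_axis(axyz, c(0, 0, 0), perp, deg2rad(rot))
      t_ok <- NA_real_
      for (t in seq(14, 0.5, by = -0.25)) {
        cand <- sweep(cxyz, 2L, tip + t * dirv, "+")
        if (sqrt(min(dist2_mat(abxyz, cand))) < 2.75) break
        t_ok <- t
        if (count_pairs_within(h3xyz, cand, 4.5) >= 20L) break
      }
      if (is.na(t_ok)) next
      cand <- sweep(cxyz, 2L, tip + t_ok * dirv, "+")
      sc <- iface_score(cand)
      if (is.null(best) || sc < best$sc)
        best <- list(sc = sc, xyz = cand)
    }
    if (is.null(best)) best <- list(xyz = sweep(axyz, 2L, tip + 6 * dirv, "+"))
    anti[, c("x", "y", "z")] <- best$xyz

    atoms <- rbind(heavy, light, anti)
    rownames(atoms) <- NULL

    region_of <- function(labs, chain) {
      if (chain == "H") {
        r <- rep("FR", length(labs))
        r[labs %in% as.character(82:84)] <- "H1"
        r[labs %in% as.character(86:88)] <- "H2"
        r[labs %in% h3lab] <- "H3"
        r
      } else if (chain == "L") {
        r <- rep("FR", length(labs))
        r[labs %in% as.character(5:7)] <- "L1"
        r[labs %in% as.character(10:12)] <- "L2"
        r[labs %in% as.character(15:17)] <- "L3"
        r
      } else rep("ANTIGEN", length(labs))
    }
    ann <- rbind(
      data.frame(chain = "H", res_label = hlabs,
                 region = region_of(hlabs, "H"), stringsAsFactors = FALSE),
      data.frame(chain = "L", res_label = llabs,
                 region = region_of(llabs, "L"), stringsAsFactors = FALSE),
      data.frame(chain = "A", res_label = as.character(1:24),
                 region = "ANTIGEN", stringsAsFactors = FALSE))
    cx <- abcomplex(atoms, ann)
    # graft-region side chains go through the same clash-minimal placement
    # used after grafting, so the parental complex is a fixed point of the
    # self-graft operation
    graftres <- data.frame(chain = "H",
                           label = c("90", "91", "92", h3lab, "103", "104", "105"),
                           stringsAsFactors = FALSE)
    cx <- strip_side_chains(cx, graftres)
    place_side_chains(cx, graftres)
  })
}

# rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- vunit(a); b <- vunit(b)
  v <- vcross(a, b); s <- vnorm(v); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    # opposite: rotate 180 about any perpendicular axis
    p <- vunit(vcross(a, if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
    return(2 * outer(p, p) - diag(3))
  }
  vx <- matrix(c(0, v[3L], -v[2L], -v[3L], 0, v[1L], v[2L], -v[1L], 0), 3L, 3L)
  diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
}

# residue frequencies of the designed H3 sequences (used to keep generated
# loop composition in a realistic regime)
DESIGN_AA_FREQ <- local({
  seqs <- c("ARGGAVAGTGVYYFDY", "AKGGSSSGPYHFEY", "ARGIAVAGAYYFDY",
            "ARGGSFYYYYMDV", "AKGWEGTTVTLTPVDY", "ARHGVRGYYYYYMDV",
            "VRGGYLRDYYGMDV", "AKLGIGYYYYGMDV", "GRSGPRLGMYYFDF",
            "ARGRKYSSSFDY", "ARGLERSGNYYLDY", "AKLGGQGSYYHFDY",
            "ARPSGGSRSWLYYFDY", "ARGNEAGYYYGMDV", "ARNGGDSYSGYFQH",
            "ARSGRDAYNYYFDS")
  tab <- table(strsplit(paste(seqs, collapse = ""), "")[[1L]])
  tab <- tab[names(tab) != "C"]
  tab / sum(tab)
})

#' Generate a synthetic H3 sequence library
#'
#' Sequences are drawn with the residue composition of the designed loops,
#' stems drawn from germline-like stem vocabularies, lengths uniform over the
#' spec range, cysteines excluded. The parental sequence and a minimal-H3
#' control (first 3 + Gly + last 3 of the parent) are always included.
#'
#' @param spec a [fixture_spec()].
#' @param parent_h3 parental sequence.
#' @return data.frame with columns \code{id}, \code{sequence}.
#' @export
make_h3_library <- function(spec = fixture_spec(), parent_h3 = PARENT_H3) {
  with_seed(spec$seed + 1L, {
    lo <- spec$h3_length_range[1L]; hi <- spec$h3_length_range[2L]
    nstem <- c("AR", "AK", "GR", "VR", "SR", "AS")
    cstem <- c("FDY", "MDY", "MDV", "FEY", "LDY", "FDF", "FQH", "FDS", "VDY")
    n <- spec$library_size
    lens <- sample(lo:hi, n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      mid <- paste(sample(names(DESIGN_AA_FREQ), L - 5L, replace = TRUE,
                          prob = DESIGN_AA_FREQ), collapse = "")
      paste0(sample(nstem, 1L), mid, sample(cstem, 1L))
    }, "")
    minimal <- paste0(substr(parent_h3, 1L, 3L), "G",
                      substr(parent_h3, nchar(parent_h3) - 2L, nchar(parent_h3)))
    ids <- sprintf("%02d_%04d", lens, seq_len(n))
    out <- rbind(
      data.frame(id = "parent", sequence = parent_h3, stringsAsFactors = FALSE),
      data.frame(id = "minH3", sequence = minimal, stringsAsFactors = FALSE),
      data.frame(id = ids, sequence = seqs, stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  })
}

#' Write / read an H3 library as FASTA
#' @param lib data.frame with id, sequence.
#' @param path output file.
#' @return invisibly the path.
#' @export
write_h3_fasta <- function(lib, path) {
  x <- Biostrings::AAStringSet(stats::setNames(lib$sequence, lib$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_h3_fasta
#' @export
read_h3_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Generate a synthetic score table with a length bias
#'
#' Emulates the size bias of binding scoring functions: scores are drawn as
#' base - slope * length + Normal(0, noise_sd), independently for the
#' total-energy and interaction-energy columns, so longer loops score better
#' (lower) whenever the slope is positive.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame with id, length, total_energy, interaction_energy.
#' @export
make_score_table <- function(spec = fixture_spec()) {
  with_seed(spec$seed + 2L, {
    lo <- spec$h3_length_range[1L]; hi <- spec$h3_length_range[2L]
    n <- spec$library_size
    lens <- sort(rep_len(lo:hi, n))
    data.frame(
      id = sprintf("%02d_%04d", lens, seq_len(n)),
      length = lens,
      total_energy = -200 - spec$length_bias_slope * lens +
        stats::rnorm(n, 0, spec$noise_sd),
      interaction_energy = -8 - 0.25 * spec$length_bias_slope * lens +
        stats::rnorm(n, 0, 0.25 * spec$noise_sd + 1e-12),
      stringsAsFactors = FALSE)
  })
}
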