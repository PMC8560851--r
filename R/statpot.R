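# Distance-dependent statistical contact potential used to re-rank raw loop
# conformations: atom-typed (C/N/O/S classes), 8 Angstrom cutoff, 0.5
# Angstrom bins. Bin values derive from a smooth 8-4 well per type pair
# (polar-polar pairs get a deeper, hydrogen-bond-like well; carbon pairs a
# shallow hydrophobic-packing well), evaluated at bin midpoints, so the
# potential is deterministic and fully reproducible.

STATPOT_CUTOFF <- 8
STATPOT_BIN <- 0.5

.statpot_env <- new.env(parent = emptyenv())

statpot_classes <- c("C", "N", "O", "S")

statpot_table <- function() {
  if (!is.null(.statpot_env$tab)) return(.statpot_env$tab)
  eps <- matrix(0.3, 4L, 4L, dimnames = list(statpot_classes, statpot_classes))
  eps["C", "C"] <- 0.5
  eps["N", "O"] <- eps["O", "N"] <- 1.2
  eps["N", "N"] <- eps["O", "O"] <- 0.2
  eps["S", "C"] <- eps["C", "S"] <- 0.5
  eps["S", "S"] <- 0.5
  rad <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
  nb <- as.integer(STATPOT_CUTOFF / STATPOT_BIN)
  mids <- (seq_len(nb) - 0.5) * STATPOT_BIN
  tab <- array(0, dim = c(4L, 4L, nb),
               dimnames = list(statpot_classes, statpot_classes, NULL))
  for (a in 1:4) for (b in 1:4) {
    rm <- 1.05 * (rad[a] + rad[b])
    x4 <- (rm / mids)^4
    u <- eps[a, b] * (x4^2 - 2 * x4)
    u <- pmin(u, 10)                      # cap the clash bins
    tab[a, b, ] <- u
  }
  .statpot_env$tab <- tab
  tab
}

statpot_class_of <- function(elem) {
  ifelse(elem %in% statpot_classes, elem, "C")
}

#' Statistical contact potential of the H3 loop in its environment
#'
#' Sums the binned, atom-typed distance potential over loop-environment and
#' loop-loop heavy-atom pairs within 8 Angstrom (0.5 Angstrom bins). Lower
#' is better. Pairs of atoms from the same or adjacent loop residues are
#' excluded as bonded context.
#'
#' @param cx an [abcomplex()] carrying the loop conformation.
#' @param loop_rows optional atom-row indices of the loop (defaults to the
#'   annotated H3 region).
#' @return scalar energy (statistical-potential units).
#' @export
stat_potential <- function(cx, loop_rows = NULL) {
  if (is.null(loop_rows)) {
    reg <- atom_region(cx)
    loop_rows <- which(!is.na(reg) & reg == "H3")
  }
  tab <- statpot_table()
  nb <- dim(tab)[3L]
  at <- cx$atoms
  xyz <- cx_coords(cx)
  cls <- match(statpot_class_of(at$elem), statpot_classes)
  env_rows <- setdiff(seq_len(nrow(at)), loop_rows)
  # residue index for adjacency exclusions within the loop
  rkey <- atom_keys(cx)
  rind <- match(rkey, unique(rkey))

  score <- 0
  # loop-environment (exclude residues adjacent in chain: the flanks)
  if (length(env_rows)) {
    d2 <- dist2_mat(xyz[loop_rows, , drop = FALSE],
                    xyz[env_rows, , drop = FALSE])
    adj <- abs(outer(rind[loop_rows], rind[env_rows], "-")) <= 1L
    hit <- which(d2 <= STATPOT_CUTOFF^2 & !adj, arr.ind = TRUE)
    if (nrow(hit)) {
      bins <- pmin(nb, floor(sqrt(d2[hit]) / STATPOT_BIN) + 1L)
      score <- score + sum(tab[cbind(cls[loop_rows[hit[, 1L]]],
                                     cls[env_rows[hit[, 2L]]], bins)])
    }
  }
  # loop-loop, non-adjacent residues, each pair once
  d2 <- dist2_mat(xyz[loop_rows, , drop = FALSE],
                  xyz[loop_rows, , drop = FALSE])
  sep <- abs(outer(rind[loop_rows], rind[loop_rows], "-"))
  hit <- which(upper.tri(d2) & d2 <= STATPOT_CUTOFF^2 & sep > 1L,
               arr.ind = TRUE)
  if (nrow(hit)) {
    bins <- pmin(nb, floor(sqrt(d2[hit]) / STATPOT_BIN) + 1L)
    score <- score + sum(tab[cbind(cls[loop_rows[hit[, 1L]]],
                                   cls[loop_rows[hit[, 2L]]], bins)])
  }
  score
}
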