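# Internal force field: bonded terms (bond, angle, omega planarity),
# soft-sphere repulsion or 12-6 Lennard-Jones, screened Coulomb with a
# distance-dependent dielectric (eps = 4r), a distance-well hydrogen-bond
# term, harmonic positional restraints, and an L-BFGS Cartesian minimiser
# with analytic gradients. Used by the post-graft regulariser, the per-
# conformer loop minimisation and the total-energy score.

FF <- list(
  k_bond = 300, k_angle = 40, k_omega = 15,
  k_soft = 25, soft_scale = 0.85,
  lj_eps = 0.15, lj_scale = 0.95,
  coul_const = 332.0636, diel_slope = 4,
  hb_depth = 1.5, hb_d0 = 2.9, hb_sigma = 0.3,
  rama_weight = 2
)

# --- bonded topology ---------------------------------------------------------

# bonds/angles/omegas for the residues of `cx`; returns index-based term
# tables over cx$atoms rows. Peptide bonds connect consecutive residues of a
# chain when C-N < 3.5 A (larger separations are treated as real breaks).
bonded_topology <- function(cx) {
  at <- cx$atoms
  n <- nrow(at)
  key <- atom_keys(cx)
  ukey <- unique(key)
  # atom lookup: index by (residue key, atom name)
  idx <- stats::setNames(seq_len(n), paste(key, at$elety))
  gi <- function(k, a) {
    i <- idx[paste(k, a)]
    ifelse(is.na(i), NA_integer_, i)
  }
  rt <- residue_table(cx)
  rkey <- res_key(rt$chain, rt$label)

  bonds <- list(); angles <- list(); omegas <- list()
  addb <- function(i, j, r0) {
    ok <- !is.na(i) & !is.na(j)
    if (any(ok)) bonds[[length(bonds) + 1L]] <<- cbind(i[ok], j[ok], r0[ok])
  }
  adda <- function(i, j, k, t0) {
    ok <- !is.na(i) & !is.na(j) & !is.na(k)
    if (any(ok)) angles[[length(angles) + 1L]] <<- cbind(i[ok], j[ok], k[ok], t0[ok])
  }

  Ns <- gi(rkey, "N"); CAs <- gi(rkey, "CA"); Cs <- gi(rkey, "C"); Os <- gi(rkey, "O")
  addb(Ns, CAs, rep(BB_GEOM$n_ca, length(Ns)))
  addb(CAs, Cs, rep(BB_GEOM$ca_c, length(Ns)))
  addb(Cs, Os, rep(BB_GEOM$c_o, length(Ns)))
  adda(Ns, CAs, Cs, rep(BB_GEOM$ang_n_ca_c, length(Ns)))
  adda(CAs, Cs, Os, rep(BB_GEOM$ang_ca_c_o, length(Ns)))

  # inter-residue terms along each chain
  xyz <- cx_coords(cx)
  for (r in seq_len(nrow(rt) - 1L)) {
    if (rt$chain[r] != rt$chain[r + 1L]) next
    ci <- Cs[r]; ni <- Ns[r + 1L]
    if (is.na(ci) || is.na(ni)) next
    if (vnorm(xyz[ci, ] - xyz[ni, ]) > 3.5) next
    addb(ci, ni, BB_GEOM$c_n)
    adda(CAs[r], ci, ni, BB_GEOM$ang_ca_c_n)
    adda(Os[r], ci, ni, 123.0)
    adda(ci, ni, CAs[r + 1L], BB_GEOM$ang_c_n_ca)
    if (!is.na(CAs[r]) && !is.na(CAs[r + 1L]))
      omegas[[length(omegas) + 1L]] <- c(CAs[r], ci, ni, CAs[r + 1L])
  }

  # side chains (tree bonds from the placement table + ring-closure bonds)
  ring_closures <- list(
    PHE = list(c("CZ", "CE2", 1.38)),
    TYR = list(c("CZ", "CE2", 1.38)),
    TRP = list(c("NE1", "CE2", 1.37), c("CZ3", "CH2", 1.40)),
    HIS = list(c("NE2", "CD2", 1.37)),
    PRO = list(c("CD", "N", 1.47)))
  for (r in seq_len(nrow(rt))) {
    sc <- SC_TOPO_BY_RES[[rt$resid[r]]]
    if (is.null(sc)) next
    k <- rkey[r]
    for (s in seq_len(nrow(sc))) {
      i <- gi(k, sc$r3[s]); j <- gi(k, sc$atom[s])
      addb(i, j, sc$bond[s])
      adda(gi(k, sc$r2[s]), i, j, sc$angle[s])
    }
    for (rc in ring_closures[[rt$resid[r]]])
      addb(gi(k, rc[1L]), gi(k, rc[2L]), as.numeric(rc[3L]))
    # CB attachment: the N-CA-CB angle comes from the placement table; the
    # C-CA-CB angle consistent with the L-configuration improper is 108.6
    adda(gi(k, "C"), gi(k, "CA"), gi(k, "CB"), 108.6)
  }

  bonds <- if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 3)
  angles <- if (length(angles)) do.call(rbind, angles) else matrix(0, 0, 4)
  omegas <- if (length(omegas)) do.call(rbind, omegas) else matrix(0, 0, 4)
  list(bonds = bonds, angles = angles, omegas = omegas)
}

# 1-2 and 1-3 exclusion pair keys from a bond list (i*n + j, i < j)
exclusion_keys <- function(bonds, n) {
  if (!nrow(bonds)) return(integer(0))
  adj <- split(c(bonds[, 2L], bonds[, 1L]), c(bonds[, 1L], bonds[, 2L]))
  keys <- c()
  pk <- function(i, j) { a <- pmin(i, j); b <- pmax(i, j); a * (n + 1) + b }
  keys <- pk(bonds[, 1L], bonds[, 2L])
  # 1-3: neighbours of neighbours
  for (b in names(adj)) {
    i <- as.integer(b)
    nb <- adj[[b]]
    if (length(nb) >= 2L) {
      cmb <- utils::combn(nb, 2L)
      keys <- c(keys, pk(cmb[1L, ], cmb[2L, ]))
    }
  }
  unique(keys)
}

# --- energy terms ------------------------------------------------------------

wrap180 <- function(x) ((x + 180) %% 360) - 180

# vectorised dihedral over index quads
dihedral_vec <- function(xyz, quads) {
  if (!nrow(quads)) return(numeric(0))
  a <- xyz[quads[, 1L], , drop = FALSE]; b <- xyz[quads[, 2L], , drop = FALSE]
  c3 <- xyz[quads[, 3L], , drop = FALSE]; d <- xyz[quads[, 4L], , drop = FALSE]
  b1 <- b - a; b2 <- c3 - b; b3 <- d - c3
  n1 <- cbind(b1[, 2L] * b2[, 3L] - b1[, 3L] * b2[, 2L],
              b1[, 3L] * b2[, 1L] - b1[, 1L] * b2[, 3L],
              b1[, 1L] * b2[, 2L] - b1[, 2L] * b2[, 1L])
  n2 <- cbind(b2[, 2L] * b3[, 3L] - b2[, 3L] * b3[, 2L],
              b2[, 3L] * b3[, 1L] - b2[, 1L] * b3[, 3L],
              b2[, 1L] * b3[, 2L] - b2[, 2L] * b3[, 1L])
  b2n <- sqrt(rowSums(b2^2))
  m1 <- cbind(n1[, 2L] * b2[, 3L] - n1[, 3L] * b2[, 2L],
              n1[, 3L] * b2[, 1L] - n1[, 1L] * b2[, 3L],
              n1[, 1L] * b2[, 2L] - n1[, 2L] * b2[, 1L]) / b2n
  rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2)))
}

# Build the nonbonded pair list between `rows_a` and `rows_b` (or within
# rows_a when rows_b NULL), excluding bonded (1-2, 1-3) pairs and pairs
# within the same residue (those are governed by the bonded terms).
nb_pairs <- function(cx, rows_a, rows_b = NULL, cutoff = 8, excl = NULL) {
  xyz <- cx_coords(cx)
  n <- nrow(xyz)
  if (is.null(rows_b)) {
    d2 <- dist2_mat(xyz[rows_a, , drop = FALSE], xyz[rows_a, , drop = FALSE])
    hit <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
    i <- rows_a[hit[, 1L]]; j <- rows_a[hit[, 2L]]
  } else {
    d2 <- dist2_mat(xyz[rows_a, , drop = FALSE], xyz[rows_b, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    i <- rows_a[hit[, 1L]]; j <- rows_b[hit[, 2L]]
  }
  if (length(i)) {
    key <- atom_keys(cx)
    keep <- key[i] != key[j]
    i <- i[keep]; j <- j[keep]
  }
  if (!is.null(excl) && length(i)) {
    pk <- pmin(i, j) * (n + 1) + pmax(i, j)
    keep <- !(pk %in% excl)
    i <- i[keep]; j <- j[keep]
  }
  cbind(i, j)
}

# --- objective assembly ------------------------------------------------------

# Builds an objective (energy + analytic gradient) over the free atoms.
# `mode` selects the nonbonded model: "soft" (regularisation) or "full"
# (LJ + screened Coulomb + HB well, used for loop minimisation).
make_objective <- function(cx, free, mode = c("soft", "full"),
                           bb_restraint = 0, sc_restraint = 0,
                           restraint_atoms = c("N", "CA", "C", "O"),
                           pair_cutoff = 7) {
  mode <- match.arg(mode)
  at <- cx$atoms
  n <- nrow(at)
  xyz0 <- cx_coords(cx)
  topo <- bonded_topology(cx)
  excl <- exclusion_keys(topo$bonds, n)

  freemask <- rep(FALSE, n); freemask[free] <- TRUE
  # terms touching at least one free atom
  tb <- topo$bonds[rowSums(matrix(freemask[topo$bonds[, 1:2]], ncol = 2)) > 0, , drop = FALSE]
  ta <- topo$angles[rowSums(matrix(freemask[topo$angles[, 1:3]], ncol = 3)) > 0, , drop = FALSE]
  to <- topo$omegas[rowSums(matrix(freemask[topo$omegas[, 1:4]], ncol = 4)) > 0, , drop = FALSE]
  om_target <- if (nrow(to)) {
    now <- dihedral_vec(xyz0, to)
    ifelse(abs(now) < 90, 0, 180)
  } else numeric(0)

  # nonbonded candidates: free-free and free-(nearby fixed)
  env <- setdiff(which(!freemask), free)
  near_env <- env[sqrt(apply(dist2_mat(xyz0[env, , drop = FALSE],
                                       xyz0[free, , drop = FALSE]), 1L, min)) <= pair_cutoff + 3]
  pr <- rbind(nb_pairs(cx, free, cutoff = pair_cutoff, excl = excl),
              nb_pairs(cx, free, near_env, cutoff = pair_cutoff, excl = excl))
  radsum <- vdw_radius(at$elem[pr[, 1L]]) + vdw_radius(at$elem[pr[, 2L]])
  qq <- atom_charge(at$resid, at$elety)
  qprod <- qq[pr[, 1L]] * qq[pr[, 2L]]
  role <- hb_role(at$resid, at$elety)
  hb_pair <- (role[pr[, 1L]] %in% c("donor", "both") & role[pr[, 2L]] %in% c("acceptor", "both")) |
    (role[pr[, 2L]] %in% c("donor", "both") & role[pr[, 1L]] %in% c("acceptor", "both"))

  restr <- free[at$elety[free] %in% restraint_atoms]
  restr_k <- rep(bb_restraint, length(restr))
  if (sc_restraint > 0) {
    sc <- setdiff(free, restr)
    restr <- c(restr, sc); restr_k <- c(restr_k, rep(sc_restraint, length(sc)))
  }
  restr_x0 <- xyz0[restr, , drop = FALSE]

  nfree <- length(free)
  fidx <- match(seq_len(n), free)          # atom -> free slot or NA

  eval_all <- function(par) {
    xyz <- xyz0
    xyz[free, ] <- matrix(par, ncol = 3L, byrow = FALSE)
    E <- 0
    G <- matrix(0, nfree, 3L)
    addg <- function(rows, g) {
      s <- fidx[rows]
      ok <- !is.na(s)
      if (any(ok)) {
        t <- rowsum(g[ok, , drop = FALSE], s[ok])
        ii <- as.integer(rownames(t))
        G[ii, ] <<- G[ii, ] + t
      }
    }
    # bonds
    if (nrow(tb)) {
      dvec <- xyz[tb[, 1L], , drop = FALSE] - xyz[tb[, 2L], , drop = FALSE]
      d <- sqrt(rowSums(dvec^2))
      dd <- d - tb[, 3L]
      E <- E + FF$k_bond * sum(dd^2)
      gmag <- 2 * FF$k_bond * dd / pmax(d, 1e-8)
      g1 <- dvec * gmag
      addg(tb[, 1L], g1); addg(tb[, 2L], -g1)
    }
    # angles
    if (nrow(ta)) {
      u <- xyz[ta[, 1L], , drop = FALSE] - xyz[ta[, 2L], , drop = FALSE]
      v <- xyz[ta[, 3L], , drop = FALSE] - xyz[ta[, 2L], , drop = FALSE]
      nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
      uh <- u / nu; vh <- v / nv
      ct <- pmin(1 - 1e-10, pmax(-1 + 1e-10, rowSums(uh * vh)))
      th <- acos(ct)
      st <- sqrt(1 - ct^2)
      dth <- th - deg2rad(ta[, 4L])
      E <- E + FF$k_angle * sum(dth^2)
      pref <- 2 * FF$k_angle * dth
      gi <- (uh * ct - vh) / (nu * st) * pref
      gk <- (vh * ct - uh) / (nv * st) * pref
      addg(ta[, 1L], gi); addg(ta[, 3L], gk); addg(ta[, 2L], -(gi + gk))
    }
    # omega planarity
    if (nrow(to)) {
      a <- xyz[to[, 1L], , drop = FALSE]; b <- xyz[to[, 2L], , drop = FALSE]
      c3 <- xyz[to[, 3L], , drop = FALSE]; d4 <- xyz[to[, 4L], , drop = FALSE]
      b1 <- b - a; b2 <- c3 - b; b3 <- d4 - c3
      n1 <- rowcross(b1, b2); n2 <- rowcross(b2, b3)
      b2n <- sqrt(rowSums(b2^2))
      phi <- { m1 <- rowcross(n1, b2 / b2n); rad2deg(atan2(rowSums(m1 * n2), rowSums(n1 * n2))) }
      dphi <- deg2rad(wrap180(phi - om_target))
      E <- E + FF$k_omega * sum(dphi^2)
      pref <- 2 * FF$k_omega * dphi
      n1sq <- rowSums(n1^2); n2sq <- rowSums(n2^2)
      ga <- n1 * (b2n / pmax(n1sq, 1e-10))
      gd <- -n2 * (b2n / pmax(n2sq, 1e-10))
      c1 <- rowSums(b1 * b2) / pmax(b2n^2, 1e-10)
      c2 <- rowSums(b3 * b2) / pmax(b2n^2, 1e-10)
      gb <- -(1 + c1) * ga + c2 * gd
      gc <- c1 * ga - (1 + c2) * gd
      addg(to[, 1L], ga * pref); addg(to[, 2L], gb * pref)
      addg(to[, 3L], gc * pref); addg(to[, 4L], gd * pref)
    }
    # nonbonded
    if (nrow(pr)) {
      dvec <- xyz[pr[, 1L], , drop = FALSE] - xyz[pr[, 2L], , drop = FALSE]
      d <- sqrt(rowSums(dvec^2))
      d <- pmax(d, 0.3)
      if (mode == "soft") {
        r0 <- FF$soft_scale * radsum
        ov <- pmax(0, r0 - d)
        E <- E + FF$k_soft * sum(ov^2)
        gmag <- ifelse(ov > 0, -2 * FF$k_soft * ov / d, 0)
        g1 <- dvec * gmag
        addg(pr[, 1L], g1); addg(pr[, 2L], -g1)
      } else {
        rm <- FF$lj_scale * radsum
        x6 <- (rm / d)^6
        E <- E + FF$lj_eps * sum(x6^2 - 2 * x6)
        gmag_lj <- FF$lj_eps * (-12 * x6^2 + 12 * x6) / d
        Ec <- FF$coul_const * qprod / (FF$diel_slope * d^2)
        E <- E + sum(Ec)
        gmag_c <- -2 * Ec / d
        g_hb <- numeric(length(d))
        if (any(hb_pair)) {
          z <- (d - FF$hb_d0) / FF$hb_sigma
          well <- exp(-0.5 * z^2) * hb_pair
          E <- E - FF$hb_depth * sum(well)
          g_hb <- FF$hb_depth * well * z / FF$hb_sigma
        }
        gmag <- (gmag_lj + gmag_c + g_hb) / d
        g1 <- dvec * gmag
        addg(pr[, 1L], g1); addg(pr[, 2L], -g1)
      }
    }
    # positional restraints
    if (length(restr) && any(restr_k > 0)) {
      dvec <- xyz[restr, , drop = FALSE] - restr_x0
      E <- E + sum(restr_k * rowSums(dvec^2))
      addg(restr, dvec * (2 * restr_k))
    }
    list(value = E, grad = as.numeric(G))
  }

  cache <- new.env(parent = emptyenv())
  fn <- function(par) {
    r <- eval_all(par)
    cache$par <- par; cache$grad <- r$grad
    r$value
  }
  gr <- function(par) {
    if (!is.null(cache$par) && identical(cache$par, par)) return(cache$grad)
    eval_all(par)$grad
  }
  list(fn = fn, gr = gr, x0 = as.numeric(xyz0[free, , drop = FALSE]),
       free = free)
}

rowcross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

# minimise the free atoms of a complex; returns the updated complex
minimize_cartesian <- function(cx, free, mode = "soft", bb_restraint = 0,
                               sc_restraint = 0, maxit = 500L,
                               pair_cutoff = 7) {
  if (!length(free)) return(cx)
  obj <- make_objective(cx, free, mode = mode, bb_restraint = bb_restraint,
                        sc_restraint = sc_restraint, pair_cutoff = pair_cutoff)
  opt <- stats::optim(obj$x0, fn = obj$fn, gr = obj$gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, pgtol = 0.1, factr = 1e7))
  xyz <- matrix(opt$par, ncol = 3L)
  cx <- set_cx_coords(cx, free, xyz)
  attr(cx, "min_value") <- opt$value
  cx
}
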