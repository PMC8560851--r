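test_that("self-graft reproduces the parental graft region", {
  cx <- toy_complex()
  g <- toy_self_graft()
  expect_lt(g$anchor_rmsd, 1e-9)
  labs <- c("90", "91", "92", cx$h3_map, "103", "104", "105")
  old <- cx$atoms[h3graft:::atom_rows(cx, "H", labs), ]
  new <- g$complex$atoms[h3graft:::atom_rows(g$complex, "H", labs), ]
  m <- merge(old, new, by = c("resno", "insert", "elety"))
  expect_equal(nrow(m), nrow(old))
  expect_lt(max(abs(cbind(m$x.x - m$x.y, m$y.x - m$y.y, m$z.x - m$z.y))),
            1e-3)
})

test_that("grafting a longer template changes only the graft region", {
  cx <- toy_complex()
  lib <- toy_stem_library()
  t16 <- Filter(function(t) t$h3_length == 16 && t$cluster_id == "C1", lib)[[1]]
  g <- graft_stem(cx, t16, "ARGGAVAGTGVYYFDY")
  expect_equal(h3_length(g$complex), 16L)
  expect_equal(h3_sequence(g$complex), "ARGGAVAGTGVYYFDY")
  # antigen and remote framework untouched bitwise
  for (sel in list(c("A", "5"), c("H", "85"), c("L", "10"), c("H", "110"))) {
    o <- cx$atoms[h3graft:::atom_rows(cx, sel[1], sel[2]),
                  c("x", "y", "z", "elety")]
    n <- g$complex$atoms[h3graft:::atom_rows(g$complex, sel[1], sel[2]),
                         c("x", "y", "z", "elety")]
    rownames(o) <- rownames(n) <- NULL
    expect_identical(o, n)
  }
  # graft geometry is chemically sane after regularisation
  labs <- c("92", g$complex$h3_map, "103")
  for (j in seq_len(length(labs) - 1L)) {
    b1 <- h3graft:::residue_backbone(g$complex, "H", labs[j])
    b2 <- h3graft:::residue_backbone(g$complex, "H", labs[j + 1L])
    expect_lt(abs(h3graft:::vnorm(b1$C - b2$N) - 1.33), 0.06)
  }
  expect_error(graft_stem(cx, t16, "SHORTSEQ"), "does not match")
})

test_that("anchor fit beats random rigid placements", {
  cx <- toy_complex()
  lib <- toy_stem_library()
  t12 <- Filter(function(t) t$h3_length == 12 && t$cluster_id == "C2", lib)[[1]]
  g <- graft_stem(cx, t12, "ARGRKYSSSFDY", regularize_after = FALSE)
  anchor_labs <- c("90", "91", "92", "103", "104", "105")
  panch <- t(vapply(anchor_labs, function(l)
    h3graft:::residue_backbone(cx, "H", l)$CA, numeric(3)))
  tanch <- t(vapply(anchor_labs, function(l) {
    i <- which(t12$atoms$label == l & t12$atoms$elety == "CA")
    as.numeric(t12$atoms[i, c("x", "y", "z")])
  }, numeric(3)))
  set.seed(99)
  for (k in 1:100) {
    ax <- h3graft:::vunit(rnorm(3)); th <- runif(1, -pi, pi)
    K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    moved <- sweep(tanch %*% t(R), 2, rnorm(3, sd = 2), "+")
    moved <- sweep(moved, 2, colMeans(moved) - colMeans(panch), "-")
    alt <- sqrt(mean(rowSums((moved - panch)^2)))
    expect_gte(alt, g$anchor_rmsd - 1e-9)
  }
})

test_that("side-chain placement is clash-minimal over the rotamer set", {
  cx <- toy_complex()
  # glycine keeps no side chain, alanine exactly one CB
  g <- graft_stem(cx, toy_self_template(), "SRWGGDGFYAGDA",
                  regularize_after = FALSE)
  at <- g$complex$atoms
  gly <- h3graft:::atom_rows(g$complex, "H", g$complex$h3_map[11])
  expect_equal(sort(at$elety[gly]), sort(c("N", "CA", "C", "O")))
  ala <- h3graft:::atom_rows(g$complex, "H", g$complex$h3_map[13])
  expect_equal(sort(at$elety[ala]), sort(c("N", "CA", "C", "O", "CB")))
  # leucine in open space: chosen rotamer has zero clashes and exhaustive
  # enumeration finds no rotamer with fewer
  g2 <- graft_stem(cx, toy_self_template(), "SRWGGDGLYAMDY",
                   regularize_after = FALSE)
  cx2 <- g2$complex
  lab <- cx2$h3_map[8]
  rows <- h3graft:::atom_rows(cx2, "H", lab)
  stopifnot(cx2$atoms$resid[rows][1] == "LEU")
  other <- setdiff(seq_len(nrow(cx2$atoms)), rows)
  oxyz <- h3graft:::cx_coords(cx2, other)
  orad <- h3graft:::vdw_radius(cx2$atoms$elem[other])
  count_cl <- function(sc) {
    rad <- h3graft:::vdw_radius(h3graft:::element_of(rownames(sc)))
    d <- sqrt(h3graft:::dist2_mat(sc, oxyz))
    sum(d < 0.6 * outer(rad, orad, "+"))
  }
  bb <- h3graft:::residue_backbone(cx2, "H", lab)
  placed_cl <- {
    sc_rows <- rows[!cx2$atoms$elety[rows] %in% c("N", "CA", "C", "O")]
    sc <- h3graft:::cx_coords(cx2, sc_rows)
    rownames(sc) <- cx2$atoms$elety[sc_rows]
    count_cl(sc)
  }
  all_cl <- apply(h3graft:::ROTAMERS$LEU, 1, function(chi)
    count_cl(h3graft:::build_sidechain("LEU", bb, chi)))
  expect_equal(placed_cl, min(all_cl))
  expect_error(place_side_chains(cx, data.frame(chain = "H", label = "999")),
               "not found")
})

test_that("regularisation restores bonded geometry without touching the environment", {
  g <- toy_self_graft()
  cx <- g$complex
  region <- data.frame(chain = "H", label = c("90", "91", "92", cx$h3_map,
                                              "103", "104", "105"))
  # stretch one peptide bond to 1.8 A by displacing a residue's N
  lab <- cx$h3_map[5]
  prevlab <- cx$h3_map[4]
  bbp <- h3graft:::residue_backbone(cx, "H", prevlab)
  rows <- h3graft:::atom_rows(cx, "H", lab)
  ni <- rows[cx$atoms$elety[rows] == "N"]
  nvec <- as.numeric(cx$atoms[ni, c("x", "y", "z")])
  dirv <- h3graft:::vunit(nvec - bbp$C)
  cx$atoms[ni, c("x", "y", "z")] <- bbp$C + 1.8 * dirv
  fixed_before <- cx$atoms[h3graft:::atom_rows(cx, "A", as.character(1:24)),
                           c("x", "y", "z")]
  cx2 <- regularize_region(cx, region)
  b1 <- h3graft:::residue_backbone(cx2, "H", prevlab)
  b2 <- h3graft:::residue_backbone(cx2, "H", lab)
  expect_lt(abs(h3graft:::vnorm(b1$C - b2$N) - 1.33), 0.05)
  # environment exactly fixed
  fixed_after <- cx2$atoms[h3graft:::atom_rows(cx2, "A", as.character(1:24)),
                           c("x", "y", "z")]
  expect_identical(fixed_before, fixed_after)
  # stationarity: an ideal, clash-free loop barely moves under regularisation
  labs <- as.character(88:106)
  atoms <- h3graft:::build_peptide_atoms("H", labs,
                                         paste(rep("A", 19), collapse = ""),
                                         rep(-57, 19), rep(-47, 19))
  ann <- data.frame(chain = "H", res_label = labs, region = "FR")
  ann$region[labs %in% as.character(93:102)] <- "H3"
  mini <- abcomplex(atoms, ann)
  reg2 <- regularize_region(mini, data.frame(chain = "H",
                                             label = as.character(93:102)))
  dev <- max(abs(h3graft:::cx_coords(reg2) - h3graft:::cx_coords(mini)))
  expect_lt(dev, 0.01)
})
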