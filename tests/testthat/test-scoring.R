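test_that("Boltzmann averaging obeys its limits and invariances", {
  expect_equal(boltzmann_average(5, -3, kT = 1), 5)
  expect_equal(boltzmann_average(c(-10, -20), c(-4, -4), kT = 1), -15)
  v <- c(2, 7, -1, 4); e <- c(-3, -9, -5, -2)
  # kT -> 0 selects the minimum-energy value; kT -> Inf the plain mean
  expect_equal(boltzmann_average(v, e, kT = 1e-6), v[which.min(e)])
  expect_equal(boltzmann_average(v, e, kT = 1e6), mean(v), tolerance = 1e-4)
  # invariance under shifting all weight energies
  expect_equal(boltzmann_average(v, e, kT = 0.7),
               boltzmann_average(v, e + 123.4, kT = 0.7), tolerance = 1e-12)
  # hand-computed two-conformer oracle
  w <- exp(-(c(-6, -4) - (-6)) / 2)
  expect_equal(boltzmann_average(c(1, 3), c(-6, -4), kT = 2),
               sum(c(1, 3) * w) / sum(w), tolerance = 1e-12)
  expect_error(boltzmann_average(numeric(0), numeric(0)), "empty")
  # result bounded by the value range
  set.seed(5)
  for (k in 1:20) {
    vv <- rnorm(6); ee <- rnorm(6)
    ba <- boltzmann_average(vv, ee, kT = runif(1, 0.1, 10))
    expect_gte(ba, min(vv) - 1e-12)
    expect_lte(ba, max(vv) + 1e-12)
  }
})

test_that("total energy separates into intra-loop terms at infinite dilution", {
  cx <- toy_self_graft()$complex
  e0 <- total_energy(cx)
  expect_equal(total_energy(cx), e0)   # deterministic
  # move everything except the heavy chain far away
  far <- cx
  other <- which(far$atoms$chain != "H")
  far <- h3graft:::set_cx_coords(far, other,
                                 h3graft:::cx_coords(far, other) + 1000)
  # heavy chain alone
  alone_atoms <- cx$atoms[cx$atoms$chain == "H", ]
  ann <- cx$annotation[cx$annotation$chain == "H", ]
  alone <- abcomplex(alone_atoms, ann)
  expect_equal(total_energy(far), total_energy(alone), tolerance = 1e-9)
  # a forced heavy-atom overlap strictly increases the energy
  clash <- cx
  lr <- h3graft:::loop_rows_of(cx)
  reg <- h3graft:::atom_region(cx)
  ag <- which(!is.na(reg) & reg == "ANTIGEN")
  tgt <- h3graft:::cx_coords(cx, ag[1]) + c(1.5, 0, 0)
  clash <- h3graft:::set_cx_coords(clash, lr[1], matrix(tgt, 1))
  expect_gt(total_energy(clash), e0)
})

test_that("Shrake-Rupley area matches the two-sphere closed form", {
  # two unit-radius spheres, centre distance 2.4, probe 0: the accessible
  # area of each is 4*pi*r^2 minus the spherical cap 2*pi*r*h with
  # h = r - d/2 for equal radii
  r <- 1.7; d <- 2.4
  xyz <- rbind(c(0, 0, 0), c(d, 0, 0))
  a <- shrake_rupley(xyz, c(r, r), probe = 0, n_points = 2000L)
  h <- r - d / 2
  expected <- 4 * pi * r^2 - 2 * pi * r * h
  expect_equal(a[1], expected, tolerance = 0.02 * expected)
  expect_equal(a[2], expected, tolerance = 0.02 * expected)
  # isolated sphere: full area
  a1 <- shrake_rupley(matrix(0, 1, 3), 1.5, probe = 1.4, n_points = 500L)
  expect_equal(a1, 4 * pi * 2.9^2, tolerance = 1e-6)
})

test_that("interaction energy behaves at its limits and in its linearity", {
  cx <- toy_self_graft()$complex
  p <- sie_params()
  e <- interaction_energy(cx, p)
  expect_true(is.finite(e))
  # infinite separation: score equals the constant C
  far <- cx
  reg <- h3graft:::atom_region(cx)
  ag <- which(!is.na(reg) & reg == "ANTIGEN")
  far <- h3graft:::set_cx_coords(far, ag, h3graft:::cx_coords(far, ag) + 1e4)
  expect_equal(interaction_energy(far, p), p$C, tolerance = 1e-9)
  # linear in alpha about the constant
  p2 <- sie_params(alpha = 2 * p$alpha)
  expect_equal(interaction_energy(cx, p2) - p$C,
               2 * (e - p$C), tolerance = 1e-9)
  # symmetric under swapping which body is called the antigen (C = 0)
  swapped <- cx
  ann <- swapped$annotation
  is_ag <- ann$region == "ANTIGEN"
  ann$region[is_ag] <- "FR"
  ann$region[!is_ag & ann$region != "H3"] <- "ANTIGEN"
  # keep a valid H3 on the old antigen chain for the container invariants
  ann$region[ann$chain == "A" & ann$res_label %in% as.character(10:22)] <- "H3"
  ann$region[ann$chain == "H" & ann$region == "H3"] <- "ANTIGEN"
  swapped <- abcomplex(swapped$atoms, ann)
  p0 <- sie_params(C = 0)
  expect_equal(interaction_energy(swapped, p0), interaction_energy(cx, p0),
               tolerance = 1e-6)
  # missing antigen annotation
  ann2 <- cx$annotation[cx$annotation$region != "ANTIGEN", ]
  at2 <- cx$atoms[cx$atoms$chain != "A", ]
  expect_error(interaction_energy(abcomplex(at2, ann2)), "ANTIGEN")
})

test_that("ensemble scoring averages with total-energy weights", {
  ens <- minimize_ensemble(cull_ensemble(toy_ensemble(), 30L, 3L),
                           maxit = 40L)
  merged <- retain_per_stem(list(ens), keep = 3L)
  fin <- refine_ensemble(merged, 1L, 1L, window = 50, seed = 2L)
  rec <- score_ensemble(fin, kT = 1, prescore_maxit = 30L)
  expect_equal(rec$n_conformers, length(fin$conformers))
  expect_equal(rec$h3_length, 13L)
  tot <- vapply(fin$conformers, function(cf) cf$total_energy, 0)
  expect_equal(rec$avg_total, boltzmann_average(tot, tot, 1), tolerance = 1e-9)
  expect_gte(rec$avg_total, min(tot) - 1e-9)
  expect_lte(rec$avg_total, max(tot) + 1e-9)
  # single-conformer ensemble: averages equal that conformer's scores
  one <- fin; one$conformers <- fin$conformers[1]
  rec1 <- score_ensemble(one, kT = 1, prescore_maxit = 30L)
  expect_equal(rec1$avg_total, one$conformers[[1]]$total_energy)
  # permutation invariance
  perm <- fin; perm$conformers <- rev(fin$conformers)
  recp <- score_ensemble(perm, kT = 1, prescore_maxit = 30L)
  expect_equal(recp$avg_total, rec$avg_total, tolerance = 1e-9)
  expect_equal(recp$avg_interaction, rec$avg_interaction, tolerance = 1e-9)
  expect_error(score_ensemble(list(candidate_id = "x", conformers = list())),
               "empty")
})
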