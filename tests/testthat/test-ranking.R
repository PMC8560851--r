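mk_records <- function(score_tab) {
  data.frame(candidate_id = score_tab$id, h3_length = score_tab$length,
             avg_total = score_tab$total_energy,
             avg_interaction = score_tab$interaction_energy,
             n_conformers = 1L, stringsAsFactors = FALSE)
}

test_that("stratified Z centres each length stratum at zero", {
  st <- make_score_table(fixture_spec(seed = 9, library_size = 60))
  z <- stratified_z(mk_records(st))
  for (len in unique(z$h3_length)) {
    zt <- z$z_total[z$h3_length == len & z$scorable]
    if (!length(zt)) next
    expect_lt(abs(median(zt)), 1e-9)
    expect_lt(abs(median(z$z_interaction[z$h3_length == len & z$scorable])),
              1e-9)
  }
  expect_equal(z$z_composite, (z$z_total + z$z_interaction) / 2)
  # candidate whose scores sit at the stratum medians has composite zero
  rec <- mk_records(st)
  len0 <- rec$h3_length[1]
  idx <- rec$h3_length == len0
  rec$avg_total[which(idx)[1]] <- median(rec$avg_total[idx][-1])
  rec$avg_interaction[which(idx)[1]] <- median(rec$avg_interaction[idx][-1])
  # with an odd remaining count the first row equals the overall median
  z2 <- stratified_z(rec)
  if (sum(idx) %% 2 == 0)
    expect_lt(abs(z2$z_composite[1]), 0.8)  # at worst near the centre
})

test_that("stratified Z is invariant under per-stratum affine rescaling", {
  st <- make_score_table(fixture_spec(seed = 10, library_size = 40))
  rec <- mk_records(st)
  z1 <- stratified_z(rec)
  rec2 <- rec
  for (len in unique(rec2$h3_length)) {
    i <- rec2$h3_length == len
    a <- runif(1, 0.5, 3); b <- rnorm(1, sd = 10)
    rec2$avg_total[i] <- a * rec2$avg_total[i] + b
    rec2$avg_interaction[i] <- a * rec2$avg_interaction[i] + b
  }
  z2 <- stratified_z(rec2)
  expect_equal(z2$z_total, z1$z_total, tolerance = 1e-9)
  expect_equal(z2$z_interaction, z1$z_interaction, tolerance = 1e-9)
})

test_that("length stratification defeats the size bias of raw scores", {
  st <- make_score_table(fixture_spec(seed = 11, library_size = 120,
                                      length_bias_slope = 3, noise_sd = 1))
  rec <- mk_records(st)
  z <- stratified_z(rec)
  # global (single-stratum) Z: pretend all lengths are equal
  recg <- rec; recg$h3_length <- 1L
  zg <- stratified_z(recg)
  top10_global <- rec$h3_length[order(zg$z_composite)][1:10]
  top10_strat <- rec$h3_length[order(z$z_composite)][1:10]
  expect_true(all(top10_global >= sort(unique(rec$h3_length),
                                       decreasing = TRUE)[3]))
  expect_gte(length(unique(top10_strat)), 3L)
})

test_that("ranks are dense permutations and singleton strata are unscorable", {
  st <- make_score_table(fixture_spec(seed = 12, library_size = 30))
  rec <- mk_records(st)
  rec <- rbind(rec, data.frame(candidate_id = "solo", h3_length = 29L,
                               avg_total = -500, avg_interaction = -50,
                               n_conformers = 1L))
  z <- stratified_z(rec)
  expect_false(z$scorable[z$candidate_id == "solo"])
  expect_true(is.na(z$z_composite[z$candidate_id == "solo"]))
  ok <- z$scorable
  # dense ranks: consecutive integers from 1, one per distinct value (the
  # stratum medians tie at z = 0 across strata, sharing the smaller rank)
  expect_setequal(z$rank_composite[ok],
                  seq_len(length(unique(z$z_composite[ok]))))
  expect_setequal(z$rank_total, seq_len(length(unique(rec$avg_total))))
  # the unscorable candidate never enters the cutoff set
  expect_false("solo" %in% apply_cutoff(z, cutoff = 100))
})

test_that("the -1.5 cutoff admits the published design Z-scores", {
  ref <- bh1_reference_designs()
  designs <- ref[!ref$id %in% c("parent", "minH3"), ]
  z <- data.frame(candidate_id = designs$id, h3_length = designs$h3_length,
                  z_total = designs$z_score, z_interaction = designs$z_score,
                  z_composite = designs$z_score, scorable = TRUE)
  expect_equal(length(apply_cutoff(z, -1.5)), 16L)
  # boundary: exactly -1.5 passes
  zb <- data.frame(candidate_id = "b", h3_length = 10L, z_total = -1.5,
                   z_interaction = -1.5, z_composite = -1.5, scorable = TRUE)
  expect_equal(apply_cutoff(zb, -1.5), "b")
  expect_equal(apply_cutoff(zb[0, ], -1.5), character(0))
})

test_that("the Ramachandran check accepts regular structure, flags outliers", {
  cx <- toy_complex()
  rc <- ramachandran_check(cx)
  expect_true(rc$pass)
  # classification sanity: canonical helix favoured, (0, 0) disallowed
  expect_equal(rama_classify(-57, -47, "ALA"), "core")
  expect_equal(rama_classify(0, 0, "ALA"), "disallowed")
  expect_false(rama_classify(0, 0, "GLY") == "core")
  # a purpose-built helical mini-chain passes; forcing one loop residue to
  # (0, 0) fails and names the offender
  mk_mini <- function(bad = FALSE) {
    labs <- as.character(88:106)
    phi <- rep(-57, 19); psi <- rep(-47, 19)
    if (bad) { phi[10] <- 0; psi[10] <- 0 }   # residue 97
    atoms <- h3graft:::build_peptide_atoms("H", labs,
                                           paste(rep("A", 19), collapse = ""),
                                           phi, psi)
    ann <- data.frame(chain = "H", res_label = labs, region = "FR")
    ann$region[labs %in% as.character(93:102)] <- "H3"
    abcomplex(atoms, ann)
  }
  expect_true(ramachandran_check(mk_mini(FALSE))$pass)
  rcb <- ramachandran_check(mk_mini(TRUE))
  expect_false(rcb$pass)
  expect_true("97" %in% rcb$offenders$label)
})

test_that("the hydrogen-bond screen is anchored at the parent", {
  cx <- toy_complex()
  hb <- hb_screen(cx, cx)
  expect_true(hb$pass)
  expect_equal(hb$hb_energy, hb$parent_hb_energy)
  expect_equal(hb$hb_flaw, hb$parent_hb_flaw)
  # pulling the antigen away zeroes the intermolecular HB energy
  far <- cx
  reg <- h3graft:::atom_region(cx)
  ag <- which(!is.na(reg) & reg == "ANTIGEN")
  far <- h3graft:::set_cx_coords(far, ag, h3graft:::cx_coords(far, ag) + 1e3)
  hf <- h3graft:::hb_terms(far)
  expect_equal(hf$hb_energy, 0)
  # one-sided rule: a candidate better than parent passes regardless
  hb2 <- hb_screen(cx, far, tolerance = 1)
  expect_lte(hb2$hb_energy, hb2$parent_hb_energy + 1)
  # rule arithmetic: worse by more than the tolerance fails
  if (h3graft:::hb_terms(cx)$hb_energy < -1) {
    hb3 <- hb_screen(far, cx, tolerance = 1)
    expect_false(hb3$pass)
  }
})

test_that("curation checks codify the inspection rules", {
  cx <- toy_complex()
  cu <- curation_checks(cx, cx)
  expect_true(cu$pass)
  expect_equal(cu$shared_fraction, 1)
  # H3 translated away from the epitope fails the shared-contact rule
  off <- cx
  lr <- h3graft:::loop_rows_of(cx)
  off <- h3graft:::set_cx_coords(off, lr, sweep(h3graft:::cx_coords(off, lr), 2, c(100, 100, 100), '+'))
  cuo <- curation_checks(off, cx)
  expect_false(cuo$pass_epitope)
  expect_equal(cuo$shared_fraction, 0)
  # salt-bridge rule: parent with a 3.0 A Arg-Asp pair; candidate broken
  mkpair <- function(dist) {
    cc <- cx
    argrows <- h3graft:::atom_rows(cc, "H", cc$h3_map[2])
    asprows <- h3graft:::atom_rows(cc, "H", cc$h3_map[12])
    nh1 <- argrows[cc$atoms$elety[argrows] == "NH1"]
    od1 <- asprows[cc$atoms$elety[asprows] == "OD1"]
    od <- h3graft:::cx_coords(cc, od1)
    cc <- h3graft:::set_cx_coords(cc, nh1, od + c(dist, 0, 0))
    cc
  }
  close_parent <- mkpair(3.0)
  expect_equal(h3graft:::stem_saltbridge_dist(close_parent), 3.0,
               tolerance = 1e-9)
  cu_ok <- curation_checks(mkpair(3.5), close_parent)
  expect_true(cu_ok$pass_saltbridge)
  cu_bad <- curation_checks(mkpair(6.0), close_parent)
  expect_false(cu_bad$pass_saltbridge)
})

test_that("the selection cascade composes the filters in order", {
  cx <- toy_complex()
  z <- data.frame(candidate_id = c("good", "badz"),
                  h3_length = c(13L, 13L),
                  z_total = c(-2, 1), z_interaction = c(-2, 1),
                  z_composite = c(-2, 1),
                  rank_total = 1:2, rank_interaction = 1:2,
                  rank_composite = 1:2, scorable = TRUE)
  rep <- select_candidates(z, list(good = cx), cx, cutoff = -1.5)
  expect_equal(rep$candidate_id, c("good", "badz"))  # ordered by Z
  expect_true(rep$selected[rep$candidate_id == "good"])
  expect_false(rep$selected[rep$candidate_id == "badz"])
  expect_match(rep$reasons[rep$candidate_id == "badz"], "cutoff")
  # permissive thresholds reduce selection to the cutoff set
  rep2 <- select_candidates(z, list(good = cx), cx, cutoff = 100,
                            hb_tolerance = 1e6, shared_threshold = 0)
  expect_true(all(rep2$passed_z))
  # planted decoy with a destroyed epitope is removed with a reason
  off <- cx
  lr <- h3graft:::loop_rows_of(cx)
  off <- h3graft:::set_cx_coords(off, lr, sweep(h3graft:::cx_coords(off, lr), 2, c(100, 100, 100), '+'))
  z3 <- z[1, ]; z3$candidate_id <- "decoy"
  rep3 <- select_candidates(z3, list(decoy = off), cx, cutoff = -1.5)
  expect_false(rep3$selected)
  expect_match(rep3$reasons, "epitope")
})
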