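test_that("tip windows follow the length rules", {
  expect_error(tip_window(5), "at least 6")
  expect_equal(tip_window(6)[c("start", "end")], list(start = 1L, end = 6L))
  expect_true(tip_window(7)$empty)
  expect_equal(tip_window(8)[c("start", "end")], list(start = 2L, end = 6L))
  expect_equal(tip_window(9)[c("start", "end")], list(start = 3L, end = 7L))
  expect_equal(tip_window(13)[c("start", "end")], list(start = 3L, end = 10L))
  expect_equal(tip_window(16)[c("start", "end")], list(start = 3L, end = 13L))
  # minimum 5-residue search for loops of 8+
  for (L in 8:16) {
    tw <- tip_window(L)
    expect_gte(tw$end - tw$start + 1L, 5L)
  }
})

test_that("tip sampling produces closed, deterministic, clash-checked ensembles", {
  ens <- toy_ensemble(n = 30L, seed = 7L)
  expect_equal(length(ens$conformers), 30L)
  gaps <- vapply(ens$conformers, function(cf) cf$closure_gap, 0)
  expect_true(all(gaps <= 0.5))
  ens2 <- sample_tip(toy_self_graft(), n_samples = 30L, seed = 7L,
                     candidate_id = "parent")
  expect_equal(ens2$conformers[[13]]$xyz, ens$conformers[[13]]$xyz)
  ens3 <- sample_tip(toy_self_graft(), n_samples = 10L, seed = 8L)
  expect_gt(max(abs(ens3$conformers[[1]]$xyz - ens$conformers[[1]]$xyz)), 1e-6)
  # omega angles stay trans over the sampled loop (the C-side junction to
  # the fixed anchor absorbs the closure gap and is repaired on
  # minimisation, so it is checked after minimize_loop instead)
  cxi <- instantiate_conformer(ens3, 1L)
  dh <- h3graft:::loop_dihedrals(cxi)
  tw <- tip_window(h3_length(cxi))
  om <- dh$omega[(tw$start + 1L):(tw$end + 1L)]  # rebuilt residues
  expect_true(all(abs(abs(om[!is.na(om)]) - 180) < 30))
})

test_that("a 7-residue loop passes through as its grafted conformation", {
  cx <- toy_complex()
  lib <- toy_stem_library()
  t7 <- Filter(function(t) t$h3_length == 7 && t$cluster_id == "C1", lib)[[1]]
  g <- graft_stem(cx, t7, "SRWGMDY")
  ens <- sample_tip(g, n_samples = 100L, seed = 1L, candidate_id = "minH3")
  expect_equal(length(ens$conformers), 1L)
  expect_equal(ens$conformers[[1]]$xyz,
               h3graft:::cx_coords(g$complex, h3graft:::loop_rows_of(g$complex)))
})

test_that("the statistical potential matches a brute-force oracle and the cutoff", {
  ens <- toy_ensemble()
  cxi <- instantiate_conformer(ens, 2L)
  fast <- stat_potential(cxi)
  # brute force: scalar double loop over all pairs with the same binning
  tab <- h3graft:::statpot_table()
  at <- cxi$atoms
  xyz <- h3graft:::cx_coords(cxi)
  reg <- h3graft:::atom_region(cxi)
  loop <- which(!is.na(reg) & reg == "H3")
  cls <- match(h3graft:::statpot_class_of(at$elem), h3graft:::statpot_classes)
  rk <- h3graft:::atom_keys(cxi)
  ri <- match(rk, unique(rk))
  slow <- 0
  for (i in loop) for (j in seq_len(nrow(at))) {
    if (j %in% loop && j <= i) next
    if (abs(ri[i] - ri[j]) <= 1) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > 8) next
    b <- min(16L, floor(d / 0.5) + 1L)
    slow <- slow + tab[cls[i], cls[j], b]
  }
  expect_equal(fast, slow, tolerance = 1e-9)
  # identical conformation, identical energy
  expect_identical(stat_potential(cxi), stat_potential(cxi))
  # loop far from everything: environment term exactly zero
  cxfar <- cxi
  lr <- h3graft:::loop_rows_of(cxi)
  cxfar <- h3graft:::set_cx_coords(cxfar, lr,
                                   h3graft:::cx_coords(cxi, lr) + 500)
  loop_only <- 0
  for (ii in seq_along(loop)) for (jj in seq_along(loop)) {
    i <- loop[ii]; j <- loop[jj]
    if (j <= i || abs(ri[i] - ri[j]) <= 1) next
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > 8) next
    b <- min(16L, floor(d / 0.5) + 1L)
    loop_only <- loop_only + tab[cls[i], cls[j], b]
  }
  expect_equal(stat_potential(cxfar), loop_only, tolerance = 1e-9)
})

test_that("contact counting is exact, symmetric and monotone in the cutoff", {
  expect_equal(contact_count(matrix(c(0, 0, 0), 1), matrix(c(4.4, 0, 0), 1)), 1L)
  expect_equal(contact_count(matrix(c(0, 0, 0), 1), matrix(c(4.6, 0, 0), 1)), 0L)
  expect_equal(contact_count(matrix(c(0, 0, 0), 1),
                             matrix(numeric(0), ncol = 3)), 0L)
  set.seed(12)
  x <- matrix(rnorm(150, sd = 4), ncol = 3)
  y <- matrix(rnorm(90, sd = 4), ncol = 3)
  expect_equal(contact_count(x, y, 4.5), brute_contacts(x, y, 4.5))
  expect_equal(contact_count(x, y, 4.5), contact_count(y, x, 4.5))
  for (cut in c(2, 4, 6, 8))
    expect_gte(contact_count(x, y, cut + 1), contact_count(x, y, cut))
})

test_that("culling keeps the lowest-scoring conformers of the rescored head", {
  ens <- toy_ensemble()
  culled <- cull_ensemble(ens, keep_rescore = 30L, keep_top = 10L)
  expect_equal(culled$stage, "culled")
  expect_equal(length(culled$conformers), 10L)
  # sort oracle: retained energies are the 10 smallest of the rescored head
  full <- cull_ensemble(ens, keep_rescore = 30L, keep_top = 30L)
  all_e <- sort(vapply(full$conformers, function(cf) cf$stat_energy, 0))
  kept_e <- sort(vapply(culled$conformers, function(cf) cf$stat_energy, 0))
  expect_equal(kept_e, all_e[1:10], tolerance = 1e-12)
  expect_warning(cull_ensemble(ens, keep_rescore = 30L, keep_top = 50L),
                 "keeping all")
  expect_error(cull_ensemble(culled, 10, 5), "initial")
})

test_that("the contact filter thresholds at the reference median", {
  ens <- toy_ensemble()
  mk <- function(counts) {
    e <- cull_ensemble(toy_ensemble(), keep_rescore = 30L,
                       keep_top = length(counts))
    for (i in seq_along(counts)) e$conformers[[i]]$contact_count <- counts[i]
    e$conformers <- e$conformers[seq_along(counts)]
    e
  }
  ref <- mk(c(2L, 4L, 6L, 8L, 10L))
  cand <- mk(c(5L, 6L, 7L))
  out <- contact_filter(cand, ref)
  expect_equal(attr(out, "contact_threshold"), 6)
  expect_equal(vapply(out$conformers, function(cf) cf$contact_count, 0L),
               c(6L, 7L))
  # median zero keeps everything
  ref0 <- mk(c(0L, 0L, 0L, 10L, 10L))
  cand0 <- mk(c(0L, 1L, 2L))
  out0 <- contact_filter(cand0, ref0)
  expect_equal(length(out0$conformers), 3L)
  expect_error(contact_filter(cand, mk(integer(0))), "empty")
})

test_that("loop minimisation is a descent with a fixed environment", {
  ens <- cull_ensemble(toy_ensemble(), keep_rescore = 30L, keep_top = 4L)
  cxi <- instantiate_conformer(ens, 1L)
  obj0 <- h3graft:::make_objective(cxi, h3graft:::loop_rows_of(cxi),
                                   mode = "full")
  e0 <- obj0$fn(obj0$x0)
  env_rows <- setdiff(seq_len(nrow(cxi$atoms)), h3graft:::loop_rows_of(cxi))
  env_before <- h3graft:::cx_coords(cxi, env_rows)
  cxm <- minimize_loop(cxi, maxit = 80L)
  expect_lte(attr(cxm, "min_value"), e0 + 1e-9)
  expect_identical(h3graft:::cx_coords(cxm, env_rows), env_before)
  # stationarity: restarting the minimiser at its own solution (same
  # objective, same neighbour list) does not move or improve it
  obj1 <- h3graft:::make_objective(cxm, h3graft:::loop_rows_of(cxm),
                                   mode = "full")
  opt1 <- stats::optim(obj1$x0, obj1$fn, obj1$gr, method = "L-BFGS-B",
                       control = list(maxit = 3000, pgtol = 0.1, factr = 1e7))
  opt2 <- stats::optim(opt1$par, obj1$fn, obj1$gr, method = "L-BFGS-B",
                       control = list(maxit = 3000, pgtol = 0.1, factr = 1e7))
  expect_lt(abs(opt2$value - opt1$value), 0.01)
  # closure maintained: junction bond near ideal
  dh <- h3graft:::loop_dihedrals(cxm)
  L <- h3_length(cxm)
  junction <- h3graft:::vnorm(dh$bb[[L + 1]]$C - dh$bb[[L + 2]]$N)
  expect_lt(abs(junction - 1.33), 0.2)
})

test_that("per-stem retention keeps the configured counts", {
  ens <- minimize_ensemble(cull_ensemble(toy_ensemble(), 30L, 6L),
                           maxit = 30L)
  ensB <- ens
  names(ensB$bases) <- "B"
  for (i in seq_along(ensB$conformers)) ensB$conformers[[i]]$stem <- "B"
  merged <- retain_per_stem(list(ens, ensB), keep = 4L)
  expect_equal(length(merged$conformers), 8L)
  stems <- vapply(merged$conformers, function(cf) cf$stem, "")
  expect_equal(sort(unique(stems)), c("B", names(ens$bases)))
  # keep exceeding availability keeps everything
  merged2 <- retain_per_stem(list(ens), keep = 100L)
  expect_equal(length(merged2$conformers), 6L)
  # retained are the best by minimised energy
  e_all <- sort(vapply(ens$conformers, function(cf) cf$min_energy, 0))
  e_kept <- sort(vapply(retain_per_stem(list(ens), 4L)$conformers,
                        function(cf) cf$min_energy, 0))
  expect_equal(e_kept, e_all[1:4])
})

test_that("refinement respects the retention window and keeps the incumbent", {
  ens <- minimize_ensemble(cull_ensemble(toy_ensemble(), 30L, 4L),
                           maxit = 50L)
  merged <- retain_per_stem(list(ens), keep = 3L)
  ref <- refine_ensemble(merged, stage1_expansions = 2L,
                         stage2_expansions = 2L, window = 5, seed = 3L)
  expect_equal(ref$stage, "final")
  te <- vapply(ref$conformers, function(cf) cf$total_energy, 0)
  expect_true(all(te <= min(te) + 5 + 1e-9))
  # the best refined energy never exceeds the best incumbent energy
  inc <- h3graft:::ensure_total_energy(merged)
  inc_best <- min(vapply(inc$conformers, function(cf) cf$total_energy, 0))
  expect_lte(min(te), inc_best + 1e-9)
  # zero window keeps only ties with the best
  ref0 <- refine_ensemble(merged, 1L, 1L, window = 0, seed = 3L)
  te0 <- vapply(ref0$conformers, function(cf) cf$total_energy, 0)
  expect_true(all(abs(te0 - min(te0)) < 1e-9))
  # determinism
  ref2 <- refine_ensemble(merged, stage1_expansions = 2L,
                          stage2_expansions = 2L, window = 5, seed = 3L)
  expect_equal(vapply(ref2$conformers, function(cf) cf$total_energy, 0), te)
})

test_that("ensemble archives write one model per conformer with a sidecar", {
  ens <- cull_ensemble(toy_ensemble(), keep_rescore = 30L, keep_top = 5L)
  ens <- h3graft:::ensure_contacts(ens)
  dir <- tempfile()
  pdb <- write_ensemble(ens, dir)
  lines <- readLines(pdb)
  expect_equal(sum(grepl("^MODEL", lines)), length(ens$conformers))
  expect_equal(sum(grepl("^ENDMDL", lines)), length(ens$conformers))
  side <- read.delim(file.path(dir, "parent.tsv"))
  expect_equal(nrow(side), length(ens$conformers))
  expect_true(all(side$closure_gap <= 0.5))
  expect_true(all(is.finite(side$stat_energy)))
})
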