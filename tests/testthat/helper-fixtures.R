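# Shared fixtures, memoised so expensive constructions run once per session.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

toy_complex <- function(seed = 1L) {
  memo(paste0("toy", seed), make_toy_complex(fixture_spec(seed = seed)))
}

toy_stem_library <- function(seed = 1L) {
  memo(paste0("stems", seed),
       default_stem_library(toy_complex(seed), lengths = c(7L, 12L, 13L, 16L),
                            n_clusters = 2L, seed = seed))
}

toy_self_template <- function(seed = 1L) {
  memo(paste0("selftpl", seed), template_from_complex(toy_complex(seed)))
}

# parental self-graft (no regularisation): identical to the parent
toy_self_graft <- function(seed = 1L) {
  memo(paste0("selfgraft", seed), {
    cx <- toy_complex(seed)
    graft_stem(cx, toy_self_template(seed), h3_sequence(cx),
               regularize_after = FALSE)
  })
}

# a small sampled ensemble on the parental graft, reused by several tests
toy_ensemble <- function(n = 30L, seed = 7L) {
  memo(paste0("ens", n, "_", seed),
       sample_tip(toy_self_graft(), n_samples = n, seed = seed,
                  candidate_id = "parent"))
}

# scaled-down screen shared between property and acceptance tests:
# parent + minimal control + decoy candidates at the desk-scale counts
toy_screen <- function() {
  memo("screen", {
    cx <- toy_complex()
    lib <- toy_screen_library()
    screen_h3_library(cx, lib, toy_stem_library(),
                      config = desk_config(seed = 1L),
                      keep_ensembles = TRUE)
  })
}

toy_screen_library <- function() {
  # the parental binder planted among decoys, three per length stratum (a
  # robust per-length Z needs more than two members per stratum: with two,
  # |z| = 0.674 identically)
  memo("screenlib", {
    full <- make_h3_library(fixture_spec(seed = 3L, library_size = 120L))
    dec13 <- full[nchar(full$sequence) == 13L & full$id != "parent", , drop = FALSE]
    dec12 <- full[nchar(full$sequence) == 12L, , drop = FALSE]
    rbind(full[full$id == "parent", , drop = FALSE],
          utils::head(dec13, 3L), utils::head(dec12, 3L))
  })
}

expect_coords_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}

# brute-force pair count oracle
brute_contacts <- function(x, y, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(x))) for (j in seq_len(nrow(y)))
    if (sqrt(sum((x[i, ] - y[j, ])^2)) <= cutoff) n <- n + 1L
  n
}
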