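# End-to-end H3 library screen: stem matching, grafting, ensemble
# generation/refinement, two-track scoring, length-stratified consensus
# ranking and the selection cascade.

#' Screen configuration
#'
#' Counts and windows of the hierarchical protocol. Defaults are the
#' full-scale study conditions (5000 sampled tips, rescore 1000, keep 250,
#' 100 per stem, 5- then 25-fold refinement expansion, 5-unit retention
#' windows, 4.5 Angstrom contacts, stem retention window 1.7, Z cutoff
#' -1.5). \code{desk_config()} is a scaled-down preset for interactive use
#' and testing.
#'
#' @param n_samples sampled tip conformations per grafted stem.
#' @param keep_rescore head of the ensemble rescored by the contact
#'   potential.
#' @param keep_top conformations kept after rescoring.
#' @param keep_per_stem conformations kept per stem after minimisation.
#' @param expansions1,expansions2 perturb-and-reclose expansions per
#'   conformer in the two refinement stages.
#' @param window retention window above the best total energy (energy
#'   units).
#' @param contact_cutoff antigen contact distance, Angstrom.
#' @param retention_window stem-match retention window (log-odds units).
#' @param z_cutoff composite Z selection threshold.
#' @param kT Boltzmann temperature factor.
#' @param minimize_maxit,prescore_maxit minimiser budgets.
#' @param sample_max_tries retry budget multiplier for tip sampling.
#' @param seed RNG seed for the whole screen.
#' @return named list of settings.
#' @export
screen_config <- function(n_samples = 5000L, keep_rescore = 1000L,
                          keep_top = 250L, keep_per_stem = 100L,
                          expansions1 = 5L, expansions2 = 25L, window = 5,
                          contact_cutoff = 4.5, retention_window = 1.7,
                          z_cutoff = -1.5, kT = 1, minimize_maxit = 150L,
                          prescore_maxit = 80L, sample_max_tries = 25L,
                          seed = 1L) {
  as.list(environment())
}

#' @rdname screen_config
#' @param ... overrides passed to [screen_config()].
#' @export
desk_config <- function(...) {
  cfg <- screen_config(n_samples = 200L, keep_rescore = 100L, keep_top = 25L,
                       keep_per_stem = 10L, expansions1 = 2L,
                       expansions2 = 3L, minimize_maxit = 80L,
                       prescore_maxit = 50L)
  utils::modifyList(cfg, list(...))
}

#' Generate the scored ensemble for one candidate sequence
#'
#' Runs stem matching, grafting, tip sampling, contact-potential culling,
#' antigen-contact filtering, minimisation, per-stem retention and two-stage
#' refinement for a single H3 sequence.
#'
#' @param parent prepared parental [abcomplex()].
#' @param sequence candidate H3 (one-letter).
#' @param stem_library list of \code{stem_template}s.
#' @param config a [screen_config()].
#' @param candidate_id identifier.
#' @return a final-stage \code{loop_ensemble}.
#' @export
build_candidate_ensemble <- function(parent, sequence, stem_library,
                                     config = desk_config(),
                                     candidate_id = sequence) {
  m <- match_stems(sequence, stem_library, config$retention_window)
  tpls <- attr(m, "templates")[m$retained]
  per_stem <- list()
  for (ti in seq_along(tpls)) {
    g <- graft_stem(parent, tpls[[ti]], sequence)
    ens <- sample_tip(g, n_samples = config$n_samples,
                      seed = config$seed + 101L * ti,
                      candidate_id = candidate_id,
                      max_tries = config$sample_max_tries)
    reference <- ens
    ens <- cull_ensemble(ens, config$keep_rescore, config$keep_top)
    ens <- contact_filter(ens, reference, config$contact_cutoff)
    if (!length(ens$conformers)) {
      # an empty post-filter ensemble falls back to the culled set: the
      # contact filter must never erase a stem outright
      ens <- cull_ensemble(reference, config$keep_rescore, config$keep_top)
    }
    ens <- minimize_ensemble(ens, maxit = config$minimize_maxit)
    per_stem[[length(per_stem) + 1L]] <- ens
  }
  merged <- retain_per_stem(per_stem, keep = config$keep_per_stem)
  refine_ensemble(merged, stage1_expansions = config$expansions1,
                  stage2_expansions = config$expansions2,
                  window = config$window, seed = config$seed)
}

#' Screen an H3 sequence library against a parental complex
#'
#' For every candidate sequence with a matching stem template the full
#' ensemble protocol is run and scored; score records are converted to
#' length-stratified consensus Z-scores and the selection cascade is
#' applied. Candidates whose length has no stem template are skipped (and
#' listed in \code{skipped}).
#'
#' @param parent prepared parental [abcomplex()].
#' @param library data.frame with id, sequence (e.g. [make_h3_library()]).
#' @param stem_library list of \code{stem_template}s.
#' @param config a [screen_config()].
#' @param keep_ensembles keep the per-candidate ensembles in the result
#'   (memory-hungry for large screens).
#' @return list with \code{records} (ScoreRecords), \code{zrecords},
#'   \code{report} (selection report), \code{medians} (per-length
#'   median/scale table for retrospective scoring), \code{best_complexes},
#'   \code{skipped} and, optionally, \code{ensembles}.
#' @export
screen_h3_library <- function(parent, library, stem_library,
                              config = desk_config(),
                              keep_ensembles = FALSE) {
  records <- list(); best <- list(); skipped <- character(0)
  ensembles <- list()
  for (i in seq_len(nrow(library))) {
    id <- library$id[i]; seqs <- library$sequence[i]
    ens <- tryCatch(
      build_candidate_ensemble(parent, seqs, stem_library, config,
                               candidate_id = id),
      error = function(e) {
        if (grepl("no stem template", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(ens)) { skipped <- c(skipped, id); next }
    records[[length(records) + 1L]] <-
      score_ensemble(ens, kT = config$kT,
                     prescore_maxit = config$prescore_maxit)
    best[[id]] <- instantiate_conformer(ens, 1L)  # sorted by total energy
    if (keep_ensembles) ensembles[[id]] <- ens
  }
  if (!length(records)) stop("no candidate could be screened")
  records <- do.call(rbind, records)
  zrec <- stratified_z(records)
  report <- select_candidates(zrec, best, parent, cutoff = config$z_cutoff)
  out <- list(records = records, zrecords = zrec, report = report,
              medians = score_medians(records), best_complexes = best,
              skipped = skipped)
  if (keep_ensembles) out$ensembles <- ensembles
  out
}

#' Write the score/selection tables of a screen result
#' @param result a [screen_h3_library()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_screen_tables <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(result$records, file.path(dir, "score_table.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$report, file.path(dir, "selection_report.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$medians, file.path(dir, "score_medians.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
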