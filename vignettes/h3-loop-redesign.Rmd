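---
title: "Redesigning antibody CDR-H3 loops by stem grafting, ensemble sampling and consensus scoring"
author: "h3graft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Redesigning antibody CDR-H3 loops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(h3graft)
```

## The problem

The third heavy-chain complementarity-determining region (CDR-H3) dominates
antigen recognition in most antibodies, but unlike the other five CDRs it has
no canonical conformational classes: its length and sequence are
hypervariable. `h3graft` implements a wholesale H3 replacement protocol: given
a parental antibody–antigen complex, a library of candidate H3 sequences of
heterogeneous length (such as germline-derived human repertoire sequences) is
virtually grafted into the parental framework, loop conformational ensembles
are generated and refined, antigen binding is scored with two complementary
scoring tracks, and candidates are ranked by a length-stratified consensus
Z-score with structural filters.

The pipeline is organised as:

1. **Structure preparation** (`read_structure()`, `prepare_complex()`):
   heavy-atom coordinates with a user-supplied region annotation
   (framework, CDRs under the IMGT delineation, antigen). Waters and
   metal/halide ions are removed, disulfides recorded, missing side-chain
   atoms completed at ideal geometry, and chain breaks flagged with neutral
   cap markers.
2. **Stem grafting** (`match_stems()`, `build_template()`, `graft_stem()`):
   each H3 sequence is matched to stem-cluster templates of the same length;
   the template's 90–105 backbone is superposed on the six anchor CA atoms
   (residues 90–92 and 103–105) and transplanted; the loop is mutated to the
   candidate sequence with clash-minimal rotamers and regularised.
3. **Ensemble generation** (`sample_tip()`, `cull_ensemble()`,
   `contact_filter()`, `minimize_ensemble()`, `retain_per_stem()`,
   `refine_ensemble()`): the loop tip is sampled from Ramachandran
   propensity maps and closed by cyclic coordinate descent; the raw ensemble
   is culled with a statistical contact potential, filtered by
   antigen-contact count, minimised, retained per stem and refined by
   perturb-and-reclose expansion.
4. **Scoring and selection** (`score_ensemble()`, `stratified_z()`,
   `apply_cutoff()`, `select_candidates()`): Boltzmann-weighted ensemble
   averages of a total-energy track and an interaction-energy track are
   converted to per-length Z-scores, merged, cut at −1.5 and passed through
   Ramachandran, hydrogen-bond and curation filters.

## Numbering convention

All loop positions use an internal map with position 1 at heavy-chain
residue 93 and position L at residue 102; position L−1 is 101 and loops
longer than 10 residues insert at position 100 (100A, 100B, ...). The graft
region spans residues 90–105; the three flanking residues on each side
(90–92, 103–105) are the rigid anchors. The shortened stems kept fixed
during tip sampling are the first 2 and last 3 loop residues, so the tip
window is positions 3..L−3 for loops of 10 or more residues, shrinking for
shorter loops down to a single pass-through conformation at length 7
(`tip_window()`).

## The protocol's counts and windows

The hierarchical ensemble protocol retains, per grafted stem: 5000 sampled
tip conformations, of which the first 1000 are re-ranked by the statistical
potential and the best 250 kept; conformations with fewer antigen contacts
(4.5 Å heavy-atom rule) than the median of the re-ranked head are removed;
the survivors are energy-minimised and the best 100 per stem retained.
Refinement then expands each conformer 5-fold (stage 1) and 25-fold
(stage 2) by perturb-and-reclose moves over the full loop, merging stems
and keeping everything within 5 energy units of the best total energy after
each stage. Stem templates are matched with a BLOSUM62 profile over the
seven canonical stem positions and all templates within 1.7 score units of
the best match are used. These defaults (`screen_config()`) are the
full-scale study conditions; `desk_config()` scales the counts to
200/100/25/10 with 2-/3-fold expansions for interactive work and for the
test suite, which runs the screen on a toy complex with a handful of
candidates.

## Internal engines and their scope

The protocol logic — stage order, counts, windows, medians, stratification
— is the contribution this package reproduces. The engines inside each
stage are deliberately compact, documented components rather than
re-implementations of any external program:

* **Sampling/closure**: residue-type-conditioned Ramachandran rasters
  (general/Gly/Pro, four classes built by dilating favoured-region
  rectangles on a 5° torus grid) provide φ/ψ proposals; cyclic coordinate
  descent closes the chain onto the fixed C-side anchor triplet. A
  conformation is accepted when the closure gap (RMSD of the rebuilt anchor
  N/CA/C against its fixed position) is at most 0.5 Å and no heavy-atom
  pair comes closer than 0.6 × the sum of van der Waals radii. Omega
  angles are held trans.
* **Statistical potential**: an atom-typed (C/N/O/S) distance potential,
  8 Å cutoff in 0.5 Å bins, with a deeper well for polar N–O pairs and a
  shallow hydrophobic-packing well for carbon pairs; bin values derive
  from a smooth 8–4 form evaluated at bin midpoints.
* **Force field**: bond/angle/omega harmonic terms at ideal internal
  coordinates (side-chain geometry measured once from ideal residue
  templates), 12-6 Lennard-Jones, screened Coulomb with a
  distance-dependent dielectric ε = 4r and coarse heavy-atom charges, and
  a distance-well hydrogen-bond term. Minimisation is L-BFGS in Cartesian
  space with analytic gradients (verified against finite differences in
  the tests); the post-graft regulariser uses soft-sphere repulsion and
  harmonic backbone restraints (5 kcal/mol/Å² default) with the antigen
  excluded, mirroring the protocol's choice to restore loop geometry
  without interface deflection.
* **Interaction score**: a solvated-interaction-energy style functional,
  α·(E_vdW + E_Coulomb(Din) + reaction-field approximation + γ·ΔSASA) + C,
  with the published coefficient lineage as defaults (α = 0.1048,
  Din = 2.25, γ = 0.0129 kcal/mol/Å², C = −2.89 kcal/mol) exposed in
  `sie_params()`. ΔSASA comes from an in-package Shrake–Rupley
  implementation (validated against the closed-form two-sphere buried
  area) restricted to interface atoms; the reaction-field term is a
  Born-style penalty proportional to the buried area of charged atoms.
* **Boltzmann averaging**: both score tracks are averaged with weights
  exp(−(E−E_min)/kT) taken from the total-energy track; kT defaults to 1
  energy unit (the protocol does not fix a temperature; the limit kT→0 is
  a best-conformer selector and kT→∞ the plain mean, both covered by
  tests).

## Ranking and selection

Scoring functions favour larger interfaces, so longer loops outscore
shorter ones; Z-scores are therefore computed per H3 length stratum,
z = (score − median)/(1.4826·MAD), with a standard-deviation option.
The composite is the unweighted mean of the two tracks' Z-scores (the
consensus weighting is not otherwise specified); candidates at or below
−1.5 enter the filter cascade. A stratum of size one cannot be scored and
is flagged unscorable. On synthetic score tables with a positive
length-bias slope the stratified top-10 spans several lengths while a
single-stratum ("global") Z-score concentrates on the longest loops —
this property, and the recovery of a candidate planted several robust
standard deviations better than its stratum (found by the stratified
cutoff, buried by the global one), are asserted in the acceptance tests.
Recovery is validated at the ranking layer because, at desk scale on a
toy system, the structural screen's score differences between a true
binder and decoys are smaller than the internal-energy noise — the
stratified consensus is the component whose discrimination the package
can honestly certify.

Selection then applies, on each candidate's best total-energy conformer:

* a **Ramachandran check** of residues 92–103 (no residue in the
  disallowed raster class);
* a **hydrogen-bond screen**: intermolecular HB energy (distance well at
  2.9 Å modulated by the donor-antecedent angle; hydrogens are implicit)
  and a buried-unsatisfied-polar flaw count, each of which must not be
  worse than the parental value by more than 1 unit. The two one-sided
  tests are applied independently — the stricter of the two readings the
  protocol description admits.
* **curation rules** codifying visual inspection: shared-epitope fraction
  ≥ 0.25 relative to the parental H3 contacts; the stem Arg(2)–Asp(L−1)
  salt bridge must be maintained when the parental loop exhibits it; and
  the grafted loop must not newly bury a charged atom (SASA < 5 Ų)
  without an opposite charge within 4.5 Å. The latter two are judged
  relative to the parent: the rules ask whether the design *preserves*
  parental interactions and whether the *graft* buries charges, so
  pre-existing parental features never disqualify a candidate.

## What the fixtures emulate — and what they do not

`make_toy_complex()` builds a ~80-residue antibody-like scaffold: a
heavy-chain β-hairpin whose turn carries a 13-residue H3 with the parental
sequence, anchor bases ~10 Å apart (the typical H3 base span), a light-chain
hairpin, and a rigid convex helical antigen slid along the loop's
protrusion axis until the parental H3 makes at least 5 heavy-atom contacts
at 4.5 Å without steric overlap. Graft-region side chains go through the
same clash-minimal placement used after grafting, which makes the parental
complex an exact fixed point of the self-graft operation — the anchor for
the identity tests. `make_h3_library()` draws loop compositions from the
residue frequencies of the experimentally tested designs, germline-like
stem vocabularies, lengths uniform over 7–16, with cysteines excluded and
the parental sequence plus a minimal-H3 control (first 3 + Gly + last 3 of
the parent) always present. `make_score_table()` reproduces the
length-bias phenomenon synthetically.

These fixtures exercise every stage's logic, but a toy hairpin is not an
immunoglobulin fold: passing tests demonstrate the correctness of the
protocol machinery (grafting identities, closure bounds, retention
arithmetic, stratification, filter logic), not predictive accuracy on real
antibody–antigen systems, which additionally depends on the quality of the
scoring engines this package deliberately keeps simple.

## Numerical choices and degenerate inputs

* Closure tolerance 0.5 Å and trans-omega tolerance ±30° are package
  choices. The junction omega at the C-side anchor can transiently exceed
  the tolerance by the amount the closure gap allows; it is restored by
  the bonded terms during minimisation.
* Minimiser budgets are iteration-capped (`minimize_maxit`, default 150;
  80 in the desk preset); energies are non-increasing per call, and the
  neighbour list is built per call, so re-minimising an already-minimised
  conformation with a rebuilt list may still descend — the stationarity
  guarantee applies to the fixed objective.
* Ensembles smaller than a retention count are kept whole (with a warning
  at the culling stage); an empty post-filter ensemble falls back to the
  culled set so the contact filter never erases a stem.
* Ties in ranks share the smaller rank and subsequent ranks are dense.
  MAD of zero falls back to the standard deviation, then to 1.
* Per-region RMSD refuses H3 comparisons across different loop lengths;
  region cells absent from either structure are NA, never zero.
* When a crystal structure contains several complex copies, the first
  copy in file order is used (multi-model files contribute model 1 only).

## Retrospective crystal-loop grafting

`retrospective_graft()` superposes a design's co-crystal structure onto
the parent via framework backbone, transplants the crystal H3
conformation, copies the design-crystal rotamer for any environment side
chain that clashes with the incoming loop, minimises the loop in the fixed
environment and scores the single structure; Z-scores reuse the per-length
medians stored from the original screen (`score_medians()`). Grafting the
parent's own loop back into the parent reproduces the parental
single-structure scores to numerical precision — the identity contract
verified in the acceptance tests.

## Problem sizes used by the test-suite and acceptance runs

The bundled checks run the screen at the desk scale (200 sampled tips,
rescore 100, keep 25, 10 per stem, 2-/3-fold expansions) on the toy
complex with a parental candidate plus length-matched decoys; property
suites use brute-force oracles at small n (quadratic contact counting,
exhaustive rotamer enumeration, closed-form two-sphere areas, sort/median
oracles). The published-table statistics are recomputed from the bundled
reference data (`bh1_reference_designs()`), which types the experimental
dissociation constants, screen Z-scores and ranks of the 16 tested designs
plus the parental and minimal-H3 controls.

## Known limitations

* The stem-matching profile is a BLOSUM62 log-odds sum over the seven
  canonical stem positions; the 1.7 retention window is preserved
  numerically, but its scale depends on the scoring model, so the window
  is configurable.
* Structures are heavy-atom only; protonation states and explicit
  hydrogen-bond network optimisation are out of scope, and polar-hydrogen
  geometry is implied by donor-antecedent angles.
* The energy models are compact internal components: scores are useful
  for ranking within a screen, not as transferable binding free energies.
* Kabat/IMGT renumbering is not performed; regions come from the
  annotation table supplied by the user or the fixture generator.
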