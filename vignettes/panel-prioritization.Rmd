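---
title: "Structure-based prioritization of imine reductase screening panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based prioritization of imine reductase screening panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iredpanel)
```

## The problem

Imine reductases (IREDs) are NADPH-dependent enzymes that reduce imines
and iminium ions to chiral amines and catalyze reductive amination of
ketones with amines. Finding an IRED that converts a given substrate
usually means expressing and screening large enzyme panels. `iredpanel`
implements a structure-based computational funnel that ranks candidate
IRED sequences for one target imine so that a small panel — 20 sequences
by default — can be screened instead of hundreds.

The funnel has five stages:

1. **Sequence preprocessing.** Each candidate sequence is assigned the
   characterized IRED structure with the highest global-alignment
   identity as its template; candidates whose best template is not one of
   the 13 characterized IRED structures (`IRED_TEMPLATE_IDS`) are dropped
   as non-homologs. For database construction, homology-search hits are
   filtered (identity > 30%, coverage > 80%, E-value < 10, all strict),
   deduplicated, and clustered greedily at identity 0.7.
2. **Structure modeling.** IREDs are homodimers with the active site at
   the monomer interface, so the single-chain query/template alignment is
   doubled around a chain-break token before being handed to the modeling
   backend. Models are accepted only if at least 90% of their assessable
   residues fall in the favorable/core region of the Ramachandran plot.
3. **Docking preparation.** Qualified models are superposed onto the
   dimer template through paired CA atoms (Kabsch least squares), the
   template's NADPH is copied verbatim into the modeled cofactor site,
   and the docking box is centered on the template's bound ligand with a
   cubic edge of `max(2.9 × Rg(substrate), 10 Å)`.
4. **Pose selection.** For every docked pose the distance from the
   cofactor's hydride-donating C4 atom to the substrate's imine nitrogen
   is measured. Poses closer than 3.5 Å (clash) or farther than 6.0 Å
   (beyond hydride-transfer range) are removed, strictly; among the
   survivors the pose with the smallest distance is kept.
5. **Rescoring and ranking.** Residues whose minimum heavy-atom distance
   to the substrate is at most 8 Å form the active-site shell. With
   `n_acidic` (ASP/GLU count), `n_basic` (LYS/ARG count) and `n_his`
   (HIS present, 0/1), the refined score is

   $$\mathrm{score} = 4.0\,v + 1.0\,N_\mathrm{acidic}
     - 9.0\,N_\mathrm{His} + 9.0\,N_\mathrm{basic},$$

   where $v$ is the pose's docking (Vina-style) binding score. Lower is
   better: the binding term is negative-better, an active-site histidine
   (the catalytic proton donor) improves the rank, and basic residues,
   which compete with the iminium intermediate, worsen it. Candidates are
   sorted ascending and the top `panel_size` form the screening panel.

Homology modeling and the docking search itself sit behind backend
contracts (`build_model()`, `dock()`); the package ships in-memory and
directory-backed fixture backends and does not re-implement either
engine.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `min_distance`, `max_distance` | 3.5, 6.0 Å | C4···N pose window, strict at both ends |
| `radius` (shell) | 8.0 Å | inclusive min heavy-atom distance defining the shell |
| `w_vina, w_acidic, w_his, w_basic` | 4, 1, 9, 9 | refined-score weights (`w_his` enters negatively) |
| `cutoff_fraction` | 0.90 | inclusive Ramachandran core fraction for a qualified model |
| `box_scale`, `min_edge` | 2.9, 10 Å | docking-box edge rule on the substrate Rg |
| `exhaustiveness` | 10 | docking search effort recorded for backends |
| `panel_size` | 20 | screened panel size |
| `low_cutoff`, `high_cutoff` | 2%, 50% | conversion cutoffs for the two hit-rate definitions (inclusive) |
| `lo`, `hi`, `step` (tuning) | −10, 10, 1 | weight grid |

Choices the underlying method leaves open, decided here:

* **Identity definition.** Global alignment with BLOSUM62, gap opening
  10 / extension 0.5. The denominator is alignment columns for template
  assignment and the shorter sequence for clustering, matching the
  conventions of the standard clustering tools; both are configurable.
* **Strictness.** "over 30%", "over 80%", "under 10" are strict
  inequalities; "within 8 Å" and the 90% qualification cutoff are
  inclusive (the inclusive cutoff avoids a floating-point knife edge at
  exactly 0.90).
* **Ramachandran regions.** Rectangles: phi ∈ [−180, −30] with psi ∈
  [−90, 45] or [90, 180]. Only the in/out classification feeds the
  pipeline, so rectangle fidelity is sufficient; the map is replaceable
  via `qualification_config()`.
* **Shell census.** Heavy atoms only, all substrate atoms (not just the
  iminium carbon), both chains, cofactor and substrate excluded;
  protonation-variant residue names (HID/HIE/HIP, ASH, GLH, LYN) are
  normalized before classification so counts do not depend on the file
  dialect.
* **Tie-breaks.** Pose selection: distance, then binding score, then
  pose index. Ranking: refined score, then binding score, then sequence
  id. Tuning: high-cutoff hit rate, then low-cutoff hit rate, then
  smallest L1 norm, then lexicographic weight order. Template
  assignment: identity, then lexicographic template id. Every tie-break
  is deterministic, which is what makes reruns byte-identical.
* **Candidates without a surviving pose** are reported with status
  `no_valid_pose` and excluded from the ranked panel rather than being
  silently dropped; `model_unqualified` and `not_homolog` mark the
  earlier exits, and backend failures map onto the status of the stage
  that failed.
* **Hit-rate cutoffs** are inclusive (≥) for both the 2% and 50%
  definitions, including inside the tuning objective.

## Evaluation and tuning

Given screening outcomes (sequence id, % conversion), the package
computes hit rates at the two cutoffs, whether any tied-best sequence of
the whole panel was retrieved in the selection, the analytic probability
of retrieving a best hit by uniform random selection,

$$P = 1 - \binom{N-m}{k}\Big/\binom{N}{k},$$

(reducing to $k/N$ for a unique best hit), and a resampled random
baseline: `n_draws` uniform k-subsets, summarized by mean hit rate, SEM
and a `mean ± 1.96 × SEM` interval clipped to [0, 1]. All stochastic
operations require an explicit seed and are bit-reproducible under it.

`tune_weights()` performs the exhaustive grid search: every weight
vector on the grid ranks the calibration table, the top `panel_size` are
selected, and the objective is the hit rate at the high cutoff.

```{r tuning-example}
panel <- make_panel(60, "score_linked", noise_sd = 0, seed = 3)
w <- tune_weights(panel$calibration,
                  tuning_grid(lo = -2, hi = 6, step = 2,
                              tuned_weights = c("w_vina", "w_his")),
                  evaluation_config(panel_size = 15))
c(w$w_vina, w$w_his, attr(w, "objective"))
```

## What the synthetic generators emulate — and what they do not

The generators exist so that every stage is testable without downloads
or engines:

* `make_receptor()` places single-CA residues at **exactly** requested
  minimum heavy-atom distances from a four-atom toy imine, plus a 5-atom
  cofactor group whose C4 atom sits at the requested C4···N distance.
  Axis-aligned placements use dyadic coordinates (the substrate nitrogen
  sits at x = 1.25 Å) so that boundary distances such as 3.5, 6.0 and
  8.0 Å are represented exactly in floating point; the generator
  re-measures every placement and refuses to emit a fixture that
  deviates by more than 1e-6 Å. A distant alanine anchor keeps the
  receptor a valid protein even with no shell placements.
* `make_pose_set()` translates the base pose along the C4–N axis and
  pins the nitrogen at exactly `c4 + d·u`, so a requested distance grid
  is reproduced without round-off.
* `make_rama_chain()` builds an ideal N–CA–C backbone by internal-
  coordinate chaining with the requested phi/psi per residue. It uses
  `n_assessed + 2` residues (the termini have no complete dihedral
  neighborhood) so that core fractions on a `1/n_assessed` grid are
  exact.
* `make_panel()` draws conversions either uniformly on [0, 100] or as a
  strictly decreasing affine map of a known true refined score plus
  Gaussian noise, enabling tuning-recovery tests.

These fixtures deliberately lack everything that makes real structures
hard: side chains, hydrogens, clashes, loop variability, induced fit,
realistic docking score landscapes, and the correlation structure of
real screening campaigns. Green tests therefore certify the *logic* of
the funnel — boundary semantics, counting, ranking, tie-breaks,
statistics — not the accuracy of homology models or docking poses, which
live behind the backend contracts.

## Numerical choices

* Superposition uses the Kabsch SVD solution with the determinant
  correction (proper rotations only); rank-deficient (collinear) point
  sets are rejected.
* Dihedrals use the standard signed atan2 torsion in (−180, 180];
  under this convention reversing the atom order preserves the angle and
  mirror reflection flips its sign. Collinear triples are an error, not
  an NA.
* The hypergeometric retrieval probability is computed on the log-choose
  scale to avoid overflow for large panels.
* Degenerate inputs fail loudly by design: empty sequences, duplicate
  ids, duplicate atoms, out-of-range nitrogen indices, zero or multiple
  C4 atoms, pose/distance length mismatches, and conversions outside
  [0, 100] all raise errors naming the offender.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely on generated
fixtures: receptors with up to ~12 placed residues, pose grids of 51
distances, backbone chains of 102 residues, panels of 60–200 synthetic
sequences, a 5×5 tuning grid on 200 candidates, 1000 random rigid
motions for the superposition property, and 10^4 resampling draws for
the random baseline. These sizes were chosen to exercise every branch
and boundary while keeping a full run in the tens of seconds on one CPU.

## Known limitations

* Clustering is greedy longest-first against representatives only — the
  documented behavior of the standard tool at small scale, without its
  word-filter accelerations; it is quadratic and meant for panels, not
  databases.
* The Ramachandran region map is rectangular and shared by all residue
  types (glycine and pre-proline are not special-cased).
* The shell census treats every residue equally regardless of side-chain
  orientation, as the rescoring function requires counts only.
* No enantioselectivity or conversion prediction is attempted; ranking
  quality on real panels is bounded by the external modeling and docking
  engines plugged into the backend contracts.
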