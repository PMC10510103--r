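#' Homology-search filter settings
#'
#' Thresholds applied to tabular homology-search hits when assembling a
#' sequence database from public repositories. All three criteria are strict
#' inequalities: a hit is kept when identity exceeds `min_identity`, coverage
#' exceeds `min_coverage` and the E-value falls below `max_e_value`.
#'
#' @param min_identity Minimum sequence identity as a fraction (exclusive).
#' @param min_coverage Minimum query coverage as a fraction (exclusive).
#' @param max_e_value Maximum E-value (exclusive).
#' @param cluster_threshold Identity threshold used by [dedupe_and_cluster()].
#' @return A `homology_filter_config` list.
#' @export
homology_filter_config <- function(min_identity = 0.30,
                                   min_coverage = 0.80,
                                   max_e_value = 10,
                                   cluster_threshold = 0.7) {
  assert_fraction(min_identity, "min_identity")
  assert_fraction(min_coverage, "min_coverage")
  assert_scalar_number(max_e_value, "max_e_value")
  assert_fraction(cluster_threshold, "cluster_threshold")
  if (max_e_value < 0) abort("`max_e_value` must be nonnegative")
  structure(
    list(min_identity = min_identity, min_coverage = min_coverage,
         max_e_value = max_e_value, cluster_threshold = cluster_threshold),
    class = "homology_filter_config"
  )
}

#' Ramachandran model-qualification settings
#'
#' A model qualifies when the fraction of assessed residues falling in the
#' favorable/core region reaches `cutoff_fraction` (inclusive, to avoid a
#' floating-point knife edge at the boundary). The region map is a data frame
#' of phi/psi rectangles; a residue is in-region when its (phi, psi) pair
#' falls inside any rectangle.
#'
#' @param cutoff_fraction Minimum core fraction for a qualified model.
#' @param region_map Data frame with columns `phi_min`, `phi_max`, `psi_min`,
#'   `psi_max` (degrees) defining the favorable/core region.
#' @return A `qualification_config` list.
#' @export
qualification_config <- function(cutoff_fraction = 0.90,
                                 region_map = default_core_regions()) {
  assert_fraction(cutoff_fraction, "cutoff_fraction")
  if (cutoff_fraction <= 0) abort("`cutoff_fraction` must be positive")
  need <- c("phi_min", "phi_max", "psi_min", "psi_max")
  if (!is.data.frame(region_map) || !all(need %in% names(region_map))) {
    abort("`region_map` must be a data frame with columns ",
          paste(need, collapse = ", "))
  }
  structure(
    list(cutoff_fraction = cutoff_fraction, region_map = region_map),
    class = "qualification_config"
  )
}

#' Default favorable/core Ramachandran region
#'
#' Rectangular approximation of the core region: phi in \[-180, -30\] with
#' psi in \[-90, 45\] (helical) or \[90, 180\] (extended). Glycine and
#' pre-proline residues use the same map. Only the in/out classification
#' feeds the pipeline, so rectangles suffice; supply a custom map through
#' [qualification_config()] for finer region shapes.
#'
#' @return Data frame of phi/psi rectangles.
#' @export
default_core_regions <- function() {
  data.frame(
    region = c("core_helical", "core_extended"),
    phi_min = c(-180, -180), phi_max = c(-30, -30),
    psi_min = c(-90, 90), psi_max = c(45, 180)
  )
}

#' Docking search settings
#'
#' @param exhaustiveness Search effort passed to the docking backend
#'   (default 10).
#' @param box_scale Cubic box edge as a multiple of the substrate radius of
#'   gyration (default 2.9, the published optimum of the box-sizing rule).
#' @param min_edge Minimum box edge in Angstroms; the floor engages for very
#'   small substrates.
#' @return A `docking_config` list.
#' @export
docking_config <- function(exhaustiveness = 10L, box_scale = 2.9,
                           min_edge = 10.0) {
  assert_scalar_number(exhaustiveness, "exhaustiveness")
  if (exhaustiveness < 1) abort("`exhaustiveness` must be >= 1")
  assert_scalar_number(box_scale, "box_scale")
  if (box_scale <= 0) abort("`box_scale` must be positive")
  assert_scalar_number(min_edge, "min_edge")
  structure(
    list(exhaustiveness = as.integer(exhaustiveness),
         box_scale = box_scale, min_edge = min_edge),
    class = "docking_config"
  )
}

#' Catalytic-geometry pose filter settings
#'
#' Poses are screened on the distance between the cofactor C4 atom (the
#' hydride donor of the NADPH nicotinamide ring) and the imine nitrogen of
#' the docked substrate. Poses strictly below `min_distance` are removed as
#' clashes; poses strictly above `max_distance` are removed as beyond
#' hydride-transfer range.
#'
#' @param min_distance Lower C4...N cutoff in Angstroms (default 3.5).
#' @param max_distance Upper C4...N cutoff in Angstroms (default 6.0).
#' @param c4_atom_name Atom name of the hydride-donating cofactor carbon.
#' @param cofactor_resname Residue name of the cofactor hetero group.
#' @return A `pose_filter_config` list.
#' @export
pose_filter_config <- function(min_distance = 3.5, max_distance = 6.0,
                               c4_atom_name = "C4",
                               cofactor_resname = "NAP") {
  assert_scalar_number(min_distance, "min_distance")
  assert_scalar_number(max_distance, "max_distance")
  if (min_distance <= 0 || min_distance >= max_distance) {
    abort("need 0 < min_distance < max_distance")
  }
  structure(
    list(min_distance = min_distance, max_distance = max_distance,
         c4_atom_name = c4_atom_name, cofactor_resname = cofactor_resname),
    class = "pose_filter_config"
  )
}

#' Active-site shell settings
#'
#' A protein residue belongs to the shell when the minimum heavy-atom
#' distance between any of its atoms and any substrate atom is at most
#' `radius` (inclusive). The residue classes drive the three count terms of
#' the refined score.
#'
#' @param radius Shell radius in Angstroms (default 8.0).
#' @param acidic_set,basic_set,his_set Residue names (3-letter, after
#'   protonation-variant normalization) counted as acidic, basic or
#'   histidine.
#' @return A `shell_config` list.
#' @export
shell_config <- function(radius = 8.0,
                         acidic_set = c("ASP", "GLU"),
                         basic_set = c("LYS", "ARG"),
                         his_set = "HIS") {
  assert_scalar_number(radius, "radius")
  if (radius <= 0) abort("`radius` must be positive")
  sets <- c(acidic_set, basic_set, his_set)
  if (anyDuplicated(sets)) abort("residue class sets must be disjoint")
  structure(
    list(radius = radius, acidic_set = acidic_set, basic_set = basic_set,
         his_set = his_set),
    class = "shell_config"
  )
}

#' Refined-score weights
#'
#' The refined score is
#' `w_vina * vina + w_acidic * n_acidic - w_his * n_his + w_basic * n_basic`;
#' lower is better. `w_his` enters with a negative sign because an
#' active-site histidine (the proton donor of the catalytic mechanism)
#' improves the ranking. Defaults are the tuned weights 4.0, 1.0, 9.0, 9.0.
#'
#' @param w_vina,w_acidic,w_his,w_basic Term weights.
#' @return A `scoring_weights` list.
#' @export
scoring_weights <- function(w_vina = 4.0, w_acidic = 1.0, w_his = 9.0,
                            w_basic = 9.0) {
  for (nm in c("w_vina", "w_acidic", "w_his", "w_basic")) {
    assert_scalar_number(get(nm), nm)
  }
  structure(
    list(w_vina = w_vina, w_acidic = w_acidic, w_his = w_his,
         w_basic = w_basic),
    class = "scoring_weights"
  )
}

#' Panel-evaluation settings
#'
#' @param panel_size Number of sequences selected for screening (default 20).
#' @param low_cutoff,high_cutoff Conversion cutoffs in percent for the two
#'   hit-rate definitions (inclusive `>=`; defaults 2 and 50).
#' @param n_draws Monte-Carlo draws for the random-selection baseline.
#' @param seed Seed for stochastic operations (required there).
#' @param ci_multiplier Multiplier on the SEM for the confidence interval
#'   (1.96 for a 95% level).
#' @return An `evaluation_config` list.
#' @export
evaluation_config <- function(panel_size = 20L, low_cutoff = 2,
                              high_cutoff = 50, n_draws = 10000L,
                              seed = NULL, ci_multiplier = 1.96) {
  assert_scalar_number(panel_size, "panel_size")
  assert_scalar_number(low_cutoff, "low_cutoff")
  assert_scalar_number(high_cutoff, "high_cutoff")
  if (low_cutoff < 0 || low_cutoff > 100 || high_cutoff < 0 ||
      high_cutoff > 100) {
    abort("conversion cutoffs must lie in [0, 100]")
  }
  assert_scalar_number(n_draws, "n_draws")
  if (n_draws < 1) abort("`n_draws` must be >= 1")
  if (!is.null(seed)) assert_scalar_number(seed, "seed")
  structure(
    list(panel_size = as.integer(panel_size), low_cutoff = low_cutoff,
         high_cutoff = high_cutoff, n_draws = as.integer(n_draws),
         seed = seed, ci_multiplier = ci_multiplier),
    class = "evaluation_config"
  )
}

#' Weight-tuning grid
#'
#' @param lo,hi Inclusive grid bounds for each tuned weight (defaults -10
#'   and 10).
#' @param step Grid spacing (default 1.0).
#' @param tuned_weights Which weights to tune; the remainder stay at their
#'   values in the base [scoring_weights()].
#' @return A `tuning_grid` list.
#' @export
tuning_grid <- function(lo = -10, hi = 10, step = 1.0,
                        tuned_weights = c("w_vina", "w_acidic", "w_his",
                                          "w_basic")) {
  assert_scalar_number(lo, "lo"); assert_scalar_number(hi, "hi")
  if (lo > hi) abort("`lo` must not exceed `hi`")
  assert_scalar_number(step, "step")
  if (step <= 0) abort("`step` must be positive")
  known <- c("w_vina", "w_acidic", "w_his", "w_basic")
  if (length(tuned_weights) == 0 || !all(tuned_weights %in% known)) {
    abort("`tuned_weights` must be a nonempty subset of ",
          paste(known, collapse = ", "))
  }
  structure(
    list(lo = lo, hi = hi, step = step, tuned_weights = tuned_weights),
    class = "tuning_grid"
  )
}
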