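# Deterministic fixture generators: toy receptors with residues at exact
# distances, cofactor with a labeled C4 atom, pose sets on controlled
# C4...N distance grids, synthetic screening panels, Ramachandran chains.
# Every generator re-measures its own geometric claims and stores the
# achieved values alongside the requested ones.

#' Minimal imine substrate used by the fixture generators
#'
#' Four heavy atoms of a toy ketimine: the iminium carbon at the origin, the
#' imine nitrogen 1.25 Angstroms along +x (atom index 2), and two flanking
#' carbons. Coordinates are dyadic rationals, so axis-aligned fixture
#' placements at dyadic target distances are exact in floating point.
#'
#' @return Data frame with columns `name`, `element`, `x`, `y`, `z`.
#' @export
default_substrate <- function() {
  data.frame(
    name = c("C1", "N1", "C2", "C3"),
    element = c("C", "N", "C", "C"),
    x = c(0, 1.25, -0.75, -0.75),
    y = c(0, 0, 1.25, -1.25),
    z = c(0, 0, 0, 0)
  )
}

# unit directions used for residue placement: axis-aligned slots first
# (exact arithmetic), then a golden-spiral fill
placement_directions <- function(n) {
  axes <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0),
                c(0, 0, 1))
  if (n <= nrow(axes)) return(axes[seq_len(n), , drop = FALSE])
  extra <- n - nrow(axes)
  i <- seq_len(extra)
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i - 0.5) / max(extra, 1)
  r <- sqrt(pmax(1 - z^2, 0))
  th <- golden * i + 0.7  # offset keeps spiral points off the axes
  rbind(axes, cbind(r * cos(th), r * sin(th), z))
}

# place a point along direction u whose min distance to `coords` is d
place_at_min_distance <- function(coords, u, d) {
  proj <- as.numeric(coords %*% u)
  s <- coords[which.max(proj), ]
  p <- s + d * u
  achieved <- min(sqrt(rowSums(sweep(coords, 2, p)^2)))
  if (abs(achieved - d) > 1e-9) {
    f <- function(t) {
      q <- s + t * u
      min(sqrt(rowSums(sweep(coords, 2, q)^2))) - d
    }
    t_star <- uniroot(f, c(0, d + 20), tol = 1e-13)$root
    p <- s + t_star * u
    achieved <- min(sqrt(rowSums(sweep(coords, 2, p)^2)))
    if (abs(achieved - d) > 1e-6) {
      abort("unsatisfiable residue placement at distance ", d)
    }
  }
  list(xyz = p, achieved = achieved)
}

#' Generate a toy receptor with residues at exact shell distances
#'
#' Builds a receptor whose listed residues sit at exactly the requested
#' minimum heavy-atom distances from the substrate (to within 1e-6
#' Angstroms; axis-aligned slots are exact), plus a 5-atom cofactor group
#' with a labeled C4 atom placed so that the C4...N distance to the
#' substrate pose equals `c4_n_distance`, and the corresponding pose. The
#' generator re-measures every placement and stores the achieved distances.
#'
#' @param placements Data frame with columns `resname` and `distance`
#'   (target min heavy-atom distance in Angstroms), or `NULL` for none.
#' @param c4_n_distance Requested C4...N distance (Angstroms).
#' @param substrate Substrate atom data frame (default
#'   [default_substrate()]).
#' @param n_atom_index 1-based index of the imine nitrogen in `substrate`.
#' @param vina_score Binding score attached to the generated pose.
#' @param model_id Receptor id.
#' @param cofactor_resname Cofactor residue name.
#' @return List with `receptor` (a [structure_model()]), `pose` (a
#'   [pose()]), and `achieved` (data frame of requested vs re-measured
#'   distances, including the C4...N distance).
#' @export
make_receptor <- function(placements = NULL, c4_n_distance = 4.2,
                          substrate = default_substrate(),
                          n_atom_index = 2L, vina_score = -8.0,
                          model_id = "fixture_receptor",
                          cofactor_resname = "NAP") {
  sub_xyz <- coords_of(substrate)
  n_xyz <- sub_xyz[n_atom_index, ]

  # distant anchor residue: keeps the receptor a valid protein even with
  # no shell placements, without ever entering the 8 A shell
  ctr <- colMeans(sub_xyz)
  anchor <- data.frame(
    record = "ATOM", name = "CA", element = "C", resname = "ALA",
    resid = 99L, chain = "A", x = ctr[1], y = ctr[2], z = ctr[3] + 40
  )

  rows <- list(anchor)
  achieved <- data.frame(what = character(0), requested = numeric(0),
                         achieved = numeric(0))
  if (!is.null(placements) && nrow(placements) > 0) {
    if (any(placements$distance <= 0)) {
      abort("placement distances must be positive")
    }
    dirs <- placement_directions(nrow(placements))
    for (i in seq_len(nrow(placements))) {
      pl <- place_at_min_distance(sub_xyz, dirs[i, ],
                                  placements$distance[i])
      rows[[i + 1L]] <- data.frame(
        record = "ATOM", name = "CA", element = "C",
        resname = placements$resname[i], resid = 100L + i,
        chain = "A", x = pl$xyz[1], y = pl$xyz[2], z = pl$xyz[3]
      )
      achieved <- rbind(achieved, data.frame(
        what = paste0(placements$resname[i], "_", 100L + i),
        requested = placements$distance[i], achieved = pl$achieved
      ))
    }
  }

  # cofactor below the substrate plane; C4 exactly c4_n_distance from N
  c4 <- n_xyz + c(0, 0, -c4_n_distance)
  cof_offsets <- rbind(C4 = c(0, 0, 0), C3N = c(1.40, 0, -0.40),
                       C5N = c(-1.40, 0, -0.40), N1N = c(0.70, 1.20, -0.80),
                       C2N = c(-0.70, -1.20, -0.80))
  cof <- data.frame(
    record = "HETATM", name = rownames(cof_offsets), element = "C",
    resname = cofactor_resname, resid = 901L, chain = "A",
    x = c4[1] + cof_offsets[, 1], y = c4[2] + cof_offsets[, 2],
    z = c4[3] + cof_offsets[, 3]
  )
  cof$element[cof$name == "N1N"] <- "N"

  atoms <- do.call(rbind, c(rows, list(cof)))
  receptor <- structure_model(atoms, model_id = model_id)
  p <- pose(substrate, vina_score = vina_score,
            n_atom_index = n_atom_index, pose_index = 1L)
  achieved <- rbind(achieved, data.frame(
    what = "c4_n", requested = c4_n_distance,
    achieved = sqrt(sum((c4 - n_xyz)^2))
  ))
  if (any(abs(achieved$requested - achieved$achieved) > 1e-6)) {
    abort("fixture self-check failed: achieved distances deviate")
  }
  list(receptor = receptor, pose = p, achieved = achieved)
}

#' Generate a pose set at controlled C4...N distances
#'
#' Translates the base pose rigidly along the C4-to-nitrogen axis so that
#' each output pose has exactly the requested C4...N distance, and attaches
#' the given binding scores.
#'
#' @param distances Requested C4...N distances (Angstroms).
#' @param scores Binding scores, aligned with `distances`.
#' @param base The base [pose()] (e.g. from [make_receptor()]).
#' @param c4_xyz Coordinates of the cofactor C4 atom.
#' @return List of [pose()] objects with `pose_index` 1..n; the re-measured
#'   distances are stored in attribute `"achieved"`.
#' @export
make_pose_set <- function(distances, scores, base, c4_xyz) {
  if (length(distances) != length(scores)) {
    abort("`distances` and `scores` differ in length")
  }
  n0 <- as.numeric(base$substrate_atoms[base$n_atom_index,
                                        c("x", "y", "z")])
  v <- n0 - c4_xyz
  d0 <- sqrt(sum(v^2))
  if (d0 < 1e-9) abort("base pose nitrogen coincides with C4")
  u <- v / d0
  out <- vector("list", length(distances))
  achieved <- numeric(length(distances))
  for (i in seq_along(distances)) {
    shift <- (distances[i] - d0) * u
    at <- base$substrate_atoms
    at$x <- at$x + shift[1]; at$y <- at$y + shift[2]
    at$z <- at$z + shift[3]
    # pin the nitrogen exactly at c4 + d*u so the requested distance is
    # reproduced without accumulating translation round-off
    at[base$n_atom_index, c("x", "y", "z")] <-
      as.list(c4_xyz + distances[i] * u)
    out[[i]] <- pose(at, vina_score = scores[i],
                     n_atom_index = base$n_atom_index, pose_index = i)
    n_new <- as.numeric(at[base$n_atom_index, c("x", "y", "z")])
    achieved[i] <- sqrt(sum((n_new - c4_xyz)^2))
  }
  if (any(abs(achieved - distances) > 1e-9)) {
    abort("fixture self-check failed: pose distances deviate")
  }
  attr(out, "achieved") <- achieved
  out
}

# next backbone atom from the previous three by bond/angle/torsion (NeRF)
place_next_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- torsion_deg * pi / 180
  bc <- c - b
  bc_n <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc_n[3] - ab[3] * bc_n[2],
         ab[3] * bc_n[1] - ab[1] * bc_n[3],
         ab[1] * bc_n[2] - ab[2] * bc_n[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc_n[3] - n[3] * bc_n[2],
         n[3] * bc_n[1] - n[1] * bc_n[3],
         n[1] * bc_n[2] - n[2] * bc_n[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc_n + d2[2] * m + d2[3] * n
}

#' Generate a backbone chain with a controlled core fraction
#'
#' Builds an N-CA-C backbone (ideal bond lengths/angles, trans peptide)
#' whose assessed residues have phi/psi dihedrals set to an ideal-helix
#' point inside the favorable/core region for the first
#' `round(core_fraction * n_assessed)` of them and to a point outside the
#' region for the rest. With the two terminal residues (no complete
#' dihedral neighborhood), the chain has `n_assessed + 2` residues, so core
#' fractions on a 1/n_assessed grid are represented exactly.
#'
#' @param n_assessed Number of residues with measurable phi/psi.
#' @param core_fraction Target fraction of assessed residues in the core.
#' @param core_angles,outside_angles `(phi, psi)` pairs used for the two
#'   classes (defaults: ideal helix (-60, -45); outside point (60, 60)).
#' @param chain Chain id.
#' @param model_id Model id.
#' @return A [structure_model()] with attribute `"achieved_core_fraction"`,
#'   the core fraction re-measured from the generated coordinates.
#' @export
make_rama_chain <- function(n_assessed = 100L, core_fraction = 1.0,
                            core_angles = c(-60, -45),
                            outside_angles = c(60, 60),
                            chain = "H", model_id = "rama_chain") {
  assert_fraction(core_fraction, "core_fraction")
  n_res <- n_assessed + 2L
  k <- round(core_fraction * n_assessed)
  # phi/psi per residue; terminal values are unassessed filler
  phis <- c(core_angles[1],
            rep(core_angles[1], k), rep(outside_angles[1], n_assessed - k),
            core_angles[1])
  psis <- c(core_angles[2],
            rep(core_angles[2], k), rep(outside_angles[2], n_assessed - k),
            core_angles[2])

  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.2; a_cacn <- 116.2; a_cnca <- 121.7
  xyz <- matrix(NA_real_, nrow = 3L * n_res, ncol = 3)
  # residue 1 seed triad in the xy-plane
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(b_nca, 0, 0)
  ang <- a_ncac * pi / 180
  xyz[3, ] <- xyz[2, ] + b_cac * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_res - 1L)) {
    base <- 3L * (i - 1L)
    xyz[base + 4L, ] <- place_next_atom(xyz[base + 1L, ], xyz[base + 2L, ],
                                        xyz[base + 3L, ], b_cn, a_cacn,
                                        psis[i])
    xyz[base + 5L, ] <- place_next_atom(xyz[base + 2L, ], xyz[base + 3L, ],
                                        xyz[base + 4L, ], b_nca, a_cnca,
                                        180)
    xyz[base + 6L, ] <- place_next_atom(xyz[base + 3L, ], xyz[base + 4L, ],
                                        xyz[base + 5L, ], b_cac, a_ncac,
                                        phis[i + 1L])
  }
  atoms <- data.frame(
    record = "ATOM",
    name = rep(c("N", "CA", "C"), n_res),
    element = rep(c("N", "C", "C"), n_res),
    resname = "ALA",
    resid = rep(seq_len(n_res), each = 3L),
    chain = chain,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
  m <- structure_model(atoms, model_id = model_id)
  pp <- chain_phi_psi(m, chain)
  achieved <- mean(in_region_map(pp$phi, pp$psi,
                                 default_core_regions()))
  target <- k / n_assessed
  if (nrow(pp) != n_assessed || abs(achieved - target) > 1e-9) {
    abort("fixture self-check failed: achieved core fraction ", achieved,
          " != target ", target)
  }
  attr(m, "achieved_core_fraction") <- achieved
  m
}

#' Generate a synthetic screening panel
#'
#' Emulates an IRED screening campaign: a set of sequence ids with percent
#' conversions, plus the calibration table (binding score and active-site
#' counts per sequence) used for weight tuning. In `uniform` mode
#' conversions are drawn uniformly on \[0, 100\]. In `score_linked` mode
#' each sequence gets a binding score and residue counts, a true refined
#' score under `true_weights`, and a conversion that is a strictly
#' decreasing affine map of that score plus Gaussian noise (sd =
#' `noise_sd`), clipped to \[0, 100\] — so with zero noise the true score
#' ordering and the conversion ordering coincide, enabling
#' tuning-recovery tests.
#'
#' @param n_sequences Panel size.
#' @param conversion_model `"uniform"` or `"score_linked"`.
#' @param noise_sd Conversion noise standard deviation in percent.
#' @param seed Seed (required; the generator is deterministic under it).
#' @param true_weights Weights defining the true score in `score_linked`
#'   mode.
#' @return List with `outcomes` (sequence_id, conversion), `calibration`
#'   (sequence_id, vina_score, n_acidic, n_basic, n_his, conversion) and
#'   `true_weights`.
#' @export
make_panel <- function(n_sequences, conversion_model = c("uniform",
                                                         "score_linked"),
                       noise_sd = 5, seed = 1L,
                       true_weights = scoring_weights()) {
  conversion_model <- match.arg(conversion_model)
  if (n_sequences < 1) abort("`n_sequences` must be >= 1")
  ids <- sprintf("seq_%04d", seq_len(n_sequences))
  local_seed(seed, {
    vina <- runif(n_sequences, -12, -4)
    n_acidic <- sample(0:3, n_sequences, replace = TRUE)
    n_basic <- sample(0:2, n_sequences, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1))
    n_his <- stats::rbinom(n_sequences, 1, 0.6)
    if (conversion_model == "uniform") {
      conversion <- runif(n_sequences, 0, 100)
    } else {
      s <- true_weights$w_vina * vina + true_weights$w_acidic * n_acidic -
        true_weights$w_his * n_his + true_weights$w_basic * n_basic
      span <- max(s) - min(s)
      if (span < 1e-12) span <- 1
      clean <- 95 * (max(s) - s) / span + 2
      conversion <- pmin(pmax(clean + rnorm(n_sequences, 0, noise_sd), 0),
                         100)
    }
  })
  list(
    outcomes = data.frame(sequence_id = ids, conversion = conversion),
    calibration = data.frame(sequence_id = ids, vina_score = vina,
                             n_acidic = n_acidic, n_basic = n_basic,
                             n_his = n_his, conversion = conversion),
    true_weights = true_weights
  )
}

#' Generate a random protein sequence
#'
#' @param length Sequence length.
#' @param seed Seed.
#' @return A single amino-acid string over the 20 standard letters.
#' @export
random_protein <- function(length, seed = 1L) {
  local_seed(seed, {
    s <- paste(sample(setdiff(AA_ALPHABET20X, "X"), length,
                      replace = TRUE), collapse = "")
  })
  s
}

#' Mutate a protein sequence at random positions
#'
#' @param seq Amino-acid string.
#' @param n_subs Number of point substitutions.
#' @param seed Seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, n_subs, seed = 1L) {
  ch <- strsplit(seq, "")[[1]]
  n_subs <- min(n_subs, length(ch))
  local_seed(seed, {
    pos <- sample(seq_along(ch), n_subs)
    for (p in pos) {
      ch[p] <- sample(setdiff(setdiff(AA_ALPHABET20X, "X"), ch[p]), 1)
    }
  })
  paste(ch, collapse = "")
}
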