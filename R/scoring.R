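# Core rescoring: catalytic-geometry pose selection, active-site residue
# profiling, the count-modified refined score, ranking, panel selection.

#' Distance from the cofactor C4 atom to the pose's imine nitrogen
#'
#' The hydride transferred during imine reduction leaves from the C4 atom of
#' the NADPH nicotinamide ring; its distance to the imine nitrogen of the
#' docked substrate is the catalytic-competence criterion used to screen
#' poses.
#'
#' @param p A [pose()].
#' @param receptor Receptor [structure_model()] containing exactly one
#'   cofactor atom named `cfg$c4_atom_name` in the `cfg$cofactor_resname`
#'   group.
#' @param cfg A [pose_filter_config()].
#' @return Euclidean C4...N distance in Angstroms.
#' @export
c4_n_distance <- function(p, receptor, cfg = pose_filter_config()) {
  i <- which(receptor$resname == cfg$cofactor_resname &
               receptor$name == cfg$c4_atom_name)
  if (length(i) != 1) {
    abort("receptor must contain exactly one ", cfg$cofactor_resname, " ",
          cfg$c4_atom_name, " atom; found ", length(i))
  }
  c4 <- c(receptor$x[i], receptor$y[i], receptor$z[i])
  n <- as.numeric(p$substrate_atoms[p$n_atom_index, c("x", "y", "z")])
  sqrt(sum((c4 - n)^2))
}

#' Select the catalytically most plausible pose
#'
#' Removes poses whose C4...N distance is strictly below `min_distance`
#' (clash) or strictly above `max_distance` (beyond hydride-transfer range),
#' then returns the surviving pose with the smallest distance. Distance ties
#' break to the lower binding score, then to the lower pose index.
#'
#' @param poses List of [pose()] objects.
#' @param distances Numeric vector of C4...N distances aligned with `poses`.
#' @param cfg A [pose_filter_config()].
#' @return List with elements `pose` and `distance`, or `NULL` when no pose
#'   survives the distance window.
#' @export
select_best_pose <- function(poses, distances,
                             cfg = pose_filter_config()) {
  if (length(poses) != length(distances)) {
    abort("`poses` and `distances` differ in length")
  }
  keep <- which(distances >= cfg$min_distance &
                  distances <= cfg$max_distance)
  if (length(keep) == 0) return(NULL)
  scores <- vapply(poses, `[[`, numeric(1), "vina_score")
  idx <- vapply(poses, `[[`, integer(1), "pose_index")
  best <- keep[order(distances[keep], scores[keep], idx[keep])][1]
  list(pose = poses[[best]], distance = distances[best])
}

# map protonation-state residue-name variants onto canonical names so
# counts do not depend on the file dialect
normalize_resname <- function(resname) {
  map <- c(HID = "HIS", HIE = "HIS", HIP = "HIS", HSD = "HIS",
           HSE = "HIS", HSP = "HIS", ASH = "ASP", GLH = "GLU",
           LYN = "LYS", ARN = "ARG", CYX = "CYS")
  out <- unname(map[resname])
  ifelse(is.na(out), resname, out)
}

#' Profile the active-site shell around a docked substrate
#'
#' A protein residue is in the shell when the minimum heavy-atom distance
#' between its atoms and the substrate atoms is at most `cfg$radius`
#' (inclusive). Cofactor and substrate atoms are excluded from the census;
#' all chains are considered; hydrogens are ignored. Counts acidic and basic
#' residues and flags the presence of histidine
#' (`n_his` is 0/1 regardless of how many histidines fall in the shell).
#'
#' @param receptor Receptor [structure_model()].
#' @param p The selected [pose()].
#' @param cfg A [shell_config()].
#' @param cofactor_resname Residue name excluded from the census.
#' @return An `active_site_profile` list with `n_acidic`, `n_basic`,
#'   `n_his` and a `shell_residues` data frame (chain, resid, resname,
#'   min_distance).
#' @export
active_site_profile <- function(receptor, p, cfg = shell_config(),
                                cofactor_resname = "NAP") {
  prot <- receptor[receptor$record == "ATOM" &
                     receptor$resname != cofactor_resname &
                     !(receptor$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(prot) == 0) abort("receptor has no protein residues")
  sub <- p$substrate_atoms[!(p$substrate_atoms$element %in% c("H", "D")),
                           , drop = FALSE]
  if (nrow(sub) == 0) abort("pose has no heavy atoms")
  d <- cross_dist(coords_of(prot), coords_of(sub))
  mind <- apply(d, 1, min)
  key <- paste(prot$chain, prot$resid, sep = "\r")
  res_min <- tapply(mind, key, min)
  first <- !duplicated(key)
  info <- data.frame(chain = prot$chain[first], resid = prot$resid[first],
                     resname = normalize_resname(prot$resname[first]),
                     key = key[first])
  info$min_distance <- as.numeric(res_min[info$key])
  shell <- info[info$min_distance <= cfg$radius,
                c("chain", "resid", "resname", "min_distance")]
  shell <- shell[order(shell$min_distance), , drop = FALSE]
  rownames(shell) <- NULL
  structure(
    list(n_acidic = sum(shell$resname %in% cfg$acidic_set),
         n_basic = sum(shell$resname %in% cfg$basic_set),
         n_his = as.integer(any(shell$resname %in% cfg$his_set)),
         shell_residues = shell),
    class = "active_site_profile"
  )
}

#' Active-site profile from bare counts
#'
#' Convenience constructor used by calibration tables and worked examples
#' where the counts are given directly rather than measured from a
#' structure.
#'
#' @param n_acidic,n_basic Nonnegative residue counts.
#' @param n_his 0 or 1.
#' @return An `active_site_profile` list (empty `shell_residues`).
#' @export
site_profile <- function(n_acidic = 0L, n_basic = 0L, n_his = 0L) {
  if (n_acidic < 0 || n_basic < 0) abort("residue counts must be >= 0")
  if (!n_his %in% c(0L, 1L)) abort("`n_his` must be 0 or 1")
  structure(
    list(n_acidic = as.integer(n_acidic), n_basic = as.integer(n_basic),
         n_his = as.integer(n_his),
         shell_residues = data.frame(chain = character(0),
                                     resid = integer(0),
                                     resname = character(0),
                                     min_distance = numeric(0))),
    class = "active_site_profile"
  )
}

#' Residue-count-modified binding score
#'
#' `w_vina * vina_score + w_acidic * n_acidic - w_his * n_his +
#' w_basic * n_basic`, with the tuned defaults 4.0, 1.0, 9.0, 9.0.
#' Lower is better: the dominant docking term is negative-better, an
#' active-site histidine (catalytic proton donor) improves the score, and
#' basic residues (which compete with the iminium intermediate) worsen it.
#'
#' @param vina_score Binding score of the selected pose.
#' @param profile An `active_site_profile`.
#' @param w A [scoring_weights()].
#' @return The refined score.
#' @export
refined_score <- function(vina_score, profile, w = scoring_weights()) {
  w$w_vina * vina_score + w$w_acidic * profile$n_acidic -
    w$w_his * profile$n_his + w$w_basic * profile$n_basic
}

#' Construct a scored candidate
#'
#' One row of the ranking: a candidate is `scored` exactly when a pose
#' survived the distance filter and all scoring fields are present;
#' otherwise the status records where it dropped out (`no_valid_pose`,
#' `model_unqualified`, `not_homolog`).
#'
#' @param sequence_id Candidate id.
#' @param status One of `scored`, `no_valid_pose`, `model_unqualified`,
#'   `not_homolog`.
#' @param selected_pose The selected [pose()] (scored candidates only).
#' @param c4_n_distance Its C4...N distance.
#' @param profile Its `active_site_profile`.
#' @param refined_score Its refined score.
#' @return A `scored_candidate` list.
#' @export
scored_candidate <- function(sequence_id,
                             status = c("scored", "no_valid_pose",
                                        "model_unqualified", "not_homolog"),
                             selected_pose = NULL, c4_n_distance = NULL,
                             profile = NULL, refined_score = NULL) {
  status <- match.arg(status)
  full <- !is.null(selected_pose) && !is.null(c4_n_distance) &&
    !is.null(profile) && !is.null(refined_score)
  if ((status == "scored") != full) {
    abort("status 'scored' requires (exactly) all scoring fields present")
  }
  structure(
    list(sequence_id = sequence_id, status = status,
         selected_pose = selected_pose, c4_n_distance = c4_n_distance,
         profile = profile, refined_score = refined_score),
    class = "scored_candidate"
  )
}

#' Rank scored candidates by refined score
#'
#' Scored candidates are sorted by refined score ascending (lower = better);
#' ties break to the lower binding score, then to the lexicographically
#' smaller sequence id. Candidates that dropped out earlier keep their
#' status and are appended after the scored ones in input order.
#'
#' @param candidates List of [scored_candidate()] objects.
#' @return The reordered list.
#' @export
rank_candidates <- function(candidates) {
  if (length(candidates) == 0) return(candidates)
  status <- vapply(candidates, `[[`, character(1), "status")
  scored <- candidates[status == "scored"]
  rest <- candidates[status != "scored"]
  if (length(scored) > 0) {
    rs <- vapply(scored, `[[`, numeric(1), "refined_score")
    vina <- vapply(scored, function(c) c$selected_pose$vina_score,
                   numeric(1))
    ids <- vapply(scored, `[[`, character(1), "sequence_id")
    scored <- scored[order(rs, vina, ids)]
  }
  c(scored, rest)
}

#' Select the screening panel from a ranking
#'
#' @param ranked Output of [rank_candidates()].
#' @param k Panel size (default 20).
#' @return The first `min(k, number of scored candidates)` scored
#'   candidates.
#' @export
select_panel <- function(ranked, k = 20L) {
  assert_scalar_number(k, "k")
  if (k < 0) abort("`k` must be >= 0")
  status <- vapply(ranked, `[[`, character(1), "status")
  scored <- ranked[status == "scored"]
  head(scored, k)
}

#' Tabulate a ranking for export
#'
#' @param ranked Output of [rank_candidates()].
#' @return Data frame with columns rank (NA for unscored), sequence_id,
#'   vina_score, c4_n_distance, n_acidic, n_basic, n_his, refined_score,
#'   status.
#' @export
ranking_table <- function(ranked) {
  if (length(ranked) == 0) {
    return(data.frame(rank = integer(0), sequence_id = character(0),
                      vina_score = numeric(0), c4_n_distance = numeric(0),
                      n_acidic = integer(0), n_basic = integer(0),
                      n_his = integer(0), refined_score = numeric(0),
                      status = character(0)))
  }
  rows <- lapply(ranked, function(c) {
    scored <- c$status == "scored"
    data.frame(
      sequence_id = c$sequence_id,
      vina_score = if (scored) c$selected_pose$vina_score else NA_real_,
      c4_n_distance = if (scored) c$c4_n_distance else NA_real_,
      n_acidic = if (scored) c$profile$n_acidic else NA_integer_,
      n_basic = if (scored) c$profile$n_basic else NA_integer_,
      n_his = if (scored) c$profile$n_his else NA_integer_,
      refined_score = if (scored) c$refined_score else NA_real_,
      status = c$status
    )
  })
  out <- do.call(rbind, rows)
  out$rank <- NA_integer_
  out$rank[out$status == "scored"] <- seq_len(sum(out$status == "scored"))
  out[, c("rank", "sequence_id", "vina_score", "c4_n_distance",
          "n_acidic", "n_basic", "n_his", "refined_score", "status")]
}

#' Write a ranking to CSV
#'
#' @param ranked Output of [rank_candidates()].
#' @param path Output path.
#' @export
write_ranking <- function(ranked, path) {
  write.csv(ranking_table(ranked), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
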