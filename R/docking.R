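# Docking support: box construction from the reference ligand and substrate
# gyration radius, pose-file I/O, docking backend contract.

#' Radius of gyration of a coordinate set
#'
#' Unweighted root-mean-square distance of the atoms to their centroid.
#'
#' @param coords n x 3 coordinate matrix (Angstroms).
#' @return Radius of gyration in Angstroms.
#' @export
radius_of_gyration <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) abort("radius of gyration of an empty set")
  ctr <- colMeans(coords)
  sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
}

#' Construct the docking box
#'
#' The box is centered on the centroid of the template's bound reference
#' ligand (which marks the active site) and is cubic with edge
#' `max(box_scale * Rg(substrate), min_edge)`, following the published
#' box-sizing rule of edge ~ 2.9 x the ligand radius of gyration with a
#' floor for very small substrates.
#'
#' @param reference_ligand Atom data frame (or n x 3 matrix) of the
#'   template's bound ligand.
#' @param substrate Atom data frame (or n x 3 matrix) of the substrate.
#' @param cfg A [docking_config()].
#' @return A `docking_box` list with `center` (3-vector) and `edge`
#'   (3-vector, equal components for the default cube).
#' @export
compute_box <- function(reference_ligand, substrate,
                        cfg = docking_config()) {
  ref <- if (is.data.frame(reference_ligand)) coords_of(reference_ligand)
    else as.matrix(reference_ligand)
  sub <- if (is.data.frame(substrate)) coords_of(substrate)
    else as.matrix(substrate)
  if (nrow(ref) == 0 || nrow(sub) == 0) {
    abort("reference ligand and substrate must be nonempty")
  }
  edge <- max(cfg$box_scale * radius_of_gyration(sub), cfg$min_edge)
  structure(
    list(center = colMeans(ref), edge = rep(edge, 3)),
    class = "docking_box"
  )
}

#' Construct a docked pose
#'
#' @param substrate_atoms Data frame with columns `name`, `element`, `x`,
#'   `y`, `z` (one row per substrate atom).
#' @param vina_score Docking binding score (lower = better).
#' @param n_atom_index 1-based row index of the imine nitrogen in
#'   `substrate_atoms`.
#' @param pose_index 1-based pose number.
#' @return A `pose` list.
#' @export
pose <- function(substrate_atoms, vina_score, n_atom_index,
                 pose_index = 1L) {
  need <- c("name", "element", "x", "y", "z")
  if (!is.data.frame(substrate_atoms) ||
      !all(need %in% names(substrate_atoms))) {
    abort("`substrate_atoms` must have columns ",
          paste(need, collapse = ", "))
  }
  assert_scalar_number(vina_score, "vina_score")
  assert_scalar_number(n_atom_index, "n_atom_index")
  if (n_atom_index < 1 || n_atom_index > nrow(substrate_atoms)) {
    abort("`n_atom_index` out of range (1-based atom index)")
  }
  structure(
    list(pose_index = as.integer(pose_index),
         substrate_atoms = as.data.frame(substrate_atoms)[, need],
         vina_score = vina_score,
         n_atom_index = as.integer(n_atom_index)),
    class = "pose"
  )
}

#' Fixture docking backend
#'
#' Stands in for a docking engine behind the docking contract: pose sets are
#' looked up from a named list keyed by `"<receptor id>/<substrate id>"`.
#'
#' @param pose_sets Named list; each element a list of [pose()] objects.
#' @return A `docking_backend` object for [dock()].
#' @export
fixture_docking_backend <- function(pose_sets) {
  if (!is.list(pose_sets) || is.null(names(pose_sets))) {
    abort("`pose_sets` must be a named list of pose lists")
  }
  structure(list(pose_sets = pose_sets),
            class = c("fixture_docking_backend", "docking_backend"))
}

#' Dock a substrate into a receptor (docking backend contract)
#'
#' @param backend A docking backend.
#' @param receptor Receptor [structure_model()] (cofactor already placed).
#' @param substrate_id Substrate identifier.
#' @param box A `docking_box` from [compute_box()].
#' @param cfg A [docking_config()]; recorded as attribute `"config"` of the
#'   returned pose list.
#' @return List of [pose()] objects sorted by `vina_score` ascending.
#' @export
dock <- function(backend, receptor, substrate_id, box,
                 cfg = docking_config()) {
  UseMethod("dock")
}

#' @export
dock.fixture_docking_backend <- function(backend, receptor, substrate_id,
                                         box, cfg = docking_config()) {
  key <- paste0(model_id(receptor), "/", substrate_id)
  poses <- backend$pose_sets[[key]]
  if (is.null(poses)) {
    abort("no fixture pose set stored for '", key, "'")
  }
  poses <- poses[order(vapply(poses, `[[`, numeric(1), "vina_score"))]
  attr(poses, "config") <- cfg
  poses
}

#' Read docked poses from a multi-model coordinate file
#'
#' Expects the docking-output dialect written by [write_poses()]:
#' MODEL/ENDMDL blocks, each carrying a `REMARK VINA RESULT:` score line, a
#' `REMARK N_ATOM_INDEX` line, and HETATM substrate atoms.
#'
#' @param path Path to the pose file.
#' @return List of [pose()] objects in file order.
#' @export
read_poses <- function(path) {
  if (!file.exists(path)) abort("pose file not found: ", path)
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) != length(ends)) {
    abort("unbalanced MODEL/ENDMDL blocks in ", path)
  }
  lapply(seq_along(starts), function(k) {
    block <- lines[starts[k]:ends[k]]
    idx <- as.integer(sub("^MODEL\\s+", "", block[1]))
    score_line <- grep("^REMARK VINA RESULT:", block, value = TRUE)
    if (length(score_line) == 0) {
      abort("pose ", idx, " lacks a REMARK VINA RESULT score line")
    }
    score <- as.numeric(strsplit(trimws(
      sub("^REMARK VINA RESULT:", "", score_line[1])), "\\s+")[[1]][1])
    n_line <- grep("^REMARK N_ATOM_INDEX", block, value = TRUE)
    if (length(n_line) == 0) {
      abort("pose ", idx, " lacks a REMARK N_ATOM_INDEX line")
    }
    n_idx <- as.integer(sub("^REMARK N_ATOM_INDEX\\s+", "", n_line[1]))
    at_lines <- grep("^(ATOM  |HETATM)", block)
    if (length(at_lines) == 0) abort("pose ", idx, " has no atoms")
    rows <- lapply(at_lines, function(i) {
      parse_pdb_line(block[i], starts[k] + i - 1L)
    })
    atoms <- do.call(rbind, lapply(rows, as.data.frame))
    pose(atoms[, c("name", "element", "x", "y", "z")],
         vina_score = score, n_atom_index = n_idx, pose_index = idx)
  })
}

#' Write docked poses to a multi-model coordinate file
#'
#' Round-trips through [read_poses()] preserving coordinates (3 decimals),
#' scores, the imine-nitrogen index and pose order.
#'
#' @param poses List of [pose()] objects.
#' @param path Output path.
#' @export
write_poses <- function(poses, path) {
  out <- character(0)
  for (p in poses) {
    at <- p$substrate_atoms
    lines <- vapply(seq_len(nrow(at)), function(i) {
      format_pdb_atom(list(record = "HETATM", name = at$name[i],
                           element = at$element[i], resname = "LIG",
                           chain = "X", resid = 1L,
                           x = at$x[i], y = at$y[i], z = at$z[i]), i)
    }, character(1))
    out <- c(out,
             sprintf("MODEL %8d", p$pose_index),
             sprintf("REMARK VINA RESULT: %10.3f", p$vina_score),
             sprintf("REMARK N_ATOM_INDEX %d", p$n_atom_index),
             lines, "ENDMDL")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read substrate coordinates
#'
#' Accepts either an XYZ-style coordinate list (optional count/comment
#' header, then `element x y z` per line) or a V2000 MOL/SD atom block.
#'
#' @param path Path to the substrate file.
#' @return Data frame with columns `name`, `element`, `x`, `y`, `z`.
#' @export
read_substrate <- function(path) {
  if (!file.exists(path)) abort("substrate file not found: ", path)
  lines <- readLines(path)
  if (length(lines) >= 4 &&
      grepl("V2000", lines[4])) {
    counts <- strsplit(trimws(lines[4]), "\\s+")[[1]]
    n_atoms <- as.integer(counts[1])
    rows <- lapply(seq_len(n_atoms), function(i) {
      f <- strsplit(trimws(lines[4 + i]), "\\s+")[[1]]
      data.frame(element = f[4], x = as.numeric(f[1]),
                 y = as.numeric(f[2]), z = as.numeric(f[3]))
    })
    at <- do.call(rbind, rows)
  } else {
    body <- lines[grepl("^\\s*[A-Za-z]{1,2}(\\s+-?[0-9.eE+-]+){3}\\s*$",
                        lines)]
    if (length(body) == 0) abort("no coordinates found in ", path)
    rows <- lapply(body, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      data.frame(element = f[1], x = as.numeric(f[2]),
                 y = as.numeric(f[3]), z = as.numeric(f[4]))
    })
    at <- do.call(rbind, rows)
  }
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")])))) {
    abort("non-numeric coordinates in ", path)
  }
  counts <- ave(seq_along(at$element), at$element, FUN = seq_along)
  at$name <- paste0(toupper(at$element), counts)
  at[, c("name", "element", "x", "y", "z")]
}
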