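# Structure handling: coordinate I/O, Ramachandran qualification, rigid
# superposition onto the template, cofactor transfer, modeling backend.

#' Construct a structure model
#'
#' A structure model is a data frame of atoms with one row per atom and
#' columns `record` (ATOM/HETATM), `name`, `element`, `resname`, `resid`,
#' `chain`, `x`, `y`, `z` (Angstroms), carrying the model id as an
#' attribute.
#'
#' @param atoms Data frame with the columns above.
#' @param model_id Identifier for the model.
#' @return A `structure_model` data frame.
#' @export
structure_model <- function(atoms, model_id = "model") {
  need <- c("record", "name", "element", "resname", "resid", "chain",
            "x", "y", "z")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms))) {
    abort("`atoms` must have columns ", paste(need, collapse = ", "))
  }
  atoms <- as.data.frame(atoms)[, need]
  atoms$resid <- as.integer(atoms$resid)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    abort("atom coordinates must be finite")
  }
  key <- paste(atoms$chain, atoms$resid, atoms$name)
  if (anyDuplicated(key)) {
    abort("duplicate (chain, resid, name) atoms: ",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  rownames(atoms) <- NULL
  structure(atoms, class = c("structure_model", "data.frame"),
            model_id = model_id)
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model '%s': %d atoms, %d residues, chains %s>\n",
              attr(x, "model_id"), nrow(x),
              length(unique(paste(x$chain, x$resid))),
              paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

model_id <- function(model) attr(model, "model_id") %||% "model"

parse_pdb_line <- function(line, lineno) {
  name <- trimws(substr(line, 13, 16))
  resname <- trimws(substr(line, 18, 20))
  chain <- trimws(substr(line, 22, 22))
  resid <- suppressWarnings(as.integer(trimws(substr(line, 23, 26))))
  xyz <- suppressWarnings(as.numeric(c(
    substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54)
  )))
  element <- trimws(substr(line, 77, 78))
  if (!nzchar(element)) element <- substr(gsub("[0-9]", "", name), 1, 1)
  if (!nzchar(name) || !nzchar(resname) || is.na(resid) ||
      any(is.na(xyz))) {
    abort("unparseable coordinate record at line ", lineno, ": ", line)
  }
  list(record = trimws(substr(line, 1, 6)), name = name,
       element = element, resname = resname, resid = resid,
       chain = if (nzchar(chain)) chain else "A",
       x = xyz[1], y = xyz[2], z = xyz[3])
}

#' Read a protein structure from a PDB-dialect file
#'
#' Parses ATOM and HETATM records (fixed-column PDB layout); other record
#' types are ignored. An unparseable coordinate record raises an error
#' naming its line number.
#'
#' @param path Path to the coordinate file.
#' @param model_id Model id; defaults to the file name without extension.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, model_id = NULL) {
  if (!file.exists(path)) abort("structure file not found: ", path)
  lines <- readLines(path)
  sel <- grep("^(ATOM  |HETATM)", lines)
  if (length(sel) == 0) abort("no ATOM/HETATM records in ", path)
  rows <- lapply(sel, function(i) parse_pdb_line(lines[i], i))
  atoms <- do.call(rbind, lapply(rows, as.data.frame))
  structure_model(atoms,
                  model_id = model_id %||%
                    sub("\\.[^.]*$", "", basename(path)))
}

format_pdb_atom <- function(a, serial) {
  name <- if (nchar(a$name) < 4) sprintf(" %-3s", a$name) else a$name
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, serial, name, a$resname, a$chain, a$resid,
          a$x, a$y, a$z, 1.00, 0.00, a$element)
}

#' Write a structure model to a PDB-dialect file
#'
#' Round-trips through [read_structure()] preserving atom names, residue
#' numbering, chain ids and coordinates to 3 decimals.
#'
#' @param model A [structure_model()].
#' @param path Output path.
#' @export
write_structure <- function(model, path) {
  lines <- vapply(seq_len(nrow(model)), function(i) {
    format_pdb_atom(as.list(model[i, ]), i)
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Signed dihedral angle of four points
#'
#' Standard torsion convention: looking down the p2-p3 axis, the angle is
#' positive for a clockwise rotation of p4 relative to p1. Satisfies
#' `dihedral(p1, p2, p3, p4) == dihedral(p4, p3, p2, p1)` and flips sign
#' under mirror reflection.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstroms).
#' @return Angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-12 || sum(n2^2) < 1e-12) {
    abort("degenerate dihedral: three consecutive points are collinear")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

backbone_atom <- function(model, chain, resid, name) {
  i <- which(model$chain == chain & model$resid == resid &
               model$name == name & model$record == "ATOM")
  if (length(i) != 1) return(NULL)
  c(model$x[i], model$y[i], model$z[i])
}

# phi/psi for every residue of a chain where both are computable
chain_phi_psi <- function(model, chain) {
  resids <- sort(unique(model$resid[model$chain == chain &
                                      model$record == "ATOM"]))
  out <- list()
  for (r in resids) {
    prev_c <- backbone_atom(model, chain, r - 1L, "C")
    n <- backbone_atom(model, chain, r, "N")
    ca <- backbone_atom(model, chain, r, "CA")
    cc <- backbone_atom(model, chain, r, "C")
    next_n <- backbone_atom(model, chain, r + 1L, "N")
    if (is.null(prev_c) || is.null(n) || is.null(ca) || is.null(cc) ||
        is.null(next_n)) {
      next
    }
    out[[length(out) + 1L]] <- data.frame(
      chain = chain, resid = r,
      phi = dihedral(prev_c, n, ca, cc),
      psi = dihedral(n, ca, cc, next_n)
    )
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

in_region_map <- function(phi, psi, region_map) {
  hit <- rep(FALSE, length(phi))
  for (i in seq_len(nrow(region_map))) {
    hit <- hit | (phi >= region_map$phi_min[i] &
                    phi <= region_map$phi_max[i] &
                    psi >= region_map$psi_min[i] &
                    psi <= region_map$psi_max[i])
  }
  hit
}

#' Qualify a structure model on the Ramachandran plot
#'
#' Computes backbone phi/psi for every residue with a complete dihedral
#' neighborhood (all chains), classifies each against the favorable/core
#' region map, and qualifies the model when the core fraction reaches the
#' cutoff (inclusive).
#'
#' @param model A [structure_model()].
#' @param cfg A [qualification_config()].
#' @return A `ramachandran_assessment` list with `core_fraction`,
#'   `qualified`, and a `per_residue` data frame (chain, resid, phi, psi,
#'   region label `core`/`outside`).
#' @export
ramachandran_qualify <- function(model, cfg = qualification_config()) {
  chains <- unique(model$chain[model$record == "ATOM"])
  if (length(chains) == 0) abort("model has no protein residues")
  per <- list()
  for (ch in chains) {
    n_res <- length(unique(model$resid[model$chain == ch &
                                         model$record == "ATOM"]))
    if (n_res < 3) {
      warning("chain ", ch, " has fewer than 3 residues; skipped")
      next
    }
    pp <- chain_phi_psi(model, ch)
    if (!is.null(pp)) per[[length(per) + 1L]] <- pp
  }
  if (length(per) == 0) {
    abort("no assessable residues (complete backbone neighborhoods) found")
  }
  per <- do.call(rbind, per)
  core <- in_region_map(per$phi, per$psi, cfg$region_map)
  per$region <- ifelse(core, "core", "outside")
  frac <- mean(core)
  structure(
    list(core_fraction = frac,
         qualified = frac >= cfg$cutoff_fraction,
         per_residue = per),
    class = "ramachandran_assessment"
  )
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired coordinate sets, via SVD of the cross-covariance with the usual
#' determinant correction.
#'
#' @param mobile,reference Paired n x 3 coordinate matrices, n >= 3.
#' @return A `rigid_transform` list with `rotation` (3 x 3, det +1),
#'   `translation` (3-vector) and post-fit `rmsd`; the transform maps
#'   `mobile %*% t(rotation) + translation` onto `reference`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3) {
    abort("`mobile` and `reference` must be equal-size n x 3 matrices")
  }
  if (nrow(mobile) < 3) abort("superposition needs at least 3 point pairs")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  a <- sweep(mobile, 2, mc); b <- sweep(reference, 2, rc)
  h <- crossprod(a, b)
  sv <- svd(h)
  if (sv$d[2] < 1e-10) {
    abort("degenerate (rank-deficient) point configuration")
  }
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- a %*% t(rot)
  rmsd <- sqrt(mean(rowSums((fitted - b)^2)))
  structure(
    list(rotation = rot, translation = as.numeric(rc - rot %*% mc),
         rmsd = rmsd),
    class = "rigid_transform"
  )
}

#' Apply a rigid transform to a structure model
#'
#' @param model A [structure_model()].
#' @param tf A `rigid_transform` from [kabsch_superpose()].
#' @return The transformed model.
#' @export
apply_transform <- function(model, tf) {
  xyz <- coords_of(model) %*% t(tf$rotation)
  xyz <- sweep(xyz, 2, tf$translation, "+")
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}

#' Derive a CA residue pairing from a sequence alignment
#'
#' Matched (gap-free) alignment columns become residue-index pairs, counting
#' from the first residue of each sequence.
#'
#' @param aln A `pairwise_alignment`.
#' @param query_start,template_start Residue number of the first residue.
#' @return Data frame with columns `model_resid`, `template_resid`.
#' @export
pairing_from_alignment <- function(aln, query_start = 1L,
                                   template_start = 1L) {
  qc <- strsplit(aln$query_row, "")[[1]]
  tc <- strsplit(aln$template_row, "")[[1]]
  qi <- cumsum(qc != "-"); ti <- cumsum(tc != "-")
  keep <- qc != "-" & tc != "-"
  data.frame(model_resid = qi[keep] + query_start - 1L,
             template_resid = ti[keep] + template_start - 1L)
}

#' Superpose a model onto the template through paired CA atoms
#'
#' @param model,template [structure_model()] objects.
#' @param pairing Data frame with columns `model_resid`, `template_resid`
#'   and optionally `model_chain`, `template_chain` (default: first protein
#'   chain of each structure).
#' @return `model` with all atoms moved by the CA-fit rigid transform; the
#'   fitted `rigid_transform` is attached as attribute `"transform"`.
#' @export
align_to_template <- function(model, template, pairing) {
  if (!is.data.frame(pairing) || nrow(pairing) == 0) {
    abort("`pairing` must be a nonempty data frame of residue-index pairs")
  }
  mchain <- pairing$model_chain %||%
    rep(model$chain[model$record == "ATOM"][1], nrow(pairing))
  tchain <- pairing$template_chain %||%
    rep(template$chain[template$record == "ATOM"][1], nrow(pairing))
  get_ca <- function(m, chain, resid, label) {
    ca <- backbone_atom(m, chain, resid, "CA")
    if (is.null(ca)) {
      abort("missing CA atom for ", label, " residue ", chain, ":", resid)
    }
    ca
  }
  mob <- t(mapply(function(ch, r) get_ca(model, ch, r, "model"),
                  mchain, pairing$model_resid))
  ref <- t(mapply(function(ch, r) get_ca(template, ch, r, "template"),
                  tchain, pairing$template_resid))
  tf <- kabsch_superpose(mob, ref)
  out <- apply_transform(model, tf)
  attr(out, "transform") <- tf
  out
}

#' Copy the template's cofactor into an aligned model
#'
#' With the model already superposed onto the template, the template's
#' cofactor atoms are copied verbatim (coordinates unchanged) into the model
#' as a hetero group, placing NADPH in the modeled cofactor site.
#'
#' @param model Aligned [structure_model()] without a cofactor.
#' @param template Template [structure_model()] carrying the cofactor.
#' @param cofactor_resname Cofactor residue name (default `"NAP"`).
#' @return `model` with the cofactor atoms appended.
#' @export
transfer_cofactor <- function(model, template, cofactor_resname = "NAP") {
  cof <- template[template$resname == cofactor_resname, , drop = FALSE]
  if (nrow(cof) == 0) {
    abort("template has no residue named ", cofactor_resname)
  }
  if (any(model$resname == cofactor_resname)) {
    abort("model already contains a ", cofactor_resname,
          " group; refusing to overwrite")
  }
  cof$record <- "HETATM"
  out <- rbind(as.data.frame(model), cof)
  structure_model(out, model_id = model_id(model))
}

#' Fixture modeling backend
#'
#' Stands in for a homology-modeling engine behind the modeling contract:
#' models are looked up verbatim from a named list keyed by query id.
#'
#' @param models Named list of [structure_model()] objects keyed by query id.
#' @return A `modeling_backend` object for [build_model()].
#' @export
fixture_modeling_backend <- function(models) {
  if (!is.list(models) || is.null(names(models))) {
    abort("`models` must be a named list of structure models")
  }
  structure(list(models = models),
            class = c("fixture_modeling_backend", "modeling_backend"))
}

#' Build a structure model for a query (modeling backend contract)
#'
#' @param backend A modeling backend.
#' @param query_id Candidate sequence id.
#' @param alignment Double-chain `pairwise_alignment` for the query.
#' @param template Dimer template [structure_model()].
#' @return A [structure_model()].
#' @export
build_model <- function(backend, query_id, alignment, template) {
  UseMethod("build_model")
}

#' @export
build_model.fixture_modeling_backend <- function(backend, query_id,
                                                 alignment, template) {
  m <- backend$models[[query_id]]
  if (is.null(m)) {
    abort("no fixture model stored for query '", query_id, "'")
  }
  m
}
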