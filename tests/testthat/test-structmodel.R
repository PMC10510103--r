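test_that("structure files round-trip through write/read", {
  fx <- make_receptor(data.frame(resname = c("ASP", "HIS"),
                                 distance = c(5, 6)))
  m <- fx$receptor
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2), nrow(m))
  expect_identical(m2$name, m$name)
  expect_identical(m2$resid, m$resid)
  expect_identical(m2$chain, m$chain)
  expect_equal(coords_len <- coords_of(m2), coords_of(m),
               tolerance = 1e-3)
})

test_that("unparseable coordinate records error with their line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  fx <- make_receptor(data.frame(resname = "ASP", distance = 5))
  write_structure(fx$receptor, f)
  lines <- readLines(f)
  lines[3] <- "ATOM   garbage line with no coordinates"
  writeLines(lines, f)
  expect_error(read_structure(f), "line 3")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("structure_model enforces atom uniqueness and finite coords", {
  at <- data.frame(record = "ATOM", name = "CA", element = "C",
                   resname = "ALA", resid = 1L, chain = "A",
                   x = 0, y = 0, z = 0)
  expect_error(structure_model(rbind(at, at)), "duplicate")
  at$x <- Inf
  expect_error(structure_model(at), "finite")
})

test_that("dihedral follows the standard signed-torsion convention", {
  # planar trans arrangement
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0)),
               180)
  # explicit gauche geometry: rotate the last point +60 degrees about x
  th <- 60 * pi / 180
  p4 <- c(1, cos(th), sin(th))
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), p4), 60,
               tolerance = 1e-6)
  # mirror reflection flips the sign
  mir <- function(p) c(p[1], p[2], -p[3])
  expect_equal(
    dihedral(mir(c(0, 1, 0)), mir(c(0, 0, 0)), mir(c(1, 0, 0)), mir(p4)),
    -60, tolerance = 1e-6)
  # chosen convention: reversing the atom order preserves the angle
  expect_equal(dihedral(p4, c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 60,
               tolerance = 1e-6)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("ideal helix qualifies with core fraction 1", {
  helix <- make_rama_chain(n_assessed = 30, core_fraction = 1.0)
  r <- ramachandran_qualify(helix)
  expect_equal(r$core_fraction, 1.0)
  expect_true(r$qualified)
  expect_equal(nrow(r$per_residue), 30)
  expect_true(all(r$per_residue$region == "core"))
})

test_that("qualification cutoff: 85% fails, exactly 90% qualifies", {
  m85 <- make_rama_chain(n_assessed = 100, core_fraction = 0.85)
  r85 <- ramachandran_qualify(m85)
  expect_equal(r85$core_fraction, 0.85)
  expect_false(r85$qualified)

  m90 <- make_rama_chain(n_assessed = 100, core_fraction = 0.90)
  r90 <- ramachandran_qualify(m90)
  expect_equal(r90$core_fraction, 0.90)
  expect_true(r90$qualified)
})

test_that("core fraction is monotone as region rectangles grow", {
  m <- make_rama_chain(n_assessed = 50, core_fraction = 0.7,
                       outside_angles = c(60, 60))
  small <- default_core_regions()
  grown <- small
  grown$phi_max <- grown$phi_max + 120  # now covers phi = 60
  f1 <- ramachandran_qualify(m, qualification_config(
    region_map = small))$core_fraction
  f2 <- ramachandran_qualify(m, qualification_config(
    region_map = grown))$core_fraction
  expect_gte(f2, f1)
})

test_that("chains too short to assess are skipped or rejected", {
  fx <- make_receptor(data.frame(resname = c("ASP", "GLY"),
                                 distance = c(5, 6)))
  # CA-only residues: nothing assessable anywhere
  expect_error(ramachandran_qualify(fx$receptor), "no assessable")

  # a 2-residue chain is skipped with a warning; the helix still assesses
  helix <- make_rama_chain(n_assessed = 10, core_fraction = 1.0)
  stub <- data.frame(record = "ATOM", name = "CA", element = "C",
                     resname = "ALA", resid = 1:2, chain = "S",
                     x = c(0, 3), y = 50, z = 50)
  m <- structure_model(rbind(as.data.frame(helix), stub), "stubbed")
  expect_warning(r <- ramachandran_qualify(m), "fewer than 3")
  expect_true(r$qualified)
})

test_that("kabsch recovers exact and rigidly moved configurations", {
  set.seed(9)
  pts <- matrix(rnorm(30), ncol = 3)
  tf0 <- kabsch_superpose(pts, pts)
  expect_equal(tf0$rmsd, 0, tolerance = 1e-10)
  expect_equal(tf0$rotation, diag(3), tolerance = 1e-8)

  rot <- random_rotation()
  moved <- sweep(pts %*% t(rot), 2, c(3, -1, 5), "+")
  tf <- kabsch_superpose(moved, pts)
  expect_lt(tf$rmsd, 1e-6)
  expect_equal(det(tf$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(pts[1:2, ], pts[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate")
})

test_that("kabsch rmsd on a perturbed set matches the numeric minimizer", {
  set.seed(17)
  ref <- matrix(rnorm(30, sd = 4), ncol = 3)
  mob <- ref
  mob[4, ] <- mob[4, ] + c(1, 0, 0)  # 1 A perturbation of one atom
  rot <- random_rotation()
  mob <- sweep(mob %*% t(rot), 2, c(-2, 1, 3), "+")
  tf <- kabsch_superpose(mob, ref)
  expect_equal(tf$rmsd, oracle_min_rmsd(mob, ref), tolerance = 1e-6)
})

test_that("align_to_template moves the model onto the template", {
  fx <- make_pipeline_fixture()
  template <- fx$template_structure
  model <- fx$modeling_backend$models$q_good
  ca <- template[template$record == "ATOM" & template$name == "CA", ]
  pairing <- data.frame(model_resid = ca$resid, template_resid = ca$resid,
                        model_chain = ca$chain, template_chain = ca$chain)
  aligned <- align_to_template(model, template, pairing)
  prot <- template[template$record == "ATOM", ]
  expect_equal(coords_of(aligned), coords_of(prot), tolerance = 1e-6,
               ignore_attr = TRUE)
  tf <- attr(aligned, "transform")
  expect_equal(tf$translation, c(-5, 3, -2), tolerance = 1e-6)

  expect_error(align_to_template(model, template, data.frame()),
               "nonempty")
  bad <- data.frame(model_resid = 9999, template_resid = 9999)
  expect_error(align_to_template(model, template, bad), "missing CA")
})

test_that("transfer_cofactor copies atoms verbatim and never moves others", {
  fx <- make_pipeline_fixture()
  template <- fx$template_structure
  model <- structure_model(
    template[template$resname != "NAP", , drop = FALSE], "m")
  before <- coords_of(model)
  out <- transfer_cofactor(model, template, "NAP")
  expect_equal(sum(out$resname == "NAP"), 5)
  expect_identical(coords_of(out)[seq_len(nrow(model)), , drop = FALSE],
                   before)
  cof_t <- template[template$resname == "NAP", ]
  cof_o <- out[out$resname == "NAP", ]
  expect_identical(unname(coords_of(cof_o)), unname(coords_of(cof_t)))
  expect_true(any(cof_o$name == "C4"))

  expect_error(transfer_cofactor(model, model, "NAP"), "no residue")
  expect_error(transfer_cofactor(out, template, "NAP"), "refusing")
})

test_that("fixture modeling backend returns stored models verbatim", {
  fx <- make_pipeline_fixture()
  aln <- build_dimer_alignment(align_sequences("ACDE", "ACDE"))
  m <- build_model(fx$modeling_backend, "q_good", aln,
                   fx$template_structure)
  expect_identical(as.data.frame(m),
                   as.data.frame(fx$modeling_backend$models$q_good))
  expect_s3_class(m, "structure_model")
  expect_error(build_model(fx$modeling_backend, "nope", aln,
                           fx$template_structure), "nope")
})
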