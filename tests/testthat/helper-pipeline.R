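# Shared end-to-end fixture: a toy template dimer-surrogate structure, a
# small template sequence library, five candidate sequences exercising
# every pipeline status, and fixture modeling/docking backends.

combine_models <- function(a, b, model_id = "combined") {
  structure_model(rbind(as.data.frame(a), as.data.frame(b)),
                  model_id = model_id)
}

make_pipeline_fixture <- function(seed = 42) {
  base_seq <- random_protein(60, seed = seed)
  other_seq <- random_protein(60, seed = seed + 1)
  templates <- c("5OCM" = base_seq, "1AAA" = other_seq)

  # template structure: qualifying helix + active-site residues + cofactor
  # (from make_receptor) + the bound reference ligand marking the site
  site <- make_receptor(
    placements = data.frame(resname = c("ASP", "HIS", "LYS"),
                            distance = c(5.0, 6.0, 8.5)),
    c4_n_distance = 4.2, model_id = "template"
  )
  helix <- make_rama_chain(n_assessed = 20, core_fraction = 1.0,
                           chain = "H")
  ref_lig <- data.frame(
    record = "HETATM", name = c("C1L", "C2L"), element = "C",
    resname = "LIG", resid = 950L, chain = "A",
    x = c(0, 1.3), y = 0, z = 0
  )
  template_structure <- combine_models(
    combine_models(site$receptor, helix), ref_lig,
    model_id = "template"
  )
  c4_xyz <- c(1.25, 0, -4.2)

  # candidate models: template protein part (no cofactor, no ligand),
  # rigidly displaced so the superposition stage has work to do
  protein_part <- template_structure[
    template_structure$record == "ATOM", , drop = FALSE]
  shift_model <- function(m, id, dx) {
    m <- structure_model(as.data.frame(m), model_id = id)
    m$x <- m$x + dx[1]; m$y <- m$y + dx[2]; m$z <- m$z + dx[3]
    m
  }
  models <- list(
    q_good = shift_model(protein_part, "q_good", c(5, -3, 2)),
    q_second = shift_model(protein_part, "q_second", c(-2, 7, 1)),
    q_nopose = shift_model(protein_part, "q_nopose", c(0, 0, 9))
  )
  # q_badmodel: a chain with most residues outside the core region
  models$q_badmodel <- make_rama_chain(n_assessed = 20,
                                       core_fraction = 0.5,
                                       model_id = "q_badmodel")

  queries <- c(
    q_good = mutate_sequence(base_seq, 4, seed = seed + 2),
    q_second = mutate_sequence(base_seq, 8, seed = seed + 3),
    q_nopose = mutate_sequence(base_seq, 6, seed = seed + 4),
    q_badmodel = mutate_sequence(base_seq, 5, seed = seed + 5),
    q_foreign = mutate_sequence(other_seq, 4, seed = seed + 6)
  )

  base_pose <- site$pose
  pose_sets <- list(
    "q_good/sub1" = make_pose_set(c(3.0, 3.9, 5.2), c(-7, -9.0, -8),
                                  base_pose, c4_xyz),
    "q_second/sub1" = make_pose_set(c(4.4, 6.5), c(-8.5, -9.5),
                                    base_pose, c4_xyz),
    "q_nopose/sub1" = make_pose_set(c(3.4, 6.1), c(-9, -8),
                                    base_pose, c4_xyz)
  )

  list(
    queries = queries, templates = templates,
    template_structure = template_structure,
    substrate = default_substrate(), c4_xyz = c4_xyz,
    modeling_backend = fixture_modeling_backend(models),
    docking_backend = fixture_docking_backend(pose_sets),
    config = pipeline_config(reference_ligand_resname = "LIG")
  )
}
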