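# End-to-end orchestration: template assignment -> dimer alignment ->
# modeling backend -> Ramachandran qualification -> superposition and
# cofactor transfer -> docking backend -> pose filter -> shell profile ->
# refined score -> ranking.

#' Aggregate pipeline configuration
#'
#' Collects the per-stage configurations plus pipeline-level settings.
#' Unknown arguments are rejected.
#'
#' @param ired_ids Template ids accepted as characterized IREDs.
#' @param qualification A [qualification_config()].
#' @param docking A [docking_config()].
#' @param pose_filter A [pose_filter_config()].
#' @param shell A [shell_config()].
#' @param weights A [scoring_weights()].
#' @param evaluation An [evaluation_config()].
#' @param chain_break Chain-break token for the dimer alignment.
#' @param cofactor_resname Cofactor residue name.
#' @param reference_ligand_resname Residue name of the template's bound
#'   ligand marking the active site (docking-box center).
#' @param panel_size Screening panel size.
#' @param seed Pipeline seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(ired_ids = IRED_TEMPLATE_IDS,
                            qualification = qualification_config(),
                            docking = docking_config(),
                            pose_filter = pose_filter_config(),
                            shell = shell_config(),
                            weights = scoring_weights(),
                            evaluation = evaluation_config(),
                            chain_break = "/",
                            cofactor_resname = "NAP",
                            reference_ligand_resname = "LIG",
                            panel_size = 20L,
                            seed = 1L) {
  stopifnot(inherits(qualification, "qualification_config"),
            inherits(docking, "docking_config"),
            inherits(pose_filter, "pose_filter_config"),
            inherits(shell, "shell_config"),
            inherits(weights, "scoring_weights"),
            inherits(evaluation, "evaluation_config"))
  structure(
    list(ired_ids = ired_ids, qualification = qualification,
         docking = docking, pose_filter = pose_filter, shell = shell,
         weights = weights, evaluation = evaluation,
         chain_break = chain_break, cofactor_resname = cofactor_resname,
         reference_ligand_resname = reference_ligand_resname,
         panel_size = as.integer(panel_size), seed = seed),
    class = "pipeline_config"
  )
}

score_one_candidate <- function(qid, query, templates, template_structure,
                                substrate, substrate_id,
                                modeling_backend, docking_backend, config,
                                log) {
  hit <- assign_template(setNames(query, qid), templates)
  log("candidate ", qid, ": template ", hit$template_id,
      sprintf(" (identity %.3f)", hit$identity))
  if (!(hit$template_id %in% config$ired_ids)) {
    return(scored_candidate(qid, status = "not_homolog"))
  }
  aln <- align_sequences(query, templates[[hit$template_id]])
  dimer <- build_dimer_alignment(aln, config$chain_break)

  model <- tryCatch(
    build_model(modeling_backend, qid, dimer, template_structure),
    error = function(e) e
  )
  if (inherits(model, "error")) {
    log("candidate ", qid, ": modeling failed (",
        conditionMessage(model), ")")
    return(scored_candidate(qid, status = "model_unqualified"))
  }
  assess <- tryCatch(
    ramachandran_qualify(model, config$qualification),
    error = function(e) e
  )
  if (inherits(assess, "error") || !assess$qualified) {
    return(scored_candidate(qid, status = "model_unqualified"))
  }

  scored <- tryCatch({
    ca_m <- model[model$record == "ATOM" & model$name == "CA", ]
    ca_t <- template_structure[template_structure$record == "ATOM" &
                                 template_structure$name == "CA", ]
    shared <- merge(ca_m[, c("chain", "resid")],
                    ca_t[, c("chain", "resid")])
    pairing <- data.frame(model_resid = shared$resid,
                          template_resid = shared$resid,
                          model_chain = shared$chain,
                          template_chain = shared$chain)
    aligned <- align_to_template(model, template_structure, pairing)
    prepared <- transfer_cofactor(aligned, template_structure,
                                  config$cofactor_resname)
    ref_lig <- template_structure[
      template_structure$resname == config$reference_ligand_resname, ]
    if (nrow(ref_lig) == 0) {
      abort("template has no reference ligand ",
            config$reference_ligand_resname)
    }
    box <- compute_box(ref_lig, substrate, config$docking)
    poses <- dock(docking_backend, prepared, substrate_id, box,
                  config$docking)
    dists <- vapply(poses, c4_n_distance, numeric(1),
                    receptor = prepared, cfg = config$pose_filter)
    sel <- select_best_pose(poses, dists, config$pose_filter)
    if (is.null(sel)) {
      scored_candidate(qid, status = "no_valid_pose")
    } else {
      prof <- active_site_profile(prepared, sel$pose, config$shell,
                                  config$cofactor_resname)
      scored_candidate(
        qid, status = "scored", selected_pose = sel$pose,
        c4_n_distance = sel$distance, profile = prof,
        refined_score = refined_score(sel$pose$vina_score, prof,
                                      config$weights)
      )
    }
  }, error = function(e) {
    log("candidate ", qid, ": docking stage failed (",
        conditionMessage(e), ")")
    scored_candidate(qid, status = "no_valid_pose")
  })
  scored
}

#' Run the full ranking pipeline
#'
#' Executes every stage for each candidate sequence and ranks the
#' survivors. Every input sequence appears in the result exactly once with
#' a status; a failure at the modeling stage yields `model_unqualified`, a
#' failure at the docking/scoring stage yields `no_valid_pose`, and the run
#' continues with the remaining candidates.
#'
#' @param queries Named character vector of candidate sequences (or an
#'   `AAStringSet`).
#' @param templates Named character vector of template sequences keyed by
#'   template id.
#' @param template_structure Template [structure_model()] (dimer, with the
#'   cofactor and bound reference ligand).
#' @param substrate Substrate atom data frame (`name`, `element`, `x`,
#'   `y`, `z`).
#' @param n_index 1-based index of the imine nitrogen in `substrate`.
#' @param modeling_backend A modeling backend (see
#'   [fixture_modeling_backend()], [dir_modeling_backend()]).
#' @param docking_backend A docking backend (see
#'   [fixture_docking_backend()], [dir_docking_backend()]).
#' @param config A [pipeline_config()].
#' @param substrate_id Substrate id used for backend lookups.
#' @param verbose Emit per-candidate log messages.
#' @return List with `ranking` (ranked [scored_candidate()] list), `table`
#'   (the [ranking_table()]), and `panel` (top `config$panel_size` scored
#'   candidates).
#' @export
run_ranking <- function(queries, templates, template_structure, substrate,
                        n_index, modeling_backend, docking_backend,
                        config = pipeline_config(),
                        substrate_id = "substrate", verbose = FALSE) {
  queries <- as_sequence_set(queries, "query set")
  templates <- as_sequence_set(templates, "template library")
  assert_scalar_number(n_index, "n_index")
  if (n_index < 1 || n_index > nrow(substrate)) {
    abort("`n_index` must be a 1-based atom index into the substrate (1..",
          nrow(substrate), ")")
  }
  log <- if (verbose) function(...) message(...) else function(...) NULL
  candidates <- lapply(names(queries), function(qid) {
    score_one_candidate(qid, queries[[qid]], templates,
                        template_structure, substrate, substrate_id,
                        modeling_backend, docking_backend, config, log)
  })
  ranked <- rank_candidates(candidates)
  list(ranking = ranked, table = ranking_table(ranked),
       panel = select_panel(ranked, config$panel_size))
}

#' Evaluate a ranking against screening outcomes
#'
#' Takes the ranking produced by [run_ranking()] (or its table), selects
#' the top `cfg$panel_size` scored sequences and evaluates them with
#' [evaluate_panel()]. Ids present in the ranking but absent from the
#' outcomes raise an error listing the offenders.
#'
#' @param ranking_table A [ranking_table()] data frame.
#' @param outcomes Screening outcomes (`sequence_id`, `conversion`).
#' @param cfg An [evaluation_config()] with `seed`.
#' @return An `evaluation_report` (see [evaluate_panel()]).
#' @export
run_evaluate <- function(ranking_table, outcomes,
                         cfg = evaluation_config(seed = 1L)) {
  scored <- ranking_table[ranking_table$status == "scored", ]
  if (nrow(scored) == 0) abort("ranking contains no scored candidates")
  selected <- head(scored$sequence_id[order(scored$rank)], cfg$panel_size)
  evaluate_panel(selected, outcomes, cfg)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param report An `evaluation_report`.
#' @param path_prefix Output path prefix; writes `<prefix>.json` and
#'   `<prefix>.csv`.
#' @export
write_report <- function(report, path_prefix) {
  flat <- data.frame(
    hit_rate_low = report$hit_rate_low,
    hit_rate_high = report$hit_rate_high,
    best_hit_retrieved = report$best_hit_retrieved,
    retrieval_probability = report$retrieval_probability,
    random_mean_hit_rate = report$random$mean_hit_rate,
    random_sem = report$random$sem,
    random_ci_lo = report$random$ci95[1],
    random_ci_hi = report$random$ci95[2],
    random_retrieval_frequency = report$random$retrieval_frequency
  )
  jsonlite::write_json(as.list(flat), paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(flat, paste0(path_prefix, ".csv"), row.names = FALSE)
  invisible(path_prefix)
}

#' Modeling backend reading pre-built models from a directory
#'
#' Models are stored as `<query id>.pdb` files.
#'
#' @param dir Directory of model files.
#' @return A `modeling_backend`.
#' @export
dir_modeling_backend <- function(dir) {
  if (!dir.exists(dir)) abort("model directory not found: ", dir)
  structure(list(dir = dir),
            class = c("dir_modeling_backend", "modeling_backend"))
}

#' @export
build_model.dir_modeling_backend <- function(backend, query_id, alignment,
                                             template) {
  path <- file.path(backend$dir, paste0(query_id, ".pdb"))
  if (!file.exists(path)) {
    abort("no stored model for query '", query_id, "' in ", backend$dir)
  }
  read_structure(path, model_id = query_id)
}

#' Docking backend reading stored pose sets from a directory
#'
#' Pose sets are stored as `<receptor id>__<substrate id>.pdb` files in the
#' multi-model dialect of [write_poses()].
#'
#' @param dir Directory of pose files.
#' @return A `docking_backend`.
#' @export
dir_docking_backend <- function(dir) {
  if (!dir.exists(dir)) abort("pose directory not found: ", dir)
  structure(list(dir = dir),
            class = c("dir_docking_backend", "docking_backend"))
}

#' @export
dock.dir_docking_backend <- function(backend, receptor, substrate_id, box,
                                     cfg = docking_config()) {
  path <- file.path(backend$dir,
                    paste0(model_id(receptor), "__", substrate_id, ".pdb"))
  if (!file.exists(path)) {
    abort("no stored pose set for '", model_id(receptor), "/",
          substrate_id, "' in ", backend$dir)
  }
  poses <- read_poses(path)
  poses <- poses[order(vapply(poses, `[[`, numeric(1), "vina_score"))]
  attr(poses, "config") <- cfg
  poses
}
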