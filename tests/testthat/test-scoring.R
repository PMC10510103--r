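test_that("C4-to-nitrogen distance is a plain euclidean distance", {
  at <- data.frame(name = c("C1", "N1"), element = c("C", "N"),
                   x = c(2, 0), y = c(2, 3), z = c(2, 4))
  rec <- structure_model(data.frame(
    record = c("ATOM", "HETATM"), name = c("CA", "C4"),
    element = "C", resname = c("ALA", "NAP"), resid = c(1L, 901L),
    chain = "A", x = 0, y = 0, z = 0))
  p <- pose(at, vina_score = -5, n_atom_index = 2L)
  expect_equal(c4_n_distance(p, rec), 5)  # 3-4-5 triangle

  p0 <- pose(data.frame(name = "N1", element = "N", x = 0, y = 0, z = 0),
             vina_score = 0, n_atom_index = 1L)
  expect_equal(c4_n_distance(p0, rec), 0)

  fx <- make_receptor(c4_n_distance = 4.2)
  expect_equal(c4_n_distance(fx$pose, fx$receptor), 4.2, tolerance = 1e-9)

  two_c4 <- structure_model(data.frame(
    record = "HETATM", name = c("C4", "C4"), element = "C",
    resname = "NAP", resid = 901L, chain = c("A", "B"),
    x = c(0, 1), y = 0, z = 0))
  expect_error(c4_n_distance(p0, two_c4), "exactly one")
})

test_that("pose selection applies the strict distance window then argmin", {
  fx <- make_receptor()
  c4 <- c(1.25, 0, -4.2)
  poses <- make_pose_set(c(3.0, 3.6, 4.2, 6.5), c(-8, -8, -8, -8),
                         fx$pose, c4)
  d <- vapply(poses, c4_n_distance, numeric(1), receptor = fx$receptor)
  sel <- select_best_pose(poses, d)
  expect_equal(sel$distance, 3.6)

  # both boundary violations removed: nothing survives
  out <- make_pose_set(c(3.4, 6.1), c(-9, -8), fx$pose, c4)
  d2 <- vapply(out, c4_n_distance, numeric(1), receptor = fx$receptor)
  expect_null(select_best_pose(out, d2))

  # distance tie -> lower vina score; score tie -> lower pose index
  tie <- make_pose_set(c(4.0, 4.0), c(-7.0, -9.0), fx$pose, c4)
  dt <- vapply(tie, c4_n_distance, numeric(1), receptor = fx$receptor)
  expect_equal(select_best_pose(tie, dt)$pose$vina_score, -9.0)
  tie2 <- make_pose_set(c(4.0, 4.0), c(-9.0, -9.0), fx$pose, c4)
  expect_equal(select_best_pose(tie2, dt)$pose$pose_index, 1L)

  expect_error(select_best_pose(poses, d[1:2]), "length")
})

test_that("selected pose distance always lies inside the window", {
  fx <- make_receptor()
  set.seed(21)
  for (i in 1:25) {
    ds <- round(runif(6, 2, 8), 2)
    ps <- make_pose_set(ds, runif(6, -10, -5), fx$pose, c(1.25, 0, -4.2))
    sel <- select_best_pose(ps, ds)
    if (is.null(sel)) {
      expect_true(all(ds < 3.5 | ds > 6.0))
    } else {
      expect_gte(sel$distance, 3.5)
      expect_lte(sel$distance, 6.0)
      expect_equal(sel$distance, min(ds[ds >= 3.5 & ds <= 6.0]))
    }
  }
})

test_that("active-site profile counts classes within the inclusive shell", {
  fx <- make_receptor(data.frame(
    resname = c("ASP", "GLU", "LYS", "HIS"),
    distance = c(5.0, 7.9, 8.1, 6.0)))
  prof <- active_site_profile(fx$receptor, fx$pose)
  expect_equal(prof$n_acidic, 2)  # ASP at 5.0, GLU at 7.9
  expect_equal(prof$n_basic, 0)   # LYS at 8.1 is outside
  expect_equal(prof$n_his, 1)
  expect_equal(nrow(prof$shell_residues), 3)

  far <- make_receptor(data.frame(resname = c("ASP", "LYS"),
                                  distance = c(9, 10)))
  prof0 <- active_site_profile(far$receptor, far$pose)
  expect_equal(c(prof0$n_acidic, prof0$n_basic, prof0$n_his), c(0, 0, 0))

  # histidine is presence/absence, not a count
  two_his <- make_receptor(data.frame(resname = c("HIS", "HIS"),
                                      distance = c(5, 6)))
  expect_equal(active_site_profile(two_his$receptor, two_his$pose)$n_his,
               1)
})

test_that("protonation-variant residue names are normalized before
           classification", {
  fx <- make_receptor(data.frame(resname = c("HID", "ASH", "LYN"),
                                 distance = c(5, 6, 7)))
  prof <- active_site_profile(fx$receptor, fx$pose)
  expect_equal(prof$n_acidic, 1)
  expect_equal(prof$n_basic, 1)
  expect_equal(prof$n_his, 1)
})

test_that("shell membership is monotone in the radius", {
  fx <- make_receptor(data.frame(
    resname = c("ASP", "GLU", "LYS", "ARG", "HIS"),
    distance = c(3, 5, 7, 9, 11)))
  prev <- 0
  for (r in c(2, 4, 6, 8, 10, 12)) {
    prof <- active_site_profile(fx$receptor, fx$pose,
                                shell_config(radius = r))
    n <- nrow(prof$shell_residues)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("shell counting equals the brute-force pairwise oracle", {
  set.seed(31)
  resnames <- c("ASP", "GLU", "LYS", "ARG", "HIS", "ALA", "SER", "PHE")
  for (i in 1:20) {
    k <- sample(3:7, 1)
    pl <- data.frame(
      resname = sample(resnames, k, replace = TRUE),
      distance = round(runif(k, 3, 12), 2)
    )
    fx <- make_receptor(pl)
    prof <- active_site_profile(fx$receptor, fx$pose)
    oracle <- oracle_shell_counts(fx$receptor, fx$pose)
    expect_equal(prof$n_acidic, oracle$n_acidic)
    expect_equal(prof$n_basic, oracle$n_basic)
    expect_equal(prof$n_his, oracle$n_his)
  }
})

test_that("refined score evaluates the weighted linear combination", {
  expect_equal(refined_score(0, site_profile(0, 0, 0)), 0)
  expect_equal(refined_score(1.0, site_profile(0, 0, 0)), 4.0)
  expect_equal(refined_score(-8.0, site_profile(2, 1, 1)), -30.0)
})

test_that("refined score is linear in each count", {
  set.seed(41)
  w <- scoring_weights()
  for (i in 1:30) {
    v <- runif(1, -12, 0)
    na <- sample(0:5, 1); nb <- sample(0:5, 1); nh <- sample(0:1, 1)
    base <- refined_score(v, site_profile(na, nb, nh), w)
    expect_equal(refined_score(v, site_profile(na + 1, nb, nh), w) - base,
                 w$w_acidic)
    expect_equal(refined_score(v, site_profile(na, nb + 1, nh), w) - base,
                 w$w_basic)
    if (nh == 0) {
      expect_equal(refined_score(v, site_profile(na, nb, 1), w) - base,
                   -w$w_his)
    }
    expect_equal(refined_score(v + 1, site_profile(na, nb, nh), w) - base,
                 w$w_vina)
  }
})

make_cand <- function(id, refined, vina = -8, status = "scored") {
  if (status != "scored") return(scored_candidate(id, status = status))
  fx <- make_receptor()
  p <- fx$pose; p$vina_score <- vina
  scored_candidate(id, status = "scored", selected_pose = p,
                   c4_n_distance = 4.2, profile = site_profile(),
                   refined_score = refined)
}

test_that("ranking sorts ascending with the full tie-break chain", {
  cands <- list(make_cand("a", -30), make_cand("b", -12),
                make_cand("c", -45))
  ranked <- rank_candidates(cands)
  expect_equal(vapply(ranked, `[[`, numeric(1), "refined_score"),
               c(-45, -30, -12))

  tie <- list(make_cand("a", -30, vina = -6),
              make_cand("b", -30, vina = -8))
  expect_equal(rank_candidates(tie)[[1]]$sequence_id, "b")
  tie2 <- list(make_cand("z", -30, vina = -8),
               make_cand("a", -30, vina = -8))
  expect_equal(rank_candidates(tie2)[[1]]$sequence_id, "a")

  expect_length(rank_candidates(list()), 0)
})

test_that("ranking is a status-preserving permutation, unscored last", {
  cands <- list(make_cand("a", -30), make_cand("x", NA, status =
                  "not_homolog"),
                make_cand("b", -40),
                make_cand("y", NA, status = "no_valid_pose"))
  ranked <- rank_candidates(cands)
  ids <- vapply(ranked, `[[`, character(1), "sequence_id")
  expect_setequal(ids, c("a", "b", "x", "y"))
  expect_equal(ids[1:2], c("b", "a"))
  expect_equal(vapply(ranked[3:4], `[[`, character(1), "status"),
               c("not_homolog", "no_valid_pose"))

  # stable under score-preserving shuffles
  set.seed(5)
  ranked2 <- rank_candidates(sample(cands))
  expect_equal(vapply(ranked2[1:2], `[[`, character(1), "sequence_id"),
               c("b", "a"))
})

test_that("panel selection returns the top scored candidates", {
  cands <- lapply(1:50, function(i) {
    make_cand(sprintf("s%02d", i), refined = -i)
  })
  ranked <- rank_candidates(cands)
  expect_length(select_panel(ranked), 20)
  expect_equal(select_panel(ranked)[[1]]$sequence_id, "s50")
  expect_length(select_panel(ranked[1:12], 20), 12)
  expect_length(select_panel(ranked, 0), 0)
})

test_that("ranking table and CSV export carry the documented schema", {
  cands <- list(make_cand("a", -30), make_cand("x", NA,
                                               status = "not_homolog"))
  tab <- ranking_table(rank_candidates(cands))
  expect_equal(names(tab),
               c("rank", "sequence_id", "vina_score", "c4_n_distance",
                 "n_acidic", "n_basic", "n_his", "refined_score",
                 "status"))
  expect_equal(tab$rank, c(1L, NA_integer_))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ranking(rank_candidates(cands), f)
  back <- read.csv(f)
  expect_equal(back$sequence_id, c("a", "x"))
  expect_equal(back$refined_score, c(-30, NA))
})

test_that("scored_candidate enforces the status/fields consistency", {
  expect_error(scored_candidate("a", status = "scored"), "scored")
  expect_error(
    scored_candidate("a", status = "no_valid_pose",
                     refined_score = -1, c4_n_distance = 4,
                     profile = site_profile(),
                     selected_pose = make_receptor()$pose),
    "scored")
})
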