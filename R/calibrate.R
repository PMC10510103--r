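# Evaluation against screening outcomes and grid-search weight tuning.

check_outcomes <- function(outcomes) {
  need <- c("sequence_id", "conversion")
  if (!is.data.frame(outcomes) || !all(need %in% names(outcomes))) {
    abort("`outcomes` must have columns sequence_id, conversion")
  }
  if (any(outcomes$conversion < 0 | outcomes$conversion > 100)) {
    abort("conversions must lie in [0, 100] percent")
  }
  if (anyDuplicated(outcomes$sequence_id)) {
    abort("duplicate sequence ids in outcomes")
  }
  outcomes
}

#' Hit rate of a selected panel
#'
#' Fraction of the selected sequences whose screened conversion meets the
#' cutoff (inclusive `>=`).
#'
#' @param selected Character vector of selected sequence ids.
#' @param outcomes Data frame with columns `sequence_id` and `conversion`
#'   (percent in \[0, 100\]).
#' @param cutoff Conversion cutoff in percent.
#' @return Hit rate as a fraction in \[0, 1\].
#' @export
hit_rate <- function(selected, outcomes, cutoff) {
  check_outcomes(outcomes)
  if (length(selected) == 0) abort("empty selection")
  miss <- setdiff(selected, outcomes$sequence_id)
  if (length(miss) > 0) {
    abort("selected ids missing from outcomes: ",
          paste(miss, collapse = ", "))
  }
  conv <- outcomes$conversion[match(selected, outcomes$sequence_id)]
  mean(conv >= cutoff)
}

#' Was the panel's best hit retrieved?
#'
#' @param selected Character vector of selected sequence ids.
#' @param outcomes Screening outcomes (see [hit_rate()]).
#' @return `TRUE` iff any sequence attaining the maximum conversion of the
#'   whole panel is in `selected` (any tied-best counts).
#' @export
best_hit_retrieval <- function(selected, outcomes) {
  check_outcomes(outcomes)
  if (nrow(outcomes) == 0) abort("empty outcomes")
  best <- outcomes$sequence_id[outcomes$conversion ==
                                 max(outcomes$conversion)]
  any(best %in% selected)
}

#' Analytic probability of retrieving a best hit by random selection
#'
#' For a panel of `n_total` sequences with `n_best` tied-best hits, the
#' probability that a uniformly random `k`-subset contains at least one of
#' them is `1 - choose(n_total - n_best, k) / choose(n_total, k)`
#' (hypergeometric tail at zero); this reduces to `k / n_total` for a
#' unique best hit.
#'
#' @param n_total Panel size N.
#' @param k Selection size.
#' @param n_best Number of tied-best sequences m.
#' @return Retrieval probability in \[0, 1\].
#' @export
retrieval_probability <- function(n_total, k, n_best = 1L) {
  assert_scalar_number(n_total, "n_total")
  assert_scalar_number(k, "k")
  assert_scalar_number(n_best, "n_best")
  if (n_best < 1 || n_best > n_total || k < 0 || k > n_total) {
    abort("need 1 <= n_best <= n_total and 0 <= k <= n_total")
  }
  1 - exp(lchoose(n_total - n_best, k) - lchoose(n_total, k))
}

#' Random-selection baseline by resampling
#'
#' Draws `cfg$n_draws` uniform `panel_size`-subsets of the outcomes without
#' replacement and summarizes the hit rate at `cutoff` (mean, SEM, the
#' `mean +/- ci_multiplier * SEM` interval clipped to \[0, 1\]) and the
#' fraction of draws containing a tied-best sequence.
#'
#' @param outcomes Screening outcomes (see [hit_rate()]).
#' @param cfg An [evaluation_config()] with `seed` set.
#' @param cutoff Conversion cutoff in percent (default `cfg$high_cutoff`).
#' @return A list with `mean_hit_rate`, `sem`, `ci95` (length-2 vector),
#'   `retrieval_frequency`, `n_draws`.
#' @export
random_baseline <- function(outcomes, cfg = evaluation_config(seed = 1L),
                            cutoff = cfg$high_cutoff) {
  check_outcomes(outcomes)
  k <- cfg$panel_size
  if (nrow(outcomes) < k) {
    abort("panel (", nrow(outcomes), ") smaller than selection size ", k)
  }
  if (is.null(cfg$seed)) abort("random_baseline requires `cfg$seed`")
  hits <- outcomes$conversion >= cutoff
  best <- outcomes$conversion == max(outcomes$conversion)
  n <- nrow(outcomes)
  rates <- numeric(cfg$n_draws)
  got_best <- logical(cfg$n_draws)
  local_seed(cfg$seed, {
    for (i in seq_len(cfg$n_draws)) {
      draw <- sample.int(n, k)
      rates[i] <- mean(hits[draw])
      got_best[i] <- any(best[draw])
    }
  })
  m <- mean(rates)
  sem <- stats::sd(rates) / sqrt(cfg$n_draws)
  ci <- pmin(pmax(m + c(-1, 1) * cfg$ci_multiplier * sem, 0), 1)
  list(mean_hit_rate = m, sem = sem, ci95 = ci,
       retrieval_frequency = mean(got_best), n_draws = cfg$n_draws)
}

# run code under a temporary RNG state seeded with `seed`
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

#' Evaluate a ranked panel against screening outcomes
#'
#' @param selected Character vector of selected sequence ids.
#' @param outcomes Screening outcomes (see [hit_rate()]).
#' @param cfg An [evaluation_config()] (with `seed` for the resampled
#'   baseline).
#' @return An `evaluation_report` list: `hit_rate_low`, `hit_rate_high`,
#'   `best_hit_retrieved`, `retrieval_probability` (analytic, for the
#'   actual selection size and tie count), and the [random_baseline()]
#'   fields under `random`.
#' @export
evaluate_panel <- function(selected, outcomes,
                           cfg = evaluation_config(seed = 1L)) {
  check_outcomes(outcomes)
  n_best <- sum(outcomes$conversion == max(outcomes$conversion))
  rb <- random_baseline(outcomes, cfg)
  structure(
    list(
      hit_rate_low = hit_rate(selected, outcomes, cfg$low_cutoff),
      hit_rate_high = hit_rate(selected, outcomes, cfg$high_cutoff),
      best_hit_retrieved = best_hit_retrieval(selected, outcomes),
      retrieval_probability = retrieval_probability(nrow(outcomes),
                                                    length(selected),
                                                    n_best),
      random = rb
    ),
    class = "evaluation_report"
  )
}

check_calibration <- function(calibration) {
  need <- c("sequence_id", "vina_score", "n_acidic", "n_basic", "n_his",
            "conversion")
  if (!is.data.frame(calibration) || !all(need %in% names(calibration))) {
    abort("`calibration` must have columns ", paste(need, collapse = ", "))
  }
  calibration
}

# top-k hit rate for one weight vector on the calibration table
tuning_objective <- function(calibration, wv, wa, wh, wb, k, cutoff) {
  score <- wv * calibration$vina_score + wa * calibration$n_acidic -
    wh * calibration$n_his + wb * calibration$n_basic
  ord <- order(score, calibration$vina_score, calibration$sequence_id)
  top <- ord[seq_len(min(k, length(ord)))]
  mean(calibration$conversion[top] >= cutoff)
}

#' Tune refined-score weights by exhaustive grid search
#'
#' Evaluates every weight vector on the grid: candidates are ranked by the
#' resulting refined score, the top `panel_size` are selected, and the
#' objective is the hit rate at `cfg$high_cutoff`. Ties break to the higher
#' hit rate at `cfg$low_cutoff`, then to the smaller L1 norm of the weight
#' vector, then to lexicographic order of `(w_vina, w_acidic, w_his,
#' w_basic)`.
#'
#' @param calibration Data frame with columns `sequence_id`, `vina_score`,
#'   `n_acidic`, `n_basic`, `n_his`, `conversion`.
#' @param grid A [tuning_grid()].
#' @param cfg An [evaluation_config()].
#' @param base Weights used for components not in `grid$tuned_weights`.
#' @return The winning [scoring_weights()], with attributes
#'   `"objective"` (high-cutoff hit rate) and `"objective_low"`.
#' @export
tune_weights <- function(calibration, grid = tuning_grid(),
                         cfg = evaluation_config(),
                         base = scoring_weights()) {
  check_calibration(calibration)
  if (nrow(calibration) <= cfg$panel_size) {
    abort("calibration set must be larger than the panel size")
  }
  values <- seq(grid$lo, grid$hi, by = grid$step)
  if (length(values) == 0) abort("empty tuning grid")
  axes <- lapply(c("w_vina", "w_acidic", "w_his", "w_basic"), function(nm) {
    if (nm %in% grid$tuned_weights) values else base[[nm]]
  })
  g <- expand.grid(w_vina = axes[[1]], w_acidic = axes[[2]],
                   w_his = axes[[3]], w_basic = axes[[4]],
                   KEEP.OUT.ATTRS = FALSE)
  hi <- numeric(nrow(g)); lo <- numeric(nrow(g))
  for (i in seq_len(nrow(g))) {
    hi[i] <- tuning_objective(calibration, g$w_vina[i], g$w_acidic[i],
                              g$w_his[i], g$w_basic[i], cfg$panel_size,
                              cfg$high_cutoff)
    lo[i] <- tuning_objective(calibration, g$w_vina[i], g$w_acidic[i],
                              g$w_his[i], g$w_basic[i], cfg$panel_size,
                              cfg$low_cutoff)
  }
  l1 <- abs(g$w_vina) + abs(g$w_acidic) + abs(g$w_his) + abs(g$w_basic)
  best <- order(-hi, -lo, l1, g$w_vina, g$w_acidic, g$w_his, g$w_basic)[1]
  out <- scoring_weights(g$w_vina[best], g$w_acidic[best], g$w_his[best],
                         g$w_basic[best])
  attr(out, "objective") <- hi[best]
  attr(out, "objective_low") <- lo[best]
  out
}

#' Read screening outcomes from CSV
#'
#' @param path CSV with header `sequence_id,conversion`.
#' @return Data frame of outcomes.
#' @export
read_outcomes <- function(path) {
  check_outcomes(read.csv(path, stringsAsFactors = FALSE))
}
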