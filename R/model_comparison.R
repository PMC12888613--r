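#' Leave-one-participant-out cross-validation for one model
#'
#' Withholds one participant at a time, fits the model to the remaining
#' participants, and scores the model's teacher-forced predictions for the
#' held-out participant by mean squared error over their valid trials
#' (favorability scale). The held-out participant contributes no parameters:
#' predictions use the training fit's condition-level point estimates
#' (self-reference-point models still use the held-out participant's own
#' self-ratings, which are task inputs, not fitted quantities).
#'
#' In `"fast"` mode each training fold is fitted by pooled penalized maximum
#' likelihood (sigma profiled out analytically); `"accuracy"` mode runs the
#' full hierarchical sampler per fold and predicts with posterior means. A
#' fold whose fit fails is dropped with a warning and the remaining folds are
#' scored.
#'
#' @param trials Trial table for one condition; >= 3 participants.
#' @param model A `model_spec`.
#' @param lexicon,rp,sim Task structures.
#' @param mode `"fast"` (default) or `"accuracy"`.
#' @param config [mcmc_config()] for accuracy mode.
#' @param seed Seed for fold-level fits.
#' @return A `score_table` data.frame (`model_id`, `participant_id`, `mse`)
#'   with attribute `"overall_mse"` (mean of fold scores).
#' @export
logo_cv <- function(trials, model, lexicon, rp = NULL, sim = NULL,
                    mode = c("fast", "accuracy"), config = mcmc_config(),
                    seed = 1L) {
  mode <- match.arg(mode)
  pids <- unique(trials$participant_id)
  if (length(pids) < 3L) stop("LOGO-CV needs at least 3 participants")
  scores <- rep(NA_real_, length(pids))
  for (i in seq_along(pids)) {
    held <- pids[i]
    train <- trials[trials$participant_id != held, , drop = FALSE]
    test <- trials[trials$participant_id == held, , drop = FALSE]
    params <- tryCatch({
      if (mode == "fast")
        fit_pooled(train, model, lexicon, rp, sim, seed = seed + i)
      else
        posterior_params(
          fit_hierarchical(train, model, lexicon, rp, sim,
                           config = mcmc_config(config$chains,
                                                config$warmup_draws,
                                                config$sampling_draws,
                                                seed = config$seed + i)),
          lexicon)
    }, error = function(e) NULL)
    if (is.null(params)) next
    scores[i] <- fold_mse(test, model, params, lexicon, rp, sim)
  }
  if (anyNA(scores)) {
    warning(sum(is.na(scores)), " fold fit(s) failed for ", model$model_id,
            "; overall MSE computed over the successful folds")
  }
  out <- data.frame(model_id = model$model_id, participant_id = pids,
                    mse = scores, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  attr(out, "overall_mse") <- mean(scores, na.rm = TRUE)
  out
}

fold_mse <- function(test, model, params, lexicon, rp, sim) {
  seqs <- participant_sequence(test, lexicon)
  pred <- trajectory(model, params, seqs, lexicon, rp,
                     unique(test$participant_id), sim)
  r <- (seqs$prediction - pred)[seqs$valid]
  mean(r^2)
}

#' Naive mean-prediction baseline
#'
#' The dashed-line reference of the model-comparison barplots: per fold,
#' predict the grand mean of the training participants' (reverse-coded)
#' ratings for every held-out trial, scored like [logo_cv()].
#'
#' @inheritParams logo_cv
#' @return A `score_table` with `model_id = "naive_mean"`.
#' @export
naive_baseline <- function(trials, lexicon) {
  pids <- unique(trials$participant_id)
  if (length(pids) < 2L) stop("need at least 2 participants")
  seqs <- lapply(pids, function(pid)
    participant_sequence(trials[trials$participant_id == pid, , drop = FALSE],
                         lexicon))
  names(seqs) <- pids
  obs <- lapply(seqs, function(s) s$prediction[s$valid])
  scores <- vapply(seq_along(pids), function(i) {
    train_mean <- mean(unlist(obs[-i], use.names = FALSE))
    mean((obs[[i]] - train_mean)^2)
  }, 0)
  out <- data.frame(model_id = "naive_mean", participant_id = pids,
                    mse = scores, stringsAsFactors = FALSE)
  class(out) <- c("score_table", "data.frame")
  attr(out, "overall_mse") <- mean(scores)
  out
}

#' Compare two models' cross-validated scores
#'
#' The paired decision rule: `delta_mse = mean(A - B)` over participants,
#' `se = sd(A - B) / sqrt(n)`, and the two models are credibly different when
#' `|delta_mse| > 2 * se` — roughly the conventional frequentist significance
#' boundary.
#'
#' @param scoresA,scoresB `score_table` rows for two models over the same
#'   participants.
#' @return A `comparison_result` list: `model_a`, `model_b`, `delta_mse`,
#'   `se`, `credible`.
#' @export
compare_models <- function(scoresA, scoresB) {
  a <- scoresA[order(scoresA$participant_id), ]
  b <- scoresB[order(scoresB$participant_id), ]
  if (!identical(a$participant_id, b$participant_id))
    stop("score tables must cover the same participants (paired)")
  d <- a$mse - b$mse
  ok <- !is.na(d)
  delta <- mean(d[ok])
  se <- sd(d[ok]) / sqrt(sum(ok))
  structure(list(model_a = scoresA$model_id[1], model_b = scoresB$model_id[1],
                 delta_mse = delta, se = se, n = sum(ok),
                 credible = abs(delta) > 2 * se),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s vs %s: dMSE = %.4f, SE = %.4f -> %s\n",
              x$model_a, x$model_b, x$delta_mse, x$se,
              if (x$credible) "credibly different (|dMSE| > 2 SE)"
              else "not credibly different"))
  invisible(x)
}

#' Rank models by cross-validated MSE
#'
#' Sorts models by overall MSE (ascending), breaking exact ties by fewer free
#' parameter blocks and then by model id, and reports the best-equivalence
#' set: the best model plus every model not credibly different from it under
#' the pairwise 2xSE rule (no multiplicity correction).
#'
#' @param table A `score_table` stacking fold scores of several models over
#'   the same participants (e.g. `rbind` of [logo_cv()] outputs).
#' @return A `model_ranking`: data.frame (`model_id`, `overall_mse`,
#'   `n_params`, `delta_to_best`, `se_to_best`, `in_best_set`) sorted by rank.
#' @export
rank_models <- function(table) {
  models <- unique(table$model_id)
  if (length(models) < 2L) stop("need at least 2 models to rank")
  per <- lapply(models, function(m) table[table$model_id == m, , drop = FALSE])
  names(per) <- models
  pid_sets <- lapply(per, function(x) sort(x$participant_id))
  if (!all(vapply(pid_sets, identical, TRUE, pid_sets[[1]])))
    stop("inconsistent participant coverage across models")
  overall <- vapply(per, function(x) mean(x$mse, na.rm = TRUE), 0)
  npar <- vapply(models, function(m) {
    if (m == "naive_mean") 0L else get_model(m)$n_params
  }, 0L)
  ord <- order(overall, npar, models)
  models <- models[ord]; overall <- overall[ord]; npar <- npar[ord]
  best <- per[[models[1]]]
  cmp <- lapply(models, function(m) compare_models(per[[m]], best))
  out <- data.frame(
    model_id = models, overall_mse = unname(overall), n_params = unname(npar),
    delta_to_best = vapply(cmp, `[[`, 0, "delta_mse"),
    se_to_best = vapply(cmp, `[[`, 0, "se"),
    in_best_set = !vapply(cmp, `[[`, TRUE, "credible"),
    stringsAsFactors = FALSE)
  class(out) <- c("model_ranking", "data.frame")
  out
}
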