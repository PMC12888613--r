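#' Absolute prediction error
#'
#' The trial-level accuracy measure: `PE = |F - P|`, the absolute difference
#' between the profile's self-rating (feedback F) and the participant's
#' prediction P. Invariant under reverse coding applied to both arguments.
#'
#' @param feedback,prediction Ratings within the scale bounds.
#' @param scale_min,scale_max Rating-scale bounds (for validation).
#' @return Absolute PE(s); integer-valued for integer inputs.
#' @export
#' @examples
#' prediction_error(7, 2)  # 5
prediction_error <- function(feedback, prediction, scale_min = 1, scale_max = 8) {
  if (any(feedback < scale_min | feedback > scale_max, na.rm = TRUE) ||
      any(prediction < scale_min | prediction > scale_max, na.rm = TRUE))
    stop("ratings outside scale bounds [", scale_min, ", ", scale_max, "]")
  abs(feedback - prediction)
}

cell_stats <- function(x) {
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  se <- s / sqrt(n)
  data.frame(mean = m, sd = s, n = n,
             ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
}

#' Condition summaries of ratings and prediction errors
#'
#' Cell means, SDs and normal-approximation 95% confidence intervals of
#' other-ratings (participants' predictions) and absolute PEs per participant
#' group x profile type, optionally split by trait valence. Ratings are
#' reverse-coded onto the favorability scale unless `by_valence = TRUE`
#' (valence-split summaries keep the raw scale so the two valences remain
#' distinguishable). Only valid trials contribute; empty cells are reported
#' as missing rows, not zeros.
#'
#' @param trials A trial table.
#' @param lexicon A `trait_lexicon`.
#' @param by_valence Split cells by trait valence (default `FALSE`).
#' @return Data.frame with one row per cell and measure (`rating`, `pe`).
#' @export
condition_summary <- function(trials, lexicon, by_valence = FALSE) {
  t <- trials[as.logical(trials$valid), , drop = FALSE]
  if (nrow(t) == 0L) stop("no valid trials")
  val <- lexicon$valence[match(t$trait_id, lexicon$trait_id)]
  if (by_valence) {
    pred <- t$prediction
    fb <- t$feedback
  } else {
    b <- scale_bounds(lexicon)
    pred <- reverse_code(t$prediction, val, b[1], b[2])
    fb <- reverse_code(t$feedback, val, b[1], b[2])
  }
  pe <- abs(fb - pred)
  key <- if (by_valence) list(group = t$group, profile_class = t$profile_class,
                              valence = val)
         else list(group = t$group, profile_class = t$profile_class)
  kdf <- as.data.frame(key, stringsAsFactors = FALSE)
  grp <- interaction(kdf, drop = TRUE, lex.order = TRUE, sep = "\r")
  idx <- split(seq_len(nrow(kdf)), grp)
  cells <- kdf[vapply(idx, `[`, 0L, 1L), , drop = FALSE]
  out <- do.call(rbind, lapply(c(rating = "rating", pe = "pe"), function(meas) {
    x <- if (meas == "rating") pred else pe
    agg <- do.call(rbind, lapply(idx, function(i) cell_stats(x[i])))
    cbind(measure = meas, cells, agg, row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}

#' PE-by-trial linear trends with cluster bootstrap CIs
#'
#' Per participant group x profile type, the ordinary-least-squares slope of
#' absolute PE on the within-profile trial number — negative slopes indicate
#' learning. Uncertainty comes from a cluster bootstrap: participants are
#' resampled with replacement and the slope recomputed, giving percentile
#' 95% intervals that respect the repeated-measures structure.
#'
#' @param trials A trial table.
#' @param lexicon A `trait_lexicon`.
#' @param n_boot Bootstrap resamples (>= 200).
#' @param seed Integer seed.
#' @return Data.frame per cell: `slope`, `ci_lo`, `ci_hi`, `n_boot`,
#'   `n_participants`.
#' @export
pe_trend <- function(trials, lexicon, n_boot = 500L, seed = 1L) {
  if (n_boot < 200L) stop("n_boot must be at least 200")
  t <- trials[as.logical(trials$valid), , drop = FALSE]
  val <- lexicon$valence[match(t$trait_id, lexicon$trait_id)]
  b <- scale_bounds(lexicon)
  pe <- abs(reverse_code(t$feedback, val, b[1], b[2]) -
              reverse_code(t$prediction, val, b[1], b[2]))
  cells <- unique(t[, c("group", "profile_class")])
  cells <- cells[order(cells$group, cells$profile_class), , drop = FALSE]
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- t$group == cells$group[i] & t$profile_class == cells$profile_class[i]
    d <- data.frame(pid = t$participant_id[sel], x = t$trial_index[sel],
                    y = pe[sel])
    pids <- unique(d$pid)
    if (length(pids) < 3L)
      stop("fewer than 3 participants in cell ", cells$group[i], " x ",
           cells$profile_class[i])
    ols_slope <- function(dd) {
      xc <- dd$x - mean(dd$x)
      sum(xc * dd$y) / sum(xc^2)
    }
    by_pid <- split(d, d$pid)
    boot <- vapply(seq_len(n_boot), function(r) {
      take <- sample(pids, length(pids), replace = TRUE)
      ols_slope(do.call(rbind, by_pid[take]))
    }, 0)
    ci <- quantile(boot, c(0.025, 0.975), names = FALSE)
    data.frame(group = cells$group[i], profile_class = cells$profile_class[i],
               slope = ols_slope(d), ci_lo = ci[1], ci_hi = ci[2],
               n_boot = n_boot, n_participants = length(pids),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
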