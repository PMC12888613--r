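#' Specify one generative trait-learning model
#'
#' The model space crosses three generative families with three reference-point
#' regimes. *No-learning* models answer with a fixed reference point — the
#' population's average trait ratings or the participant's own self-ratings —
#' and never update. *Coarse-granularity* models keep one expectation per Big
#' Five factor and move it toward feedback by a delta rule with learning rate
#' alpha. *Fine-granularity* models keep one expectation per trait and
#' propagate each trial's prediction error to every trait in proportion to
#' trait-trait similarity. Learning models optionally mix a reference point
#' into their prediction with weight w, and optionally estimate the initial
#' expectations V0 instead of fixing them at the scale midpoint.
#'
#' @param family `"no_learning"`, `"coarse"` or `"fine"`.
#' @param reference_point `"none"`, `"population"` or `"self"`. No-learning
#'   models require a reference point.
#' @param v0_mode `"fixed_midpoint"` (V0 = scale midpoint, 4.5 on the 1-8
#'   scale) or `"estimated"` (V0 a free per-trait vector; learning models only).
#' @return A `model_spec` list with fields `model_id`, `family`,
#'   `reference_point`, `v0_mode`, `n_params`.
#' @export
#' @examples
#' model_spec("fine", "self")$model_id   # "fine_selfRP"
model_spec <- function(family = c("no_learning", "coarse", "fine"),
                       reference_point = c("none", "population", "self"),
                       v0_mode = c("fixed_midpoint", "estimated")) {
  family <- match.arg(family)
  reference_point <- match.arg(reference_point)
  v0_mode <- match.arg(v0_mode)
  if (family == "no_learning") {
    if (reference_point == "none")
      stop("no_learning models require a population or self reference point")
    if (v0_mode == "estimated")
      stop("no_learning models have no V0 to estimate")
  }
  rp_tag <- switch(reference_point, none = "noRP", population = "popRP", self = "selfRP")
  id <- if (family == "no_learning") paste0("nolearn_", sub("RP$", "", rp_tag))
        else paste0(family, "_", rp_tag)
  if (v0_mode == "estimated") id <- paste0(id, "_v0")
  n_params <- 1L +                                  # sigma
    (family != "no_learning") +                     # alpha
    (family != "no_learning" && reference_point != "none") +  # w
    (v0_mode == "estimated")                        # v0 block
  structure(list(model_id = id, family = family,
                 reference_point = reference_point, v0_mode = v0_mode,
                 n_params = n_params),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$model_id, "\n  family:", x$family,
      "| reference point:", x$reference_point, "| V0:", x$v0_mode,
      "|", x$n_params, "free parameter blocks\n")
  invisible(x)
}

#' Enumerate the model registry
#'
#' Returns the eight base models — two no-learning (population / self
#' reference point), three coarse and three fine (no / population / self
#' reference point) — optionally extended with the estimated-V0 variants of
#' the six learning models.
#'
#' @param extended Include `_v0` variants (default `FALSE`).
#' @return Named list of `model_spec`, keyed by `model_id`.
#' @export
enumerate_models <- function(extended = FALSE) {
  specs <- list(
    model_spec("no_learning", "population"),
    model_spec("no_learning", "self"),
    model_spec("coarse", "none"),
    model_spec("coarse", "population"),
    model_spec("coarse", "self"),
    model_spec("fine", "none"),
    model_spec("fine", "population"),
    model_spec("fine", "self")
  )
  if (extended) {
    learn <- Filter(function(m) m$family != "no_learning", specs)
    specs <- c(specs, lapply(learn, function(m)
      model_spec(m$family, m$reference_point, "estimated")))
  }
  names(specs) <- vapply(specs, `[[`, "", "model_id")
  specs
}

#' Look up a model by id
#' @param model_id A registry key such as `"fine_selfRP"` or `"coarse_noRP_v0"`.
#' @return The matching `model_spec`.
#' @export
get_model <- function(model_id) {
  reg <- enumerate_models(extended = TRUE)
  if (!model_id %in% names(reg))
    stop("unknown model_id '", model_id, "'; known: ",
         paste(names(reg), collapse = ", "))
  reg[[model_id]]
}

#' Construct and validate a parameter vector
#'
#' @param model A `model_spec`.
#' @param alpha Learning rate in \[0, 1\] (learning models).
#' @param w Reference-point weight in \[0, 1\] (models with a reference point;
#'   the prediction is `w * RP + (1 - w) * V`).
#' @param sigma Response-noise SD on the rating scale, > 0.
#' @param v0 Per-trait initial expectations (favorability scale); required when
#'   `v0_mode = "estimated"`, otherwise filled with the scale midpoint.
#' @param lexicon A `trait_lexicon` (fixes the length of `v0`).
#' @return A `param_vector` list.
#' @export
param_vector <- function(model, lexicon, alpha = NULL, w = NULL,
                         sigma = 1, v0 = NULL) {
  learning <- model$family != "no_learning"
  has_rp <- learning && model$reference_point != "none"
  if (learning) {
    if (is.null(alpha)) stop(model$model_id, " requires alpha")
    if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  } else if (!is.null(alpha)) {
    stop("no_learning models have no alpha")
  }
  if (has_rp) {
    if (is.null(w)) stop(model$model_id, " requires w")
    if (w < 0 || w > 1) stop("w must be in [0, 1]")
  } else if (!is.null(w)) {
    stop(model$model_id, " has no reference-point weight w")
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (model$v0_mode == "estimated") {
    if (is.null(v0)) stop(model$model_id, " requires a v0 vector")
  } else if (is.null(v0)) {
    v0 <- rep(scale_midpoint(lexicon), nrow(lexicon))
  }
  if (length(v0) != nrow(lexicon))
    stop("v0 length must equal lexicon size (", nrow(lexicon), ")")
  structure(list(alpha = alpha, w = w, sigma = sigma, v0 = as.numeric(v0)),
            class = "param_vector")
}

n_factors_of <- function(lexicon) length(unique(lexicon$factor))

factor_index <- function(lexicon) {
  as.integer(factor(lexicon$factor, levels = unique(lexicon$factor)))
}

#' Initialize a model's latent state
#'
#' Fine models start at `V(i) = v0(i)`; coarse models at the per-factor mean
#' of `v0`; no-learning models carry no state. In `fixed_midpoint` mode the
#' initial expectations sit at the scale midpoint (4.5 on the 1-8 scale).
#'
#' @inheritParams param_vector
#' @param params A `param_vector`.
#' @return A `latent_state` list with `values` (named: one per trait for fine,
#'   one per factor for coarse) and `trial_index` (1-based).
#' @export
init_state <- function(model, params, lexicon) {
  values <- switch(model$family,
    no_learning = numeric(0),
    fine = setNames(params$v0, lexicon$label),
    coarse = {
      f <- factor(lexicon$factor, levels = unique(lexicon$factor))
      tapply(params$v0, f, mean)
    })
  structure(list(values = values, trial_index = 1L), class = "latent_state")
}

#' One-trial prediction
#'
#' The model's expected rating (favorability scale) for a trait before seeing
#' that trial's feedback. No-learning models return the reference point;
#' learning models return their current expectation `V`, or the convex mixture
#' `w * RP + (1 - w) * V` when a reference point is in play.
#'
#' @inheritParams init_state
#' @param state A `latent_state`.
#' @param trait 1-based trait index into the lexicon.
#' @param rp A `reference_points` object (see [build_reference_points()]);
#'   models with `reference_point = "none"` may pass `NULL`.
#' @param participant_id Participant whose self-ratings to use for self-RP
#'   models.
#' @export
predict_rating <- function(model, state, trait, params, lexicon,
                           rp = NULL, participant_id = NULL) {
  rpv <- rp_vector(model, rp, lexicon, participant_id)
  if (model$family == "no_learning") return(unname(rpv[trait]))
  v <- if (model$family == "fine") state$values[[trait]]
       else state$values[[factor_index(lexicon)[trait]]]
  if (model$reference_point == "none") return(v)
  params$w * unname(rpv[trait]) + (1 - params$w) * v
}

#' One-trial update (teacher forcing)
#'
#' Moves the latent expectations toward the observed feedback. Coarse: only
#' the observed trait's factor value changes, by `alpha * (F - V_f)`. Fine:
#' every trait moves by `alpha * s(i, j) * (F - V_j)` where j is the observed
#' trait. No-learning models are a no-op.
#'
#' @inheritParams predict_rating
#' @param feedback Observed feedback (favorability scale).
#' @param sim A `similarity_matrix` (fine models).
#' @export
update_state <- function(model, state, trait, feedback, params, lexicon,
                         sim = NULL) {
  if (model$family == "coarse") {
    f <- factor_index(lexicon)[trait]
    state$values[[f]] <- state$values[[f]] +
      params$alpha * (feedback - state$values[[f]])
  } else if (model$family == "fine") {
    if (is.null(sim)) stop("fine models require a similarity matrix")
    if (nrow(sim) != nrow(lexicon))
      stop("similarity matrix dimension mismatch")
    delta <- feedback - state$values[[trait]]
    state$values <- state$values + params$alpha * sim[, trait] * delta
  }
  state$trial_index <- state$trial_index + 1L
  state
}

# --- reference points ---------------------------------------------------

#' Bundle reference points for prediction
#'
#' @param lexicon A `trait_lexicon`.
#' @param population Per-trait population mean ratings, raw scale (length =
#'   lexicon size).
#' @param self_ratings Matrix or data.frame of per-participant self-ratings,
#'   raw scale: one row per participant (rownames = participant ids), one
#'   column per trait.
#' @return A `reference_points` list holding both on the favorability scale.
#' @export
build_reference_points <- function(lexicon, population = NULL, self_ratings = NULL) {
  out <- list(population = NULL, self = NULL)
  if (!is.null(population)) {
    stopifnot(length(population) == nrow(lexicon))
    out$population <- to_favorability(as.numeric(population), lexicon)
  }
  if (!is.null(self_ratings)) {
    m <- as.matrix(self_ratings)
    stopifnot(ncol(m) == nrow(lexicon))
    if (is.null(rownames(m))) stop("self_ratings must have participant ids as rownames")
    out$self <- to_favorability(m, lexicon)
  }
  structure(out, class = "reference_points")
}

rp_vector <- function(model, rp, lexicon, participant_id = NULL) {
  switch(model$reference_point,
    none = NULL,
    population = {
      if (is.null(rp) || is.null(rp$population))
        stop("model ", model$model_id, " requires population reference ratings")
      rp$population
    },
    self = {
      if (is.null(rp) || is.null(rp$self))
        stop("model ", model$model_id, " requires participant self-ratings")
      if (is.null(participant_id) || !participant_id %in% rownames(rp$self))
        stop("no self-ratings found for participant '", participant_id, "'")
      rp$self[participant_id, ]
    })
}

# --- sequence-level computation -----------------------------------------

# Convert one participant's ordered trial rows to the internal sequence form
# (favorability scale, 1-based trait indices, block ids from profile order).
participant_sequence <- function(trials, lexicon) {
  stopifnot(all(c("trait_id", "profile_id", "prediction", "feedback") %in% names(trials)))
  trait <- match(trials$trait_id, lexicon$trait_id)
  if (anyNA(trait)) stop("trial trait_id not present in lexicon")
  neg <- lexicon$valence[trait] == "negative"
  b <- scale_bounds(lexicon)
  flip <- function(x) ifelse(neg, (b[1] + b[2]) - x, x)
  list(trait = trait,
       block = cumsum(c(1L, trials$profile_id[-1] != trials$profile_id[-nrow(trials)])),
       prediction = flip(trials$prediction),
       feedback = flip(trials$feedback),
       valid = if ("valid" %in% names(trials)) as.logical(trials$valid)
               else rep(TRUE, nrow(trials)))
}

family_code <- function(family) {
  match(family, c("no_learning", "coarse", "fine")) - 1L
}

# Fast teacher-forced trajectory for one participant (C++ core).
trajectory <- function(model, params, seq, lexicon, rp = NULL,
                       participant_id = NULL, sim = NULL) {
  rpv <- rp_vector(model, rp, lexicon, participant_id)
  use_rp <- model$reference_point != "none"
  if (model$family == "fine") {
    if (is.null(sim)) stop("fine models require a similarity matrix")
    S <- unclass(sim)
  } else {
    S <- matrix(0, 0, 0)
  }
  tl_trajectory(seq$trait - 1L, seq$block, seq$feedback,
                family_code(model$family), use_rp,
                if (is.null(params$alpha)) 0 else params$alpha,
                if (is.null(params$w)) 0 else params$w,
                params$v0,
                if (use_rp || model$family == "no_learning") rpv else numeric(0),
                factor_index(lexicon) - 1L, S, n_factors_of(lexicon))
}

#' Teacher-forced predicted ratings for a trial table
#'
#' Runs each participant's model through their observed feedback sequence and
#' returns the model's expected rating for every trial (favorability scale).
#' The latent state resets at every profile change — each profile is a new
#' person to learn about.
#'
#' @param model A `model_spec`.
#' @param params A `param_vector`.
#' @param trials Trial table rows (may span several participants), ordered by
#'   participant, then presentation order.
#' @param lexicon,rp,sim See [param_vector()], [build_reference_points()],
#'   [block_similarity()].
#' @return Numeric vector of predicted ratings, one per trial row.
#' @export
predict_trials <- function(model, params, trials, lexicon, rp = NULL, sim = NULL) {
  unlist(lapply(split(seq_len(nrow(trials)), trials$participant_id)[
                  unique(trials$participant_id)],
                function(idx) {
    seq <- participant_sequence(trials[idx, , drop = FALSE], lexicon)
    trajectory(model, params, seq, lexicon, rp,
               participant_id = trials$participant_id[idx[1]], sim = sim)
  }), use.names = FALSE)
}

#' Gaussian sequence log-likelihood
#'
#' Log-likelihood of a participant's observed predictions under a model:
#' the sum over valid trials of the Gaussian log-density of the observed
#' prediction around the model's teacher-forced expected rating with SD
#' `sigma`. Invalid (excluded) trials contribute zero.
#'
#' @inheritParams predict_trials
#' @param trials One participant's ordered trial rows (or several; likelihoods
#'   add across participants sharing the same parameters).
#' @return Scalar log-likelihood.
#' @export
sequence_loglik <- function(model, params, trials, lexicon, rp = NULL, sim = NULL) {
  if (params$sigma <= 0) stop("sigma must be positive")
  total <- 0
  for (pid in unique(trials$participant_id)) {
    rows <- trials[trials$participant_id == pid, , drop = FALSE]
    seq <- participant_sequence(rows, lexicon)
    pred <- trajectory(model, params, seq, lexicon, rp, pid, sim)
    total <- total + tl_gauss_loglik(seq$prediction, pred, seq$valid, params$sigma)
  }
  total
}

#' Simulate responses from a model
#'
#' Draws one response per trial: the teacher-forced expected rating plus
#' Gaussian noise with SD `sigma`, rounded to the nearest integer and clipped
#' to the rating scale. Returned on the favorability scale; the noise does not
#' feed back into the latent state (updates use the profile's feedback only).
#'
#' @inheritParams predict_trials
#' @return Integer vector of simulated responses, one per trial row.
#' @export
simulate_responses <- function(model, params, trials, lexicon, rp = NULL, sim = NULL) {
  pred <- predict_trials(model, params, trials, lexicon, rp, sim)
  b <- scale_bounds(lexicon)
  noisy <- round(pred + rnorm(length(pred), 0, params$sigma))
  as.integer(pmin(pmax(noisy, b[1]), b[2]))
}
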