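# Shared fixtures and independent oracles, built in code at test time.

# Reduced 10-trait lexicon (2 per factor, one positive / one negative) for
# fast unit tests; the full 40-trait space is exercised where the design
# matters.
tiny_lexicon <- function() {
  build_default_lexicon(factor_counts = setNames(rep(2L, 5), c(
    "Neuroticism", "Extraversion", "Openness", "Agreeableness",
    "Conscientiousness")),
    positive_per_factor = setNames(rep(1L, 5), c(
      "Neuroticism", "Extraversion", "Openness", "Agreeableness",
      "Conscientiousness")),
    strict = FALSE)
}

# A small study simulated on a given lexicon.
tiny_study <- function(seed = 1, n_bpd = 3, n_con = 3,
                       generating_model = "fine_noRP",
                       lexicon = tiny_lexicon(), ...) {
  simulate_default_study(seed = seed, n_bpd = n_bpd, n_con = n_con,
                         generating_model = generating_model,
                         lexicon = lexicon, ...)
}

# A random trial skeleton (no behavioural content needed) for one
# participant: each trait once per block, blocks in profile order.
random_session <- function(lexicon, n_blocks = 2, seed = 1,
                           pid = "P1", group = "BPD_like") {
  set.seed(seed)
  nt <- nrow(lexicon)
  do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(participant_id = pid, group = group,
               profile_id = paste0("prof", b),
               profile_class = if (b %% 2 == 1) "CON_like" else "BPD_like",
               trial_index = seq_len(nt),
               trait_id = sample(lexicon$trait_id),
               prediction = sample(1:8, nt, replace = TRUE),
               feedback = sample(1:8, nt, replace = TRUE),
               valid = TRUE, stringsAsFactors = FALSE)
  }))
}

# --- independent oracle: naive per-trial re-implementation ---------------
# Recomputes the teacher-forced log-likelihood directly from the model
# equations with plain R loops, independently of the package's sequence code.
oracle_loglik <- function(model, params, trials, lexicon, rp = NULL,
                          sim = NULL, participant_id = trials$participant_id[1]) {
  nt <- nrow(lexicon)
  mid <- mean(c(attr(lexicon, "scale_min"), attr(lexicon, "scale_max")))
  fac <- lexicon$factor
  neg <- lexicon$valence == "negative"
  fav <- function(x, i) if (neg[i]) 9 - x else x
  rpv <- switch(model$reference_point,
                none = NULL,
                population = rp$population,
                self = rp$self[participant_id, ])
  v0 <- if (is.null(params$v0)) rep(mid, nt) else params$v0
  ll <- 0
  for (prof in unique(trials$profile_id)) {
    rows <- trials[trials$profile_id == prof, , drop = FALSE]
    V <- v0                       # per-trait state; coarse reads factor means
    if (model$family == "coarse")
      Vf <- sapply(unique(fac), function(f) mean(v0[fac == f]))
    for (r in seq_len(nrow(rows))) {
      i <- match(rows$trait_id[r], lexicon$trait_id)
      F <- fav(rows$feedback[r], i)
      P <- fav(rows$prediction[r], i)
      base <- switch(model$family,
                     no_learning = rpv[i],
                     coarse = Vf[[fac[i]]],
                     fine = V[i])
      pred <- if (model$family == "no_learning") base
              else if (model$reference_point == "none") base
              else params$w * rpv[i] + (1 - params$w) * base
      if (rows$valid[r])
        ll <- ll + dnorm(P, pred, params$sigma, log = TRUE)
      if (model$family == "coarse") {
        Vf[[fac[i]]] <- Vf[[fac[i]]] + params$alpha * (F - Vf[[fac[i]]])
      } else if (model$family == "fine") {
        V <- V + params$alpha * sim[, i] * (F - V[i])
      }
    }
  }
  ll
}

# Random valid parameters for any model.
random_params <- function(model, lexicon, seed = 1) {
  set.seed(seed)
  learning <- model$family != "no_learning"
  param_vector(model, lexicon,
               alpha = if (learning) runif(1, 0.05, 0.95),
               w = if (learning && model$reference_point != "none")
                 runif(1, 0.05, 0.95),
               sigma = runif(1, 0.3, 1.5),
               v0 = if (model$v0_mode == "estimated")
                 runif(nrow(lexicon), 2, 7))
}

# Reference points compatible with a lexicon and a set of participant ids.
tiny_rp <- function(lexicon, pids, seed = 1) {
  set.seed(seed)
  self <- matrix(sample(1:8, length(pids) * nrow(lexicon), replace = TRUE),
                 nrow = length(pids), dimnames = list(pids, NULL))
  build_reference_points(lexicon,
                         population = runif(nrow(lexicon), 2, 7),
                         self_ratings = self)
}
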