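#' Study design of the trait-learning task
#'
#' The task presents six learning profiles — three with borderline-like
#' (BPD-like) trait patterns and three control-like — in the fixed order
#' CON, BPD, CON, BPD, BPD, CON. Each profile block shows all traits once in
#' a per-participant shuffled order (40 trials per block, 240 in total for
#' the default lexicon). Cohort sizes default to the study's 30 BPD-like and
#' 31 control-like participants.
#'
#' @param profile_order Character vector of profile classes per block.
#' @param trials_per_profile Trials per block (= lexicon size; each trait
#'   shown once).
#' @param n_bpd,n_con Cohort sizes.
#' @param seed Master seed; participant-level streams are derived from it.
#' @return A `study_design` list.
#' @export
study_design <- function(profile_order = c("CON_like", "BPD_like", "CON_like",
                                           "BPD_like", "BPD_like", "CON_like"),
                         trials_per_profile = 40L,
                         n_bpd = 30L, n_con = 31L, seed = 1L) {
  stopifnot(all(profile_order %in% c("BPD_like", "CON_like")),
            trials_per_profile > 0L, n_bpd >= 0L, n_con >= 0L)
  structure(list(profile_order = profile_order,
                 trials_per_profile = as.integer(trials_per_profile),
                 n_bpd = as.integer(n_bpd), n_con = as.integer(n_con),
                 seed = as.integer(seed)),
            class = "study_design")
}

# Small deterministic substream seeds below 2^31.
substream_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1009 + index * 7919) %% 2147483629)
}

clip_rating <- function(x, lexicon) {
  b <- scale_bounds(lexicon)
  as.integer(pmin(pmax(round(x), b[1]), b[2]))
}

#' Default per-class trait distributions
#'
#' Per-trait means and SDs of the two profile/participant classes on the raw
#' 1-8 scale. Defaults place the control-like class at mean 6.28 on positive
#' and 2.84 on negative traits and the BPD-like class at 5.79 / 3.89 — the
#' two groups' observed valence-specific self-rating means — giving a
#' favorability gap of about 0.77 rating points. The item-level SD defaults
#' to 1.3.
#'
#' @param lexicon A `trait_lexicon`.
#' @param means Named list: per class, `c(positive =, negative =)` raw-scale
#'   means.
#' @param sd Item-level SD (scalar or per-trait).
#' @return Named list of per-class data.frames (`mean`, `sd`, one row per
#'   trait).
#' @export
default_class_params <- function(lexicon,
                                 means = list(
                                   CON_like = c(positive = 6.28, negative = 2.84),
                                   BPD_like = c(positive = 5.79, negative = 3.89)),
                                 sd = 1.3) {
  lapply(means, function(m) {
    data.frame(trait_id = lexicon$trait_id,
               mean = unname(m[lexicon$valence]),
               sd = rep_len(sd, nrow(lexicon)))
  })
}

#' Screen a candidate profile against its class distribution
#'
#' The profile-selection rule: a profile is a typical class exemplar when at
#' most six traits deviate from the class mean by more than one class SD.
#'
#' @param profile A `profile_spec` (or any list with `true_ratings`).
#' @param class_reference Data.frame with per-trait `mean` and `sd`.
#' @param max_deviations Allowed count of out-of-band traits (default 6).
#' @return List `deviations` (count) and `pass` (flag).
#' @export
validate_profile <- function(profile, class_reference, max_deviations = 6L) {
  r <- profile$true_ratings
  stopifnot(length(r) == nrow(class_reference))
  dev <- sum(abs(r - class_reference$mean) > class_reference$sd)
  list(deviations = dev, pass = dev <= max_deviations)
}

#' Generate learning profiles
#'
#' Draws per-class profile rating vectors (rounded and clipped to the rating
#' scale) and screens each against the one-SD typicality rule of
#' [validate_profile()], resampling until it passes within a bounded retry
#' budget. Candidates are drawn at a fraction of the class SD
#' (`selection_sd_frac`) because screened exemplars are by construction less
#' dispersed than the population they come from.
#'
#' @param class_params Per-class trait mean/SD tables
#'   (see [default_class_params()]).
#' @param lexicon A `trait_lexicon`.
#' @param n_per_class Profiles per class (default 3).
#' @param seed Integer seed.
#' @param selection_sd_frac Candidate-draw SD as a fraction of the class SD.
#' @param max_retries Retry budget per profile.
#' @return List of `profile_spec` objects (`profile_id`, `profile_class`,
#'   `true_ratings`), classes interleaved as drawn.
#' @export
generate_profiles <- function(class_params, lexicon, n_per_class = 3L,
                              seed = 1L, selection_sd_frac = 0.75,
                              max_retries = 500L) {
  set.seed(seed)
  out <- list()
  for (cls in names(class_params)) {
    ref <- class_params[[cls]]
    for (k in seq_len(n_per_class)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        r <- clip_rating(rnorm(nrow(ref), ref$mean, ref$sd * selection_sd_frac),
                         lexicon)
        p <- structure(list(profile_id = paste0(sub("_like", "", cls), "_", k),
                            profile_class = cls, true_ratings = r),
                       class = "profile_spec")
        if (validate_profile(p, ref)$pass) { ok <- TRUE; break }
      }
      if (!ok)
        stop("retry budget exhausted generating a ", cls, " profile; ",
             "class_params incompatible with the typicality screen")
      out[[p$profile_id]] <- p
    }
  }
  out
}

#' Synthetic reference raters, similarity, and population norms
#'
#' Simulates a reference population of raters under a one-factor-per-Big-Five
#' latent model: each rater has one latent score per factor; a trait's raw
#' rating is its class-mixture mean plus `loading` times the factor score
#' (sign-flipped for negative traits) plus noise. The resulting rating table
#' yields (i) an empirical trait-trait similarity matrix with a realistic
#' within-factor block structure and (ii) per-trait population mean ratings
#' used as the population reference point.
#'
#' @param lexicon A `trait_lexicon`.
#' @param n_raters Reference-sample size (default 300).
#' @param seed Integer seed.
#' @param loading Factor loading in rating units (default 0.8).
#' @param noise Residual SD in rating units (default 1).
#' @param class_params Optional class tables; defaults to
#'   [default_class_params()], mixed 50/50.
#' @return List: `ratings` (raters x traits, raw scale), `similarity`
#'   (a `similarity_matrix`), `population` (raw-scale per-trait means).
#' @export
synthetic_reference <- function(lexicon, n_raters = 300L, seed = 1L,
                                loading = 0.8, noise = 1,
                                class_params = default_class_params(lexicon)) {
  set.seed(seed)
  nt <- nrow(lexicon)
  fidx <- factor_index(lexicon)
  mix_mean <- rowMeans(vapply(class_params, function(cp) cp$mean,
                              numeric(nt)))
  sign <- ifelse(lexicon$valence == "negative", -1, 1)
  f <- matrix(rnorm(n_raters * max(fidx)), n_raters)
  raw <- matrix(mix_mean, n_raters, nt, byrow = TRUE) +
    loading * f[, fidx] * matrix(sign, n_raters, nt, byrow = TRUE) +
    matrix(rnorm(n_raters * nt, 0, noise), n_raters)
  b <- scale_bounds(lexicon)
  ratings <- matrix(pmin(pmax(round(raw), b[1]), b[2]), n_raters, nt)
  list(ratings = ratings,
       similarity = empirical_similarity(ratings, lexicon),
       population = colMeans(ratings))
}

#' Generate a synthetic participant cohort
#'
#' Draws each participant's generative parameters from condition-level
#' distributions (logit-normal for alpha and w around natural-scale medians,
#' log-normal for sigma) and an integer self-rating vector from the group's
#' valence-specific means — the BPD-like group rating itself less favorably.
#'
#' @param design A [study_design()].
#' @param lexicon A `trait_lexicon`.
#' @param generating_model `model_spec` (or model id) every participant
#'   responds with; default `"fine_noRP"`, the winning model family.
#' @param hyperparams Named list per group with elements `alpha_mu`,
#'   `alpha_tau` (logit scale tau), `w_mu`, `w_tau`, `sigma_mu`, `sigma_tau`
#'   (log scale tau), `self_means` (`c(positive=, negative=)` raw scale),
#'   `self_sd`.
#' @return List of `participant_spec` (`participant_id`, `group`,
#'   `self_ratings`, `generating_model`, `true_params`).
#' @export
generate_cohort <- function(design, lexicon,
                            generating_model = "fine_noRP",
                            hyperparams = default_hyperparams()) {
  if (is.character(generating_model)) generating_model <- get_model(generating_model)
  counts <- c(BPD_like = design$n_bpd, CON_like = design$n_con)
  pnames <- free_param_names(generating_model)
  cohort <- list()
  idx <- 0L
  for (grp in names(counts)) {
    h <- hyperparams[[grp]]
    for (k in seq_len(counts[[grp]])) {
      idx <- idx + 1L
      set.seed(substream_seed(design$seed, idx))
      alpha <- if ("alpha" %in% pnames)
        ilogit(rnorm(1, logit(h$alpha_mu), h$alpha_tau)) else NULL
      w <- if ("w" %in% pnames)
        ilogit(rnorm(1, logit(h$w_mu), h$w_tau)) else NULL
      sigma <- exp(rnorm(1, log(h$sigma_mu), h$sigma_tau))
      self <- clip_rating(rnorm(nrow(lexicon),
                                unname(h$self_means[lexicon$valence]),
                                h$self_sd), lexicon)
      v0 <- if (generating_model$v0_mode == "estimated")
        pmin(pmax(rnorm(nrow(lexicon), h$v0_mu, h$v0_tau),
                  scale_bounds(lexicon)[1]), scale_bounds(lexicon)[2])
      else NULL
      pid <- sprintf("%s_%02d", sub("_like", "", grp), k)
      cohort[[pid]] <- structure(
        list(participant_id = pid, group = grp, self_ratings = self,
             generating_model = generating_model,
             true_params = param_vector(generating_model, lexicon,
                                        alpha = alpha, w = w, sigma = sigma,
                                        v0 = v0)),
        class = "participant_spec")
    }
  }
  cohort
}

#' Default cohort hyperparameters
#'
#' Desk-scale defaults: median learning rate 0.3, reference weight 0.4,
#' response noise 0.7 rating points; self-rating means at the groups'
#' observed valence-specific values (control-like more favorable by ~0.77
#' favorability points).
#'
#' @param alpha_mu,sigma_mu Natural-scale medians shared by both groups.
#' @return Named list of per-group hyperparameter lists.
#' @export
default_hyperparams <- function(alpha_mu = 0.3, sigma_mu = 0.7) {
  base <- list(alpha_mu = alpha_mu, alpha_tau = 0.5,
               w_mu = 0.4, w_tau = 0.5,
               sigma_mu = sigma_mu, sigma_tau = 0.25,
               v0_mu = 5, v0_tau = 1, self_sd = 1.3)
  list(BPD_like = c(base, list(self_means = c(positive = 5.79, negative = 3.89))),
       CON_like = c(base, list(self_means = c(positive = 6.28, negative = 2.84))))
}

#' Simulate the full learning task
#'
#' Presents the profiles to every participant in the design's block order
#' (classes mapped to profiles in their listed order), with an independently
#' shuffled trait order per participant and block (derived from the design's
#' master seed). Each trial's feedback is the profile's true rating; the
#' participant's prediction is generated by their own model
#' (teacher-forced expected rating plus Gaussian noise, rounded and clipped).
#'
#' @param cohort Output of [generate_cohort()].
#' @param profiles Output of [generate_profiles()]; must contain at least as
#'   many profiles of each class as the design order requires.
#' @param design A [study_design()].
#' @param lexicon A `trait_lexicon`.
#' @param sim A `similarity_matrix` (fine generating models).
#' @param rp_population Raw-scale per-trait population reference ratings
#'   (population-RP generating models).
#' @param exclusions When `TRUE`, mark 0-2 random trait words per participant
#'   invalid in all blocks (emulating not-understood items). Default `FALSE`.
#' @return A long trial table (`participant_id`, `group`, `profile_id`,
#'   `profile_class`, `trial_index`, `trait_id`, `prediction`, `feedback`,
#'   `valid`) with attributes `reference_points` and `ground_truth`.
#' @export
simulate_study <- function(cohort, profiles, design, lexicon, sim = NULL,
                           rp_population = NULL, exclusions = FALSE) {
  stopifnot(length(cohort) > 0L)
  classes <- vapply(profiles, `[[`, "", "profile_class")
  seq_ids <- character(length(design$profile_order))
  used <- c(BPD_like = 0L, CON_like = 0L)
  for (b in seq_along(design$profile_order)) {
    cls <- design$profile_order[b]
    pool <- names(profiles)[classes == cls]
    used[cls] <- used[cls] + 1L
    if (used[cls] > length(pool))
      stop("design order needs ", used[cls], " ", cls,
           " profiles but only ", length(pool), " supplied")
    seq_ids[b] <- pool[used[cls]]
  }
  if (design$trials_per_profile != nrow(lexicon))
    stop("trials_per_profile must equal lexicon size (each trait shown once)")

  self_mat <- do.call(rbind, lapply(cohort, `[[`, "self_ratings"))
  rownames(self_mat) <- names(cohort)
  rp <- build_reference_points(lexicon, population = rp_population,
                               self_ratings = self_mat)

  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    set.seed(substream_seed(design$seed + 104729, i))
    order_per_block <- lapply(seq_ids, function(id) sample.int(nrow(lexicon)))
    tr <- do.call(rbind, lapply(seq_along(seq_ids), function(b) {
      prof <- profiles[[seq_ids[b]]]
      traits <- order_per_block[[b]]
      data.frame(participant_id = p$participant_id, group = p$group,
                 profile_id = prof$profile_id,
                 profile_class = prof$profile_class,
                 trial_index = seq_len(nrow(lexicon)),
                 trait_id = lexicon$trait_id[traits],
                 prediction = NA_integer_,
                 feedback = prof$true_ratings[traits],
                 valid = TRUE, stringsAsFactors = FALSE)
    }))
    if (exclusions) {
      n_excl <- sample(0:2, 1)
      if (n_excl > 0) {
        bad <- sample(lexicon$trait_id, n_excl)
        tr$valid[tr$trait_id %in% bad] <- FALSE
      }
    }
    pred_fav <- simulate_responses(p$generating_model, p$true_params, tr,
                                   lexicon, rp, sim)
    # responses come back on the favorability scale; store raw
    neg <- lexicon$valence[match(tr$trait_id, lexicon$trait_id)] == "negative"
    bsum <- sum(scale_bounds(lexicon))
    tr$prediction <- as.integer(ifelse(neg, bsum - pred_fav, pred_fav))
    rows[[i]] <- tr
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  attr(trials, "reference_points") <- rp
  attr(trials, "ground_truth") <- cohort
  trials
}

#' One-call synthetic study
#'
#' Convenience wrapper chaining [default_class_params()],
#' [generate_profiles()], [synthetic_reference()], [generate_cohort()] and
#' [simulate_study()] with a single seed — the standard entry point for
#' recovery simulations and examples.
#'
#' @param seed Master seed.
#' @param n_bpd,n_con Cohort sizes.
#' @param generating_model Model id or `model_spec` participants respond with.
#' @param lexicon Trait lexicon (default the full 40-trait space).
#' @param hyperparams See [generate_cohort()].
#' @param exclusions See [simulate_study()].
#' @return List: `trials`, `cohort`, `profiles`, `lexicon`, `sim`, `rp`,
#'   `design`.
#' @export
simulate_default_study <- function(seed = 1L, n_bpd = 30L, n_con = 31L,
                                   generating_model = "fine_noRP",
                                   lexicon = build_default_lexicon(),
                                   hyperparams = default_hyperparams(),
                                   exclusions = FALSE) {
  design <- study_design(n_bpd = n_bpd, n_con = n_con,
                         trials_per_profile = nrow(lexicon), seed = seed)
  cp <- default_class_params(lexicon)
  profiles <- generate_profiles(cp, lexicon, seed = substream_seed(seed, 1))
  ref <- synthetic_reference(lexicon, seed = substream_seed(seed, 2))
  cohort <- generate_cohort(design, lexicon, generating_model, hyperparams)
  trials <- simulate_study(cohort, profiles, design, lexicon,
                           sim = ref$similarity,
                           rp_population = ref$population,
                           exclusions = exclusions)
  list(trials = trials, cohort = cohort, profiles = profiles,
       lexicon = lexicon, sim = ref$similarity,
       rp = attr(trials, "reference_points"), design = design)
}
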