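#' MCMC configuration
#'
#' Sampler settings and convergence thresholds for [fit_hierarchical()].
#' Group-level parameters are sampled on unconstrained scales (logit for
#' alpha and w, log for sigma, identity for V0 in rating units).
#'
#' @param chains Number of chains (>= 2).
#' @param warmup_draws Adaptation iterations discarded per chain.
#' @param sampling_draws Retained iterations per chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param max_rhat Potential-scale-reduction threshold (default 1.01).
#' @param min_ess Bulk effective-sample-size threshold (default 400).
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 2L, warmup_draws = 500L, sampling_draws = 500L,
                        seed = 1L, max_rhat = 1.01, min_ess = 400) {
  if (chains < 2L) stop("need at least 2 chains")
  if (warmup_draws <= 0L || sampling_draws <= 0L) stop("draw counts must be positive")
  structure(list(chains = as.integer(chains),
                 warmup_draws = as.integer(warmup_draws),
                 sampling_draws = as.integer(sampling_draws),
                 seed = as.integer(seed),
                 max_rhat = max_rhat, min_ess = min_ess),
            class = "mcmc_config")
}

logit <- function(p) log(p) - log1p(-p)
ilogit <- function(x) 1 / (1 + exp(-x))

# Which participant-level parameters a model frees, in sampler order.
free_param_names <- function(model) {
  c(if (model$family != "no_learning") "alpha",
    if (model$family != "no_learning" && model$reference_point != "none") "w",
    "sigma")
}

# unconstrained z -> natural-scale named list for one participant
z_to_params <- function(z, pnames, model, lexicon, v0 = NULL) {
  vals <- list(alpha = NULL, w = NULL, sigma = NULL)
  for (k in seq_along(pnames)) {
    vals[[pnames[k]]] <- switch(pnames[k],
      alpha = ilogit(z[k]), w = ilogit(z[k]), sigma = exp(z[k]))
  }
  if (is.null(v0)) v0 <- rep(scale_midpoint(lexicon), nrow(lexicon))
  param_vector(model, lexicon, alpha = vals$alpha, w = vals$w,
               sigma = vals$sigma, v0 = v0)
}

# Precompute per-participant sequences, 0-based indices and reference-point
# vectors once; likelihood evals then go straight to the C++ trajectory.
prepare_condition_data <- function(trials, model, lexicon, rp, sim) {
  pids <- unique(trials$participant_id)
  seqs <- lapply(pids, function(pid)
    participant_sequence(trials[trials$participant_id == pid, , drop = FALSE],
                         lexicon))
  seqs <- lapply(seqs, function(s) { s$trait0 <- s$trait - 1L; s })
  names(seqs) <- pids
  use_rp <- model$reference_point != "none"
  rpv <- if (use_rp || model$family == "no_learning")
    lapply(setNames(pids, pids), function(pid) rp_vector(model, rp, lexicon, pid))
  else NULL
  S <- if (model$family == "fine") {
    if (is.null(sim)) stop("fine models require a similarity matrix")
    if (nrow(sim) != nrow(lexicon)) stop("similarity matrix dimension mismatch")
    matrix(as.numeric(sim), nrow(sim))
  } else matrix(0, 0, 0)
  # concatenated arrays for single-call whole-condition likelihoods
  starts <- c(0L, cumsum(vapply(seqs, function(x) length(x$trait), 0L)))
  rp_mat <- if (!is.null(rpv)) do.call(cbind, rpv) else matrix(0, 0, 0)
  list(pids = pids, seqs = seqs, model = model, lexicon = lexicon,
       rp = rp, sim = sim,
       fam = family_code(model$family), use_rp = use_rp, rpv = rpv, S = S,
       fidx0 = factor_index(lexicon) - 1L, nf = n_factors_of(lexicon),
       v0_default = rep(scale_midpoint(lexicon), nrow(lexicon)),
       cat = list(trait0 = unlist(lapply(seqs, `[[`, "trait0"), use.names = FALSE),
                  block = unlist(lapply(seqs, `[[`, "block"), use.names = FALSE),
                  feedback = unlist(lapply(seqs, `[[`, "feedback"), use.names = FALSE),
                  observed = unlist(lapply(seqs, `[[`, "prediction"), use.names = FALSE),
                  valid = unlist(lapply(seqs, `[[`, "valid"), use.names = FALSE),
                  starts = starts),
       rp_mat = rp_mat)
}

subject_loglik <- function(dat, pid, params) {
  seq <- dat$seqs[[pid]]
  pred <- tl_trajectory(seq$trait0, seq$block, seq$feedback,
                        dat$fam, dat$use_rp,
                        if (is.null(params$alpha)) 0 else params$alpha,
                        if (is.null(params$w)) 0 else params$w,
                        if (is.null(params$v0)) dat$v0_default else params$v0,
                        if (is.null(dat$rpv)) numeric(0) else dat$rpv[[pid]],
                        dat$fidx0, dat$S, dat$nf)
  tl_gauss_loglik(seq$prediction, pred, seq$valid, params$sigma)
}

# Whole-condition per-participant log-likelihoods in one C++ call; z is the
# n_subjects x n_params unconstrained matrix.
all_subject_logliks <- function(dat, z, pnames, v0 = NULL) {
  n_s <- length(dat$pids)
  a <- w <- numeric(n_s); sg <- rep(1, n_s)
  for (k in seq_along(pnames)) {
    col <- if (pnames[k] == "sigma") exp(z[, k]) else ilogit(z[, k])
    if (pnames[k] == "alpha") a <- col
    else if (pnames[k] == "w") w <- col
    else sg <- col
  }
  tl_subject_logliks(dat$cat$trait0, dat$cat$block, dat$cat$feedback,
                     dat$cat$observed, dat$cat$valid, dat$cat$starts,
                     dat$fam, dat$use_rp, a, w, sg,
                     if (is.null(v0)) dat$v0_default else v0,
                     dat$rp_mat, dat$fidx0, dat$S, dat$nf)
}

# Lean parameter container for sampler-internal likelihood calls (skips
# param_vector validation).
fast_params <- function(z, pnames, v0 = NULL) {
  p <- list(alpha = NULL, w = NULL, sigma = NULL, v0 = v0)
  for (k in seq_along(pnames))
    p[[pnames[k]]] <- if (pnames[k] == "sigma") exp(z[k]) else ilogit(z[k])
  p
}

#' Hierarchical Bayesian fit of one condition
#'
#' Fits a model to all participants of one condition (participant group x
#' profile type) with participant-level parameters drawn from condition-level
#' distributions: on unconstrained scales, `z_s ~ Normal(mu, tau)` per
#' parameter (logit-alpha, logit-w, log-sigma), with priors
#' `mu ~ Normal(0, 1)` and `tau ~ HalfNormal(1)`. Estimated-V0 variants add a
#' condition-level per-trait vector `v0[i] ~ Normal(v0_bar, tau_v0)` with
#' `v0_bar ~ Normal(midpoint, 2)` (rating units), shrinking trait-wise initial
#' expectations toward a condition mean.
#'
#' Sampling is adaptive random-walk Metropolis-within-Gibbs: joint
#' per-participant proposals with Robbins-Monro scale adaptation during
#' warmup, conjugate Gibbs updates for each `mu`, and random-walk updates for
#' each `log tau` (and the V0 block). Convergence is checked with split-chain
#' potential scale reduction and effective sample size (via coda); a fit
#' missing the thresholds is returned with `warning_flag = TRUE`, never
#' silently accepted.
#'
#' @param trials Trial table restricted to one condition; >= 2 participants.
#' @param model A `model_spec`.
#' @param lexicon,rp,sim Task structures (see [build_reference_points()]).
#' @param config An [mcmc_config()].
#' @return A `tl_posterior` with draws of group-level parameters on both the
#'   sampling scale (`mu_*`, `tau_*`) and the natural scale (`alpha_pop`,
#'   `w_pop`, `sigma_pop`, `v0_mean`), plus participant-level natural-scale
#'   draws (`alpha[pid]`, ...), diagnostics, and acceptance rates.
#' @export
fit_hierarchical <- function(trials, model, lexicon, rp = NULL, sim = NULL,
                             config = mcmc_config()) {
  dat <- prepare_condition_data(trials, model, lexicon, rp, sim)
  n_s <- length(dat$pids)
  if (n_s < 2L)
    stop("hierarchical spread is unidentifiable with a single participant; ",
         "use fit_map_subject()")
  pnames <- free_param_names(model)
  n_p <- length(pnames)
  est_v0 <- model$v0_mode == "estimated"
  nt <- nrow(lexicon)
  mid <- scale_midpoint(lexicon)
  n_iter <- config$warmup_draws + config$sampling_draws

  run_chain <- function(chain_id) {
    set.seed(config$seed + chain_id)
    z <- matrix(rnorm(n_s * n_p, 0, 0.5), n_s, n_p)
    mu <- rnorm(n_p, 0, 0.5)
    tau <- rep(0.5, n_p)
    v0 <- rep(mid, nt)
    v0_bar <- mid
    tau_v0 <- 0.5
    prop_scale <- matrix(0.3, n_s, n_p)   # per-participant, per-parameter RW scales
    tau_scale <- rep(0.5, n_p)
    nc_scale <- rep(0.3, n_p)
    v0_scale <- rep(0.4, nt)
    shift_scale <- 0.2
    v0nc_scale <- 0.3
    accept_s <- numeric(n_s)

    ll_s <- all_subject_logliks(dat, z, pnames, if (est_v0) v0 else NULL)

    keep <- config$sampling_draws
    draw_names <- c(paste0("mu_", pnames), paste0("tau_", pnames),
                    paste0(pnames, "_pop"),
                    if (est_v0) c("v0_mean", "v0_bar", "tau_v0"),
                    unlist(lapply(pnames, function(p) paste0(p, "[", dat$pids, "]"))))
    draws <- matrix(NA_real_, keep, length(draw_names),
                    dimnames = list(NULL, draw_names))

    for (it in seq_len(n_iter)) {
      adapting <- it <= config$warmup_draws
      # participant-level RW-MH, one parameter at a time
      for (s in seq_len(n_s)) {
        n_acc <- 0
        for (k in seq_len(n_p)) {
          z_new <- z[s, ]
          z_new[k] <- z_new[k] + rnorm(1, 0, prop_scale[s, k])
          ll_new <- subject_loglik(dat, dat$pids[s],
                                   fast_params(z_new, pnames,
                                               if (est_v0) v0 else NULL))
          log_r <- (ll_new + dnorm(z_new[k], mu[k], tau[k], log = TRUE)) -
            (ll_s[s] + dnorm(z[s, k], mu[k], tau[k], log = TRUE))
          acc <- is.finite(log_r) && log(runif(1)) < log_r
          if (acc) { z[s, ] <- z_new; ll_s[s] <- ll_new; n_acc <- n_acc + 1 }
          if (adapting)
            prop_scale[s, k] <- exp(log(prop_scale[s, k]) +
                                      (as.numeric(acc) - 0.44) / sqrt(it))
        }
        if (!adapting) accept_s[s] <- accept_s[s] + n_acc / n_p
      }
      # group means: conjugate Gibbs, prior N(0, 1)
      for (k in seq_len(n_p)) {
        post_var <- 1 / (n_s / tau[k]^2 + 1)
        mu[k] <- rnorm(1, post_var * sum(z[, k]) / tau[k]^2, sqrt(post_var))
      }
      # group spreads: RW on log tau, prior HalfNormal(1) (centered step)
      for (k in seq_len(n_p)) {
        lt_new <- log(tau[k]) + rnorm(1, 0, tau_scale[k])
        t_new <- exp(lt_new)
        log_r <- sum(dnorm(z[, k], mu[k], t_new, log = TRUE)) -
          sum(dnorm(z[, k], mu[k], tau[k], log = TRUE)) +
          dnorm(t_new, 0, 1, log = TRUE) - dnorm(tau[k], 0, 1, log = TRUE) +
          lt_new - log(tau[k])                        # Jacobian
        acc <- is.finite(log_r) && log(runif(1)) < log_r
        if (acc) tau[k] <- t_new
        if (adapting)
          tau_scale[k] <- exp(log(tau_scale[k]) + (as.numeric(acc) - 0.44) / sqrt(it))
      }
      # interweaved non-centered step: hold u = (z - mu)/tau fixed, propose
      # tau, rescale z with it -- breaks the funnel coupling of tau and z
      for (k in seq_len(n_p)) {
        u <- (z[, k] - mu[k]) / tau[k]
        lt_new <- log(tau[k]) + rnorm(1, 0, nc_scale[k])
        t_new <- exp(lt_new)
        z_try <- z
        z_try[, k] <- mu[k] + t_new * u
        ll_try <- all_subject_logliks(dat, z_try, pnames,
                                      if (est_v0) v0 else NULL)
        log_r <- sum(ll_try) - sum(ll_s) +
          dnorm(t_new, 0, 1, log = TRUE) - dnorm(tau[k], 0, 1, log = TRUE) +
          lt_new - log(tau[k])
        acc <- is.finite(log_r) && log(runif(1)) < log_r
        if (acc) { tau[k] <- t_new; z <- z_try; ll_s <- ll_try }
        if (adapting)
          nc_scale[k] <- exp(log(nc_scale[k]) + (as.numeric(acc) - 0.44) / sqrt(it))
      }
      # condition-level V0 block
      if (est_v0) {
        for (i in sample.int(nt)) {
          v_new <- v0
          v_new[i] <- v0[i] + rnorm(1, 0, v0_scale[i])
          ll_new_all <- all_subject_logliks(dat, z, pnames, v_new)
          log_r <- sum(ll_new_all) - sum(ll_s) +
            dnorm(v_new[i], v0_bar, tau_v0, log = TRUE) -
            dnorm(v0[i], v0_bar, tau_v0, log = TRUE)
          acc <- is.finite(log_r) && log(runif(1)) < log_r
          if (acc) { v0 <- v_new; ll_s <- ll_new_all }
          if (adapting)
            v0_scale[i] <- exp(log(v0_scale[i]) + (as.numeric(acc) - 0.44) / sqrt(it))
        }
        # translation move: shift the whole V0 block and its mean together --
        # the per-coordinate walk moves the average initial expectation only
        # diffusively, this targets that slow direction directly
        delta <- rnorm(1, 0, shift_scale)
        v_new <- v0 + delta
        ll_try <- all_subject_logliks(dat, z, pnames, v_new)
        log_r <- sum(ll_try) - sum(ll_s) +
          dnorm(v0_bar + delta, mid, 2, log = TRUE) -
          dnorm(v0_bar, mid, 2, log = TRUE)
        acc <- is.finite(log_r) && log(runif(1)) < log_r
        if (acc) { v0 <- v_new; v0_bar <- v0_bar + delta; ll_s <- ll_try }
        if (adapting)
          shift_scale <- exp(log(shift_scale) + (as.numeric(acc) - 0.44) / sqrt(it))
        post_var <- 1 / (nt / tau_v0^2 + 1 / 4)       # prior N(mid, 2)
        v0_bar <- rnorm(1, post_var * (sum(v0) / tau_v0^2 + mid / 4), sqrt(post_var))
        lt_new <- log(tau_v0) + rnorm(1, 0, 0.3)
        t_new <- exp(lt_new)
        log_r <- sum(dnorm(v0, v0_bar, t_new, log = TRUE)) -
          sum(dnorm(v0, v0_bar, tau_v0, log = TRUE)) +
          dnorm(t_new, 0, 1, log = TRUE) - dnorm(tau_v0, 0, 1, log = TRUE) +
          lt_new - log(tau_v0)
        if (is.finite(log_r) && log(runif(1)) < log_r) tau_v0 <- t_new
        # interweaved non-centered step for the V0 spread: hold the scaled
        # deviations fixed, propose tau_v0, rescale the block
        u <- (v0 - v0_bar) / tau_v0
        lt_new <- log(tau_v0) + rnorm(1, 0, v0nc_scale)
        t_new <- exp(lt_new)
        v_new <- v0_bar + t_new * u
        ll_try <- all_subject_logliks(dat, z, pnames, v_new)
        log_r <- sum(ll_try) - sum(ll_s) +
          dnorm(t_new, 0, 1, log = TRUE) - dnorm(tau_v0, 0, 1, log = TRUE) +
          lt_new - log(tau_v0)
        acc <- is.finite(log_r) && log(runif(1)) < log_r
        if (acc) { tau_v0 <- t_new; v0 <- v_new; ll_s <- ll_try }
        if (adapting)
          v0nc_scale <- exp(log(v0nc_scale) + (as.numeric(acc) - 0.44) / sqrt(it))
      }

      if (!adapting) {
        j <- it - config$warmup_draws
        nat_group <- vapply(seq_len(n_p), function(k) switch(pnames[k],
          alpha = ilogit(mu[k]), w = ilogit(mu[k]), sigma = exp(mu[k])), 0)
        part_nat <- unlist(lapply(seq_len(n_p), function(k) switch(pnames[k],
          alpha = ilogit(z[, k]), w = ilogit(z[, k]), sigma = exp(z[, k]))))
        draws[j, ] <- c(mu, tau, nat_group,
                        if (est_v0) c(mean(v0), v0_bar, tau_v0),
                        part_nat)
      }
    }
    list(draws = draws, accept = accept_s / config$sampling_draws)
  }

  chains <- lapply(seq_len(config$chains), run_chain)
  all_draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  chain_id <- rep(seq_len(config$chains), each = config$sampling_draws)

  diag <- posterior_diagnostics(chains, config)
  warn <- any(diag$rhat > config$max_rhat, na.rm = TRUE) ||
    any(diag$ess < config$min_ess, na.rm = TRUE)
  if (warn)
    warning("convergence thresholds not met (max rhat = ",
            round(max(diag$rhat, na.rm = TRUE), 3), ", min ess = ",
            round(min(diag$ess, na.rm = TRUE)), "); treat estimates with care")

  structure(list(draws = all_draws, chain = chain_id,
                 participant_ids = dat$pids, model = model,
                 condition = attr(trials, "condition"),
                 free_params = pnames,
                 diagnostics = diag, warning_flag = warn,
                 accept_rates = rowMeans(do.call(cbind, lapply(chains, `[[`, "accept"))),
                 config = config),
            class = "tl_posterior")
}

# Split-chain Rhat and ESS on the group-level columns, via coda.
posterior_diagnostics <- function(chains, config) {
  cols <- colnames(chains[[1]]$draws)
  group_cols <- cols[!grepl("\\[", cols)]
  half <- floor(config$sampling_draws / 2)
  split_list <- list()
  for (ch in chains) {
    split_list <- c(split_list,
                    list(ch$draws[seq_len(half), group_cols, drop = FALSE],
                         ch$draws[half + seq_len(half), group_cols, drop = FALSE]))
  }
  ml <- coda::mcmc.list(lapply(split_list, coda::mcmc))
  rhat <- tryCatch(coda::gelman.diag(ml, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, length(group_cols)))
  ess <- tryCatch(coda::effectiveSize(ml), error = function(e)
    rep(NA_real_, length(group_cols)))
  data.frame(parameter = group_cols, rhat = as.numeric(rhat),
             ess = as.numeric(ess), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' @export
print.tl_posterior <- function(x, ...) {
  cat("<tl_posterior>", x$model$model_id,
      if (!is.null(x$condition)) paste0("[", paste(x$condition, collapse = " x "), "]"),
      "\n ", nrow(x$draws), "draws,", max(x$chain), "chains,",
      length(x$participant_ids), "participants\n")
  gc <- x$diagnostics
  cat("  max rhat:", round(max(gc$rhat, na.rm = TRUE), 3),
      "| min ess:", round(min(gc$ess, na.rm = TRUE)),
      if (x$warning_flag) "| CONVERGENCE WARNING", "\n")
  invisible(x)
}

#' Posterior draws of one parameter
#'
#' @param post A `tl_posterior`.
#' @param parameter Natural-scale group parameter: `"alpha"`, `"w"`,
#'   `"sigma"`, `"v0_mean"` (aliases for `alpha_pop` etc.), any draw column
#'   name, or `"alpha[<pid>]"` for participant-level draws.
#' @return Numeric vector of draws.
#' @export
posterior_draws <- function(post, parameter) {
  alias <- c(alpha = "alpha_pop", w = "w_pop", sigma = "sigma_pop",
             v0 = "v0_mean")
  if (parameter %in% names(alias)) parameter <- alias[[parameter]]
  if (!parameter %in% colnames(post$draws))
    stop("parameter '", parameter, "' not in posterior; available: ",
         paste(head(colnames(post$draws), 12), collapse = ", "), ", ...")
  post$draws[, parameter]
}

#' Posterior-mean parameter vector of a condition fit
#'
#' Condition-level point estimates (posterior means of the natural-scale
#' group parameters), e.g. for predicting a held-out participant.
#'
#' @param post A `tl_posterior`.
#' @param lexicon The `trait_lexicon` used in fitting.
#' @return A `param_vector`.
#' @export
posterior_params <- function(post, lexicon) {
  m <- post$model
  grab <- function(nm) if (nm %in% colnames(post$draws)) mean(post$draws[, nm]) else NULL
  v0 <- if (m$v0_mode == "estimated")
    rep(grab("v0_mean"), nrow(lexicon)) else NULL
  param_vector(m, lexicon, alpha = grab("alpha_pop"), w = grab("w_pop"),
               sigma = grab("sigma_pop"), v0 = v0)
}

# --- MAP fits ------------------------------------------------------------

# Weak proper priors on the unconstrained scale, matching the hierarchical
# model's hyperpriors centred at mu = 0, tau = 1.
map_log_prior <- function(z, pnames) {
  sum(dnorm(z[seq_along(pnames)], 0, 1.5, log = TRUE))
}

#' Single-participant MAP estimate
#'
#' Bounded maximization of [sequence_loglik()] plus weak Normal(0, 1.5)
#' priors on the unconstrained parameter scales, with seeded multi-start
#' (default 5 starts) and best-of selection. A fast fallback and sampler
#' initializer where the hierarchical machinery is not identified (one
#' participant).
#'
#' @param trials One participant's trial rows.
#' @inheritParams fit_hierarchical
#' @param n_starts Number of random restarts (>= 1).
#' @param seed Seed for the restarts.
#' @return A `param_vector` with attribute `"loglik"` (the unpenalized
#'   log-likelihood at the optimum).
#' @export
fit_map_subject <- function(trials, model, lexicon, rp = NULL, sim = NULL,
                            n_starts = 5L, seed = 1L) {
  pid <- unique(trials$participant_id)
  if (length(pid) != 1L) stop("fit_map_subject expects exactly one participant")
  dat <- prepare_condition_data(trials, model, lexicon, rp, sim)
  pnames <- free_param_names(model)
  est_v0 <- model$v0_mode == "estimated"
  nt <- nrow(lexicon)
  mid <- scale_midpoint(lexicon)

  obj <- function(theta) {
    z <- theta[seq_along(pnames)]
    v0 <- if (est_v0) theta[-seq_along(pnames)] else NULL
    params <- z_to_params(z, pnames, model, lexicon, v0)
    ll <- subject_loglik(dat, pid, params)
    pen <- map_log_prior(z, pnames) +
      if (est_v0) sum(dnorm(v0, mid, 2, log = TRUE)) else 0
    -(ll + pen)
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    init <- c(rnorm(length(pnames), 0, 1),
              if (est_v0) rnorm(nt, mid, 0.5))
    fit <- tryCatch(optim(init, obj, method = "BFGS",
                          control = list(maxit = 300)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed (flat likelihood?)")
  z <- best$par[seq_along(pnames)]
  v0 <- if (est_v0) best$par[-seq_along(pnames)] else NULL
  params <- z_to_params(z, pnames, model, lexicon, v0)
  attr(params, "loglik") <- subject_loglik(dat, pid, params)
  params
}

# Pooled penalized-ML fit used per LOGO-CV training fold in fast mode: one
# shared parameter set across the training participants, sigma profiled out
# analytically (Gaussian MLE: RMS residual), light logit-scale ridge keeping
# alpha and w interior. 1-d golden-section search for alpha-only models,
# Nelder-Mead for (alpha, w), BFGS when an estimated V0 block is added.
fit_pooled <- function(trials, model, lexicon, rp = NULL, sim = NULL,
                       seed = 1L) {
  dat <- prepare_condition_data(trials, model, lexicon, rp, sim)
  est_v0 <- model$v0_mode == "estimated"
  nt <- nrow(lexicon)
  mid <- scale_midpoint(lexicon)

  sse_of <- function(alpha = NULL, w = NULL, v0 = NULL) {
    if (is.null(v0) && !est_v0) v0 <- rep(mid, nt)
    params <- param_vector(model, lexicon, alpha = alpha, w = w, sigma = 1,
                           v0 = v0)
    sse <- 0; nv <- 0
    for (pid in dat$pids) {
      seq <- dat$seqs[[pid]]
      pred <- trajectory(model, params, seq, lexicon, rp, pid, sim)
      r <- (seq$prediction - pred)[seq$valid]
      sse <- sse + sum(r^2); nv <- nv + length(r)
    }
    list(sse = sse, n = nv)
  }
  finish <- function(alpha = NULL, w = NULL, v0 = NULL) {
    s <- sse_of(alpha, w, v0)
    sigma <- sqrt(max(s$sse / max(s$n, 1), 1e-6))
    param_vector(model, lexicon, alpha = alpha, w = w, sigma = sigma,
                 v0 = if (est_v0) v0 else NULL)
  }

  has_alpha <- model$family != "no_learning"
  has_w <- has_alpha && model$reference_point != "none"
  ridge <- function(z) 0.5 * (z / 3)^2

  if (!has_alpha) return(finish())
  if (!est_v0 && !has_w) {
    opt <- optimize(function(za) sse_of(ilogit(za))$sse + ridge(za),
                    interval = c(-7, 7))
    return(finish(alpha = ilogit(opt$minimum)))
  }
  n_core <- 1L + has_w
  obj <- function(theta) {
    za <- theta[1]; zw <- if (has_w) theta[2] else NULL
    v0 <- if (est_v0) theta[-seq_len(n_core)] else NULL
    sse_of(ilogit(za), if (has_w) ilogit(zw), v0)$sse +
      ridge(za) + (if (has_w) ridge(zw) else 0) +
      (if (est_v0) 0.05 * sum((v0 - mid)^2) else 0)
  }
  set.seed(seed)
  init <- c(rnorm(n_core, 0, 0.5), if (est_v0) rep(mid, nt))
  fit <- optim(init, obj, method = if (est_v0) "BFGS" else "Nelder-Mead",
               control = list(maxit = if (est_v0) 200 else 500))
  finish(alpha = ilogit(fit$par[1]),
         w = if (has_w) ilogit(fit$par[2]),
         v0 = if (est_v0) fit$par[-seq_len(n_core)])
}

# --- intervals and contrasts --------------------------------------------

#' Shortest probability interval (SPI)
#'
#' The narrowest contiguous interval containing the requested posterior mass:
#' among all windows of `ceiling(mass * n)` consecutive sorted draws, the one
#' of minimal width. For unimodal posteriors this is the highest-density
#' interval.
#'
#' @param samples Numeric draw vector (>= 100 draws).
#' @param mass Probability mass in (0, 1); default 0.95.
#' @return Length-2 numeric `c(lo, hi)`.
#' @export
#' @examples
#' shortest_interval(rnorm(1e4), 0.95)
shortest_interval <- function(samples, mass = 0.95) {
  n <- length(samples)
  if (n < 100L) stop("need at least 100 draws for a stable interval")
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(samples)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  lo_idx <- seq_len(n - k)
  widths <- x[lo_idx + k] - x[lo_idx]
  i <- lo_idx[which.min(widths)]
  c(x[i], x[i + k])
}

#' Posterior contrast of two condition-level means
#'
#' Samples the posterior difference distribution of a group-level parameter
#' between two condition fits: elementwise differences of the draws (A minus
#' B), summarized by the posterior mean and the 95% shortest probability
#' interval. The difference is called credible when the interval excludes
#' zero.
#'
#' @param postA,postB `tl_posterior` objects with the parameter in common.
#' @param parameter Group-level parameter name (see [posterior_draws()]).
#' @param mass Interval mass (default 0.95).
#' @return A `contrast_summary` list: `mean_difference`, `interval`,
#'   `credible`, `parameter`.
#' @export
contrast_group_means <- function(postA, postB, parameter, mass = 0.95) {
  a <- posterior_draws(postA, parameter)
  b <- posterior_draws(postB, parameter)
  n <- min(length(a), length(b))
  d <- a[seq_len(n)] - b[seq_len(n)]
  int <- shortest_interval(d, mass)
  structure(list(parameter = parameter, mean_difference = mean(d),
                 interval = int, mass = mass,
                 credible = int[1] > 0 || int[2] < 0),
            class = "contrast_summary")
}

#' @export
print.contrast_summary <- function(x, ...) {
  cat(sprintf("contrast on %s: delta = %.3f, %d%% SPI = [%.3f, %.3f]%s\n",
              x$parameter, x$mean_difference, round(100 * x$mass),
              x$interval[1], x$interval[2],
              if (x$credible) " (credible)" else ""))
  invisible(x)
}

#' Export posterior draws in long format
#'
#' @param post A `tl_posterior`.
#' @param path Optional CSV path; when given, written and returned invisibly.
#' @return Long data.frame `chain, draw, parameter, value`.
#' @export
posterior_to_long <- function(post, path = NULL) {
  per_chain <- nrow(post$draws) / max(post$chain)
  long <- data.frame(
    chain = rep(post$chain, ncol(post$draws)),
    draw = rep(rep(seq_len(per_chain), max(post$chain)), ncol(post$draws)),
    parameter = rep(colnames(post$draws), each = nrow(post$draws)),
    value = as.vector(post$draws),
    stringsAsFactors = FALSE)
  if (!is.null(path)) { write.csv(long, path, row.names = FALSE); return(invisible(long)) }
  long
}
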