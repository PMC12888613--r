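test_that("shortest probability interval matches normal quantiles and beats equal tails", {
  set.seed(1)
  x <- rnorm(1e5)
  si <- shortest_interval(x, 0.95)
  expect_lt(abs(si[1] - (-1.96)), 0.05)
  expect_lt(abs(si[2] - 1.96), 0.05)
  expect_equal(shortest_interval(rep(3.2, 200), 0.95), c(3.2, 3.2))
  # skewed draws: SPI is narrower than the equal-tailed interval
  e <- rexp(5e4)
  spi <- shortest_interval(e, 0.95)
  eti <- quantile(e, c(0.025, 0.975), names = FALSE)
  expect_lt(diff(spi), diff(eti))
  expect_error(shortest_interval(rnorm(50)), "at least 100")
})

test_that("single-subject MAP recovers generating parameters on low-noise data", {
  lex <- build_default_lexicon()
  hp <- default_hyperparams(alpha_mu = 0.5, sigma_mu = 0.2)
  hp <- lapply(hp, function(h) { h$alpha_tau <- 1e-6; h$sigma_tau <- 1e-6; h })
  st <- simulate_default_study(seed = 31, n_bpd = 1, n_con = 1,
                               hyperparams = hp, lexicon = lex)
  m <- get_model("fine_noRP")
  t1 <- st$trials[st$trials$participant_id == "BPD_01", ]
  truth <- attr(st$trials, "ground_truth")[["BPD_01"]]$true_params
  fit <- fit_map_subject(t1, m, st$lexicon, st$rp, st$sim, seed = 4)
  expect_lt(abs(fit$alpha - truth$alpha), 0.1)
  expect_true(fit$alpha >= 0 && fit$alpha <= 1 && fit$sigma > 0)
  expect_gte(attr(fit, "loglik"),
             sequence_loglik(m, truth, t1, st$lexicon, st$rp, st$sim))
  expect_error(fit_map_subject(st$trials, m, st$lexicon, st$rp, st$sim),
               "one participant")
})

test_that("hierarchical fits are seed-deterministic and refuse single participants", {
  st <- tiny_study(seed = 3, n_bpd = 3, n_con = 3)
  cond <- split_conditions(st$trials)[["BPD_on_BPD"]]
  m <- get_model("coarse_noRP")
  cfg <- mcmc_config(warmup_draws = 100, sampling_draws = 100, seed = 5)
  p1 <- suppressWarnings(fit_hierarchical(cond, m, st$lexicon, st$rp, st$sim, cfg))
  p2 <- suppressWarnings(fit_hierarchical(cond, m, st$lexicon, st$rp, st$sim, cfg))
  expect_identical(p1$draws, p2$draws)
  one <- cond[cond$participant_id == cond$participant_id[1], ]
  expect_error(fit_hierarchical(one, m, st$lexicon, st$rp, st$sim, cfg),
               "single participant")
  expect_setequal(p1$diagnostics$parameter,
                  c("mu_alpha", "mu_sigma", "tau_alpha", "tau_sigma",
                    "alpha_pop", "sigma_pop"))
})

test_that("with no informative trials the posterior returns the prior", {
  st <- tiny_study(seed = 9, n_bpd = 2, n_con = 2)
  cond <- split_conditions(st$trials)[["BPD_on_BPD"]]
  cond$valid <- FALSE           # likelihood contributes nothing
  m <- get_model("coarse_noRP")
  cfg <- mcmc_config(warmup_draws = 400, sampling_draws = 1500, seed = 11)
  post <- suppressWarnings(fit_hierarchical(cond, m, st$lexicon, st$rp,
                                            st$sim, cfg))
  mu <- posterior_draws(post, "mu_alpha")
  # prior: mu ~ N(0, 1)
  expect_lt(abs(mean(mu)), 0.15)
  expect_lt(abs(sd(mu) - 1), 0.2)
})

test_that("no-learning data do not break the sampler and sigma is recovered", {
  lex <- tiny_lexicon()
  hp <- default_hyperparams(sigma_mu = 0.7)
  st <- tiny_study(seed = 13, n_bpd = 4, n_con = 4,
                   generating_model = "nolearn_self", lexicon = lex,
                   hyperparams = hp)
  cond <- split_conditions(st$trials)[["BPD_on_BPD"]]
  m <- get_model("nolearn_self")
  cfg <- mcmc_config(warmup_draws = 300, sampling_draws = 300, seed = 17)
  post <- suppressWarnings(fit_hierarchical(cond, m, st$lexicon, st$rp,
                                            st$sim, cfg))
  s_draws <- posterior_draws(post, "sigma")
  si <- shortest_interval(s_draws, 0.95)
  # generating sigma median 0.7; discretized responses inflate it somewhat
  expect_true(si[1] < 1.1 && si[2] > 0.4)
})

test_that("posterior contrasts behave like paired difference distributions", {
  st <- tiny_study(seed = 19, n_bpd = 3, n_con = 3)
  conds <- split_conditions(st$trials)
  m <- get_model("coarse_noRP")
  cfg <- mcmc_config(warmup_draws = 150, sampling_draws = 200, seed = 23)
  pa <- suppressWarnings(fit_hierarchical(conds[[1]], m, st$lexicon, st$rp,
                                          st$sim, cfg))
  pb <- suppressWarnings(fit_hierarchical(conds[[4]], m, st$lexicon, st$rp,
                                          st$sim, cfg))
  same <- contrast_group_means(pa, pa, "alpha")
  expect_false(same$credible)
  expect_true(same$interval[1] <= 0 && same$interval[2] >= 0)
  ab <- contrast_group_means(pa, pb, "alpha")
  ba <- contrast_group_means(pb, pa, "alpha")
  expect_equal(ab$mean_difference, -ba$mean_difference)
  # location shift: fabricate a shifted copy
  pshift <- pa
  pshift$draws[, "alpha_pop"] <- pa$draws[, "alpha_pop"] + 0.4
  sh <- contrast_group_means(pa, pshift, "alpha")
  expect_equal(sh$mean_difference, -0.4, tolerance = 1e-12)
  expect_error(contrast_group_means(pa, pb, "w"), "not in posterior")
})

test_that("posterior draws export to long format with chain and draw indices", {
  st <- tiny_study(seed = 29, n_bpd = 2, n_con = 2)
  cond <- split_conditions(st$trials)[[1]]
  m <- get_model("nolearn_pop")
  post <- suppressWarnings(fit_hierarchical(cond, m, st$lexicon, st$rp, st$sim,
    mcmc_config(warmup_draws = 50, sampling_draws = 60, seed = 31)))
  long <- posterior_to_long(post)
  expect_setequal(names(long), c("chain", "draw", "parameter", "value"))
  expect_equal(nrow(long), nrow(post$draws) * ncol(post$draws))
  expect_equal(max(long$draw), 60)
  f <- tempfile(fileext = ".csv")
  posterior_to_long(post, f)
  expect_true(file.exists(f))
})
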