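test_that("LOGO-CV produces one score per participant", {
  st <- tiny_study(seed = 41, n_bpd = 2, n_con = 2)
  m <- get_model("coarse_noRP")
  sc <- logo_cv(st$trials, m, st$lexicon, st$rp, st$sim, seed = 1)
  expect_equal(nrow(sc), 4L)
  expect_setequal(sc$participant_id, unique(st$trials$participant_id))
  expect_true(all(sc$mse >= 0))
  expect_equal(attr(sc, "overall_mse"), mean(sc$mse))
  expect_error(logo_cv(st$trials[st$trials$participant_id %in%
                                   c("BPD_01", "BPD_02"), ],
                       m, st$lexicon, st$rp, st$sim), "at least 3")
})

test_that("no-learning LOGO-CV scores equal their direct closed form", {
  st <- tiny_study(seed = 43, n_bpd = 3, n_con = 3)
  m <- get_model("nolearn_pop")
  sc <- logo_cv(st$trials, m, st$lexicon, st$rp, st$sim, seed = 1)
  lex <- st$lexicon
  # oracle: deviations of each held-out participant's reverse-coded
  # predictions from the fixed population reference (no fitting involved)
  for (i in seq_len(nrow(sc))) {
    t <- st$trials[st$trials$participant_id == sc$participant_id[i], ]
    idx <- match(t$trait_id, lex$trait_id)
    neg <- lex$valence[idx] == "negative"
    obs <- ifelse(neg, 9 - t$prediction, t$prediction)
    expected <- mean((obs - st$rp$population[idx])^2)
    expect_equal(sc$mse[i], expected, tolerance = 1e-10)
  }
})

test_that("the naive baseline matches direct arithmetic and ignores row order", {
  st <- tiny_study(seed = 47, n_bpd = 3, n_con = 3)
  lex <- st$lexicon
  nb <- naive_baseline(st$trials, lex)
  idx <- match(st$trials$trait_id, lex$trait_id)
  neg <- lex$valence[idx] == "negative"
  obs <- ifelse(neg, 9 - st$trials$prediction, st$trials$prediction)
  pid <- st$trials$participant_id
  for (i in seq_len(nrow(nb))) {
    held <- nb$participant_id[i]
    expected <- mean((obs[pid == held] - mean(obs[pid != held]))^2)
    expect_equal(nb$mse[i], expected, tolerance = 1e-12)
  }
  # permutation invariance of the trial rows
  perm <- st$trials[sample(nrow(st$trials)), ]
  nb2 <- naive_baseline(perm, lex)
  nb2 <- nb2[match(nb$participant_id, nb2$participant_id), ]
  expect_equal(nb2$mse, nb$mse)
  # constant training ratings: every squared error is (rating - c)^2
  const <- st$trials
  const$prediction <- 5
  pos_only <- const[lex$valence[match(const$trait_id, lex$trait_id)] ==
                      "positive", ]
  nbc <- naive_baseline(pos_only, lex)
  expect_true(all(nbc$mse == 0))
})

test_that("the paired 2xSE rule flags credible score differences", {
  a <- data.frame(model_id = "A", participant_id = sprintf("P%02d", 1:10),
                  mse = c(1.2, 0.9, 1.1, 1.4, 1.0, 1.3, 0.8, 1.2, 1.1, 1.0))
  b <- a; b$model_id <- "B"
  expect_equal(compare_models(a, b)$delta_mse, 0)
  expect_false(compare_models(a, b)$credible)
  # SE matches the brute-force formula
  set.seed(5)
  b$mse <- a$mse + rnorm(10, 0.2, 0.1)
  cmp <- compare_models(a, b)
  d <- a$mse - b$mse
  expect_equal(cmp$se, sd(d) / sqrt(10), tolerance = 1e-12)
  expect_equal(cmp$delta_mse, mean(d), tolerance = 1e-12)
  # rule boundary: construct differences with |delta| just above/below 2 SE
  base <- scale(rnorm(12))[, 1]          # mean 0, sd 1
  for (fac in c(2.001, 1.999)) {
    d <- base + fac / sqrt(12)           # mean = fac * se since sd = 1
    a2 <- data.frame(model_id = "A", participant_id = sprintf("P%02d", 1:12),
                     mse = 2 + d)
    b2 <- data.frame(model_id = "B", participant_id = sprintf("P%02d", 1:12),
                     mse = 2)
    expect_equal(compare_models(a2, b2)$credible, fac > 2)
  }
  # antisymmetry
  expect_equal(compare_models(a, b)$delta_mse, -compare_models(b, a)$delta_mse)
  bad <- b; bad$participant_id[1] <- "P99"
  expect_error(compare_models(a, bad), "same participants")
})

test_that("model ranking sorts by MSE with parameter-count tie-breaks and a best set", {
  pids <- sprintf("P%02d", 1:8)
  mk <- function(id, scores) data.frame(model_id = id, participant_id = pids,
                                        mse = scores)
  set.seed(7)
  noise <- rnorm(8, 0, 0.05)
  # fine_selfRP trails by 0.2 with fold-level scatter well above 2xSE of the
  # paired differences; nolearn_pop trails by 1.0 with tight scatter
  tab <- rbind(mk("fine_noRP", 1.0 + noise),
               mk("fine_selfRP", 1.0 + noise + 0.2 + scale(rnorm(8))[, 1] * 0.6),
               mk("nolearn_pop", 2.0 + rnorm(8, 0, 0.05)))
  rk <- rank_models(tab)
  expect_equal(rk$model_id[1], "fine_noRP")
  expect_true(rk$in_best_set[rk$model_id == "fine_selfRP"])
  expect_false(rk$in_best_set[rk$model_id == "nolearn_pop"])
  # exact tie: fewer free parameters first
  tie <- rbind(mk("fine_selfRP", rep(1, 8)), mk("fine_noRP", rep(1, 8)))
  expect_equal(rank_models(tie)$model_id[1], "fine_noRP")
  # input order does not matter
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(rank_models(shuffled)$model_id, rk$model_id)
  bad <- rbind(mk("fine_noRP", 1:8),
               mk("coarse_noRP", 1:8)[-1, ])
  expect_error(rank_models(bad), "participant coverage")
})

test_that("learning models beat the naive baseline on learnable synthetic data", {
  wins <- 0L
  for (seed in 1:5) {
    st <- tiny_study(seed = 600 + seed, n_bpd = 3, n_con = 3,
                     hyperparams = default_hyperparams(sigma_mu = 0.7))
    m <- get_model("fine_noRP")
    sc <- logo_cv(st$trials, m, st$lexicon, st$rp, st$sim, seed = seed)
    nb <- naive_baseline(st$trials, st$lexicon)
    wins <- wins + (attr(sc, "overall_mse") < attr(nb, "overall_mse"))
  }
  expect_gte(wins, 4L)
})

test_that("accuracy-mode folds and estimated-V0 models cross-validate", {
  lex <- tiny_lexicon()
  st <- tiny_study(seed = 59, n_bpd = 2, n_con = 2, lexicon = lex)
  m <- get_model("coarse_noRP")
  acc <- suppressWarnings(   # short chains flag their ESS, by design
    logo_cv(st$trials, m, st$lexicon, st$rp, st$sim, mode = "accuracy",
            config = mcmc_config(warmup_draws = 80, sampling_draws = 80,
                                 seed = 3)))
  expect_equal(nrow(acc), 4L)
  expect_true(all(is.finite(acc$mse)))
  # fast mode with a free V0 block (BFGS over alpha + per-trait V0)
  sc <- logo_cv(st$trials, get_model("coarse_noRP_v0"), st$lexicon, st$rp,
                st$sim, seed = 5)
  expect_true(all(is.finite(sc$mse)))
  # estimating V0 can only help a model whose true V0 is the midpoint a
  # little; sanity bound against the fixed-V0 variant
  sc0 <- logo_cv(st$trials, m, st$lexicon, st$rp, st$sim, seed = 5)
  expect_lt(abs(attr(sc, "overall_mse") - attr(sc0, "overall_mse")), 0.5)
})
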