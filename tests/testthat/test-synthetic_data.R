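test_that("profile generation is deterministic and respects the typicality screen", {
  lex <- build_default_lexicon()
  cp <- default_class_params(lex)
  p1 <- generate_profiles(cp, lex, seed = 5)
  p2 <- generate_profiles(cp, lex, seed = 5)
  expect_identical(p1, p2)
  expect_length(p1, 6L)
  for (p in p1) {
    expect_true(all(p$true_ratings %in% 1:8))
    v <- validate_profile(p, cp[[p$profile_class]])
    expect_true(v$pass)
    expect_lte(v$deviations, 6L)
  }
})

test_that("control-like profiles are more favorable than BPD-like across seeds", {
  lex <- build_default_lexicon()
  cp <- default_class_params(lex)
  neg <- lex$valence == "negative"
  fav_mean <- function(p) mean(ifelse(neg, 9 - p$true_ratings, p$true_ratings))
  diffs <- vapply(1:100, function(s) {
    ps <- generate_profiles(cp, lex, n_per_class = 1L, seed = 1000 + s)
    fav_mean(ps[["CON_1"]]) - fav_mean(ps[["BPD_1"]])
  }, 0)
  expect_gt(mean(diffs > 0), 0.95)
})

test_that("the typicality screen passes at six deviations and fails at seven", {
  lex <- tiny_lexicon()
  ref <- data.frame(trait_id = lex$trait_id, mean = rep(4, nrow(lex)),
                    sd = rep(1, nrow(lex)))
  exact <- structure(list(true_ratings = rep(4, nrow(lex))),
                     class = "profile_spec")
  expect_equal(validate_profile(exact, ref)$deviations, 0L)
  expect_true(validate_profile(exact, ref)$pass)
  dev6 <- exact; dev6$true_ratings[1:6] <- 7
  expect_true(validate_profile(dev6, ref)$pass)
  dev7 <- exact; dev7$true_ratings[1:7] <- 7
  expect_false(validate_profile(dev7, ref)$pass)
})

test_that("cohorts default to the study sizes with parameters inside their support", {
  lex <- build_default_lexicon()
  design <- study_design(seed = 2)
  cohort <- generate_cohort(design, lex, "fine_selfRP")
  groups <- table(vapply(cohort, `[[`, "", "group"))
  expect_equal(unname(groups[c("BPD_like", "CON_like")]), c(30L, 31L),
               ignore_attr = TRUE)
  for (p in cohort) {
    expect_true(p$true_params$alpha >= 0 && p$true_params$alpha <= 1)
    expect_true(p$true_params$w >= 0 && p$true_params$w <= 1)
    expect_gt(p$true_params$sigma, 0)
    expect_true(all(p$self_ratings %in% 1:8))
  }
  cohort2 <- generate_cohort(design, lex, "fine_selfRP")
  expect_identical(cohort, cohort2)
})

test_that("the simulated task reproduces the block structure of the study", {
  st <- tiny_study(seed = 51, n_bpd = 2, n_con = 2,
                   lexicon = build_default_lexicon())
  trials <- st$trials
  per <- table(trials$participant_id)
  expect_true(all(per == 240L))
  one <- trials[trials$participant_id == "BPD_01", ]
  blocks <- one$profile_class[!duplicated(one$profile_id)]
  expect_equal(blocks, c("CON_like", "BPD_like", "CON_like",
                         "BPD_like", "BPD_like", "CON_like"))
  # each trait exactly once per block
  for (prof in unique(one$profile_id)) {
    expect_setequal(one$trait_id[one$profile_id == prof], st$lexicon$trait_id)
  }
  expect_true(all(trials$prediction %in% 1:8))
  expect_true(all(trials$feedback %in% 1:8))
  expect_true(all(one$trial_index %in% 1:40))
})

test_that("noiseless self-reference agents reproduce their own self-ratings", {
  lex <- tiny_lexicon()
  hp <- default_hyperparams()
  hp <- lapply(hp, function(h) { h$sigma_mu <- 1e-6; h$sigma_tau <- 1e-9
                                 h$w_mu <- 1 - 1e-12; h$w_tau <- 1e-9; h })
  st <- tiny_study(seed = 53, n_bpd = 2, n_con = 2,
                   generating_model = "nolearn_self", lexicon = lex,
                   hyperparams = hp)
  gt <- attr(st$trials, "ground_truth")
  for (pid in names(gt)) {
    t <- st$trials[st$trials$participant_id == pid, ]
    self <- gt[[pid]]$self_ratings[match(t$trait_id, lex$trait_id)]
    expect_equal(t$prediction, self)
  }
})

test_that("optional item exclusions invalidate at most two traits per participant", {
  st <- tiny_study(seed = 57, n_bpd = 3, n_con = 3, exclusions = TRUE)
  t <- st$trials
  for (pid in unique(t$participant_id)) {
    bad <- unique(t$trait_id[t$participant_id == pid & !t$valid])
    expect_lte(length(bad), 2L)
  }
  expect_true(any(!t$valid))   # across 6 participants some exclusion occurs
})

test_that("simulation honours the seed and varies across seeds", {
  a <- tiny_study(seed = 61, n_bpd = 2, n_con = 2)
  b <- tiny_study(seed = 61, n_bpd = 2, n_con = 2)
  c <- tiny_study(seed = 62, n_bpd = 2, n_con = 2)
  expect_identical(a$trials, b$trials)
  expect_false(identical(a$trials$prediction, c$trials$prediction))
})

test_that("cohort self-ratings embed the group favorability gap", {
  lex <- build_default_lexicon()
  design <- study_design(seed = 8)
  cohort <- generate_cohort(design, lex)
  neg <- lex$valence == "negative"
  fav <- vapply(cohort, function(p)
    mean(ifelse(neg, 9 - p$self_ratings, p$self_ratings)), 0)
  grp <- vapply(cohort, `[[`, "", "group")
  gap <- mean(fav[grp == "CON_like"]) - mean(fav[grp == "BPD_like"])
  expect_gt(gap, 0.4)
  expect_lt(gap, 1.2)
})
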