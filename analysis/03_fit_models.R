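#!/usr/bin/env Rscript
# Stage 3: hierarchical Bayesian fits of the winning model (fine granularity
# without reference points, with estimated initial expectations V0) in each
# of the four conditions, posterior export, and the condition contrasts on
# learning rate and average V0 -- including the control-on-control versus
# BPD-on-control V0 contrast. Requires stage 1. Runtime: a few minutes.

suppressPackageStartupMessages(library(traitlearn))

seed <- 20260926L
out <- "results/fits"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

trials <- read_trials("results/study/trials.csv")
lex <- read_lexicon("results/study/lexicon.csv")
sim <- read_similarity("results/study/similarity.csv", lex)
# reference points rebuilt from the simulated study inputs
st <- simulate_default_study(seed = 20260926L)
rp <- st$rp

model <- get_model("fine_noRP_v0")
cfg <- mcmc_config(chains = 2, warmup_draws = 600, sampling_draws = 600,
                   seed = seed)

posts <- list()
for (cn in names(split_conditions(trials))) {
  ct <- split_conditions(trials)[[cn]]
  cat("Fitting", model$model_id, "to", cn, "(",
      length(unique(ct$participant_id)), "participants )...\n")
  posts[[cn]] <- fit_hierarchical(ct, model, lex, rp, sim, cfg)
  posterior_to_long(posts[[cn]], file.path(out, paste0("posterior_", cn, ".csv")))
  cat(sprintf("  alpha_pop = %.3f, v0_mean = %.3f, max rhat = %.3f\n",
              mean(posterior_draws(posts[[cn]], "alpha")),
              mean(posterior_draws(posts[[cn]], "v0_mean")),
              max(posts[[cn]]$diagnostics$rhat, na.rm = TRUE)))
}

cat("\nCondition contrasts (95% shortest probability intervals):\n")
contrasts <- list(
  v0_CONonCON_vs_BPDonCON =
    contrast_group_means(posts$CON_on_CON, posts$BPD_on_CON, "v0_mean"),
  alpha_CONonCON_vs_BPDonCON =
    contrast_group_means(posts$CON_on_CON, posts$BPD_on_CON, "alpha"),
  alpha_CONonBPD_vs_BPDonBPD =
    contrast_group_means(posts$CON_on_BPD, posts$BPD_on_BPD, "alpha"))
for (nm in names(contrasts)) { cat(nm, ": "); print(contrasts[[nm]]) }

ctab <- do.call(rbind, lapply(names(contrasts), function(nm) {
  ct <- contrasts[[nm]]
  data.frame(contrast = nm, parameter = ct$parameter,
             delta = ct$mean_difference,
             spi_lo = ct$interval[1], spi_hi = ct$interval[2],
             credible = ct$credible)
}))
write.csv(ctab, file.path(out, "contrasts.csv"), row.names = FALSE)
cat("\nWrote posteriors and contrasts to", out, "\n")
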