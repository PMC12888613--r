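#!/usr/bin/env Rscript
# Stage 4: leave-one-participant-out cross-validation of all eight models
# plus the naive mean-prediction baseline in every condition, the 2xSE
# comparison rule, and per-condition rankings with best-equivalence sets.
# Requires stage 1. Fast mode (pooled penalized-ML per fold).

suppressPackageStartupMessages(library(traitlearn))

seed <- 20260926L
out <- "results"
trials <- read_trials("results/study/trials.csv")
lex <- read_lexicon("results/study/lexicon.csv")
sim <- read_similarity("results/study/similarity.csv", lex)
st <- simulate_default_study(seed = 20260926L)   # rebuild reference points
rp <- st$rp

conds <- split_conditions(trials)
all_scores <- list()
for (cn in names(conds)) {
  cat("Scoring", cn, "...\n")
  scores <- do.call(rbind, lapply(enumerate_models(), function(m)
    logo_cv(conds[[cn]], m, lex, rp, sim, seed = seed)))
  scores <- rbind(scores, naive_baseline(conds[[cn]], lex))
  rk <- rank_models(scores)
  cat("  ranking:\n")
  print(rk[, c("model_id", "overall_mse", "delta_to_best", "in_best_set")],
        row.names = FALSE, digits = 4)
  write.csv(rk, file.path(out, paste0("ranking_", cn, ".csv")),
            row.names = FALSE)
  all_scores[[cn]] <- cbind(condition = cn, scores)
}
write.csv(do.call(rbind, all_scores), file.path(out, "logocv_scores.csv"),
          row.names = FALSE)

# Fig-6-style barplot of MSE differences to the best model per condition
if (requireNamespace("ggplot2", quietly = TRUE)) {
  rks <- do.call(rbind, lapply(names(conds), function(cn)
    cbind(condition = cn,
          read.csv(file.path(out, paste0("ranking_", cn, ".csv"))))))
  naive <- rks[rks$model_id == "naive_mean", ]
  gg <- ggplot2::ggplot(rks[rks$model_id != "naive_mean", ], ggplot2::aes(
    x = reorder(model_id, delta_to_best), y = delta_to_best)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(data = naive,
                        ggplot2::aes(yintercept = delta_to_best),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~condition) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "MSE difference to best model") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(file.path(out, "model_comparison.pdf"), gg,
                  width = 9, height = 6)
  cat("Wrote", file.path(out, "model_comparison.pdf"), "\n")
}
cat("Done.\n")
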