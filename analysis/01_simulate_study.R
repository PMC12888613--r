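#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study at the deposited study's scale --
# 30 BPD-like and 31 control-like participants, six screened learning
# profiles (CON, BPD, CON, BPD, BPD, CON), 240 trials each -- with known
# ground-truth parameters, and write all task tables to results/study/.

suppressPackageStartupMessages(library(traitlearn))

seed <- 20260926L
out <- "results/study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

st <- simulate_default_study(seed = seed)

write_trials(st$trials, file.path(out, "trials.csv"))
write_lexicon(st$lexicon, file.path(out, "lexicon.csv"))
write_similarity(st$sim, file.path(out, "similarity.csv"))

cohort <- do.call(rbind, lapply(attr(st$trials, "ground_truth"), function(p)
  data.frame(participant_id = p$participant_id, group = p$group,
             generating_model = p$generating_model$model_id,
             alpha = p$true_params$alpha, sigma = p$true_params$sigma,
             self_mean = mean(p$self_ratings))))
write.csv(cohort, file.path(out, "cohort_truth.csv"), row.names = FALSE)

profiles <- do.call(rbind, lapply(st$profiles, function(p)
  data.frame(profile_id = p$profile_id, profile_class = p$profile_class,
             t(p$true_ratings))))
write.csv(profiles, file.path(out, "profiles.csv"), row.names = FALSE)

jsonlite::write_json(list(seed = seed,
                          n_participants = length(unique(st$trials$participant_id)),
                          n_trials = nrow(st$trials),
                          generating_model = "fine_noRP"),
                     file.path(out, "manifest.json"), auto_unbox = TRUE)

cat("Simulated study:", length(unique(st$trials$participant_id)),
    "participants,", nrow(st$trials), "trials ->", out, "\n")
cat("Profile order:",
    paste(st$trials$profile_class[!duplicated(st$trials$profile_id)],
          collapse = ", "), "\n")
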