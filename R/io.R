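trial_columns <- c("participant_id", "group", "profile_id", "profile_class",
                   "trial_index", "trait_id", "prediction", "feedback", "valid")

#' Read a trial table
#'
#' Reads a long-format CSV/TSV of task trials (one row per participant x
#' profile x trial), validates types and ranges, and rejects malformed rows
#' with their line numbers. A column-name mapping handles externally
#' deposited files with different headers. Rows flagged `valid = FALSE` are
#' kept (they are excluded downstream from likelihoods and PE analyses, not
#' at read time).
#'
#' @param path CSV (or TSV) file with columns `participant_id`, `group`,
#'   `profile_id`, `profile_class`, `trial_index`, `trait_id`, `prediction`,
#'   `feedback`, `valid`.
#' @param scale_min,scale_max Rating bounds for validation.
#' @param col_map Optional named character vector mapping file column names
#'   to the required names, e.g. `c(subject = "participant_id")`.
#' @return A validated trial data.frame.
#' @export
read_trials <- function(path, scale_min = 1L, scale_max = 8L, col_map = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- read.csv(path, sep = sep, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    hit <- match(names(col_map), names(df))
    names(df)[hit[!is.na(hit)]] <- col_map[!is.na(hit)]
  }
  missing <- setdiff(trial_columns, names(df))
  if (length(missing))
    stop("trial file is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, trial_columns]
  df$valid <- as.logical(df$valid)
  line_no <- seq_len(nrow(df)) + 1L   # header is line 1
  bad_range <- which(df$prediction < scale_min | df$prediction > scale_max |
                       df$feedback < scale_min | df$feedback > scale_max)
  if (length(bad_range))
    stop("rating outside [", scale_min, ", ", scale_max, "] at line(s): ",
         paste(head(line_no[bad_range], 10), collapse = ", "))
  key <- paste(df$participant_id, df$profile_id, df$trait_id)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (participant, profile, trait) at line(s): ",
         paste(head(line_no[dup], 10), collapse = ", "))
  if (any(df$trial_index < 1L))
    stop("trial_index must be 1-based positive")
  df
}

#' Write a trial table
#' @param trials Trial data.frame.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  write.csv(as.data.frame(trials)[, trial_columns], path, row.names = FALSE)
  invisible(path)
}

#' Split a trial table into the four study conditions
#'
#' @param trials Trial table.
#' @return Named list of trial tables, one per participant group x profile
#'   type, each carrying a `condition` attribute.
#' @export
split_conditions <- function(trials) {
  cells <- expand.grid(group = sort(unique(trials$group)),
                       profile_class = sort(unique(trials$profile_class)),
                       stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    t <- trials[trials$group == cells$group[i] &
                  trials$profile_class == cells$profile_class[i], ,
                drop = FALSE]
    attr(t, "condition") <- c(group = cells$group[i],
                              profile_class = cells$profile_class[i])
    t
  })
  names(out) <- paste(sub("_like", "", cells$group), "on",
                      sub("_like", "", cells$profile_class), sep = "_")
  out
}

# Tiny stable content hash (FNV-1a over the serialized object) so output
# files can carry a config fingerprint without external digest packages.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Chains the stages of the study analysis on one trial table (or a freshly
#' simulated one): behavioral summaries, LOGO-CV scoring of the requested
#' models per condition, model ranking, and a JSON manifest recording seeds,
#' configuration hash and package version. Any unknown model id fails before
#' computation starts; a failing stage aborts with a stage-labeled error and
#' leaves partial outputs beside a `FAILED` marker file.
#'
#' @param config List with elements: `seed` (integer), `out_dir` (path),
#'   `model_ids` (character; default all 8 base models), `mode`
#'   (`"fast"`/`"accuracy"`), optional `trials_path` (CSV to load; when
#'   absent a synthetic study is simulated), optional `n_bpd`, `n_con`,
#'   `conditions` (names to keep, default all four), `mcmc` (list passed to
#'   [mcmc_config()]), `n_boot` for trends.
#' @return Invisibly, a list with `scores` (stacked score table), `rankings`
#'   (per condition), `summary`, `trends`, and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config[["out_dir"]]))
  seed <- if (is.null(config[["seed"]])) 1L else as.integer(config[["seed"]])
  mode <- if (is.null(config[["mode"]])) "fast" else config[["mode"]]
  model_ids <- if (is.null(config[["model_ids"]])) names(enumerate_models())
               else config[["model_ids"]]
  models <- lapply(model_ids, get_model)   # validation-first: unknown id stops here
  dir.create(config[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config[["out_dir"]], "FAILED")
  if (file.exists(marker)) file.remove(marker)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)), marker)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  lexicon <- build_default_lexicon()
  study <- stage("simulate", {
    if (!is.null(config[["trials_path"]])) {
      trials <- read_trials(config[["trials_path"]], col_map = config[["col_map"]])
      ref <- synthetic_reference(lexicon, seed = substream_seed(seed, 2))
      self_mat <- do.call(rbind, lapply(split(trials, trials$participant_id),
        function(t) {
          # self-ratings unavailable in a bare trial file: fall back to the
          # participant's mean rating per trait across profiles
          vapply(lexicon$trait_id, function(id)
            round(mean(t$prediction[t$trait_id == id])), 0)
        }))
      rp <- build_reference_points(lexicon, ref$population, self_mat)
      list(trials = trials, lexicon = lexicon, sim = ref$similarity, rp = rp)
    } else {
      simulate_default_study(seed = seed,
                             n_bpd = if (is.null(config[["n_bpd"]])) 30L else config[["n_bpd"]],
                             n_con = if (is.null(config[["n_con"]])) 31L else config[["n_con"]],
                             lexicon = lexicon)
    }
  })

  summary_df <- stage("stats", condition_summary(study$trials, study$lexicon))
  trends <- stage("stats", pe_trend(study$trials, study$lexicon,
                                    n_boot = if (is.null(config[["n_boot"]])) 500L
                                             else config[["n_boot"]],
                                    seed = seed))
  write.csv(summary_df, file.path(config[["out_dir"]], "condition_summary.csv"),
            row.names = FALSE)
  write.csv(trends, file.path(config[["out_dir"]], "pe_trends.csv"),
            row.names = FALSE)

  conditions <- split_conditions(study$trials)
  if (!is.null(config[["conditions"]]))
    conditions <- conditions[config[["conditions"]]]

  scores <- stage("logocv", {
    do.call(rbind, lapply(names(conditions), function(cn) {
      ct <- conditions[[cn]]
      rows <- do.call(rbind, lapply(models, function(m)
        logo_cv(ct, m, study$lexicon, study$rp, study$sim, mode = mode,
                config = do.call(mcmc_config,
                                 c(list(seed = seed), config[["mcmc"]])),
                seed = seed)))
      base <- naive_baseline(ct, study$lexicon)
      cbind(condition = cn, rbind(rows, base))
    }))
  })
  write.csv(scores, file.path(config[["out_dir"]], "logocv_scores.csv"),
            row.names = FALSE)

  rankings <- stage("compare", lapply(split(scores, scores$condition),
                                      function(s) rank_models(s)))
  for (cn in names(rankings))
    write.csv(rankings[[cn]],
              file.path(config[["out_dir"]], paste0("ranking_", cn, ".csv")),
              row.names = FALSE)

  manifest <- list(package_version = as.character(utils::packageVersion("traitlearn")),
                   seed = seed, mode = mode, model_ids = model_ids,
                   conditions = names(conditions),
                   config_hash = config_hash(config),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(config[["out_dir"]], "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(scores = scores, rankings = rankings, summary = summary_df,
                 trends = trends, manifest = manifest))
}
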