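#' Full pipeline configuration
#'
#' One object drives every stage; all seeds are derived from `seed` so a
#' config reproduces the whole run bit for bit.
#'
#' @param seed master seed.
#' @param cohort a [cohort_config]; its own seed is overridden by `seed`.
#' @param profiles list of four [state_profile]s.
#' @param segmentation a [segmentation_params].
#' @param sampen a [sampen_params].
#' @param wpd a [wpd_params] or `NULL` to derive from the cohort rate.
#' @param split a [split_spec]; its seed is derived from `seed`.
#' @param preprocess list with `low_hz`, `high_hz`, `amp_threshold_uV`,
#'   `pad_s`.
#' @param svm list with `C` and `gamma` (`NULL` = heuristic width).
#' @param selection list with `method` (`"sfs"`, `"chi2"`, `"mutual_info"`
#'   or `"embedded"`) and method parameters (`k`, `threshold`, `lambda`).
#' @param write_edf whether [run_pipeline()] persists the cohort as EDF.
#' @return object of class `attn_config`.
#' @export
attn_config <- function(seed = 1L,
                        cohort = cohort_config(),
                        profiles = default_state_profiles(),
                        segmentation = segmentation_params(),
                        sampen = sampen_params(),
                        wpd = NULL,
                        split = split_spec(),
                        preprocess = list(low_hz = 0.5, high_hz = 30,
                                          amp_threshold_uV = 100, pad_s = 0.5),
                        svm = list(C = 1, gamma = NULL),
                        selection = list(method = "sfs", threshold = 0.5,
                                         lambda = 0.01),
                        write_edf = TRUE) {
  cohort$seed <- as.integer(seed)
  split$seed <- derive_seed(seed, 2)
  if (is.null(wpd)) wpd <- wpd_params(cohort$fs)
  structure(list(seed = as.integer(seed), cohort = cohort, profiles = profiles,
                 segmentation = segmentation, sampen = sampen, wpd = wpd,
                 split = split, preprocess = preprocess, svm = svm,
                 selection = selection, write_edf = write_edf),
            class = "attn_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [attn_config()]; missing keys keep their
#' defaults. State profiles may be overridden with a `profiles` list of
#' `band_fractions`, `noise_mix`, `amplitude_uV` per state.
#'
#' @param path YAML file.
#' @return an `attn_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_config, y$cohort %||% list())
  profiles <- if (is.null(y$profiles)) default_state_profiles() else {
    lapply(seq_along(y$profiles), function(i) {
      p <- y$profiles[[i]]
      state_profile(p$state_id %||% i, unlist(p$band_fractions),
                    p$noise_mix, p$amplitude_uV)
    })
  }
  args <- list(seed = y$seed %||% 1L, cohort = cohort, profiles = profiles)
  if (!is.null(y$segmentation)) args$segmentation <- do.call(segmentation_params, y$segmentation)
  if (!is.null(y$sampen)) args$sampen <- do.call(sampen_params, y$sampen)
  if (!is.null(y$split)) args$split <- do.call(split_spec, y$split)
  for (k in c("preprocess", "svm", "selection", "write_edf")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(attn_config, args)
}

#' Preprocess and segment a cohort into a feature table
#'
#' Band-pass filters each recording, excises high-amplitude segments,
#' segments the concatenated clean signal into overlapping windows, and
#' extracts the feature vector of every window.
#'
#' @param cohort list of [eeg_recording]s.
#' @param config an [attn_config].
#' @return feature table data.frame.
#' @export
cohort_features <- function(cohort, config = attn_config()) {
  epochs <- list()
  for (rec in cohort) {
    pp <- preprocess_recording(rec, config$preprocess$low_hz,
                               config$preprocess$high_hz,
                               config$preprocess$amp_threshold_uV,
                               config$preprocess$pad_s)
    epochs <- c(epochs, segment(pp$recording, config$segmentation))
  }
  extract_feature_table(epochs, config$sampen, config$wpd)
}

#' Run the complete analysis pipeline
#'
#' simulate -> preprocess -> segment -> extract features -> rank -> select
#' -> evaluate. Persists the cohort (EDF + manifest, optional), the feature
#' CSV, and JSON selection/evaluation reports under `out_dir`. The "before"
#' condition uses all ten feature groups; "after" uses the selected subset.
#'
#' @param config an [attn_config].
#' @param out_dir output directory.
#' @return list with `features_path`, `selection`, `report`, where `report`
#'   contains pooled before/after accuracies, per-subject cross-session
#'   accuracies, and the paired statistics when at least three subjects and
#'   two sessions are available.
#' @export
run_pipeline <- function(config = attn_config(), out_dir = tempfile("attn")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("stage simulate: ", config$cohort$n_subjects, " subjects x ",
          config$cohort$n_sessions, " sessions x 4 tasks, seed ", config$seed)
  cohort <- make_cohort(config$cohort, config$profiles)
  if (isTRUE(config$write_edf)) write_cohort(cohort, file.path(out_dir, "cohort"))

  message("stage features: ", length(cohort), " recordings")
  features <- cohort_features(cohort, config)
  features_path <- file.path(out_dir, "features.csv")
  write_feature_table(features, features_path)
  message("  ", nrow(features), " epochs x ", length(feature_columns(features)),
          " feature columns")

  evaluator <- make_validation_evaluator(features, config$split,
                                         C = config$svm$C, gamma = config$svm$gamma)
  ranking <- rank_by_single_group_accuracy(evaluator)
  method <- config$selection$method %||% "sfs"
  message("stage select: method ", method)
  selection <- switch(method,
    sfs = sfs(ranking$group, evaluator),
    chi2 = ,
    mutual_info = {
      fr <- filter_rank(features, method)
      sw <- sweep_k(fr$group, evaluator,
                    config$selection$k %||% length(fr$group))
      structure(list(candidate_order = fr$group,
                     steps = data.frame(added = fr$group[sw$k],
                                        subset = vapply(sw$k, function(k)
                                          paste(fr$group[seq_len(k)], collapse = ","),
                                          character(1)),
                                        accuracy = sw$accuracy, retained = NA),
                     final_subset = fr$group[seq_len(sw$best_k)],
                     final_accuracy = max(sw$accuracy)),
                class = "sfs_result")
    },
    embedded = {
      es <- embedded_select(features, config$selection$threshold %||% 0.5,
                            config$selection$lambda %||% 0.01)
      structure(list(candidate_order = names(es$importance),
                     steps = data.frame(added = character(0), subset = character(0),
                                        accuracy = numeric(0), retained = logical(0)),
                     final_subset = es$selected,
                     final_accuracy = evaluator(es$selected)),
                class = "sfs_result")
    },
    stopf("unknown selection method '%s'", method))

  groups <- feature_groups(features)
  all_cols <- feature_columns(features)
  sel_cols <- unlist(groups[selection$final_subset], use.names = FALSE)
  message("stage evaluate: subset {", paste(selection$final_subset, collapse = ","), "}")
  split <- split_dataset(features, config$split)
  before <- train_and_eval(features, all_cols, split = split,
                           C = config$svm$C, gamma = config$svm$gamma)
  after <- train_and_eval(features, sel_cols, split = split,
                          C = config$svm$C, gamma = config$svm$gamma)

  report <- list(
    ranking = ranking,
    pooled = list(before = before$accuracy, after = after$accuracy),
    selection = list(method = method,
                     final_subset = selection$final_subset,
                     final_accuracy = selection$final_accuracy))
  if (config$cohort$n_sessions >= 2) {
    per_before <- subject_holdout_eval(features, all_cols,
                                       C = config$svm$C, gamma = config$svm$gamma)
    per_after <- subject_holdout_eval(features, sel_cols,
                                      C = config$svm$C, gamma = config$svm$gamma)
    report$per_subject <- data.frame(subject = per_before$subject,
                                     before = per_before$accuracy,
                                     after = per_after$accuracy)
    if (nrow(per_before) >= 3 && sd(per_after$accuracy - per_before$accuracy) > 0) {
      report$paired <- paired_comparison(per_before$accuracy, per_after$accuracy)
    }
  }
  jsonlite::write_json(list(steps = selection$steps,
                            final_subset = selection$final_subset,
                            final_accuracy = selection$final_accuracy),
                       file.path(out_dir, "selection.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       force = TRUE)
  list(features_path = features_path, selection = selection, report = report,
       out_dir = out_dir)
}

#' Replay the packaged published fixtures
#'
#' Runs the forward-selection algorithm against the packaged step-accuracy
#' lookup and the paired statistics on the packaged per-subject accuracy
#' table, and reports whether each recomputed quantity matches the printed
#' one. Involves no randomness.
#'
#' @return list with `sfs` (an `sfs_result`), `paired` (see
#'   [paired_comparison()]), and `matches` (named logical vector).
#' @export
replay_fixtures <- function() {
  t6 <- load_table6_fixture()
  res <- sfs(t6$added, table_lookup_evaluator())
  t7 <- load_table7_fixture()
  pc <- paired_comparison(t7$before, t7$after)
  matches <- c(
    sfs_decisions = identical(res$steps$retained[-1], t6$retained[-1]),
    sfs_subset = identical(res$final_subset, c("F7", "F5", "F4", "F1", "F6")),
    sfs_accuracy = isTRUE(all.equal(res$final_accuracy, 94.5)),
    t_stat = round(pc$t_stat, 3) == 3.546,
    n_improved = pc$n_improved == 11L)
  list(sfs = res, paired = pc, matches = matches)
}
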