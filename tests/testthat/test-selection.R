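test_that("single-group ranking reproduces the published candidate order from the lookup", {
  ranked <- rank_by_single_group_accuracy(table_lookup_evaluator())
  expect_identical(ranked$group,
                   c("F7", "F5", "F4", "F1", "F6", "F3", "F2", "F10", "F9", "F8"))
  expect_equal(ranked$accuracy[1], 84.8)
})

test_that("ranking tie-break is by group index and planted signal ranks first", {
  constant <- function(groups) 50
  ranked <- rank_by_single_group_accuracy(constant)
  expect_identical(ranked$group, paste0("F", 1:10))

  for (seed in 1:10) {
    df <- make_toy_features(n_per_class = 15, informative = "F6", signal = 2,
                            seed = seed)
    ev <- make_validation_evaluator(df, split_spec(seed = seed))
    ranked <- rank_by_single_group_accuracy(ev)
    expect_identical(ranked$group[1], "F6")
  }
})

test_that("SFS replays the published step log exactly", {
  t6 <- load_table6_fixture()
  res <- sfs(t6$added, table_lookup_evaluator())
  expect_identical(res$steps$retained[-1], t6$retained[-1])
  expect_identical(res$final_subset, c("F7", "F5", "F4", "F1", "F6"))
  expect_equal(res$final_accuracy, 94.5)
  expect_equal(res$steps$accuracy, t6$accuracy)
  # every candidate appears exactly once
  expect_identical(sort(res$steps$added), sort(t6$added))
})

test_that("SFS keeps only strict improvements and never falls below the seed", {
  # no addition improves -> subset stays the seed
  dec <- function(groups) 100 - length(groups)
  res <- sfs(paste0("F", 1:5), dec)
  expect_identical(res$final_subset, "F1")
  expect_equal(res$final_accuracy, 99)

  # random evaluators: final accuracy >= seed accuracy, retained flags consistent
  set.seed(20)
  for (i in 1:10) {
    accs <- new.env()
    noisy <- function(groups) {
      key <- paste(sort(groups), collapse = ",")
      if (is.null(accs[[key]])) accs[[key]] <- runif(1, 50, 100)
      accs[[key]]
    }
    res <- sfs(paste0("F", 1:6), noisy)
    expect_gte(res$final_accuracy, res$steps$accuracy[1])
    best <- res$steps$accuracy[1]
    for (k in 2:nrow(res$steps)) {
      expect_identical(res$steps$retained[k], res$steps$accuracy[k] > best)
      if (res$steps$retained[k]) best <- res$steps$accuracy[k]
    }
  }
})

test_that("SFS attains the exhaustive optimum on a toy problem where greedy is optimal", {
  # additive group values: greedy over a descending candidate order is optimal
  vals <- c(A = 8, B = 4, C = 2, D = -3)
  ev <- function(groups) 50 + sum(vals[groups])
  res <- sfs(names(sort(vals, decreasing = TRUE)), ev)
  subsets <- unlist(lapply(1:4, function(k)
    combn(names(vals), k, paste, collapse = ",", simplify = FALSE)), recursive = FALSE)
  best <- max(vapply(subsets, function(s) ev(strsplit(s, ",")[[1]]), numeric(1)))
  expect_equal(res$final_accuracy, best)
  expect_setequal(res$final_subset, c("A", "B", "C"))
})

test_that("filter ranking scores constant groups zero and finds planted signal", {
  df <- make_toy_features(n_per_class = 20, informative = "F3", signal = 4, seed = 2)
  for (ch in grep("^F5_", names(df), value = TRUE)) df[[ch]] <- 1  # constant group
  for (m in c("chi2", "mutual_info")) {
    fr <- filter_rank(df, m)
    expect_identical(fr$group[1], "F3")
    expect_equal(fr$score[fr$group == "F5"], 0)
    expect_identical(fr$group[10], "F5")
  }
})

test_that("chi2 scoring is invariant to min-max rescaling of [0,1] inputs", {
  set.seed(3)
  x <- runif(200)
  x[which.min(x)] <- 0
  x[which.max(x)] <- 1
  y <- factor(rep(1:4, 50))
  expect_equal(attnEEG:::chi2_score(x, y), attnEEG:::chi2_score((x - min(x)) / diff(range(x)), y))
})

test_that("sweep_k evaluates nested prefixes and finds the informative depth", {
  calls <- list()
  ev <- function(groups) { calls[[length(calls) + 1]] <<- groups; length(groups) * 10 }
  sw <- sweep_k(paste0("F", 1:4), ev)
  expect_equal(sw$accuracy, c(10, 20, 30, 40))
  expect_equal(sw$best_k, 4)
  for (k in 2:4) expect_true(all(calls[[k - 1]] %in% calls[[k]]))  # prefix property

  sw1 <- sweep_k("F1", function(g) 42, k_max = 1)
  expect_equal(sw1$accuracy, 42)

  # planted: 3 complementary informative groups (coarse split, 1-vs-2 and
  # 3-vs-4 refinements) so accuracy keeps improving until all three are in
  for (seed in 1:10) {
    df <- make_toy_features(n_per_class = 15, informative = character(0),
                            seed = 100 + seed)
    set.seed(200 + seed)
    for (ch in grep("^F1_", names(df))) df[[ch]] <- df[[ch]] + 3 * (df$label <= 2)
    for (ch in grep("^F2_", names(df))) df[[ch]] <- df[[ch]] + 3 * (df$label == 1)
    for (ch in grep("^F3_", names(df))) df[[ch]] <- df[[ch]] + 3 * (df$label == 3)
    ev <- make_validation_evaluator(df, split_spec(seed = seed))
    fr <- filter_rank(df, "mutual_info")
    sw <- sweep_k(fr$group, ev, k_max = 5)
    expect_gte(sw$best_k, 3)
  }
})

test_that("embedded selection keeps informative groups and drops noise", {
  df <- make_toy_features(n_per_class = 25, informative = "F2", signal = 3, seed = 4)
  res <- embedded_select(df, threshold = 0.5)
  expect_identical(res$selected, "F2")
  expect_gt(res$importance[["F2"]], 10 * max(res$importance[setdiff(names(res$importance), "F2")]))

  all_nonzero <- embedded_select(df, threshold = 0)
  expect_true("F2" %in% all_nonzero$selected)

  single <- df
  single$label <- 1
  expect_error(embedded_select(single), "two classes")
})

test_that("feature_groups partitions the feature columns", {
  df <- make_toy_features(n_per_class = 2)
  gr <- feature_groups(df)
  expect_length(gr, 10)
  expect_setequal(unlist(gr), feature_columns(df))
  expect_length(gr$F7, 10)
})
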