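test_that("rank AUC matches hand counts and concordance counting", {
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(evaluate_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  # 3 of 4 positive/negative pairs concordant (0.4 < 0.5 is the discordant one)
  expect_equal(evaluate_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)

  # oracle: direct pairwise concordance with ties counting one half
  auc_oracle <- function(s, y) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), 2) # rounding induces ties
    expect_equal(evaluate_auc(s, y), auc_oracle(s, y))
  }
})

test_that("AUC of negated scores is one minus AUC", {
  set.seed(22)
  for (i in 1:20) {
    y <- c(1, 0, rbinom(18, 1, 0.5))
    s <- rnorm(20)
    expect_equal(evaluate_auc(-s, y), 1 - evaluate_auc(s, y))
  }
})

test_that("splits are 70/30, stratified, disjoint, exhaustive, seed-deterministic", {
  y <- rep(c("high", "low"), each = 50)
  sp <- make_splits(y, n_splits = 5, train_frac = 0.7, base_seed = 9)
  expect_length(sp, 5)
  for (s in sp) {
    expect_equal(length(s$train), 70L)
    expect_equal(length(s$test), 30L)
    expect_equal(sort(c(s$train, s$test)), 1:100)
    expect_equal(sum(y[s$train] == "high"), 35L)
    expect_equal(sum(y[s$test] == "high"), 15L)
  }
  sp2 <- make_splits(y, n_splits = 5, train_frac = 0.7, base_seed = 9)
  expect_identical(sp, sp2)
  sp3 <- make_splits(y, n_splits = 5, train_frac = 0.7, base_seed = 10)
  expect_false(identical(sp, sp3))
})

test_that("CV folds partition each class across folds", {
  y <- rep(c("high", "low"), c(23, 31))
  folds <- make_cv_folds(y, k = 10, seed = 4)
  expect_length(folds, 54)
  expect_setequal(unique(folds), 1:10)
  # each sample in exactly one fold; class counts balanced within 1
  per_fold <- table(folds, y)
  expect_true(all(abs(per_fold[, "high"] - 23 / 10) < 1.01))
  expect_error(make_cv_folds(rep(c("high", "low"), c(5, 50)), k = 10), "at least")
})

test_that("a one-point grid is selected without search and CV tuning runs", {
  set.seed(31)
  n <- 60
  x <- matrix(rnorm(n * 5), n, 5)
  y <- ifelse(x[, 1] + rnorm(n, sd = 0.3) > 0, "high", "low")
  # guarantee both classes
  y[1:2] <- c("high", "low")

  fit1 <- tune_and_train(x, y, "rf", grid = tibble::tibble(
    num_trees = 50L, mtry_rule = "sqrt", min_node = 1L), seed = 1)
  expect_equal(fit1$tuned_params$num_trees, 50L)
  expect_true(is.na(fit1$cv_auc))

  grid <- tibble::tibble(num_trees = c(50L, 100L), mtry_rule = "sqrt", min_node = 1L)
  fit2 <- tune_and_train(x, y, "rf", cv_folds = 5, grid = grid, seed = 1)
  expect_true(fit2$tuned_params$num_trees %in% grid$num_trees)
  expect_gte(fit2$cv_auc, 0.5)

  fit3 <- tune_and_train(x, y, "en", cv_folds = 5, seed = 1)
  expect_true(all(c("alpha", "lambda") %in% names(fit3$tuned_params)))
  expect_error(tune_and_train(x, rep("high", n), "rf"), "both classes")
})

test_that("strongly separable planted data reaches high CV AUC", {
  set.seed(32)
  n <- 80
  x <- matrix(rnorm(n * 10), n, 10)
  cls <- rep(c("high", "low"), each = n / 2)
  x[cls == "high", 3] <- x[cls == "high", 3] + 3
  fit <- tune_and_train(x, cls, "rf", cv_folds = 5,
                        grid = tibble::tibble(num_trees = c(100L, 200L),
                                              mtry_rule = "sqrt", min_node = 1L),
                        seed = 2)
  expect_gte(fit$cv_auc, 0.95)
})

test_that("importances are non-negative, sum to one, and flow into group sums", {
  set.seed(33)
  n <- 40
  feats <- tibble::tibble(transcript_id = sprintf("t%02d", 1:n),
                          f_seq = rnorm(n), vivo_bin_01 = rnorm(n),
                          vitro_bin_01 = rnorm(n))
  labs <- tibble::tibble(transcript_id = feats$transcript_id,
                         te_class = rep(c("high", "low"), each = n / 2))
  feats$vivo_bin_01 <- feats$vivo_bin_01 + ifelse(labs$te_class == "high", 2, 0)
  attr(feats, "feature_groups") <- tibble::tibble(
    feature = c("f_seq", "vivo_bin_01", "vitro_bin_01"),
    group = c("sequence", "vivo", "vitro"))
  res <- train_te_classifiers(feats, labs, n_splits = 4, cv_folds = 2,
                              rf_grid = tibble::tibble(num_trees = 100L,
                                                       mtry_rule = "sqrt",
                                                       min_node = 1L),
                              models = "rf", base_seed = 5)
  expect_true(all(res$importance >= 0))
  expect_equal(unname(rowSums(res$importance)), rep(1, 4), tolerance = 1e-6)

  gi <- grouped_importance(res)
  sums <- dplyr::summarise(dplyr::group_by(gi$groups, split),
                           total = sum(importance))
  expect_equal(sums$total, rep(1, 4), tolerance = 1e-6)
  vivo_mean <- mean(gi$groups$importance[gi$groups$group == "vivo"])
  vitro_mean <- mean(gi$groups$importance[gi$groups$group == "vitro"])
  expect_gt(vivo_mean, vitro_mean)
  expect_equal(gi$bins$condition, c("vitro", "vivo"))
})

test_that("model comparison is a paired t-test with degenerate-variance guards", {
  a <- c(0.9, 0.8, 0.85, 0.95, 0.9)
  b <- a - 0.1 + rnorm(5, sd = 1e-4)
  out <- compare_models(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(out$statistic, unname(tt$statistic))
  expect_equal(out$p.value, tt$p.value)
  expect_lt(out$p.value, 1e-3)

  swapped <- compare_models(b, a)
  expect_equal(swapped$statistic, -out$statistic)
  expect_equal(swapped$p.value, out$p.value)

  expect_warning(same <- compare_models(a, a), "Zero variance")
  expect_true(is.nan(same$statistic))
  expect_warning(const <- compare_models(a, a - 0.1), "Zero variance")
  expect_equal(const$p.value, 0)
  expect_equal(const$statistic, Inf)
})

test_that("the split pipeline is seed-deterministic end to end", {
  sim <- simulate_te_dataset(synthetic_config("mesc_like", n_transcripts = 40, seed = 2))
  te <- quantify_te(sim$counts, sim$transcripts)
  labs <- te_labels(te)
  feats <- assemble_sequence_features(sim$transcripts)
  grid <- tibble::tibble(num_trees = 50L, mtry_rule = "sqrt", min_node = 1L)
  r1 <- train_te_classifiers(feats, labs, n_splits = 3, rf_grid = grid,
                             models = "rf", base_seed = 11)
  r2 <- train_te_classifiers(feats, labs, n_splits = 3, rf_grid = grid,
                             models = "rf", base_seed = 11)
  expect_identical(r1$splits$auc_rf, r2$splits$auc_rf)
  expect_identical(r1$importance, r2$importance)
})

test_that("label permutation destroys the signal (null AUC near 0.5)", {
  sim <- simulate_te_dataset(synthetic_config("mesc_like", n_transcripts = 120,
                                              seed = 13, missing_rate = 0))
  prof <- bin_profile(sim$tracks, sim$transcripts)
  heads <- cds_head_reactivity(sim$tracks, sim$transcripts)
  mfe <- mfe_features(sim$transcripts)
  feats <- assemble_structural_features(prof, heads, mfe)
  labs <- tibble::tibble(transcript_id = sim$truth$transcript_id,
                         te_class = sim$truth$true_class)
  perm <- labs
  set.seed(99)
  perm$te_class <- sample(perm$te_class)
  grid <- tibble::tibble(num_trees = 100L, mtry_rule = "sqrt", min_node = 1L)
  res <- train_te_classifiers(feats, perm, n_splits = 20, rf_grid = grid,
                              models = "rf", base_seed = 7)
  expect_gte(mean(res$splits$auc_rf), 0.4)
  expect_lte(mean(res$splits$auc_rf), 0.6)
})

test_that("tidy and glance return the expected tidy shapes", {
  sim <- simulate_te_dataset(synthetic_config("mesc_like", n_transcripts = 100, seed = 8))
  te <- quantify_te(sim$counts, sim$transcripts)
  feats <- assemble_sequence_features(sim$transcripts)
  res <- train_te_classifiers(feats, te_labels(te), n_splits = 3,
                              rf_grid = tibble::tibble(num_trees = 50L,
                                                       mtry_rule = "sqrt",
                                                       min_node = 1L),
                              en_grid = tibble::tibble(alpha = 0.5, lambda = 0.01),
                              base_seed = 3)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  expect_true(all(c("split", "auc_rf", "auc_en") %in% names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("mean_auc_rf", "mean_auc_en", "p.value") %in% names(gl)))
})
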