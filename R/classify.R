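# repeated stratified 70/30 splits, CV-tuned random forest and elastic net,
# rank AUC, grouped/per-bin importances

# coerce class labels to logical (TRUE = positive/high-TE class)
as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("Numeric labels must be 0/1.")
    return(labels == 1)
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("high", "low"))) {
    abort("Labels must be 0/1, logical, or 'high'/'low'.")
  }
  labels == "high"
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the probability that a randomly
#' chosen positive outranks a randomly chosen negative, with ties counting
#' one half (the Mann-Whitney formulation).
#'
#' @param scores Numeric classifier scores, higher = more positive.
#' @param labels Binary labels (0/1, logical, or `"high"`/`"low"`).
#' @return AUC in `[0, 1]`.
#' @export
evaluate_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  if (length(scores) != length(pos)) abort("`scores` and `labels` lengths differ.")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) abort("Both classes must be present to compute AUC.")
  r <- rank(scores)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Repeated stratified train/test splits
#'
#' Draws `n_splits` independent random partitions of the samples into a
#' training fraction and the complementary test set, stratified by class so
#' both classes appear on both sides of every split. Split `i` (0-based) is
#' drawn under seed `base_seed + i`, so a fixed `base_seed` reproduces the
#' whole family of splits.
#'
#' @param labels Class label per sample.
#' @param n_splits Number of random splits, default 100.
#' @param train_frac Training fraction, default 0.7; the per-class training
#'   size is `round(train_frac * n_class)`.
#' @param base_seed Base seed.
#' @return A list of `n_splits` elements, each `list(train =, test =)` of
#'   integer sample indices, disjoint and jointly exhaustive.
#' @export
make_splits <- function(labels, n_splits = 100L, train_frac = 0.7, base_seed = 1L) {
  pos <- as_positive(labels)
  n <- length(pos)
  if (n < 10L) abort("Need at least 10 samples to split.")
  assert_scalar_number(train_frac, "train_frac", min = 0, strict_min = TRUE)
  if (train_frac >= 1) abort("`train_frac` must be < 1.")
  idx_by_class <- split(seq_len(n), pos)
  if (any(lengths(idx_by_class) < 2L) || length(idx_by_class) < 2L) {
    abort("Each class needs at least 2 samples for stratified splitting.")
  }
  lapply(seq_len(n_splits), function(i) {
    with_seed(base_seed + i - 1L, {
      train <- unlist(lapply(idx_by_class, function(idx) {
        k <- round(train_frac * length(idx))
        k <- min(max(k, 1L), length(idx) - 1L) # both sides keep every class
        sample(idx, k)
      }), use.names = FALSE)
      train <- sort(train)
      list(train = train, test = setdiff(seq_len(n), train))
    })
  })
}

#' Stratified cross-validation folds
#'
#' Assigns each sample to exactly one of `k` folds, balancing classes across
#' folds.
#'
#' @param labels Class label per sample.
#' @param k Number of folds, default 10.
#' @param seed Seed for the fold assignment.
#' @return Integer vector of fold ids in `1..k`, one per sample.
#' @export
make_cv_folds <- function(labels, k = 10L, seed = 1L) {
  pos <- as_positive(labels)
  if (min(sum(pos), sum(!pos)) < k) {
    abort(sprintf("Need at least %d samples per class for %d-fold CV.", k, k))
  }
  folds <- integer(length(pos))
  with_seed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(pos == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Default hyper-parameter grids
#'
#' Random forest: number of trees {100, 500} x mtry rule {sqrt(p), p/3} x
#' minimum node size {1, 5}. Elastic net: mixing parameter alpha
#' {0.1, 0.5, 0.9} x 10 log-spaced penalty strengths.
#'
#' @return A tibble, one row per candidate parameter set.
#' @export
rf_default_grid <- function() {
  tidyr::expand_grid(num_trees = c(100L, 500L),
                     mtry_rule = c("sqrt", "third"),
                     min_node = c(1L, 5L))
}

#' @rdname rf_default_grid
#' @export
en_default_grid <- function() {
  tidyr::expand_grid(alpha = c(0.1, 0.5, 0.9),
                     lambda = 10^seq(0, -4, length.out = 10))
}

# training-partition medians (NA-safe); all-NA features impute to 0
fit_imputer <- function(x) {
  med <- apply(x, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

apply_imputer <- function(x, med) {
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

fit_scaler <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(x, scaler) {
  scale(x, center = scaler$center, scale = scaler$scale)
}

fit_one_model <- function(x, y, model, params, seed) {
  if (model == "rf") {
    p <- ncol(x)
    mtry <- if (params$mtry_rule == "sqrt") max(1L, floor(sqrt(p))) else max(1L, floor(p / 3))
    ranger::ranger(
      x = x, y = y, num.trees = params$num_trees, mtry = mtry,
      min.node.size = params$min_node, probability = TRUE,
      importance = "impurity", seed = seed, num.threads = 1L
    )
  } else {
    glmnet::glmnet(x = x, y = y, family = "binomial", alpha = params$alpha,
                   lambda = params$lambda, standardize = FALSE)
  }
}

score_one_model <- function(fit, x, model, params = NULL) {
  if (model == "rf") {
    pr <- predict(fit, data = x, num.threads = 1L)$predictions
    unname(pr[, "high"])
  } else {
    as.vector(predict(fit, newx = x, s = params$lambda, type = "response"))
  }
}

#' Tune by cross-validation and refit on the full training partition
#'
#' Exhaustive grid search: every candidate parameter set is scored by
#' stratified k-fold cross-validated AUC on the training data; the best set
#' (ties broken by grid order) is refit on the entire training partition.
#' A single-row grid is accepted as-is without running the search.
#'
#' Missing feature values are imputed with training-partition medians
#' (recomputed inside each CV fold, so no validation-fold leakage); for the
#' elastic net the features are additionally z-scored from the training
#' partition.
#'
#' @param x Numeric feature matrix (rows = samples), `NA` allowed.
#' @param y Class labels (`"high"`/`"low"`).
#' @param model `"rf"` (probability random forest, impurity importance) or
#'   `"en"` (elastic-net-penalised logistic regression).
#' @param cv_folds Number of CV folds, default 10.
#' @param grid Candidate tibble; defaults to [rf_default_grid()] /
#'   [en_default_grid()].
#' @param seed Seed controlling fold assignment and model fitting.
#' @return An object of class `te_model`: the fitted model plus
#'   `tuned_params`, the preprocessing state, and the best CV AUC (`NA` for
#'   a single-point grid).
#' @export
tune_and_train <- function(x, y, model = c("rf", "en"), cv_folds = 10L,
                           grid = NULL, seed = 1L) {
  model <- match.arg(model)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  pos <- as_positive(y)
  if (length(unique(pos)) < 2L) abort("Training data must contain both classes.")
  y <- factor(ifelse(pos, "high", "low"), levels = c("low", "high"))
  grid <- grid %||% if (model == "rf") rf_default_grid() else en_default_grid()
  grid <- as_tibble(grid)

  cv_auc <- NA_real_
  if (nrow(grid) > 1L) {
    folds <- make_cv_folds(y, k = cv_folds, seed = derive_seed(seed, 1L))
    mean_auc <- cv_grid_auc(x, y, folds, model, grid, seed)
    best <- which.max(mean_auc)
    cv_auc <- mean_auc[best]
  } else {
    best <- 1L
  }
  params <- as.list(grid[best, ])

  med <- fit_imputer(x)
  x_imp <- apply_imputer(x, med)
  scaler <- NULL
  if (model == "en") {
    scaler <- fit_scaler(x_imp)
    x_imp <- apply_scaler(x_imp, scaler)
  }
  fit <- fit_one_model(x_imp, y, model, params, seed = derive_seed(seed, 2L))
  structure(
    list(model_type = model, fit = fit, tuned_params = params, cv_auc = cv_auc,
         medians = med, scaler = scaler, feature_names = colnames(x)),
    class = "te_model"
  )
}

# mean CV AUC per grid row; one pass over folds, en shares one path per alpha
cv_grid_auc <- function(x, y, folds, model, grid, seed) {
  k <- max(folds)
  auc <- matrix(NA_real_, nrow = nrow(grid), ncol = k)
  for (f in seq_len(k)) {
    tr <- folds != f
    med <- fit_imputer(x[tr, , drop = FALSE])
    x_tr <- apply_imputer(x[tr, , drop = FALSE], med)
    x_va <- apply_imputer(x[!tr, , drop = FALSE], med)
    if (model == "en") {
      scaler <- fit_scaler(x_tr)
      x_tr <- apply_scaler(x_tr, scaler)
      x_va <- apply_scaler(x_va, scaler)
      for (a in unique(grid$alpha)) {
        rows <- which(grid$alpha == a)
        fit <- glmnet::glmnet(x_tr, y[tr], family = "binomial", alpha = a,
                              lambda = sort(grid$lambda[rows], decreasing = TRUE),
                              standardize = FALSE)
        for (r in rows) {
          sc <- as.vector(predict(fit, newx = x_va, s = grid$lambda[r],
                                  type = "response"))
          auc[r, f] <- evaluate_auc(sc, y[!tr])
        }
      }
    } else {
      for (r in seq_len(nrow(grid))) {
        fit <- fit_one_model(x_tr, y[tr], model, as.list(grid[r, ]),
                             seed = derive_seed(seed, 100L + f))
        sc <- score_one_model(fit, x_va, model)
        auc[r, f] <- evaluate_auc(sc, y[!tr])
      }
    }
  }
  rowMeans(auc)
}

#' @export
predict.te_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (is.null(colnames(newdata))) {
    if (ncol(newdata) != length(object$feature_names)) {
      abort("`newdata` has no column names and the wrong number of columns.")
    }
    colnames(newdata) <- object$feature_names
  }
  x <- newdata[, object$feature_names, drop = FALSE]
  storage.mode(x) <- "double"
  x <- apply_imputer(x, object$medians)
  if (!is.null(object$scaler)) x <- apply_scaler(x, object$scaler)
  score_one_model(object$fit, x, object$model_type, object$tuned_params)
}

# impurity importances of a fitted rf, normalised to sum 1
model_importance <- function(te_model) {
  if (te_model$model_type != "rf") abort("Importances are defined for the rf model only.")
  imp <- te_model$fit$variable.importance
  imp[imp < 0] <- 0
  s <- sum(imp)
  if (s == 0) rep(1 / length(imp), length(imp)) else imp / s
}

#' Train and evaluate both classifiers over repeated splits
#'
#' The full modelling protocol: for each of `n_splits` stratified
#' train/test partitions, both models are tuned by `cv_folds`-fold
#' cross-validation on the training portion, refit on the whole training
#' portion, and scored by rank AUC on the held-out portion; the random
#' forest's normalised impurity importances are recorded per split.
#'
#' @param features Wide feature tibble (`transcript_id` + feature columns)
#'   carrying a `feature_groups` attribute, e.g. from [combine_features()].
#' @param labels Tibble `transcript_id`, `te_class` restricted to
#'   `high`/`low` (see [te_labels()]).
#' @param n_splits Number of random splits, default 100.
#' @param train_frac Training fraction, default 0.7.
#' @param cv_folds CV folds for tuning, default 10.
#' @param rf_grid,en_grid Hyper-parameter grids; `NULL` uses the defaults.
#' @param base_seed Base seed; the whole run is reproducible from it.
#' @param models Which models to run; default both.
#' @return An object of class `te_split_results` with a per-split results
#'   tibble, the per-split importance matrix, and the feature-group
#'   registry. Use [tidy()] / [glance()] to extract tidy summaries and
#'   [grouped_importance()] for the importance analysis.
#' @export
train_te_classifiers <- function(features, labels, n_splits = 100L,
                                 train_frac = 0.7, cv_folds = 10L,
                                 rf_grid = NULL, en_grid = NULL,
                                 base_seed = 1L, models = c("rf", "en")) {
  assert_columns(labels, c("transcript_id", "te_class"), "Label table")
  groups <- attr(features, "feature_groups")
  if (is.null(groups)) abort("`features` must carry a `feature_groups` attribute.")
  dat <- inner_join(labels, features, by = "transcript_id")
  if (nrow(dat) < 10L) abort("Need at least 10 labelled transcripts.")
  y <- dat$te_class
  x <- as.matrix(dat[, groups$feature, drop = FALSE])
  storage.mode(x) <- "double"

  splits <- make_splits(y, n_splits = n_splits, train_frac = train_frac,
                        base_seed = base_seed)
  imp <- matrix(NA_real_, nrow = n_splits, ncol = ncol(x),
                dimnames = list(NULL, colnames(x)))
  rows <- vector("list", n_splits)
  for (i in seq_len(n_splits)) {
    sp <- splits[[i]]
    seed_i <- derive_seed(base_seed, i)
    auc_rf <- auc_en <- NA_real_
    params_rf <- params_en <- list()
    if ("rf" %in% models) {
      fit_rf <- tune_and_train(x[sp$train, , drop = FALSE], y[sp$train], "rf",
                               cv_folds = cv_folds, grid = rf_grid, seed = seed_i)
      auc_rf <- evaluate_auc(predict(fit_rf, x[sp$test, , drop = FALSE]), y[sp$test])
      imp[i, ] <- model_importance(fit_rf)
      params_rf <- fit_rf$tuned_params
    }
    if ("en" %in% models) {
      fit_en <- tune_and_train(x[sp$train, , drop = FALSE], y[sp$train], "en",
                               cv_folds = cv_folds, grid = en_grid, seed = seed_i)
      auc_en <- evaluate_auc(predict(fit_en, x[sp$test, , drop = FALSE]), y[sp$test])
      params_en <- fit_en$tuned_params
    }
    rows[[i]] <- tibble(split = i - 1L, seed = seed_i, auc_rf = auc_rf,
                        auc_en = auc_en, params_rf = list(params_rf),
                        params_en = list(params_en))
  }
  structure(
    list(splits = bind_rows(rows), importance = imp, feature_groups = groups,
         n_samples = nrow(dat), models = models),
    class = "te_split_results"
  )
}

#' @exportS3Method base::print
print.te_split_results <- function(x, ...) {
  cat(sprintf("<te_split_results> %d splits, %d samples, %d features\n",
              nrow(x$splits), x$n_samples, ncol(x$importance)))
  if ("rf" %in% x$models) {
    cat(sprintf("  mean test AUC (random forest): %.3f\n", mean(x$splits$auc_rf)))
  }
  if ("en" %in% x$models) {
    cat(sprintf("  mean test AUC (elastic net):   %.3f\n", mean(x$splits$auc_en)))
  }
  invisible(x)
}

#' Grouped and per-bin feature importances
#'
#' Per split, sums the random forest's normalised importances within each
#' feature group (sequence / vivo / vitro / insilico); across splits,
#' averages the importance of each metagene bin feature, giving the per-bin
#' importance curves for the two probing conditions.
#'
#' @param results A `te_split_results` object (run with the rf model).
#' @return An object of class `te_importance_summary`: `$groups` (tibble
#'   `split`, `group`, `importance`) and `$bins` (tibble `condition`, `bin`,
#'   `mean_importance`).
#' @export
grouped_importance <- function(results) {
  if (!inherits(results, "te_split_results")) abort("`results` must be a te_split_results object.")
  imp <- results$importance
  if (all(is.na(imp))) abort("No importances recorded: run with the rf model.")
  groups <- results$feature_groups
  unknown <- setdiff(colnames(imp), groups$feature)
  if (length(unknown) > 0) {
    abort(sprintf("Unregistered feature(s): %s", paste(unknown, collapse = ", ")))
  }
  grp <- groups$group[match(colnames(imp), groups$feature)]
  group_sums <- t(apply(imp, 1L, function(v) tapply(v, grp, sum)))
  group_tbl <- tidyr::pivot_longer(
    bind_cols(tibble(split = results$splits$split), as_tibble(group_sums)),
    -"split", names_to = "group", values_to = "importance"
  )
  is_bin <- grepl("^(vivo|vitro)_bin_[0-9]+$", colnames(imp))
  bin_tbl <- tibble(
    feature = colnames(imp)[is_bin],
    condition = sub("_bin_.*$", "", colnames(imp)[is_bin]),
    bin = as.integer(sub("^.*_bin_", "", colnames(imp)[is_bin])),
    mean_importance = colMeans(imp[, is_bin, drop = FALSE])
  )
  bin_tbl <- arrange(bin_tbl[, c("condition", "bin", "mean_importance")],
                     .data$condition, .data$bin)
  structure(list(groups = group_tbl, bins = bin_tbl),
            class = "te_importance_summary")
}

#' Paired comparison of two models' per-split AUCs
#'
#' Two-sided paired t-test on the per-split AUC differences of two models
#' evaluated on identical splits. When the differences have zero variance
#' the t statistic degenerates: a warning is raised and the p-value is
#' reported as 0 (non-zero constant difference) or `NA` (identical
#' vectors).
#'
#' @param auc_a,auc_b Per-split AUC vectors of equal length from the same
#'   splits.
#' @return One-row tibble: `estimate` (mean difference a - b), `statistic`
#'   (t), `p.value`, `n`.
#' @export
compare_models <- function(auc_a, auc_b) {
  if (length(auc_a) != length(auc_b)) abort("AUC vectors must have equal length.")
  d <- auc_a - auc_b
  n <- length(d)
  if (n < 2L) abort("Need at least 2 paired AUCs.")
  if (sd(d) == 0) {
    warn("Zero variance of paired AUC differences; t statistic degenerate.")
    est <- mean(d)
    return(tibble(estimate = est,
                  statistic = if (est == 0) NaN else sign(est) * Inf,
                  p.value = if (est == 0) NA_real_ else 0,
                  n = n))
  }
  tt <- stats::t.test(auc_a, auc_b, paired = TRUE)
  tibble(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
         p.value = tt$p.value, n = n)
}

#' @export
tidy.te_split_results <- function(x, ...) {
  out <- x$splits
  out$params_rf <- purrr::map_chr(out$params_rf, function(p) {
    if (length(p) == 0) NA_character_ else paste(names(p), unlist(p), sep = "=", collapse = ";")
  })
  out$params_en <- purrr::map_chr(out$params_en, function(p) {
    if (length(p) == 0) NA_character_ else paste(names(p), signif(unlist(p), 4), sep = "=", collapse = ";")
  })
  out
}

#' @export
glance.te_split_results <- function(x, ...) {
  cmp <- if (all(c("rf", "en") %in% x$models)) {
    compare_models(x$splits$auc_rf, x$splits$auc_en)
  } else {
    tibble(estimate = NA_real_, statistic = NA_real_, p.value = NA_real_, n = nrow(x$splits))
  }
  tibble(
    n_splits = nrow(x$splits), n_samples = x$n_samples,
    mean_auc_rf = mean(x$splits$auc_rf), mean_auc_en = mean(x$splits$auc_en),
    auc_diff = cmp$estimate, statistic = cmp$statistic, p.value = cmp$p.value
  )
}
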