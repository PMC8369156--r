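# Trust-classifier training and selection: feature tables from raw IMU
# signals, z-normalization fitted on training subjects only, class
# balancing, recursive feature elimination ranked by random-forest
# importance under leave-one-subject-out cross-validation (LOSO-CV), the
# 4-algorithm x 2-label x 5-feature-set model grid, validation-based model
# selection and random-search hyperparameter tuning.

trust_algorithms <- c("naive_bayes", "logistic_regression", "decision_tree",
                      "random_forest")

#' The 18 raw-signal feature names
#'
#' `{accel, gyro, mag} x {x, y, z} x {trunk, wheelchair}`, e.g.
#' `accel_x_trunk` or `mag_z_wheelchair`.
#'
#' @return character(18).
#' @export
feature_names <- function() {
  as.vector(t(outer(
    as.vector(outer(c("accel", "gyro", "mag"), c("x", "y", "z"), paste, sep = "_")),
    c("trunk", "wheelchair"), paste, sep = "_")))
}

#' Per-sample raw-signal features from a two-sensor session
#'
#' @param imu_trunk,imu_chair `imu_series` on a common grid.
#' @return data.frame with the 18 columns of [feature_names()].
#' @export
session_features <- function(imu_trunk, imu_chair) {
  stopifnot(nrow(imu_trunk) == nrow(imu_chair))
  out <- data.frame(
    imu_matrix(imu_trunk, "accel"), imu_matrix(imu_trunk, "gyro"),
    imu_matrix(imu_trunk, "mag"),
    imu_matrix(imu_chair, "accel"), imu_matrix(imu_chair, "gyro"),
    imu_matrix(imu_chair, "mag")
  )
  names(out) <- c(
    paste0(rep(c("accel", "gyro", "mag"), each = 3), "_", c("x", "y", "z"), "_trunk"),
    paste0(rep(c("accel", "gyro", "mag"), each = 3), "_", c("x", "y", "z"), "_wheelchair")
  )
  out[, feature_names()]
}

#' Assemble a labelled feature table for one subject
#'
#' @param imu_trunk,imu_chair `imu_series` on a common grid.
#' @param labels a `label_series` aligned with the IMU grid.
#' @param subject_id subject identifier.
#' @return data.frame with 18 feature columns, `subject_id`, `efcorrect`
#'   and `efcorrect_s5`.
#' @export
build_feature_table <- function(imu_trunk, imu_chair, labels, subject_id) {
  stopifnot(inherits(labels, "label_series"), nrow(labels) == nrow(imu_trunk))
  cbind(session_features(imu_trunk, imu_chair),
        subject_id = subject_id,
        efcorrect = labels$efcorrect,
        efcorrect_s5 = labels$efcorrect_s5)
}

#' Standardize feature columns by z-normalization
#'
#' Means and standard deviations are fitted on the reference (training)
#' subjects only and applied to all rows, so validation and test subjects
#' never influence the transform.
#'
#' @param table feature table (see [build_feature_table()]).
#' @param ref_subjects subject ids whose rows define the transform.
#' @return the table with transformed feature columns and a
#'   `standardization` attribute (`list(mu, sigma)`).
#' @export
standardize_features <- function(table, ref_subjects) {
  stopifnot(length(ref_subjects) > 0)
  feats <- feature_names()
  ref <- table[table$subject_id %in% ref_subjects, feats, drop = FALSE]
  if (!nrow(ref)) stop("no rows for the reference subjects", call. = FALSE)
  mu <- vapply(ref, mean, numeric(1))
  sigma <- vapply(ref, stats::sd, numeric(1))
  zero <- names(sigma)[sigma == 0 | is.na(sigma)]
  if (length(zero)) {
    stop("zero-variance feature(s) in reference: ",
         paste(zero, collapse = ", "), call. = FALSE)
  }
  table[feats] <- apply_standardization(table[feats], list(mu = mu, sigma = sigma))
  attr(table, "standardization") <- list(mu = mu, sigma = sigma)
  table
}

#' @rdname standardize_features
#' @param features data.frame of feature columns.
#' @param params `list(mu, sigma)` as stored by [standardize_features()].
#' @export
apply_standardization <- function(features, params) {
  nm <- names(params$mu)
  features[nm] <- sweep(sweep(as.matrix(features[nm]), 2, params$mu), 2,
                        params$sigma, "/")
  features
}

#' Balance classes by down-sampling the majority class
#'
#' @param table labelled feature table.
#' @param label_col `"efcorrect"` or `"efcorrect_s5"`.
#' @param seed RNG seed; the removal is uniform at random and reproducible.
#' @return the table with equal class counts; the minority class untouched.
#' @export
balance_classes <- function(table, label_col = "efcorrect", seed = 1) {
  y <- table[[label_col]]
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  if (n1 == n0) return(table)
  maj <- as.integer(n1 > n0)
  keep_n <- min(n1, n0)
  idx_maj <- which(y == maj)
  idx_min <- which(y != maj)
  kept <- withr::with_seed(seed, sample(idx_maj, keep_n))
  out <- table[sort(c(idx_min, kept)), , drop = FALSE]
  attr(out, "standardization") <- attr(table, "standardization")
  out
}

#' Precision, recall and accuracy of binary predictions
#'
#' Positive class is 1. With no positive predictions the precision is
#' undefined and reported as `NaN` with `precision_defined = FALSE`.
#'
#' @param predictions,labels binary vectors of equal length.
#' @return list with `precision`, `recall`, `accuracy`,
#'   `precision_defined`.
#' @export
classification_metrics <- function(predictions, labels) {
  predictions <- as.numeric(predictions); labels <- as.numeric(labels)
  stopifnot(length(predictions) == length(labels),
            all(predictions %in% c(0, 1)), all(labels %in% c(0, 1)))
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  precision <- if (tp + fp == 0) NaN else tp / (tp + fp)
  recall <- if (tp + fn == 0) NaN else tp / (tp + fn)
  list(precision = precision, recall = recall,
       accuracy = mean(predictions == labels),
       precision_defined = (tp + fp) > 0)
}

f1_score <- function(precision, recall) {
  if (is.nan(precision) || is.nan(recall) || precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

fit_algorithm <- function(algorithm, data, features, label_col, seed,
                          params = list()) {
  y <- factor(data[[label_col]], levels = c(0, 1))
  x <- data[, features, drop = FALSE]
  switch(algorithm,
    naive_bayes = e1071::naiveBayes(x = x, y = y),
    logistic_regression = {
      d <- cbind(x, .y = data[[label_col]])
      stats::glm(stats::reformulate(features, ".y"), data = d,
                 family = stats::binomial())
    },
    decision_tree = {
      d <- cbind(x, .y = y)
      rpart::rpart(stats::reformulate(features, ".y"), data = d,
                   method = "class")
    },
    random_forest = {
      d <- cbind(x, .y = y)
      ranger::ranger(
        stats::reformulate(features, ".y"), data = d,
        num.trees = params$num_trees %||% 100,
        max.depth = params$max_depth %||% 0,
        min.node.size = params$min_node_size %||% 1,
        seed = seed, num.threads = 1
      )
    },
    stop("unknown algorithm: ", algorithm, call. = FALSE)
  )
}

predict_algorithm <- function(algorithm, fit, newdata) {
  switch(algorithm,
    naive_bayes = as.integer(as.character(stats::predict(fit, newdata))),
    logistic_regression =
      as.integer(stats::predict(fit, newdata, type = "response") > 0.5),
    decision_tree =
      as.integer(as.character(stats::predict(fit, newdata, type = "class"))),
    random_forest =
      as.integer(as.character(stats::predict(
        fit, data = newdata, num.threads = 1)$predictions))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

loso_scores <- function(table, features, label_col, seed, params = list(),
                        algorithm = "random_forest", balance = TRUE,
                        importance = FALSE) {
  subjects <- unique(table$subject_id)
  if (length(subjects) < 2) {
    stop("LOSO-CV needs at least 2 subjects", call. = FALSE)
  }
  prec <- rec <- f1 <- numeric(length(subjects))
  imp <- matrix(0, length(subjects), length(features),
                dimnames = list(NULL, features))
  for (i in seq_along(subjects)) {
    train <- table[table$subject_id != subjects[i], , drop = FALSE]
    test <- table[table$subject_id == subjects[i], , drop = FALSE]
    if (balance) train <- balance_classes(train, label_col, seed = seed + i)
    if (importance && algorithm == "random_forest") {
      y <- factor(train[[label_col]], levels = c(0, 1))
      d <- cbind(train[, features, drop = FALSE], .y = y)
      fit <- ranger::ranger(stats::reformulate(features, ".y"), data = d,
                            num.trees = params$num_trees %||% 100,
                            importance = "impurity", seed = seed + i,
                            num.threads = 1)
      imp[i, ] <- fit$variable.importance[features]
    } else {
      fit <- fit_algorithm(algorithm, train, features, label_col, seed + i,
                           params)
    }
    pred <- predict_algorithm(algorithm, fit, test[, features, drop = FALSE])
    m <- classification_metrics(pred, test[[label_col]])
    prec[i] <- m$precision; rec[i] <- m$recall
    f1[i] <- f1_score(m$precision, m$recall)
  }
  list(precision = mean(prec, na.rm = TRUE), recall = mean(rec, na.rm = TRUE),
       f1 = mean(f1), importance = colMeans(imp))
}

#' Rank features by recursive elimination with LOSO-CV
#'
#' Starting from all 18 features, repeatedly fits a random forest per
#' leave-one-subject-out fold, scores the held-out subject (precision,
#' recall, F1), averages impurity importances over folds, and eliminates
#' the least important feature, one per round, until one feature remains.
#'
#' @param table standardized training feature table.
#' @param label_col label variant to rank against.
#' @param seed RNG seed (forwarded to every forest fit).
#' @param num_trees trees per forest.
#' @return list with `elimination_order` (first eliminated first),
#'   `sets` (feature set per subset size, named by size) and `scores`
#'   (data.frame: size, precision, recall, f1).
#' @export
rank_features <- function(table, label_col = "efcorrect", seed = 1,
                          num_trees = 100) {
  feats <- feature_names()
  stopifnot(all(feats %in% names(table)))
  current <- feats
  elim <- character(0)
  scores <- data.frame(size = integer(0), precision = numeric(0),
                       recall = numeric(0), f1 = numeric(0))
  sets <- list()
  while (length(current) >= 1) {
    sc <- loso_scores(table, current, label_col, seed,
                      params = list(num_trees = num_trees),
                      importance = TRUE)
    scores <- rbind(scores, data.frame(size = length(current),
                                       precision = sc$precision,
                                       recall = sc$recall, f1 = sc$f1))
    sets[[as.character(length(current))]] <- current
    if (length(current) == 1) break
    worst <- names(which.min(sc$importance))
    elim <- c(elim, worst)
    current <- setdiff(current, worst)
  }
  list(elimination_order = c(elim, current), sets = sets, scores = scores)
}

#' Select the five best feature sets from a ranking
#'
#' Subset sizes are ranked separately on precision, recall and F1; the five
#' sizes with the best mean rank win, ties broken toward the smaller
#' subset. Sizes are converted to concrete feature sets via the
#' elimination order.
#'
#' @param rank_result output of [rank_features()].
#' @return list of up to five character vectors of feature names.
#' @export
select_feature_sets <- function(rank_result) {
  sc <- rank_result$scores
  r <- (rank(-sc$precision, ties.method = "average") +
        rank(-sc$recall, ties.method = "average") +
        rank(-sc$f1, ties.method = "average")) / 3
  ord <- order(r, sc$size)
  sizes <- sc$size[ord][seq_len(min(5L, nrow(sc)))]
  lapply(sizes, function(s) rank_result$sets[[as.character(s)]])
}

new_trust_model <- function(algorithm, features, fit, standardization,
                            label_variant, seed, params = list()) {
  structure(list(algorithm = algorithm, features = features, fit = fit,
                 standardization = standardization,
                 label_variant = label_variant, seed = seed, params = params,
                 version = "1"),
            class = "trust_model")
}

#' @export
print.trust_model <- function(x, ...) {
  cat(sprintf("<trust_model v%s> %s on %d features (%s), label %s, seed %d\n",
              x$version, x$algorithm, length(x$features),
              paste(x$features, collapse = ", "), x$label_variant, x$seed))
  invisible(x)
}

#' Fit one trust classifier
#'
#' Balances the training rows, fits the requested algorithm on the given
#' (already standardized) feature table and wraps the fit together with its
#' standardization parameters, feature names, label variant and seed.
#'
#' @param table standardized training feature table (with a
#'   `standardization` attribute).
#' @param features feature names to use.
#' @param algorithm one of `naive_bayes`, `logistic_regression`,
#'   `decision_tree`, `random_forest`.
#' @param label_variant `"efcorrect"` or `"efcorrect_s5"`.
#' @param seed RNG seed.
#' @param params algorithm hyperparameters (random forest: `num_trees`,
#'   `max_depth`, `min_node_size`).
#' @return a `trust_model`.
#' @export
fit_trust_model <- function(table, features, algorithm = "random_forest",
                            label_variant = "efcorrect", seed = 1,
                            params = list()) {
  algorithm <- match.arg(algorithm, trust_algorithms)
  std <- attr(table, "standardization")
  if (is.null(std)) stop("table must be standardized first", call. = FALSE)
  train <- balance_classes(table, label_variant, seed = seed)
  fit <- fit_algorithm(algorithm, train, features, label_variant, seed, params)
  new_trust_model(algorithm, features, fit, std, label_variant, seed, params)
}

#' Predict per-sample trust from raw features
#'
#' Applies the model's stored standardization and returns binary
#' predictions (1 = earth-frame estimate trusted).
#'
#' @param model a `trust_model`.
#' @param features data.frame of raw (unstandardized) feature columns.
#' @return integer vector of 0/1 predictions.
#' @export
predict_trust <- function(model, features) {
  stopifnot(inherits(model, "trust_model"))
  z <- apply_standardization(features, model$standardization)
  predict_algorithm(model$algorithm, model$fit,
                    z[, model$features, drop = FALSE])
}

#' Train the 40-model grid
#'
#' Four algorithms x two label variants x the given feature sets, each
#' fitted on the full (balanced) training table. Individual model failures
#' are recorded and the grid continues.
#'
#' @param table standardized training feature table.
#' @param feature_sets list of feature-name vectors (typically five).
#' @param seed RNG seed.
#' @return list of `trust_model` objects (failed fits carry a `condition`);
#'   names encode algorithm, variant and set index.
#' @export
train_model_grid <- function(table, feature_sets, seed = 1) {
  grid <- expand.grid(algorithm = trust_algorithms,
                      variant = c("efcorrect", "efcorrect_s5"),
                      set = seq_along(feature_sets),
                      stringsAsFactors = FALSE)
  out <- vector("list", nrow(grid))
  names(out) <- sprintf("%s_%s_set%d", grid$algorithm, grid$variant, grid$set)
  for (i in seq_len(nrow(grid))) {
    out[[i]] <- tryCatch(
      fit_trust_model(table, feature_sets[[grid$set[i]]],
                      algorithm = grid$algorithm[i],
                      label_variant = grid$variant[i], seed = seed),
      error = function(e) structure(list(condition = e), class = "trust_model_failure")
    )
  }
  out
}

#' Select the best model on validation sessions
#'
#' Every candidate is run through the adaptive filter ([run_extended()]) on
#' each validation session; candidates are ranked by the mean of their MAE
#' rank and RMSE rank of the inclination error against the reference (ties
#' toward fewer features). Also emits the per-candidate comparison table
#' and its eight-row summary (best candidate per algorithm and label
#' variant).
#'
#' @param models list of `trust_model`s (e.g. from [train_model_grid()]).
#' @param validation_sessions list of prepared sessions (see
#'   [grid_search_beta()] for the fields).
#' @param cfg an [adaptive_config()].
#' @return list with `model` (the winner), `table` (all candidates:
#'   algorithm, label_variant, n_features, mae, rmse) and `summary8`
#'   (best per algorithm/variant).
#' @export
select_best_model <- function(models, validation_sessions,
                              cfg = adaptive_config()) {
  ok <- !vapply(models, inherits, logical(1), "trust_model_failure")
  models <- models[ok]
  stopifnot(length(models) > 0, length(validation_sessions) > 0)
  mae <- rmse <- numeric(length(models))
  for (i in seq_along(models)) {
    errs <- lapply(validation_sessions, function(s) {
      est <- run_extended(s$imu_trunk, s$imu_chair, models[[i]], cfg)
      incl <- inclination(est$trunk, est$chair,
                          neutral_index = s$neutral_index)
      incl$angle_deg - angle_vector(s$ref)
    })
    d <- unlist(errs)
    mae[i] <- mean(abs(d), na.rm = TRUE)
    rmse[i] <- sqrt(mean(d^2, na.rm = TRUE))
  }
  nfeat <- vapply(models, function(m) length(m$features), integer(1))
  tab <- data.frame(
    id = names(models) %||% as.character(seq_along(models)),
    algorithm = vapply(models, `[[`, character(1), "algorithm"),
    label_variant = vapply(models, `[[`, character(1), "label_variant"),
    n_features = nfeat, mae = mae, rmse = rmse
  )
  score <- (rank(mae, ties.method = "average") +
            rank(rmse, ties.method = "average")) / 2
  best <- order(score, nfeat)[1]
  summary8 <- do.call(rbind, lapply(
    split(tab, list(tab$algorithm, tab$label_variant), drop = TRUE),
    function(g) g[order((rank(g$mae) + rank(g$rmse)) / 2, g$n_features)[1], ]
  ))
  rownames(summary8) <- NULL
  list(model = models[[best]], table = tab, summary8 = summary8)
}

#' Random-search hyperparameter tuning for the random forest
#'
#' Samples `n_iter` configurations uniformly from a modest space (number of
#' trees 50-500, maximum depth unlimited or 3-15, minimum node size 1-20)
#' and scores each by LOSO-CV F1 on the training table.
#'
#' @param table standardized training feature table.
#' @param features feature names.
#' @param label_col label variant.
#' @param seed RNG seed; the sampled configurations and the winner are
#'   deterministic given the seed.
#' @param n_iter number of sampled configurations.
#' @return list with `params` (winning configuration), `f1`, and `trace`
#'   (data.frame of all configurations and scores).
#' @export
tune_hyperparameters <- function(table, features, label_col = "efcorrect",
                                 seed = 1, n_iter = 10) {
  cand <- withr::with_seed(seed, data.frame(
    num_trees = sample(seq(50, 500, by = 50), n_iter, replace = TRUE),
    max_depth = sample(c(0L, 3:15), n_iter, replace = TRUE),
    min_node_size = sample(1:20, n_iter, replace = TRUE)
  ))
  f1 <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    sc <- loso_scores(table, features, label_col, seed,
                      params = as.list(cand[i, ]))
    f1[i] <- sc$f1
  }
  best <- order(-f1, cand$num_trees)[1]
  list(params = as.list(cand[best, ]), f1 = f1[best],
       trace = cbind(cand, f1 = f1))
}

#' Full training pipeline for the trust classifier
#'
#' Standardization (training subjects only) is assumed done on the input
#' table. Runs feature ranking, picks the five best sets, trains the
#' 40-model grid, selects the best model on the validation sessions, tunes
#' its hyperparameters (random forest only) and refits the final model.
#'
#' @param train_table standardized feature table of the training subjects.
#' @param validation_sessions prepared validation sessions.
#' @param cfg an [adaptive_config()].
#' @param seed RNG seed.
#' @param n_tune random-search iterations (0 skips tuning).
#' @return list with `model` (final `trust_model`), `selection` (output of
#'   [select_best_model()]), `ranking` and `feature_sets`.
#' @export
train_trust_classifier <- function(train_table, validation_sessions,
                                   cfg = adaptive_config(), seed = 1,
                                   n_tune = 5) {
  ranking <- rank_features(train_table, "efcorrect", seed = seed)
  feature_sets <- select_feature_sets(ranking)
  models <- train_model_grid(train_table, feature_sets, seed = seed)
  selection <- select_best_model(models, validation_sessions, cfg)
  final <- selection$model
  if (n_tune > 0 && final$algorithm == "random_forest") {
    tuned <- tune_hyperparameters(train_table, final$features,
                                  final$label_variant, seed = seed,
                                  n_iter = n_tune)
    final <- fit_trust_model(train_table, final$features,
                             algorithm = final$algorithm,
                             label_variant = final$label_variant,
                             seed = seed, params = tuned$params)
  }
  list(model = final, selection = selection, ranking = ranking,
       feature_sets = feature_sets)
}

#' Save / load a trust model
#'
#' Versioned serialization embedding feature names, standardization
#' parameters, label variant and seed.
#'
#' @param model a `trust_model`.
#' @param path file path.
#' @return [load_trust_model()] returns a `trust_model`.
#' @export
save_trust_model <- function(model, path) {
  stopifnot(inherits(model, "trust_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_trust_model
#' @export
load_trust_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "trust_model")) stop("not a trust model", call. = FALSE)
  model
}
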