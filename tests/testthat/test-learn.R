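# synthetic feature tables with a planted class signal: three informative
# features separate the classes, the rest are pure noise
planted_table <- function(n_subjects = 4, n_per = 300, seed = 1,
                          informative = c("accel_x_trunk", "gyro_y_trunk",
                                          "mag_z_wheelchair"),
                          signal = 2) {
  set.seed(seed)
  feats <- feature_names()
  rows <- lapply(seq_len(n_subjects), function(s) {
    y <- stats::rbinom(n_per, 1, 0.5)
    X <- matrix(stats::rnorm(n_per * 18), n_per, 18,
                dimnames = list(NULL, feats))
    for (f in informative) X[, f] <- X[, f] + signal * y
    d <- as.data.frame(X)
    d$subject_id <- sprintf("P%02d", s)
    d$efcorrect <- y
    d$efcorrect_s5 <- as.integer(y & stats::rbinom(n_per, 1, 0.95))
    d
  })
  do.call(rbind, rows)
}

test_that("feature naming admits the published final feature set", {
  nm <- feature_names()
  expect_length(nm, 18)
  expect_true(all(c("accel_x_trunk", "mag_x_trunk", "mag_y_trunk",
                    "mag_x_wheelchair", "mag_z_wheelchair") %in% nm))
})

test_that("z-normalization is fitted on the reference subjects only", {
  tab <- planted_table(seed = 2)
  ref <- c("P01", "P02")
  # closed form on a constructed column
  tab$accel_x_trunk[tab$subject_id %in% ref] <-
    stats::rnorm(sum(tab$subject_id %in% ref), 5, 2)
  std <- standardize_features(tab, ref)
  params <- attr(std, "standardization")
  expect_equal(params$mu[["accel_x_trunk"]],
               mean(tab$accel_x_trunk[tab$subject_id %in% ref]))
  x <- apply_standardization(
    data.frame(accel_x_trunk = params$mu[["accel_x_trunk"]] +
                 2 * params$sigma[["accel_x_trunk"]])[, , drop = FALSE],
    list(mu = params$mu["accel_x_trunk"], sigma = params$sigma["accel_x_trunk"]))
  expect_equal(as.numeric(x$accel_x_trunk), 2)

  # shifting a column together with its reference leaves the output fixed
  tab2 <- tab
  tab2$gyro_z_trunk <- tab2$gyro_z_trunk + 7
  std2 <- standardize_features(tab2, ref)
  expect_equal(std2$gyro_z_trunk, std$gyro_z_trunk, tolerance = 1e-12)

  # zero-variance reference column errors with the feature name
  tab3 <- tab
  tab3$mag_y_trunk[tab3$subject_id %in% ref] <- 1
  expect_error(standardize_features(tab3, ref), "mag_y_trunk")

  # no leak: perturbing non-reference subjects does not change the
  # transform applied to reference rows
  tab4 <- tab
  out_rows <- !(tab4$subject_id %in% ref)
  tab4[out_rows, feature_names()] <- tab4[out_rows, feature_names()] * 100
  std4 <- standardize_features(tab4, ref)
  in_rows <- tab$subject_id %in% ref
  expect_equal(std4[in_rows, feature_names()], std[in_rows, feature_names()],
               tolerance = 1e-12)
})

test_that("class balancing down-samples the majority class reproducibly", {
  tab <- planted_table(n_subjects = 1, n_per = 140, seed = 3)
  tab$efcorrect <- rep(c(1L, 0L), c(100, 40))
  bal <- balance_classes(tab, "efcorrect", seed = 9)
  expect_equal(as.numeric(table(bal$efcorrect)), c(40, 40))
  # minority rows untouched
  expect_true(all(which(tab$efcorrect == 0) %in% as.integer(rownames(bal))))
  expect_identical(balance_classes(tab, "efcorrect", seed = 9), bal)
  expect_false(identical(balance_classes(tab, "efcorrect", seed = 10), bal))

  even <- tab[c(1:40, 101:140), ]
  expect_equal(nrow(balance_classes(even, "efcorrect", seed = 1)), 80)
  single <- tab[tab$efcorrect == 1, ]
  expect_error(balance_classes(single, "efcorrect"), "both classes")
})

test_that("classification metrics follow the standard definitions", {
  m <- classification_metrics(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(m[c("precision", "recall", "accuracy")]),
               c(precision = 1, recall = 1, accuracy = 1))
  m2 <- classification_metrics(rep(1, 10), rep(c(1, 0), 5))
  expect_equal(m2$precision, 0.5)
  expect_equal(m2$recall, 1)
  expect_equal(m2$accuracy, 0.5)
  # TP 90, FP 10, FN 5, TN 95
  pred <- rep(c(1, 1, 0, 0), c(90, 10, 5, 95))
  lab <- rep(c(1, 0, 1, 0), c(90, 10, 5, 95))
  m3 <- classification_metrics(pred, lab)
  expect_equal(m3$precision, 0.9)
  expect_equal(m3$recall, 90 / 95, tolerance = 1e-12)
  expect_equal(m3$accuracy, 0.925)
  m4 <- classification_metrics(rep(0, 6), rep(c(0, 1), 3))
  expect_true(is.nan(m4$precision))
  expect_false(m4$precision_defined)
})

test_that("recursive elimination keeps planted-signal features to the end", {
  informative <- c("accel_x_trunk", "gyro_y_trunk", "mag_z_wheelchair")
  hits <- 0
  for (rep in 1:10) {
    tab <- planted_table(seed = 100 + rep, informative = informative)
    tab <- standardize_features(tab, unique(tab$subject_id))
    rk <- rank_features(tab, "efcorrect", seed = rep, num_trees = 40)
    expect_equal(nrow(rk$scores), 18)           # one score row per size
    last3 <- rk$elimination_order[16:18]
    if (setequal(last3, informative)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("pure-noise features rank arbitrarily with chance-level scores", {
  tab <- planted_table(seed = 7, informative = character(0))
  tab <- standardize_features(tab, unique(tab$subject_id))
  rk <- rank_features(tab, "efcorrect", seed = 7, num_trees = 40)
  expect_equal(sort(rk$scores$size), 1:18)
  # balanced classes, no signal: F1 hovers near 0.5
  expect_lt(max(abs(rk$scores$f1 - 0.5)), 0.2)
})

test_that("feature-set selection applies the mean-rank and tie rules", {
  mk_rank <- function(scores) {
    sets <- lapply(scores$size, function(s) paste0("f", seq_len(s)))
    names(sets) <- scores$size
    list(scores = scores, sets = sets, elimination_order = NULL)
  }
  # improving up to size 5, flat after: the knee sizes win
  sc <- data.frame(size = 18:1,
                   precision = c(rep(0.9, 14), 0.9, 0.8, 0.7, 0.6),
                   recall = c(rep(0.9, 14), 0.9, 0.8, 0.7, 0.6),
                   f1 = c(rep(0.9, 14), 0.9, 0.8, 0.7, 0.6))
  sel <- select_feature_sets(mk_rank(sc))
  expect_equal(sort(lengths(sel)), c(4, 5, 6, 7, 8))

  # all scores equal: smallest five subset sizes win
  sc2 <- data.frame(size = 18:1, precision = 0.8, recall = 0.8, f1 = 0.8)
  expect_equal(sort(lengths(select_feature_sets(mk_rank(sc2)))), 1:5)

  # exactly five sizes available: all selected
  sc3 <- data.frame(size = 5:1, precision = stats::runif(5),
                    recall = stats::runif(5), f1 = stats::runif(5))
  expect_length(select_feature_sets(mk_rank(sc3)), 5)
})

test_that("the model grid covers 4 algorithms x 2 labels x 5 sets deterministically", {
  raw <- planted_table(seed = 5)
  tab <- standardize_features(raw, c("P01", "P02", "P03"))
  train <- tab[tab$subject_id != "P04", ]
  attr(train, "standardization") <- attr(tab, "standardization")
  sets <- list(c("accel_x_trunk", "gyro_y_trunk"),
               c("accel_x_trunk", "gyro_y_trunk", "mag_z_wheelchair"),
               feature_names()[1:4], feature_names()[1:6], feature_names())
  grid <- train_model_grid(train, sets, seed = 4)
  expect_length(grid, 40)
  # prediction takes raw features and applies the stored standardization
  probe <- raw[raw$subject_id == "P04", feature_names()]
  p1 <- predict_trust(grid[["random_forest_efcorrect_set2"]], probe)
  grid2 <- train_model_grid(train, sets, seed = 4)
  expect_identical(predict_trust(grid2[["random_forest_efcorrect_set2"]], probe), p1)
  # planted signal: tree-based models classify the held-out subject well
  lab <- raw$efcorrect[raw$subject_id == "P04"]
  expect_gt(classification_metrics(p1, lab)$accuracy, 0.9)
  p_tree <- predict_trust(grid[["decision_tree_efcorrect_set2"]], probe)
  expect_gt(classification_metrics(p_tree, lab)$accuracy, 0.9)
})

test_that("hyperparameter random search is deterministic and non-degrading", {
  tab <- standardize_features(planted_table(seed = 6),
                              sprintf("P%02d", 1:4))
  feats <- c("accel_x_trunk", "gyro_y_trunk", "mag_z_wheelchair")
  one <- tune_hyperparameters(tab, feats, seed = 3, n_iter = 1)
  expect_equal(nrow(one$trace), 1)
  t1 <- tune_hyperparameters(tab, feats, seed = 5, n_iter = 4)
  t2 <- tune_hyperparameters(tab, feats, seed = 5, n_iter = 4)
  expect_identical(t1$params, t2$params)
  # tuned configuration is not worse than chance on planted signal
  expect_gt(t1$f1, 0.8)
})

test_that("model selection ranks a label-faithful model above a corrupted one", {
  s <- generate_session(session_config(seed = 44))
  p <- prepare_session(s)
  tab <- build_feature_table(p$imu_trunk, p$imu_chair, p$labels, "P01")
  tab <- standardize_features(tab, "P01")
  good <- fit_trust_model(tab, c("accel_x_trunk", "gyro_y_trunk",
                                 "gyro_z_trunk", "accel_z_trunk"),
                          "random_forest", "efcorrect", seed = 1)
  corrupt <- tab
  corrupt$efcorrect <- sample(corrupt$efcorrect)
  attr(corrupt, "standardization") <- attr(tab, "standardization")
  bad <- fit_trust_model(corrupt, c("accel_x_trunk", "gyro_y_trunk",
                                    "gyro_z_trunk", "accel_z_trunk"),
                         "random_forest", "efcorrect", seed = 1)
  sel <- select_best_model(list(good = good, bad = bad), list(p))
  expect_identical(sel$table$id[order(sel$table$rmse)][1], "good")
  expect_equal(nrow(sel$table), 2)
  # single candidate is returned unchanged
  one <- select_best_model(list(only = good), list(p))
  expect_identical(one$model, good)
})

test_that("the comparison summary has one row per algorithm and label variant", {
  tab <- standardize_features(planted_table(seed = 8), sprintf("P%02d", 1:4))
  sets <- list(c("accel_x_trunk", "gyro_y_trunk", "mag_z_wheelchair"))
  models <- train_model_grid(tab, sets, seed = 2)
  s <- generate_session(session_config(seed = 45,
    plan = data.frame(kind = c("static_neutral", "sprint"), duration = c(22, 8))))
  p <- prepare_session(s)
  sel <- select_best_model(models, list(p))
  expect_equal(nrow(sel$summary8), 8)
  expect_setequal(unique(sel$summary8$algorithm),
                  c("naive_bayes", "logistic_regression", "decision_tree",
                    "random_forest"))
  expect_true(all(c("mae", "rmse") %in% names(sel$summary8)))
})
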