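test_that("feature matrix is concentration plus arm z-scores in stable order", {
  z <- matrix(rnorm(2 * 39), 2, 39,
              dimnames = list(c("a", "b"), paste0("arm", 1:39)))
  meta <- data.frame(sample_id = c("a", "b"), group = c("case", "control"),
                     concentration = c(0.12, 0.09))
  fm <- assemble_features(z, meta)
  expect_equal(dim(fm$x), c(2, 40))
  expect_equal(colnames(fm$x)[1], "concentration")
  expect_equal(colnames(fm$x)[-1], colnames(z))
  expect_equal(fm$y, c(1L, 0L))

  sub <- assemble_features(z, meta, features = c("concentration", "arm3"))
  expect_equal(colnames(sub$x), c("concentration", "arm3"))

  meta$concentration[2] <- NA
  expect_error(assemble_features(z, meta), "b")
  expect_error(assemble_features(z, meta[1, ]), "metadata missing")
})

test_that("train/test split is stratified, seeded and sized as requested", {
  fm <- toy_features(n = 81, seed = 2)
  fm$y <- c(rep(1L, 41), rep(0L, 40))
  sp <- split_cohort(fm, 28, seed = 9)
  expect_length(sp$train_ids, 56)
  expect_length(sp$test_ids, 25)
  expect_equal(as.integer(sp$class_counts$train), c(28L, 28L))
  expect_equal(as.integer(sp$class_counts$test), c(12L, 13L))
  expect_identical(sort(c(sp$train_ids, sp$test_ids)), sort(fm$sample_ids))
  sp2 <- split_cohort(fm, 28, seed = 9)
  expect_identical(sp$train_ids, sp2$train_ids)
  expect_error(split_cohort(fm, 41, seed = 1), "exceeds")
  expect_warning(split_cohort(toy_features(n = 10), 5, seed = 1), "empty test")
})

test_that("training respects the depth constraint and is deterministic", {
  fm <- toy_features(n = 60, separation = 6, seed = 3)
  m <- train_classifier(fm, seed = 4)
  expect_lte(model_max_depth(m), 3)
  probs <- predict_classifier(m, fm)
  expect_equal(roc_auc(probs, fm$y)$auc, 1.0)

  m2 <- train_classifier(fm, seed = 4)
  expect_identical(xgboost::xgb.save.raw(m$booster),
                   xgboost::xgb.save.raw(m2$booster))

  one <- fm
  one$y[] <- 1L
  expect_error(train_classifier(one), "both classes")
})

test_that("feature ranking is gain-based with zero-importance features last", {
  fm <- toy_features(n = 60, separation = 6, seed = 5)
  m <- train_classifier(fm, xgb_params(nrounds = 20), seed = 5)
  rk <- rank_features(m)
  expect_equal(rk$feature[1], "f1")
  expect_equal(nrow(rk), 4)  # constant concentration column + f1..f3
  expect_true(all(rk$gain[rk$feature != "f1"] < rk$gain[1]))
  # a feature the ensemble never uses has gain 0 and ranks after used ones
  expect_true(all(diff(rk$gain) <= 0))
})

test_that("top-k selection refits on exactly k features", {
  fm <- toy_features(n = 60, separation = 6, seed = 6)
  m <- train_classifier(fm, seed = 6)
  sel <- select_and_refit(fm, m, k = 2)
  expect_length(sel$features, 2)
  expect_true("f1" %in% sel$features)
  expect_identical(sel$model$feature_names, sel$features)
  all_k <- select_and_refit(fm, m, k = ncol(fm$x))
  expect_equal(predict_classifier(all_k$model,
                                  armcnv:::subset_fm(fm, fm$sample_ids)),
               predict_classifier(m, fm))
  expect_error(select_and_refit(fm, m, k = 0), "k must be")
})

test_that("ROC/AUC agrees with hand counting and the Mann-Whitney oracle", {
  r <- roc_auc(c(.9, .8, .4, .2), c(1, 1, 0, 0))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.7, 10), rep(0:1, 5))$auc, 0.5)
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  mw_auc <- function(s, y) {  # exhaustive pair counting, ties count half
    pos <- s[y == 1]; neg <- s[y == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(pairs)
  }
  set.seed(10)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    expect_equal(roc_auc(s, y)$auc, mw_auc(s, y), tolerance = 1e-12)
  }
})

test_that("cross-validation folds partition the cohort with stratification", {
  fm <- toy_features(n = 81, seed = 7, separation = 6)
  fm$y <- c(rep(1L, 41), rep(0L, 40))
  cv <- cross_validate(fm, k = 5, seed = 3)
  expect_equal(sort(as.integer(table(cv$fold))), c(16L, 16L, 16L, 16L, 17L))
  expect_setequal(names(cv$fold), fm$sample_ids)
  for (f in 1:5) {
    tab <- table(fm$y[match(names(cv$fold)[cv$fold == f], fm$sample_ids)])
    expect_true(all(abs(tab - c(8, 8.2)) <= 1.2))  # within 1 of exact strata
  }
  expect_length(cv$auc, 5)
  expect_error(cross_validate(toy_features(n = 8), k = 5),
               "at least k")
})

test_that("cross-validation on separable data reaches AUC ~ 1", {
  fm <- toy_features(n = 50, separation = 8, seed = 8)
  cv <- cross_validate(fm, k = 5, seed = 8)
  expect_gte(cv$mean_auc, 0.99)
})

test_that("attributions are additive and match brute-force Shapley", {
  fm <- toy_features(n = 40, p = 3, seed = 9, separation = 4)
  m <- train_classifier(fm, xgb_params(nrounds = 10, eta = 0.3), seed = 9)
  ex <- explain_model(m, fm)
  expect_lt(max(abs(ex$base + rowSums(ex$shap) - ex$margin)), 1e-6)

  for (i in c(1, 7, 22)) {
    phi <- brute_force_shap(m, as.list(fm$x[i, ]))
    expect_equal(unname(ex$shap[i, ]), unname(phi[colnames(ex$shap)]),
                 tolerance = 1e-6)
  }
})

test_that("a constant model attributes nothing and a stump attributes one feature", {
  fm <- toy_features(n = 30, p = 2, seed = 11)
  const <- fm
  const$x[, ] <- 1  # no split possible
  m0 <- train_classifier(const, xgb_params(nrounds = 5), seed = 1)
  ex0 <- explain_model(m0, const)
  expect_true(all(abs(ex0$shap) < 1e-9))
  expect_equal(unname(ex0$base), unname(ex0$margin), tolerance = 1e-7)

  sep <- toy_features(n = 30, p = 2, seed = 12, separation = 10)
  m1 <- train_classifier(sep, xgb_params(nrounds = 1, eta = 1), seed = 1)
  ex1 <- explain_model(m1, sep)
  expect_true(all(abs(ex1$shap[, "f2"]) < 1e-9))
  expect_true(any(abs(ex1$shap[, "f1"]) > 0.1))
})

test_that("attribution directions mirror the known biology of the features", {
  grid <- mini_grid(bins_per_arm = 25, gc_seed = 5)
  arms <- mini_arm_table(25)
  et <- default_arm_event_table(arms)
  et$gain_prob[] <- 0; et$loss_prob[] <- 0
  et$gain_prob[et$arm %in% c("3q", "8q")] <- 7 / 21
  et$loss_prob[et$arm %in% c("3p", "22q")] <- 7 / 21
  et$loss_prob[et$arm == "10q"] <- 6 / 21
  cfg <- sim_config(arms = arms, arm_event_table = et, seed = 13,
                    n_cases = 120, n_controls = 60,
                    fraction_flat_cases = 0.3, tf_min = 0.1)
  sim <- simulate_cohort(cfg, grid)
  fr <- arm_fractions(sim$counts, grid)
  ctrl <- sim$meta$sample_id[sim$meta$group == "control"]
  z <- z_scores(fr, fit_reference(fr[ctrl, ]), control_ids = ctrl)
  six <- c("concentration", "10q", "3q", "8q", "3p", "22q")
  fm <- assemble_features(z, sim$meta,
                          features = six[order(match(six, c("concentration",
                                                            colnames(z))))])
  m <- train_classifier(fm, seed = 13)
  ex <- explain_model(m, fm)
  # gains push case-ward with high z, losses with low z, concentration with
  # high values
  expect_gt(cor(fm$x[, "concentration"], ex$shap[, "concentration"]), 0)
  expect_gt(cor(fm$x[, "3q"], ex$shap[, "3q"]), 0)
  expect_gt(cor(fm$x[, "8q"], ex$shap[, "8q"]), 0)
  expect_lt(cor(fm$x[, "10q"], ex$shap[, "10q"]), 0)
  expect_lt(cor(fm$x[, "22q"], ex$shap[, "22q"]), 0)
  expect_lt(cor(fm$x[, "3p"], ex$shap[, "3p"]), 0)
})

test_that("feature mismatch between model and data is rejected", {
  fm <- toy_features(n = 30, p = 2, seed = 14)
  m <- train_classifier(fm, xgb_params(nrounds = 5))
  swapped <- fm
  colnames(swapped$x) <- rev(colnames(fm$x))
  expect_error(predict_classifier(m, swapped), "mismatch")
  expect_error(explain_model(m, swapped), "mismatch")
})
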