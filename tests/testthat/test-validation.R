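test_that("random-fold splits have pinned sizes and are seeded partitions", {
  s89 <- random_fold_split(89, 0.7, seed = 1)
  expect_length(s89$train_ids, 62)
  expect_length(s89$test_ids, 27)

  s105 <- random_fold_split(105, 2 / 3, seed = 1)
  expect_length(s105$train_ids, 70)
  expect_length(s105$test_ids, 35)

  expect_identical(random_fold_split(50, 0.5, seed = 4),
                   random_fold_split(50, 0.5, seed = 4))
  expect_false(identical(random_fold_split(50, 0.5, seed = 4)$train_ids,
                         random_fold_split(50, 0.5, seed = 5)$train_ids))

  # disjoint cover for random inputs
  for (k in 1:10) {
    n <- 10 + k * 7
    s <- random_fold_split(n, 0.3 + 0.04 * k, seed = k,
                           condition_ids = paste0("c", 1:n))
    expect_length(intersect(s$train_ids, s$test_ids), 0)
    expect_setequal(c(s$train_ids, s$test_ids), paste0("c", 1:n))
  }

  expect_error(random_fold_split(10, 0), "between 0 and 1")
  expect_error(random_fold_split(3, 0.01), "degenerate")
})

test_that("leave-one-drug-out splits partition by drug usage", {
  data <- simulate(benchmark_sem(), seed = 2, design = all_pairs_design(15))
  s <- lodo_split_by_drug(data, "D1")
  expect_length(s$test_ids, 14)   # drug 1 appears in q-1 = 14 pairs
  expect_length(s$train_ids, 91)
  expect_setequal(c(s$train_ids, s$test_ids), data$condition_ids)
  expect_true(all(data$D[s$train_ids, "D1"] == 0))
  expect_true(all(data$D[s$test_ids, "D1"] != 0))

  expect_error(lodo_split_by_drug(data, "aMEK"), "unknown drug")
  # a drug used in every condition leaves no training data
  D_all <- cbind(1, matrix(c(1, 0, 0, 1), 2))
  rownames(D_all) <- c("a", "b")
  dat_all <- perturbation_dataset(D_all, matrix(rnorm(4), 2))
  expect_error(lodo_split_by_drug(dat_all, "D1"), "every condition")
  # and one never used has no test set
  D_never <- cbind(0, matrix(c(1, 0, 0, 1), 2))
  rownames(D_never) <- c("a", "b")
  dat_never <- perturbation_dataset(D_never, matrix(rnorm(4), 2))
  expect_error(lodo_split_by_drug(dat_never, "D1"), "never applied")
})

test_that("per-condition LODO holds the selected drug out of each refit set", {
  data <- simulate(benchmark_sem(), seed = 3, design = all_pairs_design(15))
  base <- random_fold_split(data, 2 / 3, seed = 11)
  asg <- lodo_per_condition(data, base, seed = 12)
  expect_length(asg, 35)
  for (a in asg) {
    # held-out drug is one of the condition's two active drugs
    active <- names(which(data$D[a$test_id, ] != 0))
    expect_true(a$held_out_drug %in% active)
    # no training condition uses it
    expect_true(all(data$D[a$train_ids, a$held_out_drug] == 0))
    expect_true(all(a$train_ids %in% base$train_ids))
    # at most q-2 = 13 of the 70 training pairs involve any one drug
    expect_gte(length(a$train_ids), 70 - 13)
  }
  expect_identical(vapply(asg, `[[`, "", "held_out_drug"),
                   vapply(lodo_per_condition(data, base, seed = 12),
                          `[[`, "", "held_out_drug"))

  # conditions must have exactly two active drugs
  D_one <- diag(3)
  rownames(D_one) <- paste0("c", 1:3)
  dat_one <- perturbation_dataset(D_one, matrix(rnorm(9), 3))
  base_one <- new_split_for_test(dat_one)
  expect_error(lodo_per_condition(dat_one, base_one, seed = 1), "exactly 2")
})

test_that("pooled metrics behave as Pearson correlation and MAE", {
  truth <- matrix(c(0.2, -1, 0.5, 2, 0, 1), 2)
  m <- evaluate_predictions(truth, truth)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$n, 6)

  m_neg <- evaluate_predictions(truth, -truth)
  expect_equal(m_neg$pearson_r, -1)

  m_shift <- evaluate_predictions(truth, truth + 0.1)
  expect_equal(m_shift$pearson_r, 1)
  expect_equal(m_shift$mae, 0.1)

  expect_error(evaluate_predictions(matrix(1, 2, 2), matrix(1, 2, 2)),
               "constant")
  expect_error(evaluate_predictions(truth, truth[, 1:2]), "same shape")
})

test_that("noise-free data yields perfect pooled scores for both estimators", {
  orc <- oracle_benchmark()
  data0 <- noiseless_benchmark_data()
  split <- random_fold_split(data0, 2 / 3, seed = 6)
  train <- subset_conditions(data0, split$train_ids)
  test <- subset_conditions(data0, split$test_ids)
  for (pred in list(predict(fit_lr(train), test$D),
                    predict(fit_csr(train, orc$B), test$D))) {
    m <- evaluate_predictions(test$X, pred)
    expect_equal(m$pearson_r, 1, tolerance = 1e-12)
    expect_equal(m$mae, 0, tolerance = 1e-10)
  }
})

test_that("the six-panel benchmark reproduces the qualitative orderings", {
  res <- run_benchmark_experiment(seed = 2024)
  s <- res$summary
  expect_setequal(s$split, c("RF", "RF-misspecified-B", "LODO"))
  expect_equal(nrow(s), 6)

  # LR ignores B: its predictions are identical arrays across the two RF panels
  lr_rf <- res$predictions[res$predictions$estimator == "LR" &
                             res$predictions$split == "RF", ]
  lr_mis <- res$predictions[res$predictions$estimator == "LR" &
                              res$predictions$split == "RF-misspecified-B", ]
  expect_identical(lr_rf$prediction, lr_mis$prediction)

  r_of <- function(est, split) s$pearson_r[s$estimator == est & s$split == split]
  # misspecified B degrades CSR but not LR
  expect_lt(r_of("CSR", "RF-misspecified-B"), r_of("CSR", "RF"))
  expect_gt(r_of("LR", "RF-misspecified-B"), r_of("CSR", "RF-misspecified-B"))
  # LODO: CSR extrapolates, LR cannot
  expect_gt(r_of("CSR", "LODO"), r_of("LR", "LODO"))
  # both do well in plain RF
  expect_gt(r_of("LR", "RF"), 0.9)
  expect_gt(r_of("CSR", "RF"), 0.9)

  # network exports exist for the CSR panels and the RF one is close to truth
  expect_named(res$networks, c("truth", "RF", "RF-misspecified-B", "LODO"))
  expect_lt(max(abs(res$networks$RF - res$networks$truth)), 0.2)
})

test_that("repeated random-fold averaging runs at realistic dimensions", {
  data <- synthetic_melanoma_shape(seed = 42)
  expect_equal(dim(data$D), c(89, 12))
  expect_equal(dim(data$X), c(89, 87))
  res <- run_rf_protocol(data, fit_lr, reps = 50, seed = 9)
  expect_true(res$pearson_r > 0.5)
  expect_true(all(res$times_tested > 0))
  expect_equal(dim(res$mean_prediction), c(89, 87))
  # averaging only over runs where a condition was in the test set:
  # counts vary across conditions but sum to reps * 27
  expect_equal(sum(res$times_tested), 50 * 27)
})
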