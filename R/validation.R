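#' Random-fold train/test split
#'
#' Uniform random partition of n conditions into training and test sets.
#' The training size is `round(train_frac * n)` with halves rounded away
#' from zero, so 70% of 89 conditions gives the conventional 62/27 split.
#'
#' @param n number of conditions, or a [perturbation_dataset()] (whose
#'   condition ids are then used).
#' @param train_frac training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @param condition_ids optional ids; defaults to `cond1..condn`.
#' @return A list of class `split_spec` with `train_ids`, `test_ids`,
#'   `held_out_drug` (NA), `kind = "random_fold"`.
#' @export
random_fold_split <- function(n, train_frac, seed, condition_ids = NULL) {
  if (inherits(n, "perturbation_dataset")) {
    condition_ids <- condition_ids %||% n$condition_ids
    n <- length(n$condition_ids)
  }
  stopifnot(is.numeric(n), length(n) == 1L, n == round(n),
            is.numeric(train_frac), length(train_frac) == 1L)
  if (train_frac <= 0 || train_frac >= 1) {
    stop("train_frac must be strictly between 0 and 1", call. = FALSE)
  }
  condition_ids <- condition_ids %||% paste0("cond", seq_len(n))
  check_length(condition_ids, n, "condition_ids")
  n_train <- floor(train_frac * n + 0.5)  # round half away from zero
  if (n_train < 1 || n_train >= n) {
    stop(sprintf("degenerate split: %d train of %d", n_train, n),
         call. = FALSE)
  }
  train_idx <- with_seed(seed, sample.int(n, n_train))
  new_split(train_ids = condition_ids[sort(train_idx)],
            test_ids = condition_ids[sort(setdiff(seq_len(n), train_idx))],
            kind = "random_fold")
}

new_split <- function(train_ids, test_ids, kind, held_out_drug = NA_character_) {
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 held_out_drug = held_out_drug, kind = kind),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("%s split: %d train / %d test%s\n", x$kind,
              length(x$train_ids), length(x$test_ids),
              if (is.na(x$held_out_drug)) ""
              else paste0(", held-out drug ", x$held_out_drug)))
  invisible(x)
}

#' Leave-one-drug-out split
#'
#' Training conditions are all those with zero concentration of the chosen
#' drug; test conditions are all those where it was applied (alone or in
#' combination). This is the extrapolation benchmark: the model never sees
#' the held-out drug during training.
#'
#' @param data a [perturbation_dataset()].
#' @param drug drug name to hold out.
#' @return A `split_spec` of kind `"lodo_by_drug"`.
#' @export
lodo_split_by_drug <- function(data, drug) {
  stopifnot(inherits(data, "perturbation_dataset"))
  if (!drug %in% data$drug_names) {
    stop(sprintf("unknown drug '%s'", drug), call. = FALSE)
  }
  used <- data$D[, drug] != 0
  if (!any(used)) {
    stop(sprintf("drug '%s' is never applied; no test set", drug),
         call. = FALSE)
  }
  if (all(used)) {
    stop(sprintf("drug '%s' is applied in every condition; no training set",
                 drug), call. = FALSE)
  }
  new_split(train_ids = data$condition_ids[!used],
            test_ids = data$condition_ids[used],
            kind = "lodo_by_drug", held_out_drug = drug)
}

#' Per-condition leave-one-drug-out assignments
#'
#' For each test condition of a random-fold split over a two-drugs-per-
#' condition design, picks one of the condition's two active drugs uniformly
#' at random (seeded) and returns the training conditions from the base
#' split in which that drug is not used. Each test condition thus receives
#' its own held-out drug and its own reduced training set, on which the
#' estimators are refit.
#'
#' @param data a [perturbation_dataset()].
#' @param base_split a `split_spec` from [random_fold_split()].
#' @param seed integer seed for the drug selections.
#' @return A list with one element per test condition: `test_id`,
#'   `held_out_drug`, `train_ids`.
#' @export
lodo_per_condition <- function(data, base_split, seed) {
  stopifnot(inherits(data, "perturbation_dataset"),
            inherits(base_split, "split_spec"))
  test_ids <- base_split$test_ids
  picks <- with_seed(seed, vapply(test_ids, function(id) {
    active <- which(data$D[id, ] != 0)
    if (length(active) != 2L) {
      stop(sprintf(
        "condition '%s' has %d active drugs; per-condition LODO requires exactly 2",
        id, length(active)), call. = FALSE)
    }
    data$drug_names[active[sample.int(2L, 1L)]]
  }, character(1)))
  lapply(seq_along(test_ids), function(i) {
    drug <- picks[i]
    keep <- base_split$train_ids[data$D[base_split$train_ids, drug] == 0]
    list(test_id = test_ids[i], held_out_drug = drug, train_ids = keep)
  })
}

#' Pooled prediction metrics
#'
#' Flattens truth and prediction matrices across all (condition, response)
#' entries and returns the Pearson correlation and mean absolute error —
#' the pooled convention used for prediction scatter plots.
#'
#' @param truth,pred numeric matrices of identical shape (at least 2
#'   entries).
#' @return A list with `pearson_r`, `mae`, `n` (number of pooled entries).
#' @export
evaluate_predictions <- function(truth, pred) {
  truth <- as.numeric(as_numeric_matrix(as.matrix(truth), "truth"))
  pred_m <- as_numeric_matrix(as.matrix(pred), "pred")
  if (length(truth) != length(pred_m)) {
    stop("truth and pred must have the same shape", call. = FALSE)
  }
  pred <- as.numeric(pred_m)
  if (length(truth) < 2L) stop("need at least 2 entries", call. = FALSE)
  if (stats::sd(truth) == 0) {
    stop("truth is constant; correlation undefined", call. = FALSE)
  }
  list(pearson_r = stats::cor(truth, pred),
       mae = mean(abs(truth - pred)),
       n = length(truth))
}

#' Run the six-panel simulation benchmark
#'
#' Generates data from the benchmark SEM ([benchmark_sem()], all-pairs design,
#' noise sd 0.1), then fits and evaluates LR and CSR under three settings:
#'
#' * **RF** — random 2/3 training, 1/3 test; both estimators see every drug.
#' * **RF, misspecified B** — same split; CSR is fit with [misspecify_b()]
#'   applied to B (two-target strengths doubled to 1), while LR is reused
#'   unchanged since it never uses B.
#' * **LODO** — for each test condition one of its two drugs is held out at
#'   random ([lodo_per_condition()]); both estimators are refit per test
#'   condition on the reduced training set, LR with the held-out drug's
#'   coefficient forced to zero.
#'
#' @param seed master integer seed; split, noise, and drug selections derive
#'   from it via [derive_seed()].
#' @param sem generating SEM (default [benchmark_sem()]).
#' @param train_frac training fraction (default 2/3).
#' @return A list of class `eval_result` with `summary` (one row per
#'   estimator x setting: pearson_r, mae, n_test), `predictions`
#'   (long data.frame: condition_id, response, truth, prediction, split,
#'   estimator), `per_response` (per-response correlations), and
#'   `networks` (estimated structure matrices per setting, plus the truth).
#' @export
run_benchmark_experiment <- function(seed, sem = benchmark_sem(), train_frac = 2 / 3) {
  design <- all_pairs_design(length(sem$drug_names), sem$drug_names)
  data <- simulate(sem, seed = derive_seed(seed, 1), design = design)
  split <- random_fold_split(data, train_frac, seed = derive_seed(seed, 2))
  train <- subset_conditions(data, split$train_ids)
  test <- subset_conditions(data, split$test_ids)

  lr_fit <- fit_lr(train)
  csr_fit <- fit_csr(train, B = sem$B)
  csr_bad <- fit_csr(train, B = misspecify_b(sem$B))

  panels <- list(
    list(split = "RF", estimator = "LR",
         pred = predict(lr_fit, test$D), A_hat = NULL),
    list(split = "RF", estimator = "CSR",
         pred = predict(csr_fit, test$D), A_hat = csr_fit$A_hat),
    list(split = "RF-misspecified-B", estimator = "LR",
         pred = predict(lr_fit, test$D), A_hat = NULL),
    list(split = "RF-misspecified-B", estimator = "CSR",
         pred = predict(csr_bad, test$D), A_hat = csr_bad$A_hat))

  # LODO: per-test-condition refits on the reduced training sets
  assignments <- lodo_per_condition(data, split, seed = derive_seed(seed, 3))
  lodo_pred <- list(LR = NULL, CSR = NULL)
  lodo_A <- NULL
  for (est in c("LR", "CSR")) {
    preds <- matrix(NA_real_, length(assignments),
                    length(sem$response_names),
                    dimnames = list(vapply(assignments, `[[`, "", "test_id"),
                                    sem$response_names))
    for (a in assignments) {
      sub <- subset_conditions(data, a$train_ids)
      D_te <- data$D[a$test_id, , drop = FALSE]
      preds[a$test_id, ] <- if (est == "LR") {
        predict(fit_lr(sub, zeroed_drugs = a$held_out_drug), D_te)
      } else {
        fit <- fit_csr(sub, B = sem$B)
        if (est == "CSR" && is.null(lodo_A)) lodo_A <- fit$A_hat
        predict(fit, D_te)
      }
    }
    lodo_pred[[est]] <- preds
  }
  panels <- c(panels,
              list(list(split = "LODO", estimator = "LR",
                        pred = lodo_pred$LR, A_hat = NULL),
                   list(split = "LODO", estimator = "CSR",
                        pred = lodo_pred$CSR, A_hat = lodo_A)))

  summary_rows <- list()
  pred_rows <- list()
  per_resp_rows <- list()
  for (pn in panels) {
    truth <- data$X[rownames(pn$pred), , drop = FALSE]
    m <- evaluate_predictions(truth, pn$pred)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      estimator = pn$estimator, split = pn$split,
      pearson_r = m$pearson_r, mae = m$mae, n_test = nrow(pn$pred),
      stringsAsFactors = FALSE)
    pred_rows[[length(pred_rows) + 1L]] <- data.frame(
      condition_id = rep(rownames(pn$pred), ncol(pn$pred)),
      response = rep(colnames(pn$pred), each = nrow(pn$pred)),
      truth = as.numeric(truth), prediction = as.numeric(pn$pred),
      split = pn$split, estimator = pn$estimator, stringsAsFactors = FALSE)
    rs <- vapply(seq_len(ncol(truth)), function(j) {
      stats::cor(truth[, j], pn$pred[, j])
    }, numeric(1))
    per_resp_rows[[length(per_resp_rows) + 1L]] <- data.frame(
      estimator = pn$estimator, split = pn$split,
      response = colnames(truth), pearson_r = rs, stringsAsFactors = FALSE)
  }
  networks <- list(truth = sem$A,
                   RF = csr_fit$A_hat,
                   `RF-misspecified-B` = csr_bad$A_hat,
                   LODO = lodo_A)
  structure(list(summary = do.call(rbind, summary_rows),
                 predictions = do.call(rbind, pred_rows),
                 per_response = do.call(rbind, per_resp_rows),
                 networks = networks,
                 seed = seed),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat("Evaluation summary (pooled over test conditions and responses):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Repeated random-fold validation with prediction averaging
#'
#' The repeated-random-fold protocol: split the conditions
#' `train_frac`/`1 - train_frac`, fit, predict the test conditions; repeat
#' `reps` times and average the predictions for each (condition, response)
#' cell across the runs in which that condition fell in the test set;
#' finally score the averaged predictions against the truth with pooled
#' Pearson correlation and MAE.
#'
#' @param data a [perturbation_dataset()].
#' @param fit_fun function(train_data) returning a fitted model.
#' @param predict_fun function(model, D) returning predictions.
#' @param train_frac training fraction (default 0.7).
#' @param reps number of repetitions (default 1000).
#' @param seed master seed; repetition r uses `derive_seed(seed, r)`.
#' @return A list with `pearson_r`, `mae`, `n`, `mean_prediction` (the
#'   averaged prediction matrix), `times_tested` (per-condition counts).
#' @export
run_rf_protocol <- function(data, fit_fun, predict_fun = predict,
                            train_frac = 0.7, reps = 1000, seed = 1) {
  stopifnot(inherits(data, "perturbation_dataset"))
  n <- length(data$condition_ids)
  p <- length(data$response_names)
  pred_sum <- matrix(0, n, p,
                     dimnames = list(data$condition_ids, data$response_names))
  times_tested <- stats::setNames(integer(n), data$condition_ids)
  for (r in seq_len(reps)) {
    split <- random_fold_split(data, train_frac, seed = derive_seed(seed, r))
    fit <- fit_fun(subset_conditions(data, split$train_ids))
    pred <- predict_fun(fit, data$D[split$test_ids, , drop = FALSE])
    pred_sum[split$test_ids, ] <- pred_sum[split$test_ids, ] + pred
    times_tested[split$test_ids] <- times_tested[split$test_ids] + 1L
  }
  seen <- times_tested > 0
  mean_pred <- pred_sum[seen, , drop = FALSE] / times_tested[seen]
  m <- evaluate_predictions(data$X[seen, , drop = FALSE], mean_pred)
  list(pearson_r = m$pearson_r, mae = m$mae, n = m$n,
       mean_prediction = mean_pred, times_tested = times_tested)
}
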