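# Training loop behavior, metric identities, pipeline artifacts.

small_cfg <- function(n_classes = 2, dropout = 0.2, seed = 42) {
  model_config(n_classes = n_classes, tcn_channels = c(8, 8, 8),
               dropout = dropout, seed = seed)
}

test_that("training records one history entry per epoch and is reproducible", {
  ds <- make_binary_dataset(n_per_class = 3, t_len = 20, duration = 0.7)
  tc <- train_config(batch_size = 4, epochs = 3, seed = 5)
  fit1 <- train_model(ds, small_cfg(), tc)
  expect_equal(nrow(fit1$history), 3)
  expect_identical(fit1$history$epoch, 1:3)
  expect_true(all(is.finite(fit1$history$loss)))
  fit2 <- train_model(ds, small_cfg(), tc)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_identical(fit1$history, fit2$history)
})

test_that("training aborts with a diagnostic on non-finite loss", {
  ds <- make_binary_dataset(n_per_class = 2, t_len = 10, duration = 0.5)
  ds$tensors[[1]]$values[1, 1] <- NaN
  expect_error(
    train_model(ds, small_cfg(), train_config(batch_size = 4, epochs = 1)),
    "epoch 1, batch 1")
})

test_that("the model overfits a small separable synthetic set within 30 epochs", {
  ds <- make_binary_dataset(n_per_class = 10, t_len = 40, duration = 1.5,
                            effect_multiplier = 2, seed = 3)
  fit <- train_model(ds, small_cfg(dropout = 0),
                     train_config(batch_size = 20, epochs = 30, seed = 2))
  expect_equal(max(fit$history$accuracy), 1)
})

test_that("evaluate reproduces its metrics from a brute-force recount", {
  ds <- make_binary_dataset(n_per_class = 4, t_len = 20, duration = 0.7,
                            seed = 6)
  m <- init_model(small_cfg())
  rep1 <- evaluate_model(m, ds)
  rep2 <- evaluate_model(m, ds)
  expect_identical(rep1$confusion, rep2$confusion) # side-effect free
  # recount from raw predictions
  preds <- rep1$predictions
  expect_equal(rep1$accuracy, 100 * mean(preds$true == preds$predicted))
  tp <- sum(preds$true == 1 & preds$predicted == 1)
  fn <- sum(preds$true == 1 & preds$predicted == 0)
  tn <- sum(preds$true == 0 & preds$predicted == 0)
  fp <- sum(preds$true == 0 & preds$predicted == 1)
  expect_equal(rep1$confusion["DEPRESSION", "DEPRESSION"], tp,
               ignore_attr = TRUE)
  if (tp + fn > 0) expect_equal(rep1$sensitivity, 100 * tp / (tp + fn))
  if (tn + fp > 0) expect_equal(rep1$specificity, 100 * tn / (tn + fp))
  expect_equal(sum(rep1$confusion), nrow(ds$items))
})

test_that("the printed binary test confusion matrix reproduces the reported rates", {
  # the unique 62-item confusion matrix consistent with 16/24 depressed and
  # 31/38 non-depressed correct
  cm <- matrix(c(31, 7, 8, 16), 2, 2, byrow = TRUE,
               dimnames = list(true = c("NON_DEPRESSION", "DEPRESSION"),
                               predicted = c("NON_DEPRESSION", "DEPRESSION")))
  met <- metrics_from_confusion(cm, "binary")
  expect_equal(round(met$accuracy, 1), 75.8)   # 47/62
  expect_equal(round(met$sensitivity, 1), 66.7) # 16/24
  expect_equal(round(met$specificity, 1), 81.6) # 31/38
})

test_that("degenerate evaluations are handled: perfect, constant, absent class", {
  perfect <- matrix(c(5, 0, 0, 5), 2, 2)
  met <- metrics_from_confusion(perfect, "binary")
  expect_equal(met$accuracy, 100)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  # all-one-class predictor on balanced data
  constant <- matrix(c(10, 0, 10, 0), 2, 2, byrow = TRUE)
  met2 <- metrics_from_confusion(constant, "binary")
  expect_equal(met2$accuracy, 50)
  expect_equal(met2$specificity, 100)
  expect_equal(met2$sensitivity, 0)
  # class absent from the test set -> undefined metric, not 0
  absent <- matrix(c(10, 0, 0, 0), 2, 2, byrow = TRUE)
  met3 <- metrics_from_confusion(absent, "binary")
  expect_true(is.na(met3$sensitivity))
  expect_true(is.na(met3$per_class_recall[2]))
})

test_that("class weighting flips the loss toward the rare class", {
  ds <- make_binary_dataset(n_per_class = 3, t_len = 10, duration = 0.5)
  # duplicate majority items to unbalance
  idx <- c(1, 1, 1, 1, 2, 4)
  ds_unb <- structure(
    list(task = "binary",
         items = dplyr::mutate(ds$items[idx, ],
                               subject_id = sprintf("u%d", seq_along(idx))),
         tensors = stats::setNames(ds$tensors[idx],
                                   sprintf("u%d", seq_along(idx))),
         class_names = ds$class_names),
    class = "labeled_dataset")
  fit <- train_model(ds_unb, small_cfg(),
                     train_config(batch_size = 6, epochs = 1, seed = 1,
                                  weight_classes = TRUE))
  expect_s3_class(fit, "kinedep_fit")
})

test_that("run_pipeline emits all artifacts and is rerun-stable", {
  cfg <- list(
    task = "binary",
    simulate = list(n_per_band = c(NONE = 8, PROBABLE = 0, MEDIUM = 8,
                                   SEVERE = 0),
                    duration = 2, effect_multiplier = 2, seed = 3),
    preprocess = list(target_T = 60),
    split = list(test_fraction = 0.25, seed = 2, stratified = TRUE),
    model = list(tcn_channels = c(8, 8, 8), seed = 1),
    train = list(epochs = 2, seed = 4)
  )
  dir1 <- withr::local_tempdir()
  res1 <- run_pipeline(cfg, out_dir = dir1)
  for (p in res1$paths) expect_true(file.exists(p))
  expect_equal(dim(res1$report$confusion), c(2, 2))
  manifest <- readr::read_csv(res1$paths$manifest, show_col_types = FALSE)
  expect_equal(nrow(manifest), 16)
  js <- jsonlite::read_json(res1$paths$report)
  expect_equal(js$accuracy, res1$report$accuracy)
  dir2 <- withr::local_tempdir()
  res2 <- run_pipeline(cfg, out_dir = dir2)
  expect_identical(res1$report$confusion, res2$report$confusion)
  expect_equal(res1$report$accuracy, res2$report$accuracy)
})

test_that("a multi-class pipeline yields a 4x4 confusion matrix and per-class recalls", {
  cfg <- list(
    task = "multi",
    simulate = list(n_per_band = c(NONE = 6, PROBABLE = 4, MEDIUM = 4,
                                   SEVERE = 4),
                    duration = 2, effect_multiplier = 2, seed = 5),
    preprocess = list(target_T = 60),
    split = list(test_fraction = 0.3, seed = 2, stratified = TRUE),
    model = list(n_classes = 4, tcn_channels = c(8, 8, 8), seed = 1),
    train = list(epochs = 2, seed = 4)
  )
  res <- run_pipeline(cfg, out_dir = withr::local_tempdir())
  expect_equal(dim(res$report$confusion), c(4, 4))
  expect_length(res$report$per_class_recall, 4)
  expect_equal(sum(res$report$confusion), res$report$n)
})

test_that("tidiers and autoplot methods return the documented shapes", {
  ds <- make_binary_dataset(n_per_class = 3, t_len = 10, duration = 0.5)
  fit <- train_model(ds, small_cfg(),
                     train_config(batch_size = 6, epochs = 2, seed = 1))
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_equal(g$n_parameters, n_parameters(fit$model))
  rep <- evaluate_model(fit, ds)
  td <- tidy(rep)
  expect_equal(nrow(td), 2)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
})
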