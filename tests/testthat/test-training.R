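# a tiny cohort where one planted code perfectly separates cases from
# controls: every cancer patient carries "Z99" well before diagnosis
separable_data <- function(n_cases = 12, n_controls = 120) {
  set.seed(73)
  pts <- list(); evs <- list()
  mk_events <- function(id, n, start, cancer = NULL) {
    dates <- sort(start + sample.int(2500, n))
    codes <- sprintf("F%02d", sample(0:19, n, replace = TRUE))
    if (!is.null(cancer)) codes[2] <- "Z99"
    data.frame(patient_id = id, date = dates, code = codes, system = "icd10")
  }
  for (i in seq_len(n_cases)) {
    id <- sprintf("case%03d", i)
    start <- d_("2000-01-01") + sample.int(1000, 1)
    cancer <- start + 2500 + sample.int(700, 1)
    pts[[length(pts) + 1]] <- data.frame(
      patient_id = id, birth_date = start - 40 * 365, sex = NA,
      end_of_data = d_("2018-12-31"), cancer_date = cancer)
    evs[[length(evs) + 1]] <- mk_events(id, 8, start, cancer)
  }
  for (i in seq_len(n_controls)) {
    id <- sprintf("ctrl%03d", i)
    start <- d_("2000-01-01") + sample.int(1000, 1)
    pts[[length(pts) + 1]] <- data.frame(
      patient_id = id, birth_date = start - 40 * 365, sex = NA,
      end_of_data = d_("2018-12-31"), cancer_date = d_(NA))
    evs[[length(evs) + 1]] <- mk_events(id, 8, start)
  }
  co <- as_cohort(do.call(rbind, pts), do.call(rbind, evs))
  prepare_trajectories(co, seed = 21)
}

test_that("zero training epochs returns the initial model, evaluated once", {
  d <- separable_data(6, 40)
  run <- train_model(d, tiny_model_config("mlp"), epochs = 0, seed = 1)
  expect_equal(nrow(run$history), 1L)
  expect_equal(run$history$epoch, 0L)
  expect_equal(run$best_epoch, 0L)
  init <- init_risk_model(tiny_model_config("mlp"), d$vocab)
  expect_equal(run$model$params, init$params)
})

test_that("training is reproducible and the best checkpoint tracks dev AUPRC", {
  d <- separable_data(6, 40)
  mc <- tiny_model_config("mlp")
  r1 <- train_model(d, mc, epochs = 3, batch_size = 16, steps_per_epoch = 8,
                    seed = 5)
  r2 <- train_model(d, mc, epochs = 3, batch_size = 16, steps_per_epoch = 8,
                    seed = 5)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$model$params, r2$model$params)
  expect_equal(r1$best_dev_auprc, max(r1$history$dev_auprc))
  expect_equal(r1$history$dev_auprc[r1$history$epoch == r1$best_epoch],
               r1$best_dev_auprc)
})

test_that("a perfectly predictive planted code is learned quickly", {
  d <- separable_data()
  # max-pooled GRU: the planted code sits early in each case history, where
  # a briefly trained final-state GRU would forget it
  mc <- tiny_model_config("gru", gru_pooling = "max")
  run <- train_model(d, mc, lr = 1e-2, epochs = 20, batch_size = 16,
                     steps_per_epoch = 10, patience = 20, seed = 2)
  expect_gte(run$best_dev_auprc, 0.9)
  # training reduced the loss from its starting level
  h <- run$history[!is.na(run$history$train_loss)]
  expect_lt(utils::tail(h$train_loss, 1), h$train_loss[1])
})

test_that("grid search ranks by dev AUPRC and survives failing runs", {
  d <- separable_data(6, 40)
  g1 <- tiny_model_config("mlp")
  sr <- hyperparameter_search(list(g1), d, epochs = 1, batch_size = 8,
                              steps_per_epoch = 4, seed = 3)
  expect_equal(nrow(sr$ranking), 1L)
  expect_equal(sr$ranking$rank, 1L)

  # duplicate configs with the same seed tie exactly
  sr2 <- hyperparameter_search(list(g1, g1), d, epochs = 1, batch_size = 8,
                               steps_per_epoch = 4, seed = 3)
  expect_equal(sr2$ranking$dev_auprc[1], sr2$ranking$dev_auprc[2])

  # an absurd regularizer collapses the model below a moderate one
  g_mod <- tiny_model_config("mlp", lambda2 = 1e-4)
  g_huge <- tiny_model_config("mlp", lambda2 = 50)
  sr3 <- hyperparameter_search(list(g_huge, g_mod), d, lr = 5e-3, epochs = 6,
                               batch_size = 16, steps_per_epoch = 8,
                               patience = 10, seed = 2)
  expect_equal(sr3$ranking$grid_index[1], 2L)
  expect_error(hyperparameter_search(list(), d), "empty grid")
})
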