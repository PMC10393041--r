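test_that("error metrics match hand-computed values", {
  expect_equal(mae(c(100, 110), c(100, 110)), 0)
  expect_equal(mape(c(100, 110), c(100, 110)), 0)
  expect_equal(rmse(c(100, 110), c(100, 110)), 0)

  Y <- c(100, 110); Yh <- c(90, 120)
  expect_equal(mae(Y, Yh), 10)
  expect_equal(rmse(Y, Yh), 10)
  expect_equal(mape(Y, Yh), (0.1 + 10 / 110) / 2)

  # constant error e: MAE = RMSE = |e|
  x <- runif(20, 80, 200)
  expect_equal(mae(x, x + 7), 7)
  expect_equal(rmse(x, x + 7), 7)

  expect_error(mape(c(0, 1), c(1, 1)), "zero actual")
  expect_equal(mape(c(0, 1), c(1, 1), eps = 1e-6), mean(c(1 / 1e-6, 0)))
  expect_error(mae(1:3, 1:4), "shape")
})

test_that("pearson matches the textbook formula", {
  y <- c(1, 3, 2, 5)
  expect_equal(pearson(y, y), 1)
  expect_equal(pearson(y, -y + 10), -1)
  yh <- c(2, 2, 4, 4)
  num <- sum((y - mean(y)) * (yh - mean(yh)))
  den <- sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(pearson(y, yh), num / den)
  expect_error(pearson(c(1, 1), c(1, 2)), "variance")
  expect_error(pearson(1, 1), "2 points")
})

test_that("RMSE >= MAE on random evaluations (Jensen)", {
  withr::with_seed(21, {
    for (i in 1:20) {
      y <- runif(50, 60, 300)
      yh <- y + rnorm(50, 0, 15)
      expect_gte(rmse(y, yh), mae(y, yh))
    }
  })
})

fit_tiny <- function(seed = 1L, epochs = 4L, lr = 0.03, ...) {
  rec <- tiny_cohort(n = 5, lmin = 50, lmax = 80, seed = 2)
  al <- align_cohort(rec, 6, 2, 10)
  g <- cohort_srgraph(rec, 2, 10, 6)
  cfg <- tiny_config(...)
  ts <- train_spec(epochs = epochs, learning_rate = lr, batch_size = 8,
                   seed = seed)
  list(fit = heter_train(al$train, g, cfg, ts), al = al, g = g, cfg = cfg)
}

test_that("training is seed-deterministic and lr=0 is a no-op", {
  a <- fit_tiny(seed = 5)
  b <- fit_tiny(seed = 5)
  expect_identical(a$fit$loss_history, b$fit$loss_history)
  expect_identical(a$fit$params, b$fit$params)

  z <- fit_tiny(seed = 5, lr = 0)
  init <- heter_init_params({c <- z$cfg; c$seed <- 5L; c}, 5)
  expect_identical(z$fit$params, init)
  expect_equal(diff(range(z$fit$loss_history)), 0)  # flat loss, no dropout
})

test_that("training reduces the loss and evaluation is deterministic", {
  a <- fit_tiny(seed = 3, epochs = 8)
  expect_lt(tail(a$fit$loss_history, 1), a$fit$loss_history[1])
  r1 <- heter_evaluate(a$fit$params, a$al$test, a$g, a$al$norm_params, a$cfg)
  r2 <- heter_evaluate(a$fit$params, a$al$test, a$g, a$al$norm_params, a$cfg)
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$metrics, r2$metrics)
  expect_gte(r1$metrics$RMSE, r1$metrics$MAE)
  expect_equal(nrow(r1$per_horizon), a$cfg$horizon)
  expect_true(all(is.finite(unlist(r1$metrics))))
})

test_that("metrics are invariant to sample ordering", {
  a <- fit_tiny(seed = 6, epochs = 2)
  res <- heter_evaluate(a$fit$params, a$al$test, a$g, a$al$norm_params, a$cfg)
  # recompute metrics after permuting the flattened points
  perm <- sample(length(res$actuals))
  expect_equal(mae(res$actuals[perm], res$predictions[perm]), res$metrics$MAE)
  expect_equal(rmse(res$actuals[perm], res$predictions[perm]), res$metrics$RMSE)
})

test_that("persistence baseline repeats the last observation", {
  # constant series -> zero error (build a 2-sample aligned test set by hand)
  mk <- function(id, vals) segment_series(vals, 3, 1, record_id = id)
  flat <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  ramp <- (1:6) / 6
  al <- ssr_align(list(mk("a", flat), mk("b", ramp)),
                  norm_params = list(a = list(min = 100, max = 200),
                                     b = list(min = 60, max = 120)),
                  role = "test")
  pb <- persistence_baseline(al, al$norm_params, 1)
  # sample "a" is constant: its per-sample error is exactly zero
  expect_equal(pb$predictions[, 1, ], pb$actuals[, 1, ])
  # sample "b" is a ramp with slope 1/6 in normalized units, scale 60 mg/dL:
  # persistence is off by one step everywhere -> MAE = 10 on that sample
  expect_equal(abs(pb$predictions[, 2, ] - pb$actuals[, 2, ]),
               rep(60 / 6, 3))
  # evaluated identically to heter_evaluate (same metric path)
  expect_gte(pb$metrics$RMSE, pb$metrics$MAE)
})

test_that("denormalized constant 0/1 predictions hit each sample's min/max", {
  rec <- tiny_cohort(n = 3, lmin = 40, lmax = 60, seed = 8)
  al <- align_cohort(rec, 4, 1, 8)
  d <- dim(al$test$X)
  zero <- array(0, c(d[1], d[2], 1))
  one <- array(1, c(d[1], d[2], 1))
  r0 <- hetercgm:::new_prediction_result(zero, al$test, al$norm_params, "const")
  r1 <- hetercgm:::new_prediction_result(one, al$test, al$norm_params, "const")
  ids <- al$test$sample_order
  for (n in seq_len(d[2])) {
    expect_equal(unique(as.numeric(r0$predictions[, n, ])),
                 al$norm_params[[ids[n]]]$min)
    expect_equal(unique(as.numeric(r1$predictions[, n, ])),
                 al$norm_params[[ids[n]]]$max)
  }
})

test_that("grid search picks the lower-validation-MAE config", {
  rec <- tiny_cohort(n = 5, lmin = 50, lmax = 80, seed = 12)
  al <- align_cohort(rec, 6, 1, 10)
  g <- cohort_srgraph(rec, 2, 10, 6)
  cfg <- tiny_config(horizon = 1L)
  ts <- train_spec(epochs = 3, learning_rate = 0.03, batch_size = 8, seed = 1)
  # single-point grid returns that config
  g1 <- grid_search(list(list(gru_hidden = 3L)), list(train = al$train,
                    norm_params = al$norm_params), g, ts, cfg)
  expect_equal(g1$best_index, 1)
  expect_equal(g1$best_config$gru_hidden, 3L)
  expect_equal(nrow(g1$results), 1)

  g2 <- grid_search(list(list(gru_hidden = 4L), list(gru_hidden = 2L)),
                    list(train = al$train, norm_params = al$norm_params),
                    g, ts, cfg)
  expect_equal(nrow(g2$results), 2)
  expect_equal(g2$best_index, which.min(g2$results$MAE))
  expect_error(grid_search(list(), NULL, g, ts, cfg), "empty grid")
})

test_that("horizon-minutes map to steps only when divisible", {
  expect_equal(horizon_to_steps(15, 15), 1L)
  expect_equal(horizon_to_steps(30, 15), 2L)
  expect_equal(horizon_to_steps(60, 15), 4L)
  expect_error(horizon_to_steps(20, 15), "not divisible")
})

test_that("sensitivity sweep validates K and repeats deterministically", {
  rec <- tiny_cohort(n = 5, lmin = 50, lmax = 70, seed = 13)
  cfg <- tiny_config(horizon = 1L)
  ts <- train_spec(epochs = 2, learning_rate = 0.03, batch_size = 8, seed = 2)
  tab <- sensitivity_sweep("T", c(4L), rec, cfg, ts, test_points = 8)
  expect_equal(nrow(tab), 1)
  tab2 <- sensitivity_sweep("T", c(4L, 4L), rec, cfg, ts, test_points = 8)
  expect_equal(tab2[1, -1], tab2[2, -1], ignore_attr = TRUE)
  expect_error(sensitivity_sweep("K", c(2L, 5L), rec, cfg, ts, 8), "K must be")
  expect_error(sensitivity_sweep("T", integer(0), rec, cfg, ts, 8), "no values")
})
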