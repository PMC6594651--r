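test_that("EER threshold equals an exhaustive candidate scan", {
  brute_eer <- function(s, y, gamma = 2) {
    u <- sort(unique(s))
    cand <- sort(unique(c(u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2)))
    cost <- vapply(cand, function(th) {
      tp <- sum(s >= th & y == 1)
      recall <- tp / sum(y == 1)
      precision <- if (sum(s >= th) > 0) tp / sum(s >= th) else 0
      abs(1 - recall) + gamma * abs(1 - precision)
    }, numeric(1))
    cand[which(cost == min(cost))[1]]
  }
  # perfectly separated: cost 0 anywhere in the gap; smallest candidate wins
  th <- select_threshold_eer(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(as.numeric(th), 0.55)   # midpoint 0.3/0.8 is smallest zero-cost
  expect_equal(attr(th, "cost"), 0)

  set.seed(14)
  for (i in 1:50) {
    n <- sample(6:50, 1)
    s <- round(runif(n), 2)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    g <- sample(c(0.5, 1, 2, 4), 1)
    expect_equal(as.numeric(select_threshold_eer(s, y, gamma = g)),
                 brute_eer(s, y, g))
  }
})

test_that("gamma to zero pushes the threshold to maximal recall", {
  s <- c(0.9, 0.6, 0.4, 0.2); y <- c(1, 0, 1, 0)
  th <- select_threshold_eer(s, y, gamma = 1e-9)
  expect_lte(as.numeric(th), min(s[y == 1]))
  expect_error(select_threshold_eer(s, rep(1, 4)), "both classes")
})

test_that("the literal-formula flag reproduces the degenerate objective", {
  s <- c(0.9, 0.8, 0.3, 0.2); y <- c(1, 1, 0, 0)
  lit <- select_threshold_eer(s, y, literal_formula = TRUE)
  # the minus-sign objective rewards bad precision, driving theta low
  expect_lte(as.numeric(lit), 0.2)
})

test_that("training is reproducible, checkpointed, and mode-safe", {
  ds <- tiny_dataset()
  pairs <- ds$pairs
  set.seed(20)
  idx <- sample(nrow(pairs), 18)
  mk <- function(p) interaction_dataset(p, ds$proteins, ds$drugs)
  train <- mk(pairs[-idx, ]); val <- mk(pairs[idx, ])
  cfg <- tiny_config(epochs = 3L, spatial_dropout_rate = 0.2)

  fit1 <- train_dti(train, val, cfg, seed = 31)
  fit2 <- train_dti(train, val, cfg, seed = 31)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
  expect_equal(nrow(fit1$history), 3)
  expect_equal(fit1$best_epoch, which.max(fit1$history$val_aupr))

  # restored snapshot reproduces the recorded best validation AUPR
  expect_equal(aupr(fit1$val_scores, fit1$val_labels),
               max(fit1$history$val_aupr), tolerance = 1e-12)

  # no training-mode leakage at inference: two passes identical
  p1 <- predict_dti(fit1, val); p2 <- predict_dti(fit1, val)
  expect_identical(p1, p2)
  expect_true(all(p1$score > 0 & p1$score < 1))

  # zero epochs: initial state, empty history
  fit0 <- train_dti(train, val, tiny_config(epochs = 0L), seed = 31)
  expect_equal(nrow(fit0$history), 0)
  expect_identical(fit0$model$params,
                   init_dti_model(tiny_config(epochs = 0L),
                                  seed = convdti:::child_seed(31, 1))$params)

  # single-class validation is an explicit error
  val1 <- mk(dplyr::mutate(val$pairs, label = 1))
  expect_error(train_dti(train, val1, cfg), "single class")
})

test_that("grid search logs every cell and selects by validation AUPR", {
  ds <- tiny_dataset()
  set.seed(21)
  idx <- sample(nrow(ds$pairs), 18)
  mk <- function(p) interaction_dataset(p, ds$proteins, ds$drugs)
  train <- mk(ds$pairs[-idx, ]); val <- mk(ds$pairs[idx, ])
  base <- tiny_config(epochs = 1L)

  single <- grid_search_dti(list(filters_per_window = 3L), train, val,
                            base_config = base, seed = 5)
  expect_equal(nrow(single$results), 1)
  expect_equal(single$best_config$filters_per_window, 3L)

  grid <- grid_search_dti(list(filters_per_window = c(2L, 4L),
                               embedding_size = c(4L, 6L)),
                          train, val, base_config = base, seed = 5)
  expect_equal(nrow(grid$results), 4)   # full Cartesian product logged
  expect_equal(grid$results$val_aupr[grid$best_index],
               max(grid$results$val_aupr))
  expect_s3_class(tidy(grid), "tbl_df")
  expect_equal(glance(grid)$n_cells, 4)
  expect_error(grid_search_dti(list(), train, val), "non-empty")
})
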