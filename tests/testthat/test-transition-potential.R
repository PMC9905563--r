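test_that("skill measure hits its anchor points exactly", {
  expect_equal(skill_measure(1, 4), 1)
  expect_equal(skill_measure(0.25, 4), 0)
  expect_lt(skill_measure(0.1, 4), 0)
  expect_equal(skill_measure(1, 2), 1)
  # the published pastures -> grasslands transition: AR 98.2%, SM ~0.96
  expect_equal(skill_measure(0.982, 2), 0.964, tolerance = 1e-12)
  expect_error(skill_measure(0.5, 1), "n_outcome_classes")
  expect_error(skill_measure(1.2, 2), "accuracy")
})

test_that("training sampling is balanced, deterministic, and validates", {
  land <- default_land()
  specs <- data.frame(from = "forest", to = "fragmented vegetation",
                      submodel = "degradation", area_ha = 1)
  ts1 <- sample_training(land$map_t0, land$map_t1, specs, land$drivers,
                         n_per_class = 100, seed = 5)
  ts2 <- sample_training(land$map_t0, land$map_t1, specs, land$drivers,
                         n_per_class = 100, seed = 5)
  expect_identical(ts1, ts2)
  expect_equal(as.vector(table(ts1$labels)), c(100, 100))
  expect_equal(as.vector(table(ts1$split)), c(100, 100))
  expect_true(all(ts1$features >= 0 & ts1$features <= 1))
  # a transition with zero changed cells is an error naming the transition
  bad <- data.frame(from = "water", to = "forest", submodel = "x", area_ha = 1)
  expect_error(sample_training(land$map_t0, land$map_t1, bad, land$drivers,
                               10, 1), "water -> forest")
})

test_that("the MLP separates linearly separable classes", {
  set.seed(42)
  n <- 200
  feats <- rbind(cbind(stats::rnorm(n, 0, 0.5), stats::rnorm(n, 0, 0.5)),
                 cbind(stats::rnorm(n, 4, 0.5), stats::rnorm(n, 4, 0.5)))
  colnames(feats) <- c("f1", "f2")
  ts <- toy_training_set(feats, rep(c("persist", "change"), each = n))
  fit <- train_mlp(ts, hidden_size = 3, learning_rate = 0.5, momentum = 0.9,
                   epochs = 2000, seed = 1)
  expect_gte(fit$stats$accuracy_rate, 95)
  expect_gte(fit$stats$skill_measure, 0.9)
})

test_that("shuffled labels give chance-level skill", {
  set.seed(9)
  feats <- cbind(f1 = stats::runif(400), f2 = stats::runif(400))
  ts <- toy_training_set(feats, sample(rep(c("a", "b"), 200)))
  fit <- train_mlp(ts, hidden_size = 3, learning_rate = 0.5, momentum = 0.9,
                   epochs = 1000, seed = 1)
  expect_lt(abs(fit$stats$skill_measure), 0.1)
})

test_that("a hidden layer solves the XOR pattern", {
  set.seed(12)
  n <- 100
  corners <- expand.grid(a = c(0, 1), b = c(0, 1))
  idx <- rep(1:4, each = n)
  feats <- as.matrix(corners[idx, ]) + matrix(stats::rnorm(8 * n, 0, 0.08),
                                              ncol = 2)
  colnames(feats) <- c("f1", "f2")
  labels <- ifelse(xor(corners$a[idx] == 1, corners$b[idx] == 1),
                   "change", "persist")
  ts <- toy_training_set(feats, labels)
  fit <- train_mlp(ts, hidden_size = 4, learning_rate = 0.5, momentum = 0.9,
                   epochs = 4000, patience = 4000, seed = 2)
  expect_gte(fit$stats$accuracy_rate, 90)
  expect_error(train_mlp(ts, hidden_size = 0), "hidden_size")
})

test_that("training is deterministic under a fixed seed", {
  set.seed(31)
  feats <- cbind(f1 = stats::runif(100), f2 = stats::runif(100))
  ts <- toy_training_set(feats, rep(c("a", "b"), 50))
  f1 <- train_mlp(ts, learning_rate = 0.3, epochs = 300, seed = 7)
  f2 <- train_mlp(ts, learning_rate = 0.3, epochs = 300, seed = 7)
  expect_identical(f1$model$w1, f2$model$w1)
  expect_identical(f1$stats, f2$stats)
})

test_that("potential predictions stay in [0, 1] and respect monotone links", {
  set.seed(8)
  x <- stats::runif(600)
  labels <- ifelse(stats::runif(600) < lulcsim:::sigmoid(4 * x - 2),
                   "change", "persist")
  ts <- toy_training_set(cbind(drv = x), labels)
  fit <- train_mlp(ts, hidden_size = 2, learning_rate = 0.5, momentum = 0.9,
                   epochs = 3000, seed = 3)
  grid <- driver_layer("drv", matrix(seq(0, 1, length.out = 121), 11),
                       kind = "static")
  pot <- predict_potential(fit$model, list(grid), "change")
  expect_true(all(pot$values >= 0 & pot$values <= 1))
  # rank agreement with the generating logistic rule on a held-out grid
  truth <- lulcsim:::sigmoid(4 * grid$values - 2)
  expect_gte(stats::cor(as.vector(pot$values), as.vector(truth),
                        method = "spearman"), 0.9)
  expect_error(predict_potential(fit$model, list(), "change"), "missing driver")
})

test_that("all-zero weights yield a uniform 0.5 potential", {
  set.seed(1)
  ts <- toy_training_set(cbind(drv = stats::runif(40)), rep(c("a", "b"), 20))
  fit <- train_mlp(ts, hidden_size = 2, epochs = 1, seed = 1)
  fit$model$w1[] <- 0
  fit$model$w2[] <- 0
  grid <- driver_layer("drv", matrix(stats::runif(25), 5), kind = "static")
  expect_equal(predict_potential(fit$model, list(grid), "a")$values,
               matrix(0.5, 5, 5))
})

test_that("model JSON serialization round trips", {
  set.seed(2)
  ts <- toy_training_set(cbind(drv = stats::runif(60), z = stats::runif(60)),
                         rep(c("a", "b"), 30))
  fit <- train_mlp(ts, hidden_size = 2, epochs = 50, seed = 4)
  f <- withr::local_tempfile(fileext = ".json")
  write_mlp(fit$model, f)
  m2 <- read_mlp(f)
  expect_equal(m2$w1, fit$model$w1)
  expect_equal(m2$w2, fit$model$w2)
  expect_equal(m2$ranges, fit$model$ranges)
  grid <- list(driver_layer("drv", matrix(stats::runif(9), 3), "static"),
               driver_layer("z", matrix(stats::runif(9), 3), "static"))
  expect_equal(predict_potential(m2, grid, "a")$values,
               predict_potential(fit$model, grid, "a")$values)
})

test_that("an independent optimiser agrees on a separable problem", {
  skip_if_not_installed("nnet")
  set.seed(14)
  n <- 150
  feats <- rbind(cbind(stats::rnorm(n, 0, 0.6), stats::rnorm(n, 0, 0.6)),
                 cbind(stats::rnorm(n, 3, 0.6), stats::rnorm(n, 3, 0.6)))
  colnames(feats) <- c("f1", "f2")
  labels <- rep(c(0, 1), each = n)
  ts <- toy_training_set(feats, ifelse(labels == 1, "change", "persist"))
  fit <- train_mlp(ts, hidden_size = 3, learning_rate = 0.5, momentum = 0.9,
                   epochs = 2000, seed = 1)
  ref <- nnet::nnet(ts$features[ts$split == "train", ],
                    labels[ts$split == "train"], size = 3, trace = FALSE)
  ref_acc <- mean((stats::predict(ref, ts$features[ts$split == "test", ]) > 0.5) ==
                    labels[ts$split == "test"]) * 100
  expect_gte(fit$stats$accuracy_rate, ref_acc - 5)
})
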