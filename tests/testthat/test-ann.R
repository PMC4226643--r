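test_that("sigmoid saturates cleanly and is symmetric", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(3) + sigmoid(-3), 1)
  expect_true(all(is.finite(sigmoid(c(-1e6, -800, 800, 1e6)))))
  expect_true(all(sigmoid(c(-1e6, 1e6)) >= 0 & sigmoid(c(-1e6, 1e6)) <= 1))
  x <- seq(-5, 5, by = 0.25)
  expect_true(all(diff(sigmoid(x)) > 0))
})

test_that("analytic backprop gradients match central finite differences", {
  set.seed(61)
  worst <- 0
  for (t in 1:25) {
    Wh <- matrix(runif(15 * 5, -0.5, 0.5), 15, 5)
    bh <- runif(5, -0.5, 0.5)
    Wo <- matrix(runif(5 * 3, -0.5, 0.5), 5, 3)
    bo <- runif(3, -0.5, 0.5)
    x <- rnorm(15)
    target <- as.numeric(1:3 == sample(3, 1))
    an <- taxofeat:::mlp_gradients(x, target, Wh, bh, Wo, bo)
    fd <- oracle_fd_gradients(x, target, Wh, bh, Wo, bo)
    for (nm in c("dWh", "dbh", "dWo", "dbo")) {
      denom <- pmax(abs(fd[[nm]]), 1e-4)
      worst <- max(worst, max(abs(an[[nm]] - fd[[nm]]) / denom))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("training is bit-reproducible for a fixed seed", {
  tab <- toy_table()
  cfg <- train_config(learning_rate = 0.3, generations = 500L,
                      hidden = 4L, seed = 9L)
  m1 <- mlp_train(tab, cfg)
  m2 <- mlp_train(tab, cfg)
  expect_identical(m1, m2)
  m3 <- mlp_train(tab, train_config(0.3, 500L, 4L, seed = 10L))
  expect_false(identical(m1$Wh, m3$Wh))
})

test_that("an XOR-style toy set is learned to 100% training accuracy", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1),
             c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  M <- cbind(X, matrix(0, 8, 13))
  tab <- feature_table(M, rep(c("even", "odd", "odd", "even"), 2))
  model <- mlp_train(tab, train_config(learning_rate = 0.5,
                                       generations = 30000L,
                                       hidden = 4L, seed = 2L))
  pred <- mlp_predict(model, tab)
  expect_equal(pred, tab$species)
})

test_that("training loss decreases on linearly separable classes", {
  tab <- toy_table(n_per = 15, sep = 5)
  model <- mlp_train(tab, train_config(0.2, 6000L, 5L, seed = 4L))
  tr <- model$loss_trace
  expect_gt(length(tr), 10)
  q <- tr[round(seq(1, length(tr), length.out = 5))]
  expect_true(all(diff(q) < 0))          # decreasing across the run
  expect_lt(tr[length(tr)], 0.05 * tr[1])
})

test_that("prediction reports argmax species, binary step outputs and confidence", {
  tab <- toy_table()
  model <- mlp_train(tab, train_config(0.3, 4000L, 4L, seed = 5L))
  p <- mlp_predict(model, as.numeric(tab[1, feature_names()]))
  expect_true(p$species %in% model$label_map)
  expect_length(p$raw_outputs, 2)
  expect_true(all(p$binary_outputs %in% c(0L, 1L)))
  expect_identical(p$binary_outputs[[p$species]],
                   as.integer(p$raw_outputs[[p$species]] >= 0.5))
  # ties/low outputs: argmax is still returned, flagged unconfident
  weak <- model
  weak$Wo[] <- 0; weak$bo <- c(-5, -6)
  pw <- mlp_predict(weak, as.numeric(tab[1, feature_names()]))
  expect_identical(pw$species, weak$label_map[1])
  expect_false(pw$confident)
  expect_error(mlp_predict(model, rnorm(7)), "dimension mismatch")
})

test_that("the stored scaler makes prediction consistent with training units", {
  tab <- toy_table(sep = 6)
  model <- mlp_train(tab, train_config(0.3, 6000L, 4L, seed = 6L))
  acc <- mean(mlp_predict(model, tab) == tab$species)
  expect_equal(acc, 1)
  # features arrive raw; scaling happens inside predict via the scaler
  expect_equal(unname(model$scaler$mean[1]),
               mean(tab$A))
})

test_that("degenerate training inputs are rejected with clear errors", {
  tab <- toy_table()
  one <- tab[tab$species == "alpha", ]
  expect_error(mlp_train(one, train_config()), "at least 2 species")
  bad <- tab; bad$A[3] <- NaN
  expect_error(mlp_train(bad, train_config()), "row 3")
})

test_that("models survive the JSON container round-trip", {
  tab <- toy_table()
  model <- mlp_train(tab, train_config(0.3, 300L, 4L, seed = 8L))
  tf <- tempfile(fileext = ".json")
  write_mlp_model(model, tf)
  back <- read_mlp_model(tf)
  expect_equal(back$Wh, model$Wh, tolerance = 1e-12)
  expect_equal(back$scaler$sd, model$scaler$sd, tolerance = 1e-12)
  expect_identical(back$label_map, model$label_map)
  # identical predictions
  expect_identical(mlp_predict(back, tab), mlp_predict(model, tab))
  junk <- tempfile(fileext = ".json")
  writeLines('{"format": "something-else"}', junk)
  expect_error(read_mlp_model(junk), "not a taxofeat")
})
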