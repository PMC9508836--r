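# Classifier: configuration, forward-pass equivalence with a plain-R
# reference, gradient correctness, training schedule and checkpointing,
# hyperparameter sampling.

tiny_cfg <- function(...) {
  model_config(conv_layers = 3L, filters = 4L, se_every = 3L,
               se_ratio = 2L, l1 = 1e-3, input_shape = c(8L, 10L, 3L), ...)
}

rand_images <- function(n, shape = c(8, 10, 3), seed = 1) {
  set.seed(seed)
  array(sample(0:255, prod(shape) * n, replace = TRUE), c(shape, n))
}

test_that("configuration invariants are enforced", {
  expect_error(model_config(conv_layers = 8, se_every = 3), "divisible")
  expect_error(model_config(filters = 0), "positive")
  expect_error(training_config(max_epochs = 10, patience = 10),
               "patience")
  expect_error(training_config(learning_rate = 0), "learning_rate")
  cfg <- model_config()
  expect_identical(cfg$conv_layers, 9L)
  expect_identical(cfg$filters, 96L)
  expect_identical(c(cfg$rows, cfg$cols, cfg$channels), c(160L, 164L, 3L))
})

test_that("builds are seed-deterministic with the expected block count", {
  m1 <- build_network(tiny_cfg(), seed = 5)
  m2 <- build_network(tiny_cfg(), seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(tiny_cfg(), seed = 6)
  expect_false(identical(m3$params$head_w, m1$params$head_w))
  # 9 conv layers with SE every 3 -> exactly 3 SE blocks
  m9 <- build_network(model_config(filters = 8L), seed = 1)
  expect_length(m9$params$se_W1, 3L)
  expect_length(m1$params$se_W1, 1L)
})

test_that("SE block gates in [0,1], preserves shape, passes zeros", {
  set.seed(3)
  for (shape in list(c(4, 5, 6), c(8, 10, 3))) {
    x <- array(rnorm(prod(shape)), shape)
    r <- max(1, shape[3] %/% 2)
    W1 <- matrix(rnorm(r * shape[3]), r)
    W2 <- matrix(rnorm(shape[3] * r), shape[3])
    out <- se_block(x, W1, rnorm(r), W2, rnorm(shape[3]))
    expect_identical(dim(out$output), dim(x))
    expect_true(all(out$gates >= 0 & out$gates <= 1))
  }
  # gates forced to 1: identity mapping
  x <- array(rnorm(60), c(4, 5, 3))
  out <- se_block(x, matrix(0, 1, 3), 0, matrix(0, 3, 1), rep(30, 3))
  expect_equal(out$output, x, tolerance = 1e-10)
  # zero input -> zero output regardless of gates
  z <- se_block(array(0, c(4, 5, 3)), matrix(1, 1, 3), 0.5,
                matrix(1, 3, 1), 0)
  expect_identical(sum(abs(z$output)), 0)
})

test_that("compiled forward pass matches the plain-R reference", {
  model <- build_network(tiny_cfg(), seed = 11)
  # non-trivial BN running stats
  model$params$bn_rmean[[1]] <- rnorm(4, 0, 0.3)
  model$params$bn_rvar[[1]] <- runif(4, 0.5, 2)
  x <- rand_images(6, seed = 21)
  got <- predict(model, x)
  expect_true(all(got >= 0 & got <= 1))
  want <- vapply(1:6, function(i) ref_forward(model, x[, , , i]),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
  expect_identical(predict(model, x), got)   # deterministic
})

test_that("analytic gradients match finite differences", {
  cfg <- tiny_cfg()
  model <- build_network(cfg, seed = 3)
  x <- rand_images(4, seed = 9)
  y <- c(1, 0, 1, 0)
  cl <- trioDNM:::cnn_config_list(model)
  res <- trioDNM:::.cnn_batch_grad(model$params, cl, x, y, cfg$l1)
  sk <- model$params[trioDNM:::TRAINABLE]
  theta <- unlist(sk, use.names = FALSE)
  g <- unlist(res$grads, use.names = FALSE)
  eps <- 1e-6
  set.seed(1)
  idx <- sample(length(theta), 50)
  num <- vapply(idx, function(i) {
    pp <- model$params
    th <- theta; th[i] <- theta[i] + eps
    pp[trioDNM:::TRAINABLE] <- utils::relist(th, sk)
    lp <- trioDNM:::.cnn_batch_grad(pp, cl, x, y, cfg$l1)$loss
    th[i] <- theta[i] - eps
    pp[trioDNM:::TRAINABLE] <- utils::relist(th, sk)
    lm <- trioDNM:::.cnn_batch_grad(pp, cl, x, y, cfg$l1)$loss
    (lp - lm) / (2 * eps)
  }, numeric(1))
  rel <- abs(num - g[idx]) / pmax(abs(num) + abs(g[idx]), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("LR schedule decays stepwise from the initial rate", {
  expect_identical(lr_schedule(25, 1e-3), 2.5e-4)   # two decays
  expect_identical(lr_schedule(0, 1e-3), 1e-3)
  expect_identical(lr_schedule(9, 1e-3), 1e-3)
  expect_identical(lr_schedule(10, 1e-3), 5e-4)
  expect_identical(lr_schedule(99, 0.01, 0.5, 10), 0.01 * 0.5^9)
})

test_that("early stopping halts patience epochs after the best epoch", {
  model <- build_network(tiny_cfg(), seed = 2)
  x <- rand_images(12, seed = 4)
  y <- rep(c(0, 1), 6)
  # learning rate ~0: validation never improves after the first epoch
  fit <- train_cnn(model, x, y, x, y,
                   training_config(max_epochs = 30, patience = 5,
                                   learning_rate = 1e-30, batch_size = 6,
                                   seed = 1))
  expect_identical(fit$best_epoch, 1L)
  expect_identical(fit$stopped_epoch, 6L)
  expect_identical(nrow(fit$history), 6L)
  # history records the stepwise LR schedule
  expect_equal(fit$history$lr, rep(1e-30, 6))
})

test_that("best-validation checkpointing returns the argmin epoch", {
  model <- build_network(tiny_cfg(), seed = 7)
  x <- rand_images(20, seed = 5)
  y <- rep(c(0, 1), 10)
  fit <- train_cnn(model, x, y, x[, , , 1:8, drop = FALSE], y[1:8],
                   training_config(max_epochs = 6, patience = 5,
                                   learning_rate = 5e-3, batch_size = 10,
                                   seed = 2))
  expect_identical(fit$best_epoch, which.min(fit$history$val_loss))
  # returned parameters reproduce the best epoch's validation loss
  p <- predict(fit, x[, , , 1:8, drop = FALSE])
  expect_equal(trioDNM:::bce(p, y[1:8]), min(fit$history$val_loss),
               tolerance = 1e-12)
  expect_error(
    train_cnn(model, x[, , , 0, drop = FALSE], numeric(0), x, y,
              training_config(max_epochs = 2, patience = 1)),
    "empty")
})

test_that("a tiny set is memorized (training loss drives to ~zero)", {
  set.seed(31)
  ds <- simulate_dataset(10, class_mix = c(denovo = 0.5,
                                           inherited_father = 0.5),
                         type_mix = c(substitution = 1), seed = 31)
  enc <- encode_dataset(ds)
  cfg <- model_config(conv_layers = 3, filters = 4, se_every = 3,
                      se_ratio = 2, l1 = 0)
  model <- build_network(cfg, seed = 1)
  fit <- train_cnn(model, enc$x, enc$y, enc$x, enc$y,
                   training_config(max_epochs = 60, patience = 59,
                                   learning_rate = 1e-2, lr_every = 100L,
                                   batch_size = 10, seed = 1))
  expect_lt(min(fit$history$train_loss), 0.1)
})

test_that("warm start copies parameters and rejects shape mismatches", {
  a <- build_network(tiny_cfg(), seed = 1)
  b <- build_network(tiny_cfg(), seed = 99)
  w <- warm_start(b, a)
  expect_identical(w$params, a$params)
  other <- build_network(model_config(conv_layers = 3, filters = 8,
                                      se_every = 3,
                                      input_shape = c(8, 10, 3)), seed = 1)
  expect_error(warm_start(other, a), "shapes differ")
})

test_that("search-space draws respect bounds and log-uniform medians", {
  sp <- search_space()
  draws <- sample_search_space(sp, 1000, seed = 3)
  expect_true(all(draws$filters %in% c(32, 64, 96, 128)))
  expect_true(all(draws$batch_size %in% c(32, 64)))
  expect_true(all(draws$l1 >= 1e-10 & draws$l1 <= 0.1))
  expect_true(all(draws$learning_rate >= 1e-8 & draws$learning_rate <= 0.01))
  # log-uniform: about half the draws fall below the geometric midpoint
  mid <- sqrt(1e-8 * 0.01)
  frac <- mean(draws$learning_rate < mid)
  expect_gt(frac, 0.45)
  expect_lt(frac, 0.55)
})

test_that("random search returns the lowest-loss sampled configuration", {
  sp <- search_space()
  eval_fn <- function(cfg) abs(log10(cfg$learning_rate) + 3)  # best near 1e-3
  res <- hyperparameter_search(sp, budget = 20, eval_fn = eval_fn, seed = 8)
  expect_identical(nrow(res$results), 20L)
  expect_identical(res$best$val_loss, min(res$results$val_loss))
  one <- hyperparameter_search(sp, budget = 1, eval_fn = eval_fn, seed = 8)
  expect_identical(nrow(one$results), 1L)
  expect_error(hyperparameter_search(sp, 0, eval_fn), "budget")
})

test_that("probability threshold labels are inclusive at 0.5", {
  lab <- function(p) ifelse(p >= 0.5, "DNM", "IV")
  expect_identical(lab(0.5), "DNM")
  expect_identical(lab(0.49), "IV")
  model <- build_network(tiny_cfg(), seed = 1)
  img <- structure(rand_images(1), class = "dnm_image",
                   variant_type = "substitution")
  bank <- list(substitution = model)
  res <- classify_dnm(bank, img)
  expect_identical(res$label, lab(res$p_dnm))
  expect_identical(res$model_used, "substitution")
  attr(img, "variant_type") <- "insertion"
  expect_error(classify_dnm(bank, img), "no model")
})
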