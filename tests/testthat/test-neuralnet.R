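test_that("initialization is seeded and fan-in scaled", {
  expect_identical(init_network(c(4, 3, 3, 2), seed = 5),
                   init_network(c(4, 3, 3, 2), seed = 5))
  wide <- init_network(c(400, 50, 2), seed = 1)
  narrow <- init_network(c(4, 50, 2), seed = 1)
  expect_lt(sd(wide$W[[1]]), sd(narrow$W[[1]]))
  expect_true(all(wide$b[[1]] == 0))
  expect_error(init_network(c(4, 0, 2)), "positive")
})

test_that("forward pass conserves probability and respects softmax invariances", {
  p <- init_network(c(3, 4, 2), seed = 2)
  X <- matrix(rnorm(15), 5, 3)
  P <- nn_forward(p, X)
  expect_equal(unname(rowSums(P)), rep(1, 5))
  expect_true(all(P > 0 & P < 1))

  # zero network: both classes equally likely
  p0 <- p
  for (l in seq_along(p0$W)) { p0$W[[l]][] <- 0; p0$b[[l]][] <- 0 }
  expect_equal(unname(nn_forward(p0, X)), matrix(0.5, 5, 2))

  # shifting both output logits by a constant changes nothing
  p_shift <- p
  p_shift$b[[2]] <- p_shift$b[[2]] + 7.3
  expect_equal(nn_forward(p_shift, X), P, tolerance = 1e-12)

  expect_error(nn_forward(p, matrix(c(1, NA, 1), 1, 3)), "non-finite")
  expect_error(nn_forward(p, matrix(1, 1, 2)), "expects 3")
})

test_that("a tiny network reproduces hand-computed probabilities", {
  p <- init_network(c(2, 2, 2), seed = 1)
  p$W[[1]] <- matrix(c(1, 0.5, -1, 2), 2, 2)
  p$b[[1]] <- c(0.1, -0.2)
  p$W[[2]] <- matrix(c(0.3, -0.7, 1.1, 0.4), 2, 2)
  p$b[[2]] <- c(0, 0.25)
  x <- c(0.8, -0.4)
  h <- pmax(c(x %*% p$W[[1]]) + p$b[[1]], 0)
  logits <- c(h %*% p$W[[2]]) + p$b[[2]]
  expected <- exp(logits) / sum(exp(logits))
  expect_equal(unname(nn_forward(p, matrix(x, 1, 2))[1, ]), expected,
               tolerance = 1e-12)
})

test_that("cross-entropy hits its closed-form anchors", {
  p <- init_network(c(2, 2, 2), seed = 1)
  for (l in 1:2) { p$W[[l]][] <- 0; p$b[[l]][] <- 0 }
  X <- matrix(rnorm(8), 4, 2)
  y <- c("DVT", "PE", "DVT", "PE")
  expect_equal(nn_loss_grad(p, X, y)$loss, log(2))  # uniform prediction

  p$b[[2]] <- c(50, 0)  # near-certain DVT
  expect_lt(nn_loss_grad(p, X, rep("DVT", 4))$loss, 1e-12)
  expect_error(nn_loss_grad(p, X[0, , drop = FALSE], character(0)), "empty")
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(11, {
    p <- init_network(c(4, 3, 3, 2), seed = 3)
    # generic biases keep every pre-activation away from the ReLU kink,
    # where the loss is not differentiable and finite differences disagree
    for (l in seq_along(p$b)) p$b[[l]] <- rnorm(length(p$b[[l]]), sd = 0.3)
    X <- matrix(rnorm(24), 6, 4)
    y <- sample(c("DVT", "PE"), 6, replace = TRUE)
  })
  lg <- nn_loss_grad(p, X, y)
  eps <- 1e-6
  for (l in seq_along(p$W)) {
    for (idx in seq_len(length(p$W[[l]]))) {
      pp <- p; pp$W[[l]][idx] <- pp$W[[l]][idx] + eps
      pm <- p; pm$W[[l]][idx] <- pm$W[[l]][idx] - eps
      fd <- (nn_loss_grad(pp, X, y)$loss - nn_loss_grad(pm, X, y)$loss) / (2 * eps)
      g <- lg$grads$W[[l]][idx]
      expect_lt(abs(fd - g) / max(abs(fd), abs(g), 1e-8), 1e-5)
    }
    for (idx in seq_along(p$b[[l]])) {
      pp <- p; pp$b[[l]][idx] <- pp$b[[l]][idx] + eps
      pm <- p; pm$b[[l]][idx] <- pm$b[[l]][idx] - eps
      fd <- (nn_loss_grad(pp, X, y)$loss - nn_loss_grad(pm, X, y)$loss) / (2 * eps)
      g <- lg$grads$b[[l]][idx]
      expect_lt(abs(fd - g) / max(abs(fd), abs(g), 1e-8), 1e-5)
    }
  }
})

test_that("SGD separates separable data and is seed-deterministic", {
  bd <- blob_data(n_dvt = 40, n_pe = 40, sep = 4, seed = 4)
  cfg <- train_config(max_epochs = 150, patience = 15, hidden_dims = 8,
                      seed = 6)
  fit <- sgd_fit(init_network(c(2, 8, 2), seed = 1), bd$X, bd$y, cfg)
  expect_equal(evaluate(fit$params, bd$X, bd$y)$auc, 1)
  # running minimum of training loss is monotone non-increasing
  expect_true(all(diff(cummin(fit$history$train_loss)) <= 1e-12))

  fit2 <- sgd_fit(init_network(c(2, 8, 2), seed = 1), bd$X, bd$y, cfg)
  expect_identical(fit$history, fit2$history)
})

test_that("patience 0 stops exactly one epoch past the best", {
  bd <- blob_data(n_dvt = 30, n_pe = 30, sep = 1, seed = 5)
  cfg <- train_config(max_epochs = 500, patience = 0, hidden_dims = 4,
                      seed = 2)
  fit <- sgd_fit(init_network(c(2, 4, 2), seed = 4), bd$X, bd$y, cfg)
  h <- fit$history
  expect_lt(nrow(h), 500)  # stopped early
  expect_equal(which.min(h$val_loss), nrow(h) - 1L)
})

test_that("evaluation metrics match their definitions", {
  y <- c("DVT", "DVT", "DVT", "PE", "PE", "PE")
  perfect <- c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9)
  m <- evaluate(NULL, NULL, y, scores = perfect)
  expect_equal(m$auc, 1)
  expect_equal(unname(m$f1), c(1, 1))
  expect_equal(evaluate(NULL, NULL, y, scores = rev(perfect))$auc, 0)

  # one discordant pair: brute-force over all case-control pairs
  scores <- c(0.2, 0.4, 0.75, 0.3, 0.7, 0.9)
  pairs <- expand.grid(pe = which(y == "PE"), dvt = which(y == "DVT"))
  oracle <- mean(ifelse(scores[pairs$pe] > scores[pairs$dvt], 1,
                        ifelse(scores[pairs$pe] == scores[pairs$dvt], 0.5, 0)))
  expect_equal(evaluate(NULL, NULL, y, scores = scores)$auc, oracle)

  expect_error(evaluate(NULL, NULL, rep("PE", 4), scores = runif(4)),
               "one class")
})

test_that("iterative training learns a planted signal and reports history", {
  withr::with_seed(30, {
    n0 <- 160; n1 <- 60
    X <- rbind(matrix(rnorm(n0 * 10), n0, 10),
               cbind(matrix(rnorm(n1 * 4, mean = 1.6), n1, 4),
                     matrix(rnorm(n1 * 6), n1, 6)))
    y <- rep(c("DVT", "PE"), c(n0, n1))
  })
  cfg <- train_config(max_epochs = 12, patience = 3, n_iterations = 4,
                      iter_patience = 3, hidden_dims = c(16, 8), seed = 9)
  fit <- iterative_train(X, y, cfg, adasyn_config(seed = 9),
                         n_pe = 20, n_dvt = 60)
  expect_true(nrow(fit$history) >= 1 && nrow(fit$history) <= 4)
  mon <- fit$monitor_idx
  expect_gt(evaluate(fit$params, X[mon, ], y[mon])$auc, 0.8)

  fit2 <- iterative_train(X, y, cfg, adasyn_config(seed = 9),
                          n_pe = 20, n_dvt = 60)
  expect_identical(fit$history, fit2$history)  # end-to-end determinism
})
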