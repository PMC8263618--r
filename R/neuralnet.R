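## Feed-forward PE/DVT classifier: ReLU hidden layers, softmax output,
## mean cross-entropy loss, analytic backpropagation, mini-batch SGD with
## early stopping, and the iterative balanced-training loop.

#' Training configuration for the PE classifier
#'
#' Defaults follow the published training recipe: two hidden layers of
#' 395 and 128 neurons, learning rate 0.01, batch size 32, a 90/10 inner
#' train/validation split with an early-stopping callback, and an
#' iterative loop over freshly balanced 100-vs-100 sets.
#'
#' @param learning_rate SGD step size.
#' @param batch_size mini-batch size.
#' @param max_epochs epoch cap per [sgd_fit()] call.
#' @param patience epochs without inner-validation improvement tolerated
#'   before stopping (0 = stop at the first non-improving epoch).
#' @param n_iterations balanced-resampling iterations in
#'   [iterative_train()].
#' @param iter_patience iterations without monitoring-set improvement
#'   tolerated before the loop stops early.
#' @param inner_split fraction of each iteration set used for training
#'   (the rest is the inner validation split).
#' @param hidden_dims hidden-layer widths.
#' @param warm_start logical; carry weights across iterations (default
#'   TRUE — otherwise only the last iteration's set would matter).
#' @param seed integer seed.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 32,
                         max_epochs = 100, patience = 10,
                         n_iterations = 50, iter_patience = 10,
                         inner_split = 0.9, hidden_dims = c(395, 128),
                         warm_start = TRUE, seed = 1) {
  stopifnot(learning_rate > 0, all(hidden_dims >= 1))
  structure(list(
    learning_rate = as.double(learning_rate),
    batch_size = assert_count(batch_size, "batch_size", 1),
    max_epochs = assert_count(max_epochs, "max_epochs", 1),
    patience = assert_count(patience, "patience"),
    n_iterations = assert_count(n_iterations, "n_iterations", 1),
    iter_patience = assert_count(iter_patience, "iter_patience"),
    inner_split = assert_fraction(inner_split, "inner_split", 0, 1,
                                  open_lo = TRUE, open_hi = TRUE),
    hidden_dims = as.integer(hidden_dims),
    warm_start = isTRUE(warm_start),
    seed = assert_count(seed, "seed")), class = "train_config")
}

#' Initialize network parameters
#'
#' He-style fan-in scaled Gaussian weights (`sd = sqrt(2 / fan_in)`, the
#' standard choice for ReLU layers) and zero biases.
#'
#' @param dims layer widths, input first, e.g. `c(395, 395, 128, 2)`.
#' @param seed integer seed.
#' @return A `network_params` list of `W` (matrices) and `b` (vectors).
#' @export
init_network <- function(dims, seed = 1) {
  dims <- as.integer(dims)
  if (length(dims) < 2L || any(dims < 1L))
    stop("dims must be >= 2 positive layer widths", call. = FALSE)
  withr::with_seed(seed, {
    L <- length(dims) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                    sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    structure(list(W = W, b = b, dims = dims), class = "network_params")
  })
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)  # max-shift for numerical stability
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass: class probabilities
#'
#' ReLU activations on every hidden layer, numerically stabilized softmax
#' on the output layer; each returned row sums to one.
#'
#' @param params a `network_params`.
#' @param X numeric matrix (rows = subjects, columns = input features).
#' @return Probability matrix with columns `DVT`, `PE`.
#' @export
nn_forward <- function(params, X) {
  .forward_cached(params, X)$P
}

.forward_cached <- function(params, X) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite network input", call. = FALSE)
  if (ncol(X) != params$dims[1])
    stop(sprintf("input has %d columns, network expects %d",
                 ncol(X), params$dims[1]), call. = FALSE)
  L <- length(params$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  for (l in seq_len(L - 1L)) {
    Z <- sweep(A[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    A[[l + 1L]] <- pmax(Z, 0)
  }
  logits <- sweep(A[[L]] %*% params$W[[L]], 2, params$b[[L]], "+")
  P <- .softmax(logits)
  colnames(P) <- c("DVT", "PE")
  list(A = A, P = P)
}

# one-hot matrix from "DVT"/"PE" labels (column order DVT, PE)
.one_hot <- function(y) {
  y <- as.character(y)
  if (!all(y %in% c("DVT", "PE")))
    stop("labels must be 'DVT' or 'PE'", call. = FALSE)
  cbind(DVT = as.numeric(y == "DVT"), PE = as.numeric(y == "PE"))
}

#' Mean cross-entropy loss and analytic gradients
#'
#' The gradient of softmax + cross-entropy at the output layer is
#' `(P - Y) / n`; it is back-propagated through the ReLU layers to give
#' gradients for every weight matrix and bias vector.
#'
#' @param params a `network_params`.
#' @param X input matrix; `y` labels (`"DVT"`/`"PE"`).
#' @return list(loss, grads) where `grads` mirrors `params` (`W`, `b`).
#' @export
nn_loss_grad <- function(params, X, y) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty batch", call. = FALSE)
  Y <- .one_hot(y)
  fc <- .forward_cached(params, X)
  n <- nrow(X)
  loss <- -mean(log(pmax(rowSums(fc$P * Y), 1e-300)))

  L <- length(params$W)
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (fc$P - Y) / n
  for (l in L:1) {
    gW[[l]] <- crossprod(fc$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L)
      delta <- (delta %*% t(params$W[[l]])) * (fc$A[[l]] > 0)
  }
  list(loss = loss, grads = list(W = gW, b = gb))
}

#' Fit the network by mini-batch SGD with early stopping
#'
#' The data are split once (seeded) into `inner_split` training and
#' `1 - inner_split` validation parts; each epoch shuffles the training
#' part and applies plain gradient-descent updates per mini-batch. The
#' parameter snapshot with the best validation loss is retained, and
#' training stops once `patience` consecutive epochs fail to improve it.
#'
#' @param params starting `network_params` (e.g. from [init_network()],
#'   or the previous iteration's fit for a warm start).
#' @param X,y training data and labels.
#' @param cfg a [train_config()].
#' @return list with `params` (best snapshot), `history` (data.frame of
#'   epoch, train_loss, val_loss) and `best_val`.
#' @export
sgd_fit <- function(params, X, y, cfg) {
  stopifnot(inherits(params, "network_params"), inherits(cfg, "train_config"))
  X <- as.matrix(X); y <- as.character(y)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training rows", call. = FALSE)
  withr::with_seed(stage_seed(cfg$seed, "sgd"), {
    n_val <- max(1L, round((1 - cfg$inner_split) * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

    best <- params
    best_val <- Inf
    since_best <- 0L
    hist <- vector("list", cfg$max_epochs)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(length(tr_idx))
      ep_loss <- 0; n_batch <- 0L
      for (start in seq(1L, length(ord), by = cfg$batch_size)) {
        bi <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        lg <- nn_loss_grad(params, Xtr[bi, , drop = FALSE], ytr[bi])
        if (!is.finite(lg$loss))
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        for (l in seq_along(params$W)) {
          params$W[[l]] <- params$W[[l]] - cfg$learning_rate * lg$grads$W[[l]]
          params$b[[l]] <- params$b[[l]] - cfg$learning_rate * lg$grads$b[[l]]
        }
        ep_loss <- ep_loss + lg$loss; n_batch <- n_batch + 1L
      }
      val_loss <- nn_loss_grad(params, Xval, yval)$loss
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  train_loss = ep_loss / n_batch,
                                  val_loss = val_loss)
      if (val_loss < best_val - 1e-12) {
        best_val <- val_loss; best <- params; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best > cfg$patience) break
      }
    }
    list(params = best, history = do.call(rbind, hist[!vapply(hist, is.null, NA)]),
         best_val = best_val)
  })
}

#' Iterative balanced training
#'
#' Repeats, for `cfg$n_iterations`: draw a balanced set (30 real PE +
#' 70 ADASYN-synthetic PE vs 100 real DVT by default) from the training
#' pool and continue SGD from the current weights on it with its own
#' 90/10 inner split. A fixed monitoring split (10 percent of the pool,
#' stratified by class, held out before the loop) scores the model after
#' each iteration; the best-scoring snapshot across iterations is
#' returned, and the loop stops early after `iter_patience` iterations
#' without improvement.
#'
#' @param X,y training pool (standardized features, `"PE"`/`"DVT"` labels).
#' @param cfg a [train_config()].
#' @param adasyn_cfg an [adasyn_config()].
#' @param n_pe,n_dvt real subjects drawn per iteration.
#' @return list with `params` (best snapshot), `history` (per-iteration
#'   monitoring loss/AUC) and `monitor_idx` (pool rows held out for
#'   monitoring).
#' @export
iterative_train <- function(X, y, cfg, adasyn_cfg, n_pe = 30, n_dvt = 100) {
  stopifnot(inherits(cfg, "train_config"), inherits(adasyn_cfg, "adasyn_config"))
  X <- as.matrix(X); y <- as.character(y)

  monitor_idx <- withr::with_seed(stage_seed(cfg$seed, "monitor"), {
    sort(unlist(lapply(c("DVT", "PE"), function(k) {
      idx <- which(y == k)
      sample(idx, max(1L, round(0.1 * length(idx))))
    })))
  })
  pool_idx <- setdiff(seq_along(y), monitor_idx)
  Xp <- X[pool_idx, , drop = FALSE]; yp <- y[pool_idx]
  Xm <- X[monitor_idx, , drop = FALSE]; ym <- y[monitor_idx]

  params <- init_network(c(ncol(X), cfg$hidden_dims, 2L),
                         seed = stage_seed(cfg$seed, "init"))
  best <- params; best_loss <- Inf; since_best <- 0L
  hist <- vector("list", cfg$n_iterations)
  for (i in seq_len(cfg$n_iterations)) {
    it_seed <- stage_seed(cfg$seed, paste0("iteration", i))
    a_cfg <- adasyn_cfg; a_cfg$seed <- it_seed
    Di <- balanced_iteration_sample(Xp, yp, n_pe = n_pe, n_dvt = n_dvt,
                                    cfg = a_cfg)
    start <- if (cfg$warm_start) params else
      init_network(c(ncol(X), cfg$hidden_dims, 2L), seed = it_seed)
    s_cfg <- cfg; s_cfg$seed <- it_seed
    fit <- sgd_fit(start, Di$X, Di$y, s_cfg)
    params <- fit$params
    mon_loss <- nn_loss_grad(params, Xm, ym)$loss
    mon_auc <- evaluate(params, Xm, ym)$auc
    hist[[i]] <- data.frame(iteration = i, monitor_loss = mon_loss,
                            monitor_auc = mon_auc,
                            inner_best_val = fit$best_val)
    if (mon_loss < best_loss - 1e-12) {
      best_loss <- mon_loss; best <- params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best > cfg$iter_patience) break
    }
  }
  list(params = best, history = do.call(rbind, hist[!vapply(hist, is.null, NA)]),
       monitor_idx = monitor_idx)
}

#' Classification metrics: AUC, per-class F1, confusion counts
#'
#' AUC is the rank statistic of the PE-class probability (midranks for
#' ties, equivalent to the Mann-Whitney U scaled to `[0,1]`); F1 scores
#' use a 0.5 decision threshold.
#'
#' @param params a `network_params` (or NULL when `scores` is given).
#' @param X inputs; `y` labels (`"DVT"`/`"PE"`, both present).
#' @param scores optional PE-probability vector overriding the network
#'   (used to score non-network predictors such as the LIME surrogate).
#' @return list(auc, f1 = c(DVT, PE), confusion).
#' @export
evaluate <- function(params, X, y, scores = NULL) {
  y <- as.character(y)
  if (length(unique(y)) < 2L)
    stop("AUC undefined: only one class present", call. = FALSE)
  p_pe <- scores %||% nn_forward(params, X)[, "PE"]
  r <- rank(p_pe)  # midranks
  n1 <- sum(y == "PE"); n0 <- sum(y == "DVT")
  auc <- (sum(r[y == "PE"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- ifelse(p_pe >= 0.5, "PE", "DVT")
  conf <- table(observed = factor(y, c("DVT", "PE")),
                predicted = factor(pred, c("DVT", "PE")))
  f1 <- vapply(c("DVT", "PE"), function(k) {
    tp <- conf[k, k]; fp <- sum(conf[, k]) - tp; fn <- sum(conf[k, ]) - tp
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, 0)
  list(auc = auc, f1 = f1, confusion = conf)
}
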