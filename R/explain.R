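## Tabular LIME: Gaussian perturbation sampling around the training
## distribution, an exponential proximity kernel, and a ridge-stabilized
## weighted linear surrogate of the black-box PE probability. The
## surrogate's value at the subject's own feature vector is the "local
## prediction"; collected over the cohort it is the quantitative LIME
## predictor used as a GWAS phenotype.

#' LIME configuration
#'
#' @param n_perturb perturbation sample size per explained subject
#'   (includes the subject itself as row 1).
#' @param kernel_width proximity kernel width; default `0.75 * sqrt(p)`
#'   (the conventional tabular choice), resolved at explanation time from
#'   the feature count `p`.
#' @param ridge_penalty ridge penalty on the surrogate slopes (intercept
#'   unpenalized); small but positive by default so the weighted normal
#'   equations stay well-conditioned.
#' @param seed integer seed.
#' @export
lime_config <- function(n_perturb = 5000, kernel_width = NULL,
                        ridge_penalty = 1e-6, seed = 1) {
  stopifnot(is.null(kernel_width) || kernel_width > 0, ridge_penalty >= 0)
  structure(list(n_perturb = assert_count(n_perturb, "n_perturb", 2),
                 kernel_width = kernel_width,
                 ridge_penalty = as.double(ridge_penalty),
                 seed = assert_count(seed, "seed")),
            class = "lime_config")
}

.kernel_width <- function(cfg, p) cfg$kernel_width %||% (0.75 * sqrt(p))

#' Draw perturbation samples around an instance
#'
#' Rows are drawn feature-wise from `Normal(mean_i, sd_i)` of the
#' (standardized) training data — the standard tabular construction; a
#' zero-variance feature is held at the instance's value. The instance
#' itself is row 1, so its proximity weight is exactly 1. Proximity
#' weights are `exp(-d^2 / width^2)` with `d` the Euclidean distance to
#' the instance.
#'
#' @param instance numeric feature vector.
#' @param feat_mean,feat_sd per-feature training statistics.
#' @param cfg a [lime_config()].
#' @return list(X = perturbed matrix (`n_perturb` rows, instance first),
#'   weights = proximity weights).
#' @export
perturb_samples <- function(instance, feat_mean, feat_sd, cfg) {
  stopifnot(inherits(cfg, "lime_config"))
  p <- length(instance)
  stopifnot(length(feat_mean) == p, length(feat_sd) == p, all(feat_sd >= 0))
  if (cfg$n_perturb < p + 1L)
    warning("n_perturb < p + 1: surrogate is not identifiable without ridge")
  withr::with_seed(cfg$seed, {
    X <- matrix(stats::rnorm(cfg$n_perturb * p), cfg$n_perturb, p)
    X <- sweep(sweep(X, 2, feat_sd, "*"), 2, feat_mean, "+")
    zero_var <- feat_sd == 0
    if (any(zero_var))
      X[, zero_var] <- matrix(instance[zero_var], cfg$n_perturb,
                              sum(zero_var), byrow = TRUE)
    X[1, ] <- instance
    colnames(X) <- names(instance)
    d2 <- rowSums(sweep(X, 2, instance, "-")^2)
    w <- exp(-d2 / .kernel_width(cfg, p)^2)
    list(X = X, weights = w)
  })
}

#' Fit the weighted ridge linear surrogate
#'
#' Minimizes `sum_j w_j (f(x_j) - b0 - b'x_j)^2 + lambda ||b||^2` by the
#' weighted normal equations (intercept unpenalized). With `lambda = 0`
#' and a linear black box the fit recovers the black box exactly.
#'
#' @param X perturbed matrix; `y` black-box PE probabilities on its rows;
#'   `weights` proximity weights.
#' @param cfg a [lime_config()].
#' @return list(intercept, weights (named slopes), r2 = weighted R
#'   squared).
#' @export
fit_surrogate <- function(X, y, weights, cfg) {
  stopifnot(inherits(cfg, "lime_config"))
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(weights) == nrow(X))
  A <- cbind(intercept = 1, X)
  M <- crossprod(A, weights * A)
  diag(M)[-1] <- diag(M)[-1] + cfg$ridge_penalty
  beta <- tryCatch(solve(M, crossprod(A, weights * y)),
                   error = function(e)
                     stop("singular surrogate system; set ridge_penalty > 0 (",
                          conditionMessage(e), ")", call. = FALSE))
  beta <- drop(beta)
  fit <- drop(A %*% beta)
  ybar <- sum(weights * y) / sum(weights)
  ss_tot <- sum(weights * (y - ybar)^2)
  r2 <- if (ss_tot > 0) 1 - sum(weights * (y - fit)^2) / ss_tot else NA_real_
  list(intercept = unname(beta[1]), weights = beta[-1], r2 = r2)
}

#' Explain one subject: local linear surrogate of the classifier
#'
#' Composes [perturb_samples()] and [fit_surrogate()] around the
#' (standardized) instance. The local PE prediction is the surrogate
#' evaluated at the instance, clipped to `[0, 1]`.
#'
#' @param blackbox function mapping a feature matrix to PE probabilities.
#' @param instance standardized feature vector of the subject.
#' @param feat_mean,feat_sd training-distribution statistics used for
#'   perturbation (for a standardized training matrix these are near 0
#'   and 1).
#' @param cfg a [lime_config()].
#' @return A `lime_explanation`: list(intercept, weights, local_pred,
#'   r2).
#' @export
explain_instance <- function(blackbox, instance, feat_mean, feat_sd, cfg) {
  ps <- perturb_samples(instance, feat_mean, feat_sd, cfg)
  y <- as.numeric(blackbox(ps$X))
  stopifnot(length(y) == nrow(ps$X))
  fit <- fit_surrogate(ps$X, y, ps$weights, cfg)
  local_pred <- fit$intercept + sum(fit$weights * instance)
  structure(list(intercept = fit$intercept, weights = fit$weights,
                 local_pred = min(max(local_pred, 0), 1), r2 = fit$r2),
            class = "lime_explanation")
}

#' Per-subject LIME explanations for a cohort
#'
#' @param blackbox function mapping a feature matrix to PE probabilities.
#' @param X standardized cohort feature matrix (rownames = subject ids).
#' @param cfg a [lime_config()]; each subject's perturbation seed is
#'   derived from `cfg$seed` and the subject index, so single subjects
#'   can be re-explained reproducibly.
#' @return list of `lime_explanation`, named by subject id.
#' @export
explain_cohort <- function(blackbox, X, cfg) {
  X <- as.matrix(X)
  feat_mean <- colMeans(X)
  feat_sd <- sqrt(colMeans(X^2) - feat_mean^2)
  out <- vector("list", nrow(X))
  for (i in seq_len(nrow(X))) {
    cfg_i <- cfg
    cfg_i$seed <- stage_seed(cfg$seed, paste0("subject", i))
    out[[i]] <- explain_instance(blackbox, X[i, ], feat_mean, feat_sd, cfg_i)
  }
  names(out) <- rownames(X)
  out
}

#' The cohort-wide quantitative LIME predictor
#'
#' Each subject's own local surrogate, evaluated at that subject and
#' clipped to `[0, 1]` — the per-subject "local prediction" generalized
#' cohort-wide. This scalar is the quantitative phenotype scanned by
#' [quant_scan()].
#'
#' @inheritParams explain_cohort
#' @return Named numeric vector in `[0, 1]`, one value per subject; the
#'   explanations are attached as attribute `"explanations"`.
#' @export
cohort_predictor <- function(blackbox, X, cfg) {
  ex <- explain_cohort(blackbox, X, cfg)
  structure(vapply(ex, `[[`, 0, "local_pred"), explanations = ex)
}

#' Rank features by global LIME importance
#'
#' Global importance of a feature is the mean absolute local surrogate
#' weight across explained subjects.
#'
#' @param explanations list of `lime_explanation` (e.g. the
#'   `"explanations"` attribute of [cohort_predictor()]).
#' @param top_k rows to return (default 20).
#' @return data.frame(feature, importance), ordered decreasing.
#' @export
rank_global_importance <- function(explanations, top_k = 20) {
  if (!length(explanations)) stop("no explanations supplied", call. = FALSE)
  W <- do.call(rbind, lapply(explanations, `[[`, "weights"))
  imp <- colMeans(abs(W))
  ord <- order(-imp, seq_along(imp))
  utils::head(data.frame(feature = names(imp)[ord],
                         importance = unname(imp[ord]),
                         stringsAsFactors = FALSE), top_k)
}
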