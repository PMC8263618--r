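## Feature standardization and edited-nearest-neighbours (ENN)
## under-sampling of the majority class.

#' Fit a per-feature standardizer (zero mean, unit variance)
#'
#' Means and standard deviations use the population convention (divide by
#' n), so the standardized columns have variance exactly 1 under the same
#' convention. Constant features cannot be scaled; they are flagged and
#' mapped to all-zeros by [apply_standardizer()], which preserves the
#' feature count (and hence the classifier's input width) rather than
#' dropping columns.
#'
#' @param features numeric matrix, subjects by features, with column names.
#' @return A `scaling_params` list: `mean`, `sd`, `constant` (logical),
#'   all named by feature.
#' @export
fit_standardizer <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2L)
    stop("need at least 2 subjects to fit a standardizer", call. = FALSE)
  if (is.null(colnames(features)))
    stop("features must have column names", call. = FALSE)
  if (anyNA(features)) stop("features contain missing values", call. = FALSE)
  n <- nrow(features)
  m <- colMeans(features)
  v <- colMeans(features^2) - m^2   # population variance
  v[v < 0] <- 0
  s <- sqrt(v)
  constant <- s == 0
  s[constant] <- 1  # apply() then yields exact zeros for constant columns
  structure(list(mean = m, sd = s, constant = constant),
            class = "scaling_params")
}

#' Standardize features with previously fitted parameters
#'
#' Applies `z = (x - mean) / sd` per feature using the *fitted* statistics
#' (test rows are standardized with training means and sds, never
#' re-fitted).
#'
#' @param features numeric matrix with the same named columns the
#'   standardizer was fitted on.
#' @param params a `scaling_params` from [fit_standardizer()].
#' @return Standardized numeric matrix of the same shape.
#' @export
apply_standardizer <- function(features, params) {
  stopifnot(inherits(params, "scaling_params"))
  features <- as.matrix(features)
  if (!identical(colnames(features), names(params$mean)))
    stop("feature names do not match the fitted standardizer", call. = FALSE)
  sweep(sweep(features, 2, params$mean, "-"), 2, params$sd, "/")
}

#' Edited-nearest-neighbours under-sampling of the majority class
#'
#' Computes Euclidean distances between all subject pairs on the
#' standardized feature matrix and removes every *majority-class* subject
#' whose label disagrees with the simple majority vote of its `k` nearest
#' neighbours (self excluded). Minority subjects are always kept, so the
#' output is a cleaner majority class plus the intact minority class.
#' Distance ties are broken by ascending subject index, making the filter
#' deterministic.
#'
#' @param features standardized numeric matrix (subjects by features).
#' @param labels character/factor vector with exactly two classes.
#' @param majority_class label of the class to under-sample.
#' @param k odd neighbour count (default 3).
#' @return Integer vector of kept row indices (named with rownames when
#'   present), in original order.
#' @export
enn_filter <- function(features, labels, majority_class, k = 3) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  k <- assert_count(k, "k", min = 1)
  if (k %% 2L == 0L) stop("k must be odd so the vote is well-defined",
                          call. = FALSE)
  n <- nrow(features)
  if (length(labels) != n) stop("labels/features length mismatch", call. = FALSE)
  if (length(unique(labels)) != 2L)
    stop("enn_filter expects exactly two classes present", call. = FALSE)
  if (!majority_class %in% labels)
    stop("majority_class not present in labels", call. = FALSE)
  if (n < k + 1L) stop("need at least k+1 subjects", call. = FALSE)

  d <- as.matrix(stats::dist(features))
  is_major <- labels == majority_class
  drop <- logical(n)
  for (i in which(is_major)) {
    di <- d[i, ]
    di[i] <- Inf
    # ties broken by ascending subject index (stable order on the index)
    nb <- order(di, seq_len(n))[seq_len(k)]
    vote_major <- sum(labels[nb] == majority_class)
    drop[i] <- vote_major < (k + 1L) / 2L
  }
  kept <- which(!drop)
  names(kept) <- rownames(features)[kept]
  kept
}
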