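## ADASYN oversampling and assembly of the per-iteration balanced
## training set (100 PE including synthetic + 100 DVT).

#' ADASYN configuration
#'
#' @param g_total total number of synthetic minority samples per call
#'   (default 70, the number added to 30 real PE subjects to reach a
#'   balanced 100-vs-100 iteration set).
#' @param k_neighbors neighbourhood size (default 5, the algorithm's
#'   canonical choice).
#' @param seed integer seed.
#' @export
adasyn_config <- function(g_total = 70, k_neighbors = 5, seed = 1) {
  structure(list(g_total = assert_count(g_total, "g_total"),
                 k_neighbors = assert_count(k_neighbors, "k_neighbors", 1),
                 seed = assert_count(seed, "seed")),
            class = "adasyn_config")
}

# k nearest rows of `pool` to row i of `pool` (self excluded), ties by index
.knn_idx <- function(dmat, i, k, exclude = i) {
  di <- dmat[i, ]
  di[exclude] <- Inf
  order(di, seq_along(di))[seq_len(min(k, sum(is.finite(di))))]
}

#' Generate ADASYN synthetic minority samples
#'
#' For each minority point the difficulty ratio r_i is the fraction of
#' majority points among its `k_neighbors` nearest neighbours in the
#' pooled (minority + majority) set, self excluded. `g_total` synthetic
#' samples are apportioned proportionally to the normalized r_i with
#' largest-remainder rounding, so exactly `g_total` rows are returned.
#' Each synthetic sample interpolates between a minority point x_i and one
#' of its `k_neighbors` nearest *minority* neighbours x_z:
#' `s = x_i + lambda (x_z - x_i)`, lambda uniform on (0,1) — a convex
#' combination of two real minority points. When no minority point has a
#' majority neighbour (all r_i zero) the allocation falls back to uniform
#' across minority points.
#'
#' @param minority,majority numeric matrices with matching columns.
#' @param cfg an [adasyn_config()].
#' @return Matrix of `g_total` synthetic rows; attribute `"allocation"`
#'   holds the per-minority-point counts g_i.
#' @export
adasyn_generate <- function(minority, majority, cfg) {
  stopifnot(inherits(cfg, "adasyn_config"))
  minority <- as.matrix(minority); majority <- as.matrix(majority)
  m <- nrow(minority)
  if (m < 2L) stop("ADASYN needs at least 2 minority points", call. = FALSE)
  if (ncol(minority) != ncol(majority))
    stop("minority/majority feature dimensions disagree", call. = FALSE)
  k <- cfg$k_neighbors
  g_total <- cfg$g_total
  if (g_total == 0L)
    return(structure(minority[0, , drop = FALSE], allocation = integer(m)))

  pooled <- rbind(minority, majority)
  dp <- as.matrix(stats::dist(pooled))
  r <- vapply(seq_len(m), function(i) {
    nb <- .knn_idx(dp, i, k)
    sum(nb > m) / k
  }, 0)

  if (sum(r) == 0) {
    rhat <- rep(1 / m, m)   # boundary-free minority: uniform fallback
  } else {
    rhat <- r / sum(r)
  }
  g <- .largest_remainder(g_total * rhat, g_total)

  dm <- as.matrix(stats::dist(minority))
  withr::with_seed(cfg$seed, {
    out <- matrix(NA_real_, g_total, ncol(minority),
                  dimnames = list(NULL, colnames(minority)))
    row <- 1L
    for (i in seq_len(m)) {
      if (g[i] == 0L) next
      nbm <- .knn_idx(dm, i, k)
      z <- nbm[sample.int(length(nbm), g[i], replace = TRUE)]
      lam <- stats::runif(g[i])  # recycles per column: lam[r] scales row r
      out[row:(row + g[i] - 1L), ] <-
        (1 - lam) * minority[rep(i, g[i]), , drop = FALSE] +
        lam * minority[z, , drop = FALSE]
      row <- row + g[i]
    }
    structure(out, allocation = g)
  })
}

# apportion `total` integer units proportionally to weights w (sum to total)
.largest_remainder <- function(x, total) {
  base <- floor(x)
  rem <- x - base
  deficit <- total - sum(base)
  if (deficit > 0) {
    up <- order(-rem, seq_along(x))[seq_len(deficit)]
    base[up] <- base[up] + 1
  }
  as.integer(base)
}

#' Draw one balanced training iteration set
#'
#' Samples (without replacement) `n_pe` real PE and `n_dvt` real DVT
#' subjects from the training pool, generates `cfg$g_total` synthetic PE
#' samples by ADASYN computed on the drawn subsample, and returns the
#' stacked balanced set with labels — by default 30 real PE + 70 synthetic
#' PE vs 100 real DVT.
#'
#' @param X numeric feature matrix of the training pool.
#' @param y labels (`"PE"` / `"DVT"`) aligned with `X` rows.
#' @param n_pe,n_dvt real subjects drawn per class.
#' @param cfg an [adasyn_config()]; `cfg$seed` also seeds the subject draw.
#' @return list with `X` (n_pe + g_total + n_dvt rows), `y`, and
#'   `real_idx` (pool row indices of the real subjects used).
#' @export
balanced_iteration_sample <- function(X, y, n_pe = 30, n_dvt = 100, cfg) {
  stopifnot(inherits(cfg, "adasyn_config"))
  X <- as.matrix(X); y <- as.character(y)
  n_pe <- assert_count(n_pe, "n_pe", 1)
  n_dvt <- assert_count(n_dvt, "n_dvt", 1)
  pe_idx <- which(y == "PE"); dvt_idx <- which(y == "DVT")
  if (length(pe_idx) < n_pe || length(dvt_idx) < n_dvt)
    stop(sprintf("training pool too small: have %d PE / %d DVT, need %d / %d",
                 length(pe_idx), length(dvt_idx), n_pe, n_dvt),
         call. = FALSE)
  draw <- withr::with_seed(stage_seed(cfg$seed, "draw"), {
    list(pe = sort(sample(pe_idx, n_pe)), dvt = sort(sample(dvt_idx, n_dvt)))
  })
  X_pe <- X[draw$pe, , drop = FALSE]
  X_dvt <- X[draw$dvt, , drop = FALSE]
  synth <- adasyn_generate(X_pe, X_dvt, cfg)
  list(
    X = rbind(X_pe, synth, X_dvt),
    y = c(rep("PE", n_pe + nrow(synth)), rep("DVT", n_dvt)),
    real_idx = c(draw$pe, draw$dvt)
  )
}
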