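#' Fuzzy c-means configuration
#'
#' @param c number of clusters (`>= 2`).
#' @param m fuzzifier exponent (`> 1`); 2 is the conventional choice and the
#'   value used throughout this package.
#' @param tol convergence tolerance: iteration stops when the maximum
#'   absolute centroid displacement falls below `tol`.
#' @param max_iter iteration cap.
#' @param seed integer seed for the initial choice of centroids (drawn among
#'   the data objects).
#' @return an object of class `fcm_config`.
#' @export
fcm_config <- function(c = 2L, m = 2, tol = 1e-6, max_iter = 300L, seed = 1L) {
  if (c < 2L) stopf("need at least 2 clusters")
  if (m <= 1) stopf("fuzzifier m must be > 1")
  structure(list(c = as.integer(c), m = m, tol = tol,
                 max_iter = as.integer(max_iter), seed = as.integer(seed)),
            class = "fcm_config")
}

# Membership update for fixed centroids (the zero-distance branch assigns
# crisp membership, which is the limit of the update rule and keeps rows
# stochastic).
.fcm_memberships <- function(X, v, m) {
  n <- nrow(X); cc <- nrow(v)
  d2 <- matrix(0, n, cc)
  for (i in seq_len(cc))
    d2[, i] <- rowSums((X - matrix(v[i, ], n, ncol(X), byrow = TRUE))^2)
  u <- matrix(0, n, cc)
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    for (j in which(hit)) u[j, ] <- zero[j, ] / sum(zero[j, ])
  }
  reg <- !hit
  if (any(reg)) {
    p <- 1 / (m - 1)
    w <- d2[reg, , drop = FALSE]^(-p)
    u[reg, ] <- w / rowSums(w)
  }
  list(u = u, d2 = d2)
}

.fcm_objective <- function(u, d2, m) sum(u^m * d2)

#' Fuzzy c-means clustering
#'
#' Partitions objects into `c` soft clusters by minimising
#' `J = sum_j sum_i u_ij^m ||x_j - v_i||^2` (Euclidean norm), alternating
#' the centroid update `v_i = sum_j u_ij^m x_j / sum_j u_ij^m` with the
#' membership update `u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1))`. Iteration
#' starts from `c` distinct objects chosen at random (seeded) and stops when
#' the centroids move less than `tol` or `max_iter` is reached. The objective
#' is non-increasing across iterations.
#'
#' @param X numeric matrix, one row per object, one column per feature (a
#'   numeric vector is treated as one feature).
#' @param cfg an [fcm_config()].
#' @return list of class `fcm_fit`: `u` (n x c membership matrix, rows sum
#'   to 1), `v` (c x p centroids), `J` (objective per iteration),
#'   `iterations`.
#' @export
fcm_cluster <- function(X, cfg = fcm_config()) {
  stopifnot(inherits(cfg, "fcm_config"))
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stopf("X contains non-finite values")
  n <- nrow(X)
  if (n < cfg$c) stopf("need at least c = %d objects, got %d", cfg$c, n)
  distinct <- unique(X)
  if (nrow(distinct) < cfg$c)
    stopf("need at least c = %d distinct objects, got %d", cfg$c, nrow(distinct))
  v <- with_seed(cfg$seed, {
    pick <- sample.int(nrow(distinct), cfg$c)
    distinct[pick, , drop = FALSE]
  })
  J <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mm <- .fcm_memberships(X, v, cfg$m)
    u <- mm$u
    J <- c(J, .fcm_objective(u, mm$d2, cfg$m))
    um <- u^cfg$m
    v_new <- (t(um) %*% X) / colSums(um)
    shift <- max(abs(v_new - v))
    v <- v_new
    if (shift < cfg$tol || iter >= cfg$max_iter) break
  }
  mm <- .fcm_memberships(X, v, cfg$m)
  structure(list(u = mm$u, v = v, J = J, iterations = iter), class = "fcm_fit")
}
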