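# Independent oracles used to cross-check the implementation, plus small
# cached fixtures shared across test files.

# Gift-wrapping (Jarvis march) convex hull perimeter over a set of points.
# Deliberately naive O(n h); used only on small point sets.
giftwrap_hull_perimeter <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n < 3L) return(2 * sum(sqrt(sum((pts[1, ] - pts[n, ])^2))))
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- 1L
    if (cand == p) cand <- 2L
    for (q in seq_len(n)) {
      if (q == p) next
      cr <- (pts[cand, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
            (pts[cand, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      d_c <- sum((pts[cand, ] - pts[p, ])^2)
      d_q <- sum((pts[q, ] - pts[p, ])^2)
      if (cr < 0 || (cr == 0 && d_q > d_c)) cand <- q
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > n) stop("gift wrapping failed")
  }
  hp <- pts[hull, , drop = FALSE]
  sum(sqrt(rowSums((hp - hp[c(2:nrow(hp), 1L), , drop = FALSE])^2)))
}

# Direct minimisation of the reduced FCM objective over centroid locations:
# for m = 2 the optimal memberships are analytic, so J(v) can be minimised
# with a generic optimiser, independently of the alternating updates.
fcm_oracle_centroids <- function(X, c = 2L, starts = 5L, seed = 99L) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  Jv <- function(v) {
    v <- matrix(v, nrow = c)
    d2 <- sapply(seq_len(c), function(i)
      rowSums((X - matrix(v[i, ], nrow(X), ncol(X), byrow = TRUE))^2))
    d2 <- pmax(matrix(d2, nrow(X), c), 1e-12)
    sum(1 / rowSums(1 / d2))
  }
  best <- NULL
  set.seed(seed)
  for (s in seq_len(starts)) {
    v0 <- X[sample(nrow(X), c), ] + stats::rnorm(c * ncol(X), 0, 0.1)
    fit <- stats::optim(as.numeric(v0), Jv, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  matrix(best$par, nrow = c)
}

# Morphological gradient on a binary mask: foreground pixels 8-adjacent to
# background or background pixels 8-adjacent to foreground (the two-sided
# boundary band).
morph_gradient <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  dil <- matrix(FALSE, nr, nc)
  ero <- matrix(TRUE, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    s <- pad[(1:nr) + dr, (1:nc) + dc]
    dil <- dil | s
    ero <- ero & s
  }
  dil & !ero
}

# dilate a mask by one pixel (8-neighbourhood)
dilate1 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  out <- matrix(FALSE, nr, nc)
  for (dr in 0:2) for (dc in 0:2) out <- out | pad[(1:nr) + dr, (1:nc) + dc]
  out
}

# Well-separated two-class gaussian feature clouds (fractal-dimension /
# convexity shaped), for training tests that do not need the mask pipeline.
separable_features <- function(n_per_class = 100L, seed = 42L) {
  withr::with_seed(seed, {
    reg <- cbind(stats::rnorm(n_per_class, 1.18, 0.03),
                 stats::rnorm(n_per_class, 0.95, 0.01))
    irr <- cbind(stats::rnorm(n_per_class, 1.30, 0.03),
                 stats::rnorm(n_per_class, 0.75, 0.02))
  })
  data.frame(id = sprintf("s%03d", seq_len(2L * n_per_class)),
             fractal_dimension = c(reg[, 1], irr[, 1]),
             convexity = c(reg[, 2], irr[, 2]),
             label = rep(c(1L, 0L), each = n_per_class))
}

# Small mask dataset + features, generated once and reused across files.
.fixture_env <- new.env(parent = emptyenv())
small_dataset <- function() {
  if (is.null(.fixture_env$ds))
    .fixture_env$ds <- make_dataset(12, 12, seed = 31L)
  .fixture_env$ds
}
small_features <- function() {
  if (is.null(.fixture_env$ft))
    .fixture_env$ft <- pipeline_features(small_dataset())
  .fixture_env$ft
}
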