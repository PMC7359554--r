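test_that("sigmoid satisfies its identities", {
  expect_equal(sigmoid(0), 0.5)
  expect_equal(sigmoid(2) + sigmoid(-2), 1)
  expect_equal(sigmoid(100), 1, tolerance = 1e-12)
  x <- seq(-5, 5, by = 0.5)
  expect_true(all(diff(sigmoid(x)) > 0))
})

test_that("type-II pair takes its closed-form values and brackets the sigmoid", {
  expect_equal(type2_sigmoid(0, "lower", 2), 0.25)
  expect_equal(type2_sigmoid(0, "upper", 2), sqrt(0.5))
  expect_equal(type2_sigmoid(1.3, "standard"), sigmoid(1.3))
  withr::with_seed(1, x <- runif(100, -8, 8))
  lo <- type2_sigmoid(x, "lower", 2)
  up <- type2_sigmoid(x, "upper", 2)
  s <- sigmoid(x)
  expect_true(all(lo <= s & s <= up))
  expect_true(all(lo >= 0 & up <= 1))
  expect_error(type2_sigmoid(0, "lower", alpha = -1), "alpha")
})

test_that("layer ambiguity is mean (u1-u2)^2 of the layer's memberships", {
  # two tight, distant activation groups cluster near-crisply -> a near 1
  acts <- rbind(matrix(0.01 * 1:6, 3), matrix(4 + 0.01 * 1:6, 3))
  la <- layer_ambiguity(acts, fcm_config(c = 2, seed = 2))
  expect_equal(la$a, mean((la$u[, 1] - la$u[, 2])^2), tolerance = 1e-12)
  expect_gt(la$a, 0.9)
  expect_true(la$a <= 1)
  # memberships straddling the midpoint (0.9/0.1 and 0.6/0.4 style rows)
  # contribute (0.8^2 + 0.2^2)/2 = 0.34 on average
  u <- cbind(c(0.9, 0.6), c(0.1, 0.4))
  expect_equal(mean((u[, 1] - u[, 2])^2), 0.34)
  # identical rows: warning and zero ambiguity
  expect_warning(la0 <- layer_ambiguity(matrix(1, 4, 2)), "identical")
  expect_equal(la0$a, 0)
})

test_that("fuzzy gradient step scales the update by the ambiguity", {
  expect_equal(fuzzy_gd_step(1.0, 0.5, eta = 0.001, a = 0.34), 0.99983)
  w <- matrix(rnorm(6), 2, 3)
  g <- matrix(rnorm(6), 2, 3)
  expect_identical(fuzzy_gd_step(w, g, 0.1, 0), w)
  expect_equal(fuzzy_gd_step(w, g, 0.1, 1), w - 0.1 * g)
  expect_error(fuzzy_gd_step(w, g[, 1:2], 0.1, 0.5), "shape")
  expect_error(fuzzy_gd_step(w, g, 0.1, 1.2), "ambiguity")
})

test_that("forward pass equals a manual chain evaluation", {
  net <- fmlp_network(c(2L, 2L, 1L), variant = "lower", alpha = 2, init_seed = 9)
  x <- c(0.3, -1.2)
  z1 <- as.numeric(x %*% net$weights[[1]]) + net$biases[[1]]
  a1 <- sigmoid(z1)^2
  z2 <- as.numeric(a1 %*% net$weights[[2]]) + net$biases[[2]]
  manual <- sigmoid(z2)^2
  got <- fmlp_forward(net, x)
  expect_equal(got$p, manual, tolerance = 1e-12)
  expect_identical(got$p, fmlp_forward(net, x)$p)
  # all-zero weights force p = activation(0)
  net0 <- net
  net0$weights <- lapply(net0$weights, function(w) w * 0)
  expect_equal(fmlp_forward(net0, x)$p, 0.25)
})

test_that("fuzzy training with ambiguity 1 and alpha 1 reproduces standard backprop", {
  ft <- separable_features(20)
  X <- as.matrix(ft[, c("fractal_dimension", "convexity")])
  y <- ft$label
  net_s <- fmlp_network(variant = "standard", alpha = 1, eta = 0.05, init_seed = 3)
  net_f <- fmlp_network(variant = "lower", alpha = 1, eta = 0.05, init_seed = 3)
  tr_s <- fmlp_train(net_s, X, y, mode = "standard", epochs = 25)
  tr_f <- fmlp_train(net_f, X, y, mode = "fuzzy", epochs = 25, force_ambiguity = 1)
  for (l in seq_along(tr_s$weights)) {
    expect_equal(tr_f$weights[[l]], tr_s$weights[[l]], tolerance = 1e-12)
    expect_equal(tr_f$biases[[l]], tr_s$biases[[l]], tolerance = 1e-12)
  }
})

test_that("zero ambiguity freezes the weights bit-for-bit", {
  ft <- separable_features(10)
  X <- as.matrix(ft[, c("fractal_dimension", "convexity")])
  net <- fmlp_network(init_seed = 5)
  tr <- fmlp_train(net, X, ft$label, mode = "fuzzy", epochs = 3,
                   force_ambiguity = 0)
  expect_identical(tr$weights, net$weights)
  expect_identical(tr$biases, net$biases)
})

test_that("training is deterministic and learns separable features", {
  ft <- separable_features(100)
  X <- scale(as.matrix(ft[, c("fractal_dimension", "convexity")]))
  y <- ft$label
  for (v in c("standard", "lower", "upper")) {
    net <- fmlp_network(variant = v, eta = 2, init_seed = 7)
    mode <- if (v == "standard") "standard" else "fuzzy"
    tr <- fmlp_train(net, X, y, mode = mode, epochs = 150, fcm_seed = 7)
    acc <- mean(decide(fmlp_predict(tr, X))$labels == y)
    expect_gte(acc, 0.9)
    tr2 <- fmlp_train(net, X, y, mode = mode, epochs = 150, fcm_seed = 7)
    expect_identical(tr$weights, tr2$weights)
  }
  expect_error(fmlp_train(fmlp_network(), X, rep(1, nrow(X))), "class")
})

test_that("type-II envelope holds for trained activation pairs", {
  ft <- separable_features(30)
  X <- scale(as.matrix(ft[, c("fractal_dimension", "convexity")]))
  net_l <- fmlp_network(variant = "lower", init_seed = 2)
  net_u <- fmlp_network(variant = "upper", init_seed = 2)
  z <- seq(-4, 4, length.out = 41)
  expect_true(all(type2_sigmoid(z, "lower", 2) <= sigmoid(z)))
  expect_true(all(sigmoid(z) <= type2_sigmoid(z, "upper", 2)))
  # identical nets, identical input: lower-variant output below upper-variant
  p_l <- fmlp_forward(net_l, X)$p
  p_u <- fmlp_forward(net_u, X)$p
  expect_true(all(p_l <= p_u))
})

test_that("mean-threshold decision follows the stated rule", {
  d <- decide(c(0.9, 0.5, 0.1))
  expect_equal(d$threshold, 0.5)
  expect_identical(d$decisions, c("regular", "irregular", "irregular"))
  expect_identical(decide(rep(0.4, 5))$decisions, rep("irregular", 5))
  one <- decide(0.7)
  expect_equal(one$threshold, 0.7)
  expect_identical(one$decisions, "irregular")
  expect_error(decide(numeric(0)), "probabilities")
  expect_error(decide(c(0.5, 1.2)), "0, 1")
})

test_that("variant selection takes the maximum with lower tie-break", {
  expect_identical(select_variant(95.2, 90.3), list(variant = "lower", accuracy = 95.2))
  expect_identical(select_variant(50, 50), list(variant = "lower", accuracy = 50))
  expect_identical(select_variant(10, 90), list(variant = "upper", accuracy = 90))
})

test_that("model JSON serialisation round-trips", {
  net <- fmlp_network(variant = "upper", alpha = 2, eta = 0.01, init_seed = 13)
  path <- tempfile(fileext = ".json")
  save_fmlp(net, path)
  back <- load_fmlp(path)
  expect_equal(back$weights, net$weights, tolerance = 1e-12)
  expect_equal(back$biases, net$biases, tolerance = 1e-12)
  expect_identical(back$variant, net$variant)
  ft <- separable_features(5)
  X <- as.matrix(ft[, c("fractal_dimension", "convexity")])
  expect_equal(fmlp_predict(back, X), fmlp_predict(net, X), tolerance = 1e-12)
  unlink(path)
})
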