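#' Logistic sigmoid
#'
#' `sig(x) = 1 / (1 + exp(-x))`, the standard activation for binary
#' classification; saturates to 0/1 for large `|x|`.
#'
#' @param x numeric vector.
#' @return values in `[0, 1]`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Type-II fuzzy sigmoid
#'
#' A type-II fuzzy set can be built from a type-I membership function by
#' taking the exponent pair `mu^alpha` (lower) and `mu^(1/alpha)` (upper);
#' the band between the two is the footprint of uncertainty. Applied to the
#' sigmoid this gives the activation pair
#' `phi_L(x) = sig(x)^alpha` and `phi_U(x) = sig(x)^(1/alpha)`, which bracket
#' the ordinary sigmoid for `alpha > 1`.
#'
#' @param x numeric vector of pre-activations.
#' @param variant `"lower"`, `"upper"` or `"standard"`.
#' @param alpha exponent `> 0`; the conventional value is 2 (much larger
#'   exponents are not meaningful for image-derived memberships). `alpha = 1`
#'   collapses all variants onto the plain sigmoid.
#' @return values in `[0, 1]`.
#' @export
type2_sigmoid <- function(x, variant = c("lower", "upper", "standard"), alpha = 2) {
  variant <- match.arg(variant)
  if (alpha <= 0) stopf("alpha must be > 0, got %g", alpha)
  s <- sigmoid(x)
  switch(variant,
         lower    = s^alpha,
         upper    = s^(1 / alpha),
         standard = s)
}

# d/dx of the type-II sigmoid: for phi = s^e (e = alpha, 1/alpha or 1),
# phi'(x) = e * s^(e-1) * s * (1 - s).
.type2_deriv <- function(x, variant, alpha) {
  s <- sigmoid(x)
  e <- switch(variant, lower = alpha, upper = 1 / alpha, standard = 1)
  e * s^(e - 1) * s * (1 - s)
}

#' Ambiguity of a layer's activations
#'
#' Clusters the layer's activation table with fuzzy c-means (`c = 2`,
#' corresponding to the two classes of interest) and summarises how crisp
#' the memberships are: `a = mean_j (u1_j - u2_j)^2`. Maximally ambiguous
#' objects (`u1 = u2 = 0.5`) contribute 0, crisp objects contribute 1, so
#' `a` is 0 exactly when every object is ambiguous and 1 when all are crisp.
#'
#' @param activations numeric matrix, objects (by default training samples)
#'   in rows, the layer's neuron activations in columns.
#' @param cfg an [fcm_config()] with `c = 2`.
#' @param orientation `"samples"` clusters the rows as given; `"neurons"`
#'   clusters the transposed table so that neurons are the objects.
#' @return list of class `layer_ambiguity`: scalar `a` in `[0, 1]` and the
#'   membership matrix `u`.
#' @export
layer_ambiguity <- function(activations, cfg = fcm_config(c = 2L),
                            orientation = c("samples", "neurons")) {
  orientation <- match.arg(orientation)
  if (is.vector(activations)) activations <- matrix(activations, ncol = 1L)
  A <- as.matrix(activations)
  if (orientation == "neurons") A <- t(A)
  if (nrow(A) < 2L) stopf("need at least 2 objects to cluster")
  if (cfg$c != 2L) stopf("layer ambiguity is defined for c = 2 clusters")
  if (nrow(unique(A)) < 2L) {
    warning("all activation rows identical; clusters indistinct, ambiguity = 0",
            call. = FALSE)
    u <- matrix(0.5, nrow(A), 2L)
    return(structure(list(a = 0, u = u), class = "layer_ambiguity"))
  }
  fit <- fcm_cluster(A, cfg)
  a <- mean((fit$u[, 1L] - fit$u[, 2L])^2)
  structure(list(a = a, u = fit$u), class = "layer_ambiguity")
}

#' Membership-weighted (fuzzy) gradient-descent step
#'
#' `w' = w - a * eta * g`: the ordinary gradient-descent step scaled by the
#' ambiguity factor `a`. When the memberships feeding `a` are maximally
#' ambiguous (`a = 0`) the weights are left untouched; `a = 1` reduces to
#' plain gradient descent.
#'
#' @param weights,gradients numeric arrays of identical shape.
#' @param eta learning rate (`> 0`).
#' @param a ambiguity scalar in `[0, 1]`.
#' @return updated weights.
#' @export
fuzzy_gd_step <- function(weights, gradients, eta, a) {
  if (!identical(dim(weights), dim(gradients)) ||
      length(weights) != length(gradients))
    stopf("weights and gradients must have identical shape")
  if (eta <= 0) stopf("eta must be > 0")
  if (a < 0 || a > 1) stopf("ambiguity must lie in [0, 1], got %g", a)
  out <- weights - a * eta * gradients
  attributes(out) <- attributes(weights)
  out
}

#' Construct a fuzzy multilayer perceptron
#'
#' Fully-connected feedforward network for binary classification. The
#' reference architecture is 2-4-2-1: two irregularity features in, two
#' hidden layers of 4 and 2 neurons, one output neuron giving the class
#' probability. Weights are initialised uniform on (-0.5, 0.5) with a seed;
#' biases start at 0.
#'
#' @param layer_sizes integer vector of layer widths, input first, output
#'   (size 1) last.
#' @param variant activation variant: `"lower"`, `"upper"` or `"standard"`.
#' @param alpha type-II exponent (default 2).
#' @param eta learning rate (default 0.001).
#' @param epochs default training epochs (default 1).
#' @param init_seed integer seed for weight initialisation.
#' @return object of class `fmlp`, a list with `weights` and `biases` (one
#'   per connection layer) plus the hyperparameters.
#' @export
fmlp_network <- function(layer_sizes = c(2L, 4L, 2L, 1L),
                         variant = c("lower", "upper", "standard"),
                         alpha = 2, eta = 0.001, epochs = 1L, init_seed = 1L) {
  variant <- match.arg(variant)
  if (alpha <= 0) stopf("alpha must be > 0")
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stopf("need at least input and output layers")
  if (utils::tail(layer_sizes, 1L) != 1L)
    stopf("the output layer must have exactly 1 neuron")
  L <- length(layer_sizes) - 1L
  wb <- with_seed(init_seed, {
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::runif(layer_sizes[l] * layer_sizes[l + 1L], -0.5, 0.5),
                       layer_sizes[l], layer_sizes[l + 1L])
      b[[l]] <- rep(0, layer_sizes[l + 1L])
    }
    list(W = W, b = b)
  })
  structure(list(layer_sizes = layer_sizes, weights = wb$W, biases = wb$b,
                 variant = variant, alpha = alpha, eta = eta,
                 epochs = as.integer(epochs), init_seed = as.integer(init_seed)),
            class = "fmlp")
}

#' Forward pass
#'
#' Each connection layer applies an affine map followed by the network's
#' activation variant; the output layer yields the class probability.
#'
#' @param net an [fmlp_network()].
#' @param X numeric matrix of features (samples in rows) or a single feature
#'   vector.
#' @return list: `p` (vector of probabilities), `activations` (list of
#'   per-layer activation matrices, input first), `preacts` (per-layer
#'   pre-activation matrices).
#' @export
fmlp_forward <- function(net, X) {
  stopifnot(inherits(net, "fmlp"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (ncol(X) != net$layer_sizes[1L])
    stopf("expected %d features, got %d", net$layer_sizes[1L], ncol(X))
  if (!all(is.finite(X))) stopf("features contain non-finite values")
  L <- length(net$weights)
  acts <- vector("list", L + 1L)
  pres <- vector("list", L)
  acts[[1L]] <- X
  a <- X
  for (l in seq_len(L)) {
    z <- a %*% net$weights[[l]] +
      matrix(net$biases[[l]], nrow(a), length(net$biases[[l]]), byrow = TRUE)
    a <- type2_sigmoid(z, net$variant, net$alpha)
    pres[[l]] <- z
    acts[[l + 1L]] <- a
  }
  list(p = as.numeric(a), activations = acts, preacts = pres)
}

#' Train by (fuzzy) gradient descent
#'
#' Full-batch training. Each epoch: (i) a forward pass caches every layer's
#' activations; (ii) in fuzzy mode, each non-output layer's activation table
#' is clustered with fuzzy c-means and summarised into an ambiguity scalar
#' (see [layer_ambiguity()]); (iii) the error delta
#' `(true - pred) * phi'(z)` is backpropagated through the chain rule with
#' the variant's derivative; (iv) each weight matrix is updated with
#' [fuzzy_gd_step()], scaled by the ambiguity of the layer its connections
#' originate from (the output layer is never clustered). Standard mode fixes
#' the ambiguity at 1 and uses the plain sigmoid.
#'
#' @param net an [fmlp_network()].
#' @param X numeric feature matrix, samples in rows.
#' @param y integer labels in `{0, 1}` (1 = regular); both classes must be
#'   present with at least 2 samples each.
#' @param mode `"fuzzy"` or `"standard"`.
#' @param epochs number of full-batch iterations; defaults to the network's
#'   setting.
#' @param ambiguity_scope `"layer"` keeps one scalar per layer; `"global"`
#'   averages the per-layer scalars into a single network-wide factor.
#' @param orientation passed to [layer_ambiguity()].
#' @param fcm_seed seed for the per-epoch fuzzy c-means initialisations.
#' @param force_ambiguity optional scalar in `[0, 1]` that bypasses the
#'   clustering and fixes every layer's ambiguity (0 freezes the weights,
#'   1 recovers plain gradient descent).
#' @return the trained network, with an `ambiguity_trace` attribute holding
#'   the per-epoch ambiguity scalars (fuzzy mode).
#' @export
fmlp_train <- function(net, X, y, mode = c("fuzzy", "standard"),
                       epochs = NULL, ambiguity_scope = c("layer", "global"),
                       orientation = c("samples", "neurons"), fcm_seed = 1L,
                       force_ambiguity = NULL) {
  mode <- match.arg(mode)
  ambiguity_scope <- match.arg(ambiguity_scope)
  orientation <- match.arg(orientation)
  stopifnot(inherits(net, "fmlp"))
  if (is.vector(X)) X <- matrix(X, ncol = net$layer_sizes[1L])
  X <- unname(as.matrix(X))   # column names would leak into weight dimnames
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stopf("labels must be 0 or 1")
  if (min(table(y)) < 2L || length(unique(y)) < 2L)
    stopf("need at least 2 samples of each class")
  if (nrow(X) != length(y)) stopf("X and y disagree on sample count")
  if (is.null(epochs)) epochs <- net$epochs
  n <- nrow(X)
  L <- length(net$weights)
  act_variant <- if (mode == "standard") "standard" else net$variant
  trace <- matrix(NA_real_, epochs, L)
  for (ep in seq_len(epochs)) {
    fwd <- fmlp_forward(structure(modifyList(net, list(variant = act_variant)),
                                  class = "fmlp"), X)
    amb <- rep(1, L)
    if (mode == "fuzzy") {
      if (!is.null(force_ambiguity)) {
        amb <- rep(force_ambiguity, L)
      } else {
        for (l in seq_len(L)) {   # activations of the layer feeding W[[l]]
          A <- fwd$activations[[l]]
          cfg <- fcm_config(c = 2L, seed = as.integer(fcm_seed) + 13L * ep + l)
          amb[l] <- suppressWarnings(layer_ambiguity(A, cfg, orientation)$a)
        }
        if (ambiguity_scope == "global") amb <- rep(mean(amb), L)
      }
    }
    trace[ep, ] <- amb
    # backpropagation of delta = dE/dz for E = 1/2 sum (y - p)^2
    deltas <- vector("list", L)
    err <- y - fwd$p
    deltas[[L]] <- matrix(err * .type2_deriv(fwd$preacts[[L]], act_variant, net$alpha),
                          ncol = 1L)
    if (L > 1L) for (l in (L - 1L):1L) {
      back <- deltas[[l + 1L]] %*% t(net$weights[[l + 1L]])
      deltas[[l]] <- back * .type2_deriv(fwd$preacts[[l]], act_variant, net$alpha)
    }
    for (l in seq_len(L)) {
      gW <- -crossprod(fwd$activations[[l]], deltas[[l]]) / n
      gb <- -colMeans(deltas[[l]])
      net$weights[[l]] <- fuzzy_gd_step(net$weights[[l]], gW, net$eta, amb[l])
      net$biases[[l]] <- fuzzy_gd_step(net$biases[[l]], gb, net$eta, amb[l])
    }
  }
  attr(net, "ambiguity_trace") <- trace
  attr(net, "mode") <- mode
  net
}

#' Predict class probabilities
#'
#' @param net a trained [fmlp_network()].
#' @param X feature matrix.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
fmlp_predict <- function(net, X) fmlp_forward(net, X)$p

#' Threshold decision over a batch of probabilities
#'
#' The decision threshold is the arithmetic mean of the prediction
#' probabilities of the batch; a sample is called regular when its
#' probability strictly exceeds the threshold and irregular otherwise
#' (boundary cases are irregular). A fixed threshold, e.g. one derived from
#' the training set, can be supplied instead.
#'
#' @param probs numeric vector of probabilities in `[0, 1]`.
#' @param threshold optional fixed threshold; default is `mean(probs)`.
#' @return list of class `prediction_set`: `probabilities`, `threshold`,
#'   `decisions` (character, `"regular"`/`"irregular"`), `labels` (integer,
#'   regular = 1).
#' @export
decide <- function(probs, threshold = NULL) {
  if (!length(probs)) stopf("no probabilities supplied")
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    stopf("probabilities must lie in [0, 1]")
  if (is.null(threshold)) threshold <- mean(probs)
  lab <- as.integer(probs > threshold)
  structure(list(probabilities = probs, threshold = threshold,
                 decisions = ifelse(lab == 1L, "regular", "irregular"),
                 labels = lab),
            class = "prediction_set")
}

#' Select the better type-II variant
#'
#' The type-II pair yields two classifiers; the one with the higher accuracy
#' is reported as the network's accuracy. Ties resolve to the lower variant.
#'
#' @param acc_lower,acc_upper accuracies in `[0, 100]`.
#' @return list: `variant` (`"lower"`/`"upper"`), `accuracy`.
#' @export
select_variant <- function(acc_lower, acc_upper) {
  stopifnot(acc_lower >= 0, acc_lower <= 100, acc_upper >= 0, acc_upper <= 100)
  if (acc_upper > acc_lower) list(variant = "upper", accuracy = acc_upper)
  else list(variant = "lower", accuracy = acc_lower)
}

#' Serialise a network to JSON
#'
#' @param net an [fmlp_network()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_fmlp <- function(net, path) {
  stopifnot(inherits(net, "fmlp"))
  obj <- list(layer_sizes = net$layer_sizes,
              weights = lapply(net$weights, as.numeric),  # column-major flat
              biases = lapply(net$biases, as.numeric),
              variant = net$variant, alpha = net$alpha, eta = net$eta,
              epochs = net$epochs, init_seed = net$init_seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a network from JSON
#'
#' @param path file written by [save_fmlp()].
#' @return an object of class `fmlp`.
#' @export
load_fmlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(obj$layer_sizes)
  W <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(unlist(obj$weights[[l]]), sizes[l], sizes[l + 1L])
  }
  b <- obj$biases
  if (!is.list(b)) b <- list(b)
  b <- lapply(b, as.numeric)
  structure(list(layer_sizes = sizes, weights = W, biases = b,
                 variant = obj$variant, alpha = obj$alpha, eta = obj$eta,
                 epochs = as.integer(obj$epochs),
                 init_seed = as.integer(obj$init_seed)),
            class = "fmlp")
}
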