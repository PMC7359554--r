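# Evaluation protocol: stratified ratio splits, confusion matrices with
# regular as the positive class, accuracy / sensitivity / specificity
# reported to one decimal, ROC curves, and the three-way comparison of the
# standard network against the lower and upper type-II variants.

#' Stratified train/test split
#'
#' Seeded, stratified shuffle. The overall training size is
#' `round(ratio * n)` and is allocated across classes by largest remainder,
#' so e.g. 310 samples split 80:20 give exactly 248/62.
#'
#' @param labels integer class labels (both classes must be present).
#' @param ratio character `"80:20"`, `"70:30"`, `"60:40"` or `"50:50"`, or a
#'   numeric training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
split_dataset <- function(labels, ratio = "80:20", seed = 1L) {
  if (is.character(ratio)) {
    parts <- suppressWarnings(as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1L]]))
    if (length(parts) != 2L || any(!is.finite(parts)) || any(parts <= 0))
      stopf("malformed ratio '%s'", ratio)
    frac <- parts[1L] / sum(parts)
  } else {
    frac <- ratio
  }
  if (!is.finite(frac) || frac <= 0 || frac >= 1) stopf("training fraction must be in (0, 1)")
  labels <- as.vector(labels)
  classes <- sort(unique(labels), decreasing = TRUE)   # class 1 (regular) first
  if (length(classes) < 2L) stopf("both classes must be present")
  n <- length(labels)
  n_train <- round(frac * n)
  share <- vapply(classes, function(cl) frac * sum(labels == cl), 1)
  base <- floor(share)
  rem <- n_train - sum(base)
  if (rem > 0) {
    order_rem <- order(share - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  train <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      sample(which(labels == classes[k]), base[k])
    }))
  })
  train <- sort(as.integer(train))
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Confusion matrix with regular (label 1) as the positive class
#'
#' @param predicted,actual integer labels in `{0, 1}` (1 = regular).
#' @return list of class `confusion_matrix` with counts `tp`, `fn`, `fp`,
#'   `tn` (rows actual, columns predicted in the printed layout).
#' @export
confusion_matrix <- function(predicted, actual) {
  predicted <- as.integer(predicted); actual <- as.integer(actual)
  if (length(predicted) != length(actual)) stopf("length mismatch")
  structure(list(tp = sum(predicted == 1L & actual == 1L),
                 fn = sum(predicted == 0L & actual == 1L),
                 fp = sum(predicted == 1L & actual == 0L),
                 tn = sum(predicted == 0L & actual == 0L)),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Percentages rounded half-up to one decimal, matching how such results
#' are conventionally tabulated. A zero denominator yields `NA` (undefined),
#' never 0.
#'
#' @param cm a [confusion_matrix()] or a list with `tp`, `fn`, `fp`, `tn`.
#' @return list of class `eval_report`: `accuracy`, `sensitivity`,
#'   `specificity` (percent) and the counts.
#' @export
metrics <- function(cm) {
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  total <- tp + fn + fp + tn
  if (total <= 0) stopf("empty confusion matrix")
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1L) else NA_real_
  structure(list(accuracy = pct(tp + tn, total),
                 sensitivity = pct(tp, tp + fn),
                 specificity = pct(tn, tn + fp),
                 tp = tp, fn = fn, fp = fp, tn = tn),
            class = "eval_report")
}

#' ROC curve and area
#'
#' Sensitivity/1-specificity swept over all probability thresholds, with the
#' area under the curve by the trapezoid rule (delegated to \pkg{pROC}).
#'
#' @param probs predicted probabilities of the positive (regular) class.
#' @param labels integer labels in `{0, 1}`.
#' @return list: `points` (data frame with `fpr`, `tpr`), `auc`.
#' @export
roc_curve <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stopf("both classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(probs),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  rownames(pts) <- NULL
  list(points = pts, auc = as.numeric(r$auc))
}

#' Compare the standard network with both type-II variants
#'
#' Trains the standard MLP and the lower/upper F-MLP variants on an
#' identical stratified split and identical weight initialisation, applies
#' the mean-probability decision rule to the test predictions, and reports
#' per-variant confusion matrices and metrics plus the best type-II variant
#' (max accuracy). Features are z-scored with training-set statistics
#' before training.
#'
#' @param features data frame with columns `fractal_dimension`, `convexity`
#'   and `label` (1 = regular).
#' @param ratio split ratio (see [split_dataset()]).
#' @param seed seed for the split and the weight initialisation.
#' @param alpha type-II exponent.
#' @param eta learning rate.
#' @param epochs training epochs.
#' @param layer_sizes network architecture (input width must be 2).
#' @return list of class `fmlp_comparison`: per-variant `eval_report`s,
#'   ROC results, the selected variant and the split indices.
#' @export
compare_networks <- function(features, ratio = "80:20", seed = 1L,
                             alpha = 2, eta = 0.001, epochs = 1L,
                             layer_sizes = c(2L, 4L, 2L, 1L)) {
  need <- c("fractal_dimension", "convexity", "label")
  if (!all(need %in% names(features)))
    stopf("features must have columns %s", paste(need, collapse = ", "))
  X <- as.matrix(features[, c("fractal_dimension", "convexity")])
  y <- as.integer(features$label)
  sp <- split_dataset(y, ratio, seed)
  mu <- colMeans(X[sp$train, , drop = FALSE])
  sdv <- apply(X[sp$train, , drop = FALSE], 2L, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")
  run <- function(variant, mode) {
    net <- fmlp_network(layer_sizes, variant = variant, alpha = alpha,
                        eta = eta, epochs = as.integer(epochs), init_seed = seed)
    net <- fmlp_train(net, Z[sp$train, , drop = FALSE], y[sp$train],
                      mode = mode, fcm_seed = seed)
    p <- fmlp_predict(net, Z[sp$test, , drop = FALSE])
    dec <- decide(p)
    cm <- confusion_matrix(dec$labels, y[sp$test])
    list(net = net, report = metrics(cm), roc = roc_curve(p, y[sp$test]),
         decisions = dec)
  }
  std <- run("standard", "standard")
  low <- run("lower", "fuzzy")
  up <- run("upper", "fuzzy")
  sel <- select_variant(low$report$accuracy, up$report$accuracy)
  structure(list(standard = std, lower = low, upper = up,
                 selected = sel, split = sp, ratio = ratio, seed = seed),
            class = "fmlp_comparison")
}
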