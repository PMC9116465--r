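# The quality model: epsilon-SVR with a radial-basis kernel over the
# 444-dimensional perceptual descriptor, tuned by an inner cross-validated
# grid search on rank correlation, with feature scaling learned on the
# training rows only.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every fit reproducible without
# clobbering outer simulations.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Hyperparameter grid for the quality model
#'
#' Log-2-spaced candidate grids for the SVR regularization constant `C` and
#' kernel width `gamma`, with an inner k-fold scheme selecting the pair
#' that maximizes mean validation rank correlation (the protocol's headline
#' metric, rather than squared error). The default grid is the canonical
#' practical-guide grid for RBF SVR: `C` in 2^-5..2^15, `gamma` in
#' 2^-15..2^3, both in steps of 2^2.
#'
#' @param cost Numeric vector of candidate `C` values.
#' @param gamma Numeric vector of candidate kernel widths.
#' @param k Inner cross-validation folds (>= 2, default 5).
#' @param epsilon SVR epsilon-tube width (default 0.1).
#' @return An object of class `"ceiqa_grid"`.
#' @export
ceiqa_grid <- function(cost = 2^seq(-5, 15, by = 2),
                       gamma = 2^seq(-15, 3, by = 2),
                       k = 5L, epsilon = 0.1) {
  stopifnot(length(cost) >= 1L, length(gamma) >= 1L,
            all(cost > 0), all(gamma > 0), k >= 2L, epsilon > 0)
  structure(list(cost = cost, gamma = gamma, k = as.integer(k),
                 epsilon = epsilon), class = "ceiqa_grid")
}

#' Coarse hyperparameter grid
#'
#' A log-2 subsample of the canonical grid (steps of 2^4) for repeated-split
#' protocols where hundreds of models are refit; selection quality is close
#' to the full grid at a fraction of the fits.
#'
#' @inheritParams ceiqa_grid
#' @return An object of class `"ceiqa_grid"`.
#' @export
ceiqa_grid_coarse <- function(k = 3L) {
  ceiqa_grid(cost = 2^seq(-5, 15, by = 4), gamma = 2^seq(-15, 1, by = 4),
             k = k)
}

# Min-max scaling to [-1, 1], learned on training rows only. Constant
# dimensions map to 0.
fit_scaling <- function(X) {
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1
  list(lo = lo, span = span)
}

apply_scaling <- function(X, sc) {
  sweep(sweep(X, 2L, sc$lo), 2L, sc$span, "/") * 2 - 1
}

resolve_xy <- function(x, y) {
  if (is.data.frame(x) &&
      (!is.null(attr(x, "fingerprint")) ||
       any(c("id", "mos", "split") %in% names(x)))) {
    if (is.null(y) && !is.null(x$mos)) y <- x$mos
    fp <- attr(x, "fingerprint")
    x <- feature_matrix(x)
    attr(x, "fingerprint") <- fp
  } else if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(y)) stop("no quality scores supplied (y or a 'mos' column)",
                       call. = FALSE)
  list(x = x, y = as.numeric(y))
}

#' Fit a perceptual quality model
#'
#' Trains the quality predictor: per-dimension min-max feature scaling to
#' \[-1, 1\] (fitted on the training rows only), an inner k-fold grid
#' search over `(C, gamma)` selecting the pair with the highest mean
#' validation Spearman rank correlation, and a final epsilon-SVR refit with
#' a radial-basis kernel on all training rows. The fitted object carries
#' the feature-layout fingerprint of its training table and refuses to
#' predict from incompatible layouts.
#'
#' @param x Feature table from [extract_batch()] / [read_feature_table()],
#'   or a plain numeric matrix (one image per row).
#' @param y Numeric quality scores (MOS); taken from the table's `mos`
#'   column when omitted.
#' @param grid A [ceiqa_grid()] describing the hyperparameter search.
#' @param seed Integer seed for the inner fold assignment.
#' @return An object of class `"ceiqa"`: the fitted SVR, scaling and
#'   selected hyperparameters, the full grid-search table, and the layout
#'   fingerprint.
#' @seealso [predict.ceiqa()], [repeated_split_eval()]
#' @export
ceiqa <- function(x, y = NULL, grid = ceiqa_grid(), seed = 1L) {
  cl <- match.call()
  xy <- resolve_xy(x, y); X <- xy$x; y <- xy$y
  if (nrow(X) < 10L)
    stop("need at least 10 training rows", call. = FALSE)
  if (nrow(X) != length(y))
    stop("features and scores are misaligned", call. = FALSE)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("quality scores are constant: nothing to regress on", call. = FALSE)
  sc <- fit_scaling(X)
  Xs <- apply_scaling(X, sc)
  n <- nrow(Xs)
  k <- min(grid$k, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  combos <- expand.grid(cost = grid$cost, gamma = grid$gamma,
                        KEEP.OUT.ATTRS = FALSE)
  cv <- vapply(seq_len(nrow(combos)), function(j) {
    sr <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      if (stats::sd(y[tr]) == 0 || sum(!tr) < 3L) return(NA_real_)
      fit <- e1071::svm(Xs[tr, , drop = FALSE], y[tr],
                        type = "eps-regression", kernel = "radial",
                        cost = combos$cost[j], gamma = combos$gamma[j],
                        epsilon = grid$epsilon, scale = FALSE)
      p <- as.numeric(stats::predict(fit, Xs[!tr, , drop = FALSE]))
      if (stats::sd(p) == 0 || stats::sd(y[!tr]) == 0) return(0)
      srocc(p, y[!tr])
    }, numeric(1L))
    mean(sr, na.rm = TRUE)
  }, numeric(1L))
  best <- which.max(cv)      # ties: first in grid order (deterministic)
  svm_fit <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                        cost = combos$cost[best], gamma = combos$gamma[best],
                        epsilon = grid$epsilon, scale = FALSE)
  fitted_vals <- as.numeric(stats::predict(svm_fit, Xs))
  structure(list(
    svm = svm_fit, scaling = sc,
    cost = combos$cost[best], gamma = combos$gamma[best],
    epsilon = grid$epsilon,
    cv_table = cbind(combos, srocc = cv),
    fingerprint = attr(X, "fingerprint"),
    feature_names = colnames(X),
    y = y, fitted = fitted_vals, seed = seed, call = cl,
    format_version = 1L
  ), class = "ceiqa")
}

#' Predict quality scores
#'
#' One real-valued score per row, a pure function of the model and the
#' features. A feature table whose layout fingerprint differs from the one
#' the model was trained on is refused.
#'
#' @param object A fitted [ceiqa()] model.
#' @param newdata Feature table or numeric matrix.
#' @param ... Unused.
#' @return Numeric vector of predicted scores (length `nrow(newdata)`).
#' @export
predict.ceiqa <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    fp <- attr(newdata, "fingerprint")
    if (!is.null(fp) && !is.null(object$fingerprint) &&
        !identical(fp, object$fingerprint))
      stop(sprintf("feature-layout mismatch: model %s vs table %s",
                   object$fingerprint, fp), call. = FALSE)
    newdata <- feature_matrix(newdata)
  }
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  if (ncol(newdata) != length(object$scaling$lo))
    stop(sprintf("model expects %d features, got %d",
                 length(object$scaling$lo), ncol(newdata)), call. = FALSE)
  as.numeric(stats::predict(object$svm,
                            apply_scaling(newdata, object$scaling)))
}

#' @export
print.ceiqa <- function(x, ...) {
  cat("Perceptual quality model (epsilon-SVR, radial kernel)\n")
  cat(sprintf("  training images: %d   features: %d\n",
              length(x$y), length(x$scaling$lo)))
  cat(sprintf("  selected C = %g, gamma = %g (epsilon = %g)\n",
              x$cost, x$gamma, x$epsilon))
  cat(sprintf("  inner-CV SROCC at selection: %.4f\n",
              max(x$cv_table$srocc, na.rm = TRUE)))
  if (!is.null(x$fingerprint))
    cat("  feature layout:", x$fingerprint, "\n")
  invisible(x)
}

#' @export
summary.ceiqa <- function(object, ...) {
  res <- object$y - object$fitted
  structure(list(
    model = object,
    train_srocc = srocc(object$fitted, object$y),
    train_rmse = sqrt(mean(res^2)),
    n_sv = object$svm$tot.nSV,
    cv_top = utils::head(object$cv_table[
      order(-object$cv_table$srocc), , drop = FALSE], 5L)
  ), class = "summary.ceiqa")
}

#' @export
print.summary.ceiqa <- function(x, ...) {
  print(x$model)
  cat(sprintf("  support vectors: %d\n", x$n_sv))
  cat(sprintf("  training SROCC %.4f, training RMSE %.4f\n",
              x$train_srocc, x$train_rmse))
  cat("  top grid-search cells (inner-CV SROCC):\n")
  print(x$cv_top, row.names = FALSE)
  invisible(x)
}

#' @export
fitted.ceiqa <- function(object, ...) object$fitted

#' @export
residuals.ceiqa <- function(object, ...) object$y - object$fitted

#' Diagnostic plot: predicted score against subjective score
#'
#' Scatter of fitted (or newly predicted) scores against MOS with the
#' five-parameter logistic regression curve used by the evaluation
#' protocol.
#'
#' @param x A fitted [ceiqa()] model.
#' @param newdata,newy Optional held-out features and scores; defaults to
#'   the training data.
#' @param ... Passed to [plot()].
#' @return Invisibly, the [logistic_fit()] used for the curve.
#' @export
plot.ceiqa <- function(x, newdata = NULL, newy = NULL, ...) {
  pred <- if (is.null(newdata)) x$fitted else predict(x, newdata)
  mos <- if (is.null(newy)) x$y else newy
  plot(pred, mos, xlab = "predicted quality score", ylab = "MOS",
       pch = 16, col = "#00000088", ...)
  lf <- logistic_fit(pred, mos)
  xs <- seq(min(pred), max(pred), length.out = 200L)
  graphics::lines(xs, predict_logistic(lf, xs), lty = 2, col = "red3")
  invisible(lf)
}

#' Persist and restore a quality model
#'
#' Round-trips the fitted model through a single serialized artifact with
#' an explicit format-version field; predictions after a round trip are
#' bit-identical. Truncated or foreign files raise a load error.
#'
#' @param model A fitted [ceiqa()] model.
#' @param path File path for the model artifact.
#' @return `path` invisibly (`save_ceiqa`); the model (`load_ceiqa`).
#' @export
save_ceiqa <- function(model, path) {
  stopifnot(inherits(model, "ceiqa"))
  saveRDS(list(format = "ceiqa-model", version = model$format_version,
               model = model), path)
  invisible(path)
}

#' @rdname save_ceiqa
#' @export
load_ceiqa <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot load model file: ", conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "ceiqa-model"))
    stop("not a ceiqa model artifact: ", path, call. = FALSE)
  if (!identical(obj$version, 1L))
    stop("unsupported model format version: ", obj$version, call. = FALSE)
  obj$model
}
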