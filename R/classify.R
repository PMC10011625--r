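# RBF-kernel SVM training and hyperparameter grid search.
# The SVM itself is LIBSVM via e1071 (one-vs-one multiclass voting), matching
# the software lineage this method was developed with.

#' SVM configuration
#'
#' @param C,gamma Optional fixed regularization parameter and RBF kernel
#'   width `K(x, y) = exp(-gamma * ||x - y||^2)`. When both are given,
#'   [grid_search()] is skipped and these values are used directly.
#' @param c_grid,gamma_grid Geometric search grids; defaults are the
#'   canonical LIBSVM grids `2^(-5), 2^(-3), ..., 2^15` and
#'   `2^(-15), 2^(-13), ..., 2^3`.
#' @param inner_folds Stratified cross-validation folds used by the grid
#'   search (>= 2; reduced with a warning when a class is smaller).
#' @param scale Standardize features before fitting (default `FALSE`; APAAC
#'   components are already jointly normalized).
#' @return List of class `svm_config`.
#' @export
svm_config <- function(C = NULL, gamma = NULL,
                       c_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       inner_folds = 5L, scale = FALSE) {
  if (!length(c_grid) || !length(gamma_grid) ||
      any(c_grid <= 0) || any(gamma_grid <= 0)) {
    abort_validation("c_grid and gamma_grid must be non-empty with positive entries")
  }
  if (inner_folds < 2) abort_validation("inner_folds must be >= 2")
  structure(list(C = C, gamma = gamma,
                 c_grid = sort(unique(c_grid)),
                 gamma_grid = sort(unique(gamma_grid)),
                 inner_folds = as.integer(inner_folds), scale = scale),
            class = "svm_config")
}

check_training_input <- function(x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) abort_validation("x rows and y length differ")
  bad <- which(!apply(is.finite(x), 1, all))
  if (length(bad)) {
    abort_validation(sprintf("non-finite feature value(s) in row(s): %s",
                             paste(bad, collapse = ", ")))
  }
  if (length(unique(y)) < 2) {
    abort_validation("training requires at least 2 classes")
  }
  x
}

#' Train an RBF-kernel SVM
#'
#' One-vs-one multiclass voting (the LIBSVM scheme). Deterministic given
#' identical data and configuration.
#'
#' @param x Feature matrix (rows = samples).
#' @param y Label vector.
#' @param C Regularization parameter (> 0).
#' @param gamma Kernel width (> 0).
#' @param scale Standardize features before fitting.
#' @return Object of class `apaac_svm` wrapping the fitted model, its class
#'   list and hyperparameters.
#' @export
train_svm <- function(x, y, C, gamma, scale = FALSE) {
  x <- check_training_input(x, y)
  y <- factor(y, levels = unique(as.character(y)))
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = scale)
  structure(list(fit = fit, classes = levels(y), C = C, gamma = gamma),
            class = "apaac_svm")
}

#' @export
predict.apaac_svm <- function(object, newdata, ...) {
  as.character(stats::predict(object$fit, as.matrix(newdata)))
}

#' @export
print.apaac_svm <- function(x, ...) {
  cat(sprintf("apaac_svm: RBF kernel, C = %g, gamma = %g, %d classes (%s)\n",
              x$C, x$gamma, length(x$classes), paste(x$classes, collapse = ", ")))
  invisible(x)
}

# Stratified fold assignment: within each class, seeded shuffle then
# round-robin fold labels.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Grid search for (C, gamma)
#'
#' Evaluates every pair in the configured geometric grids by mean stratified
#' k-fold accuracy and returns the maximizer. Ties at the maximal accuracy
#' are resolved by refitting the tied pairs on the full data and preferring
#' the fewest support vectors (the `#SV/n` bound on leave-one-out error),
#' then smaller C, then smaller gamma. A singleton grid is returned directly
#' without fitting.
#'
#' @param x Feature matrix.
#' @param y Labels.
#' @param config An [svm_config()].
#' @param seed Seed for the fold shuffle.
#' @return List with `C`, `gamma`, `accuracy` (inner-CV accuracy of the
#'   selected pair, `NA` for a singleton grid) and the full `table` of
#'   per-pair accuracies.
#' @export
grid_search <- function(x, y, config = svm_config(), seed = 1L) {
  x <- check_training_input(x, y)
  y <- as.character(y)
  cg <- config$c_grid
  gg <- config$gamma_grid
  if (length(cg) == 1L && length(gg) == 1L) {
    return(list(C = cg, gamma = gg, accuracy = NA_real_, table = NULL))
  }
  k <- config$inner_folds
  min_class <- min(table(y))
  if (min_class < k) {
    k <- max(2L, as.integer(min_class))
    warning(sprintf("reducing inner folds to %d (smallest class has %d samples)",
                    k, min_class), call. = FALSE)
  }
  fold <- stratified_folds(y, k, seed)
  grid <- expand.grid(gamma = gg, C = cg)  # C varies slowest
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      m <- train_svm(x[tr, , drop = FALSE], y[tr],
                     C = grid$C[g], gamma = grid$gamma[g], scale = config$scale)
      correct <- correct + sum(predict(m, x[!tr, , drop = FALSE]) == y[!tr])
    }
    acc[g] <- correct / length(y)
  }
  # Ties at the maximal CV accuracy are common on cleanly separable data
  # (every pair classifies the balanced folds perfectly, including near-
  # degenerate corners whose decision function is almost constant and
  # collapses to majority voting under the slight class imbalance of
  # leave-one-out). Among tied pairs we therefore prefer the model with the
  # fewest support vectors -- #SV/n upper-bounds the leave-one-out error --
  # and only then fall back to smaller C, then smaller gamma.
  tied <- which(acc == max(acc))
  if (length(tied) > 1L) {
    nsv <- vapply(tied, function(g) {
      m <- train_svm(x, y, C = grid$C[g], gamma = grid$gamma[g],
                     scale = config$scale)
      as.integer(m$fit$tot.nSV)
    }, integer(1))
    ord <- tied[order(nsv, grid$C[tied], grid$gamma[tied])]
    best <- ord[1]
  } else {
    best <- tied
  }
  list(C = grid$C[best], gamma = grid$gamma[best], accuracy = acc[best],
       table = cbind(grid[c("C", "gamma")], accuracy = acc))
}

#' Median-distance kernel width heuristic
#'
#' `gamma = 1 / median(||x_i - x_j||^2)` over all sample pairs: places the
#' RBF kernel in its locally-adaptive (interpolating) regime for the given
#' feature scale. Used by permutation / null controls, where a near-constant
#' kernel would collapse to majority voting instead of chance-level
#' prediction.
#'
#' @param x Feature matrix.
#' @return A positive scalar.
#' @export
median_gamma <- function(x) {
  d2 <- stats::median(stats::dist(as.matrix(x))^2)
  if (!is.finite(d2) || d2 <= 0) abort_compute("degenerate feature distances")
  1 / d2
}

# Resolve (C, gamma) for a dataset: fixed values if both set, else search.
resolve_hyperparams <- function(x, y, config, seed) {
  if (!is.null(config$C) && !is.null(config$gamma)) {
    list(C = config$C, gamma = config$gamma, accuracy = NA_real_, table = NULL)
  } else {
    grid_search(x, y, config, seed)
  }
}

#' Save / load a trained model
#'
#' The file embeds a schema version, the APAAC parameters, property-scale
#' checksums and the class list so that encode-time and predict-time
#' configurations cannot silently diverge.
#'
#' @param model An `apaac_svm`.
#' @param path File path.
#' @param params The [apaac_params()] used for encoding.
#' @param scales The scales used for encoding.
#' @return `path` invisibly (`save_model`); the model with metadata
#'   (`load_model`).
#' @export
save_model <- function(model, path, params = apaac_params(),
                       scales = default_scales()) {
  obj <- list(schema = 1L, model = model, params = unclass(params),
              checksums = c(h1 = scale_checksum(scales$h1),
                            h2 = scale_checksum(scales$h2)))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, scales = default_scales()) {
  obj <- readRDS(path)
  if (!identical(obj$schema, 1L)) abort_parse("unknown model schema version")
  now <- c(h1 = scale_checksum(scales$h1), h2 = scale_checksum(scales$h2))
  if (!identical(unname(obj$checksums), unname(now))) {
    abort_validation("property-scale checksum mismatch between model and current scales")
  }
  obj$model$params <- do.call(apaac_params, obj$params)
  obj$model
}
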