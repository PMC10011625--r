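# Jackknife evaluation, confusion tallies, per-class metrics and the
# (omega, lambda) sweep.

#' Jackknife (leave-one-out) prediction
#'
#' Each record is predicted by an SVM trained on all other records. In
#' `"fixed"` mode (C, gamma) are resolved once on the full dataset — by grid
#' search unless the configuration pins them — and reused in every fold; in
#' `"nested"` mode the grid search is re-run inside every fold (slower, less
#' optimistic).
#'
#' @param data A [protein_dataset()] with >= 2 classes.
#' @param params An [apaac_params()].
#' @param config An [svm_config()].
#' @param mode `"fixed"` (default) or `"nested"`.
#' @param seed Seed for fold shuffling in grid searches.
#' @param scales Standardized property scales.
#' @return Character vector of predicted labels, one per record in record
#'   order, with attribute `hyperparams` (the resolved C and gamma; a list
#'   per fold in nested mode).
#' @export
jackknife <- function(data, params = apaac_params(), config = svm_config(),
                      mode = c("fixed", "nested"), seed = 1L,
                      scales = default_scales()) {
  mode <- match.arg(mode)
  classes <- dataset_classes(data)
  if (length(classes) < 2) abort_validation("jackknife requires >= 2 classes")
  sizes <- table(factor(data$label, levels = classes))
  if (any(sizes < 2)) {
    warning(sprintf(
      "singleton class(es) %s can never be predicted correctly when held out",
      paste(names(sizes)[sizes < 2], collapse = ", ")), call. = FALSE)
  }
  enc <- encode_dataset(data, params, scales)
  x <- enc$x
  y <- enc$y
  n <- nrow(x)
  pred <- character(n)
  if (mode == "fixed") {
    hp <- resolve_hyperparams(x, y, config, seed)
    for (i in seq_len(n)) {
      m <- train_svm(x[-i, , drop = FALSE], y[-i], hp$C, hp$gamma,
                     scale = config$scale)
      pred[i] <- predict(m, x[i, , drop = FALSE])
    }
    attr(pred, "hyperparams") <- list(C = hp$C, gamma = hp$gamma, mode = mode)
  } else {
    hps <- vector("list", n)
    for (i in seq_len(n)) {
      hp <- resolve_hyperparams(x[-i, , drop = FALSE], y[-i], config, seed)
      m <- train_svm(x[-i, , drop = FALSE], y[-i], hp$C, hp$gamma,
                     scale = config$scale)
      pred[i] <- predict(m, x[i, , drop = FALSE])
      hps[[i]] <- list(C = hp$C, gamma = hp$gamma)
    }
    attr(pred, "hyperparams") <- list(per_fold = hps, mode = mode)
  }
  pred
}

#' Confusion matrix
#'
#' @param y_true,y_pred Equal-length label vectors; predicted labels must be
#'   a subset of the class set.
#' @param classes Optional ordered class labels; defaults to order of first
#'   appearance in `y_true` then `y_pred`.
#' @return Integer matrix, rows = true class, columns = predicted class.
#' @export
#' @examples
#' confusion(c("A", "A", "B"), c("A", "B", "B"))
confusion <- function(y_true, y_pred, classes = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort_validation("y_true and y_pred must have equal length")
  }
  if (is.null(classes)) classes <- unique(c(y_true, y_pred))
  if (!all(y_pred %in% classes) || !all(y_true %in% classes)) {
    abort_validation("labels outside the class set")
  }
  cm <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

# One-vs-rest binarization of a confusion matrix for one class.
binarize <- function(cm, cls) {
  if (!cls %in% rownames(cm)) abort_validation(sprintf("unknown class '%s'", cls))
  tp <- cm[cls, cls]
  fn <- sum(cm[cls, ]) - tp
  fp <- sum(cm[, cls]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Per-class sensitivity, specificity, precision and MCC
#'
#' One-vs-rest binarization of the confusion matrix:
#' `Sn = TP/(TP+FN)`, `Sp = TN/(TN+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`.
#' Precision (`PPV = TP/(TP+FP)`) is also reported because some published
#' tables in this literature print positive predictive value under the
#' heading Sp. Any 0/0 is returned as 0 and the metric is listed in
#' `undefined`.
#'
#' @param cm Confusion matrix from [confusion()].
#' @param cls Class label.
#' @return List with `Sn`, `Sp`, `PPV`, `MCC`, the binary tally, and the
#'   character vector `undefined`.
#' @export
class_metrics <- function(cm, cls) {
  b <- binarize(cm, cls)
  tp <- as.numeric(b["TP"]); fn <- as.numeric(b["FN"])
  fp <- as.numeric(b["FP"]); tn <- as.numeric(b["TN"])
  undef <- character(0)
  ratio <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(0) }
    num / den
  }
  sn <- ratio(tp, tp + fn, "Sn")
  sp <- ratio(tn, tn + fp, "Sp")
  ppv <- ratio(tp, tp + fp, "PPV")
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) { undef <- c(undef, "MCC"); 0 } else {
    (tp * tn - fp * fn) / sqrt(denom)
  }
  list(Sn = sn, Sp = sp, PPV = ppv, MCC = mcc, tally = b, undefined = undef)
}

#' Overall accuracy
#'
#' Fraction of correctly classified records: `trace(cm) / sum(cm)`. For two
#' classes this is `(TP + TN) / (TP + TN + FP + FN)`.
#'
#' @param cm Confusion matrix.
#' @return Number in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort_validation("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Per-class metrics report
#'
#' One row per class (`class`, `n`, `Sn`, `Sp`, `PPV`, `MCC`) with overall
#' accuracy and run metadata carried as attributes; the print method mirrors
#' the standard per-location results table of this literature.
#'
#' @param cm Confusion matrix.
#' @param meta Optional named list of run metadata (params, seeds, mode,
#'   grids, checksums) embedded in the report.
#' @return Data frame of class `metrics_report` with attributes `oa`, `cm`,
#'   `meta`, `undefined`.
#' @export
metrics_report <- function(cm, meta = list()) {
  classes <- rownames(cm)
  rows <- lapply(classes, function(cls) {
    m <- class_metrics(cm, cls)
    data.frame(class = cls, n = sum(cm[cls, ]), Sn = m$Sn, Sp = m$Sp,
               PPV = m$PPV, MCC = m$MCC, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  undef <- lapply(classes, function(cls) class_metrics(cm, cls)$undefined)
  names(undef) <- classes
  structure(out, class = c("metrics_report", "data.frame"),
            oa = overall_accuracy(cm), cm = cm, meta = meta,
            undefined = undef)
}

#' @export
print.metrics_report <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df[c("Sn", "Sp", "PPV", "MCC")] <- round(df[c("Sn", "Sp", "PPV", "MCC")], digits)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("OA (%%): %.1f\n", 100 * attr(x, "oa")))
  invisible(x)
}

#' Write a metrics report to TSV and JSON
#'
#' The TSV mirrors the per-location results-table layout (class, n, Sn, Sp,
#' PPV, MCC; footer row OA); the JSON additionally carries the confusion
#' matrix, metadata and undefined-metric flags.
#'
#' @param report A [metrics_report()].
#' @param tsv_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, the report.
#' @export
write_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    df <- as.data.frame(report)
    lines <- c(paste(names(df), collapse = "\t"),
               apply(df, 1, paste, collapse = "\t"),
               sprintf("OA\t%s\t\t\t\t", format(attr(report, "oa"))))
    writeLines(lines, tsv_path)
  }
  if (!is.null(json_path)) {
    obj <- list(per_class = as.data.frame(report),
                oa = attr(report, "oa"),
                confusion = list(classes = rownames(attr(report, "cm")),
                                 counts = unname(apply(attr(report, "cm"), 1,
                                                       as.integer, simplify = FALSE))),
                undefined = attr(report, "undefined"),
                meta = attr(report, "meta"))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(report)
}

#' Jackknife sweep over the (omega, lambda) grid
#'
#' Runs a full jackknife evaluation in every cell of the omega x lambda
#' grid, records the overall accuracy and selects the maximizer; ties are
#' broken by smaller lambda, then smaller omega. Defaults are the published
#' protocol grids: omega in {0.05, 0.1, 0.2, 0.3, 0.4, 0.5}, lambda in 2..9
#' (48 cells). Note the selection optimizes the same jackknife criterion it
#' reports, so the selected cell's accuracy is optimistically biased.
#'
#' @param data A [protein_dataset()].
#' @param omega_grid,lam_grid Numeric grids.
#' @param config An [svm_config()].
#' @param mode Jackknife mode, see [jackknife()].
#' @param seed Seed forwarded to every cell's jackknife.
#' @param scales Property scales.
#' @param keep_reports Retain the full [metrics_report()] per cell.
#' @return Object of class `apaac_sweep`: list with `table` (data frame
#'   omega, lam, oa), `best` (omega, lam, oa), and optionally `reports`.
#' @export
sweep_apaac <- function(data,
                        omega_grid = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                        lam_grid = 2:9,
                        config = svm_config(), mode = "fixed", seed = 1L,
                        scales = default_scales(), keep_reports = FALSE) {
  if (!length(omega_grid) || !length(lam_grid)) {
    abort_validation("omega_grid and lam_grid must be non-empty")
  }
  classes <- dataset_classes(data)
  # rows ordered by (lam, omega) ascending so the first maximum realizes the
  # tie-break: smaller lambda, then smaller omega
  cells <- expand.grid(omega = sort(unique(omega_grid)),
                       lam = sort(unique(lam_grid)))
  cells <- cells[order(cells$lam, cells$omega), , drop = FALSE]
  oa <- numeric(nrow(cells))
  reports <- if (keep_reports) vector("list", nrow(cells)) else NULL
  for (i in seq_len(nrow(cells))) {
    params <- apaac_params(lam = cells$lam[i], omega = cells$omega[i])
    pred <- jackknife(data, params, config, mode = mode, seed = seed,
                      scales = scales)
    cm <- confusion(data$label, pred, classes = classes)
    oa[i] <- overall_accuracy(cm)
    if (keep_reports) reports[[i]] <- metrics_report(cm)
  }
  best <- which.max(oa)
  structure(list(
    table = data.frame(omega = cells$omega, lam = cells$lam, oa = oa,
                       row.names = NULL),
    best = list(omega = cells$omega[best], lam = cells$lam[best], oa = oa[best]),
    reports = reports), class = "apaac_sweep")
}

#' @export
print.apaac_sweep <- function(x, ...) {
  cat(sprintf("apaac_sweep: %d cells; best OA %.4f at omega = %g, lambda = %d\n",
              nrow(x$table), x$best$oa, x$best$omega, x$best$lam))
  invisible(x)
}
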