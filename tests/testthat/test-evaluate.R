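# Small deterministic dataset that is trivially separable by composition:
# two classes of duplicated homopolymer-like sequences.
trivial_dataset <- function(n_per = 5) {
  ids <- c(sprintf("a%d", seq_len(n_per)), sprintf("b%d", seq_len(n_per)))
  seqs <- c(rep(strrep("ACACACACAC", 3), n_per),
            rep(strrep("KLKLKLKLKL", 3), n_per))
  suppressWarnings(protein_dataset(ids, seqs, rep(c("A", "B"), each = n_per)))
}

pinned_cfg <- function(C = 8, gamma = 1) {
  svm_config(C = C, gamma = gamma, c_grid = C, gamma_grid = gamma)
}

test_that("confusion tallies counts with conserved totals", {
  cm <- confusion(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(cm["A", "A"], 1L)
  expect_equal(cm["A", "B"], 1L)
  expect_equal(cm["B", "B"], 1L)
  expect_equal(sum(cm), 3L)

  y <- sample(c("x", "y", "z"), 50, replace = TRUE)
  cm2 <- confusion(y, y)
  expect_equal(sum(diag(cm2)), 50L)
  expect_equal(sum(cm2) - sum(diag(cm2)), 0L)
  expect_error(confusion(c("A", "B"), "A"), "equal length")
})

test_that("per-class metrics match hand-evaluated formulas", {
  m <- class_metrics(tally_cm(5, 0, 0, 5), "pos")
  expect_equal(m[c("Sn", "Sp", "MCC")], list(Sn = 1, Sp = 1, MCC = 1))

  m2 <- class_metrics(tally_cm(8, 2, 1, 9), "pos")
  expect_equal(m2$Sn, 0.8)
  expect_equal(m2$Sp, 0.9)
  expect_equal(m2$MCC, 70 / sqrt(9900), tolerance = 1e-12)
  expect_equal(m2$PPV, 8 / 9)
})

test_that("one-vs-rest tallies respect row/column marginals and MCC symmetry", {
  set.seed(41)
  y_true <- sample(c("a", "b", "c", "d"), 80, replace = TRUE)
  y_pred <- sample(c("a", "b", "c", "d"), 80, replace = TRUE)
  cm <- confusion(y_true, y_pred)
  for (cls in rownames(cm)) {
    m <- class_metrics(cm, cls)
    expect_equal(unname(m$tally["TP"] + m$tally["FN"]), sum(cm[cls, ]))
    expect_equal(unname(m$tally["TP"] + m$tally["FP"]), sum(cm[, cls]))
    # MCC invariant under TP<->TN, FP<->FN swap
    swapped <- class_metrics(tally_cm(m$tally["TN"], m$tally["FP"],
                                      m$tally["FN"], m$tally["TP"]), "pos")
    expect_equal(swapped$MCC, m$MCC, tolerance = 1e-12)
  }
})

test_that("overall accuracy is trace over total", {
  cm <- confusion(c("A", "A", "B"), c("A", "A", "B"))
  expect_equal(overall_accuracy(cm), 1)
  cm0 <- confusion(c("A", "A", "B"), c("B", "B", "A"))
  expect_equal(overall_accuracy(cm0), 0)
  m <- matrix(c(50, 3, 3, 42), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(overall_accuracy(m), 92 / 98)
  expect_error(overall_accuracy(matrix(0, 2, 2,
                                       dimnames = list(c("A", "B"), c("A", "B")))),
               "empty")
})

test_that("jackknife predicts every record from the others", {
  d <- trivial_dataset()
  pred <- jackknife(d, apaac_params(2, 0.1), pinned_cfg(), seed = 1)
  expect_length(pred, nrow(d))
  cm <- confusion(d$label, pred, dataset_classes(d))
  expect_equal(overall_accuracy(cm), 1)
  # OA equals independently recomputed mean per-record correctness
  expect_equal(overall_accuracy(cm), mean(pred == d$label))
})

test_that("jackknife warns on singleton classes, which score Sn 0", {
  d <- trivial_dataset(4)
  solo <- suppressWarnings(protein_dataset("solo", strrep("DEDEDEDEDE", 3), "C"))
  d2 <- suppressWarnings(protein_dataset(c(d$id, solo$id),
                                         c(d$sequence, solo$sequence),
                                         c(d$label, solo$label)))
  expect_warning(pred <- jackknife(d2, apaac_params(2, 0.1), pinned_cfg(),
                                   seed = 1),
                 "singleton")
  cm <- confusion(d2$label, pred, dataset_classes(d2))
  expect_equal(class_metrics(cm, "C")$Sn, 0)
  expect_error(jackknife(suppressWarnings(
    protein_dataset("x", "ACDEACDE", "only")), apaac_params(2, 0.1)),
    ">= 2 classes")
})

test_that("nested-mode jackknife re-searches per fold and stays exact here", {
  d <- trivial_dataset(3)
  cfg <- svm_config(c_grid = c(1, 8), gamma_grid = c(0.1, 1), inner_folds = 2)
  pred <- suppressWarnings(jackknife(d, apaac_params(2, 0.1), cfg,
                                     mode = "nested", seed = 1))
  expect_equal(mean(pred == d$label), 1)
  expect_equal(attr(pred, "hyperparams")$mode, "nested")
})

test_that("metrics report mirrors the per-location table layout", {
  d <- trivial_dataset()
  pred <- jackknife(d, apaac_params(2, 0.1), pinned_cfg(), seed = 1)
  cm <- confusion(d$label, pred, dataset_classes(d))
  rep <- metrics_report(cm, meta = list(lam = 2, omega = 0.1, seed = 1))
  expect_equal(rep$class, c("A", "B"))
  expect_equal(names(rep), c("class", "n", "Sn", "Sp", "PPV", "MCC"))
  expect_equal(attr(rep, "oa"), 1)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tsv, json)
  lines <- readLines(tsv)
  expect_match(lines[1], "^class\tn\tSn\tSp\tPPV\tMCC$")
  expect_match(lines[length(lines)], "^OA\t")
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$oa, 1)
  expect_equal(parsed$meta$lam, 2)
})

test_that("sweep enumerates the grid, selects by OA and breaks ties toward small lambda", {
  d <- trivial_dataset(4)
  sw <- sweep_apaac(d, omega_grid = 0.1, lam_grid = c(3, 7),
                    config = pinned_cfg(), seed = 1)
  expect_equal(nrow(sw$table), 2L)
  # trivially separable: both cells reach OA 1 and the tie goes to lambda 3
  expect_equal(sw$table$oa, c(1, 1))
  expect_equal(sw$best$lam, 3)

  # single cell sweep is bit-consistent with a direct jackknife run
  sw1 <- sweep_apaac(d, omega_grid = 0.2, lam_grid = 4,
                     config = pinned_cfg(), seed = 5)
  pred <- jackknife(d, apaac_params(4, 0.2), pinned_cfg(), seed = 5)
  oa <- overall_accuracy(confusion(d$label, pred, dataset_classes(d)))
  expect_identical(sw1$best$oa, oa)
  expect_identical(sw1$table$oa, oa)
})
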