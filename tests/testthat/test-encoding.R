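test_that("scale standardization matches a two-pass computation and is idempotent", {
  for (nm in c("hydrophobicity", "hydrophilicity")) {
    raw <- load_scale(system.file("extdata", paste0(nm, ".tsv"),
                                  package = "apaacsvm"), standardize = FALSE)
    std <- standardize_scale(raw)
    # independent two-pass mean / population-sd computation
    m <- sum(raw$values) / 20
    s <- sqrt(sum((raw$values - m)^2) / 20)
    expect_equal(std$values, (raw$values - m) / s, tolerance = 1e-12)
    expect_lt(abs(mean(std$values)), 1e-12)
    expect_lt(abs(sqrt(mean((std$values - mean(std$values))^2)) - 1), 1e-12)
    # fixed point
    expect_identical(standardize_scale(std), std)
  }
  flat <- aa_scale("flat", setNames(rep(1, 20), aa_alphabet()))
  expect_error(standardize_scale(flat), "degenerate scale")
})

test_that("aac computes occurrence frequencies in the canonical residue order", {
  expect_equal(unname(aac(paste(aa_alphabet(), collapse = ""))), rep(0.05, 20))
  v <- aac("AAAA")
  expect_equal(unname(v[1]), 1)
  expect_equal(sum(v[-1]), 0)
  expect_equal(unname(aac("AAC")[1:2]), c(2 / 3, 1 / 3))
  expect_error(aac(""), "non-empty")

  set.seed(11)
  for (i in 1:25) {
    s <- random_seq(sample(5:200, 1))
    v <- aac(s)
    expect_lt(abs(sum(v) - 1), 1e-12)
    expect_equal(unname(v), unname(oracle_aac(s)), tolerance = 1e-15)
    # shuffle invariance
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(aac(sh), v, tolerance = 1e-15)
  }
})

test_that("correlation factors: closed forms, reversal invariance, order sensitivity", {
  h1 <- std_scales$h1; h2 <- std_scales$h2
  tau <- correlation_factors("AAAAAA", 2, h1, h2)
  expect_equal(unname(tau), rep(c(h1$values[["A"]]^2, h2$values[["A"]]^2), 2),
               tolerance = 1e-15)

  set.seed(12)
  for (i in 1:20) {
    s <- random_seq(sample(10:120, 1))
    lam <- sample(1:5, 1)
    tau <- correlation_factors(s, lam, h1, h2)
    rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    expect_equal(correlation_factors(rev_s, lam, h1, h2), tau, tolerance = 1e-12)
  }

  # a shuffle generically changes tau for a non-constant sequence
  set.seed(13)
  s <- random_seq(60)
  tau <- correlation_factors(s, 2, h1, h2)
  changed <- FALSE
  for (i in 1:20) {
    sh <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    if (max(abs(correlation_factors(sh, 2, h1, h2) - tau)) > 1e-6) changed <- TRUE
  }
  expect_true(changed)

  expect_error(correlation_factors("ACD", 3, h1, h2), "length 3")
  raw <- load_scale(system.file("extdata", "hydrophobicity.tsv",
                                package = "apaacsvm"), standardize = FALSE)
  expect_error(correlation_factors("ACDEFG", 2, raw, h2), "standardized")
})

test_that("correlation factors agree with the nested-loop oracle", {
  h1 <- std_scales$h1; h2 <- std_scales$h2
  h1v <- raw_scale_values(h1); h2v <- raw_scale_values(h2)
  set.seed(14)
  s <- random_seq(12)
  expect_equal(unname(correlation_factors(s, 3, h1, h2)),
               oracle_tau(s, 3, h1v, h2v), tolerance = 1e-12)
  for (i in 1:15) {
    s <- random_seq(sample(15:100, 1))
    lam <- sample(1:9, 1)
    expect_equal(unname(correlation_factors(s, lam, h1, h2)),
                 oracle_tau(s, lam, h1v, h2v), tolerance = 1e-12)
  }
})

test_that("apaac reduces to aac at lambda 0, sums to one, recovers aac as omega -> 0", {
  set.seed(15)
  for (i in 1:10) {
    s <- random_seq(sample(10:150, 1))
    expect_equal(as.numeric(apaac(s, apaac_params(0, 0.3))), unname(aac(s)),
                 tolerance = 1e-15)
    v <- apaac(s, apaac_params(sample(1:9, 1), runif(1, 0.05, 0.5)))
    expect_lt(abs(sum(v) - 1), 1e-9)
    # omega -> 0+ limit
    v0 <- apaac(s, apaac_params(4, 1e-12))
    expect_equal(unname(v0[1:20]), unname(aac(s)), tolerance = 1e-9)
    expect_lt(max(abs(v0[21:28])), 1e-9)
  }
})

test_that("apaac matches the composed brute-force oracle", {
  h1v <- raw_scale_values(std_scales$h1); h2v <- raw_scale_values(std_scales$h2)
  set.seed(16)
  s <- random_seq(30)
  expect_equal(as.numeric(apaac(s, apaac_params(7, 0.1))),
               oracle_apaac(s, 7, 0.1, h1v, h2v), tolerance = 1e-12)
})

test_that("encode_dataset shapes, alignment and length validation", {
  set.seed(17)
  d3 <- suppressWarnings(protein_dataset(
    c("a", "b", "c"), c(random_seq(30), random_seq(40), random_seq(50)),
    c("x", "y", "x")))
  enc <- encode_dataset(d3, apaac_params(7, 0.1))
  expect_equal(dim(enc$x), c(3L, 34L))
  expect_equal(rownames(enc$x), d3$id)
  expect_equal(enc$y, d3$label)
  expect_equal(unname(enc$x[2, ]),
               as.numeric(apaac(d3$sequence[2], apaac_params(7, 0.1))))

  empty <- protein_dataset(character(), character())
  expect_equal(nrow(encode_dataset(empty, apaac_params(2, 0.1))$x), 0L)

  short <- protein_dataset(c("s1", "s2", "ok"),
                           c("ACDE", "GHIK", random_seq(30)))
  err <- tryCatch(encode_dataset(short, apaac_params(7, 0.1)),
                  error = conditionMessage)
  expect_match(err, "s1")
  expect_match(err, "s2")
  expect_no_match(err, "\\bok\\b")
})

test_that("feature matrices written to TSV carry self-describing headers", {
  d <- generate_dataset(2, 3, c(40, 60), seed = 4)
  enc <- encode_dataset(d, apaac_params(2, 0.1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_features(enc, f)
  tab <- read.delim(f, check.names = FALSE)
  expect_equal(names(tab)[1:2], c("id", "label"))
  expect_equal(names(tab)[3:6], c("Pc1.A", "Pc1.C", "Pc1.D", "Pc1.E"))
  expect_equal(names(tab)[23:26], c("Pc2.Hb.1", "Pc2.Hl.1", "Pc2.Hb.2", "Pc2.Hl.2"))
  expect_equal(as.matrix(tab[, -(1:2)]), enc$x, tolerance = 1e-12,
               ignore_attr = TRUE)
})
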