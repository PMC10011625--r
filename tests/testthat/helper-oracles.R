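# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals) so they can arbitrate the vectorized implementations.

random_seq <- function(L) {
  paste(sample(aa_alphabet(), L, replace = TRUE), collapse = "")
}

# Naive nested-loop lag correlation factors.
oracle_tau <- function(sequence, lam, h1_values, h2_values) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  out <- numeric(2 * lam)
  for (j in seq_len(lam)) {
    s1 <- 0; s2 <- 0
    for (i in seq_len(L - j)) {
      s1 <- s1 + h1_values[[chars[i]]] * h1_values[[chars[i + j]]]
      s2 <- s2 + h2_values[[chars[i]]] * h2_values[[chars[i + j]]]
    }
    out[2 * j - 1] <- s1 / (L - j)
    out[2 * j] <- s2 / (L - j)
  }
  out
}

# Naive per-residue frequency count.
oracle_aac <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  vapply(aa_alphabet(), function(a) sum(chars == a), numeric(1)) / length(chars)
}

# Full composition: frequencies + weighted correlation factors with the
# explicit joint normalization.
oracle_apaac <- function(sequence, lam, omega, h1_values, h2_values) {
  f <- oracle_aac(sequence)
  tau <- if (lam > 0) oracle_tau(sequence, lam, h1_values, h2_values) else numeric(0)
  D <- sum(f) + omega * sum(tau)
  unname(c(f / D, omega * tau / D))
}

# Direct evaluation of the binary-tally metric formulas, with 0/0 -> 0.
oracle_binary_metrics <- function(tp, fn, fp, tn) {
  div0 <- function(num, den) if (den == 0) 0 else num / den
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  list(
    Sn = div0(tp, tp + fn),
    Sp = div0(tn, tn + fp),
    PPV = div0(tp, tp + fp),
    MCC = if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom),
    OA = div0(tp + tn, tp + tn + fp + fn)
  )
}

# Build the 2x2 confusion matrix realizing a binary tally.
tally_cm <- function(tp, fn, fp, tn) {
  matrix(as.integer(c(tp, fn, fp, tn)), nrow = 2, byrow = TRUE,
         dimnames = list(true = c("pos", "neg"), predicted = c("pos", "neg")))
}

# Raw scale values keyed by residue, for the oracles.
raw_scale_values <- function(scale) as.list(scale$values)

std_scales <- default_scales()
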