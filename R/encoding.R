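# AAC and APAAC feature encoding.

#' APAAC parameters
#'
#' @param lam Sequence-order rank lambda: maximum lag over which
#'   residue-property correlations are computed. Non-negative integer;
#'   `lam = 0` reduces APAAC to plain amino-acid composition.
#' @param omega Weight omega (> 0) balancing the correlation factors against
#'   the composition terms in the joint normalization.
#' @return List of class `apaac_params`.
#' @export
apaac_params <- function(lam = 7L, omega = 0.1) {
  if (length(lam) != 1L || is.na(lam) || lam != as.integer(lam) || lam < 0) {
    abort_validation("lam must be a single integer >= 0")
  }
  if (length(omega) != 1L || is.na(omega) || omega <= 0) {
    abort_validation("omega must be a single number > 0")
  }
  structure(list(lam = as.integer(lam), omega = as.numeric(omega)),
            class = "apaac_params")
}

#' Amino-acid composition (AAC)
#'
#' The 20-dimensional vector of residue occurrence frequencies, in the fixed
#' order of [aa_alphabet()]. Components sum to 1.
#'
#' @param sequence Sanitized sequence string.
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' aac("AAC")
aac <- function(sequence) {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence)) {
    abort_validation("sequence must be a single non-empty string")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = aa_alphabet()))
  if (sum(counts) != length(chars)) {
    abort_validation("sequence contains characters outside the 20-letter alphabet")
  }
  out <- as.numeric(counts) / length(chars)
  names(out) <- paste0("Pc1.", aa_alphabet())
  out
}

#' Sequence-order correlation factors
#'
#' For each lag `j = 1..lam` computes the average product of standardized
#' property values of residues `j` positions apart:
#' `tau[2j-1] = mean_i h1(R_i) * h1(R_(i+j))` over the `L - j` pairs, and
#' `tau[2j]` likewise for `h2`. Hydrophobicity precedes hydrophilicity at
#' each lag; values may be negative.
#'
#' @param sequence Sanitized sequence of length `L >= lam + 1`.
#' @param lam Maximum lag (>= 0).
#' @param h1,h2 Standardized [aa_scale()] objects (hydrophobicity,
#'   hydrophilicity).
#' @return Numeric vector of length `2 * lam`.
#' @export
correlation_factors <- function(sequence, lam, h1, h2) {
  stopifnot(inherits(h1, "aa_scale"), inherits(h2, "aa_scale"))
  if (!h1$standardized || !h2$standardized) {
    abort_validation("correlation factors require standardized scales")
  }
  lam <- as.integer(lam)
  if (lam == 0L) return(numeric(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (L <= lam) {
    abort_validation(sprintf("sequence length %d <= lambda %d; need L >= lambda + 1",
                             L, lam))
  }
  v1 <- unname(h1$values[chars])
  v2 <- unname(h2$values[chars])
  if (anyNA(v1) || anyNA(v2)) {
    abort_validation("sequence contains characters outside the 20-letter alphabet")
  }
  tau <- numeric(2L * lam)
  for (j in seq_len(lam)) {
    idx <- seq_len(L - j)
    tau[2L * j - 1L] <- sum(v1[idx] * v1[idx + j]) / (L - j)
    tau[2L * j]      <- sum(v2[idx] * v2[idx + j]) / (L - j)
  }
  names(tau) <- as.vector(rbind(paste0("Pc2.Hb.", seq_len(lam)),
                                paste0("Pc2.Hl.", seq_len(lam))))
  tau
}

#' Amphiphilic pseudo amino acid composition (APAAC)
#'
#' Encodes a sequence as the `20 + 2*lam` vector combining amino-acid
#' frequencies `f` with omega-weighted correlation factors `tau`, jointly
#' normalized by `D = 1 + omega * sum(tau)`:
#' the first 20 components are `f_u / D`, the remaining `2*lam` are
#' `omega * tau_j / D`. All components sum to 1.
#'
#' @param sequence Sanitized sequence of length `L >= lam + 1`.
#' @param params An [apaac_params()] (or `lam`/`omega` passed individually).
#' @param scales List with standardized scales `h1` and `h2`; defaults to
#'   [default_scales()].
#' @return Named numeric vector of length `20 + 2 * lam` with attributes
#'   `lam` and `omega`.
#' @export
#' @examples
#' v <- apaac("MKVLAAGIVLLLSAAP", apaac_params(lam = 3, omega = 0.1))
#' sum(v)
apaac <- function(sequence, params = apaac_params(), scales = default_scales()) {
  stopifnot(inherits(params, "apaac_params"))
  f <- aac(sequence)
  tau <- correlation_factors(sequence, params$lam, scales$h1, scales$h2)
  D <- 1 + params$omega * sum(tau)
  if (abs(D) <= 1e-9) {
    abort_compute("degenerate normalization: 1 + omega * sum(tau) is ~0")
  }
  out <- c(f, params$omega * tau) / D
  attr(out, "lam") <- params$lam
  attr(out, "omega") <- params$omega
  out
}

#' Encode a dataset as an APAAC feature matrix
#'
#' @param data A [protein_dataset()].
#' @param params An [apaac_params()].
#' @param scales Standardized scales as in [apaac()].
#' @return List with `x` (numeric matrix, one row per record, row names =
#'   ids), `y` (character label vector aligned to rows) and `params`.
#' @export
encode_dataset <- function(data, params = apaac_params(),
                           scales = default_scales()) {
  stopifnot(inherits(data, "protein_dataset"))
  p <- 20L + 2L * params$lam
  too_short <- nchar(data$sequence) < params$lam + 1L
  if (any(too_short)) {
    abort_validation(sprintf(
      "sequence(s) shorter than lambda + 1 = %d: %s", params$lam + 1L,
      paste(data$id[too_short], collapse = ", ")))
  }
  x <- matrix(0, nrow = nrow(data), ncol = p)
  for (i in seq_len(nrow(data))) {
    x[i, ] <- apaac(data$sequence[i], params, scales)
  }
  colnames(x) <- names(apaac_colnames(params$lam))
  rownames(x) <- data$id
  list(x = x, y = data$label, params = params)
}

apaac_colnames <- function(lam) {
  nm <- paste0("Pc1.", aa_alphabet())
  if (lam > 0) {
    nm <- c(nm, as.vector(rbind(paste0("Pc2.Hb.", seq_len(lam)),
                                paste0("Pc2.Hl.", seq_len(lam)))))
  }
  stats::setNames(seq_along(nm), nm)
}

#' Write a feature matrix to TSV
#'
#' Header row carries the canonical column names (`Pc1.A` ... then
#' `Pc2.Hb.j` / `Pc2.Hl.j` per lag); first column is the record id, second
#' the label when present.
#'
#' @param encoded Result of [encode_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(encoded, path) {
  df <- data.frame(id = rownames(encoded$x), label = encoded$y,
                   encoded$x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
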