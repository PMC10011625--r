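# Internal helpers shared across modules.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter residue codes in the fixed alphabetical order used by
#' every feature vector produced by this package.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Classed conditions so the CLI can map error families to exit codes.
abort_parse <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("apaac_parse_error", "error", "condition")))
}

abort_validation <- function(msg) {
  stop(errorCondition(msg, class = c("apaac_validation_error", "error", "condition")))
}

abort_compute <- function(msg) {
  stop(errorCondition(msg, class = c("apaac_compute_error", "error", "condition")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
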