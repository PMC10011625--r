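# Amino-acid property scales: loading and standardization.

#' Construct an amino-acid property scale
#'
#' @param name Scale name (e.g. `"hydrophobicity"`).
#' @param values Numeric vector of length 20 named by the residues of
#'   [aa_alphabet()] (any order; stored in canonical order).
#' @param standardized Logical; `TRUE` only if `values` already have mean 0
#'   and population standard deviation 1 over the 20 residues.
#' @return An object of class `aa_scale`.
#' @export
aa_scale <- function(name, values, standardized = FALSE) {
  if (length(values) != 20L || is.null(names(values))) {
    abort_validation("scale must be a named numeric vector of 20 residue values")
  }
  if (!setequal(names(values), aa_alphabet())) {
    abort_validation("scale names must be exactly the 20 standard residues")
  }
  values <- values[aa_alphabet()]
  if (standardized) {
    m <- mean(values)
    s <- sqrt(mean((values - m)^2))
    if (abs(m) > 1e-12 || abs(s - 1) > 1e-12) {
      abort_validation("scale marked standardized but mean/popsd are not 0/1")
    }
  }
  structure(list(name = name, values = values, standardized = standardized),
            class = "aa_scale")
}

#' @export
print.aa_scale <- function(x, ...) {
  cat(sprintf("aa_scale '%s' (%s)\n", x$name,
              if (x$standardized) "standardized" else "raw"))
  print(round(x$values, 4))
  invisible(x)
}

#' Standardize a property scale
#'
#' Converts raw property values to zero mean and unit population standard
#' deviation over the 20 residues:
#' `h(i) = (h0(i) - mean(h0)) / popsd(h0)`. Idempotent on already
#' standardized scales.
#'
#' @param scale An [aa_scale()].
#' @return A standardized `aa_scale`.
#' @export
standardize_scale <- function(scale) {
  stopifnot(inherits(scale, "aa_scale"))
  if (scale$standardized) return(scale)
  v <- scale$values
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s <= 0) abort_validation(sprintf("degenerate scale '%s': zero variance", scale$name))
  aa_scale(scale$name, (v - m) / s, standardized = TRUE)
}

#' Load a property scale from a TSV file
#'
#' File format: 20 lines of `residue<TAB>value`, `#` comments allowed.
#'
#' @param path File path.
#' @param name Scale name; defaults to the file stem.
#' @param standardize Standardize after loading (default `TRUE`).
#' @return An [aa_scale()].
#' @export
load_scale <- function(path, name = NULL, standardize = TRUE) {
  if (!file.exists(path)) abort_parse(sprintf("scale file not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) abort_parse("scale file must be residue<TAB>value")
  v <- as.numeric(tab[[2]])
  names(v) <- toupper(trimws(tab[[1]]))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  out <- aa_scale(name, v)
  if (standardize) out <- standardize_scale(out)
  out
}

#' Default APAAC property scales
#'
#' The hydrophobicity table of the classic pseudo amino acid composition
#' descriptor and the Hopp-Woods hydrophilicity table, shipped as editable
#' TSV files under `extdata/` and standardized at load.
#'
#' @param standardize Standardize the scales (default `TRUE`).
#' @return List with elements `h1` (hydrophobicity) and `h2`
#'   (hydrophilicity).
#' @export
#' @examples
#' sc <- default_scales()
#' round(sc$h1$values, 3)
default_scales <- function(standardize = TRUE) {
  list(
    h1 = load_scale(system.file("extdata", "hydrophobicity.tsv",
                                package = "apaacsvm"),
                    "hydrophobicity", standardize),
    h2 = load_scale(system.file("extdata", "hydrophilicity.tsv",
                                package = "apaacsvm"),
                    "hydrophilicity", standardize)
  )
}

# Stable fingerprint of a scale's values, embedded in reports so encode-time
# and predict-time configurations cannot silently diverge.
scale_checksum <- function(scale) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(scale$values),
                   formatC(scale$values, digits = 15, format = "g"),
                   sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}
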