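# Reading, validating and labeling protein sequences.

#' Construct a labeled protein dataset
#'
#' A `protein_dataset` is a data frame with columns `id`, `sequence` and
#' `label` (label may be `NA` until labeling). Sequences must use the
#' 20-letter standard amino-acid alphabet; ids must be unique and non-empty.
#'
#' @param id Character vector of record identifiers.
#' @param sequence Character vector of amino-acid sequences (already
#'   sanitized; see [sanitize_sequence()]).
#' @param label Optional character vector of class labels (subcellular
#'   locations). Defaults to `NA`.
#' @return An object of class `protein_dataset` (a data frame).
#' @export
#' @examples
#' d <- protein_dataset(c("p1", "p2"), c("ACDE", "GGGGG"), c("Cyto", "Memb"))
#' dataset_classes(d)
protein_dataset <- function(id, sequence, label = NA_character_) {
  id <- as.character(id)
  sequence <- as.character(sequence)
  label <- rep_len(as.character(label), length(id))
  if (length(sequence) != length(id)) {
    abort_validation("id and sequence must have equal length")
  }
  if (any(!nzchar(id))) abort_validation("record ids must be non-empty")
  if (anyDuplicated(id)) {
    abort_validation(sprintf("duplicate record id(s): %s",
                             paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  bad <- grepl(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), sequence)
  if (any(bad)) {
    abort_validation(sprintf(
      "sequence(s) contain characters outside the 20-letter alphabet: %s",
      paste(id[bad], collapse = ", ")))
  }
  if (any(!nzchar(sequence))) {
    abort_validation(sprintf("empty sequence(s): %s",
                             paste(id[!nzchar(sequence)], collapse = ", ")))
  }
  dup_seq <- duplicated(sequence)
  if (any(dup_seq)) {
    warning(sprintf(
      "%d duplicate sequence(s) under distinct ids; duplicates bias jackknife estimates",
      sum(dup_seq)), call. = FALSE)
  }
  structure(data.frame(id = id, sequence = sequence, label = label,
                       stringsAsFactors = FALSE),
            class = c("protein_dataset", "data.frame"))
}

#' Ordered class labels of a dataset
#'
#' @param data A [protein_dataset()].
#' @return Character vector of distinct non-missing labels in order of first
#'   appearance.
#' @export
dataset_classes <- function(data) {
  lab <- data$label
  unique(lab[!is.na(lab)])
}

#' @export
print.protein_dataset <- function(x, ...) {
  cls <- dataset_classes(x)
  cat(sprintf("protein_dataset: %d record(s), %d class(es)\n", nrow(x), length(cls)))
  if (length(cls)) {
    tab <- table(factor(x$label, levels = cls))
    cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Sanitize a raw amino-acid sequence
#'
#' Uppercases, removes whitespace and gap characters, then applies the
#' nonstandard-residue policy. `strict` rejects any character outside the
#' 20-letter alphabet; `drop` removes ambiguity codes and other nonstandard
#' characters (B, J, O, U, X, Z, ...) with a warning.
#'
#' @param raw Raw sequence string.
#' @param policy `"strict"` (default) or `"drop"`.
#' @return Sanitized sequence string.
#' @export
#' @examples
#' sanitize_sequence("acd e", "strict")
#' suppressWarnings(sanitize_sequence("ACDX", "drop"))
sanitize_sequence <- function(raw, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  if (length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    abort_validation("raw sequence must be a single non-empty string")
  }
  x <- toupper(gsub("[\\s.*-]+", "", raw, perl = TRUE))
  if (!nzchar(x)) abort_validation("sequence empty after removing whitespace/gaps")
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  ok <- chars %in% aa_alphabet()
  if (all(ok)) return(x)
  if (policy == "strict") {
    i <- which(!ok)[1]
    abort_validation(sprintf(
      "nonstandard residue '%s' at position %d (strict policy)", chars[i], i))
  }
  warning(sprintf("dropped %d nonstandard residue(s): %s", sum(!ok),
                  paste(unique(chars[!ok]), collapse = ", ")), call. = FALSE)
  out <- paste(chars[ok], collapse = "")
  if (!nzchar(out)) abort_validation("sequence empty after dropping nonstandard residues")
  out
}

#' Read a labeled FASTA file
#'
#' Multi-line bodies are concatenated, whitespace stripped and letters
#' uppercased; record order is preserved. Labels come either from the FASTA
#' header convention `>id|class` or from a separate tab-separated table
#' `id<TAB>class` supplied via `labels`.
#'
#' @param path FASTA file path.
#' @param labels Optional label source: a path to a TSV file or a data frame
#'   with columns `id` and `label`. When given, every FASTA id must appear in
#'   the table. When `NULL`, headers of the form `id|class` are split; plain
#'   headers yield unlabeled records.
#' @param policy Sanitization policy passed to [sanitize_sequence()].
#' @return A [protein_dataset()].
#' @export
read_fasta <- function(path, labels = NULL, policy = c("strict", "drop")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) abort_parse(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^>", lines) & nzchar(trimws(lines)))
  first_hdr <- which(grepl("^>", lines))[1]
  if (length(body) && (is.na(first_hdr) || body[1] < first_hdr)) {
    abort_parse(sprintf("malformed FASTA: sequence body before first header at line %d",
                        body[1]))
  }
  if (is.na(first_hdr)) {
    return(protein_dataset(character(), character()))
  }
  seqs <- Biostrings::readBStringSet(path)
  headers <- names(seqs)
  # header token up to first whitespace; optional `id|class` split
  token <- sub("\\s.*$", "", headers)
  has_label <- grepl("|", token, fixed = TRUE)
  id <- ifelse(has_label, sub("\\|.*$", "", token), token)
  hdr_label <- ifelse(has_label, sub("^[^|]*\\|", "", token), NA_character_)
  if (any(!nzchar(id))) abort_parse("FASTA header with empty id")
  if (anyDuplicated(id)) {
    abort_parse(sprintf("duplicate FASTA id(s): %s",
                        paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  label <- hdr_label
  if (!is.null(labels)) {
    tab <- if (is.character(labels)) read_label_table(labels) else labels
    if (!all(c("id", "label") %in% names(tab))) {
      abort_parse("label table must have columns id and label")
    }
    m <- match(id, tab$id)
    if (anyNA(m)) {
      abort_validation(sprintf("id(s) missing from label table: %s",
                               paste(id[is.na(m)], collapse = ", ")))
    }
    label <- as.character(tab$label)[m]
  }
  seq_chr <- vapply(as.character(seqs), sanitize_sequence, character(1),
                    policy = policy, USE.NAMES = FALSE)
  protein_dataset(id, seq_chr, label)
}

read_label_table <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("label table not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) abort_parse("label table must be two tab-separated columns")
  data.frame(id = as.character(tab[[1]]), label = as.character(tab[[2]]),
             stringsAsFactors = FALSE)
}

#' Write a dataset as FASTA (and optionally a label table)
#'
#' Headers are `>id|label` for labeled records, `>id` otherwise, so that
#' [read_fasta()] is an exact inverse.
#'
#' @param data A [protein_dataset()].
#' @param path Output FASTA path.
#' @param label_path Optional path for a TSV label table `id<TAB>label`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path, label_path = NULL) {
  nm <- ifelse(is.na(data$label), data$id, paste(data$id, data$label, sep = "|"))
  x <- Biostrings::BStringSet(data$sequence)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, width = 60L)
  if (!is.null(label_path)) {
    utils::write.table(data.frame(id = data$id, label = data$label),
                       label_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Load a dataset manifest
#'
#' A manifest is a two-column tab-separated file `class<TAB>accession`
#' (comment lines starting with `#` allowed) that records the published class
#' membership of a benchmark set. Templates for the CL317, ZW225 and ZD98
#' apoptosis-protein benchmarks, with placeholder accessions, ship under
#' `system.file("extdata", "manifests", package = "apaacsvm")`.
#'
#' @param path Manifest file path.
#' @return Named list mapping each class (in order of first appearance) to
#'   its character vector of accessions, with attribute `total`.
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) abort_parse(sprintf("manifest not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  cls <- character(0); acc <- character(0)
  for (i in keep) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    parts <- parts[nzchar(trimws(parts))]
    if (length(parts) != 2) {
      abort_parse(sprintf("manifest line %d is not two tab-separated fields", i))
    }
    cls <- c(cls, trimws(parts[1])); acc <- c(acc, trimws(parts[2]))
  }
  if (anyDuplicated(acc)) {
    abort_validation(sprintf("accession(s) listed more than once: %s",
                             paste(unique(acc[duplicated(acc)]), collapse = ", ")))
  }
  out <- split(acc, factor(cls, levels = unique(cls)))
  attr(out, "total") <- length(acc)
  out
}

#' Fetch manifest sequences from UniProt (network helper)
#'
#' Resolves a manifest's accessions against the UniProt REST API and writes a
#' labeled FASTA. Purely a convenience for rebuilding published benchmark
#' sets; requires network access and is not used anywhere else in the
#' package.
#'
#' @param manifest Named list from [load_manifest()].
#' @param path Output FASTA path.
#' @param base_url UniProt REST endpoint.
#' @return `path`, invisibly.
#' @export
fetch_manifest <- function(manifest, path,
                           base_url = "https://rest.uniprot.org/uniprotkb") {
  con <- file(path, "w"); on.exit(close(con))
  for (cls in names(manifest)) {
    for (acc in manifest[[cls]]) {
      url <- sprintf("%s/%s.fasta", base_url, acc)
      txt <- tryCatch(readLines(url, warn = FALSE), error = function(e) NULL)
      if (is.null(txt)) {
        warning(sprintf("could not fetch %s", acc), call. = FALSE)
        next
      }
      seq <- paste(txt[-1], collapse = "")
      writeLines(c(sprintf(">%s|%s", acc, cls), seq), con)
    }
  }
  invisible(path)
}
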