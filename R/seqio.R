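#' Sequence record
#'
#' The universal input unit: an identifier, optional description, residue
#' string and molecule type. Residues are uppercased at construction and
#' validated against the molecule's alphabet.
#'
#' @param id Record identifier (unique within a set).
#' @param residues Residue string (non-empty).
#' @param molecule `"protein"`, `"dna"` or `"rna"`.
#' @param description Free-text description.
#' @param validate Reject residues outside the unambiguous alphabet
#'   (default). Ambiguity codes (B, Z, X, U in protein context, '*', ...)
#'   are errors naming the offending position; silent remapping would
#'   corrupt descriptor comparability.
#' @return A `seq_record`.
#' @export
#' @examples
#' r <- seq_record("frag1", "IGIHVGR", "protein")
#' seq_chars(r)
seq_record <- function(id, residues, molecule = c("protein", "dna", "rna"),
                       description = "", validate = TRUE) {
  molecule <- match.arg(molecule)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop(sprintf("record '%s': empty sequence", id))
  if (validate) {
    alpha <- residue_alphabet(molecule)
    chars <- strsplit(residues, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% alpha$symbols)
    if (length(bad))
      stop(sprintf("record '%s': illegal %s residue '%s' at position %d",
                   id, molecule, chars[bad[1]], bad[1]))
  }
  structure(list(id = id, description = description,
                 residues = residues, molecule = molecule),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s, %d residues]\n", x$id, x$molecule,
              nchar(x$residues)))
  invisible(x)
}

#' Residues of a record as a character vector
#' @param seq A `seq_record` or plain residue string.
#' @return Character vector of single residues, uppercased.
#' @export
seq_chars <- function(seq) {
  s <- if (inherits(seq, "seq_record")) seq$residues else toupper(seq)
  strsplit(s, "", fixed = TRUE)[[1]]
}

seq_length <- function(seq) {
  if (inherits(seq, "seq_record")) nchar(seq$residues) else nchar(seq)
}

#' Read a FASTA file into sequence records
#'
#' Wraps the Biostrings FASTA reader and applies the package's validation
#' contract: ids are the first whitespace-delimited header token, residues
#' are uppercased, gap characters `-` are stripped with a warning, and
#' duplicate ids or illegal residues are errors naming the record.
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @param molecule Declared molecule type of all records.
#' @return List of [seq_record()]s in file order.
#' @export
read_fasta <- function(path, molecule = c("protein", "dna", "rna")) {
  molecule <- match.arg(molecule)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("empty FASTA file: %s", path))
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  descs <- sub("^\\S+\\s*", "", headers)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- toupper(as.character(set[[i]]))
    if (grepl("-", s, fixed = TRUE)) {
      warning(sprintf("record '%s': stripping gap characters", ids[i]))
      s <- gsub("-", "", s, fixed = TRUE)
    }
    out[[i]] <- seq_record(ids[i], s, molecule, descs[i])
  }
  out
}

#' Write sequence records to FASTA
#'
#' @param records List of [seq_record()]s.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    s <- r$residues
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- similarity matrices ----------------------------------------------

SYMMETRIC_MEASURES <- c("identity_pct", "similarity_pct", "af_distance")
MATRIX_MEASURES <- c(SYMMETRIC_MEASURES, "bitscore")

#' All-vs-all similarity matrix container
#'
#' @param values Square numeric matrix.
#' @param labels Unique sequence ids (row/column order).
#' @param measure One of `"identity_pct"`, `"similarity_pct"`,
#'   `"bitscore"`, `"af_distance"`.
#' @param diagonal One-line statement of the diagonal convention.
#' @return A `similarity_matrix`.
#' @export
similarity_matrix <- function(values, labels, measure,
                              diagonal = "self-comparison") {
  measure <- match.arg(measure, MATRIX_MEASURES)
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(labels) == nrow(values))
  if (anyDuplicated(labels)) stop("similarity matrix labels must be unique")
  if (measure %in% c("identity_pct", "similarity_pct") &&
      (min(values) < -1e-9 || max(values) > 100 + 1e-9))
    stop(sprintf("%s entries must lie in [0, 100]", measure))
  if (measure %in% SYMMETRIC_MEASURES &&
      max(abs(values - t(values))) >= 1e-9)
    stop(sprintf("matrix tagged with symmetric measure '%s' is asymmetric",
                 measure))
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, measure = measure,
                 diagonal_convention = diagonal),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d x %d, measure = %s\n",
              nrow(x$values), ncol(x$values), x$measure))
  invisible(x)
}

#' Write a similarity matrix as TSV
#'
#' Header row and column of labels; values at 4 decimal places; the
#' measure and diagonal convention are recorded in leading `#` comment
#' lines so the file round-trips through [read_matrix()].
#'
#' @param matrix A [similarity_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "similarity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# measure=%s", matrix$measure), con)
  writeLines(sprintf("# diagonal=%s", matrix$diagonal_convention), con)
  writeLines(paste(c("id", matrix$labels), collapse = "\t"), con)
  for (i in seq_along(matrix$labels)) {
    writeLines(paste(c(matrix$labels[i],
                       sprintf("%.4f", matrix$values[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a similarity matrix written by [write_matrix()]
#' @param path TSV file.
#' @return A [similarity_matrix()].
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  measure <- sub("^# measure=", "", grep("^# measure=", meta, value = TRUE))
  diagonal <- sub("^# diagonal=", "", grep("^# diagonal=", meta, value = TRUE))
  body <- lines[!grepl("^#", lines)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]][-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  labels <- vapply(rows, `[`, "", 1L)
  stopifnot(identical(labels, header))
  if (measure %in% SYMMETRIC_MEASURES) vals <- (vals + t(vals)) / 2
  similarity_matrix(vals, labels, measure, diagonal)
}

#' Read a key=value configuration file
#'
#' Plain-text configuration: one `key = value` pair per line, `#` comments
#' ignored. Values are returned as strings; numeric-looking values are
#' converted.
#' @param path Config file.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
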