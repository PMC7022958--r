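#' Default substitution matrix for a molecule type
#'
#' BLOSUM62 for proteins (the standard table shipped with Biostrings);
#' match +5 / mismatch -4 for DNA and RNA.
#'
#' @param molecule `"protein"`, `"dna"` or `"rna"`.
#' @return Numeric substitution matrix with residue dimnames.
#' @export
default_submat <- function(molecule = c("protein", "dna", "rna")) {
  molecule <- match.arg(molecule)
  if (molecule == "protein") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    return(e$BLOSUM62)
  }
  sym <- residue_alphabet(molecule)$symbols
  m <- matrix(-4, 4, 4, dimnames = list(sym, sym))
  diag(m) <- 5
  m
}

#' Pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch global or Smith-Waterman local alignment (Gotoh
#' three-state recursion) with gap cost `gap_open + (L-1) * gap_extend`
#' for a gap of length L. Traceback is deterministic with ties broken
#' diagonal > up > left. Identity is the EMBOSS convention: identical
#' columns over the full alignment length including gap columns;
#' similarity counts columns that are identical or have a positive
#' substitution score.
#'
#' @param a,b [seq_record()]s of the same molecule type (or plain strings
#'   with `molecule` given).
#' @param mode `"global"` or `"local"`.
#' @param submat Substitution matrix (default [default_submat()]).
#' @param gap_open,gap_extend Positive gap penalties (defaults 10 / 0.5,
#'   the EMBOSS needle/water defaults).
#' @param molecule Molecule type when `a`, `b` are plain strings.
#' @param denominator `"alignment"` (default, full alignment length) or
#'   `"shorter"` (length of the shorter sequence) for the identity and
#'   similarity percentages.
#' @return An `alignment_result`: `aligned_a`, `aligned_b`, `score`,
#'   `identity_pct`, `similarity_pct`, `aligned_length`, `mode`.
#' @export
#' @examples
#' r <- align("AAAA", "AAAT", molecule = "dna")
#' r$identity_pct
align <- function(a, b, mode = c("global", "local"), submat = NULL,
                  gap_open = 10, gap_extend = 0.5, molecule = NULL,
                  denominator = c("alignment", "shorter")) {
  mode <- match.arg(mode)
  denominator <- match.arg(denominator)
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive")
  if (inherits(a, "seq_record") && inherits(b, "seq_record") &&
      a$molecule != b$molecule)
    stop(sprintf("molecule mismatch: %s vs %s", a$molecule, b$molecule))
  if (is.null(molecule))
    molecule <- if (inherits(a, "seq_record")) a$molecule else "protein"
  sa <- if (inherits(a, "seq_record")) a$residues else toupper(a)
  sb <- if (inherits(b, "seq_record")) b$residues else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  if (is.null(submat)) submat <- default_submat(molecule)
  chars <- paste(rownames(submat), collapse = "")
  res <- align_cpp(sa, sb, submat, chars, gap_open, gap_extend,
                   mode == "local")
  ca <- strsplit(res$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(res$aligned_b, "", fixed = TRUE)[[1]]
  alen <- length(ca)
  ident <- simil <- 0L
  if (alen) {
    both <- ca != "-" & cb != "-"
    eq <- both & ca == cb
    pos <- both
    pos[both] <- submat[cbind(ca[both], cb[both])] > 0
    ident <- sum(eq)
    simil <- sum(eq | pos)
  }
  denom <- if (denominator == "alignment") alen else min(nchar(sa), nchar(sb))
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score,
                 identity_pct = if (denom) 100 * ident / denom else 0,
                 similarity_pct = if (denom) 100 * simil / denom else 0,
                 aligned_length = alen, mode = mode),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s, score %.1f, id %.1f%%, sim %.1f%%, len %d\n",
              x$mode, x$score, x$identity_pct, x$similarity_pct,
              x$aligned_length))
  invisible(x)
}

#' Karlin-Altschul normalization parameters
#'
#' Defaults lambda = 0.267, K = 0.041, the widely used ungapped
#' approximation constants for BLOSUM62 gapped scoring; `search_m` and
#' `search_n` are the effective search-space lengths for E-values.
#'
#' @param lambda,K Positive Karlin-Altschul constants.
#' @param search_m,search_n Effective search-space sizes.
#' @return A `ka_params` list.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041,
                      search_m = 1000L, search_n = 1000L) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K, search_m = search_m,
                 search_n = search_n), class = "ka_params")
}

#' Bit score and E-value of a raw alignment score
#'
#' bits = (lambda * raw - ln K) / ln 2; E = K m n exp(-lambda * raw).
#' The bit score normalizes the raw score so it is comparable across
#' scoring systems and search sizes.
#'
#' @param raw Raw alignment score.
#' @param params A [ka_params()] object.
#' @return Numeric scalar.
#' @export
bit_score <- function(raw, params = ka_params()) {
  (params$lambda * raw - log(params$K)) / log(2)
}

#' @rdname bit_score
#' @export
evalue <- function(raw, params = ka_params()) {
  params$K * params$search_m * params$search_n * exp(-params$lambda * raw)
}

#' All-vs-all pairwise similarity matrix
#'
#' Compares every pair of records with the built-in aligner and assembles
#' an n x n [similarity_matrix()]. Identity and similarity use global
#' alignment; bit scores use local alignment raw scores through
#' [bit_score()]. Symmetric measures compute the upper triangle only and
#' mirror it. Diagonal: identity/similarity 100, bitscore the
#' self-alignment bit score.
#'
#' @param records List of >= 2 [seq_record()]s with unique ids.
#' @param measure `"identity_pct"`, `"similarity_pct"` or `"bitscore"`.
#' @param submat,gap_open,gap_extend Passed to [align()].
#' @param params [ka_params()] for bit scores.
#' @return A [similarity_matrix()].
#' @export
all_vs_all <- function(records, measure = c("identity_pct",
                                            "similarity_pct", "bitscore"),
                       submat = NULL, gap_open = 10, gap_extend = 0.5,
                       params = ka_params()) {
  measure <- match.arg(measure)
  if (length(records) < 2) stop("all_vs_all needs at least 2 records")
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate record ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  n <- length(records)
  V <- matrix(0, n, n)
  mode <- if (measure == "bitscore") "local" else "global"
  val <- function(i, j) {
    r <- align(records[[i]], records[[j]], mode, submat, gap_open, gap_extend)
    switch(measure, identity_pct = r$identity_pct,
           similarity_pct = r$similarity_pct,
           bitscore = bit_score(r$score, params))
  }
  for (i in seq_len(n)) {
    V[i, i] <- if (measure == "bitscore") val(i, i) else 100
    if (i < n) for (j in (i + 1):n) V[i, j] <- V[j, i] <- val(i, j)
  }
  similarity_matrix(V, ids, measure,
                    diagonal = if (measure == "bitscore")
                      "self local bit score" else "self-comparison = 100")
}

#' Twilight-zone classification of a pairwise comparison
#'
#' Protein rules: midnight zone below 20% identity; twilight zone at
#' 20-35%; above otherwise. The safe-homolog flag requires an alignment of
#' at least 100 residues with identity above 30%. Bit-score significance:
#' bits > 50, or bits > 40 when the search comprises at most 7000
#' sequences. DNA/RNA use a single twilight threshold (default 55%,
#' configurable within the reported 50-60 band): below it is twilight,
#' otherwise above.
#'
#' @param identity_pct Pairwise identity in [0, 100].
#' @param aligned_length Alignment length in residues.
#' @param bits Optional bit score.
#' @param molecule Molecule type.
#' @param db_size Optional number of sequences in the search.
#' @param rna_threshold Twilight threshold for nucleotide comparisons.
#' @return A `zone_call`: `zone` (`"midnight"`, `"twilight"`, `"above"`),
#'   `safe_homolog`, `bit_significant` (NA when `bits` missing),
#'   `molecule`.
#' @export
#' @examples
#' classify_zone(25, 150)$zone
classify_zone <- function(identity_pct, aligned_length = NA_integer_,
                          bits = NULL, molecule = c("protein", "dna", "rna"),
                          db_size = NULL, rna_threshold = 55) {
  molecule <- match.arg(molecule)
  if (is.na(identity_pct) || identity_pct < 0 || identity_pct > 100)
    stop("identity_pct must lie in [0, 100]")
  if (molecule == "protein") {
    zone <- if (identity_pct < 20) "midnight"
            else if (identity_pct <= 35) "twilight"
            else "above"
    safe <- !is.na(aligned_length) && aligned_length >= 100 &&
      identity_pct > 30
  } else {
    if (rna_threshold < 50 || rna_threshold > 60)
      stop("rna_threshold must lie in [50, 60]")
    zone <- if (identity_pct < rna_threshold) "twilight" else "above"
    safe <- FALSE
  }
  bit_sig <- if (is.null(bits)) NA else {
    bits > 50 || (!is.null(db_size) && db_size <= 7000 && bits > 40)
  }
  structure(list(zone = zone, safe_homolog = safe,
                 bit_significant = bit_sig, molecule = molecule),
            class = "zone_call")
}

#' Greedy redundancy reduction by global identity
#'
#' Iterates records in input order and keeps a record iff its global
#' identity to every already-kept record is below the cutoff;
#' deterministic, so the first member of each redundant cluster survives.
#'
#' @param records List of [seq_record()]s.
#' @param identity_cutoff Percent identity cutoff in (0, 100).
#' @param ... Passed to [align()].
#' @return The surviving records, in input order.
#' @export
redundancy_reduce <- function(records, identity_cutoff, ...) {
  if (identity_cutoff <= 0 || identity_cutoff >= 100)
    stop("identity_cutoff must lie in (0, 100)")
  kept <- list()
  for (r in records) {
    ok <- TRUE
    for (k in kept) {
      if (align(r, k, "global", ...)$identity_pct >= identity_cutoff) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- r
  }
  kept
}

#' Zone-call table for a set of records
#'
#' Convenience wrapper: all-vs-all identity plus local bit scores, one
#' [classify_zone()] row per pair.
#'
#' @param records List of [seq_record()]s.
#' @param ... Passed to [all_vs_all()].
#' @return data.frame with columns `a`, `b`, `identity_pct`, `bits`,
#'   `zone`, `safe_homolog`, `bit_significant`.
#' @export
zone_table <- function(records, ...) {
  idm <- all_vs_all(records, "identity_pct", ...)
  n <- length(records)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      al <- align(records[[i]], records[[j]], "global")
      loc <- align(records[[i]], records[[j]], "local")
      bits <- bit_score(loc$score)
      z <- classify_zone(idm$values[i, j], al$aligned_length, bits,
                         records[[i]]$molecule, db_size = n)
      rows[[length(rows) + 1L]] <- data.frame(
        a = records[[i]]$id, b = records[[j]]$id,
        identity_pct = idm$values[i, j], bits = bits, zone = z$zone,
        safe_homolog = z$safe_homolog, bit_significant = z$bit_significant)
    }
  }
  do.call(rbind, rows)
}
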