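#' @useDynLib seqtopo, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
DNA4 <- c("A", "C", "G", "T")
RNA4 <- c("A", "C", "G", "U")

#' Residue alphabet for a molecule type
#'
#' Returns the canonical unambiguous alphabet: the 20 natural amino acids
#' for proteins, the 4 nucleotides for DNA/RNA. All downstream grouping
#' schemes, property tables and descriptor vectors are indexed by these
#' symbols in this fixed order.
#'
#' @param molecule One of `"protein"`, `"dna"`, `"rna"`.
#' @return An object of class `residue_alphabet` with fields `name`,
#'   `symbols` (ordered character vector) and `molecule`.
#' @export
#' @examples
#' residue_alphabet("dna")$symbols
residue_alphabet <- function(molecule = c("protein", "dna", "rna")) {
  molecule <- match.arg(molecule)
  symbols <- switch(molecule, protein = AA20, dna = DNA4, rna = RNA4)
  structure(list(name = molecule, symbols = symbols, molecule = molecule),
            class = "residue_alphabet")
}

# internal registry of grouping schemes; each entry is a function returning
# a fresh grouping_scheme so user-level mutation never leaks back
.scheme_registry <- new.env(parent = emptyenv())

new_grouping_scheme <- function(name, mapping, directions = NULL, molecule = "protein") {
  alpha <- residue_alphabet(molecule)
  stopifnot(setequal(names(mapping), alpha$symbols))
  if (!is.null(directions)) {
    dirs <- do.call(rbind, directions)
    canonical <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    key <- function(m) sort(paste(m[, 1], m[, 2]))
    if (!identical(key(dirs), key(canonical)))
      stop("spatial scheme must assign the four axis directions (+-1,0),(0,+-1) to four distinct groups")
  }
  structure(list(name = name, mapping = mapping, directions = directions,
                 molecule = molecule),
            class = "grouping_scheme")
}

register_grouping <- function(name, builder) assign(name, builder, envir = .scheme_registry)

#' Retrieve a residue grouping scheme by name
#'
#' Grouping schemes partition an alphabet into labelled classes and, for
#' spatial schemes, assign each class a unit direction vector in the 2D
#' Cartesian plane. They parameterize pseudo-folding, four-color maps and
#' reduced-alphabet descriptors.
#'
#' Built-in schemes:
#' \describe{
#'   \item{hp4}{Hydrophobicity/polarity partition of the 20 amino acids into
#'     nonpolar, polar, acidic and basic classes, each on one Cartesian
#'     axis. Membership: nonpolar = G,A,V,L,I,P,F,M,W; polar = S,T,C,Y,N,Q;
#'     acidic = D,E; basic = K,R,H. Axes: nonpolar +x, polar -x, basic +y,
#'     acidic -y.}
#'   \item{charge5}{Five-group charge-based reduced alphabet
#'     (I = A,S,G; II = M,L,I,V; III = K,R,T,H; IV = N,D,E,Q; V = F,Y,W)
#'     with proline and cysteine kept as their own singleton groups.
#'     Non-spatial (no direction vectors).}
#'   \item{nandy_dna}{Each DNA nucleotide on its own axis:
#'     G +x, A -x, C +y, T -y.}
#'   \item{nandy_rna}{As `nandy_dna` with U in place of T.}
#' }
#'
#' @param name Scheme name. Additional schemes can be added with
#'   [register_grouping_scheme()].
#' @return A `grouping_scheme`: `mapping` (named character vector,
#'   residue -> group label), `directions` (named list of integer
#'   2-vectors keyed by group label, or `NULL`), `molecule`.
#' @export
#' @examples
#' get_grouping("hp4")$mapping[["D"]]
get_grouping <- function(name) {
  if (!exists(name, envir = .scheme_registry, inherits = FALSE)) {
    avail <- sort(ls(.scheme_registry))
    stop(sprintf("unknown grouping scheme '%s'; available: %s",
                 name, paste(avail, collapse = ", ")))
  }
  get(name, envir = .scheme_registry)()
}

#' Register a custom grouping scheme
#'
#' @param name Scheme name used with [get_grouping()].
#' @param mapping Named character vector, residue -> group label, covering
#'   the full alphabet of `molecule`.
#' @param directions Optional named list, group label -> integer 2-vector;
#'   when given, the four spatial groups must cover the four axis
#'   directions.
#' @param molecule Molecule type of the alphabet.
#' @return Invisibly, the validated scheme.
#' @export
register_grouping_scheme <- function(name, mapping, directions = NULL,
                                     molecule = "protein") {
  scheme <- new_grouping_scheme(name, mapping, directions, molecule)
  register_grouping(name, function() scheme)
  invisible(scheme)
}

local({
  hp4_map <- c(
    G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
    I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
    W = "nonpolar",
    S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar",
    Q = "polar",
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic")
  hp4_dirs <- list(nonpolar = c(1L, 0L), polar = c(-1L, 0L),
                   basic = c(0L, 1L), acidic = c(0L, -1L))
  register_grouping("hp4", function()
    new_grouping_scheme("hp4", hp4_map[AA20], hp4_dirs, "protein"))

  ch5_map <- c(A = "I", S = "I", G = "I",
               M = "II", L = "II", I = "II", V = "II",
               K = "III", R = "III", T = "III", H = "III",
               N = "IV", D = "IV", E = "IV", Q = "IV",
               F = "V", Y = "V", W = "V",
               P = "P", C = "C")
  register_grouping("charge5", function()
    new_grouping_scheme("charge5", ch5_map[AA20], NULL, "protein"))

  dna_map <- c(G = "G", A = "A", C = "C", T = "T")
  dna_dirs <- list(G = c(1L, 0L), A = c(-1L, 0L), C = c(0L, 1L), T = c(0L, -1L))
  register_grouping("nandy_dna", function()
    new_grouping_scheme("nandy_dna", dna_map[DNA4], dna_dirs, "dna"))

  rna_map <- c(G = "G", A = "A", C = "C", U = "U")
  rna_dirs <- list(G = c(1L, 0L), A = c(-1L, 0L), C = c(0L, 1L), U = c(0L, -1L))
  register_grouping("nandy_rna", function()
    new_grouping_scheme("nandy_rna", rna_map[RNA4], rna_dirs, "rna"))
})

# ---- property tables ---------------------------------------------------

# Side-chain formal charge at pH 7; Kyte-Doolittle hydropathy; a Pauling
# electronegativity proxy per residue (mean electronegativity of side-chain
# heavy atoms; C 2.55, N 3.04, O 3.44, S 2.58; glycine uses the backbone H/C).
.property_values <- list(
  charge = c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1, G = 0,
             H = 0.1, I = 0, L = 0, K = 1, M = 0, F = 0, P = 0, S = 0,
             T = 0, W = 0, Y = 0, V = 0),
  hydrophobicity = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                     Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                     L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                     S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2),
  electronegativity = c(A = 2.55, R = 2.79, N = 2.99, D = 3.14, C = 2.56,
                        Q = 2.92, E = 3.10, G = 2.37, H = 2.71, I = 2.55,
                        L = 2.55, K = 2.63, M = 2.56, F = 2.55, P = 2.55,
                        S = 2.85, T = 2.77, W = 2.61, Y = 2.66, V = 2.55)
)

#' Construct or look up a residue property table
#'
#' A property table maps every symbol of an alphabet to a real value and
#' carries a transform applied before the values are used as probability
#' weights (Markov initial vectors, transition weighting). Built-in tables:
#' `"charge"` (pH 7 side-chain formal charge), `"hydrophobicity"`
#' (Kyte-Doolittle), `"electronegativity"` (Pauling-scale proxy per
#' residue), `"uniform"` (all 1).
#'
#' @param name Built-in table name, or a label for `values`.
#' @param values Optional named numeric vector covering the alphabet; when
#'   given, overrides the built-ins.
#' @param transform `"abs"`, `"shift"` (subtract the minimum) or `"none"`;
#'   the transform must make all values usable as nonnegative weights.
#' @param molecule Molecule type of the alphabet.
#' @param on_ambiguous `"reject"` (default) errors on residues outside the
#'   alphabet; `"mean"` maps them to the alphabet-mean value.
#' @return A `property_table` with fields `name`, `values` (raw), `transform`,
#'   `molecule`, `on_ambiguous`.
#' @export
#' @examples
#' tab <- property_table("charge")
#' lookup_property(tab, "R")
property_table <- function(name, values = NULL,
                           transform = c("abs", "shift", "none"),
                           molecule = "protein",
                           on_ambiguous = c("reject", "mean")) {
  transform <- match.arg(transform)
  on_ambiguous <- match.arg(on_ambiguous)
  alpha <- residue_alphabet(molecule)
  if (is.null(values)) {
    if (name == "uniform") {
      values <- stats::setNames(rep(1, length(alpha$symbols)), alpha$symbols)
    } else {
      if (!name %in% names(.property_values) || molecule != "protein")
        stop(sprintf("no built-in property table '%s' for %s", name, molecule))
      values <- .property_values[[name]]
    }
  }
  if (!all(alpha$symbols %in% names(values)))
    stop("property table must cover the full alphabet")
  values <- values[alpha$symbols]
  structure(list(name = name, values = values, transform = transform,
                 molecule = molecule, on_ambiguous = on_ambiguous),
            class = "property_table")
}

transform_values <- function(table) {
  v <- table$values
  v <- switch(table$transform, abs = abs(v), shift = v - min(v), none = v)
  if (any(v < 0))
    stop(sprintf("property table '%s': negative weights after transform '%s'",
                 table$name, table$transform))
  v
}

#' Look up a (transformed) property value for one residue
#'
#' @param table A [property_table()].
#' @param residue Single residue character; lowercase is folded to upper.
#' @return The transformed value.
#' @export
lookup_property <- function(table, residue) {
  stopifnot(inherits(table, "property_table"), nchar(residue) == 1L)
  residue <- toupper(residue)
  v <- transform_values(table)
  if (!residue %in% names(v)) {
    if (table$on_ambiguous == "mean") return(mean(v))
    stop(sprintf("residue '%s' is not in the %s alphabet of table '%s'",
                 residue, table$molecule, table$name))
  }
  v[[residue]]
}

#' Residue weights for a whole sequence
#'
#' Vectorized [lookup_property()] over the residues of a sequence record.
#' @param table A [property_table()].
#' @param seq A [seq_record()] or character string of residues.
#' @return Numeric vector of transformed weights, one per residue.
#' @export
sequence_weights <- function(table, seq) {
  chars <- seq_chars(seq)
  v <- transform_values(table)
  miss <- !chars %in% names(v)
  if (any(miss)) {
    if (table$on_ambiguous == "mean") {
      out <- numeric(length(chars))
      out[!miss] <- v[chars[!miss]]
      out[miss] <- mean(v)
      return(out)
    }
    stop(sprintf("residue '%s' at position %d is not in the %s alphabet",
                 chars[which(miss)[1]], which(miss)[1], table$molecule))
  }
  unname(v[chars])
}

#' Write / read a grouping scheme or property table as TSV
#'
#' Two-column TSV (`residue`, `group` or `value`) so schemes and tables can
#' be exchanged with configuration files.
#' @param x A `grouping_scheme` or `property_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scheme_tsv <- function(x, path) {
  if (inherits(x, "grouping_scheme")) {
    df <- data.frame(residue = names(x$mapping), group = unname(x$mapping))
  } else if (inherits(x, "property_table")) {
    df <- data.frame(residue = names(x$values), value = unname(x$values))
  } else stop("x must be a grouping_scheme or property_table")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
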