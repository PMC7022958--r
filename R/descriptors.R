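#' Estrada spectral moments of a sequence graph
#'
#' The k-th spectral moment is the trace of the k-th power of an adjacency
#' matrix of the graph: mu_0 is the matrix dimension, mu_1 is 0 for the
#' zero-diagonal 0/1 adjacency, and mu_k counts the closed walks of length
#' k (on vertices, or on edges of the line graph when
#' `matrix_kind = "edge"`). The edge kind is the package default for
#' descriptor vectors, mirroring the workflow that raises the edge
#' adjacency matrix of a pseudo-folded map to successive powers and takes
#' the trace.
#'
#' @param graph A `seq_graph`.
#' @param k_max Highest power (>= 0).
#' @param matrix_kind `"edge"` (line-graph adjacency) or `"vertex"`.
#' @return A `spectral_moments` object: numeric `moments` named
#'   `mu0..mu<k_max>`, plus `matrix_kind`, `k_max`, `source`.
#' @export
#' @examples
#' g <- walk_to_graph(pseudo_fold_2d("IGIHVGR", get_grouping("hp4")))
#' spectral_moments(g, 2)$moments
spectral_moments <- function(graph, k_max = 15L,
                             matrix_kind = c("edge", "vertex")) {
  matrix_kind <- match.arg(matrix_kind)
  if (k_max < 0) stop("k_max must be >= 0")
  A <- if (matrix_kind == "edge") edge_adjacency(graph) else vertex_adjacency(graph)
  moments <- trace_powers(A, k_max)
  names(moments) <- paste0("mu", 0:k_max)
  structure(list(moments = moments, matrix_kind = matrix_kind,
                 k_max = as.integer(k_max), source = graph$source),
            class = "spectral_moments")
}

# traces of M^0..M^k by repeated multiplication
trace_powers <- function(M, k_max) {
  n <- nrow(M)
  out <- numeric(k_max + 1)
  out[1] <- n
  if (k_max >= 1) {
    P <- M
    out[2] <- sum(diag(P))
    k <- 1
    while (k < k_max) {
      P <- P %*% M
      k <- k + 1
      out[k + 1] <- sum(diag(P))
    }
  }
  out
}

#' Property-weighted Markov chain of a sequence
#'
#' Builds the property-transition stochastic matrix on the sequence
#' backbone: chain adjacency a_ij = 1 iff |i - j| <= 1 (self-transitions
#' included, which is what makes the self-returning probabilities on the
#' main diagonal nonzero), and
#' Pi_ij = a_ij w_j / sum_l a_il w_l, with w the transformed residue
#' property values (e.g. absolute side-chain charge). The initial vector
#' p0_i = w_i / sum_j w_j spreads the property distribution over the whole
#' backbone rather than only covalent neighbors.
#'
#' @param seq A [seq_record()] or residue string.
#' @param property A [property_table()] defined on all residues.
#' @param include_self Keep the diagonal of the chain adjacency (default);
#'   switchable for the strict nearest-neighbor variant.
#' @return A `markov_model`: `transition` (n x n row-stochastic), `initial`
#'   (length-n probability vector), `property`, `n`.
#' @export
markov_transition <- function(seq, property, include_self = TRUE) {
  w <- sequence_weights(property, seq)
  n <- length(w)
  if (sum(w) <= 0)
    stop(sprintf("property '%s': total transformed weight is zero",
                 property$name))
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    idx <- lo:hi
    if (!include_self) idx <- setdiff(idx, i)
    wi <- w[idx]
    if (sum(wi) == 0) {            # neighbors all zero-weight: fall back to uniform
      P[i, idx] <- 1 / length(idx)
    } else {
      P[i, idx] <- wi / sum(wi)
    }
  }
  structure(list(transition = P, initial = w / sum(w),
                 property = property$name, n = n),
            class = "markov_model")
}

#' Stochastic spectral moments of a Markov model
#'
#' pi_k = trace of the k-th power of the transition matrix: the sum of the
#' self-returning probabilities after k steps. pi_0 = n and 0 <= pi_k <= n
#' for k >= 1.
#'
#' @param model A [markov_transition()] model.
#' @param k_max Highest power.
#' @return Named numeric vector `pi0..pi<k_max>`.
#' @export
stochastic_spectral_moments <- function(model, k_max = 15L) {
  stopifnot(inherits(model, "markov_model"), k_max >= 0)
  out <- trace_powers(model$transition, k_max)
  names(out) <- paste0("pi", 0:k_max)
  out
}

#' Markov entropies of a propagated property distribution
#'
#' Propagates the initial property distribution p0 through the chain,
#' p(k) = p0 Pi^k (left multiplication), and returns the Shannon entropy
#' of each p(k) in bits, with 0 log 0 = 0. Entropies lie in [0, log2 n].
#'
#' @param model A [markov_transition()] model.
#' @param k_max Highest step count.
#' @param base Logarithm base (2 = bits, the default).
#' @return Named numeric vector `theta0..theta<k_max>`.
#' @export
markov_entropies <- function(model, k_max = 15L, base = 2) {
  stopifnot(inherits(model, "markov_model"), k_max >= 0)
  p <- model$initial
  out <- numeric(k_max + 1)
  out[1] <- shannon_of(p, base)
  k <- 0
  while (k < k_max) {
    p <- as.vector(p %*% model$transition)
    k <- k + 1
    out[k + 1] <- shannon_of(p, base)
  }
  names(out) <- paste0("theta", 0:k_max)
  out
}

shannon_of <- function(p, base = 2) {
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Classical topological indices of a connected graph
#'
#' Standard graph invariants on shortest-path distances d_uv and degrees:
#' Wiener W = sum_{u<v} d_uv; Harary H = sum_{u<v} 1/d_uv; Randic
#' chi = sum_edges (deg_u deg_v)^(-1/2); Balaban
#' J = (m/(mu+1)) sum_edges (S_u S_v)^(-1/2) with S_u the distance sum and
#' mu the cyclomatic number; Kier-Hall simple chi of orders 0-2 (vertices,
#' edges, 2-paths); Moreau-Broto autocorrelation ATS_d over topological
#' distances 1..5 weighted by a residue property (weight 1 when absent);
#' and vertex spectral moments k = 0..5.
#'
#' @param graph A connected `seq_graph` (disconnected input is an error:
#'   whole-graph distance indices are undefined; reduce per-color
#'   subgraphs to their largest component first, see
#'   [largest_component()]).
#' @param properties Optional [property_table()]; node weights are the
#'   transformed property of each node's residue where the graph records
#'   residues (star graphs), else 1.
#' @return Named numeric vector of indices (`wiener`, `harary`, `randic`,
#'   `balaban`, `chi0`..`chi2`, `ats1`..`ats5`, `mu0`..`mu5`).
#' @export
#' @examples
#' classical_tis(star_graph("AAG"))[["wiener"]]
classical_tis <- function(graph, properties = NULL) {
  n <- n_nodes(graph)
  m <- n_edges(graph)
  if (!is_connected_graph(graph))
    stop("classical topological indices require a connected graph")
  D <- igraph::distances(as_igraph(graph))
  A <- vertex_adjacency(graph)
  deg <- rowSums(A)
  ut <- upper.tri(D)
  wiener <- sum(D[ut])
  harary <- sum(1 / D[ut])
  e <- graph$edges
  randic <- if (m) sum(1 / sqrt(deg[e[, 1]] * deg[e[, 2]])) else 0
  mu_cyc <- m - n + 1L
  S <- rowSums(D)
  balaban <- if (m) (m / (mu_cyc + 1)) * sum(1 / sqrt(S[e[, 1]] * S[e[, 2]])) else 0
  chi0 <- sum(1 / sqrt(deg[deg > 0]))
  chi1 <- randic
  # order-2 chi: all simple paths u-v-w (u < w), weight (deg_u deg_v deg_w)^(-1/2)
  chi2 <- 0
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) >= 2) {
      pairs <- utils::combn(nb, 2)
      chi2 <- chi2 + sum(1 / sqrt(deg[pairs[1, ]] * deg[v] * deg[pairs[2, ]]))
    }
  }
  w <- node_weights(graph, properties)
  ats <- vapply(1:5, function(d) {
    sel <- ut & D == d
    if (!any(sel)) return(0)
    idx <- which(sel, arr.ind = TRUE)
    sum(w[idx[, 1]] * w[idx[, 2]])
  }, numeric(1))
  mus <- trace_powers(A, 5)
  out <- c(wiener = wiener, harary = harary, randic = randic,
           balaban = balaban, chi0 = chi0, chi1 = chi1, chi2 = chi2,
           stats::setNames(ats, paste0("ats", 1:5)),
           stats::setNames(mus, paste0("mu", 0:5)))
  out
}

node_weights <- function(graph, properties) {
  n <- n_nodes(graph)
  if (is.null(properties)) return(rep(1, n))
  if (!"residue" %in% names(graph$nodes)) return(rep(1, n))
  v <- transform_values(properties)
  res <- graph$nodes$residue
  w <- ifelse(res %in% names(v), v[res], mean(v))  # center vertex gets mean weight
  unname(w)
}

#' Largest connected component of a sequence graph
#'
#' Helper for per-color map subgraphs, which may be disconnected; the
#' whole-graph distance indices are then computed on the largest
#' component (ties broken by lowest node index), with a message.
#' @param graph A `seq_graph`.
#' @return A `seq_graph` restricted to the largest component.
#' @export
largest_component <- function(graph) {
  comp <- igraph::components(as_igraph(graph))
  if (comp$no <= 1L) return(graph)
  message(sprintf("graph is disconnected (%d components); using largest",
                  comp$no))
  keep <- which(comp$membership == which.max(comp$csize))
  remap <- match(seq_len(n_nodes(graph)), keep)
  e <- graph$edges
  e <- e[e[, 1] %in% keep & e[, 2] %in% keep, , drop = FALSE]
  e[] <- remap[e]
  new_seq_graph(graph$nodes[keep, , drop = FALSE], e, graph$source,
                graph$node_multiplicity[keep])
}

#' Sequence autocorrelation vector over a residue property
#'
#' Broto-Moreau-style autocorrelation on the linear chain: for each lag l,
#' ATS_l = sum_{i=1}^{n-l} w_i w_{i+l}, where w are the transformed
#' property values. Lags of at least the sequence length have an empty sum
#' and yield 0 (flagged in the names by convention of returning them
#' anyway). The normalized variant divides by the number of summed pairs.
#'
#' @param seq A [seq_record()] or residue string, length > 1.
#' @param property A [property_table()].
#' @param max_lag Largest lag, between 1 and 15 (default 15).
#' @param normalized Divide ATS_l by (n - l).
#' @return Named numeric vector `ats_lag1..ats_lag<max_lag>`.
#' @export
aasa_autocorrelation <- function(seq, property, max_lag = 15L,
                                 normalized = FALSE) {
  if (max_lag < 1 || max_lag > 15) stop("max_lag must be in 1..15")
  w <- sequence_weights(property, seq)
  n <- length(w)
  if (n <= 1) stop("autocorrelation needs a sequence of length > 1")
  out <- vapply(seq_len(max_lag), function(l) {
    if (l >= n) return(0)
    v <- sum(w[1:(n - l)] * w[(1 + l):n])
    if (normalized) v / (n - l) else v
  }, numeric(1))
  names(out) <- paste0("ats_lag", seq_len(max_lag))
  out
}

#' Residue composition and k-mer frequencies
#'
#' `composition()` returns symbol counts divided by length over the full
#' alphabet (absent symbols get 0). `kmer_freqs()` returns overlapping
#' k-word counts divided by the number of windows (n - k + 1); only words
#' observed in the sequence appear unless `full = TRUE` for small k.
#'
#' @param seq A [seq_record()] (molecule known) or residue string (with
#'   `molecule` given).
#' @param molecule Molecule type when `seq` is a plain string.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
composition <- function(seq, molecule = NULL) {
  if (inherits(seq, "seq_record")) molecule <- seq$molecule
  if (is.null(molecule)) stop("molecule type required for plain strings")
  alpha <- residue_alphabet(molecule)
  chars <- seq_chars(seq)
  counts <- table(factor(chars, levels = alpha$symbols))
  out <- as.numeric(counts) / length(chars)
  names(out) <- alpha$symbols
  out
}

#' @rdname composition
#' @param k Word length, `1 <= k < sequence length`.
#' @param full Enumerate the full alphabet^k word space (zeros included);
#'   only allowed when the word space has at most 160000 words.
#' @export
kmer_freqs <- function(seq, k, molecule = NULL, full = FALSE) {
  if (inherits(seq, "seq_record")) molecule <- seq$molecule
  chars <- seq_chars(seq)
  n <- length(chars)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < sequence length")
  words <- vapply(seq_len(n - k + 1), function(i)
    paste(chars[i:(i + k - 1)], collapse = ""), "")
  if (full) {
    if (is.null(molecule)) stop("molecule type required for full word space")
    alpha <- residue_alphabet(molecule)$symbols
    if (length(alpha)^k > 160000) stop("word space too large for full = TRUE")
    space <- apply(do.call(expand.grid,
                           rep(list(alpha), k))[, k:1, drop = FALSE],
                   1, paste, collapse = "")
    counts <- table(factor(words, levels = sort(space)))
  } else {
    counts <- table(words)
  }
  out <- as.numeric(counts) / length(words)
  names(out) <- names(counts)
  out
}

#' Word-level Shannon entropy of a sequence
#'
#' Entropy (bits by default) of the overlapping word_len-tuple frequency
#' distribution: the uncertainty of finding a given symbol or word along
#' the sequence.
#'
#' @param seq A [seq_record()] or residue string.
#' @param word_len Tuple length (must be < sequence length).
#' @param base Logarithm base.
#' @return Entropy value.
#' @export
shannon_entropy <- function(seq, word_len = 1L, base = 2) {
  n <- seq_length(seq)
  if (word_len >= n && !(word_len == 1L && n == 1L))
    stop("word_len must be smaller than the sequence length")
  chars <- seq_chars(seq)
  words <- vapply(seq_len(n - word_len + 1), function(i)
    paste(chars[i:(i + word_len - 1)], collapse = ""), "")
  freq <- as.numeric(table(words)) / length(words)
  shannon_of(freq, base)
}

#' Lempel-Ziv (LZ76) sequence complexity
#'
#' Number of phrases in the exhaustive LZ76 parsing of the string: each new
#' phrase is the shortest prefix of the remaining string that does not
#' occur as a substring of everything parsed so far plus the phrase minus
#' its last character. Low-complexity (repetitive) sequences produce fewer
#' phrases than random ones of the same length.
#'
#' @param seq A [seq_record()] or residue string.
#' @return Integer phrase count.
#' @export
lz_complexity <- function(seq) {
  s <- seq_chars(seq)
  n <- length(s)
  if (n == 0) return(0L)
  cplx <- 1L
  prefix_end <- 1L   # s[1..prefix_end] parsed
  i <- prefix_end + 1L
  while (i <= n) {
    # find longest match of s[i..] inside s[1 .. i+len-2] (allows overlap)
    len <- 1L
    repeat {
      if (i + len - 1L > n) break
      pat <- s[i:(i + len - 1L)]
      hay <- s[1:(i + len - 2L)]
      found <- FALSE
      if (length(hay) >= len) {
        for (st in seq_len(length(hay) - len + 1L)) {
          if (all(hay[st:(st + len - 1L)] == pat)) { found <- TRUE; break }
        }
      }
      if (!found) break
      len <- len + 1L
    }
    cplx <- cplx + 1L
    i <- i + len
  }
  cplx
}

#' Distribution divergences and distances
#'
#' `kl_divergence()` regularizes both distributions with a pseudocount and
#' renormalizes before computing sum p log2(p/q) (>= 0 by Gibbs'
#' inequality). `js_divergence()` is the symmetric Jensen-Shannon
#' divergence in bits, bounded by [0, 1]. `euclidean_distance()` is the
#' ordinary L2 distance. Distributions must share a dimension; align k-mer
#' vectors on the union of their words first (see
#' [align_distributions()]).
#'
#' @param p,q Nonnegative numeric vectors of equal length summing to 1
#'   (within 1e-6 before regularization).
#' @param pseudocount Added to every cell before renormalization.
#' @return Numeric scalar.
#' @export
kl_divergence <- function(p, q, pseudocount = 1e-6) {
  check_dists(p, q)
  p <- (p + pseudocount) / sum(p + pseudocount)
  q <- (q + pseudocount) / sum(q + pseudocount)
  sum(p * log2(p / q))
}

#' @rdname kl_divergence
#' @export
js_divergence <- function(p, q) {
  check_dists(p, q)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl0 <- function(a, b) { sel <- a > 0; sum(a[sel] * log2(a[sel] / b[sel])) }
  0.5 * kl0(p, m) + 0.5 * kl0(q, m)
}

#' @rdname kl_divergence
#' @export
euclidean_distance <- function(p, q) {
  check_dists(p, q, probs = FALSE)
  sqrt(sum((p - q)^2))
}

check_dists <- function(p, q, probs = TRUE) {
  if (length(p) != length(q))
    stop("distributions must have the same dimension")
  if (probs && (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6))
    stop("p and q must each sum to 1")
  invisible(TRUE)
}

#' Align two named frequency vectors on the union of their names
#' @param p,q Named numeric vectors (e.g. [kmer_freqs()] output).
#' @return List with elements `p` and `q` on the common name space.
#' @export
align_distributions <- function(p, q) {
  words <- sort(union(names(p), names(q)))
  pad <- function(v) { out <- stats::setNames(numeric(length(words)), words)
    out[names(v)] <- v; out }
  list(p = pad(p), q = pad(q))
}

#' Full descriptor vector for one sequence
#'
#' Convenience wrapper producing a named numeric feature vector for a
#' sequence under one graphical representation, the common input row for
#' feature tables.
#'
#' @param seq A [seq_record()].
#' @param representation `"cartesian"`, `"fourcolor"`, `"star"`,
#'   `"star_embedded"` (spectral moments of that graph) or `"chain"`
#'   (Markov descriptors on the backbone chain).
#' @param scheme Grouping scheme (spatial ones for cartesian/fourcolor);
#'   defaults to `hp4` for proteins and `nandy_dna`/`nandy_rna` otherwise.
#' @param property Property table for Markov/autocorrelation descriptors
#'   (default `"charge"` with abs transform for proteins, `"uniform"`
#'   otherwise).
#' @param k_max Spectral-moment / Markov order.
#' @param matrix_kind Adjacency kind for spectral moments.
#' @return Named numeric vector; names carry the representation prefix.
#' @export
descriptor_vector <- function(seq,
                              representation = c("cartesian", "fourcolor",
                                                 "star", "star_embedded",
                                                 "chain"),
                              scheme = NULL, property = NULL, k_max = 15L,
                              matrix_kind = "edge") {
  representation <- match.arg(representation)
  if (is.null(scheme) && representation %in% c("cartesian", "fourcolor")) {
    scheme <- switch(seq$molecule, protein = get_grouping("hp4"),
                     dna = get_grouping("nandy_dna"),
                     rna = get_grouping("nandy_rna"))
  }
  if (is.null(property)) {
    property <- if (seq$molecule == "protein")
      property_table("charge") else property_table("uniform", molecule = seq$molecule)
  }
  feats <- switch(representation,
    cartesian = {
      g <- walk_to_graph(pseudo_fold_2d(seq, scheme))
      spectral_moments(g, k_max, matrix_kind)$moments
    },
    fourcolor = {
      # per-color subgraph moments: the whole filled spiral is the same
      # graph for every sequence of one length, so the information sits in
      # the color-class subgraphs; edgeless classes contribute zeros
      subs <- map_to_graph(four_color_spiral(seq, scheme), "per_color")
      groups <- sort(unique(unname(scheme$mapping)))
      unlist(lapply(groups, function(gname) {
        g <- subs[[gname]]
        mom <- if (is.null(g) || (n_edges(g) == 0 && matrix_kind == "edge"))
          stats::setNames(rep(0, k_max + 1), paste0("mu", 0:k_max))
        else spectral_moments(g, k_max, matrix_kind)$moments
        stats::setNames(mom, paste0(gname, "_", names(mom)))
      }))
    },
    star = spectral_moments(star_graph(seq, FALSE), k_max, matrix_kind)$moments,
    star_embedded = spectral_moments(star_graph(seq, TRUE), k_max, matrix_kind)$moments,
    chain = {
      model <- markov_transition(seq, property)
      c(stochastic_spectral_moments(model, k_max),
        markov_entropies(model, k_max))
    })
  stats::setNames(as.numeric(feats),
                  paste(representation, names(feats), sep = "_"))
}
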