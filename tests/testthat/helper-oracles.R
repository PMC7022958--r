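# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths (edge_adjacency, trace_powers, align_cpp).

# count closed walks of length k in a 0/1 adjacency matrix by depth-first
# path walking over neighbor lists
count_closed_walks <- function(A, k) {
  n <- nrow(A)
  if (k == 0) return(n)
  nb <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  total <- 0
  walk <- function(current, target, remaining) {
    if (remaining == 0) return(as.numeric(current == target))
    s <- 0
    for (j in nb[[current]]) s <- s + walk(j, target, remaining - 1)
    s
  }
  for (start in seq_len(n)) total <- total + walk(start, start, k)
  total
}

# line-graph adjacency via igraph, independent of edge_adjacency()
line_graph_adjacency <- function(graph) {
  lg <- igraph::make_line_graph(as_igraph(graph))
  M <- as.matrix(igraph::as_adjacency_matrix(lg))
  M[M > 1] <- 1   # igraph line graphs of multigraph-free input are simple
  unname(M)
}

# Floyd-Warshall all-pairs shortest paths on a 0/1 adjacency matrix
floyd_warshall <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A > 0] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      relax <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], relax)
    }
  }
  D
}

# quadratic-space reference Gotoh affine-gap aligner, score only; coded
# independently of the C++ engine (plain R loops, same scoring model:
# gap of length L costs open + (L-1) * extend)
ref_align_score <- function(a, b, smat, open, ext, local = FALSE) {
  A <- strsplit(toupper(a), "")[[1]]
  B <- strsplit(toupper(b), "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (local) {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    X[2:(n + 1), 1] <- -(open + (seq_len(n) - 1) * ext)
    if (m > 0) Y[1, 2:(m + 1)] <- -(open + (seq_len(m) - 1) * ext)
  }
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- smat[A[i], B[j]]
      mv <- max(M[i, j], X[i, j], Y[i, j]) + s
      if (local && mv < 0) mv <- 0
      M[i + 1, j + 1] <- mv
      X[i + 1, j + 1] <- max(M[i, j + 1] - open, X[i, j + 1] - ext,
                             Y[i, j + 1] - open)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open, Y[i + 1, j] - ext,
                             X[i + 1, j] - open)
      if (local && M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
    }
  }
  if (local) best else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# random connected simple graph: spanning tree plus a few extra edges
random_connected_graph <- function(n, extra = 2L) {
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  for (k in seq_len(extra)) {
    cand <- sort(sample.int(n, 2))
    edges <- rbind(edges, cand)
  }
  nodes <- data.frame(x = seq_len(n), y = 0)
  seqtopo:::new_seq_graph(nodes, edges, "cartesian")
}

# random protein record
random_protein <- function(n, id = "r") {
  seq_record(id, paste(sample(seqtopo:::AA20, n, TRUE), collapse = ""),
             "protein")
}

# brute-force AUROC: pairwise comparison counting with half-credit ties
brute_auroc <- function(scores, pos) {
  ps <- scores[pos]; ns <- scores[!pos]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}
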