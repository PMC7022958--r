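#' Pseudo-fold a sequence into a 2D-Cartesian lattice walk
#'
#' Arranges a linear sequence as a walk on the integer lattice: the walk
#' is anchored at the origin (0,0), which is not itself a residue, and
#' residue i sits at the previous position plus the unit direction vector
#' of its physicochemical group. For proteins under the `hp4` scheme this
#' is the 2D-HP map (hydrophobicity/polarity axes); for DNA/RNA under the
#' `nandy_*` schemes each nucleotide has its own axis.
#'
#' @param seq A [seq_record()] or residue string.
#' @param scheme A spatial [get_grouping()] scheme (must carry direction
#'   vectors) whose molecule type matches the sequence.
#' @return A `lattice_walk`: `positions` (n x 2 integer matrix, one row per
#'   residue), `residues`, `scheme` name.
#' @export
#' @examples
#' w <- pseudo_fold_2d(seq_record("f", "IGIHVGR", "protein"), get_grouping("hp4"))
#' w$positions
pseudo_fold_2d <- function(seq, scheme) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  if (is.null(scheme$directions))
    stop(sprintf("scheme '%s' has no direction vectors; cannot pseudo-fold",
                 scheme$name))
  chars <- seq_chars(seq)
  groups <- scheme$mapping[chars]
  bad <- which(is.na(groups))
  if (length(bad))
    stop(sprintf("residue '%s' at position %d is not mapped by scheme '%s'",
                 chars[bad[1]], bad[1], scheme$name))
  steps <- t(vapply(groups, function(g) scheme$directions[[g]], integer(2)))
  positions <- apply(steps, 2, cumsum)
  if (length(chars) == 1L) positions <- matrix(positions, nrow = 1)
  colnames(positions) <- c("x", "y")
  structure(list(positions = positions, residues = chars,
                 scheme = scheme$name),
            class = "lattice_walk")
}

new_seq_graph <- function(nodes, edges, source, multiplicity = NULL) {
  n <- nrow(nodes)
  if (is.null(multiplicity)) multiplicity <- rep(1L, n)
  edges <- unique(t(apply(edges, 1, sort)))
  if (nrow(edges)) {
    keep <- edges[, 1] != edges[, 2]
    edges <- edges[keep, , drop = FALSE]
  }
  structure(list(nodes = nodes, edges = edges,
                 node_multiplicity = multiplicity, source = source),
            class = "seq_graph")
}

#' @export
print.seq_graph <- function(x, ...) {
  cat(sprintf("<seq_graph> %s: %d nodes, %d edges\n", x$source,
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a sequence graph
#' @param graph A `seq_graph`.
#' @return Integer count.
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Collapse a lattice walk into a simple graph
#'
#' Residues occupying the same lattice point are merged into one node
#' (multiplicity recorded); edges join the nodes of consecutive residues,
#' with parallel edges collapsed and self-loops (a step returning to the
#' same merged node cannot occur on a unit-step walk) excluded. The result
#' is the 2D-Cartesian map graph whose adjacency matrices feed the
#' spectral-moment descriptors: a walk that never self-intersects gives a
#' path, while pseudo-folding shows up as merged nodes and cycles.
#'
#' @param walk A [pseudo_fold_2d()] result.
#' @return A connected `seq_graph` with `source = "cartesian"`; node table
#'   has columns `x`, `y`.
#' @export
walk_to_graph <- function(walk) {
  stopifnot(inherits(walk, "lattice_walk"))
  key <- paste(walk$positions[, 1], walk$positions[, 2])
  uniq <- !duplicated(key)
  node_key <- key[uniq]
  node_idx <- match(key, node_key)
  nodes <- data.frame(x = walk$positions[uniq, 1],
                      y = walk$positions[uniq, 2])
  mult <- as.integer(table(factor(node_idx, levels = seq_len(nrow(nodes)))))
  n <- length(key)
  if (n > 1) {
    edges <- cbind(node_idx[-n], node_idx[-1])
  } else {
    edges <- matrix(integer(0), ncol = 2)
  }
  new_seq_graph(nodes, edges, "cartesian", mult)
}

#' Vertex adjacency matrix of a sequence graph
#' @param graph A `seq_graph`.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
vertex_adjacency <- function(graph) {
  n <- n_nodes(graph)
  A <- matrix(0, n, n)
  e <- graph$edges
  if (nrow(e)) {
    A[e] <- 1
    A[e[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

#' Edge adjacency matrix of a sequence graph
#'
#' Square 0/1 matrix over the edges: entry (i, j) is 1 iff edges i != j
#' share an endpoint (the adjacency matrix of the line graph). Its k-th
#' power traces are the Estrada spectral moments of the edge adjacency
#' matrix.
#'
#' @param graph A `seq_graph` with at least one edge.
#' @return m x m symmetric 0/1 matrix, zero diagonal, m = number of edges.
#' @export
edge_adjacency <- function(graph) {
  e <- graph$edges
  m <- nrow(e)
  if (m == 0L) stop("edge adjacency is undefined for an edgeless graph")
  # node-edge incidence B satisfies t(B) %*% B = E + 2 I for a simple graph
  B <- matrix(0, n_nodes(graph), m)
  B[cbind(e[, 1], seq_len(m))] <- 1
  B[cbind(e[, 2], seq_len(m))] <- 1
  E <- crossprod(B) - 2 * diag(m)
  E[E > 1] <- 1  # guard; cannot occur for a simple graph
  E
}

# square-spiral coordinates: start (0,0), first step +x, counterclockwise,
# run lengths 1,1,2,2,3,3,...
spiral_coords <- function(n) {
  out <- matrix(0L, n, 2)
  dirs <- rbind(c(1L, 0L), c(0L, 1L), c(-1L, 0L), c(0L, -1L))
  pos <- c(0L, 0L)
  i <- 1L; d <- 1L; run <- 1L
  while (i < n) {
    for (rep in 1:2) {
      for (s in seq_len(run)) {
        pos <- pos + dirs[d, ]
        i <- i + 1L
        out[i, ] <- pos
        if (i == n) return(out)
      }
      d <- d %% 4L + 1L
    }
    run <- run + 1L
  }
  out
}

#' Lay a sequence on a four-color square spiral
#'
#' One square cell per residue, placed along a square spiral that starts
#' at (0,0), steps first in +x and turns counterclockwise; each cell is
#' colored by the residue's group label (four physicochemical classes for
#' proteins, the four nucleotides for DNA).
#'
#' @param seq A [seq_record()] or residue string.
#' @param scheme A [get_grouping()] scheme mapping every residue.
#' @return A `four_color_map`: `cells` data.frame (x, y, color, rank).
#' @export
four_color_spiral <- function(seq, scheme) {
  stopifnot(inherits(scheme, "grouping_scheme"))
  chars <- seq_chars(seq)
  groups <- scheme$mapping[chars]
  bad <- which(is.na(groups))
  if (length(bad))
    stop(sprintf("residue '%s' at position %d is not mapped by scheme '%s'",
                 chars[bad[1]], bad[1], scheme$name))
  xy <- spiral_coords(length(chars))
  structure(list(cells = data.frame(x = xy[, 1], y = xy[, 2],
                                    color = unname(groups),
                                    rank = seq_along(chars)),
                 scheme = scheme$name),
            class = "four_color_map")
}

#' Graph(s) from a four-color map
#'
#' In `whole` mode the cells are the nodes and edges join side-sharing
#' (von Neumann) neighbor cells. In `per_color` mode the map is split into
#' the subgraphs induced by each color class; these may be disconnected
#' (the connectivity invariant is deliberately waived for color classes).
#'
#' @param map A [four_color_spiral()] result.
#' @param mode `"whole"` or `"per_color"`.
#' @return A `seq_graph`, or a named list of `seq_graph`s keyed by color.
#' @export
map_to_graph <- function(map, mode = c("whole", "per_color")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "four_color_map"))
  cells <- map$cells
  build <- function(sub) {
    n <- nrow(sub)
    key <- paste(sub$x, sub$y)
    edges <- matrix(integer(0), ncol = 2)
    if (n > 1) {
      shifts <- rbind(c(1L, 0L), c(0L, 1L))  # one direction per axis avoids duplicates
      for (s in 1:2) {
        nb <- match(paste(sub$x + shifts[s, 1], sub$y + shifts[s, 2]), key)
        hit <- which(!is.na(nb))
        if (length(hit)) edges <- rbind(edges, cbind(hit, nb[hit]))
      }
    }
    new_seq_graph(data.frame(x = sub$x, y = sub$y), edges, "fourcolor")
  }
  if (mode == "whole") return(build(cells))
  lapply(split(cells, cells$color), build)
}

#' Star graph of a sequence
#'
#' An abstract 2D representation with an imaginary center emitting one ray
#' per residue type present in the sequence; the nodes on ray r form a
#' path whose length is the count of residue r, so each residue occupies
#' one ray position (assigned in order of occurrence along the sequence).
#' With `embedded = TRUE` the original sequence topology is superimposed:
#' extra edges join the ray vertices of consecutive sequence positions
#' (deduplicated, no self-loops).
#'
#' @param seq A [seq_record()] or residue string (non-empty).
#' @param embedded Add sequence-order edges (the "embedded" star variant).
#' @return A `seq_graph` with `source = "star_pure"` or `"star_embedded"`;
#'   node 1 is the center, other nodes carry `residue` and `ray_pos`
#'   columns, rays ordered by canonical alphabet order for reproducible
#'   matrix indexing.
#' @export
#' @examples
#' g <- star_graph(seq_record("s", "AAG", "protein"))
#' n_nodes(g); n_edges(g)
star_graph <- function(seq, embedded = FALSE) {
  chars <- seq_chars(seq)
  if (!length(chars)) stop("cannot build a star graph from an empty sequence")
  types <- sort(unique(chars))  # canonical alphabet order
  nodes <- data.frame(residue = c("*", unlist(lapply(types, function(t)
    rep(t, sum(chars == t))))),
    stringsAsFactors = FALSE)
  nodes$ray_pos <- c(0L, unlist(lapply(types, function(t)
    seq_len(sum(chars == t)))))
  # node index for ray position p of type t
  offset <- stats::setNames(cumsum(c(1L, vapply(types, function(t)
    sum(chars == t), integer(1))))[seq_along(types)], types)
  node_of <- function(type, p) offset[[type]] + p
  edges <- matrix(integer(0), ncol = 2)
  for (t in types) {
    cnt <- sum(chars == t)
    ray <- vapply(seq_len(cnt), function(p) node_of(t, p), integer(1))
    edges <- rbind(edges, cbind(c(1L, ray[-cnt]), ray))
  }
  if (embedded && length(chars) > 1) {
    occ <- integer(length(chars))       # ray position of each sequence index
    seen <- stats::setNames(integer(length(types)), types)
    for (i in seq_along(chars)) {
      seen[chars[i]] <- seen[chars[i]] + 1L
      occ[i] <- node_of(chars[i], seen[[chars[i]]])
    }
    edges <- rbind(edges, cbind(occ[-length(occ)], occ[-1]))
  }
  new_seq_graph(nodes, edges,
                if (embedded) "star_embedded" else "star_pure")
}

#' Convert a sequence graph to an igraph object
#' @param graph A `seq_graph`.
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = n_nodes(graph), directed = FALSE)
  if (nrow(graph$edges)) g <- igraph::add_edges(g, t(graph$edges))
  g
}

#' Is the graph connected?
#' @param graph A `seq_graph`.
#' @return Logical.
#' @export
is_connected_graph <- function(graph) {
  if (n_nodes(graph) <= 1L) return(TRUE)
  igraph::is_connected(as_igraph(graph))
}

#' Export a sequence graph as an edge-list TSV
#' @param graph A `seq_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_graph_tsv <- function(graph, path) {
  df <- data.frame(from = graph$edges[, 1], to = graph$edges[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
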