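# closed-walk counter by stepwise neighbor-list propagation: exact integer
# dynamic programming over walk endpoints, independent of the package's
# matrix-power implementation; cross-validated against the recursive DFS
# walker (count_closed_walks) in the descriptor tests
count_closed_walks_dp <- function(A, k_max) {
  n <- nrow(A)
  nb <- lapply(seq_len(n), function(i) which(A[i, ] > 0))
  out <- numeric(k_max + 1)
  out[1] <- n
  for (s in seq_len(n)) {
    cnt <- numeric(n)
    cnt[s] <- 1
    for (k in seq_len(k_max)) {
      nxt <- numeric(n)
      for (v in which(cnt > 0)) {
        for (u in nb[[v]]) nxt[u] <- nxt[u] + cnt[v]
      }
      cnt <- nxt
      out[k + 1] <- out[k + 1] + cnt[s]
    }
  }
  out
}

# structured small-graph suite: all paths, cycles and stars on <= max_n nodes
structured_graph_suite <- function(max_n = 8) {
  suite <- list()
  for (n in 2:max_n) {
    path <- cbind(1:(n - 1), 2:n)
    suite <- c(suite, list(seqtopo:::new_seq_graph(
      data.frame(x = 1:n, y = 0), path, "cartesian")))
    if (n >= 3) {
      suite <- c(suite, list(
        seqtopo:::new_seq_graph(data.frame(x = 1:n, y = 0),
                                rbind(path, c(n, 1L)), "cartesian"),
        seqtopo:::new_seq_graph(data.frame(x = 1:n, y = 0),
                                cbind(rep(1L, n - 1), 2:n), "cartesian")))
    }
  }
  suite
}
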