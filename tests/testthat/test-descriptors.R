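hp4 <- get_grouping("hp4")
uni <- property_table("uniform")

test_that("spectral moments equal closed-walk counts on small graphs", {
  set.seed(11)
  suite <- list()
  # all paths, cycles and stars on <= 8 nodes
  for (n in 2:8) {
    suite <- c(suite, list(
      seqtopo:::new_seq_graph(data.frame(x = 1:n, y = 0),
                              cbind(1:(n - 1), 2:n), "cartesian")))
    if (n >= 3) suite <- c(suite, list(
      seqtopo:::new_seq_graph(data.frame(x = 1:n, y = 0),
                              rbind(cbind(1:(n - 1), 2:n), c(n, 1L)),
                              "cartesian"),
      seqtopo:::new_seq_graph(data.frame(x = 1:n, y = 0),
                              cbind(rep(1L, n - 1), 2:n), "cartesian")))
  }
  for (i in 1:15) suite <- c(suite, list(
    random_connected_graph(sample(3:8, 1), sample(0:3, 1))))
  for (g in suite) {
    A <- vertex_adjacency(g)
    mv <- spectral_moments(g, 6, "vertex")$moments
    for (k in 0:6) expect_equal(mv[[k + 1]], count_closed_walks(A, k))
    L <- line_graph_adjacency(g)
    me <- spectral_moments(g, 4, "edge")$moments
    for (k in 0:4) expect_equal(me[[k + 1]], count_closed_walks(L, k))
  }
})

test_that("the IGIHVGR worked example yields mu0 = 6, mu1 = 0, mu2 = 10", {
  g <- walk_to_graph(pseudo_fold_2d("IGIHVGR", hp4))
  m <- spectral_moments(g, 2, "edge")$moments
  expect_equal(unname(m), c(6, 0, 10))
})

test_that("vertex moments obey the edge-count and bipartite identities", {
  set.seed(12)
  for (i in 1:10) {
    r <- random_protein(sample(10:50, 1))
    g <- walk_to_graph(pseudo_fold_2d(r, hp4))
    m <- spectral_moments(g, 3, "vertex")$moments
    expect_equal(m[["mu2"]], 2 * n_edges(g))
    expect_equal(m[["mu1"]], 0)
    # lattice walk graphs are subgraphs of the bipartite grid: no odd walks
    expect_equal(m[["mu3"]], 0)
  }
})

test_that("markov transition matches the uniform-weight hand computation", {
  m <- markov_transition(seq_record("x", "GGG", "protein"), uni)
  expect_equal(m$transition,
               matrix(c(1/2, 1/2, 0, 1/3, 1/3, 1/3, 0, 1/2, 1/2),
                      3, 3, byrow = TRUE))
  expect_equal(m$initial, rep(1/3, 3))
  expect_equal(sum(stochastic_spectral_moments(m, 1)[["pi1"]]), 4/3)
  m1 <- markov_transition(seq_record("y", "K", "protein"), uni)
  expect_equal(m1$transition, matrix(1, 1, 1))
  expect_equal(m1$initial, 1)
})

test_that("markov models keep stochasticity under powering and propagation", {
  set.seed(13)
  tables <- list(uni, property_table("charge"),
                 property_table("hydrophobicity", transform = "shift"))
  for (i in 1:40) {
    r <- random_protein(sample(5:40, 1))
    tab <- tables[[sample.int(3, 1)]]
    m <- markov_transition(r, tab)
    expect_true(all(m$transition >= 0))
    P <- diag(m$n)
    for (k in 1:10) {
      P <- P %*% m$transition
      expect_equal(rowSums(P), rep(1, m$n), tolerance = 1e-8)
    }
    pis <- stochastic_spectral_moments(m, 6)
    expect_equal(pis[["pi0"]], m$n)
    expect_true(all(pis[-1] >= 0 & pis[-1] <= m$n + 1e-12))
    # oracle: trace of explicit repeated powering
    P6 <- Reduce(`%*%`, rep(list(m$transition), 6))
    expect_equal(pis[["pi6"]], sum(diag(P6)), tolerance = 1e-10)
    th <- markov_entropies(m, 8)
    expect_true(all(th >= -1e-12 & th <= log2(m$n) + 1e-12))
    p <- m$initial
    for (k in 1:8) {
      p <- as.vector(p %*% m$transition)
      expect_equal(sum(p), 1, tolerance = 1e-8)
    }
    expect_equal(th[["theta8"]], -sum(p[p > 0] * log2(p[p > 0])))
  }
})

test_that("markov entropy endpoints behave like Shannon entropy", {
  m <- markov_transition(seq_record("x", "ACDE", "protein"), uni)
  expect_equal(markov_entropies(m, 0)[["theta0"]], 2)  # uniform over 4
  # point-mass start: charge weights are nonzero only at K here
  km <- markov_transition(seq_record("y", "GGKGG", "protein"),
                          property_table("charge"))
  expect_equal(markov_entropies(km, 0)[["theta0"]], 0)
})

test_that("classical TIs match distance oracles on the AAG star and beyond", {
  tis <- classical_tis(star_graph("AAG"))
  expect_equal(tis[["wiener"]], 10)
  two <- seqtopo:::new_seq_graph(data.frame(x = 1:2, y = 0),
                                 rbind(c(1L, 2L)), "cartesian")
  t2 <- classical_tis(two)
  expect_equal(t2[["wiener"]], 1)
  expect_equal(t2[["harary"]], 1)
  expect_equal(t2[["randic"]], 1)
  set.seed(14)
  for (i in 1:25) {
    r <- random_protein(sample(4:30, 1))
    g <- star_graph(r, embedded = (i %% 2 == 0))
    tis <- classical_tis(g)
    D <- floyd_warshall(vertex_adjacency(g))
    ut <- upper.tri(D)
    expect_equal(tis[["wiener"]], sum(D[ut]))
    expect_equal(tis[["harary"]], sum(1 / D[ut]))
    npairs <- sum(ut)
    expect_lte(tis[["harary"]], npairs + 1e-9)
    expect_gte(tis[["wiener"]], npairs)
    expect_equal(tis[["chi1"]], tis[["randic"]])
  }
})

test_that("Moreau-Broto terms respond to property weighting", {
  g <- star_graph("AAG")
  unw <- classical_tis(g)
  # distance-1 pairs: 3 edges, unit weights
  expect_equal(unw[["ats1"]], 3)
  wtd <- classical_tis(g, property_table("hydrophobicity",
                                         transform = "shift"))
  expect_false(isTRUE(all.equal(unw[["ats1"]], wtd[["ats1"]])))
})

test_that("disconnected graphs are rejected and reducible to components", {
  part <- seqtopo:::new_seq_graph(data.frame(x = 1:4, y = 0),
                                  rbind(c(1L, 2L), c(3L, 4L)), "cartesian")
  expect_error(classical_tis(part), "connected")
  expect_message(big <- largest_component(part), "largest")
  expect_equal(n_nodes(big), 2)
  expect_silent(classical_tis(big))
})

test_that("autocorrelation vectors match direct summation", {
  vals <- stats::setNames(rep(0, 20), seqtopo:::AA20)
  vals[c("A", "C", "D")] <- c(1, 2, 3)
  tab <- property_table("toy", values = vals, transform = "none")
  a <- aasa_autocorrelation(seq_record("x", "ACD", "protein"), tab, 2)
  expect_equal(a[["ats_lag1"]], 1 * 2 + 2 * 3)
  expect_equal(a[["ats_lag2"]], 1 * 3)
  n <- 12
  u <- aasa_autocorrelation(random_protein(n), uni, 15)
  expect_equal(unname(u), c(pmax(n - 1:11, 0), rep(0, 4)))
  expect_error(aasa_autocorrelation(seq_record("s", "A", "protein"), uni),
               "length > 1")
  expect_error(aasa_autocorrelation(random_protein(10), uni, 16), "1..15")
})

test_that("composition and k-mer frequencies normalize over their windows", {
  r <- seq_record("x", "AAG", "protein")
  comp <- composition(r)
  expect_equal(comp[["A"]], 2 / 3)
  expect_equal(comp[["G"]], 1 / 3)
  expect_equal(sum(comp), 1)
  expect_equal(sum(comp == 0), 18)
  k2 <- kmer_freqs(r, 2)
  expect_equal(k2[["AA"]], 0.5)
  expect_equal(k2[["AG"]], 0.5)
  expect_error(kmer_freqs(r, 3), "k must satisfy")
  set.seed(15)
  for (i in 1:5) {
    r <- random_protein(40)
    expect_equal(sum(kmer_freqs(r, sample(1:4, 1))), 1)
  }
})

test_that("entropy, LZ76 and divergences behave per theory", {
  expect_equal(shannon_entropy("AAAA", 1), 0)
  expect_equal(shannon_entropy("ACGT", 1), 2)
  set.seed(16)
  rand8 <- paste(sample(c("A", "C", "G", "T"), 8, TRUE), collapse = "")
  expect_lt(lz_complexity("AAAAAAAA"), lz_complexity(rand8))
  # hand parse: A | AC | G | T | ACC | AT | TG  (each phrase is the
  # shortest prefix of the remainder not seen in the preceding text)
  expect_equal(lz_complexity("AACGTACCATTG"), 7)
  p <- c(0.5, 0.3, 0.2)
  q <- c(0.2, 0.5, 0.3)
  expect_equal(kl_divergence(p, p), 0, tolerance = 1e-9)
  expect_equal(js_divergence(p, q), js_divergence(q, p))
  expect_gte(js_divergence(p, q), 0)
  expect_lte(js_divergence(p, q), 1)
  expect_equal(euclidean_distance(p, q), sqrt(sum((p - q)^2)))
  expect_error(kl_divergence(p, c(0.5, 0.5)), "dimension")
  set.seed(17)
  for (i in 1:200) {
    a <- runif(8); a <- a / sum(a)
    b <- runif(8); b <- b / sum(b)
    expect_gte(kl_divergence(a, b), 0)   # Gibbs' inequality
  }
  al <- align_distributions(c(AA = 0.5, AC = 0.5), c(AC = 0.25, GG = 0.75))
  expect_named(al$p, c("AA", "AC", "GG"))
  expect_equal(sum(al$q), 1)
})

test_that("descriptor vectors are finite, named and representation-tagged", {
  set.seed(18)
  r <- random_protein(40)
  for (rep in c("cartesian", "fourcolor", "star", "star_embedded", "chain")) {
    v <- descriptor_vector(r, rep, k_max = 6)
    expect_true(all(is.finite(v)))
    expect_true(all(startsWith(names(v), rep)))
    expect_false(anyDuplicated(names(v)) > 0)
  }
})
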