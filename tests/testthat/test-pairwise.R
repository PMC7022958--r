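test_that("alignment scores match the reference DP on random pairs", {
  set.seed(21)
  b62 <- default_submat("protein")
  nuc <- default_submat("dna")
  for (i in 1:25) {
    if (i %% 2 == 0) {
      a <- random_protein(sample(5:60, 1))$residues
      b <- random_protein(sample(5:60, 1))$residues
      smat <- b62; mol <- "protein"
    } else {
      a <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(5:60, 1), TRUE),
                 collapse = "")
      smat <- nuc; mol <- "dna"
    }
    for (mode in c("global", "local")) {
      got <- align(a, b, mode, molecule = mol)$score
      want <- ref_align_score(a, b, smat, 10, 0.5, mode == "local")
      expect_equal(got, want, info = sprintf("%s #%d", mode, i))
    }
  }
})

test_that("self-alignment gives 100% identity and symmetric scores", {
  set.seed(22)
  for (i in 1:5) {
    r <- random_protein(sample(20:80, 1))
    self <- align(r, r)
    expect_equal(self$identity_pct, 100)
    expect_equal(self$similarity_pct, 100)
    s <- random_protein(sample(20:80, 1), "other")
    expect_equal(align(r, s)$score, align(s, r)$score)
    expect_equal(align(r, s, "local")$score, align(s, r, "local")$score)
  }
})

test_that("aligned strings reconstruct the input and score consistently", {
  set.seed(23)
  b62 <- default_submat("protein")
  for (i in 1:10) {
    a <- random_protein(sample(10:40, 1))$residues
    b <- random_protein(sample(10:40, 1))$residues
    r <- align(a, b, "global")
    expect_equal(gsub("-", "", r$aligned_a), a)
    expect_equal(gsub("-", "", r$aligned_b), b)
    expect_equal(nchar(r$aligned_a), nchar(r$aligned_b))
    # recompute the score of the emitted alignment column by column
    ca <- strsplit(r$aligned_a, "")[[1]]
    cb <- strsplit(r$aligned_b, "")[[1]]
    sc <- 0
    gap_side <- ""
    for (col in seq_along(ca)) {
      side <- if (ca[col] == "-") "a" else if (cb[col] == "-") "b" else ""
      if (nzchar(side)) {
        sc <- sc - if (side == gap_side) 0.5 else 10
      } else {
        sc <- sc + b62[ca[col], cb[col]]
      }
      gap_side <- side
    }
    expect_equal(sc, r$score)
    expect_lte(r$identity_pct, r$similarity_pct)
  }
})

test_that("gapless mismatch example gives 75% identity", {
  r <- align("AAAA", "AAAT", molecule = "dna")
  expect_equal(r$identity_pct, 75)
  expect_equal(r$aligned_length, 4)
})

test_that("molecule mismatch and empty input are rejected", {
  p <- seq_record("p", "MKV", "protein")
  d <- seq_record("d", "ACG", "dna")
  expect_error(align(p, d), "molecule mismatch")
  expect_error(align("", "ACG", molecule = "dna"), "empty")
  expect_error(align("AC", "GT", molecule = "dna", gap_open = -1),
               "positive")
})

test_that("bit scores and e-values follow the Karlin-Altschul formulas", {
  expect_equal(bit_score(100), (0.267 * 100 - log(0.041)) / log(2))
  expect_equal(bit_score(100), 43.128, tolerance = 1e-3)
  raws <- seq(10, 200, by = 10)
  bits <- bit_score(raws)
  es <- evalue(raws)
  expect_true(all(diff(bits) > 0))
  expect_true(all(diff(es) < 0))
  p <- ka_params(search_m = 200, search_n = 300)
  expect_equal(evalue(0, p), 0.041 * 200 * 300)
})

test_that("all-vs-all matrices are symmetric with the stated diagonal", {
  set.seed(24)
  recs <- list(seq_record("a", "MKVLILAC", "protein"),
               seq_record("b", "MKVLILAC", "protein", validate = TRUE),
               seq_record("c", "WWHHEEDD", "protein"))
  recs[[2]]$id <- "b"
  m <- all_vs_all(recs, "identity_pct")
  expect_equal(unname(diag(m$values)), rep(100, 3))
  expect_equal(m$values[["a", "b"]], 100)
  expect_equal(m$values, t(m$values))
  bs <- all_vs_all(recs, "bitscore")
  expect_gt(bs$values[["a", "a"]], bs$values[["a", "c"]])
  dup <- list(recs[[1]], recs[[1]])
  expect_error(all_vs_all(dup, "identity_pct"), "duplicate")
  expect_error(all_vs_all(recs[1], "identity_pct"), "at least 2")
})

test_that("relabeling input order never changes pairwise identities", {
  set.seed(25)
  recs <- lapply(1:5, function(i) random_protein(30, paste0("s", i)))
  m1 <- all_vs_all(recs, "identity_pct")
  perm <- c(3, 1, 5, 2, 4)
  m2 <- all_vs_all(recs[perm], "identity_pct")
  for (i in 1:5) for (j in 1:5) {
    expect_equal(m2$values[[recs[[i]]$id, recs[[j]]$id]],
                 m1$values[[recs[[i]]$id, recs[[j]]$id]])
  }
})

test_that("zone classification applies the published thresholds", {
  expect_equal(classify_zone(25, 150)$zone, "twilight")
  expect_equal(classify_zone(15, 150)$zone, "midnight")
  expect_equal(classify_zone(50, 150)$zone, "above")
  expect_equal(classify_zone(52, 120, molecule = "rna")$zone, "twilight")
  expect_equal(classify_zone(57, 120, molecule = "rna")$zone, "above")
  expect_true(classify_zone(32, 120)$safe_homolog)
  expect_false(classify_zone(32, 80)$safe_homolog)
  expect_false(classify_zone(28, 300)$safe_homolog)
  expect_true(classify_zone(40, 120, bits = 55)$bit_significant)
  expect_false(classify_zone(40, 120, bits = 45)$bit_significant)
  expect_true(classify_zone(40, 120, bits = 45,
                            db_size = 5000)$bit_significant)
  expect_error(classify_zone(130, 100), "\\[0, 100\\]")
  expect_error(classify_zone(52, 100, molecule = "rna",
                             rna_threshold = 70), "\\[50, 60\\]")
})

test_that("zone classification is total and piecewise-constant on [0,100]", {
  grid <- seq(0, 100, by = 0.5)
  zones <- vapply(grid, function(x) classify_zone(x, 200)$zone, "")
  expect_true(all(zones %in% c("midnight", "twilight", "above")))
  expect_equal(unique(zones[grid < 20]), "midnight")
  expect_equal(unique(zones[grid >= 20 & grid <= 35]), "twilight")
  expect_equal(unique(zones[grid > 35]), "above")
})

test_that("redundancy reduction keeps the first of each cluster", {
  r <- seq_record("orig", strrep("MKVLILACDE", 6), "protein")
  copies <- lapply(1:5, function(i) {
    x <- r; x$id <- paste0("copy", i); x
  })
  set.seed(26)
  unrelated <- random_protein(60, "unrel")
  out <- redundancy_reduce(c(list(r), copies, list(unrelated)), 40)
  expect_equal(vapply(out, `[[`, "", "id"), c("orig", "unrel"))
  two <- redundancy_reduce(list(r, copies[[1]]), 90)
  expect_equal(vapply(two, `[[`, "", "id"), "orig")
  distinct <- list(seq_record("x", "MKVLILACDE", "protein"),
                   seq_record("y", "WWHHRRGGSS", "protein"))
  expect_length(redundancy_reduce(distinct, 40), 2)
})
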