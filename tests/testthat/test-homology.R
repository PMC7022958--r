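make_table <- function(n_per_class = 10, sep = 3, seed = 41) {
  withr::with_seed(seed, {
    x1 <- rnorm(n_per_class)
    x2 <- rnorm(n_per_class) + sep
    tab <- data.frame(f1 = c(x1, x2),
                      f2 = rnorm(2 * n_per_class))
    rownames(tab) <- paste0("s", seq_len(2 * n_per_class))
    labels <- rep(c("negative", "positive"), each = n_per_class)
    list(tab = tab, labels = labels)
  })
}

test_that("feature tables have deterministic shape and rows", {
  set.seed(42)
  recs <- list(random_protein(30, "a"), random_protein(30, "b"))
  tab <- build_feature_table(recs,
    recipe = list(list(representation = "cartesian", k_max = 3)))
  expect_equal(dim(tab), c(2, 4))
  expect_equal(rownames(tab), c("a", "b"))
  twin <- recs[[1]]
  twin$id <- "a_twin"
  same <- build_feature_table(list(recs[[1]], twin))
  expect_equal(unname(unlist(same[1, ])), unname(unlist(same[2, ])))
  expect_error(build_feature_table(list(recs[[1]], recs[[1]])),
               "duplicate sequence ids")
  two <- build_feature_table(recs,
    recipe = list(list(representation = "cartesian", k_max = 3),
                  list(representation = "star", k_max = 2)))
  expect_equal(ncol(two), 4 + 3)
})

test_that("descriptor failures name the sequence and recipe", {
  # uncharged sequence: the charge-weighted Markov chain is undefined
  recs <- list(seq_record("uncharged", "GGGGGG", "protein"))
  expect_error(build_feature_table(recs,
    recipe = list(list(representation = "chain", k_max = 2,
                       property = property_table("charge")))),
    "chain.*uncharged")
})

test_that("classifiers separate separable data and enforce preconditions", {
  d <- make_table(10, sep = 6)
  for (model in c("decision_tree", "linear")) {
    fit <- suppressWarnings(train_classifier(d$tab, model,
                                             labels = d$labels))
    pred <- predict(fit, d$tab)
    ev <- evaluate_predictions(pred, d$labels)
    expect_equal(ev[["accuracy"]], 1)
    expect_equal(ev[["auroc"]], 1)
  }
  expect_error(train_classifier(d$tab, labels = rep("x", 20)), "2 classes")
  expect_error(train_classifier(d$tab[1:6, ], labels = rep(c("a", "b"), 3)),
               ">= 5 rows")
})

test_that("predictions are invariant to row and feature-column order", {
  d <- make_table(12, sep = 2.5)
  fit <- train_classifier(d$tab, "decision_tree", labels = d$labels)
  base <- predict(fit, d$tab)
  perm <- sample(nrow(d$tab))
  byrow <- predict(fit, d$tab[perm, ])
  expect_equal(byrow$score, base$score[perm])
  bycol <- predict(fit, d$tab[, c("f2", "f1")])
  expect_equal(bycol$score, base$score)
})

test_that("AUROC rank statistic matches brute-force pair counting", {
  set.seed(43)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    scores <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # forces ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(auroc(scores, pos), brute_auroc(scores, pos))
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("permuted labels give chance-level cross-validated AUROC", {
  d <- make_table(20, sep = 4)
  aucs <- vapply(1:5, function(r) {
    perm <- withr::with_seed(100 + r, sample(d$labels))
    cv_auroc(d$tab, perm, "decision_tree", folds = 5, seed = r)$auroc
  }, numeric(1))
  expect_true(all(aucs > 0.3 & aucs < 0.7))
  # and the true labeling scores far above chance
  expect_gt(cv_auroc(d$tab, d$labels, "decision_tree", 5, 1)$auroc, 0.9)
})

test_that("combined scorer weights track discriminatory ability", {
  set.seed(44)
  n <- 200
  labels <- rep(c(FALSE, TRUE), each = n / 2)
  informative <- ifelse(labels, rnorm(n, 2), rnorm(n, 0))
  noise <- rnorm(n)
  sc <- fit_combined_scorer(data.frame(informative, noise), labels)
  expect_gt(sc$auc[["informative"]], 0.85)
  expect_gt(sc$weights[["informative"]], 0.9)
  expect_equal(sum(sc$weights), 1)
  comb <- combined_score(sc, data.frame(informative, noise))
  expect_gte(auroc(comb, labels), auroc(noise, labels))
  # degenerate measure: zero weight with warning
  expect_warning(
    dg <- fit_combined_scorer(data.frame(informative,
                                         flat = rep(1, n)), labels),
    "degenerate")
  expect_equal(dg$weights[["flat"]], 0)
})

test_that("combined score reduces to a single normalized measure at weight 1", {
  set.seed(45)
  m1 <- runif(50); m2 <- runif(50)
  labels <- m1 > 0.5   # makes m1 perfectly informative
  sc <- fit_combined_scorer(data.frame(m1, m2), labels)
  manual <- (m1 - min(m1)) / diff(range(m1))
  expect_equal(combined_score(sc, data.frame(m1, m2)),
               sc$weights[["m1"]] * manual +
                 sc$weights[["m2"]] * (m2 - min(m2)) / diff(range(m2)))
  # identical measures: combination equals the measure under any weights
  sc2 <- suppressWarnings(fit_combined_scorer(data.frame(a = m1, b = m1),
                                              labels))
  expect_equal(combined_score(sc2, data.frame(a = m1, b = m1)), manual)
})

test_that("combined score is monotone in each member measure", {
  set.seed(46)
  labels <- rep(c(FALSE, TRUE), 25)
  base <- data.frame(m1 = rnorm(50) + labels, m2 = rnorm(50) + 0.5 * labels)
  sc <- fit_combined_scorer(base, labels)
  x <- data.frame(m1 = 0.3, m2 = 0.4)
  s0 <- combined_score(sc, x)
  for (d in c(0.05, 0.2)) {
    expect_gte(combined_score(sc, data.frame(m1 = 0.3 + d, m2 = 0.4)), s0)
    expect_gte(combined_score(sc, data.frame(m1 = 0.3, m2 = 0.4 + d)), s0)
  }
})

test_that("k-NN over combined similarity votes with the neighborhood", {
  set.seed(47)
  labels <- rep(c("out", "in"), each = 20)
  m1 <- c(rnorm(20, 0), rnorm(20, 3))
  m2 <- rnorm(40)
  sc <- fit_combined_scorer(data.frame(m1, m2), labels == "in")
  hit <- knn_combined(sc, data.frame(m1, m2), labels, k = 5)
  expect_equal(hit$label, "in")
})

test_that("ensemble voting implements the stated rules and agreement", {
  votes <- data.frame(dtm = c(TRUE, TRUE, FALSE, TRUE),
                      hmm = c(TRUE, TRUE, TRUE, FALSE),
                      blast = c(TRUE, FALSE, FALSE, FALSE),
                      row.names = paste0("q", 1:4))
  un <- ensemble_vote(votes, "unanimous")
  expect_equal(unname(un$consensus), c(TRUE, FALSE, FALSE, FALSE))
  mj <- ensemble_vote(votes, "majority")
  expect_equal(unname(mj$consensus), c(TRUE, TRUE, FALSE, FALSE))
  wt <- ensemble_vote(votes, "weighted", weights = c(3, 1, 1))
  expect_equal(unname(wt$consensus), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(un$per_predictor[["dtm"]], 3)
  # set identity: |A and B| + |A minus B| = |A|
  both <- sum(votes$dtm & votes$hmm)
  only_a <- sum(votes$dtm & !votes$hmm)
  expect_equal(both + only_a, sum(votes$dtm))
  expect_error(ensemble_vote(votes[, 1, drop = FALSE]), ">= 2")
  votes$hmm[2] <- NA
  expect_error(ensemble_vote(votes), "same sequence set")
  chr <- data.frame(a = c("positive", "negative"),
                    b = c("positive", "positive"))
  expect_equal(unname(ensemble_vote(chr, "unanimous")$consensus),
               c(TRUE, FALSE))
})
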