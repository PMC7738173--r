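test_that("splits honour fractions, ratios and disjointness", {
  set.seed(1)
  positives <- data.frame(kinase = sprintf("K%d", 1:20),
                          substrate = sprintf("S%03d", 1:1000),
                          site_residue = "S", site_pos = 1:1000,
                          stringsAsFactors = FALSE)
  pool <- data.frame(kinase = "KX", substrate = sprintf("N%05d", 1:11000),
                     site_residue = "S", site_pos = 1:11000,
                     stringsAsFactors = FALSE)
  cfg <- benchmark_config(n_runs = 1, train_fraction = 0.9,
                          pos_neg_ratio = 1, rng_seed = 4)
  sp <- make_split(positives, pool, cfg, run_index = 1)
  expect_equal(sum(sp$test$label == 1), 100)
  expect_equal(sum(sp$test$label == 0), 100)
  expect_equal(sum(sp$train$label == 1), 900)
  expect_equal(sum(sp$train$label == 0), 900)

  cfg10 <- benchmark_config(n_runs = 1, pos_neg_ratio = 10, rng_seed = 4)
  sp10 <- make_split(positives, pool, cfg10, run_index = 1)
  expect_equal(sum(sp10$test$label == 1), 100)
  expect_equal(sum(sp10$test$label == 0), 1000)

  key <- function(df) phoslink:::statement_key(df)
  expect_equal(length(intersect(key(sp$train), key(sp$test))), 0)

  # reproducible per run index
  expect_identical(make_split(positives, pool, cfg, 3),
                   make_split(positives, pool, cfg, 3))
  expect_false(identical(make_split(positives, pool, cfg, 3),
                         make_split(positives, pool, cfg, 4)))
  expect_error(make_split(positives, pool[1:10, ], cfg10), "pool too small")
})

test_that("score assignment zeroes uncovered statements and counts coverage", {
  test_set <- data.frame(kinase = "K", substrate = sprintf("S%d", 1:10),
                         site_residue = "S", site_pos = 1:10,
                         label = rep(c(1L, 0L), 5), stringsAsFactors = FALSE)
  none <- assign_scores(test_set, function(st) rep(NA_real_, nrow(st)))
  expect_true(all(none$scored$score == 0))
  expect_equal(none$coverage$total, 0)

  all_cov <- assign_scores(test_set, function(st) runif(nrow(st)))
  expect_equal(all_cov$coverage$total, 100)
  expect_equal(all_cov$coverage$missed_negatives, 0)

  # mixed coverage: counters equal a brute-force recount
  mixed_scorer <- function(st) ifelse(st$site_pos %% 3 == 0, NA_real_, 0.5)
  mixed <- assign_scores(test_set, mixed_scorer)
  covered <- test_set$site_pos %% 3 != 0
  expect_equal(mixed$coverage$total, 100 * mean(covered))
  expect_equal(mixed$coverage$positive,
               100 * mean(covered[test_set$label == 1]))
  expect_equal(mixed$coverage$negative,
               100 * mean(covered[test_set$label == 0]))
  expect_equal(mixed$coverage$missed_negatives,
               100 - mixed$coverage$negative)
  expect_equal(nrow(mixed$scored), nrow(test_set))
})

test_that("precision at K counts positives among the top-ranked statements", {
  scores <- seq(1, 0.05, length.out = 20)
  labels <- c(rep(1, 9), 0, rep(0, 10))  # 9 positives in the top 10
  expect_equal(precision_at_k(scores, labels, 10), 0.9)
  expect_equal(precision_at_k(rep(1, 5), rep(1, 5), 5), 1)
  expect_warning(p <- precision_at_k(scores, labels, 50), "full set")
  expect_equal(p, mean(labels))

  # random scores on balanced labels average about one half
  set.seed(5)
  ps <- replicate(300, precision_at_k(runif(40), rep(c(1, 0), 20), 10))
  expect_equal(mean(ps), 0.5, tolerance = 0.03)
})

test_that("AUC computation matches the all-pairs concordance oracle", {
  # perfect separation
  perfect <- curves_and_aucs(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(perfect$au_roc, 1)
  expect_equal(perfect$au_pr, 1)
  # all-equal scores: one operating point, chance AU-ROC
  flat <- curves_and_aucs(rep(0.5, 10), rep(c(1, 0), 5))
  expect_equal(flat$au_roc, 0.5)
  expect_equal(flat$au_pr, 0.5)

  set.seed(6)
  for (i in 1:10) {
    scores <- sample(seq(0, 1, 0.1), 20, replace = TRUE)  # many ties
    labels <- sample(c(0, 1), 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- curves_and_aucs(scores, labels)
    expect_equal(got$au_roc, mann_whitney_auc(scores, labels),
                 tolerance = 1e-12)
    # permutation invariance
    perm <- sample.int(20)
    expect_equal(curves_and_aucs(scores[perm], labels[perm])$au_roc,
                 got$au_roc, tolerance = 1e-12)
    expect_equal(curves_and_aucs(scores[perm], labels[perm])$au_pr,
                 got$au_pr, tolerance = 1e-12)
  }
  expect_error(curves_and_aucs(c(1, 2), c(1, 1)), "both labels")
})

test_that("AU-ROC agrees with an independent ROC implementation", {
  set.seed(7)
  scores <- runif(200)
  labels <- rbinom(200, 1, plogis(3 * scores - 1.5))
  got <- curves_and_aucs(scores, labels)$au_roc
  want <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                         direction = "<")))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("benchmark runs are reproducible and scorer-symmetric", {
  set.seed(8)
  positives <- data.frame(kinase = sample(sprintf("K%d", 1:5), 120, TRUE),
                          substrate = sprintf("S%03d", 1:120),
                          site_residue = "S", site_pos = 1:120,
                          stringsAsFactors = FALSE)
  pool <- data.frame(kinase = "KX", substrate = sprintf("N%04d", 1:1300),
                     site_residue = "S", site_pos = 1:1300,
                     stringsAsFactors = FALSE)
  # deterministic scorer: hash-based pseudo-score, independent of training
  fake_factory <- function(train) {
    function(st) phoslink:::stable_hash(st$substrate) / 2147483647
  }
  cfg <- benchmark_config(n_runs = 3, K_list = c(5, 10), rng_seed = 2)
  res <- run_benchmark(positives, pool,
                       list(a = fake_factory, b = fake_factory), cfg)
  a_rows <- res$runs[res$runs$scorer == "a", -2]
  b_rows <- res$runs[res$runs$scorer == "b", -2]
  rownames(a_rows) <- rownames(b_rows) <- NULL
  expect_equal(a_rows, b_rows)
  expect_true(all(res$summary$au_roc_sd >= 0))
  res2 <- run_benchmark(positives, pool, list(a = fake_factory), cfg)
  expect_equal(res2$runs$au_pr, a_rows$au_pr)
})

test_that("sensitivity is the eligible-substrate fraction with predictions", {
  expect_equal(round(sensitivity(c("PKA", "TGM2", "PSMC5", "PA2G4"),
                                 sprintf("E%d", 1:7)), 2), 0)
  eligible <- c("PKA", "TGM2", "PSMC5", "PA2G4", "X1", "X2", "X3")
  expect_equal(round(sensitivity(c("PKA", "TGM2", "PSMC5", "PA2G4"),
                                 eligible), 2), 0.57)
  expect_equal(sensitivity(eligible, eligible), 1)
  expect_equal(sensitivity("ZZZ", eligible), 0)
  expect_error(sensitivity("A", character(0)), "empty")
})
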