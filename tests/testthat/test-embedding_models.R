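test_that("TransE score is the negated translation distance", {
  expect_equal(score_transe(c(1, 0), c(0, 1), c(1, 1)), 0)
  expect_equal(score_transe(c(0, 0), c(3, 4), c(0, 0), norm = "L2"), -5)
  expect_equal(score_transe(c(0, 0), c(3, 4), c(0, 0), norm = "L1"), -7)
  expect_error(score_transe(c(1, 2), c(1, 2, 3), c(1, 2)), "dimension")

  # agreement with brute-force distances on random triples, both norms
  set.seed(1)
  for (i in 1:100) {
    s <- rnorm(8); r <- rnorm(8); o <- rnorm(8)
    expect_equal(score_transe(s, r, o, "L2"), -sqrt(sum((s + r - o)^2)))
    expect_equal(score_transe(s, r, o, "L1"), -sum(abs(s + r - o)))
  }
})

test_that("DistMult is the printed trilinear form and is symmetric", {
  expect_equal(score_distmult(c(1, 2), c(1, 0), c(3, 4)), 3)
  set.seed(2)
  for (i in 1:50) {
    s <- rnorm(6); r <- rnorm(6); o <- rnorm(6)
    expect_equal(score_distmult(s, r, o), sum(s * r * o))
    expect_equal(score_distmult(s, r, o), score_distmult(o, r, s))
  }
  s <- rnorm(6); o <- rnorm(6)
  expect_equal(score_distmult(s, rep(1, 6), o), sum(s * o))
})

test_that("ComplEx reduces to DistMult on real vectors and is antisymmetric for imaginary relations", {
  set.seed(3)
  for (i in 1:50) {
    s <- rnorm(5); r <- rnorm(5); o <- rnorm(5)
    expect_equal(score_complex(s, r, o), score_distmult(s, r, o),
                 tolerance = 1e-12)
    ri <- complex(real = 0, imaginary = rnorm(5))
    expect_equal(score_complex(s, ri, o), -score_complex(o, ri, s),
                 tolerance = 1e-10)
  }
  # brute-force complex-arithmetic oracle
  for (i in 1:100) {
    s <- complex(real = rnorm(4), imaginary = rnorm(4))
    r <- complex(real = rnorm(4), imaginary = rnorm(4))
    o <- complex(real = rnorm(4), imaginary = rnorm(4))
    oracle <- 0
    for (j in 1:4) oracle <- oracle + s[j] * r[j] * Conj(o[j])
    expect_equal(score_complex(s, r, o), Re(oracle), tolerance = 1e-10)
  }
})

test_that("matrix scoring path matches the single-vector score functions", {
  set.seed(4)
  d <- 6
  E <- matrix(rnorm(5 * d), 5)
  R <- matrix(rnorm(3 * d), 3)
  si <- c(1, 2, 5); ri <- c(1, 3, 2); oi <- c(3, 4, 1)
  for (model in c("TransE", "DistMult")) {
    got <- phoslink:::score_rows(model, E, R, si, ri, oi, d)
    want <- vapply(1:3, function(i) {
      if (model == "TransE") score_transe(E[si[i], ], R[ri[i], ], E[oi[i], ])
      else score_distmult(E[si[i], ], R[ri[i], ], E[oi[i], ])
    }, numeric(1))
    expect_equal(got, want, tolerance = 1e-12)
  }
  Ec <- matrix(rnorm(5 * 2 * d), 5)
  Rc <- matrix(rnorm(3 * 2 * d), 3)
  got <- phoslink:::score_rows("ComplEx", Ec, Rc, si, ri, oi, d)
  want <- vapply(1:3, function(i) {
    cvec <- function(M, j) complex(real = M[j, 1:d],
                                   imaginary = M[j, (d + 1):(2 * d)])
    score_complex(cvec(Ec, si[i]), cvec(Rc, ri[i]), cvec(Ec, oi[i]))
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("logistic calibration is a strictly increasing map onto (0,1)", {
  expect_equal(calibrate_score(0), 0.5)
  expect_gt(calibrate_score(100), 1 - 1e-12)
  expect_lt(calibrate_score(-100), 1e-12)
  x <- sort(rnorm(50))
  expect_true(all(diff(calibrate_score(x)) > 0))
  expect_equal(order(calibrate_score(x)), order(x))
})

test_that("training reduces the hinge loss and is bitwise reproducible", {
  sim <- small_sim()
  k <- sim$config$k
  motifs <- infer_family_motifs(sim$network, motif_config(k = k))
  compat <- phoslink:::site_compatibility(sim$network, motifs, k)
  triples <- to_knowledge_graph(sim$network, motifs, k, compat = compat)
  negs <- generate_negatives(triples, sim$network, motifs, k,
                             negative_config(rng_seed = 3), compat = compat)

  for (model in c("TransE", "DistMult", "ComplEx")) {
    cfg <- train_config(model, d = 16, epochs = 30, rng_seed = 3)
    fit <- train_embeddings(triples, negs, cfg)
    expect_true(all(is.finite(fit$loss_trace)))
    # non-increasing in moving average
    ma <- stats::filter(fit$loss_trace, rep(1 / 5, 5), sides = 1)
    ma <- ma[!is.na(ma)]
    expect_true(all(diff(ma) < 1e-6))
    # margin satisfaction improves over the untrained initialisation
    init <- train_embeddings(triples, negs,
                             train_config(model, d = 16, epochs = 0,
                                          rng_seed = 3))
    expect_gt(margin_satisfaction(fit, triples, negs),
              margin_satisfaction(init, triples, negs))
    # determinism
    fit2 <- train_embeddings(triples, negs, cfg)
    expect_identical(fit$loss_trace, fit2$loss_trace)
    expect_identical(fit$E, fit2$E)
  }
})

test_that("checkpoints round-trip scores exactly", {
  sim <- small_sim()
  k <- sim$config$k
  motifs <- infer_family_motifs(sim$network, motif_config(k = k))
  triples <- to_knowledge_graph(sim$network, motifs, k)
  negs <- generate_negatives(triples, sim$network, motifs, k,
                             negative_config(rng_seed = 3))
  model <- train_embeddings(triples, negs,
                            train_config("ComplEx", d = 8, epochs = 10,
                                         rng_seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_equal(score_triples(back, triples), score_triples(model, triples),
               tolerance = 1e-12)
})

test_that("grid search reports folds x configurations and returns the argmax", {
  sim <- small_sim()
  k <- sim$config$k
  motifs <- infer_family_motifs(sim$network, motif_config(k = k))
  compat <- phoslink:::site_compatibility(sim$network, motifs, k)
  triples <- to_knowledge_graph(sim$network, motifs, k, compat = compat)
  negs <- generate_negatives(triples, sim$network, motifs, k,
                             negative_config(rng_seed = 3), compat = compat)

  one <- data.frame(model = "DistMult", d = 8)
  gs1 <- grid_search(triples, negs, one, folds = 2, epochs = 5, rng_seed = 3)
  expect_equal(gs1$best_config$model, "DistMult")
  expect_equal(gs1$best_config$d, 8)
  expect_equal(nrow(gs1$report), 2)

  grid <- data.frame(model = c("DistMult", "ComplEx"), d = c(8, 8))
  gs <- grid_search(triples, negs, grid, folds = 3, epochs = 5, rng_seed = 3)
  expect_equal(nrow(gs$report), 6)
  means <- stats::aggregate(au_roc ~ model, gs$report, mean)
  expect_equal(gs$best_config$model,
               means$model[which.max(means$au_roc)])
  expect_true(gs$test_auroc >= 0 && gs$test_auroc <= 1)
  expect_error(grid_search(triples, negs, grid[0, ], folds = 2), "")
})
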