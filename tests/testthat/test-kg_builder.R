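test_that("KG conversion fans out over compatible family motifs", {
  net <- tiny_network()
  k <- 2
  # SUBA site 3 window "ASQPR" (pos 3, k=2), SUBA/SUBB site 9 window "ASFDE"/"ASFAA"
  m_a <- manual_motif(list(c(A = 1), c(S = 1), c(Q = 1)), family = "FAMX",
                      id = "FAMX.m1")
  m_b <- manual_motif(list(c(S = 1), c(Q = 2), c(P = 1)), family = "FAMX",
                      id = "FAMX.m2")
  m_y <- manual_motif(list(c(A = -1), c(S = -1), c(F = -1)), family = "FAMY",
                      id = "FAMY.m1")
  motifs <- list(FAMX.m1 = m_a, FAMX.m2 = m_b, FAMY.m1 = m_y)
  triples <- to_knowledge_graph(net, motifs, k)
  # statement (KIN1, SUBA, S3): both FAMX motifs compatible -> 2 triples;
  # statement (KIN1, SUBB, S9): window ASFAA compatible with m1 (A+S) and m2
  # (S at offset?) -- compute expected from compatibility directly
  expected <- 0
  wins <- context_windows(net, k)
  for (i in seq_len(nrow(wins))) {
    fam_motifs <- Filter(function(m) m$family == wins$family[i], motifs)
    expected <- expected +
      sum(vapply(fam_motifs, function(m) is_compatible(m, wins$window[i]),
                 logical(1)))
  }
  expect_equal(attr(triples, "n_fanout"), expected)
  expect_equal(nrow(triples),
               nrow(unique(triples[, c("kinase", "motif_id", "substrate")])))
  # FAMY's anti-motif is incompatible: KIN2's statement is dropped
  expect_false("KIN2" %in% triples$kinase)
  expect_equal(attr(triples, "n_statements_dropped"), 1)
})

test_that("triple count equals the per-statement compatibility bookkeeping on synthetic data", {
  sim <- small_sim()
  motifs <- infer_family_motifs(sim$network, motif_config(k = sim$config$k))
  triples <- to_knowledge_graph(sim$network, motifs, sim$config$k)
  wins <- context_windows(sim$network, sim$config$k)
  fanout <- 0
  dropped <- 0
  for (i in seq_len(nrow(wins))) {
    fam_motifs <- Filter(function(m) m$family == wins$family[i], motifs)
    n <- sum(vapply(fam_motifs, function(m) is_compatible(m, wins$window[i]),
                    logical(1)))
    fanout <- fanout + n
    if (n == 0) dropped <- dropped + 1
  }
  expect_equal(attr(triples, "n_fanout"), fanout)
  expect_equal(attr(triples, "n_statements_dropped"), dropped)
})

test_that("back-conversion fans out over compatible sites and dedups by max score", {
  net <- tiny_network()
  k <- 2
  m_a <- manual_motif(list(c(A = 1), c(S = 1)), family = "FAMX",
                      id = "FAMX.m1", center_offset = 2)
  m_b <- manual_motif(list(c(S = 1), c(F = 1)), family = "FAMX",
                      id = "FAMX.m2", center_offset = 1)
  motifs <- list(FAMX.m1 = m_a, FAMX.m2 = m_b)
  scored <- data.frame(kinase = c("KIN1", "KIN1"),
                       motif_id = c("FAMX.m1", "FAMX.m2"),
                       substrate = "SUBA", score = c(0.7, 0.4),
                       stringsAsFactors = FALSE)
  preds <- back_convert(scored, net, motifs, k)
  # both SUBA sites (3 and 9) have A-S context -> compatible with both
  # motifs; duplicates keep the maximum (0.7)
  expect_equal(nrow(preds), 2)
  expect_true(all(preds$score == 0.7))
  expect_setequal(preds$site_pos, c(3L, 9L))

  # order independence of dedup-by-max
  preds2 <- back_convert(scored[2:1, ], net, motifs, k)
  expect_equal(preds2[order(preds2$site_pos), ],
               preds[order(preds$site_pos), ])

  # an incompatible motif yields no predictions
  anti <- manual_motif(list(c(A = -5), c(S = -5)), family = "FAMX",
                       id = "FAMX.m3")
  out <- back_convert(
    data.frame(kinase = "KIN1", motif_id = "FAMX.m3", substrate = "SUBA",
               score = 0.9, stringsAsFactors = FALSE),
    net, list(FAMX.m3 = anti), k)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_triples_without_sites"), 1)
})

test_that("every converted statement is recovered by back-converting its triple", {
  sim <- small_sim()
  k <- sim$config$k
  motifs <- infer_family_motifs(sim$network, motif_config(k = k))
  compat <- phoslink:::site_compatibility(sim$network, motifs, k)
  triples <- to_knowledge_graph(sim$network, motifs, k, compat = compat)
  triples$score <- 0.9
  preds <- back_convert(triples, sim$network, motifs, k, compat = compat)
  pred_keys <- paste(preds$kinase, preds$substrate, preds$site_pos)
  st <- sim$network$statements
  wins <- context_windows(sim$network, k)
  for (i in seq_len(nrow(st))) {
    fam_motifs <- Filter(function(m) m$family == wins$family[i], motifs)
    covered <- any(vapply(fam_motifs,
                          function(m) is_compatible(m, wins$window[i]),
                          logical(1)))
    if (covered) {
      expect_true(paste(st$kinase[i], st$substrate[i], st$site_pos[i]) %in%
                    pred_keys)
    }
  }
})

test_that("candidate streaming enumerates the Cartesian product in chunks", {
  net <- tiny_network()
  # 2 kinases x 3 (substrate, site) pairs
  nxt <- generate_candidates(net, chunk_size = 4, include_known = TRUE)
  expect_equal(attr(nxt, "n_total"), 6)
  got <- list()
  while (!is.null(ch <- nxt())) got[[length(got) + 1]] <- ch
  all_rows <- do.call(rbind, got)
  expect_equal(nrow(all_rows), 6)
  expect_equal(vapply(got, nrow, integer(1)), c(4L, 2L))

  # known statements excluded by default
  nxt2 <- generate_candidates(net, chunk_size = 100)
  rest <- nxt2()
  expect_equal(nrow(rest), 3)  # 6 minus the 3 known
  expect_false(any(phoslink:::statement_key(rest) %in%
                     phoslink:::statement_key(net$statements)))
})

test_that("KG TSV export writes subject/relation/object", {
  sim <- small_sim()
  motifs <- infer_family_motifs(sim$network, motif_config(k = sim$config$k))
  triples <- to_knowledge_graph(sim$network, motifs, sim$config$k)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_kg_tsv(triples, tsv)
  back <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  expect_equal(names(back), c("subject", "relation", "object"))
  expect_equal(nrow(back), nrow(triples))
})
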