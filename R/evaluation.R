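# Comparative-validation harness: repeated train/test splits over positive
# statements and an unconstrained random-combination negative pool,
# zero-score assignment for uncovered statements, ranking metrics (AU-PR,
# AU-ROC, precision-at-K), coverage accounting and assay sensitivity.

#' Benchmark configuration
#'
#' Defaults follow the reference protocol: 100 independent 90/10 splits
#' with a 1:1 positive:negative ratio and precision at K = 10 and 50.
#'
#' @param n_runs number of independent split/train/test repetitions.
#' @param train_fraction fraction of positives assigned to training.
#' @param pos_neg_ratio negatives sampled per positive (1 for 1:1, 10 for
#'   1:10).
#' @param K_list cutoffs for precision-at-K.
#' @param rng_seed root seed; per-run seeds are derived from it.
#' @return list of class \code{benchmark_config}.
#' @export
benchmark_config <- function(n_runs = 100, train_fraction = 0.9,
                             pos_neg_ratio = 1, K_list = c(10, 50),
                             rng_seed = 42) {
  stopifnot(train_fraction > 0, train_fraction < 1, pos_neg_ratio >= 1)
  structure(list(n_runs = n_runs, train_fraction = train_fraction,
                 pos_neg_ratio = pos_neg_ratio, K_list = K_list,
                 rng_seed = rng_seed),
            class = "benchmark_config")
}

#' Unconstrained benchmark negative pool
#'
#' Random combinations of network kinases with (substrate, site) pairs,
#' excluding known positive statements. This pool is intentionally
#' unconstrained (no family or motif filtering), unlike the training-time
#' corruption operators.
#'
#' @param network a \code{phospho_network}.
#' @param n pool size requested.
#' @param rng_seed seed.
#' @return statement data.frame (kinase, substrate, site_residue,
#'   site_pos); may be smaller than \code{n} when the candidate space is
#'   exhausted.
#' @export
random_negative_pool <- function(network, n, rng_seed = 42) {
  st <- network$statements
  kinases <- sort(unique(st$kinase))
  sites <- unique(st[, c("substrate", "site_residue", "site_pos")])
  sites <- sites[order(sites$substrate, sites$site_pos), , drop = FALSE]
  known <- statement_key(st)
  n_space <- length(kinases) * nrow(sites)
  with_seed(rng_seed, {
    take <- min(n_space, max(2 * n, n + length(known)))
    idx <- sample.int(n_space, take)
    ki <- ((idx - 1) %/% nrow(sites)) + 1
    si <- ((idx - 1) %% nrow(sites)) + 1
    pool <- data.frame(kinase = kinases[ki],
                       substrate = sites$substrate[si],
                       site_residue = sites$site_residue[si],
                       site_pos = sites$site_pos[si],
                       stringsAsFactors = FALSE)
    pool <- pool[!statement_key(pool) %in% known, , drop = FALSE]
    pool <- utils::head(pool, n)
    rownames(pool) <- NULL
    pool
  })
}

#' Seeded train/test split of positives and pool negatives
#'
#' @param positives positive statements.
#' @param negative_pool pool from [random_negative_pool()].
#' @param config a [benchmark_config()].
#' @param run_index 1-based run number (drives the per-run seed).
#' @return list with \code{train} and \code{test} statement data.frames,
#'   each carrying a \code{label} column (1 positive, 0 negative); train
#'   and test are disjoint across both labels and honour
#'   \code{pos_neg_ratio}.
#' @export
make_split <- function(positives, negative_pool, config, run_index = 1) {
  cols <- c("kinase", "substrate", "site_residue", "site_pos")
  positives <- positives[, cols, drop = FALSE]
  negative_pool <- negative_pool[, cols, drop = FALSE]
  n <- nrow(positives)
  n_train <- round(config$train_fraction * n)
  need_neg <- config$pos_neg_ratio * n
  if (nrow(negative_pool) < need_neg) {
    stop("negative pool too small: need ", need_neg, ", have ",
         nrow(negative_pool))
  }
  with_seed(derive_seed(config$rng_seed, paste("split", run_index)), {
    perm <- sample.int(n)
    tr_pos <- positives[perm[seq_len(n_train)], , drop = FALSE]
    te_pos <- positives[perm[-seq_len(n_train)], , drop = FALSE]
    nperm <- sample.int(nrow(negative_pool), need_neg)
    n_tr_neg <- config$pos_neg_ratio * n_train
    tr_neg <- negative_pool[nperm[seq_len(n_tr_neg)], , drop = FALSE]
    te_neg <- negative_pool[nperm[-seq_len(n_tr_neg)], , drop = FALSE]
    lab <- function(df, l) { df$label <- l; rownames(df) <- NULL; df }
    list(train = rbind(lab(tr_pos, 1L), lab(tr_neg, 0L)),
         test = rbind(lab(te_pos, 1L), lab(te_neg, 0L)))
  })
}

#' Score a test set, assigning zero to uncovered statements
#'
#' @param test_set statement data.frame with a \code{label} column.
#' @param scorer function(statements) returning numeric scores with NA for
#'   statements it cannot score (uncovered).
#' @return list: \code{scored} (test set with a \code{score} column, NA
#'   replaced by 0) and \code{coverage} (percent total/positive/negative
#'   coverage and percent missed negatives).
#' @export
assign_scores <- function(test_set, scorer) {
  raw <- scorer(test_set)
  stopifnot(length(raw) == nrow(test_set))
  covered <- !is.na(raw)
  pos <- test_set$label == 1
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  neg_cov <- pct(covered[!pos])
  scored <- test_set
  scored$score <- ifelse(covered, raw, 0)
  list(scored = scored,
       coverage = list(total = pct(covered),
                       positive = pct(covered[pos]),
                       negative = neg_cov,
                       missed_negatives = 100 - neg_cov))
}

#' Precision at K
#'
#' Fraction of true positives among the K highest-scored statements.
#' Ties are broken by stable input order by default; set
#' \code{tie_permutations > 0} to average over that many random
#' permutations of tied blocks instead.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @param k cutoff; when larger than the set size the full set is used
#'   with a warning.
#' @param tie_permutations number of random tie permutations to average
#'   over (0 = stable order).
#' @param rng_seed seed used when \code{tie_permutations > 0}.
#' @return precision in [0, 1].
#' @export
precision_at_k <- function(scores, labels, k, tie_permutations = 0,
                           rng_seed = 42) {
  stopifnot(length(scores) == length(labels))
  if (k > length(scores)) {
    warning("K exceeds set size; computing over the full set")
    k <- length(scores)
  }
  top_frac <- function(ord) mean(labels[ord][seq_len(k)] == 1)
  if (tie_permutations == 0) {
    return(top_frac(order(-scores)))
  }
  with_seed(rng_seed, {
    mean(vapply(seq_len(tie_permutations), function(i) {
      jitter_ord <- sample.int(length(scores))
      ord <- jitter_ord[order(-scores[jitter_ord])]
      top_frac_perm <- mean(labels[ord][seq_len(k)] == 1)
      top_frac_perm
    }, numeric(1)))
  })
}

#' Area under the ROC and precision-recall curves
#'
#' Scores are grouped by threshold (ties form a single operating point).
#' AU-ROC is computed by the trapezoidal rule over the ROC curve -- with
#' tie grouping this equals the Mann-Whitney all-pairs statistic with ties
#' counted one half. AU-PR uses step-wise interpolation of the PR curve
#' (the precision of each threshold group weighted by its recall
#' increment).
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @param curve also return the curve points.
#' @return list with \code{au_roc}, \code{au_pr} and optionally
#'   \code{roc} / \code{pr} data.frames.
#' @export
curves_and_aucs <- function(scores, labels, curve = FALSE) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) stop("both labels must be present")
  ord <- order(-scores)
  s <- scores[ord]
  l <- labels[ord]
  # threshold grouping: last index of each distinct score
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l == 1)[grp_end]
  fp <- cumsum(l == 0)[grp_end]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  au_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  au_pr <- sum(diff(c(0, recall)) * precision)
  out <- list(au_roc = au_roc, au_pr = au_pr)
  if (curve) {
    out$roc <- data.frame(fpr = fpr, tpr = tpr)
    out$pr <- data.frame(recall = recall, precision = precision)
  }
  out
}

#' Statement scorer backed by the embedding pipeline
#'
#' Returns a scorer factory for [run_benchmark()]: given a training split
#' it infers nothing new (motifs are fixed upfront), converts the positive
#' training statements to knowledge-graph triples, generates constrained
#' negatives, trains an embedding model and returns a closure scoring
#' arbitrary statements. A statement's score is the maximum calibrated
#' triple score over the compatible motifs of the kinase's family; NA
#' (uncovered) when no motif is compatible or an entity was unseen.
#'
#' @param network the full \code{phospho_network} (site universe and
#'   families).
#' @param motifs motif list inferred from the full network.
#' @param k context size.
#' @param config a [train_config()].
#' @param neg_config a [negative_config()].
#' @param compat optional precomputed site-compatibility scan.
#' @return function(train_split) -> function(statements) -> scores.
#' @export
kge_statement_scorer <- function(network, motifs, k,
                                 config = train_config(),
                                 neg_config = negative_config(),
                                 compat = NULL) {
  if (is.null(compat)) compat <- site_compatibility(network, motifs, k)
  fam_of_motif <- vapply(motifs, function(m) m$family, character(1))

  statement_triples <- function(statements) {
    skey <- paste(statements$substrate, statements$site_pos, sep = "@")
    fams <- unname(network$families[statements$kinase])
    rows <- vector("list", nrow(statements))
    for (i in seq_len(nrow(statements))) {
      if (is.na(fams[i]) || !skey[i] %in% colnames(compat$compat)) next
      mids <- names(motifs)[fam_of_motif == fams[i]]
      mids <- mids[compat$compat[mids, skey[i]]]
      if (length(mids) == 0) next
      rows[[i]] <- data.frame(stmt = i, kinase = statements$kinase[i],
                              motif_id = mids,
                              substrate = statements$substrate[i],
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  }

  function(train_split) {
    train_pos <- train_split[train_split$label == 1, , drop = FALSE]
    sub_net <- network
    sub_net$statements <- merge_seq_ids(train_pos, network)
    triples <- to_knowledge_graph(sub_net, motifs, k, compat = compat)
    negatives <- generate_negatives(triples, network, motifs, k,
                                    neg_config, compat = compat)
    model <- train_embeddings(triples, negatives, config)
    function(statements) {
      tr <- statement_triples(statements)
      out <- rep(NA_real_, nrow(statements))
      if (!is.null(tr)) {
        sc <- score_triples(model, tr)
        ok <- !is.na(sc)
        if (any(ok)) {
          best <- tapply(sc[ok], tr$stmt[ok], max)
          out[as.integer(names(best))] <- as.numeric(best)
        }
      }
      out
    }
  }
}

# Reattach seq_id (validated sequence record) to a statement subset drawn
# from a compiled network.
merge_seq_ids <- function(statements, network) {
  full <- network$statements
  idx <- match(statement_key(statements), statement_key(full))
  st <- statements[, c("kinase", "substrate", "site_residue", "site_pos")]
  st$organism <- full$organism[idx]
  st$seq_id <- full$seq_id[idx]
  st[!is.na(idx), , drop = FALSE]
}

#' Run the repeated-split benchmark
#'
#' For each of \code{config$n_runs} seeded splits, trains/applies every
#' scorer and computes AU-PR, AU-ROC, precision-at-K and coverage on the
#' scored test set (uncovered statements scored zero).
#'
#' @param positives positive statements.
#' @param pool unconstrained negative pool.
#' @param scorers named list of scorer factories
#'   (function(train_split) -> function(statements) -> scores).
#' @param config a [benchmark_config()].
#' @return list: \code{runs} (per-run metric data.frame) and
#'   \code{summary} (mean and sd per scorer and metric).
#' @export
run_benchmark <- function(positives, pool, scorers, config = benchmark_config()) {
  runs <- NULL
  for (r in seq_len(config$n_runs)) {
    split <- make_split(positives, pool, config, run_index = r)
    for (nm in names(scorers)) {
      scorer <- scorers[[nm]](split$train)
      res <- assign_scores(split$test, scorer)
      met <- curves_and_aucs(res$scored$score, res$scored$label)
      row <- data.frame(run = r, scorer = nm, au_pr = met$au_pr,
                        au_roc = met$au_roc,
                        coverage_total = res$coverage$total,
                        coverage_positive = res$coverage$positive,
                        coverage_negative = res$coverage$negative,
                        missed_negatives = res$coverage$missed_negatives,
                        stringsAsFactors = FALSE)
      for (K in config$K_list) {
        row[[paste0("p_at_", K)]] <-
          precision_at_k(res$scored$score, res$scored$label, K)
      }
      runs <- rbind(runs, row)
    }
  }
  metric_cols <- setdiff(names(runs), c("run", "scorer"))
  summary <- do.call(rbind, lapply(split(runs, runs$scorer), function(df) {
    means <- vapply(metric_cols, function(cn) mean(df[[cn]]), numeric(1))
    sds <- vapply(metric_cols, function(cn) stats::sd(df[[cn]]), numeric(1))
    out <- data.frame(scorer = df$scorer[1], stringsAsFactors = FALSE)
    for (cn in metric_cols) {
      out[[paste0(cn, "_mean")]] <- means[[cn]]
      out[[paste0(cn, "_sd")]] <- sds[[cn]]
    }
    out
  }))
  rownames(summary) <- NULL
  list(runs = runs, summary = summary)
}

#' Assay sensitivity of substrate predictions
#'
#' \code{S = |predicted ∩ eligible| / |eligible|}: the fraction of
#' assay-identified substrates, restricted to those present in the input
#' network, that received at least one high-stringency site prediction.
#'
#' @param predicted_substrates substrates with at least one high-stringency
#'   prediction for the assayed kinase.
#' @param eligible_substrates assay-identified substrates present in the
#'   network.
#' @return sensitivity in [0, 1].
#' @export
sensitivity <- function(predicted_substrates, eligible_substrates) {
  eligible <- unique(eligible_substrates)
  if (length(eligible) == 0) stop("eligible substrate set is empty")
  length(intersect(unique(predicted_substrates), eligible)) / length(eligible)
}
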