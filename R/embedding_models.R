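# Knowledge-graph embedding models: TransE, DistMult, ComplEx.
#
# Entities and relations are embedded as d-dimensional vectors (complex
# valued for ComplEx, stored as [Re | Im] blocks of width 2d). Training
# minimises the pairwise hinge loss
#     sum max(0, margin - score(positive) + score(negative))
# by mini-batch stochastic gradient descent, each positive paired with its
# own generated negatives.

MODEL_ORDER <- c("TransE", "DistMult", "ComplEx")

#' Training configuration
#'
#' Defaults follow the reference hyperparameter grid: 100 epochs, 10
#' mini-batches per epoch, margin 1, learning rate 0.1, two negatives per
#' positive (handled by the negative sampler).
#'
#' @param model one of \code{"TransE"}, \code{"DistMult"}, \code{"ComplEx"}.
#' @param d embedding size (grid values 50, 100, 150, 250, 500).
#' @param epochs training epochs.
#' @param n_batches mini-batches per epoch.
#' @param margin hinge-loss margin.
#' @param distance_norm \code{"L1"} or \code{"L2"} (TransE only).
#' @param learning_rate SGD step size.
#' @param rng_seed seed for initialisation and batch shuffling.
#' @param normalize_entities project entity vectors to unit norm after each
#'   batch; defaults to TRUE for TransE (standard stabilisation), FALSE
#'   otherwise.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(model = "ComplEx", d = 50, epochs = 100,
                         n_batches = 10, margin = 1, distance_norm = "L2",
                         learning_rate = 0.1, rng_seed = 42,
                         normalize_entities = NULL) {
  model <- match.arg(model, MODEL_ORDER)
  distance_norm <- match.arg(distance_norm, c("L2", "L1"))
  if (is.null(normalize_entities)) normalize_entities <- model == "TransE"
  structure(list(model = model, d = d, epochs = epochs,
                 n_batches = n_batches, margin = margin,
                 distance_norm = distance_norm,
                 learning_rate = learning_rate, rng_seed = rng_seed,
                 normalize_entities = normalize_entities),
            class = "train_config")
}

#' TransE score of a single triple
#'
#' A true triple should satisfy \code{subject + relation ~ object}; the
#' score is the negated distance \code{-||s + r - o||} under the chosen
#' norm, so higher is more plausible and 0 is the maximum.
#'
#' @param s_vec,r_vec,o_vec real vectors of equal length.
#' @param norm \code{"L2"} (Euclidean) or \code{"L1"} (Manhattan).
#' @return numeric score (<= 0).
#' @export
score_transe <- function(s_vec, r_vec, o_vec, norm = "L2") {
  check_dims(s_vec, r_vec, o_vec)
  delta <- s_vec + r_vec - o_vec
  if (norm == "L2") -sqrt(sum(delta^2)) else -sum(abs(delta))
}

#' DistMult score of a single triple
#'
#' The trilinear form \code{sum_i s_i r_i o_i}; symmetric in subject and
#' object.
#'
#' @param s_vec,r_vec,o_vec real vectors of equal length.
#' @return numeric score.
#' @export
score_distmult <- function(s_vec, r_vec, o_vec) {
  check_dims(s_vec, r_vec, o_vec)
  sum(s_vec * r_vec * o_vec)
}

#' ComplEx score of a single triple
#'
#' The real part of the trilinear form with the conjugated object,
#' \code{Re(sum_i s_i r_i conj(o_i))}. Reduces to DistMult on real vectors;
#' purely imaginary relation vectors give an antisymmetric score.
#'
#' @param s_vec,r_vec,o_vec complex (or real) vectors of equal length.
#' @return numeric score.
#' @export
score_complex <- function(s_vec, r_vec, o_vec) {
  check_dims(s_vec, r_vec, o_vec)
  Re(sum(as.complex(s_vec) * as.complex(r_vec) * Conj(as.complex(o_vec))))
}

check_dims <- function(s, r, o) {
  if (length(s) != length(r) || length(r) != length(o)) {
    stop("embedding dimension mismatch")
  }
  invisible(TRUE)
}

#' Map a raw embedding score to a probabilistic score in (0, 1)
#'
#' Strictly increasing logistic map; raw score 0 calibrates to 0.5 (the
#' "higher-than-random plausibility" point used by the medium-stringency
#' threshold), so ranking by calibrated score equals ranking by raw score.
#'
#' @param raw_score numeric vector of raw scores.
#' @return numeric vector in (0, 1).
#' @export
calibrate_score <- function(raw_score) {
  stats::plogis(raw_score)
}

# ---- internal vectorised scoring / gradients over parameter matrices ----

# E: n_e x p, R: n_r x p (p = d, or 2d for ComplEx). si/ri/oi: index vectors.
score_rows <- function(model, E, R, si, ri, oi, d, norm = "L2") {
  S <- E[si, , drop = FALSE]; Rl <- R[ri, , drop = FALSE]
  O <- E[oi, , drop = FALSE]
  switch(model,
    TransE = {
      delta <- S + Rl - O
      if (norm == "L2") -sqrt(rowSums(delta^2)) else -rowSums(abs(delta))
    },
    DistMult = rowSums(S * Rl * O),
    ComplEx = {
      re <- seq_len(d); im <- d + re
      rowSums(S[, re, drop = FALSE] * Rl[, re, drop = FALSE] * O[, re, drop = FALSE] +
              S[, im, drop = FALSE] * Rl[, re, drop = FALSE] * O[, im, drop = FALSE] +
              S[, re, drop = FALSE] * Rl[, im, drop = FALSE] * O[, im, drop = FALSE] -
              S[, im, drop = FALSE] * Rl[, im, drop = FALSE] * O[, re, drop = FALSE])
    })
}

# Gradients of the score wrt the subject, relation and object rows.
grad_rows <- function(model, E, R, si, ri, oi, d, norm = "L2") {
  S <- E[si, , drop = FALSE]; Rl <- R[ri, , drop = FALSE]
  O <- E[oi, , drop = FALSE]
  switch(model,
    TransE = {
      delta <- S + Rl - O
      if (norm == "L2") {
        nrm <- sqrt(rowSums(delta^2))
        nrm[nrm == 0] <- 1
        g <- -delta / nrm
      } else {
        g <- -sign(delta)
      }
      list(s = g, r = g, o = -g)
    },
    DistMult = list(s = Rl * O, r = S * O, o = S * Rl),
    ComplEx = {
      re <- seq_len(d); im <- d + re
      s_re <- S[, re, drop = FALSE]; s_im <- S[, im, drop = FALSE]
      r_re <- Rl[, re, drop = FALSE]; r_im <- Rl[, im, drop = FALSE]
      o_re <- O[, re, drop = FALSE]; o_im <- O[, im, drop = FALSE]
      list(s = cbind(r_re * o_re + r_im * o_im, r_re * o_im - r_im * o_re),
           r = cbind(s_re * o_re + s_im * o_im, s_re * o_im - s_im * o_re),
           o = cbind(s_re * r_re - s_im * r_im, s_re * r_im + s_im * r_re))
    })
}

#' Train an embedding model on labeled triples
#'
#' Minimises the pairwise hinge loss over (positive, negative) pairs by
#' mini-batch SGD. Each positive is paired with its own negatives (the
#' \code{pos_index} column of \code{negatives}). Initialisation is a seeded
#' uniform Xavier scheme; for ComplEx the real and imaginary parts are
#' initialised independently. The run is fully deterministic given
#' \code{config$rng_seed}.
#'
#' @param positives positive triples (kinase, motif_id, substrate).
#' @param negatives negative triples with a \code{pos_index} column.
#' @param config a [train_config()].
#' @return object of class \code{kg_embedding}: entity/relation index maps,
#'   parameter matrices, the config and the per-epoch mean hinge-loss trace.
#' @export
train_embeddings <- function(positives, negatives, config = train_config()) {
  stopifnot(nrow(positives) > 0)
  entities <- sort(unique(c(positives$kinase, positives$substrate,
                            negatives$kinase, negatives$substrate)))
  relations <- sort(unique(c(positives$motif_id, negatives$motif_id)))
  e_id <- stats::setNames(seq_along(entities), entities)
  r_id <- stats::setNames(seq_along(relations), relations)

  d <- config$d
  p <- if (config$model == "ComplEx") 2 * d else d
  lim <- sqrt(6 / (2 * d))

  pos_s <- e_id[positives$kinase]; pos_r <- r_id[positives$motif_id]
  pos_o <- e_id[positives$substrate]
  neg_s <- e_id[negatives$kinase]; neg_r <- r_id[negatives$motif_id]
  neg_o <- e_id[negatives$substrate]
  pair_pos <- negatives$pos_index  # pair i: (positive pair_pos[i], negative i)
  n_pairs <- length(pair_pos)
  stopifnot(n_pairs > 0)

  loss_trace <- numeric(config$epochs)
  with_seed(config$rng_seed, {
    E <- matrix(stats::runif(length(entities) * p, -lim, lim),
                nrow = length(entities))
    R <- matrix(stats::runif(length(relations) * p, -lim, lim),
                nrow = length(relations))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_pairs)
      batches <- split(ord, ceiling(seq_along(ord) / ceiling(n_pairs / config$n_batches)))
      epoch_loss <- 0
      for (b in batches) {
        ps <- pos_s[pair_pos[b]]; pr <- pos_r[pair_pos[b]]
        po <- pos_o[pair_pos[b]]
        ns <- neg_s[b]; nr <- neg_r[b]; no <- neg_o[b]
        sp <- score_rows(config$model, E, R, ps, pr, po, d, config$distance_norm)
        sn <- score_rows(config$model, E, R, ns, nr, no, d, config$distance_norm)
        viol <- config$margin - sp + sn
        active <- viol > 0
        epoch_loss <- epoch_loss + sum(pmax(viol, 0))
        if (any(active)) {
          gp <- grad_rows(config$model, E, R, ps[active], pr[active],
                          po[active], d, config$distance_norm)
          gn <- grad_rows(config$model, E, R, ns[active], nr[active],
                          no[active], d, config$distance_norm)
          # d loss / d theta: -grad(score_pos) on positive rows,
          #                   +grad(score_neg) on negative rows
          ent_idx <- c(ps[active], po[active], ns[active], no[active])
          ent_grad <- rbind(-gp$s, -gp$o, gn$s, gn$o)
          agg <- rowsum(ent_grad, group = ent_idx)
          rows <- as.integer(rownames(agg))
          E[rows, ] <- E[rows, ] - config$learning_rate * agg

          rel_idx <- c(pr[active], nr[active])
          rel_grad <- rbind(-gp$r, gn$r)
          ragg <- rowsum(rel_grad, group = rel_idx)
          rrows <- as.integer(rownames(ragg))
          R[rrows, ] <- R[rrows, ] - config$learning_rate * ragg

          if (config$normalize_entities) {
            nrm <- sqrt(rowSums(E[rows, , drop = FALSE]^2))
            nrm[nrm < 1e-12] <- 1
            E[rows, ] <- E[rows, , drop = FALSE] / nrm
          }
        }
      }
      loss_trace[epoch] <- epoch_loss / n_pairs
    }
    structure(list(entities = e_id, relations = r_id, E = E, R = R,
                   config = config, loss_trace = loss_trace),
              class = "kg_embedding")
  })
}

#' @export
print.kg_embedding <- function(x, ...) {
  cat("kg_embedding:", x$config$model, "d =", x$config$d, "|",
      length(x$entities), "entities,", length(x$relations), "relations |",
      "final loss", signif(utils::tail(x$loss_trace, 1), 4), "\n")
  invisible(x)
}

#' Score triples under a trained embedding model
#'
#' @param model a \code{kg_embedding}.
#' @param triples data.frame (kinase, motif_id, substrate).
#' @param calibrated return logistic-calibrated scores in (0,1) (default)
#'   rather than raw scores.
#' @return numeric vector; NA for triples mentioning an entity or relation
#'   absent from the training vocabulary (uncovered).
#' @export
score_triples <- function(model, triples, calibrated = TRUE) {
  si <- model$entities[triples$kinase]
  ri <- model$relations[triples$motif_id]
  oi <- model$entities[triples$substrate]
  ok <- !is.na(si) & !is.na(ri) & !is.na(oi)
  out <- rep(NA_real_, nrow(triples))
  if (any(ok)) {
    raw <- score_rows(model$config$model, model$E, model$R,
                      si[ok], ri[ok], oi[ok], model$config$d,
                      model$config$distance_norm)
    out[ok] <- if (calibrated) calibrate_score(raw) else raw
  }
  out
}

#' Fraction of (positive, negative) pairs ranked correctly
#'
#' @param model a \code{kg_embedding}.
#' @param positives,negatives triple data.frames (negatives carry
#'   \code{pos_index}).
#' @return fraction of pairs with score(positive) > score(negative).
#' @export
margin_satisfaction <- function(model, positives, negatives) {
  sp <- score_triples(model, positives, calibrated = FALSE)
  sn <- score_triples(model, negatives, calibrated = FALSE)
  mean(sp[negatives$pos_index] > sn, na.rm = TRUE)
}

#' Save a trained model checkpoint (versioned JSON)
#'
#' @param model a \code{kg_embedding}.
#' @param path output path.
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(schema = "phoslink-checkpoint-1",
                  model = model$config$model,
                  config = unclass(model$config),
                  entities = names(model$entities),
                  relations = names(model$relations),
                  E = lapply(seq_len(nrow(model$E)), function(i) model$E[i, ]),
                  R = lapply(seq_len(nrow(model$R)), function(i) model$R[i, ]),
                  loss_trace = model$loss_trace)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint path.
#' @return a \code{kg_embedding}.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, "phoslink-checkpoint-1")) {
    stop("unrecognised checkpoint schema")
  }
  cfg <- payload$config
  config <- train_config(model = cfg$model, d = cfg$d, epochs = cfg$epochs,
                         n_batches = cfg$n_batches, margin = cfg$margin,
                         distance_norm = cfg$distance_norm,
                         learning_rate = cfg$learning_rate,
                         rng_seed = cfg$rng_seed,
                         normalize_entities = cfg$normalize_entities)
  to_mat <- function(rows) do.call(rbind, lapply(rows, function(r) unlist(r)))
  ents <- unlist(payload$entities)
  rels <- unlist(payload$relations)
  structure(list(entities = stats::setNames(seq_along(ents), ents),
                 relations = stats::setNames(seq_along(rels), rels),
                 E = to_mat(payload$E), R = to_mat(payload$R),
                 config = config,
                 loss_trace = unlist(payload$loss_trace)),
            class = "kg_embedding")
}

#' Grid search over model configurations with k-fold cross validation
#'
#' Splits the positive edges 80/20 into a train+validation part and a
#' held-out test part, runs k-fold cross validation on the train+validation
#' part for every configuration in the grid, and selects the configuration
#' with the highest mean validation AU-ROC (ties broken towards the smaller
#' embedding size, then the simpler model: TransE < DistMult < ComplEx).
#'
#' @param positives positive triples.
#' @param negatives constrained negatives with \code{pos_index}.
#' @param grid data.frame of configurations with columns \code{model},
#'   \code{d} and optionally \code{distance_norm}.
#' @param folds number of CV folds.
#' @param train_fraction fraction of positives in the train+validation part.
#' @param epochs,n_batches,margin,learning_rate fixed hyperparameters
#'   shared by all grid points.
#' @param rng_seed seed for the 80/20 split, fold assignment and training.
#' @return list: \code{best_config} (a [train_config()]), \code{report}
#'   (one row per configuration x fold with the validation AU-ROC) and
#'   \code{test_auroc} of the best configuration retrained on the full
#'   train+validation part.
#' @export
grid_search <- function(positives, negatives, grid, folds = 10,
                        train_fraction = 0.8, epochs = 100, n_batches = 10,
                        margin = 1, learning_rate = 0.1, rng_seed = 42) {
  stopifnot(nrow(grid) > 0)
  n <- nrow(positives)
  assign <- with_seed(rng_seed, {
    trainval <- sample.int(n, round(train_fraction * n))
    fold_of <- sample(rep_len(seq_len(folds), length(trainval)))
    list(trainval = trainval, fold_of = fold_of)
  })
  trainval <- assign$trainval
  fold_of <- assign$fold_of

  eval_fold <- function(config, fold) {
    tr_pos_idx <- trainval[fold_of != fold]
    va_pos_idx <- trainval[fold_of == fold]
    tr_pos <- positives[tr_pos_idx, , drop = FALSE]
    tr_neg <- negatives[negatives$pos_index %in% tr_pos_idx, , drop = FALSE]
    tr_neg$pos_index <- match(tr_neg$pos_index, tr_pos_idx)
    va_pos <- positives[va_pos_idx, , drop = FALSE]
    va_neg <- negatives[negatives$pos_index %in% va_pos_idx, , drop = FALSE]
    model <- train_embeddings(tr_pos, tr_neg, config)
    sc <- c(score_triples(model, va_pos), score_triples(model, va_neg))
    sc[is.na(sc)] <- 0  # uncovered statements score zero
    lab <- c(rep(1L, nrow(va_pos)), rep(0L, nrow(va_neg)))
    curves_and_aucs(sc, lab)$au_roc
  }

  report <- NULL
  for (g in seq_len(nrow(grid))) {
    config <- train_config(
      model = as.character(grid$model[g]), d = grid$d[g],
      epochs = epochs, n_batches = n_batches, margin = margin,
      distance_norm = if ("distance_norm" %in% names(grid))
        as.character(grid$distance_norm[g]) else "L2",
      learning_rate = learning_rate, rng_seed = rng_seed)
    for (fold in seq_len(folds)) {
      auroc <- eval_fold(config, fold)
      report <- rbind(report, data.frame(
        model = config$model, d = config$d,
        distance_norm = config$distance_norm, fold = fold,
        au_roc = auroc, stringsAsFactors = FALSE))
    }
  }

  means <- stats::aggregate(au_roc ~ model + d + distance_norm, data = report,
                            FUN = mean)
  means$model_rank <- match(means$model, MODEL_ORDER)
  means <- means[order(-means$au_roc, means$d, means$model_rank), ]
  best <- means[1, ]
  best_config <- train_config(
    model = best$model, d = best$d, epochs = epochs, n_batches = n_batches,
    margin = margin, distance_norm = best$distance_norm,
    learning_rate = learning_rate, rng_seed = rng_seed)

  # retrain best on the full train+validation part, report test AU-ROC
  tr_pos <- positives[trainval, , drop = FALSE]
  tr_neg <- negatives[negatives$pos_index %in% trainval, , drop = FALSE]
  tr_neg$pos_index <- match(tr_neg$pos_index, trainval)
  te_idx <- setdiff(seq_len(n), trainval)
  te_pos <- positives[te_idx, , drop = FALSE]
  te_neg <- negatives[negatives$pos_index %in% te_idx, , drop = FALSE]
  model <- train_embeddings(tr_pos, tr_neg, best_config)
  sc <- c(score_triples(model, te_pos), score_triples(model, te_neg))
  sc[is.na(sc)] <- 0
  lab <- c(rep(1L, nrow(te_pos)), rep(0L, nrow(te_neg)))
  test_auroc <- if (length(unique(lab)) == 2)
    curves_and_aucs(sc, lab)$au_roc else NA_real_

  list(best_config = best_config, report = report, test_auroc = test_auroc)
}
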