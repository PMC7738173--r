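# Full-data prediction: stringency thresholds, streaming candidate scoring,
# prediction export and per-protein query.

#' Compute the high-stringency threshold from positive scores
#'
#' Returns the largest threshold \code{t} such that at least
#' \code{positive_retention} of the scores are strictly above \code{t}
#' (empirical lower quantile with a strict-inequality convention): with the
#' default retention of 0.995, 99.5% of the known phosphorylations score
#' above the returned value.
#'
#' @param positive_scores calibrated scores of the known positive edges.
#' @param positive_retention fraction of positives that must exceed the
#'   threshold.
#' @return numeric threshold.
#' @export
compute_high_threshold <- function(positive_scores, positive_retention = 0.995) {
  stopifnot(length(positive_scores) > 0,
            positive_retention > 0, positive_retention <= 1)
  n <- length(positive_scores)
  m <- ceiling(positive_retention * n)  # scores that must lie above t
  cutoff <- sort(positive_scores, decreasing = TRUE)[m]
  cutoff - max(1e-9, abs(cutoff) * 1e-9)
}

#' Stringency thresholds
#'
#' @param high high-stringency threshold (from [compute_high_threshold()]).
#' @param medium medium-stringency threshold; 0.5, the point of
#'   higher-than-random plausibility under the logistic calibration.
#' @param positive_retention retention fraction used to derive \code{high}.
#' @return list of class \code{stringency_thresholds}.
#' @export
stringency_thresholds <- function(high, medium = 0.5,
                                  positive_retention = 0.995) {
  stopifnot(high > 0, high < 1)
  structure(list(high = high, medium = medium,
                 positive_retention = positive_retention),
            class = "stringency_thresholds")
}

#' Classify scores into stringency bands
#'
#' Strict inequalities at both cutoffs: \code{high} when score > high
#' threshold, \code{medium} when score > 0.5 (but not high), otherwise
#' \code{below}.
#'
#' @param score numeric scores in [0, 1].
#' @param thresholds a [stringency_thresholds()].
#' @return character vector in \{"high", "medium", "below"\}.
#' @export
classify_stringency <- function(score, thresholds) {
  ifelse(score > thresholds$high, "high",
         ifelse(score > thresholds$medium, "medium", "below"))
}

#' Train the final model on the full knowledge graph
#'
#' Convenience wrapper: converts the whole network, generates constrained
#' negatives, trains, scores all positive edges and derives the
#' high-stringency threshold from them.
#'
#' @param network a \code{phospho_network} with families.
#' @param motifs motif list.
#' @param k context size.
#' @param config a [train_config()].
#' @param neg_config a [negative_config()].
#' @param positive_retention retention for the high threshold.
#' @param compat optional precomputed site-compatibility scan.
#' @return list: \code{model}, \code{triples} (positive edges with
#'   calibrated scores), \code{thresholds}, \code{compat}.
#' @export
train_full_model <- function(network, motifs, k, config = train_config(),
                             neg_config = negative_config(),
                             positive_retention = 0.995, compat = NULL) {
  if (is.null(compat)) compat <- site_compatibility(network, motifs, k)
  triples <- to_knowledge_graph(network, motifs, k, compat = compat)
  negatives <- generate_negatives(triples, network, motifs, k, neg_config,
                                  compat = compat)
  model <- train_embeddings(triples, negatives, config)
  triples$score <- score_triples(model, triples)
  thr <- stringency_thresholds(
    compute_high_threshold(triples$score, positive_retention),
    positive_retention = positive_retention)
  list(model = model, triples = triples, thresholds = thr, compat = compat)
}

#' Score the full candidate space and export site-specific predictions
#'
#' Streams the Cartesian kinase x (substrate, site) candidate space in
#' chunks; each candidate is converted to knowledge-graph edges over the
#' compatible motifs of the kinase's family, scored under the trained
#' model, reduced to the maximum calibrated score per site, classified by
#' stringency and appended to a CSV prediction store. The full candidate
#' space is never materialised in memory.
#'
#' @param network a \code{phospho_network} with families.
#' @param motifs motif list.
#' @param fit result of [train_full_model()].
#' @param k context size.
#' @param out_csv output CSV path (kinase, substrate, residue, position,
#'   score, stringency).
#' @param chunk_size candidates per chunk.
#' @param include_known also score candidates recorded as known positives.
#' @param stringency minimum band exported: \code{"all"}, \code{"medium"}
#'   or \code{"high"}.
#' @return summary list: counts of scored predictions total/high/medium,
#'   number of unscorable candidates, and the store path.
#' @export
predict_all <- function(network, motifs, fit, k, out_csv,
                        chunk_size = 50000, include_known = FALSE,
                        stringency = "all") {
  stringency <- match.arg(stringency, c("all", "medium", "high"))
  compat <- fit$compat
  fam_of_motif <- vapply(motifs, function(m) m$family, character(1))
  nxt <- generate_candidates(network, chunk_size, include_known)
  n_total <- 0L; n_high <- 0L; n_medium <- 0L; n_uncovered <- 0L
  first <- TRUE
  while (!is.null(chunk <- nxt())) {
    if (nrow(chunk) == 0) next
    skey <- paste(chunk$substrate, chunk$site_pos, sep = "@")
    fams <- unname(network$families[chunk$kinase])
    rows <- vector("list", nrow(chunk))
    for (i in seq_len(nrow(chunk))) {
      mids <- names(motifs)[fam_of_motif == fams[i]]
      mids <- mids[compat$compat[mids, skey[i]]]
      if (length(mids) == 0) {
        n_uncovered <- n_uncovered + 1L
        next
      }
      rows[[i]] <- data.frame(cand = i, kinase = chunk$kinase[i],
                              motif_id = mids,
                              substrate = chunk$substrate[i],
                              stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, rows)
    if (is.null(tr)) next
    sc <- score_triples(fit$model, tr)
    keep <- !is.na(sc)
    n_uncovered <- n_uncovered +
      length(setdiff(unique(tr$cand[!keep]), unique(tr$cand[keep])))
    if (!any(keep)) next
    best <- tapply(sc[keep], tr$cand[keep], max)
    idx <- as.integer(names(best))
    preds <- data.frame(kinase = chunk$kinase[idx],
                        substrate = chunk$substrate[idx],
                        site_residue = chunk$site_residue[idx],
                        site_pos = chunk$site_pos[idx],
                        score = as.numeric(best),
                        stringsAsFactors = FALSE)
    preds$stringency <- classify_stringency(preds$score, fit$thresholds)
    n_total <- n_total + nrow(preds)
    n_high <- n_high + sum(preds$stringency == "high")
    n_medium <- n_medium + sum(preds$stringency == "medium")
    if (stringency == "high") {
      preds <- preds[preds$stringency == "high", , drop = FALSE]
    } else if (stringency == "medium") {
      preds <- preds[preds$stringency != "below", , drop = FALSE]
    }
    utils::write.table(preds, out_csv, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = first,
                       append = !first)
    first <- FALSE
  }
  if (first) {
    # no predictions: still emit a header-only store
    utils::write.table(
      data.frame(kinase = character(), substrate = character(),
                 site_residue = character(), site_pos = integer(),
                 score = numeric(), stringency = character()),
      out_csv, sep = ",", quote = FALSE, row.names = FALSE)
  }
  list(n_total = n_total, n_high = n_high, n_medium = n_medium,
       n_uncovered = n_uncovered, path = out_csv)
}

#' Query a prediction store for one protein
#'
#' @param store_csv path of a store written by [predict_all()].
#' @param protein accession to look up.
#' @param role \code{"kinase"}, \code{"substrate"} or \code{"both"}.
#' @param stringency minimum band returned: \code{"all"}, \code{"medium"}
#'   or \code{"high"}.
#' @return data.frame of matching predictions, score-descending; empty
#'   (with a warning) for an unknown protein.
#' @export
query_predictions <- function(store_csv, protein,
                              role = c("both", "kinase", "substrate"),
                              stringency = "all") {
  role <- match.arg(role)
  stringency <- match.arg(stringency, c("all", "medium", "high"))
  preds <- utils::read.csv(store_csv, stringsAsFactors = FALSE)
  hit <- switch(role,
                kinase = preds$kinase == protein,
                substrate = preds$substrate == protein,
                both = preds$kinase == protein | preds$substrate == protein)
  out <- preds[hit, , drop = FALSE]
  if (nrow(out) == 0) warning("protein '", protein, "' not found in store")
  if (stringency == "high") {
    out <- out[out$stringency == "high", , drop = FALSE]
  } else if (stringency == "medium") {
    out <- out[out$stringency != "below", , drop = FALSE]
  }
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
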