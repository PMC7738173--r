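# Conversion between the phosphorylation network and the knowledge graph.
#
# Forward: each statement <K, L, S> becomes one edge <K, M, S> per motif M of
# K's family that is compatible with L's context window (compatibility =
# strictly positive PSSM score). Backward: a scored edge <K, M, S> fans out
# to one site-specific prediction per known site of S compatible with M;
# duplicates keep the maximum score.

# Precompute per-motif compatibility of every distinct (substrate, site)
# window of a network. Returns a logical matrix [motif_id x site_key] plus
# the site table; this is the workhorse behind conversion, back-conversion
# and constrained negative sampling.
site_compatibility <- function(network, motifs, k) {
  wins <- context_windows(network, k)
  sites <- wins[!duplicated(wins[, c("substrate", "site_pos")]),
                c("substrate", "site_residue", "site_pos", "window")]
  rownames(sites) <- NULL
  key <- paste(sites$substrate, sites$site_pos, sep = "@")
  compat <- matrix(FALSE, nrow = length(motifs), ncol = nrow(sites),
                   dimnames = list(names(motifs), key))
  score <- matrix(NA_real_, nrow = length(motifs), ncol = nrow(sites),
                  dimnames = list(names(motifs), key))
  for (mid in names(motifs)) {
    sc <- vapply(sites$window, function(w) score_window(motifs[[mid]], w),
                 numeric(1), USE.NAMES = FALSE)
    score[mid, ] <- sc
    compat[mid, ] <- sc > 0
  }
  list(sites = sites, key = key, compat = compat, score = score)
}

#' Convert a phosphorylation network to positive knowledge-graph triples
#'
#' @param network a \code{phospho_network} with families attached.
#' @param motifs named motif list from [infer_family_motifs()].
#' @param k context size used for motif inference.
#' @param compat optional precomputed result of the internal site
#'   compatibility scan (recomputed when NULL).
#' @return data.frame of distinct positive triples with columns
#'   \code{kinase}, \code{motif_id}, \code{substrate}. Attributes:
#'   \code{n_statements_dropped} (statements with no compatible family
#'   motif) and \code{n_fanout} (total statement-motif compatibilities
#'   before triple deduplication).
#' @export
to_knowledge_graph <- function(network, motifs, k, compat = NULL) {
  if (is.null(compat)) compat <- site_compatibility(network, motifs, k)
  st <- network$statements
  fam_of_motif <- vapply(motifs, function(m) m$family, character(1))
  st_fam <- unname(network$families[st$kinase])

  rows <- vector("list", nrow(st))
  dropped <- 0L
  fanout <- 0L
  skey <- paste(st$substrate, st$site_pos, sep = "@")
  for (i in seq_len(nrow(st))) {
    if (is.na(st_fam[i])) {
      dropped <- dropped + 1L
      next
    }
    mids <- names(motifs)[fam_of_motif == st_fam[i]]
    mids <- mids[compat$compat[mids, skey[i]]]
    if (length(mids) == 0) {
      dropped <- dropped + 1L
      next
    }
    fanout <- fanout + length(mids)
    rows[[i]] <- data.frame(kinase = st$kinase[i], motif_id = mids,
                            substrate = st$substrate[i],
                            stringsAsFactors = FALSE)
  }
  triples <- do.call(rbind, rows)
  if (is.null(triples)) {
    triples <- data.frame(kinase = character(), motif_id = character(),
                          substrate = character(), stringsAsFactors = FALSE)
  }
  triples <- triples[!duplicated(triple_key(triples)), , drop = FALSE]
  rownames(triples) <- NULL
  attr(triples, "n_statements_dropped") <- dropped
  attr(triples, "n_fanout") <- fanout
  triples
}

triple_key <- function(tr) {
  paste(tr$kinase, tr$motif_id, tr$substrate, sep = "\r")
}

#' Knowledge-graph summary statistics
#'
#' @param triples positive triples from [to_knowledge_graph()].
#' @param motifs the motif list used for the conversion.
#' @return list: triple count, family count, motif (relation-type) count and
#'   average motifs per family (2 decimals).
#' @export
kg_stats <- function(triples, motifs) {
  fams <- unique(vapply(motifs, function(m) m$family, character(1)))
  list(n_triples = nrow(triples),
       n_families = length(fams),
       n_motifs = length(motifs),
       motifs_per_family = if (length(fams) > 0)
         round(length(motifs) / length(fams), 2) else 0)
}

#' Back-convert scored triples to site-specific predictions
#'
#' Each scored edge \code{<K, M, S>} yields one prediction per known site of
#' \code{S} whose context window is compatible with \code{M}. Predictions
#' duplicated across motifs (same kinase, substrate, site) keep only the
#' maximum score, which is order-independent.
#'
#' @param scored_triples data.frame with \code{kinase}, \code{motif_id},
#'   \code{substrate}, \code{score} (scores in \code{[0,1]}).
#' @param network the \code{phospho_network} providing the known-site map.
#' @param motifs motif list.
#' @param k context size.
#' @param compat optional precomputed site-compatibility scan.
#' @return data.frame with \code{kinase}, \code{substrate},
#'   \code{site_residue}, \code{site_pos}, \code{score}; attribute
#'   \code{n_triples_without_sites} counts triples yielding no prediction.
#' @export
back_convert <- function(scored_triples, network, motifs, k, compat = NULL) {
  if (is.null(compat)) compat <- site_compatibility(network, motifs, k)
  sites <- compat$sites
  rows <- vector("list", nrow(scored_triples))
  no_sites <- 0L
  for (i in seq_len(nrow(scored_triples))) {
    tr <- scored_triples[i, ]
    idx <- which(sites$substrate == tr$substrate &
                   compat$compat[tr$motif_id, ])
    if (length(idx) == 0) {
      no_sites <- no_sites + 1L
      next
    }
    rows[[i]] <- data.frame(kinase = tr$kinase, substrate = tr$substrate,
                            site_residue = sites$site_residue[idx],
                            site_pos = sites$site_pos[idx],
                            score = tr$score, stringsAsFactors = FALSE)
  }
  preds <- do.call(rbind, rows)
  if (is.null(preds)) {
    preds <- data.frame(kinase = character(), substrate = character(),
                        site_residue = character(), site_pos = integer(),
                        score = numeric(), stringsAsFactors = FALSE)
  }
  preds <- dedup_predictions(preds)
  attr(preds, "n_triples_without_sites") <- no_sites
  preds
}

# Keep the maximum score per (kinase, substrate, site).
dedup_predictions <- function(preds) {
  if (nrow(preds) == 0) return(preds)
  key <- paste(preds$kinase, preds$substrate, preds$site_residue,
               preds$site_pos, sep = "\r")
  ord <- order(key, -preds$score)
  preds <- preds[ord, , drop = FALSE]
  preds <- preds[!duplicated(key[ord]), , drop = FALSE]
  rownames(preds) <- NULL
  preds
}

#' Stream the Cartesian candidate space kinase x (substrate, site)
#'
#' Returns a closure yielding successive chunks of the candidate table so
#' the full product (which reaches 10^7 rows on realistic corpora) is never
#' materialised at once. Each call returns a data.frame chunk or NULL when
#' exhausted.
#'
#' @param network a \code{phospho_network}.
#' @param chunk_size rows per chunk.
#' @param include_known include candidates already recorded as positive
#'   statements (default FALSE: they are excluded).
#' @return function() yielding data.frames with \code{kinase},
#'   \code{substrate}, \code{site_residue}, \code{site_pos}; the total
#'   candidate-space size is available via attribute \code{n_total} on the
#'   closure (pre-exclusion).
#' @export
generate_candidates <- function(network, chunk_size = 50000,
                                include_known = FALSE) {
  st <- network$statements
  kinases <- sort(unique(st$kinase))
  sites <- unique(st[, c("substrate", "site_residue", "site_pos")])
  sites <- sites[order(sites$substrate, sites$site_pos), , drop = FALSE]
  known <- statement_key(st)
  n_total <- length(kinases) * nrow(sites)
  pos <- 0

  nxt <- function() {
    if (pos >= n_total) return(NULL)
    take <- min(chunk_size, n_total - pos)
    idx <- pos + seq_len(take)
    pos <<- pos + take
    ki <- ((idx - 1) %/% nrow(sites)) + 1
    si <- ((idx - 1) %% nrow(sites)) + 1
    chunk <- data.frame(kinase = kinases[ki],
                        substrate = sites$substrate[si],
                        site_residue = sites$site_residue[si],
                        site_pos = sites$site_pos[si],
                        stringsAsFactors = FALSE)
    if (!include_known) {
      chunk <- chunk[!statement_key(chunk) %in% known, , drop = FALSE]
    }
    chunk
  }
  attr(nxt, "n_total") <- n_total
  nxt
}

#' Export triples as 3-column TSV (subject, relation, object)
#'
#' @param triples triple data.frame; an optional \code{label} column is
#'   written as a fourth column.
#' @param path output path.
#' @export
write_kg_tsv <- function(triples, path) {
  cols <- c("kinase", "motif_id", "substrate",
            intersect("label", names(triples)))
  out <- triples[, cols, drop = FALSE]
  names(out) <- c("subject", "relation", "object",
                  if ("label" %in% cols) "label")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
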