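# Biologically constrained negative generation for training.
#
# Two corruption operators on a positive edge <K, M, S>:
#   * kinase corruption: replace K by a kinase from a different family;
#   * substrate corruption: replace S by a substrate all of whose known
#     sites score non-positively against M's scoring matrix.
# Unconstrained random-combination negatives used by the benchmark harness
# live in the evaluation module; the operators here are for training only.

#' Negative-sampling configuration
#'
#' @param negatives_per_positive negatives generated per positive edge.
#' @param rng_seed root seed; per-positive seeds are derived from it so the
#'   output is invariant to input order.
#' @param max_rejection_tries retry cap when a drawn negative collides with
#'   a positive edge.
#' @return list of class \code{negative_config}.
#' @export
negative_config <- function(negatives_per_positive = 2, rng_seed = 42,
                            max_rejection_tries = 100) {
  stopifnot(negatives_per_positive >= 1, max_rejection_tries >= 1)
  structure(list(negatives_per_positive = negatives_per_positive,
                 rng_seed = rng_seed,
                 max_rejection_tries = max_rejection_tries),
            class = "negative_config")
}

#' Corrupt the kinase slot of a positive triple
#'
#' @param triple one-row data.frame (kinase, motif_id, substrate).
#' @param families named vector accession -> family.
#' @param kinase_pool candidate replacement kinases.
#' @return one-row negative triple, or NULL when no kinase outside the
#'   original family exists (caller falls back to substrate corruption).
#' @export
corrupt_kinase <- function(triple, families, kinase_pool) {
  fam <- families[[triple$kinase]]
  eligible <- kinase_pool[families[kinase_pool] != fam]
  eligible <- eligible[!is.na(eligible)]
  if (length(eligible) == 0) return(NULL)
  pick <- eligible[sample.int(length(eligible), 1)]
  data.frame(kinase = pick, motif_id = triple$motif_id,
             substrate = triple$substrate, stringsAsFactors = FALSE)
}

#' Corrupt the substrate slot of a positive triple
#'
#' The replacement substrate must have every known site scoring
#' non-positively against the triple's motif. Eligibility is resolved
#' exactly from the precomputed site-compatibility scan (equivalent to
#' rejection sampling against the constraint, but never emits a violator).
#'
#' @param triple one-row data.frame (kinase, motif_id, substrate).
#' @param compat site-compatibility scan from the knowledge-graph builder.
#' @param substrate_pool candidate replacement substrates.
#' @return one-row negative triple, or NULL when no substrate qualifies
#'   (caller falls back to kinase corruption).
#' @export
corrupt_substrate <- function(triple, compat, substrate_pool) {
  hit <- compat$compat[triple$motif_id, ]
  # substrates with at least one compatible site are ineligible
  bad <- unique(compat$sites$substrate[hit])
  eligible <- setdiff(substrate_pool, c(bad, triple$substrate))
  if (length(eligible) == 0) return(NULL)
  pick <- eligible[sample.int(length(eligible), 1)]
  data.frame(kinase = triple$kinase, motif_id = triple$motif_id,
             substrate = pick, stringsAsFactors = FALSE)
}

#' Generate constrained training negatives
#'
#' Emits \code{negatives_per_positive} negatives per positive edge,
#' alternating the kinase- and substrate-corruption operators (falling back
#' to the other operator when one is unavailable). No emitted negative
#' collides with a positive edge; draws are seeded per positive so the
#' result is reproducible and independent of input order.
#'
#' @param positives positive triples (kinase, motif_id, substrate).
#' @param network the \code{phospho_network} (for families and pools).
#' @param motifs motif list.
#' @param k context size.
#' @param config a [negative_config()].
#' @param compat optional precomputed site-compatibility scan.
#' @return data.frame of negative triples with a \code{pos_index} column
#'   linking each negative to the row of its source positive.
#' @export
generate_negatives <- function(positives, network, motifs, k,
                               config = negative_config(), compat = NULL) {
  stopifnot(nrow(positives) > 0)
  if (is.null(compat)) compat <- site_compatibility(network, motifs, k)
  families <- network$families
  kinase_pool <- sort(unique(network$statements$kinase))
  substrate_pool <- sort(unique(network$statements$substrate))
  pos_keys <- triple_key(positives)

  out <- vector("list", nrow(positives))
  unavailable <- 0L
  for (i in seq_len(nrow(positives))) {
    tr <- positives[i, ]
    negs <- list()
    for (j in seq_len(config$negatives_per_positive)) {
      op_kinase_first <- (j %% 2 == 1)
      drawn <- with_seed(derive_seed(config$rng_seed,
                                     paste(pos_keys[i], j)), {
        neg <- NULL
        for (try in seq_len(config$max_rejection_tries)) {
          cand <- if (op_kinase_first) {
            corrupt_kinase(tr, families, kinase_pool) %||%
              corrupt_substrate(tr, compat, substrate_pool)
          } else {
            corrupt_substrate(tr, compat, substrate_pool) %||%
              corrupt_kinase(tr, families, kinase_pool)
          }
          if (is.null(cand)) break
          if (!triple_key(cand) %in% pos_keys) {
            neg <- cand
            break
          }
        }
        neg
      })
      if (is.null(drawn)) {
        unavailable <- unavailable + 1L
        next
      }
      drawn$pos_index <- i
      negs[[length(negs) + 1]] <- drawn
    }
    out[[i]] <- if (length(negs) > 0) do.call(rbind, negs) else NULL
  }
  if (unavailable > 0) {
    msg("negative sampling: %d draw(s) had no eligible corruption", unavailable)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(kinase = character(), motif_id = character(),
                      substrate = character(), pos_index = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  attr(res, "n_unavailable") <- unavailable
  res
}
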