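# Per-family motif inference from phosphosite context windows.
#
# Windows are pre-aligned on the phosphoacceptor, so motif discovery reduces
# to counting: build the full-width position frequency matrix of a batch,
# greedily select up to `max_motifs` contiguous sub-windows containing the
# centre by information content against the batch background, and emit each
# as a log-odds position-specific scoring matrix (PSSM). A window is
# "compatible" with a motif when its summed PSSM score is strictly positive.

#' Motif-inference configuration
#'
#' @param k context size (residues per side of the phosphosite).
#' @param batch_size context sequences per inference batch.
#' @param max_motifs_per_batch upper bound on motifs emitted per batch.
#' @param pseudocount Laplace pseudocount added per residue per position.
#' @param background_order Markov order of the background model. Only order
#'   0 (per-residue frequencies) is supported; see the package vignette.
#' @return list of class \code{motif_config}.
#' @export
motif_config <- function(k = 7, batch_size = 50, max_motifs_per_batch = 10,
                         pseudocount = 1, background_order = 0) {
  stopifnot(k >= 1, batch_size >= 1, max_motifs_per_batch >= 1,
            pseudocount > 0)
  if (background_order != 0) {
    stop("only background_order = 0 is supported")
  }
  structure(list(k = k, batch_size = batch_size,
                 max_motifs_per_batch = max_motifs_per_batch,
                 pseudocount = pseudocount,
                 background_order = background_order),
            class = "motif_config")
}

#' Partition a family's windows into inference batches
#'
#' Deterministic: windows are ordered by substrate accession then site
#' position before splitting, so identical inputs always yield identical
#' batches regardless of input order.
#'
#' @param windows data.frame with at least \code{substrate},
#'   \code{site_pos}, \code{window} columns (one family's windows).
#' @param batch_size maximum windows per batch.
#' @return list of character vectors (the window strings), each of length
#'   \code{<= batch_size}; empty list for empty input.
#' @export
batch_windows <- function(windows, batch_size) {
  if (nrow(windows) == 0) return(list())
  ord <- order(windows$substrate, windows$site_pos)
  w <- windows$window[ord]
  idx <- ceiling(seq_along(w) / batch_size)
  unname(split(w, idx))
}

#' Background residue distribution of a window batch
#'
#' Order-0 model: pseudocounted per-residue frequencies over all counted
#' positions of the batch (padding and ambiguity codes are excluded).
#'
#' @param windows character vector of window strings.
#' @param pseudocount Laplace pseudocount per residue.
#' @return named numeric vector over the 20 amino acids, summing to 1.
#' @export
build_background <- function(windows, pseudocount = 1) {
  chars <- unlist(strsplit(windows, ""), use.names = FALSE)
  chars <- chars[chars %in% AA_ALPHABET]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  freq <- (as.numeric(counts) + pseudocount) /
    (sum(counts) + pseudocount * length(AA_ALPHABET))
  stats::setNames(freq, AA_ALPHABET)
}

# Position frequency matrix of a batch: (2k+1) x 20, pseudocounted and
# normalised per position over counted residues.
position_frequencies <- function(windows, pseudocount = 1) {
  mat <- do.call(rbind, strsplit(windows, ""))
  width <- ncol(mat)
  freq <- matrix(0, nrow = width, ncol = length(AA_ALPHABET),
                 dimnames = list(NULL, AA_ALPHABET))
  for (p in seq_len(width)) {
    col <- mat[, p]
    col <- col[col %in% AA_ALPHABET]
    counts <- table(factor(col, levels = AA_ALPHABET))
    freq[p, ] <- (as.numeric(counts) + pseudocount) /
      (sum(counts) + pseudocount * length(AA_ALPHABET))
  }
  freq
}

#' Infer motifs from one batch of centre-aligned windows
#'
#' Computes the batch position frequency matrix and background, ranks
#' contiguous sub-windows (width >= 2, containing the centre position) by
#' total relative entropy against the background net of the small-sample
#' baseline (an n-sequence empirical distribution carries about
#' \code{19 / (2 n ln 2)} bits of apparent information even under the
#' background, and each position is charged that cost), and emits up to
#' \code{max_motifs_per_batch} of them as log-odds PSSMs. Already-selected
#' positions are masked (their information content is zeroed) before the
#' next pick; selection stops when no candidate sub-window retains positive
#' net information. Ties break towards the smallest start offset. At least
#' one motif is always emitted for a non-empty batch.
#'
#' @param batch character vector of window strings, all of equal odd length.
#' @param family family name used to namespace motif ids.
#' @param config a [motif_config()].
#' @param index_offset integer added to emitted motif indices (used when a
#'   family spans several batches so ids stay unique).
#' @return list of \code{pssm_motif} objects, ids \code{"FAMILY.m<i>"}.
#' @export
infer_motifs <- function(batch, family, config = motif_config(),
                         index_offset = 0) {
  stopifnot(length(batch) > 0)
  widths <- nchar(batch)
  stopifnot(length(unique(widths)) == 1, widths[1] %% 2 == 1)
  width <- widths[1]
  center <- (width + 1) / 2

  freq <- position_frequencies(batch, config$pseudocount)
  bg <- build_background(batch, config$pseudocount)
  logodds <- log2(sweep(freq, 2, bg, "/"))
  # per-position information content (relative entropy vs background)
  ic <- rowSums(freq * logodds)
  ic[ic < 0] <- 0  # numerical guard; relative entropy is >= 0

  # apparent information carried by pure sampling noise (asymptotic mean
  # KL divergence of an n-sample empirical distribution, in bits)
  null_ic <- (length(AA_ALPHABET) - 1) / (2 * length(batch) * log(2))

  motifs <- list()
  avail_ic <- ic
  for (m in seq_len(config$max_motifs_per_batch)) {
    best <- NULL
    best_score <- -Inf
    for (a in seq_len(center)) {
      for (b in center:width) {
        if (b - a + 1 < 2) next
        total <- sum(avail_ic[a:b]) - null_ic * (b - a + 1)
        if (total > best_score + 1e-12) {
          best_score <- total
          best <- c(a, b)
        }
      }
    }
    if (is.null(best) || (m > 1 && best_score <= 1e-12)) break
    a <- best[1]; b <- best[2]
    motifs[[m]] <- new_pssm_motif(
      id = sprintf("%s.m%d", family, m + index_offset),
      family = family,
      start = a,
      center_offset = center - a + 1,
      pssm = logodds[a:b, , drop = FALSE],
      freq = freq[a:b, , drop = FALSE],
      background = bg,
      n_sequences = length(batch))
    avail_ic[a:b] <- 0
  }
  motifs
}

new_pssm_motif <- function(id, family, start, center_offset, pssm, freq,
                           background, n_sequences) {
  structure(list(id = id, family = family, width = nrow(pssm),
                 start = start, center_offset = center_offset,
                 pssm = pssm, freq = freq, background = background,
                 n_sequences = n_sequences),
            class = "pssm_motif")
}

#' @export
print.pssm_motif <- function(x, ...) {
  cat("pssm_motif", x$id, "(family", paste0(x$family, ","),
      "width", x$width, "of", x$n_sequences, "sequences)\n")
  invisible(x)
}

#' Infer motifs for every kinase family of a network
#'
#' Batches each family's context windows ([batch_windows()]) and runs
#' [infer_motifs()] on each batch, namespacing ids by family so relation
#' labels are globally unique.
#'
#' @param network a \code{phospho_network} with a family map attached.
#' @param config a [motif_config()].
#' @return named list of \code{pssm_motif} objects keyed by motif id.
#' @export
infer_family_motifs <- function(network, config = motif_config()) {
  wins <- context_windows(network, config$k)
  if (anyNA(wins$family)) stop("network has no family map attached")
  out <- list()
  for (family in sort(unique(wins$family))) {
    fam_wins <- wins[wins$family == family, , drop = FALSE]
    # one window per distinct substrate site (several kinases of the family
    # may target the same site)
    fam_wins <- fam_wins[!duplicated(fam_wins[, c("substrate", "site_pos")]), ]
    offset <- 0
    for (batch in batch_windows(fam_wins, config$batch_size)) {
      ms <- infer_motifs(batch, family, config, index_offset = offset)
      offset <- offset + length(ms)
      for (mo in ms) out[[mo$id]] <- mo
    }
  }
  out
}

#' Score a context window against a motif
#'
#' The score is the sum over motif positions of the log-odds weight of the
#' window residue aligned to that position. Padding (\code{"-"}) and
#' ambiguity codes contribute exactly 0. For windows wider than the motif,
#' all alignment offsets at which the motif covers the window centre are
#' evaluated and the best is returned.
#'
#' @param motif a \code{pssm_motif}.
#' @param window window string (length >= motif width, odd length).
#' @return numeric score; positive means motif-compatible.
#' @export
score_window <- function(motif, window) {
  chars <- strsplit(window, "")[[1]]
  n <- length(chars)
  w <- motif$width
  if (n < w) stop("window shorter than motif width")
  center <- (n + 1) / 2
  # offsets such that the motif, placed at window positions a..a+w-1,
  # covers the centre position
  starts <- max(1, center - w + 1):min(center, n - w + 1)
  best <- -Inf
  for (a in starts) {
    s <- 0
    for (j in seq_len(w)) {
      ch <- chars[a + j - 1]
      if (ch %in% AA_ALPHABET) s <- s + motif$pssm[j, ch]
    }
    if (s > best) best <- s
  }
  unname(best)
}

#' Motif-compatibility predicate
#'
#' @param motif a \code{pssm_motif}.
#' @param window window string.
#' @return TRUE iff [score_window()] is strictly positive.
#' @export
is_compatible <- function(motif, window) {
  score_window(motif, window) > 0
}

#' Write motifs in MEME minimal motif format
#'
#' Emits the version line, protein alphabet, background frequencies and one
#' \code{MOTIF} block with a letter-probability matrix per motif.
#'
#' @param motifs list of \code{pssm_motif} objects.
#' @param path output path.
#' @export
write_meme_motifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste("ALPHABET=", paste(AA_ALPHABET, collapse = "")), ""),
             con)
  if (length(motifs) > 0) {
    bg <- motifs[[1]]$background
    writeLines(c("Background letter frequencies",
                 paste(sprintf("%s %.6f", names(bg), bg), collapse = " "),
                 ""), con)
  }
  for (mo in motifs) {
    writeLines(sprintf("MOTIF %s", mo$id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= %d w= %d nsites= %d E= 0",
      length(AA_ALPHABET), mo$width, mo$n_sequences), con)
    for (i in seq_len(mo$width)) {
      writeLines(paste(sprintf("%.6f", mo$freq[i, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Serialize motifs to JSON (log-odds and background included)
#'
#' @param motifs list of \code{pssm_motif} objects.
#' @param path output path.
#' @export
write_motifs_json <- function(motifs, path) {
  payload <- lapply(motifs, function(mo) {
    list(id = mo$id, family = mo$family, width = mo$width,
         start = mo$start, center_offset = mo$center_offset,
         pssm = lapply(seq_len(nrow(mo$pssm)), function(i) as.list(mo$pssm[i, ])),
         freq = lapply(seq_len(nrow(mo$freq)), function(i) as.list(mo$freq[i, ])),
         background = as.list(mo$background),
         n_sequences = mo$n_sequences)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read motifs from the JSON dialect written by [write_motifs_json()]
#'
#' @param path JSON file path.
#' @return named list of \code{pssm_motif} objects.
#' @export
read_motifs_json <- function(path) {
  payload <- jsonlite::read_json(path)
  out <- list()
  for (p in payload) {
    to_mat <- function(rows) {
      m <- do.call(rbind, lapply(rows, function(r) unlist(r[AA_ALPHABET])))
      colnames(m) <- AA_ALPHABET
      m
    }
    mo <- new_pssm_motif(p$id, p$family, p$start, p$center_offset,
                         to_mat(p$pssm), to_mat(p$freq),
                         unlist(p$background)[AA_ALPHABET], p$n_sequences)
    out[[mo$id]] <- mo
  }
  out
}
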