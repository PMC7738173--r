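# Independent brute-force oracles used by several test files.

# All-pairs Mann-Whitney AU-ROC with ties counted one half.
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Recompute a PSSM score from raw batch counts by explicit summation.
oracle_pssm_score <- function(batch, start, width, window, pseudocount = 1) {
  aa <- phoslink:::AA_ALPHABET
  chars <- lapply(batch, function(w) strsplit(w, "")[[1]])
  all_chars <- unlist(chars)
  all_chars <- all_chars[all_chars %in% aa]
  bg <- sapply(aa, function(a) {
    (sum(all_chars == a) + pseudocount) /
      (length(all_chars) + 20 * pseudocount)
  })
  wchars <- strsplit(window, "")[[1]]
  total <- 0
  for (j in seq_len(width)) {
    p <- start + j - 1
    col <- sapply(chars, `[`, p)
    col <- col[col %in% aa]
    res <- wchars[p]
    if (!res %in% aa) next
    f <- (sum(col == res) + pseudocount) / (length(col) + 20 * pseudocount)
    total <- total + log2(f / bg[[res]])
  }
  total
}
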