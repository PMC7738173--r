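# Shared fixtures, built in code. The reference simulation (default
# generator settings) is computed once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# Reference synthetic network: generator defaults, fixed seed.
ref_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    .fixture_cache$sim <- simulate_network(synth_config(rng_seed = 7))
  }
  .fixture_cache$sim
}

ref_motifs <- function() {
  if (is.null(.fixture_cache$motifs)) {
    sim <- ref_sim()
    .fixture_cache$motifs <-
      infer_family_motifs(sim$network, motif_config(k = sim$config$k))
  }
  .fixture_cache$motifs
}

ref_compat <- function() {
  if (is.null(.fixture_cache$compat)) {
    sim <- ref_sim()
    .fixture_cache$compat <-
      phoslink:::site_compatibility(sim$network, ref_motifs(), sim$config$k)
  }
  .fixture_cache$compat
}

# A small simulation for cheaper end-to-end tests.
small_sim <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- simulate_network(
      synth_config(n_substrates = 60, edges_per_kinase = 12, rng_seed = 11))
  }
  .fixture_cache$small
}

# Hand-built three-protein network with known sequences and sites.
tiny_network <- function() {
  sequences <- data.frame(
    id = c("SUBA", "SUBB", "KIN1", "KIN2"),
    seq = c("MASQPRRASFDE", "MTTYQRRASFAA", "MKKKKKKKKK", "MRRRRRRRRR"),
    is_isoform = FALSE, stringsAsFactors = FALSE)
  statements <- data.frame(
    kinase = c("KIN1", "KIN1", "KIN2"),
    substrate = c("SUBA", "SUBB", "SUBA"),
    site_residue = c("S", "S", "S"),
    site_pos = c(3L, 9L, 9L),
    organism = "test", stringsAsFactors = FALSE)
  families <- c(KIN1 = "FAMX", KIN2 = "FAMY")
  validate_against_sequences(statements, sequences, families)
}

# A handcrafted motif with explicit weights (all other residues 0).
manual_motif <- function(weights, family = "FAMX", id = "FAMX.m1",
                         center_offset = NULL) {
  width <- length(weights)
  pssm <- matrix(0, nrow = width, ncol = 20,
                 dimnames = list(NULL, phoslink:::AA_ALPHABET))
  for (i in seq_len(width)) {
    for (res in names(weights[[i]])) pssm[i, res] <- weights[[i]][[res]]
  }
  phoslink:::new_pssm_motif(
    id = id, family = family, start = 1,
    center_offset = center_offset %||% ((width + 1) / 2),
    pssm = pssm, freq = matrix(1 / 20, width, 20,
                               dimnames = list(NULL, phoslink:::AA_ALPHABET)),
    background = stats::setNames(rep(1 / 20, 20), phoslink:::AA_ALPHABET),
    n_sequences = 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_window <- function(width) {
  paste(sample(phoslink:::AA_ALPHABET, width, replace = TRUE), collapse = "")
}
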