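# Synthetic phosphorylation networks with planted family-specific motif
# structure. The generator emits the exact statement-TSV / FASTA /
# family-TSV dialects consumed by the parsers, so every pipeline stage can
# be exercised without any licensed download.

#' Synthetic-network configuration
#'
#' Defaults describe the reference validation network used throughout the
#' test suite: 4 kinase families of 5 kinases, 200 substrates with 3
#' phosphosites each, context size 7 and a strong (0.9) planted motif
#' signal, with a 2x2 block structure over kinase and substrate groups.
#'
#' @param n_families number of kinase families.
#' @param kinases_per_family kinases per family.
#' @param n_substrates number of substrate proteins.
#' @param sites_per_substrate phosphosites per substrate.
#' @param seq_length substrate sequence length (must accommodate
#'   non-overlapping site windows).
#' @param k context size (residues per side of a site).
#' @param motif_strength probability that a planted site window is drawn
#'   from the owning family's motif profile rather than background.
#' @param edges_per_kinase target number of statements per kinase.
#' @param block_structure kinase-group x substrate-group affinity matrix
#'   governing which family group owns the substrates of each substrate
#'   group; NULL for a diagonal-heavy 2x2 default.
#' @param profile_focus probability mass of the preferred residue at each
#'   non-centre profile position.
#' @param pair_site_rate probability that a kinase targeting a substrate
#'   phosphorylates each individual site of it (at least one is always
#'   taken), so kinase-substrate pairs typically span several sites.
#' @param rng_seed seed; the whole network is a deterministic function of
#'   the configuration.
#' @return list of class \code{synth_config}.
#' @export
synth_config <- function(n_families = 4, kinases_per_family = 5,
                         n_substrates = 200, sites_per_substrate = 3,
                         seq_length = 80, k = 7, motif_strength = 0.9,
                         edges_per_kinase = 30, block_structure = NULL,
                         profile_focus = 0.7, pair_site_rate = 0.8,
                         rng_seed = 42) {
  stopifnot(n_families >= 1, kinases_per_family >= 1, n_substrates >= 1,
            sites_per_substrate >= 1, seq_length >= 1, k >= 1,
            motif_strength >= 0, motif_strength <= 1, edges_per_kinase >= 1,
            pair_site_rate > 0, pair_site_rate <= 1)
  if (is.null(block_structure)) {
    block_structure <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  }
  structure(list(n_families = n_families,
                 kinases_per_family = kinases_per_family,
                 n_substrates = n_substrates,
                 sites_per_substrate = sites_per_substrate,
                 seq_length = seq_length, k = k,
                 motif_strength = motif_strength,
                 edges_per_kinase = edges_per_kinase,
                 block_structure = block_structure,
                 profile_focus = profile_focus,
                 pair_site_rate = pair_site_rate,
                 rng_seed = rng_seed),
            class = "synth_config")
}

# Draw one window of width 2k+1 from a family profile matrix (rows =
# positions, cols = residues); the centre row is the site residue
# distribution.
draw_window <- function(profile) {
  paste(vapply(seq_len(nrow(profile)), function(p) {
    sample(colnames(profile), 1, prob = profile[p, ])
  }, character(1)), collapse = "")
}

#' Simulate a phosphorylation network with planted motif structure
#'
#' The generative model mirrors the structure of curated kinase-substrate
#' corpora: kinase families have exclusive sequence preferences, families
#' of the same group own the substrates of the substrate groups they are
#' affine to, and a kinase that targets a substrate typically
#' phosphorylates several of its sites (so the average number of sites per
#' kinase is roughly \code{sites_per_substrate x pair_site_rate} times the
#' number of substrates per kinase, as in real corpora).
#'
#' Concretely: each family receives a hidden position-weight profile over
#' the \code{2k+1}-residue site window (a preferred residue with
#' probability \code{profile_focus} at every non-centre position and a
#' family-specific phosphoacceptor in \{S, T, Y\} at the centre). Each
#' substrate is owned by one family, drawn via the block-structure
#' affinity between family groups and substrate groups; with probability
#' \code{motif_strength} each of its site windows is drawn from the
#' owner's profile, otherwise from background. Kinases draw substrates
#' owned by their family and phosphorylate each site with probability
#' \code{pair_site_rate} until \code{edges_per_kinase} statements are
#' reached. Statements are read back from the final sequences, so the
#' emitted network always passes sequence validation without drops.
#'
#' @param config a [synth_config()].
#' @return list: \code{network} (a compiled \code{phospho_network}),
#'   \code{truth} (hidden profiles, substrate ownership, group
#'   assignments) and \code{config}.
#' @export
simulate_network <- function(config = synth_config()) {
  win_width <- 2 * config$k + 1
  if (config$sites_per_substrate * win_width > config$seq_length) {
    stop("sites exceed sequence capacity: need at least ",
         config$sites_per_substrate * win_width, " residues")
  }
  with_seed(config$rng_seed, {
    families <- sprintf("FAM%02d", seq_len(config$n_families))
    kinases <- sprintf("KIN%03d", seq_len(config$n_families *
                                            config$kinases_per_family))
    fam_of_kin <- stats::setNames(rep(families, each = config$kinases_per_family),
                                  kinases)
    substrates <- sprintf("SUB%04d", seq_len(config$n_substrates))

    n_kgroup <- nrow(config$block_structure)
    n_sgroup <- ncol(config$block_structure)
    fam_group <- stats::setNames(rep_len(seq_len(n_kgroup), config$n_families),
                                 families)
    sub_group <- stats::setNames(rep_len(seq_len(n_sgroup), config$n_substrates),
                                 substrates)

    # hidden family profiles over the window
    centers <- stats::setNames(sample(c("S", "T", "Y"), config$n_families,
                                      replace = TRUE), families)
    profiles <- lapply(families, function(f) {
      prof <- matrix(1 / 20, nrow = win_width, ncol = 20,
                     dimnames = list(NULL, AA_ALPHABET))
      for (p in seq_len(win_width)) {
        if (p == config$k + 1) {
          prof[p, ] <- 0
          prof[p, centers[[f]]] <- 1
        } else {
          pref <- sample(AA_ALPHABET, 1)
          prof[p, ] <- (1 - config$profile_focus) / 19
          prof[p, pref] <- config$profile_focus
        }
      }
      prof
    })
    names(profiles) <- families

    # substrate ownership: substrate group -> affine family group -> family
    owner <- vapply(substrates, function(s) {
      w <- config$block_structure[, sub_group[[s]]]
      kg <- sample.int(n_kgroup, 1, prob = w)
      sample(families[fam_group == kg], 1)
    }, character(1))

    # substrate sequences: uniform background; planted sites drawn from
    # the owner family's profile, others get a random S/T/Y centre
    site_starts <- ((seq_len(config$sites_per_substrate) - 1) * win_width) + 1
    site_pos <- site_starts + config$k
    planted <- matrix(FALSE, nrow = config$n_substrates,
                      ncol = config$sites_per_substrate,
                      dimnames = list(substrates, NULL))
    seqs <- stats::setNames(character(config$n_substrates), substrates)
    for (s in substrates) {
      chars <- sample(AA_ALPHABET, config$seq_length, replace = TRUE)
      chars[site_pos] <- sample(c("S", "T", "Y"), length(site_pos),
                                replace = TRUE)
      for (j in seq_along(site_pos)) {
        if (stats::runif(1) < config$motif_strength) {
          planted[s, j] <- TRUE
          win <- strsplit(draw_window(profiles[[owner[[s]]]]), "")[[1]]
          chars[(site_pos[j] - config$k):(site_pos[j] + config$k)] <- win
        }
      }
      seqs[[s]] <- paste(chars, collapse = "")
    }

    # edges: kinases draw substrates owned by their family and target each
    # site with probability pair_site_rate (at least one per pair)
    edges <- NULL
    for (kin in kinases) {
      f <- fam_of_kin[[kin]]
      owned <- substrates[owner == f]
      if (length(owned) == 0) owned <- substrates
      pool <- sample(owned)
      n_stmt <- 0
      for (s in pool) {
        if (n_stmt >= config$edges_per_kinase) break
        take <- stats::runif(config$sites_per_substrate) < config$pair_site_rate
        if (!any(take)) take[sample.int(config$sites_per_substrate, 1)] <- TRUE
        pos <- site_pos[take]
        edges <- rbind(edges, data.frame(kinase = kin, substrate = s,
                                         site_pos = pos,
                                         stringsAsFactors = FALSE))
        n_stmt <- n_stmt + length(pos)
      }
    }
    edges <- edges[!duplicated(edges), , drop = FALSE]

    # statements read residues from the final sequences
    residues <- substr(seqs[edges$substrate],
                       edges$site_pos, edges$site_pos)
    statements <- data.frame(kinase = edges$kinase,
                             substrate = edges$substrate,
                             site_residue = residues,
                             site_pos = edges$site_pos,
                             organism = "synthetic",
                             stringsAsFactors = FALSE)
    statements <- statements[!duplicated(statement_key(statements)), ]

    sequences <- data.frame(id = substrates, seq = unname(seqs[substrates]),
                            is_isoform = FALSE, stringsAsFactors = FALSE)
    network <- validate_against_sequences(statements, sequences, fam_of_kin)
    truth <- list(profiles = profiles, centers = centers,
                  fam_of_kin = fam_of_kin, fam_group = fam_group,
                  sub_group = sub_group, owner = owner, planted = planted)
    list(network = network, truth = truth, config = config)
  })
}

#' Write a simulated network in the three input dialects
#'
#' @param sim result of [simulate_network()].
#' @param dir output directory (created if missing).
#' @return named paths of the statement TSV, FASTA and family TSV.
#' @export
write_simulated_inputs <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(statements = file.path(dir, "statements.tsv"),
             fasta = file.path(dir, "substrates.fasta"),
             families = file.path(dir, "families.tsv"))
  write_statements(sim$network, paths["statements"])
  write_protein_fasta(sim$network$sequences, paths["fasta"])
  write_family_map(sim$network$families, paths["families"])
  paths
}

#' Hold out a fraction of statements for link-prediction validation
#'
#' Uniform removal under the constraint that every kinase and substrate
#' keeps at least one observed statement where possible.
#'
#' @param network a \code{phospho_network}.
#' @param fraction fraction of statements to hold out (0 < fraction < 1).
#' @param rng_seed seed.
#' @return list: \code{observed} (network with held-out statements
#'   removed) and \code{held_out} (the removed statements).
#' @export
holdout_edges <- function(network, fraction, rng_seed = 42) {
  stopifnot(fraction > 0, fraction < 1)
  st <- network$statements
  n_out <- round(fraction * nrow(st))
  with_seed(rng_seed, {
    kin_count <- table(st$kinase)
    sub_count <- table(st$substrate)
    out_idx <- integer(0)
    for (i in sample.int(nrow(st))) {
      if (length(out_idx) >= n_out) break
      if (kin_count[[st$kinase[i]]] > 1 && sub_count[[st$substrate[i]]] > 1) {
        out_idx <- c(out_idx, i)
        kin_count[[st$kinase[i]]] <- kin_count[[st$kinase[i]]] - 1
        sub_count[[st$substrate[i]]] <- sub_count[[st$substrate[i]]] - 1
      }
    }
    observed <- network
    observed$statements <- st[-out_idx, , drop = FALSE]
    rownames(observed$statements) <- NULL
    held <- st[out_idx, , drop = FALSE]
    rownames(held) <- NULL
    list(observed = observed, held_out = held)
  })
}
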