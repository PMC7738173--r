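# Parsing, validation and compilation of the phosphorylation network.
#
# The network is built from three inputs:
#   * a statement table of <kinase, substrate, site> rows (TSV),
#   * protein sequences in FASTA (UniProt-style or bare-accession headers),
#   * a kinase -> family classification table (two-column TSV).

#' Parse a kinase-substrate statement table
#'
#' Reads a tab-separated table of phosphorylation statements and returns one
#' deduplicated row per \code{<kinase, substrate, site>} for the requested
#' organism. The site token combines the phosphoacceptor residue and its
#' 1-based position, e.g. \code{"S127"} for serine 127.
#'
#' @param path path to the TSV file (header row required).
#' @param organism_filter organism to retain; both the kinase and the
#'   substrate organism columns (when present) must match.
#' @param columns named list mapping the roles \code{kinase},
#'   \code{substrate}, \code{site}, \code{kin_organism}, \code{sub_organism}
#'   to header names. Organism columns are optional in the file; the
#'   remaining three are required.
#' @return data.frame with columns \code{kinase}, \code{substrate},
#'   \code{site_residue}, \code{site_pos}, \code{organism}. Rows with
#'   malformed site tokens or a non-S/T/Y residue are skipped (counts are
#'   attached as the \code{"skipped"} attribute).
#' @export
parse_statements <- function(path,
                             organism_filter = "human",
                             columns = list(kinase = "KINASE",
                                            substrate = "SUBSTRATE",
                                            site = "SITE",
                                            kin_organism = "KIN_ORGANISM",
                                            sub_organism = "SUB_ORGANISM")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, quote = "")
  required <- c("kinase", "substrate", "site")
  for (role in required) {
    nm <- columns[[role]]
    if (is.null(nm) || !nm %in% names(tab)) {
      stop("statement table is missing required column '",
           nm %||% role, "' (role: ", role, ")")
    }
  }
  kin <- as.character(tab[[columns$kinase]])
  sub <- as.character(tab[[columns$substrate]])
  site <- as.character(tab[[columns$site]])

  keep <- rep(TRUE, nrow(tab))
  for (role in c("kin_organism", "sub_organism")) {
    nm <- columns[[role]]
    if (!is.null(nm) && nm %in% names(tab)) {
      keep <- keep & (tolower(as.character(tab[[nm]])) ==
                        tolower(organism_filter))
    }
  }

  m <- regmatches(site, regexec("^([A-Za-z])([0-9]+)$", site))
  residue <- vapply(m, function(x) if (length(x) == 3) toupper(x[2]) else NA_character_,
                    character(1))
  pos <- vapply(m, function(x) if (length(x) == 3) as.integer(x[3]) else NA_integer_,
                integer(1))

  malformed <- is.na(residue) | is.na(pos) | pos < 1
  non_sty <- !malformed & !(residue %in% c("S", "T", "Y"))
  if (any(malformed & keep)) {
    msg("dropped %d row(s) with malformed site token", sum(malformed & keep))
  }
  if (any(non_sty & keep)) {
    msg("dropped %d row(s) with non-S/T/Y phosphoacceptor", sum(non_sty & keep))
  }
  keep <- keep & !malformed & !non_sty

  out <- data.frame(kinase = kin[keep], substrate = sub[keep],
                    site_residue = residue[keep], site_pos = pos[keep],
                    organism = organism_filter, stringsAsFactors = FALSE)
  out <- out[!duplicated(statement_key(out)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(malformed = sum(malformed),
                            non_sty = sum(non_sty))
  out
}

statement_key <- function(st) {
  paste(st$kinase, st$substrate, st$site_residue, st$site_pos, sep = "\r")
}

#' Read protein sequences from FASTA
#'
#' Accepts UniProt-style \code{sp|ACC|NAME} headers as well as bare-accession
#' headers. Isoform records are recognised by a dash in the accession
#' (e.g. \code{P04637-2}). Sequences containing characters outside the 20
#' canonical residues plus the tolerated ambiguity codes (X, U, B, Z) are
#' dropped with a warning.
#'
#' @param path FASTA file path.
#' @return data.frame with columns \code{id}, \code{seq}, \code{is_isoform}.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  ids <- vapply(headers, function(h) {
    tok <- strsplit(h, "[[:space:]]+")[[1]][1]
    if (grepl("\\|", tok)) strsplit(tok, "\\|")[[1]][2] else tok
  }, character(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(set))

  allowed <- c(AA_ALPHABET, setdiff(ZERO_SCORE_CHARS, PAD_CHAR))
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% allowed) || length(ch) == 0,
                logical(1))
  if (any(bad)) {
    warning(sum(bad), " sequence(s) with unrecognised characters dropped")
  }
  data.frame(id = ids[!bad], seq = seqs[!bad],
             is_isoform = grepl("-", ids[!bad], fixed = TRUE),
             stringsAsFactors = FALSE)
}

#' Parse a kinase-family classification table
#'
#' @param path two-column TSV (kinase accession, family name) with a header.
#' @return named character vector mapping accession to family. Kinases
#'   listed under more than one family are dropped with a warning (the
#'   classification must be unambiguous).
#' @export
parse_family_map <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (ncol(tab) < 2) stop("family table must have two columns")
  kin <- as.character(tab[[1]])
  fam <- as.character(tab[[2]])
  n_fam <- tapply(fam, kin, function(x) length(unique(x)))
  conflicted <- names(n_fam)[n_fam > 1]
  if (length(conflicted) > 0) {
    warning("dropped ", length(conflicted),
            " kinase(s) with conflicting family annotations: ",
            paste(utils::head(conflicted, 5), collapse = ", "))
    keep <- !kin %in% conflicted
    kin <- kin[keep]; fam <- fam[keep]
  }
  first <- !duplicated(kin)
  stats::setNames(fam[first], kin[first])
}

# Resolve the sequence record used to validate a substrate site: canonical
# accession first, then isoforms of the same accession root, first match wins.
resolve_sequence_ids <- function(substrate, sequences) {
  canonical <- if (substrate %in% sequences$id) substrate else character(0)
  iso <- sort(sequences$id[startsWith(sequences$id, paste0(substrate, "-"))])
  c(canonical, iso)
}

#' Validate statements against protein sequences
#'
#' Retains a statement only when some sequence record of its substrate
#' (canonical first, then isoforms) carries the stated residue at the stated
#' position. Statements centred on ambiguous residues or whose substrate has
#' no sequence are discarded; discard reasons are counted.
#'
#' @param statements data.frame as returned by [parse_statements()].
#' @param sequences data.frame as returned by [read_protein_fasta()].
#' @param families optional named vector from [parse_family_map()]. When
#'   supplied, statements whose kinase has no family are dropped (counted).
#' @return a \code{phospho_network} object: list with elements
#'   \code{statements} (with an extra \code{seq_id} column naming the
#'   validated sequence record), \code{sequences}, \code{families} and
#'   \code{counts}.
#' @export
validate_against_sequences <- function(statements, sequences, families = NULL) {
  seq_lookup <- stats::setNames(sequences$seq, sequences$id)
  seq_id <- character(nrow(statements))
  status <- character(nrow(statements))
  for (i in seq_len(nrow(statements))) {
    ids <- resolve_sequence_ids(statements$substrate[i], sequences)
    if (length(ids) == 0) {
      status[i] <- "missing_sequence"
      next
    }
    status[i] <- "mismatch"
    for (id in ids) {
      s <- seq_lookup[[id]]
      p <- statements$site_pos[i]
      if (p <= nchar(s) &&
          substr(s, p, p) == statements$site_residue[i]) {
        status[i] <- "ok"
        seq_id[i] <- id
        break
      }
    }
  }

  counts <- c(retained = sum(status == "ok"),
              mismatch = sum(status == "mismatch"),
              missing_sequence = sum(status == "missing_sequence"),
              no_family = 0L)
  st <- statements[status == "ok", , drop = FALSE]
  st$seq_id <- seq_id[status == "ok"]

  if (!is.null(families)) {
    has_fam <- st$kinase %in% names(families)
    counts["no_family"] <- sum(!has_fam)
    if (any(!has_fam)) {
      msg("dropped %d statement(s) whose kinase has no family annotation",
          sum(!has_fam))
    }
    st <- st[has_fam, , drop = FALSE]
  }
  rownames(st) <- NULL

  structure(list(statements = st, sequences = sequences,
                 families = families, counts = counts),
            class = "phospho_network")
}

#' @export
print.phospho_network <- function(x, ...) {
  s <- network_stats(x)
  cat("phospho_network:", s$n_statements, "statements |",
      s$n_kinases, "kinases |", s$n_substrates, "substrates |",
      s$n_sites, "substrate-site pairs\n")
  invisible(x)
}

#' Extract the phosphosite context window of a statement
#'
#' Returns the \code{2k+1} residues centred on the phosphosite, padded with
#' \code{"-"} where the window overruns the sequence ends.
#'
#' @param network a \code{phospho_network}.
#' @param index row index of the statement.
#' @param k context size (residues on each side of the site).
#' @return character scalar of length \code{2k+1}.
#' @export
extract_context <- function(network, index, k) {
  st <- network$statements[index, ]
  seqs <- stats::setNames(network$sequences$seq, network$sequences$id)
  window_at(seqs[[st$seq_id]], st$site_pos, k)
}

#' Context window at an arbitrary sequence position
#'
#' @param seq amino-acid string.
#' @param pos 1-based centre position.
#' @param k context size.
#' @return string of length \code{2k+1}, \code{"-"}-padded at boundaries.
#' @export
window_at <- function(seq, pos, k) {
  stopifnot(k >= 1, pos >= 1)
  n <- nchar(seq)
  lo <- pos - k
  hi <- pos + k
  core <- substr(seq, max(lo, 1), min(hi, n))
  paste0(strrep(PAD_CHAR, max(0, 1 - lo)), core,
         strrep(PAD_CHAR, max(0, hi - n)))
}

#' Context windows for every retained statement
#'
#' @param network a \code{phospho_network}.
#' @param k context size.
#' @return data.frame: one row per statement with \code{kinase},
#'   \code{substrate}, \code{site_residue}, \code{site_pos}, \code{family}
#'   (NA when no family map is attached) and \code{window}.
#' @export
context_windows <- function(network, k) {
  st <- network$statements
  seqs <- stats::setNames(network$sequences$seq, network$sequences$id)
  win <- vapply(seq_len(nrow(st)), function(i) {
    window_at(seqs[[st$seq_id[i]]], st$site_pos[i], k)
  }, character(1))
  fam <- if (is.null(network$families)) rep(NA_character_, nrow(st)) else
    unname(network$families[st$kinase])
  data.frame(kinase = st$kinase, substrate = st$substrate,
             site_residue = st$site_residue, site_pos = st$site_pos,
             seq_id = st$seq_id, family = fam, window = win,
             stringsAsFactors = FALSE)
}

#' Summary statistics of a compiled network
#'
#' @param network a \code{phospho_network}.
#' @return list with statement/kinase/substrate/site counts and the two
#'   per-kinase ratios (substrates per kinase, substrate-site pairs per
#'   kinase), rounded to 2 decimals. All zeros for an empty network.
#' @export
network_stats <- function(network) {
  st <- network$statements
  n_kin <- length(unique(st$kinase))
  n_sub <- length(unique(st$substrate))
  n_site <- nrow(unique(st[, c("substrate", "site_residue", "site_pos")]))
  list(n_statements = nrow(st),
       n_kinases = n_kin,
       n_substrates = n_sub,
       n_sites = n_site,
       substrates_per_kinase = if (n_kin > 0) round(n_sub / n_kin, 2) else 0,
       sites_per_kinase = if (n_kin > 0) round(n_site / n_kin, 2) else 0)
}

#' Write statements back to the TSV statement dialect
#'
#' Inverse of [parse_statements()]; round-trips the retained statement set.
#'
#' @param network a \code{phospho_network} (or a statement data.frame).
#' @param path output path.
#' @export
write_statements <- function(network, path) {
  st <- if (inherits(network, "phospho_network")) network$statements else network
  out <- data.frame(KINASE = st$kinase, SUBSTRATE = st$substrate,
                    SITE = paste0(st$site_residue, st$site_pos),
                    KIN_ORGANISM = st$organism, SUB_ORGANISM = st$organism,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write protein sequences to FASTA
#'
#' @param sequences data.frame as from [read_protein_fasta()].
#' @param path output path.
#' @export
write_protein_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(stats::setNames(sequences$seq, sequences$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a kinase-family table
#'
#' @param families named vector (accession -> family).
#' @param path output path.
#' @export
write_family_map <- function(families, path) {
  utils::write.table(
    data.frame(KINASE = names(families), FAMILY = unname(families)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
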