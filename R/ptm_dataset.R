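# PTM site dataset: parsing, validation and collation onto one
# representative protein per gene.

#' Construct a PTM dataset object
#'
#' Low-level constructor used by [parse_site_table()] and the synthetic
#' generator. A `ptm_dataset` holds the validated site records, the protein
#' sequences they are anchored to, and a provenance log of every collation
#' decision.
#'
#' @param sites data.frame with columns `protein_id`, `gene_id`, `position`
#'   (1-based integer), `residue` (one of S/T/Y/K), `ptm_type` (one of
#'   `Ac`, `pST`, `pY`, `Ub`) and `flank13` (13-mer centred on the site,
#'   terminal positions padded with `_`).
#' @param sequences named character vector of amino-acid sequences; names
#'   are protein ids. Every `protein_id` in `sites` must be present.
#' @param gene_ids named character vector mapping protein id to gene id;
#'   defaults to the mapping found in `sites` (proteins without sites get
#'   their own id as gene id).
#' @param log character vector of provenance messages.
#' @return An object of class `ptm_dataset`.
#' @export
new_ptm_dataset <- function(sites, sequences, gene_ids = NULL, log = character()) {
  stopifnot(is.data.frame(sites), is.character(sequences), !is.null(names(sequences)))
  missing_seq <- setdiff(unique(sites$protein_id), names(sequences))
  if (length(missing_seq) > 0L)
    stopf("no sequence for protein id(s): %s", paste(missing_seq, collapse = ", "))
  if (is.null(gene_ids)) {
    gene_ids <- structure(names(sequences), names = names(sequences))
    if (nrow(sites) > 0L) {
      m <- !duplicated(sites$protein_id)
      gene_ids[sites$protein_id[m]] <- sites$gene_id[m]
    }
  }
  sites$position <- as.integer(sites$position)
  rownames(sites) <- NULL
  structure(
    list(
      sites = sites,
      sequences = sequences,
      gene_ids = gene_ids[names(sequences)],
      log = log
    ),
    class = "ptm_dataset"
  )
}

#' @export
print.ptm_dataset <- function(x, ...) {
  cat(sprintf(
    "ptm_dataset: %d modifications on %d of %d proteins\n",
    nrow(x$sites), length(unique(x$sites$protein_id)), length(x$sequences)
  ))
  tab <- table(factor(x$sites$ptm_type, levels = PTM_TYPES))
  cat("  per type: ", paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                            collapse = "  "), "\n", sep = "")
  if (length(x$log) > 0L) cat(sprintf("  %d log entries\n", length(x$log)))
  invisible(x)
}

#' Number of modification records in a dataset
#'
#' A "modification" is a unique (protein, position, type) triple; a lysine
#' carrying both Ac and Ub contributes two.
#'
#' @param dataset a `ptm_dataset`.
#' @return Integer count.
#' @export
n_sites <- function(dataset) nrow(dataset$sites)

#' Read protein sequences from FASTA
#'
#' @param path FASTA file; the first whitespace-delimited token of each
#'   header is taken as the protein id.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' 13-mer flank around a sequence position
#'
#' Returns the 13-character window centred on `position`, padding positions
#' beyond either terminus with `_`.
#'
#' @param sequence amino-acid string.
#' @param position 1-based position (vectorised).
#' @return Character vector of 13-mers.
#' @export
flank13_of <- function(sequence, position) {
  n <- nchar(sequence)
  vapply(position, function(p) {
    idx <- (p - 6L):(p + 6L)
    ch <- ifelse(idx < 1L | idx > n, "_",
                 substring(sequence, pmax(idx, 1L), pmax(idx, 1L)))
    paste(ch, collapse = "")
  }, character(1))
}

SITE_COLUMNS <- c("protein_id", "gene_id", "position", "residue", "ptm_type", "flank13")

# Validate site rows against sequences. Returns list(sites, rejected, log).
validate_sites <- function(sites, sequences) {
  reason <- rep(NA_character_, nrow(sites))
  sites$position <- suppressWarnings(as.integer(sites$position))
  lens <- nchar(sequences)[sites$protein_id]

  bad <- is.na(sites$position) | sites$position < 1L | sites$position > lens
  reason[bad & is.na(reason)] <- "position outside protein bounds"

  ok_type <- sites$ptm_type %in% PTM_TYPES
  reason[!ok_type & is.na(reason)] <- "unknown ptm_type"

  ok_res <- sites$residue %in% c("S", "T", "Y", "K")
  reason[!ok_res & is.na(reason)] <- "residue not one of S/T/Y/K"

  idx <- is.na(reason)
  if (any(idx)) {
    seq_res <- substring(sequences[sites$protein_id[idx]],
                         sites$position[idx], sites$position[idx])
    mism <- seq_res != sites$residue[idx]
    reason[idx][mism] <- "annotated residue does not match sequence"
  }

  idx <- is.na(reason)
  if (any(idx)) {
    compat <- is_compatible(sites$residue[idx], sites$ptm_type[idx])
    reason[idx][!compat] <- "residue incompatible with ptm_type"
  }

  idx <- is.na(reason)
  if (any(idx)) {
    expected <- mapply(function(p, pos) flank13_of(sequences[[p]], pos),
                       sites$protein_id[idx], sites$position[idx])
    mism <- expected != sites$flank13[idx]
    reason[idx][mism] <- "flank13 does not match sequence"
  }

  # duplicate (protein, position, type): keep the first record
  key <- paste(sites$protein_id, sites$position, sites$ptm_type, sep = "\r")
  dup <- duplicated(key) & is.na(reason)
  reason[dup] <- "duplicate (protein, position, type) record"

  keep <- is.na(reason)
  rejected <- sites[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  log <- if (nrow(rejected) > 0L) {
    sprintf("rejected %s pos %d (%s): %s", rejected$protein_id,
            rejected$position, rejected$ptm_type, rejected$reason)
  } else character()
  list(sites = sites[keep, , drop = FALSE], rejected = rejected, log = log)
}

#' Parse a tab-delimited PTM site table
#'
#' Reads a site table and its companion FASTA, validates every row
#' (position bounds, residue identity against the sequence, residue/type
#' compatibility, flank consistency, duplicate records) and returns a
#' validated `ptm_dataset`. Malformed rows are rejected individually and
#' recorded in the dataset log; a protein id missing from the FASTA is a
#' hard error.
#'
#' @param path tab-delimited table with header columns
#'   `protein_id`, `gene_id`, `position`, `residue`, `ptm_type`, `flank13`.
#' @param fasta_path FASTA file with one record per protein id.
#' @return A `ptm_dataset`; rejected rows are available via
#'   `attr(dataset, "rejected")` and summarised in `dataset$log`.
#' @export
parse_site_table <- function(path, fasta_path) {
  sequences <- read_protein_fasta(fasta_path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  missing_col <- setdiff(SITE_COLUMNS, names(tab))
  if (length(missing_col) > 0L)
    stopf("site table missing column(s): %s", paste(missing_col, collapse = ", "))
  tab <- tab[, SITE_COLUMNS]
  unknown <- setdiff(unique(tab$protein_id), names(sequences))
  if (length(unknown) > 0L)
    stopf("site table refers to protein id(s) absent from FASTA: %s",
          paste(utils::head(unknown, 5), collapse = ", "))
  v <- validate_sites(tab, sequences)
  ds <- new_ptm_dataset(v$sites, sequences, log = v$log)
  attr(ds, "rejected") <- v$rejected
  ds
}

#' Collate a PTM dataset onto one representative protein per gene
#'
#' Applies the two collation rules used to build the unified modification
#' dataset: (1) proteins with byte-identical sequences are collapsed onto a
#' single identifier (the lexicographically smallest), taking the union of
#' their site records deduplicated by (position, type); (2) for each gene
#' id, only the most highly modified protein is retained (ties again broken
#' by smallest protein id). The operation is idempotent.
#'
#' @param dataset a `ptm_dataset`.
#' @return A collated `ptm_dataset` with an extended provenance log.
#' @export
collate <- function(dataset) {
  sites <- dataset$sites
  sequences <- dataset$sequences
  gene_ids <- dataset$gene_ids
  log <- dataset$log

  ## 1. merge identical sequences
  grp <- split(names(sequences), sequences)
  for (ids in grp) {
    if (length(ids) < 2L) next
    ids <- sort(ids)
    rep_id <- ids[1L]
    others <- ids[-1L]
    sel <- sites$protein_id %in% others
    if (any(sel)) {
      sites$protein_id[sel] <- rep_id
      sites$gene_id[sel] <- gene_ids[[rep_id]]
    }
    key <- paste(sites$protein_id, sites$position, sites$ptm_type, sep = "\r")
    sites <- sites[!duplicated(key), , drop = FALSE]
    sequences <- sequences[setdiff(names(sequences), others)]
    gene_ids <- gene_ids[names(sequences)]
    log <- c(log, sprintf("merged identical sequences %s -> %s",
                          paste(others, collapse = ","), rep_id))
  }

  ## 2. one representative protein per gene: most sites, tie -> smallest id
  counts <- table(factor(sites$protein_id, levels = names(sequences)))
  by_gene <- split(names(sequences), gene_ids)
  drop_ids <- character()
  for (ids in by_gene) {
    if (length(ids) < 2L) next
    cnt <- as.integer(counts[ids])
    ord <- order(-cnt, ids)
    keep <- ids[ord[1L]]
    dropped <- setdiff(ids, keep)
    drop_ids <- c(drop_ids, dropped)
    log <- c(log, sprintf(
      "gene %s: kept %s (%d sites), dropped %s",
      gene_ids[[keep]], keep, max(cnt),
      paste(sprintf("%s(%d)", dropped, counts[dropped]), collapse = ",")))
  }
  if (length(drop_ids) > 0L) {
    sites <- sites[!(sites$protein_id %in% drop_ids), , drop = FALSE]
    sequences <- sequences[setdiff(names(sequences), drop_ids)]
    gene_ids <- gene_ids[names(sequences)]
  }

  out <- new_ptm_dataset(sites, sequences, gene_ids, log)
  out
}

#' Per-protein modification profile
#'
#' @param dataset a `ptm_dataset`.
#' @param protein_id single protein id.
#' @return List with `counts` (named integer vector over Ac/pST/pY/Ub) and
#'   `multiplicity` (number of distinct PTM types present, 0-4).
#' @export
protein_ptm_profile <- function(dataset, protein_id) {
  if (!protein_id %in% names(dataset$sequences))
    stopf("unknown protein id: %s", protein_id)
  s <- dataset$sites[dataset$sites$protein_id == protein_id, , drop = FALSE]
  counts <- table(factor(s$ptm_type, levels = PTM_TYPES))
  counts <- structure(as.integer(counts), names = PTM_TYPES)
  list(counts = counts, multiplicity = sum(counts > 0L))
}

#' Per-protein modification count matrix
#'
#' @param dataset a `ptm_dataset`.
#' @param proteins protein ids to include (default: every protein in the
#'   dataset, unmodified proteins included as zero rows).
#' @return Integer matrix, one row per protein, columns Ac/pST/pY/Ub.
#' @export
ptm_count_matrix <- function(dataset, proteins = names(dataset$sequences)) {
  m <- matrix(0L, nrow = length(proteins), ncol = length(PTM_TYPES),
              dimnames = list(proteins, PTM_TYPES))
  s <- dataset$sites[dataset$sites$protein_id %in% proteins, , drop = FALSE]
  if (nrow(s) > 0L) {
    tab <- table(factor(s$protein_id, levels = proteins),
                 factor(s$ptm_type, levels = PTM_TYPES))
    m[] <- as.integer(tab)
  }
  m
}

#' Tabulate per-protein profiles for a whole dataset
#'
#' @param dataset a `ptm_dataset`.
#' @return data.frame with protein_id, gene_id, length, the four per-type
#'   counts, total and multiplicity.
#' @export
ptm_profile_table <- function(dataset) {
  m <- ptm_count_matrix(dataset)
  data.frame(
    protein_id = rownames(m),
    gene_id = unname(dataset$gene_ids[rownames(m)]),
    length = unname(nchar(dataset$sequences[rownames(m)])),
    as.data.frame(m),
    total = rowSums(m),
    multiplicity = rowSums(m > 0L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write a site table in the package's tab-delimited dialect
#'
#' @param dataset a `ptm_dataset`.
#' @param path output file.
#' @export
write_site_table <- function(dataset, path) {
  utils::write.table(dataset$sites[, SITE_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
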