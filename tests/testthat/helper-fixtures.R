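# Small deterministic fixtures built in code.

# A sequence with known residue layout: positions given in `at` get the
# named residue, everything else is alanine.
seq_with <- function(len, at = integer(), residue = character()) {
  ch <- rep("A", len)
  ch[at] <- residue
  paste(ch, collapse = "")
}

site_row <- function(protein_id, position, ptm_type, sequences,
                     gene_id = protein_id) {
  res <- substring(sequences[[protein_id]], position, position)
  data.frame(protein_id = protein_id, gene_id = gene_id,
             position = position, residue = res, ptm_type = ptm_type,
             flank13 = flank13_of(sequences[[protein_id]], position),
             stringsAsFactors = FALSE)
}

# Tiny 3-protein dataset: PA carries a dually modified lysine plus a pY,
# PB carries 3 pST, PC is unmodified.
toy_dataset <- function() {
  seqs <- c(
    PA = seq_with(30, at = c(10, 20), residue = c("K", "Y")),
    PB = seq_with(40, at = c(5, 15, 25), residue = c("S", "T", "S")),
    PC = seq_with(25)
  )
  sites <- rbind(
    site_row("PA", 10, "Ac", seqs),
    site_row("PA", 10, "Ub", seqs),
    site_row("PA", 20, "pY", seqs),
    site_row("PB", 5, "pST", seqs),
    site_row("PB", 15, "pST", seqs),
    site_row("PB", 25, "pST", seqs)
  )
  new_ptm_dataset(sites, seqs)
}

# Dataset with n proteins of one fixed length; counts[i] sites of `type`
# are placed on the first residues (made compatible) of protein i.
counts_dataset <- function(counts, type = "pST", len = 100L) {
  res <- PTM_COMPAT[[type]][1L]
  ids <- sprintf("Q%02d", seq_along(counts))
  seqs <- vapply(counts, function(k)
    seq_with(len, at = seq_len(max(k, 1L)), residue = rep(res, max(k, 1L))),
    character(1))
  names(seqs) <- ids
  rows <- list()
  for (i in seq_along(counts)) {
    if (counts[i] > 0L)
      rows[[length(rows) + 1L]] <- site_row(ids[i], seq_len(counts[i]),
                                            rep(type, counts[i]), seqs)
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    toy_dataset()$sites[0, ]
  new_ptm_dataset(sites, seqs)
}

# complex_set from a plain named list
cset <- function(...) new_complex_set(list(...))

# small synthetic bundle reused by several tests
small_bundle <- function(seed = 11) {
  generate_synthetic_bundle(synthetic_config(
    n_proteins = 60,
    complexes = list(n = 30, size_min = 3, size_lambda = 2,
                     enriched_fraction = 0.1, multiplier = 5,
                     types = PTM_TYPES),
    seed = seed))
}
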