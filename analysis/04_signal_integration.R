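#!/usr/bin/env Rscript
# Stage 4: which subunits carry the enrichment signal?
#
# For each enriched complex group, member proteins are partitioned by PTM
# multiplicity (1-4 distinct types) and the observed 4x4 (multiplicity x
# type) total-signal matrix is compared with 1000 equally sized random
# complex samples, giving a Z-score per cell.

library(ptmscape)

ds <- collate(parse_site_table("results/data/sites.tsv",
                               "results/data/proteome.fasta"))
cx <- filter_and_collapse(parse_complexes("results/data/complexes.tsv"), ds)
enr <- read.delim("results/enrichment.tsv")

for (t in PTM_TYPES) {
  ids <- unique(enr$complex_id[enr$selected & enr$ptm_type == t])
  if (length(ids) < 2L) {
    cat(sprintf("%s: %d enriched complex(es), skipped\n", t, length(ids)))
    next
  }
  z <- signal_matrix_analysis(ids, cx, ds, S = 1000L, seed = 202L)
  out <- data.frame(group = t, multiplicity = rep(1:4, 4),
                    ptm_type = rep(PTM_TYPES, each = 4),
                    observed = as.vector(z$observed),
                    null_mean = as.vector(z$null_mean),
                    null_sd = as.vector(z$null_sd),
                    z = as.vector(z$z))
  write.table(out, sprintf("results/signal_matrix_%s.tsv", t),
              sep = "\t", quote = FALSE, row.names = FALSE)
  top <- out[which.max(abs(out$z)), ]
  cat(sprintf("%s group (%d complexes): strongest cell %d_PTMs x %s, Z = %.1f\n",
              t, length(ids), top$multiplicity, top$ptm_type, top$z))
  sh <- composition_shares(ids, cx, ds)
  cat(sprintf("   composition: %s\n",
              paste(sprintf("%s %.1f%%", names(sh), sh), collapse = "  ")))
}
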