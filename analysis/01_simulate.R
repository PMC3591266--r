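#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the structure of the real data the analysis was designed for:
# a proteome with human-like composition, four PTM classes implanted at
# background rates in the observed proportions (pS/T > Ub > pY > Ac),
# S/T/K-rich hotspot spans, a complex set with a minority of complexes
# enriched for one PTM class, and domain/disorder/mutation annotations.
# All downstream stages read only the files written here.

library(ptmscape)

seed <- 20260927L
dir <- "results/data"

cfg <- synthetic_config(
  n_proteins = 400,
  complexes = list(n = 150, size_min = 3L, size_lambda = 2,
                   enriched_fraction = 0.1, multiplier = 5,
                   types = PTM_TYPES),
  seed = seed
)
b <- generate_synthetic_bundle(cfg, dir = dir)

cat(sprintf("proteome: %d proteins, %d modifications (%s)\n",
            length(b$dataset$sequences), n_sites(b$dataset),
            paste(sprintf("%s=%d", PTM_TYPES,
                          as.integer(table(factor(b$dataset$sites$ptm_type,
                                                  levels = PTM_TYPES)))),
                  collapse = " ")))
cat(sprintf("complexes: %d (%d enriched by construction)\n",
            length(b$complexes$members), sum(b$truth$enriched$enriched)))
cat(sprintf("hotspots: %d spans on %d proteins\n",
            nrow(b$truth$hotspots), length(unique(b$truth$hotspots$protein_id))))
cat(sprintf("inputs written under %s\n", dir))
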