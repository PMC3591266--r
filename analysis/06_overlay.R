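#!/usr/bin/env Rscript
# Stage 6: where do dense PTM windows sit relative to domains, disorder
# and cancer mutations?
#
# Consecutive non-overlapping 20AA windows are classified on four axes:
# domain overlap (Int/Lg/Sm/Ext), disorder content (High/Med/Low/none),
# PTM density bin (high/medium/low/unmodified) and mutation burden
# (>= 2 mutations flags a window).

library(ptmscape)

ds <- collate(parse_site_table("results/data/sites.tsv",
                               "results/data/proteome.fasta"))
dom <- parse_domain_table("results/data/domains.tsv", ds)
dis <- parse_disorder_tracks("results/data/disorder.tsv", ds)
mut <- parse_mutation_table("results/data/mutations.tsv", ds)
cat(attr(mut, "log"), "\n")

w <- overlay_windows(ds, dom, dis, mut)
write.table(w, "results/overlay_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

hi <- w$density_bin == "high"
cat(sprintf("%d of %d windows are high-density; %.0f%% of those outside domains\n",
            sum(hi), nrow(w), 100 * mean(w$domain_class[hi] == "Ext")))
cat(sprintf("disordered sequence in %.0f%% of high-density windows (%.0f%% fully disordered)\n",
            100 * mean(w$disorder_class[hi] != "none"),
            100 * mean(w$disorder_class[hi] == "High")))

tab <- mutated_fraction_table(w)
write.table(tab, "results/mutated_fractions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mutated-window fractions:\n")
print(tab, row.names = FALSE)
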