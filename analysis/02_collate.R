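#!/usr/bin/env Rscript
# Stage 2: parse, validate and collate the PTM site table.
#
# Every site record is checked against its protein sequence (position
# bounds, residue identity, residue/type compatibility, 13-mer flank);
# identical sequences are collapsed onto one identifier and one
# representative isoform is kept per gene (the most modified).

library(ptmscape)

ds <- parse_site_table("results/data/sites.tsv", "results/data/proteome.fasta")
rej <- attr(ds, "rejected")
cat(sprintf("parsed %d valid records (%d rejected)\n", n_sites(ds), nrow(rej)))

col <- collate(ds)
cat(sprintf("collated: %d modifications on %d proteins (%d modified)\n",
            n_sites(col), length(col$sequences),
            length(unique(col$sites$protein_id))))

dir.create("results", showWarnings = FALSE)
write_site_table(col, "results/collated_sites.tsv")
writeLines(col$log, "results/collation_log.txt")
write.table(ptm_profile_table(col), "results/protein_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

prof <- ptm_profile_table(col)
multi <- mean(prof$multiplicity[prof$total > 0] >= 2)
cat(sprintf("%.0f%% of modified proteins carry more than one PTM class\n",
            100 * multi))
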