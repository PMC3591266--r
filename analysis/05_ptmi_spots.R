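#!/usr/bin/env Rscript
# Stage 5: dense modification regions (PTMi spots).
#
# Overlapping 20AA windows (10AA step) are scanned per protein; local
# density peaks are selected; windows above density 0.3 are merged into
# PTMi spots classified single/multi by the PTM types they contain. The
# within-protein type-permutation null asks whether multi-type dense
# peaks occur more or less often than chance. Spots are then annotated
# for hyperphospho-degron signatures and PY-NLS core motifs.

library(ptmscape)

ds <- collate(parse_site_table("results/data/sites.tsv",
                               "results/data/proteome.fasta"))
cfg <- scan_config()

peaks <- do.call(rbind, lapply(unique(ds$sites$protein_id), function(p) {
  pk <- local_peaks(scan_windows(ds, p, cfg))
  if (nrow(pk)) pk else NULL
}))
cat(sprintf("%d local density peaks on %d proteins (%d above density %.1f)\n",
            nrow(peaks), length(unique(peaks$protein_id)),
            sum(peaks$ptm_density > cfg$theta), cfg$theta))
write.table(peaks, "results/density_peaks.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

spots <- call_spots_all(ds, cfg)
cat(sprintf("%d PTMi spots on %d proteins (lengths %d-%d AA; %d single / %d multi)\n",
            nrow(spots), length(unique(spots$protein_id)),
            min(spots$length), max(spots$length),
            sum(spots$classification == "single"),
            sum(spots$classification == "multi")))
write_spots_bed(spots, "results/ptmi_spots.bed")

mp <- multi_ptm_high_density_counts(ds, cfg, R = 100L, seed = 303L)
cat(sprintf("high-density peaks: observed %d multi / %d single vs null median %g / %g\n",
            mp$observed["multi"], mp$observed["single"],
            median(mp$null[, "multi"]), median(mp$null[, "single"])))

deg <- find_hyperphospho_degrons(spots, ds)
cat(sprintf("%d candidate hyperphospho-degron spots (>=4 pS/T, >=1 S/T-P, >=1 Ub)\n",
            nrow(deg)))
write.table(deg, "results/degron_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

nls <- do.call(rbind, lapply(unique(spots$protein_id),
                             function(p) find_py_nls(ds, p)))
if (!is.null(nls) && nrow(nls)) {
  write.table(nls, "results/py_nls_candidates.tsv", sep = "\t",
              quote = FALSE, row.names = FALSE)
  cat(sprintf("%d PY-NLS core motifs on spot-bearing proteins (%d with modified spans)\n",
              nrow(nls), sum(nls$n_mods_in_span > 0)))
} else {
  cat("no PY-NLS core motifs on spot-bearing proteins\n")
}
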