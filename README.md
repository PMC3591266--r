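# ptmscape

Coordinated regulation by post-translational modifications (PTMs) —
lysine acetylation (Ac), lysine ubiquitination (Ub), tyrosine
phosphorylation (pY) and serine/threonine phosphorylation (pS/T) — acts
at two levels: protein complexes that selectively accumulate one
modification class, and short stretches of sequence that pack many
modifications into a few residues. `ptmscape` implements both analyses
as a tested R package plus a numbered analysis workflow:

1. **Collation** — site-level PTM records (13-mer anchored) are
   validated against protein sequences and reduced to one representative
   protein per gene, keeping the most modified isoform.
2. **Complex enrichment** — for every complex and PTM type the pair
   *(T, M)* = (total, median) of per-subunit site counts is compared
   with a null cloud built by permuting whole per-protein annotation
   bundles within 16 covariate bins (complex-frequency quartile x length
   quartile), pooled over *R* = 100 replicates. The selection statistic
   is the joint exceedance
   *q = Pr{ T\* ≥ T and M\* ≥ M }* over the null pairs *(T\*, M\*)*;
   a complex is selected when *q* < 1% (pS/T: 5%).
3. **Signal integration** — member proteins of each enriched group are
   split by PTM multiplicity (1–4 distinct types) and the 4 × 4
   (multiplicity × type) matrix of total signal is scored as
   *Z = (obs − mean)/sd* against *S* = 1000 random complex samples of
   equal size.
4. **PTMi spots** — 20AA windows at a 10AA step give per-window PTM
   density (records per residue; a lysine with Ac *and* Ub counts
   twice) and S/T/Y/K density; non-overlapping local density peaks are
   selected greedily; windows with density > 0.3 (i.e. ≥ 7 modified
   residues per 20AA, 2⁷ = 128 occupancy states) merge into PTMi spots,
   classified single/multi by the types present. A within-protein
   permutation of type labels (positions fixed) tests whether
   multi-type dense peaks occur by chance. Spots are annotated for
   hyperphospho-degron signatures (≥ 4 pS/T, ≥ 1 proline-directed
   [S/T]P site, ≥ 1 Ub) and PY-NLS core motifs ([R/H/K]-X(2,5)-P-Y).
5. **Overlay** — consecutive 20AA windows are cross-classified by
   domain overlap (Int = 20AA, Lg = 11–19, Sm = 1–10, Ext = 0),
   disorder content (High = 20, Med = 11–19, Low = 1–10, none = 0),
   density bin (> 0.3 high, (0.05, 0.3] medium, (0, 0.05] low) and
   cancer-mutation burden (≥ 2 mutations flags a window).

A synthetic-data generator (`synthetic_config()`,
`generate_synthetic_bundle()`) emulates the statistical structure of
the real inputs — background rates in the observed per-type
proportions, disorder-like hotspot spans, enriched complexes, domain /
disorder / mutation annotations — so the entire pipeline is testable
without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on one
synthetic dataset and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_collate.R
Rscript analysis/03_complex_enrichment.R
Rscript analysis/04_signal_integration.R
Rscript analysis/05_ptmi_spots.R
Rscript analysis/06_overlay.R
```

A run with the committed seed prints, among other things:

```
collated: 4188 modifications on 400 proteins (397 modified)
enriched complexes per type:  Ac=5  pST=16  pY=4  Ub=7
Ub group (7 complexes): strongest cell 3_PTMs x Ub, Z = 6.3
40 PTMi spots on 38 proteins (lengths 20-60 AA; 19 single / 21 multi)
high-density peaks: observed 19 multi / 24 single vs null median 39 / 4
43 of 8543 windows are high-density; 63% of those outside domains
```

Reading these: the permutation null selects complexes enriched for each
class (15 were implanted by construction); the Z-matrix shows the Ub
signal concentrated on multiply modified subunits of Ub-enriched
complexes; dense spots emerge at the implanted hotspot spans; observed
multi-type dense peaks (19) fall far below the within-protein
permutation expectation (median 39), i.e. type mixing in dense regions
is *less* than random — and the mutated-window fraction of high-density
windows outside domains (0.74 in this run) approaches that of
domain-internal windows (0.82), against a 0.26 background.

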