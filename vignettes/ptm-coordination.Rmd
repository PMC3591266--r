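---
title: "Methods: PTM coordination on complexes and in dense sequence windows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PTM coordination on complexes and in dense sequence windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`ptmscape` analyses how four PTM classes — Ac, pS/T, pY, Ub — are
distributed across a protein-complex network and along protein
sequences. The counting unit everywhere is a *modification record*: a
unique (protein, position, type) triple. A lysine carrying both Ac and
Ub contributes two records, which is why a window's PTM density can
exceed its modifiable-residue (S/T/Y/K) density.

## Collation

Input sites are 13-mer-anchored records validated against their protein
sequence: the position must be inside the protein, the annotated
residue must match the sequence and be chemically compatible with the
type (Ac/Ub on K, pY on Y, pS/T on S/T), and the 13-mer flank must
equal the sequence-derived flank (terminal positions padded with `_`).
Rows failing any check are rejected individually and logged; a protein
absent from the FASTA is a hard error, since nothing downstream can be
validated without the sequence.

Collation then applies two reductions: proteins with byte-identical
sequences are merged onto one identifier (site union, deduplicated by
position and type), and one isoform per gene is kept — the one with the
most records. Both tie-breaks use the lexicographically smallest
identifier, making collation deterministic and idempotent. Conflicting
flanks at one position cannot survive collation because every retained
flank must equal the sequence-derived one.

## Complex enrichment

Per complex and type we compute the pair (total, median) of per-member
record counts; members missing from the PTM dataset count zero, because
complex membership does not imply detectable modification. Medians of
even-sized member vectors are the mean of the central pair.

The null model permutes *annotation bundles*: all records of a protein
move as one unit to another protein identity. To control for the mild
dependence of modification count on protein length and on how often a
protein appears in the complex dataset, permutation is restricted to
bins formed by crossing the quartiles of both covariates (16 bins; a
value equal to a quartile boundary goes to the lower quartile; a
degenerate covariate collapses its axis with a logged fallback). Whole
bundles are exchanged, so per-bin bundle multisets and global per-type
totals are conserved exactly — the test suite asserts this exactly, not
approximately. The permuted dataset is a counting null only; positions
are not re-validated against the new sequences, which is irrelevant for
complex statistics and intentional.

Selection uses the joint empirical exceedance
`q = Pr(null total >= observed total AND null median >= observed median)`
over the pooled cloud of `R = 100` permutations x all complexes of that
type. The published analysis drew 99%/95% density contours on the same
cloud and selected the complexes beyond them; the joint exceedance is a
monotone operationalisation of the same "upper-right separation" that
needs no 2D density estimate, and whether the original contour was
computed on the joint density or per axis is unknowable from the text.
Raising the confidence can only shrink the selected set. Cutoffs
default to 99% (Ac, pY, Ub) and 95% (pS/T), whose broad distribution
makes its null upper tail heavier.

## Signal integration

For a group of enriched complexes, member proteins (deduplicated across
complexes, unmodified members dropped) are split by multiplicity — the
number of distinct PTM types on the protein, 1 to 4 — and the total
signal per type gives a 4 x 4 matrix. The null resamples `S = 1000`
equally sized complex sets from the whole universe *without*
replacement (the source text says only "randomly sampled"; without
replacement matches resampling "the same number of complexes", and a
`replace` argument exposes the alternative). Z-scores use the
population (n-denominator) standard deviation, recorded in the output
metadata. Cells with zero null sd are reported as an explicit undefined
flag, never as infinity; |Z| > 35 carries a saturation flag mirroring
the display convention of the original heatmaps. Normality of the
resampled totals is an approximation; the calibration test requires
only that |Z| > 2 occurs in at most 10% of cells on null-sampled
groups.

## Window scanning and PTMi spots

Two scanning modes share one window width `W = 20` residues:

* overlapping scan, step 10, for local density structure;
* tiled scan, step `W`, for whole-protein classification.

A trailing stretch shorter than `W` is not scanned (logged). Local
peaks are windows whose density is >= both span-overlapping neighbours
and that carry at least one record; the final peak set is chosen
greedily by descending density (ties leftmost), discarding candidates
that overlap an accepted peak. Zero-modification windows are never
peaks: a peak is meant to be a modification feature, and admitting
empty windows would make peak counts depend on protein length alone.

Windows with density strictly above `theta = 0.3` (i.e. at least 7
records per 20 residues, hence 2^7 = 128 binary occupancy states) are
merged into PTMi spots when their spans overlap or abut; the spot
density is recomputed over the merged span. No maximum spot length is
enforced — observed lengths are an output, not a constraint. Spots are
`single` or `multi` by the number of distinct types present.

The within-protein null shuffles the multiset of type labels over the
protein's records, keeping every modified position fixed, so the
type-blind density profile — and therefore the peak set itself — is
exactly invariant; only the type composition inside each peak varies.
The default mode permutes labels literally, which can place an Ac label
on a serine; a `compatible` mode restricts exchanges to records on
chemically compatible residues (in practice, Ac/Ub swap among lysines)
for users who want a chemically valid null. The literal mode is the
default because it is the stricter randomisation of type identity.

Motif annotators are regular-expression rules, not motif discovery: the
PY-NLS core `[RHK].{2,5}PY` (shortest match per start; the upstream
10 residues are reported for manual inspection because the
basic/hydrophobic-stretch requirement has no accepted formalisation),
and the hyperphospho-degron filter (>= 4 pS/T in a spot, >= 1 of them
immediately followed by proline — the `[S/T]P` dipeptide stands in for
"proline-directed kinase motif" — and >= 1 Ub in the spot).

## Overlay

Tiled windows are classified on four independent axes. Domain overlap
uses the *maximum single-domain* intersection (Int 20, Lg 11–19, Sm
1–10, Ext 0); using the union across overlapping domains is a
configurable alternative, but the maximum was chosen so that one
deeply overlapping domain cannot be imitated by several grazing ones.
Disorder uses counts of disordered residues with the same 20/11–19/1–10
breaks; a window with exactly 10 disordered residues is classed `Low`
(the count convention; the ratio convention `x >= 0.5` would call it
medium — the two differ only at exactly 10 of 20 residues). Density
bins put exactly 0.05 in `low` and exactly 0.3 in `medium`, with
`unmodified` kept separate so that `low` means exactly one record per
20AA window; comparisons use a 1e-9 guard so that 1/20 is never
misclassified by floating-point error. Mutation records must match the
annotated reference residue or they are dropped and counted; windows
with >= `kappa = 2` mutations are "mutated" (an alternate cutoff of 3
is a parameter, not a code path).

# Synthetic data: what it emulates and what it does not

The generator produces every input dialect the parsers consume.
Defaults were fixed once, before any pipeline result was inspected, to
values a proteomics practitioner would call realistic:

* protein lengths log-normal(meanlog = log 400, sdlog = 0.45, min 50) —
  a right-skewed proteome around ~400 residues;
* human-like amino-acid composition; hotspot spans are re-drawn from a
  low-complexity composition in which residues compatible with the
  span's target type carry half the mass (disordered S/T-rich or
  histone-tail-like K-rich stretches), since dense modification
  requires modifiable residues;
* background rates are densities (records per sequence residue) in the
  observed per-type proportions (pS/T 0.56, Ub 0.24, pY 0.13, Ac 0.07
  of a ~0.017/residue total), realised per compatible residue so every
  emitted record passes validation;
* hotspot spans of 20–60 residues (the observed spot-length range),
  type-pure by default, placed uniformly without overlap; an exact
  per-hotspot site count can be requested, in which case the span's
  composition is forced to contain enough compatible residues to host
  it;
* complexes of 3 + Poisson(2) members; 10% designated enriched, whose
  members carry a 5x background rate of one target type;
* mutations at 0.05/residue outside domains — about one per 20AA
  window, the order of magnitude of the public cancer mutation corpus
  this emulates — times 3 inside domains and times 3 inside dense-PTM
  windows.

The generator does not emulate sequence homology, domain grammar,
isoform structure beyond what the collation tests graft on, kinase
specificity, or correlated modification between interacting proteins.
Passing tests therefore demonstrate that the *methods* behave as
specified under controlled truth, not that any biological conclusion
transfers to real data.

# Problem sizes and numerical choices

The test and acceptance workloads use sizes chosen to give stable
statistics at interactive runtimes: calibration pools 20 independent
universes of 150 proteins / 50 complexes with `R = 100` permutations;
sensitivity uses one universe of 600 fixed-length (400AA) proteins with
200 five-member complexes, 20 of them implanted at 5x; spot recovery
uses 200 single-protein simulations with exactly 8 implanted sites in a
20AA span; the directional check uses 20 universes of 40 hotspot
proteins; the mutation-ratio check pools 50 universes of 500
fixed-length (300AA) proteins. All randomness flows from named seeds
derived from one master seed (kept below 2^31), and the RNG state of
the caller is never disturbed.

Quantile boundaries use R's default (type 7) quantiles with the
lower-quartile convention for exact boundary values. `sample()` is
wrapped to avoid R's scalar expansion so degenerate ranges (for
example a fixed 20-residue hotspot span) behave as written.

# Known limitations

* **Grid-straddling dense regions.** With the documented 10AA scan
  step, a 20AA dense region whose start is offset 3–7 residues from
  the scan grid splits its records across two windows that can each
  fall at or below the 0.3 threshold, so no spot is called. The spot
  caller therefore misses a predictable fraction of off-grid implants
  (the acceptance script measures the recovery rate); a step of 1
  closes the gap at 10x scan cost, and `scan_config(step = ...)`
  exposes that choice, but the package keeps the documented default.
* The annotation-permutation null conditions on the observed bundle
  multiset; it does not model measurement bias shared by proteins in
  the same complex (e.g. abundance-driven detection).
* Z-scores inherit the normal approximation of the resampling
  distribution; for very small groups the undefined/saturation flags
  matter more than the numeric Z.
* The degron and PY-NLS rules are deliberately minimal regular
  expressions; they annotate candidates and make no claim of kinase or
  karyopherin specificity.
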