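---
title: "eccforge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eccforge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`eccforge` is a desk-scale pipeline for extrachromosomal circular DNA
(eccDNA) analysis from rolling-circle-amplified (RCA) nanopore concatemer
reads, of the kind produced in plant eccDNA surveys: circular molecules are
enriched by exonuclease digestion of linear DNA, amplified by phi29
rolling-circle amplification into long linear concatemers, and sequenced as
long reads. Each read is then several head-to-tail copies ("passes") of the
circle monomer, which is the signature the caller exploits. The package
covers six stages:

1. a synthetic-data generator (annotated toy genome, planted circular
   templates, concatemer and background reads with truth tables,
   zero-inflated count matrices), so that every downstream stage is testable
   without any sequencing download;
2. an eccDNA caller based on tandem repeat-unit decomposition with
   linear/genomic-tandem exclusion and read-support filtering;
3. a multiple-fragment (MF) circle detector computing per-read Nfullpass
   and Nfragment and grouping MF circles by core gene;
4. cross-sample locus identity unification;
5. genomic-feature classification (ecGenes, ecTEs, ecNon-codingRNAs,
   NUMT/NUPT overlaps, full-length ecRepeatUnits);
6. GMPR-normalized earth-mover's-distance (EMD) permutation testing with
   exclusive/differential classification.

All coordinates are 0-based half-open internally; BED output shares that
convention, GFF3 output is 1-based closed. An overlap of length 0 is never
a hit anywhere.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs.

**Genome.** `generate_genome()` draws random chromosomes (default 2 x
100 kb, GC 0.44, roughly the GC content of a rice chromosome arm) and
plants: non-overlapping gene models with 5'UTR/CDS/3'UTR parts tiling the
body; TE, repeat-unit, ncRNA and NUMT/NUPT annotation intervals (overlaps
among tracks allowed, as in real annotation); and genomic tandem arrays —
literal head-to-tail repeats of a 150-400 bp monomer (3-6 copies) written
into the sequence. The arrays exist so that the caller's exclusion rule for
reads originating from linear genomic repeats is testable by construction
rather than by accident. TE superfamilies (Gypsy, Copia, hAT, Tc1_Mariner,
Stowaway, Kiddo, Zator, Mutator, Helitron, ...) map to their class
(retrotransposon vs DNA transposon) through a lookup table shipped in
`inst/extdata/te_superfamilies.tsv`. Identical spec and seed give
byte-identical output.

**Circle templates.** `plant_circles()` draws single-fragment template
lengths from a log-normal law with median 500 bp and sigma 0.8, truncated
to [200 bp, 37 kb] — matching the published eccDNA size range (200 bp to
37 kb) and its ~500 bp mode. Multi-fragment templates join 2-10
non-contiguous genomic fragments (each at least 300 bp so the mapper has
seed room), with at least one cross-chromosome template when two or more
are requested; `ltr_flanked_pair` templates place their two fragments
around an annotated LTR-superfamily TE, emulating the LTR homologous
recombination origin proposed for two-fragment circles. A fixed-length law
(`list(law = "fixed", lengths = ...)`) exists purely to probe filter
boundaries. Planted fragments avoid tandem arrays and one another
(best-effort, so truth loci are unambiguous).

**Reads.** `simulate_rca_reads()` draws the pass count as
`1 + Poisson(mean - 1)` (default) plus a uniform partial pass; the shifted
law guarantees at least one full pass so decomposition is well-posed. The
empirical pass-count law of real rRCA libraries is not known to us; the
shifted Poisson is a free modelling choice, and a geometric alternative is
provided. Each read is a random rotation of the monomer, repeated, with
independent per-base substitutions/insertions/deletions at configured rates
(at most 0.2 each) and reverse-complemented with probability 0.5. The truth
table records template, pass count, phase, strand, and error counts per
read. Background reads are contiguous genomic substrings (linear) or
substrings of a planted tandem array spanning at least two monomer copies.

What the generator does *not* emulate: realistic nanopore error profiles
(homopolymer bias, quality-score structure), chimeric reads, or organelle
genomes (NUMT/NUPT are planted nuclear labels only). Passing tests
therefore demonstrate correctness of the algorithms under idealized error
models, not performance on real flow-cell data.

**Count matrices.** `simulate_count_matrix()` draws zero-inflated Poisson
counts (`Bernoulli(1 - pi) * Poisson(lambda)`), default `pi = 0.3`,
`lambda = 10`, for a 2-group x 2-replicate design — the distribution family
observed for real ecGene count matrices. Planted exclusive features have no
zero inflation and mean `exclusive_lambda` in their group and structural
zeros in the other; the default `exclusive_lambda = 50` models a clearly
amplified circle. This matters: zero inflation alone produces
exclusive-looking patterns whose cross-split EMDs reach ~3 lambda, so an
exclusive effect must clear that bar to be recoverable at all. Planted
differential features multiply lambda by 4 in one group.

# The caller

`ecc_call()` runs per read:

1. **Linear exclusion** (`is_genomic_tandem()`): the raw read is mapped; if
   any collinear genomic window spans at least 80% of the read length, the
   read's structure already exists in the linear genome (a plain genomic
   read, or a read from a genomic tandem array) and needs no circular
   interpretation — it is excluded. A concatemer of a genuine circle fails
   this test because any collinear window covers only about one monomer.
2. **Tandem decomposition** (`decompose_concatemer()`): the dominant
   self-repeat period is the rounded median of near-modal distances between
   consecutive occurrences of repeated 15-mers; the read is chopped into
   period-length windows; the tandem run extends while the adjacent-window
   normalized edit distance stays below 0.45; divergence is the mean
   adjacent-unit edit distance divided by the unit length; a trailing
   partial window that matches the consensus prefix contributes
   fractionally to the copy number; the consensus is a per-column majority
   over the full units (ties to the alphabetically first base). The 0.45
   run-inclusion constant sits between the 25% divergence bound the filter
   must still *measure* (plus headroom up to the ~40% used in boundary
   constructions) and the ~0.53 normalized edit distance of unrelated
   random DNA; it is an internal constant, not a user filter.
3. **Unit filters** (`passes_unit_filters()`): reject units shorter than
   200 bp, fewer than 2 units, or divergence exceeding 25%. The three
   conditions act independently; the divergence bound is inclusive at 25%
   (the rejection verb is "exceeding"). The 200 bp unit floor is what gives
   every emitted locus its minimum size of 200 bp.
4. **Consensus mapping** (`map_consensus()`): exact 15-mer seeds, chained
   per chromosome/strand into diagonal bands (anti-diagonals for the minus
   strand), split at read gaps over 150 bp, then extended at both ends by
   greedy x-drop ungapped extension (match +1, mismatch -2, drop 12). The
   extension step matters: seed-only endpoints lose tens of bases under
   sequencing errors, and both the +/-20 bp boundary guarantees and the MF
   detector's endpoint-identity test depend on tight ends. A rotated
   consensus maps as up to two wrap-around segments; segments within one
   unit length of the dominant one are merged into the candidate locus
   interval. The mapper is intentionally minimal and adequate to ~5%
   divergence; pre-computed PAF alignments (`read_paf()`) can substitute
   for it — the pipeline contract is the alignment-segment table, not the
   aligner.
5. **Aligned fraction**: the fraction of read length explained by tiling
   the consensus alignment across the detected units,
   `min(1, n_units * unit_length * covered_fraction / read_length)`. This
   realizes the per-read "80% of read length aligning" criterion exactly on
   error-free reads (a read with a random 20% tail measures exactly 0.80).
6. **Locus calling** (`call_loci()`): reads with aligned fraction >= 0.80
   support their candidate interval; candidates cluster by single-linkage
   reciprocal overlap >= 0.80; the emitted locus takes the member-wise
   lower-median endpoints (deterministic, robust to outlier reads, ties
   resolved to the lower coordinate); loci with fewer than 3 supporting
   reads are discarded.

The defaults (200 bp / 2 units / 25% / 3 reads / 80%) reproduce the
published identification criteria verbatim and are all exposed in
`caller_params()`.

# Multiple-fragment detection

`mf_detect()` maps each raw read; every pass of every fragment yields its
own segment because passes sit on distinct alignment diagonals. Segments
are ordered by read coordinate, overlaps trimmed at the midpoint, and
assigned identity classes: a segment joins a class when it shares
chromosome and strand and either both reference endpoints agree with the
class's running median endpoints within 20 bp, or its interval Jaccard with
the class exceeds 0.5. The Jaccard fallback absorbs the residual endpoint
jitter and end-truncation that errors inflict on individual segments;
distinct fragments of one circle occupy disjoint reference intervals, so it
cannot conflate them.

`detect_cycle()` then finds the smallest period `p` of the identity
sequence, tolerating mismatches only at comparisons that involve the first
or last segment (partial traversals at the read ends). `Nfragment = p`;
`Nfullpass` is the number of complete cycles, the trailing partial cycle
never counting — a conservative reading of "full pass". Which fragment
anchors a pass is immaterial: rotation changes the cycle's phase, not its
period. Reads are classified with both thresholds at 1, read as minima:
`Nfragment = 1` reads are single-fragment (the dominant class in real
data), `Nfragment >= 2` reads are MF-eccDNAs. MF reads are grouped by
(core gene, Nfragment) to reduce redundancy, where the core gene maximizes
the summed overlap with the cycle fragments (ties to the smaller
chromosome/start). A group is flagged `ltr_flanked` when, for every member
read, each inter-fragment genomic gap contains at least one
LTR-superfamily TE of a single subfamily.

# ID unification

`unify_ids()` assigns one unified ID per connected component of the graph
whose edges join same-chromosome loci overlapping by strictly more than
200 bp ("more than 200 bp" is read strictly; the threshold is
configurable). Transitive merging follows from "same ID" being an
equivalence relation; the merge is applied uniformly within and across
samples (whether the original study merged within-sample loci is not
stated; uniformity is the simpler invariant-preserving choice). Chaining
across long regions is an accepted consequence and is visible in the
`regions` table as wide unified spans. Original locus coordinates are never
altered; strand is ignored. The implementation is a sorted sweep with
union-find; tests hold it equal to an all-pairs oracle on random instances.
`catalog_counts()` sums supporting reads per unified ID and sample, with
zeros for absent samples.

# Annotation

`classify_location()` assigns each unified region exactly one of
gene / up2kb / down2kb / intergenic, in that priority order — the printed
proportions of these classes form a partition summing to 100%, which forces
mutual exclusion. The 2 kb windows are gene-orientation-relative (upstream
of a minus-strand gene lies to its right in genome coordinates);
`stranded = FALSE` switches to coordinate-relative windows. Multi-gene
conflicts resolve to the largest overlap, ties to the smaller start (which
of the two rules real pipelines used is not printed; largest-overlap is the
standard bedtools-style choice). `classify_gene_parts()` reports the
5'UTR/CDS/3'UTR parts overlapped by at least 1 bp and flags regions fully
containing a gene span. `overlap_track()` emits one record per
(region, feature) pair at >= 1 bp intersection — these labels are
non-exclusive, so a region can be ecGene and ecTE at once.
`full_length_repeat_units()` requires inclusive containment of the repeat
unit in the region. `summarize_annotation()` produces location and
gene-part percentages, TE class and superfamily ratios (per sample when a
`sample_id` column is present), and full-length counts; empty catalogs
yield zero counts, never NaN.

# Differential analysis

**GMPR size factors.** For samples i, j the pairwise ratio `r_ij` is the
median of count ratios over features non-zero in both; the size factor of
sample i is the geometric mean of its pairwise ratios *including the
self-ratio of 1*, rescaled so the factors have geometric mean 1. Including
the self-ratio makes the factor exactly proportional to depth on noiseless
proportional data (doubling one of two samples doubles the factor ratio),
which is the property normalization exists for; it also makes the factor
scale exactly with any single-sample rescaling. A sample sharing no
non-zero feature with any other is a hard error naming the sample.

**EMD.** The between-group score is the exact 1-D earth-mover's distance:
the integral of the absolute difference between the two empirical CDFs,
computed on GMPR-normalized counts without binning. For equal group sizes
this equals the mean absolute difference of sorted values; the binned
variant used by histogram implementations converges to it as bins shrink,
and exactness makes closed-form test values possible (0; 4.0; 1.0).

**Permutation p and q.** A 2v2 design has only three distinct unordered
label splits. The null distribution pools, across all features, the EMD
values of the *non-observed* splits (two per feature), and
`p = (1 + #null >= observed) / (1 + #null)` (the add-one estimator avoids
p = 0); q-values are Benjamini-Hochberg. Excluding the observed labelling
from the pool is deliberate: with it included, the smallest attainable p is
1/(3m + 1), so the rank-1 BH q can never fall below ~1/3 and no feature
could ever be called. Under the global null the observed split remains
exchangeable with the pooled ones, and the seeded null simulation confirms
that the fraction of q < 0.05 features stays at or below 0.05. A
consequence worth knowing: a *single* true effect among thousands of null
features still cannot pass q < 0.05 (its minimal p is 1/(2m + 1), giving a
rank-1 q near 0.5); the q-gate becomes informative when effects arrive in
batches, as they do in real treatment contrasts.

**Classification.** Features with q >= 0.05 are `not_significant`.
Significant features present in both replicates of one group and absent
from both replicates of the other are `exclusive` to that group —
presence/absence is judged on raw counts because it is depth-robust — and
the remaining significant features are `differential`, the direction being
the group with the higher mean normalized count. The q-gate precedes the
exclusive/differential split, following the ordering "differentially
enriched ... further classified".

# Validation, problem sizes, and limitations

The test suite validates every stage against independent oracles:
brute-force all-pairs overlap and union-find implementations, hand-computed
GMPR factors, closed-form EMD values, adjacent-unit edit-distance oracles
on constructed concatemers, and Monte-Carlo checks of simulator rates. The
acceptance checks run at these sizes, chosen to exercise every boundary
while keeping a laptop run comfortable: filter boundaries on 6-read
constructions; end-to-end recovery with 50 planted circles (250-2500 bp,
6 error-free reads each, mean 5 passes) against 120 background reads, with
exact locus counts and +/-20 bp boundaries; MF recovery over
Nfragment 2..7 with 24 error-free and 72 five-percent-error reads (>= 90%
per-read recovery); 100 random unification instances; and 2000-feature
count matrices for the null-control and recovery checks.
`scripts/acceptance.R` recomputes the three boundary quantities (minimum
locus size, minimum supporting aligned fraction, maximum accepted
divergence) from scratch on any seed.

Known limitations: the internal mapper is exact-seeded and ungapped-extended,
so it degrades beyond ~5% divergence — real data should come in as PAF from
a long-read aligner; decomposition uses fixed-width windows, so unit-length
estimates drift for reads with strong indel imbalance; eccDNAs shorter than
200 bp are out of scope by design; consensus polishing is not
quality-aware; and the MF detector reports fragment cycles, not an
assembled circular consensus sequence.
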