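# eccforge

Detection, cross-sample unification, annotation and differential analysis
of extrachromosomal circular DNA (eccDNA) from rolling-circle-amplified
long reads — with a built-in synthetic-data generator so the whole pipeline
runs and validates at desk scale, without any sequencing download.

## The problem

Plant eccDNA surveys enrich circular DNA by digesting linear DNA, amplify
it with phi29 random rolling-circle amplification (RCA), and sequence the
products as nanopore long reads. Each read is then a linear concatemer:
several head-to-tail "passes" of the circle monomer. Identifying eccDNA
loci from such reads means (i) recognizing the tandem-repeat structure of a
read, (ii) ruling out reads that merely come from linear genomic repeats,
(iii) mapping the repeat-unit consensus back to the genome, and (iv)
demanding reproducible read support. Downstream, loci from many samples
must share stable IDs, be classified against genes, transposable elements
(TEs) and repeat units, and be tested for treatment-specific (exclusive)
or quantitatively shifted (differential) abundance.

`eccforge` implements that whole chain:

* **Caller** — a read supports a locus when its tandem decomposition has a
  unit of at least 200 bp, at least two units, inter-unit divergence at
  most 25%, and at least 80% of the read length aligning to the locus of
  origin; loci need at least 3 supporting reads. Reads whose full length
  aligns collinearly to one genomic window (linear reads, genomic tandem
  arrays) are excluded first.
* **Multiple-fragment detector** — per read, the ordered alignment
  segments are tested for a repeating cycle: `Nfragment` is the cycle
  period (number of distinct genomic fragments in the circle), `Nfullpass`
  the number of complete traversals; multi-fragment circles are grouped by
  core gene, with an `ltr_flanked` flag for cycles whose fragment gaps
  contain LTR elements of a single subfamily.
* **ID unification** — loci (all samples pooled) overlapping by strictly
  more than 200 bp share one unified ID (connected components).
* **Annotation** — each unified region gets exactly one location class,
  with priority `gene > up2kb > down2kb > intergenic` (2 kb windows are
  gene-orientation-aware); non-exclusive ecTE / ecNon-codingRNA /
  NUMT / NUPT overlap records; UTR/CDS composition; full-length
  ecRepeatUnits by containment.
* **Differential analysis** — GMPR size factors (geometric mean of
  pairwise median count ratios, robust to zero inflation), exact 1-D
  earth-mover's-distance scores `EMD = ∫ |ECDF_A − ECDF_B| dx` on
  normalized counts, pooled label-permutation p-values with
  Benjamini–Hochberg q-values, and classification of q < 0.05 features as
  `exclusive_<group>` (present in both replicates of one group, absent
  from both of the other) or `differential_<group>_up`.
* **Simulator** — annotated toy genome, planted circle templates
  (log-normal sizes, median 500 bp, truncated to 200 bp–37 kb;
  multi-fragment and LTR-flanked templates), RCA concatemer reads with
  truth tables, linear/tandem background reads, and zero-inflated Poisson
  count matrices with planted exclusive/differential features.

See `vignettes/eccforge-methods.Rmd` for the model details, parameter
meanings and design decisions.

## Worked example

```r
library(eccforge)

genome <- generate_genome(genome_spec(seed = 1))   # 2 x 100 kb, annotated
index  <- kmer_index(genome)

# two samples sharing 8 of their planted circles
tpA <- plant_circles(genome, n_single = 12, id_prefix = "a", seed = 2)
tpB <- c(tpA[1:8], plant_circles(genome, n_single = 4, id_prefix = "b", seed = 3))
cfg <- function(s) read_sim_config(mean_full_passes = 5,
                                   n_reads_per_template = 5, seed = s)
callA <- ecc_call(simulate_rca_reads(tpA, genome, cfg(4))$reads, index,
                  sample_id = "ctrl")
callB <- ecc_call(simulate_rca_reads(tpB, genome, cfg(5))$reads, index,
                  sample_id = "stress")
callA
#> eccDNA calls for sample ctrl: 12 locus/loci from 60 reads
#>   filtered_units: 1
#>   supporting: 59

catalog <- unify_ids(list(callA, callB))
catalog
#> Unified eccDNA catalog: 24 loci from 2 sample(s) -> 16 unified IDs (overlap > 200 bp)
head(catalog$regions, 3)
#>   unified_id chrom start   end n_members
#> 1 ecc_000001  chr1  7556  8113         2
#> 2 ecc_000002  chr1 12895 13364         2
#> 3 ecc_000003  chr1 15028 15614         1

loc <- classify_location(catalog$regions, genome$genes)
summarize_annotation(loc, te_records = overlap_track(
  catalog$regions, genome$tracks[genome$tracks$kind == "TE", ]))
#> Annotation summary over 16 unified region(s)
#>   location %: gene 12.5, up2kb 18.8, down2kb 18.8, intergenic 50.0
#>   full-length genes: 0, full-length repeat units: 0

sim <- simulate_count_matrix(count_sim_design(
  n_features = 500, exclusive_A = 1:10, exclusive_B = 11:20, seed = 6))
ecc_diff(sim$counts, sim$groups)
#> EMD differential analysis over 500 features:
#>   exclusive_A: 10
#>   exclusive_B: 10
#>   not_significant: 480
```

Reading the output: the two samples' 24 loci collapse to 16 unified IDs
because the 8 shared circles overlap by more than 200 bp across samples
(the per-locus coordinates in `catalog$id_map` stay untouched). The
annotation summary partitions those 16 regions over the four location
classes (percentages sum to 100). In the count simulation, all 20 planted
exclusive features are recovered with the correct group label and none of
the 480 null features is called.

Real data enter through the same surfaces: FASTQ reads
(`read_reads_fastq()`), a FASTA genome (`read_genome_fasta()`), GFF3 gene
models (`read_genes_gff3()`), BED6+ annotation tracks (`read_track_bed()`),
or pre-computed PAF alignments (`read_paf()`) in place of the internal
seed mapper.

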