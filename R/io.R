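# File-format boundary. Internally everything is 0-based half-open; BED
# files share that convention, GFF3 is 1-based closed (converted at this
# boundary via GRanges). FASTA/FASTQ go through Biostrings, GFF3 and plain
# BED6 through rtracklayer. Annotation tracks use BED6 plus documented extra
# columns (kind, class1, superfamily, subfamily), written/read as TSV.

#' Write genome sequences to FASTA
#' @param genome An `ecc_genome` or named character vector.
#' @param path Output file.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "ecc_genome")) genome$seq else genome
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genome sequences from FASTA
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads to FASTQ with a constant base quality
#' @param reads Named character vector.
#' @param path Output file.
#' @param quality Constant Phred quality (default 20).
#' @export
write_reads_fastq <- function(reads, path, quality = 20L) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep(rawToChar(as.raw(quality + 33L)), n), ""))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read sequences from FASTQ
#' @param path FASTQ file.
#' @return Named character vector of read sequences.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write gene models to GFF3
#' @param genes,gene_parts Gene models as produced by [generate_genome()].
#' @param path Output file.
#' @export
write_genes_gff3 <- function(genes, gene_parts, path) {
  type_map <- c(`5UTR` = "five_prime_UTR", CDS = "CDS",
                `3UTR` = "three_prime_UTR")
  gr_g <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id)
  pp <- merge(gene_parts, genes[, c("gene_id", "chrom", "strand")],
              by = "gene_id")
  gr_p <- GenomicRanges::GRanges(
    pp$chrom, IRanges::IRanges(pp$start + 1L, pp$end), strand = pp$strand,
    type = unname(type_map[pp$part]), Parent = pp$gene_id,
    phase = ifelse(pp$part == "CDS", 0L, NA_integer_))
  rtracklayer::export(c(gr_g, gr_p), path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#' @param path GFF3 file written by [write_genes_gff3()] or compatible.
#' @return List with `genes` and `gene_parts` data.frames (0-based
#'   half-open).
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  g <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = as.character(g$ID),
                      chrom = as.character(g$seqnames),
                      start = g$start - 1L, end = g$end,
                      strand = as.character(g$strand))
  type_map <- c(five_prime_UTR = "5UTR", CDS = "CDS",
                three_prime_UTR = "3UTR")
  p <- df[df$type %in% names(type_map), ]
  parent <- vapply(p$Parent, function(x) as.character(x)[1], "")
  gene_parts <- data.frame(gene_id = parent,
                           part = unname(type_map[as.character(p$type)]),
                           start = p$start - 1L, end = p$end)
  list(genes = genes, gene_parts = gene_parts)
}

#' Write an annotation track as BED6+
#'
#' Columns: chrom, start, end, name (feature_id), score (0), strand, then
#' kind, class1, superfamily, subfamily.
#' @param track Track data.frame.
#' @param path Output file.
#' @export
write_track_bed <- function(track, path) {
  out <- data.frame(track$chrom, track$start, track$end, track$feature_id,
                    0L, track$strand, track$kind, track$class1,
                    track$superfamily, track$subfamily)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an annotation track from BED6+
#' @param path File written by [write_track_bed()].
#' @return Track data.frame.
#' @export
read_track_bed <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE,
                  stringsAsFactors = FALSE, na.strings = "NA")
  data.frame(feature_id = x[[4]], kind = x[[7]], chrom = x[[1]],
             start = x[[2]], end = x[[3]], strand = x[[6]], class1 = x[[8]],
             superfamily = x[[9]], subfamily = x[[10]])
}

#' Write called loci to BED6
#'
#' name = locus_id, score = supporting read count.
#' @param loci Locus data.frame from [ecc_call()] / [call_loci()].
#' @param path Output file.
#' @export
write_loci_bed <- function(loci, path) {
  gr <- GenomicRanges::GRanges(loci$chrom,
                               IRanges::IRanges(loci$start + 1L, loci$end),
                               name = loci$locus_id, score = loci$n_reads)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read loci from BED6
#' @param path BED file.
#' @param sample_id Sample label to attach.
#' @return Locus data.frame (`sample_id`, `locus_id`, `chrom`, `start`,
#'   `end`, `n_reads`).
#' @export
read_loci_bed <- function(path, sample_id = "S1") {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(sample_id = sample_id, locus_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             n_reads = as.integer(gr$score))
}

#' Parse a PAF alignment file into alignment segments
#'
#' Reads the 12 mandatory PAF columns and returns the alignment-segment
#' data.frame consumed by [order_segments()] and [detect_cycle()], so
#' alignments from an external long-read mapper can replace the internal
#' seed mapper.
#'
#' @param path PAF file.
#' @return Data.frame with one row per alignment record: `read_id`,
#'   `read_start`, `read_end`, `chrom`, `ref_start`, `ref_end`, `strand`,
#'   `covered`, `identity`, `n_kmers`.
#' @export
read_paf <- function(path) {
  x <- read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                  stringsAsFactors = FALSE)[, 1:12]
  names(x) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                "tlen", "tstart", "tend", "nmatch", "alen", "mapq")
  data.frame(read_id = x$qname, read_start = x$qstart, read_end = x$qend,
             chrom = x$tname, ref_start = x$tstart, ref_end = x$tend,
             strand = x$strand, covered = x$nmatch,
             identity = x$nmatch / pmax(1L, x$alen),
             n_kmers = NA_integer_)
}

#' Write a feature-by-sample count matrix as TSV
#' @param counts Matrix with feature rownames and sample colnames.
#' @param path Output file.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(unified_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample count matrix from TSV
#' @param path File written by [write_count_matrix()].
#' @return Integer matrix.
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}
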