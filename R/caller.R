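# Locus calling: per-read candidate intervals from consensus mapping,
# single-linkage reciprocal-overlap clustering, and read-support filtering.

# Merge the alignment segments that belong to one circular locus: a rotated
# consensus maps as up to two wrap-around segments on nearby diagonals, so
# segments on the dominant chromosome/strand whose reference intervals lie
# within one unit length of the dominant segment are merged into the
# candidate interval.
.consensus_locus <- function(segs, unit_length) {
  if (!nrow(segs)) return(NULL)
  span <- segs$ref_end - segs$ref_start
  dom <- segs[which.max(span), ]
  near <- segs$chrom == dom$chrom & segs$strand == dom$strand &
    segs$ref_start <= dom$ref_end + unit_length &
    segs$ref_end >= dom$ref_start - unit_length
  grp <- segs[near, ]
  list(chrom = dom$chrom, start = min(grp$ref_start), end = max(grp$ref_end),
       strand = dom$strand, covered = sum(grp$covered))
}

#' Cluster per-read candidate intervals into eccDNA loci
#'
#' Reads with an aligned fraction of at least `min_read_aligned_fraction`
#' support their candidate interval; candidates are clustered per chromosome
#' by single-linkage with reciprocal overlap of at least
#' `cluster_reciprocal_overlap`; each cluster is emitted as a locus with the
#' member-wise lower-median endpoints, and loci supported by fewer than
#' `min_locus_reads` reads are discarded.
#'
#' @param candidates A data.frame with columns `read_id`, `chrom`, `start`,
#'   `end`, `aligned_fraction` (one candidate interval per read, 0-based
#'   half-open).
#' @param params A [caller_params()].
#' @param sample_id Sample label stamped into locus IDs.
#' @return A data.frame of loci: `locus_id`, `sample_id`, `chrom`, `start`,
#'   `end`, `n_reads`, `mean_aligned_fraction`, sorted by `(chrom, start)`.
#' @export
call_loci <- function(candidates, params = caller_params(),
                      sample_id = "S1") {
  empty <- data.frame(locus_id = character(0), sample_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), n_reads = integer(0),
                      mean_aligned_fraction = numeric(0))
  if (is.null(candidates) || !nrow(candidates)) return(empty)
  cand <- candidates[candidates$aligned_fraction >=
                       params$min_read_aligned_fraction, , drop = FALSE]
  if (!nrow(cand)) return(empty)
  cand <- cand[order(cand$chrom, cand$start, cand$end), , drop = FALSE]
  n <- nrow(cand)
  parent <- uf_new(n)
  recip <- params$cluster_reciprocal_overlap
  for (chrom in unique(cand$chrom)) {
    idx <- which(cand$chrom == chrom)
    active <- integer(0)
    for (i in idx) {
      active <- active[cand$end[active] > cand$start[i]]
      for (j in active) {
        olap <- min(cand$end[i], cand$end[j]) - max(cand$start[i],
                                                    cand$start[j])
        need <- recip * max(cand$end[i] - cand$start[i],
                            cand$end[j] - cand$start[j])
        if (olap >= need) parent <- uf_union(parent, j, i)
      }
      active <- c(active, i)
    }
  }
  comp <- uf_components(parent)
  rows <- lapply(split(seq_len(n), comp), function(ii) {
    data.frame(chrom = cand$chrom[ii[1]],
               start = lower_median(cand$start[ii]),
               end = lower_median(cand$end[ii]),
               n_reads = length(ii),
               mean_aligned_fraction = mean(cand$aligned_fraction[ii]),
               member_reads = I(list(cand$read_id[ii])))
  })
  loci <- do.call(rbind, rows)
  loci <- loci[loci$n_reads >= params$min_locus_reads &
                 loci$end - loci$start >= params$min_unit_length, ,
               drop = FALSE]
  if (!nrow(loci)) return(empty)
  loci <- loci[order(loci$chrom, loci$start, loci$end), , drop = FALSE]
  data.frame(locus_id = sprintf("%s_ecc%04d", sample_id,
                                seq_len(nrow(loci))),
             sample_id = sample_id, chrom = loci$chrom,
             start = as.integer(loci$start), end = as.integer(loci$end),
             n_reads = loci$n_reads,
             mean_aligned_fraction = loci$mean_aligned_fraction,
             member_reads = loci$member_reads)
}

#' Call single-fragment eccDNA loci from concatemer reads
#'
#' Runs the full per-sample identification pipeline: reads originating from
#' the linear genome (contiguous substrings or genomic tandem arrays) are
#' excluded; the remaining reads are tandem-decomposed; decompositions
#' failing the unit filters (unit < 200 bp, fewer than 2 units, divergence
#' over 25% by default) are removed; the unit consensus is mapped to the
#' genome; the per-read aligned fraction is the fraction of read length
#' explained by tiling the consensus alignment across the detected units; and
#' surviving candidates are clustered into loci with [call_loci()].
#'
#' @param reads Named character vector of read sequences.
#' @param genome An `ecc_genome`, a named character vector of chromosome
#'   sequences, or a pre-built [kmer_index()].
#' @param params A [caller_params()].
#' @param sample_id Sample label.
#' @return An object of class `ecc_calls`: a list with `loci` (see
#'   [call_loci()]), `audit` (one row per input read with its fate and
#'   measurements) and `params`.
#' @export
ecc_call <- function(reads, genome, params = caller_params(),
                     sample_id = "S1") {
  index <- if (inherits(genome, "kmer_index")) genome else
    kmer_index(genome, params$kmer_size)
  n <- length(reads)
  audit <- data.frame(
    read_id = if (is.null(names(reads))) sprintf("read_%05d", seq_len(n))
      else names(reads),
    status = character(n), unit_length = NA_integer_, n_units = NA_real_,
    unit_divergence = NA_real_, chrom = NA_character_, start = NA_integer_,
    end = NA_integer_, aligned_fraction = NA_real_,
    stringsAsFactors = FALSE)
  cand_rows <- list()
  for (i in seq_len(n)) {
    read <- reads[[i]]
    if (nchar(read) < 2L * params$kmer_size) {
      audit$status[i] <- "too_short"
      next
    }
    if (is_genomic_tandem(read, index, params)) {
      audit$status[i] <- "genomic_tandem"
      next
    }
    dec <- decompose_concatemer(read, params, read_id = audit$read_id[i])
    if (is.null(dec)) {
      audit$status[i] <- "no_period"
      next
    }
    audit$unit_length[i] <- dec$unit_length
    audit$n_units[i] <- dec$n_units
    audit$unit_divergence[i] <- dec$unit_divergence
    if (!passes_unit_filters(dec, params)) {
      audit$status[i] <- "filtered_units"
      next
    }
    segs <- map_consensus(dec$consensus, index, params)
    loc <- .consensus_locus(segs, dec$unit_length)
    if (is.null(loc)) {
      audit$status[i] <- "unmapped"
      next
    }
    mu <- min(1, loc$covered / dec$unit_length)
    af <- min(1, dec$n_units * dec$unit_length * mu / nchar(read))
    audit$chrom[i] <- loc$chrom
    audit$start[i] <- loc$start
    audit$end[i] <- loc$end
    audit$aligned_fraction[i] <- af
    if (af < params$min_read_aligned_fraction) {
      audit$status[i] <- "low_aligned_fraction"
      next
    }
    audit$status[i] <- "supporting"
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      read_id = audit$read_id[i], chrom = loc$chrom, start = loc$start,
      end = loc$end, aligned_fraction = af)
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else NULL
  loci <- call_loci(candidates, params, sample_id)
  structure(list(loci = loci, audit = audit, params = params,
                 sample_id = sample_id),
            class = "ecc_calls")
}

#' @export
print.ecc_calls <- function(x, ...) {
  cat(sprintf("eccDNA calls for sample %s: %d locus/loci from %d reads\n",
              x$sample_id, nrow(x$loci), nrow(x$audit)))
  tab <- table(x$audit$status)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}
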