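# Tandem (concatemer) decomposition of rolling-circle reads and the printed
# unit filters of the identification pipeline.

#' Parameters of the eccDNA caller
#'
#' Defaults reproduce the published identification criteria: alignments
#' shorter than 200 bp, with fewer than two repeat units, or with an
#' inter-unit divergence exceeding 25% are removed; loci must be covered by
#' at least three reads with a minimum of 80% of read length aligning.
#'
#' @param min_unit_length Minimum repeat-unit (monomer) length in bp.
#' @param min_units Minimum copy number (fractional passes count).
#' @param max_unit_divergence Maximum mean inter-unit divergence; the filter
#'   rejects strictly greater values ("exceeding").
#' @param min_locus_reads Minimum supporting reads per locus.
#' @param min_read_aligned_fraction Minimum fraction of a read's length that
#'   must align to the locus of origin for the read to support it.
#' @param kmer_size Seed k-mer size for period detection and mapping.
#' @param cluster_reciprocal_overlap Reciprocal-overlap fraction for
#'   single-linkage clustering of per-read candidate intervals.
#' @param band_tol Diagonal band tolerance (bp) when chaining seed hits.
#' @param read_gap Maximum read-coordinate gap (bp) within one segment.
#' @param min_covered Minimum seed-covered bases per alignment segment.
#' @param run_max_divergence Internal inclusion bound for extending the
#'   tandem-unit run: must exceed `max_unit_divergence` (so that reads near
#'   the rejection boundary are still measured, not truncated) while staying
#'   below the ~0.53 normalized edit distance of unrelated random DNA.
#' @param coord_tol Reference-endpoint tolerance (bp) when two alignment
#'   segments are considered the same genomic fragment.
#' @return An object of class `caller_params`.
#' @export
caller_params <- function(min_unit_length = 200L, min_units = 2,
                          max_unit_divergence = 0.25, min_locus_reads = 3L,
                          min_read_aligned_fraction = 0.80, kmer_size = 15L,
                          cluster_reciprocal_overlap = 0.80, band_tol = 30L,
                          read_gap = 150L, min_covered = 25L,
                          run_max_divergence = 0.45, coord_tol = 20L) {
  stop_if_not_scalar_prop(max_unit_divergence, "max_unit_divergence",
                          lo = 1e-9)
  stop_if_not_scalar_prop(min_read_aligned_fraction,
                          "min_read_aligned_fraction", lo = 1e-9)
  stop_if_not_scalar_prop(cluster_reciprocal_overlap,
                          "cluster_reciprocal_overlap", lo = 1e-9)
  if (min_unit_length < kmer_size)
    stop("min_unit_length must be >= kmer_size")
  if (min_units <= 0 || min_locus_reads < 1) stop("invalid support thresholds")
  structure(as.list(environment()), class = "caller_params")
}

# Per-column majority consensus over equal-length unit strings; ties resolve
# to the alphabetically first base.
.majority_consensus <- function(windows) {
  if (length(windows) == 1L) return(windows)
  d <- nchar(windows[1])
  M <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
              nrow = d)
  cnt <- vapply(DNA_BASES, function(b) rowSums(M == b), numeric(d))
  if (d == 1L) cnt <- matrix(cnt, nrow = 1)
  paste(DNA_BASES[max.col(cnt, ties.method = "first")], collapse = "")
}

#' Decompose a concatemer read into tandem repeat units
#'
#' Detects the dominant self-repeat period from the mode of distances between
#' consecutive occurrences of repeated k-mers, chops the read into
#' period-length windows, extends the tandem run while adjacent windows stay
#' within the internal divergence ceiling, measures the mean adjacent-unit
#' edit-distance divergence, counts fractional trailing passes, and builds a
#' per-column majority consensus over the full units.
#'
#' @param read A single read sequence (character).
#' @param params A [caller_params()].
#' @param read_id Optional identifier carried into the result.
#' @return An object of class `tandem_decomposition` with elements
#'   `unit_length`, `n_units` (fractional), `unit_divergence`, `consensus`
#'   and `n_full_units`, or `NULL` when no period explains at least
#'   `2 * kmer_size` matched bases.
#' @export
decompose_concatemer <- function(read, params = caller_params(),
                                 read_id = NULL) {
  n <- nchar(read)
  k <- params$kmer_size
  if (n < 2L * k) stop("read shorter than twice the k-mer size")
  km <- seq_kmers(read, k)
  occ <- split(0:(n - k), km)
  occ <- occ[lengths(occ) >= 2L]
  if (!length(occ)) return(NULL)
  diffs <- unlist(lapply(occ, diff), use.names = FALSE)
  starts <- unlist(lapply(occ, function(p) p[-length(p)]), use.names = FALSE)
  mates <- unlist(lapply(occ, function(p) p[-1]), use.names = FALSE)
  keep <- diffs >= k
  if (!any(keep)) return(NULL)
  diffs <- diffs[keep]; starts <- starts[keep]; mates <- mates[keep]
  tab <- table(diffs)
  d0 <- as.integer(names(tab)[which.max(tab)])
  sel <- abs(diffs - d0) <= max(5, round(0.02 * d0))
  d <- as.integer(round(median(diffs[sel])))
  support <- unique(c(starts[sel], mates[sel]))
  if (kmer_coverage(support, k) < 2L * k) return(NULL)
  if (d < k || d > n) return(NULL)

  m <- n %/% d
  windows <- substring(read, (0:(m - 1)) * d + 1L, (1:m) * d)
  r <- 1L
  dists <- numeric(0)
  if (m >= 2L) {
    for (i in 2:m) {
      di <- adist(windows[i - 1L], windows[i])[1, 1] / d
      if (di <= params$run_max_divergence) {
        r <- i
        dists <- c(dists, di)
      } else break
    }
  }
  consensus <- .majority_consensus(windows[seq_len(r)])
  frac <- 0
  tail_div <- NA_real_
  tail_len <- n - r * d
  if (r == m && tail_len >= max(20, 0.05 * d)) {
    tail_seq <- substr(read, r * d + 1L, n)
    td <- adist(tail_seq, substr(consensus, 1L, tail_len))[1, 1] / tail_len
    if (td <= params$run_max_divergence) {
      frac <- tail_len / d
      tail_div <- td
    }
  }
  divergence <- if (length(dists)) mean(dists) else if (frac > 0) tail_div
    else return(NULL)
  structure(list(read_id = read_id, unit_length = d, n_units = r + frac,
                 unit_divergence = divergence, consensus = consensus,
                 n_full_units = r),
            class = "tandem_decomposition")
}

#' @export
print.tandem_decomposition <- function(x, ...) {
  cat(sprintf(
    "Tandem decomposition: unit %d bp x %.2f copies, divergence %.3f\n",
    x$unit_length, x$n_units, x$unit_divergence))
  invisible(x)
}

#' Apply the published repeat-unit filters
#'
#' A decomposition passes when the unit is at least `min_unit_length` bp,
#' carries at least `min_units` copies, and the inter-unit divergence does
#' not exceed `max_unit_divergence` (inclusive bound: "exceeding 25%" is the
#' rejection condition). The three conditions are independent reject rules.
#'
#' @param dec A `tandem_decomposition` (or `NULL`, which fails).
#' @param params A [caller_params()].
#' @return `TRUE` or `FALSE`.
#' @export
passes_unit_filters <- function(dec, params = caller_params()) {
  if (is.null(dec)) return(FALSE)
  dec$unit_length >= params$min_unit_length &&
    dec$n_units >= params$min_units &&
    dec$unit_divergence <= params$max_unit_divergence
}
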