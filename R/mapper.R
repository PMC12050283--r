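# Minimal internal seed mapper: exact k-mer seeding, diagonal-band chaining.
# Adequate for consensus sequences diverging <= ~5% from the reference; for
# real data, pre-computed PAF alignments can be supplied instead (see
# read_paf()) — the pipeline contract is the alignment-segment data.frame,
# not any particular aligner.

#' Build an exact k-mer index of a genome
#'
#' @param genome An `ecc_genome` object or a named character vector of
#'   chromosome sequences.
#' @param k K-mer size (default 15).
#' @return An object of class `kmer_index`.
#' @export
kmer_index <- function(genome, k = 15L) {
  seqs <- if (inherits(genome, "ecc_genome")) genome$seq else genome
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  lens <- nchar(seqs)
  offsets <- c(0, cumsum(as.numeric(lens)))[seq_along(seqs)]
  names(offsets) <- names(seqs)
  kmers <- character(0)
  gpos <- numeric(0)
  for (i in seq_along(seqs)) {
    km <- seq_kmers(seqs[[i]], k)
    kmers <- c(kmers, km)
    gpos <- c(gpos, offsets[i] + seq_along(km) - 1)
  }
  structure(list(map = split(gpos, kmers), k = as.integer(k),
                 chrom_names = names(seqs), offsets = unname(offsets),
                 chrom_lengths = unname(lens), seq = seqs),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("k-mer index: k=%d, %d chromosome(s), %d distinct k-mers\n",
              x$k, length(x$chrom_names), length(x$map)))
  invisible(x)
}

# Seed hits of a query against the index, both orientations.
# Returns data.frame(read_pos, gpos, strand) with 0-based positions.
.seed_hits <- function(query, index) {
  k <- index$k
  km <- seq_kmers(query, k)
  if (!length(km)) {
    return(data.frame(read_pos = integer(0), gpos = numeric(0),
                      strand = character(0)))
  }
  pos <- seq_along(km) - 1L
  fwd <- index$map[km]
  nf <- lengths(fwd)
  rkm <- seq_kmers(revcomp(query), k)
  # rc kmer at rc-position j corresponds to read kmer starting at n-k-j
  rev_map <- index$map[rkm[length(rkm):1]]  # aligned to read positions
  nr <- lengths(rev_map)
  data.frame(
    read_pos = c(rep.int(pos, nf), rep.int(pos, nr)),
    gpos = c(unlist(fwd, use.names = FALSE),
             unlist(rev_map, use.names = FALSE)),
    strand = rep(c("+", "-"), c(sum(nf), sum(nr))))
}

# Decode linear genome positions into (chrom index, local position).
.decode_gpos <- function(gpos, index) {
  ci <- findInterval(gpos, c(index$offsets, sum(index$chrom_lengths)))
  list(chrom = ci, pos = gpos - index$offsets[ci])
}

# Chain seed hits into alignment segments: hits on one chromosome and strand
# are clustered by diagonal (anti-diagonal for "-") with single-linkage gap
# band_tol, then split at read-coordinate gaps larger than read_gap. Segments
# covering fewer than min_covered bases of the read are dropped.
.build_segments <- function(hits, index, band_tol = 30L, read_gap = 150L,
                            min_covered = 25L) {
  empty <- data.frame(read_start = integer(0), read_end = integer(0),
                      chrom = character(0), ref_start = integer(0),
                      ref_end = integer(0), strand = character(0),
                      covered = integer(0), identity = numeric(0),
                      n_kmers = integer(0))
  if (!nrow(hits)) return(empty)
  k <- index$k
  dec <- .decode_gpos(hits$gpos, index)
  hits$chrom_i <- dec$chrom
  hits$pos <- dec$pos
  hits$diag <- ifelse(hits$strand == "+", hits$pos - hits$read_pos,
                      hits$pos + hits$read_pos)
  out <- list()
  for (grp in split(hits, list(hits$chrom_i, hits$strand), drop = TRUE)) {
    grp <- grp[order(grp$diag), ]
    band_id <- cumsum(c(1L, diff(grp$diag) > band_tol))
    for (band in split(grp, band_id)) {
      band <- band[order(band$read_pos), ]
      seg_id <- cumsum(c(1L, diff(band$read_pos) > read_gap))
      for (seg in split(band, seg_id)) {
        covered <- kmer_coverage(seg$read_pos, k)
        if (covered < min_covered) next
        rs <- min(seg$read_pos); re <- max(seg$read_pos) + k
        out[[length(out) + 1L]] <- data.frame(
          read_start = rs, read_end = re,
          chrom = index$chrom_names[seg$chrom_i[1]],
          ref_start = as.integer(min(seg$pos)),
          ref_end = as.integer(max(seg$pos) + k),
          strand = seg$strand[1], covered = covered,
          identity = covered / (re - rs), n_kmers = nrow(seg))
      }
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$read_start, res$chrom, res$ref_start), , drop = FALSE]
}

# Greedy x-drop extension of one segment end. Walks outward base by base
# (ungapped; match +1, mismatch -2), keeps the best-scoring offset, stops
# when the running score drops `xdrop` below the best or at a boundary.
# Seed-only segments lose up to tens of bases at their ends under sequencing
# errors; extension pulls the endpoints close to the true alignment
# boundaries, which the cycle detector's endpoint-identity test relies on.
.extend_segments <- function(segs, query, index, xdrop = 12L,
                             max_ext = 200L) {
  if (!nrow(segs)) return(segs)
  n <- nchar(query)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(segs))) {
    chrom_seq <- index$seq[[segs$chrom[i]]]
    clen <- nchar(chrom_seq)
    plus <- segs$strand[i] == "+"
    # each side: walk read position q and the paired genome position
    for (side in c("left", "right")) {
      if (side == "left") {
        q0 <- segs$read_start[i] - 1L
        g0 <- if (plus) segs$ref_start[i] - 1L else segs$ref_end[i]
        stp <- -1L
      } else {
        q0 <- segs$read_end[i]
        g0 <- if (plus) segs$ref_end[i] else segs$ref_start[i] - 1L
        stp <- 1L
      }
      gstp <- if (plus) stp else -stp
      score <- 0; best <- 0; best_len <- 0L
      len <- 0L
      while (len < max_ext) {
        q <- q0 + stp * len
        g <- g0 + gstp * len
        if (q < 0L || q >= n || g < 0L || g >= clen) break
        rb <- substr(query, q + 1L, q + 1L)
        gb <- substr(chrom_seq, g + 1L, g + 1L)
        if (!plus) gb <- comp[[gb]]
        score <- score + if (rb == gb) 1 else -2
        len <- len + 1L
        if (score > best) {
          best <- score
          best_len <- len
        }
        if (score < best - xdrop) break
      }
      if (best_len > 0L) {
        if (side == "left") {
          segs$read_start[i] <- segs$read_start[i] - best_len
          if (plus) segs$ref_start[i] <- segs$ref_start[i] - best_len
          else segs$ref_end[i] <- segs$ref_end[i] + best_len
        } else {
          segs$read_end[i] <- segs$read_end[i] + best_len
          if (plus) segs$ref_end[i] <- segs$ref_end[i] + best_len
          else segs$ref_start[i] <- segs$ref_start[i] - best_len
        }
        segs$covered[i] <- segs$covered[i] + best
      }
    }
    segs$identity[i] <- min(1, segs$covered[i] /
                              (segs$read_end[i] - segs$read_start[i]))
  }
  segs
}

#' Map a sequence against the genome index
#'
#' Seed-and-chain alignment of a query (typically a repeat-unit consensus or
#' a raw read) against the k-mer index. Returns one alignment segment per
#' chained diagonal band, sorted by read coordinate.
#'
#' @param query A single DNA sequence (character).
#' @param index A [kmer_index()].
#' @param params A [caller_params()] supplying the chaining tolerances.
#' @return A data.frame with columns `read_start`, `read_end`, `chrom`,
#'   `ref_start`, `ref_end`, `strand`, `covered`, `identity`, `n_kmers`
#'   (0-based half-open coordinates).
#' @export
map_consensus <- function(query, index, params = caller_params()) {
  stopifnot(inherits(index, "kmer_index"))
  segs <- .build_segments(.seed_hits(query, index), index,
                          band_tol = params$band_tol,
                          read_gap = params$read_gap,
                          min_covered = params$min_covered)
  .extend_segments(segs, query, index)
}

#' Alignment segments of a raw read
#'
#' Identical machinery to [map_consensus()], exported under the name used by
#' the multiple-fragment detector, where every pass of every fragment yields
#' its own segment (passes of one fragment sit on distinct diagonals).
#'
#' @inheritParams map_consensus
#' @param read A single read sequence.
#' @return See [map_consensus()].
#' @export
map_read_segments <- function(read, index, params = caller_params()) {
  map_consensus(read, index, params)
}

#' Does a read originate from the linear genome?
#'
#' A read is a linear/genomic-tandem artifact — and must be excluded from
#' eccDNA calling — when the full raw read aligns collinearly to a single
#' genomic window whose reference span is at least
#' `min_read_aligned_fraction` of the read length: its repeat structure (if
#' any) already exists in the linear genome and needs no circular
#' interpretation. A concatemer of a genuine circle fails this test because
#' any collinear window covers only about one monomer of the read.
#'
#' @inheritParams map_consensus
#' @param read A single read sequence.
#' @return `TRUE` or `FALSE`.
#' @export
is_genomic_tandem <- function(read, index, params = caller_params()) {
  segs <- map_read_segments(read, index, params)
  if (!nrow(segs)) return(FALSE)
  span <- segs$ref_end - segs$ref_start
  ok <- span >= params$min_read_aligned_fraction * nchar(read) &
    segs$covered >= 0.25 * (segs$read_end - segs$read_start)
  any(ok)
}
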