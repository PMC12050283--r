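# Multiple-fragment eccDNA detection: a read whose ordered alignment
# segments repeat with period p traverses a circle made of p genomic
# fragments; Nfragment = p and Nfullpass = number of complete cycles.

#' Order and de-overlap alignment segments of one read
#'
#' Sorts segments by read start and trims read-coordinate overlaps between
#' neighbours at the midpoint of the overlapped stretch (reference
#' coordinates are adjusted strand-consistently). Segments emptied by
#' trimming are dropped.
#'
#' @param segments Alignment-segment data.frame as produced by
#'   [map_read_segments()] (or imported via [read_paf()]).
#' @return The ordered, non-overlapping segment data.frame.
#' @export
order_segments <- function(segments) {
  if (is.null(segments) || !nrow(segments)) return(segments)
  s <- segments[order(segments$read_start, segments$read_end), , drop = FALSE]
  if (nrow(s) >= 2) {
    for (i in 2:nrow(s)) {
      ov <- s$read_end[i - 1] - s$read_start[i]
      if (ov > 0) {
        mid <- (s$read_start[i] + s$read_end[i - 1]) %/% 2
        d_prev <- s$read_end[i - 1] - mid
        d_next <- mid - s$read_start[i]
        s$read_end[i - 1] <- mid
        s$read_start[i] <- mid
        if (s$strand[i - 1] == "+") s$ref_end[i - 1] <- s$ref_end[i - 1] - d_prev
        else s$ref_start[i - 1] <- s$ref_start[i - 1] + d_prev
        if (s$strand[i] == "+") s$ref_start[i] <- s$ref_start[i] + d_next
        else s$ref_end[i] <- s$ref_end[i] - d_next
      }
    }
  }
  s <- s[s$read_end > s$read_start & s$ref_end > s$ref_start, , drop = FALSE]
  rownames(s) <- NULL
  s
}

# Assign identity classes: a segment joins a class when it shares chromosome
# and strand with it and either both reference endpoints agree with the
# class's running median endpoints within coord_tol, or the interval Jaccard
# with the class exceeds 0.5. Median anchors and the Jaccard fallback absorb
# the endpoint jitter and end-truncation that sequencing errors inflict on
# individual segments; distinct fragments of one circle occupy disjoint
# reference intervals, so Jaccard cannot conflate them.
.segment_identities <- function(segs, coord_tol) {
  m <- nrow(segs)
  ids <- integer(m)
  cls <- list()  # per class: chrom, strand, member starts/ends
  for (i in seq_len(m)) {
    hit <- 0L
    best_j <- 0.5
    for (a in seq_along(cls)) {
      cl <- cls[[a]]
      if (segs$chrom[i] != cl$chrom || segs$strand[i] != cl$strand) next
      a_start <- median(cl$starts)
      a_end <- median(cl$ends)
      if (abs(segs$ref_start[i] - a_start) <= coord_tol &&
          abs(segs$ref_end[i] - a_end) <= coord_tol) {
        hit <- a
        break
      }
      olap <- min(segs$ref_end[i], a_end) - max(segs$ref_start[i], a_start)
      union <- max(segs$ref_end[i], a_end) - min(segs$ref_start[i], a_start)
      if (olap > 0 && olap / union > best_j) {
        best_j <- olap / union
        hit <- a
      }
    }
    if (hit == 0L) {
      cls[[length(cls) + 1L]] <- list(chrom = segs$chrom[i],
                                      strand = segs$strand[i],
                                      starts = segs$ref_start[i],
                                      ends = segs$ref_end[i])
      hit <- length(cls)
    } else {
      cls[[hit]]$starts <- c(cls[[hit]]$starts, segs$ref_start[i])
      cls[[hit]]$ends <- c(cls[[hit]]$ends, segs$ref_end[i])
    }
    ids[i] <- hit
  }
  ids
}

#' Detect the fragment cycle of a read
#'
#' Tests the segment identity sequence for the smallest period `p` such that
#' identities repeat with lag `p`; mismatching comparisons are tolerated only
#' when they involve the first or last segment (which may be partial
#' traversals at the read ends). `n_fragment = p`; `n_fullpass` is the number
#' of complete cycles, the trailing partial cycle never counting.
#'
#' @param segments Ordered segments from [order_segments()].
#' @param coord_tol Endpoint tolerance in bp for segment identity
#'   (default 20).
#' @return `NULL` when no repetition is observed, otherwise a list with
#'   `n_fullpass`, `n_fragment`, `cycle` (the `p` segments of one full
#'   cycle) and `ids` (identity classes of all segments).
#' @export
detect_cycle <- function(segments, coord_tol = 20L) {
  if (is.null(segments) || nrow(segments) < 2L) return(NULL)
  m <- nrow(segments)
  ids <- .segment_identities(segments, coord_tol)
  for (p in seq_len(m - 1L)) {
    i <- seq_len(m - p)
    good <- ids[i] == ids[i + p]
    bad <- which(!good)
    if (length(bad) && !all(bad == 1L | bad == (m - p))) next
    if (!any(good)) next
    first_partial <- ids[1L] != ids[1L + p]
    last_partial <- ids[m] != ids[m - p]
    m_eff <- m - as.integer(first_partial) - as.integer(last_partial)
    n_fullpass <- m_eff %/% p
    if (n_fullpass < 1L) next
    start_idx <- if (first_partial) 2L else 1L
    if (start_idx + p - 1L > m) next
    cycle <- segments[start_idx:(start_idx + p - 1L), , drop = FALSE]
    rownames(cycle) <- NULL
    return(list(n_fullpass = n_fullpass, n_fragment = p, cycle = cycle,
                ids = ids))
  }
  NULL
}

#' Classify a read by its pass and fragment counts
#'
#' The published filters set both `Nfullpass` and `Nfragment` to 1, read as
#' minimum thresholds; reads meeting them are single-fragment when
#' `Nfragment = 1` and multiple-fragment when `Nfragment >= 2`.
#'
#' @param n_fullpass,n_fragment Values from [detect_cycle()].
#' @param min_fullpass,min_fragment Minimum thresholds (default 1).
#' @return `"rejected"`, `"single"` or `"multi"`.
#' @export
classify_read <- function(n_fullpass, n_fragment, min_fullpass = 1L,
                          min_fragment = 1L) {
  if (is.null(n_fullpass) || is.null(n_fragment) ||
      n_fullpass < min_fullpass || n_fragment < min_fragment)
    return("rejected")
  if (n_fragment == 1L) "single" else "multi"
}

#' Core gene of a multiple-fragment eccDNA
#'
#' The gene with the largest summed base-pair overlap across all cycle
#' fragments; ties break to the gene with the smaller `(chrom, start)`.
#'
#' @param cycle Fragment data.frame (`chrom`, `start`, `end`) of one cycle.
#' @param genes Gene-model data.frame (`gene_id`, `chrom`, `start`, `end`).
#' @return The winning `gene_id`, or `NA` when no gene overlaps.
#' @export
assign_core_gene <- function(cycle, genes) {
  if (is.null(genes) || !nrow(genes) || is.null(cycle) || !nrow(cycle))
    return(NA_character_)
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L,
                                                  genes$end))
  gr_f <- GenomicRanges::GRanges(cycle$chrom,
                                 IRanges::IRanges(cycle$start + 1L,
                                                  cycle$end))
  hits <- GenomicRanges::findOverlaps(gr_f, gr_g)
  if (!length(hits)) return(NA_character_)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_f)[S4Vectors::queryHits(hits)],
    IRanges::ranges(gr_g)[S4Vectors::subjectHits(hits)]))
  tot <- tapply(ov, S4Vectors::subjectHits(hits), sum)
  gi <- as.integer(names(tot))
  best <- tot == max(tot)
  cand <- gi[best]
  ord <- order(genes$chrom[cand], genes$start[cand])
  genes$gene_id[cand[ord[1]]]
}

# Every inter-fragment genomic gap contains at least one LTR-superfamily TE,
# all of a single subfamily — the flag motivating an LTR homologous
# recombination origin for two-fragment circles.
.ltr_flanked <- function(cycle, tracks,
                         ltr_superfamilies = c("Gypsy", "Copia")) {
  if (is.null(tracks) || !nrow(cycle)) return(NA)
  cyc <- cycle[order(cycle$chrom, cycle$start), , drop = FALSE]
  if (length(unique(cyc$chrom)) != 1L || nrow(cyc) < 2L) return(FALSE)
  ltr <- tracks[tracks$kind == "TE" &
                  tracks$superfamily %in% ltr_superfamilies, , drop = FALSE]
  subfams <- character(0)
  for (i in seq_len(nrow(cyc) - 1L)) {
    gap_s <- cyc$end[i]
    gap_e <- cyc$start[i + 1L]
    if (gap_e <= gap_s) return(FALSE)
    inside <- ltr$chrom == cyc$chrom[1] & ltr$start >= gap_s &
      ltr$end <= gap_e
    if (!any(inside)) return(FALSE)
    subfams <- c(subfams, ltr$subfamily[inside])
  }
  length(unique(subfams)) == 1L
}

#' Group multiple-fragment eccDNA reads by core gene
#'
#' One row per `(core_gene_id, n_fragment)` with the member read count,
#' sorted by descending read count — the redundancy-reduction grouping of
#' MF-eccDNA reads.
#'
#' @param mf_reads Data.frame of classified reads with columns
#'   `core_gene_id`, `n_fragment` (and optionally `ltr_flanked`).
#' @param sample_id Sample label.
#' @return Data.frame `core_gene_id`, `n_fragment`, `read_count`,
#'   `sample_id` (plus `ltr_flanked` when available: `TRUE` iff every member
#'   read is flagged).
#' @export
group_mf <- function(mf_reads, sample_id = "S1") {
  empty <- data.frame(core_gene_id = character(0), n_fragment = integer(0),
                      read_count = integer(0), sample_id = character(0))
  if (is.null(mf_reads) || !nrow(mf_reads)) return(empty)
  key <- paste(mf_reads$core_gene_id, mf_reads$n_fragment, sep = "\r")
  rows <- lapply(split(seq_len(nrow(mf_reads)), key), function(ii) {
    out <- data.frame(core_gene_id = mf_reads$core_gene_id[ii[1]],
                      n_fragment = mf_reads$n_fragment[ii[1]],
                      read_count = length(ii), sample_id = sample_id)
    if ("ltr_flanked" %in% names(mf_reads))
      out$ltr_flanked <- all(mf_reads$ltr_flanked[ii] %in% TRUE)
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$read_count, tab$core_gene_id, tab$n_fragment), ,
             drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Detect and group multiple-fragment eccDNA reads
#'
#' Maps each read, orders its segments, detects the fragment cycle,
#' classifies the read (rejected / single / multi), assigns core genes to
#' multi reads and groups them by `(core gene, Nfragment)`.
#'
#' @param reads Named character vector of read sequences.
#' @param genome An `ecc_genome`, named sequence vector, or [kmer_index()].
#' @param genes Optional gene-model data.frame for core-gene assignment.
#' @param tracks Optional annotation-track data.frame for the `ltr_flanked`
#'   flag.
#' @param params A [caller_params()].
#' @param sample_id Sample label.
#' @param min_fullpass,min_fragment Classification thresholds (default 1).
#' @return An object of class `mf_calls`: list with `reads` (per-read
#'   data.frame: `read_id`, `class`, `n_fullpass`, `n_fragment`,
#'   `core_gene_id`, `total_monomer_length`, `ltr_flanked`), `cycles` (named
#'   list of cycle fragment data.frames for multi reads) and `groups` (from
#'   [group_mf()]).
#' @export
mf_detect <- function(reads, genome, genes = NULL, tracks = NULL,
                      params = caller_params(), sample_id = "S1",
                      min_fullpass = 1L, min_fragment = 1L) {
  index <- if (inherits(genome, "kmer_index")) genome else
    kmer_index(genome, params$kmer_size)
  n <- length(reads)
  ids <- if (is.null(names(reads))) sprintf("read_%05d", seq_len(n)) else
    names(reads)
  out <- data.frame(read_id = ids, class = "rejected",
                    n_fullpass = NA_integer_, n_fragment = NA_integer_,
                    core_gene_id = NA_character_,
                    total_monomer_length = NA_integer_, ltr_flanked = NA,
                    stringsAsFactors = FALSE)
  cycles <- list()
  for (i in seq_len(n)) {
    segs <- order_segments(map_read_segments(reads[[i]], index, params))
    cyc <- detect_cycle(segs, params$coord_tol)
    if (is.null(cyc)) next
    fragments <- data.frame(chrom = cyc$cycle$chrom,
                            start = cyc$cycle$ref_start,
                            end = cyc$cycle$ref_end,
                            strand = cyc$cycle$strand)
    out$n_fullpass[i] <- cyc$n_fullpass
    out$n_fragment[i] <- cyc$n_fragment
    out$total_monomer_length[i] <- sum(fragments$end - fragments$start)
    out$class[i] <- classify_read(cyc$n_fullpass, cyc$n_fragment,
                                  min_fullpass, min_fragment)
    if (out$class[i] == "multi") {
      cycles[[ids[i]]] <- fragments
      if (!is.null(genes))
        out$core_gene_id[i] <- assign_core_gene(fragments, genes)
      if (!is.null(tracks))
        out$ltr_flanked[i] <- .ltr_flanked(fragments, tracks)
    }
  }
  groups <- group_mf(out[out$class == "multi", , drop = FALSE], sample_id)
  structure(list(reads = out, cycles = cycles, groups = groups,
                 sample_id = sample_id),
            class = "mf_calls")
}

#' @export
print.mf_calls <- function(x, ...) {
  tab <- table(x$reads$class)
  cat(sprintf("MF detection for sample %s over %d reads:\n", x$sample_id,
              nrow(x$reads)))
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}
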