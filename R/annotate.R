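# Genomic-feature classification of unified eccDNA regions: gene /
# up2kb / down2kb / intergenic location (mutually exclusive, priority
# ordered), UTR/CDS composition, ecTE / ecNon-codingRNA / NUMT / NUPT
# overlaps (non-exclusive labels), and full-length repeat-unit containment.
# Interval arithmetic is half-open; an overlap of length 0 is never a hit.

.regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

# Best subject per query by largest intersection width; ties to the subject
# with smaller (chrom, start).
.best_overlap <- function(gr_q, gr_s, ord_chrom, ord_start,
                          min_overlap_bp = 1L) {
  hits <- GenomicRanges::findOverlaps(gr_q, gr_s,
                                      minoverlap = min_overlap_bp)
  if (!length(hits)) return(integer(0))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_q)[q], IRanges::ranges(gr_s)[s]))
  best <- integer(0)
  for (qi in unique(q)) {
    sel <- which(q == qi)
    mx <- sel[w[sel] == max(w[sel])]
    cand <- s[mx]
    o <- order(ord_chrom[cand], ord_start[cand])
    best[as.character(qi)] <- cand[o[1]]
  }
  best
}

#' Locate eccDNA regions relative to gene models
#'
#' Mutually exclusive classification with priority
#' `gene > up2kb > down2kb > intergenic`: any overlap (at least 1 bp) with a
#' gene body wins; otherwise overlap with the 2 kb window upstream of a
#' transcription start (strand-aware by default), then downstream, then
#' intergenic. The reported `gene_id` is the gene with the largest overlap
#' at the winning level, ties to the smaller `(chrom, start)`.
#'
#' @param regions Data.frame with `unified_id`, `chrom`, `start`, `end`
#'   (0-based half-open), e.g. the `regions` element of an `ecc_catalog`.
#' @param genes Gene-model data.frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`).
#' @param flank Flank width in bp (default 2000).
#' @param stranded Use gene orientation for upstream/downstream (default
#'   `TRUE`); when `FALSE` upstream means lower coordinates.
#' @return Data.frame `unified_id`, `location`, `gene_id`.
#' @export
classify_location <- function(regions, genes, flank = 2000L,
                              stranded = TRUE) {
  out <- data.frame(unified_id = regions$unified_id,
                    location = rep("intergenic", nrow(regions)),
                    gene_id = NA_character_, stringsAsFactors = FALSE)
  if (!nrow(regions) || is.null(genes) || !nrow(genes)) return(out)
  gr_r <- .regions_gr(regions)
  strand <- if (stranded) genes$strand else rep("+", nrow(genes))
  up <- ifelse(strand == "+",
               paste(pmax(0L, genes$start - flank), genes$start),
               paste(genes$end, genes$end + flank))
  dn <- ifelse(strand == "+",
               paste(genes$end, genes$end + flank),
               paste(pmax(0L, genes$start - flank), genes$start))
  parse2 <- function(x) {
    m <- do.call(rbind, strsplit(x, " ", fixed = TRUE))
    data.frame(start = as.integer(m[, 1]), end = as.integer(m[, 2]))
  }
  lvls <- list(
    gene = data.frame(start = genes$start, end = genes$end),
    up2kb = parse2(up),
    down2kb = parse2(dn))
  unassigned <- seq_len(nrow(regions))
  for (lev in names(lvls)) {
    if (!length(unassigned)) break
    iv <- lvls[[lev]]
    keep <- iv$end > iv$start
    if (!any(keep)) next
    gr_s <- GenomicRanges::GRanges(genes$chrom[keep],
                                   IRanges::IRanges(iv$start[keep] + 1L,
                                                    iv$end[keep]))
    gidx <- which(keep)
    best <- .best_overlap(gr_r[unassigned], gr_s, genes$chrom[gidx],
                          genes$start[gidx])
    if (length(best)) {
      qi <- unassigned[as.integer(names(best))]
      out$location[qi] <- lev
      out$gene_id[qi] <- genes$gene_id[gidx[best]]
      unassigned <- setdiff(unassigned, qi)
    }
  }
  out
}

#' UTR/CDS composition of gene-overlapping eccDNA regions
#'
#' For every region located in a gene, reports which gene parts (5'UTR, CDS,
#' 3'UTR) the region overlaps by at least 1 bp, and whether the region fully
#' contains the gene span (`full_length_gene`). A gene without annotated
#' parts is treated as CDS over its whole body.
#'
#' @param regions Region data.frame (`unified_id`, `chrom`, `start`, `end`).
#' @param location Result of [classify_location()] on the same regions.
#' @param genes,gene_parts Gene models and their part intervals (from
#'   [generate_genome()] or [read_genes_gff3()]).
#' @return Data.frame `unified_id`, `gene_id`, `parts` (e.g. `"5UTR+CDS"`),
#'   `full_length_gene`.
#' @export
classify_gene_parts <- function(regions, location, genes, gene_parts) {
  sel <- which(location$location == "gene")
  out <- data.frame(unified_id = character(0), gene_id = character(0),
                    parts = character(0), full_length_gene = logical(0))
  if (!length(sel)) return(out)
  part_order <- c("5UTR", "CDS", "3UTR")
  rows <- lapply(sel, function(i) {
    gid <- location$gene_id[i]
    g <- genes[genes$gene_id == gid, ]
    pp <- gene_parts[gene_parts$gene_id == gid, , drop = FALSE]
    if (!nrow(pp))
      pp <- data.frame(gene_id = gid, part = "CDS", start = g$start,
                       end = g$end)
    rs <- regions$start[i]; re <- regions$end[i]
    hit <- pmin(pp$end, re) - pmax(pp$start, rs) > 0
    parts <- intersect(part_order, pp$part[hit])
    data.frame(unified_id = regions$unified_id[i], gene_id = gid,
               parts = paste(parts, collapse = "+"),
               full_length_gene = rs <= g$start && g$end <= re)
  })
  do.call(rbind, rows)
}

#' Overlap eccDNA regions with an annotation track
#'
#' One record per `(region, feature)` pair whose intersection is at least
#' `min_overlap_bp` (default 1 bp). Used identically for TE, ncRNA, NUMT and
#' NUPT tracks; labels are non-exclusive, so one region may be an ecGene and
#' an ecTE simultaneously.
#'
#' @param regions Region data.frame (`unified_id`, `chrom`, `start`, `end`).
#' @param track Track data.frame (`feature_id`, `kind`, `chrom`, `start`,
#'   `end`, `class1`, `superfamily`, `subfamily`).
#' @param min_overlap_bp Minimum intersection in bp.
#' @return Data.frame `unified_id`, `feature_id`, `kind`, `class1`,
#'   `superfamily`, `subfamily`, `overlap_bp`.
#' @export
overlap_track <- function(regions, track, min_overlap_bp = 1L) {
  empty <- data.frame(unified_id = character(0), feature_id = character(0),
                      kind = character(0), class1 = character(0),
                      superfamily = character(0), subfamily = character(0),
                      overlap_bp = integer(0))
  if (!nrow(regions) || is.null(track) || !nrow(track)) return(empty)
  gr_r <- .regions_gr(regions)
  gr_t <- .regions_gr(track)
  hits <- GenomicRanges::findOverlaps(gr_r, gr_t,
                                      minoverlap = min_overlap_bp)
  if (!length(hits)) return(empty)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  w <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(gr_r)[q], IRanges::ranges(gr_t)[s]))
  data.frame(unified_id = regions$unified_id[q],
             feature_id = track$feature_id[s], kind = track$kind[s],
             class1 = track$class1[s], superfamily = track$superfamily[s],
             subfamily = track$subfamily[s], overlap_bp = as.integer(w))
}

#' Full-length repeat units contained in eccDNA regions
#'
#' A record is emitted when a repeat-unit interval is fully contained in the
#' eccDNA region (containment inclusive at both boundaries): these are the
#' full-length ecRepeatUnits.
#'
#' @param regions Region data.frame (`unified_id`, `chrom`, `start`, `end`).
#' @param repeat_track Track data.frame of repeat units.
#' @return Data.frame `unified_id`, `repeat_unit_id`, `family`, `subfamily`.
#' @export
full_length_repeat_units <- function(regions, repeat_track) {
  empty <- data.frame(unified_id = character(0),
                      repeat_unit_id = character(0), family = character(0),
                      subfamily = character(0))
  if (!nrow(regions) || is.null(repeat_track) || !nrow(repeat_track))
    return(empty)
  hits <- GenomicRanges::findOverlaps(.regions_gr(repeat_track),
                                      .regions_gr(regions), type = "within")
  if (!length(hits)) return(empty)
  f <- S4Vectors::queryHits(hits)
  r <- S4Vectors::subjectHits(hits)
  data.frame(unified_id = regions$unified_id[r],
             repeat_unit_id = repeat_track$feature_id[f],
             family = repeat_track$superfamily[f],
             subfamily = repeat_track$subfamily[f])
}

#' Summarize a catalog's annotation
#'
#' Location percentages over all unified IDs (the four classes partition the
#' catalog and sum to 100%), gene-part composition percentages, ecTE class
#' (DNA transposon vs retrotransposon) and superfamily ratios — per sample
#' when the TE records carry a `sample_id` column — and full-length counts.
#'
#' @param location [classify_location()] output.
#' @param parts Optional [classify_gene_parts()] output.
#' @param te_records Optional [overlap_track()] output for the TE track.
#' @param full_length Optional [full_length_repeat_units()] output.
#' @return An object of class `ecc_annotation_summary`.
#' @export
summarize_annotation <- function(location, parts = NULL, te_records = NULL,
                                 full_length = NULL) {
  n <- nrow(location)
  loc_levels <- c("gene", "up2kb", "down2kb", "intergenic")
  loc_pct <- if (n) 100 * table(factor(location$location, loc_levels)) / n
    else table(factor(character(0), loc_levels))
  loc_pct <- setNames(as.numeric(loc_pct), loc_levels)
  parts_pct <- NULL
  if (!is.null(parts) && nrow(parts)) {
    tt <- table(parts$parts)
    parts_pct <- setNames(100 * as.numeric(tt) / sum(tt), names(tt))
  }
  ratio_tab <- function(v) {
    tt <- table(v, useNA = "no")
    if (!sum(tt)) return(NULL)
    setNames(as.numeric(tt) / sum(tt), names(tt))
  }
  class1_ratio <- superfamily_ratio <- NULL
  if (!is.null(te_records) && nrow(te_records)) {
    if ("sample_id" %in% names(te_records)) {
      class1_ratio <- lapply(split(te_records$class1,
                                   te_records$sample_id), ratio_tab)
      superfamily_ratio <- lapply(split(te_records$superfamily,
                                        te_records$sample_id), ratio_tab)
    } else {
      class1_ratio <- ratio_tab(te_records$class1)
      superfamily_ratio <- ratio_tab(te_records$superfamily)
    }
  }
  structure(list(
    n_regions = n, location_pct = loc_pct, parts_pct = parts_pct,
    class1_ratio = class1_ratio, superfamily_ratio = superfamily_ratio,
    n_full_length_genes = if (is.null(parts)) 0L else
      sum(parts$full_length_gene),
    n_full_length_repeat_units = if (is.null(full_length)) 0L else
      nrow(full_length)),
    class = "ecc_annotation_summary")
}

#' @export
print.ecc_annotation_summary <- function(x, ...) {
  cat(sprintf("Annotation summary over %d unified region(s)\n", x$n_regions))
  if (x$n_regions) {
    cat("  location %:",
        paste(sprintf("%s %.1f", names(x$location_pct), x$location_pct),
              collapse = ", "), "\n")
  }
  cat(sprintf("  full-length genes: %d, full-length repeat units: %d\n",
              x$n_full_length_genes, x$n_full_length_repeat_units))
  invisible(x)
}
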