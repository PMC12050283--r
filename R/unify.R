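# Cross-sample identity unification: loci from all samples that overlap by
# more than a threshold receive one unified ID (connected components of the
# pairwise-overlap graph); original locus coordinates are never altered.

#' Unify eccDNA locus IDs across samples
#'
#' Builds a graph over all loci of all samples (including within-sample
#' pairs) with an edge whenever two loci on the same chromosome overlap by
#' strictly more than `min_overlap_bp` (the published rule: "overlaps of
#' more than 200 bp"), and assigns one unified ID per connected component.
#' Transitive (single-linkage) merging follows from "same ID" being an
#' equivalence relation; strand is ignored. IDs are `ecc_000001, ...` in
#' `(chrom, min start)` order.
#'
#' @param sets A list of per-sample locus data.frames (columns `sample_id`,
#'   `locus_id`, `chrom`, `start`, `end` and optionally `n_reads`), e.g. the
#'   `loci` element of [ecc_call()] results.
#' @param min_overlap_bp Strict overlap threshold in bp (default 200).
#' @return An object of class `ecc_catalog`: list with `id_map` (one row per
#'   input locus: `sample_id`, `locus_id`, `chrom`, `start`, `end`,
#'   `n_reads`, `unified_id`), `regions` (one row per unified ID: `chrom`,
#'   `start` = member minimum, `end` = member maximum, `n_members`) and
#'   `min_overlap_bp`.
#' @export
unify_ids <- function(sets, min_overlap_bp = 200L) {
  if (inherits(sets, "data.frame")) sets <- list(sets)
  if (!length(sets)) stop("need at least one sample locus set")
  sets <- lapply(sets, function(s) {
    if (inherits(s, "ecc_calls")) s <- s$loci
    if (anyDuplicated(s$locus_id))
      stop(sprintf("duplicate locus_id within sample %s",
                   s$sample_id[1]))
    if (!"n_reads" %in% names(s)) s$n_reads <- NA_integer_
    s[, c("sample_id", "locus_id", "chrom", "start", "end", "n_reads")]
  })
  all <- do.call(rbind, sets)
  rownames(all) <- NULL
  n <- nrow(all)
  if (!n) {
    return(structure(list(
      id_map = cbind(all, unified_id = character(0)),
      regions = data.frame(unified_id = character(0), chrom = character(0),
                           start = integer(0), end = integer(0),
                           n_members = integer(0)),
      min_overlap_bp = min_overlap_bp), class = "ecc_catalog"))
  }
  ord <- order(all$chrom, all$start, all$end)
  parent <- uf_new(n)
  for (chrom in unique(all$chrom)) {
    idx <- ord[all$chrom[ord] == chrom]
    active <- integer(0)
    for (i in idx) {
      # a previous locus j can only still link to i (or any later locus)
      # if end_j - start_i > min_overlap_bp
      active <- active[all$end[active] - all$start[i] > min_overlap_bp]
      for (j in active) {
        olap <- min(all$end[i], all$end[j]) - max(all$start[i], all$start[j])
        if (olap > min_overlap_bp &&
            uf_find(parent, i) != uf_find(parent, j))
          parent <- uf_union(parent, j, i)
      }
      active <- c(active, i)
    }
  }
  comp <- uf_components(parent)
  reg <- lapply(split(seq_len(n), comp), function(ii) {
    data.frame(chrom = all$chrom[ii[1]], start = min(all$start[ii]),
               end = max(all$end[ii]), n_members = length(ii),
               members = I(list(ii)))
  })
  reg <- do.call(rbind, reg)
  reg <- reg[order(reg$chrom, reg$start, reg$end), , drop = FALSE]
  reg$unified_id <- sprintf("ecc_%06d", seq_len(nrow(reg)))
  uid <- character(n)
  for (r in seq_len(nrow(reg))) uid[reg$members[[r]]] <- reg$unified_id[r]
  all$unified_id <- uid
  regions <- data.frame(unified_id = reg$unified_id, chrom = reg$chrom,
                        start = reg$start, end = reg$end,
                        n_members = reg$n_members)
  rownames(regions) <- NULL
  structure(list(id_map = all, regions = regions,
                 min_overlap_bp = min_overlap_bp),
            class = "ecc_catalog")
}

#' @export
print.ecc_catalog <- function(x, ...) {
  cat(sprintf(
    "Unified eccDNA catalog: %d loci from %d sample(s) -> %d unified IDs (overlap > %d bp)\n",
    nrow(x$id_map), length(unique(x$id_map$sample_id)), nrow(x$regions),
    x$min_overlap_bp))
  invisible(x)
}

#' Read-count matrix of a unified catalog
#'
#' Entry `(unified_id, sample)` is the sum of supporting-read counts over
#' that sample's member loci; a unified ID absent from a sample contributes
#' zero.
#'
#' @param catalog An [unify_ids()] result.
#' @param support Optional data.frame (`sample_id`, `locus_id`, `n_reads`)
#'   overriding the read counts carried in the catalog.
#' @return Integer matrix, unified IDs x samples.
#' @export
catalog_counts <- function(catalog, support = NULL) {
  stopifnot(inherits(catalog, "ecc_catalog"))
  m <- catalog$id_map
  if (!is.null(support)) {
    key <- paste(m$sample_id, m$locus_id)
    skey <- paste(support$sample_id, support$locus_id)
    m$n_reads <- support$n_reads[match(key, skey)]
  }
  if (anyNA(m$n_reads))
    stop("missing per-locus read support; supply `support`")
  samples <- sort(unique(m$sample_id))
  counts <- matrix(0L, nrow(catalog$regions), length(samples),
                   dimnames = list(catalog$regions$unified_id, samples))
  for (r in seq_len(nrow(m))) {
    counts[m$unified_id[r], m$sample_id[r]] <-
      counts[m$unified_id[r], m$sample_id[r]] + m$n_reads[r]
  }
  counts
}
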