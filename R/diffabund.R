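# Differential feature analysis on zero-inflated count matrices: GMPR size
# factors (geometric mean of pairwise ratios, robust to excess zeros),
# exact-ECDF earth-mover's-distance scores, pooled permutation p-values with
# Benjamini-Hochberg q-values, and exclusive/differential classification.

#' GMPR size factors for a zero-inflated count matrix
#'
#' For samples i, j the pairwise ratio `r_ij` is the median of count ratios
#' over the features where both samples are non-zero; the size factor of
#' sample i is the geometric mean of its pairwise ratios over the samples it
#' shares features with, the self-ratio of 1 included (which makes the
#' factor exactly proportional to depth on noiseless proportional data),
#' finally rescaled so the size factors have geometric mean 1. Normalized counts are `counts / s_i` per sample.
#'
#' @param counts Non-negative integer matrix, features x samples.
#' @return An object of class `gmpr_factors`: list with `s` (named positive
#'   numeric vector) and `n_shared` (matrix of pairwise shared non-zero
#'   feature counts).
#' @export
gmpr_size_factors <- function(counts) {
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("S%d", seq_len(ncol(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  p <- ncol(counts)
  if (p < 2) stop("need at least two samples")
  n_shared <- matrix(0L, p, p, dimnames = list(colnames(counts),
                                               colnames(counts)))
  r <- matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      shared <- counts[, i] > 0 & counts[, j] > 0
      n_shared[i, j] <- sum(shared)
      if (any(shared))
        r[i, j] <- median(counts[shared, i] / counts[shared, j])
    }
  }
  s <- numeric(p)
  for (i in seq_len(p)) {
    ri <- r[i, ][!is.na(r[i, ])]
    if (!length(ri))
      stop(sprintf(
        "sample '%s' shares no non-zero feature with any other sample",
        colnames(counts)[i]))
    # the self-ratio r_ii = 1 enters the geometric mean: on noiseless
    # proportional data this makes s_i exactly proportional to depth
    s[i] <- exp(mean(log(c(1, ri))))
  }
  s <- s / exp(mean(log(s)))
  structure(list(s = setNames(s, colnames(counts)), n_shared = n_shared),
            class = "gmpr_factors")
}

#' @export
print.gmpr_factors <- function(x, ...) {
  cat("GMPR size factors:\n")
  print(round(x$s, 4))
  invisible(x)
}

#' One-dimensional earth-mover's distance between two samples
#'
#' The integral over the value axis of the absolute difference between the
#' two empirical CDFs — the exact (unbinned) 1-D optimal-transport cost. For
#' equal group sizes it equals the mean absolute difference between sorted
#' values. Symmetric and scale-covariant.
#'
#' @param a,b Non-empty numeric vectors.
#' @return Non-negative scalar.
#' @export
emd_score <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  grid <- sort(unique(c(a, b)))
  if (length(grid) == 1L) return(0)
  fa <- ecdf(a)(grid)
  fb <- ecdf(b)(grid)
  ng <- length(grid)
  sum(abs(fa[-ng] - fb[-ng]) * diff(grid))
}

# All distinct unordered splits of the samples into the two given group
# sizes, as a list of logical vectors marking "group A". The observed
# labelling is one of them.
.all_splits <- function(n, nA) {
  combs <- utils::combn(n, nA)
  keep <- rep(TRUE, ncol(combs))
  if (2 * nA == n) keep <- combs[1, ] == 1  # unordered halves: fix sample 1
  lapply(which(keep), function(j) seq_len(n) %in% combs[, j])
}

#' EMD permutation test on a normalized count matrix
#'
#' Per feature, the observed EMD between the two groups is computed on
#' GMPR-normalized counts. The null distribution is built from label
#' permutations — all distinct unordered splits when fewer than `n_perm`
#' exist (a 2v2 design has 3, of which the 2 non-observed enter the null),
#' otherwise `n_perm` sampled relabellings — pooled across all features to
#' gain resolution in small designs; the observed labelling itself is
#' excluded from the pool so that small designs retain usable resolution
#' after multiplicity adjustment. The
#' p-value uses the add-one estimator `(1 + #null >= observed) /
#' (1 + #null)`; q-values are Benjamini-Hochberg.
#'
#' @param counts Raw count matrix, features x samples.
#' @param groups Named character vector mapping sample to one of two group
#'   labels (names must match `colnames(counts)`).
#' @param size_factors Optional [gmpr_size_factors()] result (computed from
#'   `counts` when `NULL`).
#' @param n_perm Maximum number of permutations.
#' @param seed Optional seed (used only when permutations are sampled).
#' @return Data.frame `unified_id`, `emd`, `p`, `q`.
#' @export
emd_permutation_test <- function(counts, groups, size_factors = NULL,
                                 n_perm = 1000L, seed = NULL) {
  groups <- groups[colnames(counts)]
  lv <- unique(unname(groups))
  if (length(lv) != 2) stop("exactly two groups are required")
  if (is.null(size_factors)) size_factors <- gmpr_size_factors(counts)
  norm <- sweep(counts, 2L, size_factors$s[colnames(counts)], "/")
  n <- ncol(norm)
  nA <- sum(groups == lv[1])
  splits <- .all_splits(n, nA)
  if (length(splits) < 2) stop("degenerate design: fewer than 2 distinct label splits")
  obs_mask <- unname(groups == lv[1])
  # the observed labelling is excluded from the null pool: with very few
  # distinct splits (3 in a 2v2 design) its inclusion would put a hard floor
  # of ~1/3 on every BH-adjusted q-value
  is_obs <- vapply(splits, function(m)
    identical(m, obs_mask) || identical(m, !obs_mask), TRUE)
  null_splits <- splits[!is_obs]
  if (!length(null_splits)) stop("degenerate design: no non-observed split")
  masks <- if (length(null_splits) <= n_perm) null_splits else
    with_seed(seed, null_splits[sample.int(length(null_splits), n_perm)])
  nf <- nrow(norm)
  emd_mat <- matrix(0, nf, length(masks))
  for (m in seq_along(masks)) {
    ma <- masks[[m]]
    for (f in seq_len(nf))
      emd_mat[f, m] <- emd_score(norm[f, ma], norm[f, !ma])
  }
  obs <- vapply(seq_len(nf), function(f)
    emd_score(norm[f, obs_mask], norm[f, !obs_mask]), numeric(1))
  null_pool <- sort(as.numeric(emd_mat))
  n_null <- length(null_pool)
  # #null >= obs via binary search on the sorted pool
  ge <- n_null - findInterval(obs - 1e-12, null_pool)
  p <- (1 + ge) / (1 + n_null)
  data.frame(unified_id = if (is.null(rownames(counts)))
    sprintf("feat_%05d", seq_len(nf)) else rownames(counts),
    emd = obs, p = p, q = p.adjust(p, "BH"))
}

#' Classify features as exclusive, differential or not significant
#'
#' Features with `q >= q_threshold` are `not_significant`. Significant
#' features present (raw count > 0) in every replicate of one group and
#' absent (zero) from every replicate of the other are `exclusive_<group>`;
#' the remaining significant features are `differential_<group>_up`, the
#' direction being the group with the higher mean normalized count.
#' Presence/absence is judged on raw counts because it is depth-robust;
#' direction uses normalized means.
#'
#' @param counts Raw count matrix.
#' @param groups Named group-label vector as in [emd_permutation_test()].
#' @param emd_results Data.frame from [emd_permutation_test()] over the same
#'   features.
#' @param size_factors Optional [gmpr_size_factors()]; recomputed when
#'   `NULL`.
#' @param q_threshold Significance gate (default 0.05).
#' @return `emd_results` with an added `class_label` column.
#' @export
classify_features <- function(counts, groups, emd_results,
                              size_factors = NULL, q_threshold = 0.05) {
  groups <- groups[colnames(counts)]
  lv <- sort(unique(unname(groups)))
  if (is.null(size_factors)) size_factors <- gmpr_size_factors(counts)
  norm <- sweep(counts, 2L, size_factors$s[colnames(counts)], "/")
  a_cols <- groups == lv[1]
  lab <- rep("not_significant", nrow(counts))
  sig <- emd_results$q < q_threshold & emd_results$emd > 0
  presA <- rowSums(counts[, a_cols, drop = FALSE] > 0) == sum(a_cols)
  absA <- rowSums(counts[, a_cols, drop = FALSE]) == 0
  presB <- rowSums(counts[, !a_cols, drop = FALSE] > 0) == sum(!a_cols)
  absB <- rowSums(counts[, !a_cols, drop = FALSE]) == 0
  up_a <- rowMeans(norm[, a_cols, drop = FALSE]) >
    rowMeans(norm[, !a_cols, drop = FALSE])
  lab[sig & presA & absB] <- paste0("exclusive_", lv[1])
  lab[sig & presB & absA] <- paste0("exclusive_", lv[2])
  rest <- sig & !(presA & absB) & !(presB & absA)
  lab[rest & up_a] <- paste0("differential_", lv[1], "_up")
  lab[rest & !up_a] <- paste0("differential_", lv[2], "_up")
  out <- emd_results
  out$class_label <- lab
  out
}

#' Differential eccDNA feature analysis
#'
#' Convenience wrapper chaining [gmpr_size_factors()],
#' [emd_permutation_test()] and [classify_features()].
#'
#' @inheritParams emd_permutation_test
#' @param q_threshold Significance gate (default 0.05).
#' @return An object of class `ecc_diff`: the classified result data.frame
#'   with the size factors in `attr(, "size_factors")`.
#' @export
ecc_diff <- function(counts, groups, n_perm = 1000L, q_threshold = 0.05,
                     seed = NULL) {
  sf <- gmpr_size_factors(counts)
  res <- emd_permutation_test(counts, groups, sf, n_perm = n_perm,
                              seed = seed)
  res <- classify_features(counts, groups, res, sf,
                           q_threshold = q_threshold)
  attr(res, "size_factors") <- sf
  class(res) <- c("ecc_diff", class(res))
  res
}

#' @export
print.ecc_diff <- function(x, ...) {
  tab <- table(x$class_label)
  cat(sprintf("EMD differential analysis over %d features:\n", nrow(x)))
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}
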