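# Shared low-level helpers. Coordinates are 0-based half-open everywhere
# inside the package; conversion to 1-based closed happens only at the
# GFF3/GRanges boundary.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @param gc_fraction GC content.
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc_fraction = 0.44) {
  at <- (1 - gc_fraction) / 2
  gc <- gc_fraction / 2
  paste(sample(DNA_BASES, n, replace = TRUE, prob = c(at, gc, gc, at)),
        collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# All k-mers of a string, in order; character(0) when too short.
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1), k:n)
}

# Total bases covered by the union of intervals [p, p + k) for 0-based
# positions `pos`.
kmer_coverage <- function(pos, k) {
  if (!length(pos)) return(0L)
  pos <- sort(unique(pos))
  if (length(pos) == 1L) return(as.integer(k))
  as.integer(sum(pmin(diff(pos), k)) + k)
}

# Lower median: for even n returns the lower of the two central order
# statistics, keeping locus endpoints on observed coordinates.
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# Apply per-base substitution/insertion/deletion errors; returns the mutated
# sequence plus per-class event counts for the truth table.
mutate_seq <- function(s, sub_rate = 0, ins_rate = 0, del_rate = 0) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) {
    return(list(seq = s, n_sub = 0L, n_ins = 0L, n_del = 0L))
  }
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(x)
  n_sub <- n_ins <- n_del <- 0L
  if (sub_rate > 0) {
    hit <- which(runif(n) < sub_rate)
    if (length(hit)) {
      shift <- sample.int(3L, length(hit), replace = TRUE)
      x[hit] <- DNA_BASES[((match(x[hit], DNA_BASES) - 1L + shift) %% 4L) + 1L]
      n_sub <- length(hit)
    }
  }
  keep <- rep(TRUE, n)
  if (del_rate > 0) {
    d <- runif(n) < del_rate
    keep[d] <- FALSE
    n_del <- sum(d)
  }
  ins_after <- character(n)
  if (ins_rate > 0) {
    i <- which(runif(n) < ins_rate)
    if (length(i)) {
      ins_after[i] <- sample(DNA_BASES, length(i), replace = TRUE)
      n_ins <- length(i)
    }
  }
  out <- paste0(ifelse(keep, x, ""), ins_after, collapse = "")
  list(seq = out, n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}

# Minimal union-find over 1..n with path compression.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

uf_components <- function(parent) {
  vapply(seq_along(parent), function(i) uf_find(parent, i), integer(1))
}

stop_if_not_scalar_prop <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}
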