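# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# Small annotated genome (2 x 50 kb) plus its k-mer index.
tiny_genome <- function() {
  if (!exists("genome", envir = .fixture_env)) {
    g <- generate_genome(genome_spec(
      n_chromosomes = 2L, chrom_length = 50000L, n_genes = 10L,
      n_tes = 15L, n_repeat_units = 10L, n_ncrnas = 5L, n_numt_nupt = 2L,
      n_genomic_tandem_arrays = 2L, seed = 11L))
    assign("genome", g, envir = .fixture_env)
    assign("index", kmer_index(g), envir = .fixture_env)
  }
  get("genome", envir = .fixture_env)
}

tiny_index <- function() {
  tiny_genome()
  get("index", envir = .fixture_env)
}

# An error-free concatemer read: `n_units` copies of a random monomer
# (optionally rotated), plus an optional partial pass.
make_concatemer <- function(unit_len, n_full, partial = 0, phase = 0,
                            monomer = NULL, gc = 0.44) {
  if (is.null(monomer)) monomer <- random_dna(unit_len, gc)
  base <- strrep(monomer, n_full + 2L)
  total <- round((n_full + partial) * unit_len)
  list(read = substr(base, phase + 1L, phase + total), monomer = monomer)
}

# Substitute exactly `n_sub` random positions of `s` with a different base.
substitute_bases <- function(s, n_sub) {
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  idx <- sample(length(x), n_sub)
  shift <- sample.int(3L, n_sub, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  x[idx] <- bases[((match(x[idx], bases) - 1L + shift) %% 4L) + 1L]
  paste(x, collapse = "")
}

# Random per-sample locus tables for unify_ids property tests.
random_locus_sets <- function(n_samples, max_loci, chroms = c("c1", "c2"),
                              span = 20000L) {
  lapply(seq_len(n_samples), function(s) {
    n <- sample.int(max_loci, 1L)
    start <- sample.int(span, n, replace = TRUE)
    len <- sample(150:1200, n, replace = TRUE)
    data.frame(sample_id = sprintf("S%d", s),
               locus_id = sprintf("S%d_l%03d", s, seq_len(n)),
               chrom = sample(chroms, n, replace = TRUE),
               start = start, end = start + len,
               n_reads = sample.int(20L, n, replace = TRUE))
  })
}

# O(n^2) all-pairs union-find oracle for ID unification.
brute_force_unify <- function(sets, min_overlap_bp) {
  all <- do.call(rbind, sets)
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    if (i == n) break
    j <- (i + 1L):n
    olap <- pmin(all$end[i], all$end[j]) - pmax(all$start[i], all$start[j])
    hits <- j[all$chrom[j] == all$chrom[i] & olap > min_overlap_bp]
    for (h in hits) {
      ri <- find(i); rh <- find(h)
      if (ri != rh) parent[rh] <- ri
    }
  }
  comps <- vapply(seq_len(n), find, integer(1))
  split(paste(all$sample_id, all$locus_id), comps)
}

# Calibrated 3-unit concatemer reads of a 400 bp monomer whose measured
# adjacent-unit edit-distance divergences sit near the requested percent
# targets (per-copy substitution rate found by bisection on the measured
# divergence).
make_divergence_reads <- function(seed, unit_len = 400L,
                                  targets = c(5, 15, 24, 26, 35, 40)) {
  reads <- character(0)
  for (t in seq_along(targets)) {
    target <- targets[t] / 100
    lo <- 0; hi <- 0.48
    read <- NULL
    for (it in 1:14) {
      r <- (lo + hi) / 2
      set.seed(seed * 1000L + t * 50L + it)
      monomer <- random_dna(unit_len)
      units <- vapply(1:3, function(i)
        substitute_bases(monomer, round(r * unit_len)), "")
      div <- mean(c(adist(units[1], units[2]),
                    adist(units[2], units[3]))) / unit_len
      read <- paste(units, collapse = "")
      if (abs(div - target) < 0.004) break
      if (div < target) lo <- r else hi <- r
    }
    reads[sprintf("div%02d", targets[t])] <- read
  }
  reads
}

# Partition of loci induced by a unify_ids() catalog, in comparable form.
catalog_partition <- function(catalog) {
  m <- catalog$id_map
  unname(split(paste(m$sample_id, m$locus_id), m$unified_id))
}

# Canonical form of a partition (sorted blocks, sorted by first element).
canon_partition <- function(p) {
  p <- lapply(p, sort)
  unname(p[order(vapply(p, `[`, "", 1L))])
}
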