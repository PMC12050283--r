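# Concatemer decomposition, unit filters, consensus mapping, linear
# exclusion, and locus calling.

test_that("decompose_concatemer recovers clean tandem structure", {
  set.seed(21)
  cc <- make_concatemer(500L, 4L)
  dec <- decompose_concatemer(cc$read)
  expect_s3_class(dec, "tandem_decomposition")
  expect_true(dec$unit_length >= 495 && dec$unit_length <= 505)
  expect_true(dec$n_units >= 3.8 && dec$n_units <= 4.2)
  expect_lt(dec$unit_divergence, 0.01)
  # consensus is a rotation of the monomer: the first unit itself
  expect_identical(dec$consensus, substr(cc$read, 1L, dec$unit_length))

  # non-repetitive sequence has no period
  expect_null(decompose_concatemer(random_dna(2000L)))

  # too-short reads error
  expect_error(decompose_concatemer(random_dna(25L)), "shorter")
})

test_that("fractional trailing passes are counted", {
  set.seed(22)
  cc <- make_concatemer(400L, 3L, partial = 0.5, phase = 113L)
  dec <- decompose_concatemer(cc$read)
  expect_equal(dec$unit_length, 400L)
  expect_equal(dec$n_units, 3.5, tolerance = 0.01)
})

test_that("measured divergence matches a brute-force edit-distance oracle", {
  # three copies, each independently substituted at 10% per base: the
  # decomposition's divergence must agree with direct adjacent-unit edit
  # distances on the constructed copies
  set.seed(23)
  for (rep in 1:3) {
    monomer <- random_dna(400L)
    units <- vapply(1:3, function(i) substitute_bases(monomer, 40L), "")
    read <- paste(units, collapse = "")
    oracle <- mean(c(adist(units[1], units[2]),
                     adist(units[2], units[3]))) / 400
    dec <- decompose_concatemer(read)
    expect_false(is.null(dec))
    expect_equal(dec$unit_length, 400L)
    expect_equal(dec$unit_divergence, oracle, tolerance = 0.2)
    # ~two independently 10%-mutated copies differ at ~18% of positions
    expect_gt(oracle, 0.12)
    expect_lt(oracle, 0.25)
  }
})

test_that("unit filters reject on length, copy number and divergence", {
  p <- caller_params()
  mk <- function(len, units, div)
    structure(list(unit_length = len, n_units = units,
                   unit_divergence = div, consensus = "A"),
              class = "tandem_decomposition")
  expect_false(passes_unit_filters(mk(199L, 3, 0.05), p))
  expect_false(passes_unit_filters(mk(250L, 1.6, 0.05), p))
  expect_true(passes_unit_filters(mk(250L, 2.5, 0.24), p))
  expect_true(passes_unit_filters(mk(200L, 2, 0.25), p))   # inclusive bounds
  expect_false(passes_unit_filters(mk(250L, 2.5, 0.251), p))
  expect_false(passes_unit_filters(NULL, p))
})

test_that("map_consensus finds exact and mutated substrings", {
  g <- tiny_genome()
  idx <- tiny_index()
  s <- substr(g$seq[["chr1"]], 20001L, 20600L)  # 600 bp, 0-based [20000,20600)
  segs <- map_consensus(s, idx)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$chrom, "chr1")
  expect_equal(segs$ref_start, 20000L)
  expect_equal(segs$ref_end, 20600L)
  expect_equal(segs$strand, "+")
  expect_equal(segs$identity, 1.0)

  rc <- eccforge:::revcomp(s)
  segs_rc <- map_consensus(rc, idx)
  expect_equal(segs_rc$strand, "-")
  expect_equal(segs_rc$ref_start, 20000L)
  expect_equal(segs_rc$ref_end, 20600L)

  set.seed(24)
  mut <- substitute_bases(s, 12L)  # 2% substitutions
  segs_m <- map_consensus(mut, idx)
  dom <- segs_m[which.max(segs_m$ref_end - segs_m$ref_start), ]
  expect_lte(abs(dom$ref_start - 20000L), 10L)
  expect_lte(abs(dom$ref_end - 20600L), 10L)
})

test_that("linear and genomic-tandem reads are excluded, circles are not", {
  g <- tiny_genome()
  idx <- tiny_index()
  bg <- simulate_background_reads(g, n_linear = 3L, n_tandem = 3L,
                                  seed = 25L)
  for (r in bg$reads) expect_true(is_genomic_tandem(r, idx))
  tp <- plant_circles(g, n_single = 1L,
                      size_law = list(law = "fixed", lengths = 500L),
                      seed = 26L)
  sim <- simulate_rca_reads(tp, g, read_sim_config(
    mean_full_passes = 5, n_reads_per_template = 3L, seed = 27L))
  for (r in sim$reads) expect_false(is_genomic_tandem(r, idx))
})

test_that("call_loci enforces support and aligned-fraction thresholds", {
  p <- caller_params()
  cand <- function(af, n = length(af))
    data.frame(read_id = sprintf("r%d", seq_len(n)), chrom = "chr1",
               start = 1000L, end = 1500L, aligned_fraction = af)
  expect_equal(nrow(call_loci(cand(rep(1, 3)), p)), 1L)
  expect_equal(call_loci(cand(rep(1, 3)), p)$n_reads, 3L)
  expect_equal(nrow(call_loci(cand(rep(1, 2)), p)), 0L)
  # one read below the 80% aligned-fraction bar does not count
  l <- call_loci(cand(c(1, 1, 0.9, 0.7)), p)
  expect_equal(l$n_reads, 3L)
  l2 <- call_loci(cand(c(1, 0.79, 0.9, 0.7)), p)
  expect_equal(nrow(l2), 0L)
  expect_equal(nrow(call_loci(NULL, p)), 0L)
})

test_that("locus intervals are member medians and clustering is stable", {
  p <- caller_params()
  cand <- data.frame(read_id = sprintf("r%d", 1:5), chrom = "chr1",
                     start = c(1000L, 1004L, 996L, 1002L, 998L),
                     end = c(1500L, 1504L, 1496L, 1510L, 1500L),
                     aligned_fraction = 1)
  l <- call_loci(cand, p)
  expect_equal(nrow(l), 1L)
  expect_equal(l$start, 1000L)  # lower median of sorted starts
  expect_equal(l$end, 1500L)
  # order-independence: shuffling the candidate rows changes nothing
  set.seed(28)
  for (i in 1:5) {
    ls <- call_loci(cand[sample.int(5), ], p)
    expect_equal(ls[, c("chrom", "start", "end", "n_reads")],
                 l[, c("chrom", "start", "end", "n_reads")])
  }
  # two well-separated clusters stay apart
  cand2 <- rbind(cand,
                 data.frame(read_id = sprintf("q%d", 1:3), chrom = "chr1",
                            start = 9000L, end = 9400L,
                            aligned_fraction = 1))
  expect_equal(nrow(call_loci(cand2, p)), 2L)
})

test_that("raising min_locus_reads never increases the number of loci", {
  set.seed(29)
  start <- sample.int(20000L, 40L)
  cand <- data.frame(read_id = sprintf("r%d", 1:40), chrom = "c1",
                     start = start, end = start + 400L,
                     aligned_fraction = 1)
  n_prev <- Inf
  for (mlr in 1:6) {
    p <- caller_params(min_locus_reads = mlr)
    n_now <- nrow(call_loci(cand, p))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("the caller recovers planted circles and rejects background", {
  g <- tiny_genome()
  idx <- tiny_index()
  tp <- plant_circles(g, n_single = 8L, size_law = list(
    law = "lognormal", meanlog = log(500), sdlog = 0.5, min = 250,
    max = 2500), seed = 30L)
  sim <- simulate_rca_reads(tp, g, read_sim_config(
    mean_full_passes = 5, n_reads_per_template = 6L, seed = 31L))
  bg <- simulate_background_reads(g, n_linear = 15L, n_tandem = 5L,
                                  seed = 32L)
  calls <- ecc_call(c(sim$reads, bg$reads), idx, sample_id = "T1")
  expect_equal(nrow(calls$loci), 8L)
  truth <- do.call(rbind, lapply(tp, `[[`, "fragments"))
  truth <- truth[order(truth$chrom, truth$start), ]
  loci <- calls$loci[order(calls$loci$chrom, calls$loci$start), ]
  expect_identical(loci$chrom, truth$chrom)
  expect_true(all(abs(loci$start - truth$start) <= 20L))
  expect_true(all(abs(loci$end - truth$end) <= 20L))
  # no background read supports any locus
  bg_ids <- names(bg$reads)
  expect_false(any(bg_ids %in% unlist(loci$member_reads)))
  # emitted-locus invariants
  expect_true(all(loci$end - loci$start >= calls$params$min_unit_length))
  expect_true(all(loci$n_reads >= calls$params$min_locus_reads))
})
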