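# Synthetic-data generator: genome, circle templates, reads, count matrices.

test_that("generate_genome honours the spec and is deterministic", {
  spec <- genome_spec(n_chromosomes = 2L, chrom_length = 50000L,
                      n_genes = 8L, n_tes = 10L, n_repeat_units = 5L,
                      n_ncrnas = 4L, n_numt_nupt = 2L,
                      n_genomic_tandem_arrays = 2L, seed = 5L)
  g1 <- generate_genome(spec)
  g2 <- generate_genome(spec)
  expect_identical(g1$seq, g2$seq)
  expect_identical(g1$genes, g2$genes)
  expect_identical(g1$tracks, g2$tracks)
  expect_length(g1$seq, 2L)
  expect_true(all(nchar(g1$seq) == 50000L))
  expect_equal(nrow(g1$genes), 8L)
  expect_equal(sum(g1$tracks$kind == "TE"), 10L)
  expect_equal(sum(g1$tracks$kind == "genomic_tandem"), 2L)
  expect_true(all(g1$tracks$end > g1$tracks$start))

  # gene parts tile the gene body without overlap
  for (gid in g1$genes$gene_id) {
    pp <- g1$gene_parts[g1$gene_parts$gene_id == gid, ]
    pp <- pp[order(pp$start), ]
    gene <- g1$genes[g1$genes$gene_id == gid, ]
    expect_equal(pp$start[1], gene$start)
    expect_equal(pp$end[nrow(pp)], gene$end)
    expect_true(all(pp$end[-nrow(pp)] == pp$start[-1]))
  }

  # empty-track case leaves the others untouched
  g0 <- generate_genome(genome_spec(n_tes = 0L, seed = 5L))
  expect_equal(sum(g0$tracks$kind == "TE"), 0L)
  expect_gt(sum(g0$tracks$kind == "ncRNA"), 0L)

  # class1 always agrees with the shipped superfamily lookup
  te <- g1$tracks[g1$tracks$kind == "TE", ]
  lut <- read.table(system.file("extdata", "te_superfamilies.tsv",
                                package = "eccforge"),
                    header = TRUE, sep = "\t")
  expect_identical(te$class1,
                   lut$class1[match(te$superfamily, lut$superfamily)])
})

test_that("genomic tandem arrays are literal head-to-tail repeats", {
  g <- tiny_genome()
  arr <- g$tracks[g$tracks$kind == "genomic_tandem", ][1, ]
  array_seq <- substr(g$seq[[arr$chrom]], arr$start + 1L, arr$end)
  monomer <- substr(array_seq, 1L, arr$monomer_length)
  expect_identical(array_seq, strrep(monomer, arr$n_copies))
})

test_that("plant_circles respects size laws and fragment structure", {
  g <- tiny_genome()
  tp <- plant_circles(g, n_single = 100L, size_law = list(
    law = "lognormal", meanlog = log(500), sdlog = 0.8, min = 200,
    max = 37000), seed = 2L)
  sizes <- vapply(tp, `[[`, 0L, "total_length")
  expect_true(all(sizes >= 200 & sizes <= 37000))
  expect_true(all(vapply(tp, function(t)
    sum(t$fragments$end - t$fragments$start), 0L) == sizes))

  tp5 <- plant_circles(g, n_single = 0L, n_multi = 5L, n_fragments = 5L,
                       seed = 3L)
  expect_true(all(vapply(tp5, function(t) nrow(t$fragments), 0L) == 5L))
  # at least one cross-chromosome template when several multis are planted
  expect_true(any(vapply(tp5, function(t)
    length(unique(t$fragments$chrom)) > 1L, TRUE)))

  # fixed-length law produces the requested sizes exactly
  tpf <- plant_circles(g, n_single = 3L, size_law = list(
    law = "fixed", lengths = c(250L, 400L, 1000L)), seed = 4L)
  expect_equal(vapply(tpf, `[[`, 0L, "total_length"), c(250L, 400L, 1000L))
})

test_that("ltr_flanked_pair templates flank an LTR feature of one subfamily", {
  g <- tiny_genome()
  tp <- plant_circles(g, n_single = 0L, n_ltr_flanked = 2L, seed = 6L)
  for (t in tp) {
    expect_identical(t$origin_tag, "ltr_flanked_pair")
    fr <- t$fragments[order(t$fragments$start), ]
    expect_equal(nrow(fr), 2L)
    gap_s <- fr$end[1]; gap_e <- fr$start[2]
    ltr <- g$tracks[g$tracks$kind == "TE" &
                      g$tracks$superfamily %in% c("Gypsy", "Copia") &
                      g$tracks$chrom == fr$chrom[1] &
                      g$tracks$start >= gap_s & g$tracks$end <= gap_e, ]
    expect_gte(nrow(ltr), 1L)
    expect_length(unique(ltr$subfamily), 1L)
  }
})

test_that("error-free RCA reads are rotations of the repeated monomer", {
  g <- tiny_genome()
  tp <- plant_circles(g, n_single = 1L,
                      size_law = list(law = "fixed", lengths = 500L),
                      seed = 7L)
  cfg <- read_sim_config(mean_full_passes = 3, n_reads_per_template = 8L,
                         revcomp_prob = 0.5, seed = 8L)
  sim <- simulate_rca_reads(tp, g, cfg)
  monomer <- template_monomer(tp[[1]], g)
  expect_equal(nchar(monomer), 500L)
  for (i in seq_along(sim$reads)) {
    tr <- sim$truth[i, ]
    r <- sim$reads[[i]]
    if (tr$strand == "-") r <- eccforge:::revcomp(r)
    # the read must equal a window of the infinitely repeated monomer
    expect_identical(r, substr(strrep(monomer, tr$n_fullpass_true + 2L),
                               tr$phase_offset + 1L,
                               tr$phase_offset + nchar(r)))
    # rotation by one monomer maps the read onto itself
    if (nchar(r) >= 1000L)
      expect_identical(substr(r, 501L, 1000L), substr(r, 1L, 500L))
  }
  # conservation: exactly one truth row per read, names match
  expect_identical(names(sim$reads), sim$truth$read_id)
  # determinism
  sim2 <- simulate_rca_reads(tp, g, cfg)
  expect_identical(sim$reads, sim2$reads)
  # empty case
  sim0 <- simulate_rca_reads(tp, g, read_sim_config(
    n_reads_per_template = 0L))
  expect_length(sim0$reads, 0L)
  expect_equal(nrow(sim0$truth), 0L)
})

test_that("substitution errors are applied at the configured rate", {
  g <- tiny_genome()
  tp <- plant_circles(g, n_single = 2L,
                      size_law = list(law = "fixed", lengths = 2000L),
                      seed = 9L)
  sim <- simulate_rca_reads(tp, g, read_sim_config(
    mean_full_passes = 5, sub_rate = 0.02, n_reads_per_template = 10L,
    seed = 10L))
  total <- sum(sim$truth$read_length)
  expect_gt(total, 50000)
  expect_equal(sum(sim$truth$n_sub) / total, 0.02, tolerance = 0.25)
  expect_true(all(sim$truth$n_ins == 0L & sim$truth$n_del == 0L))
})

test_that("background reads match their truth coordinates", {
  g <- tiny_genome()
  bg <- simulate_background_reads(g, n_linear = 5L, n_tandem = 5L,
                                  seed = 12L)
  expect_equal(nrow(bg$truth), 10L)
  for (i in seq_len(nrow(bg$truth))) {
    tr <- bg$truth[i, ]
    r <- bg$reads[[tr$read_id]]
    if (tr$strand == "-") r <- eccforge:::revcomp(r)
    expect_identical(r, substr(g$seq[[tr$chrom]], tr$start + 1L, tr$end))
  }
  # tandem reads span at least two monomer copies of their array
  tand <- bg$truth[bg$truth$background_kind == "genomic_tandem", ]
  arrays <- g$tracks[g$tracks$kind == "genomic_tandem", ]
  for (i in seq_len(nrow(tand))) {
    a <- arrays[arrays$chrom == tand$chrom[i] &
                  arrays$start <= tand$start[i] &
                  arrays$end >= tand$end[i], ]
    expect_equal(nrow(a), 1L)
    expect_gte(tand$read_length[i], 2L * a$monomer_length)
  }
  expect_length(simulate_background_reads(g, 0L, 0L)$reads, 0L)
})

test_that("count simulation reproduces the zero-inflated Poisson design", {
  # planted exclusive features are absent from the other group by construction
  d <- count_sim_design(n_features = 50L, exclusive_A = 1:5,
                        exclusive_B = 6:10, exclusive_lambda = 20,
                        seed = 13L)
  sim <- simulate_count_matrix(d)
  a_cols <- names(sim$groups)[sim$groups == "A"]
  b_cols <- names(sim$groups)[sim$groups == "B"]
  expect_true(all(sim$counts[6:10, a_cols] == 0L))
  expect_true(all(sim$counts[6:10, b_cols] > 0L))
  expect_true(all(sim$counts[1:5, b_cols] == 0L))
  expect_identical(sim$truth$label[1:10],
                   rep(c("exclusive_A", "exclusive_B"), each = 5L))

  # pi = 1 gives an all-zero matrix
  s1 <- simulate_count_matrix(count_sim_design(n_features = 100L,
                                               zero_inflation_pi = 1,
                                               seed = 1L))
  expect_true(all(s1$counts == 0L))

  # null design: observed zero fraction matches pi (Poisson(10) zeros are
  # negligible); Monte-Carlo oracle at large n
  s0 <- simulate_count_matrix(count_sim_design(n_features = 2000L,
                                               base_lambda = 10,
                                               zero_inflation_pi = 0.3,
                                               seed = 2L))
  expect_equal(mean(s0$counts == 0L), 0.3, tolerance = 0.067)

  # planted sets must be disjoint
  expect_error(count_sim_design(exclusive_A = 1:3, differential = 3:5),
               "disjoint")
})
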