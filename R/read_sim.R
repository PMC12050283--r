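# Simulation of rolling-circle-amplification concatemer reads and of linear /
# genomic-tandem background reads, each with a per-read truth table.

#' Configuration for RCA concatemer read simulation
#'
#' @param mean_full_passes Mean number of complete circle traversals per read
#'   (must be >= 1). The pass count is drawn as `1 + Poisson(mean - 1)`
#'   (`"poisson_shifted"`, the default: guarantees at least one full pass so
#'   that tandem decomposition is well-posed) or `1 + Geometric` with the same
#'   mean (`"geometric"`); a uniform partial pass in `[0, 1)` of the monomer
#'   is appended either way.
#' @param pass_count_law `"poisson_shifted"` or `"geometric"`.
#' @param sub_rate,ins_rate,del_rate Per-base error rates (each in
#'   `[0, 0.2]`).
#' @param revcomp_prob Probability that a read is reported on the reverse
#'   strand.
#' @param n_reads_per_template Reads simulated per circle template.
#' @param seed Optional integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(mean_full_passes = 4, pass_count_law = c(
                              "poisson_shifted", "geometric"),
                            sub_rate = 0, ins_rate = 0, del_rate = 0,
                            revcomp_prob = 0.5, n_reads_per_template = 5L,
                            seed = NULL) {
  pass_count_law <- match.arg(pass_count_law)
  if (mean_full_passes < 1) stop("mean_full_passes must be >= 1")
  for (r in c(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate))
    if (r < 0 || r > 0.2) stop("error rates must lie in [0, 0.2]")
  stop_if_not_scalar_prop(revcomp_prob, "revcomp_prob")
  if (n_reads_per_template < 0) stop("n_reads_per_template must be >= 0")
  structure(as.list(environment()), class = "read_sim_config")
}

.empty_truth <- function() {
  data.frame(read_id = character(0), template_id = character(0),
             background_kind = character(0), n_passes = numeric(0),
             n_fullpass_true = integer(0), phase_offset = integer(0),
             strand = character(0), read_length = integer(0),
             monomer_length = integer(0), chrom = character(0),
             start = integer(0), end = integer(0),
             n_sub = integer(0), n_ins = integer(0), n_del = integer(0))
}

#' Simulate RCA concatemer reads from circle templates
#'
#' Each read is a random rotation of the template monomer repeated for the
#' drawn number of full passes plus a uniform partial pass, with per-base
#' errors applied, and reverse-complemented with the configured probability.
#'
#' @param templates List of `circle_template` objects from [plant_circles()].
#' @param genome The [generate_genome()] result the templates refer to.
#' @param config A [read_sim_config()].
#' @return A list with `reads` (named character vector) and `truth`
#'   (data.frame, one row per read).
#' @export
simulate_rca_reads <- function(templates, genome, config = read_sim_config()) {
  stopifnot(inherits(config, "read_sim_config"))
  if (!length(templates) || config$n_reads_per_template == 0)
    return(list(reads = setNames(character(0), character(0)),
                truth = .empty_truth()))
  with_seed(config$seed, {
    reads <- character(0)
    rows <- vector("list", length(templates) * config$n_reads_per_template)
    ri <- 0L
    for (tp in templates) {
      monomer <- template_monomer(tp, genome)
      L <- nchar(monomer)
      for (j in seq_len(config$n_reads_per_template)) {
        n_full <- if (config$pass_count_law == "poisson_shifted")
          1L + rpois(1L, config$mean_full_passes - 1) else
          1L + rgeom(1L, 1 / config$mean_full_passes)
        partial <- runif(1L)
        phase <- sample.int(L, 1L) - 1L
        total_len <- max(1L, as.integer(round((n_full + partial) * L)))
        base <- strrep(monomer, n_full + 2L)
        s <- substr(base, phase + 1L, phase + total_len)
        mut <- mutate_seq(s, config$sub_rate, config$ins_rate, config$del_rate)
        strand <- "+"
        s <- mut$seq
        if (runif(1L) < config$revcomp_prob) {
          s <- revcomp(s)
          strand <- "-"
        }
        ri <- ri + 1L
        id <- sprintf("%s_read%03d", tp$template_id, j)
        reads[id] <- s
        rows[[ri]] <- data.frame(
          read_id = id, template_id = tp$template_id,
          background_kind = NA_character_, n_passes = n_full + partial,
          n_fullpass_true = n_full, phase_offset = phase, strand = strand,
          read_length = nchar(s), monomer_length = L, chrom = NA_character_,
          start = NA_integer_, end = NA_integer_, n_sub = mut$n_sub,
          n_ins = mut$n_ins, n_del = mut$n_del)
      }
    }
    list(reads = reads, truth = do.call(rbind, rows[seq_len(ri)]))
  })
}

#' Simulate linear and genomic-tandem background reads
#'
#' Linear reads are contiguous genomic substrings; tandem reads are substrings
#' of planted genomic tandem arrays spanning at least two monomer copies.
#' These are the negative controls for the caller's exclusion of reads that
#' originate from linear genomic repeats.
#'
#' @param genome A [generate_genome()] result.
#' @param n_linear,n_tandem Numbers of background reads of each kind.
#' @param length_law Log-normal length law for linear reads (list with
#'   `meanlog`, `sdlog`, `min`, `max`).
#' @param sub_rate,ins_rate,del_rate Per-base error rates.
#' @param revcomp_prob Probability of reporting the reverse strand.
#' @param seed Optional integer seed.
#' @return A list with `reads` and `truth` as in [simulate_rca_reads()];
#'   `background_kind` is `"linear"` or `"genomic_tandem"`.
#' @export
simulate_background_reads <- function(genome, n_linear = 0L, n_tandem = 0L,
                                      length_law = list(meanlog = log(2000),
                                                        sdlog = 0.5,
                                                        min = 500,
                                                        max = 20000),
                                      sub_rate = 0, ins_rate = 0,
                                      del_rate = 0, revcomp_prob = 0.5,
                                      seed = NULL) {
  stopifnot(inherits(genome, "ecc_genome"))
  arrays <- genome$tracks[genome$tracks$kind == "genomic_tandem", ]
  if (n_tandem > 0 && !nrow(arrays))
    stop("n_tandem > 0 requires at least one planted genomic tandem array")
  with_seed(seed, {
    reads <- character(0)
    rows <- list()
    emit <- function(id, kind, chrom, start, len) {
      s <- substr(genome$seq[[chrom]], start + 1L, start + len)
      mut <- mutate_seq(s, sub_rate, ins_rate, del_rate)
      s <- mut$seq
      strand <- "+"
      if (runif(1L) < revcomp_prob) {
        s <- revcomp(s)
        strand <- "-"
      }
      reads[id] <<- s
      rows[[length(rows) + 1L]] <<- data.frame(
        read_id = id, template_id = NA_character_, background_kind = kind,
        n_passes = NA_real_, n_fullpass_true = NA_integer_,
        phase_offset = NA_integer_, strand = strand, read_length = nchar(s),
        monomer_length = NA_integer_, chrom = chrom, start = start,
        end = start + len, n_sub = mut$n_sub, n_ins = mut$n_ins,
        n_del = mut$n_del)
    }
    if (n_linear > 0) {
      for (i in seq_len(n_linear)) {
        len <- 0L
        while (len < length_law$min || len > length_law$max)
          len <- as.integer(round(rlnorm(1L, length_law$meanlog,
                                         length_law$sdlog)))
        len <- min(len, genome$spec$chrom_length - 1L)
        chrom <- sample(names(genome$seq), 1L)
        start <- sample.int(genome$spec$chrom_length - len, 1L) - 1L
        emit(sprintf("bg_linear_%03d", i), "linear", chrom, start, len)
      }
    }
    if (n_tandem > 0) {
      for (i in seq_len(n_tandem)) {
        a <- arrays[sample.int(nrow(arrays), 1L), ]
        arr_len <- a$end - a$start
        min_len <- as.integer(ceiling(2.2 * a$monomer_length))
        len <- sample(min_len:arr_len, 1L)
        start <- a$start + sample.int(arr_len - len + 1L, 1L) - 1L
        emit(sprintf("bg_tandem_%03d", i), "genomic_tandem", a$chrom, start,
             len)
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else .empty_truth()
    list(reads = reads, truth = truth)
  })
}

#' Design for zero-inflated Poisson count-matrix simulation
#'
#' Emulates the unified-ID count matrix of a 2-group x 2-replicate design in
#' which counts follow a zero-inflated Poisson law, with optional planted
#' exclusive and differential features.
#'
#' @param n_features Number of features (rows).
#' @param base_lambda Poisson mean of unplanted features (scalar or
#'   per-feature vector).
#' @param zero_inflation_pi Structural-zero probability.
#' @param exclusive_A,exclusive_B Feature indices present in both replicates
#'   of one group (no zero inflation, Poisson mean `exclusive_lambda`) and
#'   structurally absent from the other.
#' @param differential Feature indices whose Poisson mean is multiplied by
#'   `differential_effect` in group `differential_up`.
#' @param exclusive_lambda Poisson mean of exclusive features in their group
#'   (must be >= 5 so presence in both replicates is near-certain; the
#'   default of 50 models a clearly amplified circle, separable from the
#'   exclusive-like patterns that zero inflation alone produces).
#' @param differential_effect Fold-change multiplier for differential
#'   features.
#' @param differential_up `"A"` or `"B"`.
#' @param group_labels Two group labels.
#' @param n_replicates Replicates per group.
#' @param seed Optional integer seed.
#' @return An object of class `count_sim_design`.
#' @export
count_sim_design <- function(n_features = 2000L, base_lambda = 10,
                             zero_inflation_pi = 0.3,
                             exclusive_A = integer(0),
                             exclusive_B = integer(0),
                             differential = integer(0),
                             exclusive_lambda = 50,
                             differential_effect = 4,
                             differential_up = "A",
                             group_labels = c("A", "B"),
                             n_replicates = 2L, seed = NULL) {
  stop_if_not_scalar_prop(zero_inflation_pi, "zero_inflation_pi")
  if (exclusive_lambda < 5)
    stop("exclusive_lambda must be >= 5")
  planted <- c(exclusive_A, exclusive_B, differential)
  if (anyDuplicated(planted))
    stop("planted feature sets must be disjoint")
  if (length(planted) && (min(planted) < 1 || max(planted) > n_features))
    stop("planted indices out of range")
  if (length(group_labels) != 2) stop("exactly two groups are supported")
  structure(as.list(environment()), class = "count_sim_design")
}

#' Simulate a zero-inflated Poisson count matrix with planted effects
#'
#' @param design A [count_sim_design()].
#' @return A list with `counts` (integer matrix, features x samples),
#'   `groups` (named character vector mapping sample to group) and `truth`
#'   (data.frame `feature`, `label`).
#' @export
simulate_count_matrix <- function(design) {
  stopifnot(inherits(design, "count_sim_design"))
  with_seed(design$seed, {
    gl <- design$group_labels
    nr <- design$n_replicates
    samples <- as.vector(t(outer(gl, seq_len(nr), function(g, r)
      sprintf("%s_%d", g, r))))
    groups <- setNames(rep(gl, each = nr), samples)
    nf <- design$n_features
    lam <- rep_len(design$base_lambda, nf)
    counts <- matrix(0L, nf, length(samples),
                     dimnames = list(sprintf("feat_%05d", seq_len(nf)),
                                     samples))
    for (j in seq_along(samples)) {
      keep <- runif(nf) >= design$zero_inflation_pi
      counts[, j] <- as.integer(keep) * rpois(nf, lam)
    }
    label <- rep("null", nf)
    for (g in gl) {
      idx <- if (g == gl[1]) design$exclusive_A else design$exclusive_B
      if (!length(idx)) next
      on_cols <- which(groups == g)
      off_cols <- which(groups != g)
      counts[idx, on_cols] <- rpois(length(idx) * length(on_cols),
                                    design$exclusive_lambda)
      counts[idx, off_cols] <- 0L
      label[idx] <- paste0("exclusive_", g)
    }
    if (length(design$differential)) {
      up_cols <- which(groups == design$differential_up)
      idx <- design$differential
      for (j in up_cols) {
        keep <- runif(length(idx)) >= design$zero_inflation_pi
        counts[idx, j] <- as.integer(keep) *
          rpois(length(idx), lam[idx] * design$differential_effect)
      }
      label[idx] <- paste0("differential_", design$differential_up, "_up")
    }
    list(counts = counts, groups = groups,
         truth = data.frame(feature = rownames(counts), label = label))
  })
}
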