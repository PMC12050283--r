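# Synthetic annotated genome: random chromosomes plus planted annotation
# tracks (genes with UTR/CDS structure, TEs, repeat units, ncRNAs, NUMT/NUPT
# labels) and literal genomic tandem arrays written into the sequence so that
# the caller's linear-repeat exclusion rule is exercised by construction.

#' Specification for a synthetic annotated genome
#'
#' Bundles the sizes and feature counts of a toy genome emulating a plant
#' chromosomal reference with its annotation tracks. All coordinates produced
#' downstream are 0-based half-open.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of every chromosome in bp.
#' @param gc_fraction GC content of the random background sequence.
#' @param n_genes Number of non-overlapping gene models (with 5'UTR/CDS/3'UTR
#'   parts) to plant.
#' @param n_tes,n_repeat_units,n_ncrnas,n_numt_nupt Numbers of transposable
#'   elements, repeat units, non-coding RNAs and NUMT/NUPT labels to plant
#'   (annotation only; overlaps among tracks are allowed, as in real genomes).
#' @param n_genomic_tandem_arrays Number of head-to-tail tandem repeat arrays
#'   (150-400 bp monomer, 3-6 copies) literally written into the sequence.
#' @param seed Integer seed; identical spec and seed give byte-identical
#'   output.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 2L, chrom_length = 100000L,
                        gc_fraction = 0.44, n_genes = 20L, n_tes = 30L,
                        n_repeat_units = 20L, n_ncrnas = 10L,
                        n_numt_nupt = 4L, n_genomic_tandem_arrays = 3L,
                        seed = 1L) {
  counts <- c(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
              n_genes = n_genes, n_tes = n_tes,
              n_repeat_units = n_repeat_units, n_ncrnas = n_ncrnas,
              n_numt_nupt = n_numt_nupt,
              n_genomic_tandem_arrays = n_genomic_tandem_arrays)
  if (any(counts < 0)) stop("all counts must be >= 0")
  if (n_chromosomes < 1) stop("need at least one chromosome")
  stop_if_not_scalar_prop(gc_fraction, "gc_fraction")
  # Longest plantable feature given the built-in size ranges below.
  longest <- max(3000,                         # gene
                 if (n_genomic_tandem_arrays > 0) 400 * 6 else 0,
                 if (n_numt_nupt > 0) 3000 else 0)
  if (chrom_length < 10 * longest)
    stop(sprintf("chrom_length must be >= %d (10 x longest plantable feature)",
                 10 * longest))
  structure(as.list(environment()), class = "genome_spec")
}

.te_superfamily_table <- function() {
  path <- system.file("extdata", "te_superfamilies.tsv", package = "eccforge")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Place an interval of length len on a random chromosome, optionally avoiding
# a set of occupied intervals (data.frame chrom/start/end). Returns
# list(chrom, start) or NULL after max_tries failures.
.place_interval <- function(chrom_names, chrom_length, len, occupied = NULL,
                            max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    chrom <- sample(chrom_names, 1L)
    if (chrom_length - len < 1) return(NULL)
    start <- sample.int(chrom_length - len, 1L) - 1L
    if (is.null(occupied) || !nrow(occupied)) return(list(chrom = chrom, start = start))
    clash <- occupied$chrom == chrom &
      occupied$end > start & occupied$start < start + len
    if (!any(clash)) return(list(chrom = chrom, start = start))
  }
  NULL
}

#' Generate a synthetic annotated genome
#'
#' Builds random chromosome sequences, writes genomic tandem arrays into
#' them, and plants gene models plus TE/repeat/ncRNA/NUMT-NUPT annotation
#' tracks. Deterministic for a given spec.
#'
#' @param spec A [genome_spec()].
#' @return An object of class `ecc_genome`: a list with elements `seq` (named
#'   character vector of chromosome sequences), `genes` (data.frame with
#'   `gene_id`, `chrom`, `start`, `end`, `strand`), `gene_parts` (data.frame
#'   with `gene_id`, `part` in `5UTR`/`CDS`/`3UTR`, `start`, `end`),
#'   `tracks` (data.frame with `feature_id`, `kind`, `chrom`, `start`, `end`,
#'   `strand`, `class1`, `superfamily`, `subfamily`, `monomer_length`,
#'   `n_copies`) and `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    chrom_names <- sprintf("chr%d", seq_len(spec$n_chromosomes))
    seqs <- setNames(
      vapply(chrom_names, function(x) random_dna(spec$chrom_length,
                                                 spec$gc_fraction), ""),
      chrom_names)

    track_rows <- list()
    occupied_arrays <- data.frame(chrom = character(0), start = integer(0),
                                  end = integer(0))

    # Genomic tandem arrays: overwrite the sequence with literal repeats so a
    # read drawn from them self-decomposes yet maps collinearly.
    if (spec$n_genomic_tandem_arrays > 0) {
      for (i in seq_len(spec$n_genomic_tandem_arrays)) {
        mono_len <- sample(150:400, 1L)
        n_copies <- sample(3:6, 1L)
        len <- mono_len * n_copies
        pl <- .place_interval(chrom_names, spec$chrom_length, len,
                              occupied_arrays)
        if (is.null(pl)) stop("cannot place genomic tandem array")
        monomer <- random_dna(mono_len, spec$gc_fraction)
        array_seq <- strrep(monomer, n_copies)
        substr(seqs[[pl$chrom]], pl$start + 1L, pl$start + len) <- array_seq
        occupied_arrays <- rbind(occupied_arrays,
          data.frame(chrom = pl$chrom, start = pl$start, end = pl$start + len))
        track_rows[[length(track_rows) + 1L]] <- data.frame(
          feature_id = sprintf("tandem_%03d", i), kind = "genomic_tandem",
          chrom = pl$chrom, start = pl$start, end = pl$start + len,
          strand = "+", class1 = NA_character_, superfamily = NA_character_,
          subfamily = NA_character_, monomer_length = mono_len,
          n_copies = n_copies)
      }
    }

    # Gene models: non-overlapping, with 5'UTR / CDS / 3'UTR tiling the body.
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        strand = character(0))
    parts_rows <- list()
    if (spec$n_genes > 0) {
      for (i in seq_len(spec$n_genes)) {
        len <- sample(800:3000, 1L)
        pl <- .place_interval(chrom_names, spec$chrom_length, len, genes)
        if (is.null(pl)) stop("cannot place gene without overlap; reduce n_genes")
        gid <- sprintf("gene_%03d", i)
        strand <- sample(c("+", "-"), 1L)
        genes <- rbind(genes, data.frame(
          gene_id = gid, chrom = pl$chrom, start = pl$start,
          end = pl$start + len, strand = strand))
        u5 <- sample(100:300, 1L); u3 <- sample(100:300, 1L)
        b <- pl$start; e <- pl$start + len
        if (strand == "+") {
          iv <- data.frame(part = c("5UTR", "CDS", "3UTR"),
                           start = c(b, b + u5, e - u3),
                           end = c(b + u5, e - u3, e))
        } else {
          iv <- data.frame(part = c("3UTR", "CDS", "5UTR"),
                           start = c(b, b + u3, e - u5),
                           end = c(b + u3, e - u5, e))
        }
        parts_rows[[i]] <- cbind(gene_id = gid, iv)
      }
    }
    gene_parts <- if (length(parts_rows)) do.call(rbind, parts_rows) else
      data.frame(gene_id = character(0), part = character(0),
                 start = integer(0), end = integer(0))

    te_table <- .te_superfamily_table()
    add_track <- function(n, kind, prefix, size_range, superfamilies = NULL) {
      if (n == 0) return(invisible(NULL))
      for (i in seq_len(n)) {
        len <- sample(size_range[1]:size_range[2], 1L)
        pl <- .place_interval(chrom_names, spec$chrom_length, len)
        if (is.null(pl)) stop(sprintf("cannot place %s feature", kind))
        if (!is.null(superfamilies)) {
          sf <- sample(superfamilies, 1L)
          c1 <- te_table$class1[match(sf, te_table$superfamily)]
          sub <- sprintf("%s_%d", sf, sample.int(3L, 1L))
        } else {
          sf <- NA_character_; c1 <- "other"; sub <- NA_character_
        }
        k <- if (kind == "NUMT_NUPT") sample(c("NUMT", "NUPT"), 1L) else kind
        track_rows[[length(track_rows) + 1L]] <<- data.frame(
          feature_id = sprintf("%s_%03d", prefix, i), kind = k,
          chrom = pl$chrom, start = pl$start, end = pl$start + len,
          strand = sample(c("+", "-"), 1L), class1 = c1, superfamily = sf,
          subfamily = sub, monomer_length = NA_integer_,
          n_copies = NA_integer_)
      }
    }
    add_track(spec$n_tes, "TE", "te", c(150, 3000),
              superfamilies = te_table$superfamily)
    add_track(spec$n_repeat_units, "repeat_unit", "repeat", c(100, 500),
              superfamilies = c("Stowaway", "Kiddo", "Zator"))
    add_track(spec$n_ncrnas, "ncRNA", "ncrna", c(100, 2000))
    add_track(spec$n_numt_nupt, "NUMT_NUPT", "organellar", c(500, 3000))

    tracks <- if (length(track_rows)) do.call(rbind, track_rows) else
      data.frame(feature_id = character(0), kind = character(0),
                 chrom = character(0), start = integer(0), end = integer(0),
                 strand = character(0), class1 = character(0),
                 superfamily = character(0), subfamily = character(0),
                 monomer_length = integer(0), n_copies = integer(0))
    rownames(tracks) <- NULL

    structure(list(seq = seqs, genes = genes, gene_parts = gene_parts,
                   tracks = tracks, spec = spec),
              class = "ecc_genome")
  })
}

#' @export
print.ecc_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosome(s) x %d bp\n",
              length(x$seq), x$spec$chrom_length))
  cat(sprintf("  genes: %d   track features: %d\n",
              nrow(x$genes), nrow(x$tracks)))
  invisible(x)
}

.default_size_law <- function() {
  list(law = "lognormal", meanlog = log(500), sdlog = 0.8,
       min = 200, max = 37000)
}

.draw_sizes <- function(n, law) {
  if (identical(law$law, "fixed")) {
    return(as.integer(rep_len(law$lengths, n)))
  }
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rlnorm(2L * (n - length(out)) + 10L, law$meanlog, law$sdlog))
    out <- c(out, x[x >= law$min & x <= law$max])
  }
  as.integer(out[seq_len(n)])
}

#' Plant circular eccDNA templates in a synthetic genome
#'
#' Single-fragment templates are drawn with a truncated log-normal size law
#' (median 500 bp, sigma 0.8, range 200 bp - 37 kb by default, matching
#' observed plant eccDNA size distributions). Multi-fragment templates join
#' 2-10 non-contiguous genomic regions; when at least two multi templates are
#' requested and the genome has several chromosomes, at least one template is
#' cross-chromosomal. `ltr_flanked_pair` templates are two-fragment templates
#' whose fragments flank an annotated LTR-superfamily TE.
#'
#' @param genome An [generate_genome()] result.
#' @param n_single,n_multi,n_ltr_flanked Numbers of templates of each kind.
#' @param size_law Either `NULL` for the default truncated log-normal law or a
#'   list `list(law = "fixed", lengths = c(...))` for exact template lengths
#'   (used to probe filter boundaries), or a lognormal law list with elements
#'   `meanlog`, `sdlog`, `min`, `max`.
#' @param n_fragments Range (or fixed value) for the fragment count of multi
#'   templates; default `2:10`.
#' @param seed Optional integer seed.
#' @return A list of `circle_template` objects, each with `template_id`,
#'   `fragments` (data.frame `chrom`,`start`,`end`,`strand`), `total_length`
#'   and `origin_tag`.
#' @export
plant_circles <- function(genome, n_single = 10L, n_multi = 0L,
                          n_ltr_flanked = 0L, size_law = NULL,
                          n_fragments = 2:10, id_prefix = "circle",
                          seed = NULL) {
  stopifnot(inherits(genome, "ecc_genome"))
  if (is.null(size_law)) size_law <- .default_size_law()
  with_seed(seed, {
    chrom_names <- names(genome$seq)
    chrom_length <- genome$spec$chrom_length
    # Avoid tandem arrays (reads from circles must not look like linear
    # repeats) and avoid overlap among planted single circles so that every
    # template maps to an unambiguous truth locus.
    occupied <- genome$tracks[genome$tracks$kind == "genomic_tandem",
                              c("chrom", "start", "end")]
    templates <- list()
    new_frag <- function(len, avoid) {
      # overlap avoidance is best-effort: when the genome is too crowded the
      # fragment is placed anyway (truth stays usable; only boundary
      # uniqueness degrades)
      pl <- .place_interval(chrom_names, chrom_length, len, avoid)
      if (is.null(pl))
        pl <- .place_interval(chrom_names, chrom_length, len, NULL)
      if (is.null(pl)) stop("circle template longer than any chromosome")
      data.frame(chrom = pl$chrom, start = pl$start, end = pl$start + len,
                 strand = "+")
    }

    if (n_single > 0) {
      sizes <- .draw_sizes(n_single, size_law)
      for (i in seq_len(n_single)) {
        fr <- new_frag(sizes[i], occupied)
        occupied <- rbind(occupied, fr[, c("chrom", "start", "end")])
        templates[[length(templates) + 1L]] <- structure(list(
          template_id = sprintf("%s_s%03d", id_prefix, i), fragments = fr,
          total_length = sizes[i], origin_tag = "single"),
          class = "circle_template")
      }
    }

    if (n_multi > 0) {
      for (i in seq_len(n_multi)) {
        nf <- if (length(n_fragments) == 1L) n_fragments else
          sample(n_fragments, 1L)
        total <- max(.draw_sizes(1L, size_law), 300L * nf)
        extra <- total - 300L * nf
        w <- runif(nf)
        lens <- 300L + as.integer(floor(extra * w / sum(w)))
        lens[nf] <- total - sum(lens[-nf])
        frs_list <- list()
        for (len_i in lens) {
          fr_i <- new_frag(len_i, occupied)
          occupied <- rbind(occupied, fr_i[, c("chrom", "start", "end")])
          frs_list[[length(frs_list) + 1L]] <- fr_i
        }
        frs <- do.call(rbind, frs_list)
        frs$strand <- sample(c("+", "-"), nf, replace = TRUE)
        if (i == 1L && n_multi >= 2L && length(chrom_names) >= 2L &&
            length(unique(frs$chrom)) == 1L) {
          # force the first template cross-chromosomal
          other <- setdiff(chrom_names, frs$chrom[1])[1]
          pl <- .place_interval(other, chrom_length, lens[1], occupied)
          frs$chrom[1] <- other; frs$start[1] <- pl$start
          frs$end[1] <- pl$start + lens[1]
        }
        templates[[length(templates) + 1L]] <- structure(list(
          template_id = sprintf("%s_m%03d", id_prefix, i), fragments = frs,
          total_length = as.integer(sum(frs$end - frs$start)),
          origin_tag = "multi"), class = "circle_template")
      }
    }

    if (n_ltr_flanked > 0) {
      ltr <- genome$tracks[genome$tracks$kind == "TE" &
                           genome$tracks$superfamily %in% c("Gypsy", "Copia"), ]
      if (!nrow(ltr)) stop("no LTR-superfamily TE available for ltr_flanked_pair templates")
      for (i in seq_len(n_ltr_flanked)) {
        te <- ltr[sample.int(nrow(ltr), 1L), ]
        l1 <- sample(300:1000, 1L); l2 <- sample(300:1000, 1L)
        s1 <- max(0L, te$start - l1)
        e2 <- min(chrom_length, te$end + l2)
        fr <- data.frame(chrom = te$chrom, start = c(s1, te$end),
                         end = c(te$start, e2), strand = "+")
        if (any(fr$end - fr$start < 200))
          stop("ltr_flanked_pair fragment shorter than 200 bp; re-seed")
        templates[[length(templates) + 1L]] <- structure(list(
          template_id = sprintf("%s_l%03d", id_prefix, i), fragments = fr,
          total_length = as.integer(sum(fr$end - fr$start)),
          origin_tag = "ltr_flanked_pair"), class = "circle_template")
      }
    }
    templates
  })
}

#' Monomer sequence of a circle template
#'
#' Strand-aware concatenation of the template's fragments in listed order —
#' the listed junction order is the ground truth for fragment-cycle
#' recovery.
#'
#' @param template A `circle_template` from [plant_circles()].
#' @param genome The `ecc_genome` the template refers to.
#' @return A single DNA string of length `template$total_length`.
#' @export
template_monomer <- function(template, genome) {
  fr <- template$fragments
  pieces <- vapply(seq_len(nrow(fr)), function(i) {
    s <- substr(genome$seq[[fr$chrom[i]]], fr$start[i] + 1L, fr$end[i])
    if (fr$strand[i] == "-") revcomp(s) else s
  }, "")
  paste(pieces, collapse = "")
}
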