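#' Simulation configuration for a clonal polyploid filament
#'
#' Parameters of the synthetic-data generator.  Defaults emulate a single
#' filament of a large vacuolated sulfur bacterium cut into six consecutive
#' segments of ~30 highly polyploid cells each: a ~3.2 Mbp genome at ~34%
#' G+C that is ~88% coding, near-clonal consensus divergence between
#' segments, and within-segment read heterogeneity (ISH) at a rate of a few
#' hundred sites per megabase with variant frequencies in [0.25, 0.5], a
#' third of the sites recurring at identical position and allele in every
#' segment.
#'
#' Mutation rates are expressed per bp *per segment relative to the common
#' ancestor reference*; the divergence observed between two simulated
#' segments is therefore about twice the per-segment rate.
#'
#' @param genome_length reference length in bp (>= 10,000 for
#'   [generate_reference()]).
#' @param gc_fraction G+C content of the reference, in (0, 1).
#' @param coding_fraction_target fraction of the genome covered by CDS,
#'   in the open interval (0, 1).
#' @param n_segments number of filament segments.
#' @param snp_rate_cds,snp_rate_ncds expected substitutions per bp per
#'   segment in coding / non-coding compartments.
#' @param indel_rate_cds,indel_rate_ncds expected single-nucleotide indels
#'   per bp per segment in coding / non-coding compartments.
#' @param ish_site_rate expected ISH events per bp per segment.
#' @param ish_freq_low,ish_freq_high bounds of the uniform distribution of
#'   true ISH variant frequencies.
#' @param colocalized_fraction proportion of distinct ISH sites present,
#'   with identical position and variant allele, in all segments.
#' @param coverage_mean mean read depth per position (Poisson).
#' @param seq_error_rate per-base sequencing error probability.
#' @param seed integer RNG seed; all sub-streams are derived from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 3.2e6,
                       gc_fraction = 0.34,
                       coding_fraction_target = 0.88,
                       n_segments = 6,
                       snp_rate_cds = 1.8e-5,
                       snp_rate_ncds = 4.25e-5,
                       indel_rate_cds = 1e-6,
                       indel_rate_ncds = 2e-5,
                       ish_site_rate = 7e-4,
                       ish_freq_low = 0.25,
                       ish_freq_high = 0.5,
                       colocalized_fraction = 1 / 3,
                       coverage_mean = 380,
                       seq_error_rate = 0.005,
                       seed = 1L) {
  cfg <- list(genome_length = as.integer(genome_length),
              gc_fraction = gc_fraction,
              coding_fraction_target = coding_fraction_target,
              n_segments = as.integer(n_segments),
              snp_rate_cds = snp_rate_cds, snp_rate_ncds = snp_rate_ncds,
              indel_rate_cds = indel_rate_cds,
              indel_rate_ncds = indel_rate_ncds,
              ish_site_rate = ish_site_rate,
              ish_freq_low = ish_freq_low, ish_freq_high = ish_freq_high,
              colocalized_fraction = colocalized_fraction,
              coverage_mean = coverage_mean,
              seq_error_rate = seq_error_rate,
              seed = as.integer(seed))
  rates <- c(cfg$snp_rate_cds, cfg$snp_rate_ncds, cfg$indel_rate_cds,
             cfg$indel_rate_ncds, cfg$ish_site_rate, cfg$seq_error_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    fp_stop("fp_config_error", "all rates must be finite and >= 0")
  if (cfg$genome_length < 1)
    fp_stop("fp_config_error", "genome_length must be positive")
  if (cfg$gc_fraction <= 0 || cfg$gc_fraction >= 1)
    fp_stop("fp_config_error", "gc_fraction must be in (0, 1)")
  if (cfg$coding_fraction_target <= 0 || cfg$coding_fraction_target >= 1)
    fp_stop("fp_config_error",
            "coding_fraction_target must be in the open interval (0, 1)")
  if (cfg$colocalized_fraction < 0 || cfg$colocalized_fraction > 1)
    fp_stop("fp_config_error", "colocalized_fraction must be in [0, 1]")
  if (cfg$ish_freq_low < 0 || cfg$ish_freq_high > 1 ||
      cfg$ish_freq_low > cfg$ish_freq_high)
    fp_stop("fp_config_error", "need 0 <= ish_freq_low <= ish_freq_high <= 1")
  if (cfg$coverage_mean <= 0)
    fp_stop("fp_config_error", "coverage_mean must be positive")
  if (cfg$n_segments < 1)
    fp_stop("fp_config_error", "n_segments must be >= 1")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random annotated reference genome
#'
#' Draws a random sequence at the configured G+C fraction and lays out
#' non-overlapping CDS intervals (gene lengths ~ Gamma with mean 1 kbp,
#' intergenic gaps ~ Geometric) so that the coding fraction matches
#' `coding_fraction_target`; a deterministic end-correction trims or
#' extends the final genes to land within +/- 0.02 of the target.
#' Output is fully determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an [annotated_genome()] with a single contig `"contig_1"`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_length < 10000)
    fp_stop("fp_config_error", "genome_length must be >= 10,000")
  L <- config$genome_length
  with_seed(derive_seed(config$seed, 0), {
    p <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
           config$gc_fraction / 2, (1 - config$gc_fraction) / 2)
    seq <- paste(sample(DNA_BASES, L, replace = TRUE, prob = p),
                 collapse = "")
    f <- config$coding_fraction_target
    mean_gene <- 1000
    mean_gap <- mean_gene * (1 - f) / f
    n_guess <- ceiling(L / (mean_gene + mean_gap)) + 50
    genes <- pmax(90L, as.integer(round(rgamma(n_guess, shape = 4,
                                               scale = mean_gene / 4))))
    gaps <- rpois(n_guess, mean_gap)
    starts <- integer(0); ends <- integer(0)
    pos <- gaps[1]
    for (i in seq_len(n_guess)) {
      if (pos >= L) break
      e <- min(pos + genes[i], L)
      if (e > pos) { starts <- c(starts, pos); ends <- c(ends, e) }
      pos <- e + gaps[min(i + 1, n_guess)]
    }
    # deterministic end-correction toward the target coding fraction
    delta <- as.integer(round(f * L)) - sum(ends - starts)
    i <- length(ends)
    while (delta != 0 && i >= 1) {
      if (delta > 0) {
        room <- (if (i == length(ends)) L else starts[i + 1] - 1L) - ends[i]
        add <- min(room, delta)
        ends[i] <- ends[i] + add; delta <- delta - add
      } else {
        cut <- min(ends[i] - starts[i] - 1L, -delta)
        ends[i] <- ends[i] - cut; delta <- delta + cut
      }
      i <- i - 1L
    }
    cds <- data.frame(contig = "contig_1", start = starts, end = ends)
    annotated_genome(c(contig_1 = seq), cds, id = "reference")
  })
}

# sample n distinct 0-based positions uniformly within a set of merged
# intervals (given as a data.table with start/end, half-open)
sample_positions <- function(intervals, n) {
  if (n == 0L) return(integer(0))
  widths <- intervals$end - intervals$start
  total <- sum(widths)
  if (n > total)
    fp_stop("fp_config_error", "more positions requested than compartment bp")
  off <- sample.int(total, n) - 1L
  cum <- cumsum(widths)
  idx <- findInterval(off, cum) + 1L
  intervals$start[idx] + (off - c(0L, cum)[idx])
}

#' Mutate the reference into one segment consensus
#'
#' Introduces substitutions and single-nucleotide indels by independent
#' uniform draws within each compartment at the compartment-specific rates,
#' and shifts the CDS annotation through the introduced indels so the
#' mutated assembly carries a consistent annotation.  Insertions are
#' recorded at the reference position of the base they follow; deletions at
#' the deleted base.
#'
#' @param reference an [annotated_genome()] from [generate_reference()].
#' @param config a [sim_config()].
#' @param segment_id integer in `[1, n_segments]`.
#' @return list with `genome` (the mutated [annotated_genome()]) and
#'   `truth` (`data.table`: segment, pos (0-based on the reference), ref,
#'   alt, class `SNP|insertion|deletion`, compartment `CDS|nCDS`).
#' @export
mutate_consensus <- function(reference, config, segment_id) {
  stopifnot(inherits(reference, "annotated_genome"),
            inherits(config, "sim_config"))
  if (segment_id < 1 || segment_id > config$n_segments)
    fp_stop("fp_config_error", "segment_id outside [1, n_segments]")
  div <- max(config$snp_rate_cds + config$indel_rate_cds,
             config$snp_rate_ncds + config$indel_rate_ncds)
  if (div > 0.1)
    fp_stop("fp_config_error",
            "rates imply >10%% divergence; anchoring assumes near-clonality")
  contig <- names(reference$contigs)[1]
  seq <- reference$contigs[[1]]
  cds_iv <- reference$cds[reference$cds$contig == contig]
  ncds_iv <- ncds_intervals(reference, contig)

  with_seed(derive_seed(config$seed, 1000 + segment_id), {
    draw <- function(iv, snp_rate, indel_rate, comp) {
      bp <- sum(iv$end - iv$start)
      n_snp <- rbinom(1, bp, snp_rate)
      n_ind <- rbinom(1, bp, indel_rate)
      pos <- sample_positions(iv, n_snp + n_ind)
      data.table(pos = pos,
                 class = rep(c("SNP", "indel"), c(n_snp, n_ind)),
                 compartment = rep(comp, n_snp + n_ind))
    }
    tr <- rbindlist(list(
      draw(cds_iv, config$snp_rate_cds, config$indel_rate_cds, "CDS"),
      draw(ncds_iv, config$snp_rate_ncds, config$indel_rate_ncds, "nCDS")))
    if (nrow(tr) == 0) {
      truth <- data.table(segment = integer(), pos = integer(),
                          ref = character(), alt = character(),
                          class = character(), compartment = character())
      g <- annotated_genome(setNames(seq, contig),
                            as.data.frame(reference$cds),
                            id = sprintf("segment_%d", segment_id))
      return(list(genome = g, truth = truth))
    }
    setorder(tr, pos)
    # positions are distinct within a compartment by construction; the two
    # compartments are disjoint, so all positions are distinct
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    refb <- v[tr$pos + 1L]
    is_snp <- tr$class == "SNP"
    alt <- character(nrow(tr))
    # substitution: uniform over the three other bases
    alt[is_snp] <- vapply(refb[is_snp], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
    # indel: insertion or deletion with equal probability
    ins <- !is_snp & runif(nrow(tr)) < 0.5
    del <- !is_snp & !ins
    alt[ins] <- sample(DNA_BASES, sum(ins), replace = TRUE)
    alt[del] <- "-"
    tr$class[ins] <- "insertion"
    tr$class[del] <- "deletion"
    tr$ref <- ifelse(tr$class == "insertion", "-", refb)
    tr$alt <- alt

    out <- v
    out[tr$pos[is_snp] + 1L] <- alt[is_snp]
    out[tr$pos[del] + 1L] <- ""
    # an insertion follows the base at its recorded position
    out[tr$pos[ins] + 1L] <- paste0(v[tr$pos[ins] + 1L], alt[ins])
    mutseq <- paste(out, collapse = "")

    # shift CDS coordinates through the indels: +1 for each insertion
    # strictly before, -1 for each deletion strictly before a boundary
    ins_pos <- sort(tr$pos[ins]); del_pos <- sort(tr$pos[del])
    shift <- function(p)
      p + findInterval(p - 1L, ins_pos) - findInterval(p - 1L, del_pos)
    new_cds <- data.frame(contig = contig,
                          start = shift(cds_iv$start),
                          end = pmin(shift(cds_iv$end), nchar(mutseq)))
    new_cds <- new_cds[new_cds$end > new_cds$start, , drop = FALSE]
    truth <- data.table(segment = as.integer(segment_id), pos = tr$pos,
                        ref = tr$ref, alt = tr$alt, class = tr$class,
                        compartment = tr$compartment)
    g <- annotated_genome(setNames(mutseq, contig), new_cds,
                          id = sprintf("segment_%d", segment_id))
    list(genome = g, truth = truth)
  })
}

#' Plant ground-truth ISH sites across segments
#'
#' Draws the set of intrasegmental-heterogeneity sites on the framework
#' (reference) coordinates.  A fraction `colocalized_fraction` of the
#' distinct sites is present, with identical position and variant allele,
#' in every segment; the remaining sites are each private to one segment
#' drawn uniformly.  The number of distinct sites is chosen so that the
#' expected number of events per segment equals
#' `ish_site_rate * genome_length`.  True variant frequencies are drawn
#' independently per (site, segment) from
#' `U(ish_freq_low, ish_freq_high)`.
#'
#' @param reference the framework [annotated_genome()].
#' @param config a [sim_config()].
#' @return `data.table`: segment, contig, pos (0-based), ref, alt, freq,
#'   colocalized (logical).
#' @export
simulate_ish_truth <- function(reference, config) {
  stopifnot(inherits(reference, "annotated_genome"),
            inherits(config, "sim_config"))
  contig <- names(reference$contigs)[1]
  L <- nchar(reference$contigs[[1]])
  f <- config$colocalized_fraction
  n <- config$n_segments
  per_seg <- config$ish_site_rate * L
  S <- as.integer(round(per_seg / (f + (1 - f) / n)))
  with_seed(derive_seed(config$seed, 500), {
    if (S == 0)
      return(data.table(segment = integer(), contig = character(),
                        pos = integer(), ref = character(),
                        alt = character(), freq = numeric(),
                        colocalized = logical()))
    pos <- sort(sample.int(L, S) - 1L)
    refb <- strsplit(reference$contigs[[1]], "", fixed = TRUE)[[1]][pos + 1L]
    altb <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1),
                   character(1))
    n_coloc <- as.integer(round(f * S))
    coloc <- rep(FALSE, S)
    if (n_coloc > 0) coloc[sample.int(S, n_coloc)] <- TRUE
    seg_of_private <- sample.int(n, S - n_coloc, replace = TRUE)
    site <- data.table(pos = pos, ref = refb, alt = altb, colocalized = coloc)
    shared <- site[coloc]
    private <- site[!coloc]
    private$segment <- seg_of_private
    rows <- rbindlist(c(
      lapply(seq_len(n), function(s) {
        if (nrow(shared) == 0) return(NULL)
        d <- copy(shared); d$segment <- s; d
      }),
      list(private)), use.names = TRUE, fill = TRUE)
    rows$freq <- runif(nrow(rows), config$ish_freq_low, config$ish_freq_high)
    rows$contig <- contig
    setorder(rows, segment, pos)
    rows[, list(segment = as.integer(segment), contig, pos, ref, alt, freq,
                colocalized)]
  })
}

#' Simulate a per-position read pileup
#'
#' Generates an mpileup-style table of per-allele read counts for one
#' segment library mapped to a framework sequence.  Coverage is Poisson
#' around `coverage_mean`.  At planted ISH sites the variant-allele count
#' is Binomial(coverage, true frequency) and the remaining reads support
#' the reference; elsewhere non-reference reads arise only from the
#' per-base sequencing error rate, split uniformly over the three other
#' bases.  Insertion/deletion read counts are emitted (as zeros; the
#' generator plants single-nucleotide-variant heterogeneity only).
#'
#' @param seq framework nucleotide sequence (single contig).
#' @param config a [sim_config()].
#' @param ish_truth rows of [simulate_ish_truth()] for this segment (may be
#'   empty); positions must lie within `seq`.
#' @param contig contig name for the output.
#' @param seed RNG seed for this library.
#' @return `data.table`: contig, pos (1-based), ref, depth, A, C, G, T,
#'   ins, del; `depth == A + C + G + T` at every row.
#' @export
simulate_pileup <- function(seq, config, ish_truth = NULL,
                            contig = "contig_1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  n <- nchar(seq)
  if (!is.null(ish_truth) && nrow(ish_truth)) {
    if (any(ish_truth$pos < 0) || any(ish_truth$pos >= n))
      fp_stop("fp_coordinate_error", "ISH truth site outside the sequence")
    if (any(ish_truth$freq < 0) || any(ish_truth$freq > 1))
      fp_stop("fp_config_error", "ISH truth frequencies must be in [0, 1]")
  }
  refv <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(refv, DNA_BASES)
  if (anyNA(code))
    fp_stop("fp_config_error", "pileup simulation requires an ACGT sequence")
  with_seed(seed, {
    cov <- rpois(n, config$coverage_mean)
    err <- rbinom(n, cov, config$seq_error_rate)
    counts <- matrix(0L, nrow = n, ncol = 4)
    # split errors uniformly over the three non-reference bases
    e1 <- rbinom(n, err, 1 / 3)
    e2 <- rbinom(n, err - e1, 1 / 2)
    e3 <- err - e1 - e2
    others <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
    i <- seq_len(n)
    counts[cbind(i, code)] <- cov - err
    counts[cbind(i, others[code, 1])] <- counts[cbind(i, others[code, 1])] + e1
    counts[cbind(i, others[code, 2])] <- counts[cbind(i, others[code, 2])] + e2
    counts[cbind(i, others[code, 3])] <- counts[cbind(i, others[code, 3])] + e3
    if (!is.null(ish_truth) && nrow(ish_truth)) {
      r <- ish_truth$pos + 1L
      altc <- match(ish_truth$alt, DNA_BASES)
      altn <- rbinom(nrow(ish_truth), cov[r], ish_truth$freq)
      counts[r, ] <- 0L
      counts[cbind(r, code[r])] <- cov[r] - altn
      counts[cbind(r, altc)] <- counts[cbind(r, altc)] + altn
    }
    data.table(contig = contig, pos = i, ref = refv, depth = cov,
               A = counts[, 1], C = counts[, 2], G = counts[, 3],
               T = counts[, 4], ins = 0L, del = 0L)
  })
}

#' Simulate a complete clonal filament experiment
#'
#' Orchestrates the generator: reference, per-segment mutated consensus
#' assemblies with shifted annotations, planted ISH truth, and per-segment
#' pileups of each library against the framework (reference) coordinates.
#' Optionally serializes everything (FASTA, GFF3, pileup TSV, truth TSV,
#' config JSON) to a directory; repeated runs with the same config are
#' byte-identical.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory.
#' @return list with `config`, `reference`, `segments` (list of
#'   [annotated_genome()]), `consensus_truth`, `ish_truth`, `pileups`
#'   (list of `data.table`).
#' @export
simulate_filament <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ref <- generate_reference(config)
  muts <- lapply(seq_len(config$n_segments), function(s)
    mutate_consensus(ref, config, s))
  segments <- lapply(muts, `[[`, "genome")
  names(segments) <- vapply(segments, `[[`, character(1), "id")
  consensus_truth <- rbindlist(lapply(muts, `[[`, "truth"))
  ish_truth <- simulate_ish_truth(ref, config)
  pileups <- lapply(seq_len(config$n_segments), function(s)
    simulate_pileup(ref$contigs[[1]], config,
                    ish_truth[ish_truth$segment == s],
                    contig = names(ref$contigs)[1],
                    seed = derive_seed(config$seed, 2000 + s)))
  names(pileups) <- names(segments)
  res <- list(config = config, reference = ref, segments = segments,
              consensus_truth = consensus_truth, ish_truth = ish_truth,
              pileups = pileups)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genome(ref, file.path(outdir, "reference.fasta"),
                 file.path(outdir, "reference.gff3"))
    for (s in seq_along(segments))
      write_genome(segments[[s]],
                   file.path(outdir, sprintf("segment_%d.fasta", s)),
                   file.path(outdir, sprintf("segment_%d.gff3", s)))
    for (s in seq_along(pileups))
      write_pileup(pileups[[s]],
                   file.path(outdir, sprintf("segment_%d.pileup.tsv", s)))
    fwrite(consensus_truth, file.path(outdir, "consensus_truth.tsv"),
           sep = "\t")
    fwrite(ish_truth, file.path(outdir, "ish_truth.tsv"), sep = "\t")
    jsonlite::write_json(unclass(config),
                         file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
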