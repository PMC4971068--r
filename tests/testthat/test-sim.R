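test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(coding_fraction_target = 1.0), class = "fp_config_error")
  expect_error(sim_config(coding_fraction_target = 0), class = "fp_config_error")
  expect_error(sim_config(snp_rate_cds = -1e-5), class = "fp_config_error")
  expect_error(sim_config(colocalized_fraction = 1.2), class = "fp_config_error")
  expect_error(sim_config(ish_freq_low = 0.6, ish_freq_high = 0.5),
               class = "fp_config_error")
  expect_error(generate_reference(sim_config(genome_length = 5000)),
               class = "fp_config_error")
})

test_that("reference generation hits the coding-fraction target", {
  cfg <- sim_config(genome_length = 2e5, coding_fraction_target = 0.88,
                    seed = 3)
  ref <- generate_reference(cfg)
  frac <- ref$cds_length / ref$total_length
  expect_gte(frac, 0.86)
  expect_lte(frac, 0.90)
  expect_equal(ref$cds_length + ref$ncds_length, ref$total_length)
  # intervals merged, within bounds, non-overlapping
  iv <- ref$cds
  expect_true(all(iv$start >= 0 & iv$end <= ref$total_length))
  expect_true(all(diff(iv$start) > 0))
  expect_true(all(iv$start[-1] >= head(iv$end, -1)))
})

test_that("generator output is byte-identical for a fixed seed", {
  cfg <- sim_config(genome_length = 20000, seed = 11, n_segments = 2,
                    ish_site_rate = 1e-3)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_filament(cfg, outdir = d1)
  simulate_filament(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = sprintf("file %s", f))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("zero mutation rates reproduce the reference exactly", {
  cfg <- sim_config(genome_length = 20000, snp_rate_cds = 0,
                    snp_rate_ncds = 0, indel_rate_cds = 0,
                    indel_rate_ncds = 0, seed = 4)
  ref <- generate_reference(cfg)
  m <- mutate_consensus(ref, cfg, 1)
  expect_identical(m$genome$contigs[[1]], ref$contigs[[1]])
  expect_identical(nrow(m$truth), 0L)
})

test_that("truth mutation counts fall in the Poisson 99% interval of the
           planted expectation", {
  # expected total ~ 130 on a 400 kbp genome
  L <- 4e5
  cfg <- sim_config(genome_length = L, snp_rate_cds = 130 / L,
                    snp_rate_ncds = 130 / L, indel_rate_cds = 0,
                    indel_rate_ncds = 0, seed = 21)
  ref <- generate_reference(cfg)
  m <- mutate_consensus(ref, cfg, 1)
  n <- nrow(m$truth)
  interval <- qpois(c(0.005, 0.995), 130)
  expect_gte(n, interval[1])
  expect_lte(n, interval[2])
})

test_that("divergence guard and segment-id bounds are enforced", {
  cfg <- sim_config(genome_length = 20000, seed = 5)
  ref <- generate_reference(cfg)
  bad <- sim_config(genome_length = 20000, snp_rate_cds = 0.2, seed = 5)
  expect_error(mutate_consensus(ref, bad, 1), class = "fp_config_error")
  expect_error(mutate_consensus(ref, cfg, 0), class = "fp_config_error")
  expect_error(mutate_consensus(ref, cfg, 7), class = "fp_config_error")
})

test_that("indel truth records are single-nucleotide events and
           compartment counts are conserved", {
  cfg <- sim_config(genome_length = 1e5, snp_rate_cds = 2e-4,
                    snp_rate_ncds = 5e-4, indel_rate_cds = 1e-4,
                    indel_rate_ncds = 3e-4, seed = 8)
  ref <- generate_reference(cfg)
  for (s in 1:2) {
    tr <- mutate_consensus(ref, cfg, s)$truth
    ind <- tr[tr$class != "SNP"]
    expect_true(all(nchar(ind$ref) == 1 & nchar(ind$alt) == 1))
    expect_true(all(ind$class %in% c("insertion", "deletion")))
    # conservation: CDS + nCDS = total, per class
    expect_identical(sum(tr$compartment == "CDS") +
                       sum(tr$compartment == "nCDS"), nrow(tr))
  }
})

test_that("doubling the non-coding SNP rate doubles the expected nCDS
           truth count", {
  L <- 2e5
  tot1 <- 0; tot2 <- 0
  for (s in 1:5) {
    c1 <- sim_config(genome_length = L, snp_rate_ncds = 1e-3,
                     indel_rate_ncds = 0, seed = 100 + s)
    c2 <- sim_config(genome_length = L, snp_rate_ncds = 2e-3,
                     indel_rate_ncds = 0, seed = 100 + s)
    ref <- generate_reference(c1)
    tot1 <- tot1 + sum(mutate_consensus(ref, c1, 1)$truth$compartment == "nCDS")
    tot2 <- tot2 + sum(mutate_consensus(ref, c2, 1)$truth$compartment == "nCDS")
  }
  # tot1 ~ Pois(120), tot2 ~ Pois(240): ratio within 3-sigma tolerance
  expect_gt(tot2 / tot1, 1.4)
  expect_lt(tot2 / tot1, 2.6)
})

test_that("noise-free pileups are pure reference", {
  cfg <- sim_config(genome_length = 10000, seq_error_rate = 0,
                    coverage_mean = 50, seed = 6)
  seq <- random_seq(5000, seed = 6)
  p <- simulate_pileup(seq, cfg, NULL, seed = 9)
  expect_true(all(p$depth == p$A + p$C + p$G + p$T))
  cnt <- as.matrix(p[, c("A", "C", "G", "T")])
  refc <- cnt[cbind(seq_len(nrow(p)), match(p$ref, c("A", "C", "G", "T")))]
  expect_identical(refc, p$depth)
})

test_that("sampled ISH allele fraction falls in the binomial 99% interval", {
  cfg <- sim_config(genome_length = 10000, coverage_mean = 400,
                    seq_error_rate = 0, seed = 6)
  seq <- random_seq(2000, seed = 13)
  ref1 <- substr(seq, 1001, 1001)
  alt1 <- setdiff(c("A", "C", "G", "T"), ref1)[1]
  truth <- data.table::data.table(segment = 1L, contig = "c", pos = 1000L,
                                  ref = ref1, alt = alt1, freq = 0.4,
                                  colocalized = FALSE)
  p <- simulate_pileup(seq, cfg, truth, seed = 22)
  row <- p[p$pos == 1001L]
  altn <- row[[alt1]]
  interval <- qbinom(c(0.005, 0.995), row$depth, 0.4)
  expect_gte(altn, interval[1])
  expect_lte(altn, interval[2])
  expect_error(
    simulate_pileup(seq, cfg,
                    data.table::data.table(segment = 1L, contig = "c",
                                           pos = 5000L, ref = "A", alt = "C",
                                           freq = 0.4, colocalized = FALSE),
                    seed = 22),
    class = "fp_coordinate_error")
})

test_that("sequencing error alone never reaches the calling threshold at
           coverage >= 100", {
  cfg <- sim_config(genome_length = 2e5, seq_error_rate = 0.01,
                    coverage_mean = 380, seed = 17)
  seq <- random_seq(2e5, seed = 17)
  p <- simulate_pileup(seq, cfg, NULL, seed = 18)
  ev <- call_ish(p, ish_config(), one_based = TRUE)
  expect_identical(nrow(ev), 0L)
})

test_that("planted ISH sites split into colocalized and private per the
           configured fraction", {
  cfg <- sim_config(genome_length = 1e5, ish_site_rate = 2e-3,
                    colocalized_fraction = 1 / 3, seed = 30)
  ref <- generate_reference(cfg)
  ish <- simulate_ish_truth(ref, cfg)
  sites <- unique(ish[, c("pos", "alt", "colocalized")])
  f <- mean(sites$colocalized)
  expect_equal(f, 1 / 3, tolerance = 0.02)
  # colocalized sites appear with identical position and allele in all segments
  shared <- ish[ish$colocalized == TRUE]
  per_site <- split(shared$segment, shared$pos)
  expect_true(all(vapply(per_site, function(s)
    identical(sort(s), 1:cfg$n_segments), logical(1))))
  # expected events per segment ~ rate * L
  expect_equal(mean(table(ish$segment)), cfg$ish_site_rate * 1e5,
               tolerance = 0.15)
})
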