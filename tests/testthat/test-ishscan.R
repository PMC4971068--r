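test_that("pileup round-trip preserves columns and validates structure", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("#contig\tpos\tref\tdepth\tA\tC\tG\tT\tins\tdel",
               "c1\t100\tA\t100\t74\t26\t0\t0\t0\t0",
               "c1\t101\tC\t50\t0\t50\t0\t0\t2\t0"), f)
  p <- read_pileup(f)
  expect_identical(nrow(p), 2L)
  expect_identical(p$pos, c(99L, 100L))   # converted to 0-based
  expect_identical(p$A[1], 74L)
  expect_identical(p$C[1], 26L)
  expect_identical(p$depth[1], 100L)
  unlink(f)
})

test_that("malformed, disordered and empty pileups are handled", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("c1\t1\tA\t50\t49\t0\t0\t0\t0\t0"), f)  # sum 49 != 50
  expect_error(read_pileup(f), class = "fp_pileup_error")
  expect_error(read_pileup(f), "depth != A\\+C\\+G\\+T at line 1")
  writeLines(c("c1\t5\tA\t10\t10\t0\t0\t0\t0\t0",
               "c1\t3\tA\t10\t10\t0\t0\t0\t0\t0"), f)
  expect_error(read_pileup(f), class = "fp_pileup_error")
  writeLines(character(0), f)
  expect_identical(nrow(read_pileup(f)), 0L)
  unlink(f)
})

test_that("ISH calling flips exactly at the coverage and frequency
           thresholds", {
  cfg <- ish_config(min_coverage = 100, min_variant_frequency = 0.25)
  # 26/100 = 0.26 >= 0.25 -> one SNV
  ev <- call_ish(pileup_columns(list(pos = 0L, ref = "A", depth = 100L,
                                     A = 74L, C = 26L)), cfg)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$class, "SNV")
  expect_identical(ev$allele, "C")
  expect_identical(ev$consensus, "A")
  expect_equal(ev$freq, 0.26)
  # coverage 99 -> below the floor, nothing
  ev <- call_ish(pileup_columns(list(pos = 0L, ref = "A", depth = 99L,
                                     A = 70L, C = 29L)), cfg)
  expect_identical(nrow(ev), 0L)
  # 48/200 = 0.24 -> below frequency threshold
  ev <- call_ish(pileup_columns(list(pos = 0L, ref = "A", depth = 200L,
                                     A = 150L, C = 48L, G = 2L)), cfg)
  expect_identical(nrow(ev), 0L)
  # exactly 50/200 = 0.25 qualifies
  ev <- call_ish(pileup_columns(list(pos = 0L, ref = "A", depth = 200L,
                                     A = 150L, C = 50L)), cfg)
  expect_identical(nrow(ev), 1L)
})

test_that("indel read counts yield events and consensus ties break
           lexicographically", {
  cfg <- ish_config()
  col <- pileup_columns(list(pos = 0L, ref = "A", depth = 120L, A = 90L,
                             C = 30L, ins = 40L, del = 30L))
  ev <- call_ish(col, cfg)
  expect_setequal(ev$class, c("SNV", "insertion", "deletion"))
  no_ind <- call_ish(col, ish_config(count_indels = FALSE))
  expect_identical(no_ind$class, "SNV")
  # tie A=C=60: consensus A (lexicographically smallest), C is the variant
  tie <- call_ish(pileup_columns(list(pos = 0L, ref = "G", depth = 120L,
                                      A = 60L, C = 60L)), cfg)
  expect_identical(tie$consensus, "A")
  expect_identical(tie$allele, "C")
})

test_that("a column yields at most 3 SNV plus 2 indel events", {
  cfg <- ish_config()
  ev <- call_ish(pileup_columns(list(pos = 0L, ref = "A", depth = 400L,
                                     A = 100L, C = 100L, G = 100L,
                                     T = 100L, ins = 400L, del = 400L)),
                 cfg)
  expect_identical(sum(ev$class == "SNV"), 3L)
  expect_identical(sum(ev$class != "SNV"), 2L)
})

test_that("raising either threshold never increases the event count", {
  cfg0 <- sim_config(genome_length = 20000, ish_site_rate = 5e-3,
                     coverage_mean = 150, seed = 31)
  ref <- generate_reference(cfg0)
  ish <- simulate_ish_truth(ref, cfg0)
  p <- simulate_pileup(ref$contigs[[1]], cfg0, ish[ish$segment == 1],
                       seed = 32)
  p$pos <- p$pos - 1L
  prev_by_freq <- Inf
  for (freq in c(0.25, 0.3, 0.35, 0.4, 0.5)) {
    n <- nrow(call_ish(p, ish_config(min_variant_frequency = freq)))
    expect_lte(n, prev_by_freq)
    prev_by_freq <- n
  }
  prev_by_cov <- Inf
  for (cov in c(31, 100, 140, 160)) {
    n <- nrow(call_ish(p, ish_config(min_coverage = cov)))
    expect_lte(n, prev_by_cov)
    prev_by_cov <- n
  }
})

test_that("called events recover planted sites with high sensitivity and
           no false sites", {
  cfg <- sim_config(genome_length = 2e5, ish_site_rate = 1e-3,
                    ish_freq_low = 0.3, ish_freq_high = 0.45,
                    coverage_mean = 380, seq_error_rate = 0.005,
                    seed = 33)
  ref <- generate_reference(cfg)
  ish <- simulate_ish_truth(ref, cfg)
  truth1 <- ish[ish$segment == 1]
  p <- simulate_pileup(ref$contigs[[1]], cfg, truth1, seed = 34)
  ev <- call_ish(p, ish_config(), segment = 1, one_based = TRUE)
  key_t <- paste(truth1$pos, truth1$alt)
  key_e <- paste(ev$pos, ev$allele)
  expect_gte(mean(key_t %in% key_e), 0.99)
  expect_identical(setdiff(key_e, key_t), character(0))
})

test_that("co-localization counts shared sites and is invariant under
           segment relabeling", {
  ev3 <- data.table::rbindlist(lapply(1:3, function(s)
    data.table::data.table(segment = s, contig = "c1", pos = 10L,
                           class = "SNV", allele = "G")))
  cl <- colocalize(ev3, 3)
  expect_identical(cl$n_sites_shared_by_all, 1L)
  expect_identical(cl$fraction_colocalized, 1)
  expect_identical(cl$fraction_not_colocalized, 0)
  disjoint <- data.table::data.table(segment = 1:3, contig = "c1",
                                     pos = c(1L, 2L, 3L), class = "SNV",
                                     allele = "G")
  cl2 <- colocalize(disjoint, 3)
  expect_identical(cl2$n_sites_shared_by_all, 0L)
  expect_identical(cl2$fraction_not_colocalized, 1)
  # relabeling
  relab <- data.table::copy(disjoint)
  relab$segment <- c(3L, 1L, 2L)
  expect_identical(colocalize(relab, 3)$n_sites_shared_by_all,
                   cl2$n_sites_shared_by_all)
  # mismatching allele at the same position is not co-localized
  mixed <- data.table::data.table(segment = 1:2, contig = "c1", pos = 10L,
                                  class = "SNV", allele = c("G", "T"))
  expect_identical(colocalize(mixed, 2)$n_sites_shared_by_all, 0L)
  # shared-by-all is bounded by the smallest per-segment site count
  expect_lte(cl$n_sites_shared_by_all, min(cl$n_events_per_segment))
})

test_that("intra- vs inter-segment ratio behaves on trivial inputs", {
  ev <- data.table::data.table(segment = rep(1:2, each = 5), contig = "c1",
                               pos = 1:10, class = "SNV", allele = "G")
  cmp <- list(list(reference_id = "segment_1", query_id = "segment_2",
                   total_snps = 5L, aligned = TRUE),
              list(reference_id = "segment_2", query_id = "segment_1",
                   total_snps = 5L, aligned = TRUE))
  r <- intra_vs_inter(ev, cmp)
  expect_equal(r$ratio, 1)
  expect_identical(r$n_pairs, 2L)
  expect_true(isTRUE(intra_vs_inter(ev[0], cmp)$empty))
  expect_true(isTRUE(intra_vs_inter(ev, list())$empty))
})
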