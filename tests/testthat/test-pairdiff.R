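test_that("identical sequences give one full-length anchor and no variants", {
  s <- random_seq(10000, seed = 1)
  a <- find_anchors(s, s, 21)
  expect_identical(nrow(a), 1L)
  expect_identical(a$qstart, 0L)
  expect_identical(a$tstart, 0L)
  expect_identical(a$length, 10000L)
  expect_identical(unname(anchored_counts(s, s)),
                   c(0L, 0L, 0L))
})

test_that("a single substitution splits the anchor into two flanking
           anchors", {
  s <- random_seq(10000, seed = 2)
  v <- strsplit(s, "")[[1]]
  v[5001] <- setdiff(c("A", "C", "G", "T"), v[5001])[1]
  q <- paste(v, collapse = "")
  a <- find_anchors(q, s, 21)
  expect_identical(nrow(a), 2L)
  expect_identical(a$qstart, c(0L, 5001L))
  expect_identical(a$length, c(5000L, 4999L))
})

test_that("anchor finding agrees with a brute-force k-mer dictionary", {
  s <- random_seq(50000, seed = 3)
  pl <- plant_variants(s, n_sub = 10, seed = 4)
  a <- find_anchors(pl$seq, s, 21)
  o <- brute_force_anchors(pl$seq, s, 21)
  expect_identical(as.data.frame(a), o)
})

test_that("anchors skip N-containing windows and k is validated", {
  s1 <- random_seq(2000, seed = 5)
  s2 <- paste0(substr(s1, 1, 1000), "N", substr(s1, 1002, 2000))
  a <- find_anchors(s2, s1, 21)
  expect_true(all(a$qstart + a$length <= 1000 | a$qstart >= 1001))
  expect_error(find_anchors(s1, s1, 20), class = "fp_config_error")
  expect_error(find_anchors(s1, s1, 9), class = "fp_config_error")
  expect_identical(nrow(find_anchors("", s1)), 0L)
})

test_that("chaining matches exhaustive enumeration and handles edge cases", {
  # weighted-LIS example: the long anchor beats the colinear short pair
  an <- data.table::data.table(qstart = c(0L, 200L, 300L),
                               tstart = c(0L, 500L, 200L),
                               length = c(100L, 100L, 400L))
  ch <- chain_anchors(an)
  oracle <- brute_force_chain(as.data.frame(an))
  expect_identical(as.data.frame(ch)[, c("qstart", "tstart", "length")],
                   oracle[, c("qstart", "tstart", "length")],
                   ignore_attr = TRUE)
  expect_identical(ch$qstart, c(0L, 300L))
  # colinear anchors are all retained
  co <- data.table::data.table(qstart = c(0L, 150L, 400L),
                               tstart = c(10L, 160L, 420L),
                               length = c(100L, 100L, 100L))
  expect_identical(nrow(chain_anchors(co)), 3L)
  # single anchor, empty input
  expect_identical(nrow(chain_anchors(co[1])), 1L)
  expect_identical(nrow(chain_anchors(co[0])), 0L)
})

test_that("chaining matches exhaustive enumeration on random anchor sets", {
  set.seed(6)
  for (i in 1:20) {
    n <- sample(3:8, 1)
    an <- data.frame(qstart = sort(sample(0:500, n)),
                     tstart = sample(0:500, n),
                     length = sample(10:80, n, replace = TRUE))
    ch <- chain_anchors(data.table::as.data.table(an))
    oracle <- brute_force_chain(an)
    expect_identical(attr(ch, "total_anchor_length"), sum(oracle$length))
  }
})

test_that("gap alignment produces the expected transcripts on toy pairs", {
  # one mismatch
  al <- align_global("ACGT", "ACTT")
  expect_identical(al$transcript, "MMXM")
  # single-base gap: present in target only -> deletion from the query
  al2 <- align_global("ACT", "ACGT")
  tc <- transcript_counts(al2$transcript)
  expect_identical(unname(tc[c("deletion", "insertion", "snp")]),
                   c(1L, 0L, 0L))
  # and the reverse orientation is a single insertion
  al3 <- align_global("ACGT", "ACT")
  expect_identical(unname(transcript_counts(al3$transcript)[["insertion"]]), 1L)
})

test_that("banded alignment equals the unbanded oracle and an independent
           aligner on random gap pairs", {
  set.seed(7)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    a <- random_seq(n)
    b <- if (runif(1) < 0.3 || n < 15) random_seq(sample(5:50, 1)) else {
      pl <- plant_variants(a, n_sub = 3, seed = i)
      pl$seq
    }
    banded <- filoplast:::cpp_banded_align(a, b, 256L)
    full <- align_global(a, b)
    expect_identical(banded$score, full$score)
    if (i <= 50) {
      pa <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                          substitutionMatrix = mat,
                                          gapOpening = 2, gapExtension = 1)
      expect_identical(full$score, as.integer(Biostrings::score(pa)))
    }
  }
})

test_that("planted substitutions and deletions are recovered at their
           coordinates with correct compartments", {
  L <- 100000
  target <- random_seq(L, seed = 8)
  cds <- data.frame(contig = "c1",
                    start = seq(0L, L - 2000L, by = 2000L),
                    end = seq(0L, L - 2000L, by = 2000L) + 1500L)
  g <- annotated_genome(c(c1 = target), cds, id = "target")
  pl <- plant_variants(target, n_sub = 25, n_del = 5, seed = 9)
  ch <- chain_anchors(find_anchors(pl$seq, target, 21))
  al <- align_gaps(pl$seq, target, ch)
  v <- call_variants(al, g, "c1")
  expect_identical(sort(v$pos[v$class == "SNP"]), sort(pl$sub_pos))
  expect_identical(sort(v$pos[v$class == "deletion"]), sort(pl$del_pos))
  expect_identical(nrow(v), 30L)
  # compartment forced by interval membership
  expected <- ifelse(v$pos %% 2000 < 1500, "CDS", "nCDS")
  expect_identical(v$compartment, expected)
})

test_that("a run of gap columns yields one event per base by default and
           one per run on request", {
  target <- random_seq(5000, seed = 10)
  v <- strsplit(target, "")[[1]]
  v[2001:2003] <- ""   # 3-base deletion from the query
  q <- paste(v, collapse = "")
  g <- annotated_genome(c(c1 = target), NULL, id = "t")
  ch <- chain_anchors(find_anchors(q, target, 21))
  al <- align_gaps(q, target, ch)
  per_base <- call_variants(al, g, "c1")
  expect_identical(sum(per_base$class == "deletion"), 3L)
  per_run <- call_variants(al, g, "c1", indel_events = "per_run")
  expect_identical(sum(per_run$class == "deletion"), 1L)
})

test_that("per-100-kbp rates reproduce published cell arithmetic", {
  expect_identical(round_half_up(rate_per_100kbp(132, 3217969), 2), 4.10)
  expect_identical(round_half_up(rate_per_100kbp(86, 3239714), 2), 2.65)
  expect_identical(round_half_up(rate_per_100kbp(300, 2544604), 2), 11.79)
  expect_identical(round_half_up(rate_per_100kbp(41, 374878), 2), 10.94)
  expect_identical(rate_per_100kbp(0, 1000), 0)
  expect_error(rate_per_100kbp(1, 0), class = "fp_config_error")
  expect_error(rate_per_100kbp(-1, 10), class = "fp_config_error")
})

test_that("self-comparison is all-zero and unalignable pairs are flagged,
           not zeroed", {
  cfg <- sim_config(genome_length = 30000, seed = 12)
  ref <- generate_reference(cfg)
  self <- compare_pair(ref, ref)
  expect_true(self$aligned)
  expect_identical(self$total_snps, 0L)
  expect_identical(self$total_indels, 0L)
  expect_identical(self$snps_per_100kbp, 0)
  other <- annotated_genome(c(c1 = random_seq(30000, seed = 99)), NULL,
                            id = "unrelated")
  cp <- compare_pair(ref, other)
  expect_false(cp$aligned)
  expect_true(is.na(cp$total_snps))
})

test_that("comparison counts satisfy compartment conservation and match
           simulator truth", {
  cfg <- sim_config(genome_length = 2e5, snp_rate_cds = 1e-4,
                    snp_rate_ncds = 3e-4, indel_rate_cds = 2e-5,
                    indel_rate_ncds = 1e-4, seed = 14)
  ref <- generate_reference(cfg)
  m <- mutate_consensus(ref, cfg, 1)
  # reference as query column: variants called on the reference coordinates
  cp <- compare_pair(m$genome, ref)
  expect_identical(cp$snps_cds + cp$snps_ncds, cp$total_snps)
  expect_identical(cp$indels_cds + cp$indels_ncds, cp$total_indels)
  expect_identical(cp$total_snps, sum(m$truth$class == "SNP"))
  expect_identical(cp$total_indels, sum(m$truth$class != "SNP"))
  expect_identical(sort(cp$variants$pos[cp$variants$class == "SNP"]),
                   sort(m$truth$pos[m$truth$class == "SNP"]))
  # compartments agree with the truth labels at SNP positions
  vt <- merge(cp$variants[cp$variants$class == "SNP"],
              m$truth[m$truth$class == "SNP"], by = "pos")
  expect_identical(vt$compartment.x, vt$compartment.y)
})

test_that("SNP counts are direction-symmetric on indel-free simulations", {
  cfg <- sim_config(genome_length = 1e5, snp_rate_cds = 2e-4,
                    snp_rate_ncds = 4e-4, indel_rate_cds = 0,
                    indel_rate_ncds = 0, seed = 15, n_segments = 2)
  ref <- generate_reference(cfg)
  a <- mutate_consensus(ref, cfg, 1)$genome
  b <- mutate_consensus(ref, cfg, 2)$genome
  ab <- compare_pair(a, b)
  ba <- compare_pair(b, a)
  expect_identical(ab$total_snps, ba$total_snps)
})
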