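#!/usr/bin/env Rscript

# Generate the synthetic clonal filament used by the downstream analyses:
# a 500 kbp, 34% G+C, 88% coding reference; six segment consensuses at
# near-clonal divergence; planted ISH sites (a third co-localized across
# all six segments); and per-segment pileups at 380x.  Full-size genome
# files and pileups go to scratch/ (regenerable from the seed); summary
# statistics of the planted truth go to results/.

suppressMessages({
  library(filoplast)
  library(data.table)
})

cfg <- sim_config(genome_length = 5e5, seed = 20260930)
dir.create("results", showWarnings = FALSE)
sim <- simulate_filament(cfg, outdir = "scratch/sim")

truth <- sim$consensus_truth
per_seg <- truth[, .(n_snps = sum(class == "SNP"),
                     n_indels = sum(class != "SNP"),
                     n_cds = sum(compartment == "CDS"),
                     n_ncds = sum(compartment == "nCDS")),
                 by = segment]
fwrite(per_seg, "results/01_truth_per_segment.tsv", sep = "\t")

sites <- unique(sim$ish_truth[, .(pos, alt, colocalized)])
overview <- data.table(
  genome_bp = sim$reference$total_length,
  coding_fraction = sim$reference$cds_length / sim$reference$total_length,
  n_segments = cfg$n_segments,
  truth_variants = nrow(truth),
  ish_distinct_sites = nrow(sites),
  ish_colocalized_fraction = mean(sites$colocalized),
  mean_ish_events_per_segment = nrow(sim$ish_truth) / cfg$n_segments)
fwrite(overview, "results/01_simulation_overview.tsv", sep = "\t")

cat(sprintf(
  "simulated %d bp genome (%.1f%% coding), %d segments, %d consensus variants, %d ISH sites (%.2f co-localized)\n",
  overview$genome_bp, 100 * overview$coding_fraction, cfg$n_segments,
  overview$truth_variants, overview$ish_distinct_sites,
  overview$ish_colocalized_fraction))
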