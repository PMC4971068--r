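#' Run the full filament-plasticity pipeline
#'
#' Orchestrates simulation (or loading of real inputs), pairwise
#' comparison of all ordered assembly pairs, ISH calling and
#' co-localization, fragment ANI over all unordered pairs, and the
#' summary tables, then serializes everything to an output directory with
#' a run manifest.  Fixed seed implies identical summary output across
#' runs.
#'
#' @param config nested list (or path to a JSON file) with sections:
#'   \describe{
#'     \item{sim}{arguments for [sim_config()]; if present the inputs are
#'       simulated.}
#'     \item{inputs}{alternatively, `fasta`/`gff3` character vectors (one
#'       per segment) and `pileups` paths; a partial specification fails
#'       fast with a listing of what is missing.}
#'     \item{ish}{arguments for [ish_config()].}
#'     \item{ani}{arguments for [ani_config()]; `run = FALSE` skips ANI.}
#'     \item{pairdiff}{`k`, `band`, `gap_cap`.}
#'   }
#' @param outdir output directory (created).
#' @return invisibly, a list with all in-memory results (`sim`,
#'   `comparisons`, `matrix`, `ish_events`, `colocalization`,
#'   `intra_vs_inter`, `ani`, `summaries`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  pd <- config$pairdiff
  k <- pd$k %||% 21; band <- pd$band %||% 256
  gap_cap <- pd$gap_cap %||% 20000

  if (!is.null(config$sim)) {
    scfg <- do.call(sim_config, config$sim)
    sim <- simulate_filament(scfg)
    genomes <- sim$segments
    pileups <- sim$pileups
  } else {
    inp <- config$inputs
    missing <- c(
      if (is.null(inp$fasta)) "inputs$fasta",
      if (is.null(inp$pileups)) "inputs$pileups")
    if (is.null(inp) || length(missing))
      fp_stop("fp_config_error",
              "incomplete configuration; missing: %s",
              paste(missing, collapse = ", "))
    sim <- NULL
    genomes <- lapply(seq_along(inp$fasta), function(i)
      read_genome(inp$fasta[i], if (!is.null(inp$gff3)) inp$gff3[i],
                  id = sprintf("segment_%d", i)))
    names(genomes) <- vapply(genomes, `[[`, character(1), "id")
    pileups <- lapply(inp$pileups, read_pileup)
    names(pileups) <- names(genomes)[seq_along(pileups)]
  }
  n <- length(genomes)
  ids <- names(genomes)

  # all ordered off-diagonal pairs
  comparisons <- list()
  for (r in seq_len(n)) for (q in seq_len(n)) {
    if (r == q) next
    comparisons[[length(comparisons) + 1]] <-
      compare_pair(genomes[[r]], genomes[[q]], k = k, band = band,
                   gap_cap = gap_cap)
  }
  mat <- build_matrix(comparisons, ids)

  icfg <- do.call(ish_config, config$ish %||% list())
  one_based <- !is.null(config$sim)  # simulated pileups carry 1-based pos
  events <- rbindlist(lapply(seq_along(pileups), function(s)
    call_ish(pileups[[s]], icfg, segment = s, one_based = one_based)))
  coloc <- colocalize(events, n_segments = n)
  ivi <- intra_vs_inter(events, comparisons)

  acfg_args <- config$ani %||% list()
  run_ani <- !isFALSE(acfg_args$run)
  acfg_args$run <- NULL
  ani <- NULL
  if (run_ani) {
    acfg <- do.call(ani_config, acfg_args)
    ani <- list()
    for (a in seq_len(n - 1)) for (b in seq((a + 1), n)) {
      res <- compute_ani(genomes[[a]], genomes[[b]], acfg, k = k)
      ani[[sprintf("%s|%s", ids[a], ids[b])]] <- res
    }
  }

  summaries <- lapply(
    c("snps_per_100kbp", "snps_cds_per_100kbp", "snps_ncds_per_100kbp",
      "indels_per_100kbp", "indels_cds_per_100kbp",
      "indels_ncds_per_100kbp"),
    function(m) summarize_rates(mat, m, seq_len(n)))
  names(summaries) <- vapply(summaries, `[[`, character(1), "metric")

  # serialize
  fwrite(format_matrix(mat), file.path(outdir, "pairwise_matrix.tsv"),
         sep = "\t")
  variants <- rbindlist(lapply(comparisons, function(cp) {
    if (!isTRUE(cp$aligned) || is.null(cp$variants) ||
        nrow(cp$variants) == 0) return(NULL)
    cbind(data.table(ref_segment = cp$reference_id,
                     query_segment = cp$query_id),
          cp$variants[, list(contig, pos = pos + 1L, class, ref, alt,
                             compartment)])
  }))
  fwrite(variants, file.path(outdir, "pairwise_variants.tsv"), sep = "\t")
  fwrite(events, file.path(outdir, "ish_events.tsv"), sep = "\t")
  if (length(coloc$site_matrix))
    fwrite(coloc$site_matrix, file.path(outdir, "ish_site_matrix.tsv"),
           sep = "\t")
  summary_json <- list(
    segments = ids,
    rate_summaries = lapply(summaries, function(s)
      list(metric = s$metric, n_values = s$n_values,
           mean = round_half_up(s$mean, 1), sd = round_half_up(s$sd, 1))),
    ish = list(
      n_events_per_segment = coloc$n_events_per_segment,
      mean_events_per_segment = mean(coloc$n_events_per_segment),
      n_sites = coloc$n_sites,
      n_sites_shared_by_all = coloc$n_sites_shared_by_all,
      fraction_colocalized = coloc$fraction_colocalized,
      fraction_colocalized_2plus = coloc$fraction_colocalized_2plus),
    intra_vs_inter = ivi,
    ani = if (!is.null(ani)) lapply(ani, function(a)
      list(two_way = if (is.na(a$two_way_ani)) NULL else
        round_half_up(a$two_way_ani, 2))))
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  cfg_file <- file.path(outdir, "config_echo.json")
  jsonlite::write_json(config, cfg_file, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    tool = "filoplast", version = as.character(packageVersion("filoplast")),
    seed = config$sim$seed %||% NA,
    config_md5 = unname(tools::md5sum(cfg_file)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(sim = sim, comparisons = comparisons, matrix = mat,
                 ish_events = events, colocalization = coloc,
                 intra_vs_inter = ivi, ani = ani, summaries = summaries))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
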