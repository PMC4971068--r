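ROW_METRICS <- c("total_snps", "snps_per_100kbp", "total_indels",
                 "indels_per_100kbp", "snps_cds", "snps_cds_per_100kbp",
                 "snps_ncds_per_100kbp", "indels_cds",
                 "indels_cds_per_100kbp", "indels_ncds_per_100kbp")

#' Pairwise heterogeneity matrix
#'
#' Assembles per-pair comparisons into the block-structured table used to
#' report filament heterogeneity: one block per reference segment with
#' rows total SNPs; SNPs/100 kbp; total indels; indels/100 kbp; SNPs in
#' CDS; SNPs in CDS/100 kbp; SNPs in nCDS/100 kbp; indels in CDS; indels
#' in CDS/100 kbp; indels in nCDS/100 kbp, and one column per query
#' segment.  Diagonal (self) cells are zero; a missing pair is an `NA`
#' gap cell, never a zero.
#'
#' @param comparisons list of [compare_pair()] results covering the
#'   ordered off-diagonal pairs (missing ones become gap cells).
#' @param segment_ids character vector of assembly ids in display order.
#' @return object of class `pairwise_matrix`: `metrics` (named list of
#'   numeric ref x query matrices, full precision) and `segment_ids`.
#' @export
build_matrix <- function(comparisons, segment_ids) {
  n <- length(segment_ids)
  mats <- lapply(ROW_METRICS, function(m) {
    M <- matrix(NA_real_, n, n, dimnames = list(segment_ids, segment_ids))
    diag(M) <- 0
    M
  })
  names(mats) <- ROW_METRICS
  for (cp in comparisons) {
    if (!cp$reference_id %in% segment_ids ||
        !cp$query_id %in% segment_ids) next
    r <- cp$reference_id; q <- cp$query_id
    for (m in ROW_METRICS)
      mats[[m]][r, q] <- if (isTRUE(cp$aligned) || !is.null(cp[[m]]))
        as.numeric(cp[[m]]) else NA_real_
  }
  structure(list(metrics = mats, segment_ids = segment_ids),
            class = "pairwise_matrix")
}

#' Build the pairwise matrix from printed counts and lengths
#'
#' Reconstructs the full rate table from a long table of pairwise variant
#' counts plus per-assembly lengths -- the arithmetic by which every
#' per-100-kbp cell of a published heterogeneity table is recomputed from
#' its printed counts.  nCDS counts are total minus CDS; every rate uses
#' the query (column) assembly's total/CDS/nCDS length as denominator.
#'
#' @param counts `data.table` with columns `ref_segment`, `query_segment`,
#'   `total_snps`, `snps_cds`, `total_indels`, `indels_cds`.
#' @param lengths `data.table` with columns `segment`, `assembly_bp`,
#'   `cds_bp`, `ncds_bp`.
#' @return a `pairwise_matrix` (full precision; round for display).
#' @export
matrix_from_counts <- function(counts, lengths) {
  segs <- as.character(lengths$segment)
  n <- length(segs)
  len <- setNames(lengths$assembly_bp, segs)
  cds <- setNames(lengths$cds_bp, segs)
  ncds <- setNames(lengths$ncds_bp, segs)
  stopifnot(all(cds + ncds == len))
  mats <- lapply(ROW_METRICS, function(m) {
    M <- matrix(NA_real_, n, n, dimnames = list(segs, segs))
    diag(M) <- 0
    M
  })
  names(mats) <- ROW_METRICS
  for (i in seq_len(nrow(counts))) {
    r <- as.character(counts$ref_segment[i])
    q <- as.character(counts$query_segment[i])
    ts <- counts$total_snps[i]; cs <- counts$snps_cds[i]
    ti <- counts$total_indels[i]; ci <- counts$indels_cds[i]
    mats$total_snps[r, q] <- ts
    mats$snps_cds[r, q] <- cs
    mats$total_indels[r, q] <- ti
    mats$indels_cds[r, q] <- ci
    mats$snps_per_100kbp[r, q] <- rate_per_100kbp(ts, len[q])
    mats$snps_cds_per_100kbp[r, q] <- rate_per_100kbp(cs, cds[q])
    mats$snps_ncds_per_100kbp[r, q] <- rate_per_100kbp(ts - cs, ncds[q])
    mats$indels_per_100kbp[r, q] <- rate_per_100kbp(ti, len[q])
    mats$indels_cds_per_100kbp[r, q] <- rate_per_100kbp(ci, cds[q])
    mats$indels_ncds_per_100kbp[r, q] <- rate_per_100kbp(ti - ci, ncds[q])
  }
  structure(list(metrics = mats, segment_ids = segs),
            class = "pairwise_matrix")
}

#' Serialize a pairwise matrix as display blocks
#'
#' @param matrix a `pairwise_matrix`.
#' @param digits decimals for rate rows (counts stay integer); rounding is
#'   half-up and applied only here, never during aggregation.
#' @return long `data.table`: ref_segment, metric, query columns.
#' @export
format_matrix <- function(matrix, digits = 2) {
  segs <- matrix$segment_ids
  rows <- list()
  for (r in segs) for (m in ROW_METRICS) {
    v <- matrix$metrics[[m]][r, ]
    if (grepl("per_100kbp", m)) v <- round_half_up(v, digits)
    rows[[length(rows) + 1]] <-
      c(list(ref_segment = r, metric = m), as.list(v))
  }
  rbindlist(rows)
}

#' Mean and standard deviation of a rate over a segment subset
#'
#' Collects the off-diagonal ordered-pair cells of one metric, either
#' within a subset (`mode = "within"`: all ordered pairs inside the
#' subset, 12 values for four segments) or involving it
#' (`mode = "involving"`: all ordered pairs with a subset member on
#' either side, 18 values for two of six segments), and returns their mean
#' and sample (n-1) standard deviation at full precision.
#'
#' @param matrix a `pairwise_matrix` (or plain numeric matrix with
#'   dimnames).
#' @param metric one of the matrix metrics, e.g. `"snps_per_100kbp"`.
#' @param segments integer or character ids of the subset (>= 2).
#' @param mode `"within"` or `"involving"`.
#' @return list of class `rate_summary`: `subset`, `metric`, `n_values`,
#'   `mean`, `sd`, `values`.
#' @export
summarize_rates <- function(matrix, metric, segments,
                            mode = c("within", "involving")) {
  mode <- match.arg(mode)
  M <- if (inherits(matrix, "pairwise_matrix"))
    matrix$metrics[[metric]] else matrix
  if (is.null(M)) fp_stop("fp_config_error", "unknown metric '%s'", metric)
  segs <- rownames(M)
  sel <- if (is.character(segments)) segments else segs[segments]
  if (length(sel) < 2 || !all(sel %in% segs))
    fp_stop("fp_config_error", "subset must name >= 2 known segments")
  idx <- which(segs %in% sel)
  take <- matrix(FALSE, nrow(M), ncol(M))
  if (mode == "within") {
    take[idx, idx] <- TRUE
  } else {
    take[idx, ] <- TRUE
    take[, idx] <- TRUE
  }
  diag(take) <- FALSE
  vals <- M[take]
  structure(list(subset = paste(sel, collapse = ","), metric = metric,
                 mode = mode, n_values = length(vals),
                 mean = mean(vals), sd = sd(vals), values = vals),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat(sprintf("%s [%s %s]: %.1f +/- %.1f (n = %d)\n", x$metric, x$mode,
              x$subset, round_half_up(x$mean, 1), round_half_up(x$sd, 1),
              x$n_values))
  invisible(x)
}

#' Bundled published filament heterogeneity table
#'
#' Loads the package's reference dataset: pairwise SNP/indel counts,
#' per-assembly lengths and the published per-100-kbp rate cells for six
#' consecutive segment assemblies of a single clonal Marithrix filament.
#' The counts and lengths reproduce the published rate cells exactly
#' under [matrix_from_counts()] except for one internally inconsistent
#' published row (segment 1, indels in CDS), whose printed count row
#' duplicates segment 3's.
#'
#' @return list: `lengths`, `counts` (long `data.table`s) and
#'   `printed_rates` (a `pairwise_matrix` holding the published cells).
#' @export
load_filament_table <- function() {
  ext <- system.file("extdata", package = "filoplast")
  lengths <- fread(file.path(ext, "marithrix_segment_lengths.tsv"))
  counts <- fread(file.path(ext, "marithrix_pairwise_counts.tsv"))
  rates_long <- fread(file.path(ext, "marithrix_pairwise_rates.tsv"))
  segs <- as.character(lengths$segment)
  mats <- lapply(split(rates_long, rates_long$metric), function(d) {
    M <- matrix(NA_real_, length(segs), length(segs),
                dimnames = list(segs, segs))
    M[cbind(as.character(d$ref_segment),
            as.character(d$query_segment))] <- d$value
    diag(M) <- 0
    M
  })
  printed <- structure(list(metrics = mats, segment_ids = segs),
                       class = "pairwise_matrix")
  list(lengths = lengths, counts = counts, printed_rates = printed)
}
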