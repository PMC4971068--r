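#' ISH calling configuration
#'
#' Thresholds for calling intrasegmental sequence heterogeneity from a
#' pileup: read heterogeneity is only robust above ~30x depth, so the
#' coverage floor must be at least 31; the defaults (coverage >= 100,
#' variant frequency >= 0.25) are the standard operating point for
#' libraries at several-hundred-fold coverage.
#'
#' @param min_coverage minimum read depth for a column to be evaluated
#'   (>= 31).
#' @param min_variant_frequency minimum variant-read fraction, in
#'   (0, 0.5].
#' @param count_indels whether insertion/deletion read counts are
#'   evaluated as candidate events.
#' @return validated list of class `ish_config`.
#' @export
ish_config <- function(min_coverage = 100, min_variant_frequency = 0.25,
                       count_indels = TRUE) {
  if (min_coverage < 31)
    fp_stop("fp_config_error",
            "min_coverage below the robustness floor of 31")
  if (min_variant_frequency <= 0 || min_variant_frequency > 0.5)
    fp_stop("fp_config_error",
            "min_variant_frequency must be in (0, 0.5]")
  structure(list(min_coverage = min_coverage,
                 min_variant_frequency = min_variant_frequency,
                 count_indels = isTRUE(count_indels)),
            class = "ish_config")
}

#' Read a pileup TSV
#'
#' Reads the pileup dialect used throughout the package: tab-separated
#' columns contig, pos (1-based), ref, depth, A, C, G, T, ins, del; lines
#' starting with `#` are comments.  To produce such a table from a sorted
#' BAM with standard tooling:
#' `samtools mpileup -aa -f ref.fa aln.bam` followed by counting the
#' A/C/G/T/insertion/deletion calls per column of the read-bases field.
#'
#' @param path file path.
#' @return validated `data.table` of pileup columns with `pos` converted
#'   to 0-based; depth must equal `A + C + G + T` on every row and
#'   positions must be non-decreasing within a contig.
#' @export
read_pileup <- function(path) {
  first <- readLines(path, n = 200L)
  skip <- if (length(first)) sum(cumprod(startsWith(first, "#"))) else 0L
  cols <- c("contig", "pos", "ref", "depth", "A", "C", "G", "T",
            "ins", "del")
  if (length(first) <= skip)
    return(data.table(contig = character(), pos = integer(),
                      ref = character(), depth = integer(), A = integer(),
                      C = integer(), G = integer(), T = integer(),
                      ins = integer(), del = integer()))
  d <- fread(path, skip = skip, header = FALSE, sep = "\t",
             col.names = cols,
             colClasses = list(character = c(1, 3),
                               integer = c(2, 4:10)))
  bad <- which(d$depth != d$A + d$C + d$G + d$T)
  if (length(bad))
    fp_stop("fp_pileup_error",
            "malformed pileup: depth != A+C+G+T at line %d",
            bad[1] + skip)
  ooo <- d[, any(diff(pos) < 0), by = contig]
  if (any(ooo$V1))
    fp_stop("fp_pileup_error", "pileup positions out of order on contig %s",
            ooo$contig[which(ooo$V1)[1]])
  if (any(d$ins > d$depth) || any(d$del > d$depth))
    fp_stop("fp_pileup_error",
            "insertion/deletion counts exceed coverage")
  d$pos <- d$pos - 1L
  d[]
}

#' Write a pileup TSV
#'
#' Inverse of [read_pileup()]; `pos` is written 1-based with a `#`-prefixed
#' header line.
#'
#' @param pileup pileup `data.table` (1-based `pos`, as produced by
#'   [simulate_pileup()]).
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_pileup <- function(pileup, path) {
  con <- file(path, "w")
  writeLines("#contig\tpos\tref\tdepth\tA\tC\tG\tT\tins\tdel", con)
  close(con)
  fwrite(pileup, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Call intrasegmental sequence heterogeneity events
#'
#' For every pileup column with depth at or above the coverage floor, the
#' consensus is the majority base (ties resolved to the lexicographically
#' smallest); every non-consensus allele -- the three other bases, plus
#' insertion and deletion counts when `count_indels` is set -- whose read
#' fraction reaches `min_variant_frequency` yields one event.  Variant
#' frequency is per-allele: variant reads over column depth.
#'
#' @param columns pileup `data.table` (0-based `pos`, from
#'   [read_pileup()], or 1-based from [simulate_pileup()] -- pass
#'   `one_based = TRUE` for the latter).
#' @param config an [ish_config()].
#' @param segment optional segment id attached to the events.
#' @param one_based whether `columns$pos` is 1-based and must be shifted.
#' @return `data.table` of events: segment, contig, pos (0-based),
#'   class `SNV|insertion|deletion`, consensus, allele, count, depth,
#'   freq; ordered by (contig, pos, allele).
#' @export
call_ish <- function(columns, config = ish_config(), segment = NA_integer_,
                     one_based = FALSE) {
  stopifnot(inherits(config, "ish_config"))
  d <- as.data.table(columns)
  if (one_based) d$pos <- d$pos - 1L
  d <- d[depth >= config$min_coverage]
  empty <- data.table(segment = integer(), contig = character(),
                      pos = integer(), class = character(),
                      consensus = character(), allele = character(),
                      count = integer(), depth = integer(), freq = numeric())
  if (nrow(d) == 0) return(empty)
  cnt <- as.matrix(d[, list(A, C, G, T)])
  cons_idx <- max.col(cnt, ties.method = "first")  # A<C<G<T on ties
  cons <- DNA_BASES[cons_idx]
  events <- list()
  for (b in seq_len(4)) {
    sel <- cons_idx != b & cnt[, b] >= config$min_variant_frequency * d$depth
    if (any(sel))
      events[[length(events) + 1]] <- data.table(
        segment = segment, contig = d$contig[sel], pos = d$pos[sel],
        class = "SNV", consensus = cons[sel], allele = DNA_BASES[b],
        count = cnt[sel, b], depth = d$depth[sel])
  }
  if (config$count_indels) {
    for (cl in c("ins", "del")) {
      cc <- d[[cl]]
      sel <- cc >= config$min_variant_frequency * d$depth & cc > 0
      if (any(sel))
        events[[length(events) + 1]] <- data.table(
          segment = segment, contig = d$contig[sel], pos = d$pos[sel],
          class = c(ins = "insertion", del = "deletion")[[cl]],
          consensus = cons[sel], allele = toupper(cl),
          count = cc[sel], depth = d$depth[sel])
    }
  }
  if (length(events) == 0) return(empty)
  out <- rbindlist(events)
  out$freq <- out$count / out$depth
  setorder(out, contig, pos, allele)
  out[]
}

#' Co-localization of ISH sites across segments
#'
#' Sites are keyed by (contig, position, event class, variant allele); a
#' site is co-localized when a matching event is present in every segment.
#' The summary also reports the looser present-in->=2-segments fraction
#' and the event-level shared fraction (shared-by-all events per segment
#' over mean events per segment) alongside the site-level default.
#'
#' @param events ISH event table (rows from [call_ish()] across segments,
#'   or the simulator's truth table) with a `segment` column.
#' @param n_segments total number of segments analyzed; segments with zero
#'   events count toward "all".
#' @return list of class `colocalization_summary`: `site_matrix`
#'   (presence/absence, segments as columns), `n_events_per_segment`,
#'   `n_sites`, `n_sites_shared_by_all`, `n_sites_shared_by_2plus`,
#'   `fraction_colocalized`, `fraction_not_colocalized`,
#'   `fraction_colocalized_2plus`, `event_fraction_shared_by_all`.
#' @export
colocalize <- function(events, n_segments) {
  ev <- as.data.table(events)
  if (!"class" %in% names(ev) && "alt" %in% names(ev)) ev$class <- "SNV"
  if (!"allele" %in% names(ev) && "alt" %in% names(ev)) ev$allele <- ev$alt
  n_per_seg <- vapply(seq_len(n_segments), function(s)
    sum(ev$segment == s), integer(1))
  if (nrow(ev) == 0) {
    return(structure(list(
      site_matrix = data.table(), n_events_per_segment = n_per_seg,
      n_sites = 0L, n_sites_shared_by_all = 0L,
      n_sites_shared_by_2plus = 0L,
      fraction_colocalized = NA_real_,
      fraction_not_colocalized = NA_real_,
      fraction_colocalized_2plus = NA_real_,
      event_fraction_shared_by_all = NA_real_),
      class = "colocalization_summary"))
  }
  key <- ev[, list(contig, pos, class, allele, segment)]
  key <- unique(key)
  wide <- data.table::dcast(key, contig + pos + class + allele ~ segment,
                            fun.aggregate = length, value.var = "segment")
  segcols <- as.character(seq_len(n_segments))
  for (s in segcols) if (!s %in% names(wide)) wide[[s]] <- 0L
  data.table::setcolorder(wide, c("contig", "pos", "class", "allele",
                                  segcols))
  pres <- as.matrix(wide[, segcols, with = FALSE]) > 0
  n_seg_per_site <- rowSums(pres)
  n_sites <- nrow(wide)
  n_all <- sum(n_seg_per_site == n_segments)
  n_2plus <- sum(n_seg_per_site >= 2)
  setorder(wide, contig, pos, class, allele)
  structure(list(
    site_matrix = wide,
    n_events_per_segment = n_per_seg,
    n_sites = n_sites,
    n_sites_shared_by_all = n_all,
    n_sites_shared_by_2plus = n_2plus,
    fraction_colocalized = n_all / n_sites,
    fraction_not_colocalized = 1 - n_all / n_sites,
    fraction_colocalized_2plus = n_2plus / n_sites,
    event_fraction_shared_by_all = n_all / mean(n_per_seg)),
    class = "colocalization_summary")
}

#' @export
print.colocalization_summary <- function(x, ...) {
  cat(sprintf(
    "colocalization: %d distinct sites, %d shared by all segments (%.3f); mean %.1f events/segment\n",
    x$n_sites, x$n_sites_shared_by_all, x$fraction_colocalized,
    mean(x$n_events_per_segment)))
  invisible(x)
}

#' Intra- vs inter-segment heterogeneity ratio
#'
#' Contrasts within-segment heterogeneity (mean ISH events per segment
#' library) with between-segment consensus divergence (mean total SNPs
#' over a set of pairwise assembly comparisons).  In polyploid filaments
#' the former exceeds the latter by an order of magnitude or more.
#'
#' @param ish_events ISH event table with a `segment` column.
#' @param comparisons list of [compare_pair()] results.
#' @param segments segment ids over which both means are taken (pairs are
#'   restricted to those whose reference and query ids end in these
#'   numbers); default all segments present.
#' @return list: `mean_ish_events`, `mean_pairwise_snps`, `ratio`,
#'   `n_segments`, `n_pairs`; or a marker list with `empty = TRUE` when
#'   either input is empty.
#' @export
intra_vs_inter <- function(ish_events, comparisons, segments = NULL) {
  ev <- as.data.table(ish_events)
  if (nrow(ev) == 0 || length(comparisons) == 0)
    return(list(empty = TRUE))
  seg_ids <- sort(unique(ev$segment))
  if (!is.null(segments)) seg_ids <- intersect(seg_ids, segments)
  per_seg <- vapply(seg_ids, function(s) sum(ev$segment == s), integer(1))
  seg_num <- function(id) as.integer(sub(".*_", "", id))
  snps <- vapply(comparisons, function(cp) {
    if (!is.null(segments) &&
        (!seg_num(cp$reference_id) %in% segments ||
         !seg_num(cp$query_id) %in% segments)) return(NA_real_)
    as.numeric(cp$total_snps)
  }, numeric(1))
  snps <- snps[!is.na(snps)]
  if (length(snps) == 0) return(list(empty = TRUE))
  list(mean_ish_events = mean(per_seg),
       mean_pairwise_snps = mean(snps),
       ratio = mean(per_seg) / mean(snps),
       n_segments = length(seg_ids),
       n_pairs = length(snps))
}
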