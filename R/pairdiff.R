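#' Find unique-k-mer anchors between two sequences
#'
#' Exact k-mer matches that occur exactly once in each sequence, merged
#' into maximal exact matches.  Windows containing non-ACGT characters
#' never seed an anchor.
#'
#' @param query,target uppercase nucleotide sequences.
#' @param k odd k-mer size in `[11, 31]`.
#' @return `data.table` with 0-based `qstart`, `tstart` and `length`,
#'   ordered by `qstart`; zero rows when either sequence is empty or no
#'   unique match exists.
#' @export
find_anchors <- function(query, target, k = 21) {
  if (k %% 2 == 0 || k < 11 || k > 31)
    fp_stop("fp_config_error", "k must be odd and in [11, 31]")
  if (nchar(query) == 0 || nchar(target) == 0)
    return(data.table(qstart = integer(), tstart = integer(),
                      length = integer()))
  m <- cpp_find_anchors(query, target, as.integer(k))
  as.data.table(m)
}

#' Chain anchors into a colinear skeleton
#'
#' Selects the subset of anchors with maximal total anchor length whose
#' start coordinates strictly increase in both sequences (weighted
#' longest-increasing-subsequence).  Consecutive anchors may overlap by at
#' most 32 bp in either coordinate -- maximal exact matches legitimately
#' overlap around indels in micro-repeat context -- and any such overlap
#' is trimmed from the start of the later anchor on output, so the
#' returned chain is non-overlapping.  Ties are broken toward the chain
#' with the smaller total gap span (sum of query-gap plus target-gap
#' lengths between consecutive anchors), then toward the leftmost query
#' coordinate.
#'
#' @param anchors `data.table` from [find_anchors()].
#' @return the chained subset, same columns, ordered by `qstart`; zero
#'   rows if no anchors were supplied.
#' @export
chain_anchors <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0) return(anchors)
  ov_max <- 32L
  a <- as.data.table(anchors)
  setorder(a, qstart, tstart)
  qs <- a$qstart; ts <- a$tstart; len <- a$length
  qe <- qs + len; te <- ts + len
  tot <- len            # best total anchor length of a chain ending at i
  gap <- rep(0, n)      # its total gap span
  lft <- qs             # its leftmost query coordinate
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    prev <- seq_len(i - 1)
    cand <- which(qs[prev] < qs[i] & ts[prev] < ts[i] &
                    qe[prev] <= qs[i] + ov_max & te[prev] <= ts[i] + ov_max)
    if (length(cand)) {
      ct <- tot[cand] + len[i]
      cg <- gap[cand] + pmax(qs[i] - qe[cand], 0) +
        pmax(ts[i] - te[cand], 0)
      best <- order(-ct, cg, lft[cand], cand)[1]
      j <- cand[best]
      if (ct[best] > tot[i] ||
          (ct[best] == tot[i] && cg[best] < gap[i])) {
        tot[i] <- ct[best]; gap[i] <- cg[best]
        lft[i] <- lft[j]; parent[i] <- j
      }
    }
  }
  end <- order(-tot, gap, lft, seq_len(n))[1]
  total_untrimmed <- tot[end]
  path <- integer(0)
  while (!is.na(end)) { path <- c(end, path); end <- parent[end] }
  ch <- a[path]
  # trim overlaps from the start of the later anchor (an exact match stays
  # exact under prefix trimming)
  if (nrow(ch) > 1) for (i in 2:nrow(ch)) {
    ov <- max(ch$qstart[i - 1] + ch$length[i - 1] - ch$qstart[i],
              ch$tstart[i - 1] + ch$length[i - 1] - ch$tstart[i], 0L)
    if (ov > 0) {
      ch$qstart[i] <- ch$qstart[i] + ov
      ch$tstart[i] <- ch$tstart[i] + ov
      ch$length[i] <- ch$length[i] - ov
    }
  }
  ch <- ch[ch$length > 0]
  # the optimum value before overlap trimming, for oracle comparisons
  attr(ch, "total_anchor_length") <- total_untrimmed
  ch
}

#' Fill inter-anchor gaps with banded global alignments
#'
#' Completes an anchor chain into a full alignment of the two sequences:
#' every gap between consecutive anchors (and the head/tail flanks) is
#' aligned globally within a band (match +1, mismatch -1, gap open -2,
#' gap extend -1).  A gap pair longer than `gap_cap` on either side is
#' flagged structurally divergent, excluded from variant calling, and
#' reported in the result.
#'
#' @param query,target the two sequences.
#' @param chain output of [chain_anchors()].
#' @param band half-width of the alignment band; widened automatically to
#'   cover each gap pair's length difference.
#' @param gap_cap maximum gap-pair length admitted to alignment.
#' @return list of class `alignment_chain`: `anchors`, `gaps` (`data.table`
#'   with 0-based half-open `qstart`, `qend`, `tstart`, `tend` and
#'   `transcript` over `M|X|I|D`), and `excluded` (structurally divergent
#'   regions, same coordinates, no transcript).
#' @export
align_gaps <- function(query, target, chain, band = 256, gap_cap = 20000) {
  if (nrow(chain) == 0)
    fp_stop("fp_alignment_error", "empty chain: pair is unalignable")
  qb <- c(0L, chain$qstart + chain$length)
  qe <- c(chain$qstart, nchar(query))
  tb <- c(0L, chain$tstart + chain$length)
  te <- c(chain$tstart, nchar(target))
  gaps <- list(); excl <- list()
  for (i in seq_along(qb)) {
    ql <- qe[i] - qb[i]; tl <- te[i] - tb[i]
    if (ql == 0 && tl == 0) next
    row <- data.table(qstart = qb[i], qend = qe[i],
                      tstart = tb[i], tend = te[i])
    if (ql > gap_cap || tl > gap_cap) {
      excl[[length(excl) + 1]] <- row
      next
    }
    al <- cpp_banded_align(substr(query, qb[i] + 1, qe[i]),
                           substr(target, tb[i] + 1, te[i]),
                           as.integer(band))
    row$transcript <- al$transcript
    gaps[[length(gaps) + 1]] <- row
  }
  structure(list(
    anchors = chain,
    gaps = if (length(gaps)) rbindlist(gaps) else
      data.table(qstart = integer(), qend = integer(), tstart = integer(),
                 tend = integer(), transcript = character()),
    excluded = if (length(excl)) rbindlist(excl) else
      data.table(qstart = integer(), qend = integer(), tstart = integer(),
                 tend = integer()),
    query_seq = query),
    class = "alignment_chain")
}

#' Call variants from a completed alignment chain
#'
#' Every mismatch column yields one SNP; a run of `r` consecutive gap
#' columns yields `r` single-nucleotide indel events of the same class
#' (set `indel_events = "per_run"` to count one event per run instead).
#' Insertions (bases present in the query only) are recorded at the target
#' position of the base they follow; deletions at the deleted target base.
#' The compartment is assigned by membership of the target position in the
#' target annotation's merged CDS intervals.  Columns pairing an N never
#' yield a call.
#'
#' @param aligned an `alignment_chain` from [align_gaps()].
#' @param target_genome the target [annotated_genome()].
#' @param contig target contig name.
#' @param indel_events `"per_base"` (default) or `"per_run"`.
#' @return `data.table`: contig, pos (0-based target), class
#'   `SNP|insertion|deletion`, ref, alt, compartment `CDS|nCDS`, sorted by
#'   (contig, pos).
#' @export
call_variants <- function(aligned, target_genome, contig,
                          indel_events = c("per_base", "per_run")) {
  indel_events <- match.arg(indel_events)
  stopifnot(inherits(aligned, "alignment_chain"))
  tseq <- target_genome$contigs[[contig]]
  calls <- lapply(seq_len(nrow(aligned$gaps)), function(i) {
    g <- aligned$gaps[i]
    ch <- strsplit(g$transcript, "", fixed = TRUE)[[1]]
    qadv <- ch %in% c("M", "X", "I")
    tadv <- ch %in% c("M", "X", "D")
    if (g$qend - g$qstart != sum(qadv) || g$tend - g$tstart != sum(tadv))
      fp_stop("fp_internal_error",
              "transcript does not consume the gap sequences")
    keep <- ch != "M"
    if (!any(keep)) return(NULL)
    tpos <- g$tstart + cumsum(tadv) - 1L   # last consumed target base
    qpos <- g$qstart + cumsum(qadv) - 1L
    d <- data.table(op = ch[keep], pos = tpos[keep], qpos = qpos[keep])
    d$ref <- ifelse(d$op == "I", "-",
                    substring(tseq, d$pos + 1L, d$pos + 1L))
    d$alt <- ifelse(d$op == "D", "-",
                    substring(aligned$query_seq, d$qpos + 1L, d$qpos + 1L))
    d
  })
  calls <- rbindlist(calls)
  if (nrow(calls) == 0)
    return(data.table(contig = character(), pos = integer(),
                      class = character(), ref = character(),
                      alt = character(), compartment = character()))
  calls$class <- c(X = "SNP", I = "insertion", D = "deletion")[calls$op]
  # ambiguous bases never produce calls
  calls <- calls[!(calls$ref %in% "N") & !(calls$alt %in% "N")]
  if (indel_events == "per_run") {
    calls$run <- cumsum(c(TRUE, diff(calls$qpos) > 1 | diff(calls$pos) > 1 |
                            calls$op[-1] != calls$op[-nrow(calls)]))
    calls <- calls[calls$op == "X" | !duplicated(calls$run)]
  }
  out <- data.table(contig = contig,
                    pos = pmax(calls$pos, 0L),
                    class = calls$class, ref = calls$ref, alt = calls$alt)
  out$compartment <- ifelse(in_cds(target_genome, contig, out$pos),
                            "CDS", "nCDS")
  setorder(out, contig, pos)
  out[]
}

#' Variant density per 100 kbp
#'
#' @param count non-negative variant count.
#' @param denominator_bp assembly (or compartment) length in bp.
#' @return `100000 * count / denominator_bp`, full precision; round with
#'   [round_half_up()] (2 decimals) for reporting.
#' @export
rate_per_100kbp <- function(count, denominator_bp) {
  if (any(denominator_bp <= 0))
    fp_stop("fp_config_error", "rate denominator must be positive")
  if (any(count < 0))
    fp_stop("fp_config_error", "count must be >= 0")
  1e5 * count / denominator_bp
}

# best-matching contig pairing between two assemblies by shared unique
# k-mer anchors; greedy on total anchored length
pair_contigs <- function(ref, query, k) {
  rn <- names(ref$contigs); qn <- names(query$contigs)
  if (length(rn) == 1 && length(qn) == 1)
    return(data.table(ref_contig = rn, query_contig = qn))
  score <- data.table()
  for (r in rn) for (q in qn) {
    a <- find_anchors(ref$contigs[[r]], query$contigs[[q]], k)
    score <- rbind(score, data.table(ref_contig = r, query_contig = q,
                                     shared = sum(a$length)))
  }
  setorder(score, -shared)
  used_r <- character(); used_q <- character(); out <- list()
  for (i in seq_len(nrow(score))) {
    if (score$shared[i] == 0) break
    if (score$ref_contig[i] %in% used_r ||
        score$query_contig[i] %in% used_q) next
    out[[length(out) + 1]] <- score[i, list(ref_contig, query_contig)]
    used_r <- c(used_r, score$ref_contig[i])
    used_q <- c(used_q, score$query_contig[i])
  }
  rbindlist(out)
}

#' Compare two near-identical assemblies
#'
#' The full anchored comparison behind each cell block of a pairwise
#' heterogeneity table: contig pairing by shared unique k-mers, anchor
#' chaining, banded gap alignment, variant calling on the query assembly's
#' coordinates and annotation, and per-100-kbp densities using the query
#' assembly's total/CDS/nCDS lengths as denominators (the convention that
#' reproduces published table arithmetic).
#'
#' @param reference,query [annotated_genome()] objects; the `query` is the
#'   column assembly whose lengths and annotation are used.
#' @param k anchor k-mer size.
#' @param band alignment band half-width.
#' @param gap_cap structural-divergence gap cap in bp.
#' @param indel_events see [call_variants()].
#' @return object of class `pairwise_comparison`: ids, `aligned` flag,
#'   `variants` (the call table), counts (`total_snps`, `snps_cds`,
#'   `snps_ncds`, `total_indels`, `indels_cds`, `indels_ncds`), the six
#'   rate fields, and `excluded` regions.  An unalignable pair is returned
#'   with `aligned = FALSE` and `NA` counts, not zeros.
#' @export
compare_pair <- function(reference, query, k = 21, band = 256,
                         gap_cap = 20000,
                         indel_events = c("per_base", "per_run")) {
  indel_events <- match.arg(indel_events)
  stopifnot(inherits(reference, "annotated_genome"),
            inherits(query, "annotated_genome"))
  pairs <- pair_contigs(reference, query, k)
  variants <- list(); excluded <- list(); any_chain <- FALSE
  if (nrow(pairs)) for (i in seq_len(nrow(pairs))) {
    rs <- reference$contigs[[pairs$ref_contig[i]]]
    qs <- query$contigs[[pairs$query_contig[i]]]
    # the reference assembly is aligned onto the query (target) assembly
    anchors <- find_anchors(rs, qs, k)
    chain <- chain_anchors(anchors)
    if (nrow(chain) == 0) next
    any_chain <- TRUE
    aligned <- align_gaps(rs, qs, chain, band = band, gap_cap = gap_cap)
    v <- call_variants(aligned, query, pairs$query_contig[i],
                       indel_events = indel_events)
    variants[[length(variants) + 1]] <- v
    if (nrow(aligned$excluded))
      excluded[[length(excluded) + 1]] <-
        cbind(data.table(contig = pairs$query_contig[i]), aligned$excluded)
  }
  res <- list(reference_id = reference$id, query_id = query$id,
              aligned = any_chain)
  if (!any_chain) {
    res$variants <- NULL
    res[c("total_snps", "snps_cds", "snps_ncds", "total_indels",
          "indels_cds", "indels_ncds", "snps_per_100kbp",
          "snps_cds_per_100kbp", "snps_ncds_per_100kbp",
          "indels_per_100kbp", "indels_cds_per_100kbp",
          "indels_ncds_per_100kbp")] <- NA_real_
    class(res) <- "pairwise_comparison"
    return(res)
  }
  v <- rbindlist(variants)
  res$variants <- v
  res$excluded <- if (length(excluded)) rbindlist(excluded) else NULL
  is_snp <- v$class == "SNP"
  is_cds <- v$compartment == "CDS"
  res$total_snps <- sum(is_snp)
  res$snps_cds <- sum(is_snp & is_cds)
  res$snps_ncds <- sum(is_snp & !is_cds)
  res$total_indels <- sum(!is_snp)
  res$indels_cds <- sum(!is_snp & is_cds)
  res$indels_ncds <- sum(!is_snp & !is_cds)
  res$snps_per_100kbp <- rate_per_100kbp(res$total_snps, query$total_length)
  res$snps_cds_per_100kbp <- rate_per_100kbp(res$snps_cds, query$cds_length)
  res$snps_ncds_per_100kbp <- rate_per_100kbp(res$snps_ncds,
                                              query$ncds_length)
  res$indels_per_100kbp <- rate_per_100kbp(res$total_indels,
                                           query$total_length)
  res$indels_cds_per_100kbp <- rate_per_100kbp(res$indels_cds,
                                               query$cds_length)
  res$indels_ncds_per_100kbp <- rate_per_100kbp(res$indels_ncds,
                                                query$ncds_length)
  class(res) <- "pairwise_comparison"
  res
}

#' @export
print.pairwise_comparison <- function(x, ...) {
  if (!x$aligned) {
    cat(sprintf("pairwise_comparison %s vs %s: no alignment\n",
                x$reference_id, x$query_id))
    return(invisible(x))
  }
  cat(sprintf(
    "pairwise_comparison %s vs %s: %d SNPs (%.2f/100kbp), %d indels (%.2f/100kbp)\n",
    x$reference_id, x$query_id, x$total_snps, x$snps_per_100kbp,
    x$total_indels, x$indels_per_100kbp))
  invisible(x)
}

#' Unbanded global alignment (reference oracle)
#'
#' Full-matrix global alignment with the same scoring as the anchored
#' route, used to cross-check that anchoring and banding do not change
#' variant counts on small pairs.
#'
#' @param query,target sequences (product of lengths limited to ~6.5e7).
#' @return list with `score` and `transcript` (over `M|X|I|D`).
#' @export
align_global <- function(query, target) {
  cpp_full_align(query, target)
}

# count SNPs/indels directly from a transcript string (used by tests and
# the ANI identity computation)
transcript_counts <- function(transcript) {
  ch <- strsplit(transcript, "", fixed = TRUE)[[1]]
  c(match = sum(ch == "M"), snp = sum(ch == "X"),
    insertion = sum(ch == "I"), deletion = sum(ch == "D"))
}
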