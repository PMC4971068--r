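#' ANI configuration
#'
#' Constants of the fragment-based average nucleotide identity procedure:
#' the genome is chopped into consecutive 1,020 bp fragments and a
#' fragment contributes to ANI only when its best placement on the other
#' genome reaches 30% identity over at least 70% of its length.
#'
#' @param fragment_length fragment size in bp (>= 100).
#' @param min_identity minimum percent identity, as a proportion in
#'   (0, 1].
#' @param min_alignable_fraction minimum aligned-length / fragment-length,
#'   in (0, 1].
#' @return validated list of class `ani_config`.
#' @export
ani_config <- function(fragment_length = 1020, min_identity = 0.30,
                       min_alignable_fraction = 0.70) {
  if (fragment_length < 100)
    fp_stop("fp_config_error", "fragment_length must be >= 100")
  if (min_identity <= 0 || min_identity > 1)
    fp_stop("fp_config_error", "min_identity must be in (0, 1]")
  if (min_alignable_fraction <= 0 || min_alignable_fraction > 1)
    fp_stop("fp_config_error", "min_alignable_fraction must be in (0, 1]")
  structure(list(fragment_length = as.integer(fragment_length),
                 min_identity = min_identity,
                 min_alignable_fraction = min_alignable_fraction),
            class = "ani_config")
}

#' Chop a genome into ANI fragments
#'
#' Consecutive non-overlapping windows of `fragment_length` per contig; a
#' trailing window shorter than `fragment_length` is kept when it is at
#' least 100 bp, else dropped.
#'
#' @param genome an [annotated_genome()].
#' @param config an [ani_config()].
#' @return `data.table`: contig, start (0-based), length, seq.
#' @export
fragment_genome <- function(genome, config = ani_config()) {
  fl <- config$fragment_length
  out <- lapply(names(genome$contigs), function(cn) {
    s <- genome$contigs[[cn]]
    len <- nchar(s)
    if (len == 0) return(NULL)
    starts <- seq(0L, len - 1L, by = fl)
    ends <- pmin(starts + fl, len)
    keep <- (ends - starts) >= 100L
    if (!any(keep)) return(NULL)
    data.table(contig = cn, start = starts[keep],
               length = ends[keep] - starts[keep],
               seq = substring(s, starts[keep] + 1L, ends[keep]))
  })
  rbindlist(Filter(Negate(is.null), out))
}

# concatenate target contigs with an N spacer so no k-mer spans a junction
concat_target <- function(genome, spacer = 100L) {
  paste(unlist(genome$contigs), collapse = strrep("N", spacer))
}

# identity and alignable fraction for one fragment, given its unique-k-mer
# anchors on the (concatenated) target
fragment_hit_from_anchors <- function(frag, tseq, anchors, band) {
  chain <- chain_anchors(anchors)
  if (nrow(chain) == 0)
    return(c(identity = 0, alignable = 0))
  flen <- nchar(frag)
  tlen <- nchar(tseq)
  matches <- sum(chain$length)
  columns <- sum(chain$length)
  consumed <- sum(chain$length)
  qb <- c(0L, chain$qstart + chain$length)
  qe <- c(chain$qstart, flen)
  # flank windows on the target sized to the fragment flank
  tb <- c(max(0L, chain$tstart[1] - chain$qstart[1]),
          chain$tstart + chain$length)
  te <- c(chain$tstart,
          min(tlen, tail(chain$tstart + chain$length, 1) +
                (flen - tail(chain$qstart + chain$length, 1))))
  for (i in seq_along(qb)) {
    ql <- qe[i] - qb[i]; tl <- te[i] - tb[i]
    if (ql <= 0 && tl <= 0) next
    if (ql <= 0 || tl <= 0) {
      # unpairable flank: unaligned fragment bases reduce alignable length
      if (i > 1 && i < length(qb)) {
        columns <- columns + max(ql, tl)
        consumed <- consumed + max(ql, 0)
      }
      next
    }
    al <- cpp_banded_align(substr(frag, qb[i] + 1, qe[i]),
                           substr(tseq, tb[i] + 1, te[i]),
                           as.integer(max(band, abs(ql - tl) + 1)))
    tc <- transcript_counts(al$transcript)
    matches <- matches + tc[["match"]]
    columns <- columns + sum(tc)
    consumed <- consumed + ql
  }
  c(identity = 100 * matches / columns, alignable = consumed / flen)
}

#' Best placement of one fragment on a target genome
#'
#' Seeds with unique-k-mer anchors, chains them, and completes the
#' placement with banded alignments of the inter-anchor gaps and flanks.
#' A fragment without any anchor (for instance all-N) is unalignable.
#'
#' @param fragment nucleotide sequence (>= 100 bp).
#' @param target an [annotated_genome()].
#' @param k seed k-mer size.
#' @param band alignment band half-width.
#' @return named numeric: `identity` (percent, over aligned columns) and
#'   `alignable` (aligned fragment bases / fragment length); `c(0, 0)`
#'   when unalignable.
#' @export
best_fragment_hit <- function(fragment, target, k = 21, band = 64) {
  if (nchar(fragment) < 100)
    fp_stop("fp_config_error", "fragment shorter than 100 bp")
  tseq <- concat_target(target)
  anchors <- find_anchors(fragment, tseq, k)
  fragment_hit_from_anchors(fragment, tseq, anchors, band)
}

#' Fragment-based average nucleotide identity
#'
#' One-way ANI(A->B) is the mean percent identity over fragments of A
#' whose best placement on B passes the identity and alignable-fraction
#' cutoffs; two-way ANI is the arithmetic mean of the two one-way values.
#' Fragments contribute unweighted.  When no fragment is retained in a
#' direction, that direction -- and consequently the two-way value -- is
#' undefined (`NA`) and a diagnostic message is recorded.
#'
#' @param A,B [annotated_genome()] objects.
#' @param config an [ani_config()].
#' @param k,band anchoring/alignment parameters.
#' @return object of class `ani_result`: `one_way_ani_AB`,
#'   `one_way_ani_BA`, `two_way_ani` (percentages, full precision),
#'   `n_fragments_total_AB/BA`, `n_fragments_retained_AB/BA`, and
#'   `diagnostic` (NULL or character).
#' @export
compute_ani <- function(A, B, config = ani_config(), k = 21, band = 64) {
  one_way <- function(src, dst) {
    frags <- fragment_genome(src, config)
    if (nrow(frags) == 0)
      return(list(ani = NA_real_, total = 0L, retained = 0L))
    tseq <- concat_target(dst)
    anchor_sets <- cpp_fragment_anchors(frags$seq, tseq, as.integer(k))
    hits <- vapply(seq_len(nrow(frags)), function(i)
      fragment_hit_from_anchors(frags$seq[i], tseq,
                                as.data.table(anchor_sets[[i]]), band),
      numeric(2))
    keep <- hits[1, ] >= 100 * config$min_identity &
      hits[2, ] >= config$min_alignable_fraction
    list(ani = if (any(keep)) mean(hits[1, keep]) else NA_real_,
         total = nrow(frags), retained = sum(keep))
  }
  ab <- one_way(A, B)
  ba <- one_way(B, A)
  two <- if (is.na(ab$ani) || is.na(ba$ani)) NA_real_ else
    mean(c(ab$ani, ba$ani))
  diag <- NULL
  if (is.na(two))
    diag <- sprintf(
      "two-way ANI undefined: retained fragments A->B = %d, B->A = %d",
      ab$retained, ba$retained)
  structure(list(one_way_ani_AB = ab$ani, one_way_ani_BA = ba$ani,
                 two_way_ani = two,
                 n_fragments_total_AB = ab$total,
                 n_fragments_retained_AB = ab$retained,
                 n_fragments_total_BA = ba$total,
                 n_fragments_retained_BA = ba$retained,
                 diagnostic = diag),
            class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  if (is.na(x$two_way_ani)) {
    cat("ani_result: undefined --", x$diagnostic, "\n")
  } else {
    cat(sprintf(
      "ani_result: two-way %.2f%% (A->B %.2f%%, B->A %.2f%%; %d/%d and %d/%d fragments retained)\n",
      round_half_up(x$two_way_ani, 2), round_half_up(x$one_way_ani_AB, 2),
      round_half_up(x$one_way_ani_BA, 2),
      x$n_fragments_retained_AB, x$n_fragments_total_AB,
      x$n_fragments_retained_BA, x$n_fragments_total_BA))
  }
  invisible(x)
}
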