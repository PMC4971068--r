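#' Annotated genome assembly
#'
#' Container for a (possibly multi-contig) nucleotide assembly plus its CDS
#' annotation.  CDS intervals are stored 0-based half-open and merged per
#' contig, so `cds_length + ncds_length == total_length` always holds --
#' the bookkeeping identity behind partitioning variant densities into
#' coding and non-coding compartments.
#'
#' @param contigs named character vector of uppercase nucleotide sequences.
#' @param cds `data.frame` with columns `contig`, `start`, `end`; 0-based
#'   half-open coordinates on the corresponding contig.  May have zero rows.
#' @param id optional assembly identifier.
#' @return object of class `annotated_genome` with elements `contigs`,
#'   `cds` (merged, sorted `data.table`), `total_length`, `cds_length`,
#'   `ncds_length` and `id`.
#' @export
annotated_genome <- function(contigs, cds = NULL, id = NA_character_) {
  if (length(contigs) == 0 || is.null(names(contigs)) || anyNA(names(contigs)))
    fp_stop("fp_config_error", "contigs must be a non-empty named character vector")
  contigs <- vapply(contigs, toupper, character(1))
  lens <- nchar(contigs)
  if (is.null(cds) || nrow(cds) == 0) {
    cds <- data.table(contig = character(), start = integer(), end = integer())
  } else {
    cds <- as.data.table(cds[, c("contig", "start", "end")])
    if (!all(cds$contig %in% names(contigs)))
      fp_stop("fp_config_error", "CDS interval on unknown contig")
    if (any(cds$start < 0) || any(cds$end > lens[cds$contig]) ||
        any(cds$end <= cds$start))
      fp_stop("fp_config_error", "CDS interval outside contig bounds or empty")
    cds <- merge_intervals(cds)
  }
  g <- list(
    contigs = contigs,
    cds = cds,
    total_length = sum(lens),
    cds_length = if (nrow(cds)) sum(cds$end - cds$start) else 0L,
    id = id
  )
  g$ncds_length <- g$total_length - g$cds_length
  class(g) <- "annotated_genome"
  g
}

# merge overlapping/adjacent CDS intervals per contig (0-based half-open)
merge_intervals <- function(cds) {
  out <- lapply(split(cds, cds$contig), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.table(contig = d$contig[1],
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  })
  setorder(rbindlist(out), contig, start)[]
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf(
    "annotated_genome '%s': %d contig(s), %s bp (CDS %s bp = %.2f%%)\n",
    x$id, length(x$contigs), format(x$total_length, big.mark = ","),
    format(x$cds_length, big.mark = ","),
    100 * x$cds_length / x$total_length))
  invisible(x)
}

# logical membership of 0-based positions in the merged CDS of one contig
in_cds <- function(genome, contig, pos0) {
  iv <- genome$cds[genome$cds$contig == contig]
  if (nrow(iv) == 0) return(rep(FALSE, length(pos0)))
  idx <- findInterval(pos0, iv$start)
  idx > 0 & pos0 < iv$end[pmax(idx, 1L)]
}

# complement of the merged CDS intervals of one contig (0-based half-open)
ncds_intervals <- function(genome, contig) {
  len <- nchar(genome$contigs[[contig]])
  iv <- genome$cds[genome$cds$contig == contig]
  if (nrow(iv) == 0)
    return(data.table(contig = contig, start = 0L, end = len))
  starts <- c(0L, iv$end)
  ends <- c(iv$start, len)
  keep <- ends > starts
  data.table(contig = contig, start = starts[keep], end = ends[keep])
}

#' Read an assembly and its CDS annotation
#'
#' @param fasta path to a FASTA file.
#' @param gff3 optional path to a GFF3 file; only `CDS` features are used.
#'   GFF3 1-based inclusive coordinates are converted to the internal
#'   0-based half-open convention.
#' @param id assembly identifier (defaults to the FASTA basename).
#' @return an [annotated_genome()].
#' @export
read_genome <- function(fasta, gff3 = NULL, id = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  contigs <- setNames(as.character(seqs), sub("\\s.*$", "", names(seqs)))
  cds <- NULL
  if (!is.null(gff3)) {
    gr <- as.data.frame(rtracklayer::import(gff3))
    gr <- gr[gr$type == "CDS", , drop = FALSE]
    if (nrow(gr))
      cds <- data.frame(contig = as.character(gr$seqnames),
                        start = gr$start - 1L,
                        end = gr$end)
  }
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(fasta))
  annotated_genome(contigs, cds, id = id)
}

#' Write an assembly and its CDS annotation
#'
#' Writes the contigs as FASTA and, if requested, the merged CDS intervals
#' as a GFF3 file (1-based inclusive, per the standard).  Output is
#' deterministic: identical genomes produce byte-identical files.
#'
#' @param genome an [annotated_genome()].
#' @param fasta output FASTA path.
#' @param gff3 optional output GFF3 path.
#' @return invisibly, the genome.
#' @export
write_genome <- function(genome, fasta, gff3 = NULL) {
  ss <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(ss, fasta)
  if (!is.null(gff3)) {
    cds <- genome$cds
    lines <- c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d",
                       names(genome$contigs), nchar(genome$contigs)))
    if (nrow(cds))
      lines <- c(lines, sprintf(
        "%s\tfiloplast\tCDS\t%d\t%d\t.\t+\t0\tID=cds%05d",
        cds$contig, cds$start + 1L, cds$end, seq_len(nrow(cds))))
    writeLines(lines, gff3)
  }
  invisible(genome)
}
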