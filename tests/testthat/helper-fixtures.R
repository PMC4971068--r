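# shared fixtures and independent oracles, built in code at test time

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant substitutions (and optionally single-base deletions) into a sequence;
# returns the mutated sequence and the 0-based positions used
plant_variants <- function(seq, n_sub = 0, n_del = 0, seed = 1) {
  set.seed(seed)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  # deletions only where the base differs from both neighbours, so the
  # optimal gap placement (hence the reported coordinate) is unambiguous
  del_ok <- which(v != c("", head(v, -1)) & v != c(v[-1], ""))
  del_ok <- del_ok[del_ok > 5 & del_ok < n - 5]
  pos <- sort(sample(max(n - 10, 1), n_sub))
  del_pos <- sort(sample(setdiff(del_ok, pos), n_del))
  for (p in pos)
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  v[del_pos] <- ""
  list(seq = paste(v, collapse = ""),
       sub_pos = pos - 1L, del_pos = del_pos - 1L)
}

# brute-force unique-k-mer anchor oracle: dictionary of all k-mers via
# substring, matches unique in both, merged along diagonals
brute_force_anchors <- function(q, t, k = 21) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }
  qk <- kmers(q); tk <- kmers(t)
  qt <- table(qk); tt <- table(tk)
  uq <- names(qt)[qt == 1]; ut <- names(tt)[tt == 1]
  shared <- intersect(uq, ut)
  shared <- shared[!grepl("N", shared, fixed = TRUE)]
  if (length(shared) == 0)
    return(data.frame(qstart = integer(), tstart = integer(),
                      length = integer()))
  qpos <- match(shared, qk) - 1L
  tpos <- match(shared, tk) - 1L
  o <- order(qpos)
  qpos <- qpos[o]; tpos <- tpos[o]
  # same-diagonal hits whose starts advance by <= k cover one contiguous
  # exact match and merge into a single MEM (mirrors the implementation's
  # documented merge rule, via an independent dictionary route)
  qs <- integer(0); ts <- integer(0); len <- integer(0)
  i <- 1
  while (i <= length(qpos)) {
    j <- i + 1
    while (j <= length(qpos) &&
           qpos[j] - qpos[j - 1] == tpos[j] - tpos[j - 1] &&
           qpos[j] > qpos[j - 1] && qpos[j] - qpos[j - 1] <= k) j <- j + 1
    qs <- c(qs, qpos[i]); ts <- c(ts, tpos[i])
    len <- c(len, as.integer(qpos[j - 1] - qpos[i] + k))
    i <- j
  }
  data.frame(qstart = qs, tstart = ts, length = len)
}

# exhaustive chain oracle: enumerate all anchor subsets, keep those with
# strictly increasing starts and pairwise overlap of at most 32 bp in each
# coordinate (the chainer's documented admission rule), maximize total
# length then minimize (clamped) gap span
brute_force_chain <- function(anchors) {
  n <- nrow(anchors)
  best <- NULL; best_len <- -1; best_gap <- Inf
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) == 0) next
    a <- anchors[sel[order(anchors$qstart[sel])], , drop = FALSE]
    qe <- a$qstart + a$length; te <- a$tstart + a$length
    ok <- all(diff(a$qstart) > 0) && all(diff(a$tstart) > 0) &&
      all(head(qe, -1) <= a$qstart[-1] + 32) &&
      all(head(te, -1) <= a$tstart[-1] + 32)
    if (!ok) next
    tot <- sum(a$length)
    gap <- if (nrow(a) > 1)
      sum(pmax(a$qstart[-1] - head(qe, -1), 0)) +
        sum(pmax(a$tstart[-1] - head(te, -1), 0))
    else 0
    if (tot > best_len || (tot == best_len && gap < best_gap)) {
      best <- a; best_len <- tot; best_gap <- gap
    }
  }
  best
}

# variant counts via the anchored pipeline, for oracle comparisons
anchored_counts <- function(query, target, k = 21, band = 256) {
  g <- annotated_genome(c(c1 = target), NULL, id = "t")
  ch <- chain_anchors(find_anchors(query, target, k))
  al <- align_gaps(query, target, ch, band = band)
  v <- call_variants(al, g, "c1")
  c(snp = sum(v$class == "SNP"),
    insertion = sum(v$class == "insertion"),
    deletion = sum(v$class == "deletion"))
}

# variant counts from the unbanded full-DP oracle
global_counts <- function(query, target) {
  tr <- align_global(query, target)$transcript
  ch <- strsplit(tr, "", fixed = TRUE)[[1]]
  c(snp = sum(ch == "X"), insertion = sum(ch == "I"),
    deletion = sum(ch == "D"))
}

# minimal pileup table builder (0-based positions, read_pileup convention)
pileup_columns <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r)
    data.table::data.table(contig = r$contig %||% "c1", pos = r$pos,
                           ref = r$ref %||% "A", depth = r$depth,
                           A = r$A %||% 0L, C = r$C %||% 0L,
                           G = r$G %||% 0L, T = r$T %||% 0L,
                           ins = r$ins %||% 0L, del = r$del %||% 0L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
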