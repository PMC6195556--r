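## -- read mapping with a mismatch cap, EM-based TPM, compositional
##    transforms, class aggregation and expression clustering --------------

## seed index: every fixed-length k-mer position of every transcript
build_seed_index <- function(tx_seqs, k) {
  dt <- data.table::rbindlist(lapply(seq_along(tx_seqs), function(t) {
    s <- tx_seqs[t]
    n <- nchar(s) - k + 1L
    if (n < 1) return(NULL)
    data.table::data.table(kmer = stringi::stri_sub(s, 1:n, length = k),
                           transcript = t, pos = 1:n)
  }))
  data.table::setkey(dt, kmer)
  dt
}

#' Map reads to the consensus with a mismatch cap
#'
#' Seed-and-verify mapper: non-overlapping exact seed k-mers propose
#' candidate placements (both strands) which are verified by counting
#' substitution mismatches over the full read; placements with at most
#' `max_mismatches` are kept. Multi-mapping reads retain all placements
#' with equal initial weight `1/n`. With at most `max_mismatches`
#' substitutions, a read with `max_mismatches + 1` disjoint seeds always
#' has one exact seed, so no qualifying placement is missed.
#'
#' @param reads merged-read table (or character vector).
#' @param transcripts consensus data.frame (`id`, `seq`, `cds_start`,
#'   `cds_end`).
#' @param max_mismatches maximum substitutions tolerated (default 3).
#' @param seed_len seed k-mer length (default 18).
#' @return list with `alignments` (data.table: read, transcript_id, start,
#'   strand, mismatches, weight) and `profiles` (per-transcript CDS coverage
#'   as in [strict_align_coverage()]).
#' @export
map_reads <- function(reads, transcripts, max_mismatches = 3L,
                      seed_len = 18L, individual_id = NA_character_) {
  stopifnot(nrow(transcripts) > 0)
  read_seqs <- if (is.character(reads)) reads else reads$seq
  read_ids <- if (is.character(reads)) as.character(seq_along(reads))
              else reads$id
  tx_seqs <- transcripts$seq
  tx_len <- nchar(tx_seqs)
  index <- build_seed_index(tx_seqs, seed_len)
  n_seeds <- max_mismatches + 1L
  ## seed table over all reads and both orientations
  seed_rows <- data.table::rbindlist(lapply(seq_along(read_seqs), function(i) {
    for_each <- function(s, strand) {
      L <- nchar(s)
      if (L < seed_len) return(NULL)
      offs <- unique(pmin(floor(seq(0, L - seed_len,
                                    length.out = n_seeds)), L - seed_len))
      data.table::data.table(read = i, strand = strand, off = offs,
                             kmer = stringi::stri_sub(s, offs + 1L,
                                                      length = seed_len))
    }
    rbind(for_each(read_seqs[i], "+"), for_each(revcomp(read_seqs[i]), "-"))
  }))
  if (nrow(seed_rows) == 0)
    return(list(alignments = data.table::data.table(), profiles = list()))
  cand <- merge(seed_rows, index, by = "kmer", allow.cartesian = TRUE)
  cand[, start := pos - off]
  cand <- unique(cand[, c("read", "strand", "transcript", "start")])
  rl <- nchar(read_seqs)[cand$read]
  cand <- cand[cand$start >= 1L & cand$start + rl - 1L <= tx_len[cand$transcript], ]
  if (nrow(cand) > 0) {
    qseq <- ifelse(cand$strand == "+", read_seqs[cand$read],
                   revcomp(read_seqs[cand$read]))
    tsub <- stringi::stri_sub(tx_seqs[cand$transcript], cand$start,
                              length = nchar(qseq))
    cand[, mismatches := mapply(str_mismatches, tsub, qseq, USE.NAMES = FALSE)]
    cand <- cand[cand$mismatches <= max_mismatches, ]
  }
  cand[, weight := 1 / .N, by = "read"]
  aln <- data.table::data.table(
    read = read_ids[cand$read],
    transcript_id = transcripts$id[cand$transcript],
    transcript = cand$transcript,
    start = cand$start, strand = cand$strand,
    mismatches = cand$mismatches, weight = cand$weight,
    read_len = nchar(read_seqs)[cand$read])
  profiles <- lapply(setNames(seq_len(nrow(transcripts)), transcripts$id),
                     function(t) {
    h <- aln[aln$transcript == t, ]
    depth <- interval_depth(tx_len[t], h$start, h$start + h$read_len - 1L)
    cds <- (transcripts$cds_start[t] + 1L):transcripts$cds_end[t]
    list(transcript_id = transcripts$id[t], individual_id = individual_id,
         depth = depth[cds], n_reads = length(unique(h$read)))
  })
  list(alignments = aln, profiles = profiles)
}

#' EM estimation of transcript abundances and TPM
#'
#' Resolves multi-mapping reads by expectation-maximization: the E-step
#' reassigns each read across its candidate transcripts proportionally to
#' current abundance divided by effective length; the M-step renormalizes.
#' `TPM_i = 1e6 * (c_i/l_i) / sum_j(c_j/l_j)` where `c` are expected read
#' counts and `l` effective lengths (CDS length by convention here).
#'
#' @param alignments alignment table from [map_reads()] (needs `read` and
#'   `transcript_id`).
#' @param effective_lengths named positive vector over all transcripts.
#' @param em_iters maximum EM iterations (default 100).
#' @param tol convergence tolerance on max absolute abundance change.
#' @return list with `tpm` (named vector over all transcripts, summing to
#'   1e6), `counts` (expected read counts), `n_reads`.
#' @export
estimate_tpm <- function(alignments, effective_lengths, em_iters = 100L,
                         tol = 1e-8) {
  stopifnot(all(effective_lengths > 0))
  tx <- names(effective_lengths)
  if (nrow(alignments) == 0) stop("zero aligned reads for this individual")
  a <- data.table::data.table(read = alignments$read,
                              tx = alignments$transcript_id)
  a <- unique(a)
  a[, li := effective_lengths[tx]]
  n_reads <- length(unique(a$read))
  theta <- setNames(rep(1 / length(tx), length(tx)), tx)
  for (it in seq_len(em_iters)) {
    a[, w := theta[tx] / li]
    a[, w := w / sum(w), by = "read"]
    counts <- a[, list(c = sum(w)), by = "tx"]
    new_theta <- setNames(numeric(length(tx)), tx)
    new_theta[counts$tx] <- counts$c / n_reads
    if (max(abs(new_theta - theta)) < tol) { theta <- new_theta; break }
    theta <- new_theta
  }
  counts <- setNames(numeric(length(tx)), tx)
  cagg <- a[, list(c = sum(w)), by = "tx"]
  counts[cagg$tx] <- cagg$c
  rate <- counts / effective_lengths
  tpm <- 1e6 * rate / sum(rate)
  list(tpm = tpm, counts = counts, n_reads = n_reads)
}

#' Multiplicative zero replacement
#'
#' Column-wise multiplicative replacement on the TPM scale: zeros become
#' `delta = delta_frac * min(nonzero)` of their column and nonzero entries
#' are scaled by `1 - sum(delta)/1e6` so every column total is preserved.
#'
#' @param m nonnegative matrix with positive column sums (TPM scale).
#' @param delta_frac fraction of the smallest nonzero value used for zeros.
#' @return strictly positive matrix with unchanged column sums.
#' @export
replace_zeros <- function(m, delta_frac = 0.65) {
  if (any(colSums(m) <= 0)) stop("matrix has an all-zero column")
  out <- m
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    z <- col == 0
    if (!any(z)) next
    delta <- delta_frac * min(col[!z])
    total <- sum(col)
    out[z, j] <- delta
    out[!z, j] <- col[!z] * (1 - sum(z) * delta / total)
  }
  out
}

#' Centered log-ratio transform
#'
#' `clr_i = ln(x_i) - mean_j ln(x_j)`; maps a strictly positive composition
#' to a vector summing to zero. Applied column-wise to matrices.
#'
#' @param x strictly positive vector or matrix (columns = compositions).
#' @return clr-transformed object of the same shape.
#' @export
clr <- function(x) {
  if (any(x <= 0)) stop("clr requires strictly positive input")
  if (is.matrix(x)) {
    lx <- log(x)
    sweep(lx, 2, colMeans(lx))
  } else {
    lx <- log(x)
    lx - mean(lx)
  }
}

#' Sum expression by toxin class
#'
#' Aggregates transcript-level rows into per-family rows (summing paralogs
#' of the same gene family); column totals over toxin rows are preserved.
#'
#' @param expression matrix transcripts x individuals.
#' @param annotations data.frame with `id`, `family` covering every row of
#'   `expression` (nontoxins may be labeled `"nontoxin"`).
#' @return matrix family x individuals.
#' @export
sum_by_class <- function(expression, annotations) {
  fam <- annotations$family[match(rownames(expression), annotations$id)]
  if (anyNA(fam)) stop("unannotated row in expression matrix")
  rowsum(expression, group = fam)
}

#' Hierarchical clustering of expression profiles
#'
#' Deterministic agglomerative clustering (euclidean distance, average
#' linkage by default) of natural-log expression, returning dendrograms and
#' leaf orders for both transcripts and individuals. Rows/columns are
#' pre-sorted by id so the result is invariant to input permutation.
#'
#' @param ln_expr finite matrix (typically `log(TPM)` after zero
#'   replacement).
#' @param method linkage passed to [stats::hclust()] (default "average").
#' @return list with `row_hclust`, `col_hclust`, `row_order`, `col_order`.
#' @export
expression_cluster <- function(ln_expr, method = "average") {
  if (ncol(ln_expr) < 2) stop("need at least two individuals to cluster")
  stopifnot(all(is.finite(ln_expr)))
  ln_expr <- ln_expr[order(rownames(ln_expr)), order(colnames(ln_expr)),
                     drop = FALSE]
  rh <- hclust(dist(ln_expr), method = method)
  ch <- hclust(dist(t(ln_expr)), method = method)
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(ln_expr)[rh$order],
       col_order = colnames(ln_expr)[ch$order])
}
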