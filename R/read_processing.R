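## -- k-mer based cross-sample contamination filtering, quality trimming,
##    and read-pair merging ------------------------------------------------

## extract all canonical k-mer windows of a set of sequences; windows
## containing N are dropped. Returns a character vector (one entry per
## window) plus, if ids given, the parallel read index.
kmer_windows <- function(seqs, k, ids = NULL) {
  widths <- nchar(seqs)
  nwin <- pmax(widths - k + 1L, 0L)
  keep <- nwin > 0L
  if (!any(keep)) return(list(kmer = character(0), read = integer(0)))
  starts <- lapply(nwin[keep], seq_len)
  kmers <- unlist(stringi::stri_sub_all(seqs[keep], from = starts, length = k),
                  use.names = FALSE)
  read <- rep(which(keep), nwin[keep])
  ok <- !stringi::stri_detect_fixed(kmers, "N")
  kmers <- kmers[ok]; read <- read[ok]
  rc <- revcomp(kmers)
  canon <- ifelse(kmers <= rc, kmers, rc)
  list(kmer = canon, read = read)
}

#' Count canonical k-mers in a read set
#'
#' Counts every length-`k` window of every read in canonical (strand
#' collapsed) form: the lexicographic minimum of the k-mer and its reverse
#' complement. Windows containing `N` are skipped; reads shorter than `k`
#' contribute nothing (with a warning).
#'
#' @param reads read table (needs a `seq` column) or character vector.
#' @param k k-mer length; default 57 and must be odd so no k-mer is its own
#'   reverse complement.
#' @param sample_id label stored on the profile.
#' @return a `kmer_profile`: list with `sample_id`, `k` and `counts`
#'   (data.table `kmer`, `count`).
#' @export
count_kmers <- function(reads, k = 57L, sample_id = NA_character_) {
  stopifnot(k >= 1, k %% 2 == 1)
  seqs <- if (is.character(reads)) reads else reads$seq
  if (length(seqs) > 0 && any(nchar(seqs) < k))
    warning("reads shorter than k contribute no k-mers")
  win <- kmer_windows(seqs, k)
  counts <- if (length(win$kmer) == 0) {
    data.table::data.table(kmer = character(0), count = integer(0))
  } else {
    dt <- data.table::data.table(kmer = win$kmer)
    dt[, list(count = .N), by = "kmer"]
  }
  structure(list(sample_id = sample_id, k = as.integer(k), counts = counts),
            class = "kmer_profile")
}

#' Identify contaminant reads by asymmetric k-mer enrichment
#'
#' A k-mer is contaminant-indicative for the focal sample iff, in some other
#' sample sharing the lane, its count is at least `min_other_count` and at
#' least `enrichment` times (focal count + 1). A read is flagged iff the
#' fraction of its valid (non-N) k-mer windows that are indicative is at
#' least `fraction` (the "25% constructed of these k-mers" rule, read
#' inclusively). Demultiplex bleed-through produces exactly this signature:
#' low focal but high foreign k-mer counts.
#'
#' @param focal_reads read table of the focal sample.
#' @param focal_profile [count_kmers()] profile of the focal sample.
#' @param other_profiles nonempty list of profiles of the other samples on
#'   the same lane; all must share `k`.
#' @param fraction window-fraction threshold (default 0.25, inclusive).
#' @param enrichment fold-enrichment required (default 10).
#' @param min_other_count minimum foreign count (default 2).
#' @return character vector of read ids to drop.
#' @export
find_contaminant_reads <- function(focal_reads, focal_profile, other_profiles,
                                   fraction = 0.25, enrichment = 10,
                                   min_other_count = 2) {
  stopifnot(length(other_profiles) >= 1)
  ks <- vapply(other_profiles, function(p) p$k, 1L)
  if (any(ks != focal_profile$k)) stop("mismatched k across profiles")
  k <- focal_profile$k
  focal <- focal_profile$counts
  indic <- unique(unlist(lapply(other_profiles, function(p) {
    m <- merge(p$counts, focal, by = "kmer", all.x = TRUE,
               suffixes = c("_other", "_focal"))
    m$count_focal[is.na(m$count_focal)] <- 0L
    m$kmer[m$count_other >= min_other_count &
           m$count_other >= enrichment * (m$count_focal + 1)]
  })))
  if (length(indic) == 0) return(character(0))
  win <- kmer_windows(focal_reads$seq, k)
  if (length(win$kmer) == 0) return(character(0))
  hit <- win$kmer %chin% indic
  dt <- data.table::data.table(read = win$read, hit = hit)
  frac <- dt[, list(f = mean(hit)), by = "read"]
  unique(focal_reads$id[frac$read[frac$f >= fraction]])
}

#' Remove cross-contaminant reads from all samples in a lane
#'
#' Runs all pairwise k-mer comparisons between samples sharing a lane and
#' drops, from each sample, every fragment with a flagged mate (both mates
#' of a mis-allocated fragment are foreign, so dropping is fragment-wise).
#'
#' @param reads combined read table with `sample` and `lane` columns.
#' @param k,fraction,enrichment,min_other_count see [find_contaminant_reads()].
#' @return list with `reads` (filtered table) and `dropped` (named list of
#'   dropped fragment ids per sample).
#' @export
decontaminate <- function(reads, k = 57L, fraction = 0.25, enrichment = 10,
                          min_other_count = 2) {
  dropped <- list()
  keep <- rep(TRUE, nrow(reads))
  for (ln in unique(reads$lane)) {
    in_lane <- reads$lane == ln
    samples <- unique(reads$sample[in_lane])
    if (length(samples) < 2) next
    profiles <- lapply(setNames(nm = samples), function(s)
      count_kmers(reads[in_lane & reads$sample == s, ], k, sample_id = s))
    for (s in samples) {
      focal <- reads[in_lane & reads$sample == s, ]
      ids <- find_contaminant_reads(focal, profiles[[s]],
                                    profiles[setdiff(samples, s)],
                                    fraction, enrichment, min_other_count)
      dropped[[s]] <- union(dropped[[s]], ids)
      keep[in_lane & reads$sample == s & reads$id %in% ids] <- FALSE
    }
  }
  list(reads = reads[keep, ], dropped = dropped)
}

#' Quality-trim reads at the first low-quality base
#'
#' 3'-trims each read at the first position whose phred score drops below
#' `phred_min` (default 5): bases from that position onward are removed.
#' Reads trimmed to length zero are flagged discarded.
#'
#' @param reads read table with `seq` and `qual` (phred+33) columns.
#' @param phred_min minimum phred score kept.
#' @return the table with trimmed `seq`/`qual` and a logical `discarded`
#'   column.
#' @export
quality_trim <- function(reads, phred_min = 5L) {
  reads <- data.table::as.data.table(data.table::copy(reads))
  thr <- as.raw(phred_min + 33L)
  cut <- vapply(reads$qual, function(q) {
    r <- charToRaw(q)
    bad <- which(r < thr)
    if (length(bad) == 0) length(r) else bad[1] - 1L
  }, 1L, USE.NAMES = FALSE)
  reads[, seq := stringi::stri_sub(seq, 1, cut)]
  reads[, qual := stringi::stri_sub(qual, 1, cut)]
  reads[, discarded := cut == 0L]
  reads
}

## best ungapped overlap merge of one pair; r2 given as sequenced (it is
## reverse-complemented internally). Returns NULL when no qualifying overlap.
merge_one_pair <- function(s1, q1, s2, q2, min_overlap, max_mismatch_frac) {
  rc2 <- revcomp(s2)
  rcq2 <- stringi::stri_reverse(q2)
  n1 <- nchar(s1); n2 <- nchar(rc2)
  if (n1 < min_overlap || n2 < min_overlap) return(NULL)
  r1 <- charToRaw(s1); r2 <- charToRaw(rc2)
  eval_overlap <- function(o) {
    mm <- sum(r1[(n1 - o + 1):n1] != r2[1:o])
    if (mm / o <= max_mismatch_frac) o - 2 * mm else -Inf
  }
  best <- NULL; best_score <- -Inf
  ## fast path: exact occurrences of the rc(mate2) prefix inside mate1
  ## propose candidate overlaps; exhaustive scan only if none qualifies
  seed_len <- min(12L, min_overlap)
  hits <- stringi::stri_locate_all_fixed(s1, substr(rc2, 1, seed_len))[[1]][, 1]
  if (!all(is.na(hits))) {
    for (o in n1 - hits + 1L) {
      if (o < min_overlap || o > min(n1, n2)) next
      score <- eval_overlap(o)
      if (score > best_score) { best_score <- score; best <- o }
    }
  }
  if (is.null(best)) {
    for (o in seq(min(n1, n2), min_overlap)) {
      score <- eval_overlap(o)
      if (score > best_score) { best_score <- score; best <- o }
    }
  }
  if (is.null(best) || !is.finite(best_score)) return(NULL)
  o <- best[1]
  ov1 <- substr(s1, n1 - o + 1, n1); ov2 <- substr(rc2, 1, o)
  qv1 <- charToRaw(substr(q1, n1 - o + 1, n1))
  qv2 <- charToRaw(substr(rcq2, 1, o))
  take2 <- qv2 > qv1                      # disagreement: higher-quality call
  ovs <- strsplit(ov1, "")[[1]]
  ovs2 <- strsplit(ov2, "")[[1]]
  ovs[take2] <- ovs2[take2]
  ovq <- rawToChar(as.raw(pmax(as.integer(qv1), as.integer(qv2))))
  list(seq = paste0(substr(s1, 1, n1 - o), paste(ovs, collapse = ""),
                    substr(rc2, o + 1, n2)),
       qual = paste0(substr(q1, 1, n1 - o), ovq,
                     substr(rcq2, o + 1, n2)),
       overlap = o)
}

#' Merge read pairs by best ungapped overlap
#'
#' For each fragment the suffix of mate 1 is aligned, without gaps, against
#' the prefix of the reverse complement of mate 2; the highest-scoring
#' overlap of at least `min_overlap` bases with mismatch fraction at most
#' `max_mismatch_frac` is merged, with disagreeing bases resolved toward the
#' higher-quality call. Pairs with no qualifying overlap are returned
#' unmerged.
#'
#' @param reads paired read table (mates share `id`).
#' @param min_overlap minimum overlap length (default 10).
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return list with `merged` (data.table id, seq, qual, sample, lane) and
#'   `unmerged` (the untouched pairs).
#' @export
merge_pairs <- function(reads, min_overlap = 10L, max_mismatch_frac = 0.1) {
  reads <- data.table::as.data.table(reads)
  r1 <- reads[reads$mate == 1L, ]
  r2 <- reads[reads$mate == 2L, ]
  data.table::setkey(r1, id); data.table::setkey(r2, id)
  common <- intersect(r1$id, r2$id)
  r1 <- r1[common]; r2 <- r2[common]
  res <- vector("list", length(common))
  for (i in seq_along(common)) {
    ## res[i] <- list(...) so a NULL (unmergeable pair) is kept as a slot
    res[i] <- list(merge_one_pair(r1$seq[i], r1$qual[i], r2$seq[i],
                                  r2$qual[i], min_overlap, max_mismatch_frac))
  }
  ok <- !vapply(res, is.null, TRUE)
  merged <- data.table::data.table(
    id = common[ok],
    seq = vapply(res[ok], `[[`, "", "seq"),
    qual = vapply(res[ok], `[[`, "", "qual"),
    sample = r1$sample[ok], lane = r1$lane[ok])
  if ("origin" %in% names(r1)) merged[, origin := r1$origin[ok]]
  list(merged = merged,
       unmerged = reads[reads$id %in% common[!ok] | !(reads$id %in% common), ])
}
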