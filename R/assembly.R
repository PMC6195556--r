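## -- greedy seed-extension de novo assembly -------------------------------
##
## Extender-style assembly: random merged reads seed contigs that are grown
## in both directions by exact fixed-length overlaps, halting on ambiguity.

#' Build an exact-overlap prefix index of reads
#'
#' Indexes every read, in both orientations, by its first `overlap` bases so
#' that the current contig end can be extended by exact-prefix lookup. Reads
#' shorter than `overlap` are excluded with a warning.
#'
#' @param reads character vector of read sequences (or a table with `seq`).
#' @param overlap exact-overlap length (default 120).
#' @return an `overlap_index`: keyed data.table (prefix, read, orient, seq)
#'   where `seq` is the read in indexed orientation.
#' @export
build_overlap_index <- function(reads, overlap = 120L) {
  stopifnot(overlap >= 1)
  seqs <- if (is.character(reads)) reads else reads$seq
  short <- nchar(seqs) < overlap
  if (any(short)) warning(sum(short), " reads shorter than overlap excluded")
  seqs <- seqs[!short]
  idx_of <- which(!short)
  dt <- data.table::data.table(
    prefix = c(stringi::stri_sub(seqs, 1, overlap),
               stringi::stri_sub(revcomp(seqs), 1, overlap)),
    read = rep(idx_of, 2L),
    orient = rep(c("+", "-"), each = length(seqs)),
    seq = c(seqs, revcomp(seqs)))
  data.table::setkey(dt, prefix)
  structure(list(index = dt, overlap = as.integer(overlap),
                 max_read_len = if (length(seqs)) max(nchar(seqs)) else 0L),
            class = "overlap_index")
}

## one-directional extension of `contig` to the right. A read extends the
## contig when its first `overlap` bases match a suffix window, the rest of
## the overlapped region agrees exactly, and it reaches past the contig end.
## Returns list(seq, used, stop_reason).
extend_right <- function(contig, index, used) {
  dt <- index$index; ov <- index$overlap
  reason <- NULL
  seen_terminal <- character(0)
  repeat {
    L <- nchar(contig)
    term <- substr(contig, L - ov + 1L, L)
    if (term %in% seen_terminal) { reason <- "cycle-guard"; break }
    seen_terminal <- c(seen_terminal, term)
    max_o <- min(index$max_read_len, L)
    starts <- (L - max_o + 1L):(L - ov + 1L)
    qry <- data.table::data.table(
      prefix = stringi::stri_sub(contig, starts, length = ov),
      cstart = starts)
    hits <- dt[qry, on = "prefix", nomatch = NULL]
    hits <- hits[!(hits$read %in% used), ]
    if (nrow(hits) > 0) {
      o <- L - hits$cstart + 1L                 # overlap length implied
      full <- stringi::stri_sub(contig, hits$cstart, L) ==
        stringi::stri_sub(hits$seq, 1L, o)
      reaches <- nchar(hits$seq) > o
      hits <- hits[full & reaches, ]
      o <- o[full & reaches]
    }
    if (nrow(hits) == 0) { reason <- "no-overlap"; break }
    ext <- substring(hits$seq, o + 1L)
    ord <- order(-nchar(ext))
    ext <- ext[ord]
    longest <- ext[1]
    consistent <- all(startsWith(longest, ext))
    if (!consistent) { reason <- "ambiguous"; break }
    used <- c(used, hits$read)
    contig <- paste0(contig, longest)
  }
  list(seq = contig, used = used, stop = reason)
}

#' Extend a seed read into a contig by exact overlaps
#'
#' Repeatedly looks up the contig's terminal `overlap`-mer in the read index;
#' when all matching unused reads agree, the longest consistent extension is
#' appended. Extension halts when no read matches (`no-overlap`), matching
#' reads disagree on the next base (`ambiguous`), or a terminal k-mer
#' repeats (`cycle-guard`). Both ends are extended and every read is usable
#' at most once per contig.
#'
#' @param seed seed read sequence (length >= `overlap`).
#' @param index an [build_overlap_index()] result.
#' @return list with `seq`, `n_reads_used`, `left_stop`, `right_stop`; the
#'   seed is an exact substring of `seq`.
#' @export
extend_seed <- function(seed, index) {
  if (nchar(seed) < index$overlap) stop("seed shorter than overlap")
  ## the seed read (and identical copies) is consumed by seeding: it must
  ## not re-extend the contig in either orientation
  dt <- index$index
  seed_reads <- unique(dt$read[dt$seq == seed | dt$seq == revcomp(seed)])
  right <- extend_right(seed, index, used = seed_reads)
  flipped <- extend_right(revcomp(right$seq), index, used = right$used)
  list(seq = revcomp(flipped$seq),
       n_reads_used = length(unique(flipped$used)) + 1L,
       left_stop = flipped$stop, right_stop = right$stop)
}

#' Greedy seed-extension assembly
#'
#' Samples `n_seeds` reads uniformly without replacement (all reads if
#' fewer), extends each with [extend_seed()], and drops contigs exactly
#' contained (either strand) in a longer contig. Reads are canonically
#' ordered internally so output is invariant to input order given
#' `rng_seed`.
#'
#' @param reads character vector of merged read sequences (or table with
#'   `seq`).
#' @param n_seeds number of seed reads (default 1000).
#' @param overlap exact-overlap length (default 120).
#' @param rng_seed integer seed for seed sampling.
#' @return data.frame: contig `id`, `seq`, `seed`, `n_reads_used`,
#'   `left_stop`, `right_stop`.
#' @export
assemble <- function(reads, n_seeds = 1000L, overlap = 120L, rng_seed = 1L) {
  seqs <- if (is.character(reads)) reads else reads$seq
  stopifnot(length(seqs) > 0)
  seqs <- sort(seqs)                       # input-order invariance
  index <- suppressWarnings(build_overlap_index(seqs, overlap))
  eligible <- which(nchar(seqs) >= overlap)
  if (length(eligible) == 0) stop("no reads as long as the overlap")
  seeds <- with_seed(rng_seed, {
    if (length(eligible) <= n_seeds) eligible
    else sort(sample(eligible, n_seeds))
  })
  contigs <- lapply(seeds, function(i) extend_seed(seqs[i], index))
  out <- data.frame(
    id = sprintf("contig%04d", seq_along(seeds)),
    seq = vapply(contigs, `[[`, "", "seq"),
    seed = seqs[seeds],
    n_reads_used = vapply(contigs, `[[`, 1L, "n_reads_used"),
    left_stop = vapply(contigs, `[[`, "", "left_stop"),
    right_stop = vapply(contigs, `[[`, "", "right_stop"),
    stringsAsFactors = FALSE)
  drop_contained(out)
}

## drop contigs exactly contained in a longer (or identical, later-ranked)
## contig on either strand
drop_contained <- function(contigs) {
  if (nrow(contigs) < 2) return(contigs)
  ord <- order(-nchar(contigs$seq), contigs$seq)
  contigs <- contigs[ord, ]
  contigs <- contigs[!duplicated(contigs$seq), ]
  keep <- rep(TRUE, nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    if (i == 1) next
    longer <- contigs$seq[seq_len(i - 1)][keep[seq_len(i - 1)]]
    if (length(longer) == 0) next
    s <- contigs$seq[i]
    if (any(stringi::stri_detect_fixed(longer, s)) ||
        any(stringi::stri_detect_fixed(longer, revcomp(s))))
      keep[i] <- FALSE
  }
  contigs <- contigs[keep, ]
  rownames(contigs) <- NULL
  contigs
}
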