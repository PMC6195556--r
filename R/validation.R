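## -- coverage-based chimera screening and presence/absence calling --------

## interval coverage: depth over 1..len from (start, end) inclusive intervals
interval_depth <- function(len, starts, ends) {
  d <- integer(len + 1L)
  if (length(starts)) {
    add <- tabulate(starts, nbins = len + 1L)
    rem <- tabulate(pmin(ends + 1L, len + 1L), nbins = len + 1L)
    d <- cumsum(add - rem)
  } else d <- integer(len + 1L)
  d[seq_len(len)]
}

## exact occurrences of reads (both strands) in a transcript set; returns
## data.table (read, transcript, start, end) in transcript coordinates
exact_hits <- function(read_seqs, tx_seqs) {
  big <- paste(tx_seqs, collapse = "#")
  off <- cumsum(c(0L, nchar(tx_seqs) + 1L))[seq_along(tx_seqs)]
  locate <- function(pats) {
    hits <- stringi::stri_locate_all_fixed(big, pats,
                                           overlap = TRUE)
    n <- vapply(hits, function(h) sum(!is.na(h[, 1])), 1L)
    data.table::data.table(
      read = rep(seq_along(pats), n),
      start_glob = unlist(lapply(hits, function(h) h[!is.na(h[, 1]), 1])),
      end_glob = unlist(lapply(hits, function(h) h[!is.na(h[, 1]), 2])))
  }
  fwd <- locate(read_seqs)
  rev <- locate(revcomp(read_seqs))
  all <- rbind(fwd, rev)
  if (nrow(all) == 0)
    return(data.table::data.table(read = integer(0), transcript = integer(0),
                                  start = integer(0), end = integer(0)))
  tix <- findInterval(all$start_glob, off + 1L)
  ## discard matches spanning a separator
  ok <- all$end_glob <= off[tix] + nchar(tx_seqs)[tix]
  all <- all[ok]; tix <- tix[ok]
  data.table::data.table(read = all$read, transcript = tix,
                         start = all$start_glob - off[tix],
                         end = all$end_glob - off[tix])
}

#' Zero-mismatch coverage of transcripts by merged reads
#'
#' Places reads only at exact full-length matches (either strand) within the
#' transcripts and accumulates per-base depth over each coding sequence.
#' This is the alignment stringency behind the chimera screen: a read with
#' any mismatch contributes nothing.
#'
#' @param reads merged-read table (or character vector of sequences).
#' @param transcripts data.frame with `id`, `seq`, `cds_start`, `cds_end`.
#' @param individual_id label stored on the profiles.
#' @return named list of coverage profiles, one per transcript: list with
#'   `transcript_id`, `individual_id`, `depth` (CDS-length integer vector),
#'   `n_reads`.
#' @export
strict_align_coverage <- function(reads, transcripts,
                                  individual_id = NA_character_) {
  read_seqs <- if (is.character(reads)) reads else reads$seq
  hits <- exact_hits(read_seqs, transcripts$seq)
  lapply(setNames(seq_len(nrow(transcripts)), transcripts$id), function(t) {
    h <- hits[hits$transcript == t, ]
    depth <- interval_depth(nchar(transcripts$seq[t]), h$start, h$end)
    cds <- (transcripts$cds_start[t] + 1L):transcripts$cds_end[t]
    list(transcript_id = transcripts$id[t], individual_id = individual_id,
         depth = depth[cds], n_reads = length(unique(h$read)))
  })
}

## centered running mean, window w (clipped at the ends)
running_mean <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Coverage-based chimera screen
#'
#' Verdict rules over the CDS depth profile of the assembling individual's
#' zero-mismatch alignment: any zero-depth base removes the transcript
#' (`remove-zero`); otherwise a max/min depth ratio above `max_ratio`
#' removes it only when the profile is multimodal (`remove-chimeric`), i.e.
#' some internal changepoint splits the CDS into two segments, each at
#' least `min_seg_frac` of its length, whose mean smoothed depths differ
#' more than `max_ratio`-fold; a high ratio without multimodality is
#' flagged but kept.
#'
#' @param profile a coverage profile from [strict_align_coverage()].
#' @param max_ratio fold-differential threshold (default 10).
#' @param window smoothing window in bases (default 25).
#' @param min_seg_frac minimum segment share of the CDS (default 0.10).
#' @return one of `"keep"`, `"remove-zero"`, `"remove-chimeric"`, `"flag"`.
#' @export
chimera_screen <- function(profile, max_ratio = 10, window = 25L,
                           min_seg_frac = 0.10) {
  depth <- profile$depth
  if (length(depth) == 0) stop("empty coverage profile")
  if (any(depth == 0)) return("remove-zero")
  if (max(depth) / min(depth) <= max_ratio) return("keep")
  sm <- running_mean(depth, window)
  n <- length(sm)
  lo <- max(2L, ceiling(min_seg_frac * n))
  hi <- min(n - 1L, n - ceiling(min_seg_frac * n))
  if (lo <= hi) {
    cs <- cumsum(sm)
    for (c in lo:hi) {
      m1 <- cs[c] / c
      m2 <- (cs[n] - cs[c]) / (n - c)
      if (max(m1, m2) / min(m1, m2) > max_ratio) return("remove-chimeric")
    }
  }
  "flag"
}

#' Toxin presence/absence call from coverage
#'
#' A transcript is called absent from an individual iff strictly more than
#' `max_low_frac` of its CDS bases have depth below `min_depth` (the 5x /
#' 10% rule). This is a reporting rule only; differential-expression tests
#' keep all transcripts.
#'
#' @param profile coverage profile (from the mismatch-tolerant mapper,
#'   [map_reads()]).
#' @param min_depth minimum depth counted as covered (default 5).
#' @param max_low_frac maximum tolerated low-coverage fraction (default
#'   0.10, strict inequality).
#' @return `TRUE` if absent, `FALSE` if present.
#' @export
call_absence_toxin <- function(profile, min_depth = 5, max_low_frac = 0.10) {
  depth <- profile$depth
  if (length(depth) == 0) stop("empty coverage profile")
  mean(depth < min_depth) > max_low_frac
}

#' Select nontoxin loci present in every individual
#'
#' A locus is retained iff every individual covers every one of its sites at
#' depth >= 1 (any zero-coverage site in any individual marks the locus
#' absent there). This is the shared-locus rule used to assemble the
#' phylotranscriptomic dataset; it is deliberately stricter than, and not
#' interchangeable with, the toxin 5x/10% rule.
#'
#' @param profiles_by_individual named list: individual ->
#'   (named list: transcript id -> coverage profile).
#' @return character vector of retained locus ids.
#' @export
select_shared_nontoxin_loci <- function(profiles_by_individual) {
  stopifnot(length(profiles_by_individual) >= 1)
  loci <- names(profiles_by_individual[[1]])
  for (p in profiles_by_individual)
    if (!setequal(names(p), loci)) stop("missing coverage profile")
  keep <- vapply(loci, function(l) {
    all(vapply(profiles_by_individual, function(p) {
      d <- p[[l]]$depth
      length(d) > 0 && all(d >= 1)
    }, TRUE))
  }, TRUE)
  loci[keep]
}

#' Absence matrix over transcripts and individuals
#'
#' Applies [call_absence_toxin()] across a full set of coverage profiles.
#'
#' @param profiles named list: individual -> (named list: transcript ->
#'   profile).
#' @param min_depth,max_low_frac see [call_absence_toxin()].
#' @return logical matrix transcripts x individuals (`TRUE` = absent).
#' @export
absence_matrix <- function(profiles, min_depth = 5, max_low_frac = 0.10) {
  indivs <- names(profiles)
  tx <- names(profiles[[1]])
  m <- vapply(indivs, function(i)
    vapply(tx, function(t)
      call_absence_toxin(profiles[[i]][[t]], min_depth, max_low_frac), TRUE),
    logical(length(tx)))
  matrix(m, nrow = length(tx), dimnames = list(tx, indivs))
}
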