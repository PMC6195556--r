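## -- reference-based annotation and cd-hit-style consensus clustering -----

## unique k-mer windows of one sequence (single orientation)
kmer_set <- function(seq, k) {
  if (nchar(seq) < k) return(character(0))
  unique(stringi::stri_sub(seq, 1:(nchar(seq) - k + 1L), length = k))
}

## ungapped identity lower bound: anchor `a` (or its reverse complement)
## inside `b` at the offset implied by the first shared 14-mer and count
## matching bases over the shorter length; NA when no anchor is found
ungapped_identity <- function(a, b) {
  n <- nchar(a)
  best <- NA_real_
  for (aa in c(a, revcomp(a))) {
    ak <- kmer_set(aa, 14L)
    hit <- which(ak %chin% kmer_set(b, 14L))
    if (length(hit) == 0) next
    pa <- hit[1]                                  # k-mer start within aa
    pb <- stringi::stri_locate_first_fixed(b, ak[pa])[1, 1]
    off <- pb - pa                                # aa position i -> b i+off
    lo <- max(1L, 1L - off); hi <- min(n, nchar(b) - off)
    if (hi < lo) next
    m <- sum(charToRaw(substr(aa, lo, hi)) !=
               charToRaw(substr(b, lo + off, hi + off)))
    cand <- (hi - lo + 1L - m) / n
    if (is.na(best) || cand > best) best <- cand
  }
  best
}

#' Pairwise sequence identity, cd-hit style
#'
#' Identity is matching columns divided by the length of the shorter
#' sequence, from a global alignment of the shorter sequence against the
#' best-matching local region of the longer (Biostrings `global-local`
#' alignment). Both strands are considered and the better one is returned.
#' A k-mer prefilter short-circuits clearly sub-threshold pairs.
#'
#' @param a,b DNA sequences (character scalars).
#' @param min_identity optional floor used by the prefilter: pairs that
#'   provably fall below it return 0 without alignment.
#' @param b_kmers optional precomputed both-strand 14-mer set of `b`
#'   (performance cache for repeated comparisons against the same sequence).
#' @return identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b, min_identity = 0, b_kmers = NULL) {
  swapped <- nchar(a) > nchar(b)
  if (swapped) { tmp <- a; a <- b; b <- tmp }
  n <- nchar(a)
  if (n == 0) return(0)
  ## exact containment (either strand) is identity 1 by definition
  if (stringi::stri_detect_fixed(b, a) ||
      stringi::stri_detect_fixed(b, revcomp(a))) return(1)
  ## prefilter: at `min_identity` over the shorter length, >= 3 exact shared
  ## 14-mers are effectively certain for realistic lengths
  if (min_identity >= 0.8 && n >= 50) {
    bk <- if (!is.null(b_kmers) && !swapped) b_kmers
          else unique(c(kmer_set(b, 14L), kmer_set(revcomp(b), 14L)))
    if (sum(kmer_set(a, 14L) %chin% bk) < 3) return(0)
    ## ungapped anchor shortcut: identity from a shared-14-mer offset is a
    ## lower bound on alignment identity, so reaching the floor suffices
    ug <- ungapped_identity(a, b)
    if (!is.na(ug) && ug >= min_identity) return(ug)
  }
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  score_one <- function(p) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = p, subject = b, type = "global-local",
      substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
    Biostrings::nmatch(aln) / n
  }
  max(score_one(a), score_one(revcomp(a)))
}

#' Greedy identity clustering with representatives
#'
#' cd-hit-style greedy clustering: sequences are sorted by decreasing length
#' (ties broken lexicographically); each sequence joins the first existing
#' cluster whose representative it matches at `>= threshold` identity (per
#' [seq_identity()]), otherwise founds a new cluster. The representative is
#' the longest member (the founder).
#'
#' @param seqs character vector of sequences.
#' @param threshold identity threshold in `(0, 1]` (default 0.98).
#' @param ids optional sequence ids (default index).
#' @return data.frame: `id`, `seq`, `cluster` (integer), `is_representative`.
#' @export
greedy_identity_cluster <- function(seqs, threshold = 0.98, ids = NULL) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(seqs) == 0)
    return(data.frame(id = character(0), seq = character(0),
                      cluster = integer(0), is_representative = logical(0)))
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  ord <- order(-nchar(seqs), seqs, ids)
  seqs <- seqs[ord]; ids <- ids[ord]
  cluster <- integer(length(seqs))
  reps <- integer(0)                       # indices of representatives
  rep_kmers <- list()                      # cached both-strand 14-mer sets
  for (i in seq_along(seqs)) {
    assigned <- FALSE
    n_i <- nchar(seqs[i])
    ## all 14-mer windows (both orientations, with multiplicity): identity
    ## >= t over the shorter length n needs >= (n-13) - 14(1-t)n of them
    ## shared with the representative (each mismatch/gap kills <= 14)
    aw <- if (n_i >= 14) stringi::stri_sub(seqs[i], 1:(n_i - 13L),
                                           length = 14L) else character(0)
    required <- max(3, floor((n_i - 13L) - 14 * (1 - threshold) * n_i))
    for (ri in seq_along(reps)) {
      r <- reps[ri]
      ## rep_kmers holds both strands, so forward windows cover both
      ## orientations of the query
      if (threshold >= 0.8 && n_i >= 50 &&
          sum(aw %chin% rep_kmers[[ri]]) < required) next
      if (seqs[i] == seqs[r] ||
          seq_identity(seqs[i], seqs[r], min_identity = threshold,
                       b_kmers = rep_kmers[[ri]]) >= threshold) {
        cluster[i] <- cluster[r]; assigned <- TRUE; break
      }
    }
    if (!assigned) {
      cluster[i] <- length(reps) + 1L
      reps <- c(reps, i)
      rep_kmers[[length(reps)]] <-
        unique(c(kmer_set(seqs[i], 14L), kmer_set(revcomp(seqs[i]), 14L)))
    }
  }
  data.frame(id = ids, seq = seqs, cluster = cluster,
             is_representative = seq_along(seqs) %in% reps,
             stringsAsFactors = FALSE)
}

## map position `pos` (1-based) in subject coords onto pattern coords of a
## pairwiseAlignment; returns NA outside the aligned region
aln_map_subject_to_pattern <- function(aln, pos) {
  pchars <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  schars <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ppos <- cumsum(pchars != "-") +
    Biostrings::start(Biostrings::pattern(aln)) - 1L
  spos <- cumsum(schars != "-") +
    Biostrings::start(Biostrings::subject(aln)) - 1L
  vapply(pos, function(p) {
    hit <- which(spos == p & schars != "-")
    if (length(hit) == 0) NA_integer_ else ppos[hit[1]]
  }, 1L)
}

#' Find the longest open reading frame
#'
#' Scans all six frames for the longest ATG-initiated ORF terminated by a
#' stop codon (or running to the sequence end), at least `min_codons` codons
#' long.
#'
#' @param seq DNA sequence.
#' @param min_codons minimum ORF length in codons including the start.
#' @return 0-based half-open `c(start, end)` on the forward strand, with
#'   attribute `strand`, or `NULL` if none qualifies.
#' @export
longest_orf <- function(seq, min_codons = 90L) {
  best <- NULL; best_len <- 0
  n <- nchar(seq)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    hits <- stringi::stri_locate_all_regex(
      s, "ATG(?:(?!TAA|TAG|TGA)[ACGT]{3})*(?:TAA|TAG|TGA)?")[[1]]
    ## regex above is greedy per start; enumerate ATG starts explicitly
    starts <- stringi::stri_locate_all_fixed(s, "ATG")[[1]][, 1]
    if (all(is.na(starts))) next
    for (st in starts) {
      m <- stringi::stri_match_first_regex(
        substr(s, st, n), "^ATG(?:(?!TAA|TAG|TGA)[ACGT]{3})*(?:TAA|TAG|TGA)?")
      if (is.na(m[1, 1])) next
      len <- nchar(m[1, 1])
      len <- len - len %% 3
      if (len / 3 >= min_codons && len > best_len) {
        best_len <- len
        a <- if (strand == "+") st - 1L else n - (st - 1L) - len
        best <- structure(c(a, a + len), strand = strand)
      }
    }
  }
  best
}

## CDS inheritance by ungapped offset arithmetic: anchor the contig (either
## strand) on the reference via a shared 14-mer, verify the overlap is a
## plausible substitution-only match, and map the reference CDS through the
## offset, clipped to the contig, kept in frame and trimmed to a codon
## multiple. Returns NULL when no consistent anchor exists (e.g. indels);
## the caller then falls back to full alignment.
inherit_cds_offset <- function(contig, ref_seq, cds_start, cds_end) {
  rk <- kmer_set(ref_seq, 14L)
  for (s in c(contig, revcomp(contig))) {
    ak <- kmer_set(s, 14L)
    shared <- which(ak %chin% rk)
    if (length(shared) == 0) next
    anchor <- ak[shared[1]]
    pa <- stringi::stri_locate_first_fixed(s, anchor)[1, 1]
    pb <- stringi::stri_locate_first_fixed(ref_seq, anchor)[1, 1]
    off <- pb - pa                        # contig position i -> ref i + off
    ## overlap of contig with the reference through this offset
    lo <- max(1L, 1L - off); hi <- min(nchar(s), nchar(ref_seq) - off)
    if (hi < lo) next
    mm <- sum(charToRaw(substr(s, lo, hi)) !=
                charToRaw(substr(ref_seq, lo + off, hi + off)))
    if (mm / (hi - lo + 1L) > 0.25) next  # offset inconsistent; use alignment
    ## reference CDS [cds_start+1, cds_end] in contig coordinates
    lo_ref <- max(cds_start + 1L, lo + off)
    hi_ref <- min(cds_end, hi + off)
    lo_ref <- lo_ref + (3L - (lo_ref - (cds_start + 1L)) %% 3L) %% 3L
    if (hi_ref <= lo_ref) next
    len <- (hi_ref - lo_ref + 1L) - (hi_ref - lo_ref + 1L) %% 3L
    if (len < 3L) next
    return(list(seq = s, cds_start = lo_ref - off - 1L,
                cds_end = lo_ref - off - 1L + len))
  }
  NULL
}

#' Annotate contigs against a curated reference set
#'
#' Each contig is compared with every reference sequence; at identity
#' `>= auto_threshold` (default 0.80) against its best match it inherits the
#' reference's family label, annotation class and CDS (mapped through the
#' alignment onto contig coordinates). Below threshold the contig is
#' `unannotated` and queued for manual review; its CDS falls back to the
#' longest ORF of at least 90 codons.
#'
#' @param contigs data.frame with `id` and `seq`.
#' @param reference data.frame with `id`, `family`, `annotation`
#'   (`"toxin"`/`"nontoxin"`), `seq`, `cds_start`, `cds_end` (0-based
#'   half-open).
#' @param auto_threshold automatic-annotation identity threshold.
#' @return data.frame of annotated transcripts: id, seq, annotation, family,
#'   identity, ref_id, cds_start, cds_end.
#' @export
annotate_by_reference <- function(contigs, reference, auto_threshold = 0.80) {
  if (nrow(reference) > 0 &&
      (is.null(reference$family) || anyNA(reference$family)))
    stop("reference records must carry family labels")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  out <- contigs[, c("id", "seq")]
  out$annotation <- "unannotated"; out$family <- NA_character_
  out$identity <- 0; out$ref_id <- NA_character_
  out$cds_start <- NA_integer_; out$cds_end <- NA_integer_
  ref_kmers <- lapply(reference$seq, function(r)
    unique(c(kmer_set(r, 14L), kmer_set(revcomp(r), 14L))))
  for (i in seq_len(nrow(contigs))) {
    idents <- vapply(seq_len(nrow(reference)), function(r)
      seq_identity(contigs$seq[i], reference$seq[r],
                   min_identity = auto_threshold, b_kmers = ref_kmers[[r]]),
      1, USE.NAMES = FALSE)
    best <- if (length(idents)) which.max(idents) else integer(0)
    if (length(best) == 1 && idents[best] >= auto_threshold) {
      ref <- reference[best, ]
      out$annotation[i] <- ref$annotation
      out$family[i] <- ref$family
      out$identity[i] <- idents[best]
      out$ref_id[i] <- ref$id
      ## fast path: a consistent ungapped anchor maps the CDS by offset
      ex <- inherit_cds_offset(contigs$seq[i], ref$seq, ref$cds_start,
                               ref$cds_end)
      if (!is.null(ex)) {
        out$seq[i] <- ex$seq
        out$cds_start[i] <- ex$cds_start
        out$cds_end[i] <- ex$cds_end
        next
      }
      ## orient contig toward the reference, then map the reference CDS
      fwd <- Biostrings::pairwiseAlignment(
        pattern = contigs$seq[i], subject = ref$seq, type = "local",
        substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
      rev <- Biostrings::pairwiseAlignment(
        pattern = revcomp(contigs$seq[i]), subject = ref$seq, type = "local",
        substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
    if (Biostrings::score(rev) > Biostrings::score(fwd)) {
        out$seq[i] <- revcomp(out$seq[i])
        aln <- rev
      } else aln <- fwd
      lo <- aln_map_subject_to_pattern(aln, ref$cds_start + 1L)
      hi <- aln_map_subject_to_pattern(aln, ref$cds_end)
      if (!is.na(lo) && !is.na(hi) && hi > lo) {
        len <- (hi - lo + 1L) - (hi - lo + 1L) %% 3L
        out$cds_start[i] <- lo - 1L
        out$cds_end[i] <- lo - 1L + len
      }
    }
    if (is.na(out$cds_start[i])) {
      orf <- longest_orf(out$seq[i])
      if (!is.null(orf)) {
        if (attr(orf, "strand") == "-") out$seq[i] <- revcomp(out$seq[i])
        orf2 <- if (attr(orf, "strand") == "-")
          c(nchar(out$seq[i]) - orf[2], nchar(out$seq[i]) - orf[1]) else orf
        out$cds_start[i] <- orf2[1]; out$cds_end[i] <- orf2[2]
      }
    }
  }
  out
}

#' Build the species consensus transcriptome
#'
#' Pools the annotated per-individual transcript sets, clusters the union at
#' `threshold` identity with [greedy_identity_cluster()], and keeps one
#' representative (the longest member) per cluster, recording which
#' individuals contributed to each consensus transcript.
#'
#' @param sets named list (individual id -> annotated transcript data.frame
#'   as from [annotate_by_reference()]).
#' @param threshold clustering identity threshold (default 0.98).
#' @return data.frame: consensus transcripts with `source_individuals`
#'   (comma-separated) and `n_individuals`.
#' @export
build_consensus <- function(sets, threshold = 0.98) {
  stopifnot(length(sets) >= 1)
  pool <- do.call(rbind, lapply(names(sets), function(ind) {
    s <- sets[[ind]]
    s$individual <- ind
    s
  }))
  ## resolve duplicate ids across individuals
  pool$uid <- make.unique(paste(pool$individual, pool$id, sep = ":"))
  cl <- greedy_identity_cluster(pool$seq, threshold, ids = pool$uid)
  merged <- merge(cl, pool, by.x = "id", by.y = "uid",
                  suffixes = c("", ".orig"))
  reps <- merged[merged$is_representative, ]
  reps <- reps[order(reps$cluster), ]
  contributors <- tapply(merged$individual, merged$cluster,
                         function(x) sort(unique(x)))
  reps$source_individuals <- vapply(contributors[as.character(reps$cluster)],
                                    paste, "", collapse = ",")
  reps$n_individuals <- vapply(contributors[as.character(reps$cluster)],
                               length, 1L)
  out <- reps[, c("id.orig", "seq", "annotation", "family", "identity",
                  "ref_id", "cds_start", "cds_end", "cluster",
                  "source_individuals", "n_individuals")]
  names(out)[1] <- "id"
  ## consensus ids must be unique even when two clusters share a member name
  out$id <- make.unique(out$id)
  rownames(out) <- NULL
  out
}
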