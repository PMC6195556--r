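## shared fixture builders; everything is generated in code at test time

## small read table from raw sequences (uniform high quality)
make_reads <- function(seqs, sample = "S1", lane = "L001", mate = 1L,
                       qual = NULL) {
  if (is.null(qual))
    qual <- vapply(nchar(seqs),
                   function(n) paste(rep("H", n), collapse = ""), "")
  data.table::data.table(
    id = sprintf("%s:r%03d", sample, seq_along(seqs)), mate = mate,
    seq = seqs, qual = qual, sample = sample, lane = lane)
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## tile a transcript with error-free reads of length rl starting every `by`;
## the final window is always included so the read set spans the transcript
tile_reads <- function(tx, rl = 60, by = 5) {
  last <- nchar(tx) - rl + 1
  starts <- unique(c(seq(1, last, by = by), last))
  vapply(starts, function(s) substr(tx, s, s + rl - 1), "")
}

## coverage profile object from a raw depth vector
make_profile <- function(depth, id = "tx1", indiv = "I1") {
  list(transcript_id = id, individual_id = indiv,
       depth = as.integer(depth), n_reads = NA_integer_)
}

## metadata-like factor table for n samples split into two groups
two_group_table <- function(n = 8) {
  data.frame(individual_id = paste0("s", seq_len(n)),
             svl_cm = seq(30, 50, length.out = n),
             sex = rep(c("F", "M"), each = n / 2),
             subspecies = "x", mtdna_lineage = "x", nontoxin_lineage = "x",
             stringsAsFactors = FALSE)
}
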