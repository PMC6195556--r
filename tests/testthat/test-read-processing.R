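test_that("k-mer counting matches window arithmetic and canonicalizes strands", {
  ## 60-base homopolymer: 60 - 57 + 1 = 4 windows, all identical
  prof <- count_kmers(strrep("A", 60), k = 57)
  expect_equal(nrow(prof$counts), 1)
  expect_equal(prof$counts$count, 4L)
  ## canonical form: A^57 < T^57 so the key is the A-run
  expect_equal(prof$counts$kmer, strrep("A", 57))

  expect_equal(nrow(count_kmers(character(0), k = 57)$counts), 0)
  expect_warning(count_kmers("ACGT", k = 57), "shorter than k")

  ## a read and its reverse complement give identical profiles
  s <- random_seq(150, seed = 8)
  p1 <- count_kmers(s, k = 57)$counts
  p2 <- count_kmers(revcomp(s), k = 57)$counts
  expect_equal(p1[order(p1$kmer)], p2[order(p2$kmer)])

  ## total window count: sum(len - k + 1) minus N-containing windows
  s2 <- c(random_seq(100, seed = 1), random_seq(80, seed = 2))
  expect_equal(sum(count_kmers(s2, k = 21)$counts$count), (100 - 20) + (80 - 20))
  with_n <- paste0(substr(s2[1], 1, 30), "N", substr(s2[1], 32, 100))
  expect_equal(sum(count_kmers(with_n, k = 21)$counts$count), 80 - 21)
})

test_that("contaminant read flagging applies the 25% window-fraction rule exactly", {
  k <- 7L
  ## focal sample: reads over alphabet segment X; other sample: segment Y
  x_tx <- random_seq(400, seed = 21)
  y_tx <- random_seq(400, seed = 22)
  focal_native <- make_reads(tile_reads(x_tx, rl = 100, by = 7), sample = "A")
  other_reads <- make_reads(tile_reads(y_tx, rl = 100, by = 2), sample = "B")
  ## a fully foreign read and a fully native read
  probe <- make_reads(c(substr(y_tx, 50, 149), substr(x_tx, 50, 149)),
                      sample = "A")
  probe$id <- c("foreign", "native")
  focal <- rbind(focal_native, probe)
  pf <- count_kmers(focal, k = k, sample_id = "A")
  po <- count_kmers(other_reads, k = k, sample_id = "B")
  ids <- find_contaminant_reads(focal, pf, list(po), fraction = 0.25)
  expect_true("foreign" %in% ids)
  expect_false("native" %in% ids)

  ## threshold arithmetic: a 100-base read has 94 windows at k=7; a chimeric
  ## read with exactly 24/94 ~ 0.255 foreign windows is dropped, 23/94 kept
  mk_chim <- function(n_foreign) {
    ## first (n_foreign + k - 1) bases foreign, rest native: the first
    ## n_foreign windows are fully foreign, remaining windows fully native
    paste0(substr(y_tx, 201, 201 + n_foreign + k - 2),
           substr(x_tx, 201, 300 - n_foreign - k + 1))
  }
  probe2 <- make_reads(c(mk_chim(24), mk_chim(23)), sample = "A")
  probe2$id <- c("drop", "keep")
  focal2 <- rbind(focal_native, probe2)
  ids2 <- find_contaminant_reads(focal2, count_kmers(focal2, k = k),
                                 list(po), fraction = 0.25)
  expect_true("drop" %in% ids2)
  expect_false("keep" %in% ids2)

  expect_error(find_contaminant_reads(focal, pf,
                                      list(count_kmers(other_reads, k = 9))),
               "mismatched k")
})

test_that("decontamination is idempotent", {
  x_tx <- random_seq(500, seed = 31)
  y_tx <- random_seq(500, seed = 32)
  a <- make_reads(tile_reads(x_tx, rl = 100, by = 4), sample = "A")
  b <- make_reads(tile_reads(y_tx, rl = 100, by = 4), sample = "B")
  ## plant a few swapped reads
  swap <- make_reads(tile_reads(y_tx, rl = 100, by = 90), sample = "A")
  swap$id <- paste0("sw", seq_len(nrow(swap)))
  reads <- rbind(a, b, swap)
  d1 <- decontaminate(reads, k = 9)
  d2 <- decontaminate(d1$reads, k = 9)
  expect_true(all(lengths(d2$dropped) == 0))
  expect_identical(d1$reads$id, d2$reads$id)
})

test_that("quality trimming cuts at the first sub-threshold base", {
  q <- function(v) rawToChar(as.raw(v + 33L))
  reads <- make_reads(c("ACGTA", "ACGTA", "ACGTA"),
                      qual = c(q(c(30, 30, 30, 30, 30)),
                               q(c(30, 30, 30, 2, 30)),
                               q(c(2, 2, 2, 2, 2))))
  tr <- quality_trim(reads, phred_min = 5)
  expect_equal(tr$seq, c("ACGTA", "ACG", ""))
  expect_equal(tr$discarded, c(FALSE, FALSE, TRUE))
  expect_equal(nchar(tr$qual), nchar(tr$seq))
  ## boundary: phred exactly 5 is kept
  tr5 <- quality_trim(make_reads("AC", qual = q(c(5, 5))), phred_min = 5)
  expect_equal(tr5$seq, "AC")
})

test_that("pair merging honors overlap arithmetic and the quality rule", {
  set.seed(2)
  frag <- random_seq(130)
  r1 <- substr(frag, 1, 90)
  r2 <- revcomp(substr(frag, 41, 130))     # 50-base true overlap
  reads <- rbind(make_reads(r1, mate = 1L), make_reads(r2, mate = 2L))
  m <- merge_pairs(reads, min_overlap = 10)
  expect_equal(nrow(m$merged), 1)
  expect_equal(nchar(m$merged$seq), 90 + 90 - 50)
  expect_equal(m$merged$seq, frag)

  ## non-overlapping mates stay unmerged
  nr <- rbind(make_reads(random_seq(60, seed = 1), mate = 1L),
              make_reads(random_seq(60, seed = 99), mate = 2L))
  m2 <- merge_pairs(nr, min_overlap = 10)
  expect_equal(nrow(m2$merged), 0)
  expect_equal(length(unique(m2$unmerged$id)), 1)

  ## disagreement resolved toward the higher-quality call
  q <- function(v) rawToChar(as.raw(v + 33L))
  frag2 <- random_seq(60, seed = 5)
  a <- substr(frag2, 1, 40)
  b_region <- substr(frag2, 21, 60)
  ## mutate the first overlap base of mate 2, but give mate 1 quality 40
  bad <- b_region
  substr(bad, 1, 1) <- setdiff(c("A", "C", "G", "T"),
                               substr(b_region, 1, 1))[1]
  reads3 <- rbind(
    make_reads(a, mate = 1L, qual = q(rep(40, 40))),
    make_reads(revcomp(bad), mate = 2L, qual = q(rep(2, 40))))
  m3 <- merge_pairs(reads3, min_overlap = 10, max_mismatch_frac = 0.1)
  expect_equal(m3$merged$seq, frag2)
})
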