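test_that("sequence identity matches an alignment oracle at key boundaries", {
  s <- random_seq(500, seed = 41)
  expect_equal(seq_identity(s, s), 1)
  expect_equal(seq_identity(s, revcomp(s)), 1)
  ## substring of a longer sequence: identity over the shorter = 1
  expect_equal(seq_identity(substr(s, 100, 300), s), 1)
  ## plant exactly 10% substitutions -> identity ~0.90, below 0.98
  mut <- strsplit(s, "")[[1]]
  set.seed(1); pos <- sample(500, 50)
  for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  m <- paste(mut, collapse = "")
  expect_equal(seq_identity(s, m), 0.90, tolerance = 0.01)
  expect_lt(seq_identity(s, m, min_identity = 0.98), 0.98)
  ## unrelated sequences are far below any threshold
  expect_lt(seq_identity(s, random_seq(500, seed = 99)), 0.6)
})

test_that("greedy clustering is deterministic and respects the threshold", {
  a <- random_seq(400, seed = 51)
  b <- random_seq(400, seed = 52)
  ## two identical -> one cluster
  cl <- greedy_identity_cluster(c(a, a), 0.98)
  expect_equal(max(cl$cluster), 1)
  expect_equal(sum(cl$is_representative), 1)
  ## 90% identity at threshold 0.98 -> two clusters
  mut <- strsplit(a, "")[[1]]
  set.seed(2); pos <- sample(400, 40)
  for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  a90 <- paste(mut, collapse = "")
  expect_equal(max(greedy_identity_cluster(c(a, a90), 0.98)$cluster), 2)
  ## ... but one cluster at threshold 0.85
  expect_equal(max(greedy_identity_cluster(c(a, a90), 0.85)$cluster), 1)
  ## threshold 1.0, all distinct -> n singletons
  cl3 <- greedy_identity_cluster(c(a, b, random_seq(300, seed = 53)), 1.0)
  expect_equal(max(cl3$cluster), 3)
  ## empty input
  expect_equal(nrow(greedy_identity_cluster(character(0), 0.98)), 0)
  ## representative is the longest member; a substring joins its cluster
  cl4 <- greedy_identity_cluster(c(substr(a, 50, 250), a), 0.98,
                                 ids = c("short", "long"))
  expect_equal(cl4$id[cl4$is_representative], "long")
  expect_equal(max(cl4$cluster), 1)
})

test_that("annotation inherits family and CDS above the 80% threshold", {
  cfg <- sim_config(seed = 6, n_individuals = 1, n_toxins = 5, n_nontoxins = 2,
                    family_counts = c(SVMP = 3, PLA2 = 2))
  ref <- generate_reference(cfg)$reference
  ## identical contig -> inherits annotation trivially
  contigs <- data.frame(id = "c1", seq = ref$seq[1], stringsAsFactors = FALSE)
  ann <- annotate_by_reference(contigs, ref)
  expect_equal(ann$annotation, "toxin")
  expect_equal(ann$family, ref$family[1])
  expect_equal(ann$identity, 1)
  expect_equal(ann$cds_start, ref$cds_start[1])
  expect_equal(ann$cds_end, ref$cds_end[1])
  ## reverse-complement contig is reoriented and annotated the same way
  ann_rc <- annotate_by_reference(
    data.frame(id = "c1rc", seq = revcomp(ref$seq[1])), ref)
  expect_equal(ann_rc$family, ref$family[1])
  expect_equal(ann_rc$seq, ref$seq[1])
  ## ~79% identity falls below the auto threshold -> unannotated
  mut <- strsplit(ref$seq[2], "")[[1]]
  set.seed(3); pos <- sample(length(mut), round(0.21 * length(mut)))
  for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
  ann79 <- annotate_by_reference(
    data.frame(id = "c2", seq = paste(mut, collapse = "")), ref)
  expect_equal(ann79$annotation, "unannotated")
  ## empty reference -> everything unannotated
  ann0 <- annotate_by_reference(contigs, ref[0, ])
  expect_equal(ann0$annotation, "unannotated")
  ## reference without family labels errors
  bad <- ref; bad$family <- NA_character_
  expect_error(annotate_by_reference(contigs, bad), "family")
})

test_that("round trip: annotating the reference against itself is 100% automatic", {
  cfg <- sim_config(seed = 7, n_individuals = 1, n_toxins = 6, n_nontoxins = 3)
  ref <- generate_reference(cfg)$reference
  ann <- annotate_by_reference(ref[, c("id", "seq")], ref)
  expect_true(all(ann$annotation != "unannotated"))
  expect_true(all(ann$identity == 1))
  expect_equal(ann$family, ref$family)
})

test_that("consensus building pools individuals and tracks provenance", {
  cfg <- sim_config(seed = 8, n_individuals = 1, n_toxins = 4, n_nontoxins = 2)
  ref <- generate_reference(cfg)$reference
  tx <- ref[, c("id", "seq", "cds_start", "cds_end")]
  tx$annotation <- ref$annotation; tx$family <- ref$family
  tx$identity <- 1; tx$ref_id <- ref$id
  ## 8 identical single-transcript sets -> consensus of 1 with 8 sources
  sets <- lapply(setNames(nm = paste0("I", 1:8)), function(i) tx[1, ])
  cons <- build_consensus(sets)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$n_individuals, 8)
  ## two individuals with disjoint transcripts -> sizes add
  cons2 <- build_consensus(list(I1 = tx[1:2, ], I2 = tx[3:4, ]))
  expect_equal(nrow(cons2), 4)
  expect_true(all(cons2$n_individuals == 1))
  ## union with shared transcripts dedupes to the distinct set
  cons3 <- build_consensus(list(I1 = tx[1:3, ], I2 = tx[2:4, ]))
  expect_equal(nrow(cons3), 4)
  shared <- cons3$n_individuals[match(tx$id[2:3], cons3$id)]
  expect_true(all(shared == 2))
})

test_that("consensus size is monotone non-increasing in the threshold", {
  set.seed(9)
  base <- random_seq(300)
  variants <- vapply(c(2, 8, 30), function(k) {
    mut <- strsplit(base, "")[[1]]
    pos <- sample(300, k)
    for (p in pos) mut[p] <- setdiff(c("A", "C", "G", "T"), mut[p])[1]
    paste(mut, collapse = "")
  }, "")
  seqs <- c(base, variants)
  sizes <- vapply(c(0.85, 0.95, 0.99, 1.0), function(t)
    max(greedy_identity_cluster(seqs, t)$cluster), 1L)
  expect_true(all(diff(sizes) >= 0))
})

test_that("longest ORF finding respects the length floor and strand", {
  cds <- paste0("ATG", strrep("GCT", 100), "TAA")  # 102 codons
  seq <- paste0(random_seq(40, seed = 61), cds, random_seq(40, seed = 62))
  orf <- longest_orf(seq, min_codons = 90)
  expect_false(is.null(orf))
  expect_equal(substr(seq, orf[1] + 1, orf[1] + 3), "ATG")
  expect_equal((orf[2] - orf[1]) %% 3, 0)
  ## same ORF on the minus strand is found with strand attribute
  orf_rc <- longest_orf(revcomp(seq), min_codons = 90)
  expect_equal(attr(orf_rc, "strand"), "-")
  ## too-short ORFs are rejected
  expect_null(longest_orf(paste0("ATG", strrep("GCT", 10), "TAA"),
                          min_codons = 90))
})
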