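test_that("the mismatch-capped mapper agrees with a brute-force scan", {
  tx <- data.frame(id = c("t1", "t2"),
                   seq = c(random_seq(400, seed = 81),
                           random_seq(350, seed = 82)),
                   cds_start = c(0, 0), cds_end = c(399, 348),
                   stringsAsFactors = FALSE)
  set.seed(5)
  ## reads: exact, 1-3 mismatches, 4 mismatches, reverse complement, junk
  base <- substr(tx$seq[1], 101, 200)
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(nchar(s), k)
    for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    paste(v, collapse = "")
  }
  reads <- c(exact = base, mm1 = mutate(base, 1), mm3 = mutate(base, 3),
             mm4 = mutate(base, 4), rc = revcomp(base),
             junk = random_seq(100, seed = 83))
  m <- map_reads(unname(reads), tx, max_mismatches = 3)
  aln <- m$alignments
  got <- setNames(rep(FALSE, length(reads)), names(reads))
  got[as.integer(unique(aln$read))] <- TRUE
  names(got) <- names(reads)
  expect_equal(unname(got),
               c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE))
  ## brute-force oracle: scan every offset of both transcripts
  brute <- function(r) {
    hits <- 0
    for (t in seq_len(2)) for (s in c(r, revcomp(r))) {
      L <- nchar(s)
      for (p in seq_len(nchar(tx$seq[t]) - L + 1)) {
        mm <- sum(charToRaw(substr(tx$seq[t], p, p + L - 1)) != charToRaw(s))
        if (mm <= 3) hits <- hits + 1
      }
    }
    hits
  }
  for (i in c(1, 3, 4)) {
    expect_equal(sum(aln$read == as.character(i)), brute(reads[[i]]),
                 info = names(reads)[i])
  }
})

test_that("multi-mapping reads split weight uniformly", {
  dup <- random_seq(200, seed = 84)
  tx <- data.frame(id = c("p1", "p2"),
                   seq = c(paste0(dup, random_seq(100, seed = 85)),
                           paste0(dup, random_seq(100, seed = 86))),
                   cds_start = c(0, 0), cds_end = c(300, 300),
                   stringsAsFactors = FALSE)
  r <- substr(dup, 50, 149)
  m <- map_reads(r, tx)
  expect_equal(nrow(m$alignments), 2)
  expect_equal(m$alignments$weight, c(0.5, 0.5))
})

test_that("TPM estimation matches closed forms and a grid-search oracle", {
  ## all reads on one transcript
  aln1 <- data.table::data.table(read = as.character(1:10),
                                 transcript_id = "a")
  eff <- c(a = 100, b = 100)
  q1 <- estimate_tpm(aln1, eff)
  expect_equal(unname(q1$tpm), c(1e6, 0))
  ## equal unique counts on equal lengths -> half a million each
  aln2 <- data.table::data.table(read = as.character(1:20),
                                 transcript_id = rep(c("a", "b"), each = 10))
  expect_equal(unname(estimate_tpm(aln2, eff)$tpm), c(5e5, 5e5))
  ## length normalization: same counts, one transcript twice as long
  q3 <- estimate_tpm(aln2, c(a = 100, b = 200))
  expect_equal(unname(q3$tpm), c(2e6 / 3, 1e6 / 3))

  ## EM vs direct likelihood maximization by grid search on a 3-transcript
  ## multi-mapping toy: reads 1-6 unique to a, 7-10 ambiguous a/b, 11-12
  ## unique to c
  aln4 <- data.table::data.table(
    read = as.character(c(1:6, 7:10, 7:10, 11:12)),
    transcript_id = c(rep("a", 6), rep("a", 4), rep("b", 4), rep("c", 2)))
  effu <- c(a = 100, b = 100, c = 100)
  q4 <- estimate_tpm(aln4, effu, em_iters = 500)
  grid <- seq(0, 1, by = 0.001)
  ## with equal lengths, P(read | theta): unique-a ~ ta, ambiguous ~ ta+tb,
  ## unique-c ~ tc = 1 - ta - tb; maximize over the simplex by grid
  best <- c(NA, NA); best_ll <- -Inf
  for (ta in grid) for (tb in seq(0, 1 - ta, by = 0.001)) {
    tc <- 1 - ta - tb
    if (tc < 2 / 12 - 0.05 || tc > 2 / 12 + 0.05) next
    ll <- 6 * log(ta + 1e-12) + 4 * log(ta + tb + 1e-12) + 2 * log(tc + 1e-12)
    if (ll > best_ll) { best_ll <- ll; best <- c(ta, tb) }
  }
  expect_equal(unname(q4$counts["a"] / 12), best[1], tolerance = 0.01)
  expect_equal(unname(q4$counts["b"] / 12), best[2], tolerance = 0.01)

  expect_error(estimate_tpm(aln1[0, ], eff), "zero aligned")
})

test_that("TPM columns sum to a million before zero replacement", {
  cfg <- sim_config(seed = 21, n_individuals = 2, n_toxins = 5,
                    n_nontoxins = 3, fragment_mean = 240, fragment_sd = 25,
                    depth_per_kb = 60, error_rate = 0.001, utr_length = 250)
  ref <- generate_reference(cfg)
  sim <- simulate_reads(ref, cfg)
  reads <- quality_trim(sim$reads); reads <- reads[!reads$discarded, ]
  eff <- setNames(ref$reference$cds_end - ref$reference$cds_start,
                  ref$reference$id)
  for (s in unique(reads$sample)) {
    mg <- merge_pairs(reads[reads$sample == s, ])$merged
    q <- estimate_tpm(map_reads(mg, ref$reference)$alignments, eff)
    expect_equal(sum(q$tpm), 1e6, tolerance = 1e-6)
  }
})

test_that("zero replacement preserves column totals and positivity", {
  m <- matrix(c(5e5, 3e5, 2e5, 0,
                4e5, 0, 6e5, 0), ncol = 2,
              dimnames = list(paste0("t", 1:4), c("i1", "i2")))
  m[, 1] <- m[, 1] / sum(m[, 1]) * 1e6
  m[, 2] <- m[, 2] / sum(m[, 2]) * 1e6
  r <- replace_zeros(m)
  expect_true(all(r > 0))
  expect_equal(colSums(r), colSums(m))
  ## delta arithmetic: zero entries get 0.65 x smallest nonzero
  expect_equal(r[4, 1], 0.65 * min(m[m[, 1] > 0, 1]), tolerance = 1e-9)
  ## rank preserved among nonzero entries
  expect_equal(order(r[1:3, 1]), order(m[1:3, 1]))
  ## matrix with no zeros unchanged
  pos <- matrix(c(2e5, 8e5, 3e5, 7e5), ncol = 2)
  expect_equal(replace_zeros(pos), pos, tolerance = 1e-12)
  expect_error(replace_zeros(matrix(c(0, 0, 1, 1), ncol = 2)), "all-zero")
})

test_that("clr is centered and matches hand arithmetic", {
  expect_equal(clr(c(1, 1, 1, 1)), c(0, 0, 0, 0))
  expect_equal(clr(c(2, 8)), c(-log(2), log(2)))
  x <- c(3.2, 11, 0.4, 7)
  expect_equal(sum(clr(x)), 0, tolerance = 1e-9)
  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2)
  expect_equal(colSums(clr(m)), c(0, 0), tolerance = 1e-9)
  expect_error(clr(c(1, 0)), "positive")
})

test_that("class aggregation sums paralogs and preserves totals", {
  expr <- matrix(1:8, nrow = 4,
                 dimnames = list(c("SVMP-1", "SVMP-2", "PLA2-1", "CTL-1"),
                                 c("i1", "i2")))
  ann <- data.frame(id = rownames(expr),
                    family = c("SVMP", "SVMP", "PLA2", "CTL"))
  cls <- sum_by_class(expr, ann)
  expect_equal(cls["SVMP", ], colSums(expr[1:2, ]))
  expect_equal(cls["PLA2", ], expr["PLA2-1", ])
  expect_equal(colSums(cls), colSums(expr))
  expect_error(sum_by_class(expr, ann[-1, ]), "unannotated")
})

test_that("expression clustering is deterministic and matches brute-force linkage", {
  set.seed(6)
  m <- matrix(rnorm(40), nrow = 8,
              dimnames = list(paste0("t", 1:8), paste0("i", 1:5)))
  cl <- expression_cluster(m)
  ## permuting rows/columns gives the same leaf orders
  cl2 <- expression_cluster(m[sample(8), sample(5)])
  expect_equal(cl$row_order, cl2$row_order)
  expect_equal(cl$col_order, cl2$col_order)
  ## cophenetic distances match stats::hclust on the same dissimilarity
  want <- hclust(dist(t(m[order(rownames(m)), order(colnames(m))])),
                 method = "average")
  expect_equal(as.matrix(cophenetic(cl$col_hclust)),
               as.matrix(cophenetic(want)))
  ## identical individuals merge first at distance zero
  m2 <- cbind(m, i6 = m[, 3])
  colnames(m2) <- c(colnames(m), "i6")
  cl3 <- expression_cluster(m2)
  h <- cl3$col_hclust
  first <- sort(h$labels[-h$merge[1, ]])
  expect_equal(first, c("i3", "i6"))
  expect_equal(h$height[1], 0)
  expect_error(expression_cluster(m[, 1, drop = FALSE]), "two individuals")
})
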