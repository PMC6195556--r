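test_that("contrast enumeration reproduces the study's 17 comparisons", {
  ct <- enumerate_contrasts(sidewinder_metadata())
  expect_equal(nrow(ct), 17)
  expect_equal(sum(ct$kind == "continuous"), 1)
  tab <- table(ct$factor)
  expect_equal(as.integer(tab[c("sex", "subspecies", "mtdna_lineage",
                                "nontoxin_lineage")]), c(1L, 3L, 6L, 6L))
  ## one 2-level factor only -> 1 contrast (+ SVL)
  ft <- two_group_table(4)
  ct2 <- suppressWarnings(enumerate_contrasts(ft))
  expect_equal(sum(ct2$factor == "sex"), 1)
  ## a 4-level factor alone contributes C(4,2) = 6
  ft$mtdna_lineage <- c("a", "b", "c", "d")
  ct3 <- suppressWarnings(enumerate_contrasts(ft))
  expect_equal(sum(ct3$factor == "mtdna_lineage"), 6)
  ## single-level factors are skipped with a warning
  expect_warning(enumerate_contrasts(two_group_table(4)), "subspecies")
})

test_that("BH adjustment matches step-up arithmetic", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.037), 0.037)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  q <- adjust_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_equal(adjust_fdr(numeric(0)), numeric(0))
})

test_that("the NB fit matches a likelihood grid on a two-group toy", {
  y <- c(12, 17, 9, 14, 30, 41, 29, 35)
  x <- factor(rep(c("a", "b"), each = 4))
  alpha <- 0.05
  fit <- fit_nb_glm(y, x, sf = rep(1, 8), dispersion = alpha)
  ## grid oracle over (mu_a, mu_b)
  grid <- seq(1, 60, by = 0.02)
  ll_a <- vapply(grid, function(m)
    sum(dnbinom(y[1:4], mu = m, size = 1 / alpha, log = TRUE)), 1)
  ll_b <- vapply(grid, function(m)
    sum(dnbinom(y[5:8], mu = m, size = 1 / alpha, log = TRUE)), 1)
  mu_a <- grid[which.max(ll_a)]; mu_b <- grid[which.max(ll_b)]
  co <- coef(fit$full)
  expect_equal(exp(co[[1]]), mu_a, tolerance = 1e-3)
  expect_equal(exp(co[[1]] + co[[2]]), mu_b, tolerance = 1e-3)
  ## deviance difference equals twice the log-likelihood gap to the
  ## common-mean fit
  ll_full <- max(ll_a) + max(ll_b)
  ll_red <- max(vapply(grid, function(m)
    sum(dnbinom(y, mu = m, size = 1 / alpha, log = TRUE)), 1))
  lrt <- fit$reduced$deviance - fit$full$deviance
  expect_equal(lrt, 2 * (ll_full - ll_red), tolerance = 1e-3)

  ## equal counts across groups -> log2fc == 0 and p near 1
  flat <- fit_nb_glm(rep(20, 8), x, rep(1, 8), 0.05)
  tc <- test_contrast(flat)
  expect_equal(tc$log2fc, 0, tolerance = 1e-8)
  expect_gt(tc$p_wald, 0.99)
})

test_that("dispersion estimates shrink toward truth under a Poisson-like limit", {
  ## Poisson data (alpha = 0): estimates approach zero as counts grow
  set.seed(11)
  counts <- t(sapply(1:200, function(g) rpois(8, 500)))
  mu <- t(apply(counts, 1, function(y) rep(mean(y), 8)))
  d <- estimate_dispersions(counts, mu)
  expect_lt(median(d$alpha), 0.01)
  ## strongly overdispersed data give clearly positive estimates
  counts2 <- t(sapply(1:200, function(g) rnbinom(8, mu = 500, size = 2)))
  mu2 <- t(apply(counts2, 1, function(y) rep(mean(y), 8)))
  d2 <- estimate_dispersions(counts2, mu2)
  expect_gt(median(d2$alpha), 0.2)
})

test_that("planted fold changes are detected and their sign recovered", {
  set.seed(13)
  ft <- two_group_table(8)
  ct <- data.frame(factor = "sex", kind = "pairwise", level_a = "F",
                   level_b = "M", name = "sex:F:M")
  n <- 60
  counts <- t(sapply(1:n, function(g) rnbinom(8, mu = 300, size = 20)))
  ## genes 1-5: 4-fold up in males; gene 6: 4-fold down
  for (g in 1:5) counts[g, 5:8] <- rnbinom(4, mu = 1200, size = 20)
  counts[6, 5:8] <- rnbinom(4, mu = 75, size = 20)
  rownames(counts) <- paste0("g", 1:n)
  colnames(counts) <- ft$individual_id
  res <- consensus_de(suppressWarnings(de_test(counts, ft, ct)))
  expect_true(all(res$consensus_significant[1:6]))
  expect_true(all(res$log2fc[1:5] > 1))
  expect_lt(res$log2fc[6], -1)
  ## permuting individual labels destroys the planted signal
  set.seed(14)
  qs <- replicate(8, {
    perm <- sample(8)
    cp <- counts[, perm]; colnames(cp) <- ft$individual_id
    r <- consensus_de(suppressWarnings(de_test(cp, ft, ct)))
    median(pmax(r$q_wald[1:6], r$q_lrt[1:6]))
  })
  expect_gt(median(qs), 0.05)
})

test_that("consensus requires significance in both test flavors", {
  res <- data.table::data.table(
    transcript_id = c("a", "b", "c", "d"), contrast = "x",
    log2fc = 1, p_wald = c(0.001, 0.001, 0.5, 0.9),
    p_lrt = c(0.002, 0.6, 0.001, 0.9),
    q_wald = c(0.004, 0.004, 0.5, 0.9),
    q_lrt = c(0.008, 0.6, 0.004, 0.9))
  out <- consensus_de(res, alpha = 0.05)
  expect_equal(out$consensus_significant, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("the NB engine broadly agrees with an independent count-model engine", {
  skip_if_not_installed("edgeR")
  set.seed(15)
  ft <- two_group_table(8)
  ct <- data.frame(factor = "sex", kind = "pairwise", level_a = "F",
                   level_b = "M", name = "sex:F:M")
  counts <- t(sapply(1:80, function(g) rnbinom(8, mu = 400, size = 10)))
  for (g in 1:8) counts[g, 5:8] <- rnbinom(4, mu = 1600, size = 10)
  rownames(counts) <- paste0("g", 1:80)
  colnames(counts) <- ft$individual_id
  mine <- suppressWarnings(de_test(counts, ft, ct))
  grp <- factor(rep(c("F", "M"), each = 4))
  y <- edgeR::DGEList(counts = counts, group = grp)
  y <- edgeR::calcNormFactors(y)
  y <- edgeR::estimateDisp(y, model.matrix(~grp))
  et <- edgeR::glmLRT(edgeR::glmFit(y, model.matrix(~grp)), coef = 2)
  ptab <- et$table
  ## planted genes are top-ranked by both engines; fold changes agree
  expect_gt(cor(mine$log2fc, ptab$logFC), 0.98)
  expect_gt(cor(-log10(mine$p_lrt + 1e-12), -log10(ptab$PValue + 1e-12)),
            0.9)
})
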