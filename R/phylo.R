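## -- Blomberg's K phylogenetic signal with permutation p-values -----------

#' Blomberg's K statistic
#'
#' Ratio-based measure of phylogenetic signal: the observed ratio of the
#' mean squared error of the trait about its phylogenetic (GLS) mean
#' (`MSE0`) to the phylogenetically corrected mean squared error (`MSE`,
#' using the Brownian-motion tip covariance `V` from branch lengths),
#' divided by the expectation of that ratio under Brownian motion,
#' `(tr(V) - n / sum(V^-1)) / (n - 1)`. `K = 1` matches the Brownian
#' expectation; `K > 1` means relatives resemble each other more than
#' expected.
#'
#' @param tree a rooted `phylo` tree with branch lengths; tip labels must
#'   cover `names(trait)`.
#' @param trait named numeric vector over the tips (non-constant).
#' @return the scalar K (nonnegative).
#' @export
blomberg_k <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(names(trait))) names(trait) <- tree$tip.label
  if (!setequal(names(trait), tree$tip.label))
    stop("trait names must match tree tips")
  x <- trait[tree$tip.label]
  n <- length(x)
  if (var(x) == 0) stop("constant trait: K undefined")
  V <- ape::vcv(tree)
  Vi <- tryCatch(solve(V), error = function(e) stop("singular BM covariance"))
  ahat <- as.numeric(sum(Vi %*% x) / sum(Vi))
  d <- x - ahat
  mse <- as.numeric(d %*% Vi %*% d) / (n - 1)
  mse0 <- sum(d^2) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for Blomberg's K
#'
#' Tip-shuffle null: trait values are permuted across tips `n_perm` times
#' and the add-one estimator `p = (1 + #{K_perm >= K_obs}) / (n_perm + 1)`
#' is returned.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param trait named trait vector over tips.
#' @param n_perm number of permutations (default 999).
#' @param seed mandatory integer seed.
#' @return list with `K`, `p_perm`, `n_perm`.
#' @export
k_permutation_test <- function(tree, trait, n_perm = 999L, seed) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(names(trait))) names(trait) <- tree$tip.label
  k_obs <- blomberg_k(tree, trait)
  with_seed(seed, {
    k_perm <- vapply(seq_len(n_perm), function(i) {
      perm <- setNames(sample(trait), names(trait))
      blomberg_k(tree, perm)
    }, 1)
    list(K = k_obs,
         p_perm = (1 + sum(k_perm >= k_obs)) / (n_perm + 1),
         n_perm = as.integer(n_perm))
  })
}

#' Phylogenetic signal of expression for every transcript
#'
#' Midpoint-roots the tree (the convention used for the nontoxin
#' phylogeny), then computes Blomberg's K and its permutation p-value for
#' each row of the natural-log expression matrix.
#'
#' @param tree `phylo` tree; tips must match `colnames(ln_expr)`.
#' @param ln_expr transcripts x individuals matrix (ln TPM after zero
#'   replacement by convention).
#' @param n_perm permutations per transcript.
#' @param seed integer seed.
#' @param midpoint root at the midpoint first (default TRUE).
#' @return data.frame: transcript_id, K, p_perm, n_perm.
#' @export
phylo_signal <- function(tree, ln_expr, n_perm = 999L, seed = 1L,
                         midpoint = TRUE) {
  if (midpoint) tree <- phangorn::midpoint(tree)
  res <- lapply(seq_len(nrow(ln_expr)), function(g) {
    trait <- setNames(ln_expr[g, ], colnames(ln_expr))
    if (var(trait) == 0)
      return(data.frame(transcript_id = rownames(ln_expr)[g], K = NA_real_,
                        p_perm = NA_real_, n_perm = n_perm))
    r <- k_permutation_test(tree, trait, n_perm, seed = seed + g)
    data.frame(transcript_id = rownames(ln_expr)[g], K = r$K,
               p_perm = r$p_perm, n_perm = r$n_perm)
  })
  do.call(rbind, res)
}
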