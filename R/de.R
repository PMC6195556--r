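## -- contrast enumeration and dual-flavor NB-GLM consensus differential
##    expression -----------------------------------------------------------

#' Enumerate differential-expression contrasts from the factor table
#'
#' One continuous contrast for SVL (body size, i.e. life stage) plus one
#' pairwise contrast per unordered level pair observed in the data for sex,
#' subspecies, mitochondrial lineage and nontoxin lineage. On the published
#' eight-individual factor structure this yields 17 contrasts
#' (1 + 1 + 3 + 6 + 6). Factors with fewer than two observed levels
#' contribute nothing, with a warning.
#'
#' @param factor_table data.frame as [sidewinder_metadata()]; needs columns
#'   `svl_cm`, `sex`, `subspecies`, `mtdna_lineage`, `nontoxin_lineage`.
#' @param discrete_factors which columns to treat as discrete factors.
#' @return data.frame: `factor`, `kind` (`"continuous"`/`"pairwise"`),
#'   `level_a`, `level_b`, `name`.
#' @export
enumerate_contrasts <- function(factor_table,
                                discrete_factors = c("sex", "subspecies",
                                                     "mtdna_lineage",
                                                     "nontoxin_lineage")) {
  stopifnot(nrow(factor_table) > 0)
  rows <- list(data.frame(factor = "svl_cm", kind = "continuous",
                          level_a = NA_character_, level_b = NA_character_,
                          stringsAsFactors = FALSE))
  for (f in discrete_factors) {
    lev <- sort(unique(factor_table[[f]]))
    if (length(lev) < 2) {
      warning("factor ", f, " has < 2 observed levels; skipped")
      next
    }
    prs <- utils::combn(lev, 2)
    rows[[length(rows) + 1]] <- data.frame(
      factor = f, kind = "pairwise", level_a = prs[1, ], level_b = prs[2, ],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$name <- ifelse(out$kind == "continuous", out$factor,
                     paste(out$factor, out$level_a, out$level_b, sep = ":"))
  rownames(out) <- NULL
  out
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's size factor is the median ratio
#' of its counts to the per-gene geometric mean, over genes expressed in
#' every sample; falls back to relative column totals when too few such
#' genes exist.
#'
#' @param counts genes x samples nonnegative matrix.
#' @return positive numeric vector of per-sample size factors (geometric
#'   mean 1).
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (sum(pos) >= 5) {
    lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
    sf <- apply(counts[pos, , drop = FALSE], 2,
                function(col) exp(median(log(col) - lgm)))
  } else {
    sf <- colSums(counts)
  }
  sf / exp(mean(log(sf)))
}

## per-gene dispersion by Cox-Reid adjusted profile likelihood on log(alpha)
## given per-sample fitted means mu and the design matrix X; the CR penalty
## 0.5 log det(X' W X) corrects the small-sample bias from estimating the
## mean parameters. Returns alpha >= floor.
ml_dispersion <- function(y, mu, X, floor = 1e-6) {
  if (all(y == 0)) return(floor)
  nll <- function(la) {
    alpha <- exp(la)
    w <- mu / (1 + alpha * mu)
    pen <- 0.5 * determinant(crossprod(X * sqrt(w)), logarithm = TRUE)$modulus
    -(sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)) - pen)
  }
  opt <- optimize(nll, interval = c(log(floor), log(20)))
  max(exp(opt$minimum), floor)
}

#' Estimate, trend, and shrink per-gene NB dispersions
#'
#' Per-gene maximum-likelihood dispersion (given design-fitted means) is
#' shrunk, on the log scale, toward a lowess trend of dispersion on mean
#' expression: `log a* = (1 - w) log a_gene + w log a_trend`. Shrinkage
#' stabilizes the small-sample dispersion estimates the same way the
#' local/tagwise-trend schemes of the standard count-model engines do.
#'
#' @param counts genes x samples matrix.
#' @param mu fitted means matrix (same shape), e.g. group means x size
#'   factors.
#' @param X design matrix of the contrast model (for the Cox-Reid
#'   adjustment); defaults to intercept-only.
#' @param shrink_weight weight on the trend (default 0.9; with eight-sample designs per-gene dispersions are noisy and a strong trend prior keeps the tests calibrated).
#' @return list with `alpha` (shrunken), `alpha_gene`, `alpha_trend`.
#' @export
estimate_dispersions <- function(counts, mu, X = NULL, shrink_weight = 0.9) {
  if (is.null(X)) X <- matrix(1, ncol(counts), 1)
  a_gene <- vapply(seq_len(nrow(counts)), function(g)
    ml_dispersion(counts[g, ], mu[g, ], X), 1)
  mean_count <- rowMeans(counts)
  ## trended dispersion: maximize the POOLED Cox-Reid APL per
  ## mean-expression bin (consistent, unlike averaging the skewed per-gene
  ## estimates), then interpolate on the log-mean axis
  ord <- order(mean_count)
  n_bins <- max(1L, min(10L, floor(nrow(counts) / 20)))
  bins <- if (n_bins < 2) list(ord)
          else split(ord, cut(seq_along(ord), n_bins, labels = FALSE))
  pooled_nll <- function(la, genes) {
    alpha <- exp(la)
    sum(vapply(genes, function(g) {
      w <- mu[g, ] / (1 + alpha * mu[g, ])
      pen <- 0.5 * determinant(crossprod(X * sqrt(w)),
                               logarithm = TRUE)$modulus
      -(sum(dnbinom(counts[g, ], size = 1 / alpha, mu = mu[g, ],
                    log = TRUE)) - pen)
    }, 1))
  }
  bin_alpha <- vapply(bins, function(genes)
    optimize(pooled_nll, interval = c(log(1e-6), log(20)),
             genes = genes)$minimum, 1)
  bin_mean <- vapply(bins, function(genes) mean(log(mean_count[genes] + 1)), 1)
  trend <- if (length(bin_mean) < 2) rep(exp(bin_alpha[1]), nrow(counts))
           else exp(approx(bin_mean, bin_alpha, xout = log(mean_count + 1),
                           rule = 2)$y)
  alpha <- exp((1 - shrink_weight) * log(a_gene) + shrink_weight * log(trend))
  list(alpha = alpha, alpha_gene = a_gene, alpha_trend = trend)
}

#' Fit the negative-binomial GLM for one gene
#'
#' Log-link NB regression (iteratively reweighted least squares via
#' [stats::glm()] with a fixed-dispersion NB family) of counts on the
#' contrast covariate with log size-factor offsets; both the full and the
#' intercept-only reduced model are fit so Wald and likelihood-ratio tests
#' can be read from the same engine.
#'
#' @param y nonnegative integer counts (rounded expected counts accepted).
#' @param x covariate: two-level factor (pairwise contrast) or numeric
#'   (continuous contrast).
#' @param sf positive size factors.
#' @param dispersion NB dispersion alpha (`var = mu + alpha mu^2`).
#' @return list of class `nb_fit`: `full`, `reduced` glm fits, `converged`.
#' @export
fit_nb_glm <- function(y, x, sf, dispersion) {
  stopifnot(length(y) == length(x), all(sf > 0), dispersion > 0)
  fam <- MASS::negative.binomial(theta = 1 / dispersion)
  off <- log(sf)
  dat <- data.frame(y = round(y), x = x, off = off)
  fit <- tryCatch({
    full <- glm(y ~ x + offset(off), family = fam, data = dat)
    reduced <- glm(y ~ 1 + offset(off), family = fam, data = dat)
    list(full = full, reduced = reduced,
         converged = full$converged && reduced$converged)
  }, error = function(e) NULL)
  if (is.null(fit)) fit <- list(full = NULL, reduced = NULL, converged = FALSE)
  class(fit) <- "nb_fit"
  fit
}

#' Wald and likelihood-ratio tests for one fitted gene
#'
#' Wald p from the contrast coefficient against its standard error on the
#' standard normal; LRT p from the full-vs-reduced deviance difference on
#' chi-squared with 1 df. The log2 fold change is the contrast coefficient
#' rescaled to base 2 (per-unit slope for continuous contrasts).
#'
#' @param fit an `nb_fit` from [fit_nb_glm()].
#' @return list `p_wald`, `p_lrt`, `log2fc` (NA when the fit failed).
#' @export
test_contrast <- function(fit) {
  if (is.null(fit$full) || !fit$converged)
    return(list(p_wald = NA_real_, p_lrt = NA_real_, log2fc = NA_real_))
  ## dispersion = 1: the NB variance is already carried by the family theta;
  ## summary.glm would otherwise rescale SEs by a noisy Pearson factor
  cf <- summary(fit$full, dispersion = 1)$coefficients
  if (nrow(cf) < 2 || is.na(cf[2, 2]) || cf[2, 2] == 0) {
    warning("zero or undefined standard error; p set to 1")
    return(list(p_wald = 1, p_lrt = 1, log2fc = unname(cf[2, 1]) / log(2)))
  }
  z <- cf[2, 1] / cf[2, 2]
  dev_diff <- fit$reduced$deviance - fit$full$deviance
  list(p_wald = 2 * pnorm(-abs(z)),
       p_lrt = pchisq(max(dev_diff, 0), df = 1, lower.tail = FALSE),
       log2fc = unname(cf[2, 1]) / log(2))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement, applied within one contrast
#' across transcripts (the package's default correction scope).
#'
#' @param p vector of p-values in `[0, 1]` (NAs preserved).
#' @return q-values of the same length.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}

#' Dual-flavor NB differential expression over a contrast set
#'
#' For each contrast, subsets the relevant individuals, computes
#' median-of-ratios size factors, estimates trended-shrunken dispersions,
#' fits the NB GLM per gene and records Wald and LRT p-values; q-values are
#' BH-adjusted within contrast for each test flavor separately.
#'
#' @param counts genes x individuals matrix of (expected) read counts.
#' @param factor_table metadata with `individual_id` matching the columns.
#' @param contrasts contrast table from [enumerate_contrasts()].
#' @param shrink_weight dispersion shrinkage weight.
#' @return data.table: transcript_id, contrast, log2fc, p_wald, p_lrt,
#'   q_wald, q_lrt.
#' @export
de_test <- function(counts, factor_table, contrasts = NULL,
                    shrink_weight = 0.9) {
  if (is.null(contrasts)) contrasts <- enumerate_contrasts(factor_table)
  stopifnot(all(colnames(counts) %in% factor_table$individual_id))
  ft <- factor_table[match(colnames(counts), factor_table$individual_id), ]
  res <- vector("list", nrow(contrasts))
  for (k in seq_len(nrow(contrasts))) {
    ct <- contrasts[k, ]
    if (ct$kind == "continuous") {
      sel <- seq_len(ncol(counts))
      x <- ft[[ct$factor]][sel]
    } else {
      sel <- which(ft[[ct$factor]] %in% c(ct$level_a, ct$level_b))
      x <- factor(ft[[ct$factor]][sel], levels = c(ct$level_a, ct$level_b))
    }
    sub <- round(counts[, sel, drop = FALSE])
    sf <- size_factors(sub)
    ## design-fitted means for dispersion estimation
    mu <- matrix(0, nrow(sub), ncol(sub))
    if (ct$kind == "pairwise") {
      for (lv in levels(x)) {
        j <- x == lv
        q <- rowSums(sub[, j, drop = FALSE]) / sum(sf[j])
        mu[, j] <- outer(q, sf[j])
      }
    } else {
      q <- rowSums(sub) / sum(sf)
      mu <- outer(q, sf)
    }
    mu <- pmax(mu, 1e-8)
    X <- stats::model.matrix(~x)
    disp <- estimate_dispersions(sub, mu, X, shrink_weight)
    tests <- lapply(seq_len(nrow(sub)), function(g) {
      test_contrast(fit_nb_glm(sub[g, ], x, sf, disp$alpha[g]))
    })
    res[[k]] <- data.table::data.table(
      transcript_id = rownames(sub),
      contrast = ct$name,
      log2fc = vapply(tests, `[[`, 1, "log2fc"),
      p_wald = vapply(tests, `[[`, 1, "p_wald"),
      p_lrt = vapply(tests, `[[`, 1, "p_lrt"))
    res[[k]][, q_wald := adjust_fdr(p_wald)]
    res[[k]][, q_lrt := adjust_fdr(p_lrt)]
  }
  data.table::rbindlist(res)
}

#' Consensus significance across the two test flavors
#'
#' A transcript x contrast result is consensus-significant iff both the
#' Wald and the LRT q-values are at most `alpha` -- the
#' significant-in-both-engines rule.
#'
#' @param results table from [de_test()] (needs q_wald, q_lrt).
#' @param alpha FDR level (default 0.05).
#' @return the table with a `consensus_significant` column.
#' @export
consensus_de <- function(results, alpha = 0.05) {
  results <- data.table::copy(data.table::as.data.table(results))
  results[, consensus_significant :=
            !is.na(q_wald) & !is.na(q_lrt) & q_wald <= alpha & q_lrt <= alpha]
  results
}
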