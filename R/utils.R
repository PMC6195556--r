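#' @import data.table
#' @importFrom stats rnorm rbinom rpois rnbinom rlnorm runif rgeom rmultinom
#'   dnbinom optimize pchisq pnorm p.adjust cor dist hclust as.dist cophenetic
#'   setNames glm coef vcov anova lowess approx aggregate sd var quantile
#'   median complete.cases offset
#' @importFrom utils head tail combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorized reverse complement over plain character vectors. `N` is
#' self-complementary.
#'
#' @param x character vector of DNA sequences (alphabet `ACGTN`).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", stringi::stri_reverse(x))
}

## phred+33 encode/decode
qual_to_int <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

int_to_qual <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

## round half away from zero at `digits` decimals (R's round() is half-even)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## truncate toward zero at `digits` decimals
trunc_digits <- function(x, digits = 0) {
  m <- 10^digits
  trunc(x * m) / m
}

#' Percentage bookkeeping
#'
#' Computes `100 * count / total` and formats it at the stated precision.
#' `mode = "round"` rounds half away from zero (used for absence shares);
#' `mode = "trunc"` truncates (used for the "only X% differentially
#' expressed" share, a deliberately conservative statement of discovery).
#'
#' @param count numerator count.
#' @param total denominator count.
#' @param digits decimal places to keep.
#' @param mode `"round"` or `"trunc"`.
#' @return numeric percentage at the requested precision.
#' @export
pct <- function(count, total, digits = 0, mode = c("round", "trunc")) {
  mode <- match.arg(mode)
  stopifnot(total > 0)
  x <- 100 * count / total
  if (mode == "round") round_half_away(x, digits) else trunc_digits(x, digits)
}

## deterministic local RNG scope: runs expr with the given seed, restores state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

## count mismatching characters between two equal-length strings
str_mismatches <- function(a, b) {
  ra <- charToRaw(a); rb <- charToRaw(b)
  stopifnot(length(ra) == length(rb))
  sum(ra != rb)
}
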