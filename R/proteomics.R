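## -- internal-standard label-free proteomic quantification ----------------

#' Fit the counts-to-concentration conversion factor for one replicate
#'
#' Least squares through the origin of the known standard amounts on their
#' observed normalized spectral counts: `b = sum(c_i s_i) / sum(s_i^2)`
#' over the three internal standards. One slope is fitted per replicate.
#'
#' @param standards data.frame with `protein_id`, `known_fmol` (three rows,
#'   positive distinct amounts).
#' @param replicate_counts named numeric vector of normalized spectral
#'   counts for this replicate; must contain all three standards with
#'   positive counts.
#' @return slope in fmol per count unit.
#' @export
fit_conversion_factor <- function(standards, replicate_counts) {
  stopifnot(nrow(standards) == 3, all(standards$known_fmol > 0),
            !anyDuplicated(standards$known_fmol))
  s <- replicate_counts[standards$protein_id]
  if (anyNA(s) || any(s <= 0))
    stop("replicate unusable: a standard is missing or has zero count")
  sum(standards$known_fmol * s) / sum(s^2)
}

#' Convert spectral counts to protein concentrations for one individual
#'
#' Per replicate, concentrations are `slope_rep * count`; the individual's
#' value is the arithmetic mean over its replicates. A protein is
#' `detected` if found in at least one replicate and `quantifiable` (and
#' hence given a concentration) only if found in all replicates; families
#' on the exclusion list (by default bradykinin-potentiating peptides and
#' myotoxins) are dropped from downstream analyses with a reason.
#'
#' @param counts proteins x replicates matrix of normalized spectral counts
#'   (standard rows included; they are removed from the output).
#' @param standards data.frame as [default_standards()].
#' @param families optional named character vector protein id -> family,
#'   used by the exclusion list.
#' @param exclude_families family labels excluded from analyses.
#' @return data.frame: protein_id, concentration (fmol; NA unless
#'   quantifiable), detected, quantifiable, excluded_reason.
#' @export
quantify_proteins <- function(counts, standards = default_standards(),
                              families = NULL,
                              exclude_families = c("BPP", "MYO")) {
  if (ncol(counts) != 3) stop("exactly three replicates are required")
  slopes <- vapply(seq_len(ncol(counts)), function(r)
    fit_conversion_factor(standards, counts[, r]), 1)
  venom <- counts[!(rownames(counts) %in% standards$protein_id), ,
                  drop = FALSE]
  detected <- rowSums(venom > 0) >= 1
  quantifiable <- rowSums(venom > 0) == ncol(venom)
  conc <- rowMeans(sweep(venom, 2, slopes, "*"))
  conc[!quantifiable] <- NA_real_
  fam <- if (is.null(families)) rep(NA_character_, nrow(venom))
         else unname(families[rownames(venom)])
  excluded <- ifelse(!is.na(fam) & fam %in% exclude_families,
                     paste0("excluded-family:", fam), NA_character_)
  data.frame(protein_id = rownames(venom), concentration = conc,
             detected = detected, quantifiable = quantifiable,
             excluded_reason = excluded, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Correlate clr transcript and protein abundances for one individual
#'
#' Spearman's rank and Pearson's product-moment correlations (plus R^2) of
#' paired clr-transformed abundances over the quantifiable, non-excluded
#' toxins of one individual.
#'
#' @param clr_transcript,clr_protein paired clr vectors (length >= 3,
#'   non-constant).
#' @return list with `rho`, `r`, `r_squared`, `n`.
#' @export
correlate_abundances <- function(clr_transcript, clr_protein) {
  stopifnot(length(clr_transcript) == length(clr_protein))
  ok <- complete.cases(clr_transcript, clr_protein)
  x <- clr_transcript[ok]; y <- clr_protein[ok]
  if (length(x) < 3) stop("need at least three paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector: correlation undefined")
  r <- cor(x, y, method = "pearson")
  list(rho = cor(x, y, method = "spearman"), r = r, r_squared = r^2,
       n = length(x))
}
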