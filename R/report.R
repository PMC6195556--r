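## -- summary bookkeeping and end-to-end orchestration ---------------------

#' Absence-summary bookkeeping
#'
#' Counts transcripts absent from at least one individual and per-individual
#' missing counts, with percentages at the reporting precision: the
#' absent-in-any share as a whole percent, per-individual shares at one
#' decimal (both rounding half away from zero).
#'
#' @param absent logical matrix transcripts x individuals (TRUE = absent).
#' @return list: n_transcripts, n_individuals, n_absent_any, pct_absent_any,
#'   per_individual (counts), min/max/mean missing and their percentages.
#' @export
summarize_absence <- function(absent) {
  stopifnot(length(absent) > 0)
  n_tx <- nrow(absent)
  per_ind <- colSums(absent)
  n_any <- sum(rowSums(absent) > 0)
  list(
    n_transcripts = n_tx,
    n_individuals = ncol(absent),
    n_absent_any = n_any,
    pct_absent_any = pct(n_any, n_tx, digits = 0),
    per_individual = per_ind,
    min_missing = min(per_ind), max_missing = max(per_ind),
    mean_missing = round_half_away(mean(per_ind), 1),
    pct_min_missing = pct(min(per_ind), n_tx, digits = 1),
    pct_max_missing = pct(max(per_ind), n_tx, digits = 1),
    pct_mean_missing = pct(mean(per_ind), n_tx, digits = 0))
}

#' Differential-expression summary bookkeeping
#'
#' Totals over the full transcript x contrast grid: number of comparisons,
#' number and identity of consensus-significant comparisons, number of
#' unique significant transcripts, and the share of significant transcripts
#' at one decimal. That share is truncated rather than rounded -- the
#' conservative convention behind statements of the form "only X% were
#' differentially expressed".
#'
#' @param results consensus-annotated table from [consensus_de()].
#' @param n_transcripts,n_contrasts grid dimensions (inferred from the
#'   table when omitted).
#' @return list with the counts and percentages.
#' @export
summarize_de <- function(results, n_transcripts = NULL, n_contrasts = NULL) {
  results <- data.table::as.data.table(results)
  if (is.null(n_transcripts)) n_transcripts <- length(unique(results$transcript_id))
  if (is.null(n_contrasts)) n_contrasts <- length(unique(results$contrast))
  sig <- results[results$consensus_significant %in% TRUE, ]
  n_sig_tx <- length(unique(sig$transcript_id))
  list(
    n_transcripts = n_transcripts,
    n_contrasts = n_contrasts,
    n_comparisons = n_transcripts * n_contrasts,
    n_significant_comparisons = nrow(sig),
    n_significant_transcripts = n_sig_tx,
    pct_significant_transcripts = pct(n_sig_tx, n_transcripts, digits = 1,
                                      mode = "trunc"))
}

#' Run the pipeline end-to-end on synthetic data
#'
#' Executes the stages in study order on a [sim_config()]: simulate reads,
#' (optionally) inject and filter cross-contamination, quality-trim, merge
#' pairs, assemble each individual, annotate against the reference toxin
#' set, screen chimeras, cluster into the species consensus, map reads with
#' the mismatch cap, estimate TPM and expected counts, call toxin
#' absences, and test differential expression over the enumerated
#' contrasts. Returns every intermediate artifact plus the summary
#' bookkeeping.
#'
#' @param config a [sim_config()].
#' @param n_seeds,assembly_overlap assembler settings (desk-scale defaults).
#' @param decontaminate_reads run the k-mer contamination filter.
#' @param de run the differential-expression stage.
#' @param alpha FDR level for the consensus rule.
#' @return list of artifacts: `truth`, `consensus`, `tpm`, `counts`,
#'   `absent`, `de`, `summary`, ...
#' @export
run_pipeline <- function(config, n_seeds = 300L, assembly_overlap = 20L,
                         decontaminate_reads = config$contamination_rate > 0,
                         de = TRUE, alpha = 0.05) {
  ref <- generate_reference(config)
  sim <- simulate_reads(ref, config)
  reads <- sim$reads
  contam <- NULL
  if (config$contamination_rate > 0) {
    inj <- inject_contamination(reads, config$contamination_rate,
                                seed = config$seed + 2L)
    reads <- inj$reads
    contam <- inj$contaminants
  }
  if (decontaminate_reads) reads <- decontaminate(reads)$reads
  reads <- quality_trim(reads)
  reads <- reads[!reads$discarded, ]
  indivs <- config$factor_table$individual_id
  merged <- lapply(setNames(nm = indivs), function(s)
    merge_pairs(reads[reads$sample == s, ])$merged)

  ## per-individual assembly + annotation + chimera screen
  assembled <- lapply(setNames(nm = indivs), function(s) {
    contigs <- assemble(merged[[s]], n_seeds = n_seeds,
                        overlap = assembly_overlap,
                        rng_seed = config$seed + 3L)
    ann <- annotate_by_reference(contigs, ref$reference)
    ann <- ann[!is.na(ann$cds_start), , drop = FALSE]
    if (nrow(ann) == 0) return(ann)
    prof <- strict_align_coverage(merged[[s]], ann, individual_id = s)
    verdict <- vapply(ann$id, function(id) chimera_screen(prof[[id]]), "")
    ann <- ann[verdict %in% c("keep", "flag"), , drop = FALSE]
    cl <- greedy_identity_cluster(ann$seq, 0.98, ids = ann$id)
    ann[ann$id %in% cl$id[cl$is_representative], , drop = FALSE]
  })
  consensus <- build_consensus(assembled, threshold = 0.98)

  ## quantification + absence calling
  maps <- lapply(setNames(nm = indivs), function(s)
    map_reads(merged[[s]], consensus, individual_id = s))
  eff_len <- setNames(consensus$cds_end - consensus$cds_start, consensus$id)
  quant <- lapply(maps, function(m) estimate_tpm(m$alignments, eff_len))
  tpm <- vapply(quant, `[[`, numeric(length(eff_len)), "tpm")
  counts <- vapply(quant, `[[`, numeric(length(eff_len)), "counts")
  profiles <- lapply(maps, `[[`, "profiles")
  tox <- consensus$annotation == "toxin"
  absent <- absence_matrix(profiles)[tox, , drop = FALSE]

  de_res <- de_summary <- NULL
  if (de && sum(tox) > 0) {
    contrasts <- enumerate_contrasts(config$factor_table)
    de_res <- consensus_de(de_test(counts[tox, , drop = FALSE],
                                   config$factor_table, contrasts), alpha)
    de_summary <- summarize_de(de_res, n_transcripts = sum(tox),
                               n_contrasts = nrow(contrasts))
  }
  toxin_share <- pct(sum(tpm[tox, ]), sum(tpm), digits = 1)
  list(truth = sim$truth, contaminants = contam, merged = merged,
       consensus = consensus, tpm = tpm, counts = counts,
       profiles = profiles, absent = absent, de = de_res,
       summary = list(
         n_consensus_toxins = sum(tox),
         n_consensus_nontoxins = sum(consensus$annotation == "nontoxin"),
         pct_toxin_expression = toxin_share,
         absence = summarize_absence(absent),
         de = de_summary))
}
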