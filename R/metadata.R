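#' Study metadata for the eight Sidewinder Rattlesnake individuals
#'
#' The individual-level factor table used throughout the package's worked
#' examples: sex, snout-to-vent length (SVL, cm), subspecies, mitochondrial
#' lineage and nontoxin (phylotranscriptomic) lineage for the eight
#' *Crotalus cerastes* whose venom glands were sequenced, plus raw and
#' merged read counts. This is the canonical factor structure over which
#' differential-expression contrasts are enumerated (1 continuous SVL
#' contrast + 1 sex + 3 subspecies pairs + 6 mtDNA-lineage pairs + 6
#' nontoxin-lineage pairs = 17 contrasts).
#'
#' @return a `data.frame` with one row per individual and columns
#'   `individual_id`, `field_id`, `subspecies`, `mtdna_lineage`,
#'   `nontoxin_lineage`, `sex`, `svl_cm`, `read_pairs`, `merged_reads`.
#' @examples
#' m <- sidewinder_metadata()
#' nrow(enumerate_contrasts(m))  # 17
#' @export
sidewinder_metadata <- function() {
  data.frame(
    individual_id = c("CAS259901", "CAS259903", "CAS259917", "CAS259905",
                      "CAS259893", "ASU36161", "ASU36167", "KW1744"),
    field_id = c("CLP2065", "CLP2068", "CLP2109", "CLP2071",
                 "CLP2057", "CLP2105", "CLP2137", "KW1744"),
    subspecies = c("cerastes", "cerastes", "cerastes", "laterorepens",
                   "laterorepens", "cercobombus", "cercobombus", "cercobombus"),
    mtdna_lineage = c("N_Mojave", "S_Mojave", "S_Mojave", "S_Mojave",
                      "Colorado", "Sonora", "Sonora", "Sonora"),
    nontoxin_lineage = c("N_Mojave", "N_Mojave", "S_Mojave", "S_Mojave",
                         "Colorado", "Sonora", "Sonora", "Sonora"),
    sex = c("M", "M", "F", "F", "M", "M", "M", "M"),
    svl_cm = c(47.8, 39.1, 40.8, 37.7, 30.9, 48.4, 45.0, 43.5),
    read_pairs = c(13285200, 11295627, 11482030, 14205702,
                   12801696, 13508336, 10860478, 17607533),
    merged_reads = c(11730533, 10012070, 9944019, 12049288,
                     11315608, 11041594, 9634955, 15388424),
    stringsAsFactors = FALSE
  )
}

#' Default toxin family composition of the consensus transcriptome
#'
#' Family labels and per-family transcript counts matching the published
#' consensus venom-gland transcriptome (62 toxin transcripts in 19 toxin
#' classes, dominated by 16 SVMPs, 15 SVSPs and 11 CTLs). Used as the
#' default family structure by the synthetic-data generator.
#'
#' @return named integer vector: family label -> number of transcripts.
#' @export
default_toxin_families <- function() {
  c(SVMP = 16L, SVSP = 15L, CTL = 11L, PLA2 = 1L, BPP = 1L,
    LAAO = 1L, VEGF = 2L, MYO = 2L, NGF = 1L, CRISP = 1L,
    `3FTx` = 2L, Vespryn = 1L, NUC = 1L, PDE = 1L, HYAL = 1L,
    KUN = 1L, Waprin = 1L, Ficolin = 2L, FusedToxin = 1L)
}
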