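---
title: "Methods: desk-scale venom-gland transcriptomics and proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale venom-gland transcriptomics and proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`venomics` implements a multi-individual venom-gland transcriptome and venom
proteome characterization pipeline at desk scale: raw paired-end reads are
screened for cross-sample contamination, trimmed, merged, assembled de novo,
annotated against a curated toxin reference, screened for chimeric assembly
artifacts, clustered into a species consensus transcriptome, quantified as
TPM, tested for differential expression across life-history and lineage
contrasts with a dual-flavor negative-binomial engine, tested for
phylogenetic signal with Blomberg's K, and tied to label-free proteomic
abundances through spiked internal standards. A synthetic-data generator
produces inputs with the statistical structure every stage assumes, so the
whole pipeline is exercisable — and its recovery properties measurable —
without any external download.

This vignette records the models, parameter choices, and numerical
decisions, in the order the pipeline runs.

## The synthetic-data generator

`sim_config()` + `generate_reference()` + `simulate_reads()` emulate a
venom-gland RNA-seq experiment over eight individuals whose metadata (sex,
snout-to-vent length, subspecies, mitochondrial lineage, phylotranscriptomic
lineage) ship as `sidewinder_metadata()`.

**Transcripts.** Toxins are partitioned into gene families with the
published family proportions (`default_toxin_families()`: 16 SVMP, 15 SVSP,
11 CTL, ... over 19 classes for the default 62). Each transcript is an
in-frame CDS (120–360 codons, ATG start, single stop) flanked by
untranslated regions (default 300 bp per side) so that coverage over the
CDS is free of transcript-end edge effects at the fragment sizes used.

**Expression.** Baseline abundances are lognormal (`expr_sdlog`, default
1.2) with toxins offset upward by `toxin_log_offset` (default 2 on the
natural-log scale), reproducing the heavy-tailed, toxin-dominated profile
of the real gland. Planted differential-expression effects are
multiplicative on the natural scale, keyed to factor levels; planted
absences zero a transcript out in chosen individuals. Each individual's
profile is normalized to the TPM scale.

**Reads.** Fragments have normal lengths (default 400 ± 50 bp, the library
target in the study design; note 2×150 bp pairs only merge when the
fragment is shorter than ~290 bp, so pipeline-level simulations that need
high merge rates configure ~240 ± 25 bp fragments explicitly). Fragments
may overhang transcript ends and are clipped — shearing produces terminal
pieces, so transcript ends are covered like interior bases — and a library
size-selection floor (`min_fragment`, default 100 bp) removes tiny clipped
pieces, as real library preparation does. The per-individual fragment total
equals `depth_per_kb × total transcript kb` exactly (multinomial
allocation proportional to abundance × length). Substitution errors are
iid per base (`error_rate`); indels are deliberately out of scope. Quality
strings use a two-state model: phred 38 throughout, with a geometric
low-quality (phred 2) 3′ tail on a fraction of reads — enough structure to
exercise the phred-5 trimmer without modeling full instrument profiles.
Sequencing depth is a free parameter of the study design (the real
per-individual totals are 10.9–17.6 million pairs, far above desk scale);
each analysis below states the depth its tests use.

**Contamination.** `inject_contamination()` mis-allocates whole fragments
(both mates, verbatim) to a uniformly chosen other sample in the same lane
with the configured probability, emulating index hopping; moved ids are
recorded as ground truth.

**Spectral counts.** `simulate_spectral_counts()` gives each replicate a
true fmol-per-count slope; expected counts are concentration/slope, with
multiplicative lognormal noise at a configured CV, and the three internal
standards (25, 250, 2500 fmol) appear as rows.

What the generator does **not** emulate: indel errors, PCR duplicates,
coverage bias along transcripts, allelic variation within an individual,
and real peptide-detectability effects in proteomics. Tests passing on
synthetic data therefore certify the pipeline's bookkeeping and recovery
logic under its stated assumptions, not robustness to those artifacts.

## Contamination filtering

The filter counts canonical 57-mers per sample (strand-collapsed; windows
containing N are skipped) and compares samples pairwise within a lane. A
k-mer is *contaminant-indicative* for a focal sample when some other
sample's count is at least `min_other_count` (2) and at least `enrichment`
(10) times the focal count plus one; a read is dropped when at least
`fraction` (0.25, inclusive) of its valid windows are indicative, and a
fragment is dropped when either mate is. The enrichment rule is this
package's operationalization of "constructed of" foreign k-mers:
demultiplex bleed-through produces exactly the low-focal/high-foreign
signature it keys on.

Two limitations are inherent and stated rather than patched. First, the
filter can only see contamination arriving from content the focal sample
does not itself express; recovery tests therefore give lane-mates largely
individual-private transcript sets (via planted absences). Second, the
margin between the foreign count and 10×(focal+1) grows with depth — at
the depths the filter is meant for (hundreds-fold and above) removal is
near-complete, while shallow simulations leave contamination hotspots
undetected. The recovery test runs at ~170× raw-read depth and observes
≥90% contaminant removal with zero native loss.

## Trimming and merging

`quality_trim()` 3′-truncates at the first base below phred 5 (bases at
exactly 5 are kept); empty reads are flagged discarded. `merge_pairs()`
aligns the suffix of mate 1 against the prefix of the reverse-complemented
mate 2 without gaps, requiring ≥10 bp overlap and ≤10% overlap mismatches,
scoring matches−2·mismatches and preferring longer overlaps at ties;
disagreeing bases take the higher-quality call, with the maximum quality
retained. An exact-prefix seed proposes candidate overlaps first; the
exhaustive scan runs only when the seed finds nothing, which keeps merging
fast on low-error data while preserving the same result.

## Assembly

`assemble()` is a greedy seed-extension assembler: `n_seeds` reads (default
1000) are sampled uniformly without replacement and extended in both
directions. At each step every read whose leading `overlap`-mer (default
120; desk-scale tests use 20 with correspondingly shorter reads) matches a
suffix window of the contig, agrees exactly over the whole overlapped
region, and reaches past the contig end is a candidate; if all candidates
agree (prefix-consistent), the longest extension is appended, otherwise
extension halts as *ambiguous*. A repeated terminal k-mer halts as
*cycle-guard*; no candidate halts as *no-overlap*. Each read is usable once
per contig; reads are indexed in both orientations; contigs exactly
contained in a longer contig (either strand) are dropped; reads are
canonically sorted internally so output is invariant to input order at a
fixed seed.

Halting on *any* disagreement is deliberately conservative. It makes
assembly exact on error-free reads — at 30× uniform coverage ≥95% of
transcripts are reconstructed at 100% identity, and every contig
re-validates by zero-mismatch read chaining — but it fragments contigs
when substitution errors are present at desk-scale depth, because a single
erroneous read in the candidate set stops extension. Integration tests
therefore run the assembly stage on error-free reads; the
mismatch-tolerant stages downstream (mapping, quantification, absence
calling) are tested with errors separately. The real study compensated
with sequencing depth three orders of magnitude above desk scale and a
second, error-tolerant assembler, whose output the consensus builder here
accepts as an additional annotated contig source.

## Annotation and the species consensus

Identity is cd-hit-style: matching columns over the length of the shorter
sequence, from a global alignment of the shorter against the best local
region of the longer (Biostrings `global-local`, match +1, mismatch −1,
gap open 5, extend 2), taking the better strand. Whether the published
"match percentage" is over nucleotides or residues is not stated; this
package uses nucleotide identity. Three sound shortcuts avoid most
alignments: exact containment is identity 1 by definition; a shared-14-mer
count below the pigeonhole bound `(n−13) − 14(1−t)n` proves identity < t;
and an ungapped anchor-offset comparison is a lower bound on alignment
identity, so reaching the threshold that way suffices. Contigs at ≥80%
identity to their best reference inherit its family and CDS (mapped by
anchor offset, or through the alignment when anchoring fails, clipped to
the contig and kept in the reference frame); below 80% they are
`unannotated` — the manual-review queue — with the longest ORF ≥90 codons
(either strand) as fallback CDS.

`greedy_identity_cluster()` sorts by decreasing length (ties
lexicographic), joins each sequence to the first representative at ≥98%
identity, and keeps the longest member as representative;
`build_consensus()` pools the per-individual annotated sets, clusters at
98%, and records contributing individuals per consensus transcript.

## Chimera screening and absence calling

The chimera screen consumes per-base CDS coverage from **zero-mismatch**
full-length read placement (the stringency stated alongside the
mismatch-purge step; reads with any mismatch contribute nothing). Planted
chimeras concatenate the 5′ half of one transcript to the 3′ half of
another, and reads are simulated only from the parents, so the junction
region receives no exactly matching reads. Verdicts: any zero-depth CDS
base → `remove-zero`; else max/min depth >10 **and** a two-segment
changepoint whose smoothed (25-base window) segment means differ >10-fold,
each segment ≥10% of the CDS → `remove-chimeric`; a >10-fold range without
that structure → `flag` (kept). "Multimodal coverage" is operationalized
as the changepoint test; window and segment floor are exposed. The screen's
recovery test runs on error-free reads at ~20×: with scattered errors the
zero-mismatch placement would thin coverage enough to produce spurious
zero-depth bases on genuine transcripts at desk-scale depth, a regime the
real screen (at far higher depth) does not enter.

Toxin absence uses the mismatch-tolerant mapper (≤3 substitutions,
seed-and-verify with `max_mismatches+1` disjoint seeds, so no qualifying
placement is missed; indel alignment is not performed because the
generator plants no indels): a transcript is absent from an individual iff
strictly more than 10% of its CDS has depth below 5×. The shared-nontoxin
rule for the phylotranscriptomic locus set is different and stricter —
any zero-coverage site in any individual excludes the locus — and the two
are never interchanged. Absence calls are reporting-only; all transcripts
enter the expression analyses.

## Quantification

Multi-mapping reads keep all ≤3-mismatch placements at equal weight;
`estimate_tpm()` resolves them by EM (E-step proportional to
abundance/length, M-step renormalization, default 100 iterations,
tolerance 1e-8 on abundances), with effective length equal to CDS length
(no fragment-length correction — a transparency choice at desk scale).
`TPM = 1e6·(c/l)/Σ(c/l)`; columns sum to 1e6 to within rounding before
zero replacement. Zeros are replaced multiplicatively per column (δ = 0.65
× smallest nonzero, nonzeros rescaled so the column total is preserved);
0.65 follows common compositional practice, as only the replacement
function, not its parameter, is fixed by convention. The clr transform is
ln(x) minus the column's mean ln(x). Class-level matrices sum paralogs per
family. Expression heatmap ordering comes from average-linkage euclidean
clustering of ln expression with rows/columns pre-sorted by id, making the
dendrograms invariant to input permutation.

## Differential expression

Contrasts: one continuous contrast for SVL plus every observed level pair
of sex, subspecies, mtDNA lineage, and nontoxin lineage — 17 on the
published factor table (1+1+3+6+6), giving 1,054 transcript-level and 323
class-level comparisons for 62 transcripts and 19 classes.

One negative-binomial GLM engine provides two test flavors, standing in
for the two published count-model engines while preserving the consensus
rule exactly. Counts are the EM expected counts, rounded — NB models need
counts, so the package tests counts rather than TPM. Normalization is
median-of-ratios size factors (log offsets). Dispersions: per-gene
Cox–Reid adjusted profile likelihood (the CR penalty ½log det(XᵀWX)
removes the small-sample bias from estimating the mean parameters), a
trended dispersion obtained by maximizing the *pooled* CR likelihood per
mean-expression bin (pooling is consistent where averaging the skewed
per-gene estimates is not), and log-scale shrinkage of gene toward trend
with weight 0.9 — with eight samples the per-gene estimates are noisy and
a strong trend prior is what keeps the tests calibrated, mirroring the
large prior-df recommendation for few-replicate designs. The Wald test
reads the contrast coefficient against its SE at fixed family dispersion
(the NB variance is already in the family; rescaling by the fitted Pearson
factor would add 6-df noise); the LRT compares full and intercept-only
deviances on χ²₁. Under the synthetic null (1000 genes, 8 samples, 4v4)
both flavors' type-I error sits near 0.05–0.065, within the (0.03, 0.07)
calibration band, and planted 4-fold effects are detected by the
consensus rule (significant in both flavors after per-contrast BH
correction at α = 0.05). FDR correction is applied within contrast;
pooling across contrasts is available by correcting the stacked table, but
per-contrast is the default, matching the per-comparison structure of the
reported tables.

## Phylogenetic signal

Blomberg's K uses the Brownian-motion tip covariance from branch lengths,
the phylogenetic GLS mean in **both** numerator and denominator mean
squared errors, and the expected ratio `(tr(V) − n/ΣV⁻¹)/(n−1)` — the form
implemented by the reference R implementation of the statistic, with which
this package agrees to machine precision; a formulation with the raw
arithmetic mean in MSE0 does not reproduce K = 1 under Brownian motion and
is not used. Mean K over 1000 BM simulations on a fixed 8-tip tree lies in
(0.9, 1.1). The permutation p-value shuffles tip labels with the add-one
estimator (1+#{K ≥ K_obs})/(n_perm+1), 999 permutations by default, seed
mandatory; trees are midpoint-rooted first, matching the convention used
for the nontoxin phylogeny. Expression enters as ln TPM after zero
replacement.

## Proteomics

Per replicate, the fmol-per-count conversion factor is least squares
through the origin of the three known standard amounts on their observed
normalized spectral counts, b = Σcs/Σs²; venom-protein concentrations are
slope × count, averaged over the three replicates. A protein is *detected*
if present in ≥1 replicate and *quantifiable* (given a concentration, used
in analyses) only if present in all three — the two published rules read
as detection vs analysis-inclusion thresholds. Bradykinin-potentiating
peptides and myotoxins are excluded by a configurable family list.
Transcript–protein agreement is Spearman's ρ and Pearson's R (with R²) on
clr-transformed paired abundances over each individual's quantifiable,
non-excluded toxins.

## Reporting conventions

Summary percentages recompute from their count numerators and denominators
at print time. Absence shares round half away from zero at the printed
precision (19/62 → 31%; 3/62 → 4.8%; 11/62 → 17.7%; mean 7.375/62 → 12%).
The differential-expression share truncates at one decimal (4/62 → 6.4%) —
the conservative convention behind "only X% were differentially
expressed"; no single rounding rule reproduces both families of printed
values, and the package states the convention it uses for each.

## Problem sizes in the test suite

The packaged tests run the generator at desk scale by choice: 2–8
individuals, 8–20 transcripts, 240 ± 25 bp fragments, and 20–30×
(assembly, screens) to ~170× (contamination filter) coverage; the DE
calibration uses 1000 simulated genes, and K calibration 1000 BM
replicates on an 8-tip tree. These sizes make every recovery property
measurable in seconds to a few minutes while preserving the operating
regime each method assumes; headline numbers that depend on the real
multi-million-read libraries are bookkeeping-checked from their printed
numerators and denominators instead.
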