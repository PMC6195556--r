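#' Simulation configuration for synthetic venom-gland data
#'
#' Builds and validates the configuration object consumed by the synthetic
#' data generator. Defaults mirror the real study design: eight individuals,
#' 62 toxin transcripts across 19 families, 150 bp paired-end reads with a
#' 400 bp target mean fragment size, and the published individual factor
#' table. Depth, noise levels and planted effects are free parameters the
#' study does not pin down; see the methods vignette for the values used in
#' the test suite.
#'
#' @param seed integer master seed; fixed seed gives byte-identical outputs.
#' @param n_individuals number of individuals (rows of `factor_table` used).
#' @param n_toxins,n_nontoxins transcript counts (`n_toxins + n_nontoxins >= 1`).
#' @param family_counts named integer vector of per-family toxin counts;
#'   rescaled to `n_toxins` preserving proportions.
#' @param read_length read length in bp (default 150).
#' @param fragment_mean,fragment_sd fragment-size distribution in bp
#'   (default 400 +/- 50). `read_length < fragment_mean` is required. Note
#'   2x150 bp pairs only overlap (and therefore merge) for fragments
#'   shorter than `2*read_length - min_overlap`.
#' @param utr_length untranslated flank length added on each side of the CDS.
#' @param min_fragment library size-selection floor: clipped transcript-end
#'   fragments shorter than this are lost (default 100 bp).
#' @param depth_per_kb expected sequenced fragments per kb of transcript at
#'   average relative abundance; total sequencing effort is
#'   `depth_per_kb * sum(transcript lengths)/1000` fragments per individual.
#' @param error_rate per-base substitution probability.
#' @param contamination_rate per-fragment probability of mis-allocation to
#'   another sample in the same lane.
#' @param absence_rate per-(transcript, individual) probability of a planted
#'   deletion; `absence_matrix` overrides it with an explicit logical matrix
#'   (transcripts x individuals).
#' @param chimera_count number of planted chimeric transcripts.
#' @param expr_sdlog lognormal sd (natural-log scale) of transcript baseline
#'   abundances; toxin means are offset upward to emulate the heavy-tailed
#'   toxin-dominated expression profile.
#' @param toxin_log_offset natural-log offset of toxin over nontoxin mean
#'   abundance (default 2; set 0 for uniform conditions).
#' @param lowq_tail_prob probability a read carries a low-quality 3' tail.
#' @param factor_table individual metadata (default [sidewinder_metadata()]).
#' @param de_effects `data.frame(transcript, factor, level, log2fc)` of
#'   planted multiplicative expression effects, applied to individuals whose
#'   `factor` value equals `level`.
#' @param absence_matrix optional explicit planted-absence matrix.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_individuals = 8L,
                       n_toxins = 62L,
                       n_nontoxins = 30L,
                       family_counts = default_toxin_families(),
                       read_length = 150L,
                       fragment_mean = 400,
                       fragment_sd = 50,
                       utr_length = 300L,
                       min_fragment = 100L,
                       depth_per_kb = 30,
                       error_rate = 0.001,
                       contamination_rate = 0,
                       absence_rate = 0,
                       chimera_count = 0L,
                       expr_sdlog = 1.2,
                       toxin_log_offset = 2,
                       lowq_tail_prob = 0.2,
                       factor_table = sidewinder_metadata(),
                       de_effects = NULL,
                       absence_matrix = NULL) {
  stopifnot(n_toxins >= 0, n_nontoxins >= 0)
  if (n_toxins + n_nontoxins < 1)
    stop("at least one transcript must be requested")
  rates <- c(error_rate, contamination_rate, absence_rate, lowq_tail_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (read_length >= fragment_mean)
    stop("read_length must be smaller than fragment_mean")
  if (n_toxins > 0 && (is.null(family_counts) || length(family_counts) == 0))
    stop("family_counts must be nonempty when toxins are requested")
  factor_table <- factor_table[seq_len(min(n_individuals, nrow(factor_table))), ,
                               drop = FALSE]
  if (nrow(factor_table) < n_individuals) {
    extra <- n_individuals - nrow(factor_table)
    pad <- factor_table[rep(seq_len(nrow(factor_table)), length.out = extra), ,
                        drop = FALSE]
    pad$individual_id <- sprintf("SIM%02d", nrow(factor_table) + seq_len(extra))
    factor_table <- rbind(factor_table, pad)
  }
  structure(list(
    seed = as.integer(seed), n_individuals = as.integer(n_individuals),
    n_toxins = as.integer(n_toxins), n_nontoxins = as.integer(n_nontoxins),
    family_counts = family_counts, read_length = as.integer(read_length),
    fragment_mean = fragment_mean, fragment_sd = fragment_sd,
    utr_length = as.integer(utr_length),
    min_fragment = as.integer(min_fragment), depth_per_kb = depth_per_kb,
    error_rate = error_rate, contamination_rate = contamination_rate,
    absence_rate = absence_rate, chimera_count = as.integer(chimera_count),
    expr_sdlog = expr_sdlog, toxin_log_offset = toxin_log_offset,
    lowq_tail_prob = lowq_tail_prob,
    factor_table = factor_table, de_effects = de_effects,
    absence_matrix = absence_matrix
  ), class = "sim_config")
}

## rescale a named family-count vector to sum to n (largest-remainder)
scale_family_counts <- function(family_counts, n) {
  if (n == 0) return(family_counts[0])
  w <- family_counts / sum(family_counts)
  base <- floor(w * n)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- w * n - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  base <- base[base > 0]
  storage.mode(base) <- "integer"
  base
}

## random in-frame CDS: ATG + codons with no internal stop + stop codon
random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  codons <- apply(matrix(sample(DNA_BASES, 3 * (n_codons - 2), replace = TRUE),
                         nrow = 3), 2, paste, collapse = "")
  bad <- codons %in% stops
  while (any(bad)) {
    codons[bad] <- apply(matrix(sample(DNA_BASES, 3 * sum(bad), replace = TRUE),
                                nrow = 3), 2, paste, collapse = "")
    bad <- codons %in% stops
  }
  paste0("ATG", paste(codons, collapse = ""), sample(stops, 1))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Generate the synthetic reference transcriptome and ground-truth skeleton
#'
#' Simulates toxin transcripts partitioned into gene families plus nontoxin
#' transcripts, each with an in-frame CDS flanked by untranslated regions,
#' per-individual lognormal expression (with planted lineage effects and
#' planted absences), and optional planted chimeric sequences built from the
#' 5' half of one toxin and the 3' half of another.
#'
#' @param config a [sim_config()] object.
#' @return list with `reference` (data.frame: id, family, annotation, seq,
#'   cds_start, cds_end 0-based half-open), `truth` (ground-truth list:
#'   `expression` relative-abundance matrix on the TPM scale,
#'   `absent` logical matrix, `chimeras` data.frame, `de_effects`,
#'   `factor_table`).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fam <- scale_family_counts(config$family_counts, config$n_toxins)
    ids <- character(0); families <- character(0)
    for (f in names(fam)) {
      ids <- c(ids, sprintf("%s-%d", f, seq_len(fam[[f]])))
      families <- c(families, rep(f, fam[[f]]))
    }
    if (config$n_nontoxins > 0) {
      ids <- c(ids, sprintf("NT-%d", seq_len(config$n_nontoxins)))
      families <- c(families, rep("nontoxin", config$n_nontoxins))
    }
    n <- length(ids)
    n_codons <- sample(120:360, n, replace = TRUE)
    cds <- vapply(n_codons, random_cds, character(1))
    utr5 <- vapply(rep(config$utr_length, n), random_dna, character(1))
    utr3 <- vapply(rep(config$utr_length, n), random_dna, character(1))
    seqs <- paste0(utr5, cds, utr3)
    cds_start <- nchar(utr5)                      # 0-based
    cds_end <- cds_start + nchar(cds)
    reference <- data.frame(
      id = ids, family = families,
      annotation = ifelse(families == "nontoxin", "nontoxin", "toxin"),
      seq = seqs, cds_start = cds_start, cds_end = cds_end,
      stringsAsFactors = FALSE)

    indivs <- config$factor_table$individual_id
    ## baseline lognormal abundance; toxins shifted up (toxin-dominated gland)
    mu <- rnorm(n, mean = ifelse(families == "nontoxin", 0,
                                 config$toxin_log_offset),
                sd = config$expr_sdlog)
    expr <- matrix(rep(exp(mu), length(indivs)), nrow = n,
                   dimnames = list(ids, indivs))
    ## mild individual-level lognormal noise
    expr <- expr * matrix(rlnorm(n * length(indivs), 0, 0.2), nrow = n)
    ## planted multiplicative effects keyed to factor levels
    if (!is.null(config$de_effects)) {
      for (k in seq_len(nrow(config$de_effects))) {
        e <- config$de_effects[k, ]
        hit <- config$factor_table[[e$factor]] == e$level
        if (!e$transcript %in% ids) stop("de_effects transcript not in reference")
        expr[e$transcript, hit] <- expr[e$transcript, hit] * 2^e$log2fc
      }
    }
    ## planted absences
    if (!is.null(config$absence_matrix)) {
      absent <- config$absence_matrix
      stopifnot(dim(absent) == dim(expr))
      dimnames(absent) <- dimnames(expr)
    } else {
      absent <- matrix(runif(n * length(indivs)) < config$absence_rate,
                       nrow = n, dimnames = dimnames(expr))
    }
    expr[absent] <- 0
    ## normalize each individual to the TPM scale
    expr <- sweep(expr, 2, colSums(expr), "/") * 1e6

    chimeras <- NULL
    if (config$chimera_count > 0) {
      tox <- which(families != "nontoxin")
      if (length(tox) < 2) stop("chimera planting needs >= 2 toxins")
      chimeras <- do.call(rbind, lapply(seq_len(config$chimera_count), function(i) {
        ab <- sample(tox, 2)
        a <- reference[ab[1], ]; b <- reference[ab[2], ]
        mid_a <- a$cds_start + (a$cds_end - a$cds_start) %/% 2
        mid_b <- b$cds_start + (b$cds_end - b$cds_start) %/% 2
        seq <- paste0(substr(a$seq, 1, mid_a),
                      substr(b$seq, mid_b + 1, nchar(b$seq)))
        data.frame(id = sprintf("CHIM-%d", i), parent5 = a$id, parent3 = b$id,
                   seq = seq, cds_start = a$cds_start,
                   cds_end = mid_a + (b$cds_end - mid_b),
                   junction = mid_a, stringsAsFactors = FALSE)
      }))
    }
    list(reference = reference,
         truth = list(expression = expr, absent = absent, chimeras = chimeras,
                      de_effects = config$de_effects,
                      factor_table = config$factor_table))
  })
}

## mutate sequences with iid substitutions at `rate`; returns character vector
add_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  widths <- nchar(seqs)
  nerr <- rbinom(length(seqs), widths, rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    pos <- sample.int(widths[i], nerr[i])
    s <- strsplit(seqs[i], "")[[1]]
    s[pos] <- vapply(s[pos], function(b) sample(setdiff(DNA_BASES, b), 1), "")
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

## two-state quality strings: phred 38 body, optional low-quality (phred 2) tail
sim_quals <- function(widths, lowq_tail_prob) {
  n <- length(widths)
  tail_len <- ifelse(runif(n) < lowq_tail_prob,
                     pmin(rgeom_plus1(n), pmax(widths %/% 3, 1L)), 0L)
  vapply(seq_len(n), function(i) {
    hi <- widths[i] - tail_len[i]
    rawToChar(as.raw(c(rep(38L + 33L, hi), rep(2L + 33L, tail_len[i]))))
  }, character(1))
}

rgeom_plus1 <- function(n) rgeom(n, 0.15) + 1L

#' Simulate paired-end reads for every individual
#'
#' Fragments are placed uniformly on each transcript with lengths drawn from
#' the configured normal fragment-size distribution; the expected fragment
#' count per transcript is proportional to true abundance x length, and the
#' per-individual total equals the requested sequencing effort exactly
#' (multinomial allocation). Planted absences produce zero reads. Reads get
#' iid substitution errors and two-state quality strings so the phred-5
#' trimmer has work to do.
#'
#' @param ref output of [generate_reference()].
#' @param config a [sim_config()].
#' @return list with `reads`: `data.table` (id, mate, seq, qual, sample,
#'   lane, origin) for both mates of every fragment, and `truth` as in
#'   [generate_reference()] augmented with `n_fragments` per individual.
#' @export
simulate_reads <- function(ref, config) {
  stopifnot(nrow(ref$reference) > 0)
  if (config$fragment_mean < config$read_length)
    stop("fragment shorter than read length")
  reference <- ref$reference; truth <- ref$truth
  rl <- config$read_length
  with_seed(config$seed + 1L, {
    lens <- nchar(reference$seq)
    total_frags <- max(1L, round(config$depth_per_kb * sum(lens) / 1000))
    out <- vector("list", ncol(truth$expression))
    indivs <- colnames(truth$expression)
    for (j in seq_along(indivs)) {
      ab <- truth$expression[, j]
      w <- ab * lens
      if (sum(w) <= 0) stop("individual with all-zero abundance")
      counts <- as.vector(rmultinom(1, total_frags, w / sum(w)))
      tix <- rep(seq_len(nrow(reference)), counts)
      n <- length(tix)
      flen <- pmin(pmax(round(rnorm(n, config$fragment_mean, config$fragment_sd)),
                        rl), lens[tix])
      ## fragments may overhang transcript ends and are clipped, so terminal
      ## bases are covered like interior ones (shearing produces end pieces)
      s0 <- floor(runif(n) * (lens[tix] + flen - 1)) + 2L - flen
      start <- pmax(s0, 1L)
      end <- pmin(s0 + flen - 1L, lens[tix])
      flen <- end - start + 1L
      ## library size selection: clipped end pieces below min_fragment are lost
      keep <- flen >= pmin(config$min_fragment, lens[tix])
      tix <- tix[keep]; start <- start[keep]; flen <- flen[keep]
      n <- length(tix)
      frag <- stringi::stri_sub(reference$seq[tix], start, length = flen)
      rc <- runif(n) < 0.5
      frag[rc] <- revcomp(frag[rc])
      r1 <- stringi::stri_sub(frag, 1, length = pmin(rl, flen))
      r2 <- revcomp(stringi::stri_sub(frag, pmax(flen - rl + 1L, 1L),
                                      length = pmin(rl, flen)))
      r1 <- add_errors(r1, config$error_rate)
      r2 <- add_errors(r2, config$error_rate)
      q1 <- sim_quals(nchar(r1), config$lowq_tail_prob)
      q2 <- sim_quals(nchar(r2), config$lowq_tail_prob)
      fid <- sprintf("%s:frag%06d", indivs[j], seq_len(n))
      out[[j]] <- data.table::data.table(
        id = rep(fid, 2L), mate = rep(c(1L, 2L), each = n),
        seq = c(r1, r2), qual = c(q1, q2),
        sample = indivs[j], lane = "L001",
        origin = rep(reference$id[tix], 2L))
    }
    reads <- data.table::rbindlist(out)
    truth$n_fragments <- setNames(rep(total_frags, length(indivs)), indivs)
    list(reads = reads, truth = truth)
  })
}

#' Inject cross-sample contamination (demultiplex bleed-through)
#'
#' Each fragment is mis-allocated, with probability `rate`, to a uniformly
#' chosen other sample sharing its lane: both mates keep their sequence and
#' quality verbatim but carry the recipient's sample label, emulating index
#' hopping. Moved fragment ids are recorded per recipient sample.
#'
#' @param reads read `data.table` as produced by [simulate_reads()].
#' @param rate per-fragment mis-allocation probability.
#' @param seed integer seed.
#' @return list with `reads` (modified table) and `contaminants`: named list,
#'   per recipient sample, of fragment ids that are foreign there.
#' @export
inject_contamination <- function(reads, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  reads <- data.table::copy(reads)
  if (rate == 0)
    return(list(reads = reads,
                contaminants = sapply(unique(reads$sample),
                                      function(s) character(0), simplify = FALSE)))
  lanes <- split(unique(reads[, c("sample", "lane")]), # samples per lane
                 unique(reads[, c("sample", "lane")])$lane)
  if (any(vapply(lanes, nrow, 1L) < 2))
    stop("contamination requires >= 2 samples in a lane")
  with_seed(seed, {
    frag <- unique(reads[, c("id", "sample", "lane")])
    move <- runif(nrow(frag)) < rate
    dest <- frag$sample
    for (i in which(move)) {
      others <- setdiff(lanes[[frag$lane[i]]]$sample, frag$sample[i])
      dest[i] <- others[sample.int(length(others), 1)]
    }
    map <- setNames(dest, frag$id)
    reads[, sample := map[id]]
    contaminants <- lapply(
      setNames(nm = sort(unique(frag$sample))),
      function(s) frag$id[move & dest == s])
    list(reads = reads, contaminants = contaminants)
  })
}

#' Default internal protein standards
#'
#' The three E. coli proteins spiked at known amounts per injection:
#' 25 fmol P00811 (Beta-lactamase ampC), 250 fmol P31658 (Protein deglycase
#' 1), 2500 fmol P31697 (Chaperone protein FimC).
#'
#' @return data.frame with `protein_id`, `known_fmol`.
#' @export
default_standards <- function() {
  data.frame(protein_id = c("P00811", "P31658", "P31697"),
             known_fmol = c(25, 250, 2500), stringsAsFactors = FALSE)
}

#' Simulate normalized spectral counts with spiked internal standards
#'
#' Expected count for a protein in a replicate equals concentration divided
#' by that replicate's true conversion slope, perturbed by multiplicative
#' lognormal noise with coefficient of variation `noise_cv`. The three
#' standards are included as rows with their known amounts.
#'
#' @param concentrations named nonnegative vector of true protein amounts
#'   (fmol) for one individual.
#' @param standards data.frame as [default_standards()].
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param n_replicates technical replicates (default 3).
#' @param true_slopes fmol-per-count conversion factor per replicate
#'   (recycled; default 1).
#' @param seed integer seed.
#' @return list with `counts` (matrix, rows = standards then proteins,
#'   columns = replicates) and `true_slopes`.
#' @export
simulate_spectral_counts <- function(concentrations, standards = default_standards(),
                                     noise_cv = 0.05, n_replicates = 3L,
                                     true_slopes = 1, seed = 1L) {
  stopifnot(nrow(standards) == 3, all(standards$known_fmol > 0))
  if (any(concentrations < 0)) stop("negative concentrations")
  true_slopes <- rep_len(true_slopes, n_replicates)
  with_seed(seed, {
    all_conc <- c(setNames(standards$known_fmol, standards$protein_id),
                  concentrations)
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    counts <- sapply(seq_len(n_replicates), function(r) {
      mu <- all_conc / true_slopes[r]
      if (sdlog > 0) mu * rlnorm(length(mu), -sdlog^2 / 2, sdlog) else mu
    })
    rownames(counts) <- names(all_conc)
    colnames(counts) <- sprintf("rep%d", seq_len(n_replicates))
    list(counts = counts, true_slopes = true_slopes)
  })
}

#' Write reads to paired FASTQ files (phred+33)
#'
#' @param reads read table as from [simulate_reads()] for one sample.
#' @param prefix output path prefix; files `<prefix>_R1.fastq` and
#'   `<prefix>_R2.fastq` are written.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pair <- function(reads, prefix) {
  paths <- paste0(prefix, c("_R1.fastq", "_R2.fastq"))
  for (m in 1:2) {
    r <- reads[reads$mate == m, ]
    lines <- as.vector(rbind(paste0("@", r$id, "/", m), r$seq, "+", r$qual))
    writeLines(lines, paths[m])
  }
  invisible(paths)
}

#' Read a FASTQ file into the package's read table format
#'
#' @param path FASTQ path (phred+33, uncompressed).
#' @param sample,lane,mate labels attached to every read.
#' @return a `data.table` with columns id, mate, seq, qual, sample, lane.
#' @export
read_fastq <- function(path, sample = NA_character_, lane = "L001", mate = 1L) {
  lines <- readLines(path)
  stopifnot(length(lines) %% 4 == 0)
  i <- seq(1, length(lines), by = 4)
  data.table::data.table(
    id = sub("/[12]$", "", sub("^@", "", lines[i])), mate = mate,
    seq = lines[i + 1], qual = lines[i + 3], sample = sample, lane = lane)
}
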