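#' Configuration for a synthetic CEL-Seq2-style library
#'
#' Bundles every tunable of the sequencing-library simulator. Per (cell, gene),
#' true molecule counts are negative-binomial with mean `baseline_means[g]`
#' (times `2^de_genes[g]` in starved cells) and dispersion `dispersion`
#' (variance `mu + dispersion * mu^2`). Captured molecules are a binomial
#' thinning at `capture_efficiency`; each captured molecule is tagged with a
#' hexamer UMI and emits `1 + Poisson(pcr_duplication_rate)` read pairs; a
#' uniform per-base substitution error is applied at `seq_error_rate`.
#'
#' Read 1 carries `[cell barcode][UMI][poly-T fill]` to `read1_length` bases,
#' mirroring a barcoded oligo-dT RT primer; read 2 is the 3'-terminal
#' `read2_length` bases of the assigned transcript (a 3'-tag protocol reads a
#' fixed window near the polyadenylation site). The default 25 x 50 paired-end
#' geometry matches a rapid-run HiSeq configuration.
#'
#' @param n_cells_per_condition Cells simulated per condition (fed, starved).
#' @param n_genes Number of genes in the toy transcriptome.
#' @param barcode_length Cell-barcode length in bases. The generated whitelist
#'   has pairwise Hamming distance >= 3, so 1-mismatch demultiplexing is
#'   unambiguous.
#' @param umi_length UMI length in bases (hexamer by default).
#' @param baseline_means Expected molecules per cell per gene (fed state).
#'   `NULL` draws log-normal means (median 5) from the seed.
#' @param dispersion NB dispersion shared across genes.
#' @param de_genes Named numeric vector: true log2 fold change (starved vs
#'   fed) for differentially expressed genes; names must be gene ids
#'   (`gene0001`, ...). `NULL` simulates no true DE.
#' @param spikein_amounts Named ordered dilution series of expected spike-in
#'   molecules added to every cell.
#' @param capture_efficiency Probability that a molecule is captured.
#' @param pcr_duplication_rate Mean extra reads per captured molecule.
#' @param seq_error_rate Per-base substitution probability.
#' @param read1_length,read2_length Read lengths in bases.
#' @param transcript_length Length of each toy transcript in bases.
#' @param seed Integer seed; all simulator randomness derives from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cells_per_condition = 20,
                       n_genes = 200,
                       barcode_length = 8,
                       umi_length = 6,
                       baseline_means = NULL,
                       dispersion = 0.2,
                       de_genes = NULL,
                       spikein_amounts = c(spike1 = 0.5, spike2 = 1, spike3 = 2,
                                           spike4 = 4, spike5 = 8, spike6 = 16),
                       capture_efficiency = 0.3,
                       pcr_duplication_rate = 1,
                       seq_error_rate = 0.001,
                       read1_length = 25,
                       read2_length = 50,
                       transcript_length = 500,
                       seed = 1L) {
  stopifnot(n_cells_per_condition >= 1, n_genes >= 1,
            umi_length >= 1, barcode_length >= 3,
            read1_length >= barcode_length + umi_length,
            read2_length >= 1,
            transcript_length >= read2_length,
            capture_efficiency >= 0, capture_efficiency <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1,
            pcr_duplication_rate >= 0,
            dispersion > 0)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  if (is.null(baseline_means)) {
    baseline_means <- with_seed(seed + 101L,
                                exp(rnorm(n_genes, mean = log(5), sd = 1)))
  }
  stopifnot(length(baseline_means) == n_genes, all(baseline_means > 0))
  names(baseline_means) <- gene_ids
  if (!is.null(de_genes)) {
    stopifnot(!is.null(names(de_genes)), all(names(de_genes) %in% gene_ids))
  }
  stopifnot(!is.null(names(spikein_amounts)), all(spikein_amounts > 0))
  structure(list(
    n_cells_per_condition = as.integer(n_cells_per_condition),
    n_genes = as.integer(n_genes),
    barcode_length = as.integer(barcode_length),
    umi_length = as.integer(umi_length),
    baseline_means = baseline_means,
    dispersion = dispersion,
    de_genes = de_genes,
    spikein_amounts = spikein_amounts,
    capture_efficiency = capture_efficiency,
    pcr_duplication_rate = pcr_duplication_rate,
    seq_error_rate = seq_error_rate,
    read1_length = as.integer(read1_length),
    read2_length = as.integer(read2_length),
    transcript_length = as.integer(transcript_length),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Deterministic toy transcriptome for a simulator configuration
#'
#' One random transcript per gene and per spike-in species, each
#' `transcript_length` bases, drawn from the configuration seed.
#'
#' @param config A [sim_config()].
#' @return A [Biostrings::DNAStringSet] named by feature id.
#' @export
toy_reference <- function(config) {
  ids <- c(names(config$baseline_means), names(config$spikein_amounts))
  seqs <- with_seed(config$seed + 211L,
                    random_dna(length(ids), config$transcript_length))
  Biostrings::DNAStringSet(setNames(seqs, ids))
}

#' Generate a cell-barcode whitelist with pairwise Hamming distance >= 3
#'
#' Barcodes are drawn uniformly and accepted greedily while maintaining the
#' distance constraint, so <=1-mismatch demultiplexing is always unambiguous.
#'
#' @param n Number of barcodes.
#' @param width Barcode length in bases.
#' @param seed Integer seed.
#' @param min_dist Minimum pairwise Hamming distance (default 3).
#' @return Character vector of `n` barcodes.
#' @export
generate_barcodes <- function(n, width, seed = 1L, min_dist = 3L) {
  if (4^width < n * 10) {
    stop("barcode length ", width, " is too short for ", n, " barcodes")
  }
  with_seed(seed + 307L, {
    accepted <- character(0)
    tries <- 0L
    while (length(accepted) < n) {
      cand <- random_dna(1, width)
      if (length(accepted) == 0 || min(hamming(rep(cand, length(accepted)), accepted)) >= min_dist) {
        accepted <- c(accepted, cand)
      }
      tries <- tries + 1L
      if (tries > 50000L) stop("could not satisfy the barcode Hamming constraint")
    }
    accepted
  })
}

## Draw `n` UMIs uniformly, re-drawing until all pairwise Hamming distances
## within the group are >= 2. Keeps molecules of one (cell, feature) group
## distinguishable under directional collapsing, so the truth table is the
## exact expected output of deduplication.
draw_umis <- function(n, width) {
  umis <- random_dna(n, width)
  if (n < 2) return(umis)
  repeat {
    if (min_pairwise_hamming(umis) >= 2) return(umis)
    ## re-draw one offender
    m <- do.call(rbind, strsplit(umis, ""))
    bad <- FALSE
    for (i in seq_len(n - 1)) {
      d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                     matrix(m[i, ], nrow = n - i, ncol = width, byrow = TRUE))
      j <- which(d < 2)
      if (length(j)) { umis[i + j[1]] <- random_dna(1, width); bad <- TRUE; break }
    }
    if (!bad) return(umis)
  }
}

#' Simulate a CEL-Seq2-style paired-end library with ground truth
#'
#' Writes paired FASTQ files and returns the molecule truth table: one row per
#' captured molecule with its cell, feature, UMI and number of emitted read
#' pairs. Fed cells use `baseline_means`; starved cells multiply the mean of
#' each gene in `de_genes` by `2^log2fc`. Spike-in molecules are appended to
#' every cell as Poisson draws at `capture_efficiency * spikein_amounts`.
#'
#' @param config A [sim_config()].
#' @param reference Toy transcriptome ([Biostrings::DNAStringSet]); defaults
#'   to [toy_reference()] of `config`.
#' @param dir Output directory for the FASTQ pair.
#' @param prefix File-name prefix.
#' @return List with `fastq1`, `fastq2` (paths), `truth` (data.frame:
#'   `cell_id`, `condition`, `feature_id`, `umi`, `n_reads`, `is_spikein`),
#'   `cells` (data.frame: `cell_id`, `condition`, `barcode`), `barcodes`
#'   (whitelist), and `reference`.
#' @export
simulate_library <- function(config, reference = NULL, dir = tempdir(),
                             prefix = "sim") {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(reference)) reference <- toy_reference(config)
  feat_ids <- c(names(config$baseline_means), names(config$spikein_amounts))
  if (!all(feat_ids %in% names(reference))) {
    stop("reference is missing sequences for some genes/spike-ins")
  }
  if (any(Biostrings::width(reference) < config$read2_length)) {
    stop("all reference transcripts must be at least read2_length bases")
  }

  n_cc <- config$n_cells_per_condition
  cells <- data.frame(
    cell_id = sprintf("cell%03d", seq_len(2L * n_cc)),
    condition = rep(c("fed", "starved"), each = n_cc),
    stringsAsFactors = FALSE
  )
  barcodes <- generate_barcodes(nrow(cells), config$barcode_length, config$seed)
  cells$barcode <- barcodes
  names(barcodes) <- cells$cell_id

  lfc <- setNames(rep(0, config$n_genes), names(config$baseline_means))
  if (!is.null(config$de_genes)) lfc[names(config$de_genes)] <- config$de_genes

  truth <- with_seed(config$seed, {
    rows <- vector("list", nrow(cells))
    for (ci in seq_len(nrow(cells))) {
      mu <- config$baseline_means
      if (cells$condition[ci] == "starved") mu <- mu * 2^lfc
      true_n <- rnbinom(config$n_genes, mu = mu, size = 1 / config$dispersion)
      captured <- rbinom(config$n_genes, true_n, config$capture_efficiency)
      spike_n <- rpois(length(config$spikein_amounts),
                       config$spikein_amounts * config$capture_efficiency)
      feat <- c(rep(names(mu), captured),
                rep(names(config$spikein_amounts), spike_n))
      if (length(feat) == 0) next
      ## UMIs drawn per (cell, feature) group with pairwise Hamming >= 2
      umi <- character(length(feat))
      for (grp in split(seq_along(feat), feat)) {
        umi[grp] <- draw_umis(length(grp), config$umi_length)
      }
      rows[[ci]] <- data.frame(
        cell_id = cells$cell_id[ci],
        condition = cells$condition[ci],
        feature_id = feat,
        umi = umi,
        n_reads = 1L + rpois(length(feat), config$pcr_duplication_rate),
        is_spikein = feat %in% names(config$spikein_amounts),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  })
  rownames(truth) <- NULL

  ## emit reads
  reads <- with_seed(config$seed + 1L, {
    idx <- rep(seq_len(nrow(truth)), truth$n_reads)
    bc <- barcodes[truth$cell_id[idx]]
    polyt <- strrep("T", config$read1_length - config$barcode_length - config$umi_length)
    r1 <- paste0(bc, truth$umi[idx], polyt)
    tail3p <- as.character(Biostrings::subseq(
      reference, start = Biostrings::width(reference) - config$read2_length + 1))
    r2 <- unname(tail3p[truth$feature_id[idx]])
    list(r1 = apply_substitutions(unname(r1), config$seq_error_rate),
         r2 = apply_substitutions(r2, config$seq_error_rate))
  })

  ids <- sprintf("read%07d", seq_along(reads$r1))
  fq1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  fq2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(reads$r1, ids)),
                              fq1, format = "fastq")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(reads$r2, ids)),
                              fq2, format = "fastq")

  list(fastq1 = fq1, fastq2 = fq2, truth = truth, cells = cells,
       barcodes = barcodes, reference = reference)
}

#' Ground-truth unique-molecule count matrix from a truth table
#'
#' Collapses the molecule truth table to features x cells unique-molecule
#' counts — the exact matrix quantification should recover at zero sequencing
#' error.
#'
#' @param truth Truth table from [simulate_library()].
#' @param features Feature universe (row order); defaults to those present.
#' @param cells Cell universe (column order); defaults to those present.
#' @return Integer matrix, features x cells.
#' @export
truth_count_matrix <- function(truth, features = NULL, cells = NULL) {
  if (is.null(features)) features <- sort(unique(truth$feature_id))
  if (is.null(cells)) cells <- sort(unique(truth$cell_id))
  tab <- table(factor(truth$feature_id, levels = features),
               factor(truth$cell_id, levels = cells))
  m <- matrix(as.integer(tab), nrow = length(features),
              dimnames = list(features, cells))
  m
}
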