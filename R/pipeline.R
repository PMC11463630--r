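#' Toy gene-set collections for a simulated transcriptome
#'
#' Builds small synthetic collections over the simulated gene universe: one
#' set per DE direction (holding the truly up-/down-regulated genes plus a
#' few background genes) and several random background sets, mimicking an
#' ontology-slim and a gene-group collection at toy scale.
#'
#' @param genes Gene universe (character).
#' @param de_genes Named log2 fold changes of the truly DE genes.
#' @param n_random Number of random background sets.
#' @param set_size Size of each random set.
#' @param seed Integer seed.
#' @return Named list of gene sets.
#' @export
toy_genesets <- function(genes, de_genes, n_random = 8, set_size = 15,
                         seed = 1L) {
  up <- names(de_genes)[de_genes > 0]
  down <- names(de_genes)[de_genes < 0]
  with_seed(seed + 709L, {
    sets <- list(
      starvation_induced = unique(c(up, sample(setdiff(genes, up), 5))),
      starvation_repressed = unique(c(down, sample(setdiff(genes, down), 5)))
    )
    for (i in seq_len(n_random)) {
      sets[[sprintf("background_set_%02d", i)]] <-
        sample(genes, min(set_size, length(genes)))
    }
    sets
  })
}

#' Demo run configuration
#'
#' Study-condition defaults at desk scale: 20 cells per feeding condition,
#' 200 genes with 12 truly up- and 12 truly down-regulated genes (|log2FC|
#' = 2), a 6-point spike-in dilution series, and a 16-fly two-day (fed then
#' starved) DAM cohort per genotype. Analysis thresholds keep their standard
#' defaults (spike ratio 0.09, linearity 0.8, padj 0.1, fold change 1.5,
#' enrichment p filter 0.1, 5-minute bouts) except the aligned-read floor,
#' which is rescaled to the demo library depth (a toy library is orders of
#' magnitude shallower than a HiSeq run; the 250,000-read default applies to
#' real data).
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed.
#' @return A nested configuration list (class `run_config`).
#' @export
demo_config <- function(out_dir = file.path(tempdir(), "stateseq_demo"),
                        seed = 42L) {
  n_genes <- 200L
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  de <- with_seed(seed + 11L, {
    picks <- sample(gene_ids, 24)
    setNames(c(rep(2, 12), rep(-2, 12)), picks)
  })
  structure(list(
    out_dir = out_dir,
    seed = as.integer(seed),
    sim = sim_config(n_cells_per_condition = 20, n_genes = n_genes,
                     de_genes = de, seed = seed),
    qc = list(max_spike_ratio = 0.09, min_spike_r = 0.8,
              min_aligned_reads = 100),
    de = list(n_variable_genes = n_genes, padj_threshold = 0.1,
              fc_highlight = 1.5),
    enrich = list(p_filter = 0.1),
    behavior = behavior_config(n_flies_per_genotype = 16,
                               genotypes = c("control", "knockdown"),
                               p_doze = rbind(control = c(0.06, 0.03),
                                              knockdown = c(0.06, 0.05)),
                               p_wake = rbind(control = c(0.04, 0.055),
                                              knockdown = c(0.04, 0.045)),
                               seed = seed + 1L),
    sleep = list(min_sleep_run = 5L)
  ), class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with `seed`, `out_dir` and the `sim`, `qc`, `de`,
#'   `enrich`, `behavior`, `sleep` parameter blocks (any omitted block keeps
#'   the demo defaults).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- demo_config(out_dir = y$out_dir %||% file.path(tempdir(), "stateseq_run"),
                     seed = as.integer(y$seed %||% 42L))
  if (!is.null(y$sim)) cfg$sim <- do.call(sim_config, modifyList(
    list(seed = cfg$seed), y$sim))
  for (blk in c("qc", "de", "enrich", "sleep")) {
    if (!is.null(y[[blk]])) cfg[[blk]] <- modifyList(cfg[[blk]], y[[blk]])
  }
  if (!is.null(y$behavior)) cfg$behavior <- do.call(behavior_config, modifyList(
    list(seed = cfg$seed + 1L), y$behavior))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run both analysis arms end to end
#'
#' Sequencing arm: simulate library, quantify (demultiplex, assign,
#' deduplicate), QC, TPM, differential expression, enrichment. Behavior arm:
#' simulate DAM traces, parse the monitor file back, score sleep, compute
#' metrics, suppression, and group statistics. Writes the seven report tables
#' (counts, QC, TPM, DE, enrichment, sleep metrics, suppression) as TSV plus
#' a YAML run log of every seed and threshold. A stage failure stops with the
#' stage name.
#'
#' @param config A `run_config` (see [demo_config()], [read_run_config()]).
#' @return Invisibly, a list with every intermediate object and the output
#'   paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  sim <- stage("simulate", simulate_library(config$sim, dir = config$out_dir))
  cm <- stage("quantify", quantify_library(
    sim$fastq1, sim$fastq2, sim$reference, sim$barcodes,
    barcode_length = config$sim$barcode_length,
    umi_length = config$sim$umi_length,
    spikein_ids = names(config$sim$spikein_amounts)))
  write.table(cm$counts, out("counts.tsv"), sep = "\t", quote = FALSE)

  qc <- stage("qc", compute_qc(cm, config$sim$spikein_amounts,
                               max_spike_ratio = config$qc$max_spike_ratio,
                               min_spike_r = config$qc$min_spike_r,
                               min_aligned_reads = config$qc$min_aligned_reads))
  write.table(qc, out("qc_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  keep_cells <- qc$cell_id[qc$pass]
  if (length(keep_cells) < 4) stop("stage 'qc' failed: too few passing cells")
  tpm <- stage("tpm", tpm_normalize(cm)[, keep_cells, drop = FALSE])
  write.table(round(tpm, 3), out("tpm.tsv"), sep = "\t", quote = FALSE)

  gcounts <- cm$counts[!cm$is_spikein, keep_cells, drop = FALSE]
  cond <- sim$cells$condition[match(keep_cells, sim$cells$cell_id)]
  de <- stage("diffexpr", run_de(
    gcounts, cond,
    n_variable_genes = min(config$de$n_variable_genes, nrow(gcounts)),
    padj_threshold = config$de$padj_threshold,
    fc_highlight = config$de$fc_highlight, ref = "fed"))
  write.table(as.data.frame(de), out("de_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  sets <- toy_genesets(rownames(gcounts), config$sim$de_genes,
                       seed = config$seed)
  gmt <- out("genesets.gmt")
  write_gmt(sets, gmt)
  detected <- rownames(gcounts)[rowSums(gcounts) > 0]
  query <- intersect(de$gene[de$significant], detected)
  enr <- if (length(query)) {
    stage("enrichment", overrepresentation(query, read_gmt(gmt), detected,
                                           p_filter = config$enrich$p_filter))
  } else NULL
  if (!is.null(enr)) {
    write.table(as.data.frame(enr), out("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  dam <- stage("simulate_dam", simulate_dam(config$behavior,
                                            file = out("monitor01.txt")))
  parsed <- stage("read_dam", read_dam(dam$file))
  metrics <- stage("sleep_metrics", cohort_metrics(
    parsed$activity, dam$flies,
    days = day_labels(config$behavior$n_days),
    min_sleep_run = config$sleep$min_sleep_run))
  metrics <- cbind(metrics[, c("fly_id", "genotype")],
                   metrics[, setdiff(names(metrics), c("fly_id", "genotype"))])
  write.table(metrics, out("sleep_metrics.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  supp <- stage("suppression", {
    s <- suppression(metrics)
    s$genotype <- dam$flies$genotype[match(s$fly_id, dam$flies$fly_id)]
    s
  })
  write.table(supp, out("suppression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  stats <- stage("group_stats", group_stats(metrics))

  log <- list(
    seed = config$seed,
    thresholds = c(config$qc, config$de, config$enrich, config$sleep),
    sim = list(n_cells_per_condition = config$sim$n_cells_per_condition,
               n_genes = config$sim$n_genes,
               capture_efficiency = config$sim$capture_efficiency,
               pcr_duplication_rate = config$sim$pcr_duplication_rate,
               seq_error_rate = config$sim$seq_error_rate),
    behavior = list(seed = config$behavior$seed,
                    p_doze = as.list(as.data.frame(config$behavior$p_doze)),
                    p_wake = as.list(as.data.frame(config$behavior$p_wake))),
    n_cells_pass_qc = length(keep_cells),
    n_de_significant = sum(de$significant)
  )
  yaml::write_yaml(log, out("run_log.yaml"))

  invisible(list(sim = sim, counts = cm, qc = qc, tpm = tpm, de = de,
                 enrichment = enr, dam = dam, metrics = metrics,
                 suppression = supp, group_stats = stats,
                 out_dir = config$out_dir))
}

#' Run the bundled demo pipeline
#'
#' Executes [run_all()] on [demo_config()]: both arms end to end on synthetic
#' data, no network, a few minutes on one CPU. Rerunning with the same seed
#' reproduces every output byte-identically.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @return Invisibly, the [run_all()] result list.
#' @export
run_demo <- function(out_dir = file.path(tempdir(), "stateseq_demo"),
                     seed = 42L) {
  run_all(demo_config(out_dir = out_dir, seed = seed))
}
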