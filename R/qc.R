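#' Per-cell quality control from spike-ins and read depth
#'
#' Applies the three cell-quality criteria used to admit single-neuron
#' transcriptomes to differential expression: (i) spike-in reads over
#' transcript reads below `max_spike_ratio`; (ii) Pearson correlation between
#' expected spike-in molecule amounts and detected spike-in molecule counts
#' above `min_spike_r`; (iii) at least `min_aligned_reads` reads assigned to
#' any reference feature (pre-deduplication). Defaults are 0.09, 0.8 and
#' 250,000.
#'
#' @param cm A `count_matrix` from [build_count_matrix()].
#' @param spikein_amounts Named expected molecule amounts, one per spike-in
#'   species; names must match spike-in rows of `cm`.
#' @param max_spike_ratio,min_spike_r,min_aligned_reads QC thresholds.
#' @return data.frame of class `cell_qc`: `cell_id`, `spike_ratio`,
#'   `spike_linearity_r`, `aligned_reads`, `pass`, `fail_reason`
#'   (`""` when passing; otherwise comma-joined criteria violated, among
#'   `spike_ratio`, `linearity`, `linearity_undefined`, `aligned_reads`).
#' @export
compute_qc <- function(cm, spikein_amounts,
                       max_spike_ratio = 0.09,
                       min_spike_r = 0.8,
                       min_aligned_reads = 250000) {
  stopifnot(inherits(cm, "count_matrix"))
  spike <- cm$is_spikein
  if (!any(spike)) stop("count matrix has no spike-in rows flagged")
  sp_ids <- names(spike)[spike]
  stopifnot(all(sp_ids %in% names(spikein_amounts)))
  expected <- spikein_amounts[sp_ids]

  spike_reads <- colSums(cm$reads[spike, , drop = FALSE])
  tx_reads <- colSums(cm$reads[!spike, , drop = FALSE])
  ratio <- ifelse(tx_reads > 0, spike_reads / tx_reads, Inf)

  r <- vapply(seq_len(ncol(cm$counts)), function(j) {
    det <- cm$counts[sp_ids, j]
    if (length(det) < 3 || stats::sd(det) == 0) return(NA_real_)
    cor(expected, det)
  }, numeric(1))

  pass_ratio <- ratio < max_spike_ratio
  pass_r <- !is.na(r) & r > min_spike_r
  pass_depth <- cm$aligned_reads >= min_aligned_reads
  reason <- mapply(function(a, b, rr, c_) {
    paste(c(if (!a) "spike_ratio",
            if (!b) if (is.na(rr)) "linearity_undefined" else "linearity",
            if (!c_) "aligned_reads"), collapse = ",")
  }, pass_ratio, pass_r, r, pass_depth)

  out <- data.frame(
    cell_id = colnames(cm$counts),
    spike_ratio = unname(ratio),
    spike_linearity_r = unname(r),
    aligned_reads = unname(cm$aligned_reads),
    pass = unname(pass_ratio & pass_r & pass_depth),
    fail_reason = unname(reason),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_qc", "data.frame")
  out
}

#' TPM normalisation of unique-molecule counts
#'
#' Transcripts-per-million over non-spike-in genes:
#' `TPM(g, c) = count(g, c) / sum_g' count(g', c) * 1e6`. No transcript-length
#' division is applied: in a 3'-tag protocol each molecule contributes one tag
#' regardless of transcript length, so molecule proportions are already the
#' quantity of interest. Spike-ins are excluded from both numerator pool and
#' denominator.
#'
#' @param cm A `count_matrix`, or a plain counts matrix (then `is_spikein`
#'   must flag spike rows).
#' @param is_spikein Logical per row when `cm` is a plain matrix.
#' @return Numeric matrix (genes x cells); every column with nonzero counts
#'   sums to 1e6.
#' @export
tpm_normalize <- function(cm, is_spikein = NULL) {
  if (inherits(cm, "count_matrix")) {
    counts <- cm$counts
    is_spikein <- cm$is_spikein
  } else {
    counts <- cm
    if (is.null(is_spikein)) is_spikein <- rep(FALSE, nrow(counts))
  }
  g <- counts[!is_spikein, , drop = FALSE]
  tot <- colSums(g)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " cell(s) with zero gene counts yield all-zero TPM columns")
  }
  tpm <- sweep(g, 2, ifelse(tot > 0, tot, 1), "/") * 1e6
  tpm
}

#' Marker fidelity and per-cell transcript detection
#'
#' Summarises marker expression (mean and median TPM across cells) and counts
#' detected genes per cell (genes with at least one molecule, the
#' "unique transcripts per cell" statistic).
#'
#' @param tpm TPM matrix from [tpm_normalize()].
#' @param markers Character vector of marker gene ids.
#' @return List with `markers` (data.frame: `marker`, `present`, `mean_tpm`,
#'   `median_tpm`) and `detected_genes` (named integer per cell). Unknown
#'   markers are reported with `present = FALSE` and a warning, never
#'   silently dropped.
#' @export
marker_summary <- function(tpm, markers) {
  present <- markers %in% rownames(tpm)
  if (any(!present)) {
    warning("markers not in gene universe: ",
            paste(markers[!present], collapse = ", "))
  }
  mk <- data.frame(
    marker = markers,
    present = present,
    mean_tpm = ifelse(present,
                      vapply(markers, function(m)
                        if (m %in% rownames(tpm)) mean(tpm[m, ]) else NA_real_,
                        numeric(1)),
                      NA_real_),
    median_tpm = ifelse(present,
                        vapply(markers, function(m)
                          if (m %in% rownames(tpm)) median(tpm[m, ]) else NA_real_,
                          numeric(1)),
                        NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(mk) <- NULL
  list(markers = mk, detected_genes = colSums(tpm > 0))
}
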