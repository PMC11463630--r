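#' Median-of-ratios size factors
#'
#' Per-cell scale factors computed against the gene-wise geometric-mean
#' reference profile, using genes with nonzero counts in every cell; factors
#' are rescaled to geometric mean 1. When no gene is everywhere-nonzero the
#' function falls back to a positive-counts variant (per-cell median over the
#' genes that are nonzero in that cell) and warns.
#'
#' @param counts Genes x cells matrix of unique-molecule counts (spike-ins
#'   excluded by the caller).
#' @return Named positive numeric vector, one factor per cell.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1)
  logmat <- log(counts)
  loggeo <- rowMeans(logmat)
  usable <- is.finite(loggeo)
  if (any(usable)) {
    logsf <- apply(logmat[usable, , drop = FALSE], 2, function(lc)
      median(lc - loggeo[usable]))
  } else {
    warning("no gene has nonzero counts in all cells; ",
            "using the positive-counts fallback")
    loggeo_pos <- apply(logmat, 1, function(lr) mean(lr[is.finite(lr)]))
    logsf <- apply(logmat, 2, function(lc) {
      ok <- is.finite(lc) & is.finite(loggeo_pos)
      if (!any(ok)) stop("a cell has no counts; remove it before size factors")
      median(lc[ok] - loggeo_pos[ok])
    })
  }
  sf <- exp(logsf - mean(logsf))
  setNames(sf, colnames(counts))
}

#' Select the most variably expressed genes
#'
#' Ranks genes by the variance of `log2(normalized count + 1)` across cells
#' and returns the top `k`; ties are broken lexicographically by gene id.
#'
#' @param counts Genes x cells count matrix.
#' @param k Number of genes to keep (default 2000, the analysis default).
#' @param sf Size factors; computed by [size_factors()] if `NULL`.
#' @return Character vector of `k` gene ids.
#' @export
select_variable_genes <- function(counts, k = 2000L, sf = NULL) {
  stopifnot(k >= 1, k <= nrow(counts))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  v <- apply(log2(norm + 1), 1, var)
  ord <- order(-v, rownames(counts))
  rownames(counts)[ord][seq_len(k)]
}

## Method-of-moments NB dispersion from normalized counts, pooled over
## conditions (residual moments within each group), floored.
mom_dispersion <- function(z, cond, floor) {
  num <- 0; den <- 0
  for (g in levels(cond)) {
    zg <- z[cond == g]
    n <- length(zg)
    if (n < 2) next
    m <- mean(zg); v <- var(zg)
    if (m > 0) {
      num <- num + (n - 1) * (v - m) / m^2
      den <- den + (n - 1)
    }
  }
  a <- if (den > 0) num / den else 0
  max(a, floor)
}

## MLE of the group mean q (on the common scale) for y ~ NB(mu = s*q, disp a),
## given size factors s and fixed dispersion a.
nb_group_mean <- function(y, s, a) {
  if (sum(y) == 0) return(0)
  q0 <- sum(y) / sum(s)
  if (a < 1e-7 || length(y) < 2) return(q0)  # Poisson MLE is exact
  nll <- function(lq) {
    -sum(stats::dnbinom(y, size = 1 / a, mu = s * exp(lq), log = TRUE))
  }
  opt <- optimise(nll, interval = log(q0) + c(-4, 4))
  exp(opt$minimum)
}

#' Negative-binomial Wald test for two-condition differential expression
#'
#' For each gene, fits per-condition means by maximum likelihood under
#' `NB(mu = s_i * q_cond, variance mu + alpha * mu^2)` with a gene-wise
#' method-of-moments dispersion (floored at `dispersion_floor`), and tests
#' `log2fc = log2(q_test / q_ref)` with a Wald statistic against the standard
#' normal. The standard error comes from the expected Fisher information of
#' the log-mean in each group. Genes with all-zero counts return `log2fc = 0`,
#' `p = 1`; a group that is all-zero uses a half-molecule continuity value so
#' the fold change stays finite (flagged in `zero_group`).
#'
#' @param counts Genes x cells count matrix (selected genes, selected cells).
#' @param condition Factor/character of length `ncol(counts)` with exactly two
#'   levels.
#' @param sf Size factors (default [size_factors()] of `counts`).
#' @param ref Reference condition (denominator of the fold change); default
#'   the first factor level.
#' @param dispersion_floor Lower bound on the dispersion (keeps the Wald SE
#'   finite for near-Poisson genes).
#' @return data.frame of class `de_result`: `gene`, `base_mean`, `log2fc`,
#'   `se_log2fc`, `stat`, `pvalue`, `dispersion`, `zero_group`.
#' @export
nb_wald_test <- function(counts, condition, sf = NULL, ref = NULL,
                         dispersion_floor = 1e-8) {
  condition <- factor(condition)
  if (nlevels(condition) != 2) stop("exactly two conditions are required")
  if (any(table(condition) < 2)) stop("each condition needs at least 2 cells")
  stopifnot(ncol(counts) == length(condition))
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(ref)) ref <- levels(condition)[1]
  stopifnot(ref %in% levels(condition))
  test_lvl <- setdiff(levels(condition), ref)
  i_ref <- condition == ref
  i_tst <- condition == test_lvl

  z <- sweep(counts, 2, sf, "/")
  res <- lapply(seq_len(nrow(counts)), function(g) {
    y <- counts[g, ]
    bm <- mean(z[g, ])
    if (sum(y) == 0) {
      return(data.frame(base_mean = 0, log2fc = 0, se_log2fc = NA_real_,
                        stat = 0, pvalue = 1, dispersion = dispersion_floor,
                        zero_group = FALSE))
    }
    a <- mom_dispersion(z[g, ], condition, dispersion_floor)
    q1 <- nb_group_mean(y[i_ref], sf[i_ref], a)
    q2 <- nb_group_mean(y[i_tst], sf[i_tst], a)
    zero_group <- q1 == 0 || q2 == 0
    if (q1 == 0) q1 <- 0.5 / sum(sf[i_ref])
    if (q2 == 0) q2 <- 0.5 / sum(sf[i_tst])
    lfc <- log2(q2 / q1)
    info <- function(q, s) sum((s * q) / (1 + a * s * q))
    se <- sqrt(1 / info(q1, sf[i_ref]) + 1 / info(q2, sf[i_tst])) / log(2)
    stat <- lfc / se
    data.frame(base_mean = bm, log2fc = lfc, se_log2fc = se, stat = stat,
               pvalue = 2 * pnorm(-abs(stat)), dispersion = a,
               zero_group = zero_group)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene = rownames(counts), out)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up BH adjustment with monotone enforcement (via [stats::p.adjust()]).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, each in `[p, 1]`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Rank and flag a differential-expression table
#'
#' Adds BH-adjusted p values and the reporting flags (`significant`:
#' `padj < padj_threshold`; `high_fc`: linear fold change above
#' `fc_highlight`, i.e. `|log2fc| > log2(fc_highlight)`), sorts by `padj`
#' then descending `|log2fc|`, and records up/down counts among significant
#' genes as attributes `n_up` / `n_down`.
#'
#' @param res A `de_result` from [nb_wald_test()].
#' @param padj_threshold Adjusted-p significance threshold (default 0.1).
#' @param fc_highlight Linear fold-change highlight threshold (default 1.5).
#' @return The ranked, flagged data.frame (class `de_report`).
#' @export
de_report <- function(res, padj_threshold = 0.1, fc_highlight = 1.5) {
  stopifnot(padj_threshold > 0, fc_highlight > 0)
  res$padj <- bh_adjust(res$pvalue)
  res$significant <- res$padj < padj_threshold
  res$high_fc <- abs(res$log2fc) > log2(fc_highlight)
  out <- res[order(res$padj, -abs(res$log2fc), res$gene), ]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$significant & out$log2fc > 0)
  attr(out, "n_down") <- sum(out$significant & out$log2fc < 0)
  class(out) <- c("de_report", class(out))
  out
}

#' @export
print.de_report <- function(x, ...) {
  cat("Differential expression:", nrow(x), "genes tested;",
      sum(x$significant), "significant (", attr(x, "n_up"), "up /",
      attr(x, "n_down"), "down )\n")
  print.data.frame(head(as.data.frame(x), 10), digits = 3)
  invisible(x)
}

#' Fed-versus-starved differential expression, end to end
#'
#' Convenience wrapper: size factors on all genes, selection of the
#' `n_variable_genes` most variable genes, NB Wald test, BH adjustment and
#' report flags.
#'
#' @param counts Genes x cells count matrix (no spike-ins).
#' @param condition Two-level condition per cell (reference first level or
#'   `ref`).
#' @param n_variable_genes Number of most-variable genes tested (default
#'   2000, capped at the gene count must hold: an error otherwise).
#' @param padj_threshold,fc_highlight Reporting thresholds (defaults 0.1,
#'   1.5).
#' @param ref Reference condition.
#' @param dispersion_floor See [nb_wald_test()].
#' @return A `de_report`.
#' @export
run_de <- function(counts, condition, n_variable_genes = 2000L,
                   padj_threshold = 0.1, fc_highlight = 1.5, ref = NULL,
                   dispersion_floor = 1e-8) {
  sf <- size_factors(counts)
  keep <- select_variable_genes(counts, k = n_variable_genes, sf = sf)
  res <- nb_wald_test(counts[keep, , drop = FALSE], condition, sf = sf,
                      ref = ref, dispersion_floor = dispersion_floor)
  de_report(res, padj_threshold = padj_threshold, fc_highlight = fc_highlight)
}
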