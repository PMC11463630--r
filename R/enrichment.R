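#' Read a gene-set collection in GMT format
#'
#' @param path Path to a `.gmt` file (one set per line: name, description,
#'   then member genes, tab-separated).
#' @param label Optional collection label attached as an attribute.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path, label = basename(path)) {
  sets <- fgsea::gmtPathways(path)
  if (any(lengths(sets) == 0)) stop("GMT contains an empty gene set")
  structure(sets, label = label, class = c("gene_set_collection", "list"))
}

#' Write a gene-set collection in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(!is.null(names(sets)), all(lengths(sets) > 0))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each set, tests whether the query (e.g. the differentially expressed
#' genes) overlaps it more than expected under sampling without replacement
#' from the universe: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with
#' universe size `N`, set size `K` (after intersecting with the universe) and
#' query size `n`. Fold enrichment is `(k/n) / (K/N)`. A raw p-value filter
#' (default 0.1) flags reported sets; an optional BH adjustment across sets
#' is off by default since the filter convention is on raw p.
#'
#' @param query Character vector of query genes (must lie in `universe`;
#'   outsiders are dropped with a warning).
#' @param collection Named list of gene sets (e.g. [read_gmt()]).
#' @param universe Character vector: the gene background (typically all genes
#'   detected in the count matrix).
#' @param p_filter Raw p-value filter for the `pass` flag (default 0.1).
#' @param adjust If `TRUE`, also compute BH-adjusted p across sets.
#' @return data.frame of class `enrichment_result`, sorted by p: `set`,
#'   `overlap` (k), `query_size` (n), `set_size` (K), `universe_size` (N),
#'   `fold_enrichment`, `log2_fold_enrichment`, `pvalue`, `pass`
#'   (+ `padj` when `adjust`).
#' @export
overrepresentation <- function(query, collection, universe, p_filter = 0.1,
                               adjust = FALSE) {
  query <- unique(query)
  if (length(query) == 0) stop("empty query")
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropping ", length(outside), " query gene(s) outside the universe")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query genes left inside the universe")
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(unique(collection[[nm]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fe <- if (K == 0) NA_real_ else (k / n) / (K / N)
    data.frame(set = nm, overlap = k, query_size = n, set_size = K,
               universe_size = N, fold_enrichment = fe,
               log2_fold_enrichment = log2(fe), pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$padj <- bh_adjust(out$pvalue)
  out$pass <- out$pvalue < p_filter
  out <- out[order(out$pvalue, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
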