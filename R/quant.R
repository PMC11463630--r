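#' Demultiplex read barcodes against a whitelist
#'
#' Each observed barcode is assigned to the unique whitelist entry within
#' `max_mismatch` substitutions. The whitelist must have pairwise Hamming
#' distance >= 2 * max_mismatch + 1, which makes every assignment unambiguous;
#' whitelists violating this are rejected rather than risking silent
#' misassignment.
#'
#' @param barcodes Character vector of observed read barcodes.
#' @param whitelist Character vector of cell barcodes (named by cell id, or
#'   unnamed in which case barcodes name themselves).
#' @param max_mismatch Maximum substitutions tolerated (default 1).
#' @return List with `cell` (character vector, `NA` for unmatched reads) and
#'   `n_unmatched`.
#' @export
demultiplex <- function(barcodes, whitelist, max_mismatch = 1L) {
  stopifnot(length(whitelist) >= 1)
  if (length(unique(nchar(whitelist))) != 1) {
    stop("whitelist barcodes must share one length")
  }
  if (min_pairwise_hamming(whitelist) < 2L * max_mismatch + 1L) {
    stop("whitelist pairwise Hamming distance must be >= ",
         2L * max_mismatch + 1L, " for unambiguous demultiplexing")
  }
  cell_ids <- names(whitelist)
  if (is.null(cell_ids)) cell_ids <- unname(whitelist)

  uniq <- unique(barcodes)
  bl <- nchar(whitelist[1])
  um <- do.call(rbind, strsplit(uniq, ""))
  if (!is.matrix(um) || ncol(um) != bl) {
    ## ragged or wrong-length barcodes: handle by per-entry nchar filter
    ok <- nchar(uniq) == bl
    assign_u <- rep(NA_character_, length(uniq))
    if (any(ok)) {
      sub <- demultiplex(uniq[ok], whitelist, max_mismatch)
      assign_u[ok] <- sub$cell
    }
    cell <- assign_u[match(barcodes, uniq)]
    return(list(cell = cell, n_unmatched = sum(is.na(cell))))
  }
  best <- rep(NA_character_, length(uniq))
  bestd <- rep(Inf, length(uniq))
  for (w in seq_along(whitelist)) {
    d <- rowSums(um != matrix(strsplit(whitelist[w], "")[[1]],
                              nrow = nrow(um), ncol = bl, byrow = TRUE))
    hit <- d <= max_mismatch & d < bestd
    best[hit] <- cell_ids[w]
    bestd[hit] <- d[hit]
  }
  cell <- best[match(barcodes, uniq)]
  list(cell = cell, n_unmatched = sum(is.na(cell)))
}

#' Build an exact k-mer index over the 3' regions of a reference
#'
#' @param reference [Biostrings::DNAStringSet] of transcripts.
#' @param min_match Seed k-mer length.
#' @param region_3p Number of 3'-terminal bases indexed per transcript
#'   (3'-tag reads come from this window).
#' @return Internal index used by [assign_transcript()].
#' @export
transcript_index <- function(reference, min_match = 15L, region_3p = 120L) {
  ids <- names(reference)
  tails <- as.character(Biostrings::subseq(
    reference,
    start = pmax(1L, Biostrings::width(reference) - region_3p + 1L)))
  kmer_gene <- new.env(parent = emptyenv())
  for (i in seq_along(tails)) {
    s <- tails[i]
    L <- nchar(s)
    if (L < min_match) next
    for (p in seq_len(L - min_match + 1L)) {
      km <- substr(s, p, p + min_match - 1L)
      cur <- kmer_gene[[km]]
      if (is.null(cur)) kmer_gene[[km]] <- ids[i]
      else if (!(ids[i] %in% cur)) kmer_gene[[km]] <- c(cur, ids[i])
    }
  }
  kmers <- ls(kmer_gene)
  genes <- vapply(kmers, function(k) paste(sort(kmer_gene[[k]]), collapse = ","),
                  character(1))
  structure(list(kmers = kmers, genes = unname(genes), k = as.integer(min_match)),
            class = "transcript_index")
}

#' Assign reads to transcripts by exact 3'-region k-mer match
#'
#' A read is assigned to the gene whose indexed 3' region shares an exact
#' k-mer (k = `min_match`) with it. Reads matching no gene, or more than one
#' gene, return `"UNASSIGNED"` (ties are never broken arbitrarily).
#'
#' @param reads Character vector of read-2 sequences.
#' @param index A [transcript_index()] (or a `DNAStringSet`, which is indexed
#'   on the fly with `min_match`).
#' @param min_match Seed length when `index` is a reference set.
#' @return Character vector of gene ids or `"UNASSIGNED"`.
#' @export
assign_transcript <- function(reads, index, min_match = 15L) {
  if (inherits(index, "DNAStringSet")) {
    index <- transcript_index(index, min_match = min_match)
  }
  stopifnot(inherits(index, "transcript_index"))
  k <- index$k
  n <- length(reads)
  if (n == 0) return(character(0))
  L <- nchar(reads)
  if (length(unique(L)) != 1) stop("reads must share one length")
  L <- L[1]
  if (L < k) return(rep("UNASSIGNED", n))
  hits <- matrix(NA_character_, nrow = n, ncol = L - k + 1L)
  for (p in seq_len(L - k + 1L)) {
    sub <- substr(reads, p, p + k - 1L)
    hits[, p] <- index$genes[match(sub, index$kmers)]
  }
  apply(hits, 1, function(h) {
    g <- unique(unlist(strsplit(h[!is.na(h)], ",", fixed = TRUE)))
    if (length(g) == 1) g else "UNASSIGNED"
  })
}

#' Directional UMI deduplication
#'
#' Collapses a UMI read-count table into unique molecules using the
#' directional network rule: a directed edge runs from UMI `a` to UMI `b`
#' when they differ at exactly one base and `count(a) >= 2 * count(b) - 1`.
#' Clusters are grown greedily from the highest-count unvisited UMI (ties
#' broken lexicographically), following directed edges transitively; the
#' number of clusters is the unique-molecule count. This tolerates the
#' one-off errors PCR and sequencing introduce into UMIs while keeping
#' genuinely distinct co-abundant UMIs apart.
#'
#' @param umi_counts Named integer vector: read count per UMI sequence.
#' @return Integer: number of unique molecules (clusters).
#' @export
dedup_directional <- function(umi_counts) {
  if (length(umi_counts) == 0) return(0L)
  umis <- names(umi_counts)
  if (is.null(umis) || any(is.na(umis))) stop("umi_counts must be named by UMI")
  if (length(unique(nchar(umis))) != 1) stop("UMIs must share one length")
  if (any(umi_counts < 1)) stop("all UMI counts must be >= 1")
  n <- length(umis)
  if (n == 1) return(1L)
  cnt <- as.numeric(umi_counts)
  m <- do.call(rbind, strsplit(umis, ""))
  ## adjacency: directed a -> b if Hamming 1 and cnt[a] >= 2*cnt[b] - 1
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    d <- rowSums(m[(i + 1):n, , drop = FALSE] !=
                   matrix(m[i, ], nrow = n - i, ncol = ncol(m), byrow = TRUE))
    for (j in which(d == 1) + i) {
      if (cnt[i] >= 2 * cnt[j] - 1) adj[[i]] <- c(adj[[i]], j)
      if (cnt[j] >= 2 * cnt[i] - 1) adj[[j]] <- c(adj[[j]], i)
    }
  }
  ord <- order(-cnt, umis)
  visited <- rep(FALSE, n)
  clusters <- 0L
  for (s in ord) {
    if (visited[s]) next
    clusters <- clusters + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nxt <- adj[[v]]
      nxt <- nxt[!visited[nxt]]
      visited[nxt] <- TRUE
      queue <- c(queue, nxt)
    }
  }
  clusters
}

#' Build a unique-molecule count matrix from read assignments
#'
#' Groups reads by (cell, feature), tabulates reads per UMI, applies
#' [dedup_directional()] per group, and records read-level totals needed for
#' quality control. `total_aligned_reads` per cell counts reads assigned to
#' any reference feature (genes plus spike-ins), before deduplication.
#'
#' @param assignments data.frame with columns `cell_id`, `umi`, `feature_id`
#'   (`"UNASSIGNED"` for unassigned reads); one row per read.
#' @param features Row universe (character); defaults to assigned features.
#' @param cells Column universe (character); defaults to observed cells.
#' @param spikein_ids Character vector naming spike-in features.
#' @return Object of class `count_matrix`: list with `counts` (unique
#'   molecules, features x cells), `reads` (pre-deduplication read counts,
#'   same shape), `is_spikein` (logical per row), `aligned_reads` (per cell),
#'   `n_unassigned` (reads with no feature).
#' @export
build_count_matrix <- function(assignments, features = NULL, cells = NULL,
                               spikein_ids = character(0)) {
  stopifnot(all(c("cell_id", "umi", "feature_id") %in% names(assignments)))
  ok <- !is.na(assignments$cell_id) & assignments$feature_id != "UNASSIGNED"
  asg <- assignments[ok, , drop = FALSE]
  if (is.null(features)) features <- sort(unique(asg$feature_id))
  if (is.null(cells)) {
    cells <- sort(unique(assignments$cell_id[!is.na(assignments$cell_id)]))
  }
  counts <- matrix(0L, nrow = length(features), ncol = length(cells),
                   dimnames = list(features, cells))
  reads <- counts
  if (nrow(asg)) {
    key <- paste(asg$cell_id, asg$feature_id, sep = "\r")
    for (grp in split(seq_len(nrow(asg)), key)) {
      g <- asg$feature_id[grp[1]]
      c_ <- asg$cell_id[grp[1]]
      if (!(g %in% features) || !(c_ %in% cells)) next
      tab <- table(asg$umi[grp])
      counts[g, c_] <- dedup_directional(setNames(as.integer(tab), names(tab)))
      reads[g, c_] <- length(grp)
    }
  }
  structure(list(
    counts = counts,
    reads = reads,
    is_spikein = setNames(features %in% spikein_ids, features),
    aligned_reads = colSums(reads),
    n_unassigned = sum(assignments$feature_id == "UNASSIGNED", na.rm = TRUE) +
      sum(is.na(assignments$cell_id))
  ), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts), "cells\n")
  cat("  spike-in rows:", sum(x$is_spikein), "\n")
  cat("  aligned reads per cell: median",
      stats::median(x$aligned_reads), "\n")
  cat("  unassigned/unmatched reads:", x$n_unassigned, "\n")
  invisible(x)
}

#' Quantify a paired-end CEL-Seq2-style library end to end
#'
#' Reads the FASTQ pair, demultiplexes read-1 barcodes, assigns read 2 to
#' transcripts by 3' k-mer match, and collapses UMIs per (cell, gene) with the
#' directional rule.
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ files (read 1 carries
#'   barcode then UMI; read 2 is the cDNA tag).
#' @param reference [Biostrings::DNAStringSet] of transcripts (genes and
#'   spike-ins).
#' @param barcodes Whitelist, named by cell id.
#' @param barcode_length,umi_length Read-1 layout.
#' @param spikein_ids Features to flag as spike-ins.
#' @param max_mismatch Barcode mismatch tolerance.
#' @param min_match Transcript-assignment seed length.
#' @return A `count_matrix` (see [build_count_matrix()]).
#' @export
quantify_library <- function(fastq1, fastq2, reference, barcodes,
                             barcode_length = nchar(barcodes[1]),
                             umi_length = 6L,
                             spikein_ids = character(0),
                             max_mismatch = 1L, min_match = 15L) {
  r1 <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  if (length(r1) != length(r2)) stop("FASTQ pair has unequal read counts")
  bc <- substr(r1, 1L, barcode_length)
  umi <- substr(r1, barcode_length + 1L, barcode_length + umi_length)
  dmx <- demultiplex(bc, barcodes, max_mismatch)
  genes <- assign_transcript(unname(r2), reference, min_match = min_match)
  asg <- data.frame(cell_id = dmx$cell, umi = unname(umi), feature_id = genes,
                    stringsAsFactors = FALSE)
  build_count_matrix(asg, features = names(reference), cells = names(barcodes),
                     spikein_ids = spikein_ids)
}
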