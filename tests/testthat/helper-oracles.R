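## Independent reference implementations used as oracles.

## Directional UMI collapsing via per-seed reachability closure on the
## subgraph of unvisited nodes (matrix closure, not BFS).
oracle_directional <- function(counts) {
  umis <- names(counts)
  n <- length(umis)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  chars <- strsplit(umis, "")
  edge <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sum(chars[[i]] != chars[[j]]) == 1 &&
        counts[i] >= 2 * counts[j] - 1) {
      edge[i, j] <- TRUE
    }
  }
  ord <- order(-as.numeric(counts), umis)
  left <- rep(TRUE, n)
  k <- 0L
  for (s in ord) {
    if (!left[s]) next
    k <- k + 1L
    ## reachability closure restricted to currently unvisited nodes
    reach <- rep(FALSE, n)
    reach[s] <- TRUE
    repeat {
      nxt <- reach
      for (v in which(reach)) nxt <- nxt | (edge[v, ] & left)
      if (identical(nxt, reach)) break
      reach <- nxt
    }
    left[reach] <- FALSE
  }
  k
}

## Random UMI multiset from the small test space.
random_umi_multiset <- function(max_distinct = 6, max_len = 4, max_count = 8) {
  len <- sample(2:max_len, 1)
  k <- sample(1:max_distinct, 1)
  pool <- unique(replicate(k * 3, paste(sample(c("A", "C", "G", "T"), len,
                                               replace = TRUE), collapse = "")))
  umis <- pool[seq_len(min(k, length(pool)))]
  setNames(sample(1:max_count, length(umis), replace = TRUE), umis)
}

## Step-up BH by the textbook formula (sorted p * m / rank, cummin from the top).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

## Upper-tail hypergeometric p by enumeration of all C(N, n) query draws.
oracle_hyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_set <- seq_len(K)  # first K elements form the set
  hits <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(hits >= k)
}

## Minimal count_matrix construction for QC fixtures.
make_cm <- function(counts, reads, spikein_ids) {
  structure(list(
    counts = counts, reads = reads,
    is_spikein = setNames(rownames(counts) %in% spikein_ids, rownames(counts)),
    aligned_reads = colSums(reads),
    n_unassigned = 0L
  ), class = "count_matrix")
}
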