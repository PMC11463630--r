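#' @keywords internal
"_PACKAGE"

#' @importFrom stats median optimise pnorm rbinom rnbinom rnorm rpois runif
#'   var sd aov TukeyHSD kruskal.test p.adjust phyper cor dnbinom setNames
#' @importFrom utils write.table read.table head modifyList combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

random_dna <- function(n, width) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, width, replace = TRUE), collapse = "")
  }, character(1))
}

## Pairwise Hamming distance between equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

## Minimum pairwise Hamming distance within a character vector.
min_pairwise_hamming <- function(x) {
  if (length(x) < 2) return(Inf)
  m <- do.call(rbind, strsplit(x, ""))
  dmin <- Inf
  for (i in seq_len(length(x) - 1)) {
    d <- rowSums(m[(i + 1):length(x), , drop = FALSE] !=
                   matrix(m[i, ], nrow = length(x) - i, ncol = ncol(m), byrow = TRUE))
    dmin <- min(dmin, d)
  }
  dmin
}

## Apply uniform substitution errors to a vector of sequences.
apply_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  idx <- which(n_err > 0)
  for (i in idx) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    for (p in pos) {
      ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1)
    }
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}
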