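sim_counts <- function(n_genes, n_per_group, mu, disp, lfc = 0, seed = 1) {
  withr::with_seed(seed, {
    fed <- matrix(rnbinom(n_genes * n_per_group, mu = mu, size = 1 / disp),
                  n_genes, n_per_group)
    stv <- matrix(rnbinom(n_genes * n_per_group, mu = mu * 2^lfc,
                          size = 1 / disp), n_genes, n_per_group)
    m <- cbind(fed, stv)
    dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("c%03d", seq_len(2 * n_per_group)))
    m
  })
}

test_that("size factors recover exact scaling relations", {
  a <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  sf <- size_factors(a)
  expect_equal(unname(sf["B"] / sf["A"]), 2)
  same <- cbind(a[, 1], a[, 1], a[, 1])
  colnames(same) <- paste0("c", 1:3)
  expect_equal(unname(size_factors(same)), rep(1, 3))
  three <- matrix(c(10, 20, 20, 40, 40, 80), nrow = 2,
                  dimnames = list(c("g1", "g2"), c("A", "B", "C")))
  sf3 <- size_factors(three)
  ## hand median-of-ratios: geomeans (20, 40); ratios 0.5, 1, 2; geometric
  ## mean already 1
  expect_equal(unname(sf3), c(0.5, 1, 2))
})

test_that("size factors agree with the DESeq2 reference on a random matrix", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  m <- matrix(rnbinom(300, mu = 40, size = 5), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  ours <- size_factors(m)
  theirs <- DESeq2::estimateSizeFactorsForMatrix(m)
  theirs <- theirs / exp(mean(log(theirs)))  # same geometric-mean-1 convention
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-10)
})

test_that("variable-gene selection ranks by log-scale variance with lexical ties", {
  m <- rbind(
    g_flat  = rep(10, 6),
    g_big   = c(1, 1, 1, 200, 200, 200),
    g_mid   = c(5, 5, 5, 40, 40, 40),
    g_small = c(8, 8, 8, 14, 14, 14),
    g_zero  = rep(0, 6))
  colnames(m) <- paste0("c", 1:6)
  sf <- setNames(rep(1, 6), colnames(m))
  expect_equal(select_variable_genes(m, 3, sf), c("g_big", "g_mid", "g_small"))
  expect_equal(sort(select_variable_genes(m, 5, sf)), sort(rownames(m)))
  expect_false("g_flat" %in% select_variable_genes(m, 3, sf))
})

test_that("identical groups give exactly zero log fold change", {
  vals <- c(3, 7, 12, 5)
  m <- matrix(c(vals, vals), nrow = 1,
              dimnames = list("g1", paste0("c", 1:8)))
  res <- nb_wald_test(m, rep(c("fed", "starved"), each = 4),
                      sf = setNames(rep(1, 8), colnames(m)))
  expect_identical(res$log2fc, 0)
  expect_equal(res$pvalue, 1)
})

test_that("negating the condition labels negates every log2fc exactly", {
  m <- sim_counts(30, 10, mu = 20, disp = 0.2, lfc = 1, seed = 3)
  cond <- rep(c("fed", "starved"), each = 10)
  sf <- size_factors(m)
  a <- nb_wald_test(m, cond, sf = sf, ref = "fed")
  b <- nb_wald_test(m, cond, sf = sf, ref = "starved")
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-7)
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-7)
})

test_that("the Wald test recovers a true log2 fold change of 2", {
  m <- sim_counts(200, 20, mu = 50, disp = 0.1, lfc = 2, seed = 42)
  res <- nb_wald_test(m, rep(c("fed", "starved"), each = 20),
                      sf = setNames(rep(1, 40), colnames(m)))
  expect_lt(abs(mean(res$log2fc) - 2), 0.25)
})

test_that("null simulations give approximately uniform Wald p values", {
  m <- sim_counts(2000, 20, mu = 50, disp = 0.1, lfc = 0, seed = 77)
  res <- nb_wald_test(m, rep(c("fed", "starved"), each = 20),
                      sf = setNames(rep(1, 40), colnames(m)))
  frac <- mean(res$pvalue < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("log2fc bias stays below 0.1 across dispersions at n = 50", {
  for (disp in c(0.05, 0.2, 0.5)) {
    m <- sim_counts(500, 50, mu = 30, disp = disp, lfc = 1.5,
                    seed = 100 + round(100 * disp))
    res <- nb_wald_test(m, rep(c("fed", "starved"), each = 50),
                        sf = setNames(rep(1, 100), colnames(m)))
    expect_lt(abs(mean(res$log2fc) - 1.5), 0.1)
  }
})

test_that("BH adjustment matches the hand-computed and oracle values", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  p <- runif(50)
  expect_equal(bh_adjust(p), oracle_bh(p))
  expect_true(all(bh_adjust(p) >= p))
  ## permutation invariance
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("the DE report flags, sorts and counts directions correctly", {
  m <- sim_counts(200, 20, mu = 50, disp = 0.1, lfc = 0, seed = 9)
  true_lfc <- setNames(rep(0, 200), rownames(m))
  up <- rownames(m)[1:10]; down <- rownames(m)[11:20]
  true_lfc[up] <- 2; true_lfc[down] <- -2
  m2 <- withr::with_seed(10, {
    x <- m
    x[up, 21:40] <- rnbinom(10 * 20, mu = 50 * 4, size = 10)
    x[down, 21:40] <- rnbinom(10 * 20, mu = 50 / 4, size = 10)
    x
  })
  res <- nb_wald_test(m2, rep(c("fed", "starved"), each = 20),
                      sf = setNames(rep(1, 40), colnames(m2)))
  rep_ <- de_report(res, padj_threshold = 0.1, fc_highlight = 1.5)
  expect_true(all(diff(rep_$padj) >= 0))
  expect_true(all(rep_$significant == (rep_$padj < 0.1)))
  expect_true(all(rep_$high_fc == (abs(rep_$log2fc) > log2(1.5))))
  flagged <- rep_[rep_$significant, ]
  correct_dir <- sign(true_lfc[flagged$gene]) == sign(flagged$log2fc) &
    true_lfc[flagged$gene] != 0
  expect_gte(mean(correct_dir), 0.9)
  ## a vacuous threshold flags nothing
  rep0 <- de_report(res, padj_threshold = 1e-300)
  expect_equal(sum(rep0$significant), 0)
})

test_that("empirical FDR stays controlled in mixed simulations", {
  ## 5% true DE at |log2fc| = 2 among 1000 genes, n = 20 cells/group
  m <- sim_counts(1000, 20, mu = 50, disp = 0.1, lfc = 0, seed = 21)
  truth <- setNames(c(rep(2, 25), rep(-2, 25), rep(0, 950)), rownames(m))
  m2 <- withr::with_seed(22, {
    x <- m
    x[1:25, 21:40] <- rnbinom(25 * 20, mu = 200, size = 10)
    x[26:50, 21:40] <- rnbinom(25 * 20, mu = 12.5, size = 10)
    x
  })
  rep_ <- de_report(nb_wald_test(m2, rep(c("fed", "starved"), each = 20),
                                 sf = setNames(rep(1, 40), colnames(m2))))
  flagged <- rep_[rep_$significant, ]
  expect_gt(nrow(flagged), 25)          # real signal is found
  expect_lte(mean(truth[flagged$gene] == 0), 0.2)
})
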