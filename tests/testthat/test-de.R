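test_that("size factors are medians of ratios to the geometric mean", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(NULL, c("A", "B")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  ident <- matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(unname(size_factors(ident)), c(1, 1, 1))
  expect_equal(unname(size_factors(m[, 1, drop = FALSE])), 1)
  # no gene covered everywhere -> error advising the fallback
  z <- matrix(c(0, 5, 5, 0), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(size_factors(z), "fallback")
  expect_true(all(size_factors(z, fallback = TRUE) > 0))
})

test_that("normalized columns have unit median ratios", {
  arch <- regulatory_architecture(400, q = 150, alpha = 0.05)
  des <- parental_design(4)
  des$size_factor <- c(0.5, 1, 2, 1, 1.5, 0.8, 1, 1)
  sim <- simulate_expression(arch, des, seed = 1)
  sf <- size_factors(sim$counts)
  use <- rowSums(sim$counts > 0) == ncol(sim$counts)
  loggeo <- rowMeans(log(sim$counts[use, ]))
  norm <- sweep(log(sim$counts[use, ]), 2, log(sf), "-")
  med <- apply(norm, 2, function(x) exp(median(x - loggeo)))
  expect_equal(unname(med), rep(1, 8), tolerance = 1e-6)
})

test_that("the NB test is calibrated under the null", {
  arch <- regulatory_architecture(600, q = 200, alpha = 0.05)
  sim <- simulate_expression(arch, parental_design(10), seed = 2)
  de <- nb_de_test(sim$counts, sim$meta, c("group", "mel", "cyd"))
  t1 <- mean(de$p < 0.05, na.rm = TRUE)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.09)
})

test_that("fourfold genes are recovered with little bias", {
  n <- 800; n_de <- 80
  arch <- regulatory_architecture(
    n, q = 200, cis_log2 = c(rep(2, n_de / 2), rep(-2, n_de / 2),
                             rep(0, n - n_de)),
    alpha = 0.05)
  sim <- simulate_expression(arch, parental_design(10), seed = 3)
  de <- nb_de_test(sim$counts, sim$meta, c("group", "mel", "cyd"))
  called <- de_call(de)
  expect_gt(mean(arch$gene[arch$cis_log2 != 0] %in% called), 0.9)
  bias <- mean(de$log2FC[arch$cis_log2 != 0] - arch$cis_log2[arch$cis_log2 != 0])
  expect_lt(abs(bias), 0.1)
})

test_that("swapping the contrast negates every log2 fold change", {
  arch <- regulatory_architecture(60, q = 100, cis_log2 = 1, alpha = 0.05)
  sim <- simulate_expression(arch, parental_design(5), seed = 4)
  a <- nb_de_test(sim$counts, sim$meta, c("group", "mel", "cyd"))
  b <- nb_de_test(sim$counts, sim$meta, c("group", "cyd", "mel"))
  expect_equal(a$log2FC, -b$log2FC, tolerance = 1e-8)
})

test_that("BH adjustment is monotone and untestable genes stay NA", {
  arch <- regulatory_architecture(100, q = 50, alpha = 0.05)
  sim <- simulate_expression(arch, parental_design(4), seed = 5)
  counts <- sim$counts
  counts[1, ] <- 0L
  de <- nb_de_test(counts, sim$meta, c("group", "mel", "cyd"))
  expect_true(de$untestable[1])
  expect_true(is.na(de$p[1]))
  ok <- !is.na(de$p)
  o <- order(de$p[ok])
  expect_true(all(diff(de$padj[ok][o]) >= -1e-12))
  expect_true(all(de$padj[ok] >= de$p[ok]))
  expect_true(all(de$padj[ok] <= 1))
  expect_error(nb_de_test(counts, sim$meta, c("group", "mel", "nope")),
               "absent")
})

test_that("the call rule needs both the fold change and the FDR", {
  res <- rbind(de_row("g1", log2FC = 0.9, padj = 0.01),
               de_row("g2", log2FC = 2.0, padj = 0.06),
               de_row("g3", log2FC = -1.3, padj = 0.01))
  expect_equal(de_call(res), "g3")
})

test_that("dual-reference filtering drops reversed or unconfirmed calls", {
  refA <- rbind(de_row("g1", 1.2, 0.01), de_row("g2", 1.2, 0.01),
                de_row("g3", 1.2, 0.01), de_row("g4", 1.5, 0.01))
  refB <- rbind(de_row("g1", -0.8, 0.01),  # reversal of the fold change
                de_row("g2", 1.1, 0.01),   # consistent
                de_row("g3", 0.3, 0.4))    # not called under reference B
  expect_warning(kept <- reference_bias_filter(refA, refB), "missing")
  expect_equal(kept, "g2")
})

test_that("candidate genes need the QTL interval and concordant calls", {
  coords <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                       chrom = "chr18",
                       start = c(1e5, 2e5, 3e5, 5e6),
                       end = c(1.1e5, 2.1e5, 3.1e5, 5.1e6),
                       stringsAsFactors = FALSE)
  sp <- rbind(de_row("g1", 1.5, 0.01), de_row("g2", 1.5, 0.01),
              de_row("g3", 1.5, 0.01), de_row("g4", 1.5, 0.01))
  f1 <- rbind(de_row("g1", 1.2, 0.01),   # candidate
              de_row("g2", -1.2, 0.01),  # opposite sign
              de_row("g3", 0.1, 0.9),    # not called in F1 comparison
              de_row("g4", 1.2, 0.01))   # outside the interval
  qtl <- list(chrom = "chr18", start = 0, end = 2.75e6)
  cand <- candidate_intersection(sp, f1, qtl, coords)
  expect_equal(cand$gene, "g1")
  bc3 <- rbind(de_row("g1", 1.2, 0.01))
  cand2 <- candidate_intersection(sp, f1, qtl, coords, bc3_de = bc3)
  expect_true(cand2$called_bc3)
  expect_error(candidate_intersection(sp, f1,
                                      list(chrom = "chr18", start = 5,
                                           end = 5),
                                      coords),
               "malformed")
})

test_that("log2FC estimates agree with an independent NB implementation", {
  skip_if_not_installed("DESeq2")
  n <- 150
  arch <- regulatory_architecture(
    n, q = 200, cis_log2 = rep(c(0, 1, -1), length.out = n), alpha = 0.05)
  sim <- simulate_expression(arch, parental_design(6), seed = 6)
  ours <- nb_de_test(sim$counts, sim$meta, c("group", "mel", "cyd"),
                     covariates = character(0))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      sim$counts, data.frame(group = factor(sim$meta$group,
                                            levels = c("cyd", "mel"))),
      ~ group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  expect_gt(cor(ours$log2FC, ref$log2FoldChange), 0.98)
  expect_lt(mean(abs(ours$log2FC - ref$log2FoldChange)), 0.15)
})
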