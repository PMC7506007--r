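test_that("per-site counts sum into gene totals per individual", {
  per_site <- data.frame(
    chrom = "chr18", pos = c(10, 20, 10, 20),
    gene = "g1", individual = c("i1", "i1", "i2", "i2"),
    count_mel = c(10, 20, 5, 5), count_cyd = c(5, 15, 2, 2),
    stringsAsFactors = FALSE)
  tab <- sum_allele_counts(per_site)
  expect_equal(tab$count_mel, c(30, 10))
  expect_equal(tab$count_cyd, c(20, 4))
  # a site assigned to two genes is an upstream error
  bad <- per_site
  bad$gene[2] <- "g2"
  bad$pos[2] <- 10
  expect_error(sum_allele_counts(bad), "more than one gene")
})

test_that("the paired allele test is calibrated and recovers cis effects", {
  null_arch <- regulatory_architecture(400, q = 1, cis_log2 = 0,
                                       alpha = 0.05)
  tab <- simulate_allele_counts(null_arch, n_individuals = 10, depth = 500,
                                seed = 1)
  res <- ase_test(tab)
  t1 <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(t1, 0.02)
  expect_lt(t1, 0.09)
  cis_arch <- regulatory_architecture(150, q = 1, cis_log2 = 1,
                                      alpha = 0.05)
  tabc <- simulate_allele_counts(cis_arch, n_individuals = 10, depth = 500,
                                 seed = 2)
  resc <- ase_test(tabc)
  expect_gt(mean(resc$p < 0.05 & resc$A > 0), 0.9)
  # estimated allelic imbalance recovers the architecture
  expect_lt(abs(mean(resc$A) - 1), 0.15)
})

test_that("swapping the allele labels negates A exactly", {
  arch <- regulatory_architecture(40, q = 1, cis_log2 = 0.5, alpha = 0.05)
  tab <- simulate_allele_counts(arch, n_individuals = 8, depth = 300,
                                seed = 3)
  swapped <- tab
  swapped$count_mel <- tab$count_cyd
  swapped$count_cyd <- tab$count_mel
  a <- ase_test(tab)
  b <- ase_test(swapped)
  expect_equal(a$A, -b$A, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-8)
})

test_that("individuals below the minimum total are dropped per gene", {
  tab <- data.frame(gene = "g1",
                    individual = c("i1", "i2", "i3"),
                    count_mel = c(100, 2, 120),
                    count_cyd = c(50, 1, 60), stringsAsFactors = FALSE)
  class(tab) <- c("allele_count_table", "data.frame")
  res <- ase_test(tab, min_total = 10)
  expect_equal(res$n_individuals, 2)
  # all individuals below the floor -> untestable
  low <- tab
  low$count_mel <- c(2, 2, 2); low$count_cyd <- c(1, 1, 1)
  res_low <- ase_test(low, min_total = 10)
  expect_true(res_low$untestable)
})

test_that("the paired test agrees with an exact binomial oracle", {
  # at high depth and tiny dispersion a strong allelic imbalance must be
  # detected by both the NB model and a pooled exact binomial test
  arch <- regulatory_architecture(1, q = 1, cis_log2 = 1, alpha = 0.001)
  tab <- simulate_allele_counts(arch, n_individuals = 10, depth = 2000,
                                seed = 4)
  res <- ase_test(tab)
  bt <- stats::binom.test(sum(tab$count_mel),
                          sum(tab$count_mel) + sum(tab$count_cyd), 0.5)
  expect_lt(res$p, 0.001)
  expect_lt(bt$p.value, 0.001)
  expect_lt(abs(res$A - log2(sum(tab$count_mel) / sum(tab$count_cyd))),
            0.05)
})

test_that("the assignment bias check flags systematic reassignment", {
  arch <- regulatory_architecture(300, q = 1, cis_log2 = 0, alpha = 0.02)
  tab <- simulate_allele_counts(arch, n_individuals = 10, depth = 500,
                                seed = 5)
  chk <- assignment_bias_check(tab)
  expect_lt(abs(chk$median_A), 0.05)
  expect_false(chk$flagged)
  biased <- tab
  moved <- round(0.1 * tab$count_cyd)
  biased$count_mel <- tab$count_mel + moved
  biased$count_cyd <- tab$count_cyd - moved
  chk2 <- assignment_bias_check(biased)
  expect_gt(chk2$median_A, 0)
  expect_true(chk2$flagged)
  one <- tab[tab$gene == tab$gene[1], ]
  expect_warning(chk3 <- assignment_bias_check(one), "unreliable")
  expect_true(is.na(chk3$flagged))
})

test_that("the cis/trans decision table follows the three Wald tests", {
  de <- rbind(de_row("cis", 2, 0.01, SE = 0.1),
              de_row("trans", 2, 0.01, SE = 0.1),
              de_row("mix", 2, 0.01, SE = 0.1),
              de_row("cons", 0.01, 0.9, SE = 0.1))
  ase <- rbind(ase_row("cis", 2, SE = 0.1),
               ase_row("trans", 0, SE = 0.1),
               ase_row("mix", 1, SE = 0.1),
               ase_row("cons", 0.01, SE = 0.1))
  ct <- cis_trans_classify(de, ase)
  expect_equal(ct$class[match(c("cis", "trans", "mix", "cons"), ct$gene)],
               c("cis_only", "trans_only", "cis_plus_trans", "conserved"))
  # a gene missing one input is ambiguous
  ct2 <- cis_trans_classify(de, ase[-1, ])
  expect_equal(ct2$class[ct2$gene == "cis"], "ambiguous")
})
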