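test_that("design validation catches unidentifiable inputs", {
  eff <- behaviour_effects()
  tr <- simulate_trials(eff, n_males = 40, seed = 1)
  expect_error(fit_multinomial(tr[1, ]), "< 2 males")
  tr2 <- tr
  tr2$geno_chr18 <- "cyd/cyd"
  expect_error(fit_multinomial(tr2), ">= 2 males per genotype class")
})

test_that("a strong chr18 effect is recovered with the right sign", {
  tr <- simulate_trials(strong_chr18(), n_males = 100, seed = 2)
  fit <- fit_multinomial(tr, n_draws = 600, n_warmup = 400, n_chains = 2,
                         seed = 3, check_convergence = FALSE)
  s <- fixed_effect_summary(fit)
  b18 <- s[s$parameter == "b_chr18_mel_only", ]
  expect_gt(b18$mean, 0)
  expect_gt(b18$lower, 0)  # the 95% CrI excludes zero
})

test_that("posterior predictive proportions are coherent", {
  tr <- simulate_trials(strong_chr18(), n_males = 80, seed = 4)
  fit <- fit_multinomial(tr, n_draws = 400, n_warmup = 300, n_chains = 2,
                         seed = 5, check_convergence = FALSE)
  het <- predicted_proportions(fit, c(chr1 = "cyd/cyd", chr17 = "cyd/cyd",
                                      chr18 = "cyd/melp"), seed = 6)
  hom <- predicted_proportions(fit, c(chr1 = "cyd/cyd", chr17 = "cyd/cyd",
                                      chr18 = "cyd/cyd"), seed = 6)
  expect_equal(sum(het$mean), 1, tolerance = 1e-9)
  expect_gt(het$mean[het$category == "mel_only"],
            hom$mean[hom$category == "mel_only"])
  expect_gt(het$mean[het$category == "mel_only"],
            het$mean[het$category == "cyd_only"])
  expect_error(predicted_proportions(fit, c(chr1 = "cyd/cyd",
                                            chr17 = "cyd/cyd",
                                            chr18 = "melp/melp")),
               "unseen genotype level")
  expect_error(predicted_proportions(fit, c(chr1 = "cyd/cyd")),
               "must name all model terms")
})

test_that("predicted proportions are exactly symmetric for a symmetric posterior", {
  # hand-built fit: all coefficients zero, no random-effect variance
  draws <- matrix(0, 100, 9,
                  dimnames = list(NULL, c(
                    "a_mel_only", "a_both",
                    "b_chr1_mel_only", "b_chr17_mel_only",
                    "b_chr18_mel_only", "b_chr1_both", "b_chr17_both",
                    "b_chr18_both", "sigma")))
  fit <- structure(list(draws = draws, terms = c("chr1", "chr17", "chr18"),
                        genotype_levels = c("cyd/cyd", "cyd/melp")),
                   class = "courtship_fit")
  p <- predicted_proportions(fit, c(chr1 = "cyd/cyd", chr17 = "cyd/cyd",
                                    chr18 = "cyd/cyd"), seed = 1)
  expect_equal(p$mean, rep(1 / 3, 3))
})

test_that("split R-hat flags an unconverged sampler", {
  m1 <- matrix(rnorm(200), 100, 2)
  m2 <- matrix(rnorm(200, mean = 50), 100, 2)
  r <- crosskit:::split_rhat(list(m1, m2))
  expect_true(all(r > 1.5))
  r_ok <- crosskit:::split_rhat(list(matrix(rnorm(400), 200, 2),
                                     matrix(rnorm(400), 200, 2)))
  expect_true(all(r_ok < 1.1))
})
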