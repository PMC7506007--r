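markers_40 <- data.frame(
  chrom = "chr1", pos = seq(1000, 99000, length.out = 40),
  allele_mel = "A", allele_cyd = "T", stringsAsFactors = FALSE)

geno_at_markers <- function(markers, a1, a2) {
  data.frame(chrom = markers$chrom, pos = markers$pos, a1 = a1, a2 = a2,
             stringsAsFactors = FALSE)
}

test_that("sharing fractions reflect carried alleles per window", {
  het <- geno_at_markers(markers_40, "A", "T")
  w <- window_share_fractions(het, markers_40)
  expect_equal(w$frac_mel, 1)
  expect_equal(w$frac_cyd, 1)
  expect_equal(w$n_informative, 40)
  cyd <- geno_at_markers(markers_40, "T", "T")
  w2 <- window_share_fractions(cyd, markers_40)
  expect_equal(w2$frac_mel, 0)
  expect_equal(w2$frac_cyd, 1)
  expect_error(window_share_fractions(het, markers_40, window_bp = 0),
               "positive")
})

test_that("windows at or below the informative floor are uninformative", {
  m25 <- markers_40[1:25, ]
  w <- window_share_fractions(geno_at_markers(m25, "A", "T"), m25)
  expect_true(is.na(w$frac_mel))
  w31 <- window_share_fractions(geno_at_markers(markers_40[1:31, ],
                                                "A", "T"),
                                markers_40[1:31, ])
  expect_false(is.na(w31$frac_mel))  # "more than 30" means 31 qualifies
})

test_that("window classification picks the nearest control profile", {
  prof <- function(fm, fc) data.frame(chrom = "chr1", start = 0, end = 1e5,
                                      n_informative = 40, frac_mel = fm,
                                      frac_cyd = fc, call = NA,
                                      stringsAsFactors = FALSE)
  f1 <- prof(1, 1); cy <- prof(0, 1)
  expect_equal(classify_windows(prof(1, 1), f1, cy)$call, "cyd/melp")
  expect_equal(classify_windows(prof(0.02, 0.99), f1, cy)$call, "cyd/cyd")
  expect_true(is.na(classify_windows(prof(0.5, 1), f1, cy)$call))  # tie
  # window missing from a control profile -> NA
  other <- prof(1, 1); other$start <- 2e5
  expect_true(is.na(classify_windows(other, f1, cy)$call))
})

test_that("the genome heterozygosity summary counts cyd/melp windows", {
  w <- data.frame(chrom = rep(c("chr1", "chr18"), each = 4),
                  start = rep(0:3 * 1e5, 2), end = rep(1:4 * 1e5, 2),
                  n_informative = 40, frac_mel = 0.5, frac_cyd = 1,
                  call = c("cyd/melp", "cyd/melp", "cyd/cyd", NA,
                           rep("cyd/melp", 4)),
                  stringsAsFactors = FALSE)
  expect_equal(genome_het_fraction(w, exclude_chrom = "chr18"), 2 / 3)
  all_het <- w; all_het$call <- "cyd/melp"
  expect_equal(genome_het_fraction(all_het), 1)
  all_hom <- w; all_hom$call <- "cyd/cyd"
  expect_equal(genome_het_fraction(all_hom), 0)
  w$call <- NA
  expect_error(genome_het_fraction(w), "no classified windows")
})

test_that("window calls match simulated ancestry tracts", {
  map <- default_genetic_map(n_autosomes = 3, length_bp = 5e6)
  panel <- simulate_species_panel(map, sites_per_chrom = 3000,
                                  diagnostic_frac = 0.7, seed = 1)
  markers <- panel_diagnostic_sites(panel)
  ped <- pedigree_spec(n_bc = 4, marker = list(chrom = "chr3",
                                               pos_bp = 360000))
  bc3 <- simulate_pedigree(ped, map, n = 4, seed = 2)
  names(bc3) <- paste0("bc", 1:4)
  genomes <- c(bc3, list(f1 = f1_genome(map),
                         cyd = pure_genome(map, "cyd")))
  rec <- simulate_genotype_records(genomes, panel,
                                   coverage_model(error_rate = 0.01),
                                   seed = 3)$records
  wsf <- function(sm) window_share_fractions(rec[rec$sample == sm, ],
                                             markers)
  f1p <- wsf("f1"); cyp <- wsf("cyd")
  # an error-free F1 control scores (1, 1) everywhere; 1% error shifts it
  # by at most a few markers per window
  expect_true(all(f1p$frac_mel > 0.9, na.rm = TRUE))
  hits <- 0; tot <- 0
  for (sm in names(bc3)) {
    w <- classify_windows(wsf(sm), f1p, cyp)
    mid <- pmin((w$start + w$end) / 2, 5e6 - 1)
    truth <- vapply(seq_len(nrow(w)), function(i) {
      a <- genotype_at(bc3[[sm]], w$chrom[i], mid[i])
      if (a[1] != a[2]) "cyd/melp" else "cyd/cyd"
    }, "")
    ok <- !is.na(w$call)
    hits <- hits + sum(w$call[ok] == truth[ok]); tot <- tot + sum(ok)
  }
  expect_gt(hits / tot, 0.98)
})

test_that("Z heterozygosity separates the sexes", {
  z <- function(n_het, n_hom) rbind(
    if (n_het) make_record(chrom = "chrZ", pos = seq_len(n_het),
                           a1 = "A", a2 = "T"),
    if (n_hom) make_record(chrom = "chrZ", pos = n_het + seq_len(n_hom),
                           a1 = "A", a2 = "A"))
  expect_equal(sex_from_z_heterozygosity(z(0, 200))$call, "female")
  expect_equal(sex_from_z_heterozygosity(z(8, 192))$call, "male")   # 4%
  expect_equal(sex_from_z_heterozygosity(z(4, 196))$call, "ambiguous")  # 2%
  expect_warning(out <- sex_from_z_heterozygosity(z(0, 10)),
                 "ambiguous")
  expect_equal(out$call, "ambiguous")
})
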