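test_that("RNA genotype filter applies QD/FS/DP and biallelic rules", {
  recs <- rbind(
    make_record(pos = 1, QD = 1.5, FS = 10, DP = 20),   # fails QD > 2
    make_record(pos = 2, QD = 5, FS = 10, DP = 4),      # fails strict DP > 4
    make_record(pos = 3, QD = 5, FS = 30, DP = 20),     # fails strict FS < 30
    make_record(pos = 4, alt = "T,G"),                  # multiallelic
    make_record(pos = 5, QD = NA),                      # missing field
    make_record(pos = 6, QD = 2.1, FS = 29.9, DP = 5)   # kept
  )
  kept <- filter_rna_genotypes(recs)
  expect_equal(kept$pos, 6)
  ds <- attr(kept, "drop_summary")
  expect_equal(ds$missing_field, 1)
  expect_equal(ds$not_biallelic, 1)
  expect_equal(ds$quality, 3)
})

test_that("resequencing filter uses strict DP and GQ bounds", {
  recs <- rbind(
    make_record(pos = 1, DP = 10, GQ = 60),  # DP lower bound is strict
    make_record(pos = 2, DP = 99, GQ = 31),  # kept
    make_record(pos = 3, DP = 50, GQ = 30),  # GQ bound is strict
    make_record(pos = 4, DP = 100, GQ = 60)  # DP upper bound is strict
  )
  kept <- filter_reseq_genotypes(recs)
  expect_equal(kept$pos, 2)
})

test_that("filters are idempotent", {
  map <- default_genetic_map(n_autosomes = 1, length_bp = 1e6)
  panel <- simulate_species_panel(map, sites_per_chrom = 300, seed = 1)
  out <- simulate_genotype_records(
    list(s = pure_genome(map, "mel")), panel,
    coverage_model(qd_fail_frac = 0.2, fs_fail_frac = 0.1), seed = 2)
  once <- filter_rna_genotypes(out$records)
  twice <- filter_rna_genotypes(once)
  attr(once, "drop_summary") <- attr(twice, "drop_summary") <- NULL
  expect_identical(once, twice)
})

test_that("fixed-allele calling uses a strict threshold and validates it", {
  summ <- data.frame(
    chrom = "chr1", pos = c(1, 2, 3), species = "mel",
    ref = "A", alt = "T", major_allele = "T",
    major_af = c(0.95, 0.90, 1.0), alt_af = c(0.95, 0.90, 1.0),
    n_called = 10, n_carriers = 10, stringsAsFactors = FALSE)
  fixed <- call_fixed(summ, "mel", af_threshold = 0.9)
  expect_equal(fixed$pos, c(1, 3))  # AF exactly at threshold is not fixed
  expect_error(call_fixed(summ, "mel", af_threshold = 0.5), "0.5")
  expect_error(call_fixed(summ, "mel", af_threshold = 1.1), "0.5")
})

test_that("diagnostic markers require opposite fixed alleles", {
  mel <- data.frame(chrom = "chr1", pos = c(1, 2, 3), allele = c("A", "A", "G"),
                    af = 1, stringsAsFactors = FALSE)
  cyd <- data.frame(chrom = "chr1", pos = c(1, 2), allele = c("T", "A"),
                    af = 1, stringsAsFactors = FALSE)
  mk <- diagnostic_markers(mel, cyd)
  # pos 2 fixed same allele, pos 3 fixed in one species only
  expect_equal(mk$pos, 1)
  expect_equal(mk$allele_mel, "A")
  expect_equal(mk$allele_cyd, "T")
  # symmetry: swapping the species swaps the allele columns
  mk2 <- diagnostic_markers(cyd, mel)
  expect_equal(mk2$allele_mel, mk$allele_cyd)
  expect_equal(mk2$allele_cyd, mk$allele_mel)
})

test_that("marker discovery recovers the simulator's diagnostic sites exactly", {
  map <- default_genetic_map(n_autosomes = 2, length_bp = 1e6)
  panel <- simulate_species_panel(map, sites_per_chrom = 250, seed = 3)
  genomes <- c(lapply(1:4, function(i) pure_genome(map, "mel")),
               lapply(1:4, function(i) pure_genome(map, "cyd")))
  names(genomes) <- c(paste0("mel", 1:4), paste0("cyd", 1:4))
  out <- simulate_genotype_records(genomes, panel,
                                   coverage_model(error_rate = 0), seed = 4)
  flt <- filter_rna_genotypes(out$records)
  spmap <- setNames(sub("[0-9]+$", "", names(genomes)), names(genomes))
  summ <- summarize_sites(flt, spmap)
  mk <- diagnostic_markers(call_fixed(summ, "mel"), call_fixed(summ, "cyd"))
  truth <- panel_diagnostic_sites(panel)
  # non-diagnostic shared-polymorphism sites can drift to fixation in a
  # finite panel, but every true diagnostic site must be recovered with
  # the correct alleles
  got <- merge(truth, mk, by = c("chrom", "pos"))
  expect_equal(nrow(got), nrow(truth))
  expect_true(all(got$allele_mel.x == got$allele_mel.y))
  expect_true(all(got$allele_cyd.x == got$allele_cyd.y))
})
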