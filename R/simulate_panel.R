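# Diverged species haplotype panels and noisy genotype-record simulation.

#' Simulate diverged species haplotype panels
#'
#' Builds resequencing-style haplotype panels for the two species at a set
#' of biallelic sites. A fraction of sites is diagnostic: every mel
#' haplotype carries one allele and every cyd haplotype the other (which of
#' ref/alt belongs to which species is randomised per site). Remaining
#' sites segregate at a shared frequency in both species, so they carry no
#' ancestry information.
#'
#' @param map a [genetic_map].
#' @param sites_per_chrom number of sites per chromosome.
#' @param n_haps haplotypes per species (10 diploid samples = 20).
#' @param diagnostic_frac fraction of sites fixed for opposite alleles.
#' @param seed optional integer seed.
#' @return object of class `species_panel`: `sites` data.frame (`chrom`,
#'   `pos`, `ref`, `alt`, `diagnostic`, `allele_mel`, `allele_cyd`) and 0/1
#'   haplotype matrices `haps_mel`, `haps_cyd` (sites x haplotypes;
#'   1 = alt allele).
#' @export
simulate_species_panel <- function(map, sites_per_chrom = 200, n_haps = 20,
                                   diagnostic_frac = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chroms <- map_chrom_ids(map)
  sites <- do.call(rbind, lapply(chroms, function(ch) {
    len <- map_chrom_length_bp(map, ch)
    pos <- sort(sample.int(len - 1L, sites_per_chrom))
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
  n <- nrow(sites)
  sites$ref <- sample(bases, n, replace = TRUE)
  sites$alt <- vapply(sites$ref,
                      function(r) sample(setdiff(bases, r), 1L), "")
  sites$diagnostic <- runif(n) < diagnostic_frac
  # at diagnostic sites, mel carries alt with prob 1/2, otherwise ref
  mel_has_alt <- sites$diagnostic & (runif(n) < 0.5)
  cyd_has_alt <- sites$diagnostic & !mel_has_alt
  haps_mel <- matrix(0L, n, n_haps)
  haps_cyd <- matrix(0L, n, n_haps)
  haps_mel[mel_has_alt, ] <- 1L
  haps_cyd[cyd_has_alt, ] <- 1L
  shared <- which(!sites$diagnostic)
  freq <- runif(length(shared), 0.1, 0.9)
  haps_mel[shared, ] <- rbinom(length(shared) * n_haps, 1L, freq)
  haps_cyd[shared, ] <- rbinom(length(shared) * n_haps, 1L, freq)
  sites$allele_mel <- ifelse(sites$diagnostic,
                             ifelse(mel_has_alt, sites$alt, sites$ref), NA)
  sites$allele_cyd <- ifelse(sites$diagnostic,
                             ifelse(cyd_has_alt, sites$alt, sites$ref), NA)
  structure(list(sites = sites, haps_mel = haps_mel, haps_cyd = haps_cyd,
                 n_haps = n_haps),
            class = "species_panel")
}

#' True diagnostic-marker set of a panel
#'
#' @param panel a `species_panel`.
#' @return data.frame with `chrom`, `pos`, `allele_mel`, `allele_cyd` —
#'   the simulator's ground truth against which marker recovery is scored.
#' @export
panel_diagnostic_sites <- function(panel) {
  s <- panel$sites[panel$sites$diagnostic, ]
  rownames(s) <- NULL
  s[, c("chrom", "pos", "allele_mel", "allele_cyd")]
}

#' Coverage/error model for genotype-record simulation
#'
#' @param mean_dp mean read depth (negative-binomial across records unless
#'   `dp_constant` is given).
#' @param dp_size negative-binomial size parameter of the depth
#'   distribution.
#' @param dp_constant if non-NULL, every record gets exactly this depth.
#' @param error_rate probability that a genotype call is replaced by a
#'   random different genotype.
#' @param qd_fail_frac fraction of sites drawn below the QD > 2 threshold.
#' @param fs_fail_frac fraction of sites drawn above the FS < 30 threshold.
#' @param gq_fail_frac fraction of records drawn at or below GQ = 30.
#' @return object of class `coverage_model`.
#' @export
coverage_model <- function(mean_dp = 30, dp_size = 10, dp_constant = NULL,
                           error_rate = 0, qd_fail_frac = 0,
                           fs_fail_frac = 0, gq_fail_frac = 0) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  structure(list(mean_dp = mean_dp, dp_size = dp_size,
                 dp_constant = dp_constant, error_rate = error_rate,
                 qd_fail_frac = qd_fail_frac, fs_fail_frac = fs_fail_frac,
                 gq_fail_frac = gq_fail_frac),
            class = "coverage_model")
}

# allele carried by an ancestry code at a panel site; non-diagnostic sites
# draw from the species' panel allele frequency
site_alleles_for_anc <- function(panel, site_idx, anc) {
  s <- panel$sites
  freq_mel <- rowMeans(panel$haps_mel)[site_idx]
  freq_cyd <- rowMeans(panel$haps_cyd)[site_idx]
  f <- ifelse(anc == SPECIES_CODES[["mel"]], freq_mel, freq_cyd)
  is_alt <- rbinom(length(site_idx), 1L, f) == 1L
  ifelse(is_alt, s$alt[site_idx], s$ref[site_idx])
}

#' Simulate genotype records for a set of genomes
#'
#' Produces VCF-like per-sample, per-site genotype records with quality
#' annotations: per-sample DP and GQ, per-site QD and FS (site-level INFO
#' semantics). Genotype errors replace the true call with a random
#' different genotype. Females are hemizygous on the Z and are emitted as
#' homozygous calls there.
#'
#' @param genomes named list of `hybrid_genome` objects.
#' @param panel a `species_panel`.
#' @param model a [coverage_model].
#' @param map a [genetic_map] (needed to identify the Z chromosome).
#' @param sex optional named character vector (`"male"`/`"female"`) per
#'   sample.
#' @param seed optional integer seed.
#' @return list with `records` (data.frame: sample, chrom, pos, ref, alt,
#'   a1, a2, gt, DP, GQ, QD, FS) and `truth` (error-free a1/a2 per record).
#' @export
simulate_genotype_records <- function(genomes, panel, model = coverage_model(),
                                      map = NULL, sex = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(genomes)))
    names(genomes) <- paste0("sample", seq_along(genomes))
  s <- panel$sites
  n_sites <- nrow(s)
  z_chrom <- if (!is.null(map)) map_z_chrom(map) else NA_character_
  # site-level INFO fields, shared by all samples
  qd_fail <- runif(n_sites) < model$qd_fail_frac
  QD <- ifelse(qd_fail, runif(n_sites, 0, 2), runif(n_sites, 2.5, 35))
  fs_fail <- runif(n_sites) < model$fs_fail_frac
  FS <- ifelse(fs_fail, runif(n_sites, 31, 60), runif(n_sites, 0, 25))
  bases <- c("A", "C", "G", "T")
  per_sample <- lapply(names(genomes), function(sm) {
    g <- genomes[[sm]]
    a1 <- character(n_sites); a2 <- character(n_sites)
    for (ch in unique(s$chrom)) {
      idx <- which(s$chrom == ch)
      anc <- genotype_at(g, ch, s$pos[idx])
      a1[idx] <- site_alleles_for_anc(panel, idx, anc[1, ])
      a2[idx] <- site_alleles_for_anc(panel, idx, anc[2, ])
    }
    if (!is.na(z_chrom) && !is.null(sex) &&
        identical(unname(sex[sm]), "female")) {
      zi <- s$chrom == z_chrom
      a2[zi] <- a1[zi]  # hemizygous Z emitted as homozygous
    }
    true_a1 <- a1; true_a2 <- a2
    if (model$error_rate > 0) {
      err <- which(runif(n_sites) < model$error_rate)
      for (i in err) {
        alleles <- c(s$ref[i], s$alt[i])
        repeat {
          cand <- sample(alleles, 2L, replace = TRUE)
          if (!identical(sort(cand), sort(c(a1[i], a2[i])))) break
        }
        a1[i] <- cand[1]; a2[i] <- cand[2]
      }
    }
    DP <- if (!is.null(model$dp_constant)) rep(model$dp_constant, n_sites)
          else rnbinom(n_sites, mu = model$mean_dp, size = model$dp_size)
    gq_fail <- runif(n_sites) < model$gq_fail_frac
    GQ <- ifelse(gq_fail, runif(n_sites, 0, 30), runif(n_sites, 31, 99))
    data.frame(sample = sm, chrom = s$chrom, pos = s$pos,
               ref = s$ref, alt = s$alt, a1 = a1, a2 = a2,
               gt = paste(a1, a2, sep = "/"),
               DP = as.integer(DP), GQ = round(GQ, 1), QD = round(QD, 2),
               FS = round(FS, 2),
               true_a1 = true_a1, true_a2 = true_a2,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, per_sample)
  truth <- all[, c("sample", "chrom", "pos", "true_a1", "true_a2")]
  records <- all[, c("sample", "chrom", "pos", "ref", "alt", "a1", "a2",
                     "gt", "DP", "GQ", "QD", "FS")]
  rownames(records) <- rownames(truth) <- NULL
  list(records = records, truth = truth)
}
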