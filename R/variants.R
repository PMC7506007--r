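# Genotype-record filtering and species-diagnostic marker construction.
# Records are data.frames with one row per sample x site: sample, chrom,
# pos, ref, alt (comma-separated if multiallelic), a1/a2 (called alleles),
# DP, GQ (per record) and QD, FS (site-level INFO values repeated per row).

n_alt_alleles <- function(alt) {
  ifelse(is.na(alt) | alt == "" | alt == ".", 0L,
         lengths(strsplit(alt, ",", fixed = TRUE)))
}

drop_summary <- function(reasons) {
  tab <- table(factor(reasons[reasons != "kept"]))
  as.list(tab)
}

#' Filter RNA-derived genotype records
#'
#' Hard-filter rule for genotypes called from RNA-seq reads: quality by
#' depth QD > 2, strand bias FS < 30, depth DP > 4, and exactly one
#' alternate allele (biallelic records only). Records with any required
#' field missing are dropped and counted.
#'
#' @param records genotype-record data.frame.
#' @return the kept records, with a `drop_summary` attribute (named counts
#'   of drop reasons).
#' @export
filter_rna_genotypes <- function(records) {
  reason <- rep("kept", nrow(records))
  miss <- is.na(records$QD) | is.na(records$FS) | is.na(records$DP) |
    is.na(records$alt)
  reason[miss] <- "missing_field"
  bad <- !miss & n_alt_alleles(records$alt) != 1L
  reason[bad] <- "not_biallelic"
  ok <- reason == "kept"
  fail <- ok & !(records$QD > 2 & records$FS < 30 & records$DP > 4)
  reason[fail] <- "quality"
  out <- records[reason == "kept", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_summary") <- drop_summary(reason)
  out
}

#' Filter resequencing genotype records
#'
#' Rule for whole-genome resequencing calls: biallelic, 10 < DP < 100 and
#' genotype quality GQ > 30 (all bounds strict).
#'
#' @inheritParams filter_rna_genotypes
#' @return the kept records, with a `drop_summary` attribute.
#' @export
filter_reseq_genotypes <- function(records) {
  reason <- rep("kept", nrow(records))
  miss <- is.na(records$DP) | is.na(records$GQ) | is.na(records$alt)
  reason[miss] <- "missing_field"
  bad <- !miss & n_alt_alleles(records$alt) != 1L
  reason[bad] <- "not_biallelic"
  ok <- reason == "kept"
  fail <- ok & !(records$DP > 10 & records$DP < 100 & records$GQ > 30)
  reason[fail] <- "quality"
  out <- records[reason == "kept", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_summary") <- drop_summary(reason)
  out
}

#' Per-site, per-species allele summaries
#'
#' Computes, for each site and species, the frequency of the major allele
#' over called alleles, the number of samples called, and the number of
#' samples carrying at least one copy of the alternate allele. Missing
#' genotypes are excluded from the denominator.
#'
#' @param records filtered genotype records (`a1`, `a2` columns).
#' @param sample_species named character vector mapping sample id to
#'   species (`"mel"`/`"cyd"`).
#' @return data.frame: chrom, pos, species, ref, alt, major_allele,
#'   major_af, alt_af, n_called, n_carriers.
#' @export
summarize_sites <- function(records, sample_species) {
  records$species <- unname(sample_species[records$sample])
  if (anyNA(records$species)) stop("samples missing from sample_species map")
  key <- interaction(records$chrom, records$pos, records$species,
                     drop = TRUE)
  pieces <- lapply(split(records, key), function(r) {
    alleles <- c(r$a1, r$a2)
    called <- !is.na(alleles) & alleles != "."
    alleles <- alleles[called]
    tab <- sort(table(alleles), decreasing = TRUE)
    carrier <- !is.na(r$a1) & (r$a1 == r$alt[1] | r$a2 == r$alt[1])
    data.frame(chrom = r$chrom[1], pos = r$pos[1], species = r$species[1],
               ref = r$ref[1], alt = r$alt[1],
               major_allele = names(tab)[1],
               major_af = as.numeric(tab[1]) / length(alleles),
               alt_af = sum(alleles == r$alt[1]) / length(alleles),
               n_called = sum(!is.na(r$a1)),
               n_carriers = sum(carrier),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$chrom, out$pos, out$species), ]
  rownames(out) <- NULL
  out
}

#' Call species-fixed alleles
#'
#' A site is called fixed (treated as homozygous) in a species when the
#' major-allele frequency exceeds `af_threshold`. Indels are excluded
#' (alleles longer than one base).
#'
#' @param summaries output of [summarize_sites].
#' @param species which species to call.
#' @param af_threshold frequency threshold, must lie in (0.5, 1]; the
#'   comparison is strict (AF = threshold is not fixed).
#' @return data.frame: chrom, pos, allele (the fixed allele), af.
#' @export
call_fixed <- function(summaries, species, af_threshold = 0.9) {
  if (af_threshold <= 0.5 || af_threshold > 1)
    stop("af_threshold must be in (0.5, 1]")
  s <- summaries[summaries$species == species, ]
  snv <- nchar(s$ref) == 1L & nchar(s$alt) == 1L
  s <- s[snv & s$major_af > af_threshold, ]
  out <- data.frame(chrom = s$chrom, pos = s$pos, allele = s$major_allele,
                    af = s$major_af, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build species-diagnostic markers
#'
#' Sites fixed in both species but for different alleles.
#'
#' @param fixed_mel,fixed_cyd outputs of [call_fixed] for the two species.
#' @return data.frame: chrom, pos, allele_mel, allele_cyd.
#' @export
diagnostic_markers <- function(fixed_mel, fixed_cyd) {
  m <- merge(fixed_mel[, c("chrom", "pos", "allele")],
             fixed_cyd[, c("chrom", "pos", "allele")],
             by = c("chrom", "pos"), suffixes = c("_mel", "_cyd"))
  m <- m[m$allele_mel != m$allele_cyd, ]
  m <- m[order(m$chrom, m$pos), ]
  rownames(m) <- NULL
  m
}
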