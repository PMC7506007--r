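# Windowed inference of hybrid genome composition from diagnostic-variant
# sharing, and pupal sexing from Z-linked heterozygosity.

#' Window-wise diagnostic-variant sharing fractions
#'
#' Tiles each chromosome into non-overlapping windows (0-based half-open,
#' from position 0) and computes, per window, the fraction of diagnostic
#' markers at which the sample carries at least one mel allele
#' (`frac_mel`) and at least one cyd allele (`frac_cyd`). A heterozygous
#' (cyd/melp) region therefore scores close to (1, 1) and a homozygous
#' cyd/cyd region close to (0, 1). Windows with `min_informative` markers
#' or fewer are reported but flagged uninformative (call `NA` downstream);
#' the informative rule is strict ("more than 30 variants" by default).
#'
#' @param sample_genotypes data.frame of one sample's filtered genotypes
#'   with columns `chrom`, `pos`, `a1`, `a2`.
#' @param markers diagnostic-marker data.frame (`chrom`, `pos`,
#'   `allele_mel`, `allele_cyd`), sorted by position.
#' @param window_bp window size in bp (> 0).
#' @param min_informative windows with `n_informative` at or below this
#'   count are uninformative.
#' @return data.frame of ancestry windows: chrom, start, end,
#'   n_informative, frac_mel, frac_cyd, call (all `NA_character_` here;
#'   assigned by [classify_windows]).
#' @export
window_share_fractions <- function(sample_genotypes, markers,
                                   window_bp = 100000,
                                   min_informative = 30) {
  if (window_bp <= 0) stop("window_bp must be positive")
  g <- merge(markers, sample_genotypes[, c("chrom", "pos", "a1", "a2")],
             by = c("chrom", "pos"))
  g <- g[!is.na(g$a1) & !is.na(g$a2), ]
  g$carries_mel <- g$a1 == g$allele_mel | g$a2 == g$allele_mel
  g$carries_cyd <- g$a1 == g$allele_cyd | g$a2 == g$allele_cyd
  g$start <- (g$pos %/% window_bp) * window_bp
  key <- paste(g$chrom, g$start)
  agg <- do.call(rbind, lapply(split(g, key), function(w) {
    data.frame(chrom = w$chrom[1], start = w$start[1],
               end = w$start[1] + window_bp,
               n_informative = nrow(w),
               frac_mel = mean(w$carries_mel),
               frac_cyd = mean(w$carries_cyd),
               stringsAsFactors = FALSE)
  }))
  agg$frac_mel[agg$n_informative <= min_informative] <- NA_real_
  agg$frac_cyd[agg$n_informative <= min_informative] <- NA_real_
  agg$call <- NA_character_
  agg <- agg[order(agg$chrom, agg$start), ]
  rownames(agg) <- NULL
  agg
}

#' Classify ancestry windows against control profiles
#'
#' Assigns each eligible window the label of the nearest control profile
#' in Euclidean distance on (frac_mel, frac_cyd): `"cyd/melp"` if nearer
#' the F1 control (heterozygous everywhere), `"cyd/cyd"` if nearer the
#' pure-cyd control. Ties, uninformative windows and windows missing from
#' a control get `NA`.
#'
#' @param windows output of [window_share_fractions] for the test sample.
#' @param f1_profile,cydno_profile same, for an F1 hybrid and a pure cyd
#'   individual genotyped the same way. Alternatively fixed profiles can
#'   be supplied as single rows with `frac_mel`/`frac_cyd` and no
#'   chrom/start (recycled to every window).
#' @return `windows` with the `call` column filled in.
#' @export
classify_windows <- function(windows, f1_profile, cydno_profile) {
  lookup <- function(profile) {
    if (!is.null(profile$chrom)) {
      i <- match(paste(windows$chrom, windows$start),
                 paste(profile$chrom, profile$start))
      cbind(profile$frac_mel[i], profile$frac_cyd[i])
    } else {
      cbind(rep(profile$frac_mel, nrow(windows)),
            rep(profile$frac_cyd, nrow(windows)))
    }
  }
  f1 <- lookup(f1_profile)
  cy <- lookup(cydno_profile)
  x <- cbind(windows$frac_mel, windows$frac_cyd)
  d_f1 <- sqrt(rowSums((x - f1)^2))
  d_cy <- sqrt(rowSums((x - cy)^2))
  call <- ifelse(d_f1 < d_cy, "cyd/melp",
          ifelse(d_cy < d_f1, "cyd/cyd", NA_character_))
  call[is.na(d_f1) | is.na(d_cy)] <- NA_character_
  windows$call <- call
  windows
}

#' Genome-wide heterozygous fraction from window calls
#'
#' Proportion of non-NA windows called heterozygous (cyd/melp), excluding
#' the stated chromosome (typically the one under selection in the cross).
#'
#' @param windows classified windows (from [classify_windows]).
#' @param exclude_chrom chromosome ids to exclude.
#' @return numeric scalar.
#' @export
genome_het_fraction <- function(windows, exclude_chrom = NULL) {
  w <- windows[!(windows$chrom %in% exclude_chrom) & !is.na(windows$call), ]
  if (nrow(w) == 0) stop("no classified windows outside excluded chromosome")
  mean(w$call == "cyd/melp")
}

#' Sex a sample from Z-linked heterozygosity
#'
#' ZZ males can be heterozygous at Z-linked sites whereas ZW females are
#' hemizygous and so appear ~0% heterozygous — in practice males sit an
#' order of magnitude above the female level. The call is `"female"` when
#' the heterozygous proportion is below `threshold`, `"male"` when it is
#' above the geometric midpoint of the order-of-magnitude guard band
#' (`threshold * sqrt(10)`), and `"ambiguous"` in between (or when fewer
#' than `min_sites` biallelic Z-linked calls are available, with a
#' warning).
#'
#' @param z_records data.frame of one sample's biallelic genotype calls
#'   on the Z chromosome (`a1`, `a2`).
#' @param sample sample id for the output.
#' @param threshold female/male guard band lower edge (default 1%).
#' @param min_sites minimum number of usable calls.
#' @return data.frame: sample, n_sites, z_het_proportion, call.
#' @export
sex_from_z_heterozygosity <- function(z_records, sample = "sample",
                                      threshold = 0.01, min_sites = 50) {
  ok <- !is.na(z_records$a1) & !is.na(z_records$a2)
  n <- sum(ok)
  if (n < min_sites) {
    warning("only ", n, " usable Z-linked calls; sex call ambiguous")
    return(data.frame(sample = sample, n_sites = n,
                      z_het_proportion = NA_real_, call = "ambiguous",
                      stringsAsFactors = FALSE))
  }
  p <- mean(z_records$a1[ok] != z_records$a2[ok])
  call <- if (p < threshold) "female"
          else if (p >= sqrt(10) * threshold) "male"
          else "ambiguous"
  data.frame(sample = sample, n_sites = n, z_het_proportion = p,
             call = call, stringsAsFactors = FALSE)
}
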