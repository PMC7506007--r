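# ABBA-BABA D and the fd admixture-proportion statistic in sliding
# windows, from population derived-allele frequencies for the quartet
# (((P1, P2), P3), O).

#' Per-site ABBA/BABA components
#'
#' Frequency-based components: ABBA = (1-p1) p2 p3 (1-pO),
#' BABA = p1 (1-p2) p3 (1-pO). The donor ("dynamic denominator") versions
#' substitute pD = max(p2, p3) for both p2 and p3, giving the value the
#' numerator would take if the donor population had donated at maximal
#' rate.
#'
#' @param p1,p2,p3,pO derived-allele frequencies in [0, 1] (vectorized).
#' @return data.frame: abba, baba, abba_d, baba_d.
#' @export
site_components <- function(p1, p2, p3, pO) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1),
            all(p3 >= 0 & p3 <= 1), all(pO >= 0 & pO <= 1))
  pD <- pmax(p2, p3)
  data.frame(
    abba = (1 - p1) * p2 * p3 * (1 - pO),
    baba = p1 * (1 - p2) * p3 * (1 - pO),
    abba_d = (1 - p1) * pD * pD * (1 - pO),
    baba_d = p1 * (1 - pD) * pD * (1 - pO)
  )
}

#' fd admixture proportion in sliding windows
#'
#' Windows slide along each chromosome (`step_bp` <= `window_bp`,
#' overlapping by default). Per window,
#' D = sum(ABBA - BABA) / sum(ABBA + BABA) and
#' fd = sum(ABBA - BABA) / sum(ABBA_D - BABA_D). fd is only defined for
#' windows with evidence of shared derived alleles: it is `NA` when
#' D <= 0, when the denominator is <= 0, or when the window holds fewer
#' than `min_sites` sites. Sites where the outgroup frequency exceeds 0.5
#' are repolarized (p -> 1 - p for all populations) so the outgroup
#' carries the ancestral allele.
#'
#' @param freqs data.frame: chrom, pos, p1, p2, p3, pO.
#' @param window_bp window size (bp).
#' @param step_bp step between window starts; default `window_bp / 5`.
#' @param min_sites minimum usable sites per window.
#' @return data.frame: chrom, start, end, n_sites, D, fd.
#' @export
fd_windows <- function(freqs, window_bp = 100000, step_bp = window_bp / 5,
                       min_sites = 100) {
  if (nrow(freqs) == 0) stop("empty frequency table")
  if (step_bp <= 0 || window_bp < step_bp)
    stop("need window_bp >= step_bp > 0")
  repol <- freqs$pO > 0.5
  for (cl in c("p1", "p2", "p3", "pO"))
    freqs[[cl]][repol] <- 1 - freqs[[cl]][repol]
  comp <- site_components(freqs$p1, freqs$p2, freqs$p3, freqs$pO)
  out <- lapply(unique(freqs$chrom), function(ch) {
    i <- freqs$chrom == ch
    pos <- freqs$pos[i]
    cc <- comp[i, ]
    starts <- seq(0, max(pos), by = step_bp)
    do.call(rbind, lapply(starts, function(s) {
      j <- pos >= s & pos < s + window_bp
      n <- sum(j)
      num <- sum(cc$abba[j] - cc$baba[j])
      den_d <- sum(cc$abba_d[j] - cc$baba_d[j])
      tot <- sum(cc$abba[j] + cc$baba[j])
      D <- if (tot > 0) num / tot else NA_real_
      fd <- if (n >= min_sites && !is.na(D) && D > 0 && den_d > 0)
        num / den_d else NA_real_
      data.frame(chrom = ch, start = s, end = s + window_bp, n_sites = n,
                 D = D, fd = fd, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a population frequency table
#'
#' Demonstration input for [fd_windows]: sites with independent symmetric
#' P2/P3 frequencies (the null of no introgression) except inside optional
#' admixed regions where a fraction of sites share the derived allele
#' between P2 and P3 (p2 = p3).
#'
#' @param n_sites sites per chromosome.
#' @param chrom_length chromosome length (bp).
#' @param chroms chromosome ids.
#' @param admixed optional data.frame (chrom, start, end, rate) of regions
#'   where sites carry shared derived alleles at the given rate.
#' @param seed optional integer seed.
#' @return data.frame: chrom, pos, p1, p2, p3, pO.
#' @export
simulate_freq_table <- function(n_sites = 5000, chrom_length = 1e6,
                                chroms = "chr18", admixed = NULL,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- sort(sample.int(chrom_length, n_sites))
    p1 <- rbeta(n_sites, 0.5, 3)
    p2 <- rbeta(n_sites, 0.5, 3)
    p3 <- rbeta(n_sites, 0.8, 0.8)
    pO <- rep(0, n_sites)
    if (!is.null(admixed)) {
      for (k in which(admixed$chrom == ch)) {
        in_reg <- pos >= admixed$start[k] & pos < admixed$end[k]
        shared <- in_reg & runif(n_sites) < admixed$rate[k]
        p2[shared] <- p3[shared]
      }
    }
    data.frame(chrom = ch, pos = pos, p1 = p1, p2 = p2, p3 = p3, pO = pO,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
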