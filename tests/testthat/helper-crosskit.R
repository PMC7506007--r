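# Shared fixtures, built in code.

# one-chromosome map for recombination tests
two_locus_map <- function(length_cM = 50, length_bp = 1e6) {
  genetic_map(data.frame(chrom = "chrA", length_bp = length_bp,
                         length_cM = length_cM, is_z = FALSE))
}

# minimal genotype record row
make_record <- function(sample = "s1", chrom = "chr1", pos = 100,
                        ref = "A", alt = "T", a1 = "A", a2 = "T",
                        DP = 20, GQ = 60, QD = 10, FS = 5) {
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref,
             alt = alt, a1 = a1, a2 = a2, gt = paste(a1, a2, sep = "/"),
             DP = DP, GQ = GQ, QD = QD, FS = FS, stringsAsFactors = FALSE)
}

# recombinant-gamete fraction between two loci over n meioses
recombinant_fraction <- function(map, chrom, bp1, bp2, n, parent = NULL,
                                 seed = 1) {
  if (is.null(parent)) parent <- f1_genome(map)
  set.seed(seed)
  rec <- 0L
  for (i in seq_len(n)) {
    g <- simulate_meiosis(parent, map)
    anc <- crosskit:::tract_anc_at(g[[chrom]], c(bp1, bp2))
    if (anc[1] != anc[2]) rec <- rec + 1L
  }
  rec / n
}

# behavioural architecture with a strong chr18 effect on mel-only initiation
strong_chr18 <- function() behaviour_effects(
  beta = matrix(c(0, 0, 1.5, 0, 0, 0), 3, 2,
                dimnames = list(c("chr1", "chr17", "chr18"),
                                c("mel_only", "both"))),
  sigma_male = 0.5)

# synthetic DE/ASE result rows with exact values, for rule-level tests
de_row <- function(gene, log2FC, padj, p = padj / 2, SE = 0.1) {
  data.frame(gene = gene, baseMean = 100, log2FC = log2FC, SE = SE,
             stat = log2FC / SE, p = p, padj = padj,
             called = NA, untestable = FALSE, stringsAsFactors = FALSE)
}

ase_row <- function(gene, A, SE = 0.05, p = 2 * pnorm(-abs(A / SE))) {
  data.frame(gene = gene, A = A, SE = SE, p = p, n_individuals = 10,
             called = NA, untestable = FALSE, stringsAsFactors = FALSE)
}
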