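# Fixed protein-coding substitutions between the species: recurrence and
# validation filters, codon effect classification, and screening by
# externally computed PROVEAN scores (scores are consumed, never computed).

#' Identify fixed coding substitutions
#'
#' Cross-validates RNA-derived variant calls against genome resequencing:
#' keeps variants with alternate-allele frequency > `af_threshold` and at
#' least `min_carriers` carrier individuals in the RNA set of a species,
#' that were also called in at least `min_reseq_called` of the
#' resequencing samples of that species, restricted to coding (CDS)
#' intervals. Variants falling in no CDS interval are skipped with a
#' warning.
#'
#' @param rna_summaries,reseq_summaries outputs of [summarize_sites] for
#'   the RNA-seq and resequencing call sets (one species).
#' @param cds CDS annotation data.frame: chrom, start, end (1-based
#'   inclusive), strand, gene, frame.
#' @param af_threshold RNA alternate-allele frequency threshold (strict >).
#' @param min_carriers minimum RNA carrier individuals (>=).
#' @param min_reseq_called minimum resequencing samples in which the site
#'   was called (>=).
#' @return data.frame: chrom, pos, gene, ref, alt, alt_af, n_carriers,
#'   n_reseq_called.
#' @export
fixed_coding_substitutions <- function(rna_summaries, reseq_summaries, cds,
                                       af_threshold = 0.8, min_carriers = 7,
                                       min_reseq_called = 8) {
  r <- rna_summaries[rna_summaries$alt_af > af_threshold &
                       rna_summaries$n_carriers >= min_carriers, ]
  key_reseq <- paste(reseq_summaries$chrom, reseq_summaries$pos)
  r$n_reseq_called <- reseq_summaries$n_called[
    match(paste(r$chrom, r$pos), key_reseq)]
  r <- r[!is.na(r$n_reseq_called) & r$n_reseq_called >= min_reseq_called, ]
  if (nrow(r) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      gene = character(0), ref = character(0),
                      alt = character(0), alt_af = numeric(0),
                      n_carriers = integer(0), n_reseq_called = integer(0)))
  gene <- rep(NA_character_, nrow(r))
  for (i in seq_len(nrow(r))) {
    hit <- which(cds$chrom == r$chrom[i] & cds$start <= r$pos[i] &
                   cds$end >= r$pos[i])
    if (length(hit)) gene[i] <- cds$gene[hit[1]]
  }
  if (anyNA(gene))
    warning(sum(is.na(gene)), " variant(s) outside annotated CDS skipped")
  r$gene <- gene
  r <- r[!is.na(gene), c("chrom", "pos", "gene", "ref", "alt", "alt_af",
                         "n_carriers", "n_reseq_called")]
  rownames(r) <- NULL
  r
}

#' Classify the coding effect of a codon substitution
#'
#' Standard genetic-code translation of the reference and alternate
#' codons. Codons containing characters outside A/C/G/T (N, gaps) are an
#' error.
#'
#' @param ref_codon,alt_codon length-3 codons (character vectors are
#'   classified elementwise).
#' @return character vector with values `"synonymous"`, `"missense"`,
#'   `"stop_gained"` or `"stop_lost"`.
#' @export
classify_coding_effect <- function(ref_codon, alt_codon) {
  code <- Biostrings::GENETIC_CODE
  chk <- function(x) {
    if (any(nchar(x) != 3) ||
        any(!grepl("^[ACGT]{3}$", x)))
      stop("codons must be length 3 over A/C/G/T")
  }
  chk(ref_codon); chk(alt_codon)
  aa_ref <- unname(code[ref_codon])
  aa_alt <- unname(code[alt_codon])
  out <- ifelse(aa_ref == aa_alt, "synonymous",
         ifelse(aa_alt == "*", "stop_gained",
         ifelse(aa_ref == "*", "stop_lost", "missense")))
  out
}

#' Extract the reference and alternate codon at a substitution
#'
#' Strand-aware codon lookup: on the minus strand the codon is read from
#' the reverse complement. Coordinates are 1-based inclusive.
#'
#' @param refseq named character vector of chromosome sequences.
#' @param cds_row one row of the CDS annotation (chrom, start, end,
#'   strand, frame).
#' @param pos substitution position (1-based).
#' @param alt alternate base (on the plus strand).
#' @return list with `ref_codon`, `alt_codon`, `codon_index` (1-based
#'   within the CDS).
#' @export
codon_at <- function(refseq, cds_row, pos, alt) {
  seq <- refseq[[cds_row$chrom]]
  if (pos < cds_row$start || pos > cds_row$end)
    stop("position outside CDS interval")
  cds_seq <- substr(seq, cds_row$start, cds_row$end)
  off <- pos - cds_row$start + 1L  # 1-based within plus-strand CDS
  alt_seq <- cds_seq
  substr(alt_seq, off, off) <- alt
  if (identical(cds_row$strand, "-")) {
    cds_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cds_seq)))
    alt_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(alt_seq)))
    off <- nchar(cds_seq) - off + 1L
  }
  frame <- if (is.null(cds_row$frame) || is.na(cds_row$frame)) 0L
           else as.integer(cds_row$frame)
  idx <- (off - 1L - frame) %/% 3L + 1L
  s <- frame + (idx - 1L) * 3L + 1L
  list(ref_codon = substr(cds_seq, s, s + 2L),
       alt_codon = substr(alt_seq, s, s + 2L),
       codon_index = idx)
}

#' Screen substitutions by PROVEAN score
#'
#' Keeps missense and stop substitutions with an externally computed
#' PROVEAN score strictly below `threshold` (default -2.5, the suggested
#' cutoff for a non-neutral effect on protein function). Substitutions
#' without a score are excluded and counted in a warning.
#'
#' @param subs data.frame with columns `effect` and `provean_score`.
#' @param threshold score cutoff (strict <).
#' @return the retained rows.
#' @export
provean_filter <- function(subs, threshold = -2.5) {
  eligible <- subs$effect %in% c("missense", "stop_gained", "stop_lost")
  unscored <- eligible & is.na(subs$provean_score)
  if (any(unscored))
    warning(sum(unscored), " unscored substitution(s) excluded")
  keep <- eligible & !is.na(subs$provean_score) &
    subs$provean_score < threshold
  out <- subs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
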