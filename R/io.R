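# Standard-format I/O. TSV is the canonical interchange; genotype records
# are also emitted as a minimal VCF v4.2 dialect (FORMAT GT:DP:GQ, site
# INFO keys QD and FS) and read back via vcfR. Coordinates: VCF and the
# CDS annotation are 1-based inclusive, BED intervals 0-based half-open.

#' Write / read a generic TSV table
#'
#' @param x data.frame.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write genotype records as a minimal VCF
#'
#' Multi-sample VCF v4.2 with INFO keys QD and FS (site-level) and
#' per-sample GT:DP:GQ. Genotypes are encoded against the site's ref/alt
#' alleles; alleles not matching either are emitted as missing.
#'
#' @param records genotype-record data.frame (see
#'   [simulate_genotype_records]).
#' @param path output path (plain text).
#' @export
write_records_vcf <- function(records, path) {
  samples <- sort(unique(records$sample))
  sites <- unique(records[, c("chrom", "pos", "ref", "alt", "QD", "FS")])
  sites <- sites[order(sites$chrom, sites$pos), ]
  key <- paste(records$chrom, records$pos)
  skey <- paste(sites$chrom, sites$pos)
  gt_code <- function(a, ref, alt) {
    ifelse(is.na(a), ".", ifelse(a == ref, "0", ifelse(a == alt, "1", ".")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Strand bias (phred)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  rec_by_site <- split(records, key)
  lines <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    r <- rec_by_site[[paste(s$chrom, s$pos)]]
    cells <- vapply(samples, function(sm) {
      rr <- r[r$sample == sm, ]
      if (nrow(rr) == 0) return("./.:.:.")
      paste0(gt_code(rr$a1[1], s$ref, s$alt), "/",
             gt_code(rr$a2[1], s$ref, s$alt), ":",
             rr$DP[1], ":", round(rr$GQ[1]))
    }, "")
    paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
            sprintf("QD=%s;FS=%s", s$QD, s$FS), "GT:DP:GQ", cells),
          collapse = "\t")
  }, "")
  writeLines(lines, con)
  invisible(path)
}

#' Read genotype records from a VCF
#'
#' Parses a (minimal-dialect) VCF via the vcfR package back into the long
#' record data.frame used by the filters.
#'
#' @param path VCF path.
#' @return genotype-record data.frame: sample, chrom, pos, ref, alt, a1,
#'   a2, gt, DP, GQ, QD, FS.
#' @export
read_records_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  qd <- as.numeric(vcfR::extract.info(v, "QD"))
  fs <- as.numeric(vcfR::extract.info(v, "FS"))
  gt <- vcfR::extract.gt(v, "GT")
  dp <- vcfR::extract.gt(v, "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, "GQ", as.numeric = TRUE)
  samples <- colnames(gt)
  out <- do.call(rbind, lapply(seq_along(samples), function(j) {
    parts <- strsplit(ifelse(is.na(gt[, j]), "./.", gt[, j]), "[/|]")
    idx1 <- vapply(parts, `[`, "", 1)
    idx2 <- vapply(parts, function(p) if (length(p) > 1) p[2] else ".", "")
    decode <- function(idx) ifelse(idx == "0", fix$REF,
                            ifelse(idx == "1", fix$ALT, NA))
    a1 <- decode(idx1); a2 <- decode(idx2)
    data.frame(sample = samples[j], chrom = fix$CHROM,
               pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
               a1 = a1, a2 = a2,
               gt = ifelse(is.na(a1) | is.na(a2), NA,
                           paste(a1, a2, sep = "/")),
               DP = as.integer(dp[, j]), GQ = as.numeric(gq[, j]),
               QD = qd, FS = fs, stringsAsFactors = FALSE)
  }))
  out <- out[order(out$sample, out$chrom, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Read a BED-like interval file (0-based half-open)
#'
#' @param path path to a headerless BED-like TSV (chrom, start, end, and
#'   optional further columns named by `extra`).
#' @param extra names of additional columns.
#' @return data.frame.
#' @export
read_bed <- function(path, extra = character(0)) {
  x <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  names(x)[seq_len(min(3 + length(extra), ncol(x)))] <-
    c("chrom", "start", "end", extra)[seq_len(min(3 + length(extra),
                                                  ncol(x)))]
  x
}

#' Read a CDS annotation (1-based inclusive intervals)
#'
#' @param path TSV with header: chrom, start, end, strand, gene, frame.
#' @return data.frame.
#' @export
read_cds_annotation <- function(path) {
  x <- read_tsv_table(path)
  need <- c("chrom", "start", "end", "strand", "gene")
  if (!all(need %in% names(x)))
    stop("CDS annotation must have columns: ", paste(need, collapse = ", "))
  if (is.null(x$frame)) x$frame <- 0L
  x
}

#' Write / read a count matrix as TSV
#'
#' Genes in rows (first column `gene`), samples in columns.
#'
#' @param counts integer matrix.
#' @param path file path.
#' @return `read_counts` returns an integer matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write_tsv_table(df, path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene
  m
}

#' Read a courtship trial table
#'
#' Loads a trial TSV (male, geno_chr1, geno_chr17, geno_chr18,
#' n_cyd_only, n_mel_only, n_both) and applies the exclusion rule: males
#' that did not initiate courtship in any trial are removed (and the
#' removal logged).
#'
#' @param path TSV path.
#' @param pool_melp treat any genotype containing a mel allele
#'   (e.g. "melp/melp") as "cyd/melp".
#' @return `trial_table` data.frame.
#' @export
read_trials <- function(path, pool_melp = FALSE) {
  x <- read_tsv_table(path)
  for (cl in c("geno_chr1", "geno_chr17", "geno_chr18")) {
    if (pool_melp)
      x[[cl]] <- ifelse(grepl("melp", x[[cl]]), "cyd/melp", "cyd/cyd")
  }
  x$n_trials_responding <- x$n_cyd_only + x$n_mel_only + x$n_both
  drop <- x$n_trials_responding == 0
  if (any(drop))
    message("excluding ", sum(drop),
            " male(s) with no courtship initiation in any trial")
  x <- x[!drop, , drop = FALSE]
  x$excluded <- FALSE
  rownames(x) <- NULL
  class(x) <- c("trial_table", "data.frame")
  x
}

#' Write a JSON summary
#'
#' @param x list to serialize.
#' @param path output path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
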