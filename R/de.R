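# Simplified negative-binomial differential expression: median-of-ratios
# normalization, per-gene moment dispersion with a small-sample floor,
# NB log-linear model with a Wald-type test on the contrast coefficient,
# and the twofold + FDR 5% call rule.

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples, using only genes with nonzero
#' counts in every sample. If no such gene exists, an error advises the
#' pseudo-reference fallback (`fallback = TRUE`), which uses the geometric
#' mean over positive counts only and takes the per-sample median over
#' genes where that sample's count is positive.
#'
#' @param counts integer matrix, genes x samples.
#' @param fallback use the positive-count pseudo-reference.
#' @return named numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts, fallback = FALSE) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  logc <- log(counts)
  if (!fallback) {
    use <- rowSums(counts > 0) == ncol(counts)
    if (!any(use))
      stop("no gene has nonzero counts in all samples; ",
           "use fallback = TRUE for the pseudo-reference fallback")
    loggeo <- rowMeans(logc[use, , drop = FALSE])
    sf <- apply(logc[use, , drop = FALSE], 2,
                function(x) exp(median(x - loggeo)))
  } else {
    loggeo <- apply(logc, 1, function(x) mean(x[is.finite(x)]))
    sf <- vapply(seq_len(ncol(counts)), function(j) {
      r <- logc[, j] - loggeo
      exp(median(r[is.finite(r)]))
    }, 0)
    names(sf) <- colnames(counts)
  }
  sf
}

# Cameron-Trivedi moment estimator of NB dispersion from a Poisson fit
moment_dispersion <- function(y, mu, n_param, floor = 1e-8) {
  df <- max(length(y) - n_param, 1)
  a <- sum((y - mu)^2 - mu) / sum(mu^2) * length(y) / df
  max(a, floor)
}

#' Negative-binomial differential expression test
#'
#' Per gene: a preliminary Poisson fit gives a method-of-moments
#' dispersion estimate (floored at `disp_floor`); the NB log-linear model
#' `count ~ contrast + covariates` with log size-factor offsets is then
#' fit at that dispersion, and the contrast coefficient is tested with a
#' Wald statistic. By default the statistic is referred to a t
#' distribution on the residual degrees of freedom with a Pearson
#' dispersion factor (quasi-likelihood flavour, better calibrated in
#' small samples); `test = "wald_normal"` gives the plain
#' observed-information normal-reference Wald test. All-zero genes are
#' flagged untestable (`p = NA`).
#'
#' @param counts integer matrix, genes x samples.
#' @param meta data.frame of sample metadata, rows matching columns of
#'   `counts`.
#' @param contrast length-3 character: variable name, numerator level,
#'   denominator level. Positive log2FC means higher in the numerator.
#' @param covariates metadata columns entered as fixed covariates
#'   (silently skipped when absent or constant).
#' @param sf size factors; default median-of-ratios with pseudo-reference
#'   fallback.
#' @param test `"ql_t"` (default) or `"wald_normal"`.
#' @param disp_floor dispersion floor.
#' @return data.frame: gene, baseMean, log2FC, SE, stat, p, padj, called
#'   (by the default twofold + FDR 5% rule), untestable.
#' @export
nb_de_test <- function(counts, meta, contrast,
                       covariates = c("sex", "batch"), sf = NULL,
                       test = c("ql_t", "wald_normal"),
                       disp_floor = 1e-8) {
  test <- match.arg(test)
  counts <- as.matrix(counts)
  stopifnot(length(contrast) == 3, contrast[1] %in% names(meta))
  grp <- meta[[contrast[1]]]
  if (!all(contrast[2:3] %in% grp))
    stop("contrast level absent from metadata: ",
         paste(setdiff(contrast[2:3], grp), collapse = ", "))
  keep <- grp %in% contrast[2:3]
  counts <- counts[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  grp <- factor(meta[[contrast[1]]], levels = c(contrast[3], contrast[2]))
  if (min(table(grp)) < 2) stop("need >= 2 samples per contrast level")
  mm <- data.frame(.group = grp)
  for (cv in covariates) {
    if (cv %in% names(meta) && length(unique(meta[[cv]])) > 1)
      mm[[cv]] <- factor(meta[[cv]])
  }
  X <- stats::model.matrix(~ ., mm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))  # drop aliased covariate columns
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  coef_idx <- which(colnames(X) == paste0(".group", contrast[2]))
  if (length(coef_idx) != 1)
    stop("contrast coefficient aliased with covariates")
  if (is.null(sf)) sf <- size_factors(counts, fallback = TRUE)
  off <- log(sf)
  n_par <- ncol(X)
  res <- data.frame(gene = rownames(counts), baseMean = NA_real_,
                    log2FC = NA_real_, SE = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_, called = FALSE,
                    untestable = FALSE, stringsAsFactors = FALSE)
  for (g in seq_len(nrow(counts))) {
    y <- counts[g, ]
    res$baseMean[g] <- mean(y / sf)
    if (all(y == 0)) { res$untestable[g] <- TRUE; next }
    pois <- try(glm.fit(X, y, family = stats::poisson(), offset = off),
                silent = TRUE)
    if (inherits(pois, "try-error")) { res$untestable[g] <- TRUE; next }
    alpha <- moment_dispersion(y, pois$fitted.values, n_par, disp_floor)
    fam <- MASS::negative.binomial(theta = 1 / alpha)
    fit <- try(glm.fit(X, y, family = fam, offset = off,
                       start = pois$coefficients), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged)
      fit <- pois  # dispersion still enters through the Pearson factor
    est <- fit$coefficients[coef_idx]
    mu <- fit$fitted.values
    w <- mu^2 / fit$family$variance(mu)
    XtWX <- crossprod(X * sqrt(w))
    cov_unscaled <- try(solve(XtWX), silent = TRUE)
    if (inherits(cov_unscaled, "try-error")) { res$untestable[g] <- TRUE; next }
    se <- sqrt(cov_unscaled[coef_idx, coef_idx])
    df_res <- length(y) - n_par
    if (test == "ql_t" && df_res > 0) {
      pearson <- sum((y - mu)^2 / fit$family$variance(mu))
      phi <- max(pearson / df_res, 1e-8)
      se <- se * sqrt(phi)
      stat <- est / se
      p <- 2 * pt(-abs(stat), df = df_res)
    } else {
      stat <- est / se
      p <- 2 * pnorm(-abs(stat))
    }
    res$log2FC[g] <- est / log(2)
    res$SE[g] <- se / log(2)
    res$stat[g] <- stat
    res$p[g] <- p
  }
  res$padj <- p.adjust(res$p, method = "BH")
  res$called <- de_called(res)
  res
}

de_called <- function(results, fc = 2, fdr = 0.05) {
  !is.na(results$padj) & results$padj < fdr &
    !is.na(results$log2FC) & abs(results$log2FC) >= log2(fc)
}

#' Differential expression call rule
#'
#' A gene is called differentially expressed when it shows at least an
#' `fc`-fold change (|log2FC| >= log2(fc)) at a BH-adjusted p below `fdr`.
#'
#' @param results output of [nb_de_test].
#' @param fc fold-change threshold.
#' @param fdr adjusted-p threshold.
#' @return character vector of called gene ids.
#' @export
de_call <- function(results, fc = 2, fdr = 0.05) {
  results$gene[de_called(results, fc, fdr)]
}

#' Dual-reference consistency filter
#'
#' Divergent gene sequences can bias read mapping, so calls are checked
#' against a second analysis mapped to the other species' reference
#' genome: a gene called under reference A survives only if it is also
#' called under reference B with a fold change of the same sign. Genes
#' missing from the second result set are excluded with a warning.
#'
#' @param results_refA,results_refB [nb_de_test] outputs from the two
#'   reference genomes.
#' @param fc,fdr call-rule parameters.
#' @return character vector of consistently called gene ids.
#' @export
reference_bias_filter <- function(results_refA, results_refB,
                                  fc = 2, fdr = 0.05) {
  called_a <- de_call(results_refA, fc, fdr)
  missing <- setdiff(called_a, results_refB$gene)
  if (length(missing))
    warning(length(missing), " called gene(s) missing under reference B, ",
            "excluded")
  called_a <- setdiff(called_a, missing)
  b <- results_refB[match(called_a, results_refB$gene), ]
  a <- results_refA[match(called_a, results_refA$gene), ]
  ok <- de_called(b, fc, fdr) & sign(a$log2FC) == sign(b$log2FC)
  called_a[ok]
}

#' Intersect candidate genes at the QTL
#'
#' Given the dominance of the mel behavioural alleles, genes underlying
#' the QTL are expected to differ both between the parental species and
#' between F1 hybrids and the cyd parent, in the same direction.
#' Candidates are genes inside the QTL interval called in the species
#' comparison and called with the same fold-change sign in the
#' F1-vs-cyd comparison. If a backcross comparison is supplied, each
#' candidate is annotated with whether it is also called there.
#'
#' @param species_de,f1_vs_cyd_de,bc3_de [nb_de_test] outputs.
#' @param qtl_interval list or data.frame with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param gene_coords data.frame: gene, chrom, start, end.
#' @param fc,fdr call-rule parameters.
#' @return data.frame of candidates: gene, log2FC_species, log2FC_f1, and
#'   `called_bc3` when `bc3_de` is given.
#' @export
candidate_intersection <- function(species_de, f1_vs_cyd_de, qtl_interval,
                                   gene_coords, bc3_de = NULL,
                                   fc = 2, fdr = 0.05) {
  if (is.null(qtl_interval$chrom) || is.null(qtl_interval$start) ||
      is.null(qtl_interval$end) || qtl_interval$end <= qtl_interval$start)
    stop("malformed QTL interval")
  gc <- gene_coords
  in_qtl <- gc$gene[gc$chrom == qtl_interval$chrom &
                      gc$start < qtl_interval$end &
                      gc$end > qtl_interval$start]
  sp_called <- de_call(species_de, fc, fdr)
  f1_called <- de_call(f1_vs_cyd_de, fc, fdr)
  cand <- intersect(intersect(in_qtl, sp_called), f1_called)
  sp <- species_de[match(cand, species_de$gene), ]
  f1 <- f1_vs_cyd_de[match(cand, f1_vs_cyd_de$gene), ]
  same_sign <- sign(sp$log2FC) == sign(f1$log2FC)
  cand <- cand[same_sign]
  out <- data.frame(gene = cand,
                    log2FC_species = sp$log2FC[same_sign],
                    log2FC_f1 = f1$log2FC[same_sign],
                    stringsAsFactors = FALSE)
  if (!is.null(bc3_de))
    out$called_bc3 <- out$gene %in% de_call(bc3_de, fc, fdr)
  rownames(out) <- NULL
  out
}
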