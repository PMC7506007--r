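# Allele-specific expression from diagnostic sites: per-gene paired test
# of the two species alleles within hybrid individuals (library size
# factors fixed to 1 — the comparison is within, not between, samples),
# plus the cis/trans regulatory decision table.

#' Sum per-site allele counts into gene totals
#'
#' Reads assigned to either species allele at diagnostic sites are summed
#' within genes, per individual. A site assigned to more than one gene is
#' an error: ambiguity must be resolved upstream.
#'
#' @param per_site data.frame: chrom, pos, gene, individual, count_mel,
#'   count_cyd.
#' @return `allele_count_table` data.frame: gene, individual, count_mel,
#'   count_cyd.
#' @export
sum_allele_counts <- function(per_site) {
  site_gene <- unique(per_site[, c("chrom", "pos", "gene")])
  if (anyDuplicated(site_gene[, c("chrom", "pos")]))
    stop("site assigned to more than one gene")
  agg <- stats::aggregate(
    cbind(count_mel, count_cyd) ~ gene + individual,
    data = per_site, FUN = sum)
  agg <- agg[order(agg$gene, agg$individual), ]
  rownames(agg) <- NULL
  class(agg) <- c("allele_count_table", "data.frame")
  agg
}

# paired NB test of the allele effect for one gene's table
ase_test_gene <- function(d, min_total = 10, disp_floor = 1e-8) {
  d <- d[d$count_mel + d$count_cyd >= min_total, ]
  n_ind <- nrow(d)
  if (n_ind < 2)
    return(list(A = NA_real_, SE = NA_real_, p = NA_real_,
                n_individuals = n_ind))
  y <- c(d$count_mel, d$count_cyd)
  ind <- factor(rep(seq_len(n_ind), 2))
  allele <- rep(c(1, 0), each = n_ind)  # mel vs cyd
  X <- cbind(stats::model.matrix(~ 0 + ind), allele)
  n_par <- ncol(X)
  pois <- glm.fit(X, y, family = stats::poisson())
  alpha <- moment_dispersion(y, pois$fitted.values, n_par, disp_floor)
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- try(glm.fit(X, y, family = fam, start = pois$coefficients),
             silent = TRUE)
  if (inherits(fit, "try-error") || !fit$converged) fit <- pois
  mu <- fit$fitted.values
  w <- mu^2 / fit$family$variance(mu)
  cov_unscaled <- try(solve(crossprod(X * sqrt(w))), silent = TRUE)
  if (inherits(cov_unscaled, "try-error"))
    return(list(A = NA_real_, SE = NA_real_, p = NA_real_,
                n_individuals = n_ind))
  est <- fit$coefficients[n_par]
  se <- sqrt(cov_unscaled[n_par, n_par])
  df_res <- length(y) - n_par
  if (df_res > 0) {
    phi <- max(sum((y - mu)^2 / fit$family$variance(mu)) / df_res, 1e-8)
    se <- se * sqrt(phi)
    p <- 2 * pt(-abs(est / se), df = df_res)
  } else {
    p <- 2 * pnorm(-abs(est / se))
  }
  list(A = est / log(2), SE = se / log(2), p = p, n_individuals = n_ind)
}

#' Test allele-specific expression
#'
#' Per gene, fits the paired negative-binomial model
#' `count ~ 0 + individual + allele` on the mel and cyd allele counts of
#' each hybrid individual, with no between-sample normalization (size
#' factors fixed to 1). Dispersion is a per-gene moment estimate; the
#' allele (mel vs cyd) coefficient is tested with a quasi-likelihood Wald
#' statistic on the residual degrees of freedom. A gene is called when
#' |A| >= log2(fc) and p < `p_cut`. Individuals with total counts below
#' `min_total` are dropped per gene; genes with fewer than two usable
#' individuals are untestable (`p = NA`).
#'
#' @param table an `allele_count_table` ([sum_allele_counts] or
#'   [simulate_allele_counts]).
#' @param min_total per-individual minimum total informative count.
#' @param fc fold-change threshold of the call rule.
#' @param p_cut p-value threshold of the call rule (raw Wald p).
#' @return data.frame: gene, A (allelic log2 fold change, mel vs cyd),
#'   SE, p, n_individuals, called, untestable.
#' @export
ase_test <- function(table, min_total = 10, fc = 2, p_cut = 0.05) {
  out <- do.call(rbind, lapply(split(table, table$gene), function(d) {
    r <- ase_test_gene(d, min_total)
    data.frame(gene = d$gene[1], A = r$A, SE = r$SE, p = r$p,
               n_individuals = r$n_individuals, stringsAsFactors = FALSE)
  }))
  out$called <- !is.na(out$p) & out$p < p_cut & abs(out$A) >= log2(fc)
  out$untestable <- is.na(out$p)
  out <- out[order(out$gene), ]
  rownames(out) <- NULL
  out
}

#' Check for systematic allele-assignment bias
#'
#' If reads were assigned to species alleles without bias, per-gene
#' allelic log2 fold changes should be centred at zero. Returns the
#' median and mean of per-gene pooled log ratios and flags a biased
#' assignment when |median| exceeds `tol`. With fewer than `min_genes`
#' genes the summary is returned with a warning and no flag.
#'
#' @param table an `allele_count_table`.
#' @param tol tolerance on the median (log2 units).
#' @param min_genes minimum number of genes for a reliable check.
#' @return list: n_genes, median_A, mean_A, flagged.
#' @export
assignment_bias_check <- function(table, tol = 0.05, min_genes = 100) {
  mel <- tapply(table$count_mel, table$gene, sum)
  cyd <- tapply(table$count_cyd, table$gene, sum)
  A <- log2((mel + 0.5) / (cyd + 0.5))
  n <- length(A)
  if (n < min_genes) {
    warning("fewer than ", min_genes, " genes; bias check unreliable")
    return(list(n_genes = n, median_A = median(A), mean_A = mean(A),
                flagged = NA))
  }
  med <- median(A)
  list(n_genes = n, median_A = med, mean_A = mean(A),
       flagged = abs(med) > tol)
}

#' Classify cis/trans regulatory architecture
#'
#' Combines the parental expression divergence P (log2FC between species)
#' and the allelic imbalance A (log2FC between alleles within F1 hybrids).
#' Purely cis-regulated genes fall on A = P (the trans environment is
#' shared within an F1); purely trans-regulated genes diverge between
#' parents with balanced alleles (A = 0). Three two-sided Wald tests at
#' level `alpha` — A != 0, P != 0 and A - P != 0 with pooled SE
#' sqrt(SE_A^2 + SE_P^2) — feed the decision table:
#'
#' * conserved: neither A nor P significant
#' * cis_only: A and P significant, A - P not
#' * trans_only: P significant, A not
#' * cis_plus_trans: A and A - P significant
#' * ambiguous: anything else, or missing inputs
#'
#' @param de_results [nb_de_test] output (parental comparison: mel vs
#'   cyd).
#' @param ase_results [ase_test] output on F1 hybrids.
#' @param alpha significance level of the three Wald tests.
#' @return data.frame: gene, P, SE_P, A, SE_A, class.
#' @export
cis_trans_classify <- function(de_results, ase_results, alpha = 0.05) {
  genes <- union(de_results$gene, ase_results$gene)
  de <- de_results[match(genes, de_results$gene), ]
  as_ <- ase_results[match(genes, ase_results$gene), ]
  P <- de$log2FC; SE_P <- de$SE
  A <- as_$A; SE_A <- as_$SE
  miss <- is.na(P) | is.na(SE_P) | is.na(A) | is.na(SE_A)
  z <- function(est, se) {
    s <- 2 * pnorm(-abs(est / se)) < alpha
    s & !is.na(s)
  }
  sigP <- z(P, SE_P)
  sigA <- z(A, SE_A)
  sigD <- z(A - P, sqrt(SE_A^2 + SE_P^2))
  cls <- rep("ambiguous", length(genes))
  cls[!sigA & !sigP] <- "conserved"
  cls[!sigA & sigP] <- "trans_only"
  cls[sigA & sigP & !sigD] <- "cis_only"
  cls[sigA & sigD] <- "cis_plus_trans"
  cls[miss] <- "ambiguous"
  data.frame(gene = genes, P = P, SE_P = SE_P, A = A, SE_A = SE_A,
             class = cls, stringsAsFactors = FALSE)
}
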