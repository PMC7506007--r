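# Generative model for expression counts: negative-binomial counts whose
# means combine a baseline, a cis-acting effect (linked to the allele
# itself) and a trans-acting effect (acting on the whole cellular
# environment), on the log2 scale.

#' Define a regulatory architecture
#'
#' Per gene: baseline expression `q` (expected counts at size factor 1),
#' cis effect `cis_log2` and trans effect `trans_log2` (log2 units), and
#' negative-binomial dispersion `alpha` (variance = mu + alpha mu^2).
#'
#' @param n_genes number of genes.
#' @param q baseline mean (scalar or length `n_genes`).
#' @param cis_log2,trans_log2 log2 effects (scalar or per gene).
#' @param alpha NB dispersion (>= 0; 0 gives Poisson counts).
#' @param gene_ids optional gene identifiers.
#' @return object of class `regulatory_architecture` (a data.frame).
#' @export
regulatory_architecture <- function(n_genes, q = 100, cis_log2 = 0,
                                    trans_log2 = 0, alpha = 0.05,
                                    gene_ids = NULL) {
  if (any(q <= 0)) stop("baseline expression q must be positive")
  if (any(alpha < 0)) stop("dispersion alpha must be non-negative")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n_genes))
  arch <- data.frame(gene = gene_ids,
                     q = rep_len(q, n_genes),
                     cis_log2 = rep_len(cis_log2, n_genes),
                     trans_log2 = rep_len(trans_log2, n_genes),
                     alpha = rep_len(alpha, n_genes),
                     stringsAsFactors = FALSE)
  class(arch) <- c("regulatory_architecture", "data.frame")
  arch
}

rnb <- function(n, mu, alpha) {
  out <- numeric(length(mu))
  pois <- alpha == 0
  if (any(pois)) out[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) out[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                                        size = 1 / alpha[!pois])
  out
}

#' Simulate a gene x sample count matrix
#'
#' Counts are drawn NB(mean = sf_s * q_g * 2^(cis_g * x_cis,s +
#' trans_g * x_trans,s), dispersion alpha_g). The design supplies, per
#' sample, the cis and trans dosages (e.g. 1/1 for the mel parent vs the
#' cyd reference 0/0; an F1 would see the full trans environment shift
#' only through its mixed allele dosage — set dosages to model the cross
#' of interest).
#'
#' @param arch a [regulatory_architecture].
#' @param design data.frame with one row per sample: columns `sample`,
#'   `x_cis`, `x_trans` and any metadata (`group`, `stage`, `sex`,
#'   `batch`); optional `size_factor` (default 1).
#' @param seed optional integer seed.
#' @return list: integer matrix `counts` (genes x samples), `meta` (the
#'   design), `truth` (the architecture: true labels for scoring).
#' @export
simulate_expression <- function(arch, design, seed = NULL) {
  stopifnot(inherits(arch, "regulatory_architecture"),
            all(c("sample", "x_cis", "x_trans") %in% names(design)))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(design$size_factor)) design$size_factor <- 1
  if (any(design$size_factor <= 0)) stop("size factors must be positive")
  n_g <- nrow(arch); n_s <- nrow(design)
  counts <- matrix(0L, n_g, n_s,
                   dimnames = list(arch$gene, design$sample))
  for (j in seq_len(n_s)) {
    mu <- design$size_factor[j] * arch$q *
      2^(arch$cis_log2 * design$x_cis[j] + arch$trans_log2 * design$x_trans[j])
    counts[, j] <- as.integer(rnb(n_g, mu, arch$alpha))
  }
  list(counts = counts, meta = design, truth = arch)
}

#' Two-group parental design helper
#'
#' A balanced design contrasting the mel parent (cis and trans dosage 1)
#' with the cyd parent (dosage 0), with alternating sexes and batches.
#'
#' @param n_per_group samples per species.
#' @return design data.frame for [simulate_expression].
#' @export
parental_design <- function(n_per_group = 10) {
  n <- 2 * n_per_group
  data.frame(
    sample = sprintf("s%02d", seq_len(n)),
    group = rep(c("mel", "cyd"), each = n_per_group),
    x_cis = rep(c(1, 0), each = n_per_group),
    x_trans = rep(c(1, 0), each = n_per_group),
    sex = rep_len(c("male", "female"), n),
    batch = rep_len(rep(c("b1", "b2"), each = 2), n),
    stringsAsFactors = FALSE
  )
}

#' Simulate allele-specific counts in F1 hybrids
#'
#' Within an F1 individual both alleles share the trans environment, so
#' the expected mel:cyd read ratio for a gene is 2^cis alone. Per
#' individual the gene's total depth is drawn around `depth`, split
#' between alleles with NB noise of dispersion `alpha`.
#'
#' @param arch a [regulatory_architecture]; only `cis_log2` and `alpha`
#'   are used.
#' @param n_individuals number of F1 individuals.
#' @param depth expected total informative read count per gene per
#'   individual (0 gives all-zero counts, flagged untestable downstream).
#' @param depth_cv coefficient of variation of per-individual depth
#'   (lognormal); 0 for constant depth.
#' @param seed optional integer seed.
#' @return data.frame (`allele_count_table`): gene, individual,
#'   count_mel, count_cyd.
#' @export
simulate_allele_counts <- function(arch, n_individuals = 10, depth = 500,
                                   depth_cv = 0.2, seed = NULL) {
  stopifnot(inherits(arch, "regulatory_architecture"), depth >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_g <- nrow(arch)
  out <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    d <- if (depth_cv > 0)
      depth * exp(rnorm(1, -depth_cv^2 / 2, depth_cv)) else depth
    r <- 2^arch$cis_log2
    mu_mel <- d * r / (1 + r)
    mu_cyd <- d / (1 + r)
    out[[i]] <- data.frame(
      gene = arch$gene,
      individual = sprintf("ind%02d", i),
      count_mel = as.integer(rnb(n_g, mu_mel, arch$alpha)),
      count_cyd = as.integer(rnb(n_g, mu_cyd, arch$alpha)),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("allele_count_table", "data.frame")
  tab
}
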