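# Generative twin of the courtship-initiation model: per responding trial
# a male initiates courtship towards the cyd female only, the mel female
# only, or both, with category probabilities from a 3-category logit
# (reference = cyd_only) with male-level random intercepts.

#' Define behavioural effect sizes
#'
#' Linear predictors for the non-reference categories (`mel_only`,
#' `both`): eta_k = intercept_k + sum_q beta[q, k] * x_q + u_k, where x_q
#' is 1 for a cyd/melp genotype at QTL q and u_k ~ N(0, sigma_male) is a
#' male-level intercept.
#'
#' @param intercepts length-2 numeric (`mel_only`, `both`).
#' @param beta 3 x 2 matrix of genotype effects (rows chr1, chr17, chr18;
#'   columns mel_only, both).
#' @param sigma_male SD of male random intercepts (>= 0).
#' @return object of class `behaviour_effects`.
#' @export
behaviour_effects <- function(intercepts = c(mel_only = 0, both = 0),
                              beta = matrix(0, 3, 2,
                                dimnames = list(c("chr1", "chr17", "chr18"),
                                                c("mel_only", "both"))),
                              sigma_male = 0) {
  if (sigma_male < 0) stop("sigma_male must be non-negative")
  stopifnot(length(intercepts) == 2, all(dim(beta) == c(3, 2)))
  structure(list(intercepts = intercepts, beta = beta,
                 sigma_male = sigma_male),
            class = "behaviour_effects")
}

#' Simulate courtship-initiation trials
#'
#' Each male receives genotypes at the three QTLs (independent 1:1
#' segregation, as in a backcross, unless `genotypes` is supplied), a pair
#' of random intercepts, and `trials_per_male` choice trials. A trial is
#' responding with probability `p_respond`; responding trials fall in one
#' of three categories by the logit model of [behaviour_effects]. Males
#' with zero responding trials are retained in the table but flagged
#' `excluded = TRUE`, mirroring the rule that non-responding males are
#' dropped before modelling.
#'
#' @param effects a [behaviour_effects].
#' @param n_males number of males.
#' @param trials_per_male trials per male (>= 1).
#' @param p_respond probability a trial has any courtship response.
#' @param genotypes optional data.frame with columns `chr1`, `chr17`,
#'   `chr18` in {"cyd/cyd", "cyd/melp"}.
#' @param seed optional integer seed.
#' @return data.frame (`trial_table`): male, geno_chr1, geno_chr17,
#'   geno_chr18, n_cyd_only, n_mel_only, n_both, n_trials_responding,
#'   excluded.
#' @export
simulate_trials <- function(effects, n_males = 139, trials_per_male = 5,
                            p_respond = 0.6, genotypes = NULL, seed = NULL) {
  stopifnot(inherits(effects, "behaviour_effects"), trials_per_male >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(genotypes)) {
    genotypes <- data.frame(
      chr1 = sample(c("cyd/cyd", "cyd/melp"), n_males, TRUE),
      chr17 = sample(c("cyd/cyd", "cyd/melp"), n_males, TRUE),
      chr18 = sample(c("cyd/cyd", "cyd/melp"), n_males, TRUE),
      stringsAsFactors = FALSE
    )
  }
  x <- as.matrix(genotypes == "cyd/melp") + 0  # n_males x 3
  counts <- matrix(0L, n_males, 3)
  n_resp <- integer(n_males)
  for (i in seq_len(n_males)) {
    u <- rnorm(2, 0, effects$sigma_male)
    eta <- c(0,
             effects$intercepts[1] + sum(effects$beta[, 1] * x[i, ]) + u[1],
             effects$intercepts[2] + sum(effects$beta[, 2] * x[i, ]) + u[2])
    p <- exp(eta - max(eta)); p <- p / sum(p)
    n_resp[i] <- rbinom(1, trials_per_male, p_respond)
    if (n_resp[i] > 0)
      counts[i, ] <- as.integer(rmultinom(1, n_resp[i], p))
  }
  tab <- data.frame(
    male = sprintf("male%03d", seq_len(n_males)),
    geno_chr1 = genotypes$chr1, geno_chr17 = genotypes$chr17,
    geno_chr18 = genotypes$chr18,
    n_cyd_only = counts[, 1], n_mel_only = counts[, 2], n_both = counts[, 3],
    n_trials_responding = n_resp,
    excluded = n_resp == 0,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("trial_table", "data.frame")
  tab
}
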