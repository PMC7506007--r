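# Bayesian multinomial mixed model of courtship initiation. Per male,
# counts of responding trials in three categories (cyd_only / mel_only /
# both) are multinomial with category-logit linear predictors: fixed
# effects of genotype at each QTL plus a male random intercept per
# non-reference category. Posterior by adaptive random-walk
# Metropolis-within-Gibbs.

trial_design <- function(trials, terms) {
  trials <- trials[!trials$excluded & trials$n_trials_responding > 0, ]
  if (nrow(trials) < 2) stop("random effect unidentifiable with < 2 males")
  y <- as.matrix(trials[, c("n_cyd_only", "n_mel_only", "n_both")])
  X <- matrix(0, nrow(trials), length(terms),
              dimnames = list(NULL, terms))
  for (q in terms) {
    col <- trials[[paste0("geno_", q)]]
    if (min(table(factor(col, levels = c("cyd/cyd", "cyd/melp")))) < 2)
      stop("need >= 2 males per genotype class at ", q)
    X[, q] <- as.numeric(col == "cyd/melp")
  }
  list(y = y, N = rowSums(y), X = X, male = trials$male)
}

# log multinomial likelihood per male given category-2/3 linear predictors
mn_loglik <- function(y, N, eta2, eta3, lconst) {
  m <- pmax(0, eta2, eta3)
  lse <- m + log(exp(-m) + exp(eta2 - m) + exp(eta3 - m))
  lconst + y[, 2] * eta2 + y[, 3] * eta3 - N * lse
}

run_chain <- function(d, n_warmup, n_draws, prior_sd, sigma_prior_sd,
                      chain_seed) {
  set.seed(chain_seed)
  n <- nrow(d$y); q <- ncol(d$X)
  lconst <- lgamma(d$N + 1) - rowSums(lgamma(d$y + 1))
  # parameter block: a2, a3, then b[term, category] column-major
  n_glob <- 2 + 2 * q
  glob <- rep(0, n_glob)
  gnames <- c("a_mel_only", "a_both",
              if (q) c(paste0("b_", colnames(d$X), "_mel_only"),
                       paste0("b_", colnames(d$X), "_both")))
  names(glob) <- gnames
  u <- matrix(0, n, 2)
  log_sigma <- log(0.5)
  etas <- function(glob, u) {
    b2 <- glob[seq_len(q) + 2]; b3 <- glob[seq_len(q) + 2 + q]
    cbind(glob[1] + if (q) drop(d$X %*% b2) else 0,
          glob[2] + if (q) drop(d$X %*% b3) else 0) + u
  }
  ll_vec <- function(glob, u) {
    e <- etas(glob, u)
    mn_loglik(d$y, d$N, e[, 1], e[, 2], lconst)
  }
  ll <- ll_vec(glob, u)
  scale_g <- rep(0.4, n_glob); scale_u <- 0.6; scale_w <- rep(0.3, n_glob)
  scale_v <- 0.3
  total <- n_warmup + n_draws
  draws <- matrix(NA_real_, n_draws, n_glob + 1,
                  dimnames = list(NULL, c(gnames, "sigma")))
  log_lik <- matrix(NA_real_, n_draws, n)
  for (it in seq_len(total)) {
    adapt <- it <= n_warmup
    rate <- if (adapt) min(0.5, 3 / sqrt(it)) else 0
    sigma <- exp(log_sigma)
    # fixed effects, one at a time
    for (j in seq_len(n_glob)) {
      cand <- glob; cand[j] <- cand[j] + rnorm(1, 0, scale_g[j])
      ll_c <- ll_vec(cand, u)
      lacc <- sum(ll_c) - sum(ll) +
        dnorm(cand[j], 0, prior_sd, log = TRUE) -
        dnorm(glob[j], 0, prior_sd, log = TRUE)
      if (log(runif(1)) < lacc) { glob <- cand; ll <- ll_c }
      if (adapt)
        scale_g[j] <- scale_g[j] *
          exp(rate * (min(1, exp(lacc)) - 0.44))
    }
    # male random intercepts, vectorized per category
    for (k in 1:2) {
      cand_u <- u; cand_u[, k] <- u[, k] + rnorm(n, 0, scale_u)
      ll_c <- ll_vec(glob, cand_u)
      lacc <- ll_c - ll +
        dnorm(cand_u[, k], 0, sigma, log = TRUE) -
        dnorm(u[, k], 0, sigma, log = TRUE)
      acc <- log(runif(n)) < lacc
      u[acc, k] <- cand_u[acc, k]
      ll[acc] <- ll_c[acc]
      if (adapt)
        scale_u <- scale_u * exp(rate * (mean(pmin(1, exp(lacc))) - 0.44))
    }
    # ancillarity swaps: shift a global effect and counter-shift the male
    # intercepts it acts through; the likelihood is invariant, so the
    # move is accepted on the priors alone and decorrelates the fixed
    # effects from the random-intercept means
    for (j in seq_len(n_glob)) {
      k <- if (j <= 2) j else if (j <= 2 + q) 1L else 2L
      v <- if (j <= 2) rep(1, n) else d$X[, (j - 3L) %% q + 1L]
      delta <- rnorm(1, 0, scale_w[j])
      cand_col <- u[, k] - delta * v
      lacc <- dnorm(glob[j] + delta, 0, prior_sd, log = TRUE) -
        dnorm(glob[j], 0, prior_sd, log = TRUE) +
        sum(dnorm(cand_col, 0, sigma, log = TRUE)) -
        sum(dnorm(u[, k], 0, sigma, log = TRUE))
      if (log(runif(1)) < lacc) {
        glob[j] <- glob[j] + delta
        u[, k] <- cand_col
      }
      if (adapt)
        scale_w[j] <- scale_w[j] * exp(rate * (min(1, exp(lacc)) - 0.44))
    }
    # random-intercept SD: independence proposal from the inverse-gamma
    # conditional of sigma^2 given u (exact but for the half-normal prior,
    # which enters the acceptance ratio), so sigma decorrelates per sweep
    n_u <- length(u)
    beta_u <- sum(u^2) / 2 + 1e-12
    s2_cand <- beta_u / rgamma(1, shape = n_u / 2)
    cand_s <- sqrt(s2_cand)
    lacc <- dnorm(cand_s, 0, sigma_prior_sd, log = TRUE) -
      dnorm(sigma, 0, sigma_prior_sd, log = TRUE) +
      log(s2_cand) - log(sigma^2)
    if (log(runif(1)) < lacc) log_sigma <- log(cand_s)
    # interweaved non-centered step: random walk on log sigma holding the
    # standardized intercepts u/sigma fixed (u rescales with sigma), which
    # breaks the funnel coupling the centered Gibbs step cannot cross
    sigma <- exp(log_sigma)
    cand_ls <- log_sigma + rnorm(1, 0, scale_v)
    ratio <- exp(cand_ls - log_sigma)
    cand_u <- u * ratio
    ll_c <- ll_vec(glob, cand_u)
    lacc <- sum(ll_c) - sum(ll) +
      dnorm(exp(cand_ls), 0, sigma_prior_sd, log = TRUE) -
      dnorm(sigma, 0, sigma_prior_sd, log = TRUE) +
      cand_ls - log_sigma
    if (log(runif(1)) < lacc) {
      log_sigma <- cand_ls
      u <- cand_u
      ll <- ll_c
    }
    if (adapt) scale_v <- scale_v * exp(rate * (min(1, exp(lacc)) - 0.44))
    if (!adapt) {
      i <- it - n_warmup
      draws[i, ] <- c(glob, exp(log_sigma))
      log_lik[i, ] <- ll
    }
  }
  list(draws = draws, log_lik = log_lik)
}

split_rhat <- function(mats) {
  # mats: list (per chain) of draws x params matrices
  halves <- unlist(lapply(mats, function(m) {
    h <- nrow(m) %/% 2
    list(m[seq_len(h), , drop = FALSE],
         m[seq_len(h) + h, , drop = FALSE])
  }), recursive = FALSE)
  vapply(seq_len(ncol(mats[[1]])), function(j) {
    x <- vapply(halves, function(m) c(mean(m[, j]), var(m[, j])),
                numeric(2))
    W <- mean(x[2, ])
    B <- var(x[1, ])
    n <- nrow(halves[[1]])
    if (W == 0) return(1)
    sqrt((n - 1) / n + B / W)
  }, 0)
}

#' Fit the multinomial mixed model of courtship initiation
#'
#' Three-category multinomial logit (reference: initiation towards the
#' cyd female only) with a fixed genotype effect per QTL in `terms` and a
#' male random intercept for each non-reference category, u ~
#' N(0, sigma_male). Priors: normal(0, 2.5) on intercepts and
#' coefficients, half-normal(0, 2) on sigma_male. Sampling is adaptive
#' random-walk Metropolis-within-Gibbs; convergence requires split R-hat
#' < 1.05 on all fixed effects and sigma_male (error otherwise, unless
#' `check_convergence = FALSE`).
#'
#' @param trials a trial table ([simulate_trials] or [read_trials]);
#'   males flagged `excluded` (no responding trials) are dropped.
#' @param terms QTLs entered as fixed effects (subset of
#'   `c("chr1", "chr17", "chr18")`; may be empty for the null model).
#' @param n_draws kept draws per chain.
#' @param n_warmup warm-up (adaptation) iterations per chain.
#' @param n_chains number of chains.
#' @param prior_sd,sigma_prior_sd prior scales.
#' @param seed integer seed (chains use seed + chain index).
#' @param check_convergence error when split R-hat >= 1.05.
#' @return object of class `courtship_fit`: `draws` (total draws x
#'   parameters, including `sigma`), `log_lik` (total draws x males),
#'   `rhat`, `terms`, `males`, `n_chains`.
#' @export
fit_multinomial <- function(trials, terms = c("chr1", "chr17", "chr18"),
                            n_draws = 2000, n_warmup = 1000, n_chains = 4,
                            prior_sd = 2.5, sigma_prior_sd = 2,
                            seed = 1, check_convergence = TRUE) {
  d <- trial_design(trials, terms)
  chains <- lapply(seq_len(n_chains), function(ci)
    run_chain(d, n_warmup, n_draws, prior_sd, sigma_prior_sd,
              chain_seed = seed + ci))
  rhat <- if (n_chains >= 2) {
    r <- split_rhat(lapply(chains, `[[`, "draws"))
    setNames(r, colnames(chains[[1]]$draws))
  } else NULL
  if (check_convergence && !is.null(rhat) && any(rhat >= 1.05))
    stop("chains did not converge; split R-hat: ",
         paste(sprintf("%s=%.3f", names(rhat), rhat), collapse = ", "))
  structure(list(
    draws = do.call(rbind, lapply(chains, `[[`, "draws")),
    log_lik = do.call(rbind, lapply(chains, `[[`, "log_lik")),
    rhat = rhat, terms = terms, males = d$male, n_chains = n_chains,
    genotype_levels = c("cyd/cyd", "cyd/melp")
  ), class = "courtship_fit")
}

#' Posterior predictive initiation proportions for a genotype
#'
#' Category probabilities for a new male of the given genotype, with the
#' male random intercept integrated out by Monte Carlo (a fresh intercept
#' pair is drawn per posterior draw). Proportions sum to one within every
#' draw.
#'
#' @param fit a `courtship_fit`.
#' @param genotype named character vector over `fit$terms` with values
#'   `"cyd/cyd"` or `"cyd/melp"`.
#' @param level credible-interval level.
#' @param seed optional integer seed for the random-intercept draws.
#' @return data.frame: category, mean, lower, upper.
#' @export
predicted_proportions <- function(fit, genotype = NULL, level = 0.95,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- length(fit$terms)
  if (q > 0) {
    if (is.null(genotype) || !all(fit$terms %in% names(genotype)))
      stop("genotype must name all model terms")
    if (!all(genotype %in% fit$genotype_levels))
      stop("unseen genotype level: ",
           paste(setdiff(genotype, fit$genotype_levels), collapse = ", "))
    x <- as.numeric(genotype[fit$terms] == "cyd/melp")
  } else x <- numeric(0)
  dr <- fit$draws
  S <- nrow(dr)
  b2 <- if (q) drop(dr[, 2 + seq_len(q), drop = FALSE] %*% x) else 0
  b3 <- if (q) drop(dr[, 2 + q + seq_len(q), drop = FALSE] %*% x) else 0
  u <- matrix(rnorm(2 * S, 0, rep(dr[, "sigma"], 2)), S, 2)
  eta2 <- dr[, 1] + b2 + u[, 1]
  eta3 <- dr[, 2] + b3 + u[, 2]
  denom <- 1 + exp(eta2) + exp(eta3)
  p <- cbind(cyd_only = 1 / denom, mel_only = exp(eta2) / denom,
             both = exp(eta3) / denom)
  a <- (1 - level) / 2
  data.frame(category = colnames(p),
             mean = colMeans(p),
             lower = apply(p, 2, quantile, a),
             upper = apply(p, 2, quantile, 1 - a),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Posterior summary of the fixed effects
#'
#' @param fit a `courtship_fit`.
#' @param level credible-interval level.
#' @return data.frame: parameter, mean, sd, lower, upper.
#' @export
fixed_effect_summary <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  dr <- fit$draws
  data.frame(parameter = colnames(dr),
             mean = colMeans(dr),
             sd = apply(dr, 2, sd),
             lower = apply(dr, 2, quantile, a),
             upper = apply(dr, 2, quantile, 1 - a),
             row.names = NULL, stringsAsFactors = FALSE)
}
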