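# Pareto-smoothed importance-sampling leave-one-out cross-validation
# (PSIS-LOO) for fitted courtship models, and the ELPD comparison rule.

# Zhang & Stephens (2009) profile-posterior fit of the generalized Pareto
# distribution to tail exceedances, with the weak shape prior used by
# standard PSIS implementations.
gpd_fit <- function(x, min_grid = 30) {
  n <- length(x)
  x <- sort.int(x)
  m <- min_grid + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(t) -mean(log1p(-t * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- exp(l_j - max(l_j)); w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  k <- (k * n + 0.5 * 10) / (n + 10)  # regularize toward 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# smooth one observation's raw log importance ratios; returns normalized
# smoothed log weights plus the Pareto k diagnostic
psis_weights <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  k <- NA_real_
  if (M >= 5 && length(unique(lr)) > 1) {
    ord <- order(lr)
    tail_ids <- ord[(S - M + 1):S]
    cutoff <- lr[ord[S - M]]
    exceed <- exp(lr[tail_ids]) - exp(cutoff)
    if (any(exceed > 0)) {
      fit <- gpd_fit(exceed[exceed > 0])
      k <- fit$k
      if (is.finite(k)) {
        p <- (seq_along(tail_ids) - 0.5) / M
        smoothed <- log(qgpd(p, fit$k, fit$sigma) + exp(cutoff))
        lr[tail_ids[order(lr[tail_ids])]] <- pmin(smoothed, 0)
      }
    }
  }
  list(lw = lr - log_sum_exp(lr), k = k)
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO expected log pointwise predictive density
#'
#' Approximate leave-one-out cross-validation from the posterior
#' log-likelihood matrix: per male, importance ratios 1/p(y_i | theta_s)
#' are Pareto-smoothed in the tail and the LOO predictive density is the
#' weighted posterior average. SE = sqrt(n * var(pointwise elpd)).
#' Observations with Pareto k > 0.7 are unreliable; if more than 10% are,
#' a warning recommends exact refits.
#'
#' @param fit a `courtship_fit` (or a draws x observations log-likelihood
#'   matrix).
#' @return object of class `elpd_loo`: `elpd`, `se`, `pointwise`,
#'   `pareto_k`, `n`.
#' @export
elpd_loo <- function(fit) {
  ll <- if (inherits(fit, "courtship_fit")) fit$log_lik else as.matrix(fit)
  n <- ncol(ll)
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    ps <- psis_weights(-ll[, i])
    pointwise[i] <- log_sum_exp(ll[, i] + ps$lw)
    pareto_k[i] <- ps$k
  }
  n_bad <- sum(pareto_k > 0.7, na.rm = TRUE)
  if (n_bad > 0.1 * n)
    warning(n_bad, " of ", n, " observations have Pareto k > 0.7; ",
            "exact refits recommended")
  structure(list(elpd = sum(pointwise), se = sqrt(n * var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k, n = n),
            class = "elpd_loo")
}

#' Compare two models by LOO ELPD
#'
#' delta_elpd = elpd(reduced) - elpd(full) (negative when the reduced
#' model predicts worse); its SE comes from the pointwise differences.
#' The QTL dropped from the reduced model is retained in the model of the
#' behaviour when |delta_elpd| exceeds 1.96 standard errors.
#'
#' @param full,reduced `courtship_fit` objects (or `elpd_loo` objects)
#'   fitted to identical observations.
#' @return object of class `elpd_comparison`: `delta_elpd`, `se_delta`,
#'   `se_units`, `retained`.
#' @export
compare_models <- function(full, reduced) {
  get_loo <- function(x) if (inherits(x, "elpd_loo")) x else elpd_loo(x)
  if (inherits(full, "courtship_fit") && inherits(reduced, "courtship_fit")
      && !identical(full$males, reduced$males))
    stop("models were fitted on different observations")
  lf <- get_loo(full); lr <- get_loo(reduced)
  if (lf$n != lr$n) stop("models were fitted on different observations")
  d <- lr$pointwise - lf$pointwise
  delta <- sum(d)
  se <- sqrt(lf$n * var(d))
  elpd_decision(delta, se)
}

#' ELPD retention decision from a (delta, SE) pair
#'
#' The decision rule applied to an already-computed ELPD difference:
#' se_units = |delta_elpd| / se_delta; the term is retained when
#' se_units > 1.96 (a 95%-confidence normal approximation). A zero
#' difference gives se_units = 0.
#'
#' @param delta_elpd ELPD difference (reduced minus full).
#' @param se_delta its standard error.
#' @return object of class `elpd_comparison`.
#' @export
elpd_decision <- function(delta_elpd, se_delta) {
  if (se_delta < 0) stop("se_delta must be non-negative")
  se_units <- if (delta_elpd == 0) 0
              else if (se_delta == 0) Inf
              else abs(delta_elpd) / se_delta
  structure(list(delta_elpd = delta_elpd, se_delta = se_delta,
                 se_units = se_units, retained = se_units > 1.96),
            class = "elpd_comparison")
}

#' @export
print.elpd_comparison <- function(x, ...) {
  cat(sprintf(
    "ELPD comparison: delta = %.2f (SE %.2f), %.2f SE units -> %s\n",
    x$delta_elpd, x$se_delta, x$se_units,
    if (x$retained) "retained" else "not retained"))
  invisible(x)
}
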