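#' Population-averaged error rate by Monte Carlo
#'
#' The individual-specific error probability at a locus is
#' `plogis(mu + eta)` with `eta ~ N(0, sigma^2)` the individual random
#' effect. The population-averaged (marginal) rate is its expectation over
#' `eta`, estimated here as the mean over `n_draws` normal draws, with the
#' Monte-Carlo standard error `sd / sqrt(n_draws)`.
#'
#' @param mu linear predictor mean (logit scale); `-Inf` gives rate 0.
#' @param sigma random-effect standard deviation (>= 0).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed optional integer seed.
#' @return list with `rate` and `se`.
#' @export
mc_marginal_rate <- function(mu, sigma, n_draws = 1e6, seed = NULL) {
  stopifnot(length(mu) == 1, sigma >= 0, n_draws >= 1)
  if (sigma == 0) return(list(rate = plogis(mu), se = 0))
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  p <- plogis(mu + rnorm(n_draws, 0, sigma))
  list(rate = mean(p), se = sd(p) / sqrt(n_draws))
}

#' Marginal per-locus rate table for a fitted model
#'
#' Population-averaged per-locus error rates at a given year (or lab),
#' computed by Monte-Carlo integration over the fitted individual random
#' effect, with one shared set of draws across loci. Loci dropped before
#' fitting (zero observed errors) are reported with rate 0 and enter the
#' across-locus mean, which covers the full panel.
#'
#' @param fit an `error_model_fit`.
#' @param year calendar year (YEAR models); a year outside 1997-2008 is
#'   computed with a warning.
#' @param lab laboratory (LAB models).
#' @param n_draws Monte-Carlo draws.
#' @param seed optional integer seed.
#' @param all_loci full locus panel for the zero-rate rows.
#' @return data.frame `locus`, `rate`, `se`, with the across-locus mean in
#'   attribute `"mean_rate"`.
#' @export
marginal_rate_table <- function(fit, year = NULL, lab = NULL,
                                n_draws = 1e6, seed = NULL,
                                all_loci = register_loci()$locus) {
  if (!is.null(year) && (year < 1997 || year > 2008)) {
    warning("year ", year, " outside the register's design range")
  }
  mu <- predict_mu(fit, year = year, lab = lab)
  sigma <- fit$sigma_ind
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  eta <- if (sigma > 0) rnorm(n_draws, 0, sigma) else numeric(0)
  rate <- se <- numeric(length(mu))
  for (l in seq_along(mu)) {
    if (sigma > 0) {
      p <- plogis(mu[l] + eta)
      rate[l] <- mean(p)
      se[l] <- sd(p) / sqrt(n_draws)
    } else {
      rate[l] <- plogis(mu[l])
    }
  }
  dropped <- setdiff(all_loci, names(mu))
  out <- data.frame(locus = c(names(mu), dropped),
                    rate = c(rate, rep(0, length(dropped))),
                    se = c(se, rep(0, length(dropped))),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rate, out$locus), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean_rate") <- mean(out$rate)
  out
}

multilocus_fields <- c("p_any", "p_one", "p_multi", "p_multi_given_any")

#' Multilocus error summary under locus independence
#'
#' Closed-form profile-level error probabilities when errors are
#' independent across loci: `P(E > 0) = 1 - prod(1 - p_l)`,
#' `P(E = 1) = sum_l p_l prod_{k != l} (1 - p_k)`, with
#' `P(E > 1) = P(E > 0) - P(E = 1)` and the conditional
#' `P(E > 1 | E > 0)` derived. E counts the loci of one profile with at
#' least one wrong allele.
#'
#' @param rates per-locus marginal error rates in \[0, 1\].
#' @return one-row data.frame (`assumption = "independent"`) with columns
#'   `p_any`, `p_one`, `p_multi`, `p_multi_given_any`, all in percent.
#' @export
multilocus_independent <- function(rates) {
  stopifnot(all(rates >= 0), all(rates <= 1))
  q <- 1 - rates
  p_any <- 1 - prod(q)
  p_one <- sum(vapply(seq_along(rates), function(l) {
    rates[l] * prod(q[-l])
  }, numeric(1)))
  p_multi <- p_any - p_one
  data.frame(assumption = "independent",
             p_any = 100 * p_any, p_one = 100 * p_one,
             p_multi = 100 * p_multi,
             p_multi_given_any = if (p_any > 0) 100 * p_multi / p_any else 0,
             stringsAsFactors = FALSE)
}

#' Multilocus error summary under within-individual dependence
#'
#' Monte-Carlo version of the profile-level summary when one shared normal
#' deviate `eta ~ N(0, sigma^2)` shifts all loci of an individual: for each
#' draw, `P_i(E > 0) = 1 - prod_l (1 - p_il)` and
#' `P_i(E = 1) = sum_l p_il prod_{k != l} (1 - p_ik)` with
#' `p_il = plogis(mu_l + eta_i)`; the population values average these over
#' draws. Loci with structural zero rates may be passed as `mu = -Inf`.
#'
#' @param mu per-locus linear predictor means (logit scale).
#' @param sigma shared random-effect standard deviation.
#' @param n_draws Monte-Carlo draws.
#' @param seed optional integer seed.
#' @param chunk draws processed per block (memory control).
#' @return one-row data.frame (`assumption = "dependent"`) with the same
#'   percent columns as [multilocus_independent()]; per-locus marginal
#'   rates from the same draws in attribute `"marginal_rates"`, Monte-Carlo
#'   standard errors of `p_any`/`p_one` in attribute `"se"`.
#' @export
multilocus_dependent <- function(mu, sigma, n_draws = 1e6, seed = NULL,
                                 chunk = 1e5) {
  stopifnot(sigma >= 0, n_draws >= 1)
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  L <- length(mu)
  sum0 <- sum1 <- sq0 <- sq1 <- 0
  msum <- numeric(L)
  done <- 0
  while (done < n_draws) {
    m <- min(chunk, n_draws - done)
    eta <- rnorm(m, 0, sigma)
    p <- plogis(outer(eta, mu, `+`))        # m x L
    q <- 1 - p
    prod_q <- apply(q, 1, prod)
    odds_sum <- rowSums(p / q)              # finite: p < 1 for finite mu
    pe0 <- 1 - prod_q
    pe1 <- prod_q * odds_sum
    sum0 <- sum0 + sum(pe0); sq0 <- sq0 + sum(pe0^2)
    sum1 <- sum1 + sum(pe1); sq1 <- sq1 + sum(pe1^2)
    msum <- msum + colSums(p)
    done <- done + m
  }
  p_any <- sum0 / n_draws
  p_one <- sum1 / n_draws
  p_multi <- p_any - p_one
  out <- data.frame(assumption = "dependent",
                    p_any = 100 * p_any, p_one = 100 * p_one,
                    p_multi = 100 * p_multi,
                    p_multi_given_any =
                      if (p_any > 0) 100 * p_multi / p_any else 0,
                    stringsAsFactors = FALSE)
  attr(out, "marginal_rates") <- msum / n_draws
  attr(out, "se") <- c(
    p_any = sqrt(max(0, sq0 / n_draws - p_any^2) / n_draws),
    p_one = sqrt(max(0, sq1 / n_draws - p_one^2) / n_draws))
  out
}

#' Dependence and independence multilocus summaries for a fitted model
#'
#' Convenience wrapper: computes the dependent summary by Monte Carlo from
#' the fitted predictors at `year` (or `lab`), then the independent summary
#' from the matched marginal per-locus rates of the same draws, so the two
#' rows differ only by the dependence assumption.
#'
#' @inheritParams marginal_rate_table
#' @return two-row data.frame (dependent, independent).
#' @export
multilocus_error_rates <- function(fit, year = NULL, lab = NULL,
                                   n_draws = 1e6, seed = NULL) {
  mu <- predict_mu(fit, year = year, lab = lab)
  dep <- multilocus_dependent(mu, fit$sigma_ind, n_draws = n_draws,
                              seed = seed)
  ind <- multilocus_independent(attr(dep, "marginal_rates"))
  out <- rbind(dep, ind)
  rownames(out) <- NULL
  out
}

#' Density of individual-specific error probabilities
#'
#' Change-of-variables density of `p = plogis(mu + eta)`,
#' `eta ~ N(0, sigma^2)`: `f(p) = dnorm(qlogis(p); mu, sigma) /
#' (p (1 - p))`. Visualizes how strongly error proneness varies between
#' individuals; for large sigma the density becomes bimodal, splitting the
#' population into near-error-free individuals and systematically
#' error-prone ones.
#'
#' @param mu linear predictor mean.
#' @param sigma random-effect standard deviation (> 0).
#' @param grid probabilities in (0, 1) at which to evaluate.
#' @return data.frame with `p` and `density`.
#' @export
density_of_rates <- function(mu, sigma,
                             grid = seq(1e-4, 1 - 1e-4, length.out = 512)) {
  stopifnot(sigma > 0, all(grid > 0), all(grid < 1))
  data.frame(p = grid,
             density = dnorm(qlogis(grid), mean = mu, sd = sigma) /
               (grid * (1 - grid)))
}
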