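test_that("the Gauss-Hermite rule integrates polynomial moments exactly", {
  r <- gh_rule(20)
  expect_equal(sum(r$weights), sqrt(pi), tolerance = 1e-12)
  expect_equal(sum(r$weights * r$nodes), 0, tolerance = 1e-12)
  expect_equal(sum(r$weights * r$nodes^2), sqrt(pi) / 2, tolerance = 1e-12)
  expect_equal(sum(r$weights * r$nodes^4), 3 * sqrt(pi) / 4,
               tolerance = 1e-12)
  r1 <- gh_rule(1)
  expect_equal(r1$nodes, 0)
  expect_equal(r1$weights, sqrt(pi))
})

test_that("model specs enforce the confounding rule and enumerate to 18", {
  expect_error(model_spec(c("YEAR", "LAB")), "confounded")
  specs <- candidate_model_set()
  expect_length(specs, 18)
  expect_false(any(vapply(specs, function(s) length(s$random) == 2,
                          logical(1))))
  specs24 <- candidate_model_set(include_both_random = TRUE)
  expect_length(specs24, 24)
  expect_equal(sum(vapply(specs24, function(s) length(s$random) == 2,
                          logical(1))), 6)
})

test_that("design construction reproduces the audit's group counts", {
  rec <- records_from_counts(register_reference("error_counts"))
  sp <- model_spec(c("LOCUS", "YEAR"), c("IND", "MP:IND"))
  des <- build_design(rec, sp)
  # zero-error levels dropped: locus EV001 and Lab 3
  expect_setequal(des$dropped$locus, "EV001")
  expect_setequal(des$dropped$lab, "Lab3")
  expect_equal(des$n_ind, 215)
  expect_equal(des$n_mp, 645)
  expect_equal(des$n_rows, 215 * 9)
  expect_equal(ncol(des$X), 1 + 8 + 1)  # intercept, 8 locus contrasts, year
  # retaining the zero-error levels triggers the separation warning
  expect_warning(build_design(rec, sp, drop_zero = FALSE), "separation")
  # reference override moves the absorbed level
  des2 <- build_design(rec, model_spec("LOCUS", "IND"),
                       reference = list(locus = "GT509"))
  expect_identical(des2$locus_levels[1], "GT509")
})

test_that("quadrature reduces to the ordinary logistic likelihood", {
  rec <- records_from_counts(register_reference("error_counts"))
  sp <- model_spec(c("LOCUS", "YEAR"), "IND")
  des <- build_design(rec, sp)
  beta <- c(-3, rnorm(ncol(des$X) - 1, 0, 0.3))
  plain <- sum(des$y * drop(des$X %*% beta) -
                 log1p(exp(drop(des$X %*% beta))))
  expect_equal(marginal_loglik(beta, 0, 0, des), plain, tolerance = 1e-10)
  expect_equal(marginal_loglik(beta, 1e-9, 0, des), plain,
               tolerance = 1e-6)
  expect_equal(marginal_loglik(beta, 0, 1e-9, des), plain,
               tolerance = 1e-6)
})

test_that("quadrature matches exact integration and is order-stable", {
  set.seed(8)
  toy <- make_records(6)
  hit <- sample(nrow(toy), 18)
  toy$reg_allele1[hit] <- 201
  toy <- finalize_records(toy)
  sp <- model_spec(character(), "IND")
  des <- build_design(toy, sp, drop_zero = FALSE)
  beta <- -0.4
  sg <- 1.2
  # per-group 1-D integrals by adaptive numerical integration (oracle)
  eta <- drop(des$X %*% beta)
  exact <- sum(vapply(split(seq_along(des$y), des$ind), function(rows) {
    f <- function(b) vapply(b, function(bb) {
      pr <- plogis(eta[rows] + bb)
      prod(ifelse(des$y[rows] == 1, pr, 1 - pr)) * dnorm(bb, 0, sg)
    }, numeric(1))
    log(stats::integrate(f, -12 * sg, 12 * sg, rel.tol = 1e-12)$value)
  }, numeric(1)))
  ll20 <- marginal_loglik(beta, sg, 0, des, order = 20)
  ll40 <- marginal_loglik(beta, sg, 0, des, order = 40)
  expect_equal(ll20, exact, tolerance = 1e-8)
  expect_lt(abs(ll40 - ll20), 1e-6)
})

test_that("nested quadrature is consistent with its one-dimensional limits", {
  set.seed(9)
  toy <- make_records(5)
  hit <- sample(nrow(toy), 14)
  toy$reg_allele1[hit] <- 204
  toy <- finalize_records(toy)
  spb <- model_spec(character(), c("IND", "MP:IND"))
  desb <- build_design(toy, spb, drop_zero = FALSE)
  spm <- model_spec(character(), "MP:IND")
  desm <- build_design(toy, spm, drop_zero = FALSE)
  spi <- model_spec(character(), "IND")
  desi <- build_design(toy, spi, drop_zero = FALSE)
  beta <- -0.6
  # sigma_ind -> 0: collapses to the multiplex-only integral
  expect_equal(marginal_loglik(beta, 1e-10, 0.9, desb),
               marginal_loglik(beta, 0, 0.9, desm), tolerance = 1e-8)
  # sigma_mp -> 0: collapses to the individual-only integral
  expect_equal(marginal_loglik(beta, 1.1, 1e-10, desb),
               marginal_loglik(beta, 1.1, 0, desi), tolerance = 1e-6)
  # genuinely nested value is finite and below the saturated bound
  llb <- marginal_loglik(beta, 0.8, 0.5, desb)
  expect_true(is.finite(llb))
  expect_lt(llb, 0)
})

test_that("marginal likelihood is invariant to individual relabeling", {
  set.seed(10)
  toy <- make_records(8)
  toy$reg_allele1[sample(nrow(toy), 12)] <- 201
  toy <- finalize_records(toy)
  sp <- model_spec(character(), "IND")
  d1 <- build_design(toy, sp, drop_zero = FALSE)
  relab <- toy
  ids <- unique(toy$individual_id)
  map <- setNames(sample(sprintf("z%02d", seq_along(ids))), ids)
  relab$individual_id <- unname(map[relab$individual_id])
  d2 <- build_design(relab, sp, drop_zero = FALSE)
  expect_equal(marginal_loglik(-0.7, 1.3, 0, d1),
               marginal_loglik(-0.7, 1.3, 0, d2), tolerance = 1e-10)
})

test_that("clustered all-or-nothing responses favor a positive sigma", {
  # 10 individuals, half error-free and half all-errors: strong clustering
  err <- matrix(FALSE, 10, 10)
  err[1:5, ] <- TRUE
  rec <- records_with_pattern(err)
  des <- build_design(rec, model_spec(character(), "IND"),
                      drop_zero = FALSE)
  expect_gt(marginal_loglik(0, 3, 0, des), marginal_loglik(0, 0, 0, des))
})

test_that("intercept-only fits recover closed forms and AIC bookkeeping", {
  err <- matrix(FALSE, 40, 10)
  err[cbind(sample(40, 30, TRUE), sample(10, 30, TRUE))] <- TRUE
  rec <- records_with_pattern(err)
  f <- mean(rec$is_error)
  sp <- model_spec()
  fit <- fit_error_model(sp, build_design(rec, sp, drop_zero = FALSE))
  expect_true(fit$converged)
  expect_equal(unname(fit$beta["(Intercept)"]), qlogis(f),
               tolerance = 1e-6)
  expect_equal(fit$k, 1)
  expect_equal(fit$aic, -2 * fit$loglik + 2)
  # adding a random term adds one AIC parameter
  spi <- model_spec(character(), "IND")
  fiti <- fit_error_model(spi, build_design(rec, spi, drop_zero = FALSE))
  expect_equal(fiti$k, 2)
})

test_that("a zero-variance truth drives sigma to the boundary", {
  sp0 <- model_spec()
  spi <- model_spec(character(), "IND")
  # under-dispersed data (every individual exactly one error): the variance
  # MLE is exactly zero and the mixed fit collapses to the logistic one
  err_u <- matrix(FALSE, 60, 10)
  err_u[cbind(1:60, rep(1:10, 6))] <- TRUE
  rec_u <- records_with_pattern(err_u)
  fit0 <- fit_error_model(sp0, build_design(rec_u, sp0, drop_zero = FALSE))
  fiti <- fit_error_model(spi, build_design(rec_u, spi, drop_zero = FALSE))
  expect_true(fiti$boundary)
  expect_lt(fiti$sigma_ind, 0.01)
  expect_lt(abs(fiti$loglik - fit0$loglik), 1e-4)
  # independent binomial truth: no spurious clustering signal (the
  # likelihood-ratio against the logistic fit stays negligible)
  set.seed(14)
  err_b <- matrix(runif(200 * 10) < 0.08, 200, 10)
  rec_b <- records_with_pattern(err_b)
  f0 <- fit_error_model(sp0, build_design(rec_b, sp0, drop_zero = FALSE))
  fi <- fit_error_model(spi, build_design(rec_b, spi, drop_zero = FALSE))
  expect_lt(fi$sigma_ind, 0.4)
  expect_lt(2 * (fi$loglik - f0$loglik), 2)
  expect_gte(fi$loglik, f0$loglik - 1e-5)
})

test_that("akaike weights follow the closed form", {
  expect_equal(akaike_weights(c(100, 100, 100)), rep(1 / 3, 3))
  w <- akaike_weights(c(10, 12))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(w[1], 0.73106, tolerance = 1e-5)
  aic <- c(295.7, 303.1, 297.5, 319.8)
  ww <- akaike_weights(aic)
  expect_equal(sum(ww), 1, tolerance = 1e-12)
  expect_equal(order(ww, decreasing = TRUE), order(aic))
  expect_error(akaike_weights(c(Inf, Inf)), "finite")
})

test_that("fit agrees with an independent GLMM implementation", {
  skip_if_not_installed("lme4")
  eff <- c(GATA417 = 1.2, GT509 = -0.5, GT310 = 0, GT211 = 0.4,
           GATA098 = -0.8)
  loci <- register_loci()
  loci <- loci[loci$locus %in% names(eff), ]
  des_sim <- simulation_design(years = 2001, individuals_per_year = 400,
                               lab_schedule = c("2001" = "Lab1"),
                               exclusions = NULL, loci = loci,
                               freq_seed = 3)
  params <- error_model_params(intercept = -2, locus_effects = eff,
                               year_slope = 0, sigma_ind = 1)
  sim <- simulate_register(des_sim, params, seed = 17)
  rec <- compare_profiles(sim$register, sim$truth)
  sp <- model_spec("LOCUS", "IND")
  des <- build_design(rec, sp)
  fit <- fit_error_model(sp, des)
  df <- des$records
  df$y <- des$y
  gm <- lme4::glmer(y ~ locus + (1 | individual_id), data = df,
                    family = stats::binomial(), nAGQ = 20)
  # same marginal likelihood surface: our MLE cannot fall below glmer's
  expect_gte(fit$loglik, as.numeric(stats::logLik(gm)) - 1e-3)
  expect_equal(fit$sigma_ind, sqrt(unname(unlist(lme4::VarCorr(gm)))),
               tolerance = 0.05)
  fe <- lme4::fixef(gm)
  expect_equal(unname(fit$beta[names(fe)]), unname(fe), tolerance = 0.05)
})

test_that("strong locus effects are selected by the candidate set", {
  eff <- c(GATA417 = 2, GT509 = -1, GT310 = 1, GT211 = -1, GATA098 = 0,
           GT023 = 1, GT575 = -1, GATA028 = 2, EV001 = 0, EV037 = -1)
  wins <- 0L
  for (s in 1:10) {
    des_sim <- simulation_design(individuals_per_year = 10,
                                 exclusions = NULL)
    params <- error_model_params(intercept = -3, locus_effects = eff,
                                 year_slope = 0, sigma_ind = 1)
    sim <- simulate_register(des_sim, params, seed = 200 + s)
    rec <- compare_profiles(sim$register, sim$truth)
    sel <- suppressWarnings(fit_candidate_set(rec, order = 10))
    if (grepl("LOCUS", sel$table$fixed[1])) wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
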