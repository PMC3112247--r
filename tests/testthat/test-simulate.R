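test_that("allele spectra span the panel ranges and are deterministic", {
  loci <- register_loci()
  f1 <- default_allele_frequencies(loci, seed = 11)
  f2 <- default_allele_frequencies(loci, seed = 11)
  f3 <- default_allele_frequencies(loci, seed = 12)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  for (i in seq_len(nrow(loci))) {
    f <- f1[[loci$locus[i]]]
    expect_true(all(f$length >= loci$len_min[i]))
    expect_true(all(f$length <= loci$len_max[i]))
    expect_true(all(diff(f$length) == loci$repeat_unit[i]))
    expect_equal(sum(f$prob), 1, tolerance = 1e-12)
  }
})

test_that("the default design reproduces the analyzed sampling frame", {
  sim <- simulate_register(seed = 1)
  prof <- sim$truth
  n_by_lab <- tapply(prof$individual_id, prof$lab,
                     function(x) length(unique(x)))
  expect_equal(as.vector(n_by_lab[c("Lab1", "Lab2", "Lab3", "Lab4")]),
               c(116, 60, 19, 39))
  expect_equal(length(unique(prof$individual_id)), 234)
  expect_equal(nrow(prof), 2340)
  # no exclusions keeps the full 240
  sim240 <- simulate_register(simulation_design(exclusions = NULL), seed = 1)
  expect_equal(length(unique(sim240$truth$individual_id)), 240)
})

test_that("a saturated logit gives half-rate mismatches and a degenerate one none", {
  eff <- genoaudit:::default_locus_effects()
  eff[] <- 0
  half <- error_model_params(intercept = 0, locus_effects = eff,
                             year_slope = 0, sigma_ind = 0)
  sim <- simulate_register(params = half, seed = 7)
  rec <- compare_profiles(sim$register, sim$truth)
  expect_equal(mean(rec$is_error), 0.5,
               tolerance = 3 * sqrt(0.25 / nrow(rec)) / 0.5)

  none <- error_model_params(intercept = -50, locus_effects = eff,
                             year_slope = 0, sigma_ind = 0)
  sim0 <- simulate_register(params = none, seed = 7)
  expect_identical(sim0$register, sim0$truth)
})

test_that("EV001 carries a structural zero error rate", {
  sim <- simulate_register(seed = 21)
  rec <- compare_profiles(sim$register, sim$truth)
  expect_equal(sum(rec$is_error[rec$locus == "EV001"]), 0)
})

test_that("generated error types match the class-renormalized mixture", {
  # elevated error rate so each seed yields hundreds of classified errors
  eff <- genoaudit:::default_locus_effects()
  eff["EV001"] <- 0
  params <- error_model_params(intercept = -1.5, locus_effects = eff * 0,
                               year_slope = 0, sigma_ind = 0)
  het_mix <- params$type_mix[c("single_false_allele", "double_false_allele",
                               "false_homozygote")]
  het_mix <- het_mix / sum(het_mix)
  rejected <- 0L
  for (s in 1:10) {
    sim <- simulate_register(params = params, seed = 100 + s)
    rec <- compare_profiles(sim$register, sim$truth)
    err <- rec[rec$is_error, ]
    het <- err$true_allele1 != err$true_allele2
    # homozygote errors can only surface as false heterozygotes
    expect_true(all(err$error_class[!het] == "false_heterozygote"))
    obs <- table(factor(err$error_class[het], levels = names(het_mix)))
    pval <- suppressWarnings(
      stats::chisq.test(obs, p = het_mix)$p.value)
    if (pval < 0.01) rejected <- rejected + 1L
  }
  expect_lte(rejected, 1L)
})

test_that("error indicators are conditionally independent across loci", {
  # with sigma = 0 the per-individual error counts are binomial: the
  # dispersion ratio is 1; a positive sigma inflates it
  eff <- genoaudit:::default_locus_effects()
  eff[] <- 0
  des <- simulation_design(individuals_per_year = 420, exclusions = NULL)
  params0 <- error_model_params(intercept = -3, locus_effects = eff,
                                year_slope = 0, sigma_ind = 0)
  sim <- simulate_register(des, params0, seed = 5)
  rec <- compare_profiles(sim$register, sim$truth)
  counts <- tapply(rec$is_error, rec$individual_id, sum)
  L <- 10
  p_hat <- mean(rec$is_error)
  disp <- var(counts) / (L * p_hat * (1 - p_hat))
  expect_lt(abs(disp - 1), 0.1)

  params1 <- error_model_params(intercept = -3, locus_effects = eff,
                                year_slope = 0, sigma_ind = 1.345)
  sim1 <- simulate_register(des, params1, seed = 5)
  rec1 <- compare_profiles(sim1$register, sim1$truth)
  counts1 <- tapply(rec1$is_error, rec1$individual_id, sum)
  p1 <- mean(rec1$is_error)
  disp1 <- var(counts1) / (L * p1 * (1 - p1))
  expect_gt(disp1, 1.3)
})

test_that("the empirical error rate matches the model-implied expectation", {
  # quadrature oracle for the population-averaged rate of every analyzed
  # individual x retained locus cell under the default generative model
  params <- error_model_params()
  sim <- simulate_register(seed = 31)
  rec <- compare_profiles(sim$register, sim$truth)
  rr <- rec[rec$locus != "EV001", ]
  mus <- outer(params$intercept +
                 params$locus_effects[setdiff(names(params$locus_effects),
                                              "EV001")],
               params$year_slope * (rr$year[!duplicated(rr$individual_id)] -
                                      params$center_year), "+")
  expected <- mean(apply(mus, c(1, 2), gh_marginal, sigma = params$sigma_ind))
  se <- sqrt(expected * (1 - expected) / nrow(rr))
  expect_lt(abs(mean(rr$is_error) - expected), 4 * se)
})
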