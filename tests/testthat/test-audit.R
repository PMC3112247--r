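test_that("classifier reproduces the audited error taxonomy", {
  cases <- list(
    # heterozygote collapsing onto one of its alleles
    list(t = c(150, 154), o = c(150, 150),
         class = "false_homozygote", count = 1L, shift = "gt_1bp"),
    # homozygote gaining a novel allele one repeat unit away
    list(t = c(150, 150), o = c(150, 152),
         class = "false_heterozygote", count = 1L, shift = "gt_1bp"),
    # one allele misread by 1 bp, partner intact
    list(t = c(221, 230), o = c(220, 230),
         class = "single_false_allele", count = 1L, shift = "eq_1bp"),
    # both alleles misread
    list(t = c(150, 154), o = c(151, 153),
         class = "double_false_allele", count = 2L, shift = "eq_1bp"),
    list(t = c(150, 154), o = c(151, 158),
         class = "double_false_allele", count = 2L, shift = "mixed"),
    # unobserved corner: heterozygote recorded as homozygote of a novel allele
    list(t = c(150, 154), o = c(151, 151),
         class = "false_homozygote", count = 2L, shift = "mixed"),
    # homozygote-to-homozygote shift hits both copies
    list(t = c(150, 150), o = c(152, 152),
         class = "double_false_allele", count = 2L, shift = "gt_1bp")
  )
  for (cs in cases) {
    got <- classify_genotype_error(cs$t, cs$o)
    expect_identical(got$error_class, cs$class,
                     label = paste(cs$t, collapse = "/"))
    expect_identical(got$allele_error_count, cs$count)
    expect_identical(got$shift_class, cs$shift)
  }
  expect_error(classify_genotype_error(c(150, 154), c(154, 150)),
               "identical")
})

test_that("allele error count equals the brute-force minimum substitutions", {
  # exhaustive oracle over every genotype pair from a 6-length alphabet:
  # count = 2 minus the multiset intersection size, via table comparison
  alphabet <- 150:155
  pairs <- expand.grid(a = alphabet, b = alphabet)
  pairs <- pairs[pairs$a <= pairs$b, ]
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      t <- c(pairs$a[i], pairs$b[i])
      o <- c(pairs$a[j], pairs$b[j])
      if (identical(t, o)) next
      tt <- table(factor(t, levels = alphabet))
      to <- table(factor(o, levels = alphabet))
      oracle <- 2L - as.integer(sum(pmin(tt, to)))
      got <- classify_genotype_error(t, o)
      expect_identical(got$allele_error_count, oracle,
                       label = paste(t[1], t[2], "->", o[1], o[2]))
    }
  }
})

test_that("compare_profiles produces one classified record per cell", {
  truth <- as_profiles(data.frame(
    individual_id = rep(c("a", "b"), each = 2),
    year = 2001, lab = "Lab1",
    locus = rep(c("GT509", "GATA417"), 2),
    allele1 = c(203, 227, 207, 231),
    allele2 = c(207, 231, 207, 239)
  ))
  reg <- truth
  reg$allele1[reg$individual_id == "a" & reg$locus == "GT509"] <- 204
  rec <- compare_profiles(reg, truth)
  expect_equal(nrow(rec), 4)
  expect_equal(sum(rec$is_error), 1)
  hit <- rec[rec$is_error, ]
  expect_identical(hit$error_class, "single_false_allele")
  expect_identical(hit$shift_class, "eq_1bp")
  expect_true(all(rec$is_error == (rec$allele_error_count > 0)))
  expect_true(all((rec$error_class == "none") == !rec$is_error))

  # identical inputs: no errors at all
  clean <- compare_profiles(truth, truth)
  expect_false(any(clean$is_error))

  expect_error(compare_profiles(reg[reg$individual_id == "a", ], truth),
               "different individuals")
  expect_error(compare_profiles(reg[-1, ], truth[-3, ]), "different loci")
})

test_that("tally round-trips the published count table", {
  counts <- register_reference("error_counts")
  rec <- records_from_counts(counts)
  expect_equal(nrow(rec), 2340)
  expect_equal(sum(rec$is_error), 31)
  # false allele sizes make up 18 of the 31 locus-level errors
  expect_equal(sum(rec$error_class %in%
                     c("single_false_allele", "double_false_allele")), 18)
  tal <- tally_errors(rec)
  for (i in seq_len(nrow(counts))) {
    col <- paste0("n_", counts$shift_class[i])
    got <- tal[tal$lab == counts$lab[i] &
               tal$error_class == counts$error_class[i], col]
    expect_equal(got, counts$n[i],
                 label = paste(counts$lab[i], counts$error_class[i],
                               counts$shift_class[i]))
  }
  # lab totals, the audited column sums
  lab1 <- tal[tal$lab == "Lab1", ]
  expect_equal(lab1$n_total[match(c("single_false_allele",
                                    "double_false_allele",
                                    "false_homozygote",
                                    "false_heterozygote"),
                                  lab1$error_class)], c(10, 6, 9, 2))
  # an error-free audit gives an all-zero table
  zero <- tally_errors(make_records(3))
  expect_true(all(zero$n_total == 0))
})

test_that("empirical rates follow the binomial formulas and invariants", {
  err <- data.frame(row = c(1, 13, 25), reg1 = c(201, 201, 201),
                    reg2 = c(201, 208, 209))
  rec <- make_records(5, errors = err)  # one double, one single, one double
  rates <- empirical_error_rates(rec, "total")
  m <- nrow(rec)
  expect_equal(rates$p_l, 3 / m)
  expect_equal(rates$p_a, 5 / (2 * m))
  expect_equal(rates$sd_pl, sqrt((3 / m) * (1 - 3 / m) / m))
  expect_equal(rates$sd_pa, sqrt((5 / (2 * m)) * (1 - 5 / (2 * m)) / (2 * m)))
  expect_equal(rates$pred, 1 - (1 - rates$p_a)^2)

  # p_a <= p_l <= 2 p_a on the audit-shaped fixture, per lab
  lab <- empirical_error_rates(records_from_counts(
    register_reference("error_counts")), "lab")
  expect_true(all(lab$p_a <= lab$p_l + 1e-12))
  expect_true(all(lab$p_l <= 2 * lab$p_a + 1e-12))
  expect_error(empirical_error_rates(rec[0, ], "total"), "no comparison")
})

test_that("independence prediction is anchored, monotone and dominates p_a", {
  expect_equal(predict_pl_from_pa(0), 0)
  expect_equal(predict_pl_from_pa(1), 1)
  p <- seq(0, 0.5, by = 0.01)
  pred <- predict_pl_from_pa(p)
  expect_true(all(diff(pred) > 0))
  expect_true(all(pred[-1] > p[-1]))
  expect_error(predict_pl_from_pa(1.2), "0, 1")
  expect_error(predict_pl_from_pa(-0.1), "0, 1")
})
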