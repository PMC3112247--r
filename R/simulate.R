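#' Sampling design for a synthetic register audit
#'
#' Describes the audit's sampling frame: 20 individuals drawn per catch year
#' 1997-2008, a year-to-laboratory schedule (Lab1 1997-2002, Lab2 2003-2005,
#' Lab3 2006, Lab4 2007-2008), the locus panel with its multiplex partition,
#' and per-locus allele frequency spectra. The default exclusion schedule
#' removes six failed samples (two from 1997, one each from 1998, 2000, 2006
#' and 2008), reproducing the analyzed per-lab sample sizes 116/60/19/39;
#' set `exclusions = NULL` to keep all 240.
#'
#' @param years calendar years sampled.
#' @param individuals_per_year samples drawn per year.
#' @param lab_schedule named character vector mapping year -> laboratory;
#'   must cover `years`.
#' @param exclusions named integer vector: number of samples per year that
#'   failed to amplify and are dropped, or NULL for none.
#' @param loci locus metadata as from [register_loci()].
#' @param allele_freqs per-locus allele frequency spectra as from
#'   [default_allele_frequencies()]; defaults to spectra drawn with
#'   `freq_seed`.
#' @param freq_seed seed for the default spectra.
#' @return list of class `simulation_design`.
#' @export
simulation_design <- function(years = 1997:2008, individuals_per_year = 20,
                              lab_schedule = default_lab_schedule(),
                              exclusions = c("1997" = 2, "1998" = 1,
                                             "2000" = 1, "2006" = 1,
                                             "2008" = 1),
                              loci = register_loci(), allele_freqs = NULL,
                              freq_seed = 777) {
  if (!all(as.character(years) %in% names(lab_schedule))) {
    stop("lab_schedule must cover every sampled year")
  }
  if (is.null(allele_freqs)) {
    allele_freqs <- default_allele_frequencies(loci, seed = freq_seed)
  }
  stopifnot(setequal(names(allele_freqs), loci$locus))
  for (f in allele_freqs) {
    stopifnot(abs(sum(f$prob) - 1) < 1e-8, all(f$prob >= 0))
  }
  if (!is.null(exclusions)) {
    stopifnot(all(names(exclusions) %in% as.character(years)))
  }
  structure(list(years = years, individuals_per_year = individuals_per_year,
                 lab_schedule = lab_schedule, exclusions = exclusions,
                 loci = loci, allele_freqs = allele_freqs),
            class = "simulation_design")
}

#' @rdname simulation_design
#' @export
default_lab_schedule <- function() {
  c("1997" = "Lab1", "1998" = "Lab1", "1999" = "Lab1", "2000" = "Lab1",
    "2001" = "Lab1", "2002" = "Lab1", "2003" = "Lab2", "2004" = "Lab2",
    "2005" = "Lab2", "2006" = "Lab3", "2007" = "Lab4", "2008" = "Lab4")
}

#' Synthetic per-locus allele frequency spectra
#'
#' The register's true allele frequencies are not public, so spectra are
#' drawn once from a symmetric Dirichlet over a repeat-unit ladder spanning
#' each locus's observed allele-length range (4-bp steps for GATA loci,
#' 2-bp otherwise). No downstream population-level quantity depends on the
#' particular spectra; they only set heterozygosity in the generator.
#'
#' @param loci locus metadata with `len_min`, `len_max`, `repeat_unit`.
#' @param seed integer seed; a fixed seed gives identical spectra.
#' @param concentration Dirichlet concentration per allele.
#' @return named list: per locus a data.frame with `length` (bp) and `prob`.
#' @export
default_allele_frequencies <- function(loci = register_loci(), seed = 777,
                                       concentration = 5) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  out <- lapply(seq_len(nrow(loci)), function(i) {
    support <- seq(loci$len_min[i], loci$len_max[i], by = loci$repeat_unit[i])
    w <- rgamma(length(support), shape = concentration)
    data.frame(length = support, prob = w / sum(w))
  })
  names(out) <- loci$locus
  out
}

#' Generative parameters of the error model
#'
#' The error indicator at locus l of individual i is Bernoulli with
#' probability `plogis(eta_il)`, where
#' `eta_il = intercept + locus_effects[l] + year_slope * (year - center_year)
#' + b_i + b_im`, with `b_i ~ N(0, sigma_ind^2)` shared across the
#' individual's loci and `b_im ~ N(0, sigma_mp^2)` shared within each
#' multiplex assay of that individual. Defaults are the best-fitting model's
#' estimates for the minke whale register (intercept -4.74, year slope
#' -0.36 per year centered at 2001, individual variance 1.81); EV001, at
#' which no errors were observed, gets an effect of `-Inf` (structural zero
#' rate). When `lab_effects` is supplied it replaces the year trend.
#'
#' Conditional on an error, the error type is drawn from `type_mix`
#' renormalized to the types compatible with the true genotype's class:
#' heterozygotes can show a single or double false allele size or collapse
#' to a false homozygote; homozygotes can only show a false heterozygote
#' (one shifted gene copy). Shifted alleles move by 1 bp with probability
#' `p_shift_1bp` and otherwise by one repeat unit.
#'
#' @param intercept logit-scale intercept.
#' @param locus_effects named numeric vector of per-locus offsets
#'   (`-Inf` allowed for structural zeros).
#' @param year_slope fixed-effect slope on the centered year covariate.
#' @param lab_effects optional named vector of per-lab offsets replacing the
#'   year trend (reference lab 0).
#' @param center_year centering constant for YEAR.
#' @param sigma_ind,sigma_mp random-effect standard deviations (>= 0).
#' @param type_mix error-type mixture, summing to 1, named
#'   `single_false_allele`, `double_false_allele`, `false_homozygote`,
#'   `false_heterozygote`. Defaults to the audited proportions 12/6/10/3
#'   out of 31.
#' @param p_shift_1bp probability a shifted allele moves exactly 1 bp.
#' @return list of class `error_model_params`.
#' @export
error_model_params <- function(intercept = -4.74,
                               locus_effects = default_locus_effects(),
                               year_slope = -0.36, lab_effects = NULL,
                               center_year = 2001,
                               sigma_ind = sqrt(1.81), sigma_mp = 0,
                               type_mix = c(single_false_allele = 12,
                                            double_false_allele = 6,
                                            false_homozygote = 10,
                                            false_heterozygote = 3) / 31,
                               p_shift_1bp = 0.45) {
  stopifnot(sigma_ind >= 0, sigma_mp >= 0,
            abs(sum(type_mix) - 1) < 1e-8, all(type_mix >= 0),
            p_shift_1bp >= 0, p_shift_1bp <= 1)
  need <- c("single_false_allele", "double_false_allele",
            "false_homozygote", "false_heterozygote")
  stopifnot(setequal(names(type_mix), need))
  het_w <- type_mix[c("single_false_allele", "double_false_allele",
                      "false_homozygote")]
  if (sum(het_w) <= 0) {
    stop("type_mix has no error type compatible with heterozygous genotypes")
  }
  structure(list(intercept = intercept, locus_effects = locus_effects,
                 year_slope = year_slope, lab_effects = lab_effects,
                 center_year = center_year, sigma_ind = sigma_ind,
                 sigma_mp = sigma_mp, type_mix = type_mix[need],
                 p_shift_1bp = p_shift_1bp),
            class = "error_model_params")
}

#' @rdname error_model_params
#' @export
default_locus_effects <- function() {
  c(GATA417 = 1.59, EV037 = 0.40, GATA028 = 0.40, GT575 = 0.09,
    GT509 = -0.35, GT310 = -0.35, GT211 = -0.35, GT023 = -0.35,
    GATA098 = -1.08, EV001 = -Inf)
}

#' Linear predictor means implied by generator parameters
#'
#' Returns `mu_l = intercept + locus_effects + year_slope * (year -
#' center_year)` (or the lab offset) for every locus, the fixed part of the
#' generative logit. Used by tests to compare simulated rates against their
#' quadrature expectation.
#'
#' @param params an `error_model_params`.
#' @param year calendar year, or NULL when `lab` is given.
#' @param lab laboratory level, used when `params$lab_effects` is set.
#' @return named numeric vector over loci (may contain `-Inf`).
#' @export
predictor_means <- function(params, year = NULL, lab = NULL) {
  mu <- params$intercept + params$locus_effects
  if (!is.null(params$lab_effects)) {
    stopifnot(!is.null(lab))
    off <- if (lab %in% names(params$lab_effects)) params$lab_effects[[lab]] else 0
    mu <- mu + off
  } else {
    stopifnot(!is.null(year))
    mu <- mu + params$year_slope * (year - params$center_year)
  }
  mu
}

#' Simulate a register and its re-genotyped truth
#'
#' Draws true genotypes as Hardy-Weinberg pairs from the per-locus allele
#' spectra, then perturbs a copy of them with genotyping errors generated by
#' the logistic mixed model in [error_model_params()]: per individual a
#' shared normal deviate (and optionally one per multiplex assay) shifts the
#' logit error probability at all loci, errors are drawn as independent
#' Bernoulli trials conditional on those deviates, and each error mutates
#' the observed genotype according to its drawn type.
#'
#' @param design a [simulation_design()].
#' @param params an [error_model_params()].
#' @param seed integer seed.
#' @return list with canonical profile tables `truth` and `register`, plus
#'   `params`, `design` and `seed` attached for provenance.
#' @export
simulate_register <- function(design = simulation_design(),
                              params = error_model_params(), seed = 1) {
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  loci <- design$loci
  L <- nrow(loci)
  years <- rep(design$years, each = design$individuals_per_year)
  if (!is.null(design$exclusions)) {
    drop <- integer(0)
    for (yr in names(design$exclusions)) {
      idx <- which(years == as.integer(yr))
      drop <- c(drop, idx[seq_len(design$exclusions[[yr]])])
    }
    years <- years[-drop]
  }
  n <- length(years)
  ids <- sprintf("W%04d", seq_len(n))
  labs <- unname(design$lab_schedule[as.character(years)])

  # true genotypes: n x L allele pairs under Hardy-Weinberg equilibrium
  a1 <- matrix(0L, n, L)
  a2 <- matrix(0L, n, L)
  for (l in seq_len(L)) {
    f <- design$allele_freqs[[loci$locus[l]]]
    a1[, l] <- sample(f$length, n, replace = TRUE, prob = f$prob)
    a2[, l] <- sample(f$length, n, replace = TRUE, prob = f$prob)
  }

  # linear predictor and error indicators
  mp_levels <- sort(unique(loci$multiplex))
  mp_idx <- match(loci$multiplex, mp_levels)
  b_ind <- rnorm(n, 0, params$sigma_ind)
  b_mp <- matrix(rnorm(n * length(mp_levels), 0, params$sigma_mp),
                 n, length(mp_levels))
  eta <- matrix(params$intercept, n, L)
  for (l in seq_len(L)) {
    eta[, l] <- eta[, l] + params$locus_effects[[loci$locus[l]]] +
      b_ind + b_mp[, mp_idx[l]]
  }
  if (!is.null(params$lab_effects)) {
    off <- ifelse(labs %in% names(params$lab_effects),
                  unlist(params$lab_effects)[labs], 0)
    eta <- eta + off
  } else {
    eta <- eta + params$year_slope * (years - params$center_year)
  }
  err <- matrix(rbinom(n * L, 1, plogis(as.vector(eta))), n, L) == 1

  o1 <- a1
  o2 <- a2
  cells <- which(err, arr.ind = TRUE)
  if (nrow(cells) > 0) {
    for (k in seq_len(nrow(cells))) {
      i <- cells[k, 1]
      l <- cells[k, 2]
      g <- mutate_genotype(c(a1[i, l], a2[i, l]), loci$repeat_unit[l], params)
      o1[i, l] <- g[1]
      o2[i, l] <- g[2]
    }
  }

  build <- function(m1, m2) {
    as_profiles(data.frame(
      individual_id = rep(ids, each = L),
      year = rep(years, each = L),
      lab = rep(labs, each = L),
      locus = rep(loci$locus, n),
      allele1 = as.vector(t(m1)),
      allele2 = as.vector(t(m2)),
      multiplex = rep(loci$multiplex, n),
      stringsAsFactors = FALSE
    ), loci = loci)
  }
  list(truth = build(a1, a2), register = build(o1, o2),
       params = params, design = design, seed = seed)
}

# Mutate one true genotype according to a drawn error type. The observed
# class must survive the audit's classifier, so shifted alleles never land
# on the partner allele (which would silently change the class).
mutate_genotype <- function(gt, unit, params) {
  het <- gt[1] != gt[2]
  mix <- params$type_mix
  if (het) {
    w <- mix[c("single_false_allele", "double_false_allele",
               "false_homozygote")]
  } else {
    w <- mix["false_heterozygote"]
    if (sum(w) <= 0) w <- c(false_heterozygote = 1)
  }
  type <- sample(names(w), 1, prob = w / sum(w))
  draw_shift <- function() {
    mag <- if (runif(1) < params$p_shift_1bp) 1 else unit
    mag * sample(c(-1L, 1L), 1)
  }
  shift_one <- function(value, avoid) {
    for (try in 1:50) {
      cand <- value + draw_shift()
      if (cand > 0 && !(cand %in% avoid)) return(cand)
    }
    cand <- value + unit  # deterministic fallback
    while (cand %in% avoid) cand <- cand + unit
    cand
  }
  switch(type,
    single_false_allele = {
      j <- sample(1:2, 1)
      gt[j] <- shift_one(gt[j], avoid = gt[-j])
      gt
    },
    double_false_allele = {
      # both copies must land off the true pair, or the audit would read
      # the outcome as a single false allele
      for (try in 1:50) {
        cand <- c(shift_one(gt[1], avoid = gt),
                  shift_one(gt[2], avoid = gt))
        if (cand[1] != cand[2]) return(cand)
      }
      c(gt[1] + unit, gt[2] - unit)
    },
    false_homozygote = {
      j <- sample(1:2, 1)
      rep(gt[j], 2)
    },
    false_heterozygote = {
      c(gt[1], shift_one(gt[2], avoid = gt[2]))
    }
  )
}

# Save/restore the global RNG state so that seeded helpers do not disturb
# the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
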