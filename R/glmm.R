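fixed_terms <- c("LOCUS", "YEAR", "LAB")
random_terms <- c("IND", "MP:IND")

#' Specify a candidate error model
#'
#' A candidate model is a subset of the fixed effects LOCUS (factor), YEAR
#' (continuous, centered calendar year) and LAB (factor), plus a subset of
#' the random intercepts IND (shared across an individual's loci) and
#' MP:IND (shared within each multiplex assay of an individual). YEAR and
#' LAB are confounded by the laboratory schedule and never appear together.
#'
#' @param fixed character subset of `c("LOCUS", "YEAR", "LAB")`.
#' @param random character subset of `c("IND", "MP:IND")`.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(fixed = character(), random = character()) {
  fixed <- as.character(fixed)
  random <- as.character(random)
  fixed <- fixed[fixed != "-" & fixed != ""]
  random <- random[random != "-" & random != ""]
  stopifnot(all(fixed %in% fixed_terms), all(random %in% random_terms))
  if (all(c("YEAR", "LAB") %in% fixed)) {
    stop("YEAR and LAB are confounded and cannot enter the same model")
  }
  structure(list(fixed = sort(unique(fixed)), random = sort(unique(random))),
            class = "model_spec")
}

#' @rdname model_spec
#' @param x a `model_spec`.
#' @param ... unused.
#' @export
format.model_spec <- function(x, ...) {
  f <- if (length(x$fixed)) paste(x$fixed, collapse = "+") else "-"
  r <- if (length(x$random)) paste(x$random, collapse = "+") else "-"
  paste0(f, " | ", r)
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model:", format(x), "\n")
  invisible(x)
}

#' Enumerate the candidate model set
#'
#' The 6 admissible fixed-effect structures (LOCUS+YEAR, YEAR, LAB+LOCUS,
#' LAB, LOCUS, intercept-only) crossed with 3 random structures (IND,
#' MP:IND, none) give 18 candidate models. Models with both random effects
#' can be appended for completeness, but are excluded by default: whenever
#' both are present the MP:IND variance collapses to zero on audit-shaped
#' data, reducing them to the IND-only models.
#'
#' @param include_both_random also enumerate the 6 IND+MP:IND models.
#' @return list of [model_spec()] objects.
#' @export
candidate_model_set <- function(include_both_random = FALSE) {
  fixed_sets <- list(c("LOCUS", "YEAR"), "YEAR", c("LAB", "LOCUS"), "LAB",
                     "LOCUS", character(0))
  random_sets <- list("IND", "MP:IND", character(0))
  if (include_both_random) {
    random_sets <- c(random_sets, list(c("IND", "MP:IND")))
  }
  out <- list()
  for (f in fixed_sets) for (r in random_sets) {
    out[[length(out) + 1L]] <- model_spec(f, r)
  }
  out
}

#' Build model data from comparison records
#'
#' Turns classified comparison records into the response vector and design
#' matrix of a candidate model. Factor levels carrying no information about
#' the remaining parameters -- loci and labs at which no error was observed
#' -- are removed (rows dropped) before fitting; with the audit data these
#' are locus EV001 and Lab 3. LOCUS and LAB use treatment contrasts against
#' the alphabetically first retained level (overridable); YEAR enters as
#' calendar year minus `center_year`. Rows are ordered by individual and
#' multiplex so random-effect groups are contiguous.
#'
#' @param records comparison records from [compare_profiles()].
#' @param spec a [model_spec()].
#' @param center_year centering constant for YEAR.
#' @param drop_zero drop zero-error locus/lab levels (the audit's rule).
#' @param reference optional named list with `locus` and/or `lab` reference
#'   levels.
#' @return list with `y`, `X`, group indices `ind` and `mp` (contiguous
#'   integer codes), counts, the retained records, and level metadata.
#' @export
build_design <- function(records, spec, center_year = 2001,
                         drop_zero = TRUE, reference = list()) {
  stopifnot(inherits(spec, "model_spec"))
  rec <- records
  dropped <- list(locus = character(0), lab = character(0))
  if (drop_zero) {
    repeat {
      zl <- tapply(rec$is_error, rec$locus, sum)
      zb <- tapply(rec$is_error, rec$lab, sum)
      drop_l <- names(zl)[zl == 0]
      drop_b <- names(zb)[zb == 0]
      if (length(drop_l) == 0 && length(drop_b) == 0) break
      dropped$locus <- union(dropped$locus, drop_l)
      dropped$lab <- union(dropped$lab, drop_b)
      rec <- rec[!(rec$locus %in% drop_l) & !(rec$lab %in% drop_b), ,
                 drop = FALSE]
      if (nrow(rec) == 0) stop("all records dropped: no errors observed")
    }
  }
  rec <- rec[order(rec$individual_id, rec$multiplex, rec$locus), ,
             drop = FALSE]
  relevel_first <- function(x, ref) {
    lev <- sort(unique(x))
    if (!is.null(ref)) {
      stopifnot(ref %in% lev)
      lev <- c(ref, setdiff(lev, ref))
    }
    factor(x, levels = lev)
  }
  terms <- c("1")
  df <- data.frame(row = seq_len(nrow(rec)))
  if ("LOCUS" %in% spec$fixed) {
    df$locus <- relevel_first(rec$locus, reference$locus)
    terms <- c(terms, "locus")
  }
  if ("YEAR" %in% spec$fixed) {
    df$year_c <- rec$year - center_year
    terms <- c(terms, "year_c")
  }
  if ("LAB" %in% spec$fixed) {
    df$lab <- relevel_first(rec$lab, reference$lab)
    terms <- c(terms, "lab")
  }
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = "+"))), df)
  y <- as.integer(rec$is_error)
  # separation hazard: retained factor levels with all-zero responses
  for (v in intersect(c("locus", "lab"), names(df))) {
    lv <- tapply(y, df[[v]], sum)
    if (any(lv == 0)) {
      warning("all-zero responses at ", v, " level(s) ",
              paste(names(lv)[lv == 0], collapse = ", "),
              ": perfect-separation hazard")
    }
  }
  ind <- as.integer(factor(rec$individual_id,
                           levels = unique(rec$individual_id)))
  mp_key <- paste(rec$individual_id, rec$multiplex, sep = "\r")
  mp <- as.integer(factor(mp_key, levels = unique(mp_key)))
  list(y = y, X = X, ind = ind, mp = mp,
       n_ind = max(ind), n_mp = max(mp), n_rows = nrow(rec),
       records = rec, spec = spec, center_year = center_year,
       dropped = dropped,
       locus_levels = if ("LOCUS" %in% spec$fixed) levels(df$locus) else
         sort(unique(rec$locus)),
       lab_levels = if ("LAB" %in% spec$fixed) levels(df$lab) else
         sort(unique(rec$lab)))
}

group_starts <- function(idx) {
  # 0-based offsets of contiguous groups
  stopifnot(!is.unsorted(idx))
  c(0L, which(diff(idx) != 0L), length(idx))
}

#' Marginal log-likelihood of a logistic mixed model
#'
#' Integrates the conditional Bernoulli likelihood over the normal random
#' intercepts by adaptive Gauss-Hermite quadrature, recentered at each
#' group's conditional mode with Laplace curvature scaling. With one random
#' effect the integral is one-dimensional per group; with both, each
#' individual's integral nests the per-multiplex integrals inside the
#' individual-level one. With no random effect (both sigmas zero) the value
#' is the ordinary logistic log-likelihood, exactly.
#'
#' @param beta fixed-effect coefficients, in the column order of
#'   `design$X`.
#' @param sigma_ind,sigma_mp random-intercept standard deviations (>= 0;
#'   zero removes the term).
#' @param design model data from [build_design()].
#' @param order quadrature order (nodes per dimension).
#' @return the marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(beta, sigma_ind = 0, sigma_mp = 0, design,
                            order = 20) {
  stopifnot(order >= 1, sigma_ind >= 0, sigma_mp >= 0)
  if (any(!is.finite(beta))) stop("non-finite coefficients")
  eta <- drop(design$X %*% beta)
  y <- design$y
  use_ind <- sigma_ind > 0
  use_mp <- sigma_mp > 0
  if (!use_ind && !use_mp) {
    return(sum(y * eta - log1p(exp(eta))))
  }
  rule <- gh_rule(order)
  logw <- log(rule$weights)
  if (use_ind && use_mp) {
    bstarts <- group_starts(design$mp)
    # map blocks to individuals: individual of each block's first row
    blk_ind <- design$ind[bstarts[-length(bstarts)] + 1L]
    istarts <- group_starts(blk_ind)
    return(aghq_nested_loglik_cpp(eta, y, istarts, bstarts,
                                  sigma_ind, sigma_mp,
                                  rule$nodes, logw))
  }
  grp <- if (use_ind) design$ind else design$mp
  aghq_loglik_cpp(eta, y, group_starts(grp),
                  if (use_ind) sigma_ind else sigma_mp,
                  rule$nodes, logw)
}

#' Fit a candidate error model by maximum likelihood
#'
#' Maximizes [marginal_loglik()] over the fixed-effect coefficients and the
#' log random-effect standard deviations with L-BFGS-B, multi-started from
#' the ordinary logistic solution with sigma in `sigma_starts`. The AIC
#' parameter count is the number of coefficients plus one per random term.
#' The convergence flag requires optimizer success, a small scaled gradient
#' and a positive-definite Hessian on the non-boundary parameters;
#' non-convergence is flagged, not thrown, so bootstrap replicates can
#' account for it.
#'
#' @param spec a [model_spec()].
#' @param design model data from [build_design()] (built with the same
#'   spec).
#' @param order quadrature order.
#' @param sigma_starts starting values for each random-effect SD.
#' @param control passed to [stats::optim()] (L-BFGS-B).
#' @return list of class `error_model_fit`: `beta` (named), `sigma_ind`,
#'   `sigma_mp`, `loglik`, `k`, `aic`, `vcov` (of `c(beta, log sigma)`),
#'   `converged`, `boundary`, and design metadata in `info`.
#' @export
fit_error_model <- function(spec, design, order = 20,
                            sigma_starts = c(0.1, 1),
                            control = list()) {
  stopifnot(identical(spec$fixed, design$spec$fixed),
            identical(spec$random, design$spec$random))
  X <- design$X
  y <- design$y
  p <- ncol(X)
  nr <- length(spec$random)
  g0 <- suppressWarnings(glm.fit(X, y, family = binomial()))
  beta0 <- g0$coefficients
  beta0[!is.finite(beta0)] <- 0
  sig_of <- function(theta) {
    s <- c(ind = 0, mp = 0)
    if (nr > 0) {
      vals <- exp(theta[p + seq_len(nr)])
      if ("IND" %in% spec$random) s["ind"] <- vals[match("IND", spec$random)]
      if ("MP:IND" %in% spec$random) {
        s["mp"] <- vals[match("MP:IND", spec$random)]
      }
    }
    s
  }
  negll <- function(theta) {
    if (any(!is.finite(theta))) return(1e10)
    s <- sig_of(theta)
    ll <- tryCatch(
      marginal_loglik(theta[seq_len(p)], s["ind"], s["mp"], design, order),
      error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # analytic gradient (quadrature-weighted posterior expectations) for the
  # no-random and single-random cases; nested models fall back to finite
  # differences inside optim
  rule <- gh_rule(order)
  logw <- log(rule$weights)
  neggrad <- NULL
  if (nr == 0) {
    neggrad <- function(theta) {
      pr <- plogis(drop(X %*% theta))
      -drop(crossprod(X, y - pr))
    }
  } else if (nr == 1) {
    grp <- if (spec$random == "IND") design$ind else design$mp
    gstarts <- group_starts(grp)
    neggrad <- function(theta) {
      if (any(!is.finite(theta))) return(rep(0, length(theta)))
      eta <- drop(X %*% theta[seq_len(p)])
      gl <- aghq_loglik_grad_cpp(eta, y, gstarts, exp(theta[p + 1]),
                                 rule$nodes, logw)
      -c(drop(crossprod(X, gl$R)), gl$dlogsigma)
    }
  }
  ctrl <- utils::modifyList(list(maxit = 500, factr = 1e7), control)
  lower <- c(rep(-Inf, p), rep(log(1e-4), nr))
  upper <- c(rep(Inf, p), rep(log(50), nr))
  best <- NULL
  starts <- if (nr == 0) list(numeric(0)) else
    lapply(sigma_starts, function(s) rep(log(s), nr))
  for (s0 in starts) {
    opt <- tryCatch(
      optim(c(beta0, s0), negll, gr = neggrad, method = "L-BFGS-B",
            lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    best <- list(par = c(beta0, if (nr) rep(log(0.5), nr)),
                 value = negll(c(beta0, if (nr) rep(log(0.5), nr))),
                 convergence = 1L)
  } else {
    # polish to drive the gradient below the convergence tolerance; at this
    # tolerance L-BFGS-B may stop on a failed line search at the optimum, so
    # optimizer success from either stage counts
    ok0 <- best$convergence == 0
    pol <- tryCatch(
      optim(best$par, negll, gr = neggrad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = utils::modifyList(ctrl, list(factr = 10))),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) {
      if (ok0) pol$convergence <- 0L
      best <- pol
    }
  }
  theta <- best$par
  s <- sig_of(theta)
  boundary <- nr > 0 && any(exp(theta[p + seq_len(nr)]) < 5e-3)
  loglik <- -best$value
  # convergence diagnostics: scaled central-difference gradient and Hessian
  free <- seq_len(p + nr)
  if (boundary) {
    at_bound <- p + which(exp(theta[p + seq_len(nr)]) < 5e-3)
    free <- setdiff(free, at_bound)
  }
  grad <- num_grad(negll, theta, free)
  gnorm <- if (length(grad)) max(abs(grad)) else 0
  H <- tryCatch(optimHess(theta, negll), error = function(e) NULL)
  hess_pd <- FALSE
  vcov <- NULL
  if (!is.null(H)) {
    Hf <- H[free, free, drop = FALSE]
    ev <- tryCatch(eigen(Hf, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA_real_)
    hess_pd <- all(is.finite(ev)) && all(ev > 0)
    if (hess_pd) {
      vcov <- matrix(NA_real_, p + nr, p + nr)
      vcov[free, free] <- solve(Hf)
    }
  }
  # the flag is diagnostics-driven: the optimizer's own status is unreliable
  # when the starting value is already the optimum (failed line search)
  converged <- gnorm < 1e-5 * max(1, abs(loglik)) &&
    (hess_pd || length(free) == 0)
  k <- p + nr
  beta <- theta[seq_len(p)]
  names(beta) <- colnames(X)
  theta_names <- c(colnames(X),
                   if (nr) paste0("log_sigma_", spec$random))
  if (!is.null(vcov)) dimnames(vcov) <- list(theta_names, theta_names)
  fit <- list(spec = spec, beta = beta,
              sigma_ind = unname(s["ind"]), sigma_mp = unname(s["mp"]),
              loglik = loglik, k = k, aic = -2 * loglik + 2 * k,
              vcov = vcov, theta = theta, theta_names = theta_names,
              converged = converged, boundary = boundary,
              info = list(center_year = design$center_year,
                          locus_levels = design$locus_levels,
                          lab_levels = design$lab_levels,
                          dropped = design$dropped,
                          n_ind = design$n_ind, n_mp = design$n_mp,
                          n_rows = design$n_rows))
  class(fit) <- "error_model_fit"
  fit
}

num_grad <- function(fn, theta, idx = seq_along(theta), h = 1e-5) {
  vapply(idx, function(i) {
    tp <- theta; tm <- theta
    hi <- h * max(1, abs(theta[i]))
    tp[i] <- tp[i] + hi
    tm[i] <- tm[i] - hi
    (fn(tp) - fn(tm)) / (2 * hi)
  }, numeric(1))
}

#' @export
print.error_model_fit <- function(x, ...) {
  cat("logistic mixed error model:", format(x$spec), "\n")
  cat(sprintf("  logLik %.3f  k %d  AIC %.2f  %s%s\n", x$loglik, x$k, x$aic,
              if (x$converged) "converged" else "NOT CONVERGED",
              if (x$boundary) " (sigma at boundary)" else ""))
  print(round(x$beta, 4))
  if (x$sigma_ind > 0 || "IND" %in% x$spec$random) {
    cat(sprintf("  sigma_IND    %.4f\n", x$sigma_ind))
  }
  if (x$sigma_mp > 0 || "MP:IND" %in% x$spec$random) {
    cat(sprintf("  sigma_MP:IND %.4f\n", x$sigma_mp))
  }
  invisible(x)
}

#' Per-locus linear predictor means of a fitted model
#'
#' Evaluates the fitted fixed-effect predictor for every retained locus at a
#' given year (YEAR models) or laboratory (LAB models). Loci dropped before
#' fitting (zero observed errors) are not returned here; downstream tables
#' report them with rate zero.
#'
#' @param fit an `error_model_fit` (or one restored by [read_fit_json()]).
#' @param year calendar year for YEAR models.
#' @param lab laboratory level for LAB models.
#' @return named numeric vector of predictor means over retained loci.
#' @export
predict_mu <- function(fit, year = NULL, lab = NULL) {
  beta <- fit$beta
  spec <- fit$spec
  info <- fit$info
  mu0 <- unname(beta["(Intercept)"])
  loci <- setdiff(info$locus_levels, info$dropped$locus)
  mu <- rep(mu0, length(loci))
  names(mu) <- loci
  if ("LOCUS" %in% spec$fixed) {
    offs <- beta[paste0("locus", loci)]
    offs[is.na(offs)] <- 0  # reference level
    mu <- mu + unname(offs)
  }
  if ("YEAR" %in% spec$fixed) {
    if (is.null(year)) stop("model includes YEAR: supply year")
    mu <- mu + unname(beta["year_c"]) * (year - info$center_year)
  }
  if ("LAB" %in% spec$fixed) {
    if (is.null(lab)) stop("model includes LAB: supply lab")
    off <- beta[paste0("lab", lab)]
    if (is.na(off)) off <- 0
    mu <- mu + unname(off)
  }
  mu
}

#' Akaike weights
#'
#' `w_k = exp(-Delta_k / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_k = AIC_k - min(AIC)`; the weights sum to one and order inversely
#' to AIC.
#'
#' @param aic vector of AIC values (at least one finite).
#' @return weight vector of the same length.
#' @export
akaike_weights <- function(aic) {
  if (!any(is.finite(aic))) stop("no finite AIC values")
  d <- aic - min(aic, na.rm = TRUE)
  w <- exp(-d / 2)
  w[!is.finite(w)] <- 0
  w / sum(w)
}

#' Fit and rank the candidate model set
#'
#' Fits every candidate model to the comparison records, sorts by AIC,
#' attaches Akaike weights, and reports combined weights for model groups
#' (containing YEAR, LAB, LOCUS, IND, MP:IND).
#'
#' @param records comparison records from [compare_profiles()].
#' @param center_year centering constant for YEAR.
#' @param order quadrature order.
#' @param include_both_random also fit the 6 models with both random
#'   effects (excluded from the ranked table).
#' @param specs optional list of [model_spec()]s overriding the default
#'   candidate set.
#' @return list with `table` (model, fixed, random, sigma, loglik, k, aic,
#'   delta, weight, converged -- sorted by AIC, labelled M1, M2, ...),
#'   `fits` (in table order), `group_weights`, and `both_random_fits` when
#'   requested.
#' @export
fit_candidate_set <- function(records, center_year = 2001, order = 20,
                              include_both_random = FALSE, specs = NULL) {
  if (is.null(specs)) specs <- candidate_model_set()
  fits <- lapply(specs, function(sp) {
    des <- build_design(records, sp, center_year = center_year)
    fit_error_model(sp, des, order = order)
  })
  both <- NULL
  if (include_both_random) {
    both_specs <- lapply(candidate_model_set(TRUE), identity)
    both_specs <- Filter(function(sp) length(sp$random) == 2, both_specs)
    both <- lapply(both_specs, function(sp) {
      des <- build_design(records, sp, center_year = center_year)
      fit_error_model(sp, des, order = order)
    })
  }
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  ord <- order(aic)
  fits <- fits[ord]
  aic <- aic[ord]
  w <- akaike_weights(aic)
  tab <- data.frame(
    model = paste0("M", seq_along(fits)),
    fixed = vapply(fits, function(f)
      if (length(f$spec$fixed)) paste(f$spec$fixed, collapse = "+") else "-",
      character(1)),
    random = vapply(fits, function(f)
      if (length(f$spec$random)) paste(f$spec$random, collapse = "+") else "-",
      character(1)),
    sigma = vapply(fits, function(f) {
      if ("IND" %in% f$spec$random) f$sigma_ind
      else if ("MP:IND" %in% f$spec$random) f$sigma_mp
      else NA_real_
    }, numeric(1)),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aic = aic,
    delta = aic - min(aic),
    weight = w,
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE
  )
  has <- function(what, where) {
    vapply(fits, function(f) what %in% f$spec[[where]], logical(1))
  }
  group_weights <- c(
    YEAR = sum(w[has("YEAR", "fixed")]),
    LAB = sum(w[has("LAB", "fixed")]),
    LOCUS = sum(w[has("LOCUS", "fixed")]),
    IND = sum(w[has("IND", "random")]),
    `MP:IND` = sum(w[has("MP:IND", "random")])
  )
  names(fits) <- tab$model
  out <- list(table = tab, fits = fits, group_weights = group_weights)
  if (!is.null(both)) out$both_random_fits <- both
  out
}
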