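#' Resample individuals with replacement
#'
#' Cluster bootstrap resampling: draws n individuals with replacement from
#' the n in `records` and stacks their complete locus sets. Duplicated
#' individuals receive fresh ids (suffix `#copy`), so each copy gets its
#' own random-effect level when refitted.
#'
#' @param records comparison records from [compare_profiles()].
#' @param seed optional integer seed.
#' @return resampled comparison records.
#' @export
resample_individuals <- function(records, seed = NULL) {
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old))
  }
  ids <- unique(records$individual_id)
  draw <- sample(ids, length(ids), replace = TRUE)
  rows <- split(seq_len(nrow(records)), records$individual_id)
  out <- lapply(seq_along(draw), function(k) {
    r <- records[rows[[draw[k]]], , drop = FALSE]
    r$individual_id <- paste0(r$individual_id, "#", k)
    r
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Cluster-bootstrap standard deviation of a fitted quantity
#'
#' Each replicate resamples individuals (whole clusters) with replacement
#' to the original sample size, rebuilds the model data (re-applying the
#' zero-error level drops), refits the model, and evaluates `quantity` on
#' the fit. The SD is computed across converged replicates; a second SD
#' counts every non-converged replicate's estimate as zero, an upper bound
#' for the effect of non-convergence on the spread.
#'
#' @param records comparison records from [compare_profiles()].
#' @param spec a [model_spec()].
#' @param quantity function of an `error_model_fit` returning a scalar (or
#'   named vector).
#' @param B number of bootstrap replicates (>= 2).
#' @param seed integer seed; fixed seed gives identical replicate draws.
#' @param order quadrature order for the refits.
#' @param center_year centering constant for YEAR.
#' @return list of class `bootstrap_result`: `sd`, `sd_warn0`,
#'   `warning_fraction`, `estimates` (B x q matrix), `warned` (logical B),
#'   `B`, `seed`, `unreliable` (TRUE when more than half the replicates
#'   failed to converge).
#' @export
bootstrap_sd <- function(records, spec, quantity, B = 500, seed = 1,
                         order = 20, center_year = 2001) {
  stopifnot(B >= 2)
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  est <- NULL
  warned <- logical(B)
  for (b in seq_len(B)) {
    rep_rec <- resample_individuals(records)
    fit <- tryCatch({
      des <- suppressWarnings(
        build_design(rep_rec, spec, center_year = center_year))
      fit_error_model(spec, des, order = order)
    }, error = function(e) NULL)
    if (is.null(fit)) {
      warned[b] <- TRUE
      q <- NULL
    } else {
      warned[b] <- !fit$converged
      q <- tryCatch(quantity(fit), error = function(e) NULL)
    }
    if (is.null(q)) {
      q <- if (is.null(est)) NA_real_ else rep(NA_real_, ncol(est))
      warned[b] <- TRUE
    }
    if (is.null(est)) {
      est <- matrix(NA_real_, B, length(q),
                    dimnames = list(NULL, names(q)))
    }
    est[b, ] <- q
  }
  ok <- !warned & !apply(est, 1, anyNA)
  sd_plain <- apply(est[ok, , drop = FALSE], 2, sd)
  est0 <- est
  est0[!ok, ] <- 0
  sd_warn0 <- apply(est0, 2, sd)
  structure(list(sd = sd_plain, sd_warn0 = sd_warn0,
                 warning_fraction = mean(warned),
                 estimates = est, warned = warned, B = B, seed = seed,
                 unreliable = mean(warned) > 0.5),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("cluster bootstrap, B = %d (seed %d)\n", x$B, x$seed))
  tab <- data.frame(sd = x$sd, sd_warn0 = x$sd_warn0)
  print(round(tab, 5))
  cat(sprintf("warning fraction %.3f%s\n", x$warning_fraction,
              if (x$unreliable) "  [UNRELIABLE: >50% warned]" else ""))
  invisible(x)
}
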