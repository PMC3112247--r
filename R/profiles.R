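#' The register's locus panel
#'
#' Metadata for the ten microsatellite loci of the minke whale DNA register:
#' repeat unit length (2 bp for dinucleotide, 4 bp for GATA tetranucleotide
#' loci), the multiplex PCR assay each locus is run in, and the observed
#' allele-length range in base pairs. The grouping of the ten loci into the
#' three multiplexes is this package's own assignment (the assay composition
#' is not part of the published design); it partitions the panel so that each
#' individual has exactly three multiplex-within-individual groups.
#'
#' @return data.frame with columns `locus`, `repeat_unit`, `multiplex`,
#'   `len_min`, `len_max`.
#' @export
register_loci <- function() {
  data.frame(
    locus = c("GT509", "GT310", "GT211", "GT023", "GATA098", "GATA417",
              "GATA028", "GT575", "EV001", "EV037"),
    repeat_unit = c(2, 2, 2, 2, 4, 4, 4, 2, 2, 2),
    multiplex = c("MP1", "MP1", "MP1", "MP1", "MP2", "MP2",
                  "MP2", "MP3", "MP3", "MP3"),
    len_min = c(203, 117, 106, 103, 93, 223, 202, 155, 153, 203),
    len_max = c(217, 125, 116, 115, 107, 252, 223, 166, 175, 211),
    stringsAsFactors = FALSE
  )
}

#' Audit configuration
#'
#' Bundles the tuning constants shared across the pipeline: the locus panel
#' and multiplex partition, the centering constant for the YEAR covariate
#' (the middle of the register's 1997-2008 period), the Monte-Carlo draw
#' count used for population averaging, the bootstrap replicate count, the
#' quadrature order, and the seed.
#'
#' @param loci locus metadata as from [register_loci()].
#' @param center_year calendar year subtracted from the YEAR covariate.
#' @param n_draws Monte-Carlo draws for marginalization (>= 1).
#' @param n_boot bootstrap replicates (>= 1).
#' @param quad_order Gauss-Hermite order per random-effect dimension.
#' @param seed integer seed recorded alongside results.
#' @return list of class `audit_config`.
#' @export
audit_config <- function(loci = register_loci(), center_year = 2001,
                         n_draws = 1e6, n_boot = 500, quad_order = 20,
                         seed = 1) {
  stopifnot(n_draws >= 1, n_boot >= 1, quad_order >= 1)
  structure(list(loci = loci, center_year = center_year,
                 n_draws = as.integer(n_draws), n_boot = as.integer(n_boot),
                 quad_order = as.integer(quad_order), seed = as.integer(seed)),
            class = "audit_config")
}

profile_columns <- c("individual_id", "year", "lab", "locus",
                     "allele1", "allele2", "multiplex")

#' Canonicalize a profile table
#'
#' A profile table holds one row per individual x locus with the unordered
#' allele pair stored min-first. Genotypes are phase-free, so the two allele
#' columns carry no gene-copy order; canonical form sorts alleles within a
#' row and rows by (individual_id, locus). Exact duplicate rows collapse;
#' duplicated (individual, locus) rows with conflicting alleles are an
#' integrity error, as are conflicting year/lab metadata for an individual.
#'
#' @param x data.frame with columns `individual_id`, `year`, `lab`, `locus`,
#'   `allele1`, `allele2` and optionally `multiplex` (filled from
#'   [register_loci()] when absent).
#' @param loci locus metadata used to fill the multiplex column.
#' @return canonical data.frame with the columns above.
#' @export
as_profiles <- function(x, loci = register_loci()) {
  need <- setdiff(profile_columns, "multiplex")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    stop("profile table lacks column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"multiplex" %in% names(x)) {
    x$multiplex <- loci$multiplex[match(x$locus, loci$locus)]
    if (anyNA(x$multiplex)) {
      stop("unknown locus without multiplex assignment: ",
           paste(unique(x$locus[is.na(x$multiplex)]), collapse = ", "))
    }
  }
  x <- x[profile_columns]
  if (any(!is.finite(x$allele1)) || any(!is.finite(x$allele2)) ||
      any(x$allele1 <= 0) || any(x$allele2 <= 0)) {
    stop("allele lengths must be positive")
  }
  for (v in c("individual_id", "lab", "locus", "multiplex")) {
    x[[v]] <- as.character(x[[v]])
  }
  for (v in c("year", "allele1", "allele2")) x[[v]] <- as.integer(x[[v]])
  a1 <- pmin(x$allele1, x$allele2)
  a2 <- pmax(x$allele1, x$allele2)
  x$allele1 <- a1
  x$allele2 <- a2
  x <- unique(x)
  key <- paste(x$individual_id, x$locus, sep = "\r")
  if (anyDuplicated(key)) {
    bad <- unique(key[duplicated(key)])
    stop("conflicting duplicate rows for individual x locus: ",
         paste(gsub("\r", ":", bad), collapse = ", "))
  }
  meta <- unique(x[c("individual_id", "year", "lab")])
  if (anyDuplicated(meta$individual_id)) {
    stop("inconsistent year/lab metadata within an individual")
  }
  x <- x[order(x$individual_id, x$locus), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read genotype profiles from a TSV file
#'
#' @param path path to a tab-separated table with columns `individual_id`,
#'   `year`, `lab`, `locus`, `allele1`, `allele2` and optionally `multiplex`.
#' @param loci locus metadata for multiplex assignment.
#' @return canonical profile table (see [as_profiles()]).
#' @export
read_profiles <- function(path, loci = register_loci()) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as_profiles(x, loci = loci)
}

#' Write genotype profiles to a TSV file
#'
#' Writes the canonical sorted form (alleles min-first, rows ordered by
#' individual and locus) so that write/read round-trips are the identity.
#'
#' @param profiles profile table, canonicalized via [as_profiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (nrow(profiles) > 0) profiles <- as_profiles(profiles)
  else profiles <- profiles[profile_columns]
  write.table(profiles, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference summaries of the minke whale register audit
#'
#' Loads the published summary tables of the 240-sample re-genotyping audit
#' of the Norwegian minke whale DNA register, shipped with the package as
#' plain text: empirical per-lab error rates (`lab_rates`), locus-level
#' error counts by laboratory, class, and base-pair shift (`error_counts`),
#' the 18-model candidate set with AIC values (`candidate_models`), the best
#' model's population-averaged per-locus rates with bootstrap SDs
#' (`best_model_rates`, the parenthesized `sd_warn0` column counts
#' non-converged bootstrap replicates as zero), and the best model's
#' coefficients with the per-locus allele-length ranges
#' (`best_model_coefficients`).
#'
#' @param name one of the table names above, or `NULL` for all of them.
#' @return a data.frame, or a named list of data.frames when `name` is NULL.
#' @export
register_reference <- function(name = NULL) {
  tables <- c("lab_rates", "error_counts", "candidate_models",
              "best_model_rates", "best_model_coefficients")
  load1 <- function(nm) {
    path <- system.file("extdata", "register_audit", paste0(nm, ".tsv"),
                        package = "genoaudit", mustWork = TRUE)
    read.delim(path, stringsAsFactors = FALSE)
  }
  if (is.null(name)) {
    out <- lapply(tables, load1)
    names(out) <- tables
    return(out)
  }
  name <- match.arg(name, tables)
  load1(name)
}

#' Write a model fit as JSON
#'
#' Serializes the coefficient vector, random-effect standard deviations,
#' log-likelihood, AIC and design metadata of an [fit_error_model()] result
#' so that marginal-rate computations can be replayed from file.
#'
#' @param fit an `error_model_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "error_model_fit"))
  obj <- list(
    model = list(fixed = fit$spec$fixed, random = fit$spec$random),
    beta = as.list(fit$beta),
    sigma_ind = fit$sigma_ind,
    sigma_mpind = fit$sigma_mp,
    loglik = fit$loglik,
    k = fit$k,
    aic = fit$aic,
    converged = fit$converged,
    boundary = fit$boundary,
    info = fit$info
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a model fit from JSON
#'
#' @param path a file written by [write_fit_json()].
#' @return an `error_model_fit` usable by [predict_mu()] and
#'   [marginal_rate_table()] (design matrices are not restored).
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- list(
    spec = model_spec(fixed = unlist(obj$model$fixed),
                      random = unlist(obj$model$random)),
    beta = unlist(obj$beta),
    sigma_ind = obj$sigma_ind %||% 0,
    sigma_mp = obj$sigma_mpind %||% 0,
    loglik = obj$loglik,
    k = obj$k,
    aic = obj$aic,
    converged = isTRUE(obj$converged),
    boundary = isTRUE(obj$boundary),
    info = obj$info
  )
  class(fit) <- "error_model_fit"
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a
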