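# Build a comparison-record table from minimal inputs; genotypes default to
# an error-free heterozygote and are overwritten per row where given.
make_records <- function(n_ind, loci = register_loci(), lab = "Lab1",
                         year = 2001, errors = NULL) {
  L <- nrow(loci)
  ids <- sprintf("%s_i%04d", lab, seq_len(n_ind))
  rec <- data.frame(
    individual_id = rep(ids, each = L),
    year = year, lab = lab,
    locus = rep(loci$locus, n_ind),
    multiplex = rep(loci$multiplex, n_ind),
    reg_allele1 = 200, reg_allele2 = 208,
    true_allele1 = 200, true_allele2 = 208,
    stringsAsFactors = FALSE
  )
  if (!is.null(errors)) {
    for (k in seq_len(nrow(errors))) {
      i <- errors$row[k]
      rec$reg_allele1[i] <- errors$reg1[k]
      rec$reg_allele2[i] <- errors$reg2[k]
    }
  }
  finalize_records(rec)
}

# attach is_error / class columns by running the package classifier
finalize_records <- function(rec) {
  rec$is_error <- !(rec$reg_allele1 == rec$true_allele1 &
                    rec$reg_allele2 == rec$true_allele2)
  rec$error_class <- "none"
  rec$allele_error_count <- 0L
  rec$shift_class <- "not_applicable"
  if (any(rec$is_error)) {
    i <- rec$is_error
    cls <- genoaudit:::classify_errors_vec(
      pmin(rec$true_allele1, rec$true_allele2)[i],
      pmax(rec$true_allele1, rec$true_allele2)[i],
      pmin(rec$reg_allele1, rec$reg_allele2)[i],
      pmax(rec$reg_allele1, rec$reg_allele2)[i])
    rec$error_class[i] <- cls$error_class
    rec$allele_error_count[i] <- cls$allele_error_count
    rec$shift_class[i] <- cls$shift_class
  }
  rec
}

# records with a prescribed error indicator per individual x locus
records_with_pattern <- function(err, loci = register_loci(), lab = "Lab1",
                                 year = 2001) {
  n <- nrow(err)
  rec <- make_records(n, loci = loci, lab = lab, year = year)
  hit <- which(as.vector(t(err)))
  rec$reg_allele1[hit] <- 201  # single false allele, 1 bp
  finalize_records(rec)
}

# Gauss-Hermite population-average oracle, independent of the Monte-Carlo
# marginalization code under test
gh_marginal <- function(mu, sigma, order = 60) {
  r <- gh_rule(order)
  sum(r$weights / sqrt(pi) * plogis(mu + sqrt(2) * sigma * r$nodes))
}
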