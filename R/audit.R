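error_classes <- c("single_false_allele", "double_false_allele",
                   "false_homozygote", "false_heterozygote")

#' Classify a genotyping error
#'
#' Compares an unordered true allele pair with an observed pair and assigns
#' the audited error taxonomy: a heterozygote observed as a homozygote is a
#' `false_homozygote`; a homozygote observed as a heterozygote is a
#' `false_heterozygote`; otherwise one or two shifted allele lengths give
#' `single_false_allele` or `double_false_allele`. The allele error count is
#' the minimum number of single-allele substitutions transforming one
#' multiset into the other (alleles are paired so as to minimize mismatches,
#' ties broken by the smaller total base-pair shift). The shift class is
#' `eq_1bp` when every erroneous allele moved exactly 1 bp, `gt_1bp` when
#' every shift exceeded 1 bp, and `mixed` otherwise.
#'
#' @param true_gt,obs_gt numeric length-2 vectors (unordered allele pairs in
#'   bp); the pairs must differ.
#' @return list with `error_class`, `allele_error_count`, `shift_class`.
#' @export
classify_genotype_error <- function(true_gt, obs_gt) {
  stopifnot(length(true_gt) == 2, length(obs_gt) == 2)
  t1 <- min(true_gt); t2 <- max(true_gt)
  o1 <- min(obs_gt); o2 <- max(obs_gt)
  if (t1 == o1 && t2 == o2) stop("genotypes are identical; not an error")
  cls <- classify_errors_vec(t1, t2, o1, o2)
  list(error_class = cls$error_class,
       allele_error_count = cls$allele_error_count,
       shift_class = cls$shift_class)
}

# Vectorized classifier over canonical (sorted) pairs; pairs assumed to differ.
classify_errors_vec <- function(t1, t2, o1, o2) {
  true_het <- t1 != t2
  obs_het <- o1 != o2
  # two pairings of the unordered pairs
  mA <- (t1 != o1) + (t2 != o2)
  mB <- (t1 != o2) + (t2 != o1)
  sA <- abs(t1 - o1) + abs(t2 - o2)
  sB <- abs(t1 - o2) + abs(t2 - o1)
  useA <- (mA < mB) | (mA == mB & sA <= sB)
  count <- ifelse(useA, mA, mB)
  p1 <- ifelse(useA, abs(t1 - o1), abs(t1 - o2))  # per-slot shifts
  p2 <- ifelse(useA, abs(t2 - o2), abs(t2 - o1))
  shifts_min <- pmin(ifelse(p1 > 0, p1, Inf), ifelse(p2 > 0, p2, Inf))
  shifts_max <- pmax(p1, p2)
  cls <- ifelse(true_het & !obs_het, "false_homozygote",
         ifelse(!true_het & obs_het, "false_heterozygote",
         ifelse(count == 1L, "single_false_allele", "double_false_allele")))
  shift <- ifelse(shifts_max == 1, "eq_1bp",
           ifelse(shifts_min > 1, "gt_1bp", "mixed"))
  list(error_class = cls, allele_error_count = as.integer(count),
       shift_class = shift)
}

#' Compare register profiles against re-genotyped truth
#'
#' Produces one comparison record per individual x locus. An error is a
#' difference between the two unordered allele pairs; errors are classified
#' with [classify_genotype_error()]. Both tables must cover the same
#' individuals with the same loci.
#'
#' @param register profile table with the register's stored genotypes.
#' @param truth profile table with the re-genotyped (consensus) genotypes.
#' @return data.frame with columns `individual_id`, `year`, `lab`, `locus`,
#'   `multiplex`, the two genotypes, `is_error`, `error_class`,
#'   `allele_error_count`, `shift_class`.
#' @export
compare_profiles <- function(register, truth) {
  register <- as_profiles(register)
  truth <- as_profiles(truth)
  if (!setequal(register$individual_id, truth$individual_id)) {
    stop("register and truth cover different individuals")
  }
  kr <- paste(register$individual_id, register$locus, sep = "\r")
  kt <- paste(truth$individual_id, truth$locus, sep = "\r")
  if (!setequal(kr, kt)) stop("register and truth cover different loci")
  register <- register[match(kt, kr), , drop = FALSE]
  rec <- data.frame(
    individual_id = truth$individual_id,
    year = truth$year,
    lab = truth$lab,
    locus = truth$locus,
    multiplex = truth$multiplex,
    reg_allele1 = register$allele1, reg_allele2 = register$allele2,
    true_allele1 = truth$allele1, true_allele2 = truth$allele2,
    stringsAsFactors = FALSE
  )
  rec$is_error <- !(rec$reg_allele1 == rec$true_allele1 &
                    rec$reg_allele2 == rec$true_allele2)
  rec$error_class <- "none"
  rec$allele_error_count <- 0L
  rec$shift_class <- "not_applicable"
  if (any(rec$is_error)) {
    i <- rec$is_error
    cls <- classify_errors_vec(rec$true_allele1[i], rec$true_allele2[i],
                               rec$reg_allele1[i], rec$reg_allele2[i])
    rec$error_class[i] <- cls$error_class
    rec$allele_error_count[i] <- cls$allele_error_count
    rec$shift_class[i] <- cls$shift_class
  }
  rownames(rec) <- NULL
  rec
}

#' Tally classified errors by laboratory
#'
#' Counts locus-level errors per laboratory, error class and base-pair shift
#' class, the audit's headline summary table.
#'
#' @param records comparison records from [compare_profiles()].
#' @return data.frame with columns `lab`, `error_class`, `n_total`,
#'   `n_eq_1bp`, `n_gt_1bp`, `n_mixed`, covering every lab x class cell.
#' @export
tally_errors <- function(records) {
  labs <- sort(unique(records$lab))
  grid <- expand.grid(lab = labs, error_class = error_classes,
                      stringsAsFactors = FALSE)
  err <- records[records$is_error, , drop = FALSE]
  cnt <- function(shift) {
    if (is.null(shift)) sel <- err
    else sel <- err[err$shift_class == shift, , drop = FALSE]
    key <- paste(sel$lab, sel$error_class)
    tab <- table(key)
    out <- as.integer(tab[paste(grid$lab, grid$error_class)])
    ifelse(is.na(out), 0L, out)
  }
  grid$n_total <- cnt(NULL)
  grid$n_eq_1bp <- cnt("eq_1bp")
  grid$n_gt_1bp <- cnt("gt_1bp")
  grid$n_mixed <- cnt("mixed")
  grid[order(grid$lab, match(grid$error_class, error_classes)), ,
       drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}

#' Empirical per-locus and per-allele error rates
#'
#' For each group, the per-locus rate `p_l` is the fraction of individual x
#' locus records with at least one wrong allele, and the per-allele rate
#' `p_a` is the number of wrong gene copies over twice the record count.
#' Standard deviations are binomial, `sqrt(p (1 - p) / m)` with `m` the
#' respective observation count, and `pred` is the per-locus rate implied by
#' `p_a` under within-locus independence ([predict_pl_from_pa()]).
#'
#' @param records comparison records from [compare_profiles()].
#' @param by grouping: `"lab"`, `"year"`, `"locus"` or `"total"`.
#' @return data.frame with columns `group`, `n_individuals`, `n_records`,
#'   `p_l`, `sd_pl`, `p_a`, `sd_pa`, `pred`.
#' @export
empirical_error_rates <- function(records,
                                  by = c("lab", "year", "locus", "total")) {
  by <- match.arg(by)
  g <- if (by == "total") rep("Total", nrow(records)) else
    as.character(records[[by]])
  if (nrow(records) == 0) stop("no comparison records")
  groups <- sort(unique(g))
  out <- lapply(groups, function(grp) {
    r <- records[g == grp, , drop = FALSE]
    m <- nrow(r)
    p_l <- mean(r$is_error)
    p_a <- sum(r$allele_error_count) / (2 * m)
    data.frame(group = grp,
               n_individuals = length(unique(r$individual_id)),
               n_records = m,
               p_l = p_l, sd_pl = sqrt(p_l * (1 - p_l) / m),
               p_a = p_a, sd_pa = sqrt(p_a * (1 - p_a) / (2 * m)),
               pred = predict_pl_from_pa(p_a),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-locus error rate implied by a per-allele rate
#'
#' Under independence of the two gene copies within a locus, a per-allele
#' error rate `p_a` implies a per-locus rate `1 - (1 - p_a)^2`. Comparing
#' this prediction with the observed per-locus rate flags within-sample
#' error clustering.
#'
#' @param p_a per-allele error rate(s) in \[0, 1\].
#' @return predicted per-locus rate(s).
#' @examples
#' predict_pl_from_pa(0.00812)  # 0.0161741
#' @export
predict_pl_from_pa <- function(p_a) {
  if (any(!is.finite(p_a)) || any(p_a < 0) || any(p_a > 1)) {
    stop("p_a must lie in [0, 1]")
  }
  1 - (1 - p_a)^2
}

#' Rebuild comparison records from a published count table
#'
#' Inverse of [tally_errors()] for reproducing an audit from its summary:
#' given per-lab counts of each error class and shift class plus per-lab
#' sample sizes, constructs a full comparison-record table (n individuals x
#' 10 loci per lab) whose classified tally reproduces the counts exactly.
#' Genotypes are synthetic templates realizing each class/shift cell;
#' errors are spread over distinct individual x locus cells.
#'
#' @param counts data.frame with columns `lab`, `error_class`,
#'   `shift_class` (`eq_1bp`/`gt_1bp`) and `n`, as in
#'   `register_reference("error_counts")`.
#' @param lab_design data.frame with columns `lab`, `n_analyzed` and a
#'   representative `year` per lab; defaults to the register's audit design.
#' @param loci locus metadata.
#' @param error_free_loci loci never assigned an error (the audit observed
#'   none at EV001).
#' @return comparison records as from [compare_profiles()].
#' @export
records_from_counts <- function(counts, lab_design = NULL,
                                loci = register_loci(),
                                error_free_loci = "EV001") {
  if (is.null(lab_design)) {
    lab_design <- data.frame(
      lab = c("Lab1", "Lab2", "Lab3", "Lab4"),
      n_analyzed = c(116, 60, 19, 39),
      year = c(2000, 2004, 2006, 2008)
    )
  }
  template <- function(class, shift) {
    # true pair, observed pair realizing the class at the given bp shift
    switch(paste(class, shift),
      "single_false_allele eq_1bp" = list(c(200, 208), c(201, 208)),
      "single_false_allele gt_1bp" = list(c(200, 208), c(204, 208)),
      "double_false_allele eq_1bp" = list(c(200, 208), c(201, 209)),
      "double_false_allele gt_1bp" = list(c(200, 208), c(204, 212)),
      "false_homozygote eq_1bp"    = list(c(200, 201), c(200, 200)),
      "false_homozygote gt_1bp"    = list(c(200, 208), c(200, 200)),
      "false_heterozygote eq_1bp"  = list(c(200, 200), c(200, 201)),
      "false_heterozygote gt_1bp"  = list(c(200, 200), c(200, 208)),
      stop("no template for ", class, " / ", shift)
    )
  }
  L <- nrow(loci)
  all_rec <- list()
  for (i in seq_len(nrow(lab_design))) {
    lab <- lab_design$lab[i]
    n <- lab_design$n_analyzed[i]
    ids <- sprintf("%s_%03d", lab, seq_len(n))
    rec <- data.frame(
      individual_id = rep(ids, each = L),
      year = lab_design$year[i],
      lab = lab,
      locus = rep(loci$locus, n),
      multiplex = rep(loci$multiplex, n),
      reg_allele1 = 200, reg_allele2 = 208,
      true_allele1 = 200, true_allele2 = 208,
      stringsAsFactors = FALSE
    )
    cc <- counts[counts$lab == lab & counts$n > 0, , drop = FALSE]
    if (nrow(cc) > 0) {
      n_err <- sum(cc$n)
      # distinct individual x locus cells, stepping by L+1 to rotate loci,
      # skipping the loci the audit found error-free
      cells <- unique(c(seq(1L, nrow(rec), by = L + 1L), seq_len(nrow(rec))))
      cells <- cells[!(rec$locus[cells] %in% error_free_loci)]
      if (n_err > length(cells)) stop("more errors than records for ", lab)
      cells <- cells[seq_len(n_err)]
      cell_i <- 1L
      for (j in seq_len(nrow(cc))) {
        for (k in seq_len(cc$n[j])) {
          tpl <- template(cc$error_class[j], cc$shift_class[j])
          cell <- cells[cell_i]
          rec$true_allele1[cell] <- min(tpl[[1]])
          rec$true_allele2[cell] <- max(tpl[[1]])
          rec$reg_allele1[cell] <- min(tpl[[2]])
          rec$reg_allele2[cell] <- max(tpl[[2]])
          cell_i <- cell_i + 1L
        }
      }
    }
    all_rec[[i]] <- rec
  }
  rec <- do.call(rbind, all_rec)
  rec$is_error <- !(rec$reg_allele1 == rec$true_allele1 &
                    rec$reg_allele2 == rec$true_allele2)
  rec$error_class <- "none"
  rec$allele_error_count <- 0L
  rec$shift_class <- "not_applicable"
  if (any(rec$is_error)) {
    i <- rec$is_error
    cls <- classify_errors_vec(rec$true_allele1[i], rec$true_allele2[i],
                               rec$reg_allele1[i], rec$reg_allele2[i])
    rec$error_class[i] <- cls$error_class
    rec$allele_error_count[i] <- cls$allele_error_count
    rec$shift_class[i] <- cls$shift_class
  }
  rownames(rec) <- NULL
  rec
}
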