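#!/usr/bin/env Rscript
# Stage 3: fit the 18-model candidate set (fixed effects from
# {LOCUS, YEAR, LAB}, YEAR and LAB never together; random intercepts IND or
# MP:IND or none) to the audit's comparison records by adaptive
# Gauss-Hermite maximum likelihood, rank by AIC, and report Akaike weights
# and combined weights per term.

suppressPackageStartupMessages(library(genoaudit))

records <- read.delim("results/comparison_records.tsv",
                      stringsAsFactors = FALSE)
sel <- suppressWarnings(fit_candidate_set(records))

write.table(sel$table, "results/model_selection.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
best <- sel$fits[[1]]
write_fit_json(best, "results/best_fit.json")

cat("candidate models by AIC:\n")
print(transform(sel$table, weight = signif(weight, 3),
                sigma = round(sigma, 2), aic = round(aic, 1),
                loglik = NULL, delta = round(delta, 1)), digits = 4)
cat("\ncombined Akaike weights by term:\n")
print(round(sel$group_weights, 3))
cat("\nbest model:\n")
print(best)
cat("\nwrote results/model_selection.tsv, results/best_fit.json\n")
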