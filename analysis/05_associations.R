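#!/usr/bin/env Rscript
# Association analysis: age-adjusted standardized betas and age-partial
# correlations of each index with each risk factor, and Fisher-z
# comparisons of correlated correlations (is the best index's correlation
# with a risk factor significantly stronger than a competitor's?).

library(metscreen)

cohort <- read_subjects("results/cohort.csv")
panel <- compute_indexes(cohort)

res <- run_analyze(cohort, age_strata = list(c(18, Inf)))
write.csv(res$associations, "results/associations.csv", row.names = FALSE)

risk_factors <- c("sbp", "dbp", "hdl", "glucose", "tg")
rows <- list()
for (rf in risk_factors) {
  for (ix in setdiff(index_names(), "wthr")) {
    r_xa <- pearson_r(cohort[[rf]], panel$wthr)$r
    r_xb <- pearson_r(cohort[[rf]], panel[[ix]])$r
    r_ab <- pearson_r(panel$wthr, panel[[ix]])$r
    ct <- compare_correlated(r_xa, r_xb, r_ab, nrow(cohort))
    ct$risk_factor <- rf; ct$competitor <- ix
    rows[[length(rows) + 1L]] <- ct
  }
}
cc <- do.call(rbind, rows)
write.csv(cc, "results/correlated_correlation_tests.csv", row.names = FALSE)

cat(sprintf("Associations: |beta_std| ranges %.2f-%.2f across %d index x risk-factor models\n",
            min(abs(res$associations$beta_std)),
            max(abs(res$associations$beta_std)), nrow(res$associations)))
cat(sprintf("WtHR vs competitors on risk-factor correlations: %d of %d tests p < 0.05\n",
            sum(cc$p < 0.05), nrow(cc)))
cat("Wrote results/associations.csv and results/correlated_correlation_tests.csv\n")
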