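#!/usr/bin/env Rscript
# Step 4 -- smoothing and the connectivity measure: how the strength of the
# age effect and the evaluation indices change with 0/6/8 mm smoothing for
# Pearson correlation, and how distance correlation (no smoothing needed)
# compares. Includes the permutation comparison of age-effect maps.

suppressMessages(library(fcsweep))
dir.create("results", showWarnings = FALSE)

co <- generate_cohort(cohort_spec(session_lengths = c(150, 100), seed = 1))
ages <- co$traits$age

grid <- data.frame(name = c("pcor_S0", "pcor_S6", "pcor_S8", "dcor_S0", "dcor_S8"),
                   method = c("pcor", "pcor", "pcor", "dcor", "dcor"),
                   fwhm = c(0, 6, 8, 0, 8))
grid$nuisance <- "CW"; grid$filter <- "HP"; grid$prewhiten <- FALSE
grid$mean_regress <- TRUE
tab <- run_grid(co, grid, out_dir = "results/04_smoothing", k_peers = 30)
print(round(data.frame(tab[, -1], row.names = tab$metric), 3))

age_map <- function(fwhm, method) {
  res <- run_pipeline(co, nuisance = "CW", filter = "HP", prewhiten = FALSE,
                      fwhm = fwhm, method = method, mean_regress = TRUE,
                      sessions = 1)
  age_effect_map(res$conn[[1]], ages)
}
m0 <- age_map(0, "pcor"); m8 <- age_map(8, "pcor")
a0 <- mean(abs(m0[upper.tri(m0)])); a8 <- mean(abs(m8[upper.tri(m8)]))
pt <- permutation_compare_maps(abs(m8), abs(m0), n_perm = 5000, seed = 1)
cat(sprintf("\nMean |age effect| (Pcor): %.3f at 0 mm vs %.3f at 8 mm (perm. p = %.3g)\n",
            a0, a8, pt$p))

sp0 <- tab[tab$metric == "SP", ]
cat(sprintf("Peer similarity varies with smoothing by %.3f for Pcor vs %.3f for Dcor.\n",
            abs(sp0$pcor_S8 - sp0$pcor_S0), abs(sp0$dcor_S8 - sp0$dcor_S0)))
cat("Report written to results/04_smoothing/report.csv\n")
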