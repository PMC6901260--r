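#!/usr/bin/env Rscript
# Simulated mRNA FRAP at the reporter array under the three kinetic regimes:
# E3 (fast, 50 s retention), E6 (slow, 11 min retention), and E6 under
# Clk1-like acceleration (50 s retention again). The recovery ordering --
# E6 below the two fast conditions at every post-bleach frame -- is the
# kinetic signature that retention, not elongation, separates the regimes.
suppressPackageStartupMessages(library(txnfrap))

seed <- 20260101
n_sites <- 100
dir.create("results", showWarnings = FALSE)

conditions <- list(
  E3_fast      = list(gene = build_gene("E3"), retention = 50),
  E6_slow      = list(gene = build_gene("E6"), retention = 660),
  E6_clk1_fast = list(gene = build_gene("E6"), retention = 50)
)

curves <- lapply(names(conditions), function(nm) {
  cond <- conditions[[nm]]
  cv <- simulate_frap(cond$gene, kinetic_params(retention_mean = cond$retention),
                      frap_schedule("mrna-frap"), n_sites = n_sites, seed = seed)
  data.frame(condition = nm, time_s = cv$time_s, mean = cv$mean, sem = cv$sem,
             n = attr(cv, "n"))
})
tab <- do.call(rbind, curves)
write.csv(tab, "results/frap_curves.csv", row.names = FALSE)

wide <- split(tab, tab$condition)
post <- wide$E3_fast$time_s >= 0
cat("Half-recovery times (first frame above 0.5):\n")
for (nm in names(wide)) {
  t50 <- wide[[nm]]$time_s[post][which(wide[[nm]]$mean[post] >= 0.5)[1]]
  cat(sprintf("  %-13s %6.1f s\n", nm, t50))
}
cat(sprintf("E6_slow below E3_fast at %.0f%% of post-bleach frames\n",
            100 * mean(wide$E6_slow$mean[post] <= wide$E3_fast$mean[post] + 1e-8)))

jsonlite::write_json(list(script = "01_simulate_frap_curves.R", seed = seed,
                          n_sites = n_sites,
                          package_version = as.character(packageVersion("txnfrap"))),
                     "results/frap_curves_manifest.json", auto_unbox = TRUE)
cat("wrote results/frap_curves.csv\n")
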