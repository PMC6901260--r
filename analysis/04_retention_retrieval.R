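#!/usr/bin/env Rscript
# Retrieval of the transcript retention time by fitting the simulator to an
# "observed" recovery curve: an E6 curve generated at 660 s retention (and an
# independent one at 50 s) is fitted over the {50, 660} s grid; the SSE gap
# between grid points shows how sharply the FRAP shape identifies retention.
suppressPackageStartupMessages(library(txnfrap))

seed <- 20260104
dir.create("results", showWarnings = FALSE)
g <- build_gene("E6")

rows <- lapply(c(slow = 660, fast = 50), function(true_ret) {
  obs <- simulate_frap(g, kinetic_params(retention_mean = true_ret),
                       n_sites = 200, seed = seed + true_ret)
  fit <- fit_retention_time(obs, g, kinetic_params(), retention_grid = c(50, 660),
                            n_sites = 200, seed = seed)
  cbind(true_retention_s = true_ret, fit$table,
        best_retention_s = fit$best_retention)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/retention_fit.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 4)
ok <- all(tab$best_retention_s == tab$true_retention_s)
cat(if (ok) "\ngenerating retention recovered in both regimes\n" else
  "\nWARNING: retrieval missed a regime\n")

jsonlite::write_json(list(script = "04_retention_retrieval.R", seed = seed,
                          grid = c(50, 660), n_sites = 200,
                          package_version = as.character(packageVersion("txnfrap"))),
                     "results/retention_fit_manifest.json", auto_unbox = TRUE)
cat("wrote results/retention_fit.csv\n")
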