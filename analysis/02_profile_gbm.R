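#!/usr/bin/env Rscript
# Glioblastoma model: temozolomide-sensitive (U251, LN229), aged-control
# (U251-V, LN229-V) and resistant (U251-R, LN229-R) lines. Each model is a
# separate synthetic campaign with its obtained replicate structure
# (104 -> 35 and 125 -> 43 averaged spectra), profiled at k = 3; the two
# resistant lines are additionally compared head to head at k = 2.

suppressPackageStartupMessages(library(chemoprofiler))

seed <- 20230405L
outdir <- "results/gbm"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

campaigns <- list(
  list(name = "U251-model", labels = c("U251", "U251-V", "U251-R"),
       design = design_u251(), k = 3),
  list(name = "LN229-model", labels = c("LN229", "LN229-V", "LN229-R"),
       design = design_ln229(), k = 3),
  list(name = "U251R-LN229R", labels = c("U251-R", "LN229-R"),
       design = replicate_design(data.frame(
         label = c("U251-R", "LN229-R"), n_exp = c(12L, 15L),
         n_tech = c(36L, 44L))), k = 2))

for (i in seq_along(campaigns)) {
  cmp <- campaigns[[i]]
  model <- default_spectrum_model(cmp$labels)
  ds <- simulate_dataset(model, cmp$design, seed = seed + i)
  report <- run_profiling(ds$spectra, profiling_config(k = cmp$k))
  cat(sprintf("\n== %s (%d spectra, k = %d) ==\n", cmp$name,
              length(ds$spectra), cmp$k))
  print(report)
  write_profiling_report(report, outdir, prefix = cmp$name)
}
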