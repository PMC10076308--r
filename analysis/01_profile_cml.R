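#!/usr/bin/env Rscript
# Chronic myeloid leukemia model: can whole-cell MALDI-TOF profiles separate
# imatinib-sensitive (K562), aged-control (Ko562) and resistant (Ki562,
# Kv562) lines? One synthetic acquisition campaign is generated with the
# study's obtained replicate structure (77 spectra -> 40 averaged), then the
# three comparisons are profiled: K562/Ko562/Kv562 and K562/Ko562/Ki562 at
# k = 3, and the two resistant lines head to head at k = 2.

suppressPackageStartupMessages(library(chemoprofiler))

seed <- 20230405L
outdir <- "results/cml"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

lines <- c("K562", "Ko562", "Ki562", "Kv562")
model <- default_spectrum_model(lines)
campaign <- simulate_dataset(model, design_cml(), seed = seed)
save_table(campaign$truth, file.path(outdir, "planted_markers.csv"))
cat(sprintf("simulated %d spectra over %d cell lines\n",
            length(campaign$spectra), length(lines)))

comparisons <- list(
  list(name = "K562-Ko562-Kv562", labels = c("K562", "Ko562", "Kv562"), k = 3),
  list(name = "K562-Ko562-Ki562", labels = c("K562", "Ko562", "Ki562"), k = 3),
  list(name = "Kv562-Ki562", labels = c("Kv562", "Ki562"), k = 2))

for (cmp in comparisons) {
  spectra <- Filter(function(s) s$label %in% cmp$labels, campaign$spectra)
  report <- run_profiling(spectra, profiling_config(k = cmp$k))
  cat(sprintf("\n== %s (%d spectra, k = %d) ==\n", cmp$name, length(spectra),
              cmp$k))
  print(report)
  write_profiling_report(report, outdir, prefix = cmp$name)
}
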