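#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: redraw the uncertain inputs
# (consumption level, elasticity strength, energy density, BMI relative
# risks, disability weights, per-case and implementation costs) and
# rerun the whole pipeline per repetition. Reports means with 95%
# percentile uncertainty intervals and the per-draw dominance verdict.
#
# Repetitions can be set via the REPS environment-style argument:
#   Rscript analysis/05_uncertainty.R 2000

library(sbtaxsim)

n_reps <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(n_reps)) n_reps <- 400
seed <- 2018L

inputs <- read_synth_inputs("results/inputs")
scenarios <- bundled_scenarios(c("implemented", "proposed"))

rows <- list()
for (sc in scenarios) {
  message(sprintf("PSA for %s (%d repetitions) ...", sc$name, n_reps))
  psa <- pipeline_psa(sc, inputs, n_reps = n_reps, seed = seed)
  for (m in c("halys", "healthcare_offsets", "net_cost",
              "revenue_annual", "revenue_lifetime", "intake_change", "dbmi"))
    message(sprintf("  %-20s %s", m, ui_format(psa, m)))
  message(sprintf("  %-20s %s", "ICER",
                  ui_format(psa, "icer", icer = TRUE)))
  s <- psa$summary
  s$scenario <- sc$name
  rows[[sc$name]] <- s
}

utils::write.csv(do.call(rbind, rows), "results/psa_summary.csv",
                 row.names = FALSE)
message("Wrote results/psa_summary.csv")
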