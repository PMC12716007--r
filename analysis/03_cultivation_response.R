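#!/usr/bin/env Rscript
# Compares borage antioxidant/anti-inflammatory readouts across indoor
# cultivation conditions: percent change of each measure under reduced
# temperature (with and without added water stress) relative to the
# standard-temperature control.

suppressPackageStartupMessages({
  library(phytoscreen)
  library(dplyr)
})

cult <- cultivation_results()
control <- cult |>
  filter(condition == "control") |>
  select(measure, control_value = value)

changes <- cult |>
  filter(condition != "control") |>
  inner_join(control, by = "measure") |>
  mutate(percent_change = percent_change(value, control_value, digits = 0)) |>
  select(measure, condition, control_value, value, percent_change)

dir.create("results/cultivation", recursive = TRUE, showWarnings = FALSE)
write_table_csv(changes, "results/cultivation/percent_changes.csv")

cat("Percent change vs standard-temperature control:\n")
print(as.data.frame(changes))
cat("\nOutputs written to results/cultivation/\n")
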