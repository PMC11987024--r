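#!/usr/bin/env Rscript
# Plate-level screening: blank subtraction, per-condition normalization,
# half-time fold-changes and Mann-Whitney activity calls.

library(amylokin)

plate <- read_plate("results/sim/plate.csv", "results/sim/layout.csv")
plate <- normalize_plate(blank_subtract(plate))

compounds <- setdiff(unique(plate$layout$condition),
                     c("blank", "ctrl"))
calls <- lapply(compounds, function(cmp)
  call_activity(plate, cmp, "ctrl"))

tab <- do.call(rbind, lapply(calls, function(cl)
  data.frame(compound = cl$compound, fold_change = cl$fold_change,
             fold_change_se = cl$fold_change_se, p_value = cl$p_value,
             active = cl$active, direction = cl$direction)))
ep <- endpoint_intensity(plate)

dir.create("results", showWarnings = FALSE)
write.table(tab, "results/activity_calls.csv", sep = ",",
            row.names = FALSE, quote = FALSE)
write.table(ep, "results/endpoint_intensity.csv", sep = ",",
            row.names = FALSE, quote = FALSE)

message("Activity calls (fold-change thresholds 0.8x / 1.25x, p < 1e-4):")
print(tab, row.names = FALSE)
message("Hits: ", paste(tab$compound[which(tab$active)], collapse = ", "),
        " -> tables in results/")
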