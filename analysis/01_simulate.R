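#!/usr/bin/env Rscript
# Simulate every dataset the downstream analyses consume: a screening
# plate, an inhibitor dose series, a monomer-concentration series, and the
# auxiliary biophysics traces. Files are written under results/sim/ in the
# same delimited-text formats the readers parse, with ground-truth
# sidecars.

library(amylokin)

seed <- 1
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Simulating screening plate (control + inhibitor + inactive compound)")
plate <- gen_tht_plate(seed, conditions = list(
  ctrl = list(rates = macro_rates(0.04, 2), n_replicates = 12,
              role = "control_no_compound"),
  cmpd_active = list(rates = macro_rates(0.04 / 1.5, 2 / 1.5),
                     n_replicates = 12),
  cmpd_inactive = list(rates = macro_rates(0.04, 2), n_replicates = 12)))
write_plate(plate, file.path(out, "plate.csv"), file.path(out, "layout.csv"))

message("Simulating primary-nucleation inhibitor dose series (0-100 uM)")
series <- gen_dose_series(seed + 1, process = "primary",
                          factors = c(1, 0.7, 0.4, 0.2, 0.1))
for (j in seq_along(series$conditions)) {
  cd <- series$conditions[[j]]
  write.table(data.frame(time = series$times, cd$curves),
              file.path(out, sprintf("dose_%02d.csv", j)),
              sep = ",", row.names = FALSE, quote = FALSE)
}
gt <- attr(series, "ground_truth")
write.table(data.frame(conc = vapply(series$conditions, `[[`, 0, "conc"),
                       factor = gt$factors, lambda = gt$lambda,
                       kappa = gt$kappa),
            file.path(out, "dose_ground_truth.csv"),
            sep = ",", row.names = FALSE, quote = FALSE)

message("Simulating monomer-concentration series (8-30 uM)")
ms <- gen_monomer_series(seed + 2)
for (j in seq_along(ms$conditions)) {
  cd <- ms$conditions[[j]]
  write.table(data.frame(time = ms$times, cd$curves),
              file.path(out, sprintf("monomer_%02d.csv", j)),
              sep = ",", row.names = FALSE, quote = FALSE)
}
write_params(attr(ms, "ground_truth")$params,
             file.path(out, "monomer_ground_truth.yaml"))

message("Simulating taylorgram, SPR sensorgrams and Capflex elugrams")
tg <- gen_taylorgram(seed + 3)
write_trace(tg$times, tg$intensities, file.path(out, "taylorgram.csv"))
sl <- gen_spr_trace(seed + 4, mode = "langmuir", conc = c(10, 50, 150),
                    B_max = 1e4, k_on = 2e-6, k_off = 0.05)
for (sg in sl$sensorgrams)
  write_trace(sg$times, sg$response,
              file.path(out, sprintf("spr_%guM.csv", sg$conc)))
for (i in 0:4) {
  e <- gen_elugram(seed + 5 + i, plateau = 1 - 0.065 * i, n_spikes = 4 * i)
  write_trace(e$times, e$fluorescence,
              file.path(out, sprintf("elugram_%02d.csv", i)))
}

message("Done: inputs in ", out)
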