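test_that("taylorgram fits recover the generating parameters", {
  tg <- gen_taylorgram(seed = 1, A = 2.5, t_R = 110, D = 3.1e-10,
                       noise_sd = 0)
  ft <- fit_taylorgram(tg$times, tg$intensities)
  expect_lt(rel_err(ft$A, 2.5), 1e-3)
  expect_lt(rel_err(ft$t_R, 110), 1e-3)
  expect_lt(rel_err(ft$D, 3.1e-10), 1e-3)

  # 1% noise: D within 2%
  tg2 <- gen_taylorgram(seed = 2, noise_sd = 0.01)
  ft2 <- fit_taylorgram(tg2$times, tg2$intensities)
  expect_lt(rel_err(ft2$D, tg2$ground_truth$D), 0.02)
  # the fitted R_h reproduces the generator's within the D recovery error
  expect_lt(rel_err(ft2$R_h, tg2$ground_truth$R_h), 0.025)
})

test_that("time-shifting a taylorgram shifts t_R only", {
  tg <- gen_taylorgram(seed = 3, t_R = 100, noise_sd = 0)
  f0 <- fit_taylorgram(tg$times, tg$intensities)
  f1 <- fit_taylorgram(tg$times + 20, tg$intensities)
  expect_equal(f1$t_R - f0$t_R, 20, tolerance = 0.05)
  # the peak width is what the data fix: sigma^2 = a^2 t_R / (24 D) is
  # preserved, so D scales with the fitted t_R under a time shift
  expect_lt(rel_err(f1$D / f1$t_R, f0$D / f0$t_R), 0.005)
})

test_that("Stokes-Einstein radius behaves as k_B T / (6 pi eta D)", {
  expect_equal(stokes_einstein(4.0e-10) * 1e9, 0.69615585, tolerance = 1e-6)
  expect_equal(stokes_einstein(2e-10) / stokes_einstein(4e-10), 2)
  # R_h * D is constant at fixed T, eta
  Ds <- c(1e-10, 3e-10, 9e-10)
  prod <- stokes_einstein(Ds) * Ds
  expect_equal(max(prod) / min(prod), 1, tolerance = 1e-12)
  expect_error(stokes_einstein(-1e-10), "> 0")
})

test_that("SPR biexponential fits recover rates, amplitudes and plateau", {
  sg <- gen_spr_trace(seed = 4, mode = "biexp", k1 = 0.25, k2 = 0.03,
                      A1 = 40, A2 = 15, noise_sd = 0)
  fb <- fit_spr_biexponential(sg$times, sg$response)
  expect_lt(rel_err(fb$k1, 0.25), 0.005)
  expect_lt(rel_err(fb$k2, 0.03), 0.005)
  expect_lt(rel_err(fb$plateau, 55), 0.005)
  expect_false(fb$monoexponential)

  # zero amplitudes: plateau 0
  flat <- gen_spr_trace(seed = 5, mode = "biexp", A1 = 0, A2 = 0,
                        noise_sd = 0)
  expect_lt(abs(fit_spr_biexponential(flat$times, flat$response)$plateau),
            1e-6)

  # plateau is symmetric under phase relabeling: fitted k1 >= k2 by
  # convention, so swapping the generator's labels changes nothing
  sw <- gen_spr_trace(seed = 6, mode = "biexp", k1 = 0.03, k2 = 0.25,
                      A1 = 15, A2 = 40, noise_sd = 0)
  fsw <- fit_spr_biexponential(sw$times, sw$response)
  expect_equal(fsw$plateau, fb$plateau, tolerance = 1e-6)
  expect_equal(fsw$k1, fb$k1, tolerance = 1e-6)
})

test_that("global 1:1 Langmuir fit recovers kinetics when K_D is in range", {
  sl <- gen_spr_trace(seed = 7, mode = "langmuir", conc = c(10, 50, 150),
                      B_max = 100, k_on = 1e-3, k_off = 0.05, noise_sd = 1)
  fl <- fit_spr_1to1(sl$sensorgrams)
  expect_lt(rel_err(fl$K_D, 50), 0.05)
  expect_lt(rel_err(fl$k_on, 1e-3), 0.05)
  expect_lt(rel_err(fl$k_off, 0.05), 0.05)
  expect_equal(fl$status, "ok")
})

test_that("K_D far above the analyte range is flagged, with linear plateaus", {
  sl <- gen_spr_trace(seed = 8, mode = "langmuir", conc = c(10, 50, 150),
                      B_max = 1e4, k_on = 2e-6, k_off = 0.05, noise_sd = 1)
  fl <- fit_spr_1to1(sl$sensorgrams, B_max = 1e4)
  expect_equal(fl$status, "KD_above_range")
  expect_gt(fl$plateau_linearity_r2, 0.999)
  expect_lt(rel_err(fl$K_D, 25000), 0.10)

  # zero analyte: the model response is identically zero
  blank <- gen_spr_trace(seed = 9, mode = "langmuir", conc = 0,
                         noise_sd = 0)$sensorgrams[[1]]
  expect_equal(blank$response, rep(0, length(blank$times)))
})

test_that("chemical shift perturbations use the weighted two-shift formula", {
  ref <- data.frame(residue = c("A5", "S19", "N22"),
                    dH = c(8.10, 8.30, 8.50), dN = c(120.0, 118.5, 115.2),
                    intensity = c(100, 80, 60))
  lig <- data.frame(residue = c("A5", "S19", "G33"),
                    dH = c(8.15, 8.30, 7.90), dN = c(120.4, 118.5, 110.0),
                    intensity = c(50, 80, 70))
  expect_message(out <- csp(ref, lig), "N22")
  # hand evaluation: dH = 0.05, dN = 0.4, w = 0.14
  expect_equal(out$csp[out$residue == "A5"], 0.05308483776,
               tolerance = 1e-9)
  expect_equal(out$csp[out$residue == "S19"], 0)
  expect_equal(out$intensity_ratio[out$residue == "A5"], 0.5)
  expect_setequal(attr(out, "excluded"), c("N22", "G33"))

  # symmetric under sign flips of either shift difference
  lig2 <- lig
  lig2$dH[1] <- ref$dH[1] - 0.05
  lig2$dN[1] <- ref$dN[1] - 0.4
  expect_message(out2 <- csp(ref, lig2), "N22")
  expect_equal(out2$csp[1], out$csp[1])
})

test_that("copelleting fractions follow the referenced, baselined fold-change", {
  wl <- 240:400
  mk <- function(peak, offset, drift) {
    data.frame(wavelength = wl,
               absorbance = peak * exp(-(wl - 291)^2 / (2 * 15^2)) +
                 offset + drift * (400 - wl) / 160)
  }
  ref_b <- mk(0, 0.05, 0.02); ref_a <- mk(0, 0.05, 0.02)
  smp_b <- mk(0.50, 0.05, 0.02); smp_a <- mk(0.25, 0.05, 0.02)
  out <- copelleting_fraction(smp_b, smp_a, ref_b, ref_a, lambda_max = 291)
  # reference and 400-nm terms cancel exactly: 0.25/0.50 free
  expect_equal(out$percent_free, 50, tolerance = 1e-6)
  expect_equal(out$percent_copelleted, 50, tolerance = 1e-6)

  # unchanged spectra: all compound free
  out2 <- copelleting_fraction(smp_b, smp_b, ref_b, ref_b, 291)
  expect_equal(out2$percent_free, 100, tolerance = 1e-9)

  # invariant under a common positive gain
  gain <- function(s) {s$absorbance <- 3.7 * s$absorbance; s}
  out3 <- copelleting_fraction(gain(smp_b), gain(smp_a), gain(ref_b),
                               gain(ref_a), 291)
  expect_equal(out3$percent_free, out$percent_free, tolerance = 1e-9)

  expect_error(copelleting_fraction(ref_b, smp_a, ref_b, ref_a, 291),
               "non-positive")
})

test_that("extinction coefficients follow the composition rule", {
  expect_equal(extinction_coefficient_280(0, 0, 0), 0)
  expect_equal(extinction_coefficient_280(0, 1, 1), 1615)
  # additivity
  e1 <- extinction_coefficient_280(1, 2, 0)
  e2 <- extinction_coefficient_280(0, 1, 3)
  expect_equal(extinction_coefficient_280(1, 3, 3), e1 + e2)
  expect_error(extinction_coefficient_280(-1, 0, 0), "non-negative")
})

test_that("Van Slyke buffer capacity: hand value, maximum, and far-pH limit", {
  # 160 mM single-species buffer, pKa 9.1, pH 7.4, 30 C
  expect_equal(buffer_capacity(160, 9.1, pH = 7.4, temperature = 30),
               7.0669803, tolerance = 1e-6)
  # maximal at pH = pKa, where beta = ln(10) * C / 4 + water terms
  expect_equal(buffer_capacity(160, 9.1, pH = 9.1, temperature = 30),
               92.146282, tolerance = 1e-6)
  grid <- seq(5, 12, by = 0.05)
  betas <- vapply(grid, function(ph)
    buffer_capacity(160, 9.1, pH = ph, temperature = 30), 0)
  expect_equal(grid[which.max(betas)], 9.1, tolerance = 0.08)
  # far from every pKa the water term dominates
  far <- buffer_capacity(160, 9.1, pH = 4.0, temperature = 30)
  water <- 1000 * log(10) * (10^-4 + 10^-(13.83 - 4))
  expect_equal(far, water, tolerance = 0.02)
  expect_error(buffer_capacity(160, numeric(0), 7), "pKa")
  expect_error(buffer_capacity(-1, 9.1, 7), "> 0")
})
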