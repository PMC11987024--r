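#' Default microscopic parameter set for the synthetic generators
#'
#' Multistep (saturating) secondary nucleation dominated kinetics with rate
#' constants chosen so that a 20 uM reaction has lambda ~= 0.04 h^-1 and
#' kappa ~= 2 h^-1 (half-time ~= 4 h on a 5-min grid), resembling quiescent
#' IAPP self-assembly at 30 C.
#'
#' @param m0 Initial monomer concentration (uM).
#' @return A [kinetic_params()] object.
#' @export
default_kinetics <- function(m0 = 20) {
  kinetic_params(m0 = m0, nc = 2, kn = 2e-6, kplus = 1,
                 mechanism = "secondary_multistep",
                 k2 = 0.02525, n2 = 2, K2 = 2, theta = 0.323)
}

# default 5-min plate-reader grid (h)
tht_time_grid <- function(t_max = 16) seq(0, t_max, by = 5 / 60)

#' Simulate a ThT plate
#'
#' Generates raw fluorescence traces `gain * model_curve + baseline +
#' noise` for each condition (with the gain drawn once per well, giving
#' well-to-well amplitude variability) plus blank wells `baseline + noise`.
#' The generating parameters are recorded as ground truth.
#'
#' @param seed Integer seed; identical seeds give identical plates.
#' @param conditions Named list; each element is a list with `rates` (a
#'   [macro_rates()]) or `params` (a [kinetic_params()]), optional
#'   `n_replicates` (default 3) and optional `role` (default `"sample"`).
#' @param times Sampling grid (h); default 5-min readings over 16 h.
#' @param n_blanks Number of blank wells (default 3).
#' @param noise_sd Additive Gaussian noise, as a fraction of the
#'   fluorescence plateau (default 0.01).
#' @param gain Mean fluorescence gain (plateau counts), default 1e4.
#' @param gain_sd_frac Well-to-well gain spread as a fraction of `gain`
#'   (default 0.05).
#' @param baseline Baseline fluorescence counts (default 500), shared by
#'   samples and blanks.
#' @return A [tht_plate()] with attribute `"ground_truth"`.
#' @export
gen_tht_plate <- function(seed, conditions, times = tht_time_grid(),
                          n_blanks = 3, noise_sd = 0.01, gain = 1e4,
                          gain_sd_frac = 0.05, baseline = 500) {
  stopifnot(length(conditions) >= 1L, !is.null(names(conditions)))
  with_seed(seed, {
    cols <- list(); lay <- list(); truth <- list()
    for (nm in names(conditions)) {
      cd <- conditions[[nm]]
      n_rep <- if (is.null(cd$n_replicates)) 3L else cd$n_replicates
      role <- if (is.null(cd$role)) "sample" else cd$role
      curve <- if (!is.null(cd$rates))
        rg_curve(cd$rates, times)$fraction_fibrillar
      else model_curve(cd$params, times)$fraction_fibrillar
      for (r in seq_len(n_rep)) {
        wid <- sprintf("%s_r%d", nm, r)
        g <- gain * (1 + gain_sd_frac * stats::rnorm(1))
        cols[[wid]] <- g * curve + baseline +
          stats::rnorm(length(times), 0, noise_sd * gain)
        lay[[wid]] <- data.frame(well = wid, role = role, condition = nm)
      }
      truth[[nm]] <- list(rates = cd$rates, params = cd$params,
                          n_replicates = n_rep,
                          t50 = half_time(curve, times))
    }
    for (b in seq_len(n_blanks)) {
      wid <- sprintf("blank_r%d", b)
      cols[[wid]] <- baseline + stats::rnorm(length(times), 0, noise_sd * gain)
      lay[[wid]] <- data.frame(well = wid, role = "blank",
                               condition = "blank")
    }
    plate <- tht_plate(times, do.call(cbind, cols), do.call(rbind, lay))
    attr(plate, "ground_truth") <- c(truth,
                                     list(seed = seed, noise_sd = noise_sd,
                                          gain = gain, baseline = baseline))
    plate
  })
}

#' Simulate an inhibitor dose series
#'
#' Emulates a dose-series experiment in which exactly one microscopic
#' process is perturbed per inhibitor concentration: the named process's
#' normalized rate is multiplied by the per-condition factor, which scales
#' `lambda` (primary nucleation), `kappa` (secondary nucleation) or both
#' (elongation) by the square root of that factor. Curves are generated
#' with the secondary-process closed form plus additive Gaussian noise on
#' the normalized signal.
#'
#' @param seed Integer seed.
#' @param process Which normalized rate the factors multiply:
#'   `"primary"`, `"secondary"`, `"elongation"` or `"none"`.
#' @param factors Per-condition scaling factors of the perturbed process
#'   (first entry conventionally 1 = no inhibitor).
#' @param conc Condition labels (inhibitor concentration, uM); defaults to
#'   an even spread over 0-100 uM.
#' @param base Unperturbed macroscopic rates ([macro_rates()]).
#' @param times Sampling grid (h).
#' @param n_replicates Replicate wells per condition (default 3).
#' @param noise_sd Gaussian noise on the normalized signal (default 0.01).
#' @param m0 Monomer concentration (uM), shared by all conditions.
#' @return A [dose_series()] with attribute `"ground_truth"` holding the
#'   factors and the per-condition `lambda`/`kappa` actually used.
#' @export
gen_dose_series <- function(seed, process = c("primary", "secondary",
                                              "elongation", "none"),
                            factors = c(1, 0.7, 0.4, 0.2, 0.1),
                            conc = NULL,
                            base = macro_rates(0.04, 2, 0.323),
                            times = tht_time_grid(), n_replicates = 3,
                            noise_sd = 0.01, m0 = 20) {
  process <- match.arg(process)
  if (process == "none") factors <- rep(1, length(factors))
  if (is.null(conc)) conc <- seq(0, 100, length.out = length(factors))
  stopifnot(length(conc) == length(factors))
  sf <- sqrt(factors)
  lam <- switch(process, primary = base$lambda * sf,
                elongation = base$lambda * sf,
                base$lambda + 0 * sf)
  kap <- switch(process, secondary = base$kappa * sf,
                elongation = base$kappa * sf,
                base$kappa + 0 * sf)
  with_seed(seed, {
    traces <- lapply(seq_along(factors), function(j) {
      y <- rg_fraction(times, lam[j], kap[j], base$theta)
      matrix(y, nrow = length(times), ncol = n_replicates) +
        matrix(stats::rnorm(length(times) * n_replicates, 0, noise_sd),
               nrow = length(times))
    })
    names(traces) <- sprintf("dose_%g", conc)
    series <- dose_series(times, traces, conc = conc, m0 = m0,
                          meta = list(process = process, seed = seed))
    attr(series, "ground_truth") <- list(
      process = process, factors = factors, lambda = lam, kappa = kap,
      theta = base$theta, noise_sd = noise_sd, seed = seed)
    series
  })
}

#' Simulate a monomer-concentration series
#'
#' Generates replicate normalized curves at several monomer concentrations
#' from one microscopic parameter set (each condition's `lambda`/`kappa`
#' derive from its `m0` through the mechanism's rate laws), for mechanism
#' discrimination by [fit_monomer_series()].
#'
#' @param seed Integer seed.
#' @param m0s Monomer concentrations (uM).
#' @param params Microscopic [kinetic_params()] evaluated at each `m0`
#'   (its own `m0` is replaced); default [default_kinetics()].
#' @param times Sampling grid (h).
#' @param n_replicates Replicates per concentration.
#' @param noise_sd Gaussian noise on the normalized signal.
#' @return A [dose_series()] (conditions indexed by `m0`) with ground
#'   truth attached.
#' @export
gen_monomer_series <- function(seed, m0s = c(8, 12, 18, 24, 30),
                               params = default_kinetics(),
                               times = tht_time_grid(24),
                               n_replicates = 3, noise_sd = 0.01) {
  with_seed(seed, {
    per_cond <- lapply(m0s, function(m0) {
      p <- params; p$m0 <- m0
      list(p = p, y = model_curve(p, times)$fraction_fibrillar)
    })
    traces <- lapply(per_cond, function(pc)
      matrix(pc$y, length(times), n_replicates) +
        matrix(stats::rnorm(length(times) * n_replicates, 0, noise_sd),
               length(times)))
    names(traces) <- sprintf("m0_%g", m0s)
    series <- dose_series(times, traces, conc = m0s, m0 = m0s,
                          meta = list(kind = "monomer_series", seed = seed))
    attr(series, "ground_truth") <- list(
      params = params, m0s = m0s,
      rates = lapply(per_cond, function(pc) macroscopic_rates(pc$p)),
      noise_sd = noise_sd, seed = seed)
    series
  })
}

#' Simulate a taylorgram
#'
#' Gaussian Taylor-dispersion peak with known area, center time and
#' diffusion coefficient, plus additive Gaussian noise scaled to the peak
#' height.
#'
#' @param seed Integer seed.
#' @param A Peak area.
#' @param t_R Peak-center time (s).
#' @param D Diffusion coefficient (m^2/s).
#' @param times Sampling grid (s).
#' @param noise_sd Noise as a fraction of peak height (default 0.01).
#' @param config A [taylor_config()].
#' @return List: `times`, `intensities`, `ground_truth`.
#' @export
gen_taylorgram <- function(seed, A = 1, t_R = 120, D = 2.5e-10,
                           times = seq(0.5, 240, by = 0.25),
                           noise_sd = 0.01, config = taylor_config()) {
  with_seed(seed, {
    y <- taylor_model(times, A, t_R, D, config$a)
    y <- y + stats::rnorm(length(times), 0, noise_sd * max(y))
    list(times = times, intensities = y,
         ground_truth = list(A = A, t_R = t_R, D = D,
                             R_h = stokes_einstein(D, config),
                             noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate SPR sensorgrams
#'
#' Either a biexponential association trace or a set of two-piece 1:1
#' Langmuir traces (association to `tau`, dissociation after) at several
#' analyte concentrations, with additive Gaussian noise in RU.
#'
#' @param seed Integer seed.
#' @param mode `"biexp"` or `"langmuir"`.
#' @param k1,k2,A1,A2 Biexponential rates (s^-1) and amplitudes (RU).
#' @param conc Analyte concentrations (uM), `"langmuir"` mode.
#' @param B_max,k_on,k_off Langmuir parameters (RU, uM^-1 s^-1, s^-1).
#' @param tau Dissociation start (s), default 60.
#' @param times Sampling grid (s); biexp mode uses the association window
#'   only.
#' @param noise_sd Noise (RU), default 1.
#' @return Biexp mode: list `times`, `response`, `ground_truth`.
#'   Langmuir mode: list `sensorgrams` (each `times`, `response`, `conc`)
#'   and `ground_truth`.
#' @export
gen_spr_trace <- function(seed, mode = c("biexp", "langmuir"),
                          k1 = 0.2, k2 = 0.02, A1 = 30, A2 = 20,
                          conc = c(10, 50, 150), B_max = 100,
                          k_on = 1e-3, k_off = 0.05, tau = 60,
                          times = NULL, noise_sd = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    if (mode == "biexp") {
      if (is.null(times)) times <- seq(0, 60, by = 0.25)
      y <- A1 * (1 - exp(-k1 * times)) + A2 * (1 - exp(-k2 * times)) +
        stats::rnorm(length(times), 0, noise_sd)
      list(times = times, response = y,
           ground_truth = list(k1 = k1, k2 = k2, A1 = A1, A2 = A2,
                               plateau = A1 + A2, noise_sd = noise_sd,
                               seed = seed))
    } else {
      if (is.null(times)) times <- seq(0, 180, by = 0.25)
      sgs <- lapply(conc, function(cc) {
        y <- langmuir_model(times, cc, B_max, k_on, k_off, tau) +
          stats::rnorm(length(times), 0, noise_sd)
        list(times = times, response = y, conc = cc)
      })
      list(sensorgrams = sgs,
           ground_truth = list(B_max = B_max, k_on = k_on, k_off = k_off,
                               K_D = k_off / k_on, tau = tau, conc = conc,
                               noise_sd = noise_sd, seed = seed))
    }
  })
}

#' Simulate an elugram with planted spikes
#'
#' Step-plateau elugram: near-zero baseline segment, a smooth step up to
#' the plateau, Gaussian noise, and single-sample spikes planted at
#' recorded times and heights inside the plateau window.
#'
#' @param seed Integer seed.
#' @param plateau Plateau level (normalized units, default 0.74).
#' @param n_spikes Number of planted spikes (default 5).
#' @param spike_heights Heights above the local signal; scalar or vector
#'   (default drawn from 0.02-0.2).
#' @param times Sampling grid (s), default 0.1-s sampling over 80 s.
#' @param baseline Baseline level before the step (default 0.01).
#' @param step_time,step_width Center and width (s) of the logistic step
#'   (defaults 20 and 1.5).
#' @param plateau_window Window (s) in which spikes are planted.
#' @param noise_sd Gaussian noise (default 0.002).
#' @return List of class `"elugram"` with `times`, `fluorescence` and
#'   `ground_truth` (spike indices, times, heights).
#' @export
gen_elugram <- function(seed, plateau = 0.74, n_spikes = 5,
                        spike_heights = NULL,
                        times = seq(0, 80, by = 0.1), baseline = 0.01,
                        step_time = 20, step_width = 1.5,
                        plateau_window = c(30, 78), noise_sd = 0.002) {
  with_seed(seed, {
    y <- baseline + (plateau - baseline) /
      (1 + exp(-(times - step_time) / step_width))
    y <- y + stats::rnorm(length(times), 0, noise_sd)
    idx_ok <- which(times >= plateau_window[1L] & times <= plateau_window[2L])
    spike_idx <- integer(0)
    if (n_spikes > 0L) {
      # keep planted spikes at least 5 samples apart so each is distinct
      cand <- sample(idx_ok)
      for (i in cand) {
        if (all(abs(i - spike_idx) > 5L)) spike_idx <- c(spike_idx, i)
        if (length(spike_idx) == n_spikes) break
      }
      spike_idx <- sort(spike_idx)
      if (is.null(spike_heights))
        spike_heights <- stats::runif(n_spikes, 0.02, 0.2)
      spike_heights <- rep_len(spike_heights, n_spikes)
      y[spike_idx] <- y[spike_idx] + spike_heights
    }
    structure(list(times = times, fluorescence = y,
                   meta = list(seed = seed),
                   ground_truth = list(spike_index = spike_idx,
                                       spike_times = times[spike_idx],
                                       spike_heights = spike_heights,
                                       plateau = plateau,
                                       baseline = baseline,
                                       noise_sd = noise_sd, seed = seed)),
              class = "elugram")
  })
}
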