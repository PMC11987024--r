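#' Taylor dispersion configuration
#'
#' Instrument constants for Taylor dispersion analysis.
#'
#' @param a Capillary radius (m); default 37.5 um.
#' @param temperature Capillary temperature (K); default 303 K.
#' @param eta Medium viscosity (Pa s); default 0.797 mPa s.
#' @return List of class `"taylor_config"`.
#' @export
taylor_config <- function(a = 37.5e-6, temperature = 303, eta = 0.797e-3) {
  stopifnot(a > 0, temperature > 0, eta > 0)
  structure(list(a = a, temperature = temperature, eta = eta,
                 k_B = 1.380649e-23),
            class = "taylor_config")
}

# Gaussian taylorgram model: area-normalized peak whose width is set by the
# diffusion coefficient, sigma^2 = a^2 * tR / (24 * D)
taylor_model <- function(times, A, t_R, D, a) {
  s2 <- a^2 * t_R / (24 * D)
  A / sqrt(2 * pi * s2) * exp(-(times - t_R)^2 / (2 * s2))
}

#' Fit a taylorgram
#'
#' Least-squares fit of a baseline-subtracted Taylor dispersion peak with
#' the Gaussian dispersion model
#' `I(t) = A / sqrt(2 pi sigma^2) * exp(-(t - t_R)^2 / (2 sigma^2))` with
#' `sigma^2 = a^2 t_R / (24 D)`, giving the peak area `A`, the peak-center
#' time `t_R` and the diffusion coefficient `D`; the hydrodynamic radius
#' follows from the Stokes-Einstein relation.
#'
#' @param times Measurement times (s).
#' @param intensities Baseline-subtracted fluorescence signal.
#' @param config A [taylor_config()].
#' @return List of class `"taylor_fit"`: `A`, `t_R` (s), `D` (m^2/s),
#'   `R_h` (m), standard errors, `rss`.
#' @export
fit_taylorgram <- function(times, intensities, config = taylor_config()) {
  stopifnot(inherits(config, "taylor_config"), length(times) >= 5L)
  i_max <- which.max(intensities)
  tR0 <- times[i_max]
  if (tR0 <= 0) stop("peak center at non-positive time; single dominant ",
                     "peak with t_R > 0 required")
  # moment-based width guess -> initial D
  w <- pmax(intensities, 0)
  s2_0 <- sum(w * (times - tR0)^2) / sum(w)
  if (!is.finite(s2_0) || s2_0 <= 0) s2_0 <- (diff(range(times)) / 10)^2
  D0 <- config$a^2 * tR0 / (24 * s2_0)
  A0 <- sum(w) * mean(diff(times))
  resid_fn <- function(par)
    intensities - taylor_model(times, exp(par[1L]), exp(par[2L]),
                               exp(par[3L]), config$a)
  fit <- minpack.lm::nls.lm(
    par = c(log(A0), log(tR0), log(D0)), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14))
  if (!fit$info %in% 1:4)
    stop("taylorgram fit did not converge (initial guesses: A=", signif(A0, 3),
         ", t_R=", signif(tR0, 3), " s, D=", signif(D0, 3), " m^2/s)")
  rss <- sum(fit$fvec^2)
  se_log <- lm_se(fit, rss, length(times))
  est <- exp(fit$par)
  structure(list(A = est[1L], t_R = est[2L], D = est[3L],
                 R_h = stokes_einstein(est[3L], config),
                 A_se = est[1L] * se_log[1L], t_R_se = est[2L] * se_log[2L],
                 D_se = est[3L] * se_log[3L], rss = rss),
            class = "taylor_fit")
}

#' Stokes-Einstein hydrodynamic radius
#'
#' `R_h = k_B * T / (6 pi eta D)`.
#'
#' @param D Diffusion coefficient (m^2/s), > 0.
#' @param config A [taylor_config()] supplying temperature and viscosity.
#' @return Hydrodynamic radius (m).
#' @export
stokes_einstein <- function(D, config = taylor_config()) {
  if (any(D <= 0)) stop("`D` must be > 0")
  config$k_B * config$temperature / (6 * pi * config$eta * D)
}

#' Biexponential fit of an SPR association phase
#'
#' Fits `R(t) = A1 (1 - exp(-k1 t)) + A2 (1 - exp(-k2 t))` to the
#' association window of a sensorgram; the plateau response is `A1 + A2`.
#' Rates are reported with `k1 >= k2`. When the two rates are within 5% of
#' each other the trace is flagged as effectively monoexponential (not an
#' error).
#'
#' @param times Times (s), association phase (from 0).
#' @param response Response (RU).
#' @return List of class `"biexp_fit"`: `k1`, `k2` (s^-1), `A1`, `A2`
#'   (RU), `plateau`, `rss`, `monoexponential` flag.
#' @export
fit_spr_biexponential <- function(times, response) {
  stopifnot(length(times) == length(response), length(times) >= 6L)
  plateau0 <- max(mean(utils::tail(response, max(3L, length(response) %/% 10))),
                  1e-6)
  t_half <- times[which(response >= plateau0 / 2)[1L]]
  if (!is.finite(t_half) || t_half <= 0) t_half <- stats::median(times)
  k0 <- log(2) / t_half
  resid_fn <- function(par) {
    k1 <- exp(par[1L]); k2 <- exp(par[2L])
    response - (par[3L] * (1 - exp(-k1 * times)) +
                par[4L] * (1 - exp(-k2 * times)))
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(k0 * 4), log(k0 / 2), plateau0 / 2, plateau0 / 2),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14))
  k <- exp(fit$par[1:2]); amp <- fit$par[3:4]
  ord <- order(k, decreasing = TRUE)
  k <- k[ord]; amp <- amp[ord]
  structure(list(k1 = k[1L], k2 = k[2L], A1 = amp[1L], A2 = amp[2L],
                 plateau = sum(amp), rss = sum(fit$fvec^2),
                 monoexponential = abs(k[1L] / k[2L] - 1) < 0.05),
            class = "biexp_fit")
}

# two-piece 1:1 Langmuir sensorgram: exponential association to tau, then
# exponential dissociation
langmuir_model <- function(times, conc, B_max, k_on, k_off, tau) {
  if (conc <= 0) return(rep(0, length(times)))
  K_D <- k_off / k_on
  R_eq <- B_max * conc / (conc + K_D)
  k_obs <- k_on * conc + k_off
  R_tau <- R_eq * (1 - exp(-k_obs * tau))
  ifelse(times <= tau,
         R_eq * (1 - exp(-k_obs * times)),
         R_tau * exp(-k_off * (times - tau)))
}

#' Global 1:1 Langmuir fit of SPR sensorgrams
#'
#' Globally fits single-exponential association (to `tau`) and dissociation
#' (after `tau`) across sensorgrams at several analyte concentrations,
#' sharing `B_max`, `k_on` and `k_off`; `K_D = k_off / k_on`. `B_max` can
#' be pinned (the convention used when the binding curve does not saturate
#' within the accessible concentration range). When the fitted `K_D` lies
#' far above the highest analyte concentration - the regime where the
#' plateau grows linearly with concentration and `K_D` is not determined by
#' the data - the result carries status `"KD_above_range"`.
#'
#' @param sensorgrams List of sensorgrams, each a list with `times` (s),
#'   `response` (RU) and `conc` (uM); at least 2 concentrations.
#' @param B_max Optional pinned saturation response (RU); `NULL` fits it.
#' @param tau Start of the dissociation phase (s), default 60.
#' @return List of class `"langmuir_fit"`: `B_max`, `k_on` (uM^-1 s^-1),
#'   `k_off` (s^-1), `K_D` (uM), `rss`, `status`
#'   (`"ok"` or `"KD_above_range"`), `plateau_linearity_r2`.
#' @export
fit_spr_1to1 <- function(sensorgrams, B_max = NULL, tau = 60) {
  stopifnot(length(sensorgrams) >= 2L)
  concs <- vapply(sensorgrams, `[[`, 0, "conc")
  pinned <- !is.null(B_max)
  resid_fn <- function(par) {
    kon <- exp(par[1L]); koff <- exp(par[2L])
    Bm <- if (pinned) B_max else exp(par[3L])
    unlist(lapply(sensorgrams, function(sg)
      sg$response - langmuir_model(sg$times, sg$conc, Bm, kon, koff, tau)),
      use.names = FALSE)
  }
  resp_max <- max(vapply(sensorgrams, function(sg) max(sg$response), 0))
  start <- c(log(1e-3), log(0.05), if (!pinned) log(resp_max * 2))
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-14))
  kon <- exp(fit$par[1L]); koff <- exp(fit$par[2L])
  Bm <- if (pinned) B_max else exp(fit$par[3L])
  K_D <- koff / kon
  # observed end-of-association response vs concentration: linearity marks
  # the far-from-saturation regime
  plateaus <- vapply(sensorgrams, function(sg) {
    sel <- sg$times >= tau - 5 & sg$times <= tau
    if (!any(sel)) sel <- which.min(abs(sg$times - tau))
    mean(sg$response[sel])
  }, 0)
  lin <- stats::lm(plateaus ~ concs)
  r2_lin <- summary(lin)$r.squared
  status <- if (K_D > 5 * max(concs)) "KD_above_range" else "ok"
  structure(list(B_max = Bm, k_on = kon, k_off = koff, K_D = K_D,
                 rss = sum(fit$fvec^2), status = status,
                 plateau_linearity_r2 = r2_lin, B_max_pinned = pinned,
                 tau = tau),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("1:1 Langmuir fit: B_max = %.4g RU%s, k_on = %.3g uM^-1 s^-1, k_off = %.3g s^-1\n",
              x$B_max, if (x$B_max_pinned) " (pinned)" else "",
              x$k_on, x$k_off))
  cat(sprintf("  K_D = %.4g uM [%s]\n", x$K_D,
              if (x$status == "ok") "within range" else
                "above analyte range; not determined by the data"))
  invisible(x)
}

#' Chemical shift perturbations and intensity ratios
#'
#' Matches residues between a reference (protein alone) and a ligand-present
#' peak table and computes, per residue, the weighted chemical shift
#' perturbation `CSP = sqrt( (d_dH^2 + (w * d_dN)^2) / 2 )` (amide-proton /
#' nitrogen weighting `w`, default 0.14) and the intensity ratio `I/I0`.
#' Residues present in only one table are excluded and listed.
#'
#' @param reference Data frame with columns `residue`, `dH`, `dN`,
#'   `intensity` for the protein alone.
#' @param ligand Same columns, in the presence of ligand.
#' @param weight Nitrogen shift weighting (default 0.14).
#' @return Data frame: `residue`, `csp` (ppm), `intensity_ratio`; excluded
#'   residues in attribute `"excluded"`.
#' @export
csp <- function(reference, ligand, weight = 0.14) {
  req <- c("residue", "dH", "dN", "intensity")
  stopifnot(all(req %in% names(reference)), all(req %in% names(ligand)))
  common <- intersect(reference$residue, ligand$residue)
  excluded <- union(setdiff(reference$residue, common),
                    setdiff(ligand$residue, common))
  if (length(excluded))
    message("csp: excluding unmatched residue(s): ",
            paste(excluded, collapse = ", "))
  r <- reference[match(common, reference$residue), ]
  l <- ligand[match(common, ligand$residue), ]
  d_h <- l$dH - r$dH
  d_n <- l$dN - r$dN
  out <- data.frame(residue = common,
                    csp = sqrt((d_h^2 + (weight * d_n)^2) / 2),
                    intensity_ratio = l$intensity / r$intensity)
  attr(out, "excluded") <- excluded
  out
}

# linear interpolation of a spectrum (wavelength, absorbance) at lambda
spec_at <- function(spectrum, lambda) {
  stats::approx(spectrum$wavelength, spectrum$absorbance, xout = lambda,
                rule = 1)$y
}

#' Copelleting fraction from absorbance fold-change
#'
#' Fraction of compound remaining free in solution after fibrils are
#' pelleted, from the fold-change in absorbance at the compound's
#' `lambda_max`. Each spectrum is reference-subtracted (fibrils without
#' compound) and then baselined by its residual optical density at 400 nm
#' (removing scattering and protein absorbance):
#' `A'(l) = (sample - reference)(l) - (sample - reference)(400)`.
#' Percent free = `100 * A'_after(lambda_max) / A'_before(lambda_max)`;
#' percent copelleted is its complement.
#'
#' @param sample_before,sample_after Spectra (data frames with `wavelength`
#'   in nm, `absorbance`) of the compound-containing sample before and
#'   after centrifugation.
#' @param reference_before,reference_after Matching spectra of the
#'   compound-free reference.
#' @param lambda_max Compound absorbance maximum (nm); see
#'   [compound_lambda_max()].
#' @return List: `percent_free`, `percent_copelleted`, `A_before`,
#'   `A_after`.
#' @export
copelleting_fraction <- function(sample_before, sample_after,
                                 reference_before, reference_after,
                                 lambda_max) {
  corr <- function(sample, reference) {
    d_max <- spec_at(sample, lambda_max) - spec_at(reference, lambda_max)
    d_400 <- spec_at(sample, 400) - spec_at(reference, 400)
    if (any(is.na(c(d_max, d_400))))
      stop("spectra must cover both lambda_max (", lambda_max, " nm) and 400 nm")
    d_max - d_400
  }
  A_before <- corr(sample_before, reference_before)
  A_after <- corr(sample_after, reference_after)
  if (A_before <= 0)
    stop("non-positive corrected absorbance before pelleting (",
         signif(A_before, 3), "); cannot form a fold-change")
  free <- 100 * A_after / A_before
  list(percent_free = free, percent_copelleted = 100 - free,
       A_before = A_before, A_after = A_after)
}

#' Compound absorbance maxima
#'
#' Default `lambda_max` values (nm) for the copelleting analysis.
#'
#' @return Named numeric vector (nm).
#' @export
compound_lambda_max <- function() {
  c("YX-I-1" = 252, canagliflozin = 291, doxazosin = 340,
    dapagliflozin = 276)
}

#' Molar extinction coefficient at 280 nm
#'
#' Composition rule (Expasy/ProtParam convention):
#' `eps = 5500 * n_Trp + 1490 * n_Tyr + 125 * n_cystine` (M^-1 cm^-1).
#'
#' @param n_trp Number of tryptophans.
#' @param n_tyr Number of tyrosines.
#' @param n_cystine Number of cystines (disulfide-bonded cysteine pairs).
#' @return Extinction coefficient (M^-1 cm^-1).
#' @export
extinction_coefficient_280 <- function(n_trp, n_tyr, n_cystine) {
  if (any(c(n_trp, n_tyr, n_cystine) < 0))
    stop("residue counts must be non-negative")
  5500 * n_trp + 1490 * n_tyr + 125 * n_cystine
}

# pKw(T) of water, interpolated (degrees C)
pkw_at <- function(temperature) {
  tab_T <- c(0, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50)
  tab_pkw <- c(14.94, 14.73, 14.53, 14.35, 14.17, 13.995, 13.83, 13.68,
               13.53, 13.40, 13.26)
  stats::approx(tab_T, tab_pkw, xout = temperature, rule = 2)$y
}

#' Van Slyke buffer capacity
#'
#' `beta = dC/dpH = ln(10) * ( [H+] + [OH-] + sum_i C_i Ka_i [H+] /
#' ([H+] + Ka_i)^2 )`, i.e. the concentration of strong acid/base required
#' per unit pH change, including the water autoionization terms with a
#' temperature-dependent ion product.
#'
#' @param total_conc Total buffer species concentration(s) (mM); scalar or
#'   one per pKa.
#' @param pKa_list Numeric vector of acid dissociation pKa values (>= 1).
#' @param pH Solution pH.
#' @param temperature Temperature (degrees C), default 25; sets the water
#'   ion product.
#' @return Buffer capacity beta (mM).
#' @export
buffer_capacity <- function(total_conc, pKa_list, pH, temperature = 25) {
  if (length(pKa_list) == 0L) stop("`pKa_list` must contain at least one pKa")
  if (any(total_conc <= 0)) stop("`total_conc` must be > 0")
  C <- rep_len(total_conc, length(pKa_list)) / 1000  # mM -> M
  h <- 10^(-pH)
  oh <- 10^(-(pkw_at(temperature) - pH))
  Ka <- 10^(-pKa_list)
  beta_M <- log(10) * (h + oh + sum(C * Ka * h / (h + Ka)^2))
  1000 * beta_M
}
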