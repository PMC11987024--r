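test_that("normalized rates follow the per-process rate laws", {
  p <- p_single(m0 = 10, n2 = 2)
  nu <- normalized_rates(p)
  expect_equal(nu$nu_plus, p$kplus * 10)
  expect_equal(nu$nu_n, p$kn * 10^p$nc)
  expect_equal(nu$nu_2, p$k2 * 10^2)

  # zero rate constant kills the corresponding rate regardless of m0, nc
  p0 <- kinetic_params(m0 = 50, nc = 3, kn = 0, kplus = 2)
  expect_equal(normalized_rates(p0)$nu_n, 0)

  # doubling m0^n2 doubles the single-step secondary rate
  pa <- p_single(m0 = 10); pb <- p_single(m0 = 10 * 2^(1 / 2))
  pb$k2 <- pa$k2
  expect_equal(normalized_rates(pb)$nu_2 / normalized_rates(pa)$nu_2, 2)

  # saturation limit: multistep -> single-step as K2 -> Inf
  pm <- kinetic_params(m0 = 20, nc = 2, kn = 1e-6, kplus = 1,
                       mechanism = "secondary_multistep",
                       k2 = 0.01, n2 = 2, K2 = 1e9)
  ps <- kinetic_params(m0 = 20, nc = 2, kn = 1e-6, kplus = 1,
                       mechanism = "secondary_single", k2 = 0.01, n2 = 2)
  expect_equal(normalized_rates(pm)$nu_2, normalized_rates(ps)$nu_2,
               tolerance = 1e-12)
})

test_that("missing mechanism-specific constants raise errors naming the field", {
  expect_error(kinetic_params(m0 = 10, mechanism = "fragmentation"), "kf")
  expect_error(kinetic_params(m0 = 10, mechanism = "secondary_single",
                              n2 = 2), "k2")
  expect_error(kinetic_params(m0 = 10, mechanism = "secondary_multistep",
                              k2 = 1, n2 = 2), "K2")
  expect_error(kinetic_params(m0 = -1), "m0")
})

test_that("macroscopic rates combine as square roots of the process rates", {
  p <- p_single()
  r <- macroscopic_rates(p)
  nu <- normalized_rates(p)
  expect_equal(r$lambda, sqrt(2 * nu$nu_plus * nu$nu_n / p$m0))
  expect_equal(r$kappa, sqrt(2 * nu$nu_plus * nu$nu_2))

  # kn = 0 -> lambda = 0; kf = 0 -> kappa = 0
  p0 <- kinetic_params(m0 = 10, kn = 0, kplus = 1,
                       mechanism = "fragmentation", kf = 0)
  r0 <- macroscopic_rates(p0)
  expect_equal(r0$lambda, 0)
  expect_equal(r0$kappa, 0)

  # 4x kn -> 2x lambda; 4x k2 -> 2x kappa
  p4 <- p_single(); p4$kn <- 4 * p$kn
  expect_equal(macroscopic_rates(p4)$lambda / r$lambda, 2)
  p4b <- p_single(); p4b$k2 <- 4 * p$k2
  expect_equal(macroscopic_rates(p4b)$kappa / r$kappa, 2)

  # no secondary pathway -> kappa = 0
  expect_equal(macroscopic_rates(p_oosawa())$kappa, 0)
})

test_that("the nucleation-elongation closed form is exact against the oracle", {
  times <- seq(0, 24, length.out = 200)
  for (nc in c(1.5, 2, 3)) {
    for (lam in c(0.1, 0.25, 0.42)) {  # lambda * t_max in [~2.4, 10]
      p <- p_oosawa(nc = nc, lambda = lam)
      closed <- oosawa_curve(macroscopic_rates(p), nc, times)
      oracle <- moment_ode_oracle(p, times)
      expect_lt(max(abs(closed$fraction_fibrillar -
                          oracle$fraction_fibrillar)), 0.01)
    }
  }
})

test_that("oosawa curve boundary and degenerate cases", {
  times <- seq(0, 10, by = 0.5)
  cv <- oosawa_curve(macro_rates(0.5), 2, times)
  expect_equal(cv$fraction_fibrillar[1L], 0)
  expect_true(all(diff(cv$fraction_fibrillar) >= 0))
  expect_true(all(cv$fraction_fibrillar <= 1))
  expect_equal(oosawa_curve(macro_rates(0), 2, times)$fraction_fibrillar,
               rep(0, length(times)))
  expect_error(oosawa_curve(macro_rates(0.5), 2, c(-1, 0, 1)), "non-negative")
  expect_error(oosawa_curve(macro_rates(0.5, kappa = 1), 2, times), "kappa")
})

test_that("secondary-process closed form matches oracle half-times within 5%", {
  times_for <- function(kap, ratio)
    seq(0, 3 * log(2 + 2 * ratio^2) / kap, length.out = 1200)
  for (ratio in c(5, 20, 100, 500)) {
    # saturated multistep and fragmentation carry theta ~ 0.32
    for (pf in list(p_multistep, p_frag)) {
      p <- pf()
      r <- macroscopic_rates(p)
      lam <- r$kappa / ratio
      p$kn <- lam^2 / (2 * p$kplus * p$m0^p$nc)
      r <- macroscopic_rates(p)
      tt <- times_for(r$kappa, ratio)
      t_closed <- half_time(rg_curve(r, tt, theta = 0.323))
      t_oracle <- half_time(moment_ode_oracle(p, tt))
      expect_lt(rel_err(t_closed, t_oracle), 0.05)
    }
    # single-step n2 = 2 with its matched depletion sensitivity
    p <- p_single()
    r <- macroscopic_rates(p)
    p$kn <- (r$kappa / ratio)^2 / (2 * p$kplus * p$m0^p$nc)
    r <- macroscopic_rates(p)
    tt <- times_for(r$kappa, ratio)
    t_closed <- half_time(rg_curve(r, tt, theta = theta_for(p)))
    t_oracle <- half_time(moment_ode_oracle(p, tt))
    expect_lt(rel_err(t_closed, t_oracle), 0.05)
  }
})

test_that("secondary-process closed form is stable, bounded and monotone", {
  r <- macro_rates(0.02, 1.0, 0.323)
  tt <- seq(0, 2000, length.out = 500)  # kappa*t up to 2000: overflow regime
  cv <- rg_curve(r, tt)
  expect_true(all(is.finite(cv$fraction_fibrillar)))
  expect_equal(cv$fraction_fibrillar[1L], 0)
  expect_true(all(diff(cv$fraction_fibrillar) >= 0))
  expect_true(all(cv$fraction_fibrillar <= 1))
  expect_equal(utils::tail(cv$fraction_fibrillar, 1), 1, tolerance = 1e-9)
  # lambda = 0 -> identically zero, any kappa
  expect_equal(rg_curve(macro_rates(0, 1), tt)$fraction_fibrillar,
               rep(0, length(tt)))
  expect_equal(rg_curve(macro_rates(0, 0), tt)$fraction_fibrillar,
               rep(0, length(tt)))
})

test_that("oracle conserves mass across random valid parameter sets", {
  set.seed(101)
  times <- seq(0, 12, length.out = 60)
  for (i in 1:20) {
    mech <- sample(c("fragmentation", "secondary_single",
                     "secondary_multistep"), 1)
    m0 <- runif(1, 5, 40)
    p <- kinetic_params(
      m0 = m0, nc = runif(1, 1.5, 3),
      kn = 10^runif(1, -7, -5), kplus = 10^runif(1, -0.5, 0.5),
      mechanism = mech,
      kf = if (mech == "fragmentation") 10^runif(1, -2, 0),
      k2 = if (mech != "fragmentation") 10^runif(1, -4, -2),
      n2 = if (mech != "fragmentation") runif(1, 1, 3),
      K2 = if (mech == "secondary_multistep") runif(1, 1, 20))
    curve <- moment_ode_oracle(p, times)
    m <- attr(curve, "monomer")
    M <- curve$fraction_fibrillar * m0
    expect_lt(max(abs(m + M - m0)), 1e-6 * m0)
  }
})

test_that("oracle without nucleation or seeds stays at zero", {
  p <- kinetic_params(m0 = 20, kn = 0, kplus = 1,
                      mechanism = "secondary_single", k2 = 0.01, n2 = 2)
  cv <- moment_ode_oracle(p, seq(0, 10, by = 1))
  expect_equal(cv$fraction_fibrillar, rep(0, 11))
})

test_that("oracle produces a full sigmoid in the secondary-dominated regime", {
  p <- p_multistep()
  r <- macroscopic_rates(p)
  p$kn <- (r$kappa / 50)^2 / (2 * p$kplus * p$m0^p$nc)  # kappa/lambda = 50
  tt <- seq(0, 16, length.out = 400)
  y <- moment_ode_oracle(p, tt)$fraction_fibrillar
  expect_equal(utils::tail(y, 1), 1, tolerance = 1e-4)
  expect_true(all(diff(y) >= -1e-10))
})

test_that("half-time: crossings, scale invariance, closed-form agreement", {
  expect_equal(half_time(c(0, 0.5, 1), c(0, 1, 2)), 1.0)
  # plateau-relative: amplitude scaling leaves the half-time unchanged
  y <- rg_curve(macro_rates(0.04, 2), tht_time_grid())
  expect_equal(half_time(0.7 * y$fraction_fibrillar, y$time), half_time(y))
  # dead trace (no plateau) -> explicit NA, not a number
  expect_true(is.na(half_time(rep(0, 6), 1:6)))
  expect_true(is.na(half_time(c(0.5, 0.4, 0.2, 0.1, 0, -0.1), 1:6)))
  # agreement with bisection on the nucleation-elongation closed form
  lam <- 0.5; nc <- 2
  tt <- seq(0, 24, by = 5 / 60)
  t50_grid <- half_time(oosawa_curve(macro_rates(lam), nc, tt))
  f <- function(t) oosawa_curve(macro_rates(lam), nc, c(0, t))$fraction_fibrillar[2L] - 0.5
  t50_bisect <- uniroot(f, c(0.1, 24), tol = 1e-10)$root
  expect_equal(t50_grid, t50_bisect, tolerance = 2 * (5 / 60) / t50_bisect)
})

test_that("half-time decreases strictly as lambda grows", {
  tt <- seq(0, 30, by = 0.02)
  t50 <- vapply(c(0.2, 0.3, 0.5, 0.8, 1.2),
                function(l) half_time(oosawa_curve(macro_rates(l), 2, tt)), 0)
  expect_true(all(diff(t50) < 0))
  t50k <- vapply(c(0.01, 0.02, 0.04, 0.08),
                 function(l) half_time(rg_curve(macro_rates(l, 2), tt)), 0)
  expect_true(all(diff(t50k) < 0))
})

test_that("theta_for reflects the effective secondary reaction order", {
  expect_equal(theta_for(p_frag()), 0.32)
  expect_gt(theta_for(p_single(n2 = 2)), theta_for(p_frag()))
  # strongly saturated multistep approaches the fragmentation value
  expect_lt(theta_for(p_multistep()) - 0.32, 0.02)
  expect_true(is.na(theta_for(p_oosawa())))
})
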