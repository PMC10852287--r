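# Independent re-derivation of the effective-parameter map, written as
# plain formulas against which the packaged implementation is checked.
effective_parameters_oracle <- function(mo, su, p) {
  r1v <- p$M_X / p$M_N
  r2v <- p$M_N / p$M_R
  list(
    g_eff = c(X = -p$u + p$eta_X * p$mu_d * mo[["mean_N"]],
              N = -p$m - r1v * p$mu_d * mo[["mean_X"]] +
                p$eta_N * p$mu_c * mo[["mean_R"]],
              R = p$k - p$mu_c * r2v * mo[["mean_N"]]),
    sigma_g = c(X = sqrt(p$eta_X^2 * p$sigma_d^2 * mo[["q_N"]] + p$sigma_u^2),
                N = sqrt(p$eta_N^2 * p$sigma_c^2 * mo[["q_R"]] +
                           p$sigma_d^2 * r1v * mo[["q_X"]] + p$sigma_m^2),
                R = sqrt(p$sigma_K^2 + p$sigma_c^2 * r2v * mo[["q_N"]])),
    D_eff = c(X = -p$eta_X * p$sigma_d^2 * su$nu,
              N = p$eta_N * p$sigma_c^2 * su$kappa -
                p$eta_X * r1v * p$sigma_d^2 * su$chi,
              R = 1 - p$eta_N * r2v * p$sigma_c^2 * su$nu))
}

test_that("effective parameters: empty-ecosystem and decoupled-top limits", {
  p <- trophic_params()
  zero <- setNames(rep(0, 6), c("mean_X", "mean_N", "mean_R", "q_X", "q_N", "q_R"))
  ep <- effective_parameters(zero, list(chi = 0, nu = 0, kappa = 0), p)
  expect_equal(ep$g_eff, c(X = -1, N = -1, R = 4))
  expect_equal(ep$sigma_g, c(X = 0.1, N = 0.1, R = 0.1))
  expect_equal(ep$D_eff, c(X = 0, N = 0, R = 1))
  p0 <- update_params(p, eta_X = 0)
  ep0 <- effective_parameters(c(zero[1:3], q_X = 2, q_N = 3, q_R = 4),
                              list(chi = -1, nu = -2, kappa = 3), p0)
  expect_equal(ep0$D_eff[["X"]], 0)
  expect_equal(ep0$sigma_g[["X"]], p0$sigma_u)
})

test_that("effective parameters match an independently coded oracle on random inputs", {
  set.seed(31)
  p <- trophic_params(M_X = 37, M_N = 41, M_R = 53, k = 2.5, u = 1.7,
                      sigma_c = 0.8, sigma_d = 0.3, eta_N = 0.45, eta_X = 0.95)
  for (i in 1:10) {
    mo <- setNames(runif(6, 0, 4), c("mean_X", "mean_N", "mean_R",
                                     "q_X", "q_N", "q_R"))
    su <- list(chi = -runif(1, 0, 3), nu = -runif(1, 0, 3),
               kappa = runif(1, 0, 3))
    got <- effective_parameters(mo, su, p)
    want <- effective_parameters_oracle(mo, su, p)
    expect_equal(got$g_eff, want$g_eff, tolerance = 1e-14)
    expect_equal(got$sigma_g, want$sigma_g, tolerance = 1e-14)
    expect_equal(got$D_eff, want$D_eff, tolerance = 1e-14)
  }
})

test_that("susceptibilities agree with the survivor-count form and packing identity", {
  p <- trophic_params()
  set.seed(12)
  for (i in 1:10) {
    deltas <- list(delta_X = runif(1, -2, 0), delta_N = runif(1, -1, 1),
                   delta_R = runif(1, 0.5, 3))
    su <- tryCatch(susceptibilities_from_deltas(deltas, p),
                   error = function(e) NULL)
    if (is.null(su)) next
    expect_lte(su$chi, 0)
    expect_lte(su$nu, 0)
    expect_gte(su$kappa, 0)
    # survivor-count form: M*_L = w0(delta_L) * M_L
    MXs <- w_integral(0, deltas$delta_X) * p$M_X
    MNs <- w_integral(0, deltas$delta_N) * p$M_N
    MRs <- w_integral(0, deltas$delta_R) * p$M_R
    chi_cnt <- -(p$eta_N * p$sigma_c^2) / (p$eta_X * p$sigma_d^2) *
      (MXs / p$M_X) * (p$M_N / p$M_R) * (MRs - MNs + MXs) / (MNs - MXs)
    nu_cnt <- -(p$M_R / (p$eta_N * p$M_N * p$sigma_c^2)) *
      (MNs - MXs) / (MRs - MNs + MXs)
    kappa_cnt <- (MRs - MNs + MXs) / p$M_R
    expect_equal(su$chi, chi_cnt, tolerance = 1e-12)
    expect_equal(su$nu, nu_cnt, tolerance = 1e-12)
    expect_equal(su$kappa, kappa_cnt, tolerance = 1e-12)
    # niche-ratio form: kappa = (M_R*/M_R) / (1 + 1/f)
    f <- (MRs + MXs - MNs) / (MNs - MXs)
    expect_equal(su$kappa, (MRs / p$M_R) / (1 + 1 / f), tolerance = 1e-10)
  }
})

test_that("susceptibilities report which packing inequality fails", {
  p <- trophic_params()
  # more surviving carnivores than herbivores: delta_X >> delta_N
  expect_error(
    susceptibilities_from_deltas(
      list(delta_X = 3, delta_N = -2, delta_R = 3), p),
    "more surviving herbivores", class = "infeasible_packing")
  # saturated middle level: delta_N large, delta_R very negative
  expect_error(
    susceptibilities_from_deltas(
      list(delta_X = -30, delta_N = 5, delta_R = -30), p),
    "realized niches", class = "infeasible_packing")
})

test_that("residuals vanish at the solved state and respond to perturbations", {
  p <- trophic_params()
  cs <- cavity_solve(p, seed = 1)
  x <- c(cs$mean_X, cs$mean_N, cs$mean_R, cs$q_X, cs$q_N, cs$q_R)
  expect_lt(max(abs(cavity_residuals(x, p))), 1e-6)
  expect_lt(max(abs(cavity_residuals(x, p, scaled = TRUE))), 1e-6)
  xp <- x; xp[1] <- 1.1 * xp[1]
  expect_gt(abs(cavity_residuals(xp, p)[1]), 1e-3)
})

test_that("the solved state is a fixed point with the documented structure", {
  p <- trophic_params()
  cs <- cavity_solve(p, seed = 1)
  expect_lt(cs$residual_norm, 1e-6)
  # self-consistency of the first moments by construction
  expect_equal(cs$mean_X,
               cs$sigma_g[["X"]] / cs$D_eff[["X"]] * w_integral(1, cs$delta[["X"]]),
               tolerance = 1e-8)
  expect_equal(cs$q_R,
               (cs$sigma_g[["R"]] / cs$D_eff[["R"]])^2 * w_integral(2, cs$delta[["R"]]),
               tolerance = 1e-8)
  expect_equal(unname(cs$phi), unname(w_integral(0, cs$delta)))
  expect_lte(cs$chi, 0); expect_lte(cs$nu, 0); expect_gte(cs$kappa, 0)
  expect_true(all(cs$D_eff > 0))
})

test_that("different start strategies and seeds land on the same physical branch", {
  p <- trophic_params()
  s1 <- cavity_solve(p, seed = 1)
  s2 <- cavity_solve(p, seed = 17)
  s3 <- cavity_solve(p, init = "multistart_random", seed = 5)
  for (s in list(s2, s3)) {
    expect_equal(s$mean_X, s1$mean_X, tolerance = 1e-5)
    expect_equal(s$q_N, s1$q_N, tolerance = 1e-5)
    expect_equal(s$phi[["N"]], s1$phi[["N"]], tolerance = 1e-5)
  }
  # exclusion-penalty variant stays on the same solution
  s4 <- cavity_solve(p, seed = 1, exclusion_penalty = TRUE)
  expect_equal(s4$mean_R, s1$mean_R, tolerance = 1e-6)
})

test_that("moments of one large simulated system nearly solve the cavity equations", {
  # The self-consistency map amplifies moment deviations by roughly an
  # order of magnitude, so even percent-level finite-size offsets at
  # M ~ 200 leave a visible residual; the property that matters for warm
  # starting is that simulation moments sit far closer to the root than
  # generic moment vectors do.
  p <- trophic_params(M_X = 200, M_N = 224, M_R = 248)
  inst <- sample_community(p, 55)
  ss <- integrate_to_steady_state(inst, p, seed = 56)
  x <- c(ss$mean_X, ss$mean_N, ss$mean_R,
         ss$second_moment_X, ss$second_moment_N, ss$second_moment_R)
  rms <- function(v) sqrt(mean(v^2))
  r_sim <- rms(cavity_residuals(x, p, scaled = TRUE))
  expect_lt(r_sim, 0.5)
  expect_gt(rms(cavity_residuals(1.5 * x, p, scaled = TRUE)), 3 * r_sim)
  # and the solver polishes it to the exact root
  cs <- cavity_solve(p, init = x, seed = 1)
  expect_lt(cs$residual_norm, 1e-6)
  expect_equal(cs$mean_X, ss$mean_X, tolerance = 0.1)
})

test_that("cavity survival fractions respect rescaled competitive exclusion", {
  for (pars in list(trophic_params(),
                    trophic_params(k = 2, u = 2),
                    update_params(set_ratios(trophic_params(), r1 = 1.2,
                                             r2 = 0.5), k = 3))) {
    cs <- cavity_solve(pars, seed = 3)
    expect_lte(r1(pars) * cs$phi[["X"]], cs$phi[["N"]] + 1e-10)
    expect_lte(r2(pars) * cs$phi[["N"]],
               cs$phi[["R"]] + r1(pars) * r2(pars) * cs$phi[["X"]] + 1e-10)
  }
})
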