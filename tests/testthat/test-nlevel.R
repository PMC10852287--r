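test_that("N-level rates reduce to the three-level rates and match a loop oracle", {
  p3 <- trophic_params(M_X = 5, M_N = 7, M_R = 9)
  np <- as_nlevel_params(p3)
  inst3 <- sample_community(p3, 13)
  # embed the same draw: A[[2]] = c, A[[3]] = d, g = (K, -m, -u)
  instn <- structure(list(A = list(NULL, inst3$c, inst3$d),
                          g = list(inst3$K, -inst3$m_vec, -inst3$u_vec),
                          seed = 13), class = "nlevel_instance")
  set.seed(14)
  state3 <- runif(21, 0, 2)             # ordered X, N, R
  staten <- c(state3[13:21], state3[6:12], state3[1:5])  # ordered R, N, X
  r3 <- trophic_rhs(state3, inst3, p3)
  rn <- nlevel_rhs(staten, instn, np)
  expect_equal(rn, c(r3[13:21], r3[6:12], r3[1:5]), tolerance = 1e-12)
  expect_equal(nlevel_rhs(numeric(21), instn, np), numeric(21))
  expect_error(nlevel_rhs(numeric(3), instn, np), "state length")
})

test_that("4-level rates match a hand-written loop", {
  np <- nlevel_params(M = c(4, 3, 3, 2), mu_alpha = c(0, 1, 1, 1),
                      sigma_alpha = c(0, 0.4, 0.4, 0.4),
                      g_mean = c(3, -1, -0.8, -0.6),
                      g_sd = rep(0.1, 4), D = c(1, 0.2, 0, 0),
                      eta = c(1, 0.9, 0.8, 0.7))
  inst <- sample_nlevel_community(np, 3)
  set.seed(4)
  y <- runif(12, 0, 2)
  B <- split(y, rep(1:4, c(4, 3, 3, 2)))
  out <- numeric(0)
  for (i in 1:4) {
    g <- inst$g[[i]] - np$D[i] * B[[i]]
    if (i > 1) g <- g + np$eta[i] * as.numeric(inst$A[[i]] %*% B[[i - 1]])
    if (i < 4) g <- g + as.numeric(-t(inst$A[[i + 1]]) %*% B[[i + 1]])
    out <- c(out, B[[i]] * g)
  }
  expect_equal(nlevel_rhs(y, inst, np), out, tolerance = 1e-12)
})

test_that("the 3-level special case reproduces the dedicated solver exactly", {
  p3 <- trophic_params()
  cs <- cavity_solve(p3, seed = 1)
  ns <- nlevel_solve(as_nlevel_params(p3), seed = 1)
  expect_equal(ns$mean_B, c(cs$mean_R, cs$mean_N, cs$mean_X), tolerance = 1e-6)
  expect_equal(ns$q, c(cs$q_R, cs$q_N, cs$q_X), tolerance = 1e-6)
  # susceptibility sign adapter: chi_i = <dB/dg> vs the death-rate convention
  expect_equal(ns$chi, c(cs$kappa, -cs$nu, -cs$chi), tolerance = 1e-6)
  expect_equal(ns$D_eff,
               unname(cs$D_eff[c("R", "N", "X")]), tolerance = 1e-6)
  expect_equal(ns$phi, unname(cs$phi[c("R", "N", "X")]), tolerance = 1e-6)
})

test_that("a decoupled dead top level goes extinct; the bottom level solves alone", {
  np <- nlevel_params(M = c(40, 36), mu_alpha = c(0, 0),
                      sigma_alpha = c(0, 1e-12),
                      g_mean = c(4, -1), g_sd = c(0.5, 0.01),
                      D = c(1, 1), eta = c(1, 1))
  ns <- nlevel_solve(np, init = "multistart_random", seed = 2)
  expect_equal(ns$mean_B[2], 0, tolerance = 1e-8)
  expect_equal(ns$q[2], 0, tolerance = 1e-8)
  # bottom level: single-level truncated-Gaussian logistic self-consistency
  # (no interactions): B = max(0, g + sigma z), delta = g/sigma
  d1 <- np$g_mean[1] / np$g_sd[1]
  expect_equal(ns$mean_B[1], np$g_sd[1] * w_integral(1, d1), tolerance = 1e-6)
  expect_equal(ns$q[1], np$g_sd[1]^2 * w_integral(2, d1), tolerance = 1e-6)
})

test_that("TAP per-species sampling reproduces the truncated-Gaussian law", {
  p3 <- trophic_params()
  ns <- nlevel_solve(as_nlevel_params(p3), seed = 1)
  set.seed(99)
  for (i in 1:3) {
    z <- rnorm(1e5)
    B <- pmax(0, (ns$g_eff[i] + ns$sigma_g[i] * z) / ns$D_eff[i])
    se1 <- sd(B) / sqrt(length(B))
    expect_lt(abs(mean(B) - ns$mean_B[i]), 4 * se1)
    se2 <- sd(B^2) / sqrt(length(B))
    expect_lt(abs(mean(B^2) - ns$q[i]), 4 * se2)
    se0 <- sqrt(ns$phi[i] * (1 - ns$phi[i]) / length(B))
    expect_lt(abs(mean(B > 0) - ns$phi[i]), 4 * se0 + 1e-6)
  }
})

test_that("a 4-level cavity solution matches direct simulation", {
  np <- nlevel_params(M = c(60, 54, 48, 42), mu_alpha = c(0, 1, 1, 1),
                      sigma_alpha = c(0, 0.5, 0.5, 0.5),
                      g_mean = c(4, -1, -0.8, -0.5),
                      g_sd = rep(0.1, 4), D = c(1, 0, 0, 0),
                      eta = c(1, 0.8, 0.8, 0.8))
  ns <- nlevel_solve(np, seed = 3)
  n_sys <- 12
  seeds <- multitroph:::split_seeds(7L, n_sys)
  stats <- sapply(seeds, function(s) {
    inst <- sample_nlevel_community(np, s)
    r <- integrate_nlevel(inst, np, seed = s + 1L)
    c(r$mean_B, r$phi)
  })
  m <- rowMeans(stats)
  se <- apply(stats, 1, sd) / sqrt(n_sys)
  want <- c(ns$mean_B, ns$phi)
  expect_true(all(abs(m - want) < 4 * pmax(se, 1e-3)))
})

test_that("the interior control ratio reduces to the packing order parameter", {
  p3 <- trophic_params()
  cs <- cavity_solve(p3, seed = 1)
  np <- as_nlevel_params(p3)
  ns <- nlevel_solve(np, seed = 1)
  expect_equal(order_parameter_level(ns, np, 2),
               packing_order_parameter(cs), tolerance = 1e-6)
  expect_error(order_parameter_level(ns, np, 1), "interior")
  expect_error(order_parameter_level(ns, np, 3), "interior")
  # chi^{i+1} -> 0 gives pure bottom-up control
  ns0 <- ns
  ns0$chi[3] <- 0
  expect_equal(order_parameter_level(ns0, np, 2), 0)
  # symmetric construction gives exactly 1/2
  sym_p <- nlevel_params(M = c(10, 10, 10), mu_alpha = c(0, 1, 1),
                         sigma_alpha = c(0, 0.5, 0.5),
                         g_mean = c(1, 0, -1), g_sd = rep(0.1, 3),
                         D = c(1, 0, 1), eta = c(1, 1, 1))
  sym_s <- list(chi = c(2, 1, 2))
  expect_equal(order_parameter_level(sym_s, sym_p, 2), 0.5)
})
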