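# Independent oracles shared across test files. These deliberately avoid
# the package's own closed-form/vectorized code paths.

# adaptive quadrature of the truncated-Gaussian integral
w_quadrature <- function(n, delta) {
  stats::integrate(function(x) (x + delta)^n * exp(-x^2 / 2) / sqrt(2 * pi),
                   lower = -delta, upper = Inf,
                   rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# naive element-wise loop implementation of the three-level rates
rhs_loop_oracle <- function(state, instance, params) {
  M_X <- nrow(instance$d); M_N <- ncol(instance$d); M_R <- ncol(instance$c)
  X <- state[1:M_X]; N <- state[M_X + 1:M_N]; R <- state[M_X + M_N + 1:M_R]
  out <- numeric(length(state))
  for (a in 1:M_X) {
    s <- 0
    for (j in 1:M_N) s <- s + instance$d[a, j] * N[j]
    out[a] <- X[a] * (params$eta_X * s - instance$u_vec[a])
  }
  for (i in 1:M_N) {
    s1 <- 0; s2 <- 0
    for (Q in 1:M_R) s1 <- s1 + instance$c[i, Q] * R[Q]
    for (b in 1:M_X) s2 <- s2 + instance$d[b, i] * X[b]
    out[M_X + i] <- N[i] * (params$eta_N * s1 - instance$m_vec[i] - s2)
  }
  for (P in 1:M_R) {
    s <- 0
    for (j in 1:M_N) s <- s + instance$c[j, P] * N[j]
    out[M_X + M_N + P] <- R[P] * (instance$K[P] - R[P] - s)
  }
  out
}

# direct stiff integration of the single-species-per-level toy chain
toy_ode_oracle <- function(k1, m1, u1, eta_N, eta_X, D_R, D_N, D_X,
                           c11, d11, y0 = c(1, 1, 1), t_final = 5000) {
  f <- function(t, y, p) {
    y <- pmax(y, 0)
    list(c(y[1] * (k1 - D_R * y[1] - c11 * y[2]),
           y[2] * (eta_N * c11 * y[1] - m1 - D_N * y[2] - d11 * y[3]),
           y[3] * (eta_X * d11 * y[2] - u1 - D_X * y[3])))
  }
  out <- deSolve::ode(y0, c(0, t_final), f, NULL, method = "lsoda",
                      rtol = 1e-12, atol = 1e-14)
  y <- pmax(out[nrow(out), -1], 0)
  y[y < 1e-8] <- 0
  stats::setNames(y, c("R", "N", "X"))
}

# reference condition used throughout (dense three-level community)
reference_params <- function(...) trophic_params(...)
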