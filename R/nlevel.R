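# N-trophic-level generalization: per-level intra-specific competition D^i
# and conversion efficiencies eta^i, with the three-level model as the
# special case D = (1, 0, 0), eta = (1, eta_N, eta_X).
#
# Level index 1 is the bottom (primary producers), N the top. Level i
# consumes level i-1 through a random preference matrix A[[i]] (M_i x
# M_{i-1}) whose entries have mean mu_alpha[i]/M_{i-1} and SD
# sigma_alpha[i]/sqrt(M_{i-1}) -- the same prey-pool scaling as the
# three-level model, which the stated reduction requires.
#
# Susceptibility sign convention: chi_i = <dB_i/dg_i> >= 0 (derivative with
# respect to the level's own growth rate). The three-level module's chi and
# nu are derivatives with respect to death rates, so the reduction adapter
# flips their signs: chi_1 = kappa, chi_2 = -nu, chi_3 = -chi.

#' Parameters of an N-trophic-level ensemble
#'
#' @param M Numeric vector of level sizes, bottom first; length sets the
#'   number of levels (\eqn{\ge 2}). Fractional sizes are allowed in the
#'   analytic layer (only the ratios enter); sampling requires whole
#'   numbers.
#' @param mu_alpha,sigma_alpha Per-level mean/SD scales of the consumption
#'   preferences of level \code{i} feeding on level \code{i - 1}; entry 1
#'   (the bottom level consumes nothing) is ignored and stored as 0.
#' @param g_mean,g_sd Per-level growth/death rate means and SDs. Physical
#'   ecosystems have \code{g_mean[1] > 0} (bottom level grows) and
#'   \code{g_mean[i] < 0} above.
#' @param D Per-level bare intra-specific competition coefficients.
#' @param eta Per-level conversion efficiencies in \eqn{[0, 1]}; entry 1 is
#'   ignored.
#' @return Object of class \code{"nlevel_params"} with derived size ratios
#'   \code{r[i] = M[i]/M[i-1]} (where defined).
#' @seealso [as_nlevel_params()] for the three-level embedding,
#'   [nlevel_solve()], [sample_nlevel_community()]
#' @export
nlevel_params <- function(M, mu_alpha, sigma_alpha, g_mean, g_sd, D, eta) {
  n <- length(M)
  if (n < 2) stop("at least two trophic levels are required", call. = FALSE)
  for (v in list(mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 g_mean = g_mean, g_sd = g_sd, D = D, eta = eta)) {
    if (length(v) != n) {
      stop("all per-level parameter vectors must have length ", n,
           call. = FALSE)
    }
  }
  if (any(M < 1)) stop("level sizes must be >= 1", call. = FALSE)
  if (any(sigma_alpha < 0) || any(g_sd < 0) || any(D < 0)) {
    stop("sigma_alpha, g_sd and D must be >= 0", call. = FALSE)
  }
  if (any(eta < 0 | eta > 1)) stop("eta must lie in [0, 1]", call. = FALSE)
  mu_alpha[1] <- 0; sigma_alpha[1] <- 0
  structure(list(n_levels = n, M = M, mu_alpha = mu_alpha,
                 sigma_alpha = sigma_alpha, g_mean = g_mean, g_sd = g_sd,
                 D = D, eta = eta,
                 r = c(NA_real_, M[-1] / M[-n])),
            class = "nlevel_params")
}

#' Embed a three-level parameter set in the N-level form
#'
#' Maps a [trophic_params()] object to the equivalent [nlevel_params()]:
#' levels (plants, herbivores, carnivores) become levels (1, 2, 3) with
#' \code{D = (1, 0, 0)}, \code{eta = (1, eta_N, eta_X)},
#' \code{g_mean = (k, -m, -u)}.
#'
#' @param params A [trophic_params()] object.
#' @return An \code{"nlevel_params"} object.
#' @export
as_nlevel_params <- function(params) {
  stopifnot(inherits(params, "trophic_params"))
  nlevel_params(M = c(params$M_R, params$M_N, params$M_X),
                mu_alpha = c(0, params$mu_c, params$mu_d),
                sigma_alpha = c(0, params$sigma_c, params$sigma_d),
                g_mean = c(params$k, -params$m, -params$u),
                g_sd = c(params$sigma_K, params$sigma_m, params$sigma_u),
                D = c(1, 0, 0),
                eta = c(1, params$eta_N, params$eta_X))
}

#' Sample a random N-level community instance
#'
#' @param params An [nlevel_params()] object with whole-number level sizes.
#' @param seed Integer seed.
#' @return Object of class \code{"nlevel_instance"}: \code{A}, a list whose
#'   i-th element is the \code{M[i] x M[i-1]} preference matrix (element 1
#'   is \code{NULL}), and \code{g}, a list of per-level growth-rate
#'   vectors.
#' @export
sample_nlevel_community <- function(params, seed) {
  stopifnot(inherits(params, "nlevel_params"))
  if (any(params$M != round(params$M))) {
    stop("sample_nlevel_community requires whole-number level sizes",
         call. = FALSE)
  }
  n <- params$n_levels
  M <- as.integer(params$M)
  out <- withr::with_seed(seed, {
    A <- vector("list", n)
    for (i in 2:n) {
      A[[i]] <- matrix(stats::rnorm(M[i] * M[i - 1],
                                    params$mu_alpha[i] / M[i - 1],
                                    params$sigma_alpha[i] / sqrt(M[i - 1])),
                       M[i], M[i - 1])
    }
    g <- lapply(seq_len(n), function(i) {
      stats::rnorm(M[i], params$g_mean[i], params$g_sd[i])
    })
    list(A = A, g = g)
  })
  out$seed <- seed
  class(out) <- "nlevel_instance"
  out
}

#' Right-hand side of the N-level dynamics
#'
#' Per-capita rate of species \eqn{\mu} on level \eqn{i}:
#' \eqn{g^i_\mu - D^i B^i_\mu + \eta^i \sum_\nu \alpha^{i,i-1}_{\mu\nu}
#' B^{i-1}_\nu - \sum_\nu \alpha^{i+1,i}_{\nu\mu} B^{i+1}_\nu}, with all
#' out-of-range level terms zero.
#'
#' @param state Concatenated abundance vector, bottom level first.
#' @param instance A [sample_nlevel_community()] instance.
#' @param params The matching [nlevel_params()].
#' @return Rate vector \eqn{dB/dt} with the same ordering.
#' @export
nlevel_rhs <- function(state, instance, params) {
  M <- as.integer(params$M)
  if (length(state) != sum(M)) {
    stop("state length ", length(state), " does not match sum(M) = ", sum(M),
         call. = FALSE)
  }
  B <- split(state, rep(seq_along(M), M))
  g <- nlevel_percapita(B, instance, params)
  unlist(lapply(seq_along(M), function(i) B[[i]] * g[[i]]), use.names = FALSE)
}

nlevel_percapita <- function(B, instance, params) {
  n <- params$n_levels
  lapply(seq_len(n), function(i) {
    rate <- instance$g[[i]] - params$D[i] * B[[i]]
    if (i > 1) {
      rate <- rate + params$eta[i] * drop(instance$A[[i]] %*% B[[i - 1]])
    }
    if (i < n) {
      rate <- rate - drop(crossprod(instance$A[[i + 1]], B[[i + 1]]))
    }
    rate
  })
}

#' Integrate an N-level community to steady state
#'
#' Same protocol as [integrate_to_steady_state()]: chunked lsoda with a
#' biomass-rate convergence test and projection of decaying transients to
#' zero at readout.
#'
#' @inheritParams nlevel_rhs
#' @param config An [integration_config()].
#' @param init Optional initial state; default uniform on
#'   \code{[init_low, init_high]}.
#' @param seed Seed for the initial condition.
#' @return List with per-level abundance list \code{B_star}, per-level
#'   \code{mean_B}, \code{q}, \code{phi}, plus \code{converged},
#'   \code{residual}, \code{t_end}.
#' @export
integrate_nlevel <- function(instance, params, config = integration_config(),
                             init = NULL, seed = instance$seed) {
  M <- as.integer(params$M)
  if (is.null(init)) {
    init <- withr::with_seed(seed, stats::runif(sum(M), config$init_low,
                                                config$init_high))
  }
  idx <- rep(seq_along(M), M)
  percap_flat <- function(y) {
    unlist(nlevel_percapita(split(y, idx), instance, params),
           use.names = FALSE)
  }
  res <- integrate_chunked(init,
                           function(y) nlevel_rhs(y, instance, params),
                           percap_flat, config)
  y <- res$state
  y[extinct_at_readout(y, percap_flat(y), config)] <- 0
  B <- unname(split(y, idx))
  list(B_star = B,
       mean_B = vapply(B, mean, numeric(1)),
       q = vapply(B, function(b) mean(b^2), numeric(1)),
       phi = vapply(B, function(b) mean(b > 0), numeric(1)),
       converged = res$converged, residual = res$residual, t_end = res$t_end)
}

# Self-consistency map for the N-level cavity equations. Unknowns: mean_B,
# q, chi per level (all >= 0; chi in the dB/dg convention). Returns
# predictions and effective quantities, with clamped D_eff and a violation
# measure that is zero when all D_eff are positive.
nlevel_core <- function(mean_B, q, chi, params) {
  n <- params$n_levels
  pad <- function(v) c(0, v, 0)   # boundary convention: level 0 and N+1
  mB <- pad(mean_B); qq <- pad(q); ch <- pad(chi)
  mu <- c(params$mu_alpha, 0); sg <- c(params$sigma_alpha, 0)
  eta <- c(params$eta, 0); r <- c(params$r, 0)
  i <- seq_len(n)
  g_eff <- params$g_mean - r[i + 1] * mu[i + 1] * mB[i + 2] +
    params$eta * params$mu_alpha * mB[i]
  s2 <- params$eta^2 * params$sigma_alpha^2 * qq[i] +
    sg[i + 1]^2 * r[i + 1] * qq[i + 2] + params$g_sd^2
  s <- sqrt(pmax(s2, 1e-300))
  D_eff <- params$D + params$eta * params$sigma_alpha^2 * ch[i] +
    eta[i + 1] * r[i + 1] * sg[i + 1]^2 * ch[i + 2]
  violation <- sum(pmax(0, -D_eff))
  Dc <- pmax(D_eff, 1e-12)
  delta <- g_eff / s
  w0 <- vapply(delta, function(x) w_integral(0, x), numeric(1))
  w1 <- vapply(delta, function(x) w_integral(1, x), numeric(1))
  w2 <- vapply(delta, function(x) w_integral(2, x), numeric(1))
  list(g_eff = g_eff, sigma_g = s, D_eff = D_eff, delta = delta, phi = w0,
       pred_mean = (s / Dc) * w1, pred_q = (s / Dc)^2 * w2,
       pred_chi = w0 / Dc, violation = violation)
}

nlevel_solver_residuals <- function(x, params, penalty_weight = 1e3) {
  n <- params$n_levels
  mean_B <- x[seq_len(n)]; q <- x[n + seq_len(n)]; chi <- x[2 * n + seq_len(n)]
  core <- nlevel_core(mean_B, q, chi, params)
  res <- c((mean_B - core$pred_mean) / pmax(1, abs(core$pred_mean)),
           (q - core$pred_q) / pmax(1, abs(core$pred_q)),
           (chi - core$pred_chi) / pmax(1, abs(core$pred_chi)))
  if (core$violation > 0) res <- res + penalty_weight * core$violation
  res
}

#' Solve the N-level cavity equations
#'
#' Solves the 3N self-consistency equations (per level: mean abundance,
#' second moment, susceptibility \eqn{\chi^i = \langle \partial B^i /
#' \partial g^i \rangle \ge 0}) by Levenberg-Marquardt least squares in
#' log-space, from a warm-up simulation, random multistarts, or an explicit
#' 3N-vector \code{(mean_B, q, chi)}.
#'
#' @param params An [nlevel_params()] object.
#' @param init \code{"warm_start_simulation"}, \code{"multistart_random"},
#'   or a positive numeric vector of length \code{3 * n_levels}.
#' @param seed Integer seed for warm-up/multistart draws.
#' @param n_starts Maximum number of starting points.
#' @param tol Acceptance threshold on the sum of squared scaled residuals.
#' @return Object of class \code{"nlevel_state"} with per-level vectors
#'   \code{mean_B}, \code{q}, \code{chi}, \code{g_eff}, \code{sigma_g},
#'   \code{D_eff}, \code{delta}, \code{phi}, and \code{residual_norm}.
#' @export
nlevel_solve <- function(params, init = "warm_start_simulation", seed = 1,
                         n_starts = 12, tol = 1e-12) {
  stopifnot(inherits(params, "nlevel_params"))
  n <- params$n_levels
  starts <- nlevel_starts(params, init, seed, n_starts)
  best <- NULL
  for (st in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = log(pmax(st, 1e-10)),
      fn = function(theta) nlevel_solver_residuals(exp(theta), params),
      control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                           ptol = 1e-15)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    x <- exp(fit$par)
    core <- nlevel_core(x[seq_len(n)], x[n + seq_len(n)],
                        x[2 * n + seq_len(n)], params)
    res <- c(x[seq_len(n)] - core$pred_mean, x[n + seq_len(n)] - core$pred_q,
             x[2 * n + seq_len(n)] - core$pred_chi) /
      pmax(1, abs(c(core$pred_mean, core$pred_q, core$pred_chi)))
    ss <- sum(res^2)
    feasible <- core$violation == 0
    if (is.null(best) || (feasible && ss < best$ss)) {
      best <- list(x = x, core = core, ss = ss, feasible = feasible)
    }
    if (feasible && ss < tol) break
  }
  if (is.null(best) || !best$feasible || best$ss >= tol) {
    stop("nlevel_solve failed to converge: best sum of squared scaled ",
         "residuals = ", signif(if (is.null(best)) Inf else best$ss, 4),
         call. = FALSE)
  }
  x <- unname(best$x); core <- best$core
  structure(list(mean_B = x[seq_len(n)], q = x[n + seq_len(n)],
                 chi = x[2 * n + seq_len(n)],
                 g_eff = core$g_eff, sigma_g = core$sigma_g,
                 D_eff = core$D_eff, delta = core$delta, phi = core$phi,
                 residual_norm = sqrt(best$ss), params = params),
            class = "nlevel_state")
}

nlevel_starts <- function(params, init, seed, n_starts) {
  n <- params$n_levels
  if (is.numeric(init)) {
    stopifnot(length(init) == 3 * n, all(init > 0))
    jit <- withr::with_seed(seed, replicate(max(0, n_starts - 1),
      init * stats::runif(3 * n, 0.5, 1.5), simplify = FALSE))
    c(list(as.numeric(init)), jit)
  } else if (identical(init, "warm_start_simulation")) {
    base <- 10
    M_small <- pmax(2, round(base * params$M / params$M[1]))
    p_small <- params
    p_small$M <- M_small
    p_small$r <- c(NA_real_, M_small[-1] / M_small[-n])
    inst <- sample_nlevel_community(p_small, seed)
    ss <- integrate_nlevel(inst, p_small, integration_config(), seed = seed)
    chi0 <- rep(0.3, n)
    ws <- pmax(c(ss$mean_B, ss$q, chi0), 1e-4)
    draws <- withr::with_seed(seed + 1L, replicate(max(0, n_starts - 1),
      ws * stats::runif(3 * n, 0.5, 1), simplify = FALSE))
    c(list(ws), draws)
  } else if (identical(init, "multistart_random")) {
    withr::with_seed(seed, replicate(n_starts,
      10^stats::runif(3 * n, -2, 0.5), simplify = FALSE))
  } else {
    stop("init must be a 3N-vector, \"warm_start_simulation\" or ",
         "\"multistart_random\"", call. = FALSE)
  }
}

#' @export
print.nlevel_state <- function(x, ...) {
  n <- length(x$mean_B)
  cat(sprintf("N-level cavity solution (%d levels, residual norm %.2e)\n",
              n, x$residual_norm))
  for (i in seq_len(n)) {
    cat(sprintf("  level %d: <B> = %.4g, q = %.4g, phi = %.3f, D_eff = %.4g\n",
                i, x$mean_B[i], x$q[i], x$phi[i], x$D_eff[i]))
  }
  invisible(x)
}

#' Top-down/bottom-up control ratio at an interior level
#'
#' Decomposes the emergent competition coefficient of an interior level
#' into the feedback mediated by the level above
#' (\eqn{\eta^{i+1} r^{i+1} (\sigma_\alpha^{i+1})^2 \chi^{i+1}}) and the
#' feedback mediated by the level below
#' (\eqn{\eta^i (\sigma_\alpha^i)^2 \chi^{i-1}}), and returns the top-down
#' fraction, in \eqn{[0, 1]}.
#'
#' @param state An [nlevel_solve()] solution.
#' @param params The matching [nlevel_params()].
#' @param i Interior level index (\eqn{1 < i < N}).
#' @return Numeric in \eqn{[0, 1]}; 0 means pure bottom-up control.
#' @export
order_parameter_level <- function(state, params, i) {
  n <- params$n_levels
  if (!(i > 1 && i < n)) {
    stop("undefined level: the control ratio is defined for interior ",
         "levels 1 < i < ", n, call. = FALSE)
  }
  top <- params$eta[i + 1] * params$r[i + 1] * params$sigma_alpha[i + 1]^2 *
    state$chi[i + 1]
  bottom <- params$eta[i] * params$sigma_alpha[i]^2 * state$chi[i - 1]
  top / (top + bottom)
}
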