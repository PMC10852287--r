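# Zero-temperature cavity (mean-field) solution of the three-level model.
#
# Six unknowns: the pool means <X>, <N>, <R> and second moments <X^2>,
# <N^2>, <R^2>. From these the effective growth rates g_eff and their SDs
# follow directly; the survival arguments Delta = g_eff/sigma_geff give the
# level susceptibilities in closed form, which in turn give the emergent
# competition coefficients D_eff; the truncated-Gaussian laws then predict
# the moments back. A solution is a fixed point of that loop.

.MOMENT_NAMES <- c("mean_X", "mean_N", "mean_R", "q_X", "q_N", "q_R")

#' Effective mean-field parameters from moments and susceptibilities
#'
#' Maps level moments and susceptibilities to the effective single-species
#' parameters of the coarse-grained steady state: mean effective growth
#' rates, their standard deviations, and the emergent competition
#' coefficients
#' \deqn{D_{eff}^X = -\eta_X \sigma_d^2 \nu,\quad
#'       D_{eff}^N = \eta_N \sigma_c^2 \kappa - \eta_X r_1 \sigma_d^2 \chi,\quad
#'       D_{eff}^R = 1 - \eta_N r_2 \sigma_c^2 \nu.}
#'
#' @param moments Named numeric vector with elements \code{mean_X},
#'   \code{mean_N}, \code{mean_R}, \code{q_X}, \code{q_N}, \code{q_R}
#'   (pool means and second moments).
#' @param susceptibilities Named numeric vector or list with \code{chi}
#'   (\eqn{\langle \partial X/\partial u\rangle \le 0}), \code{nu}
#'   (\eqn{\langle \partial N/\partial m\rangle \le 0}) and \code{kappa}
#'   (\eqn{\langle \partial R/\partial K\rangle \ge 0}).
#' @param params A [trophic_params()] object.
#' @return List with named 3-vectors \code{g_eff}, \code{sigma_g},
#'   \code{D_eff} (components \code{X}, \code{N}, \code{R}).
#' @export
effective_parameters <- function(moments, susceptibilities, params) {
  mo <- as.list(moments); su <- as.list(susceptibilities); p <- params
  stopifnot(all(.MOMENT_NAMES %in% names(mo)),
            all(c("chi", "nu", "kappa") %in% names(su)))
  r1v <- r1(p); r2v <- r2(p)
  g_eff <- c(X = -p$u + p$eta_X * p$mu_d * mo$mean_N,
             N = -p$m - r1v * p$mu_d * mo$mean_X + p$eta_N * p$mu_c * mo$mean_R,
             R = p$k - p$mu_c * r2v * mo$mean_N)
  sigma_g <- sqrt(c(
    X = p$eta_X^2 * p$sigma_d^2 * mo$q_N + p$sigma_u^2,
    N = p$eta_N^2 * p$sigma_c^2 * mo$q_R + p$sigma_d^2 * r1v * mo$q_X +
      p$sigma_m^2,
    R = p$sigma_K^2 + p$sigma_c^2 * r2v * mo$q_N))
  D_eff <- c(X = -p$eta_X * p$sigma_d^2 * su$nu,
             N = p$eta_N * p$sigma_c^2 * su$kappa -
               p$eta_X * r1v * p$sigma_d^2 * su$chi,
             R = 1 - p$eta_N * r2v * p$sigma_c^2 * su$nu)
  list(g_eff = g_eff, sigma_g = sigma_g, D_eff = D_eff)
}

#' Level susceptibilities from the survival arguments
#'
#' Closed-form elimination of the susceptibilities: with \eqn{w_0(\Delta)}
#' the survival fraction of each level,
#' \deqn{\kappa = w_0(\Delta_R) - r_2 w_0(\Delta_N) + r_1 r_2 w_0(\Delta_X),}
#' \deqn{\nu = -\frac{w_0(\Delta_N) - r_1 w_0(\Delta_X)}{\eta_N \sigma_c^2\,\kappa},\qquad
#'       \chi = -\frac{\eta_N \sigma_c^2\, w_0(\Delta_X)\, \kappa}
#'                   {\eta_X \sigma_d^2\,(w_0(\Delta_N) - r_1 w_0(\Delta_X))}.}
#' Physical solutions require \eqn{w_0(\Delta_N) > r_1 w_0(\Delta_X)}
#' (surviving herbivores outnumber surviving carnivores) and
#' \eqn{\kappa > 0} (the middle level does not saturate all its realized
#' niches); outside that region an error of class
#' \code{"infeasible_packing"} names the violated inequality.
#'
#' @param deltas Named numeric vector with \code{delta_X}, \code{delta_N},
#'   \code{delta_R}.
#' @inheritParams effective_parameters
#' @return List with \code{chi} (\eqn{\le 0}), \code{nu} (\eqn{\le 0}),
#'   \code{kappa} (\eqn{\ge 0}).
#' @export
susceptibilities_from_deltas <- function(deltas, params) {
  d <- as.list(deltas)
  stopifnot(all(c("delta_X", "delta_N", "delta_R") %in% names(d)))
  w0X <- w_integral(0, d$delta_X)
  w0N <- w_integral(0, d$delta_N)
  w0R <- w_integral(0, d$delta_R)
  r1v <- r1(params); r2v <- r2(params)
  den_N <- w0N - r1v * w0X
  kap <- w0R - r2v * w0N + r1v * r2v * w0X
  if (den_N <= 0) {
    stop(structure(class = c("infeasible_packing", "error", "condition"),
                   list(message = paste0(
                     "infeasible species packing: w0(delta_N) - r1*w0(delta_X) = ",
                     signif(den_N, 4), " <= 0 (competitive exclusion requires ",
                     "more surviving herbivores than carnivores)"),
                     call = NULL)))
  }
  if (kap <= 0) {
    stop(structure(class = c("infeasible_packing", "error", "condition"),
                   list(message = paste0(
                     "infeasible species packing: w0(delta_R) - r2*w0(delta_N) + ",
                     "r1*r2*w0(delta_X) = ", signif(kap, 4),
                     " <= 0 (herbivores exceed their realized niches)"),
                     call = NULL)))
  }
  chi <- if (params$eta_X * params$sigma_d^2 > 0) {
    -(params$eta_N * params$sigma_c^2 * w0X * kap) /
      (params$eta_X * params$sigma_d^2 * den_N)
  } else 0
  nu <- -den_N / (params$eta_N * params$sigma_c^2 * kap)
  list(chi = chi, nu = nu, kappa = kap)
}

# Full evaluation of the self-consistency map at a moment vector, with
# soft-clamped packing denominators so optimizers can traverse the
# infeasible region; `violation` is 0 exactly on the physical domain.
cavity_core <- function(moments, params) {
  p <- params
  mo <- as.list(moments)
  r1v <- r1(p); r2v <- r2(p)
  g <- c(X = -p$u + p$eta_X * p$mu_d * mo$mean_N,
         N = -p$m - r1v * p$mu_d * mo$mean_X + p$eta_N * p$mu_c * mo$mean_R,
         R = p$k - p$mu_c * r2v * mo$mean_N)
  s2 <- c(X = p$eta_X^2 * p$sigma_d^2 * mo$q_N + p$sigma_u^2,
          N = p$eta_N^2 * p$sigma_c^2 * mo$q_R + p$sigma_d^2 * r1v * mo$q_X +
            p$sigma_m^2,
          R = p$sigma_K^2 + p$sigma_c^2 * r2v * mo$q_N)
  s <- sqrt(pmax(s2, 1e-300))
  delta <- g / s
  w0 <- vapply(delta, function(x) w_integral(0, x), numeric(1))
  w1 <- vapply(delta, function(x) w_integral(1, x), numeric(1))
  w2 <- vapply(delta, function(x) w_integral(2, x), numeric(1))
  den_N <- w0[["N"]] - r1v * w0[["X"]]
  kap_raw <- w0[["R"]] - r2v * w0[["N"]] + r1v * r2v * w0[["X"]]
  violation <- max(0, -den_N) + max(0, -kap_raw)
  eps <- 1e-12
  den_Nc <- max(den_N, eps)
  kapc <- max(kap_raw, eps)
  chi <- if (p$eta_X * p$sigma_d^2 > 0) {
    -(p$eta_N * p$sigma_c^2 * w0[["X"]] * kapc) /
      (p$eta_X * p$sigma_d^2 * den_Nc)
  } else 0
  nu <- -den_Nc / (p$eta_N * p$sigma_c^2 * kapc)
  D <- c(X = -p$eta_X * p$sigma_d^2 * nu,
         N = p$eta_N * p$sigma_c^2 * kapc - p$eta_X * r1v * p$sigma_d^2 * chi,
         R = 1 - p$eta_N * r2v * p$sigma_c^2 * nu)
  Dc <- pmax(D, eps)
  ratio <- s / Dc
  pred <- c(mean_X = ratio[["X"]] * w1[["X"]],
            mean_N = ratio[["N"]] * w1[["N"]],
            mean_R = ratio[["R"]] * w1[["R"]],
            q_X = ratio[["X"]]^2 * w2[["X"]],
            q_N = ratio[["N"]]^2 * w2[["N"]],
            q_R = ratio[["R"]]^2 * w2[["R"]])
  list(g_eff = g, sigma_g = s, delta = delta, phi = w0,
       chi = chi, nu = nu, kappa = kapc, kappa_raw = kap_raw,
       den_N = den_N, D_eff = D, predicted = pred, violation = violation)
}

#' Residuals of the cavity self-consistency equations
#'
#' Evaluates the six self-consistency residuals \eqn{\langle X \rangle -
#' (\sigma_{g}^X/D_{eff}^X) w_1(\Delta_X), \ldots, \langle R^2 \rangle -
#' (\sigma_{g}^R/D_{eff}^R)^2 w_2(\Delta_R)} at a candidate moment vector.
#' A root of this map (in the physical packing region) is the mean-field
#' solution.
#'
#' @param unknowns Numeric vector of length 6, ordered as
#'   \code{(mean_X, mean_N, mean_R, q_X, q_N, q_R)}, all \eqn{\ge 0}.
#' @inheritParams effective_parameters
#' @param scaled If \code{TRUE}, each residual is divided by
#'   \code{max(1, |predicted term|)} (the scaling used by the solver to
#'   balance moment magnitudes).
#' @return Numeric vector of 6 residuals, named as the unknowns.
#' @export
cavity_residuals <- function(unknowns, params, scaled = FALSE) {
  stopifnot(length(unknowns) == 6, all(unknowns >= 0))
  mo <- stats::setNames(as.numeric(unknowns), .MOMENT_NAMES)
  core <- cavity_core(mo, params)
  if (core$violation > 0) {
    # reuse the strict path for a named infeasibility error
    susceptibilities_from_deltas(
      list(delta_X = core$delta[["X"]], delta_N = core$delta[["N"]],
           delta_R = core$delta[["R"]]), params)
  }
  res <- mo - core$predicted
  if (scaled) res <- res / pmax(1, abs(core$predicted))
  res
}

# solver-facing residuals: scaled, smooth penalty outside physical region
solver_residuals <- function(moments, params, exclusion_penalty = FALSE,
                             penalty_weight = 1e3) {
  core <- cavity_core(moments, params)
  res <- (moments - core$predicted) / pmax(1, abs(core$predicted))
  if (core$violation > 0) res <- res + penalty_weight * core$violation
  if (exclusion_penalty) {
    r1v <- r1(params); r2v <- r2(params)
    res <- c(res,
             penalty_weight * max(0, r1v * core$phi[["X"]] - core$phi[["N"]]),
             penalty_weight * max(0, r2v * core$phi[["N"]] - core$phi[["R"]] -
                                    r1v * r2v * core$phi[["X"]]))
  }
  res
}

warm_start_moments <- function(params, seed, base_M_N = 10) {
  p_small <- update_params(params,
                           M_N = base_M_N,
                           M_X = max(2, round(base_M_N * r1(params))),
                           M_R = max(2, round(base_M_N / r2(params))))
  inst <- sample_community(p_small, seed)
  ss <- integrate_to_steady_state(inst, p_small, integration_config(),
                                  seed = seed)
  mom <- c(ss$mean_X, ss$mean_N, ss$mean_R,
           ss$second_moment_X, ss$second_moment_N, ss$second_moment_R)
  pmax(mom, 1e-4)
}

#' Solve the three-level cavity equations
#'
#' Finds the six moments solving the self-consistency system by nonlinear
#' least squares (Levenberg-Marquardt) on the scaled residuals, optimized
#' in log-space so positivity is enforced without explicit constraints.
#' Starting points come either from a small warm-up simulation (default;
#' a 10-herbivore-scale community is integrated once and its pooled moments
#' bracket the multistart range between half and the full value), from
#' random log-uniform multistarts, or from an explicit 6-vector (e.g. the
#' solution at a neighbouring point of a parameter scan).
#'
#' A start is accepted when the sum of squared scaled residuals falls below
#' \code{tol} and the solution lies strictly inside the physical packing
#' region; otherwise further starts are tried.
#'
#' @inheritParams effective_parameters
#' @param init Either \code{"warm_start_simulation"},
#'   \code{"multistart_random"}, or a numeric 6-vector
#'   \code{(mean_X, mean_N, mean_R, q_X, q_N, q_R)}.
#' @param seed Integer seed controlling the warm-up simulation and
#'   multistart draws.
#' @param n_starts Maximum number of starting points.
#' @param tol Acceptance threshold on the sum of squared scaled residuals.
#' @param exclusion_penalty If \code{TRUE}, adds penalty residuals that push
#'   the optimizer to respect the rescaled competitive-exclusion
#'   inequalities (an optional accuracy aid; the accepted solution is always
#'   validated against the plain residuals).
#' @return An object of class \code{"cavity_state"}: the six moments, the
#'   susceptibilities \code{chi}, \code{nu}, \code{kappa}, effective
#'   parameters \code{g_eff}, \code{sigma_g}, \code{D_eff}, survival
#'   arguments \code{delta}, survival fractions \code{phi}, the niche ratio
#'   \code{f}, and \code{residual_norm}.
#' @export
cavity_solve <- function(params, init = "warm_start_simulation", seed = 1,
                         n_starts = 12, tol = 1e-12,
                         exclusion_penalty = FALSE) {
  stopifnot(inherits(params, "trophic_params"))
  if (params$sigma_c <= 0 || params$sigma_d <= 0) {
    stop("cavity_solve requires sigma_c > 0 and sigma_d > 0 ",
         "(the mean-field closure is built on preference variance)",
         call. = FALSE)
  }
  # fall back through start strategies rather than failing outright
  strategies <- unique(c(list(init), list("warm_start_simulation",
                                          "multistart_random")))
  best <- NULL
  for (strategy in strategies) {
    starts <- tryCatch(cavity_starts(params, strategy, seed, n_starts),
                       error = function(e) list())
    for (st in starts) {
      fit <- try(minpack.lm::nls.lm(
        par = log(pmax(st, 1e-10)),
        fn = function(theta) solver_residuals(
          stats::setNames(exp(theta), .MOMENT_NAMES), params,
          exclusion_penalty = exclusion_penalty),
        control = minpack.lm::nls.lm.control(maxiter = 400, ftol = 1e-15,
                                             ptol = 1e-15)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      mom <- stats::setNames(exp(fit$par), .MOMENT_NAMES)
      core <- cavity_core(mom, params)
      ss <- sum(((mom - core$predicted) / pmax(1, abs(core$predicted)))^2)
      feasible <- core$violation == 0
      if (is.null(best) || (feasible && ss < best$ss)) {
        best <- list(mom = mom, core = core, ss = ss, feasible = feasible)
      }
      if (feasible && ss < tol) break
    }
    if (!is.null(best) && best$feasible && best$ss < tol) break
  }
  if (is.null(best) || !best$feasible || best$ss >= tol) {
    stop("cavity_solve failed to converge: best sum of squared scaled ",
         "residuals = ", signif(if (is.null(best)) Inf else best$ss, 4),
         " (tol ", signif(tol, 4), "); try more starts or a warm start",
         call. = FALSE)
  }
  as_cavity_state(best$mom, best$core, params, sqrt(best$ss))
}

cavity_starts <- function(params, init, seed, n_starts) {
  if (is.numeric(init)) {
    stopifnot(length(init) == 6, all(init > 0))
    jitters <- withr::with_seed(seed, replicate(max(0, n_starts - 1),
      init * stats::runif(6, 0.5, 1.5), simplify = FALSE))
    c(list(as.numeric(init)), jitters)
  } else if (identical(init, "warm_start_simulation")) {
    ws <- warm_start_moments(params, seed)
    draws <- withr::with_seed(seed + 1L, replicate(max(0, n_starts - 1),
      ws * stats::runif(6, 0.5, 1), simplify = FALSE))
    c(list(ws), draws)
  } else if (identical(init, "multistart_random")) {
    withr::with_seed(seed, replicate(n_starts,
      10^stats::runif(6, -2, 0.5), simplify = FALSE))
  } else {
    stop("init must be a 6-vector, \"warm_start_simulation\" or ",
         "\"multistart_random\"", call. = FALSE)
  }
}

as_cavity_state <- function(mom, core, params, residual_norm) {
  r1v <- r1(params); r2v <- r2(params)
  phi <- core$phi
  f <- (phi[["R"]] / r2v + r1v * phi[["X"]] - phi[["N"]]) /
    (phi[["N"]] - r1v * phi[["X"]])
  structure(list(
    mean_X = mom[["mean_X"]], mean_N = mom[["mean_N"]], mean_R = mom[["mean_R"]],
    q_X = mom[["q_X"]], q_N = mom[["q_N"]], q_R = mom[["q_R"]],
    chi = core$chi, nu = core$nu, kappa = core$kappa,
    g_eff = core$g_eff, sigma_g = core$sigma_g, D_eff = core$D_eff,
    delta = core$delta, phi = phi, f = f,
    residual_norm = residual_norm, params = params
  ), class = "cavity_state")
}

#' @export
print.cavity_state <- function(x, ...) {
  cat(sprintf("Cavity solution (residual norm %.2e)\n", x$residual_norm))
  cat(sprintf("  <X> = %.4g, <N> = %.4g, <R> = %.4g\n",
              x$mean_X, x$mean_N, x$mean_R))
  cat(sprintf("  phi_X = %.3f, phi_N = %.3f, phi_R = %.3f (f = %.3f)\n",
              x$phi[["X"]], x$phi[["N"]], x$phi[["R"]], x$f))
  cat(sprintf("  D_eff: X = %.4g, N = %.4g, R = %.4g\n",
              x$D_eff[["X"]], x$D_eff[["N"]], x$D_eff[["R"]]))
  invisible(x)
}
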