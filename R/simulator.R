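# ODE integration of sampled communities to steady state, and pooled
# ensemble statistics matching the averages the cavity solution predicts.

#' Integration settings for steady-state runs
#'
#' @param t_final Integration horizon (time units). Integration proceeds in
#'   chunks and stops early once the steady-state residual criterion is
#'   met, so \code{t_final} is a cap, not a fixed cost.
#' @param chunk Length of one integration chunk between residual checks.
#' @param max_step Maximum integrator step (passed to the adaptive solver).
#' @param rel_tol,abs_tol Relative/absolute integrator tolerances.
#' @param extinction_threshold Abundances below this at readout are set to
#'   exactly 0 and counted extinct. Applied at readout only, never during
#'   integration.
#' @param extinction_rate_tol Per-capita growth-rate tolerance for the
#'   extinction classification at readout (see
#'   [integrate_to_steady_state()] for the full rule). Species decaying
#'   faster than this while small, or faster than 100 times this at any
#'   abundance, are projected to their limit (exactly 0) and counted
#'   extinct.
#' @param extinction_macro_abundance Abundance above which a species is
#'   considered macroscopic: weakly negative growth rates (within 100x the
#'   rate tolerance) do not kill a macroscopic species, since marginal
#'   survivors approach their equilibrium from above with small negative
#'   rates.
#' @param init_low,init_high Initial abundances are drawn uniformly on
#'   \code{[init_low, init_high]} (default \code{[1, 2]}).
#' @param steady_state_residual_tol Convergence criterion: the run is
#'   declared converged when the largest absolute biomass rate
#'   \eqn{|B_i \, g_i|} (abundance times per-capita growth rate) among
#'   non-extinct species falls below this value. Biomass rates, rather than
#'   per-capita rates, are used so that species on their way to extinction
#'   -- whose per-capita rates stay finite while their abundances decay
#'   exponentially -- do not mask equilibration of the community.
#' @return An object of class \code{"integration_config"}.
#' @export
integration_config <- function(t_final = 1000, chunk = 100, max_step = Inf,
                               rel_tol = 1e-8, abs_tol = 1e-10,
                               extinction_threshold = 1e-6,
                               extinction_rate_tol = 1e-4,
                               extinction_macro_abundance = 1e-2,
                               init_low = 1, init_high = 2,
                               steady_state_residual_tol = 1e-4) {
  stopifnot(t_final > 0, chunk > 0, extinction_threshold > 0,
            extinction_rate_tol > 0, extinction_macro_abundance > 0,
            init_low > 0, init_low < init_high,
            steady_state_residual_tol > 0)
  structure(list(t_final = t_final, chunk = chunk, max_step = max_step,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 extinction_threshold = extinction_threshold,
                 extinction_rate_tol = extinction_rate_tol,
                 extinction_macro_abundance = extinction_macro_abundance,
                 init_low = init_low, init_high = init_high,
                 steady_state_residual_tol = steady_state_residual_tol),
            class = "integration_config")
}

#' Right-hand side of the three-level dynamics
#'
#' Per-capita rates: carnivores \eqn{\dot X_\alpha/X_\alpha = \eta_X \sum_j
#' d_{\alpha j} N_j - u_\alpha} (conversion efficiency applies to
#' consumption, not mortality); herbivores \eqn{\dot N_i/N_i = \eta_N
#' \sum_Q c_{iQ} R_Q - m_i - \sum_\beta d_{\beta i} X_\beta}; plants
#' \eqn{\dot R_P/R_P = K_P - R_P - \sum_j c_{jP} N_j}. Zero abundance is
#' absorbing (zero rate).
#'
#' @param state Numeric vector \code{c(X, N, R)} of length
#'   \code{M_X + M_N + M_R}.
#' @param instance A [sample_community()] instance.
#' @param params The matching [trophic_params()].
#' @return Numeric rate vector of the same length and ordering.
#' @export
trophic_rhs <- function(state, instance, params) {
  M_X <- nrow(instance$d); M_N <- ncol(instance$d); M_R <- ncol(instance$c)
  if (length(state) != M_X + M_N + M_R) {
    stop("state length ", length(state), " does not match M_X + M_N + M_R = ",
         M_X + M_N + M_R, call. = FALSE)
  }
  X <- state[seq_len(M_X)]
  N <- state[M_X + seq_len(M_N)]
  R <- state[M_X + M_N + seq_len(M_R)]
  gX <- params$eta_X * drop(instance$d %*% N) - instance$u_vec
  gN <- params$eta_N * drop(instance$c %*% R) - instance$m_vec -
    drop(crossprod(instance$d, X))
  gR <- instance$K - R - drop(crossprod(instance$c, N))
  c(X * gX, N * gN, R * gR)
}

# per-capita growth rates, used for the steady-state residual
percapita_rates <- function(state, instance, params) {
  M_X <- nrow(instance$d); M_N <- ncol(instance$d); M_R <- ncol(instance$c)
  X <- state[seq_len(M_X)]
  N <- state[M_X + seq_len(M_N)]
  R <- state[M_X + M_N + seq_len(M_R)]
  c(params$eta_X * drop(instance$d %*% N) - instance$u_vec,
    params$eta_N * drop(instance$c %*% R) - instance$m_vec -
      drop(crossprod(instance$d, X)),
    instance$K - R - drop(crossprod(instance$c, N)))
}

# Extinction classification shared by readouts: a species is projected to
# zero when it is (i) below the abundance threshold without clearly
# positive growth, (ii) small and decaying faster than the rate tolerance,
# or (iii) collapsing fast at any abundance. Macroscopic species with
# weakly negative rates are marginal survivors still settling from above
# and are kept.
extinct_at_readout <- function(y, g, config) {
  rtol <- config$extinction_rate_tol
  (y < config$extinction_threshold & g <= rtol) |
    (g < -rtol & y < config$extinction_macro_abundance) |
    (g < -100 * rtol)
}

# Chunked adaptive integration with an explicit residual stopping rule.
# `rate_fn(state)` returns d(state)/dt, `percap_fn(state)` per-capita rates.
integrate_chunked <- function(y0, rate_fn, percap_fn, config) {
  derivs <- function(t, y, parms) list(rate_fn(pmax(y, 0)))
  t_done <- 0
  y <- y0
  converged <- FALSE
  residual <- Inf
  while (t_done < config$t_final) {
    t_next <- min(t_done + config$chunk, config$t_final)
    sol <- deSolve::ode(y = y, times = c(t_done, t_next), func = derivs,
                        parms = NULL, method = "lsoda",
                        rtol = config$rel_tol, atol = config$abs_tol,
                        hmax = config$max_step)
    y <- unname(sol[nrow(sol), -1])
    if (any(!is.finite(y))) {
      stop(structure(class = c("integration_error", "error", "condition"),
                     list(message = paste0("integrator produced non-finite state at t = ",
                                           t_next),
                          call = NULL, partial_state = y, t = t_next)))
    }
    y <- pmax(y, 0)
    t_done <- t_next
    g <- percap_fn(y)
    alive <- y >= config$extinction_threshold
    residual <- if (any(alive)) max(abs((y * g)[alive])) else 0
    # settled only when no below-threshold species is still invading
    # (positive per-capita growth at tiny abundance regrows later and
    # reshapes the community)
    invading <- any(!alive & y > 0 & g > config$extinction_rate_tol)
    if (residual < config$steady_state_residual_tol && !invading) {
      converged <- TRUE
      break
    }
  }
  list(state = y, t_end = t_done, converged = converged, residual = residual)
}

#' Integrate one community to steady state
#'
#' Integrates the three-level dynamics from random positive initial
#' abundances with a stiff-capable adaptive solver (lsoda), in chunks, until
#' the largest absolute biomass rate among non-extinct species drops below
#' \code{config$steady_state_residual_tol} or \code{config$t_final} is
#' reached. At readout, species below \code{extinction_threshold} or still
#' decaying faster than \code{extinction_rate_tol} (per capita) are
#' projected to their limit, exactly zero, and counted extinct.
#'
#' Moments (\code{mean_*}, \code{second_moment_*}) are averages over the
#' full regional pool, extinct species included as zeros -- the same
#' averages the mean-field solution predicts.
#'
#' @inheritParams trophic_rhs
#' @param config An [integration_config()].
#' @param init Optional explicit initial state vector; by default drawn
#'   uniformly on \code{[init_low, init_high]} using \code{seed}.
#' @param seed Seed for the initial condition (defaults to
#'   \code{instance$seed}).
#' @return An object of class \code{"steady_state_summary"} with abundance
#'   vectors \code{X_star}, \code{N_star}, \code{R_star}, survivor counts,
#'   pooled moments, the final residual, and a \code{converged} flag
#'   (non-convergence is reported, not thrown).
#' @export
integrate_to_steady_state <- function(instance, params,
                                      config = integration_config(),
                                      init = NULL, seed = instance$seed) {
  M_X <- nrow(instance$d); M_N <- ncol(instance$d); M_R <- ncol(instance$c)
  M <- M_X + M_N + M_R
  if (is.null(init)) {
    init <- withr::with_seed(seed, stats::runif(M, config$init_low,
                                                config$init_high))
  }
  stopifnot(length(init) == M, all(init > 0))
  res <- integrate_chunked(init,
                           function(y) trophic_rhs(y, instance, params),
                           function(y) percapita_rates(y, instance, params),
                           config)
  y <- res$state
  g <- percapita_rates(y, instance, params)
  y[extinct_at_readout(y, g, config)] <- 0
  X <- y[seq_len(M_X)]; N <- y[M_X + seq_len(M_N)]; R <- y[M_X + M_N + seq_len(M_R)]
  structure(list(
    X_star = X, N_star = N, R_star = R,
    survivors_X = sum(X > 0), survivors_N = sum(N > 0), survivors_R = sum(R > 0),
    mean_X = mean(X), mean_N = mean(N), mean_R = mean(R),
    second_moment_X = mean(X^2), second_moment_N = mean(N^2),
    second_moment_R = mean(R^2),
    converged = res$converged, residual = res$residual, t_end = res$t_end
  ), class = "steady_state_summary")
}

#' @export
print.steady_state_summary <- function(x, ...) {
  cat(sprintf("Steady state (t = %g, residual %.2e, converged: %s)\n",
              x$t_end, x$residual, x$converged))
  cat(sprintf("  survivors  X: %d/%d  N: %d/%d  R: %d/%d\n",
              x$survivors_X, length(x$X_star), x$survivors_N,
              length(x$N_star), x$survivors_R, length(x$R_star)))
  cat(sprintf("  pool means <X> = %.4g, <N> = %.4g, <R> = %.4g\n",
              x$mean_X, x$mean_N, x$mean_R))
  invisible(x)
}

#' Pooled steady-state statistics over a simulated ensemble
#'
#' Samples \code{n_systems} communities, integrates each to steady state,
#' and pools moments and survival fractions over all species of all
#' converged systems. Standard errors are between-system SDs of the
#' per-system statistics divided by \code{sqrt(n_converged)}, the natural
#' scale for comparing the pooled values with a mean-field prediction.
#'
#' @inheritParams sample_community
#' @param n_systems Number of independent systems.
#' @param config An [integration_config()].
#' @return Object of class \code{"ensemble_summary"}: pooled moments
#'   (\code{mean_X}, ..., \code{second_moment_R}), survival fractions
#'   (\code{phi_X}, \code{phi_N}, \code{phi_R}), standard errors
#'   (\code{se}, named vector), a per-system data frame (\code{per_system}),
#'   pooled abundance vectors (\code{abundances}, for histograms), and
#'   \code{n_nonconverged}.
#' @export
ensemble_statistics <- function(params, n_systems, config = integration_config(),
                                seed = 1) {
  stopifnot(n_systems >= 1)
  instances <- generate_ensemble(params, n_systems, seed)
  init_seeds <- split_seeds(seed + 1L, n_systems)
  runs <- mapply(function(inst, s) {
    integrate_to_steady_state(inst, params, config, seed = s)
  }, instances, init_seeds, SIMPLIFY = FALSE)
  conv <- vapply(runs, `[[`, logical(1), "converged")
  if (!any(conv)) {
    stop("empty statistics: no system reached the steady-state residual ",
         "criterion; raise t_final or loosen the residual tolerance",
         call. = FALSE)
  }
  kept <- runs[conv]
  per_system <- do.call(rbind, lapply(kept, function(s) {
    data.frame(mean_X = s$mean_X, mean_N = s$mean_N, mean_R = s$mean_R,
               second_moment_X = s$second_moment_X,
               second_moment_N = s$second_moment_N,
               second_moment_R = s$second_moment_R,
               phi_X = s$survivors_X / length(s$X_star),
               phi_N = s$survivors_N / length(s$N_star),
               phi_R = s$survivors_R / length(s$R_star))
  }))
  pooled <- colMeans(per_system)
  se <- apply(per_system, 2, stats::sd) / sqrt(nrow(per_system))
  structure(list(
    mean_X = pooled[["mean_X"]], mean_N = pooled[["mean_N"]],
    mean_R = pooled[["mean_R"]],
    second_moment_X = pooled[["second_moment_X"]],
    second_moment_N = pooled[["second_moment_N"]],
    second_moment_R = pooled[["second_moment_R"]],
    phi_X = pooled[["phi_X"]], phi_N = pooled[["phi_N"]],
    phi_R = pooled[["phi_R"]],
    se = se, per_system = per_system,
    abundances = list(X = unlist(lapply(kept, `[[`, "X_star")),
                      N = unlist(lapply(kept, `[[`, "N_star")),
                      R = unlist(lapply(kept, `[[`, "R_star"))),
    n_systems = n_systems, n_converged = sum(conv),
    n_nonconverged = sum(!conv)
  ), class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble of %d systems (%d converged)\n",
              x$n_systems, x$n_converged))
  cat(sprintf("  <X> = %.4g (phi_X = %.3f), <N> = %.4g (phi_N = %.3f), <R> = %.4g (phi_R = %.3f)\n",
              x$mean_X, x$phi_X, x$mean_N, x$phi_N, x$mean_R, x$phi_R))
  invisible(x)
}
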