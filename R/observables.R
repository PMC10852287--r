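# Species-packing diagnostics, top-down vs bottom-up control order
# parameters, emergent-competition decompositions, the exactly solvable
# single-species toy model, parameter scans and finite-size diagnostics.

#' Surviving-species counts
#'
#' Container for the per-level survivor counts \eqn{M^*} used by the
#' packing diagnostics. Counts may come from a simulation (integer
#' survivors) or from a cavity solution (expected counts \eqn{\phi M},
#' generally non-integer).
#'
#' @param M_X_star,M_N_star,M_R_star Surviving (or expected surviving)
#'   species per level.
#' @param source \code{"simulation"} or \code{"cavity"}.
#' @return Object of class \code{"packing_counts"}. Violations of the
#'   competitive-exclusion bounds (\eqn{M_X^* \le M_N^*},
#'   \eqn{M_N^* \le M_R^* + M_X^*}) are permitted -- finite noisy
#'   simulations can transiently break them -- but flagged via the
#'   \code{exclusion_ok} field with a warning.
#' @export
packing_counts <- function(M_X_star, M_N_star, M_R_star,
                           source = c("simulation", "cavity")) {
  source <- match.arg(source)
  stopifnot(M_X_star >= 0, M_N_star >= 0, M_R_star >= 0)
  ok <- (M_X_star <= M_N_star) && (M_N_star <= M_R_star + M_X_star)
  if (!ok) {
    warning("competitive-exclusion bounds violated by the supplied counts",
            call. = FALSE)
  }
  structure(list(M_X_star = M_X_star, M_N_star = M_N_star,
                 M_R_star = M_R_star, source = source, exclusion_ok = ok),
            class = "packing_counts")
}

#' @describeIn packing_counts Extract counts from a steady-state summary
#'   or expected counts from a cavity solution.
#' @param x A \code{"steady_state_summary"} or \code{"cavity_state"}.
#' @export
as_packing_counts <- function(x) {
  if (inherits(x, "steady_state_summary")) {
    packing_counts(x$survivors_X, x$survivors_N, x$survivors_R, "simulation")
  } else if (inherits(x, "cavity_state")) {
    p <- x$params
    packing_counts(x$phi[["X"]] * p$M_X, x$phi[["N"]] * p$M_N,
                   x$phi[["R"]] * p$M_R, "cavity")
  } else {
    stop("cannot extract packing counts from class ",
         paste(class(x), collapse = "/"), call. = FALSE)
  }
}

#' Unfilled-niche ratio f
#'
#' \eqn{f = (M_R^* + M_X^* - M_N^*)/(M_N^* - M_X^*)}: the number of
#' unfilled realized niches in the middle level per unfilled niche in the
#' top level. Controls the emergent competition coefficients, e.g.
#' \eqn{D_{eff}^R = 1 + 1/f}.
#'
#' @param counts A [packing_counts()] object.
#' @return Numeric.
#' @export
f_ratio <- function(counts) {
  stopifnot(inherits(counts, "packing_counts"))
  den <- counts$M_N_star - counts$M_X_star
  if (den == 0) {
    stop("f is undefined when M_N* = M_X*: no unfilled realized niches ",
         "in the top level (division by zero)", call. = FALSE)
  }
  (counts$M_R_star + counts$M_X_star - counts$M_N_star) / den
}

#' Emergent competition coefficients from species packing
#'
#' The packing form of the emergent competition coefficients:
#' \deqn{D_{eff}^X = \frac{\eta_X \sigma_d^2}{\eta_N \sigma_c^2 r_2}\, \frac{1}{f},\qquad
#'       D_{eff}^N = \eta_N\, \phi_N\, \sigma_c^2\, r_2\, f,\qquad
#'       D_{eff}^R = 1 + \frac{1}{f}.}
#' At a cavity solution these equal the susceptibility-based definitions.
#'
#' @param counts A [packing_counts()] object.
#' @param params A [trophic_params()] object.
#' @param phi_N Survival fraction of the middle level
#'   (\eqn{M_N^*/M_N}); defaults to \code{counts$M_N_star / params$M_N}.
#' @return Named numeric vector \code{c(X = , N = , R = )}.
#' @export
d_eff_from_packing <- function(counts, params, phi_N = NULL) {
  f <- f_ratio(counts)
  if (f <= 0) {
    stop("packing form requires f > 0 (middle level below saturation)",
         call. = FALSE)
  }
  if (is.null(phi_N)) phi_N <- counts$M_N_star / params$M_N
  r2v <- r2(params)
  c(X = (params$eta_X * params$sigma_d^2) /
      (params$eta_N * params$sigma_c^2 * r2v * f),
    N = params$eta_N * phi_N * params$sigma_c^2 * r2v * f,
    R = 1 + 1 / f)
}

#' Biomass-based control order parameter
#'
#' Splits the effective growth rate of the middle level into the predation
#' loss from the top level (\eqn{g_{eff}^{N,top} = -r_1 \mu_d \langle X
#' \rangle}) and the consumption gain from the bottom level
#' (\eqn{g_{eff}^{N,bottom} = \eta_N \mu_c \langle R \rangle}) and returns
#' \eqn{|g^{N,top}|/(|g^{N,top}| + g^{N,bottom})}: 1 is pure top-down
#' control, 0 pure bottom-up.
#'
#' @param state A [cavity_solve()] solution.
#' @param params Optional [trophic_params()]; defaults to the parameter set
#'   stored in \code{state}.
#' @return Numeric in \eqn{[0, 1]}.
#' @export
biomass_order_parameter <- function(state, params = state$params) {
  top <- r1(params) * params$mu_d * state$mean_X
  bottom <- params$eta_N * params$mu_c * state$mean_R
  if (top + bottom == 0) {
    stop("control is undefined: both the top and bottom contributions to ",
         "the middle level's growth rate vanish", call. = FALSE)
  }
  top / (top + bottom)
}

#' Species-packing control order parameter
#'
#' The fraction of realized niches that are filled in the top level,
#' \eqn{M_X^*/M_N^*}. Equals the competition-decomposition ratio
#' \eqn{D_{eff}^{N,top}/(D_{eff}^{N,top} + D_{eff}^{N,bottom})}. Values
#' above 0.5 indicate predominantly top-down control.
#'
#' @param x A [packing_counts()] object or a [cavity_solve()] solution
#'   (for which \eqn{r_1 \phi_X / \phi_N} is used).
#' @return Numeric in \eqn{[0, 1]}.
#' @export
packing_order_parameter <- function(x) {
  if (inherits(x, "cavity_state")) {
    phi_N <- x$phi[["N"]]
    if (phi_N <= 0) stop("empty middle level: phi_N = 0", call. = FALSE)
    r1(x$params) * x$phi[["X"]] / phi_N
  } else if (inherits(x, "packing_counts")) {
    if (x$M_N_star <= 0) {
      stop("empty middle level: M_N* = 0", call. = FALSE)
    }
    x$M_X_star / x$M_N_star
  } else {
    stop("x must be packing_counts or cavity_state", call. = FALSE)
  }
}

#' Derivative-based control order parameter
#'
#' Central-difference sensitivities of the middle level's mean abundance to
#' the bottom level's mean carrying capacity \eqn{k} and the top level's
#' mean death rate \eqn{u}, from cavity solutions at the four stencil
#' points. Returns the bottom-up fraction
#' \eqn{|d\langle N\rangle/dk| / (|d\langle N\rangle/dk| +
#' |d\langle N\rangle/du|)}; the complementary top-down fraction is
#' attached as attribute \code{"top_down"}.
#'
#' @inheritParams cavity_solve
#' @param h_rel Relative step for the central differences.
#' @param center Optional pre-computed [cavity_solve()] solution at
#'   \code{params}, used to warm-start the stencil solves.
#' @return Numeric in \eqn{[0, 1]} (bottom-up fraction) with attribute
#'   \code{top_down}.
#' @export
derivative_order_parameter <- function(params, h_rel = 0.01, seed = 1,
                                       center = NULL) {
  if (is.null(center)) center <- cavity_solve(params, seed = seed)
  init <- cavity_moment_vector(center)
  solve_at <- function(p) {
    cavity_solve(p, init = init, seed = seed)$mean_N
  }
  hk <- h_rel * abs(params$k)
  hu <- h_rel * abs(params$u)
  stopifnot(hk > 0, hu > 0)
  dNdk <- (solve_at(update_params(params, k = params$k + hk)) -
             solve_at(update_params(params, k = params$k - hk))) / (2 * hk)
  dNdu <- (solve_at(update_params(params, u = params$u + hu)) -
             solve_at(update_params(params, u = params$u - hu))) / (2 * hu)
  bottom_up <- abs(dNdk) / (abs(dNdk) + abs(dNdu))
  structure(bottom_up, top_down = 1 - bottom_up,
            dNdk = dNdk, dNdu = dNdu)
}

cavity_moment_vector <- function(state) {
  c(state$mean_X, state$mean_N, state$mean_R, state$q_X, state$q_N, state$q_R)
}

#' Exact steady state of the single-species toy chain
#'
#' One species per level with bare intra-specific competition on every
#' level:
#' \deqn{\dot R = R (k_1 - D_R R - c_{11} N),\quad
#'       \dot N = N (\eta_N c_{11} R - m_1 - D_N N - d_{11} X),\quad
#'       \dot X = X (\eta_X d_{11} N - u_1 - D_X X).}
#' The globally stable steady state is found by case analysis: the interior
#' 3x3 linear system first, then the two-level community (no carnivore),
#' then the plant-only community, then the empty state -- accepting the
#' first candidate that is both nonnegative and uninvadable by the excluded
#' species.
#'
#' @param k1 Plant carrying-capacity rate.
#' @param m1,u1 Herbivore and carnivore death rates.
#' @param eta_N,eta_X Conversion efficiencies.
#' @param D_R,D_N,D_X Intra-specific competition coefficients
#'   (\code{D_R > 0}).
#' @param c11,d11 Consumption rates (herbivore on plant, carnivore on
#'   herbivore).
#' @return Named numeric vector \code{c(R = , N = , X = )}, a nonnegative
#'   fixed point of the dynamics.
#' @export
toy_model_steady_state <- function(k1, m1, u1, eta_N = 0.9, eta_X = 0.9,
                                   D_R = 1, D_N = 5, D_X = 5,
                                   c11 = 4, d11 = 4) {
  stopifnot(k1 > 0, m1 > 0, u1 > 0, D_R > 0, D_N >= 0, D_X >= 0,
            c11 >= 0, d11 >= 0)
  rates <- function(R, N, X) {
    c(R = k1 - D_R * R - c11 * N,
      N = eta_N * c11 * R - m1 - D_N * N - d11 * X,
      X = eta_X * d11 * N - u1 - D_X * X)
  }
  tol <- 1e-12
  feasible <- function(R, N, X) {
    g <- rates(R, N, X)
    all(c(R, N, X) >= -tol) &&
      all(g[c(R, N, X) <= tol] <= tol)   # excluded species cannot invade
  }
  # interior: all three present
  A <- rbind(c(D_R, c11, 0),
             c(-eta_N * c11, D_N, d11),
             c(0, -eta_X * d11, D_X))
  b <- c(k1, -m1, -u1)
  sol <- tryCatch(solve(A, b), error = function(e) NULL)
  if (!is.null(sol) && all(sol > tol)) {
    return(c(R = sol[1], N = sol[2], X = sol[3]))
  }
  # two-level: plant + herbivore
  A2 <- rbind(c(D_R, c11), c(-eta_N * c11, D_N))
  sol2 <- tryCatch(solve(A2, c(k1, -m1)), error = function(e) NULL)
  if (!is.null(sol2) && all(sol2 > tol) &&
      feasible(sol2[1], sol2[2], 0)) {
    return(c(R = sol2[1], N = sol2[2], X = 0))
  }
  # plant only
  R1 <- k1 / D_R
  if (feasible(R1, 0, 0)) return(c(R = R1, N = 0, X = 0))
  c(R = 0, N = 0, X = 0)
}

#' Cavity solutions over a parameter grid
#'
#' Solves the cavity equations at every row of a parameter grid over any of
#' \code{k}, \code{u}, \code{r1}, \code{r2}, \code{sigma_c},
#' \code{sigma_d}, and returns one row per grid point with the full cavity
#' state, the emergent-competition decomposition of the middle level, and
#' the biomass- and packing-based control order parameters. Each point is
#' warm-started from the previous solved point; failures are recorded in
#' the \code{status} column, not thrown.
#'
#' @inheritParams cavity_solve
#' @param grid Data frame (or named list, expanded via [expand.grid()])
#'   whose columns are a subset of \code{k}, \code{u}, \code{r1},
#'   \code{r2}, \code{sigma_c}, \code{sigma_d}.
#' @param derivative If \code{TRUE}, also compute the derivative-based
#'   order parameter at each point (four extra cavity solves per point).
#' @return Data frame, one row per grid point.
#' @export
phase_scan <- function(params, grid, seed = 1, derivative = FALSE) {
  if (!is.data.frame(grid)) grid <- expand.grid(grid)
  allowed <- c("k", "u", "r1", "r2", "sigma_c", "sigma_d")
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) {
    stop("grid may only vary ", paste(allowed, collapse = ", "),
         "; offending column(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prev <- NULL
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    g <- as.list(grid[i, , drop = FALSE])
    if (!is.null(g$k)) p <- update_params(p, k = g$k)
    if (!is.null(g$u)) p <- update_params(p, u = g$u)
    if (!is.null(g$sigma_c)) p <- update_params(p, sigma_c = g$sigma_c)
    if (!is.null(g$sigma_d)) p <- update_params(p, sigma_d = g$sigma_d)
    p <- set_ratios(p, r1 = g$r1, r2 = g$r2)
    row <- c(g, list(status = "ok"))
    st <- tryCatch({
      init <- if (!is.null(prev)) cavity_moment_vector(prev) else
        "warm_start_simulation"
      s <- cavity_solve(p, init = init, seed = seed + i)
      prev <<- s
      s
    }, error = function(e) e)
    if (inherits(st, "error")) {
      row$status <- conditionMessage(st)
    } else {
      D_top <- -p$eta_X * r1(p) * p$sigma_d^2 * st$chi
      D_bottom <- p$eta_N * p$sigma_c^2 * st$kappa
      row <- c(row, list(
        mean_X = st$mean_X, mean_N = st$mean_N, mean_R = st$mean_R,
        q_X = st$q_X, q_N = st$q_N, q_R = st$q_R,
        chi = st$chi, nu = st$nu, kappa = st$kappa,
        g_eff_X = st$g_eff[["X"]], g_eff_N = st$g_eff[["N"]],
        g_eff_R = st$g_eff[["R"]],
        sigma_g_X = st$sigma_g[["X"]], sigma_g_N = st$sigma_g[["N"]],
        sigma_g_R = st$sigma_g[["R"]],
        D_eff_X = st$D_eff[["X"]], D_eff_N = st$D_eff[["N"]],
        D_eff_R = st$D_eff[["R"]],
        D_N_top = D_top, D_N_bottom = D_bottom,
        phi_X = st$phi[["X"]], phi_N = st$phi[["N"]], phi_R = st$phi[["R"]],
        f = st$f, residual_norm = st$residual_norm,
        packing_op = packing_order_parameter(st),
        biomass_op = biomass_order_parameter(st)))
      if (derivative) {
        dop <- tryCatch(
          derivative_order_parameter(p, seed = seed + i, center = st),
          error = function(e) NA_real_)
        row$bottom_up_fraction <- as.numeric(dop)
      }
    }
    out[[i]] <- row
  }
  cols <- unique(unlist(lapply(out, names)))
  df <- do.call(rbind, lapply(out, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  df
}

#' Finite-size deviation from the mean-field solution
#'
#' For each pool size, simulates an ensemble at fixed level-size ratios and
#' reports the mean (over systems) of the squared deviation of the
#' single-system statistics -- the three level means and three survival
#' fractions -- from the cavity solution. The cavity solution depends only
#' on the ratios, so its columns are constant across sizes.
#'
#' @inheritParams ensemble_statistics
#' @param sizes Vector of top-level pool sizes \code{M_X}; \code{M_N} and
#'   \code{M_R} follow from the ratios in \code{params} (rounded).
#' @return Data frame with one row per size: \code{M_X},
#'   \code{mean_sq_deviation}, \code{n_systems}, and the cavity reference
#'   values.
#' @export
finite_size_deviation <- function(params, sizes, n_systems,
                                  config = integration_config(), seed = 1) {
  cs <- cavity_solve(params, seed = seed)
  ref <- c(cs$mean_X, cs$mean_N, cs$mean_R, cs$phi)
  rows <- lapply(seq_along(sizes), function(si) {
    M_X <- sizes[si]
    p <- update_params(params,
                       M_X = M_X,
                       M_N = round(M_X / r1(params)),
                       M_R = round(M_X / r1(params) / r2(params)))
    es <- ensemble_statistics(p, n_systems, config, seed = seed + si)
    dev <- apply(es$per_system, 1, function(r) {
      mean((c(r[["mean_X"]], r[["mean_N"]], r[["mean_R"]],
              r[["phi_X"]], r[["phi_N"]], r[["phi_R"]]) - ref)^2)
    })
    data.frame(M_X = M_X, mean_sq_deviation = mean(dev),
               n_systems = es$n_converged,
               cavity_mean_X = cs$mean_X, cavity_mean_N = cs$mean_N,
               cavity_mean_R = cs$mean_R,
               cavity_phi_X = cs$phi[["X"]], cavity_phi_N = cs$phi[["N"]],
               cavity_phi_R = cs$phi[["R"]])
  })
  do.call(rbind, rows)
}

#' Latin-hypercube sweep of the three control order parameters
#'
#' Draws a space-filling sample of \code{(k, u, r1, r2)} and computes the
#' packing-based, biomass-based and derivative-based order parameters at
#' each point, for concordance analysis.
#'
#' @inheritParams cavity_solve
#' @param n_points Number of sweep points.
#' @param ranges Named list of \code{c(min, max)} for \code{k}, \code{u},
#'   \code{r1}, \code{r2}.
#' @return Data frame with the sampled parameters, the three order
#'   parameters (\code{packing_op}, \code{biomass_op}, \code{top_down_frac}
#'   = 1 - bottom-up derivative fraction), and a \code{status} column.
#' @export
control_sweep <- function(params, n_points = 100,
                          ranges = list(k = c(1, 5), u = c(1, 5),
                                        r1 = c(0.4, 1.2), r2 = c(0.4, 1.2)),
                          seed = 1) {
  stopifnot(all(c("k", "u", "r1", "r2") %in% names(ranges)))
  lh <- withr::with_seed(seed, lhs::randomLHS(n_points, 4))
  colnames(lh) <- c("k", "u", "r1", "r2")
  for (j in colnames(lh)) {
    lh[, j] <- ranges[[j]][1] + lh[, j] * diff(ranges[[j]])
  }
  rows <- lapply(seq_len(n_points), function(i) {
    p <- set_ratios(update_params(params, k = lh[i, "k"], u = lh[i, "u"]),
                    r1 = lh[i, "r1"], r2 = lh[i, "r2"])
    res <- tryCatch({
      st <- cavity_solve(p, seed = seed + i)
      dop <- derivative_order_parameter(p, seed = seed + i, center = st)
      list(packing_op = packing_order_parameter(st),
           biomass_op = biomass_order_parameter(st),
           top_down_frac = attr(dop, "top_down"), status = "ok")
    }, error = function(e) list(packing_op = NA_real_, biomass_op = NA_real_,
                                top_down_frac = NA_real_,
                                status = conditionMessage(e)))
    data.frame(k = lh[i, "k"], u = lh[i, "u"], r1 = lh[i, "r1"],
               r2 = lh[i, "r2"], packing_op = res$packing_op,
               biomass_op = res$biomass_op,
               top_down_frac = res$top_down_frac, status = res$status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
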