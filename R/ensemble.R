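# Parameter sets for random three-level ecosystems and sampling of
# community instances (consumer preference matrices + rate vectors).

#' Parameters of a random three-trophic-level ecosystem ensemble
#'
#' Defines the statistical ensemble of a three-level consumer resource
#' model: \code{M_R} plants (primary producers) with logistic growth to
#' random carrying capacities, \code{M_N} herbivores consuming plants
#' through a random preference matrix \code{c}, and \code{M_X} carnivores
#' consuming herbivores through a random preference matrix \code{d}.
#'
#' Entries of \code{d} are i.i.d. with mean \code{mu_d / M_N} and standard
#' deviation \code{sigma_d / sqrt(M_N)}; entries of \code{c} are i.i.d. with
#' mean \code{mu_c / M_R} and SD \code{sigma_c / sqrt(M_R)}. This scaling
#' keeps the level-summed interaction strength (e.g. \eqn{\sum_P c_{iP}
#' \approx \mu_c}) fixed as the pool sizes grow, which is the regime the
#' mean-field cavity solution describes. Carrying capacities \code{K} and
#' death rates \code{m}, \code{u} are Gaussian with the stated means/SDs.
#'
#' Defaults are a well-mixed reference condition: pool sizes 50/56/62 with
#' \code{k = 4}, \code{m = 1}, \code{u = 1}, \code{sigma_c = sigma_d = 0.5},
#' \code{mu_c = mu_d = 1}, \code{eta_X = 0.8}, \code{eta_N = 0.6}, and
#' demographic-parameter SDs of 0.1.
#'
#' Level sizes may be fractional: only the ratios \code{r1 = M_X/M_N} and
#' \code{r2 = M_N/M_R} enter the analytic (cavity) layer, and continuous
#' scans over those ratios are common. [sample_community()] requires whole
#' numbers.
#'
#' @param M_X,M_N,M_R Level sizes (carnivores, herbivores, plants), each
#'   \eqn{\ge 1}.
#' @param mu_c,mu_d Dimensionless means of the consumer preferences (before
#'   the 1/M scaling).
#' @param sigma_c,sigma_d Dimensionless SD scales of the consumer
#'   preferences (before the 1/sqrt(M) scaling), \eqn{\ge 0}.
#' @param k,sigma_K Mean and SD of plant carrying capacities.
#' @param m,sigma_m Mean and SD of herbivore death rates.
#' @param u,sigma_u Mean and SD of carnivore death rates.
#' @param eta_N,eta_X Biomass conversion efficiencies in \eqn{[0, 1]}
#'   (herbivore on plant, carnivore on herbivore).
#' @param preference_dialect \code{"gaussian"} (entries may be negative) or
#'   \code{"uniform"} (entries strictly positive, same first two moments).
#' @return An object of class \code{"trophic_params"}; the derived ratios
#'   are available via [r1()] and [r2()].
#' @seealso [sample_community()], [cavity_solve()], [ensemble_statistics()]
#' @export
trophic_params <- function(M_X = 50, M_N = 56, M_R = 62,
                           mu_c = 1, mu_d = 1,
                           sigma_c = 0.5, sigma_d = 0.5,
                           k = 4, sigma_K = 0.1,
                           m = 1, sigma_m = 0.1,
                           u = 1, sigma_u = 0.1,
                           eta_N = 0.6, eta_X = 0.8,
                           preference_dialect = c("gaussian", "uniform")) {
  preference_dialect <- match.arg(preference_dialect)
  p <- list(M_X = M_X, M_N = M_N, M_R = M_R,
            mu_c = mu_c, mu_d = mu_d,
            sigma_c = sigma_c, sigma_d = sigma_d,
            k = k, sigma_K = sigma_K,
            m = m, sigma_m = sigma_m,
            u = u, sigma_u = sigma_u,
            eta_N = eta_N, eta_X = eta_X,
            preference_dialect = preference_dialect)
  p <- lapply(p, unname)   # stray element names would leak into outputs
  validate_trophic_params(p)
  class(p) <- "trophic_params"
  p
}

validate_trophic_params <- function(p) {
  num <- c("M_X", "M_N", "M_R", "mu_c", "mu_d", "sigma_c", "sigma_d",
           "k", "sigma_K", "m", "sigma_m", "u", "sigma_u", "eta_N", "eta_X")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a finite numeric scalar", call. = FALSE)
    }
  }
  if (p$M_X < 1 || p$M_N < 1 || p$M_R < 1) {
    stop("level sizes M_X, M_N, M_R must be >= 1", call. = FALSE)
  }
  for (f in c("sigma_c", "sigma_d", "sigma_K", "sigma_m", "sigma_u")) {
    if (p[[f]] < 0) stop("'", f, "' must be >= 0", call. = FALSE)
  }
  if (p$eta_N < 0 || p$eta_N > 1 || p$eta_X < 0 || p$eta_X > 1) {
    stop("eta_N and eta_X must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @rdname trophic_params
#' @param params A \code{"trophic_params"} object.
#' @export
r1 <- function(params) params$M_X / params$M_N

#' @rdname trophic_params
#' @export
r2 <- function(params) params$M_N / params$M_R

#' @export
print.trophic_params <- function(x, ...) {
  cat("Three-level consumer resource ensemble\n")
  cat(sprintf("  pool sizes   M_X = %g, M_N = %g, M_R = %g  (r1 = %.4g, r2 = %.4g)\n",
              x$M_X, x$M_N, x$M_R, r1(x), r2(x)))
  cat(sprintf("  preferences  mu_c = %g, sigma_c = %g; mu_d = %g, sigma_d = %g [%s]\n",
              x$mu_c, x$sigma_c, x$mu_d, x$sigma_d, x$preference_dialect))
  cat(sprintf("  rates        k = %g (sd %g), m = %g (sd %g), u = %g (sd %g)\n",
              x$k, x$sigma_K, x$m, x$sigma_m, x$u, x$sigma_u))
  cat(sprintf("  efficiencies eta_N = %g, eta_X = %g\n", x$eta_N, x$eta_X))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{params} with the named fields replaced, useful
#' for scans. \code{set_ratios()} rescales \code{M_X} and \code{M_R} at
#' fixed \code{M_N} so that the pool-size ratios take exact values.
#'
#' @param params A \code{"trophic_params"} object.
#' @param ... Named fields of [trophic_params()] to replace.
#' @return A \code{"trophic_params"} object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "trophic_params"))
  repl <- lapply(list(...), unname)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad)) stop("unknown parameter field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_trophic_params(p)
  class(p) <- "trophic_params"
  p
}

#' @rdname update_params
#' @param r1,r2 Target ratios \code{M_X/M_N} and \code{M_N/M_R}.
#' @export
set_ratios <- function(params, r1 = NULL, r2 = NULL) {
  stopifnot(inherits(params, "trophic_params"))
  if (!is.null(r1)) params <- update_params(params, M_X = r1 * params$M_N)
  if (!is.null(r2)) params <- update_params(params, M_R = params$M_N / r2)
  params
}

# Deterministic seed splitting: a master seed spawns independent child
# seeds (one per system) so ensembles are reproducible and order-stable.
split_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Sample one random community instance
#'
#' Draws the consumer preference matrices \code{c} (herbivores on plants,
#' \code{M_N x M_R}) and \code{d} (carnivores on herbivores,
#' \code{M_X x M_N}) plus the carrying-capacity and death-rate vectors for
#' one realization of the ensemble described by \code{params}.
#'
#' Under the \code{"gaussian"} dialect the preference entries are exactly
#' Gaussian (negative entries allowed; truncating would shift the moments
#' the analytic solution assumes). Under the \code{"uniform"} dialect the
#' entries are uniform on \code{[mean - sqrt(3) s, mean + sqrt(3) s]} with
#' \code{mean = mu/M} and \code{s = sigma/sqrt(M)} -- identical first two
#' moments, strictly positive support. If \code{mean - sqrt(3) s < 0} the
#' uniform dialect is infeasible and an error is raised.
#'
#' @param params A [trophic_params()] object with whole-number level sizes.
#' @param seed Integer seed; the draw is fully reproducible given
#'   \code{(params, seed)}.
#' @return An object of class \code{"community_instance"}: list with
#'   elements \code{c}, \code{d}, \code{K}, \code{m_vec}, \code{u_vec},
#'   \code{seed}.
#' @export
sample_community <- function(params, seed) {
  stopifnot(inherits(params, "trophic_params"))
  sizes <- c(params$M_X, params$M_N, params$M_R)
  if (any(sizes != round(sizes))) {
    stop("sample_community requires whole-number level sizes", call. = FALSE)
  }
  M_X <- as.integer(params$M_X); M_N <- as.integer(params$M_N)
  M_R <- as.integer(params$M_R)
  inst <- withr::with_seed(seed, {
    cmat <- draw_preferences(M_N, M_R, params$mu_c, params$sigma_c,
                             params$preference_dialect, "c")
    dmat <- draw_preferences(M_X, M_N, params$mu_d, params$sigma_d,
                             params$preference_dialect, "d")
    list(c = cmat, d = dmat,
         K = stats::rnorm(M_R, params$k, params$sigma_K),
         m_vec = stats::rnorm(M_N, params$m, params$sigma_m),
         u_vec = stats::rnorm(M_X, params$u, params$sigma_u))
  })
  inst$seed <- seed
  class(inst) <- "community_instance"
  inst
}

# nrow consumers, ncol prey; mean mu/ncol, sd sigma/sqrt(ncol).
draw_preferences <- function(nr, nc, mu, sigma, dialect, label) {
  mean_e <- mu / nc
  sd_e <- sigma / sqrt(nc)
  if (dialect == "gaussian") {
    matrix(stats::rnorm(nr * nc, mean_e, sd_e), nr, nc)
  } else {
    h <- sqrt(3) * sd_e
    if (mean_e - h < 0) {
      stop("infeasible uniform dialect for matrix '", label,
           "': mean - sqrt(3)*sd = ", signif(mean_e - h, 4),
           " < 0; reduce sigma or raise mu", call. = FALSE)
    }
    matrix(stats::runif(nr * nc, mean_e - h, mean_e + h), nr, nc)
  }
}

#' @export
print.community_instance <- function(x, ...) {
  cat(sprintf("Community instance (seed %d): d is %d x %d, c is %d x %d\n",
              x$seed, nrow(x$d), ncol(x$d), nrow(x$c), ncol(x$c)))
  invisible(x)
}

#' Sample an ensemble of community instances
#'
#' Draws \code{n_systems} independent instances. Each system uses its own
#' child seed derived deterministically from \code{seed}, so the ensemble
#' is reproducible and individual systems can be regenerated in isolation.
#'
#' @inheritParams sample_community
#' @param n_systems Number of instances, \eqn{\ge 1}.
#' @return List of \code{"community_instance"} objects.
#' @export
generate_ensemble <- function(params, n_systems, seed) {
  stopifnot(n_systems >= 1)
  seeds <- split_seeds(seed, n_systems)
  lapply(seeds, function(s) sample_community(params, s))
}
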