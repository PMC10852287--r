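# Run configuration, serialization and the programmatic entry point the
# command-line wrapper (inst/cli/multitroph.R) is a thin shell around.

.CONFIG_KEYS <- c("command", "params", "nlevel", "integration", "solver",
                  "grid", "sweep", "toy", "finite_size", "n_systems",
                  "master_seed", "output_dir", "schema_version")
.SCHEMA_VERSION <- 1L

#' Read and validate a run configuration
#'
#' Reads a YAML (or JSON; YAML is a superset) configuration describing one
#' job. Top-level keys: \code{command} (one of \code{simulate},
#' \code{cavity}, \code{nlevel}, \code{scan}, \code{toy},
#' \code{finite_size}), \code{params} (fields of [trophic_params()]),
#' \code{nlevel} (fields of [nlevel_params()]), \code{integration} (fields
#' of [integration_config()]), \code{solver} (\code{init},
#' \code{n_starts}, \code{tol}), \code{grid} (named lists of values for
#' [phase_scan()]), \code{sweep} (\code{n_points}, \code{ranges}),
#' \code{toy} (arguments of [toy_model_steady_state()]),
#' \code{finite_size} (\code{sizes}, \code{n_systems}), \code{n_systems},
#' \code{master_seed}, \code{output_dir}. Unknown keys raise a schema
#' error naming the offending key.
#'
#' @param path Path to a YAML/JSON file.
#' @return A validated \code{"run_config"} list with defaults resolved.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param x A named list with the same structure as the file contents.
#' @export
as_run_config <- function(x) {
  stopifnot(is.list(x))
  bad <- setdiff(names(x), .CONFIG_KEYS)
  if (length(bad)) {
    stop("schema error: unknown configuration key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(x$command)) stop("schema error: 'command' is required",
                               call. = FALSE)
  cmds <- c("simulate", "cavity", "nlevel", "scan", "toy", "finite_size")
  if (!x$command %in% cmds) {
    stop("schema error: command must be one of ",
         paste(cmds, collapse = ", "), call. = FALSE)
  }
  check_sub <- function(sub, fn, label) {
    if (is.null(sub)) return(list())
    bad <- setdiff(names(sub), names(formals(fn)))
    if (length(bad)) {
      stop("schema error: unknown key(s) in '", label, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    sub
  }
  x$params <- check_sub(x$params, trophic_params, "params")
  x$integration <- check_sub(x$integration, integration_config, "integration")
  x$toy <- check_sub(x$toy, toy_model_steady_state, "toy")
  if (!is.null(x$nlevel)) {
    x$nlevel <- check_sub(x$nlevel, nlevel_params, "nlevel")
  }
  if (is.null(x$master_seed)) x$master_seed <- 1L
  if (is.null(x$n_systems)) x$n_systems <- 50L
  if (is.null(x$output_dir)) x$output_dir <- "."
  x$schema_version <- .SCHEMA_VERSION
  class(x) <- "run_config"
  x
}

resolved_config <- function(config) {
  out <- unclass(config)
  out$params <- unclass(do.call(trophic_params, config$params))
  out$integration <- unclass(do.call(integration_config, config$integration))
  out
}

# atomic text write: render to a sibling temp file, then rename
write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Execute a configured job
#'
#' Runs the command described by a [read_run_config()] object and writes
#' its artifacts (JSON summaries, CSV tables) plus the fully resolved
#' configuration (defaults expanded, as \code{config.yaml}) to
#' \code{output_dir}. All randomness derives from \code{master_seed}:
#' identical configurations produce byte-identical data payloads.
#'
#' @param config A \code{"run_config"} object (or a path to one).
#' @param output_dir Optional override of the configured output directory.
#' @return Invisibly, a list with the computed result object and the paths
#'   written.
#' @export
run_config_job <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir_out <- output_dir %||% config$output_dir
  if (!dir.exists(dir_out)) dir.create(dir_out, recursive = TRUE)
  params <- do.call(trophic_params, config$params)
  int_cfg <- do.call(integration_config, config$integration)
  seed <- as.integer(config$master_seed)
  solver <- config$solver %||% list()
  paths <- character(0)
  emit_json <- function(obj, name) {
    p <- file.path(dir_out, name)
    write_atomic(function(tmp) {
      jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }, p)
    paths <<- c(paths, p)
  }
  emit_csv <- function(df, name) {
    p <- file.path(dir_out, name)
    write_atomic(function(tmp) {
      utils::write.csv(df, tmp, row.names = FALSE)
    }, p)
    paths <<- c(paths, p)
  }

  result <- switch(config$command,
    simulate = {
      es <- ensemble_statistics(params, config$n_systems, int_cfg, seed)
      emit_csv(es$per_system, "per_system.csv")
      emit_json(list(schema_version = .SCHEMA_VERSION, seed = seed,
                     n_systems = es$n_systems, n_converged = es$n_converged,
                     mean_X = es$mean_X, mean_N = es$mean_N,
                     mean_R = es$mean_R,
                     second_moment_X = es$second_moment_X,
                     second_moment_N = es$second_moment_N,
                     second_moment_R = es$second_moment_R,
                     phi_X = es$phi_X, phi_N = es$phi_N, phi_R = es$phi_R),
                "simulate.json")
      es
    },
    cavity = {
      cs <- do.call(cavity_solve, c(list(params = params, seed = seed),
                                    solver))
      emit_json(cavity_state_as_list(cs), "cavity.json")
      cs
    },
    nlevel = {
      np <- if (length(config$nlevel)) do.call(nlevel_params, config$nlevel)
            else as_nlevel_params(params)
      ns <- nlevel_solve(np, seed = seed)
      emit_json(list(schema_version = .SCHEMA_VERSION, seed = seed,
                     mean_B = ns$mean_B, q = ns$q, chi = ns$chi,
                     g_eff = ns$g_eff, sigma_g = ns$sigma_g,
                     D_eff = ns$D_eff, phi = ns$phi,
                     residual_norm = ns$residual_norm),
                "nlevel.json")
      ns
    },
    scan = {
      if (is.null(config$grid)) {
        stop("schema error: 'scan' requires a 'grid' entry", call. = FALSE)
      }
      df <- phase_scan(params, config$grid, seed = seed)
      emit_csv(df, "scan.csv")
      df
    },
    toy = {
      st <- do.call(toy_model_steady_state, config$toy)
      emit_json(list(schema_version = .SCHEMA_VERSION,
                     R = st[["R"]], N = st[["N"]], X = st[["X"]]),
                "toy.json")
      st
    },
    finite_size = {
      fs <- config$finite_size %||% list()
      sizes <- fs$sizes %||% c(10, 20, 50)
      nsys <- fs$n_systems %||% config$n_systems
      df <- finite_size_deviation(params, sizes, nsys, int_cfg, seed)
      emit_csv(df, "finite_size.csv")
      df
    })

  write_atomic(function(tmp) {
    yaml::write_yaml(resolved_config(config), tmp)
  }, file.path(dir_out, "config.yaml"))
  paths <- c(paths, file.path(dir_out, "config.yaml"))
  invisible(list(result = result, paths = paths))
}

cavity_state_as_list <- function(cs) {
  list(schema_version = .SCHEMA_VERSION,
       mean_X = cs$mean_X, mean_N = cs$mean_N, mean_R = cs$mean_R,
       q_X = cs$q_X, q_N = cs$q_N, q_R = cs$q_R,
       chi = cs$chi, nu = cs$nu, kappa = cs$kappa,
       g_eff = as.list(cs$g_eff), sigma_g = as.list(cs$sigma_g),
       D_eff = as.list(cs$D_eff), delta = as.list(cs$delta),
       phi = as.list(cs$phi), f = cs$f, residual_norm = cs$residual_norm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
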