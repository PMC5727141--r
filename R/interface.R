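#' Read and validate a run configuration
#'
#' Configurations are JSON (or YAML, when the `yaml` package is available)
#' documents with a `task` field (`"reduce"`, `"simulate-rd"`,
#' `"simulate-phase"` or `"analyze"`) plus task-specific blocks:
#' `model` (name + parameter overrides), `tissue` (see [build_tissue()]),
#' `numerics` (`n_theta`, `K`, `dt`, `T`, `sample_dt`), `stochastic`
#' (`seed`, `nu`, `eps_e`, `psi`), `coupling` (`d`, `kind`, or explicit
#' term list), `init` and `output` (file paths).  All angles are radians.
#' Stochastic tasks must carry a seed; a violation names the missing field.
#'
#' @param path path to the configuration file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the 'yaml' package; use JSON")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg configuration list (already parsed).
#' @export
validate_run_config <- function(cfg) {
  if (is.null(cfg$task)) stop("config field missing: task")
  tasks <- c("reduce", "simulate-rd", "simulate-phase", "analyze")
  if (!cfg$task %in% tasks) {
    stop("config field invalid: task must be one of ",
         paste(tasks, collapse = ", "))
  }
  if (cfg$task %in% c("reduce", "simulate-rd") && is.null(cfg$model)) {
    stop("config field missing: model")
  }
  if (cfg$task %in% c("simulate-rd", "simulate-phase") &&
      is.null(cfg$tissue)) {
    stop("config field missing: tissue")
  }
  st <- cfg$stochastic
  noisy <- !is.null(st) && ((!is.null(st$nu) && any(st$nu > 0)) ||
                              (!is.null(st$nu_m) && any(st$nu_m > 0)))
  if (noisy && is.null(st$seed)) {
    stop("config field missing: stochastic$seed (required when nu > 0)")
  }
  cfg
}

.cfg_model <- function(cfg) {
  params <- cfg$model$params
  if (is.null(params)) params <- list()
  make_model(cfg$model$name, params = as.list(params))
}

.cfg_numerics <- function(cfg) {
  nm <- cfg$numerics
  list(n_theta = if (is.null(nm$n_theta)) 256 else nm$n_theta,
       K = if (is.null(nm$K)) 8 else nm$K,
       dt = nm$dt, T_end = nm$T, sample_dt = nm$sample_dt)
}

# Atomic write: serialize to a temp file in the same directory, then rename.
.write_atomic <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

.write_json <- function(x, path) {
  .write_atomic(function(tmp)
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE), path)
}

.write_csv <- function(df, path) {
  .write_atomic(function(tmp)
    utils::write.csv(df, tmp, row.names = FALSE), path)
}

#' Run a configured task
#'
#' Dispatches on `config$task` and writes the declared outputs atomically
#' (CSV for trajectories, JSON for reductions/analyses, plus a JSON run log
#' echoing the config and seed).  Identical config + seed give
#' byte-identical outputs.
#'
#' @param config path to a config file, or a configuration list.
#' @param quiet suppress progress messages on stderr.
#' @return invisibly, a list of written file paths and the in-memory
#'   results.
#' @export
pp_run <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(config)
  say <- function(...) if (!quiet) message("[polarphase] ", ...)
  outdir <- if (!is.null(cfg$output$dir)) cfg$output$dir else "."
  t0 <- Sys.time()
  res <- switch(cfg$task,
    reduce = .task_reduce(cfg, say),
    `simulate-phase` = .task_simulate_phase(cfg, say),
    `simulate-rd` = .task_simulate_rd(cfg, say),
    analyze = .task_analyze(cfg, say))
  files <- res$files
  log <- list(task = cfg$task, config = cfg,
              seed = cfg$stochastic$seed,
              wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")),
              package_version = as.character(
                utils::packageVersion("polarphase")))
  logfile <- file.path(outdir, paste0(cfg$task, "-run.json"))
  log$wall_time_s <- NULL  # keep outputs byte-reproducible
  .write_json(log, logfile)
  say("done: ", paste(basename(c(files, logfile)), collapse = ", "))
  invisible(list(files = c(files, logfile), result = res$result))
}

.task_reduce <- function(cfg, say) {
  model <- .cfg_model(cfg)
  nm <- .cfg_numerics(cfg)
  say("reducing model '", model$name, "' on n_theta = ", nm$n_theta)
  red <- reduce_model(model, n_theta = nm$n_theta, K = nm$K)
  widths <- cfg$coupling$d
  if (is.null(widths)) widths <- pi / 3
  kind <- if (is.null(cfg$coupling$kind)) "difference" else
    cfg$coupling$kind
  pcs <- lapply(widths, function(d) {
    pc <- red$coupling(d, kind = kind)
    list(d = d, kind = kind,
         terms = lapply(seq_len(nrow(pc)), function(t)
           list(amp = pc$amp[t], p = pc$p[t], q = pc$q[t], r = pc$r[t])))
  })
  doc <- list(model = list(name = model$name, params = model$params),
              n_theta = red$cell$n_theta, K = red$fourier$K,
              residual = red$cell$residual,
              u = red$fourier$u, z = red$fourier$z,
              couplings = pcs)
  outdir <- if (!is.null(cfg$output$dir)) cfg$output$dir else "."
  f <- .write_json(doc, file.path(outdir, "reduction.json"))
  list(files = f, result = red)
}

# Rebuild a phase_coupling from the serialized term list.
.coupling_from_doc <- function(doc_terms) {
  amp <- vapply(doc_terms, function(t) t$amp, numeric(1))
  p <- vapply(doc_terms, function(t) t$p, numeric(1))
  q <- vapply(doc_terms, function(t) t$q, numeric(1))
  r <- vapply(doc_terms, function(t) t$r, numeric(1))
  phase_coupling(amp, p, q, r)
}

.cfg_coupling <- function(cfg) {
  cp <- cfg$coupling
  if (!is.null(cp$reduction_file)) {
    doc <- jsonlite::fromJSON(cp$reduction_file, simplifyVector = FALSE)
    tabs <- lapply(doc$couplings, function(co)
      list(d = co$d, pc = .coupling_from_doc(co$terms)))
    return(function(d) {
      for (t in tabs) if (abs(t$d - d) < 1e-9) return(t$pc)
      stop("reduction file has no coupling for width d = ", d)
    })
  }
  if (identical(cp$name, "gle_closed_form")) {
    return(function(d) phase_coupling(
      amp = c(sin(d) / (4 * pi), sin(d) / (4 * pi), d / (4 * pi)),
      p = c(0, 2, 2), q = c(1, 2, 1), r = c(-1, 0, 1)))
  }
  if (!is.null(cp$terms)) {
    pc <- .coupling_from_doc(cp$terms)
    return(function(d) pc)
  }
  stop("config field missing: coupling (reduction_file, name or terms)")
}

.task_simulate_phase <- function(cfg, say) {
  tissue <- build_tissue(cfg$tissue)
  cfun <- .cfg_coupling(cfg)
  st <- cfg$stochastic
  signal <- NULL
  if (!is.null(st$eps_e) && st$eps_e != 0) {
    signal <- list(eps_e = st$eps_e, psi = st$psi,
                   amplitude = st$signal_amplitude)
    if (is.null(signal$amplitude)) {
      stop("config field missing: stochastic$signal_amplitude")
    }
  }
  noise <- if (!is.null(st$nu) && st$nu > 0) list(nu = st$nu) else NULL
  eps <- if (is.null(cfg$epsilon)) 1 else cfg$epsilon
  spec <- phase_model(tissue, cfun, epsilon = eps, signal = signal,
                      noise = noise)
  nm <- .cfg_numerics(cfg)
  N <- nrow(tissue$cells)
  ic <- cfg$init
  init <- if (is.null(ic) || identical(ic$kind, "uniform")) {
    initial_phases("uniform", N, seed = st$seed,
                   lo = if (is.null(ic$lo)) -0.5 else ic$lo,
                   hi = if (is.null(ic$hi)) 0.5 else ic$hi)
  } else {
    initial_phases("constant", N, phi0 = ic$phi0)
  }
  say("integrating phase model: ", N, " cells to T = ", nm$T_end)
  traj <- integrate_phase(spec, init, T_end = nm$T_end,
                          dt = if (is.null(nm$dt)) 0.01 else nm$dt,
                          sample_dt = nm$sample_dt, seed = st$seed)
  outdir <- if (!is.null(cfg$output$dir)) cfg$output$dir else "."
  long <- data.frame(time = rep(traj$time, each = N),
                     cell_id = rep(seq_len(N), length(traj$time)),
                     phase = as.vector(t(traj$phi)))
  f1 <- .write_csv(long, file.path(outdir, "phases.csv"))
  op <- t(apply(traj$phi, 1, order_parameter))
  f2 <- .write_csv(data.frame(time = traj$time, Q = op[, 1],
                              Phi = op[, 2]),
                   file.path(outdir, "order_parameter.csv"))
  list(files = c(f1, f2), result = traj)
}

.task_simulate_rd <- function(cfg, say) {
  model <- .cfg_model(cfg)
  tissue <- build_tissue(cfg$tissue)
  nm <- .cfg_numerics(cfg)
  st <- cfg$stochastic
  N <- nrow(tissue$cells)
  n_theta <- nm$n_theta
  ic <- cfg$init
  init <- if (!is.null(ic) && identical(ic$kind, "steady")) {
    cell <- find_steady_state(model, n_theta = n_theta)
    tissue_init_steady(cell, rep_len(unlist(ic$phases), N))
  } else {
    tissue_init_pattern(model, n_theta, N,
                        phi0 = if (is.null(ic$phi0)) 0 else ic$phi0)
  }
  noise <- NULL
  if (!is.null(st$nu_m) && any(st$nu_m > 0)) {
    noise <- list(nu = st$nu_m, seed = st$seed)
  }
  signal <- NULL
  if (!is.null(st$eps_e) && st$eps_e != 0) {
    signal <- list(eps_e = st$eps_e, psi = st$psi)
  }
  eps <- if (is.null(cfg$epsilon)) 0 else cfg$epsilon
  say("integrating RD tissue: ", N, " cells to T = ", nm$T_end)
  traj <- integrate_tissue_rd(tissue, model, epsilon = eps, init = init,
                              T_end = nm$T_end, dt = nm$dt,
                              kind = if (is.null(cfg$coupling$kind))
                                "difference" else cfg$coupling$kind,
                              noise = noise, signal = signal,
                              sample_dt = nm$sample_dt)
  outdir <- if (!is.null(cfg$output$dir)) cfg$output$dir else "."
  long <- data.frame(time = rep(traj$time, each = N),
                     cell_id = rep(seq_len(N), length(traj$time)),
                     phase = as.vector(t(traj$phase)),
                     C = as.vector(t(traj$C)))
  f1 <- .write_csv(long, file.path(outdir, "rd_phases.csv"))
  list(files = f1, result = traj)
}

.task_analyze <- function(cfg, say) {
  out <- list()
  an <- cfg$analyze
  if (!is.null(an$delta)) {
    out$lambda <- lapply(an$delta, function(d)
      list(delta = d, lambda = elongation_lambda(d)))
  }
  if (!is.null(an$two_cell)) {
    tc <- an$two_cell
    df <- two_cell_analysis(tc$a, tc$b, tc$c,
                            epsilon = if (is.null(tc$epsilon)) 1 else
                              tc$epsilon)
    out$two_cell <- df
  }
  if (!is.null(an$heterogeneity)) {
    h <- an$heterogeneity
    out$heterogeneity_rate <- heterogeneity_rate(h$alpha, h$b, h$c)
  }
  if (!is.null(cfg$tissue) && !is.null(cfg$coupling)) {
    tissue <- build_tissue(cfg$tissue)
    cfun <- .cfg_coupling(cfg)
    out$effective_field <- in_phase_effective_field(tissue, cfun)
  }
  outdir <- if (!is.null(cfg$output$dir)) cfg$output$dir else "."
  f <- .write_json(out, file.path(outdir, "analysis.json"))
  list(files = f, result = out)
}
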