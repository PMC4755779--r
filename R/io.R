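#' Load and validate a run configuration
#'
#' Configurations are YAML (or JSON) files with a `model` block (`n`,
#' `dominance`, `p` and `r` tables keyed by fraction strings such as
#' `"1/4"`), a `task` (one of `classify`, `threshold`, `simulate`, `phase`,
#' `mc-experiment`, `validate`) and a task-specific options block. Unknown
#' keys are rejected; defaults `r["0"] = 1` and `p["1"] = 1` are injected
#' (and logged) when absent, and contradicting them explicitly is an
#' error. Every z key must parse as an exact fraction in `[0, 1]`, and for
#' tasks that build the full model every grid point required by
#' [required_z_grid()] must be present.
#'
#' @param path file path of the configuration.
#' @return object of class `run_config`: the validated configuration list,
#'   with `$model` replaced by a built [model_params()] object where the
#'   task requires one (all tasks except `threshold` and `mc-experiment`,
#'   which need only parts of the grid).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = FALSE)
    else yaml::read_yaml(path)
  validate_config(cfg, source = path)
}

config_tasks <- c("classify", "threshold", "simulate", "phase",
                  "mc-experiment", "validate")

validate_config <- function(cfg, source = "<config>") {
  allowed_top <- c("model", "task", "options", "seed", "output")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown) > 0) {
    abort(sprintf("unknown top-level config key(s): %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$task) || !cfg$task %in% config_tasks) {
    abort(sprintf("task must be one of: %s", paste(config_tasks, collapse = ", ")))
  }
  if (is.null(cfg$model)) abort("config needs a 'model' block")
  unknown <- setdiff(names(cfg$model), c("n", "dominance", "p", "r"))
  if (length(unknown) > 0) {
    abort(sprintf("unknown model key(s): %s", paste(unknown, collapse = ", ")))
  }
  n <- check_n(cfg$model$n %||% abort("model$n is required"))
  dominance <- cfg$model$dominance %||% "recessive"
  if (!dominance %in% c("recessive", "dominant")) {
    abort("model$dominance must be 'recessive' or 'dominant'")
  }
  p <- unlist(cfg$model$p) %||% setNames(numeric(0), character(0))
  r <- unlist(cfg$model$r) %||% setNames(numeric(0), character(0))
  if (length(p) > 0 && !("1" %in% parse_z(names(p)))) {
    inform("config: injecting default p[1] = 1 (all males queen-laid when all workers are sterile)")
  }
  if (length(r) > 0 && !("0" %in% parse_z(names(r)))) {
    inform("config: injecting default baseline r[0] = 1")
  }
  phen <- phenotype_functions(p = p, r = r)
  # classify/simulate/validate need the full z grid; threshold, phase and
  # mc-experiment validate just the values they use (phase varies r over axes)
  model <- if (cfg$task %in% c("threshold", "phase", "mc-experiment")) {
    list(n = n, dominance = dominance, phenotypes = phen)
  } else {
    grid <- required_z_grid(n, dominance)
    extra <- setdiff(union(names(phen$p), names(phen$r)), grid)
    if (length(extra) > 0) {
      abort(sprintf("z key(s) not on the required grid for n = %d (%s): %s",
                    n, dominance, paste(extra, collapse = ", ")))
    }
    model_params(n, dominance, phen)
  }
  opts <- validate_options(cfg$task, cfg$options %||% list(), n)
  structure(list(task = cfg$task, model = model, options = opts,
                 seed = cfg$seed, output = cfg$output, source = source),
            class = "run_config")
}

validate_options <- function(task, opts, n) {
  allowed <- switch(task,
    classify = character(0),
    threshold = c("n_values"),
    simulate = c("initial", "epsilon", "horizon", "rtol", "atol", "n_out"),
    phase = c("axes", "r_z1", "r_z2", "n_values", "what", "r_fixed"),
    `mc-experiment` = c("scenario", "mu", "sigma", "rho", "n_samples",
                        "seed", "method"),
    validate = c("n_points", "seed", "horizon")
  )
  unknown <- setdiff(names(opts), allowed)
  if (length(unknown) > 0) {
    abort(sprintf("unknown option(s) for task '%s': %s", task,
                  paste(unknown, collapse = ", ")))
  }
  if (task == "simulate") {
    if (is.null(opts$initial)) abort("simulate task needs options$initial")
    if (is.character(opts$initial) && length(opts$initial) == 1L) {
      if (!opts$initial %in% c("invasion", "stability")) {
        abort("options$initial must be 'invasion', 'stability' or a named frequency map")
      }
    }
  }
  if (task == "phase" && is.null(opts$axes)) abort("phase task needs options$axes")
  if (task == "mc-experiment") {
    if (is.null(opts$scenario) || !opts$scenario %in% c("invasion", "regime")) {
      abort("mc-experiment task needs options$scenario: 'invasion' or 'regime'")
    }
    if (is.null(opts$sigma)) abort("mc-experiment task needs options$sigma")
  }
  opts
}

#' Execute a validated configuration
#'
#' Dispatches a [load_config()] result to the corresponding package
#' function and wraps the result in a serialisable envelope. The
#' `validate` task runs an oracle-versus-analytic concordance sweep:
#' random phenotype configurations around the model's, compared between
#' [classify_regime()] and the ODE oracles, reporting any disagreement
#' with the full parameter set.
#'
#' @param config a `run_config`.
#' @param seed optional integer overriding the config's seed.
#' @return object of class `result_envelope`: list with `task`, `results`
#'   (a tibble or list of tibbles), `version`, `timestamp`, `config`.
#' @export
run_config <- function(config, seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- seed %||% config$seed
  model <- config$model
  opts <- config$options
  results <- switch(config$task,
    classify = {
      cls <- classify_regime(model)
      list(regime = cls$regime,
           invasion = tidy(cls$invasion), stability = tidy(cls$stability))
    },
    threshold = run_threshold_task(model, opts),
    simulate = run_simulate_task(model, opts),
    phase = {
      pd <- phase_diagram(
        p = model$phenotypes, axes = unlist(opts$axes),
        r_z1 = seq_spec(opts$r_z1), r_z2 = seq_spec(opts$r_z2),
        n_values = unlist(opts$n_values) %||% model$n,
        dominance = model$dominance,
        r_fixed = unlist(opts$r_fixed) %||% c("0" = 1),
        what = opts$what %||% "regime")
      list(grid = as_tibble(pd))
    },
    `mc-experiment` = {
      proc <- sampling_procedure(
        sigma = opts$sigma, mu = opts$mu %||% 1, rho = opts$rho %||% 0,
        n_samples = opts$n_samples %||% 1e6,
        seed = opts$seed %||% seed)
      out <- if (opts$scenario == "invasion") {
        invasion_outcome_probabilities(model$dominance, model$phenotypes,
                                       proc, opts$method %||% "monte_carlo")
      } else {
        regime_outcome_probabilities(model$phenotypes, proc, n = model$n,
                                     dominance = model$dominance)
      }
      list(probabilities = as_tibble(out),
           method = attr(out, "method"), scenario = attr(out, "scenario"))
    },
    validate = run_validate_task(model, opts, seed)
  )
  structure(list(task = config$task, results = results,
                 version = as.character(utils::packageVersion("haplosterile")),
                 timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
                 config = config[c("task", "options", "seed", "source")]),
            class = "result_envelope")
}

seq_spec <- function(x) {
  if (is.null(x)) abort("phase task needs r_z1 and r_z2 ranges")
  if (!is.null(names(x)) && all(c("from", "to") %in% names(x))) {
    return(seq(x$from, x$to, by = x$by %||% ((x$to - x$from) / 50)))
  }
  unlist(x)
}

run_threshold_task <- function(model, opts) {
  n_values <- unlist(opts$n_values) %||% model$n
  ph <- model$phenotypes
  rows <- purrr::map(n_values, function(n) {
    if (model$dominance == "recessive") {
      z_inv <- z_key(1L, 2L * check_n(n))
      p_inv <- if (z_inv %in% names(ph$p)) p_at(ph, z_inv) else NULL
      thr <- recessive_invasion_threshold(n, p_at(ph, "0"), p_inv)
      r_have <- z_inv %in% names(ph$r)
      tibble(n = n, dominance = model$dominance, decisive_z = z_inv,
             threshold = thr,
             r_value = if (r_have) r_at(ph, z_inv) else NA_real_,
             invades = if (r_have) r_at(ph, z_inv) / r_at(ph, "0") > thr else NA)
    } else {
      p_half <- p_at(ph, "1/2")
      r0 <- r_at(ph, "0")
      lhs <- (r_at(ph, "1/2") / r0) *
        (1 + p_half * r_at(ph, z_key(1L, check_n(n))) / r0)
      tibble(n = n, dominance = model$dominance, decisive_z = "1/2",
             threshold = 2, r_value = lhs, invades = lhs > 2)
    }
  })
  list(thresholds = dplyr::bind_rows(rows))
}

run_simulate_task <- function(model, opts) {
  initial <- if (is.character(opts$initial) && length(opts$initial) == 1L) {
    eps <- opts$epsilon %||% 1e-3
    if (opts$initial == "invasion") invasion_state(model$n, eps)
    else stability_state(model$n, eps)
  } else {
    x <- pure_state(model$n, "A") * 0
    init <- unlist(opts$initial)
    bad <- setdiff(names(init), names(x))
    if (length(bad) > 0) {
      abort(sprintf("unknown colony label(s) in initial state: %s",
                    paste(bad, collapse = ", ")))
    }
    x[names(init)] <- init
    x
  }
  tr <- simulate_dynamics(model, initial,
                          horizon = opts$horizon %||% 1e4,
                          rtol = opts$rtol %||% 1e-10,
                          atol = opts$atol %||% 1e-12,
                          n_out = opts$n_out %||% 201L)
  list(trajectory = tidy(tr), summary = glance(tr))
}

run_validate_task <- function(model, opts, seed) {
  sweep <- concordance_sweep(
    n_values = model$n, dominance = model$dominance,
    n_points = opts$n_points %||% 50L,
    seed = opts$seed %||% seed %||% 1L)
  list(sweep = sweep,
       disagreements = dplyr::filter(
         sweep, .data$oracle_outcome != "inconclusive" & !.data$agrees))
}

#' Oracle-versus-analytic concordance sweep
#'
#' Draws random phenotype configurations (p values uniform in \[0, 1\], r
#' values uniform in \[0.8, 1.4\]), discards those closer than `exclusion`
#' to an invasion or stability boundary in any r coordinate, and compares
#' the analytic invasion and stability conditions against the ODE oracles.
#' Conclusive oracle verdicts must agree with the analytic reports; the
#' second-order cases (recessive invasion declines, dominant stability
#' declines) are often inconclusive at finite horizon, which the sweep
#' reports but does not count as disagreement.
#'
#' @param n_values mate numbers to stratify over.
#' @param dominance dominance mode(s).
#' @param n_points number of retained parameter sets per (n, dominance)
#'   stratum.
#' @param exclusion minimum |margin| (in the decisive r coordinate) from
#'   each boundary.
#' @param seed integer seed for the parameter draws.
#' @return tibble with one row per parameter set and check
#'   (invasion/stability): the drawn phenotypes, analytic verdict, oracle
#'   verdict and agreement flag.
#' @export
concordance_sweep <- function(n_values = c(1L, 2L),
                              dominance = c("recessive", "dominant"),
                              n_points = 25L, exclusion = 0.01, seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (n in n_values) for (dom in dominance) {
    kept <- 0L
    while (kept < n_points) {
      ph <- random_phenotypes(n, dom)
      model <- model_params(n, dom, ph)
      inv <- invasion_condition(model)
      st <- stability_condition(model)
      if (min(abs(inv$margin), abs(st$margin)) <= exclusion) next
      kept <- kept + 1L
      o_inv <- oracle_invasion(model)
      o_st <- oracle_stability(model)
      rows[[length(rows) + 1L]] <- tibble(
        n = n, dominance = dom, draw = kept,
        check = c("invasion", "stability"),
        analytic_holds = c(inv$holds, st$holds),
        analytic_margin = c(inv$margin, st$margin),
        oracle_outcome = c(o_inv$outcome, o_st$outcome),
        # oracle "grows" means: invasion holds / stability fails
        agrees = c(
          o_inv$outcome == "inconclusive" ||
            (o_inv$outcome == "grows") == inv$holds,
          o_st$outcome == "inconclusive" ||
            (o_st$outcome == "declines") == st$holds
        )
      )
    }
  }
  dplyr::bind_rows(rows)
}

random_phenotypes <- function(n, dominance) {
  grid <- required_z_grid(n, dominance)
  p <- stats::runif(length(grid))
  r <- stats::runif(length(grid), 0.8, 1.4)
  names(p) <- names(r) <- grid
  p["1"] <- 1
  r["0"] <- 1
  phenotype_functions(p = p, r = r)
}

#' Write a result envelope to disk
#'
#' JSON output is canonical (recursively sorted keys, 17 significant
#' digits) so that writing the same envelope twice gives byte-identical
#' files; CSV output writes one RFC-4180 file per tabular component of the
#' results, with deterministic column order.
#'
#' @param env a [run_config()] result envelope.
#' @param dir output directory (created if needed).
#' @param format `"json"`, `"csv"` or both.
#' @param stem file-name stem (default the task name).
#' @return invisibly, the paths written.
#' @export
write_results <- function(env, dir, format = c("json", "csv"), stem = NULL) {
  stopifnot(inherits(env, "result_envelope"))
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- stem %||% env$task
  paths <- character(0)
  if ("json" %in% format) {
    path <- file.path(dir, paste0(stem, ".json"))
    writeLines(jsonlite::toJSON(sort_keys(unclass(env)), digits = NA,
                                auto_unbox = TRUE, dataframe = "rows",
                                null = "null", na = "null", pretty = TRUE),
               path)
    paths <- c(paths, path)
  }
  if ("csv" %in% format) {
    tabs <- Filter(is.data.frame, env$results)
    for (nm in names(tabs)) {
      path <- file.path(dir, paste0(stem, "_", nm, ".csv"))
      write.csv(tabs[[nm]], path, row.names = FALSE)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

sort_keys <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    return(lapply(x, sort_keys))
  }
  x
}

#' @export
print.result_envelope <- function(x, ...) {
  cat(sprintf("<result_envelope> task '%s' (haplosterile %s, %s)\n",
              x$task, x$version, x$timestamp))
  utils::str(x$results, max.level = 1, give.attr = FALSE)
  invisible(x)
}
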