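#' Run a configured experiment
#'
#' Single entry point over the whole pipeline, driven by a serializable run
#' configuration (an R list or a JSON file). A run writes its result tables
#' (tab-separated, 17-significant-digit formatting so repeated runs are
#' byte-identical), a config echo (`config_echo.json`) sufficient to
#' reproduce it, and a plain-text log, all inside the declared output
#' directory.
#'
#' Config fields: `experiment` (one of `simulate`, `stimulus`, `scan1d`,
#' `scan2d`, `local`, `sobol`, `full_study`), `stimulus` (paradigm name plus
#' generator arguments), `params` (named theta overrides of the packaged
#' nominal fixture), `options` (experiment-specific: `parameter`, `pair`,
#' `multipliers`, `deltas`, `n_base`, `priors_width`, `mode`, `grid_2d`),
#' `seed`, `out`.
#'
#' @param config a list or path to a JSON config file.
#' @param out output directory; overrides `config$out`.
#' @return Invisibly, a list with the computed result objects and the paths
#'   written.
#' @export
bm_run <- function(config, out = NULL) {
  cfg <- bm_load_config(config)
  if (!is.null(out)) cfg$out <- out
  if (is.null(cfg$out)) abort("config field 'out' (output directory) is required")
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                                append = TRUE)
  cat("", file = logf) # truncate
  log_line("experiment=%s seed=%d", cfg$experiment, cfg$seed)

  stim <- do.call(cfg$stimulus$paradigm_fn, cfg$stimulus$args)
  params <- cfg$params_obj
  opts <- cfg$options
  paths <- character()
  results <- list()

  write_table <- function(df, name) {
    p <- file.path(cfg$out, name)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], fmt17)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
    p
  }
  write_json <- function(x, name) {
    p <- file.path(cfg$out, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    paths <<- c(paths, p)
    p
  }

  run_simulate <- function() {
    sim <- simulate_bold(stim, params)
    write_table(setNames(tibble::as_tibble(sim),
                         c("time_s", "f", "s", "v", "q", "y")),
                "trajectory.tsv")
    log_line("simulate: %d samples", nrow(sim))
    list(sim = sim)
  }
  run_stimulus <- function() {
    bm_write_stimulus(stim, file.path(cfg$out, "stimulus.tsv"))
    paths <<- c(paths, file.path(cfg$out, "stimulus.tsv"))
    list(stimulus = stim)
  }
  run_scan1d <- function(y_nom = NULL) {
    parameter <- opts$parameter %||% "kappa_s"
    sc <- scan_1d(stim, params, parameter, multipliers = opts$multipliers,
                  y_nom = y_nom)
    write_table(tidy(sc), sprintf("scan1d_%s.tsv", parameter))
    deltas <- opts$deltas %||% c(0.1, 0.2, 0.3)
    asym <- vapply(deltas, function(d) {
      tryCatch(scan_asymmetry(sc, d), error = function(e) NA_real_)
    }, numeric(1))
    write_json(list(parameter = parameter,
                    minimum_multiplier = attr(sc, "minimum_multiplier"),
                    asymmetry = setNames(as.list(asym),
                                         paste0("delta_", deltas))),
               sprintf("scan1d_%s_summary.json", parameter))
    log_line("scan1d %s: argmin %g", parameter, attr(sc, "minimum_multiplier"))
    list(scan = sc)
  }
  run_scan2d <- function(y_nom = NULL) {
    pair <- opts$pair %||% c("epsilon", "tau_inv")
    sc <- scan_2d(stim, params, pair, error_ceiling = opts$error_ceiling %||% 30,
                  y_nom = y_nom)
    write_table(tidy(sc), sprintf("scan2d_%s_%s.tsv", pair[1], pair[2]))
    write_json(list(pair = pair,
                    compensation_index = attr(sc, "compensation_index")),
               sprintf("scan2d_%s_%s_summary.json", pair[1], pair[2]))
    list(scan = sc)
  }
  run_local <- function() {
    ls <- local_sensitivity(stim, params)
    write_table(tidy(ls), "local_sensitivity.tsv")
    write_json(list(jacobian_rank = attr(ls, "jacobian_rank"),
                    rel_step = attr(ls, "rel_step")),
               "local_sensitivity_meta.json")
    list(local = ls)
  }
  run_sobol <- function() {
    sob <- balloon_sobol(stim, n_base = opts$n_base %||% 256, seed = cfg$seed,
                         nominal = params, mode = opts$mode %||% "l2_norm",
                         n_boot = opts$n_boot %||% 200)
    write_table(sob$first_order, "sobol_first_order.tsv")
    if (!is.null(sob$second_order)) {
      write_table(sob$second_order, "sobol_second_order.tsv")
    }
    write_json(list(n_base = sob$n_base, seed = sob$seed,
                    scalarizer = sob$scalarizer, rejections = sob$rejections,
                    total_variance = sob$total_variance),
               "sobol_meta.json")
    log_line("sobol: %d rejections", sob$rejections)
    list(sobol = sob)
  }

  results <- switch(cfg$experiment,
    simulate = run_simulate(),
    stimulus = run_stimulus(),
    scan1d = run_scan1d(),
    scan2d = run_scan2d(),
    local = run_local(),
    sobol = run_sobol(),
    full_study = {
      st <- bm_full_study(stim, params, seed = cfg$seed,
                          grid_2d = opts$grid_2d %||% "full",
                          n_base = opts$n_base %||% 256,
                          n_boot = opts$n_boot %||% 200)
      write_table(dplyr::select(st$scan1d_summary,
                                -dplyr::any_of("asymmetry_delta")),
                  "study_scan1d_summary.tsv")
      write_table(st$compensation, "study_compensation.tsv")
      write_table(tidy(st$local), "study_local.tsv")
      write_table(st$sobol$first_order, "study_sobol_first.tsv")
      write_json(st$summary, "study_summary.json")
      st
    },
    abort(sprintf("unknown experiment '%s' (config field 'experiment')",
                  cfg$experiment)))

  write_json(cfg$echo, "config_echo.json")
  log_line("done: %d files", length(paths))
  invisible(list(results = results, paths = paths, config = cfg$echo))
}

bm_load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) abort("config must be a list or a JSON file path")
  experiment <- config$experiment %||% "simulate"
  valid <- c("simulate", "stimulus", "scan1d", "scan2d", "local", "sobol",
             "full_study")
  if (!experiment %in% valid) {
    abort(sprintf("config field 'experiment' must be one of: %s",
                  paste(valid, collapse = ", ")))
  }
  seed <- as.integer(config$seed %||% 1L)
  stim_cfg <- config$stimulus %||% list(paradigm = "block")
  paradigm <- stim_cfg$paradigm %||% "block"
  gen <- switch(paradigm,
    block = stim_block, event_related = stim_event, mixed = stim_mixed,
    abort("config field 'stimulus.paradigm' must be block, event_related or mixed"))
  args <- stim_cfg[setdiff(names(stim_cfg), "paradigm")]
  bad <- setdiff(names(args), names(formals(gen)))
  if (length(bad)) {
    abort(sprintf("unknown stimulus arguments: %s",
                  paste0("stimulus.", bad, collapse = ", ")))
  }
  params <- bm_nominal_params()
  if (!is.null(config$params)) {
    theta <- bm_theta(params)
    ov <- unlist(config$params)
    bad <- setdiff(names(ov), names(theta))
    if (length(bad)) {
      abort(sprintf("unknown parameter overrides: %s",
                    paste0("params.", bad, collapse = ", ")))
    }
    theta[names(ov)] <- ov
    params <- bm_from_theta(theta)
  }
  list(experiment = experiment, seed = seed,
       stimulus = list(paradigm_fn = gen, args = args),
       params_obj = params,
       options = config$options %||% list(),
       out = config$out,
       echo = list(experiment = experiment, seed = seed,
                   stimulus = c(list(paradigm = paradigm), args),
                   params = as.list(bm_theta(params)),
                   options = config$options %||% list(),
                   out = config$out))
}

#' Run the complete identifiability study
#'
#' All seven one-parameter scans, all 21 two-parameter scans, the local
#' Jacobian-projection analysis and the Sobol run, on one stimulus, sharing
#' a single cached nominal simulation. Stage failures are isolated: a
#' failing stage is recorded in the summary and the remaining stages still
#' run.
#'
#' @param stimulus a `bm_stimulus`; default the reference 5-cycle block
#'   design.
#' @param nominal nominal [balloon_params()].
#' @param seed integer seed (Sobol stage).
#' @param grid_2d `"full"` (21 x 21 per pair) or `"reduced"` (11 x 11, for
#'   quick runs).
#' @param n_base,n_boot Sobol sample sizes.
#' @param deltas asymmetry offsets evaluated per 1D scan.
#' @param radius compensation-index ring radius.
#' @return A `bm_study` list: per-stage results plus a `summary` list with
#'   the per-parameter minimum/asymmetry table, the pairwise compensation
#'   matrix, the projection ranking and the Sobol ranking.
#' @export
bm_full_study <- function(stimulus = stim_block(),
                          nominal = bm_nominal_params(), seed = 1,
                          grid_2d = c("full", "reduced"), n_base = 256,
                          n_boot = 200, deltas = c(0.1, 0.2, 0.3),
                          radius = 0.3) {
  grid_2d <- match.arg(grid_2d)
  labs <- bm_theta_labels()
  y_nom <- simulate_bold(stimulus, nominal)$y
  failures <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      failures[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  scans1d <- lapply(setNames(labs, labs), function(p) {
    stage(paste0("scan1d_", p), scan_1d(stimulus, nominal, p, y_nom = y_nom))
  })
  scan1d_summary <- dplyr::bind_rows(lapply(labs, function(p) {
    sc <- scans1d[[p]]
    if (is.null(sc)) return(tibble::tibble(parameter = p))
    asym <- vapply(deltas, function(d) {
      tryCatch(scan_asymmetry(sc, d), error = function(e) NA_real_)
    }, numeric(1))
    tibble::tibble(parameter = p,
                   minimum_multiplier = attr(sc, "minimum_multiplier"),
                   max_error = max(sc$error, na.rm = TRUE),
                   asymmetry_delta = list(setNames(asym, deltas)))
  }))

  grid_fn <- function(p) {
    g <- bm_default_multipliers(p, nominal, "2d")
    if (grid_2d == "reduced") g[seq(1, length(g), by = 2)] else g
  }
  pair_idx <- combn(7, 2)
  scans2d <- lapply(seq_len(ncol(pair_idx)), function(c2) {
    pr <- labs[pair_idx[, c2]]
    stage(paste(c("scan2d", pr), collapse = "_"),
          scan_2d(stimulus, nominal, pr, multipliers1 = grid_fn(pr[1]),
                  multipliers2 = grid_fn(pr[2]), radius = radius,
                  y_nom = y_nom))
  })
  compensation <- dplyr::bind_rows(lapply(seq_along(scans2d), function(i) {
    pr <- labs[pair_idx[, i]]
    ci <- if (is.null(scans2d[[i]])) NA_real_
          else attr(scans2d[[i]], "compensation_index")
    tibble::tibble(parameter1 = pr[1], parameter2 = pr[2],
                   compensation_index = ci)
  }))

  local <- stage("local", local_sensitivity(stimulus, nominal))
  sobol <- stage("sobol", balloon_sobol(stimulus, nominal = nominal,
                                        n_base = n_base, seed = seed,
                                        n_boot = n_boot))

  min_comp <- compensation[which.min(compensation$compensation_index), ]
  summary <- list(
    scan1d = lapply(seq_len(nrow(scan1d_summary)), function(i) {
      r <- scan1d_summary[i, ]
      list(parameter = r$parameter,
           minimum_multiplier = r$minimum_multiplier,
           max_error = r$max_error,
           asymmetry = as.list(r$asymmetry_delta[[1]]))
    }),
    compensation_minimum = list(pair = c(min_comp$parameter1,
                                         min_comp$parameter2),
                                index = min_comp$compensation_index),
    pi_ranking = if (!is.null(local)) {
      local$parameter[order(-local$pi_normalized)]
    },
    sobol_ranking = if (!is.null(sobol)) {
      sobol$first_order$parameter[order(-sobol$first_order$index)]
    },
    failures = failures
  )
  structure(list(scans1d = scans1d, scan1d_summary = scan1d_summary,
                 scans2d = scans2d, compensation = compensation,
                 local = local, sobol = sobol, summary = summary,
                 failures = failures),
            class = "bm_study")
}

#' @export
print.bm_study <- function(x, ...) {
  cat("<bm_study>\n")
  cat("1D minima:\n")
  print(dplyr::select(x$scan1d_summary, -dplyr::any_of("asymmetry_delta")))
  cat("lowest compensation pair:",
      paste(x$summary$compensation_minimum$pair, collapse = " / "), "\n")
  if (!is.null(x$summary$sobol_ranking)) {
    cat("Sobol ranking:", paste(x$summary$sobol_ranking, collapse = " > "),
        "\n")
  }
  invisible(x)
}
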