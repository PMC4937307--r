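# File formats, pipeline configuration and command-line orchestration.
# Traces, step tables and rate tables are flat tab-separated text; the
# pipeline configuration and result documents are flat JSON.

#' Write and read extension traces as tab-separated text
#'
#' The dialect is plain TSV with comment-prefixed header lines carrying the
#' generation parameters as `# key=value`, followed by the columns
#' `time_s`, `extension_nm`, `force_pN`. The reader tolerates a missing
#' force column (constant-force dialect) when the header carries a
#' `force_pN` key.
#'
#' @param trace a `fork_trace`.
#' @param path file path.
#' @return `read_trace()` returns a `fork_trace`; `write_trace()` returns
#'   `path` invisibly.
#' @export
write_trace <- function(trace, path) {
  meta <- attr(trace, "meta")
  hdr <- c(sprintf("# sample_rate=%g", attr(trace, "sample_rate")),
           vapply(names(meta), function(k) {
             v <- meta[[k]]
             if (length(v) == 1 && (is.numeric(v) || is.character(v))) {
               sprintf("# %s=%s", k, format(v, digits = 12))
             } else NA_character_
           }, character(1)))
  hdr <- hdr[!is.na(hdr)]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_s\textension_nm\tforce_pN", con)
  utils::write.table(data.frame(trace$t, trace$x, trace$F), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path, n = 200)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- regmatches(h, regexec("^#\\s*([^=\\s]+)=(.*)$", h))[[1]]
    if (length(kv) == 3) {
      val <- suppressWarnings(as.numeric(kv[3]))
      meta[[kv[2]]] <- if (is.na(val)) kv[3] else val
    }
  }
  d <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  if (!all(c("time_s", "extension_nm") %in% names(d))) {
    stop("trace file must contain columns time_s and extension_nm")
  }
  F_col <- if ("force_pN" %in% names(d)) {
    d$force_pN
  } else if (!is.null(meta$force_pN)) {
    rep(meta$force_pN, nrow(d))
  } else {
    stop("no force column and no force_pN header key in ", path)
  }
  sr <- meta$sample_rate
  if (is.null(sr)) sr <- 1 / stats::median(diff(d$time_s))
  meta$sample_rate <- NULL
  .new_trace(d$time_s, d$extension_nm, F_col, sr, meta = meta)
}

#' Write a step table as tab-separated text
#'
#' Columns: `t_s`, `level_before_nm`, `level_after_nm`, `size_nm`,
#' `size_bp`, `quality`.
#'
#' @param fit a `step_fit` from [find_steps()].
#' @param path file path.
#' @export
write_steps <- function(fit, path) {
  k <- fit$n_steps
  d <- data.frame(
    t_s = fit$t,
    level_before_nm = fit$levels[seq_len(k)],
    level_after_nm = fit$levels[seq_len(k) + 1],
    size_nm = fit$step_sizes_nm,
    size_bp = fit$step_sizes_bp,
    quality = fit$quality
  )
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read rate tables as tab-separated text
#'
#' Columns: `F_pN`, `v_bp_s`, `v_err`, `branch`, `condition`.
#'
#' @param measurements a `rate_measurements` data.frame.
#' @param path file path.
#' @export
write_rate_table <- function(measurements, path) {
  d <- data.frame(F_pN = measurements$F, v_bp_s = measurements$v,
                  v_err = measurements$v_err, branch = measurements$branch,
                  condition = measurements$condition)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  out <- data.frame(F = d$F_pN, v = d$v_bp_s, v_err = d$v_err,
                    branch = d$branch, condition = d$condition,
                    stringsAsFactors = FALSE)
  class(out) <- c("rate_measurements", "data.frame")
  out
}

#' Write a flat result document as JSON
#'
#' Nested lists are flattened to dotted keys so the document stays a flat
#' key/value map. Every document carries the package version for
#' provenance.
#'
#' @param result a named list of scalar values (or nested lists of them).
#' @param path file path.
#' @export
write_result <- function(result, path) {
  flat <- .flatten(result)
  flat$package_version <- as.character(utils::packageVersion("forkRPA"))
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.flatten <- function(x, prefix = "") {
  out <- list()
  for (k in names(x)) {
    key <- if (prefix == "") k else paste0(prefix, ".", k)
    v <- x[[k]]
    if (is.list(v)) {
      out <- c(out, .flatten(v, key))
    } else if (length(v) == 1) {
      out[[key]] <- v
    } else {
      out[[key]] <- paste(format(v, digits = 10), collapse = ",")
    }
  }
  out
}

.config_blocks <- c("elasticity", "kinetic", "simulation", "detection",
                    "fitting", "seed", "output_dir")

#' Load and validate a pipeline configuration
#'
#' The configuration is a JSON document with blocks `elasticity`,
#' `kinetic`, `simulation`, `detection`, `fitting` plus top-level `seed`
#' and `output_dir`. Unknown top-level keys and unknown keys inside the
#' `elasticity`/`kinetic` blocks are rejected; each block is validated by
#' constructing the corresponding parameter object before any stage runs.
#'
#' @param x path to a JSON file, or an equivalent named list.
#' @return A validated list of class `pipeline_config` with elements
#'   `elasticity` ([elasticity_model()]), `kinetic`
#'   ([kinetic_parameters()]), `simulation`, `detection`, `fitting`,
#'   `seed`, `output_dir`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE)
         else x
  unknown <- setdiff(names(cfg), .config_blocks)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("configuration must set a seed")
  el_args <- cfg$elasticity
  if (!is.null(el_args)) {
    bad <- setdiff(names(el_args), names(formals(elasticity_model)))
    if (length(bad)) stop("unknown elasticity keys: ",
                          paste(bad, collapse = ", "))
  }
  elasticity <- do.call(elasticity_model, as.list(el_args))
  kin_args <- cfg$kinetic
  if (is.null(kin_args)) stop("configuration must contain a kinetic block")
  bad <- setdiff(names(kin_args), names(formals(kinetic_parameters)))
  if (length(bad)) stop("unknown kinetic keys: ", paste(bad, collapse = ", "))
  kinetic <- do.call(kinetic_parameters, as.list(kin_args))
  sim <- as.list(cfg$simulation)
  det <- as.list(cfg$detection)
  fitg <- as.list(cfg$fitting)
  structure(list(elasticity = elasticity, kinetic = kinetic,
                 simulation = sim, detection = det, fitting = fitg,
                 seed = as.integer(cfg$seed),
                 output_dir = if (is.null(cfg$output_dir)) "."
                              else cfg$output_dir),
            class = "pipeline_config")
}

.sim_config_from_pipeline <- function(cfg, seed_offset = 0L) {
  sim <- cfg$simulation
  sched <- if (!is.null(sim$force_schedule)) {
    as.data.frame(sim$force_schedule)
  } else {
    data.frame(duration = 60, force = 12)
  }
  simulation_config(
    kinetic = cfg$kinetic, elasticity = cfg$elasticity,
    hairpin_size = if (is.null(sim$hairpin_size)) 488 else sim$hairpin_size,
    noise_sd = if (is.null(sim$noise_sd)) 5 else sim$noise_sd,
    sample_rate = if (is.null(sim$sample_rate)) 300 else sim$sample_rate,
    seed = cfg$seed + seed_offset,
    force_schedule = sched,
    drift_nm_per_s = if (is.null(sim$drift_nm_per_s)) 0
                     else sim$drift_nm_per_s
  )
}

#' Pipeline command: simulate traces
#'
#' Simulates `n_traces` fork traces under the configured kinetics (seeds
#' `seed`, `seed + 1`, ...), writing each as TSV plus a ground-truth event
#' sidecar (`*_events.tsv`) listing true event times and sizes.
#'
#' @param config a [pipeline_config()] (or path/list accepted by it).
#' @param out_dir output directory; default the config's `output_dir`.
#' @param n_traces number of traces; default `simulation$n_traces` or 1.
#' @return Character vector of trace file paths, invisibly.
#' @export
cmd_simulate <- function(config, out_dir = NULL, n_traces = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(n_traces)) {
    n_traces <- if (is.null(cfg$simulation$n_traces)) 1
                else cfg$simulation$n_traces
  }
  paths <- character(n_traces)
  for (i in seq_len(n_traces)) {
    tr <- simulate_fork_trace(.sim_config_from_pipeline(cfg, i - 1L))
    paths[i] <- file.path(out_dir, sprintf("trace_%03d.tsv", i))
    write_trace(tr, paths[i])
    utils::write.table(attr(tr, "events"),
                       sub("\\.tsv$", "_events.tsv", paths[i]),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}

#' Pipeline command: analyze traces
#'
#' Runs the analysis stages on a set of trace files: per-segment rate
#' estimation, step detection with a step-size histogram fit, the
#' two-term Arrhenius fit when the pooled rates span both branches, the
#' derived energetics, and sliding analysis when the trace contains
#' force cycles. Stage failures are recorded in the result rather than
#' aborting the independent stages.
#'
#' @param trace_files character vector of trace TSV paths.
#' @param config a [pipeline_config()] (or path/list accepted by it).
#' @param out optional path for the JSON result document.
#' @return The result list, invisibly when `out` is given.
#' @export
cmd_analyze <- function(trace_files, config, out = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else pipeline_config(config)
  if (length(trace_files) == 0) stop("no trace files given")
  det <- cfg$detection
  result <- list(seed = cfg$seed, n_traces = length(trace_files))
  traces <- lapply(trace_files, read_trace)
  rates <- list(); fits <- list(); errors <- character(0)
  for (tr in traces) {
    r <- rle(tr$F)
    ends <- cumsum(r$lengths); starts <- c(1, utils::head(ends, -1) + 1)
    sr <- attr(tr, "sample_rate")
    for (i in seq_along(r$values)) {
      # rate windows need at least ~1 s of constant force; shorter phases
      # (e.g. a brief opening pulse) are transient and skipped
      if (r$lengths[i] < max(10, round(sr))) next
      win <- c(tr$t[starts[i]], tr$t[ends[i]])
      rates[[length(rates) + 1]] <-
        tryCatch(estimate_trace_rate(tr, win, model = cfg$elasticity,
                                     geometry = cfg$kinetic$geometry),
                 error = function(e) NULL)
    }
    fits[[length(fits) + 1]] <- tryCatch(
      find_steps(tr,
                 min_dwell = if (is.null(det$min_dwell)) 0.3
                             else det$min_dwell,
                 acceptance_threshold = if (is.null(det$acceptance_threshold))
                                          1.5 else det$acceptance_threshold,
                 geometry = cfg$kinetic$geometry, model = cfg$elasticity),
      error = function(e) {
        errors <<- c(errors, paste("step detection:", conditionMessage(e)))
        NULL
      })
  }
  rates <- do.call(rbind, rates[!vapply(rates, is.null, logical(1))])
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!is.null(rates) && nrow(rates) > 0) {
    result$n_rate_measurements <- nrow(rates)
    result$mean_rate_bp_s <- mean(rates$v)
  }
  hist_fit <- tryCatch(fit_step_histogram(fits), error = function(e) NULL)
  if (!is.null(hist_fit)) {
    result$step_mean_bp <- hist_fit$mean_bp
    result$step_sd_bp <- hist_fit$sd_bp
    result$step_n <- hist_fit$n_steps
  }
  if (!is.null(rates) && nrow(rates) >= 4 &&
      any(rates$v > 0) && any(rates$v < 0)) {
    fit <- tryCatch(
      fit_eq1(rates, F_unz = cfg$kinetic$F_unz,
              concentration = cfg$kinetic$concentration,
              model = cfg$elasticity, geometry = cfg$kinetic$geometry,
              n_boot = if (is.null(cfg$fitting$n_boot)) 200
                       else cfg$fitting$n_boot,
              seed = cfg$seed),
      error = function(e) {
        errors <<- c(errors, paste("rate fit:", conditionMessage(e)))
        NULL
      })
    if (!is.null(fit)) {
      result$fit <- as.list(fit$estimates)
      result$fit$F_equi <- fit$F_equi_derived
      en <- tryCatch(binding_energetics(fit$params, cfg$elasticity,
                                        F_equi = fit$F_equi_derived),
                     error = function(e) NULL)
      if (!is.null(en)) {
        result$energetics <- list(F_equi = en$F_equi,
                                  dG_bp_per_bp = en$dG_bp_per_bp,
                                  dG_bind = en$dG_bind)
      }
    }
  }
  # sliding analysis when force cycles are present
  has_cycles <- any(vapply(traces, function(tr) {
    sum(diff(rle(tr$F)$values) < 0) >= 1 && length(unique(tr$F)) >= 2
  }, logical(1)))
  if (has_cycles) {
    ev <- do.call(rbind, lapply(traces, function(tr) {
      tryCatch(classify_closing_cycles(tr, model = cfg$elasticity,
                                       hairpin_size =
                                         attr(tr, "meta")$hairpin_size),
               error = function(e) NULL)
    }))
    if (!is.null(ev) && nrow(ev) > 0) {
      result$n_cycles <- nrow(ev)
      result$gradual_fraction <- mean(ev$gradual)
      fr <- tryCatch(fit_friction(ev, F_unz = cfg$kinetic$F_unz,
                                  model = cfg$elasticity),
                     error = function(e) NULL)
      if (!is.null(fr)) {
        result$friction <- list(zeta = fr$zeta, zeta_err = fr$zeta_err,
                                D = fr$D, r_squared = fr$r_squared)
      }
    }
  }
  if (length(errors) > 0) result$errors <- paste(errors, collapse = "; ")
  if (!is.null(out)) {
    write_result(result, out)
    return(invisible(result))
  }
  result
}

#' Pipeline command: binding energetics from a parameter document
#'
#' Accepts a [kinetic_parameters()] object, a `fit_result`, or a flat
#' key/value list with the standard parameter names, and returns the
#' derived energetics (equilibrium force, per-bp pairing energy, binding
#' free energy).
#'
#' @param params parameters in any of the accepted forms.
#' @param model an [elasticity_model()].
#' @param out optional path for the JSON result document.
#' @return An `energetics_result` (see [binding_energetics()]).
#' @export
cmd_energetics <- function(params, model = elasticity_model(), out = NULL) {
  p <- if (inherits(params, "fit_result")) {
    params$params
  } else if (inherits(params, "kinetic_parameters")) {
    params
  } else {
    need <- c("k_on_per_nM", "k_off", "dz_on", "dz_off", "F_unz",
              "concentration")
    miss <- setdiff(need, names(params))
    if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
    kinetic_parameters(params$k_on_per_nM, params$k_off, params$dz_on,
                       params$dz_off, params$F_unz, params$concentration,
                       footprint = if (is.null(params$footprint)) 23
                                   else params$footprint)
  }
  en <- binding_energetics(p, model)
  if (!is.null(out)) {
    write_result(list(F_equi = en$F_equi, dG_bp_per_bp = en$dG_bp_per_bp,
                      dG_bind = en$dG_bind, footprint = en$footprint), out)
  }
  en
}

#' Command-line entry point
#'
#' Dispatches the pipeline subcommands `simulate`, `analyze`, `find-steps`,
#' `fit-rates`, `energetics` and `sliding`. Shared flags: `--config` (JSON
#' configuration), `--seed` (overrides the config seed), `--out` (output
#' file or directory). `analyze`, `find-steps`, `fit-rates` and `sliding`
#' take trace or rate-table files as positional arguments.
#'
#' Exit status: 0 on success, 2 for configuration errors, 3 for I/O errors,
#' 4 for convergence/analysis errors.
#'
#' @param args character vector of command-line arguments; defaults to
#'   `commandArgs(trailingOnly = TRUE)`.
#' @return Integer exit status, invisibly.
#' @export
fork_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: forkrpa <simulate|analyze|find-steps|fit-rates|",
                 "energetics|sliding> [files] --config cfg.json",
                 "[--seed N] [--out path]")
  if (length(args) == 0) { message(usage); return(invisible(2L)) }
  cmd <- args[1]; rest <- args[-1]
  opt <- list(config = NULL, seed = NULL, out = NULL, files = character(0))
  i <- 1
  while (i <= length(rest)) {
    a <- rest[i]
    if (a %in% c("--config", "--seed", "--out")) {
      if (i == length(rest)) { message("missing value for ", a)
        return(invisible(2L)) }
      opt[[sub("^--", "", a)]] <- rest[i + 1]; i <- i + 2
    } else {
      opt$files <- c(opt$files, a); i <- i + 1
    }
  }
  get_cfg <- function() {
    if (is.null(opt$config)) stop("--config is required", call. = FALSE)
    cfg <- pipeline_config(opt$config)
    if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
    cfg
  }
  status <- tryCatch({
    switch(cmd,
      "simulate" = {
        cfg <- get_cfg()
        cmd_simulate(cfg, out_dir = if (is.null(opt$out)) cfg$output_dir
                                    else opt$out)
      },
      "analyze" = {
        cfg <- get_cfg()
        if (length(opt$files) == 0) stop("no trace files", call. = FALSE)
        cmd_analyze(opt$files, cfg,
                    out = if (is.null(opt$out))
                            file.path(cfg$output_dir, "result.json")
                          else opt$out)
      },
      "find-steps" = {
        cfg <- get_cfg()
        for (f in opt$files) {
          fit <- find_steps(read_trace(f), model = cfg$elasticity)
          write_steps(fit, if (is.null(opt$out))
                             sub("\\.tsv$", "_steps.tsv", f)
                           else opt$out)
        }
      },
      "fit-rates" = {
        cfg <- get_cfg()
        rates <- do.call(rbind, lapply(opt$files, read_rate_table))
        fit <- fit_eq1(rates, F_unz = cfg$kinetic$F_unz,
                       concentration = cfg$kinetic$concentration,
                       model = cfg$elasticity, seed = cfg$seed)
        write_result(c(as.list(fit$estimates),
                       list(F_equi = fit$F_equi_derived)),
                     if (is.null(opt$out)) "fit.json" else opt$out)
      },
      "energetics" = {
        cfg <- get_cfg()
        cmd_energetics(cfg$kinetic, cfg$elasticity,
                       out = if (is.null(opt$out)) "energetics.json"
                             else opt$out)
      },
      "sliding" = {
        cfg <- get_cfg()
        ev <- do.call(rbind, lapply(opt$files, function(f) {
          classify_closing_cycles(read_trace(f), model = cfg$elasticity)
        }))
        fr <- fit_friction(ev, F_unz = cfg$kinetic$F_unz,
                           model = cfg$elasticity)
        write_result(list(zeta = fr$zeta, zeta_err = fr$zeta_err, D = fr$D,
                          r_squared = fr$r_squared,
                          n_events = fr$n_events),
                     if (is.null(opt$out)) "sliding.json" else opt$out)
      },
      { message("unknown command: ", cmd); message(usage)
        return(invisible(2L)) }
    )
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    msg <- conditionMessage(e)
    if (grepl("config|seed|unknown|missing", msg, ignore.case = TRUE)) 2L
    else if (grepl("file|path|read|write|cannot open", msg,
                   ignore.case = TRUE)) 3L
    else 4L
  })
  invisible(status)
}
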