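# End-to-end workflow: trajectory estimation -> gradient matching -> inference
# -> exports, driven programmatically or from YAML configs.

#' Fit a gLV model to a dataset end to end
#'
#' Runs the two-step workflow: (1) estimate concentration trajectories and
#' gradients (first-order differences, or the penalized-spline smoother);
#' (2) build the gradient-match system and infer parameters with the chosen
#' algorithm.
#'
#' @param ds an `mb_dataset`.
#' @param method `"mlrr"`, `"mlcrr"`, `"bal"` or `"bvs"`.
#' @param config list: `trajectory` (`"finite_diff"` default, or `"bapcs"`),
#'   `log_space` (per-capita gradient matching, default `FALSE`), `lambdas`
#'   ([ridge_penalty()]; or `cv = TRUE` to select by cross-validation),
#'   `bapcs` / `bayes` sub-configs, `seed` (used for any stochastic step).
#' @return A [glv_params()] (ML methods) or `glv_posterior` (Bayesian), with
#'   the trajectory estimate in `attr(, "trajectory")`.
#' @export
infer_glv <- function(ds, method = "mlcrr", config = list()) {
  method <- match.arg(method, c("mlrr", "mlcrr", "bal", "bvs"))
  traj_method <- config$trajectory %||% "finite_diff"
  traj <- switch(traj_method,
    finite_diff = finite_difference_estimate(ds),
    bapcs = fit_bapcs(ds, modifyList(config$bapcs %||% list(),
                                     list(seed = config$seed %||%
                                            (config$bapcs %||% list())$seed))),
    stop(sprintf("unknown trajectory method '%s'", traj_method)))
  sys <- build_gradient_match_system(traj, ds,
                                     log_space = isTRUE(config$log_space))
  fit <- switch(method,
    mlrr = ,
    mlcrr = {
      lam <- if (isTRUE(config$cv))
        select_lambda_cv(ds, traj, fitter = method)
      else config$lambdas %||% ridge_penalty(0.01, 0.01)
      if (method == "mlrr") fit_mlrr(sys, lam) else fit_mlcrr(sys, lam)
    },
    bal = fit_bal(sys, modifyList(config$bayes %||% list(),
                                  list(seed = config$seed %||% 1))),
    bvs = fit_bvs(sys, modifyList(config$bayes %||% list(),
                                  list(seed = config$seed %||% 1))))
  attr(fit, "trajectory") <- traj
  fit
}

pipeline_keys <- c("counts", "biomass", "metadata", "trajectory", "method",
                   "analyses", "seed", "outdir", "lambdas", "cv", "bayes",
                   "bapcs", "log_space", "invader", "dose", "horizon",
                   "stability_threshold", "enum_thin")

#' Run the full analysis pipeline from a config
#'
#' Reads a dataset, fits the requested model and writes all requested
#' artifacts into a run directory: resolved config copy, structured log with
#' package version and seed, trajectory TSV, parameter TSVs, posterior TSV
#' and network edge list + GraphML (Bayesian methods), stability and
#' keystoneness tables, and the cross-validation report.
#'
#' @param config a YAML file path or an equivalent named list. Keys:
#'   `counts`, `biomass`, `metadata` (input TSVs), `trajectory`, `method`,
#'   `analyses` (subset of `"network"`, `"stability"`, `"keystoneness"`,
#'   `"crossval"`), `seed`, `outdir`, plus optional method options
#'   (`lambdas`, `cv`, `bayes`, `bapcs`, `log_space`, `invader`, `dose`,
#'   `horizon`, `stability_threshold`, `enum_thin`).
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), pipeline_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  method <- cfg$method %||% "mlcrr"
  analyses <- cfg$analyses %||% character(0)
  if ("network" %in% analyses && !method %in% c("bvs"))
    stop("network edge evidence (Bayes factors) requires method 'bvs'")
  outdir <- cfg$outdir %||% stop("config must set outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed %||% 1)

  ds <- read_dataset(cfg$counts, cfg$biomass, cfg$metadata)
  yaml::write_yaml(cfg, file.path(outdir, "config.yml"))
  log_lines <- c(
    sprintf("microdyn %s", as.character(utils::packageVersion("microdyn"))),
    sprintf("R %s", R.version.string),
    sprintf("seed %s", cfg$seed %||% 1),
    sprintf("inputs %s", paste(vapply(
      c(cfg$counts, cfg$biomass, cfg$metadata),
      function(p) unname(tools::md5sum(p)), ""), collapse = " ")),
    sprintf("method %s trajectory %s", method,
            cfg$trajectory %||% "finite_diff"))

  fit <- infer_glv(ds, method = method,
                   config = cfg[intersect(names(cfg),
                                          c("trajectory", "lambdas", "cv",
                                            "bayes", "bapcs", "log_space",
                                            "seed"))])
  traj <- attr(fit, "trajectory")
  trajectory_table(traj, file.path(outdir, "trajectories.tsv"))
  est <- if (inherits(fit, "glv_posterior")) posterior_median_params(fit)
         else fit
  write_glv_params(est, outdir)
  if (inherits(fit, "glv_posterior"))
    write_posterior(fit, file.path(outdir, "posterior.tsv"))

  thr <- cfg$stability_threshold %||% 0.9
  ethin <- cfg$enum_thin %||% 20
  if ("network" %in% analyses) {
    ev <- edge_evidence(fit)
    write_edge_list(ev, file.path(outdir, "edges.tsv"),
                    graphml_path = file.path(outdir, "network.graphml"))
  }
  if ("stability" %in% analyses) {
    scan <- enumerate_subcommunities(fit, stability_threshold = thr,
                                     enum_thin = ethin)
    write_stability_scan(scan, file.path(outdir, "stability.tsv"))
  }
  if ("keystoneness" %in% analyses) {
    ky <- keystoneness(fit, stability_threshold = thr, enum_thin = ethin)
    write.table(ky, file.path(outdir, "keystoneness.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if ("crossval" %in% analyses) {
    cvres <- holdout_forecast(ds, method,
                              cfg[intersect(names(cfg),
                                            c("trajectory", "lambdas",
                                              "bayes", "bapcs"))])
    write.table(cvres, file.path(outdir, "crossval.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  writeLines(log_lines, file.path(outdir, "run.log"))
  invisible(outdir)
}

benchmark_keys <- c("regime", "methods", "n_replicates", "seed", "outdir",
                    "config", "holdout")

#' Run the simulation benchmark from a config
#'
#' @param config YAML path or list with keys `regime` (arguments to
#'   [simulation_regime()]), `methods`, `n_replicates`, `seed`, `outdir`,
#'   optional `config` (method options) and `holdout`.
#' @return The metrics data.frame, invisibly; writes `metrics.tsv` and
#'   `summary.tsv` under `outdir`.
#' @export
run_benchmark <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  unknown <- setdiff(names(cfg), benchmark_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  methods <- cfg$methods %||% c("mlcrr", "spearman")
  bad <- setdiff(methods, c("mlrr", "mlcrr", "bal", "bvs", "spearman"))
  if (length(bad))
    stop("unknown method name(s): ", paste(bad, collapse = ", "))
  outdir <- cfg$outdir %||% stop("config must set outdir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  regime <- do.call(simulation_regime,
                    modifyList(cfg$regime %||% list(),
                               list(seed = cfg$seed %||% 1)))
  res <- run_benchmark_regime(regime, methods,
                              n_replicates = cfg$n_replicates %||% 2,
                              config = cfg$config %||% list(),
                              holdout = isTRUE(cfg$holdout))
  write.table(res, file.path(outdir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summ <- stats::aggregate(value ~ method + metric, res,
                           function(v) mean(v, na.rm = TRUE))
  write.table(summ, file.path(outdir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(res)
}
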