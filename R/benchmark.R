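# Simulation benchmark: ground-truth gLV systems with acceptance filtering,
# Dirichlet-multinomial count noise, performance metrics, hold-one-subject-out
# forecasting, and the study-design guideline.

#' Define a simulation regime
#'
#' Defaults follow the benchmark's densest design: a 10-species system
#' observed over 30 days with an invading species introduced at day 10, ten
#' subjects, 27 time points, and a 20% probability of interaction between
#' species pairs. Sequencing depth is varied between 1000 and 25,000 reads
#' (sweeps from 200 supported). Count noise is Dirichlet-multinomial
#' (compositional, overdispersed — deliberately a different noise family than
#' the negative-binomial observation model used for inference); biomass noise
#' is Normal on the log10 scale.
#'
#' @param L number of taxa, the last one being the invader (default 10).
#' @param horizon study length in days (default 30).
#' @param invasion_day day the invader is introduced (default 10).
#' @param subjects number of subjects (default 10).
#' @param n_timepoints samples per subject: 27, 18, 12 or 8 (default 27).
#' @param depth reads per sample (default 25000).
#' @param p_interact probability an ordered off-diagonal pair interacts
#'   (default 0.2).
#' @param dmd_dispersion Dirichlet-multinomial overdispersion, `1/precision`;
#'   0 recovers the multinomial (default 1/800, giving count CV about 1.5x
#'   multinomial at depth 1000).
#' @param biomass_sd_log10 sd of biomass noise on the log10 scale (default
#'   0.1).
#' @param growth_meanlog,growth_sdlog lognormal growth-rate hyperparameters
#'   (default log(0.25), 0.3: relaxation over roughly 4-10 days).
#' @param self_meanlog,self_sdlog lognormal magnitude of self-interaction
#'   (default log(0.5), 0.3).
#' @param interact_sd sd of nonzero off-diagonal interactions (default 0.1).
#' @param ic_logmin,ic_logmax initial conditions displace each taxon from its
#'   steady state by a factor `exp(+/- u)`, `u ~ Uniform(ic_logmin,
#'   ic_logmax)` with random sign (defaults log(8), log(40)): colonisation
#'   starts far from equilibrium, giving informative transients.
#' @param invader_dose_frac invader dose as a fraction of the steady-state
#'   community total (default 0.01).
#' @param seed RNG seed (mandatory for generation).
#' @return Named list of class `sim_regime`.
#' @export
simulation_regime <- function(L = 10, horizon = 30, invasion_day = 10,
                              subjects = 10, n_timepoints = 27, depth = 25000,
                              p_interact = 0.2, dmd_dispersion = 1 / 800,
                              biomass_sd_log10 = 0.1,
                              growth_meanlog = log(0.25), growth_sdlog = 0.3,
                              self_meanlog = log(0.5), self_sdlog = 0.3,
                              interact_sd = 0.1, ic_logmin = log(8),
                              ic_logmax = log(40),
                              invader_dose_frac = 0.01, seed = NULL) {
  stopifnot(depth >= 1, n_timepoints >= 2)
  structure(as.list(environment()), class = "sim_regime")
}

# Per-taxon signed log-uniform displacement of the steady state: every taxon
# starts several-fold away from equilibrium (in either direction), so each
# subject shows informative transients.
sample_initial_conditions <- function(xstar, regime) {
  L <- length(xstar)
  u <- runif(L, regime$ic_logmin, regime$ic_logmax)
  xstar * exp(u * sample(c(-1, 1), L, replace = TRUE))
}

# Sample days: day 0, the horizon end, and even coverage in between (the
# invasion day is always included so post-invasion dynamics are covered).
design_days <- function(regime) {
  d <- seq(0, regime$horizon, length.out = regime$n_timepoints)
  d <- sort(unique(c(d, regime$invasion_day)))
  if (length(d) > regime$n_timepoints) {
    # drop the interior point closest to the inserted invasion day
    cand <- setdiff(seq_along(d), c(1, length(d), which(d == regime$invasion_day)))
    drop <- cand[which.min(abs(d[cand] - regime$invasion_day))]
    d <- d[-drop]
  }
  d
}

#' Generate an accepted ground-truth gLV system
#'
#' Rejection-samples gLV parameters (lognormal growth rates, negative
#' lognormal self-interaction, off-diagonal interactions present with
#' probability `p_interact`) until the acceptance filter passes: (i) the full
#' community has a feasible, stable interior steady state (all taxa present at
#' steady state); (ii) over `n_ic` random initial conditions integrated to the
#' horizon, at least 75% yield a coefficient of variation > 0.25 for every
#' taxon's trajectory (so accepted systems show informative transients rather
#' than sitting at a fixed point).
#'
#' @param regime a [simulation_regime()] (its `seed` is used).
#' @param n_ic initial conditions tested by the filter (default 20).
#' @param max_reject rejection cap (default 10000).
#' @return A [glv_params()] with attributes `xstar` (steady state),
#'   `n_rejected`, `cv_pass_frac`.
#' @export
generate_ground_truth <- function(regime, n_ic = 20, max_reject = 10000) {
  if (!is.null(regime$seed)) set.seed(regime$seed)
  L <- regime$L
  for (trial in seq_len(max_reject)) {
    alpha <- rlnorm(L, regime$growth_meanlog, regime$growth_sdlog)
    beta <- matrix(0, L, L)
    off <- which(row(beta) != col(beta))
    hit <- off[runif(length(off)) < regime$p_interact]
    beta[hit] <- rnorm(length(hit), 0, regime$interact_sd)
    diag(beta) <- -rlnorm(L, regime$self_meanlog, regime$self_sdlog)
    pars <- glv_params(alpha, beta)
    ssv <- steady_state(pars)
    if (ssv$degenerate || !ssv$feasible) next
    if (!is_stable(pars, seq_len(L), ssv$x)) next
    tgrid <- seq(0, regime$horizon, length.out = 31)
    pass <- 0
    for (k in seq_len(n_ic)) {
      x0 <- sample_initial_conditions(ssv$x, regime)
      tr <- glv_integrate(pars, x0, tgrid)
      if (isTRUE(attr(tr, "blowup"))) next
      cv <- apply(tr, 2, function(v) sd(v) / max(mean(v), 1e-12))
      if (all(cv > 0.25)) pass <- pass + 1
    }
    if (pass / n_ic >= 0.75) {
      attr(pars, "xstar") <- ssv$x
      attr(pars, "n_rejected") <- trial - 1
      attr(pars, "cv_pass_frac") <- pass / n_ic
      return(pars)
    }
  }
  stop("acceptance filter rejected ", max_reject,
       " systems; adjust generator hyperparameters")
}

#' Dirichlet-multinomial sample
#'
#' @param n number of samples.
#' @param size total count per sample.
#' @param prob proportion vector.
#' @param dispersion overdispersion `1/precision`; 0 gives multinomial.
#' @return taxa x n count matrix.
#' @export
rdirmult <- function(n, size, prob, dispersion) {
  prob <- prob / sum(prob)
  if (dispersion <= 0) return(rmultinom(n, size, prob))
  a <- prob / dispersion
  out <- matrix(0L, length(prob), n)
  for (i in seq_len(n)) {
    g <- rgamma(length(prob), shape = a)
    g[a == 0] <- 0
    p <- if (sum(g) > 0) g / sum(g) else prob
    out[, i] <- rmultinom(1, size, p)
  }
  out
}

#' Simulate a noisy dataset from a ground-truth system
#'
#' Per subject: initial concentrations are drawn lognormally around the
#' steady state (the invader starts at zero and receives its dose at the
#' invasion day), the gLV system is integrated, and at each design day counts
#' are drawn Dirichlet-multinomial from the concentration proportions while
#' biomass is drawn Normal around the log10 total concentration.
#'
#' @param truth an accepted [generate_ground_truth()] system.
#' @param regime the [simulation_regime()].
#' @param seed RNG seed for the noise draws (defaults to `regime$seed + 1`).
#' @return List: `dataset` (an `mb_dataset`), `truth_traj` (noise-free L x N
#'   concentration matrices per subject at the design days), `days`.
#' @export
simulate_dataset <- function(truth, regime, seed = NULL) {
  if (is.null(seed)) seed <- (regime$seed %||% 0) + 1
  set.seed(seed)
  L <- regime$L
  xstar <- attr(truth, "xstar")
  if (is.null(xstar)) xstar <- steady_state(truth)$x
  days <- design_days(regime)
  dose <- regime$invader_dose_frac * sum(xstar)
  counts <- biomass <- times <- events <- list()
  truth_traj <- list()
  for (s in seq_len(regime$subjects)) {
    sid <- sprintf("subj%02d", s)
    for (retry in 1:5) {
      x0 <- sample_initial_conditions(xstar, regime)
      x0[L] <- 0  # invader absent until the invasion day
      tr <- glv_integrate(truth, x0, days,
                          events = data.frame(time = regime$invasion_day,
                                              taxon = L, add = dose))
      if (!isTRUE(attr(tr, "blowup"))) break
      if (retry == 5) stop("integration blow-up persisted over 5 retries")
    }
    conc <- t(tr)  # L x N
    rownames(conc) <- truth$taxa
    prop <- pmax(conc, 0)
    Y <- matrix(0L, L, length(days))
    for (j in seq_len(length(days)))
      Y[, j] <- rdirmult(1, regime$depth, prop[, j] + 1e-12,
                         regime$dmd_dispersion)
    rownames(Y) <- truth$taxa
    w <- 10^(log10(pmax(colSums(conc), 1e-12)) +
             rnorm(length(days), 0, regime$biomass_sd_log10))
    counts[[sid]] <- Y
    biomass[[sid]] <- w
    times[[sid]] <- days
    events[[sid]] <- data.frame(time = regime$invasion_day, taxon = L,
                                add = dose)
    truth_traj[[sid]] <- conc
  }
  list(dataset = mb_dataset(counts, biomass, times, taxa = truth$taxa,
                            events = events),
       truth_traj = truth_traj, days = days)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve (midrank convention)
#'
#' @param score numeric scores.
#' @param label 0/1 (or logical) ground-truth labels.
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auc_roc <- function(score, label) {
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- as.logical(label[keep])
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)  # midranks: ties get half credit
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score an inference run against ground truth
#'
#' Computes the benchmark's four metrics: (a) RMSE of growth rates; (b) RMSE
#' of interaction parameters; (c) AUC ROC for presence/absence of directed
#' off-diagonal interactions (from a continuous score matrix); (d) RMSE of
#' predicted trajectories on unseen initial conditions, passed through from
#' [holdout_forecast()]. Trajectory RMSEs are computed on log10
#' concentrations with a floor of 1e-10 of the maximum concentration.
#'
#' @param truth ground-truth [glv_params()].
#' @param inferred inferred [glv_params()] (or `NULL` to skip (a)-(b)).
#' @param scores L x L network score matrix (or `NULL` to skip (c)).
#' @param forecast_rmse held-out trajectory RMSE (or `NA`).
#' @return Named list: `rmse_growth`, `rmse_interaction`, `auc`,
#'   `rmse_trajectory`.
#' @export
score_inference <- function(truth, inferred = NULL, scores = NULL,
                            forecast_rmse = NA_real_) {
  out <- list(rmse_growth = NA_real_, rmse_interaction = NA_real_,
              auc = NA_real_, rmse_trajectory = forecast_rmse)
  if (!is.null(inferred)) {
    out$rmse_growth <- sqrt(mean((inferred$alpha - truth$alpha)^2))
    out$rmse_interaction <- sqrt(mean((inferred$beta - truth$beta)^2))
  }
  if (!is.null(scores)) {
    off <- row(truth$beta) != col(truth$beta)
    out$auc <- auc_roc(scores[off], truth$beta[off] != 0)
  }
  out
}

#' Restrict a dataset to a subset of subjects
#'
#' @param ds an `mb_dataset`.
#' @param subjects character vector of subject ids to keep.
#' @return The restricted dataset.
#' @export
ds_subset <- function(ds, subjects) {
  ds$subjects <- subjects
  ds$times <- ds$times[subjects]
  ds$counts <- ds$counts[subjects]
  ds$readdepth <- ds$readdepth[subjects]
  ds$biomass <- ds$biomass[subjects]
  if (length(ds$events)) ds$events <- ds$events[subjects]
  ds
}

#' Hold-one-subject-out trajectory forecasting
#'
#' For each subject in turn: the model is fitted on the remaining subjects,
#' the held-out subject's trajectory is forecast by numerical integration
#' from its first measured concentrations (with its own perturbation
#' schedule), and the RMSE against its measured log10 concentrations is
#' recorded. For Bayesian fits the forecast is made per (re-thinned) retained
#' draw and the median trajectory is scored.
#'
#' @param ds an `mb_dataset`.
#' @param method `"mlrr"`, `"mlcrr"`, `"bal"` or `"bvs"`.
#' @param config list: `trajectory` (`"finite_diff"` or `"bapcs"`), `lambdas`
#'   ([ridge_penalty()]), `bapcs` and `bayes` config lists, `forecast_thin`
#'   (draw re-thinning for Bayesian forecasts, default 20).
#' @return data.frame with `subject` and `rmse`; subjects with a single time
#'   point are skipped with a note attribute.
#' @export
holdout_forecast <- function(ds, method = "mlcrr", config = list()) {
  out <- NULL
  skipped <- character(0)
  for (s in ds$subjects) {
    if (length(ds$times[[s]]) < 2) {
      skipped <- c(skipped, s)
      next
    }
    train <- ds_subset(ds, setdiff(ds$subjects, s))
    fit <- infer_glv(train, method = method, config = config)
    rmse <- forecast_subject_rmse(fit, ds, s,
                                  thin = config$forecast_thin %||% 20)
    out <- rbind(out, data.frame(subject = s, rmse = rmse))
  }
  attr(out, "skipped") <- skipped
  out
}

# Forecast one held-out subject under a fit (point estimate or posterior) and
# return the log10 RMSE against its measured concentrations.
forecast_subject_rmse <- function(fit, ds, s, thin = 20) {
  tt <- ds$times[[s]]
  w <- ds$biomass[[s]]
  w[is.na(w)] <- mean(w, na.rm = TRUE)
  obs <- sweep(sweep(ds$counts[[s]], 2, ds$readdepth[[s]], "/"), 2, w, "*")
  if (inherits(fit, "glv_posterior")) {
    nd <- dim(fit$beta)[1]
    didx <- seq(1, nd, by = max(1, thin))
    preds <- array(NA_real_, c(length(didx), length(tt), length(fit$taxa)))
    for (i in seq_along(didx)) {
      p <- posterior_draw(fit, didx[i])
      tr <- glv_integrate(p, obs[, 1], tt, schedules = ds$perturbations,
                          subject = s, events = ds$events[[s]])
      if (!isTRUE(attr(tr, "blowup"))) preds[i, , ] <- tr
    }
    med <- apply(preds, c(2, 3), median, na.rm = TRUE)
    if (all(is.na(med))) return(Inf)
    log10_rmse(t(med), obs)
  } else {
    forecast_rmse(fit, ds, s)
  }
}

#' Absolute-Spearman-correlation network baseline
#'
#' The standard correlational alternative to dynamical inference: for every
#' taxon pair, the absolute Spearman rank correlation of their estimated
#' concentration series (relative abundance times biomass) pooled across
#' subjects. The score is undirected and copied to both ordered pairs so it
#' can be evaluated against a directed ground-truth network. Pairs involving
#' a constant series get score 0 (flagged via the `constant` attribute).
#'
#' @param ds an `mb_dataset`.
#' @return Symmetric L x L score matrix in `[0, 1]` with `NA` diagonal.
#' @export
spearman_baseline <- function(ds) {
  L <- length(ds$taxa)
  series <- NULL
  for (s in ds$subjects) {
    w <- ds$biomass[[s]]
    w[is.na(w)] <- mean(w, na.rm = TRUE)
    conc <- sweep(sweep(ds$counts[[s]], 2, ds$readdepth[[s]], "/"), 2, w, "*")
    series <- cbind(series, conc)
  }
  sc <- matrix(0, L, L, dimnames = list(ds$taxa, ds$taxa))
  const <- apply(series, 1, function(v) length(unique(v)) == 1)
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (const[i] || const[j]) next
      sc[i, j] <- sc[j, i] <- abs(cor(series[i, ], series[j, ],
                                      method = "spearman"))
    }
  }
  diag(sc) <- NA
  attr(sc, "constant") <- const
  sc
}

#' Minimal time points per subject for reliable inference
#'
#' An ecosystem with L taxa has about L^2 potential interactions; with
#' regularisation and sparsity roughly `L^2 / 2` informative data points
#' suffice, so a study with S subjects should sample at least
#' `ceil((L^2 / 2) / S)` time points per subject (under perturbations —
#' repeated steady-state measurements are not informative).
#'
#' @param L number of taxa to be modeled.
#' @param S number of subjects.
#' @return Integer time points per subject.
#' @export
recommend_min_timepoints <- function(L, S) {
  if (L < 1 || S < 1) stop("L and S must be positive")
  as.integer(ceiling((L^2 / 2) / S))
}

#' Run one benchmark regime over replicate systems
#'
#' Generates `n_replicates` independent accepted (system, dataset) pairs and
#' scores the requested inference methods plus the Spearman baseline with the
#' four benchmark metrics. Replicate seeds are derived from the regime seed,
#' making the run bit-reproducible.
#'
#' @param regime a [simulation_regime()] (seed required).
#' @param methods character subset of `c("mlrr", "mlcrr", "bal", "bvs",
#'   "spearman")`.
#' @param n_replicates replicate count (default 20; the full-scale study uses
#'   400).
#' @param config method configuration as in [holdout_forecast()].
#' @param holdout if `TRUE` also compute the hold-one-subject-out trajectory
#'   RMSE (costly; default `FALSE`).
#' @return Tidy data.frame: `replicate`, `method`, `metric`, `value`.
#' @export
run_benchmark_regime <- function(regime, methods = c("mlcrr", "spearman"),
                                 n_replicates = 20, config = list(),
                                 holdout = FALSE) {
  if (is.null(regime$seed)) stop("regime seed required")
  set.seed(regime$seed)
  seeds <- sample.int(2^31 - 2, n_replicates)
  rows <- NULL
  for (rep_i in seq_len(n_replicates)) {
    reg <- regime
    reg$seed <- seeds[rep_i]
    truth <- generate_ground_truth(reg)
    sim <- simulate_dataset(truth, reg)
    ds <- sim$dataset
    for (m in methods) {
      if (m == "spearman") {
        sc <- spearman_baseline(ds)
        met <- score_inference(truth, NULL, sc)
      } else {
        fit <- infer_glv(ds, method = m,
                         config = modifyList(config,
                                             list(seed = seeds[rep_i])))
        est <- if (inherits(fit, "glv_posterior"))
          posterior_median_params(fit) else fit
        sc <- network_scores(m, fit, ds)
        frm <- if (holdout)
          mean(holdout_forecast(ds, m, config)$rmse) else NA_real_
        met <- score_inference(truth, est, sc, frm)
      }
      rows <- rbind(rows, data.frame(replicate = rep_i, method = m,
                                     metric = names(met),
                                     value = unlist(met),
                                     row.names = NULL))
    }
  }
  rows
}
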