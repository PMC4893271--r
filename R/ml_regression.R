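# Maximum-likelihood gLV inference: ridge regression (MLRR) and constrained
# ridge via quadratic programming (MLCRR), with cross-validated penalties.

#' Ridge penalty configuration
#'
#' The penalty matrix is diagonal with two values: one shared by the growth
#' and perturbation columns, one for the interaction columns.
#'
#' @param lambda_growth penalty on growth + perturbation coefficients.
#' @param lambda_interaction penalty on interaction coefficients.
#' @return Named list.
#' @export
ridge_penalty <- function(lambda_growth = 1, lambda_interaction = 1) {
  stopifnot(lambda_growth >= 0, lambda_interaction >= 0)
  list(lambda_growth = lambda_growth, lambda_interaction = lambda_interaction)
}

# Diagonal of the penalty matrix for one taxon block.
penalty_diag <- function(L, P, lambdas) {
  c(lambdas$lambda_growth, rep(lambdas$lambda_interaction, L),
    rep(lambdas$lambda_growth, P))
}

# Ridge solve with optional equality-pinned coordinates (values in `pin`,
# named by index). Returns the full coefficient vector.
ridge_solve <- function(X, y, pen, pin = NULL) {
  p <- ncol(X)
  free <- setdiff(seq_len(p), as.integer(names(pin)))
  theta <- numeric(p)
  if (length(pin)) theta[as.integer(names(pin))] <- unlist(pin)
  if (!length(free)) return(theta)
  y_adj <- y
  if (length(pin))
    y_adj <- y - X[, as.integer(names(pin)), drop = FALSE] %*% unlist(pin)
  A <- crossprod(X[, free, drop = FALSE]) + diag(pen[free], length(free))
  b <- crossprod(X[, free, drop = FALSE], y_adj)
  sol <- try(solve(A, b), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("singular normal equations; use a penalty lambda > 0")
  theta[free] <- sol
  theta
}

ridge_objective <- function(X, y, pen, theta) {
  sum((y - X %*% theta)^2) + sum(pen * theta^2)
}

# Assemble a glv_params object from per-taxon coefficient vectors.
assemble_params <- function(blocks, sys) {
  L <- sys$L; P <- sys$P
  alpha <- rep(NA_real_, L)
  beta <- matrix(NA_real_, L, L)
  gamma <- matrix(NA_real_, L, P)
  for (l in seq_len(L)) {
    th <- blocks[[l]]
    if (is.null(th)) next
    alpha[l] <- th[1]
    beta[l, ] <- th[1 + seq_len(L)]
    if (P > 0) gamma[l, ] <- th[1 + L + seq_len(P)]
  }
  glv_params(alpha, beta, gamma, taxa = sys$taxa)
}

#' Unconstrained maximum-likelihood ridge regression (MLRR)
#'
#' Per target taxon, minimises
#' `||response - predictors %*% theta||^2 + theta' Lambda theta` with a
#' diagonal penalty (see [ridge_penalty()]); the gradient-match system is
#' block-diagonal across target taxa, so blocks are solved independently. No
#' sign constraints are imposed.
#'
#' @param sys a [build_gradient_match_system()] result.
#' @param lambdas a [ridge_penalty()].
#' @return A [glv_params()]; taxa contributing no rows get `NA` parameters.
#' @export
fit_mlrr <- function(sys, lambdas = ridge_penalty()) {
  pen <- penalty_diag(sys$L, sys$P, lambdas)
  blocks <- vector("list", sys$L)
  for (l in seq_len(sys$L)) {
    idx <- which(sys$taxon == l)
    if (!length(idx)) next
    blocks[[l]] <- ridge_solve(sys$predictors[idx, , drop = FALSE],
                               sys$response[idx], pen)
  }
  fit <- assemble_params(blocks, sys)
  attr(fit, "objective") <- sum(vapply(seq_len(sys$L), function(l) {
    idx <- which(sys$taxon == l)
    if (!length(idx)) return(0)
    ridge_objective(sys$predictors[idx, , drop = FALSE], sys$response[idx],
                    pen, blocks[[l]])
  }, 1))
  fit
}

#' Constrained maximum-likelihood ridge regression (MLCRR)
#'
#' Same objective as [fit_mlrr()] subject to the biological constraints
#' `alpha_l >= eps` (positive growth) and `beta_ll <= -eps` (self-limitation,
#' i.e. logistic growth up to a carrying capacity). With exactly two bound
#' constraints per taxon block the quadratic program is solved exactly by
#' enumerating the four possible active sets and picking the feasible solution
#' of minimal objective; the KKT conditions of the returned solution are
#' verified.
#'
#' @inheritParams fit_mlrr
#' @param eps strict-inequality buffer (default 1e-5).
#' @return A [glv_params()] with attribute `kkt_ok`.
#' @export
fit_mlcrr <- function(sys, lambdas = ridge_penalty(), eps = 1e-5) {
  pen <- penalty_diag(sys$L, sys$P, lambdas)
  blocks <- vector("list", sys$L)
  kkt_ok <- TRUE
  for (l in seq_len(sys$L)) {
    idx <- which(sys$taxon == l)
    if (!length(idx)) next
    X <- sys$predictors[idx, , drop = FALSE]
    y <- sys$response[idx]
    ia <- 1L           # alpha coordinate
    id <- 1L + l       # beta_ll coordinate
    cand <- list(
      ridge_solve(X, y, pen),
      ridge_solve(X, y, pen, pin = setNames(list(eps), ia)),
      ridge_solve(X, y, pen, pin = setNames(list(-eps), id)),
      ridge_solve(X, y, pen, pin = setNames(list(eps, -eps), c(ia, id)))
    )
    feas <- vapply(cand, function(th)
      th[ia] >= eps - 1e-12 && th[id] <= -eps + 1e-12, TRUE)
    obj <- vapply(cand, function(th) ridge_objective(X, y, pen, th), 1)
    obj[!feas] <- Inf
    best <- cand[[which.min(obj)]]
    # KKT: free coords have zero gradient; active bounds have correctly
    # signed multipliers.
    g <- 2 * (crossprod(X, X %*% best - y) + pen * best)
    tol <- 1e-6 * max(1, max(abs(g)))
    ok <- TRUE
    for (j in seq_along(best)) {
      if (j == ia && abs(best[j] - eps) < 1e-12) ok <- ok && g[j] >= -tol
      else if (j == id && abs(best[j] + eps) < 1e-12) ok <- ok && g[j] <= tol
      else ok <- ok && abs(g[j]) <= tol
    }
    kkt_ok <- kkt_ok && ok
    blocks[[l]] <- best
  }
  fit <- assemble_params(blocks, sys)
  attr(fit, "objective") <- sum(vapply(seq_len(sys$L), function(l) {
    idx <- which(sys$taxon == l)
    if (!length(idx)) return(0)
    ridge_objective(sys$predictors[idx, , drop = FALSE], sys$response[idx],
                    pen, blocks[[l]])
  }, 1))
  attr(fit, "kkt_ok") <- kkt_ok
  fit
}

#' Cross-validated penalty selection
#'
#' Leave-one-subject-out cross-validation over a log-spaced grid of penalty
#' pairs. The score is the forecast RMSE on the held-out subject: the model is
#' fitted on the remaining subjects' gradient-match rows, the held-out
#' subject's trajectory is forecast by numerical integration from its first
#' observed concentrations, and the RMSE is computed on the log10 scale. With
#' a single subject the fold structure falls back to leaving out the second
#' half of the time series (with a warning).
#'
#' @param ds an `mb_dataset`.
#' @param traj a [trajectory_estimate()] for `ds`.
#' @param grid numeric vector of candidate lambda values (all pairs are
#'   scored); default `10^seq(-3, 3)`.
#' @param fitter `"mlcrr"` (default) or `"mlrr"`.
#' @return A [ridge_penalty()] with attribute `cv_table` (one row per
#'   (lambda pair, fold) with the fold RMSE).
#' @export
select_lambda_cv <- function(ds, traj, grid = 10^seq(-3, 3), fitter = "mlcrr") {
  fit_fun <- switch(fitter, mlcrr = fit_mlcrr, mlrr = fit_mlrr,
                    stop("unknown fitter"))
  single <- length(ds$subjects) < 2
  if (single)
    warning("single subject: falling back to leave-time-block-out CV")
  pairs <- expand.grid(lambda_growth = grid, lambda_interaction = grid)
  tab <- NULL
  for (i in seq_len(nrow(pairs))) {
    lam <- ridge_penalty(pairs$lambda_growth[i], pairs$lambda_interaction[i])
    if (!single) {
      for (s in ds$subjects) {
        tr <- traj
        keep <- setdiff(ds$subjects, s)
        tr$grid <- tr$grid[keep]; tr$f <- tr$f[keep]; tr$fprime <- tr$fprime[keep]
        ds_tr <- ds; ds_tr$subjects <- keep
        sys <- build_gradient_match_system(tr, ds_tr)
        fit <- fit_fun(sys, lam)
        rmse <- forecast_rmse(fit, ds, s)
        tab <- rbind(tab, data.frame(lambda_growth = lam$lambda_growth,
                                     lambda_interaction = lam$lambda_interaction,
                                     fold = s, rmse = rmse))
      }
    } else {
      s <- ds$subjects[1]
      tt <- traj$grid[[s]]
      half <- tt < median(tt)
      tr <- traj
      tr$f[[s]] <- tr$f[[s]][, half, drop = FALSE]
      tr$fprime[[s]] <- tr$fprime[[s]][, half, drop = FALSE]
      tr$grid[[s]] <- tt[half]
      sys <- build_gradient_match_system(tr, ds)
      fit <- fit_fun(sys, lam)
      rmse <- forecast_rmse(fit, ds, s)
      tab <- rbind(tab, data.frame(lambda_growth = lam$lambda_growth,
                                   lambda_interaction = lam$lambda_interaction,
                                   fold = "block2", rmse = rmse))
    }
  }
  agg <- stats::aggregate(rmse ~ lambda_growth + lambda_interaction, tab,
                          function(v) mean(v, na.rm = TRUE))
  best <- agg[which.min(agg$rmse), ]
  out <- ridge_penalty(best$lambda_growth, best$lambda_interaction)
  attr(out, "cv_table") <- tab
  out
}

# Forecast one subject from its first measured concentrations and return the
# log10 RMSE against its measured concentrations.
forecast_rmse <- function(params, ds, s) {
  tt <- ds$times[[s]]
  w <- ds$biomass[[s]]
  w[is.na(w)] <- mean(w, na.rm = TRUE)
  obs <- sweep(sweep(ds$counts[[s]], 2, ds$readdepth[[s]], "/"), 2, w, "*")
  p <- params
  p$alpha[is.na(p$alpha)] <- 0
  p$beta[is.na(p$beta)] <- 0
  if (ncol(p$gamma)) p$gamma[is.na(p$gamma)] <- 0
  pred <- glv_integrate(p, obs[, 1], tt,
                        schedules = ds$perturbations, subject = s,
                        events = ds$events[[s]])
  if (isTRUE(attr(pred, "blowup"))) return(Inf)
  log10_rmse(t(pred), obs)
}

# RMSE on the log10 scale with a relative floor.
log10_rmse <- function(pred, obs, floor_frac = 1e-10) {
  fl <- floor_frac * max(obs, pred, 1e-300)
  sqrt(mean((log10(pmax(pred, fl)) - log10(pmax(obs, fl)))^2))
}

#' Write inferred gLV parameters as TSV matrices
#'
#' @param params a [glv_params()].
#' @param dir output directory.
#' @return Invisibly, the file paths (alpha, beta, gamma).
#' @export
write_glv_params <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("alpha.tsv", "beta.tsv", "gamma.tsv"))
  write.table(data.frame(taxon = params$taxa, alpha = params$alpha),
              paths[1], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(taxon = params$taxa, params$beta, check.names = FALSE),
              paths[2], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(taxon = params$taxa, params$gamma, check.names = FALSE),
              paths[3], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
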