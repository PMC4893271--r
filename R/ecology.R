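# Downstream ecological predictions: steady states, Jacobian stability,
# sub-community enumeration, invasion challenges, keystoneness.

# Coerce a point estimate into a one-draw posterior so every analysis can run
# on either input.
as_posterior <- function(fit) {
  if (inherits(fit, "glv_posterior")) return(fit)
  if (!inherits(fit, "glv_params")) stop("need glv_params or glv_posterior")
  L <- length(fit$alpha); P <- ncol(fit$gamma)
  new_glv_posterior(matrix(fit$alpha, 1), array(fit$beta, c(1, L, L)),
                    array(fit$gamma, c(1, L, P)), NULL, NULL,
                    "point", fit$taxa, list(pi0 = NA))
}

#' Interior steady state of a sub-community
#'
#' Solves `beta_sub x* = -(alpha_sub + gamma_sub u)` for the interior fixed
#' point of the gLV system restricted to a taxon subset, with the listed
#' perturbations held on. The state is feasible when every component is
#' strictly positive.
#'
#' @param params a [glv_params()].
#' @param subset integer indices (or taxon names) of the sub-community.
#' @param active indices of perturbations held active.
#' @return List with `x` (named concentrations, `NULL` if degenerate),
#'   `feasible`, and `degenerate` (singular interaction submatrix, reported
#'   distinctly from infeasibility).
#' @export
steady_state <- function(params, subset = seq_along(params$alpha),
                         active = integer(0)) {
  if (is.character(subset)) subset <- match(subset, params$taxa)
  g <- net_growth(params, active)[subset]
  B <- params$beta[subset, subset, drop = FALSE]
  x <- try(solve(B, -g), silent = TRUE)
  if (inherits(x, "try-error") || any(!is.finite(x)))
    return(list(x = NULL, feasible = FALSE, degenerate = TRUE,
                subset = subset))
  names(x) <- params$taxa[subset]
  list(x = x, feasible = all(x > 0), degenerate = FALSE, subset = subset)
}

#' Jacobian stability of an interior steady state
#'
#' At an interior fixed point the gLV Jacobian restricted to the subset is
#' `J = diag(x*) %*% beta_sub`; the state is (locally asymptotically) stable
#' when every eigenvalue of `J` has negative real part.
#'
#' @param params a [glv_params()].
#' @param subset taxon subset (indices or names).
#' @param xstar interior steady state for the subset.
#' @return `TRUE`/`FALSE`.
#' @export
is_stable <- function(params, subset, xstar) {
  if (is.character(subset)) subset <- match(subset, params$taxa)
  J <- diag(xstar, length(xstar)) %*% params$beta[subset, subset, drop = FALSE]
  all(Re(eigen(J, only.values = TRUE)$values) < 0)
}

#' Enumerate sub-communities by stability probability
#'
#' Examines every non-empty taxon subset (`2^L - 1` combinations, hard-capped
#' at L = 20) and, for each retained (optionally re-thinned) posterior draw,
#' determines whether the subset has a feasible (all concentrations > 0) and
#' stable steady state. Subsets whose estimated probability of stability
#' exceeds the threshold are returned. Draws with a singular interaction
#' submatrix are counted as degenerate, excluded from the stable fraction's
#' numerator.
#'
#' @param fit a `glv_posterior` or a point-estimate [glv_params()].
#' @param active indices of perturbations held on.
#' @param stability_threshold retain subsets with
#'   `stability_prob > stability_threshold` (default 0.9).
#' @param enum_thin additional thinning of retained draws before enumeration
#'   (default 20, giving the workflow's enumeration subsample).
#' @param taxa_subset optional restriction of the enumerated universe (e.g.
#'   commensals only).
#' @return Object of class `stability_scan`: list of per-subset reports
#'   (`subset`, `members`, `size`, `stability_prob`, `xstar` mean over
#'   feasible-stable draws, `n_draws`), with attributes `n_examined`,
#'   `draws_used`, `threshold`.
#' @export
enumerate_subcommunities <- function(fit, active = integer(0),
                                     stability_threshold = 0.9,
                                     enum_thin = 20,
                                     taxa_subset = NULL) {
  ps <- as_posterior(fit)
  L_all <- length(ps$taxa)
  universe <- if (is.null(taxa_subset)) seq_len(L_all) else {
    if (is.character(taxa_subset)) match(taxa_subset, ps$taxa) else taxa_subset
  }
  L <- length(universe)
  if (L > 20) stop("more than 20 taxa: enumeration is 2^L; group taxa first")
  nd <- dim(ps$beta)[1]
  didx <- seq(1, nd, by = max(1, enum_thin))
  n_sub <- 2^L - 1
  subsets <- lapply(seq_len(n_sub), function(m)
    universe[which(bitwAnd(m, bitwShiftL(1, seq_len(L) - 1)) != 0)])
  n_stable <- integer(n_sub)
  x_sum <- lapply(subsets, function(s) numeric(length(s)))
  n_degen <- integer(n_sub)
  for (d in didx) {
    pars <- posterior_draw(ps, d)
    for (m in seq_len(n_sub)) {
      ssv <- steady_state(pars, subsets[[m]], active)
      if (ssv$degenerate) {
        n_degen[m] <- n_degen[m] + 1
        next
      }
      if (ssv$feasible && is_stable(pars, subsets[[m]], ssv$x)) {
        n_stable[m] <- n_stable[m] + 1
        x_sum[[m]] <- x_sum[[m]] + ssv$x
      }
    }
  }
  reports <- list()
  for (m in seq_len(n_sub)) {
    prob <- n_stable[m] / length(didx)
    if (prob > stability_threshold) {
      reports[[length(reports) + 1]] <- list(
        subset = subsets[[m]],
        members = ps$taxa[subsets[[m]]],
        size = length(subsets[[m]]),
        stability_prob = prob,
        xstar = x_sum[[m]] / max(n_stable[m], 1),
        n_draws = length(didx),
        n_degenerate = n_degen[m])
    }
  }
  structure(reports, class = "stability_scan",
            n_examined = n_sub, draws_used = length(didx),
            threshold = stability_threshold)
}

#' @export
print.stability_scan <- function(x, ...) {
  cat(sprintf("stability_scan: %d subsets examined, %d above threshold %.2f (%d draws)\n",
              attr(x, "n_examined"), length(x), attr(x, "threshold"),
              attr(x, "draws_used")))
  invisible(x)
}

#' Simulate an invasion challenge against a stable sub-community
#'
#' For each (re-thinned) posterior draw under which the sub-community is
#' feasible and stable, the community is initialised at that draw's own
#' steady state, the invader is added at the given dose, and the joint
#' (sub-community + invader) gLV system is integrated for the horizon. The
#' invader's final concentration is summarised as the median and the median
#' absolute deviation across draws; draws whose integration blows up are
#' excluded and counted.
#'
#' @param fit a `glv_posterior` or [glv_params()].
#' @param subcommunity taxon indices or names (not containing the invader).
#' @param invader taxon index or name.
#' @param dose invader starting concentration (e.g. 1e5 CFU/g).
#' @param horizon integration time in days (e.g. 28).
#' @param active indices of perturbations held on.
#' @param enum_thin re-thinning of retained draws (default 20).
#' @return List: `median`, `mad` (raw median absolute deviation), `n_draws`
#'   (used), `n_blowup`, `finals` (per-draw final invader concentrations).
#' @export
challenge_invasion <- function(fit, subcommunity, invader, dose, horizon = 28,
                               active = integer(0), enum_thin = 20) {
  ps <- as_posterior(fit)
  if (is.character(subcommunity)) subcommunity <- match(subcommunity, ps$taxa)
  if (is.character(invader)) invader <- match(invader, ps$taxa)
  if (invader %in% subcommunity) stop("invader must not be in the sub-community")
  nd <- dim(ps$beta)[1]
  didx <- seq(1, nd, by = max(1, enum_thin))
  finals <- numeric(0)
  n_blow <- 0
  joint <- c(subcommunity, invader)
  for (d in didx) {
    pars <- posterior_draw(ps, d)
    ssv <- steady_state(pars, subcommunity, active)
    if (length(subcommunity) > 0) {
      if (ssv$degenerate || !ssv$feasible ||
          !is_stable(pars, subcommunity, ssv$x)) next
      x0 <- c(ssv$x, dose)
    } else x0 <- dose
    sub_pars <- glv_params(net_growth(pars, active)[joint],
                           pars$beta[joint, joint, drop = FALSE],
                           taxa = ps$taxa[joint])
    tr <- glv_integrate(sub_pars, x0, seq(0, horizon, length.out = 57))
    if (isTRUE(attr(tr, "blowup"))) {
      n_blow <- n_blow + 1
      next
    }
    finals <- c(finals, tr[nrow(tr), length(joint)])
  }
  list(median = if (length(finals)) median(finals) else NA_real_,
       mad = if (length(finals)) mad(finals, constant = 1) else NA_real_,
       n_draws = length(finals), n_blowup = n_blow, finals = finals)
}

#' Rank invader-excluding communities per community size
#'
#' For each possible sub-community size, finds the community of commensal
#' taxa that (a) is stable with probability above the threshold and (b)
#' minimises the median invader concentration at the horizon after an
#' invasion challenge. Ties in the median are broken by higher stability
#' probability. Sizes with no sufficiently stable community are omitted.
#'
#' @inheritParams challenge_invasion
#' @param stability_threshold minimal stability probability (default 0.9).
#' @return data.frame with columns `size`, `members`, `cdi_median`,
#'   `cdi_mad`, `stability_prob`; attribute `omitted_sizes`.
#' @export
rank_exclusion_communities <- function(fit, invader, dose, horizon = 28,
                                       active = integer(0),
                                       stability_threshold = 0.9,
                                       enum_thin = 20) {
  ps <- as_posterior(fit)
  if (is.character(invader)) invader <- match(invader, ps$taxa)
  commensals <- setdiff(seq_along(ps$taxa), invader)
  scan <- enumerate_subcommunities(ps, active, stability_threshold,
                                   enum_thin, taxa_subset = commensals)
  out <- NULL
  omitted <- integer(0)
  for (sz in seq_along(commensals)) {
    cand <- Filter(function(r) r$size == sz, scan)
    if (!length(cand)) {
      omitted <- c(omitted, sz)
      next
    }
    res <- lapply(cand, function(r)
      challenge_invasion(ps, r$subset, invader, dose, horizon, active,
                         enum_thin))
    med <- vapply(res, function(z) z$median, 1)
    prob <- vapply(cand, function(r) r$stability_prob, 1)
    ord <- order(med, -prob)
    b <- ord[1]
    out <- rbind(out, data.frame(
      size = sz,
      members = paste(cand[[b]]$members, collapse = ","),
      cdi_median = med[b], cdi_mad = res[[b]]$mad,
      stability_prob = prob[b]))
  }
  attr(out, "omitted_sizes") <- omitted
  out
}

#' Keystoneness of each taxon
#'
#' Starting from the baseline community — the largest taxon combination that
#' stably coexists (ties broken by higher stability probability, then
#' lexicographically) — each member is removed in turn and the reduced
#' community's steady state is recomputed. Keystoneness `Ky` is the Euclidean
#' distance between the baseline steady-state profile and the reduced
#' profile, computed over the surviving taxa only (the removed taxon's own
#' concentration does not contribute). Taxa whose removal leaves no stable
#' configuration are reported with `NA` keystoneness and `stable_after_removal
#' = FALSE`.
#'
#' @param fit a `glv_posterior` or [glv_params()].
#' @param active indices of perturbations held on.
#' @param stability_threshold baseline/rescan stability threshold.
#' @param enum_thin draw re-thinning for the scan.
#' @return data.frame ranked by `Ky` descending: `taxon`, `Ky`,
#'   `stable_after_removal`, `in_baseline`; attribute `baseline` (the member
#'   taxa).
#' @export
keystoneness <- function(fit, active = integer(0), stability_threshold = 0.9,
                         enum_thin = 20) {
  ps <- as_posterior(fit)
  scan <- enumerate_subcommunities(ps, active, stability_threshold, enum_thin)
  if (!length(scan)) stop("no stable community above the threshold")
  sizes <- vapply(scan, function(r) r$size, 1)
  probs <- vapply(scan, function(r) r$stability_prob, 1)
  keys <- vapply(scan, function(r) paste(r$subset, collapse = ","), "")
  ord <- order(-sizes, -probs, keys)
  base <- scan[[ord[1]]]
  nd <- dim(ps$beta)[1]
  didx <- seq(1, nd, by = max(1, enum_thin))
  rows <- NULL
  for (tx in base$subset) {
    reduced <- setdiff(base$subset, tx)
    ky_draws <- numeric(0)
    n_ok <- 0
    for (d in didx) {
      pars <- posterior_draw(ps, d)
      ss_b <- steady_state(pars, base$subset, active)
      if (ss_b$degenerate || !ss_b$feasible ||
          !is_stable(pars, base$subset, ss_b$x)) next
      if (!length(reduced)) {  # removing the sole member: no survivors
        n_ok <- n_ok + 1
        ky_draws <- c(ky_draws, 0)
        next
      }
      ss_r <- steady_state(pars, reduced, active)
      if (ss_r$degenerate || !ss_r$feasible ||
          !is_stable(pars, reduced, ss_r$x)) next
      n_ok <- n_ok + 1
      surv <- match(reduced, base$subset)
      ky_draws <- c(ky_draws, sqrt(sum((ss_b$x[surv] - ss_r$x)^2)))
    }
    stable_after <- n_ok / length(didx) > stability_threshold
    rows <- rbind(rows, data.frame(
      taxon = ps$taxa[tx],
      Ky = if (stable_after) median(ky_draws) else NA_real_,
      stable_after_removal = stable_after,
      in_baseline = TRUE))
  }
  for (tx in setdiff(seq_along(ps$taxa), base$subset))
    rows <- rbind(rows, data.frame(taxon = ps$taxa[tx], Ky = NA_real_,
                                   stable_after_removal = NA,
                                   in_baseline = FALSE))
  rows <- rows[order(-xtfrm(rows$Ky), rows$taxon, na.last = TRUE), ]
  rownames(rows) <- NULL
  attr(rows, "baseline") <- base$members
  rows
}

#' Compare stable-state biodiversity between two regimes
#'
#' Tests the null hypothesis that the numbers of stably coexisting taxa per
#' stable state are equal under two regimes (e.g. two diets) with a
#' two-sample Wilcoxon rank-sum test.
#'
#' For small samples the null distribution of the rank-sum statistic is
#' enumerated exactly (midranks, so ties are handled); larger samples use the
#' usual normal approximation.
#'
#' @param scan_a,scan_b `stability_scan` objects (or numeric vectors of
#'   stable-state sizes).
#' @return List: `statistic` (rank sum of regime A), `p_value` (two-sided),
#'   `sizes_a`, `sizes_b`.
#' @export
compare_regime_biodiversity <- function(scan_a, scan_b) {
  sz <- function(x) if (is.numeric(x)) x else vapply(x, function(r) r$size, 1)
  a <- sz(scan_a); b <- sz(scan_b)
  if (!length(a) || !length(b))
    stop("a regime has zero stable states; cannot compare biodiversity")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  if (choose(n1 + n2, n1) <= 5000) {
    combos <- utils::combn(n1 + n2, n1)
    w_all <- colSums(matrix(r[combos], nrow = n1))
    dev <- abs(w_all - mean(w_all))
    p <- mean(dev >= abs(w_obs - mean(w_all)) - 1e-9)
  } else {
    p <- suppressWarnings(wilcox.test(a, b))$p.value
  }
  list(statistic = w_obs, p_value = p, sizes_a = a, sizes_b = b)
}

#' Write a stability scan as a tidy table
#'
#' @param scan a `stability_scan`.
#' @param path TSV output path.
#' @return The data.frame, invisibly.
#' @export
write_stability_scan <- function(scan, path) {
  df <- do.call(rbind, lapply(scan, function(r)
    data.frame(size = r$size, members = paste(r$members, collapse = ","),
               stability_prob = r$stability_prob)))
  if (is.null(df)) df <- data.frame(size = integer(0), members = character(0),
                                    stability_prob = numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
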