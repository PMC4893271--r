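# Extended generalized Lotka-Volterra model: parameters, integration,
# gradient-matching design matrices.

#' Construct a set of gLV parameters
#'
#' The extended gLV model for taxon l is
#' `dx_l/dt = alpha_l x_l + sum_j beta_lj x_l x_j + sum_p gamma_lp x_l u_p(t)`,
#' with growth rates `alpha` (1/day), pairwise interactions `beta`
#' (1/(day * concentration)) and perturbation effects `gamma` (1/day) switched
#' by binary indicators `u_p(t)`.
#'
#' @param alpha numeric length-L growth-rate vector.
#' @param beta L x L interaction matrix; `beta[l, j]` is the effect of taxon j
#'   on taxon l.
#' @param gamma L x P perturbation-effect matrix (may have zero columns).
#' @param taxa optional taxon labels.
#' @return An object of class `glv_params`.
#' @export
glv_params <- function(alpha, beta, gamma = NULL, taxa = NULL) {
  L <- length(alpha)
  beta <- matrix(as.numeric(beta), L, L)
  if (is.null(gamma)) gamma <- matrix(numeric(0), L, 0)
  gamma <- matrix(as.numeric(gamma), L)
  if (is.null(taxa)) taxa <- if (!is.null(names(alpha))) names(alpha)
                             else paste0("taxon", seq_len(L))
  structure(list(alpha = setNames(as.numeric(alpha), taxa),
                 beta = structure(beta, dimnames = list(taxa, taxa)),
                 gamma = gamma, taxa = taxa),
            class = "glv_params")
}

#' @export
print.glv_params <- function(x, ...) {
  cat(sprintf("glv_params: L = %d taxa, P = %d perturbation(s)\n",
              length(x$alpha), ncol(x$gamma)))
  invisible(x)
}

#' Effective growth rates under active perturbations
#'
#' Returns `alpha_l + sum_{p in active} gamma_lp`, the net growth rate of each
#' taxon while the listed perturbations are switched on (e.g. growth plus
#' susceptibility to a low-fiber diet).
#'
#' @param params a [glv_params()] object.
#' @param active integer/logical index of active perturbations (default none).
#' @return Numeric vector of length L.
#' @export
net_growth <- function(params, active = integer(0)) {
  g <- params$alpha
  if (length(active) && ncol(params$gamma) > 0)
    g <- g + rowSums(params$gamma[, active, drop = FALSE])
  g
}

#' Numerically integrate the gLV equations
#'
#' Solves the gLV system with a stiff-capable adaptive integrator (`lsoda`).
#' Perturbation switch points inside the requested window are inserted as
#' integration breakpoints so the discontinuous indicators never straddle a
#' solver step. Concentrations are clipped at zero; a taxon at exactly zero
#' stays at zero. States exceeding `blowup_factor` times the largest initial
#' concentration abort integration with a flagged failure rather than
#' returning silent NaNs.
#'
#' @param params a [glv_params()] object.
#' @param x0 non-negative initial concentration vector (length L).
#' @param t_grid increasing vector of output days.
#' @param schedules list of [perturbation_schedule()]s (one per gamma column).
#' @param subject subject id used to look up schedule intervals.
#' @param events optional data.frame `(time, taxon, add)` of concentration
#'   doses added at given times (used for invasion challenges).
#' @param rtol,atol solver tolerances.
#' @param blowup_factor divergence threshold (default 1e12).
#' @return `length(t_grid) x L` matrix of concentrations with attributes
#'   `blowup` (logical) and `t_blowup` (time of divergence or `NA`).
#' @export
glv_integrate <- function(params, x0, t_grid, schedules = list(),
                          subject = NULL, events = NULL,
                          rtol = 1e-6, atol = 1e-9, blowup_factor = 1e12) {
  L <- length(params$alpha)
  stopifnot(length(x0) == L, all(x0 >= 0), all(diff(t_grid) > 0))
  cap <- blowup_factor * max(max(x0), 1e-30)

  switch_pts <- numeric(0)
  for (sch in schedules) {
    iv <- if (is.null(subject)) NULL else sch$intervals[[subject]]
    if (!is.null(iv)) switch_pts <- c(switch_pts, iv[is.finite(iv)])
  }
  ev_times <- if (!is.null(events)) events$time else numeric(0)
  ev_times <- ev_times[ev_times >= t_grid[1] & ev_times < t_grid[length(t_grid)]]
  brk <- sort(unique(c(t_grid[1], t_grid[length(t_grid)],
                       switch_pts[switch_pts > t_grid[1] &
                                  switch_pts < t_grid[length(t_grid)]],
                       ev_times)))

  u_at <- function(t) {
    if (length(schedules) == 0) return(numeric(0))
    vapply(schedules, function(sch) {
      iv <- if (is.null(subject)) NULL else sch$intervals[[subject]]
      if (is.null(iv) || nrow(iv) == 0) return(0)
      as.numeric(any(t >= iv[, 1] & t < iv[, 2]))
    }, 1)
  }

  out <- matrix(NA_real_, length(t_grid), L,
                dimnames = list(NULL, params$taxa))
  out[1, ] <- x0
  state <- x0
  blow <- FALSE
  t_blow <- NA_real_

  for (k in seq_len(length(brk) - 1)) {
    a <- brk[k]; b <- brk[k + 1]
    if (!is.null(events)) {
      hit <- which(abs(events$time - a) < 1e-12)
      for (h in hit) {
        j <- if (is.character(events$taxon[h]))
          match(events$taxon[h], params$taxa) else events$taxon[h]
        state[j] <- state[j] + events$add[h]
      }
    }
    u <- u_at(a + (b - a) * 1e-9)  # indicator constant on (a, b)
    geff <- params$alpha + if (length(u)) drop(params$gamma %*% u) else 0
    deriv <- function(t, x, parms) {
      x <- pmax(x, 0)
      list(x * (geff + drop(params$beta %*% x)))
    }
    inner <- sort(unique(c(a, t_grid[t_grid > a & t_grid < b], b)))
    sol <- try(deSolve::ode(y = state, times = inner, func = deriv,
                            parms = NULL, method = "lsoda",
                            rtol = rtol, atol = atol), silent = TRUE)
    bad_row <- NULL
    if (inherits(sol, "try-error") || nrow(sol) < length(inner)) {
      blow <- TRUE
    } else {
      xs <- sol[, -1, drop = FALSE]
      bad <- which(!is.finite(xs) | xs > cap, arr.ind = TRUE)
      if (nrow(bad)) {
        blow <- TRUE
        bad_row <- min(bad[, 1])
      }
    }
    if (blow) {
      t_blow <- if (!is.null(bad_row)) sol[bad_row, 1] else a
      break
    }
    keep <- inner %in% t_grid
    out[match(inner[keep], t_grid), ] <- pmax(xs[keep, , drop = FALSE], 0)
    state <- pmax(xs[nrow(xs), ], 0)
  }
  structure(out, blowup = blow, t_blowup = t_blow)
}

#' Assemble the gradient-matching regression system
#'
#' Gradient matching converts ODE parameter estimation into linear regression:
#' the estimated gradient of taxon l is regressed on the regressors
#' `(f_l, f_l * f_j for all j, f_l * u_p for all p)`, so each row has
#' `1 + L + P` predictors and the coefficient vector is
#' `(alpha_l, beta_l., gamma_l.)`. Rows are grouped by target taxon (the
#' system is block-diagonal across taxa). Grid points where the estimated
#' concentration is not strictly positive contribute no row, so taxa never
#' observed in a subject are simply absent from that subject's block.
#'
#' @param traj a [trajectory_estimate()] supplying `f` and `fprime` per
#'   subject on a grid aligned with the dataset's perturbation schedules.
#' @param ds the `mb_dataset` (supplies subjects and perturbation schedules).
#' @param log_space if `TRUE`, each row is divided by `f_l` (per-capita form);
#'   default `FALSE` matches the concentration-space formulation.
#' @return An object of class `gradient_match_system`: list with `response`,
#'   `predictors`, `taxon`, `subject`, `time`, `L`, `P`, `taxa`.
#' @export
build_gradient_match_system <- function(traj, ds, log_space = FALSE) {
  taxa <- ds$taxa
  L <- length(taxa)
  P <- length(ds$perturbations)
  resp <- numeric(0)
  pred <- NULL
  row_taxon <- integer(0)
  row_subject <- character(0)
  row_time <- numeric(0)
  for (s in ds$subjects) {
    g <- traj$grid[[s]]
    f <- traj$f[[s]]        # L x G
    fp <- traj$fprime[[s]]  # L x G
    if (is.null(g)) stop(sprintf("trajectory estimate lacks subject '%s'", s))
    U <- pert_matrix(ds, s, g)  # P x G
    for (l in seq_len(L)) {
      keep <- which(f[l, ] > 0)
      if (!length(keep)) next
      fl <- f[l, keep]
      X <- cbind(fl, t(f[, keep, drop = FALSE]) * fl,
                 if (P > 0) t(U[, keep, drop = FALSE]) * fl)
      y <- fp[l, keep]
      if (log_space) {
        X <- X / fl
        y <- y / fl
      }
      resp <- c(resp, y)
      pred <- rbind(pred, X)
      row_taxon <- c(row_taxon, rep(l, length(keep)))
      row_subject <- c(row_subject, rep(s, length(keep)))
      row_time <- c(row_time, g[keep])
    }
  }
  colnames(pred) <- c("growth", paste0("beta:", taxa),
                      if (P > 0) paste0("gamma:", names(ds$perturbations)))
  structure(list(response = resp, predictors = pred, taxon = row_taxon,
                 subject = row_subject, time = row_time,
                 L = L, P = P, taxa = taxa),
            class = "gradient_match_system")
}

#' @export
print.gradient_match_system <- function(x, ...) {
  cat(sprintf("gradient_match_system: %d rows, %d predictors (1 + %d + %d)\n",
              length(x$response), 1 + x$L + x$P, x$L, x$P))
  invisible(x)
}

# Map a fitted coefficient vector (1 + L + P) for taxon l into param slots.
unpack_block <- function(theta, l, L, P) {
  list(alpha = theta[1], beta = theta[1 + seq_len(L)],
       gamma = if (P > 0) theta[1 + L + seq_len(P)] else numeric(0))
}

#' Export trajectories as a tidy table
#'
#' @param traj a trajectory estimate.
#' @param path optional TSV output path.
#' @return data.frame with columns subject, taxon, day, concentration,
#'   gradient.
#' @export
trajectory_table <- function(traj, path = NULL) {
  rows <- do.call(rbind, lapply(names(traj$grid), function(s) {
    g <- traj$grid[[s]]
    data.frame(subject = s,
               taxon = rep(rownames(traj$f[[s]]), each = length(g)),
               day = rep(g, times = nrow(traj$f[[s]])),
               concentration = as.vector(t(traj$f[[s]])),
               gradient = as.vector(t(traj$fprime[[s]])))
  }))
  if (!is.null(path))
    write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rows
}
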