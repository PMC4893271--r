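# Shared fixtures, all generated in code.

# Tiny 3-taxa, 2-subject, 4-timepoint dataset with one perturbation.
toy_dataset <- function(pert = TRUE) {
  days <- c(0, 1, 2, 4)
  counts <- list(
    m1 = matrix(c(10, 20, 70, 15, 25, 60, 20, 30, 50, 25, 35, 40), 3, 4,
                dimnames = list(c("A", "B", "C"), NULL)),
    m2 = matrix(c(30, 30, 40, 35, 25, 40, 40, 20, 40, 45, 15, 40), 3, 4,
                dimnames = list(c("A", "B", "C"), NULL)))
  biomass <- list(m1 = c(2, 2.5, 3, 3.5), m2 = c(4, 4, 4, 4))
  perts <- if (pert)
    list(diet = perturbation_schedule("diet",
      list(m1 = cbind(1, 2), m2 = cbind(1, 2)))) else list()
  mb_dataset(counts, biomass, list(m1 = days, m2 = days),
             perturbations = perts)
}

# Deterministic 3-species gLV truth with two interaction edges.
toy_glv <- function() {
  glv_params(c(0.5, 0.4, 0.6),
             matrix(c(-1, 0.6, 0,
                      0, -0.8, -0.5,
                      0, 0, -0.9), 3, 3),
             taxa = c("A", "B", "C"))
}

# Noise-free multi-subject trajectory estimate from a gLV truth, with exact
# gradients from the model right-hand side.
exact_trajectories <- function(params, x0s, t_grid) {
  grid <- f <- fp <- list()
  for (s in seq_along(x0s)) {
    id <- sprintf("s%d", s)
    tr <- glv_integrate(params, x0s[[s]], t_grid)
    fm <- t(tr)
    grid[[id]] <- t_grid
    f[[id]] <- fm
    fp[[id]] <- fm * (params$alpha + params$beta %*% fm)
  }
  trajectory_estimate(grid, f, fp)
}

# Minimal dataset shim for build_gradient_match_system when only subjects,
# taxa and perturbations are needed.
ds_shim <- function(traj, taxa, perturbations = list()) {
  list(subjects = names(traj$grid), taxa = taxa,
       perturbations = perturbations)
}

# Short-chain Bayesian config for tests.
test_bayes <- function(seed, iterations = 2500, burnin = 500, thin = 10)
  list(iterations = iterations, burnin = burnin, thin = thin, seed = seed)
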