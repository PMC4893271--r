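# Replicated high-signal fixture: noise-free trajectories from a known system
# with small relative gradient noise, plus the matching count dataset.
high_signal_fixture <- function(seed, L3 = TRUE, depth = 25000,
                                grid = seq(0, 20, 0.25), n_subj = 5,
                                noise = 0.02) {
  set.seed(seed)
  p <- if (L3) toy_glv() else
    glv_params(c(0.5, 0.4), matrix(c(-1, 0.6, 0, -0.8), 2, 2),
               taxa = c("A", "B"))
  L <- length(p$alpha)
  x0s <- lapply(seq_len(n_subj), function(s) runif(L, 0.05, 1.5))
  traj <- exact_trajectories(p, x0s, grid)
  counts <- biomass <- times <- list()
  for (s in names(traj$f)) {
    conc <- traj$f[[s]]
    prop <- sweep(conc, 2, colSums(conc), "/")
    Y <- round(prop * depth)
    Y[Y == 0] <- 1
    counts[[s]] <- Y
    biomass[[s]] <- colSums(conc)
    times[[s]] <- grid
  }
  ds <- mb_dataset(counts, biomass, times, taxa = p$taxa)
  for (s in names(traj$fprime)) {
    fp <- traj$fprime[[s]]
    traj$fprime[[s]] <- fp * (1 + matrix(rnorm(length(fp), 0, noise),
                                         nrow(fp)))
  }
  list(truth = p,
       sys = build_gradient_match_system(traj, ds_shim(traj, p$taxa)),
       ds = ds)
}

test_that("retained-draw accounting matches the chain schedule", {
  expect_equal(retained_draws(25000, 2500, 20), 1125)  # = 22500 / 20
  expect_equal(retained_draws(300, 100, 10), 20)
  fx <- high_signal_fixture(1, L3 = FALSE)
  fit <- fit_bal(fx$sys, test_bayes(1, iterations = 300, burnin = 100,
                                    thin = 10))
  expect_equal(nrow(fit$alpha), 20)
})

test_that("BAL recovers a strongly informative fixture with coverage", {
  fx <- high_signal_fixture(2, n_subj = 8, noise = 0.01)
  fit <- suppressWarnings(fit_bal(fx$sys, test_bayes(3, iterations = 4000,
                                                     burnin = 1000)))
  med <- posterior_median_params(fit)
  scale_b <- sqrt(mean(fx$truth$beta^2))
  expect_lt(max(abs(med$alpha - fx$truth$alpha)) /
              sqrt(mean(fx$truth$alpha^2)), 0.02)
  expect_lt(max(abs(med$beta - fx$truth$beta)) / scale_b, 0.02)
  # 95% credible intervals cover the true interactions
  for (l in 1:3) for (j in 1:3) {
    ci <- quantile(fit$beta[, l, j], c(0.025, 0.975))
    expect_true(fx$truth$beta[l, j] >= ci[1] - 1e-6 &&
                fx$truth$beta[l, j] <= ci[2] + 1e-6)
  }
})

test_that("a prior-only run centers off-diagonal interactions at zero", {
  fx <- high_signal_fixture(3, L3 = FALSE)
  fit <- suppressWarnings(
    fit_bal(fx$sys, c(test_bayes(4), list(likelihood_weight = 0))))
  off <- fit$beta[, 1, 2]
  expect_lt(abs(median(off)), 0.5)
  expect_gt(mean(off > 0), 0.3)  # roughly symmetric about zero
  expect_lt(mean(off > 0), 0.7)
  # truncations still respected
  expect_true(all(fit$alpha > 0))
  expect_true(all(fit$beta[, 1, 1] < 0))
})

test_that("BVS finds the true edge and rejects the null on a 2-taxon system", {
  fx <- high_signal_fixture(10, L3 = FALSE)
  fit <- suppressWarnings(fit_bvs(fx$sys, test_bayes(2)))
  ev <- edge_evidence(fit)
  expect_gt(ev$pip[2, 1], 0.95)  # true edge beta_21 = 0.6
  expect_lt(ev$pip[1, 2], 0.5)   # absent reverse edge
})

test_that("BAL and BVS agree on a high-signal fixture", {
  fx <- high_signal_fixture(4)
  bal <- suppressWarnings(fit_bal(fx$sys, test_bayes(5)))
  bvs <- suppressWarnings(fit_bvs(fx$sys, test_bayes(5)))
  scale_b <- sqrt(mean(fx$truth$beta^2))
  expect_lt(max(abs(apply(bal$beta, c(2, 3), mean) -
                    apply(bvs$beta, c(2, 3), mean))) / scale_b, 0.05)
})

test_that("pi0 = 1 degenerates BVS to an all-edges model", {
  fx <- high_signal_fixture(5, L3 = FALSE)
  fit <- suppressWarnings(
    fit_bvs(fx$sys, c(test_bayes(6, iterations = 500, burnin = 100),
                      list(pi0 = 1))))
  expect_true(all(fit$z_beta == 1L))
})

test_that("indicator arrays have one entry per candidate edge", {
  # L = 13, P = 1: 13 x 12 interaction indicators + 13 perturbation ones
  L <- 13
  set.seed(9)
  n <- 60
  X <- matrix(rnorm(n * (1 + L + 1)), n)
  sys <- structure(list(response = rnorm(n), predictors = X,
                        taxon = rep(1L, n), subject = rep("s", n),
                        time = seq_len(n), L = L, P = 1,
                        taxa = paste0("t", 1:L)),
                   class = "gradient_match_system")
  fit <- suppressWarnings(
    fit_bvs(sys, test_bayes(7, iterations = 200, burnin = 50, thin = 10)))
  expect_equal(dim(fit$z_beta)[2:3], c(13, 13))
  expect_equal(dim(fit$z_gamma)[2:3], c(13, 1))
  off <- !diag(TRUE, 13)
  expect_equal(sum(off), 13 * 12)
  expect_true(all(fit$z_beta[, 1, 1] == 1L))  # self always included
})

test_that("Bayes factors follow the posterior-odds identity", {
  mk <- function(pip, n = 1100, pi0 = 0.5) {
    z <- array(0L, c(n, 2, 2))
    z[, 1, 2] <- rep(c(1L, 0L), round(c(pip * n, (1 - pip) * n)))
    z[, 2, 1] <- 1L
    z[, 1, 1] <- z[, 2, 2] <- 1L
    ps <- list(alpha = matrix(1, n, 2), beta = array(0, c(n, 2, 2)),
               gamma = array(0, c(n, 2, 0)), z_beta = z,
               z_gamma = array(0L, c(n, 2, 0)), method = "bvs",
               taxa = c("A", "B"), meta = list(pi0 = pi0))
    class(ps) <- "glv_posterior"
    ps
  }
  ev <- edge_evidence(mk(0.5))
  expect_equal(ev$bf[1, 2], 1)
  ev2 <- edge_evidence(mk(10 / 11))
  expect_equal(ev2$bf[1, 2], 10, tolerance = 1e-9)
  expect_true(ev2$strong[1, 2])
  # pip = 1 gets the capped lower bound n * (1 - pi0) / pi0
  ev3 <- edge_evidence(mk(1))
  expect_equal(ev3$bf[1, 2], 1100)
  expect_true(ev3$capped[1, 2])
  # strictly increasing in pip
  pips <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  bfs <- vapply(pips, function(p) edge_evidence(mk(p))$bf[1, 2], 1)
  expect_true(all(diff(bfs) > 0))
  expect_error(edge_evidence(mk(0.5, pi0 = 1)), "strictly inside")
  expect_error(edge_evidence(fit_bal(high_signal_fixture(1, L3 = FALSE)$sys,
                                     test_bayes(1, 300, 100, 10))),
               "BVS posterior")
})

test_that("network scores have the documented ranges and structure", {
  fx <- high_signal_fixture(6, L3 = FALSE)
  bvs <- suppressWarnings(fit_bvs(fx$sys, test_bayes(8, 500, 100, 10)))
  sc <- network_scores("bvs", bvs)
  expect_true(all(is.na(diag(sc))))
  expect_true(all(sc[!is.na(sc)] >= 0 & sc[!is.na(sc)] <= 1))
  mlf <- fit_mlcrr(fx$sys, ridge_penalty(0.01, 0.01))
  scm <- network_scores("mlcrr", mlf)
  expect_true(all(scm[!is.na(scm)] >= 0))
  # spearman: perfectly monotone co-varying pair scores 1 both ways
  days <- 0:9
  Y <- matrix(c(rep(1L, 10), 2L^(0:9), rev(2L^(0:9))), 3, 10, byrow = TRUE,
              dimnames = list(c("flat", "up", "down"), NULL))
  dsm <- mb_dataset(list(s = Y), list(s = rep(1, 10)), list(s = days))
  ssc <- network_scores("spearman", ds = dsm)
  expect_equal(ssc["up", "down"], 1)
  expect_equal(ssc["down", "up"], 1)
  expect_equal(ssc["up", "flat"], 0)  # constant series flagged to zero
  # mismatched fit and method
  expect_error(network_scores("bvs", mlf), "BVS posterior")
  expect_error(network_scores("mlcrr", bvs), "glv_params")
  expect_error(network_scores("nope", mlf), "unknown method")
})

test_that("relabeling taxa permutes posterior summaries consistently", {
  fx <- high_signal_fixture(7)
  fit1 <- suppressWarnings(fit_bvs(fx$sys, test_bayes(9, 800, 200, 10)))
  perm <- c(2, 3, 1)
  sys2 <- fx$sys
  # permute predictor beta-columns and relabel row taxa
  inv <- order(perm)
  sys2$predictors <- fx$sys$predictors[, c(1, 1 + inv), drop = FALSE]
  sys2$taxon <- perm[fx$sys$taxon]
  ord <- order(sys2$taxon)
  sys2$taxon <- sys2$taxon[ord]
  sys2$predictors <- sys2$predictors[ord, ]
  sys2$response <- fx$sys$response[ord]
  sys2$taxa <- fx$sys$taxa[inv]
  fit2 <- suppressWarnings(fit_bvs(sys2, test_bayes(9, 800, 200, 10)))
  m1 <- apply(fit1$beta, c(2, 3), median)
  m2 <- apply(fit2$beta, c(2, 3), median)
  expect_equal(m2[perm[1], perm[2]], m1[1, 2], tolerance = 0.1)
  expect_equal(m2[perm[2], perm[1]], m1[2, 1], tolerance = 0.1)
})
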