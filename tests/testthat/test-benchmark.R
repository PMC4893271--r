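test_that("Dirichlet-multinomial draws close to the right moments", {
  set.seed(14)
  p <- c(0.5, 0.3, 0.15, 0.05)
  n <- 500
  # first moment: expected counts = depth x proportion
  Y <- rdirmult(n, 1000, p, dispersion = 1 / 800)
  expect_equal(rowMeans(Y) / 1000, p, tolerance = 0.02)
  expect_true(all(colSums(Y) == 1000))  # compositional closure
  # dispersion -> 0 recovers multinomial variance; positive dispersion
  # inflates it by (depth + precision) / (1 + precision)
  Y0 <- rdirmult(n, 1000, p, dispersion = 0)
  v_mult <- 1000 * p * (1 - p)
  expect_equal(apply(Y0, 1, var), v_mult, tolerance = 0.25)
  infl <- (1000 + 800) / (1 + 800)
  expect_equal(mean(apply(Y, 1, var) / v_mult), infl, tolerance = 0.35)
  # zero-probability taxa never get counts
  Yz <- rdirmult(50, 500, c(0.7, 0.3, 0), dispersion = 1 / 100)
  expect_true(all(Yz[3, ] == 0))
})

test_that("accepted ground-truth systems respect constraints and the filter", {
  reg <- simulation_regime(seed = 101)
  truth <- generate_ground_truth(reg)
  expect_true(all(truth$alpha > 0))
  expect_true(all(diag(truth$beta) < 0))
  expect_true(steady_state(truth)$feasible)
  expect_gte(attr(truth, "cv_pass_frac"), 0.75)
  # a system pinned at its fixed point (no displacement) has CV 0 and is
  # rejected by the filter
  regfp <- simulation_regime(ic_logmin = 0, ic_logmax = 1e-9, seed = 102)
  expect_error(generate_ground_truth(regfp, max_reject = 3), "rejected")
})

test_that("interaction density matches the 20% edge probability", {
  set.seed(15)
  fracs <- vapply(1:30, function(i) {
    reg <- simulation_regime(seed = 4000 + i)
    truth <- generate_ground_truth(reg)
    off <- row(truth$beta) != col(truth$beta)
    mean(truth$beta[off] != 0)
  }, 1)
  # binomial sampling of 90 ordered pairs per system, 30 systems
  expect_equal(mean(fracs), 0.2, tolerance = 0.03)
})

test_that("simulated datasets carry the invader and the design days", {
  reg <- simulation_regime(n_timepoints = 12, depth = 1000, seed = 103)
  truth <- generate_ground_truth(reg)
  sim <- simulate_dataset(truth, reg)
  ds <- sim$dataset
  expect_equal(length(ds$subjects), 10)
  expect_equal(length(sim$days), 12)
  expect_true(0 %in% sim$days && 30 %in% sim$days &&
              10 %in% sim$days)  # invasion day covered
  expect_true(all(vapply(ds$readdepth, function(r) all(r == 1000), TRUE)))
  # invader (last taxon) is absent before the invasion day
  pre <- sim$days < 10
  for (s in ds$subjects)
    expect_true(all(sim$truth_traj[[s]][reg$L, pre] == 0))
  # and present afterwards
  post <- sim$days > 10
  expect_true(all(sim$truth_traj[[ds$subjects[1]]][reg$L, post] > 0))
})

test_that("AUC follows the midrank convention and the hand example", {
  # identity and anti-identity
  truth <- c(1, 0, 1, 0)
  expect_equal(auc_roc(c(0.9, 0.1, 0.8, 0.2), truth), 1)
  expect_equal(auc_roc(c(0.1, 0.9, 0.2, 0.8), truth), 0)
  # hand example: pairs (e1 true 0.9, e2 false 0.8, e3 true 0.4, e4 false 0.1)
  expect_equal(auc_roc(c(0.9, 0.8, 0.4, 0.1), c(1, 0, 1, 0)), 0.75)
  # ties get half credit
  expect_equal(auc_roc(c(0.5, 0.5), c(1, 0)), 0.5)
  # one-class labels are undefined
  expect_true(is.na(auc_roc(c(0.2, 0.4), c(1, 1))))
  # brute-force pair-counting oracle on random data
  set.seed(16)
  sc <- runif(50)
  lab <- rbinom(50, 1, 0.4)
  pairs <- expand.grid(i = which(lab == 1), j = which(lab == 0))
  brute <- mean(ifelse(sc[pairs$i] > sc[pairs$j], 1,
                       ifelse(sc[pairs$i] == sc[pairs$j], 0.5, 0)))
  expect_equal(auc_roc(sc, lab), brute)
})

test_that("inference scoring returns the four benchmark metrics", {
  truth <- toy_glv()
  m <- score_inference(truth, truth, abs(truth$beta) + 0, 0.3)
  expect_equal(m$rmse_growth, 0)
  expect_equal(m$rmse_interaction, 0)
  expect_equal(m$auc, 1)
  expect_equal(m$rmse_trajectory, 0.3)
  # scores equal to 1 - truth indicator give AUC 0
  off <- row(truth$beta) != col(truth$beta)
  anti <- 1 - (abs(truth$beta) > 0)
  expect_equal(score_inference(truth, NULL, anti)$auc, 0)
})

test_that("spearman baseline matches the rank-formula hand computation", {
  # x = 1,2,3,4 vs y = 2,1,4,3: rho = 0.6
  Y <- matrix(c(10, 20, 30, 40, 20, 10, 40, 30, 5, 5, 5, 5), 3, 4,
              byrow = TRUE, dimnames = list(c("x", "y", "z"), NULL))
  # biomass equal to read depth so concentrations equal raw counts
  ds <- mb_dataset(list(s = Y), list(s = colSums(Y)), list(s = 0:3))
  sc <- spearman_baseline(ds)
  expect_equal(sc["x", "y"], 0.6, tolerance = 1e-9)
  expect_equal(sc["y", "x"], 0.6, tolerance = 1e-9)
  expect_equal(sc["x", "z"], 0)  # constant series flagged to 0
  expect_true(attr(sc, "constant")["z"])
  # independent noise scores low
  set.seed(17)
  Yn <- matrix(rpois(200, 100), 2, 100,
               dimnames = list(c("a", "b"), NULL))
  dsn <- mb_dataset(list(s = Yn), list(s = colSums(Yn)), list(s = 1:100))
  expect_lt(spearman_baseline(dsn)["a", "b"], 0.3)
})

test_that("the study-design guideline reproduces its worked example", {
  expect_equal(recommend_min_timepoints(13, 5), 17L)
  expect_equal(recommend_min_timepoints(2, 1), 2L)
  expect_equal(recommend_min_timepoints(10, 10), 5L)
  expect_error(recommend_min_timepoints(0, 5), "positive")
})

test_that("hold-one-subject-out forecasting is accurate on clean dense data", {
  # two identical noise-free subjects, dense sampling, dosing event known
  p <- toy_glv()
  xstar <- steady_state(p)$x
  days <- seq(0, 15, 0.25)
  x0 <- xstar * c(2, 0.5, 0)  # invader (taxon 3) introduced later
  dose <- 0.05
  tr <- glv_integrate(p, x0, days,
                      events = data.frame(time = 5, taxon = 3, add = dose))
  conc <- t(tr)
  prop <- sweep(conc, 2, colSums(conc), "/")
  Y <- round(prop * 200000)
  Y[Y == 0 & prop > 0] <- 1
  rownames(Y) <- p$taxa
  ev <- data.frame(time = 5, taxon = 3, add = dose)
  ds <- mb_dataset(list(s1 = Y, s2 = Y),
                   list(s1 = colSums(conc), s2 = colSums(conc)),
                   list(s1 = days, s2 = days),
                   taxa = p$taxa, events = list(s1 = ev, s2 = ev))
  res <- holdout_forecast(ds, "mlcrr",
                          list(lambdas = ridge_penalty(1e-6, 1e-6)))
  expect_equal(nrow(res), 2)
  expect_true(all(res$rmse < 0.05))
  # forecasting the training subject itself is optimistic on average
  fit <- infer_glv(ds, "mlcrr", list(lambdas = ridge_penalty(1e-6, 1e-6)))
  self_rmse <- vapply(ds$subjects, function(s)
    microdyn:::forecast_rmse(fit, ds, s), 1)
  expect_lte(mean(self_rmse), mean(res$rmse) + 0.01)
  # RMSE of identical trajectories is zero
  expect_equal(microdyn:::log10_rmse(matrix(1:4, 2), matrix(1:4, 2)), 0)
})

test_that("benchmark replicates are reproducible under a fixed master seed", {
  reg <- simulation_regime(L = 4, subjects = 3, n_timepoints = 8,
                           depth = 1000, seed = 106)
  r1 <- run_benchmark_regime(reg, c("mlcrr", "spearman"), n_replicates = 2)
  r2 <- run_benchmark_regime(reg, c("mlcrr", "spearman"), n_replicates = 2)
  expect_identical(r1, r2)
  expect_equal(sort(unique(r1$method)), c("mlcrr", "spearman"))
  expect_equal(nrow(r1), 2 * 2 * 4)  # replicates x methods x metrics
  # constrained fits never violate the sign constraints
  sub <- subset(r1, method == "mlcrr" & metric == "rmse_growth")
  expect_true(all(is.finite(sub$value)))
})
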