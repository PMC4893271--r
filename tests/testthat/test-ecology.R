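test_that("steady states solve the interior fixed-point system", {
  p <- glv_params(c(1, 2), diag(c(-1, -1)))
  expect_equal(unname(steady_state(p)$x), c(1, 2))  # decoupled capacities
  p2 <- glv_params(c(1, 1), matrix(c(-1, 0.5, 0, -1), 2, 2))
  expect_equal(unname(steady_state(p2)$x), c(1, 1.5))
  p3 <- glv_params(c(1, 1), matrix(c(-1, -2, -2, -1), 2, 2))
  ss3 <- steady_state(p3)
  expect_equal(unname(ss3$x), c(1 / 3, 1 / 3))
  expect_true(ss3$feasible)
  # singular interaction submatrix is degenerate, not infeasible
  p4 <- glv_params(c(1, 1), matrix(c(-1, -1, 1, 1), 2, 2))
  ss4 <- steady_state(p4)
  expect_true(ss4$degenerate)
  # infeasible: a negative component
  p5 <- glv_params(c(1, -2), diag(c(-1, -1)))
  expect_false(steady_state(p5)$feasible)
  expect_false(steady_state(p5)$degenerate)
})

test_that("Jacobian stability matches hand eigenvalues and long-run dynamics", {
  # diagonal beta with negative entries: stable
  p <- glv_params(c(1, 2), diag(c(-1, -1)))
  expect_true(is_stable(p, 1:2, steady_state(p)$x))
  # symmetric competitive case: J = diag(1/3) beta has eigenvalues -1, +1/3
  p3 <- glv_params(c(1, 1), matrix(c(-1, -2, -2, -1), 2, 2))
  x3 <- steady_state(p3)$x
  ev <- eigen(diag(x3) %*% p3$beta)$values
  expect_equal(sort(Re(ev)), c(-1, 1 / 3), tolerance = 1e-12)
  expect_false(is_stable(p3, 1:2, x3))

  # classifier agrees with integration from perturbed starts on random systems
  set.seed(12)
  tested <- 0
  while (tested < 20) {
    alpha <- rlnorm(3, log(0.5), 0.4)
    beta <- matrix(rnorm(9, 0, 0.4), 3, 3)
    diag(beta) <- -rlnorm(3, log(0.8), 0.3)
    p <- glv_params(alpha, beta)
    ss <- steady_state(p)
    if (ss$degenerate || !ss$feasible) next
    tested <- tested + 1
    stable <- is_stable(p, 1:3, ss$x)
    x0 <- ss$x * (1 + runif(3, -0.01, 0.01))
    tr <- glv_integrate(p, x0, seq(0, 400, length.out = 81))
    if (isTRUE(attr(tr, "blowup"))) {
      expect_false(stable)
      next
    }
    drift_end <- max(abs(tr[81, ] - ss$x) / ss$x)
    if (stable) expect_lt(drift_end, 0.01) else expect_gt(drift_end, 0.01)
  }
})

test_that("sub-community enumeration counts and filters correctly", {
  p <- toy_glv()
  scan <- enumerate_subcommunities(p, stability_threshold = 0)
  expect_equal(attr(scan, "n_examined"), 7)  # 2^3 - 1
  # point estimates give stability probabilities of exactly 0 or 1
  probs <- vapply(scan, function(r) r$stability_prob, 1)
  expect_true(all(probs %in% c(0, 1)))
  # the full community of this fixture is stable
  sizes <- vapply(scan, function(r) r$size, 1)
  expect_true(3 %in% sizes[probs == 1])
  # threshold filtering is monotone
  n_hi <- length(enumerate_subcommunities(p, stability_threshold = 0.9))
  expect_lte(n_hi, length(scan))
  expect_error(enumerate_subcommunities(
    glv_params(rep(1, 21), diag(-1, 21))), "20 taxa")
})

test_that("sub-community steady states agree with long-time integration", {
  set.seed(13)
  p <- toy_glv()
  for (subset in list(1, c(1, 2), c(2, 3), 1:3)) {
    ss <- steady_state(p, subset)
    if (!ss$feasible || !is_stable(p, subset, ss$x)) next
    sub <- glv_params(p$alpha[subset], p$beta[subset, subset, drop = FALSE])
    x0 <- ss$x * runif(length(subset), 0.5, 2)
    tr <- glv_integrate(sub, x0, seq(0, 300, length.out = 61))
    expect_equal(unname(tr[61, ]), unname(ss$x), tolerance = 1e-4)
  }
})

test_that("invasion challenges behave like the underlying dynamics", {
  # empty sub-community: single-species invader grows to carrying capacity
  p <- glv_params(c(0.8, 0.5), matrix(c(-1, 0, 0, -2), 2, 2))
  out <- challenge_invasion(p, integer(0), invader = 1, dose = 0.01,
                            horizon = 50)
  expect_equal(out$median, 0.8, tolerance = 1e-3)  # -alpha / beta_ll
  # dose zero stays zero
  out0 <- challenge_invasion(p, 2, invader = 1, dose = 0, horizon = 20)
  expect_equal(out0$median, 0)
  # invader with negative net growth and no support decays below its dose
  pneg <- glv_params(c(0.6, -0.3),
                     matrix(c(-1, 0, -0.2, -0.5), 2, 2))
  outn <- challenge_invasion(pneg, 1, invader = 2, dose = 1e5, horizon = 28)
  expect_lt(outn$median, 1e5)
})

test_that("exclusion ranking picks the most inhibitory stable community", {
  # invader C; taxon B inhibits C strongly, taxon A does not
  p <- glv_params(c(1, 1, 0.5),
                  matrix(c(-1, 0, 0,
                           0, -1, -0.9,
                           0, 0, -1), 3, 3, byrow = TRUE),
                  taxa = c("A", "B", "C"))
  # note: beta rows are target taxa; C is inhibited by B (beta_cb = -0.9)
  p$beta <- matrix(c(-1, 0, 0,
                     0, -1, 0,
                     0, -0.9, -1), 3, 3, byrow = TRUE,
                   dimnames = list(p$taxa, p$taxa))
  tab <- rank_exclusion_communities(p, invader = "C", dose = 0.01,
                                    horizon = 60, stability_threshold = 0)
  expect_equal(nrow(tab), 2)  # sizes 1 and 2
  expect_equal(tab$members[tab$size == 1], "B")
  expect_lt(tab$cdi_median[tab$size == 2], 0.5)  # C suppressed below capacity
})

test_that("keystoneness reproduces the hand example and its invariances", {
  p2 <- glv_params(c(1, 1), matrix(c(-1, 0.5, 0, -1), 2, 2),
                   taxa = c("sp1", "sp2"))
  ky <- keystoneness(p2)
  expect_equal(ky$Ky[ky$taxon == "sp1"], 0.5)  # sp2 shifts 1.5 -> 1
  expect_equal(ky$Ky[ky$taxon == "sp2"], 0)
  expect_equal(ky$taxon[1], "sp1")  # ranked descending
  # decoupled community: removing any taxon leaves the others unchanged
  pd <- glv_params(c(1, 2, 0.5), diag(c(-1, -0.5, -1)))
  kyd <- keystoneness(pd)
  expect_true(all(kyd$Ky == 0))
  # invariant to taxon ordering
  perm <- c(2, 1)
  p2p <- glv_params(p2$alpha[perm], p2$beta[perm, perm],
                    taxa = p2$taxa[perm])
  kyp <- keystoneness(p2p)
  expect_equal(kyp$Ky[kyp$taxon == "sp1"], 0.5)
  expect_equal(kyp$Ky[kyp$taxon == "sp2"], 0)
})

test_that("regime biodiversity comparison uses the exact rank-sum test", {
  same <- compare_regime_biodiversity(c(2, 3, 3, 4), c(3, 2, 4, 3))
  expect_gt(same$p_value, 0.5)
  # disjoint {1,1,1} vs {5,5,5}: the most extreme of choose(6,3) = 20
  # orderings on each side -> two-sided p = 2/20
  apart <- compare_regime_biodiversity(c(1, 1, 1), c(5, 5, 5))
  expect_equal(apart$p_value, 0.1, tolerance = 1e-9)
  one <- compare_regime_biodiversity(1, 2)
  expect_true(one$p_value > 0 && one$p_value <= 1)
  expect_error(compare_regime_biodiversity(numeric(0), c(1, 2)),
               "zero stable states")
})
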