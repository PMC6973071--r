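# Karplus forward model and pseudorotation grid inversion.

test_that("karplus_j evaluates the three-term relation", {
  co <- c(7.3, -1.1, 0.4)
  expect_equal(karplus_j(90, co), co[3], tolerance = 1e-12)
  expect_equal(karplus_j(0, co), sum(co), tolerance = 1e-12)
  expect_equal(karplus_j(180, co), co[1] - co[2] + co[3], tolerance = 1e-12)
})

test_that("predict_couplings composes the pucker and Karplus models", {
  par <- test_karplus_params()
  # constant model: J independent of (P, tau_m)
  pc <- par[par$path == "H1'-H2'", ]
  pc$A <- 0; pc$B <- 0; pc$C <- 5; pc$a <- 1; pc$b <- 0
  class(pc) <- class(par)
  for (P in c(0, 77, 240)) {
    expect_equal(predict_couplings(P, 38, pc)$J_Hz, 5, tolerance = 1e-12)
  }
  # planar ring: all torsions zero, J fixed at theta = b
  p0 <- predict_couplings(123, 0, par)
  expect_equal(p0$J_Hz,
               vapply(seq_len(nrow(par)), function(i)
                 karplus_j(par$b[i], unlist(par[i, c("A", "B", "C")])),
                 numeric(1)),
               tolerance = 1e-9)
  # slope of J(F2'-H1') changes sign across the sweep where cos(theta) is
  # extremal (brute-force curve from the forward model)
  Ps <- seq(0, 180, by = 1)
  J <- vapply(Ps, function(P)
    predict_couplings(P, 38, par, "F2'-H1'")$J_Hz, numeric(1))
  expect_gt(length(rle(sign(diff(J)))$lengths), 1)
})

test_that("simulation is seeded, truncated and unbiased", {
  par <- test_karplus_params()
  s0 <- simulate_couplings(55, 35, par, noise_sd = 0, seed = 9)
  expect_equal(s0$J_Hz, predict_couplings(55, 35, par)$J_Hz,
               tolerance = 1e-12)
  s1 <- simulate_couplings(55, 35, par, noise_sd = 0.3, seed = 42)
  s2 <- simulate_couplings(55, 35, par, noise_sd = 0.3, seed = 42)
  expect_identical(s1, s2)
  expect_true(all(s1$J_Hz >= 0))
  # CLT: 1e4 draws of one path, sample mean within 3 SE of the prediction
  jp <- predict_couplings(55, 35, par, "F2'-H3'")$J_Hz
  draws <- vapply(seq_len(1e4), function(s)
    simulate_couplings(55, 35, par, 0.3, seed = s, paths = "F2'-H3'")$J_Hz,
    numeric(1))
  expect_lt(abs(mean(draws) - jp), 3 * 0.3 / sqrt(1e4))
})

test_that("zero-noise inversion recovers every node of a coarse lattice", {
  par <- test_karplus_params()
  grid <- list(P = seq(0, 358, by = 2), tau = seq(25, 45, by = 1))
  for (P in seq(0, 350, by = 30)) {
    for (tau in c(26, 34, 42)) {
      obs <- simulate_couplings(P, tau, par, noise_sd = 0, seed = 1)
      fit <- fit_pseudorotation(obs, par, grid = grid)
      expect_lte(quadfold:::.angdiff(fit$best$P, P), 2, label = sprintf(
        "P recovery at (%g, %g)", P, tau))
      expect_lte(abs(fit$best$tau_m - tau), 1, label = sprintf(
        "tau recovery at (%g, %g)", P, tau))
    }
  }
})

test_that("noisy inversion recovers P within noise propagation bounds", {
  # Monte-Carlo recovery oracle: median |P_best - P_true| over 100 seeds
  par <- test_karplus_params()
  err <- vapply(seq_len(100), function(s) {
    obs <- simulate_couplings(55, 35, par, noise_sd = 0.3, seed = s)
    fit <- fit_pseudorotation(obs, par, k = 1)
    quadfold:::.angdiff(fit$best$P, 55)
  }, numeric(1))
  # 0.3 Hz on couplings with |dJ/dP| >~ 0.2 Hz/deg maps to a few degrees
  expect_lt(median(err), 5)
  expect_lt(mean(err <= 10), 1.01)  # sanity: errors are bounded
})

test_that("compatibility criterion behaves as documented", {
  par <- test_karplus_params()
  obs <- simulate_couplings(55, 35, par, noise_sd = 0.3, seed = 6)
  # compatible set shrinks monotonically as k decreases
  sizes <- vapply(c(3, 2, 1, 0.5), function(k)
    sum(fit_pseudorotation(obs, par, k = k)$compatible), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  # k = 0 on noisy data: nothing is compatible, flag raised, best node kept
  f0 <- fit_pseudorotation(obs, par, k = 0)
  expect_true(f0$no_solution_at_k)
  expect_identical(length(f0$P_intervals), 0L)
  expect_lt(quadfold:::.angdiff(f0$best$P, 55), 10)
  # chisq invariant under path relabeling (row order)
  f1 <- fit_pseudorotation(obs, par)
  f2 <- fit_pseudorotation(obs[rev(seq_len(nrow(obs))), ], par)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-12)
})

test_that("degenerate observations yield disjoint compatible intervals", {
  par <- test_karplus_params()
  # a single H1'-H2' observation at P = 54 has nu1 ~ 0; the same torsion (and
  # coupling) recurs near P = 234, so two disjoint arcs must be reported
  obs <- predict_couplings(54, 36, par, paths = "H1'-H2'")
  obs$sigma_Hz <- 0.3
  fit <- fit_pseudorotation(obs, par, k = 1)
  expect_gte(length(fit$P_intervals), 2)
  # intervals are reported separately, never silently merged
  widths <- vapply(fit$P_intervals, function(iv) iv["hi"] - iv["lo"],
                   numeric(1))
  expect_true(all(widths < 180))
})
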