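# Superposition, ensemble RMSD, distances, ring proximity, pucker survey.

test_that("superpose recovers rigid motions and rejects degeneracy", {
  set.seed(7)
  A <- matrix(rnorm(60), 20, 3)
  s <- superpose(A, A)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)

  R <- quadfold:::.rotmat(c(2, -1, 1), 71)
  t0 <- c(3, 4, -5)
  B <- sweep(A %*% t(R), 2, t0, "+")
  s2 <- superpose(A, B)
  expect_equal(s2$rmsd, 0, tolerance = 1e-9)
  expect_equal(s2$rotation, R, tolerance = 1e-9)
  expect_equal(s2$translation, t0, tolerance = 1e-9)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-12)

  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line), "degenerate")
})

test_that("rmsd is symmetric and zero for identical models", {
  ens <- perturb_ensemble(build_quadruplex(g4_preset("parallel")), 4, 0,
                          seed = 1)
  st <- ensemble_rmsd(ens, "all", "pairwise")
  expect_equal(st$rmsd_mean, 0, tolerance = 1e-9)
  ens2 <- perturb_ensemble(build_quadruplex(g4_preset("parallel")), 4, 0.3,
                           seed = 2)
  st2 <- ensemble_rmsd(ens2, "all", "pairwise")
  expect_equal(st2$rmsd_matrix, t(st2$rmsd_matrix), tolerance = 1e-9)
  expect_true(all(diag(st2$rmsd_matrix) == 0))
})

test_that("pairwise rmsd of isotropic noise matches the analytic value", {
  # closed-form oracle: per-atom difference of two noisy copies has variance
  # 6 sigma^2, so E[RMSD] ~ sqrt(6) sigma for many atoms (superposition
  # absorbs a vanishing share of DOF)
  sigma <- 0.5
  ens <- perturb_ensemble(build_quadruplex(g4_preset("parallel")), 10, sigma,
                          seed = 31)
  st <- ensemble_rmsd(ens, "all", "pairwise")
  expect_lt(abs(st$rmsd_mean - sqrt(6) * sigma) / (sqrt(6) * sigma), 0.1)
})

test_that("to-mean rmsd never exceeds pairwise rmsd", {
  for (seed in 1:3) {
    ens <- perturb_ensemble(build_quadruplex(g4_preset("parallel")), 6, 0.4,
                            seed = seed)
    p <- ensemble_rmsd(ens, "all", "pairwise")$rmsd_mean
    m <- ensemble_rmsd(ens, "all", "to_mean")$rmsd_mean
    expect_lte(m, p + 1e-9)
  }
})

test_that("rmsd metrics are invariant under a global rigid motion", {
  ens <- perturb_ensemble(build_quadruplex(g4_preset("vloop-ODN1415")), 4,
                          0.2, seed = 3)
  moved <- apply_rigid(ens, angle = 67, shift = c(10, 0, -4))
  expect_equal(ensemble_rmsd(ens, "all", "pairwise")$rmsd_mean,
               ensemble_rmsd(moved, "all", "pairwise")$rmsd_mean,
               tolerance = 1e-9)
})

test_that("interproton distance statistics are plain Euclidean distances", {
  ens <- perturb_ensemble(build_quadruplex(g4_preset("parallel")), 3, 0,
                          seed = 1)
  a <- ens$atoms
  # fixed synthetic pair 3.0 A apart in every model
  probe <- a[a$atom %in% c("H8", "H1'") & a$seq_index == 1, ]
  st <- interproton_distance_stats(
    ens, list(seq_index = 1, atom = "H8"), list(seq_index = 1, atom = "H1'"))
  d0 <- quadfold:::.vnorm(unlist(probe[probe$atom == "H8",
                                       c("x", "y", "z")][1, ]) -
                          unlist(probe[probe$atom == "H1'",
                                       c("x", "y", "z")][1, ]))
  expect_equal(st$min, d0, tolerance = 1e-9)
  expect_equal(st$max, d0, tolerance = 1e-9)
  expect_identical(length(st$per_model), 3L)
  expect_false(st$rebuilt_a)

  # two-model pair at 2.0 / 4.0 A
  b <- a[a$model %in% 1:2, ]
  sel <- b$atom == "H8" & b$seq_index == 1 & b$model == 2
  b$x[sel] <- b$x[b$atom == "H1'" & b$seq_index == 1 & b$model == 2] + 4
  b$y[sel] <- b$y[b$atom == "H1'" & b$seq_index == 1 & b$model == 2]
  b$z[sel] <- b$z[b$atom == "H1'" & b$seq_index == 1 & b$model == 2]
  sel1 <- b$atom == "H8" & b$seq_index == 1 & b$model == 1
  b$x[sel1] <- b$x[b$atom == "H1'" & b$seq_index == 1 & b$model == 1] + 2
  b$y[sel1] <- b$y[b$atom == "H1'" & b$seq_index == 1 & b$model == 1]
  b$z[sel1] <- b$z[b$atom == "H1'" & b$seq_index == 1 & b$model == 1]
  st2 <- interproton_distance_stats(
    structure_ensemble(b), list(seq_index = 1, atom = "H8"),
    list(seq_index = 1, atom = "H1'"))
  expect_equal(c(st2$min, st2$mean, st2$max), c(2, 3, 4), tolerance = 1e-9)
})

test_that("missing protons are rebuilt from heavy atoms and flagged", {
  ens <- build_quadruplex(g4_preset("parallel"))
  a <- ens$atoms
  ref <- a[a$atom == "H8" & a$seq_index == 1, c("x", "y", "z")]
  a2 <- a[!(a$atom == "H8" & a$seq_index == 1), ]
  ens2 <- structure_ensemble(a2)
  st <- interproton_distance_stats(
    ens2, list(seq_index = 1, atom = "H8"), list(seq_index = 1, atom = "H1'"))
  expect_true(st$rebuilt_a)
  r <- get_residue(ens2, 1, 1)
  reb <- quadfold:::.rebuild_proton(r, "H8")
  expect_lt(quadfold:::.vnorm(reb - unlist(ref)), 0.2)
})

test_that("ring proximity reports distance, height and the in-plane flag", {
  nt <- build_nucleotide(18, 38, -120, "G")
  bp <- base_plane(nt)
  mk <- function(p) {
    X <- rbind(nt$atoms, PRB = p)
    df <- data.frame(model = 1L, chain = "A",
                     seq_index = c(rep(1L, nrow(nt$atoms)), 2L),
                     res_name = c(rep("DG", nrow(nt$atoms)), "XYZ"),
                     atom = rownames(X),
                     element = substr(rownames(X), 1, 1),
                     x = X[, 1], y = X[, 2], z = X[, 3],
                     stringsAsFactors = FALSE)
    suppressWarnings(normalize_nomenclature(structure_ensemble(df)))
  }
  above <- mk(bp$centroid6 + 2 * bp$normal)
  r1 <- ring_proximity(above, list(seq_index = 2, atom = "PRB"), 1)
  expect_equal(r1$dist_A, 2, tolerance = 1e-9)
  expect_equal(abs(r1$height_A), 2, tolerance = 1e-9)
  expect_false(r1$in_plane)

  # in-plane direction: use an in-plane unit vector
  e1 <- quadfold:::.vunit(nt$atoms["N1", ] - bp$centroid6)
  inpl <- mk(bp$centroid6 + 3 * e1)
  r2 <- ring_proximity(inpl, list(seq_index = 2, atom = "PRB"), 1)
  expect_equal(r2$dist_A, 3, tolerance = 1e-6)
  expect_equal(r2$height_A, 0, tolerance = 1e-6)
  expect_true(r2$in_plane)
})

test_that("V-loop pucker survey reproduces the generating anchors", {
  spec <- g4_preset("vloop-ODN1415")
  spec$core$P[spec$core$seq_index == 14] <- 20
  spec$core$P[spec$core$seq_index == 15] <- 55
  ens <- perturb_ensemble(build_quadruplex(spec), 3, 0.02, seed = 8)
  sv <- survey_vloop_puckers(list(ens))
  expect_identical(nrow(sv), 6L)
  pre <- sv[sv$role == "preceding_vloop", ]
  post <- sv[sv$role == "following_vloop", ]
  expect_true(all(pre$seq_index == 14))
  expect_true(all(post$seq_index == 15))
  expect_true(all(abs(pre$P_deg - 20) < 10))
  expect_true(all(abs(post$P_deg - 55) < 10))

  # ensembles without a V-loop are skipped with a warning
  par_ens <- build_quadruplex(g4_preset("parallel"))
  expect_warning(sv2 <- survey_vloop_puckers(list(par_ens)), "skipped")
  expect_identical(nrow(sv2), 0L)
})
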