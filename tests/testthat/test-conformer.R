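# Glycosidic torsion, base planes, pseudo-hydrogen bonds.

test_that("constructed nucleotides return their exact glycosidic torsion", {
  for (chi in c(60, -120, 75, -45)) {
    nt <- build_nucleotide(18, 38, chi, "G", "deoxy")
    g <- glycosidic_chi(nt)
    expect_lt(quadfold:::.angdiff(g$chi, chi), 0.1)
  }
  expect_identical(glycosidic_chi(build_nucleotide(18, 38, 60))$cls, "syn")
  expect_identical(glycosidic_chi(build_nucleotide(18, 38, -120))$cls, "anti")
})

test_that("chi classification is total with documented boundary handling", {
  expect_identical(classify_chi(0), "syn")        # closed at 0
  expect_identical(classify_chi(90), "syn")       # closed at +90
  expect_identical(classify_chi(-90), "high-anti")# closed at -90
  expect_identical(classify_chi(-0.001), "high-anti")
  expect_identical(classify_chi(90.001), "anti")  # wrap side
  expect_identical(classify_chi(180), "anti")
  expect_identical(classify_chi(-180), "anti")    # wraps to +180
  expect_identical(classify_chi(-120), "anti")
  for (chi in seq(-179.5, 180, by = 0.5)) {
    expect_true(classify_chi(chi) %in% c("syn", "anti", "high-anti"))
  }
  # config-overridable ranges
  expect_identical(classify_chi(100, list(syn = c(0, 110),
                                          high_anti = c(-90, 0))), "syn")
})

test_that("chi is invariant under rigid motion", {
  ens <- build_quadruplex(g4_preset("parallel"))
  moved <- apply_rigid(ens)
  r1 <- get_residue(ens, 1, 6)
  r2 <- get_residue(moved, 1, 6)
  expect_lt(quadfold:::.angdiff(glycosidic_chi(r1)$chi,
                                glycosidic_chi(r2)$chi), 1e-9)
})

test_that("base_plane fits planar templates exactly and rotates covariantly", {
  nt <- build_nucleotide(18, 38, -120, "G")
  bp <- base_plane(nt)
  expect_lt(bp$max_residual, 1e-6)
  expect_equal(quadfold:::.vnorm(bp$normal), 1, tolerance = 1e-12)
  R <- quadfold:::.rotmat(c(1, -1, 2), 49)
  nt2 <- nt
  nt2$atoms <- nt$atoms %*% t(R)
  bp2 <- base_plane(nt2)
  # normal rotates identically (up to sign of the fit)
  d <- abs(sum(bp2$normal * as.vector(R %*% bp$normal)))
  expect_equal(d, 1, tolerance = 1e-9)
  # non-planar ring reports its residual
  nt3 <- nt
  nt3$atoms["N1", 3] <- nt3$atoms["N1", 3] + 0.4
  expect_gt(base_plane(nt3)$max_residual, 0.1)
})

test_that("pseudo-hydrogen-bond screening applies geometric cutoffs", {
  # constructed donor-H...F triple: N at origin, H on x, F beyond
  mk <- function(fx, fy) {
    data.frame(model = 1L, chain = "A",
               seq_index = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L),
               res_name = "DG",
               atom = c("N1", "H1", "F2'", "O4'", "C1'", "C2'", "C3'", "C4'"),
               element = c("N", "H", "F", "O", "C", "C", "C", "C"),
               x = c(0, 1.0, fx, 20, 21, 22, 23, 24),
               y = c(0, 0, fy, 0, 0, 0, 0, 0),
               z = 0, stringsAsFactors = FALSE)
  }
  pos <- structure_ensemble(mk(3.0, 0))   # H...F = 2.0 A, angle 180
  hb <- detect_pseudo_hbonds(pos)
  expect_identical(nrow(hb), 1L)
  expect_equal(hb$dist_A, 2.0, tolerance = 1e-9)
  expect_false(hb$no_H[1])
  neg <- structure_ensemble(mk(4.2, 0))   # H...F = 3.2 A
  expect_identical(nrow(detect_pseudo_hbonds(neg)), 0L)
  # angle criterion: H...F 2.0 A but D-H...A angle 90 deg
  bent <- structure_ensemble(mk(1.0, 2.0))
  expect_identical(nrow(detect_pseudo_hbonds(bent)), 0L)

  # no hydrogens: heavy-atom fallback with flag
  noH <- pos
  noH$atoms <- noH$atoms[noH$atoms$element != "H", ]
  hb2 <- detect_pseudo_hbonds(structure_ensemble(noH$atoms))
  expect_identical(nrow(hb2), 1L)
  expect_true(all(hb2$no_H))
  expect_false(is.null(attr(hb2, "cutoffs")))
})
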