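# Tetrad, stacking, column, groove, loop and V-loop detection.

test_that("ideal synthetic tetrads give exactly four edges forming a cycle", {
  spec <- g4_preset("parallel")
  spec$core <- spec$core[spec$core$layer == 0, ]
  spec$senses <- 1
  spec$sequence <- spec$sequence
  ens <- build_quadruplex(spec)
  edges <- detect_hoogsteen_pairs(ens)
  expect_identical(nrow(edges), 4L)
  cyc <- detect_tetrads(edges)
  expect_identical(length(cyc), 1L)
  expect_identical(canonical_cycle(cyc[[1]]), "1>5>9>13")
  expect_true(all(edges$d_N1O6 < 3.2 & edges$d_N2N7 < 3.2))

  # displacing one base breaks the cycle
  a <- ens$atoms
  mv <- a$seq_index == 5
  a$x[mv] <- a$x[mv] + 5
  broken <- structure_ensemble(a)
  e2 <- detect_hoogsteen_pairs(broken)
  expect_identical(nrow(e2), 2L)
  expect_identical(length(detect_tetrads(e2)), 0L)
})

test_that("detect_tetrads handles degenerate edge graphs", {
  # a directed 3-cycle has no tetrad
  e3 <- data.frame(donor_seq = c(1L, 2L, 3L), acceptor_seq = c(2L, 3L, 1L),
                   chain = "A", d_N1O6 = 2.9, d_N2N7 = 2.9,
                   plane_angle_deg = 0)
  expect_identical(length(detect_tetrads(e3)), 0L)
  # a residue shared between two 4-cycles is an ambiguity error
  e8 <- data.frame(
    donor_seq = c(1L, 2L, 3L, 4L, 4L, 5L, 6L, 7L),
    acceptor_seq = c(2L, 3L, 4L, 1L, 5L, 6L, 7L, 4L),
    chain = "A", d_N1O6 = 2.9, d_N2N7 = 2.9, plane_angle_deg = 0)
  expect_error(detect_tetrads(e8), "more than one tetrad")
})

test_that("stacking polarity reflects relative cycle senses", {
  ens <- build_quadruplex(g4_preset("parallel"))
  topo <- analyze_topology(ens)
  expect_identical(topo$stack$interfaces, c("homopolar", "homopolar"))

  # reversing the middle layer's sense makes both interfaces heteropolar
  spec <- g4_preset("parallel")
  spec$senses <- c(1, -1, 1)
  spec$core$chi[spec$core$layer == 1] <- 75  # keep chemistry consistent
  ens2 <- build_quadruplex(spec)
  topo2 <- analyze_topology(ens2)
  expect_identical(topo2$stack$interfaces, c("heteropolar", "heteropolar"))
})

test_that("topology is invariant under rigid motion", {
  ens <- build_quadruplex(g4_preset("vloop-ODN1415"))
  t1 <- analyze_topology(ens)
  t2 <- analyze_topology(apply_rigid(ens, angle = 113, shift = c(-8, 2, 30)))
  cyc <- function(t) vapply(t$stack$layers, canonical_cycle, character(1))
  expect_identical(cyc(t1), cyc(t2))
  expect_identical(t1$stack$interfaces, t2$stack$interfaces)
  expect_identical(sort(t1$grooves$label), sort(t2$grooves$label))
  expect_identical(t1$loops$cls, t2$loops$cls)
  expect_identical(t1$vloops[[1]]$turn_locus, t2$vloops[[1]]$turn_locus)
})

test_that("every residue sits in at most one tetrad on all presets", {
  for (nm in c("parallel", "hybrid-ODN", "vloop-ODN1415", "vloop-typeB")) {
    topo <- analyze_topology(build_quadruplex(g4_preset(nm)))
    members <- unlist(topo$tetrads)
    expect_identical(anyDuplicated(members), 0L, label = nm)
    expect_identical(length(topo$columns), 4L, label = nm)
  }
})

test_that("V-loop detection distinguishes the two turn loci", {
  tA <- expect_preset_oracle("vloop-ODN1415")
  vA <- tA$vloops[[1]]
  expect_identical(vA$turn_locus, "within_following_tract")
  expect_identical(vA$pucker5$octant, "north-east")
  expect_identical(vA$pucker3$octant, "north-east")

  tB <- expect_preset_oracle("vloop-typeB")
  vB <- tB$vloops[[1]]
  expect_identical(vB$turn_locus, "between_linked_residues")
  expect_identical(vB$chi3$cls, "syn")
  expect_identical(vB$pucker5$octant, "south")
})

test_that("no-tetrad inputs yield an empty topology, not an error", {
  topo <- analyze_topology(build_random_coil())
  expect_true(topo$empty)
  expect_identical(length(topo$tetrads), 0L)
})
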