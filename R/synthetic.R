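# Synthetic structure generation: furanose rings at prescribed pseudorotation,
# nucleotides at prescribed glycosidic torsion, Hoogsteen tetrads, and complete
# mock quadruplexes from declarative topology specifications.
#
# Loop backbone geometry is schematic (Bezier interpolation): adequate for the
# topology detectors, which read base and phosphate geometry, not loop
# stereochemistry. No central cations are placed; the detectors do not use
# them.

.quadfold_cache <- new.env(parent = emptyenv())

# backbone rotamer used for syn core residues in the quadruplex builder
# (calibrated once so that groove widths of the canonical templates land in
# the documented narrow/medium/wide bands; see the methods vignette)
.syn_backbone <- c(gamma = 190, beta = 20)

.ring_bonds <- data.frame(
  a = c("O4'", "C1'", "C2'", "C3'", "C4'"),
  b = c("C1'", "C2'", "C3'", "C4'", "O4'"),
  len = c(1.414, 1.528, 1.525, 1.523, 1.446),
  stringsAsFactors = FALSE)

#' Build a furanose ring at prescribed pseudorotation
#'
#' Places the five ring atoms with out-of-plane displacements following the
#' cosine model, then refines Cartesian coordinates against standard C-C/C-O
#' bond lengths and the target torsions. The achieved phase angle is within
#' 2 degrees of the request (validated through [pseudorotation()]).
#'
#' @param P target phase angle, degrees.
#' @param tau_m target amplitude, degrees in \[0, 50\].
#' @return list with `coords` (5 x 3 matrix, rownames O4', C1', C2', C3', C4'),
#'   `achieved_P`, `achieved_tau_m`, `closure_residual` (max bond-length
#'   deviation, Angstrom).
#' @export
build_sugar_ring <- function(P, tau_m) {
  stopifnot(tau_m >= 0, tau_m <= 50)
  key <- sprintf("ring|%.4f|%.4f", .wrap360(P), tau_m)
  hit <- .quadfold_cache[[key]]
  if (!is.null(hit)) return(hit)

  nu_t <- torsions_from_pucker(P, tau_m)
  r0 <- mean(.ring_bonds$len) / (2 * sin(pi / 5))
  phi <- .deg2rad(72 * (0:4))
  base_xy <- cbind(r0 * cos(phi), r0 * sin(phi))

  obj <- function(p) {
    X <- matrix(p, 5, 3)
    rownames(X) <- .ring_atoms
    blen <- sqrt(rowSums((X[.ring_bonds$a, ] - X[.ring_bonds$b, ])^2))
    nu <- vapply(.nu_paths, function(pp) {
      dihedral_angle(X[pp[1], ], X[pp[2], ], X[pp[3], ], X[pp[4], ])
    }, numeric(1))
    sum(((blen - .ring_bonds$len) * 50)^2) +
      sum((.angdiff(nu, nu_t) * 0.2)^2)
  }

  # pick the out-of-plane phase offset that best seeds the optimizer
  best <- NULL
  for (delta in seq(0, 324, by = 36)) {
    z <- 0.0065 * tau_m * cos(.deg2rad(P + 144 * (0:4 - 2) + delta))
    X0 <- cbind(base_xy, z)
    v <- obj(as.vector(X0))
    if (is.null(best) || v < best$v) best <- list(X0 = X0, v = v)
  }
  fit <- stats::optim(as.vector(best$X0), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  X <- matrix(fit$par, 5, 3)
  rownames(X) <- .ring_atoms
  colnames(X) <- c("x", "y", "z")
  blen <- sqrt(rowSums((X[.ring_bonds$a, ] - X[.ring_bonds$b, ])^2))
  closure <- max(abs(blen - .ring_bonds$len))
  if (closure > 0.02) {
    stop(sprintf("ring closure did not converge (residual %.4f A)", closure))
  }
  pk <- pseudorotation(ring_torsions(X), planar_tol = 0)
  achieved_P <- if (tau_m < 1) NA_real_ else .wrap360(pk$P_unstable %||% pk$P)
  out <- list(coords = X, achieved_P = achieved_P,
              achieved_tau_m = pk$tau_m, closure_residual = closure)
  .quadfold_cache[[key]] <- out
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ring normal with sign fixed by vertex order (Newell's method)
.ring_normal_ordered <- function(X) {
  n <- c(0, 0, 0)
  m <- nrow(X)
  for (i in seq_len(m)) {
    j <- if (i == m) 1 else i + 1
    n <- n + .vcross(X[i, ], X[j, ])
  }
  .vunit(n)
}

# the two tetrahedral substituent directions at ring atom `center` with ring
# neighbours nb1, nb2; slot A is on the +normal side
.sp3_slots <- function(center, nb1, nb2, normal) {
  u1 <- .vunit(nb1 - center)
  u2 <- .vunit(nb2 - center)
  bis <- -.vunit(u1 + u2)
  perp <- .vunit(.vcross(u1, u2))
  half <- .deg2rad(109.47 / 2)
  dA <- .vunit(bis * cos(half) + perp * sin(half))
  dB <- .vunit(bis * cos(half) - perp * sin(half))
  if (sum(dA * normal) < sum(dB * normal)) {
    tmp <- dA; dA <- dB; dB <- tmp
  }
  list(A = dA, B = dB)
}

# Attach a sugar (ring + substituents + short backbone) to base atoms given in
# global coordinates. `base_xyz` must contain the template atoms including the
# C1X glycosidic marker. Returns a named coordinate matrix for the complete
# nucleotide (base atoms without C1X, plus sugar/backbone).
.attach_sugar <- function(base_xyz, P, tau_m, chi, variant = "deoxy",
                          base_type = "G", gamma = 54, beta = 180) {
  glyN <- if (base_type %in% .purine_bases) "N9" else "N1"
  glyC <- if (base_type %in% .purine_bases) "C4" else "C2"
  ring <- build_sugar_ring(P, tau_m)$coords

  # canonical-frame slot at C1' that carries the base
  nrm <- .ring_normal_ordered(ring)
  sl1 <- .sp3_slots(ring["C1'", ], ring["O4'", ], ring["C2'", ], nrm)
  n9_pos <- base_xyz[glyN, ]
  c1_target <- base_xyz["C1X", ]

  # rigid-place the ring: C1' at the template marker, base slot toward N9
  R1 <- .rot_between(sl1$A, .vunit(n9_pos - c1_target))
  S <- sweep(ring, 2, ring["C1'", ]) %*% t(R1)
  S <- sweep(S, 2, c1_target, "+")

  # set chi by rotating the sugar about the glycosidic bond
  cur <- dihedral_angle(S["O4'", ], S["C1'", ], n9_pos, base_xyz[glyC, ])
  ax <- n9_pos - S["C1'", ]
  rot_about <- function(X, origin, axis, theta) {
    R <- .rotmat(axis, theta)
    sweep(sweep(X, 2, origin) %*% t(R), 2, origin, "+")
  }
  S2 <- rot_about(S, S["C1'", ], ax, chi - cur)
  chk <- dihedral_angle(S2["O4'", ], S2["C1'", ], n9_pos, base_xyz[glyC, ])
  if (.angdiff(chk, chi) > 1e-6) {
    S2 <- rot_about(S, S["C1'", ], ax, -(chi - cur))
  }
  S <- S2

  # decorate: substituents from the tetrahedral slots (slot A = base face)
  nrmg <- .ring_normal_ordered(S)
  if (sum(nrmg * .vunit(n9_pos - S["C1'", ])) < 0) nrmg <- -nrmg
  slots <- function(center, n1, n2) .sp3_slots(S[center, ], S[n1, ], S[n2, ], nrmg)
  add <- list()
  s1 <- slots("C1'", "O4'", "C2'")
  add[["H1'"]] <- S["C1'", ] + 1.09 * s1$B
  s4 <- slots("C4'", "C3'", "O4'")
  add[["C5'"]] <- S["C4'", ] + 1.51 * s4$A
  add[["H4'"]] <- S["C4'", ] + 1.09 * s4$B
  s3 <- slots("C3'", "C2'", "C4'")
  add[["O3'"]] <- S["C3'", ] + 1.42 * s3$B
  add[["H3'"]] <- S["C3'", ] + 1.09 * s3$A
  s2 <- slots("C2'", "C1'", "C3'")
  if (variant == "deoxy") {
    add[["H2'"]] <- S["C2'", ] + 1.09 * s2$B
    add[["H2''"]] <- S["C2'", ] + 1.09 * s2$A
  } else if (variant %in% c("ribo", "LNA")) {
    add[["O2'"]] <- S["C2'", ] + 1.41 * s2$B
    add[["H2'"]] <- S["C2'", ] + 1.09 * s2$A
  } else if (variant == "2F-ribo") {
    add[["F2'"]] <- S["C2'", ] + 1.39 * s2$B
    add[["H2'"]] <- S["C2'", ] + 1.09 * s2$A
  } else if (variant == "2F-arabino") {
    add[["F2'"]] <- S["C2'", ] + 1.39 * s2$A
    add[["H2'"]] <- S["C2'", ] + 1.09 * s2$B
  } else {
    add[["H2'"]] <- S["C2'", ] + 1.09 * s2$B
    add[["H2''"]] <- S["C2'", ] + 1.09 * s2$A
  }
  # short 5' backbone: defaults gamma ~ +54 (gauche+), beta ~ 180
  add[["O5'"]] <- .place_atom(S["C3'", ], S["C4'", ], add[["C5'"]],
                              1.42, 110.5, gamma)
  add[["H5'"]] <- .place_atom(S["C3'", ], S["C4'", ], add[["C5'"]],
                              1.09, 109.5, gamma + 120)
  add[["H5''"]] <- .place_atom(S["C3'", ], S["C4'", ], add[["C5'"]],
                               1.09, 109.5, gamma - 120)
  add[["P"]] <- .place_atom(S["C4'", ], add[["C5'"]], add[["O5'"]],
                            1.59, 120.9, beta)

  keep <- setdiff(rownames(base_xyz), "C1X")
  out <- rbind(base_xyz[keep, , drop = FALSE], S,
               do.call(rbind, add))
  rownames(out) <- c(keep, rownames(S), names(add))
  colnames(out) <- c("x", "y", "z")
  out
}

#' Build a single nucleotide at prescribed conformation
#'
#' The planar base template is attached at C1' with an exact glycosidic
#' dihedral; the 2'-substituent is placed according to the sugar variant
#' (F2' for 2F-ribo/2F-arabino, O2' for ribo, two protons for deoxy).
#'
#' @param P,tau_m sugar pseudorotation target (degrees).
#' @param chi glycosidic torsion (degrees).
#' @param base one of "G", "A", "C", "T".
#' @param variant sugar variant (see [default_aliases()] vocabulary).
#' @return a `g4_residue` (see [get_residue()]) positioned with the base near
#'   the origin in the z = 0 plane.
#' @export
build_nucleotide <- function(P, tau_m, chi, base = "G", variant = "deoxy") {
  stopifnot(base %in% names(.base_templates))
  tmpl <- .base_templates[[base]]
  X <- .attach_sugar(tmpl, P, tau_m, chi, variant, base_type = base)
  out <- list(chain = "A", seq_index = 1L,
              res_name = .variant_resname(base, variant),
              base_type = base, variant = variant, atoms = X)
  class(out) <- "g4_residue"
  out
}

.variant_resname <- function(base, variant) {
  if (base == "G") {
    switch(variant, deoxy = "DG", ribo = "G", `2F-ribo` = "GF2",
           `2F-arabino` = "GFA", LNA = "LNG", "DG")
  } else {
    paste0("D", base)
  }
}

# ---------------------------------------------------------------------------
# Guanine tetrad template: one monomer pose (x, y, theta) such that under
# four-fold symmetry about z the Hoogsteen contacts N1->O6 and N2->N7 to the
# clockwise neighbour (at azimuth -90) are both ~2.9 A, the N1-H1 bond points
# at the acceptor O6, and the glycosidic attachment points outward.
# With the base template facing +z the donor edge runs clockwise as seen from
# +z; build_quadruplex arranges columns clockwise so that unflipped layers
# give donor cycles of increasing column index.
.tetrad_monomer <- function() {
  hit <- .quadfold_cache[["tetrad_monomer"]]
  if (!is.null(hit)) return(hit)
  G <- .base_templates$G
  Rn <- .rotmat(c(0, 0, 1), -90)
  pose <- function(p) {
    R <- .rotmat(c(0, 0, 1), p[3])
    sweep(G %*% t(R), 2, c(p[1], p[2], 0), "+")
  }
  obj <- function(p) {
    M0 <- pose(p)
    M1 <- M0 %*% t(Rn)
    d1 <- .vnorm(M0["N1", ] - M1["O6", ])
    d2 <- .vnorm(M0["N2", ] - M1["N7", ])
    ang <- .angle3(M0["H1", ], M0["N1", ], M1["O6", ])
    rad <- .vnorm(M0["C1X", 1:2])
    (d1 - 2.9)^2 + (d2 - 2.9)^2 + 0.001 * ang^2 + 2 * max(0, 5.2 - rad)^2
  }
  best <- NULL
  starts <- rbind(c(1.5, 3.2, 0), c(3, 3, 45), c(-3, 3, 135), c(4, 0, 90))
  for (th in c(0, 90, 180, 270)) starts <- rbind(starts, c(2, 4, th))
  for (i in seq_len(nrow(starts))) {
    f <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-15))
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (best$value > 0.05) stop("tetrad template optimization failed")
  M0 <- pose(best$par)
  .quadfold_cache[["tetrad_monomer"]] <- M0
  M0
}

# ---------------------------------------------------------------------------
#' Named topology presets for the synthetic generator
#'
#' `"parallel"`: canonical all-anti parallel three-layer fold with three
#' propeller loops. `"hybrid-ODN"`: (3+1) hybrid with propeller, diagonal and
#' lateral loops. `"vloop-ODN1415"`: three-layer fold with two lateral loops,
#' a zero-nucleotide V-loop between residues 14 (syn) and 15 (anti) on
#' adjacent antiparallel columns, and a propeller loop; the backbone turn sits
#' within the following G-tract (inversion between residues 15 and 16).
#' `"vloop-typeB"`: as before but with a syn 3'-anchor, putting the backbone
#' turn between the two V-loop linked residues.
#'
#' @param name preset name.
#' @return a topology specification list (fields: name, sequence, core,
#'   senses, variants, expected) accepted by [build_quadruplex()].
#' @export
g4_preset <- function(name = c("parallel", "hybrid-ODN", "vloop-ODN1415",
                               "vloop-typeB")) {
  name <- match.arg(name)
  P_N <- 18; P_NE <- 55; P_S <- 162; TAU <- 36
  CHI_SYN <- 75; CHI_ANTI <- -120
  core_df <- function(seq_index, column, layer, chi, P, tau_m = TAU) {
    data.frame(seq_index = seq_index, column = column, layer = layer,
               chi = chi, P = P, tau_m = tau_m, stringsAsFactors = FALSE)
  }
  if (name == "parallel") {
    seqs <- strsplit("GGGTGGGTGGGTGGG", "")[[1]]
    core <- core_df(
      seq_index = c(1, 2, 3, 5, 6, 7, 9, 10, 11, 13, 14, 15),
      column = rep(0:3, each = 3),
      layer = rep(0:2, times = 4),
      chi = rep(CHI_ANTI, 12),
      P = rep(P_S, 12))
    spec <- list(name = name, sequence = seqs, core = core,
                 senses = c(1, 1, 1))
    spec$expected <- list(
      n_tetrads = 3,
      cycles = c("1>5>9>13", "2>6>10>14", "3>7>11>15"),
      interfaces = c("homopolar", "homopolar"),
      orientations = c("up", "up", "up", "up"),
      broken = c(FALSE, FALSE, FALSE, FALSE),
      loops = data.frame(cls = rep("propeller", 3),
                         anchor5 = c(3, 7, 11), anchor3 = c(5, 9, 13),
                         n = c(1, 1, 1)),
      grooves_sorted = c("medium", "medium", "medium", "medium"),
      n_vloops = 0)
  } else if (name == "hybrid-ODN") {
    seqs <- strsplit("GGGATGGGACACAGGGGACGGG", "")[[1]]
    core <- rbind(
      core_df(1:3,   0, c(2, 1, 0), CHI_ANTI, P_S),
      core_df(6:8,   1, c(2, 1, 0), CHI_ANTI, P_S),
      core_df(14:16, 3, c(0, 1, 2), CHI_SYN,  P_S),
      core_df(20:22, 2, c(2, 1, 0), CHI_ANTI, P_S))
    spec <- list(name = name, sequence = seqs, core = core,
                 senses = c(1, 1, 1))
    spec$expected <- list(
      n_tetrads = 3,
      interfaces = c("homopolar", "homopolar"),
      orientations = c(up = 3, down = 1),
      loops = data.frame(cls = c("propeller", "diagonal", "lateral"),
                         anchor5 = c(3, 8, 16), anchor3 = c(6, 14, 20),
                         n = c(2, 5, 3)),
      grooves_sorted = c("medium", "medium", "narrow", "wide"),
      n_vloops = 0)
  } else {
    seqs <- strsplit("GGGATGGGACACAGGGGACGGG", "")[[1]]
    anchor3_chi <- if (name == "vloop-typeB") CHI_SYN else CHI_ANTI
    pk14 <- if (name == "vloop-typeB") P_S else P_NE
    pk15 <- if (name == "vloop-typeB") P_S else P_NE
    var14 <- if (name == "vloop-typeB") "deoxy" else "2F-ribo"
    core <- rbind(
      core_df(c(2, 1, 14), 0, c(0, 1, 2),
              c(CHI_ANTI, CHI_SYN, CHI_SYN), c(P_S, P_S, pk14)),
      core_df(6:8, 1, c(0, 1, 2), c(CHI_SYN, CHI_ANTI, CHI_ANTI), P_S),
      core_df(c(20, 21, 22), 2, c(0, 1, 2),
              c(CHI_SYN, CHI_ANTI, CHI_ANTI), P_S),
      core_df(15:17, 3, c(0, 1, 2),
              c(anchor3_chi, CHI_ANTI, CHI_ANTI), c(pk15, P_S, P_S)))
    core$tau_m[core$seq_index %in% c(14, 15)] <- TAU
    spec <- list(name = name, sequence = seqs, core = core,
                 senses = c(1, -1, -1),
                 variants = stats::setNames(rep(var14, 2), c(14, 15)))
    spec$expected <- list(
      n_tetrads = 3,
      cycles = c("2>6>20>15", "1>16>21>7", "14>17>22>8"),
      interfaces = c("heteropolar", "homopolar"),
      orientations = c(up = 1, down = 3),
      broken_columns = 1,
      # intra-column strand inversion: in the type-B variant the turn sits
      # between the two linked residues (different columns), so no
      # within-column inversion exists
      inversion = if (name == "vloop-typeB") integer(0) else c(15, 16),
      loops = data.frame(cls = c("lateral", "lateral", "V", "propeller"),
                         anchor5 = c(2, 8, 14, 17), anchor3 = c(6, 14, 15, 20),
                         n = c(3, 5, 0, 2)),
      grooves_sorted = c("medium", "medium", "narrow", "wide"),
      grooves_vloop = "narrow",
      n_vloops = 1,
      vloop = list(anchor5 = 14, anchor3 = 15, n_intervening = 0,
                   chi5 = if (name == "vloop-typeB") "syn" else "syn",
                   chi3 = if (name == "vloop-typeB") "syn" else "anti",
                   turn_locus = if (name == "vloop-typeB")
                     "between_linked_residues" else "within_following_tract"))
  }
  spec
}

#' Build a mock quadruplex from a topology specification
#'
#' Guanine-tetrad templates are stacked with the given rise and twist;
#' each layer's Hoogsteen cycle sense is set by `spec$senses` (+1/-1; a -1
#' layer is built face-flipped, which reverses the donor cycle as seen along
#' the stack axis). Core nucleotides are attached at their prescribed
#' glycosidic torsion and sugar pucker; the backbone direction of each residue
#' then follows from layer sense and syn/anti class, which is what couples
#' strand orientation to glycosidic conformation. Loop residues are placed on
#' a schematic outward arc.
#'
#' @param spec a topology specification (see [g4_preset()]); fields:
#'   `sequence` (character vector of base letters), `core` (data.frame:
#'   seq_index, column 0..3, layer 0-based, chi degrees, P, tau_m), `senses`
#'   (+1/-1 per layer), optional `variants` (named by seq_index).
#' @param rise inter-tetrad rise, Angstrom.
#' @param twist inter-tetrad twist, degrees.
#' @return a [structure_ensemble] with one model; the generating spec is kept
#'   in `attr(, "spec")`.
#' @export
build_quadruplex <- function(spec, rise = 3.3, twist = 30) {
  seqs <- spec$sequence
  core <- spec$core
  senses <- spec$senses
  nlayer <- max(core$layer) + 1
  stopifnot(length(senses) == nlayer, all(senses %in% c(-1, 1)))
  if (anyDuplicated(core$seq_index) > 0) stop("duplicate core residue in spec")
  if (anyDuplicated(core[, c("column", "layer")]) > 0) {
    stop("unrealizable wiring: column/layer slot assigned twice")
  }
  variants <- spec$variants %||% character(0)

  M0 <- .tetrad_monomer()
  Rz <- function(a) .rotmat(c(0, 0, 1), a)
  # face flip for sense -1 layers: 180 rotation about the in-plane axis
  # through monomer 0's base centroid azimuth, so that flipped layers keep
  # their four base positions vertically aligned with unflipped layers
  cent0 <- colMeans(M0[.purine_sixring, ])
  alpha <- .rad2deg(atan2(cent0[2], cent0[1]))
  flipx <- .rotmat(c(0, 0, 1), 2 * alpha) %*% diag(c(1, -1, -1))

  residues <- list()
  for (i in seq_len(nrow(core))) {
    ci <- core$column[i]; li <- core$layer[i]
    s <- senses[li + 1]
    # columns sit clockwise (azimuth -90 * column); the monomer whose final
    # azimuth matches is m = -c for unflipped layers and m = c for flipped
    m_idx <- if (s == 1) (4 - ci) %% 4 else ci
    Tf <- Rz(-twist * li) %*% (if (s == 1) diag(3) else flipx) %*% Rz(90 * m_idx)
    B <- M0 %*% t(Tf)
    B <- sweep(B, 2, c(0, 0, -rise * li), "+")
    rownames(B) <- rownames(M0)
    var <- variants[as.character(core$seq_index[i])] %||% "deoxy"
    if (is.na(var)) var <- "deoxy"
    is_syn <- classify_chi(core$chi[i]) == "syn"
    bb <- if (is_syn) .syn_backbone else c(gamma = 54, beta = 180)
    X <- .attach_sugar(B, core$P[i], core$tau_m[i], core$chi[i],
                       variant = var, base_type = "G",
                       gamma = bb["gamma"], beta = bb["beta"])
    residues[[as.character(core$seq_index[i])]] <- X
  }

  # schematic loop / non-core residues along an outward arc between anchors
  core_set <- sort(core$seq_index)
  n_res <- length(seqs)
  noncore <- setdiff(seq_len(n_res), core_set)
  if (length(noncore) > 0) {
    runs <- split(noncore, cumsum(c(1, diff(noncore) != 1)))
    for (run in runs) {
      lo <- min(run) - 1; hi <- max(run) + 1
      pa <- if (lo >= 1 && !is.null(residues[[as.character(lo)]]))
        residues[[as.character(lo)]]["O3'", ] else c(12, 0, 2)
      pb <- if (hi <= n_res && !is.null(residues[[as.character(hi)]]))
        residues[[as.character(hi)]]["P", ] else c(12, 0, -2 - rise * nlayer)
      mid <- (pa + pb) / 2
      radial <- mid - c(0, 0, mid[3])
      dir_out <- if (.vnorm(radial) > 1e-6) .vunit(radial) else c(1, 0, 0)
      ctrl <- mid + 7 * dir_out
      k <- length(run)
      for (j in seq_len(k)) {
        t <- j / (k + 1)
        pt <- (1 - t)^2 * pa + 2 * t * (1 - t) * ctrl + t^2 * pb
        base <- seqs[run[j]]
        if (!base %in% names(.base_templates)) base <- "T"
        nt <- build_nucleotide(162, 36, -120, base = base, variant = "deoxy")
        X <- nt$atoms
        out_dir <- .vunit(pt - c(0, 0, pt[3]))
        R <- cbind(.vcross(c(0, 0, 1), out_dir), c(0, 0, 1), out_dir)
        # ensure a proper rotation
        if (det(R) < 0) R[, 1] <- -R[, 1]
        X <- sweep(sweep(X, 2, X["C1'", ]) %*% t(R), 2, pt, "+")
        residues[[as.character(run[j])]] <- X
      }
    }
  }

  rows <- list()
  for (si in seq_len(n_res)) {
    X <- residues[[as.character(si)]]
    if (is.null(X)) next
    base <- seqs[si]
    var <- if (si %in% core_set) (variants[as.character(si)] %||% "deoxy")
           else "deoxy"
    if (is.na(var)) var <- "deoxy"
    nm <- rownames(X)
    if (si == 1) {
      drop <- nm %in% c("P", "O5'", "H5'", "H5''")
      X <- X[!drop, , drop = FALSE]
      nm <- rownames(X)
    }
    elem <- toupper(substr(gsub("[^A-Za-z].*$", "", nm), 1, 1))
    elem[nm == "P"] <- "P"
    rows[[si]] <- data.frame(
      model = 1L, chain = "A", seq_index = si,
      res_name = .variant_resname(base, var),
      atom = nm, element = elem,
      x = X[, 1], y = X[, 2], z = X[, 3],
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  ens <- structure_ensemble(atoms, source_id = spec$name %||% "synthetic-g4")
  ens <- normalize_nomenclature(ens)
  attr(ens, "spec") <- spec
  ens
}

#' Replicate a structure into a noisy ensemble
#'
#' Adds i.i.d. Gaussian displacements to every atom of every generated model.
#'
#' @param ensemble a [structure_ensemble]; its first model is the template.
#' @param n_models number of models to generate (>= 2).
#' @param noise_sd per-coordinate displacement SD, Angstrom (>= 0).
#' @param seed integer seed (reproducible).
#' @return a [structure_ensemble] with `n_models` models.
#' @export
perturb_ensemble <- function(ensemble, n_models, noise_sd, seed = 1) {
  stopifnot(inherits(ensemble, "structure_ensemble"),
            n_models >= 2, noise_sd >= 0)
  a <- ensemble$atoms
  a <- a[a$model == min(a$model), ]
  set.seed(as.integer(seed))
  out <- list()
  for (m in seq_len(n_models)) {
    am <- a
    am$model <- as.integer(m)
    n <- nrow(am)
    am$x <- am$x + stats::rnorm(n, 0, noise_sd)
    am$y <- am$y + stats::rnorm(n, 0, noise_sd)
    am$z <- am$z + stats::rnorm(n, 0, noise_sd)
    out[[m]] <- am
  }
  ens <- structure_ensemble(do.call(rbind, out),
                            source_id = ensemble$source_id)
  attr(ens, "spec") <- attr(ensemble, "spec")
  ens
}

#' Build an unstructured control chain (no quadruplex)
#'
#' Places nucleotides along a wide helical path so that no Hoogsteen contacts
#' form; used as a negative control for the topology detectors.
#'
#' @param n number of residues.
#' @return a single-model [structure_ensemble] of DG residues.
#' @export
build_random_coil <- function(n = 12) {
  rows <- list()
  for (i in seq_len(n)) {
    nt <- build_nucleotide(162, 36, -120, base = "G", variant = "deoxy")
    X <- nt$atoms
    ang <- 40 * i
    pos <- c(15 * cos(.deg2rad(ang)), 15 * sin(.deg2rad(ang)), 6 * i)
    X <- sweep(sweep(X, 2, X["C1'", ]), 2, pos, "+")
    nm <- rownames(X)
    elem <- toupper(substr(gsub("[^A-Za-z].*$", "", nm), 1, 1))
    elem[nm == "P"] <- "P"
    rows[[i]] <- data.frame(model = 1L, chain = "A", seq_index = i,
                            res_name = "DG", atom = nm, element = elem,
                            x = X[, 1], y = X[, 2], z = X[, 3],
                            stringsAsFactors = FALSE)
  }
  ens <- structure_ensemble(do.call(rbind, rows), source_id = "random-coil")
  normalize_nomenclature(ens)
}
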