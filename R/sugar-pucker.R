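# Furanose pseudorotation analysis.
#
# Torsion convention (indices matter: a sign or index slip shifts P by
# multiples of 72 degrees):
#   nu0 = C4'-O4'-C1'-C2'
#   nu1 = O4'-C1'-C2'-C3'
#   nu2 = C1'-C2'-C3'-C4'
#   nu3 = C2'-C3'-C4'-O4'
#   nu4 = C3'-C4'-O4'-C1'
# Phase/amplitude follow the classical pseudorotation treatment:
#   tan P = ((nu4 + nu1) - (nu3 + nu0)) / (2 nu2 (sin 36 + sin 72)),
# with P shifted by 180 when nu2 < 0 and mapped to [0, 360); tau_m = nu2/cos P.
# The forward (cosine) model is nu_j = tau_m * cos(P + 144 (j - 2)).

.ring_atoms <- c("O4'", "C1'", "C2'", "C3'", "C4'")

.nu_paths <- list(
  nu0 = c("C4'", "O4'", "C1'", "C2'"),
  nu1 = c("O4'", "C1'", "C2'", "C3'"),
  nu2 = c("C1'", "C2'", "C3'", "C4'"),
  nu3 = c("C2'", "C3'", "C4'", "O4'"),
  nu4 = c("C3'", "C4'", "O4'", "C1'")
)

#' Endocyclic torsions of a furanose ring
#'
#' Computes the five signed ring torsions nu0..nu4 from the coordinates of the
#' ring atoms O4', C1', C2', C3', C4'.
#'
#' @param residue a residue as returned by [get_residue()], or a numeric matrix
#'   with rownames containing the five ring atom names (columns x, y, z).
#' @return named numeric vector `c(nu0, ..., nu4)` in degrees, each in
#'   (-180, 180].
#' @export
ring_torsions <- function(residue) {
  X <- if (is.matrix(residue)) residue else residue$atoms
  missing <- setdiff(.ring_atoms, rownames(X))
  if (length(missing) > 0) {
    stop("ring atoms missing for sugar analysis: ", paste(missing, collapse = ", "))
  }
  vapply(.nu_paths, function(p) {
    dihedral_angle(X[p[1], ], X[p[2], ], X[p[3], ], X[p[4], ])
  }, numeric(1))
}

#' Forward cosine model: ring torsions from pseudorotation parameters
#'
#' @param P phase angle of pseudorotation, degrees.
#' @param tau_m puckering amplitude, degrees (>= 0).
#' @return named numeric vector nu0..nu4 (degrees).
#' @export
torsions_from_pucker <- function(P, tau_m) {
  stopifnot(tau_m >= 0)
  j <- 0:4
  nu <- tau_m * cos(.deg2rad(P + 144 * (j - 2)))
  names(nu) <- paste0("nu", j)
  nu
}

#' Pseudorotation phase and amplitude from ring torsions
#'
#' Inverts the cosine model. For near-planar rings (tau_m below
#' `planar_tol`) the phase is numerically unstable and is flagged undefined.
#'
#' @param nu numeric vector of five torsions nu0..nu4 (degrees), e.g. from
#'   [ring_torsions()].
#' @param planar_tol amplitude (degrees) below which P is flagged undefined.
#' @return object of class `sugar_pucker`: list with elements `P` (degrees in
#'   \[0, 360), `NA` when undefined), `tau_m` (degrees), `defined` (logical),
#'   `octant` and `canonical` labels, and the input torsions `nu`.
#' @export
pseudorotation <- function(nu, planar_tol = 5) {
  stopifnot(length(nu) == 5)
  nu <- as.numeric(nu)
  if (all(abs(nu) < 1e-12)) {
    out <- list(P = NA_real_, tau_m = 0, defined = FALSE,
                octant = NA_character_, canonical = NA_character_, nu = nu)
    class(out) <- "sugar_pucker"
    return(out)
  }
  s36 <- sin(.deg2rad(36)); s72 <- sin(.deg2rad(72))
  num <- (nu[5] + nu[2]) - (nu[4] + nu[1])
  den <- 2 * nu[3] * (s36 + s72)
  # atan2 absorbs the nu2 < 0 phase shift
  P <- .wrap360(.rad2deg(atan2(num, den)))
  tau_m <- if (abs(cos(.deg2rad(P))) > 1e-8) {
    nu[3] / cos(.deg2rad(P))
  } else {
    num / (2 * sin(.deg2rad(P)) * (s36 + s72))
  }
  defined <- tau_m >= planar_tol
  cls <- if (defined) classify_pucker(P) else
    list(octant = NA_character_, canonical = NA_character_)
  out <- list(P = if (defined) P else NA_real_, tau_m = tau_m,
              defined = defined, octant = cls$octant,
              canonical = cls$canonical, nu = nu)
  if (!defined) out$P_unstable <- P
  class(out) <- "sugar_pucker"
  out
}

#' @export
print.sugar_pucker <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("sugar pucker: P = %.2f deg, tau_m = %.2f deg (%s, %s)\n",
                x$P, x$tau_m, x$octant, x$canonical))
  } else {
    cat(sprintf("sugar pucker: near-planar ring (tau_m = %.2f deg), P undefined\n",
                x$tau_m))
  }
  invisible(x)
}

.octant_labels <- c("north", "north-east", "east", "south-east",
                    "south", "south-west", "west", "north-west")

# the 20 standard 18-degree envelope/twist bins of the pseudorotation wheel,
# centered at P = 0, 18, ..., 342
.canonical_labels <- c(
  "C3'-endo/C2'-exo",  #   0  3T2
  "C3'-endo",          #  18  3E
  "C3'-endo/C4'-exo",  #  36  3T4
  "C4'-exo",           #  54  E4
  "O4'-endo/C4'-exo",  #  72  0T4
  "O4'-endo",          #  90  0E
  "O4'-endo/C1'-exo",  # 108  0T1
  "C1'-exo",           # 126  E1
  "C2'-endo/C1'-exo",  # 144  2T1
  "C2'-endo",          # 162  2E
  "C2'-endo/C3'-exo",  # 180  2T3
  "C3'-exo",           # 198  E3
  "C4'-endo/C3'-exo",  # 216  4T3
  "C4'-endo",          # 234  4E
  "C4'-endo/O4'-exo",  # 252  4T0
  "O4'-exo",           # 270  E0
  "C1'-endo/O4'-exo",  # 288  1T0
  "C1'-endo",          # 306  1E
  "C1'-endo/C2'-exo",  # 324  1T2
  "C2'-exo"            # 342  E2
)

#' Classify a pseudorotation phase angle
#'
#' Octants are 45-degree bins centered on north = 0, north-east = 45, ...;
#' canonical labels are the 20 standard 18-degree envelope/twist bins of the
#' pseudorotation wheel. All bins are half-open (left-closed) so every P maps
#' to exactly one label.
#'
#' @param P phase angle in degrees, any real value (wrapped to \[0, 360)).
#' @return list with `octant` and `canonical` character labels.
#' @export
classify_pucker <- function(P) {
  stopifnot(is.finite(P))
  P <- .wrap360(P)
  oct_idx <- floor(.wrap360(P + 22.5) / 45) + 1
  can_idx <- floor(.wrap360(P + 9) / 18) + 1
  list(octant = .octant_labels[oct_idx], canonical = .canonical_labels[can_idx])
}

#' Per-residue sugar pucker table for an ensemble
#'
#' @param ensemble a [structure_ensemble] object.
#' @param models integer vector of model indices (default: all).
#' @param planar_tol passed to [pseudorotation()].
#' @return data.frame with one row per (model, residue): model, chain,
#'   seq_index, res_name, P_deg, tau_m_deg, defined, octant, canonical.
#'   Residues lacking ring atoms yield NA rows.
#' @export
pucker_table <- function(ensemble, models = NULL, planar_tol = 5) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (is.null(models)) models <- seq_len(n_models(ensemble))
  res <- residue_table(ensemble)
  rows <- list()
  for (m in models) {
    for (i in seq_len(nrow(res))) {
      r <- get_residue(ensemble, m, res$seq_index[i], chain = res$chain[i])
      pk <- tryCatch(pseudorotation(ring_torsions(r), planar_tol = planar_tol),
                     error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        model = m, chain = res$chain[i], seq_index = res$seq_index[i],
        res_name = res$res_name[i],
        P_deg = if (is.null(pk)) NA_real_ else pk$P,
        tau_m_deg = if (is.null(pk)) NA_real_ else pk$tau_m,
        defined = if (is.null(pk)) NA else pk$defined,
        octant = if (is.null(pk)) NA_character_ else pk$octant,
        canonical = if (is.null(pk)) NA_character_ else pk$canonical,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
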