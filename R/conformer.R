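# Glycosidic torsion, base-plane geometry and pseudo-hydrogen-bond screening.

.purine_bases <- c("G", "A")
.pyrimidine_bases <- c("C", "T", "U")
.purine_sixring <- c("N1", "C2", "N3", "C4", "C5", "C6")
.pyrimidine_ring <- c("N1", "C2", "N3", "C4", "C5", "C6")

# default glycosidic class boundaries (degrees); overridable in classify_chi
.default_chi_ranges <- list(syn = c(0, 90), high_anti = c(-90, 0))

#' Classify a glycosidic torsion angle
#'
#' Default ranges: syn for chi in \[0, +90\], high-anti for chi in \[-90, 0),
#' anti otherwise (i.e. \[-180, -90) and the (+90, +180\] wrap side). syn G
#' residues in quadruplexes cluster near +60..80 deg, anti near -120 deg; the
#' high-anti band covers the far high-anti conformers seen at V-loop anchors
#' of some bimolecular folds.
#'
#' @param chi glycosidic torsion in degrees, (-180, 180].
#' @param ranges list with `syn` and `high_anti` closed/half-open intervals.
#' @return one of "syn", "anti", "high-anti".
#' @export
classify_chi <- function(chi, ranges = .default_chi_ranges) {
  stopifnot(is.finite(chi))
  chi <- .wrap180(chi)
  if (chi >= ranges$syn[1] && chi <= ranges$syn[2]) return("syn")
  if (chi >= ranges$high_anti[1] && chi < ranges$high_anti[2]) return("high-anti")
  "anti"
}

#' Glycosidic torsion and conformer class of a residue
#'
#' chi is O4'-C1'-N9-C4 for purines and O4'-C1'-N1-C2 for pyrimidines,
#' IUPAC-signed.
#'
#' @param residue a residue from [get_residue()].
#' @param ranges class boundaries, see [classify_chi()].
#' @return list(chi, cls).
#' @export
glycosidic_chi <- function(residue, ranges = .default_chi_ranges) {
  X <- residue$atoms
  if (residue$base_type %in% .purine_bases) {
    path <- c("O4'", "C1'", "N9", "C4")
  } else {
    path <- c("O4'", "C1'", "N1", "C2")
  }
  missing <- setdiff(path, rownames(X))
  if (length(missing) > 0) {
    stop("atoms missing for glycosidic torsion of residue ",
         residue$seq_index, ": ", paste(missing, collapse = ", "))
  }
  chi <- dihedral_angle(X[path[1], ], X[path[2], ], X[path[3], ], X[path[4], ])
  list(chi = chi, cls = classify_chi(chi, ranges))
}

#' Least-squares base plane of a residue
#'
#' Fits the six-membered ring (purines: N1, C2, N3, C4, C5, C6). The normal is
#' a unit vector; its sign is chosen so it has positive component along +z of
#' the fitting SVD frame — callers that need a stack-consistent orientation
#' should re-sign against the stack axis.
#'
#' @param residue a residue from [get_residue()].
#' @return list(centroid6, normal, max_residual).
#' @export
base_plane <- function(residue) {
  X <- residue$atoms
  ring <- if (residue$base_type %in% .purine_bases) .purine_sixring
          else .pyrimidine_ring
  missing <- setdiff(ring, rownames(X))
  if (length(missing) > 0) {
    stop("six-ring atoms missing for residue ", residue$seq_index, ": ",
         paste(missing, collapse = ", "))
  }
  fit <- .plane_fit(X[ring, , drop = FALSE])
  list(centroid6 = fit$centroid, normal = fit$normal,
       max_residual = fit$max_residual)
}

#' Per-residue glycosidic conformer table
#'
#' @param ensemble a [structure_ensemble].
#' @param models model indices (default all).
#' @param ranges class boundaries, see [classify_chi()].
#' @return data.frame: model, chain, seq_index, res_name, chi_deg, cls.
#' @export
chi_table <- function(ensemble, models = NULL, ranges = .default_chi_ranges) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (is.null(models)) models <- seq_len(n_models(ensemble))
  res <- residue_table(ensemble)
  rows <- list()
  for (m in models) {
    for (i in seq_len(nrow(res))) {
      r <- get_residue(ensemble, m, res$seq_index[i], chain = res$chain[i])
      g <- tryCatch(glycosidic_chi(r, ranges), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        model = m, chain = res$chain[i], seq_index = res$seq_index[i],
        res_name = res$res_name[i],
        chi_deg = if (is.null(g)) NA_real_ else g$chi,
        cls = if (is.null(g)) NA_character_ else g$cls,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Screen for pseudo-hydrogen bonds to 2'-substituents
#'
#' Reports donor-H...acceptor contacts with H...acceptor distance at most
#' `h_dist` and donor-H...acceptor angle at least `dha_angle` (donors: N-H,
#' plus C-H when `ch_donors = TRUE`). When the structure carries no hydrogens,
#' falls back to heavy-atom donor...acceptor distance at most `heavy_dist`
#' and flags each contact `no_H = TRUE`. Intra-residue pairs are ignored.
#' The numeric cutoffs are a package decision (common practice), echoed in the
#' output attributes.
#'
#' @param ensemble a [structure_ensemble].
#' @param acceptors atom names treated as acceptors.
#' @param h_dist,dha_angle,heavy_dist geometric cutoffs (Angstrom, degrees).
#' @param ch_donors include C-H donors.
#' @param models model indices (default all).
#' @return data.frame: model, donor_seq, donor_atom, h_atom, acceptor_seq,
#'   acceptor_atom, dist_A, angle_deg, no_H. Zero rows when no contact found.
#' @export
detect_pseudo_hbonds <- function(ensemble, acceptors = c("F2'", "O2'"),
                                 h_dist = 2.7, dha_angle = 110,
                                 heavy_dist = 3.5, ch_donors = TRUE,
                                 models = NULL) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  if (is.null(models)) models <- seq_len(n_models(ensemble))
  a <- ensemble$atoms
  out <- list()
  for (m in models) {
    am <- a[a$model == m, ]
    acc <- am[am$atom %in% acceptors, ]
    if (nrow(acc) == 0) next
    hyd <- am[am$element == "H", ]
    have_h <- nrow(hyd) > 0
    if (have_h) {
      # map each H to its covalent heavy donor (nearest heavy atom < 1.3 A)
      heavy <- am[am$element %in% c("N", if (ch_donors) "C"), ]
      for (i in seq_len(nrow(hyd))) {
        hx <- c(hyd$x[i], hyd$y[i], hyd$z[i])
        dh <- sqrt((heavy$x - hx[1])^2 + (heavy$y - hx[2])^2 +
                   (heavy$z - hx[3])^2)
        j <- which.min(dh)
        if (length(j) == 0 || dh[j] > 1.3) next
        dn <- heavy[j, ]
        da <- sqrt((acc$x - hx[1])^2 + (acc$y - hx[2])^2 + (acc$z - hx[3])^2)
        for (k in which(da <= h_dist)) {
          if (acc$seq_index[k] == hyd$seq_index[i] &&
              acc$chain[k] == hyd$chain[i]) next
          ang <- .angle3(c(dn$x, dn$y, dn$z), hx,
                         c(acc$x[k], acc$y[k], acc$z[k]))
          if (ang >= dha_angle) {
            out[[length(out) + 1]] <- data.frame(
              model = m, donor_seq = dn$seq_index, donor_atom = dn$atom,
              h_atom = hyd$atom[i], acceptor_seq = acc$seq_index[k],
              acceptor_atom = acc$atom[k], dist_A = da[k], angle_deg = ang,
              no_H = FALSE, stringsAsFactors = FALSE)
          }
        }
      }
    } else {
      don <- am[am$element %in% c("N", if (ch_donors) "C"), ]
      for (k in seq_len(nrow(acc))) {
        ax <- c(acc$x[k], acc$y[k], acc$z[k])
        dd <- sqrt((don$x - ax[1])^2 + (don$y - ax[2])^2 + (don$z - ax[3])^2)
        for (j in which(dd <= heavy_dist & dd > 1.8)) {
          if (don$seq_index[j] == acc$seq_index[k] &&
              don$chain[j] == acc$chain[k]) next
          out[[length(out) + 1]] <- data.frame(
            model = m, donor_seq = don$seq_index[j], donor_atom = don$atom[j],
            h_atom = NA_character_, acceptor_seq = acc$seq_index[k],
            acceptor_atom = acc$atom[k], dist_A = dd[j], angle_deg = NA_real_,
            no_H = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else data.frame(
    model = integer(0), donor_seq = integer(0), donor_atom = character(0),
    h_atom = character(0), acceptor_seq = integer(0),
    acceptor_atom = character(0), dist_A = numeric(0), angle_deg = numeric(0),
    no_H = logical(0), stringsAsFactors = FALSE)
  attr(res, "cutoffs") <- list(h_dist = h_dist, dha_angle = dha_angle,
                               heavy_dist = heavy_dist, ch_donors = ch_donors)
  res
}
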