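# Rigid-body superposition, ensemble RMSD, distance statistics, ring
# proximity, and the V-loop pucker survey.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping `coords_a` onto
#' `coords_b` with minimal RMSD; reflections are excluded.
#'
#' @param coords_a,coords_b n x 3 matched coordinate matrices (n >= 3).
#' @return list(rotation, translation, rmsd).
#' @export
superpose <- function(coords_a, coords_b) {
  A <- as.matrix(coords_a); B <- as.matrix(coords_b)
  stopifnot(ncol(A) == 3, ncol(B) == 3)
  if (nrow(A) != nrow(B)) stop("coordinate lists must have equal length")
  if (nrow(A) < 3) stop("need at least 3 points")
  sv <- svd(sweep(A, 2, colMeans(A)))
  if (sv$d[2] < 1e-8) stop("degenerate (collinear) point set")
  .kabsch(A, B)
}

# resolve an atom selection to a per-model coordinate matrix
# selection: "all" (heavy atoms), "protons", list(seq_index=, atoms=regex,
# heavy=TRUE/FALSE)
.resolve_selection <- function(ensemble, selection) {
  a <- ensemble$atoms
  keep <- rep(TRUE, nrow(a))
  if (is.character(selection) && length(selection) == 1) {
    if (selection == "all") {
      keep <- a$element != "H"
    } else if (selection == "protons") {
      keep <- a$element == "H"
    } else {
      stop("unknown selection keyword: ", selection)
    }
  } else if (is.list(selection)) {
    if (!is.null(selection$seq_index)) {
      keep <- keep & a$seq_index %in% selection$seq_index
    }
    if (!is.null(selection$atoms)) {
      keep <- keep & grepl(selection$atoms, a$atom)
    }
    if (isTRUE(selection$heavy) || is.null(selection$heavy)) {
      keep <- keep & a$element != "H"
    }
  } else {
    stop("selection must be a keyword or a list")
  }
  sel <- a[keep, ]
  if (nrow(sel) == 0) stop("selection matches no atoms")
  key <- paste(sel$chain, sel$seq_index, sel$atom, sep = "|")
  models <- sort(unique(a$model))
  ref_keys <- key[sel$model == models[1]]
  mats <- lapply(models, function(m) {
    sm <- sel[sel$model == m, ]
    km <- paste(sm$chain, sm$seq_index, sm$atom, sep = "|")
    if (!identical(sort(km), sort(ref_keys))) {
      stop("selection does not resolve identically in every model")
    }
    X <- as.matrix(sm[match(ref_keys, km), c("x", "y", "z")])
    rownames(X) <- ref_keys
    X
  })
  names(mats) <- models
  mats
}

# seq indices of the tetrad ("core") guanines, from model-1 topology
.core_selection <- function(ensemble) {
  topo <- analyze_topology(ensemble, model = 1)
  if (isTRUE(topo$empty)) stop("no tetrad core found for 'core' selection")
  sort(unlist(topo$tetrads))
}

#' Ensemble RMSD statistics
#'
#' `pairwise`: mean over all model pairs of the superposed RMSD. `to_mean`:
#' models are iteratively superposed onto the running mean structure until the
#' mean RMSD changes by less than 1e-6 A. The convention in use is echoed in
#' the result.
#'
#' @param ensemble a [structure_ensemble].
#' @param selection "all" (heavy atoms), "core" (heavy atoms of the tetrad
#'   guanines, detected on model 1), or a list (see details in
#'   `.resolve_selection`).
#' @param mode "pairwise" or "to_mean".
#' @return list: selection, mode, rmsd_mean, rmsd_matrix (pairwise mode),
#'   n_atoms.
#' @export
ensemble_rmsd <- function(ensemble, selection = "all",
                          mode = c("pairwise", "to_mean")) {
  mode <- match.arg(mode)
  if (identical(selection, "core")) {
    selection <- list(seq_index = .core_selection(ensemble), heavy = TRUE)
  }
  mats <- .resolve_selection(ensemble, selection)
  M <- length(mats)
  if (mode == "pairwise") {
    rm <- matrix(0, M, M)
    if (M > 1) {
      for (i in seq_len(M - 1)) for (j in (i + 1):M) {
        r <- .kabsch(mats[[i]], mats[[j]])$rmsd
        rm[i, j] <- r; rm[j, i] <- r
      }
    }
    mean_r <- if (M > 1) mean(rm[upper.tri(rm)]) else 0
    return(list(selection = selection, mode = mode, rmsd_mean = mean_r,
                rmsd_matrix = rm, n_atoms = nrow(mats[[1]])))
  }
  ref <- mats[[1]]
  prev <- Inf
  for (it in seq_len(100)) {
    fitted <- lapply(mats, function(X) {
      k <- .kabsch(X, ref)
      sweep(X %*% t(k$rotation), 2, k$translation, "+")
    })
    newref <- Reduce(`+`, fitted) / M
    rmsds <- vapply(fitted, function(X) sqrt(mean(rowSums((X - newref)^2))),
                    numeric(1))
    cur <- mean(rmsds)
    if (abs(prev - cur) < 1e-6) break
    prev <- cur
    ref <- newref
  }
  list(selection = selection, mode = mode, rmsd_mean = cur,
       rmsd_per_model = rmsds, n_atoms = nrow(mats[[1]]))
}

# geometric proton reconstruction for a few named protons, used when a
# queried proton is absent from the deposition
.rebuild_proton <- function(residue, name) {
  X <- residue$atoms
  have <- rownames(X)
  sp3 <- function(center, n1, n2, pick = "B") {
    nrm <- .ring_normal_ordered(X[intersect(.ring_atoms, have), , drop = FALSE])
    s <- .sp3_slots(X[center, ], X[n1, ], X[n2, ], nrm)
    X[center, ] + 1.09 * (if (pick == "A") s$A else s$B)
  }
  if (name == "H8" && all(c("C8", "N7", "N9") %in% have)) {
    d <- -.vunit(.vunit(X["N7", ] - X["C8", ]) + .vunit(X["N9", ] - X["C8", ]))
    return(X["C8", ] + 1.08 * d)
  }
  if (name %in% c("H1'", "H2'", "H2''", "H3'", "H4'")) {
    ok <- all(.ring_atoms %in% have)
    if (!ok) return(NULL)
    nrm <- .ring_normal_ordered(X[.ring_atoms, ])
    glyN <- intersect(c("N9", "N1"), have)
    if (length(glyN) > 0 &&
        sum(nrm * .vunit(X[glyN[1], ] - X["C1'", ])) < 0) nrm <- -nrm
    # slot A faces the base
    pickfor <- c("H1'" = "B", "H2'" = "B", "H2''" = "A", "H3'" = "A",
                 "H4'" = "B")
    ctr <- c("H1'" = "C1'", "H2'" = "C2'", "H2''" = "C2'", "H3'" = "C3'",
             "H4'" = "C4'")[name]
    nb <- list("C1'" = c("O4'", "C2'"), "C2'" = c("C1'", "C3'"),
               "C3'" = c("C2'", "C4'"), "C4'" = c("C3'", "O4'"))[[ctr]]
    s <- .sp3_slots(X[ctr, ], X[nb[1], ], X[nb[2], ], nrm)
    return(X[ctr, ] + 1.09 * (if (pickfor[name] == "A") s$A else s$B))
  }
  NULL
}

#' Distance statistics between two named atoms across an ensemble
#'
#' Simple per-model Euclidean distances. Missing protons are reconstructed
#' from heavy-atom geometry where possible and flagged.
#'
#' @param ensemble a [structure_ensemble].
#' @param atom_a,atom_b lists `list(seq_index =, atom =)`.
#' @return list(min, mean, max, per_model, rebuilt_a, rebuilt_b).
#' @export
interproton_distance_stats <- function(ensemble, atom_a, atom_b) {
  models <- sort(unique(ensemble$atoms$model))
  rebuilt_a <- FALSE; rebuilt_b <- FALSE
  fetch <- function(m, q, which) {
    x <- .atom_xyz(ensemble, m, q$seq_index, q$atom)
    if (is.null(x)) {
      r <- get_residue(ensemble, m, q$seq_index)
      x <- .rebuild_proton(r, q$atom)
      if (is.null(x)) stop("atom ", q$atom, " of residue ", q$seq_index,
                           " absent and not reconstructible")
      if (which == "a") rebuilt_a <<- TRUE else rebuilt_b <<- TRUE
    }
    x
  }
  d <- vapply(models, function(m) {
    .vnorm(fetch(m, atom_a, "a") - fetch(m, atom_b, "b"))
  }, numeric(1))
  list(min = min(d), mean = mean(d), max = max(d), per_model = d,
       rebuilt_a = rebuilt_a, rebuilt_b = rebuilt_b)
}

#' Proximity of a proton to a base ring
#'
#' Distance from the proton to the six-ring centroid, signed height above the
#' base plane, and an in-plane flag (|height| < `inplane_tol`).
#'
#' @param ensemble a [structure_ensemble].
#' @param proton list(seq_index =, atom =).
#' @param base_residue seq_index of the base whose ring is used.
#' @param inplane_tol height cutoff, Angstrom.
#' @return data.frame per model: model, dist_A, height_A, in_plane; plus an
#'   `in_plane_majority` attribute.
#' @export
ring_proximity <- function(ensemble, proton, base_residue, inplane_tol = 1.5) {
  models <- sort(unique(ensemble$atoms$model))
  rows <- lapply(models, function(m) {
    p <- .atom_xyz(ensemble, m, proton$seq_index, proton$atom)
    if (is.null(p)) {
      p <- .rebuild_proton(get_residue(ensemble, m, proton$seq_index),
                           proton$atom)
      if (is.null(p)) stop("proton not found/reconstructible: ", proton$atom)
    }
    bp <- base_plane(get_residue(ensemble, m, base_residue))
    v <- p - bp$centroid6
    h <- sum(v * bp$normal)
    data.frame(model = m, dist_A = .vnorm(v), height_A = h,
               in_plane = abs(h) < inplane_tol)
  })
  out <- do.call(rbind, rows)
  attr(out, "in_plane_majority") <- mean(out$in_plane) > 0.5
  attr(out, "inplane_tol") <- inplane_tol
  out
}

#' Survey of V-loop flanking sugar puckers across ensembles
#'
#' For every model of every input ensemble with at least one detected V-loop,
#' reports the pseudorotation phase of the residue preceding (5' anchor) and
#' following (3' anchor) the V-loop; ensembles without a V-loop are skipped
#' with a warning.
#'
#' @param ensembles list of [structure_ensemble] objects.
#' @return data.frame: structure_id, model, seq_index, role
#'   ("preceding_vloop" / "following_vloop"), P_deg, octant.
#' @export
survey_vloop_puckers <- function(ensembles) {
  rows <- list()
  for (ens in ensembles) {
    id <- ens$source_id
    got <- FALSE
    for (m in seq_len(n_models(ens))) {
      topo <- tryCatch(analyze_topology(ens, m), error = function(e) NULL)
      if (is.null(topo) || isTRUE(topo$empty) || length(topo$vloops) == 0) next
      got <- TRUE
      for (vl in topo$vloops) {
        for (role in c("preceding_vloop", "following_vloop")) {
          anc <- if (role == "preceding_vloop") vl$anchor5 else vl$anchor3
          pk <- if (role == "preceding_vloop") vl$pucker5 else vl$pucker3
          rows[[length(rows) + 1]] <- data.frame(
            structure_id = id, model = m, seq_index = anc, role = role,
            P_deg = pk$P, octant = pk$octant %||% NA_character_,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (!got) warning("no V-loop detected in ", id, "; skipped")
  }
  if (length(rows) == 0) {
    return(data.frame(structure_id = character(0), model = integer(0),
                      seq_index = integer(0), role = character(0),
                      P_deg = numeric(0), octant = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
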