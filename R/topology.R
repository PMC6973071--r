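# G-quadruplex topology: Hoogsteen edges, tetrads, stacking, columns, grooves,
# loops, V-loop records.
#
# Conventions (documented because every downstream label depends on them):
# * Hoogsteen edge i -> j uses heavy-atom criteria by default (NMR depositions
#   may lack or misplace hydrogens): N1(i)-O6(j) and N2(i)-N7(j) distances plus
#   a base-plane angle cutoff.
# * Stack axis = principal axis of tetrad centroids. Its sign is chosen so the
#   5'-most guanine tract of the core runs "up"; per-residue backbone
#   direction is the projection of C5'->C3' on that axis.
# * layer_index 0 = the outer tetrad containing the lowest-numbered core
#   guanine found in either outer tetrad ("top" in the sequence-reading sense).

.default_topology_config <- list(
  d_N1O6 = 3.5, d_N2N7 = 3.5, max_plane_angle = 35,
  groove_narrow = 14, groove_wide = 18,
  groove_narrow_c1 = 13, groove_wide_c1 = 16.5,
  reverse_cycle_direction = FALSE)

#' Detect directed Hoogsteen guanine-guanine edges
#'
#' Edge i -> j exists when N1(i)-O6(j) <= `d_N1O6`, N2(i)-N7(j) <= `d_N2N7`
#' and the angle between the two base planes is <= `max_plane_angle`.
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param config cutoff list, see `.default_topology_config`.
#' @return data.frame: donor_seq, acceptor_seq, chain, d_N1O6, d_N2N7,
#'   plane_angle_deg.
#' @export
detect_hoogsteen_pairs <- function(ensemble, model = 1,
                                   config = .default_topology_config) {
  res <- residue_table(ensemble)
  gres <- res[res$base_type == "G", ]
  need <- c("N1", "N2", "O6", "N7")
  keep <- logical(nrow(gres))
  geo <- list()
  for (i in seq_len(nrow(gres))) {
    r <- get_residue(ensemble, model, gres$seq_index[i], chain = gres$chain[i])
    if (all(need %in% rownames(r$atoms)) &&
        all(.purine_sixring %in% rownames(r$atoms))) {
      keep[i] <- TRUE
      geo[[as.character(gres$seq_index[i])]] <-
        list(atoms = r$atoms, plane = base_plane(r))
    }
  }
  gres <- gres[keep, ]
  out <- list()
  n <- nrow(gres)
  if (n >= 2) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      gi <- geo[[as.character(gres$seq_index[i])]]
      gj <- geo[[as.character(gres$seq_index[j])]]
      d1 <- .vnorm(gi$atoms["N1", ] - gj$atoms["O6", ])
      if (d1 > config$d_N1O6) next
      d2 <- .vnorm(gi$atoms["N2", ] - gj$atoms["N7", ])
      if (d2 > config$d_N2N7) next
      ang <- .rad2deg(acos(min(1, abs(sum(gi$plane$normal * gj$plane$normal)))))
      if (ang > config$max_plane_angle) next
      out[[length(out) + 1]] <- data.frame(
        donor_seq = gres$seq_index[i], acceptor_seq = gres$seq_index[j],
        chain = gres$chain[i], d_N1O6 = d1, d_N2N7 = d2,
        plane_angle_deg = ang, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(out) > 0) do.call(rbind, out) else data.frame(
    donor_seq = integer(0), acceptor_seq = integer(0), chain = character(0),
    d_N1O6 = numeric(0), d_N2N7 = numeric(0), plane_angle_deg = numeric(0),
    stringsAsFactors = FALSE)
  if (isTRUE(config$reverse_cycle_direction)) {
    tmp <- edges$donor_seq
    edges$donor_seq <- edges$acceptor_seq
    edges$acceptor_seq <- tmp
  }
  edges
}

#' Detect guanine tetrads as directed 4-cycles
#'
#' Finds all simple directed 4-cycles in the Hoogsteen edge graph,
#' deduplicated by residue set. Each cycle is reported starting from its
#' lowest seq_index, following donor -> acceptor.
#'
#' @param edges edge data.frame from [detect_hoogsteen_pairs()].
#' @return list of integer vectors (length 4). A residue appearing in more
#'   than one tetrad raises an ambiguity error listing the candidates.
#' @export
detect_tetrads <- function(edges) {
  if (nrow(edges) == 0) return(list())
  succ <- split(edges$acceptor_seq, edges$donor_seq)
  cyc <- list()
  seen <- character(0)
  for (a in as.integer(names(succ))) {
    for (b in succ[[as.character(a)]]) {
      for (c_ in succ[[as.character(b)]] %||% integer(0)) {
        if (c_ == a) next
        for (d in succ[[as.character(c_)]] %||% integer(0)) {
          if (d %in% c(a, b)) next
          if (a %in% (succ[[as.character(d)]] %||% integer(0))) {
            set <- sort(c(a, b, c_, d))
            key <- paste(set, collapse = "|")
            if (!key %in% seen) {
              seen <- c(seen, key)
              cycle <- c(a, b, c_, d)
              k <- which.min(cycle)
              cyc[[length(cyc) + 1]] <-
                cycle[((seq_len(4) + k - 2) %% 4) + 1]
            }
          }
        }
      }
    }
  }
  all_members <- unlist(cyc)
  dup <- unique(all_members[duplicated(all_members)])
  if (length(dup) > 0) {
    labs <- vapply(cyc, function(x) paste(x, collapse = ">"), character(1))
    stop("residue(s) ", paste(dup, collapse = ", "),
         " belong to more than one tetrad candidate: ",
         paste(labs, collapse = "; "))
  }
  cyc
}

# six-ring centroid of a residue (guanine)
.res_centroid <- function(ensemble, model, seq_index) {
  r <- get_residue(ensemble, model, seq_index)
  base_plane(r)$centroid6
}

#' Order tetrads along the stack axis and label stacking polarity
#'
#' The stack axis is the principal axis of the tetrad centroids; its sign is
#' set so the 5'-most core tract runs up. Adjacent tetrads whose donor-cycle
#' senses (viewed along the axis) match are labelled homopolar, otherwise
#' heteropolar.
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param tetrads list of cycles from [detect_tetrads()].
#' @return list: `layers` (list of cycles ordered by layer_index),
#'   `layer_index` of each input tetrad, `axis` (unit vector), `senses`
#'   (+1/-1 per layer), `interfaces` (character per adjacent pair),
#'   `centroids`.
#' @export
stack_tetrads <- function(ensemble, model, tetrads) {
  if (length(tetrads) < 2) stop("need at least two tetrads to stack")
  cent <- t(vapply(tetrads, function(cy) {
    colMeans(t(vapply(cy, function(s) .res_centroid(ensemble, model, s),
                      numeric(3))))
  }, numeric(3)))
  ctr <- colMeans(cent)
  sv <- svd(sweep(cent, 2, ctr))
  axis <- sv$v[, 1]

  # axis sign: the 5'-most core tract runs up
  core <- sort(unlist(tetrads))
  runs <- split(core, cumsum(c(1, diff(core) != 1)))
  tract1 <- runs[[1]]
  dirsum <- 0
  for (s in tract1) {
    c5 <- .atom_xyz(ensemble, model, s, "C5'")
    c3 <- .atom_xyz(ensemble, model, s, "C3'")
    if (!is.null(c5) && !is.null(c3)) dirsum <- dirsum + sum((c3 - c5) * axis)
  }
  if (dirsum < 0) axis <- -axis

  proj <- as.vector(cent %*% axis)
  ord <- order(proj, decreasing = TRUE)  # provisional: top = largest proj
  outer_ids <- c(ord[1], ord[length(ord)])
  min_outer <- vapply(outer_ids, function(i) min(tetrads[[i]]), numeric(1))
  if (min_outer[2] < min_outer[1]) ord <- rev(ord)

  layer_index <- match(seq_along(tetrads), ord) - 1L
  senses <- vapply(seq_along(tetrads), function(i) {
    cy <- tetrads[[i]]
    pts <- t(vapply(cy, function(s) .res_centroid(ensemble, model, s),
                    numeric(3)))
    s <- 0
    for (k in 1:4) {
      k2 <- if (k == 4) 1 else k + 1
      s <- s + sum(.vcross(pts[k, ] - cent[i, ], pts[k2, ] - cent[i, ]) * axis)
    }
    sign(s)
  }, numeric(1))
  layers <- tetrads[ord]
  lsense <- senses[ord]
  interfaces <- vapply(seq_len(length(layers) - 1), function(i) {
    if (lsense[i] == lsense[i + 1]) "homopolar" else "heteropolar"
  }, character(1))
  list(layers = layers, layer_index = layer_index, axis = axis,
       senses = lsense, interfaces = interfaces, centroids = cent[ord, ])
}

# per-residue backbone direction (+1 up / -1 down) along the stack axis
.res_direction <- function(ensemble, model, seq_index, axis) {
  c5 <- .atom_xyz(ensemble, model, seq_index, "C5'")
  c3 <- .atom_xyz(ensemble, model, seq_index, "C3'")
  if (is.null(c5) || is.null(c3)) return(NA_real_)
  sign(sum((c3 - c5) * axis))
}

#' Extract the four G-columns from a tetrad stack
#'
#' Residues are matched across adjacent layers by nearest base centroid
#' (optimal assignment over all permutations per layer pair). Orientation is
#' the majority backbone direction of the column's residues; `broken` flags
#' sequence-discontiguous columns; strand-inversion points are adjacent layer
#' pairs whose residues run in opposite directions.
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param stack output of [stack_tetrads()].
#' @return list of columns, each: residues (by layer), orientation ("up" /
#'   "down"), directions (+1/-1 per residue), broken, inversions (list of
#'   residue pairs), azimuth_deg.
#' @export
extract_columns <- function(ensemble, model, stack) {
  layers <- stack$layers
  L <- length(layers)
  cents <- lapply(layers, function(cy) {
    t(vapply(cy, function(s) .res_centroid(ensemble, model, s), numeric(3)))
  })
  perms <- .permutations4()
  cols <- lapply(seq_len(4), function(i) layers[[1]][i])
  idx_prev <- seq_len(4)
  for (l in seq_len(L - 1)) {
    A <- cents[[l]]; B <- cents[[l + 1]]
    best <- NULL
    for (p in seq_len(nrow(perms))) {
      pm <- perms[p, ]
      d <- sum(vapply(1:4, function(i) .vnorm(A[i, ] - B[pm[i], ]),
                      numeric(1)))
      if (is.null(best) || d < best$d) best <- list(d = d, pm = pm)
    }
    for (i in seq_len(4)) {
      cols[[i]] <- c(cols[[i]], layers[[l + 1]][best$pm[.col_slot(idx_prev, i, l)]])
    }
    idx_prev <- vapply(seq_len(4), function(i) best$pm[.col_slot(idx_prev, i, l)],
                       integer(1))
  }
  axis <- stack$axis
  ctr <- colMeans(do.call(rbind, cents))
  # orthonormal in-plane frame for azimuths
  e1 <- .vunit(.vcross(axis, if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
  e2 <- .vcross(axis, e1)
  out <- lapply(cols, function(rr) {
    dirs <- vapply(rr, function(s) .res_direction(ensemble, model, s, axis),
                   numeric(1))
    inv <- list()
    for (k in seq_len(length(rr) - 1)) {
      if (!is.na(dirs[k]) && !is.na(dirs[k + 1]) && dirs[k] != dirs[k + 1]) {
        inv[[length(inv) + 1]] <- c(rr[k], rr[k + 1])
      }
    }
    pos <- colMeans(t(vapply(rr, function(s)
      .res_centroid(ensemble, model, s), numeric(3))))
    v <- pos - ctr
    az <- .wrap360(.rad2deg(atan2(sum(v * e2), sum(v * e1))))
    broken <- any(abs(diff(sort(rr))) != 1) ||
      any(abs(diff(rr)) != 1)
    list(residues = rr,
         directions = dirs,
         orientation = if (sum(dirs, na.rm = TRUE) >= 0) "up" else "down",
         broken = broken, inversions = inv, azimuth_deg = az)
  })
  # cyclic order by azimuth
  az <- vapply(out, `[[`, numeric(1), "azimuth_deg")
  out[order(az)]
}

.col_slot <- function(idx_prev, i, l) {
  # residue index of column i in layer l (1-based position inside the layer)
  idx_prev[i]
}

.permutations4 <- function() {
  hit <- .quadfold_cache[["perm4"]]
  if (!is.null(hit)) return(hit)
  p <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  p <- p[apply(p, 1, function(r) length(unique(r)) == 4), ]
  colnames(p) <- NULL
  .quadfold_cache[["perm4"]] <- p
  p
}

#' Classify the four grooves of a quadruplex
#'
#' For each cyclically adjacent column pair, the mean phosphorus-phosphorus
#' distance across layers is mapped to narrow / medium / wide. The numeric
#' thresholds are package defaults calibrated on the synthetic templates (the
#' source literature uses qualitative labels only) and are configurable. When
#' P atoms are missing, C1'-C1' distances with shifted thresholds are used.
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param columns output of [extract_columns()].
#' @param config cutoff list.
#' @return data.frame: col_a, col_b (1-based indices into `columns`), members
#'   (text), mean_dist_A, metric ("P-P" or "C1'-C1'"), label.
#' @export
classify_grooves <- function(ensemble, model, columns,
                             config = .default_topology_config) {
  k <- length(columns)
  out <- list()
  for (i in seq_len(k)) {
    j <- if (i == k) 1 else i + 1
    ra <- columns[[i]]$residues
    rb <- columns[[j]]$residues
    dP <- c(); dC <- c()
    for (l in seq_along(ra)) {
      pa <- .atom_xyz(ensemble, model, ra[l], "P")
      pb <- .atom_xyz(ensemble, model, rb[l], "P")
      if (!is.null(pa) && !is.null(pb)) dP <- c(dP, .vnorm(pa - pb))
      ca <- .atom_xyz(ensemble, model, ra[l], "C1'")
      cb <- .atom_xyz(ensemble, model, rb[l], "C1'")
      if (!is.null(ca) && !is.null(cb)) dC <- c(dC, .vnorm(ca - cb))
    }
    if (length(dP) > 0) {
      d <- mean(dP); metric <- "P-P"
      lab <- if (d < config$groove_narrow) "narrow"
             else if (d < config$groove_wide) "medium" else "wide"
    } else {
      d <- mean(dC); metric <- "C1'-C1'"
      lab <- if (d < config$groove_narrow_c1) "narrow"
             else if (d < config$groove_wide_c1) "medium" else "wide"
    }
    out[[i]] <- data.frame(
      col_a = i, col_b = j,
      members = paste0(paste(ra, collapse = ","), "|",
                       paste(rb, collapse = ",")),
      mean_dist_A = d, metric = metric, label = lab,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Classify inter-column loops
#'
#' Walks the core residues in sequence order; every connector between
#' consecutive core residues in different columns is classified from the
#' anchor faces and column geometry: lateral (adjacent columns, same face),
#' diagonal (opposite columns, same face), propeller (adjacent columns,
#' opposite faces, parallel columns), V (adjacent antiparallel columns,
#' opposite faces; zero intervening residues allowed).
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param stack output of [stack_tetrads()].
#' @param columns output of [extract_columns()].
#' @return data.frame: cls, anchor5, anchor3, n_intervening, residues (text).
#' @export
classify_loops <- function(ensemble, model, stack, columns) {
  L <- length(stack$layers)
  col_of <- integer(0); layer_of <- integer(0)
  for (ci in seq_along(columns)) {
    rr <- columns[[ci]]$residues
    for (li in seq_along(rr)) {
      col_of[as.character(rr[li])] <- ci
      layer_of[as.character(rr[li])] <- li - 1L
    }
  }
  core <- sort(as.integer(names(col_of)))
  res <- residue_table(ensemble)
  out <- list()
  for (k in seq_len(length(core) - 1)) {
    a5 <- core[k]; a3 <- core[k + 1]
    ca <- col_of[as.character(a5)]; cb <- col_of[as.character(a3)]
    if (ca == cb) next
    interven <- setdiff(seq(a5 + 1, length.out = max(0, a3 - a5 - 1)), core)
    fa <- layer_of[as.character(a5)]; fb <- layer_of[as.character(a3)]
    adj <- (abs(ca - cb) %% 4) %in% c(1, 3)
    same_face <- fa == fb
    if (same_face && adj) {
      cls <- "lateral"
    } else if (same_face && !adj) {
      cls <- "diagonal"
    } else if (!same_face && adj) {
      ori_a <- columns[[ca]]$orientation
      ori_b <- columns[[cb]]$orientation
      cls <- if (ori_a != ori_b) "V" else "propeller"
    } else {
      cls <- "other"
    }
    out[[length(out) + 1]] <- data.frame(
      cls = cls, anchor5 = a5, anchor3 = a3,
      n_intervening = length(interven),
      residues = paste(interven, collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(cls = character(0), anchor5 = integer(0),
                      anchor3 = integer(0), n_intervening = integer(0),
                      residues = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Detect V-loop motifs and their conformational records
#'
#' One record per V-classified loop: anchors, intervening count, anchor
#' glycosidic classes and sugar puckers, and the backbone-turn locus:
#' `within_following_tract` when the strand inversion lies between the
#' 3'-anchor and its tract neighbour (anchors run in the same direction),
#' `between_linked_residues` when the inversion separates the two linked
#' residues themselves.
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param stack,columns,loops upstream topology components.
#' @return list of records (possibly empty): anchor5, anchor3, n_intervening,
#'   chi5, chi3, pucker5, pucker3 (P and class), turn_locus.
#' @export
detect_vloops <- function(ensemble, model, stack, columns, loops) {
  v <- loops[loops$cls == "V", , drop = FALSE]
  if (nrow(v) == 0) return(list())
  L <- length(stack$layers)
  layer_of <- integer(0)
  for (ci in seq_along(columns)) {
    rr <- columns[[ci]]$residues
    for (li in seq_along(rr)) layer_of[as.character(rr[li])] <- li - 1L
  }
  out <- list()
  for (i in seq_len(nrow(v))) {
    a5 <- v$anchor5[i]; a3 <- v$anchor3[i]
    f5 <- layer_of[as.character(a5)]; f3 <- layer_of[as.character(a3)]
    outer <- c(0L, L - 1L)
    if (!(f5 %in% outer && f3 %in% outer && f5 != f3)) {
      stop("V-loop anchors ", a5, "/", a3,
           " are not on opposite outer tetrads (layers ", f5, ", ", f3, ")")
    }
    r5 <- get_residue(ensemble, model, a5)
    r3 <- get_residue(ensemble, model, a3)
    chi5 <- glycosidic_chi(r5); chi3 <- glycosidic_chi(r3)
    pk5 <- pseudorotation(ring_torsions(r5))
    pk3 <- pseudorotation(ring_torsions(r3))
    d5 <- .res_direction(ensemble, model, a5, stack$axis)
    d3 <- .res_direction(ensemble, model, a3, stack$axis)
    locus <- if (!is.na(d5) && !is.na(d3) && d5 != d3)
      "between_linked_residues" else "within_following_tract"
    out[[length(out) + 1]] <- list(
      anchor5 = a5, anchor3 = a3, n_intervening = v$n_intervening[i],
      chi5 = chi5, chi3 = chi3, pucker5 = pk5, pucker3 = pk3,
      turn_locus = locus)
  }
  out
}

#' Full per-model topology analysis
#'
#' Runs edge detection, tetrad finding, stacking, column extraction, groove
#' and loop classification and V-loop detection for one model.
#'
#' @param ensemble a [structure_ensemble].
#' @param model model index.
#' @param config cutoffs (see `.default_topology_config`).
#' @return object of class `g4_topology`: list(edges, tetrads, stack, columns,
#'   grooves, loops, vloops, config). When fewer than two tetrads are found,
#'   the downstream components are NULL and `empty` is TRUE.
#' @export
analyze_topology <- function(ensemble, model = 1,
                             config = .default_topology_config) {
  config <- utils::modifyList(.default_topology_config, config)
  edges <- detect_hoogsteen_pairs(ensemble, model, config)
  tetrads <- detect_tetrads(edges)
  out <- list(model = model, edges = edges, tetrads = tetrads,
              config = config)
  if (length(tetrads) < 2) {
    out$empty <- TRUE
    class(out) <- "g4_topology"
    return(out)
  }
  stack <- stack_tetrads(ensemble, model, tetrads)
  columns <- extract_columns(ensemble, model, stack)
  grooves <- classify_grooves(ensemble, model, columns, config)
  loops <- classify_loops(ensemble, model, stack, columns)
  vloops <- detect_vloops(ensemble, model, stack, columns, loops)
  out$empty <- FALSE
  out$stack <- stack
  out$columns <- columns
  out$grooves <- grooves
  out$loops <- loops
  out$vloops <- vloops
  class(out) <- "g4_topology"
  out
}

#' @export
print.g4_topology <- function(x, ...) {
  cat("G4 topology (model ", x$model, "): ", length(x$tetrads), " tetrad(s)\n",
      sep = "")
  if (!isTRUE(x$empty)) {
    for (cy in x$stack$layers) cat("  cycle: ", paste(cy, collapse = ">"), "\n")
    cat("  interfaces:", paste(x$stack$interfaces, collapse = ", "), "\n")
    cat("  grooves:", paste(x$grooves$label, collapse = ", "), "\n")
    cat("  loops:", paste(sprintf("%s(%d-%d)", x$loops$cls, x$loops$anchor5,
                                  x$loops$anchor3), collapse = ", "), "\n")
    cat("  V-loops:", length(x$vloops), "\n")
  }
  invisible(x)
}
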