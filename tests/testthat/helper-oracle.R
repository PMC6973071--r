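# Shared helpers: oracle-equivalence checks between a generating topology
# spec and the detected topology, plus small fixture builders.

canonical_cycle <- function(x) {
  if (is.character(x)) x <- as.integer(strsplit(x, ">")[[1]])
  k <- which.min(x)
  paste(x[((seq_along(x) + k - 2) %% length(x)) + 1], collapse = ">")
}

groove_between <- function(topo, res_a, res_b) {
  for (i in seq_len(nrow(topo$grooves))) {
    sides <- strsplit(topo$grooves$members[i], "|", fixed = TRUE)[[1]]
    ra <- as.integer(strsplit(sides[1], ",")[[1]])
    rb <- as.integer(strsplit(sides[2], ",")[[1]])
    if ((res_a %in% ra && res_b %in% rb) || (res_a %in% rb && res_b %in% ra)) {
      return(topo$grooves$label[i])
    }
  }
  NA_character_
}

# full oracle equivalence: detected topology reproduces the generating spec
expect_preset_oracle <- function(name) {
  spec <- g4_preset(name)
  ens <- build_quadruplex(spec)
  topo <- analyze_topology(ens)
  exp <- spec$expected

  expect_false(isTRUE(topo$empty), label = paste(name, "topology empty"))
  expect_identical(length(topo$tetrads), as.integer(exp$n_tetrads),
                   label = paste(name, "tetrad count"))
  if (!is.null(exp[["cycles"]])) {
    got <- vapply(topo$stack$layers, function(cy)
      canonical_cycle(cy), character(1))
    expect_identical(got, vapply(exp[["cycles"]], canonical_cycle, character(1),
                                 USE.NAMES = FALSE),
                     label = paste(name, "tetrad cycles"))
  }
  if (!is.null(exp[["interfaces"]])) {
    expect_identical(topo$stack$interfaces, exp[["interfaces"]],
                     label = paste(name, "stacking interfaces"))
  }
  ori <- vapply(topo$columns, `[[`, character(1), "orientation")
  if (!is.null(exp[["orientations"]])) {
    if (is.null(names(exp[["orientations"]]))) {
      expect_identical(sort(ori), sort(exp[["orientations"]]),
                       label = paste(name, "column orientations"))
    } else {
      expect_identical(sum(ori == "up"), as.integer(exp[["orientations"]]["up"]),
                       label = paste(name, "up-column count"))
    }
  }
  if (!is.null(exp[["broken"]])) {
    expect_identical(sort(vapply(topo$columns, `[[`, logical(1), "broken")),
                     sort(exp[["broken"]]), label = paste(name, "broken flags"))
  }
  if (!is.null(exp[["broken_columns"]])) {
    expect_identical(sum(vapply(topo$columns, `[[`, logical(1), "broken")),
                     as.integer(exp[["broken_columns"]]),
                     label = paste(name, "broken column count"))
  }
  if (!is.null(exp[["inversion"]])) {
    inv <- unlist(lapply(topo$columns, `[[`, "inversions"))
    expect_identical(sort(unique(as.integer(inv))),
                     sort(as.integer(exp[["inversion"]])),
                     label = paste(name, "strand inversion point"))
  }
  if (!is.null(exp[["loops"]])) {
    lp <- topo$loops[order(topo$loops$anchor5), ]
    el <- exp[["loops"]][order(exp[["loops"]]$anchor5), ]
    expect_identical(lp$cls, el$cls, label = paste(name, "loop classes"))
    expect_identical(lp$anchor5, as.integer(el$anchor5),
                     label = paste(name, "loop 5' anchors"))
    expect_identical(lp$anchor3, as.integer(el$anchor3),
                     label = paste(name, "loop 3' anchors"))
    expect_identical(lp$n_intervening, as.integer(el$n),
                     label = paste(name, "loop lengths"))
  }
  if (!is.null(exp[["grooves_sorted"]])) {
    expect_identical(sort(topo$grooves$label), sort(exp[["grooves_sorted"]]),
                     label = paste(name, "groove labels"))
  }
  expect_identical(length(topo$vloops), as.integer(exp$n_vloops),
                   label = paste(name, "V-loop count"))
  if (!is.null(exp[["vloop"]])) {
    v <- topo$vloops[[1]]
    expect_identical(v$anchor5, as.integer(exp[["vloop"]]$anchor5))
    expect_identical(v$anchor3, as.integer(exp[["vloop"]]$anchor3))
    expect_identical(v$n_intervening, as.integer(exp[["vloop"]]$n_intervening))
    expect_identical(v$chi5$cls, exp[["vloop"]]$chi5)
    expect_identical(v$chi3$cls, exp[["vloop"]]$chi3)
    expect_identical(v$turn_locus, exp[["vloop"]]$turn_locus)
    expect_identical(groove_between(topo, v$anchor5, v$anchor3),
                     exp$grooves_vloop)
  }
  invisible(topo)
}

# rigid motion helper: rotate + translate every atom of an ensemble
apply_rigid <- function(ensemble, axis = c(1, 2, 2), angle = 37,
                        shift = c(5, -3, 11)) {
  R <- quadfold:::.rotmat(axis, angle)
  X <- as.matrix(ensemble$atoms[, c("x", "y", "z")]) %*% t(R)
  X <- sweep(X, 2, shift, "+")
  ensemble$atoms$x <- X[, 1]
  ensemble$atoms$y <- X[, 2]
  ensemble$atoms$z <- X[, 3]
  ensemble
}

# small explicit Karplus parameter table for tests (independent of the
# shipped data file)
test_karplus_params <- function() {
  tab <- data.frame(
    path = c("H1'-H2'", "H2'-H3'", "H3'-H4'", "F2'-H1'", "F2'-H3'"),
    A = c(10.2, 10.2, 10.2, 31.0, 31.0),
    B = c(-0.8, -0.8, -0.8, -11.0, -11.0),
    C = c(0, 0, 0, 3.0, 3.0),
    a = c(1.03, 1.06, 1.06, 1.03, 1.06),
    b = c(121.4, 2.4, -124.0, 1.4, 122.4),
    nu = c(1, 2, 3, 1, 2),
    stringsAsFactors = FALSE)
  class(tab) <- c("karplus_params", class(tab))
  tab
}
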