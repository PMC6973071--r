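# Karplus forward model and pseudorotation inversion from vicinal couplings.
#
# Each coupling path (e.g. H1'-H2', F2'-H1') is governed by one endocyclic
# torsion nu_k through a linear substituent map theta = a * nu_k + b, and a
# Karplus relation J(theta) = A cos^2(theta) + B cos(theta) + C. Coefficients
# and maps ship as a named parameter set loaded from a data file with a
# provenance header; the default set is an explicitly labelled synthetic
# stand-in (the quantitative literature relation for 2'-fluoro sugars is not
# reproduced here).

.karplus_nu_map <- c("H1'-H2'" = 1, "H2'-H3'" = 2, "H3'-H4'" = 3,
                     "F2'-H1'" = 1, "F2'-H3'" = 2)

#' Load a Karplus parameter set
#'
#' @param path TSV file with columns path, A, B, C, a, b, nu (header lines
#'   starting with '#' hold provenance). Default: the synthetic stand-in set
#'   shipped with the package.
#' @return data.frame of class `karplus_params`.
#' @export
karplus_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "karplus_synthetic.tsv",
                        package = "quadfold")
  }
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("path", "A", "B", "C", "a", "b", "nu")
  if (!all(need %in% names(tab))) {
    stop("parameter file must have columns: ", paste(need, collapse = ", "))
  }
  if (any(tab$a == 0)) stop("substituent map slope a must be nonzero")
  class(tab) <- c("karplus_params", class(tab))
  tab
}

#' Karplus relation
#'
#' @param theta torsion angle(s), degrees.
#' @param coeffs numeric c(A, B, C) in Hz.
#' @return coupling(s) in Hz: A cos^2 + B cos + C.
#' @export
karplus_j <- function(theta, coeffs) {
  ct <- cos(.deg2rad(theta))
  coeffs[1] * ct^2 + coeffs[2] * ct + coeffs[3]
}

#' Predict couplings from pseudorotation parameters
#'
#' @param P,tau_m pseudorotation phase/amplitude, degrees.
#' @param params a [karplus_params()] table.
#' @param paths coupling paths to predict (default: all in `params`).
#' @return data.frame: path, J_Hz, sigma_Hz (0 for model predictions).
#' @export
predict_couplings <- function(P, tau_m, params = karplus_params(),
                              paths = params$path) {
  missing <- setdiff(paths, params$path)
  if (length(missing) > 0) {
    stop("no parameters for path(s): ", paste(missing, collapse = ", "))
  }
  nu <- torsions_from_pucker(P, tau_m)
  rows <- lapply(paths, function(p) {
    pr <- params[params$path == p, ][1, ]
    theta <- pr$a * nu[pr$nu + 1] + pr$b
    data.frame(path = p, J_Hz = karplus_j(theta, c(pr$A, pr$B, pr$C)),
               sigma_Hz = 0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a noisy coupling set
#'
#' @param P,tau_m generating pseudorotation parameters.
#' @param params a [karplus_params()] table.
#' @param noise_sd Gaussian noise SD in Hz (>= 0); observations are truncated
#'   at zero; `sigma_Hz` of the output is `noise_sd`.
#' @param seed integer seed (reproducible).
#' @param paths coupling paths.
#' @return data.frame: path, J_Hz, sigma_Hz.
#' @export
simulate_couplings <- function(P, tau_m, params = karplus_params(),
                               noise_sd = 0.3, seed = 1,
                               paths = params$path) {
  stopifnot(noise_sd >= 0)
  pred <- predict_couplings(P, tau_m, params, paths)
  set.seed(as.integer(seed))
  pred$J_Hz <- pmax(0, pred$J_Hz + stats::rnorm(nrow(pred), 0, noise_sd))
  pred$sigma_Hz <- noise_sd
  pred
}

#' Read a coupling table
#'
#' @param path TSV with columns path, J_Hz, sigma_Hz.
#' @return data.frame.
#' @export
read_couplings <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("path", "J_Hz", "sigma_Hz")
  if (!all(need %in% names(tab)) || nrow(tab) == 0) {
    stop("coupling file must have columns path, J_Hz, sigma_Hz and >= 1 row")
  }
  if (any(tab$J_Hz < 0)) stop("couplings must be >= 0")
  tab
}

#' Grid inversion: compatible pseudorotamers from observed couplings
#'
#' Evaluates the forward model on a (P, tau_m) lattice. `chisq` is the usual
#' sum of squared sigma-scaled residuals; a node is `compatible` when every
#' observed path is reproduced within `k * sigma` (box criterion, matching
#' how hard intervals are reported in the field; the chi-square surface is
#' returned for diagnostics). Compatible P values are condensed into minimal
#' covering intervals modulo 360; multimodal sets yield multiple intervals
#' and are never merged.
#'
#' @param obs data.frame: path, J_Hz, sigma_Hz (sigma floored at 1e-6 Hz so
#'   that zero-noise synthetic sets remain usable).
#' @param params a [karplus_params()] table.
#' @param grid list(P = vector, tau = vector); default P in 0..359 step 1,
#'   tau_m 25..45 step 1.
#' @param k sigma multiplier of the compatibility box.
#' @return object of class `pseudorotation_fit`: list(grid, chisq (P x tau
#'   matrix), best = list(P, tau_m, chisq), compatible (logical matrix),
#'   P_intervals (list of c(lo, hi)), no_solution_at_k flag, k, n_obs.
#' @export
fit_pseudorotation <- function(obs, params = karplus_params(),
                               grid = list(P = seq(0, 359, by = 1),
                                           tau = seq(25, 45, by = 1)),
                               k = 1) {
  stopifnot(nrow(obs) >= 1)
  missing <- setdiff(obs$path, params$path)
  if (length(missing) > 0) {
    stop("no parameters for observed path(s): ", paste(missing, collapse = ", "))
  }
  Pv <- grid$P; Tv <- grid$tau
  nP <- length(Pv); nT <- length(Tv)
  chisq <- matrix(0, nP, nT)
  ok <- matrix(TRUE, nP, nT)
  for (r in seq_len(nrow(obs))) {
    pr <- params[params$path == obs$path[r], ][1, ]
    # nu_k over the grid: tau * cos(P + 144 (k - 2))
    cosmat <- outer(cos(.deg2rad(Pv + 144 * (pr$nu - 2))), Tv)
    theta <- pr$a * cosmat + pr$b
    Jp <- karplus_j(theta, c(pr$A, pr$B, pr$C))
    sig <- max(obs$sigma_Hz[r], 1e-6)
    dev <- Jp - obs$J_Hz[r]
    chisq <- chisq + (dev / sig)^2
    ok <- ok & (abs(dev) <= k * sig)
  }
  ib <- arrayInd(which.min(chisq), dim(chisq))
  best <- list(P = Pv[ib[1]], tau_m = Tv[ib[2]], chisq = chisq[ib])
  pok <- apply(ok, 1, any)
  intervals <- .p_intervals(Pv[pok], step = if (nP > 1) min(diff(Pv)) else 1)
  out <- list(grid = grid, chisq = chisq, best = best, compatible = ok,
              P_intervals = intervals,
              no_solution_at_k = !any(ok), k = k, n_obs = nrow(obs))
  class(out) <- "pseudorotation_fit"
  out
}

# condense compatible P values into covering intervals with wrap at 360
.p_intervals <- function(p, step = 1) {
  if (length(p) == 0) return(list())
  p <- sort(unique(p))
  breaks <- which(diff(p) > step * 1.5)
  runs <- if (length(breaks) == 0) list(p) else {
    idx <- c(0, breaks, length(p))
    lapply(seq_len(length(idx) - 1), function(i) p[(idx[i] + 1):idx[i + 1]])
  }
  iv <- lapply(runs, function(r) c(lo = min(r), hi = max(r)))
  # wrap-around: merge a run ending at the top of the circle with one
  # starting at the bottom
  if (length(iv) > 1) {
    first <- iv[[1]]; last <- iv[[length(iv)]]
    if (first["lo"] <= step * 0.75 && last["hi"] >= 360 - step * 1.5) {
      iv[[1]] <- c(lo = last["lo"] - 360, hi = first["hi"])
      names(iv[[1]]) <- c("lo", "hi")
      iv[[length(iv)]] <- NULL
    }
  }
  iv
}

#' @export
print.pseudorotation_fit <- function(x, ...) {
  cat(sprintf("pseudorotation fit: best (P, tau_m) = (%g, %g), chisq = %.3g\n",
              x$best$P, x$best$tau_m, x$best$chisq))
  if (x$no_solution_at_k) {
    cat(sprintf("no compatible node at k = %g\n", x$k))
  } else {
    for (iv in x$P_intervals) {
      cat(sprintf("compatible P: [%g, %g]\n", iv["lo"], iv["hi"]))
    }
  }
  invisible(x)
}
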