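# Free-energy reconstruction: WHAM over umbrella windows, polar
# free-energy-landscape assembly, Lennard-Jones enthalpy profiles, and the
# enthalpy-entropy decomposition of the adsorption free energy.

#' WHAM reconstruction of a potential of mean force
#'
#' Self-consistent weighted-histogram estimate of the unbiased probability
#' from harmonically biased umbrella windows:
#' `P(b) = sum_i n_i(b) / sum_i N_i exp((f_i - c_i(b)) / kBT)` with window
#' free energies `exp(-f_i/kBT) = sum_b P(b) exp(-c_i(b)/kBT)`, iterated
#' until the largest change in any `f_i` falls below `tol * kBT`.  The PMF
#' is `-kBT log P`, shifted so the value at the largest sampled reaction
#' coordinate is zero (the profile flattens to zero as the adsorbate
#' leaves the interaction range).
#'
#' Adjacent windows must overlap: every neighbouring pair has to share at
#' least one occupied histogram bin, otherwise the gap is reported by its
#' window centers.
#'
#' @param windows list of `umbrella_window` objects (fields `center`,
#'   `force_constant`, `samples`).
#' @param temperature K.
#' @param bin_width histogram bin along the reaction coordinate, nm.
#' @param tol relative convergence threshold on the window free energies.
#' @param max_iter iteration budget.
#' @param min_count bins with fewer total samples are dropped from the
#'   reported profile (a guard against log-of-small-count noise at the
#'   histogram fringes; all bins still enter the self-consistent
#'   iteration).
#' @return an object of class `pmf_profile`: `xi` (bin centers, nm),
#'   `delta_g` (kJ/mol), `std` (`NA` for a single window set; see
#'   [pmf_average()]), `reference`, `n_windows`, `iterations`.
#' @export
wham <- function(windows, temperature = 300, bin_width = 0.02,
                 tol = 1e-7, max_iter = 1e5, min_count = 5) {
  stopifnot(length(windows) >= 1, temperature > 0, bin_width > 0)
  kT <- .kB * temperature
  centers <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(centers)
  windows <- windows[ord]
  centers <- centers[ord]
  ks <- vapply(windows, `[[`, numeric(1), "force_constant")
  samples <- lapply(windows, `[[`, "samples")
  if (any(vapply(samples, length, integer(1)) == 0))
    stop("every window needs samples")

  rng <- range(unlist(samples))
  edges <- seq(floor(rng[1] / bin_width) * bin_width,
               ceiling(rng[2] / bin_width) * bin_width, by = bin_width)
  if (length(edges) < 3) edges <- c(edges[1] - bin_width, edges,
                                    edges[length(edges)] + bin_width)
  mids <- edges[-1] - bin_width / 2
  nb <- length(mids)
  nw <- length(windows)

  n_ib <- vapply(samples, function(s)
    graphics::hist(s, breaks = edges, plot = FALSE)$counts,
    numeric(nb)) # nb x nw
  n_ib <- matrix(n_ib, nrow = nb)
  N_i <- colSums(n_ib)

  # adjacency overlap check
  if (nw > 1) {
    for (i in seq_len(nw - 1)) {
      if (!any(n_ib[, i] > 0 & n_ib[, i + 1] > 0))
        stop(sprintf(
          "no histogram overlap between windows centered at %g and %g nm",
          centers[i], centers[i + 1]))
    }
  }

  # bias energies c_i(b)
  bias <- outer(mids, seq_len(nw),
                function(x, i) 0.5 * ks[i] * (x - centers[i])^2)
  ebias <- exp(-bias / kT) # nb x nw

  f <- rep(0, nw)
  tot_b <- rowSums(n_ib)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- ebias %*% (N_i * exp(f / kT)) # nb x 1
    p <- tot_b / pmax(as.numeric(denom), .Machine$double.xmin)
    fz <- -kT * log(pmax(as.numeric(crossprod(ebias, p)),
                         .Machine$double.xmin))
    fz <- fz - fz[1]
    delta <- max(abs(fz - f))
    f <- fz
    if (delta < tol * kT) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kJ/mol)",
                   iter, delta))
  }

  occupied <- tot_b >= max(min_count, 1)
  if (!any(occupied)) stop("no bin reaches min_count samples")
  g <- rep(NA_real_, nb)
  g[occupied] <- -kT * log(p[occupied])
  # anchor: zero over the largest-xi plateau -- the count-weighted mean of
  # the occupied bins at or beyond the last window center (falling back to
  # the last occupied bin)
  plateau <- occupied & mids >= max(centers) - bin_width / 2
  if (!any(plateau)) plateau <- seq_len(nb) == max(which(occupied))
  g <- g - sum(g[plateau] * tot_b[plateau]) / sum(tot_b[plateau])
  structure(list(xi = mids[occupied], delta_g = g[occupied],
                 std = rep(NA_real_, sum(occupied)),
                 reference = "zero-at-max-xi",
                 n_windows = nw, iterations = iter),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(paste0("PMF: %d bins, xi in [%.3g, %.3g] nm, ",
                     "min dG = %.2f kJ/mol at xi = %.3g nm (%s)\n"),
              length(x$xi), min(x$xi), max(x$xi), min(x$delta_g),
              x$xi[which.min(x$delta_g)], x$reference))
  invisible(x)
}

#' Average PMF replicas
#'
#' Interpolates replica PMFs onto the grid of the first and reports the
#' pointwise mean and standard deviation.
#'
#' @param pmfs list of `pmf_profile` objects.
#' @return a `pmf_profile` with `std` filled in.
#' @export
pmf_average <- function(pmfs) {
  stopifnot(length(pmfs) >= 1)
  xi <- pmfs[[1]]$xi
  g <- vapply(pmfs, function(p) stats::approx(p$xi, p$delta_g, xi,
                                              rule = 1)$y,
              numeric(length(xi)))
  g <- matrix(g, nrow = length(xi))
  keep <- rowSums(is.na(g)) == 0
  structure(list(xi = xi[keep],
                 delta_g = rowMeans(g[keep, , drop = FALSE]),
                 std = apply(g[keep, , drop = FALSE], 1, function(z)
                   if (length(z) > 1) stats::sd(z) else 0),
                 reference = pmfs[[1]]$reference,
                 n_windows = pmfs[[1]]$n_windows,
                 iterations = NA_integer_),
            class = "pmf_profile")
}

#' Assemble a polar free-energy landscape
#'
#' Collects PMFs measured at several particle orientations (rotation angle
#' theta about the axis orthogonal to the \{100\} and \{111\} normals) into
#' a (theta, xi) free-energy matrix on a common xi grid, and reports the
#' location of the global minimum.  With \{100\} at theta = 0, the \{111\}
#' normal sits at theta = 54.7 degrees.
#'
#' @param pmfs list of `pmf_profile` objects.
#' @param thetas orientation angles in degrees, one per PMF (taken from
#'   `names(pmfs)` when omitted).
#' @return an object of class `polar_fel`: `thetas`, `xi`, `delta_g`
#'   (theta x xi matrix), `minimum` (list with `theta`, `xi`, `delta_g`,
#'   `degenerate`).
#' @export
assemble_polar_fel <- function(pmfs, thetas = NULL) {
  stopifnot(length(pmfs) >= 2)
  if (is.null(thetas)) thetas <- as.numeric(names(pmfs))
  if (length(thetas) != length(pmfs) || anyNA(thetas))
    stop("one finite theta per PMF is required")
  lo <- max(vapply(pmfs, function(p) min(p$xi), numeric(1)))
  hi <- min(vapply(pmfs, function(p) max(p$xi), numeric(1)))
  if (lo >= hi) stop("PMF xi ranges are disjoint; no common grid")
  step <- min(vapply(pmfs, function(p) min(diff(p$xi)), numeric(1)))
  xi <- seq(lo, hi, by = step)
  g <- t(vapply(pmfs, function(p)
    stats::approx(p$xi, p$delta_g, xi, rule = 2)$y, numeric(length(xi))))
  ord <- order(thetas)
  thetas <- thetas[ord]
  g <- g[ord, , drop = FALSE]
  gmin <- min(g)
  hits <- which(g <= gmin + 1e-9, arr.ind = TRUE)
  degenerate <- length(unique(hits[, 1])) > 1
  minimum <- list(theta = thetas[hits[1, 1]], xi = xi[hits[1, 2]],
                  delta_g = gmin, degenerate = degenerate)
  structure(list(thetas = thetas, xi = xi, delta_g = g, minimum = minimum),
            class = "polar_fel")
}

#' @export
print.polar_fel <- function(x, ...) {
  cat(sprintf("polar FEL: %d orientations x %d xi bins\n",
              length(x$thetas), length(x$xi)))
  cat(sprintf("  global minimum %.2f kJ/mol at theta = %.1f deg, xi = %.3g nm%s\n",
              x$minimum$delta_g, x$minimum$theta, x$minimum$xi,
              if (x$minimum$degenerate) " (degenerate in theta)" else ""))
  invisible(x)
}

#' Lennard-Jones interaction parameters
#'
#' 12-6 Lennard-Jones parameters for the particle-adsorbate pair, either
#' given directly for the pair or per species (combined with geometric
#' mean for epsilon and arithmetic mean for sigma).  An optional charge
#' pair adds a Coulomb term.  Interactions are truncated at `cutoff`
#' (default 1 nm).
#'
#' @param epsilon well depth, kJ/mol: a scalar for the pair or a length-2
#'   vector `(particle, adsorbate)` to be combined.
#' @param sigma contact distance, nm: scalar or length-2 as above.
#' @param cutoff truncation radius, nm.
#' @param charges optional length-2 vector of charges (e) for a Coulomb
#'   term.
#' @return an object of class `lj_params`.
#' @export
lj_params <- function(epsilon, sigma, cutoff = 1.0, charges = NULL) {
  comb_eps <- if (length(epsilon) == 2) sqrt(prod(epsilon)) else epsilon[1]
  comb_sig <- if (length(sigma) == 2) mean(sigma) else sigma[1]
  if (comb_eps < 0 || comb_sig <= 0 || cutoff <= 0)
    stop("need epsilon >= 0, sigma > 0, cutoff > 0")
  structure(list(epsilon = comb_eps, sigma = comb_sig, cutoff = cutoff,
                 charges = charges),
            class = "lj_params")
}

# pair energy for distances r (vectorised); no cutoff applied here
lj_pair_energy <- function(r, params) {
  sr6 <- (params$sigma / r)^6
  e <- 4 * params$epsilon * (sr6^2 - sr6)
  if (!is.null(params$charges)) {
    kc <- 138.935458 # kJ mol^-1 nm e^-2
    e <- e + kc * prod(params$charges) / r
  }
  e
}

#' Interaction-energy (enthalpy) profile along a reaction coordinate
#'
#' For each adsorbate configuration along xi, sums the pairwise 12-6
#' Lennard-Jones energy (plus an optional Coulomb term) between every
#' particle atom and every adsorbate site within the cutoff, and
#' references the profile to zero at the largest xi.  The resulting curve
#' plays the role of the enthalpy change during a single adsorption
#' event.
#'
#' @param xi reaction-coordinate values, nm, one per configuration.
#' @param configurations list of M x 3 adsorbate site matrices
#'   (particle-centered frame, nm).
#' @param particle a `faceted_nanoparticle`.
#' @param params [lj_params()].
#' @return data frame with columns `xi` and `delta_h` (kJ/mol).
#' @export
lj_energy_profile <- function(xi, configurations, particle, params) {
  stopifnot(length(xi) == length(configurations),
            inherits(particle, "faceted_nanoparticle"),
            inherits(params, "lj_params"))
  np <- particle$positions
  e <- vapply(configurations, function(cfg) {
    cfg <- as.matrix(cfg)
    d <- vapply(seq_len(nrow(cfg)), function(i)
      sqrt(rowSums(sweep(np, 2, cfg[i, ])^2)), numeric(nrow(np)))
    d <- as.numeric(d)
    if (any(d < 1e-12)) stop("overlapping sites (r = 0)")
    d <- d[d <= params$cutoff]
    if (!length(d)) 0 else sum(lj_pair_energy(d, params))
  }, numeric(1))
  ord <- order(xi)
  e <- e - e[ord[length(ord)]] # zero at the largest xi
  data.frame(xi = xi, delta_h = e)
}

#' Enthalpy-entropy decomposition of an adsorption PMF
#'
#' Combines a free-energy profile with an interaction-energy (enthalpy)
#' profile via `T dS(xi*) = dH(xi*) - dG(xi*)` on the shared support,
#' where `xi* = xi - R` measures distance from the particle surface
#' rather than its center.  All three curves are re-anchored to zero at
#' the largest xi*, so the identity `dG - dH + T dS = 0` holds pointwise
#' by construction.
#'
#' @param pmf a `pmf_profile`.
#' @param enthalpy data frame with columns `xi`, `delta_h` (as from
#'   [lj_energy_profile()]).
#' @param particle_radius particle radius R, nm.
#' @return an object of class `thermo_profiles`: data frame with columns
#'   `xi_star`, `delta_g`, `delta_h`, `t_delta_s` (kJ/mol).
#' @export
decompose_thermo <- function(pmf, enthalpy, particle_radius = 0) {
  stopifnot(inherits(pmf, "pmf_profile"),
            all(c("xi", "delta_h") %in% names(enthalpy)))
  lo <- max(min(pmf$xi), min(enthalpy$xi))
  hi <- min(max(pmf$xi), max(enthalpy$xi))
  if (lo >= hi)
    stop("PMF and enthalpy supports do not overlap; cannot interpolate")
  keep <- pmf$xi >= lo - 1e-12 & pmf$xi <= hi + 1e-12
  xi <- pmf$xi[keep]
  g <- pmf$delta_g[keep]
  h <- stats::approx(enthalpy$xi, enthalpy$delta_h, xi, rule = 1)$y
  g <- g - g[length(g)]
  h <- h - h[length(h)]
  out <- data.frame(xi_star = xi - particle_radius,
                    delta_g = g, delta_h = h, t_delta_s = h - g)
  class(out) <- c("thermo_profiles", "data.frame")
  out
}
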