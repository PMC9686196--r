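# Synthetic-data generators.  A kinetic Monte Carlo surrogate reproduces the
# statistical structure the downstream analyses assume -- dispersed oligomers
# that self-aggregate into clusters and then adsorb onto the nanoparticle
# with a tunable {111}-vs-{100} affinity -- and a Metropolis sampler draws
# umbrella-window samples from analytic 1D potentials under harmonic biases.
# Both carry ground truth for parameter-recovery tests.

#' Parameters of the synthetic adsorption model
#'
#' Defaults mirror the conditions of the reference study: 60 oligomers in a
#' 13 nm periodic box around a 4 nm Wulff particle, a 100 ns horizon
#' discretised as 1000 frames of 100 ps.  The kinetic rules are: oligomer
#' clusters perform periodic random walks (rigid clusters step slower, in
#' proportion to size^(-1/3)); two free clusters merge irreversibly when
#' their centers approach within `aggregation_radius`; a free cluster whose
#' sites come within `adsorption_radius` of a nanoparticle surface atom
#' binds with probability `base_binding_prob` times `facet_affinity` if the
#' nearest surface atom is a \{111\} terrace atom, times 1 if \{100\}, and
#' times (1 + facet_affinity)/2 if an edge atom.  Binding is irreversible.
#'
#' @param particle a `faceted_nanoparticle`, fixed at the box center.
#' @param n_oligomers number of oligomers.
#' @param box_edge cubic box edge, nm.
#' @param step_time time per frame, ps.
#' @param n_frames number of frames.
#' @param diffusion_step rms displacement of a monomer per frame, nm.
#' @param aggregation_radius center-center merge distance, nm.
#' @param adsorption_radius site-to-surface-atom binding distance, nm.
#' @param facet_affinity binding-probability ratio
#'   P(bind | nearest \{111\}) / P(bind | nearest \{100\}); must be > 0.
#' @param base_binding_prob per-contact per-frame binding probability on a
#'   \{100\} anchor, in \[0, 1\].
#' @param sites_per_oligomer sites per oligomer cloud.
#' @param gyration_radius oligomer cloud radius, nm.
#' @param min_separation initial center separation, nm.
#' @param record_stride store every `record_stride`-th frame.
#' @param seed master integer seed.
#' @return an object of class `adsorption_params`.
#' @export
adsorption_params <- function(particle,
                              n_oligomers = 60,
                              box_edge = 13,
                              step_time = 100,
                              n_frames = 1000,
                              diffusion_step = 0.5,
                              aggregation_radius = 1.0,
                              adsorption_radius = 0.45,
                              facet_affinity = 1,
                              base_binding_prob = 0.1,
                              sites_per_oligomer = 69,
                              gyration_radius = 0.5,
                              min_separation = 1.5,
                              record_stride = 10,
                              seed = 1) {
  stopifnot(inherits(particle, "faceted_nanoparticle"),
            n_oligomers >= 1, box_edge > 0, step_time > 0,
            diffusion_step > 0, aggregation_radius > 0,
            adsorption_radius > 0, facet_affinity > 0,
            base_binding_prob >= 0, base_binding_prob <= 1,
            sites_per_oligomer >= 1, gyration_radius > 0,
            record_stride >= 1)
  if (n_frames < 1) stop("need at least one frame")
  if (max(abs(particle$positions)) * 2 > box_edge)
    stop("nanoparticle larger than the box")
  if (base_binding_prob * max(facet_affinity, 1) > 1)
    stop("base_binding_prob x facet_affinity exceeds 1")
  structure(as.list(environment()), class = "adsorption_params")
}

#' Simulate a synthetic adsorption trajectory
#'
#' Runs the kinetic Monte Carlo model of [adsorption_params()] and returns
#' the recorded frames plus a ground-truth log of every merge and binding
#' event (with the facet label of the anchoring surface atom).  Bound
#' clusters stay bound; a free cluster that touches an already adsorbed
#' cluster joins it.  Deterministic for a fixed seed.
#'
#' @param params an [adsorption_params()] object.
#' @return an object of class `synthetic_trajectory` with elements `sites`
#'   (n_sites x 3 x n_recorded array, nm), `times` (ps), `oligomer_id`,
#'   `membership` (oligomer x recorded-frame cluster ids), `truth_log`
#'   (data frame of events), `box_edge`, `particle`, `params`.
#' @export
#' @examples
#' np <- build_wulff_nanoparticle(lattice_spec(), wulff_spec(0.96, 2.0))
#' pars <- adsorption_params(np, n_oligomers = 5, box_edge = 8,
#'                           n_frames = 50, sites_per_oligomer = 8, seed = 1)
#' traj <- simulate_adsorption(pars)
#' head(traj$truth_log)
simulate_adsorption <- function(params) {
  stopifnot(inherits(params, "adsorption_params"))
  p <- params
  np_pos <- sweep(p$particle$positions, 2, rep(p$box_edge / 2, 3), "+")
  surf <- p$particle$facet_labels != "BULK"
  surf_pos <- np_pos[surf, , drop = FALSE]
  surf_lab <- as.character(p$particle$facet_labels[surf])

  with_seed(substream_seed(p$seed, "trajectory"), {
    keep_out <- max(sqrt(rowSums(p$particle$positions^2))) +
      p$gyration_radius + p$adsorption_radius + 0.1
    init <- place_oligomers(p$n_oligomers, p$box_edge,
                            p$sites_per_oligomer, p$gyration_radius,
                            p$min_separation,
                            exclusion_center = rep(p$box_edge / 2, 3),
                            exclusion_radius = keep_out)
    n <- p$n_oligomers
    spo <- p$sites_per_oligomer
    cl_of <- seq_len(n)              # cluster id per oligomer
    centers <- init$centers          # one row per cluster id (grows stale rows)
    off_center <- matrix(0, n, 3)    # oligomer center offset within cluster
    site_off <- init$offsets         # rigid per-oligomer site offsets
    active <- rep(TRUE, n)           # cluster id still alive
    bound <- rep(FALSE, n)           # cluster id adsorbed
    ext_olig <- vapply(seq_len(n), function(i)
      max(sqrt(rowSums(site_off[, , i, drop = FALSE][, , 1,
                                                     drop = TRUE]^2))),
      numeric(1))
    extent <- ext_olig               # per cluster

    rec_idx <- unique(c(seq(1L, p$n_frames, by = p$record_stride),
                        p$n_frames))
    n_rec <- length(rec_idx)
    sites_arr <- array(NA_real_, c(n * spo, 3, n_rec))
    membership <- matrix(NA_integer_, n, n_rec)
    log_rows <- list()
    rec_ptr <- 1L

    olig_sites <- function(i) {
      ctr <- centers[cl_of[i], ] + off_center[i, ]
      sweep(site_off[, , i, drop = FALSE][, , 1, drop = TRUE], 2, ctr, "+")
    }
    cluster_size <- function(cid) sum(cl_of == cid)

    for (f in seq_len(p$n_frames)) {
      ## diffusion of free clusters
      for (cid in which(active & !bound)) {
        sz <- cluster_size(cid)
        step <- rnorm(3, sd = p$diffusion_step / sqrt(3)) * sz^(-1 / 3)
        centers[cid, ] <- wrap_box(centers[cid, ] + step, p$box_edge)
      }

      ## merges: union clusters whose centers are within aggregation_radius
      ids <- which(active)
      if (length(ids) > 1) {
        ctr <- centers[ids, , drop = FALSE]
        dd <- as.matrix_dist(pairdist_cpp(ctr, p$box_edge, 0L), length(ids))
        close_pairs <- which(dd <= p$aggregation_radius, arr.ind = TRUE)
        close_pairs <- close_pairs[close_pairs[, 1] < close_pairs[, 2], ,
                                   drop = FALSE]
        if (nrow(close_pairs) > 0) {
          parent <- seq_along(ids)
          findp <- function(i) { while (parent[i] != i) i <- parent[i]; i }
          for (r in seq_len(nrow(close_pairs))) {
            a <- findp(close_pairs[r, 1]); b <- findp(close_pairs[r, 2])
            if (a != b) parent[max(a, b)] <- min(a, b)
          }
          roots <- vapply(seq_along(ids), findp, integer(1))
          for (g in unique(roots[duplicated(roots)])) {
            grp <- ids[roots == g]
            keep <- if (any(bound[grp])) grp[bound[grp]][1] else grp[1]
            ref <- centers[keep, ]
            members <- which(cl_of %in% grp)
            sizes <- vapply(grp, cluster_size, numeric(1))
            # mass-weighted merged center (minimum-image relative to `keep`)
            rel <- min_image(sweep(centers[grp, , drop = FALSE], 2, ref),
                             p$box_edge)
            newc <- if (any(bound[grp])) ref else
              wrap_box(ref + colSums(rel * sizes) / sum(sizes), p$box_edge)
            for (i in members) {
              oldc <- centers[cl_of[i], ] + off_center[i, ]
              off_center[i, ] <- min_image(oldc - newc, p$box_edge)
            }
            centers[keep, ] <- newc
            active[setdiff(grp, keep)] <- FALSE
            bound[keep] <- any(bound[grp])
            cl_of[members] <- keep
            extent[keep] <- max(sqrt(rowSums(off_center[members, ,
                                                        drop = FALSE]^2)) +
                                  ext_olig[members])
            log_rows[[length(log_rows) + 1L]] <- data.frame(
              frame = f, time_ps = f * p$step_time, event = "merge",
              cluster_id = keep,
              oligomer_ids = paste(sort(members), collapse = ","),
              facet = NA_character_, stringsAsFactors = FALSE)
          }
        }
      }

      ## binding attempts for free clusters near the surface
      for (cid in which(active & !bound)) {
        cd <- dist_to_point_cpp(matrix(centers[cid, ], 1), rep(0, 3), 0)
        near <- nearest_neighbour_cpp(matrix(centers[cid, ], 1), surf_pos,
                                      p$box_edge)
        if (near$distance[1] - extent[cid] > p$adsorption_radius) next
        members <- which(cl_of == cid)
        st <- do.call(rbind, lapply(members, olig_sites))
        nn <- nearest_neighbour_cpp(st, surf_pos, p$box_edge)
        j <- which.min(nn$distance)
        if (nn$distance[j] > p$adsorption_radius) next
        anchor <- surf_lab[nn$index[j]]
        mult <- switch(anchor, F111 = p$facet_affinity, F100 = 1,
                       (1 + p$facet_affinity) / 2)
        if (runif(1) < min(1, p$base_binding_prob * mult)) {
          bound[cid] <- TRUE
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            frame = f, time_ps = f * p$step_time, event = "bind",
            cluster_id = cid,
            oligomer_ids = paste(sort(members), collapse = ","),
            facet = anchor, stringsAsFactors = FALSE)
        }
      }

      ## record
      if (rec_ptr <= n_rec && f == rec_idx[rec_ptr]) {
        st <- do.call(rbind, lapply(seq_len(n), olig_sites))
        sites_arr[, , rec_ptr] <- wrap_box(st, p$box_edge)
        membership[, rec_ptr] <- cl_of
        rec_ptr <- rec_ptr + 1L
      }
    }

    truth_log <- if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(frame = integer(0), time_ps = numeric(0),
                 event = character(0), cluster_id = integer(0),
                 oligomer_ids = character(0), facet = character(0),
                 stringsAsFactors = FALSE)
    structure(list(sites = sites_arr,
                   times = rec_idx * p$step_time,
                   oligomer_id = init$oligomer_id,
                   membership = membership,
                   truth_log = truth_log,
                   box_edge = p$box_edge,
                   particle = p$particle,
                   params = p),
              class = "synthetic_trajectory")
  })
}

# expand a packed lower-triangle distance vector into a symmetric matrix
as.matrix_dist <- function(dv, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- dv
  m <- m + t(m)
  diag(m) <- Inf
  m
}

#' @export
print.synthetic_trajectory <- function(x, ...) {
  cat(sprintf(paste0("synthetic trajectory: %d oligomers x %d sites, ",
                     "%d recorded frames over %.0f ps, box %.1f nm\n"),
              max(x$oligomer_id), sum(x$oligomer_id == 1L),
              length(x$times), max(x$times), x$box_edge))
  cat(sprintf("  events: %d merges, %d bindings\n",
              sum(x$truth_log$event == "merge"),
              sum(x$truth_log$event == "bind")))
  invisible(x)
}

#' Estimate the facet affinity from binding events
#'
#' Recovers the \{111\}-vs-\{100\} binding bias from one or more synthetic
#' trajectories as the ratio of per-facet binding rates per unit bare facet
#' area: `alpha_hat = (N111 / S111) / (N100 / S100)`, with a 95% binomial
#' confidence interval propagated from the anchored-event counts
#' (edge-anchored events are excluded).
#'
#' @param trajs a `synthetic_trajectory` or list of them (replicas).
#' @param options [sasa_options()] for the bare-particle facet areas.
#' @return list with `alpha_hat`, `ci` (length-2 vector), `n111`, `n100`.
#' @export
estimate_facet_affinity <- function(trajs, options = sasa_options()) {
  if (inherits(trajs, "synthetic_trajectory")) trajs <- list(trajs)
  particle <- trajs[[1]]$particle
  sr <- per_facet_sasa(particle, options = options)
  s111 <- sr$facet_totals[["F111"]]; s100 <- sr$facet_totals[["F100"]]
  fac <- unlist(lapply(trajs, function(t)
    t$truth_log$facet[t$truth_log$event == "bind"]))
  n111 <- sum(fac == "F111", na.rm = TRUE)
  n100 <- sum(fac == "F100", na.rm = TRUE)
  if (n111 + n100 == 0) stop("no facet-anchored binding events")
  est <- (n111 / s111) / max(n100, 0.5) * s100
  ci_p <- stats::binom.test(n111, n111 + n100)$conf.int
  odds <- ci_p / (1 - ci_p)
  list(alpha_hat = est, ci = sort(odds * s100 / s111),
       n111 = n111, n100 = n100)
}

## ---- umbrella sampling -----------------------------------------------

#' Analytic 1D test potentials
#'
#' Named potentials used to generate umbrella-window samples with known
#' ground truth: `"flat"` (U = 0), `"harmonic"`
#' (0.5 kappa (xi - x0)^2), `"gaussian_well"`
#' (-depth exp(-(xi - x0)^2 / (2 width^2)), a single adsorption-like well),
#' `"double_well"` (depth ((xi - x0)^2/width^2 - 1)^2), and `"tabulated"`
#' (linear interpolation of `xi`/`u` vectors).
#'
#' @param id potential name.
#' @param x0 center, nm.
#' @param kappa harmonic stiffness, kJ mol^-1 nm^-2.
#' @param depth well depth / barrier scale, kJ/mol.
#' @param width length scale, nm.
#' @param xi,u grid for `"tabulated"`.
#' @return an object of class `potential_spec`.
#' @export
#' @examples
#' pot <- make_potential("gaussian_well", x0 = 1.7, depth = 10, width = 0.15)
#' potential_energy(pot, c(1.7, 2.5))
make_potential <- function(id = c("flat", "harmonic", "gaussian_well",
                                  "double_well", "tabulated"),
                           x0 = 0, kappa = 1000, depth = 10, width = 0.2,
                           xi = NULL, u = NULL) {
  id <- match.arg(id)
  fun <- switch(id,
    flat = function(x) rep(0, length(x)),
    harmonic = function(x) 0.5 * kappa * (x - x0)^2,
    gaussian_well = function(x) -depth * exp(-(x - x0)^2 / (2 * width^2)),
    double_well = function(x) depth * ((x - x0)^2 / width^2 - 1)^2,
    tabulated = {
      if (is.null(xi) || is.null(u)) stop("tabulated potential needs xi and u")
      function(x) stats::approx(xi, u, x, rule = 2)$y
    })
  structure(list(id = id, fun = fun,
                 params = list(x0 = x0, kappa = kappa, depth = depth,
                               width = width)),
            class = "potential_spec")
}

#' @rdname make_potential
#' @param pot a `potential_spec`.
#' @export
potential_energy <- function(pot, xi) {
  stopifnot(inherits(pot, "potential_spec"))
  pot$fun(xi)
}

#' Umbrella-sampling specification
#'
#' Windows along a 1D reaction coordinate with harmonic biases
#' `0.5 k (xi - center)^2`.  The default force constant, 10000
#' kJ mol^-1 nm^-2 at 300 K, matches the restraint strength of the
#' adsorption study; window spacing is a free choice (default 0.1 nm).
#'
#' @param potential a [make_potential()] object.
#' @param window_centers strictly increasing centers, nm.
#' @param force_constant harmonic bias constant, kJ mol^-1 nm^-2.
#' @param temperature K.
#' @param n_samples_per_window samples recorded per window.
#' @param seed master integer seed.
#' @param burn_in discarded adaptation steps per window.
#' @param thin record every `thin`-th Metropolis move.
#' @return an object of class `umbrella_spec`.
#' @export
umbrella_spec <- function(potential, window_centers,
                          force_constant = 10000, temperature = 300,
                          n_samples_per_window = 5000, seed = 1,
                          burn_in = 1000, thin = 5) {
  stopifnot(inherits(potential, "potential_spec"),
            length(window_centers) >= 1,
            all(diff(window_centers) > 0),
            force_constant > 0, temperature > 0,
            n_samples_per_window >= 1)
  structure(as.list(environment()), class = "umbrella_spec")
}

#' Sample umbrella windows from an analytic potential
#'
#' For each window draws `n_samples_per_window` values from the biased
#' density `exp(-(U(xi) + 0.5 k (xi - center)^2) / kBT)` by Metropolis
#' Monte Carlo.  The proposal step is auto-tuned to a 30-50% acceptance
#' rate during burn-in; a sampling-phase acceptance below 1% raises an
#' error.  Reproducible for a fixed seed (one substream per window).
#'
#' @param spec an [umbrella_spec()].
#' @return list of `umbrella_window` objects (fields `center`,
#'   `force_constant`, `samples`).
#' @export
#' @examples
#' spec <- umbrella_spec(make_potential("flat"), window_centers = 1,
#'                       n_samples_per_window = 500, seed = 1)
#' w <- sample_umbrella_windows(spec)[[1]]
#' c(mean(w$samples), stats::var(w$samples))
sample_umbrella_windows <- function(spec) {
  stopifnot(inherits(spec, "umbrella_spec"))
  kT <- .kB * spec$temperature
  # natural scale of the biased distribution
  sigma0 <- sqrt(kT / spec$force_constant)
  lapply(seq_along(spec$window_centers), function(i) {
    ctr <- spec$window_centers[i]
    with_seed(substream_seed(spec$seed, paste0("window", i)), {
      etot <- function(x)
        potential_energy(spec$potential, x) +
          0.5 * spec$force_constant * (x - ctr)^2
      x <- ctr
      ex <- etot(x)
      step <- 2.5 * sigma0
      acc_win <- 0L
      # burn-in with step adaptation every 50 moves
      for (t in seq_len(spec$burn_in)) {
        xp <- x + runif(1, -step, step)
        ep <- etot(xp)
        if (log(runif(1)) < (ex - ep) / kT) {
          x <- xp; ex <- ep; acc_win <- acc_win + 1L
        }
        if (t %% 50L == 0L) {
          r <- acc_win / 50
          if (r > 0.5) step <- step * 1.25
          else if (r < 0.3) step <- step / 1.25
          acc_win <- 0L
        }
      }
      n_mv <- spec$n_samples_per_window * spec$thin
      acc <- 0L
      samples <- numeric(spec$n_samples_per_window)
      for (t in seq_len(n_mv)) {
        xp <- x + runif(1, -step, step)
        ep <- etot(xp)
        if (log(runif(1)) < (ex - ep) / kT) { x <- xp; ex <- ep; acc <- acc + 1L }
        if (t %% spec$thin == 0L) samples[t %/% spec$thin] <- x
      }
      if (acc / n_mv < 0.01) stop("step size misconfigured")
      structure(list(center = ctr, force_constant = spec$force_constant,
                     samples = samples),
                class = "umbrella_window")
    })
  })
}

#' Write umbrella windows as two-column text plus a JSON manifest
#'
#' Each window becomes `window_NN.txt` (sample index, xi in nm) and the
#' manifest records centers, force constant and temperature -- the same
#' metadata a pull-code post-processor expects.
#'
#' @param windows list of `umbrella_window`.
#' @param dir output directory (created if needed).
#' @param temperature K, stored in the manifest.
#' @param seed optional seed recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir, temperature = 300,
                                   seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    files[i] <- sprintf("window_%02d.txt", i)
    utils::write.table(
      data.frame(index = seq_along(w$samples), xi = w$samples),
      file.path(dir, files[i]),
      sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    files = files,
    centers = vapply(windows, `[[`, numeric(1), "center"),
    force_constant = windows[[1]]$force_constant,
    temperature = temperature, seed = seed)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Read umbrella windows written by [write_umbrella_windows()]
#'
#' @param dir directory containing `manifest.json` and window files.
#' @return list with `windows` (list of `umbrella_window`) and
#'   `temperature`.
#' @export
read_umbrella_windows <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("manifest.json not found in ", dir)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  windows <- lapply(seq_along(m$files), function(i) {
    d <- utils::read.table(file.path(dir, m$files[i]))
    structure(list(center = m$centers[i],
                   force_constant = m$force_constant,
                   samples = d[[2]]),
              class = "umbrella_window")
  })
  list(windows = windows, temperature = m$temperature)
}
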