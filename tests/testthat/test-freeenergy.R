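# WHAM, polar FEL assembly, LJ profiles and the thermodynamic decomposition.

kT300 <- 0.008314462618 * 300

test_that("WHAM is flat for a flat potential with overlapping windows", {
  spec <- umbrella_spec(make_potential("flat"), seq(1.6, 2.4, 0.2),
                        force_constant = 100, n_samples_per_window = 30000,
                        seed = 1)
  pmf <- wham(sample_umbrella_windows(spec), bin_width = 0.04)
  sel <- pmf$xi >= 1.6 & pmf$xi <= 2.4
  expect_lt(diff(range(pmf$delta_g[sel])), 0.2)
  expect_equal(pmf$reference, "zero-at-max-xi")
})

test_that("WHAM recovers a planted single well from overlapping windows", {
  pot <- make_potential("gaussian_well", x0 = 1.7, depth = 10, width = 0.15)
  spec <- umbrella_spec(pot, seq(1.5, 2.5, 0.04),
                        n_samples_per_window = 8000, seed = 1)
  pmf <- wham(sample_umbrella_windows(spec))
  sel <- pmf$xi >= 1.5 & pmf$xi <= 2.5
  truth <- potential_energy(pot, pmf$xi[sel])
  g <- pmf$delta_g[sel]
  truth <- truth - truth[sum(sel)]
  g <- g - g[sum(sel)]
  expect_lt(sqrt(mean((g - truth)^2)), 0.5)
  # the well bottom is located correctly
  expect_equal(pmf$xi[sel][which.min(g)], 1.7, tolerance = 0.03 / 1.7)
})

test_that("a single unbiased window reduces to -kT log(histogram)", {
  set.seed(2)
  x <- rnorm(20000, 2, 0.1)
  w <- list(structure(list(center = 2, force_constant = 1e-9, samples = x),
                      class = "umbrella_window"))
  pmf <- wham(w, bin_width = 0.02, min_count = 20)
  h <- hist(x, breaks = seq(floor(min(x) / 0.02) * 0.02,
                            ceiling(max(x) / 0.02) * 0.02, 0.02),
            plot = FALSE)
  ref <- -kT300 * log(h$counts[h$counts >= 20])
  # equal up to one additive constant
  dev <- (pmf$delta_g - mean(pmf$delta_g)) - (ref - mean(ref))
  expect_lt(max(abs(dev)), 1e-6)
})

test_that("WHAM reports missing overlap by naming the gap", {
  spec <- umbrella_spec(make_potential("flat"), c(1.0, 3.0),
                        n_samples_per_window = 500, seed = 1)
  w <- sample_umbrella_windows(spec)
  expect_error(wham(w), "no histogram overlap.*1 and 3")
})

test_that("WHAM is invariant under coordinate shifts and window merging", {
  pot <- make_potential("gaussian_well", x0 = 1.7, depth = 6, width = 0.2)
  spec <- umbrella_spec(pot, seq(1.5, 2.1, 0.05),
                        n_samples_per_window = 3000, seed = 5)
  w <- sample_umbrella_windows(spec)
  pmf <- wham(w)
  # shift every center and sample by the same constant
  wsh <- lapply(w, function(x) {
    x$center <- x$center + 0.5; x$samples <- x$samples + 0.5; x
  })
  pmf_sh <- wham(wsh)
  expect_equal(pmf_sh$xi, pmf$xi + 0.5, tolerance = 1e-9)
  expect_equal(pmf_sh$delta_g, pmf$delta_g, tolerance = 1e-6)
  # duplicating a window as two half-sets leaves the result unchanged
  half <- length(w[[4]]$samples) / 2
  wdup <- c(w[-4], list(
    structure(list(center = w[[4]]$center, force_constant = 10000,
                   samples = w[[4]]$samples[seq_len(half)]),
              class = "umbrella_window"),
    structure(list(center = w[[4]]$center, force_constant = 10000,
                   samples = w[[4]]$samples[-seq_len(half)]),
              class = "umbrella_window")))
  pmf_dup <- wham(wdup)
  expect_equal(pmf_dup$delta_g, pmf$delta_g, tolerance = 1e-4)
})

test_that("polar FEL assembly locates planted minima", {
  xi <- seq(1.2, 2.6, 0.02)
  mk <- function(depth, x0) structure(
    list(xi = xi, delta_g = -depth * exp(-(xi - x0)^2 / (2 * 0.1^2)),
         std = rep(NA_real_, length(xi)), reference = "zero-at-max-xi"),
    class = "pmf_profile")
  pmfs <- list(mk(8, 2.2), mk(9, 2.2), mk(14, 2.2), mk(10, 2.2))
  fel <- assemble_polar_fel(pmfs, thetas = c(0, 18.2, 36.5, 54.7))
  expect_equal(fel$minimum$theta, 36.5)
  fel2 <- assemble_polar_fel(list(mk(8, 2.2), mk(9, 2.3), mk(10, 2.2),
                                  mk(14, 2.2)),
                             thetas = c(0, 18.2, 36.5, 54.7))
  expect_equal(fel2$minimum$theta, 54.7)
  expect_true(fel2$minimum$xi > 2 && fel2$minimum$xi < 2.5)
  expect_false(fel2$minimum$degenerate)
  # identical PMFs: the minimum is degenerate in theta and flagged
  fel3 <- assemble_polar_fel(list(mk(5, 2.0), mk(5, 2.0)), thetas = c(0, 54.7))
  expect_true(fel3$minimum$degenerate)
})

test_that("FEL interpolation matches analytic evaluation on shifted grids", {
  f <- function(x) 3 * (x - 2)^2 - 5
  g1 <- seq(1.2, 2.6, 0.02)
  g2 <- seq(1.21, 2.61, 0.02)
  p1 <- structure(list(xi = g1, delta_g = f(g1), std = rep(NA_real_,
                                                           length(g1)),
                       reference = "r"), class = "pmf_profile")
  p2 <- structure(list(xi = g2, delta_g = f(g2) - 1, std = rep(NA_real_,
                                                               length(g2)),
                       reference = "r"), class = "pmf_profile")
  fel <- assemble_polar_fel(list(p1, p2), thetas = c(0, 54.7))
  for (i in 1:2)
    expect_equal(fel$delta_g[i, ], f(fel$xi) - (i - 1), tolerance = 1e-3)
  # disjoint ranges are refused
  p3 <- structure(list(xi = g1 + 5, delta_g = f(g1), std = rep(NA_real_,
                                                               length(g1)),
                       reference = "r"), class = "pmf_profile")
  expect_error(assemble_polar_fel(list(p1, p3), thetas = c(0, 10)),
               "disjoint")
})

test_that("LJ pair energies and cutoff behaviour are exact", {
  par <- lj_params(epsilon = 0.8, sigma = 0.3)
  # zero crossing at r = sigma, minimum -epsilon at r = 2^(1/6) sigma
  expect_equal(npadsorb:::lj_pair_energy(0.3, par), 0)
  expect_equal(npadsorb:::lj_pair_energy(2^(1 / 6) * 0.3, par), -0.8)
  # combining rules: geometric epsilon, arithmetic sigma
  par2 <- lj_params(epsilon = c(0.4, 1.6), sigma = c(0.2, 0.4))
  expect_equal(par2$epsilon, 0.8)
  expect_equal(par2$sigma, 0.3)
  # configurations entirely beyond the cutoff give an identically zero profile
  xi <- c(2.2, 2.6, 3.0)
  cfgs <- lapply(xi, function(z) matrix(c(0, 0, z + np_small$radius_estimate),
                                        1))
  prof <- lj_energy_profile(xi, cfgs, np_small,
                            lj_params(0.5, 0.3, cutoff = 1.0))
  expect_true(all(prof$delta_h == 0))
  expect_error(
    lj_energy_profile(0, list(np_small$positions[1, , drop = FALSE]),
                      np_small, par),
    "overlapping sites")
})

test_that("truncated LJ profiles agree with the no-cutoff oracle", {
  xi <- seq(1.3, 2.2, 0.1)
  cfgs <- lapply(xi, function(z)
    rbind(c(0, 0, z), c(0.1, 0, z + 0.1), c(0, -0.1, z + 0.2)))
  par <- lj_params(0.6, 0.3, cutoff = 1.0)
  prof <- lj_energy_profile(xi, cfgs, np_small, par)
  raw <- vapply(cfgs, function(cfg)
    oracle_lj_total(np_small$positions, cfg, 0.6, 0.3), numeric(1))
  raw <- raw - raw[length(raw)]
  # truncation bound: every discarded pair is farther than the cutoff
  n_pairs <- nrow(np_small$positions) * 3
  bound <- 2 * n_pairs * 4 * 0.6 * (0.3 / 1.0)^6
  expect_true(all(abs(prof$delta_h - raw) <= bound))
})

test_that("the thermodynamic decomposition is an exact identity", {
  xi <- seq(1.0, 3.0, 0.05)
  pmf <- structure(list(xi = xi,
                        delta_g = -12 * exp(-(xi - 1.4)^2 / 0.05),
                        std = rep(NA_real_, length(xi)),
                        reference = "zero-at-max-xi"),
                   class = "pmf_profile")
  dh <- data.frame(xi = xi, delta_h = -20 * exp(-(xi - 1.35)^2 / 0.04))
  th <- decompose_thermo(pmf, dh, particle_radius = 1.0)
  expect_equal(max(abs(th$delta_g - th$delta_h + th$t_delta_s)), 0)
  expect_equal(th$xi_star, xi - 1.0)
  expect_equal(th$delta_g[nrow(th)], 0)
  expect_equal(th$t_delta_s[nrow(th)], 0)
  # dH identical to dG implies TdS = 0
  dh2 <- data.frame(xi = xi, delta_h = pmf$delta_g)
  th2 <- decompose_thermo(pmf, dh2)
  expect_true(all(abs(th2$t_delta_s) < 1e-12))
  # equal-entropy facets: the dG difference equals the dH difference
  dh_111 <- data.frame(xi = xi, delta_h = -25 * exp(-(xi - 1.4)^2 / 0.05))
  dh_100 <- data.frame(xi = xi, delta_h = -18 * exp(-(xi - 1.4)^2 / 0.05))
  ts <- -6 * exp(-(xi - 1.4)^2 / 0.06)
  g111 <- structure(list(xi = xi, delta_g = dh_111$delta_h - ts,
                         std = rep(NA_real_, length(xi)), reference = "r"),
                    class = "pmf_profile")
  g100 <- structure(list(xi = xi, delta_g = dh_100$delta_h - ts,
                         std = rep(NA_real_, length(xi)), reference = "r"),
                    class = "pmf_profile")
  t111 <- decompose_thermo(g111, dh_111, 1)
  t100 <- decompose_thermo(g100, dh_100, 1)
  expect_equal(t111$delta_g - t100$delta_g, t111$delta_h - t100$delta_h,
               tolerance = 1e-12)
  expect_equal(t111$t_delta_s, t100$t_delta_s, tolerance = 1e-12)
  # non-overlapping supports are refused
  expect_error(decompose_thermo(pmf, data.frame(xi = xi + 10,
                                                delta_h = ts)),
               "overlap")
})
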