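# Wulff construction, facet classification and crystallographic utilities.

test_that("Wulff construction reproduces the reference 4 nm gold particle", {
  np <- build_wulff_nanoparticle(lat_au, wulff_spec(0.96, 4.0))
  expect_identical(nrow(np$positions), 1925L)
  expect_equal(equivalent_diameter(np), 3.96, tolerance = 0.01 / 3.96)
  expect_equal(colMeans(np$positions), rep(0, 3), tolerance = 1e-9)
  expect_true(all(table(np$facet_labels)[c("F111", "F100", "EDGE")] > 0))
})

test_that("a one-atom mass target yields a single edge-labelled atom", {
  d1 <- equivalent_diameter(1, lattice = lat_au)
  np <- build_wulff_nanoparticle(lat_au, wulff_spec(0.96, d1))
  expect_identical(nrow(np$positions), 1L)
  expect_equal(as.character(np$facet_labels), "EDGE")
  expect_error(build_wulff_nanoparticle(lat_au, wulff_spec(0.96, d1 / 3)),
               "target below minimal cluster")
  expect_error(lattice_spec(structure = "bcc"), "unsupported")
})

test_that("builder agrees with the brute-force lattice-enumeration oracle", {
  # atom-count agreement away from the oracle equivalence regime
  for (g in c(0.7, 0.96)) {
    np <- build_wulff_nanoparticle(lat_au, wulff_spec(g, 4.0))
    expect_identical(nrow(np$positions), nrow(oracle_wulff(0.4078, g, 4.0)),
                     info = paste("gamma", g))
  }
  # exact position equality for small targets
  for (g in c(0.8, 1.0)) {
    np <- build_wulff_nanoparticle(lat_au, wulff_spec(g, 1.8))
    orc <- oracle_wulff(0.4078, g, 1.8)
    expect_identical(nrow(np$positions), nrow(orc))
    a_srt <- np$positions[do.call(order, as.data.frame(np$positions)), ]
    b_srt <- orc[do.call(order, as.data.frame(orc)), ]
    expect_lt(max(abs(a_srt - b_srt)), 1e-6)
  }
})

test_that("built clusters are invariant under octahedral rotations", {
  np <- np_small
  key <- function(p) sort(apply(round(p / 1e-6) * 1e-6, 1, paste,
                                collapse = "/"))
  ref <- key(np$positions)
  rots <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  angs <- c(90, 180, 90, 120)
  for (i in seq_along(rots)) {
    r <- rotate_particle(np, rots[[i]], angs[i])
    expect_identical(key(r$positions), ref, info = paste("axis", i))
  }
})

test_that("coordination classification matches the O(N^2) oracle and slabs", {
  cn_pkg <- npadsorb:::coordination_cpp(np_small$positions, 0.34)
  expect_identical(as.integer(cn_pkg),
                   oracle_coordination(np_small$positions, 0.34))
  # interior of a perfect block is BULK (CN 12)
  block <- oracle_fcc_lattice(0.4078, 3)
  lab <- classify_atoms(block, lattice = lat_au)
  center <- which(rowSums(block^2) < 1e-12)
  expect_identical(as.character(lab[center]), "BULK")
  # top-layer atoms of {111} and {100} slabs
  for (fam in c("111", "100")) {
    slab <- oracle_slab(0.4078, fam)
    lab <- classify_atoms(slab, lattice = lat_au)
    central_top <- which(rowSums(slab^2) < 1e-12)
    expect_identical(as.character(lab[central_top]), paste0("F", fam),
                     info = fam)
  }
  expect_error(classify_atoms(np_small, neighbor_cutoff = 0.25),
               "ambiguous shell cutoff")
  expect_error(classify_atoms(np_small, neighbor_cutoff = 0.45),
               "ambiguous shell cutoff")
})

test_that("the {111} surface share decreases with the surface-energy ratio", {
  shares <- vapply(c(0.7, 0.96, 1.4), function(g) {
    np <- build_wulff_nanoparticle(lat_au, wulff_spec(g, 4.0))
    tb <- table(np$facet_labels)
    as.numeric(tb["F111"] / (tb["F111"] + tb["F100"]))
  }, numeric(1))
  expect_true(all(diff(shares) < 0))
})

test_that("atomic packing factors match the closed forms", {
  expect_equal(atomic_packing_factor(c(1, 1, 1)), 0.907, tolerance = 1e-3)
  expect_equal(atomic_packing_factor(c(1, 0, 0)), 0.785, tolerance = 1e-3)
  # {111} equals hexagonal disc packing pi/(2 sqrt(3)) to 4 decimals
  expect_equal(round(atomic_packing_factor(miller_plane(c(1, 1, 1))), 4),
               round(pi / (2 * sqrt(3)), 4))
  expect_error(atomic_packing_factor(c(1, 1, 0)), "unsupported")
})

test_that("interplanar angles are correct", {
  expect_equal(interplanar_angle(c(1, 0, 0), c(1, 1, 1)), 54.7356,
               tolerance = 1e-4)
  expect_equal(interplanar_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(interplanar_angle(c(1, 0, 0), c(1, 1, 0)), 45)
  expect_error(interplanar_angle(c(0, 0, 0), c(1, 1, 1)), "zero")
})

test_that("rigid rotations preserve geometry and map facet normals", {
  np <- np_small
  expect_equal(rotate_particle(np, c(0, 0, 1), 0)$positions, np$positions)
  expect_equal(rotate_particle(np, c(1, 2, 3), 360)$positions, np$positions,
               tolerance = 1e-9)
  r <- rotate_particle(np, c(1, 1, 1), 71.3)
  expect_equal(sort(npadsorb:::pairdist_cpp(r$positions, 0, 0L)),
               sort(npadsorb:::pairdist_cpp(np$positions, 0, 0L)), tolerance = 1e-9)
  expect_identical(r$facet_labels, np$facet_labels)
  # rotating by the interplanar angle about r = n100 x n111 maps the {111}
  # normal onto the former {100} normal
  n100 <- c(0, 0, 1)
  n111 <- c(1, 1, 1) / sqrt(3)
  axis <- c(n111[2] * n100[3] - n111[3] * n100[2],
            n111[3] * n100[1] - n111[1] * n100[3],
            n111[1] * n100[2] - n111[2] * n100[1])
  th <- interplanar_angle(c(0, 0, 1), c(1, 1, 1)) * pi / 180
  k <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  expect_equal(as.numeric(R %*% n111), n100, tolerance = 1e-9)
})

test_that("equivalent diameter follows the atomic-volume formula", {
  expect_equal(equivalent_diameter(1925, lattice = lat_au), 3.96,
               tolerance = 0.01 / 3.96)
  a <- 0.4078
  expect_equal(equivalent_diameter(4, lattice = lat_au),
               (6 * a^3 / pi)^(1 / 3))
  expect_error(equivalent_diameter(0, lattice = lat_au), "at least 1")
})
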