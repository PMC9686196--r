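# Density-based cluster counting and radial distribution analyses.

make_blobs <- function(k, n_per, sd = 0.15, centers_box = 10, seed = 1,
                       noise = 0) {
  set.seed(seed)
  ctr <- matrix(runif(3 * k, 2, centers_box - 2), ncol = 3)
  while (k > 1 && min(dist(ctr)) < 2.5)
    ctr <- matrix(runif(3 * k, 2, centers_box - 2), ncol = 3)
  pts <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(3 * n_per, sd = sd), ncol = 3), 2, ctr[i, ], "+")))
  if (noise > 0)
    pts <- rbind(pts, matrix(runif(3 * noise, 0, centers_box), ncol = 3))
  pts
}

test_that("dispersed oligomer clouds are counted one cluster each", {
  p <- place_oligomers(15, 12, sites_per_oligomer = 69,
                       gyration_radius = 0.5, min_separation = 2.5, seed = 2)
  res <- count_clusters(p$sites, clustering_params(), box_edge = 12)
  expect_identical(res$n_clusters, 15L)
  # labels agree with the oligomer partition (up to label names)
  tab <- table(p$oligomer_id, res$labels)
  expect_true(all(apply(tab > 0, 1, sum) == 1))
})

test_that("one merged blob is one cluster and small frames are noise", {
  blob <- matrix(rnorm(3 * 200, sd = 0.3), ncol = 3) + 5
  res <- count_clusters(blob, clustering_params(min_samples = 5,
                                                min_cluster_size = 60),
                        box_edge = 10)
  expect_identical(res$n_clusters, 1L)
  few <- matrix(runif(3 * 20, 0, 10), ncol = 3)
  res2 <- count_clusters(few, clustering_params(), box_edge = 10)
  expect_identical(res2$n_clusters, 0L)
  expect_error(count_clusters(few[0, ], clustering_params()), "at least one")
})

test_that("planted blobs plus sparse noise match the DBSCAN oracle", {
  for (k in c(2, 4)) {
    pts <- make_blobs(k, 80, sd = 0.12, seed = 10 + k, noise = 30)
    pars <- clustering_params(min_samples = 5, min_cluster_size = 60)
    res <- count_clusters(pts, pars, box_edge = 10)
    expect_identical(res$n_clusters, as.integer(k))
    orc <- oracle_dbscan(pts, eps = 0.35, min_pts = 5, box = 10)
    big <- names(which(table(orc[orc > 0]) >= 60))
    expect_identical(length(big), as.integer(k))
    # every planted blob is pure: one cluster label, same for both methods
    blob_labels <- res$labels[seq_len(k * 80)]
    truth <- rep(seq_len(k), each = 80)
    for (b in seq_len(k)) {
      expect_identical(length(unique(blob_labels[truth == b])), 1L)
      expect_identical(length(unique(orc[seq_len(k * 80)][truth == b])), 1L)
    }
  }
})

test_that("labels are invariant under permutation and rigid motion", {
  pts <- make_blobs(3, 70, sd = 0.12, seed = 5, noise = 15)
  pars <- clustering_params(min_samples = 5, min_cluster_size = 60)
  base <- count_clusters(pts, pars) # open boundaries
  perm <- sample(nrow(pts))
  res_p <- count_clusters(pts[perm, ], pars)
  expect_identical(res_p$n_clusters, base$n_clusters)
  # same partition after inverting the permutation
  expect_true(all(table(base$labels, res_p$labels[order(perm)]) %in%
                    c(0, table(base$labels))))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  res_r <- count_clusters(pts %*% t(R) + 1.5, pars)
  expect_identical(res_r$n_clusters, base$n_clusters)
  # rotation is exact up to floating point; allow a single borderline flip
  expect_gt(mean((res_r$labels == 0) == (base$labels == 0)), 0.995)
})

test_that("excess-of-mass selection agrees on well-separated blobs", {
  pts <- make_blobs(3, 80, sd = 0.12, seed = 9)
  for (sel in c("leaf", "eom")) {
    res <- count_clusters(pts, clustering_params(min_samples = 5,
                                                 min_cluster_size = 60,
                                                 selection = sel))
    expect_identical(res$n_clusters, 3L, info = sel)
  }
})

test_that("cluster-count series decays faster at higher concentration", {
  series_for <- function(n, seeds) {
    trajs <- lapply(seeds, function(s)
      small_traj(seed = s, n = n, frames = 150, spo = 10, box = 9,
                 p0 = 0, agg = 1.0, stride = 25))
    cluster_count_series(trajs, clustering_params(min_samples = 4,
                                                  min_cluster_size = 8))
  }
  lo <- series_for(8, 301:303)
  hi <- series_for(24, 401:403)
  # initial counts match the ground truth (first frame follows one step,
  # so a rare early merge is legitimate)
  expect_gte(lo$n_clusters_mean[1], 8 - 1)
  expect_gte(hi$n_clusters_mean[1], 24 - 1)
  # normalised decay is faster for the concentrated system
  expect_lt(min(hi$n_clusters_mean / 24), min(lo$n_clusters_mean / 8))
  # replicated frozen frame has zero spread
  one <- small_traj(seed = 5, n = 6, frames = 40, spo = 10, stride = 40)
  cs <- cluster_count_series(list(one, one),
                             clustering_params(min_samples = 4,
                                               min_cluster_size = 8))
  expect_true(all(cs$n_clusters_sd == 0))
})

test_that("reference RDF is flat for ideal-gas placements", {
  set.seed(3)
  n <- 4000
  tr <- structure(list(
    sites = array(runif(n * 3, 0, 10), c(n, 3, 1)),
    times = 0, oligomer_id = rep(1L, n), membership = NULL,
    truth_log = data.frame(), box_edge = 10, particle = NULL,
    params = NULL), class = "synthetic_trajectory")
  prof <- rdf_to_reference(tr, bin_width = 0.25, r_max = 5)
  sel <- prof$r_centers > 1 # skip tiny-shell counting noise
  shell_v <- 4 / 3 * pi * ((prof$r_centers + 0.125)^3 -
                             (prof$r_centers - 0.125)^3)
  expected <- n / 1000 * shell_v
  dev <- abs(prof$values[sel] - 1) * expected[sel] / sqrt(expected[sel])
  expect_true(all(dev < 3.5)) # within ~3 sigma Poisson bands
  expect_error(rdf_to_reference(tr, r_max = 6), "minimum-image")
})

test_that("a planted shell produces a peak at its radius", {
  u <- npadsorb:::golden_spiral_points(2000) * 2.5
  tr <- structure(list(
    sites = array(sweep(u, 2, rep(5, 3), "+"), c(2000, 3, 1)),
    times = 0, oligomer_id = rep(1L, 2000), membership = NULL,
    truth_log = data.frame(), box_edge = 10, particle = NULL,
    params = NULL), class = "synthetic_trajectory")
  prof <- rdf_to_reference(tr, bin_width = 0.1, r_max = 5)
  expect_equal(prof$r_centers[which.max(prof$values)], 2.5,
               tolerance = 0.051 / 2.5)
})

test_that("pair-distance histograms are conservative and oracle-exact", {
  # a compact configuration in a large box, so r_max spans all pairs
  p <- place_oligomers(4, 6, sites_per_oligomer = 12, min_separation = 2,
                       seed = 6)
  tr <- structure(list(
    sites = array(p$sites, c(nrow(p$sites), 3, 1)),
    times = 0, oligomer_id = p$oligomer_id, membership = NULL,
    truth_log = data.frame(), box_edge = 22, particle = NULL,
    params = NULL), class = "synthetic_trajectory")
  prof <- pair_distance_distribution(tr, bin_width = 0.05, r_max = 11)
  n <- nrow(p$sites)
  shell_v <- 4 / 3 * pi * ((prof$r_centers + 0.025)^3 -
                             (prof$r_centers - 0.025)^3)
  expect_equal(sum(prof$values * shell_v), n * (n - 1) / 2)
  # against the brute-force double loop
  orc <- oracle_pairdist(p$sites, box = 22)
  h <- hist(orc, breaks = seq(0, 11, 0.05), plot = FALSE)
  expect_equal(prof$values * shell_v, h$counts)
})

test_that("the intramolecular region is invariant across frames", {
  # rigid, well-separated clouds: distances below ~2x the cloud diameter
  # come only from within oligomers and must not change in time
  tr <- small_traj(seed = 13, n = 2, frames = 60, spo = 20, box = 12,
                   p0 = 0, agg = 0.05, stride = 20,
                   min_separation = 5)
  pr <- lapply(seq_along(tr$times), function(k)
    pair_distance_distribution(tr, bin_width = 0.05, r_max = 1.2,
                               frames = k))
  intra <- vapply(pr, function(p) p$values[p$r_centers < 0.3],
                  numeric(sum(pr[[1]]$r_centers < 0.3)))
  expect_true(all(apply(intra, 1, function(z) diff(range(z))) < 1e-9))
  # two isolated sites at distance d occupy the single matching bin
  two <- structure(list(
    sites = array(rbind(c(1, 1, 1), c(1, 1, 2.13)), c(2, 3, 1)),
    times = 0, oligomer_id = 1:2, membership = NULL,
    truth_log = data.frame(), box_edge = 8, particle = NULL,
    params = NULL), class = "synthetic_trajectory")
  p2 <- pair_distance_distribution(two, bin_width = 0.1, r_max = 4)
  expect_identical(which(p2$values > 0), which(abs(p2$r_centers - 1.15) < 1e-9))
})
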