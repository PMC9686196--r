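# Cluster-count kinetics via hierarchical density-based clustering, plus
# radial distribution analyses.
#
# The clusterer follows the HDBSCAN* recipe at the level needed for
# molecular aggregates: core distances (distance to the min_samples-th
# nearest neighbour, counting the point itself), mutual-reachability
# distances, a single-linkage hierarchy, and extraction of clusters of at
# least min_cluster_size from the condensed tree (leaf selection by
# default, excess-of-mass stability selection available).  Points shed
# above the selected clusters are noise.

#' Density-based clustering parameters
#'
#' Defaults follow the aggregate analysis of the reference study:
#' `min_samples = 7` (noise tolerance), `min_cluster_size = 60` (just under
#' the 69 atoms of one oligomer, so a single free chain still counts as a
#' cluster), manhattan metric, leaf cluster selection.
#'
#' @param min_samples neighbour count defining the core distance.
#' @param min_cluster_size smallest admissible cluster.
#' @param metric `"manhattan"` or `"euclidean"`, computed under the cubic
#'   minimum-image convention when a box is given.
#' @param selection `"leaf"` or `"eom"` (excess of mass).
#' @return an object of class `clustering_params`.
#' @export
clustering_params <- function(min_samples = 7, min_cluster_size = 60,
                              metric = c("manhattan", "euclidean"),
                              selection = c("leaf", "eom")) {
  metric <- match.arg(metric)
  selection <- match.arg(selection)
  if (min_samples < 1 || min_cluster_size < 1)
    stop("min_samples and min_cluster_size must be >= 1")
  structure(list(min_samples = as.integer(min_samples),
                 min_cluster_size = as.integer(min_cluster_size),
                 metric = metric, selection = selection),
            class = "clustering_params")
}

#' Count density-based clusters in one frame
#'
#' @param frame_sites N x 3 matrix of adsorbate site coordinates (nm);
#'   nanoparticle atoms must not be included.
#' @param params [clustering_params()].
#' @param box_edge cubic box edge for minimum-image distances, or `NULL`
#'   for open boundaries.
#' @return list with `n_clusters` and `labels` (integer vector, 0 = noise).
#' @export
#' @examples
#' pts <- rbind(matrix(rnorm(300, 0), ncol = 3),
#'              matrix(rnorm(300, 8), ncol = 3))
#' count_clusters(pts, clustering_params(min_samples = 3,
#'                                       min_cluster_size = 50))$n_clusters
count_clusters <- function(frame_sites, params = clustering_params(),
                           box_edge = NULL) {
  stopifnot(inherits(params, "clustering_params"))
  x <- as.matrix(frame_sites)
  n <- nrow(x)
  if (n < 1) stop("need at least one site")
  if (n < params$min_cluster_size)
    return(list(n_clusters = 0L, labels = rep(0L, n)))

  box <- if (is.null(box_edge)) 0 else box_edge
  metric_code <- if (params$metric == "manhattan") 1L else 0L
  dv <- pairdist_cpp(x, box, metric_code)
  dm <- as.matrix_dist(dv, n)

  # core distance: min_samples-th nearest neighbour, counting the point
  k <- min(params$min_samples, n)
  core <- apply(dm, 1, function(r) sort(r, partial = k - 1)[max(k - 1, 1)])
  if (k == 1L) core <- rep(0, n)
  # mutual reachability
  mr <- pmax(dm, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  labels <- condensed_labels(hc, n, params$min_cluster_size,
                             params$selection)
  list(n_clusters = length(setdiff(unique(labels), 0L)), labels = labels)
}

# Cluster extraction from a single-linkage dendrogram, condensed at
# min_cluster_size.  Internal nodes where both children hold >= mcs leaves
# are true splits; maximal subtrees without a true split are the condensed
# leaves.  "leaf" selection takes those; "eom" climbs back up while a
# parent's stability (summed 1/h persistence of its shed points and
# children) exceeds its children's.
condensed_labels <- function(hc, n, mcs, selection) {
  merge <- hc$merge
  height <- hc$height
  m <- nrow(merge)
  # subtree leaf counts and member lists per internal node
  size <- integer(m)
  members <- vector("list", m)
  for (i in seq_len(m)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    ma <- if (a < 0) -a else members[[a]]
    mb <- if (b < 0) -b else members[[b]]
    members[[i]] <- c(ma, mb)
    size[i] <- length(members[[i]])
  }
  true_split <- logical(m)
  for (i in seq_len(m)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    sa <- if (a < 0) 1L else size[a]
    sb <- if (b < 0) 1L else size[b]
    true_split[i] <- sa >= mcs && sb >= mcs
  }
  has_split_below <- logical(m)
  for (i in seq_len(m)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    ha <- if (a < 0) FALSE else has_split_below[a]
    hb <- if (b < 0) FALSE else has_split_below[b]
    has_split_below[i] <- true_split[i] || ha || hb
  }

  labels <- rep(0L, n)
  if (m == 0) {
    if (n >= mcs) labels[] <- 1L
    return(labels)
  }
  next_label <- 0L
  # iterative top-down walk from the root
  assign_leaf <- function(node) {
    next_label <<- next_label + 1L
    labels[members[[node]]] <<- next_label
  }
  stack <- m # root node index
  while (length(stack)) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (size[node] < mcs) next
    if (!has_split_below[node]) { assign_leaf(node); next }
    # descend through shedding merges until the true split
    cur <- node
    repeat {
      a <- merge[cur, 1]; b <- merge[cur, 2]
      sa <- if (a < 0) 1L else size[a]
      sb <- if (b < 0) 1L else size[b]
      if (true_split[cur]) { stack <- c(stack, a, b); break }
      # one side is < mcs and sheds as noise inside a non-leaf region
      big <- if (sa >= sb) a else b
      if (big < 0) break # degenerate: nothing left to follow
      cur <- big
      if (!has_split_below[cur]) {
        if (size[cur] >= mcs) assign_leaf(cur)
        break
      }
    }
  }
  if (selection == "eom") {
    labels <- eom_relabel(hc, labels, members, merge, height, size,
                          true_split, mcs, n)
  }
  labels
}

# Excess-of-mass selection: compute the stability of every condensed-tree
# node (lambda = 1/height) and select ancestors whose stability exceeds the
# sum of their children's.  Falls back to the leaf labelling when the tree
# has a single cluster node.
eom_relabel <- function(hc, leaf_labels, members, merge, height, size,
                        true_split, mcs, n) {
  splits <- which(true_split)
  if (length(splits) <= 1) return(leaf_labels)
  m <- nrow(merge)
  # birth height of the cluster containing each node: height of the nearest
  # true split above
  parent <- integer(m)
  for (i in seq_len(m)) {
    a <- merge[i, 1]; b <- merge[i, 2]
    if (a > 0) parent[a] <- i
    if (b > 0) parent[b] <- i
  }
  # cluster nodes: children of true splits with >= mcs leaves, plus root
  cl_nodes <- m
  for (s in splits) for (ch in merge[s, ]) {
    sz <- if (ch < 0) 1L else size[ch]
    if (sz >= mcs) cl_nodes <- c(cl_nodes, ch)
  }
  cl_nodes <- unique(cl_nodes[cl_nodes > 0])
  birth <- vapply(cl_nodes, function(nd) {
    p <- if (nd == m) 0L else parent[nd]
    while (p != 0L && !true_split[p]) p <- parent[p]
    if (p == 0L) Inf else height[p]
  }, numeric(1))
  # stability: sum over points of (1/h_fall - 1/h_birth)
  stab <- vapply(seq_along(cl_nodes), function(ii) {
    nd <- cl_nodes[ii]
    hb <- birth[ii]
    lam_b <- if (is.finite(hb)) 1 / hb else 0
    # points fall at the height of the merge that last attaches them
    pts <- members[[nd]]
    fall <- rep(height[nd], length(pts))
    sum(pmax(0, 1 / pmax(fall, 1e-300) - lam_b))
  }, numeric(1))
  # children map among cluster nodes
  child_of <- lapply(cl_nodes, function(nd) {
    kids <- integer(0)
    desc <- nd
    # direct cluster children: cluster nodes whose nearest cluster ancestor is nd
    for (jj in seq_along(cl_nodes)) {
      other <- cl_nodes[jj]
      if (other == nd) next
      p <- parent[other]
      while (p != 0L && !(p %in% cl_nodes)) p <- parent[p]
      if (p == nd || (p == 0L && nd == m)) kids <- c(kids, jj)
    }
    kids
  })
  selected <- logical(length(cl_nodes))
  score <- numeric(length(cl_nodes))
  ord <- order(size[cl_nodes]) # children before parents
  for (ii in ord) {
    kids <- child_of[[ii]]
    if (!length(kids)) { selected[ii] <- TRUE; score[ii] <- stab[ii]; next }
    kid_score <- sum(score[kids])
    if (stab[ii] > kid_score && is.finite(birth[ii])) {
      selected[ii] <- TRUE
      score[ii] <- stab[ii]
      # deselect descendants
      desc <- kids
      while (length(desc)) {
        selected[desc] <- FALSE
        desc <- unlist(child_of[desc])
      }
    } else {
      score[ii] <- kid_score
    }
  }
  labels <- rep(0L, n)
  lab <- 0L
  for (ii in which(selected)) {
    lab <- lab + 1L
    labels[members[[cl_nodes[ii]]]] <- lab
  }
  if (lab == 0L) return(leaf_labels)
  labels
}

#' Cluster-count time series across replicas
#'
#' Applies [count_clusters()] to every recorded frame of one or more
#' replica trajectories and aggregates counts as mean and standard
#' deviation per time point.
#'
#' @param trajs a `synthetic_trajectory` or a list of replicas with
#'   identical recording schedules.
#' @param params [clustering_params()].
#' @param frames indices of recorded frames to evaluate (default all).
#' @return an object of class `cluster_count_series`: data frame with
#'   `time_ps`, `n_clusters_mean`, `n_clusters_sd`, plus a `counts`
#'   attribute (replica x frame matrix).
#' @export
cluster_count_series <- function(trajs, params = clustering_params(),
                                 frames = NULL) {
  if (inherits(trajs, "synthetic_trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  if (is.null(frames)) frames <- seq_along(trajs[[1]]$times)
  counts <- vapply(trajs, function(tr) {
    vapply(frames, function(k)
      count_clusters(tr$sites[, , k, drop = FALSE][, , 1, drop = TRUE],
                     params, box_edge = tr$box_edge)$n_clusters,
      integer(1))
  }, integer(length(frames)))
  counts <- matrix(counts, nrow = length(frames))
  out <- data.frame(
    time_ps = trajs[[1]]$times[frames],
    n_clusters_mean = rowMeans(counts),
    n_clusters_sd = apply(counts, 1, function(z)
      if (length(z) > 1) stats::sd(z) else 0))
  attr(out, "counts") <- t(counts)
  class(out) <- c("cluster_count_series", "data.frame")
  out
}

## ---- radial distribution analyses ------------------------------------

rdf_profile <- function(r_centers, values, bin_width, kind) {
  structure(list(r_centers = r_centers, values = values,
                 bin_width = bin_width, kind = kind),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("RDF profile (%s): %d bins of %.3g nm, r in [%.3g, %.3g] nm\n",
              x$kind, length(x$r_centers), x$bin_width,
              min(x$r_centers), max(x$r_centers)))
  invisible(x)
}

#' Radial distribution of sites around a reference point
#'
#' Shell-count histogram of oligomer-site distances from a fixed reference
#' (by default the particle at the box center), normalised by shell volume
#' and by the mean site density, so an ideal-gas arrangement gives 1 at
#' large r.  Distances use the minimum image; `r_max` may not exceed half
#' the box edge.
#'
#' @param traj a `synthetic_trajectory`.
#' @param reference_point length-3 position, nm (default: box center).
#' @param bin_width histogram bin, nm.
#' @param r_max histogram range, nm.
#' @param frames recorded-frame indices to average over (default all).
#' @return an `rdf_profile` with `values` averaged over frames.
#' @export
rdf_to_reference <- function(traj, reference_point = NULL,
                             bin_width = 0.05, r_max = NULL,
                             frames = NULL) {
  stopifnot(inherits(traj, "synthetic_trajectory"))
  box <- traj$box_edge
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9)
    stop("r_max exceeds half the box edge (minimum-image violation)")
  if (is.null(reference_point)) reference_point <- rep(box / 2, 3)
  if (is.null(frames)) frames <- seq_along(traj$times)
  if (length(frames) == 0 || dim(traj$sites)[1] == 0)
    stop("empty trajectory")
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  counts <- numeric(length(edges) - 1)
  for (k in frames) {
    d <- dist_to_point_cpp(traj$sites[, , k, drop = FALSE][, , 1,
                                                           drop = TRUE],
                           reference_point, box)
    h <- graphics::hist(d[d < max(edges)], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  shell_v <- 4 / 3 * pi * diff(edges^3)
  rho <- dim(traj$sites)[1] / box^3
  vals <- counts / (length(frames) * shell_v * rho)
  rdf_profile(edges[-1] - bin_width / 2, vals, bin_width, "site-to-reference")
}

#' Pair-distance distribution of oligomer sites
#'
#' Histograms all intersite pair distances (minimum image), normalised by
#' shell volume only — the unnormalised g* variant whose short-range part
#' (r below ~0.3 nm) reflects the rigid intra-oligomer geometry and is
#' invariant in time, while the growth of intermediate-range peaks tracks
#' self-aggregation and adsorption.
#'
#' @inheritParams rdf_to_reference
#' @return an `rdf_profile`; `values` have units nm^-3 (counts per shell
#'   volume per frame).
#' @export
pair_distance_distribution <- function(traj, bin_width = 0.05,
                                       r_max = NULL, frames = NULL) {
  stopifnot(inherits(traj, "synthetic_trajectory"))
  box <- traj$box_edge
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2 + 1e-9)
    stop("r_max exceeds half the box edge (minimum-image violation)")
  if (is.null(frames)) frames <- seq_along(traj$times)
  if (length(frames) == 0 || dim(traj$sites)[1] < 2)
    stop("empty trajectory")
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  counts <- numeric(length(edges) - 1)
  for (k in frames) {
    d <- pairdist_cpp(traj$sites[, , k, drop = FALSE][, , 1, drop = TRUE],
                      box, 0L)
    h <- graphics::hist(d[d < max(edges)], breaks = edges, plot = FALSE)
    counts <- counts + h$counts
  }
  shell_v <- 4 / 3 * pi * pmax(diff(edges^3), .Machine$double.eps)
  vals <- counts / (length(frames) * shell_v)
  rdf_profile(edges[-1] - bin_width / 2, vals, bin_width, "site-pair")
}
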