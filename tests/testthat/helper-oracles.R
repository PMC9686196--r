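# Independent brute-force oracles used to check the package implementations.
# These deliberately take different code paths (plain R double loops,
# unit-cell replication instead of site enumeration, fixed-radius DBSCAN
# instead of the hierarchical clusterer).

# O(N^2) neighbour count, plain R
oracle_coordination <- function(pos, cutoff) {
  n <- nrow(pos)
  cn <- integer(n)
  for (i in seq_len(n)) {
    d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2 +
      (pos[, 3] - pos[i, 3])^2
    cn[i] <- sum(d2 <= cutoff^2) - 1L
  }
  cn
}

# FCC lattice by unit-cell replication (4-atom basis), centered on an atom
oracle_fcc_lattice <- function(a, ncell) {
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  cells <- as.matrix(expand.grid(i = -ncell:ncell, j = -ncell:ncell,
                                 k = -ncell:ncell))
  pos <- do.call(rbind, lapply(seq_len(nrow(basis)), function(b)
    sweep(cells, 2, basis[b, ], "+")))
  unname(pos * a)
}

# Wulff cluster by scanning the polyhedron scale on a replicated lattice,
# keeping the attainable atom count nearest the mass target
oracle_wulff <- function(a, gamma, diameter, n_scan = 6000) {
  n_target <- (pi / 6) * diameter^3 / (a^3 / 4)
  ncell <- ceiling(diameter / a) + 2
  pos <- oracle_fcc_lattice(a, ncell)
  n100 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  s8 <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1))) / sqrt(3)
  d100 <- apply(pos %*% t(n100), 1, max)
  d111 <- apply(pos %*% t(s8), 1, max)
  best <- NULL
  for (s in seq(a / 4, diameter, length.out = n_scan)) {
    keep <- d100 <= s + 1e-9 & d111 <= gamma * s + 1e-9
    n <- sum(keep)
    if (n >= 1 && (is.null(best) || abs(n - n_target) < abs(best$n - n_target)))
      best <- list(n = n, s = s)
  }
  keep <- d100 <= best$s + 1e-9 & d111 <= gamma * best$s + 1e-9
  pos[keep, , drop = FALSE]
}

# fixed-radius DBSCAN (BFS), euclidean, optional cubic minimum image
oracle_dbscan <- function(x, eps, min_pts, box = NULL) {
  n <- nrow(x)
  dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sweep(x, 2, x[i, ])
    if (!is.null(box)) d <- d - box * round(d / box)
    dm[i, ] <- sqrt(rowSums(d^2))
  }
  nb <- lapply(seq_len(n), function(i) which(dm[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (core[j]) {
        for (k in nb[[j]]) {
          if (labels[k] == 0L) {
            labels[k] <- cl
            queue <- c(queue, k)
          }
        }
      }
    }
  }
  labels
}

# all-pairs minimum-image distances, plain double loop
oracle_pairdist <- function(x, box = NULL) {
  n <- nrow(x)
  out <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- x[i, ] - x[j, ]
      if (!is.null(box)) d <- d - box * round(d / box)
      out <- c(out, sqrt(sum(d^2)))
    }
  }
  out
}

# total LJ energy without any cutoff, double loop
oracle_lj_total <- function(np_pos, cfg, eps, sig) {
  e <- 0
  for (i in seq_len(nrow(cfg))) {
    r <- sqrt(rowSums(sweep(np_pos, 2, cfg[i, ])^2))
    sr6 <- (sig / r)^6
    e <- e + sum(4 * eps * (sr6^2 - sr6))
  }
  e
}

# finite FCC slab whose central top-layer atom has the coordination of an
# infinite surface; `normal` is "111" or "100"
oracle_slab <- function(a, normal, half_extent = 4) {
  pos <- oracle_fcc_lattice(a, half_extent + 2)
  n <- if (normal == "111") c(1, 1, 1) / sqrt(3) else c(0, 0, 1)
  proj <- pos %*% n
  slab <- pos[proj <= 1e-9, , drop = FALSE]
  lateral <- slab - outer(as.numeric(slab %*% n), n)
  keep <- sqrt(rowSums(lateral^2)) <= half_extent * a
  slab[keep, , drop = FALSE]
}
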