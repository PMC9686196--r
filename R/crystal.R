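#' Lattice specification
#'
#' Describes the crystal lattice of the nanoparticle material.  Only the
#' face-centered cubic (FCC) family is supported; the default is bulk gold
#' with lattice constant 0.4078 nm.
#'
#' @param element chemical symbol.
#' @param lattice_constant cubic cell edge in nm; must be positive.
#' @param structure crystal family tag; only `"fcc"`.
#' @return an object of class `lattice_spec`.
#' @export
#' @examples
#' lattice_spec()
lattice_spec <- function(element = "Au", lattice_constant = 0.4078,
                         structure = "fcc") {
  if (!is.numeric(lattice_constant) || lattice_constant <= 0)
    stop("lattice_constant must be > 0")
  structure <- tolower(structure)
  if (!identical(structure, "fcc"))
    stop("unsupported lattice structure: only FCC is implemented")
  structure(list(element = element, lattice_constant = lattice_constant,
                 structure = structure),
            class = "lattice_spec")
}

#' Wulff-shape specification
#'
#' The equilibrium (Wulff) shape places each facet at a distance from the
#' particle center proportional to its surface energy.  Truncation is along
#' the \{100\} and \{111\} plane families only; `gamma_ratio` is the
#' dimensionless surface-energy ratio gamma\{111\}/gamma\{100\} and
#' `target_diameter` is the equivalent spherical diameter (nm) fixing the
#' particle mass.
#'
#' @param gamma_ratio surface-energy ratio gamma\{111\}/gamma\{100\}, > 0.
#' @param target_diameter equivalent spherical diameter in nm, > 0.
#' @return an object of class `wulff_spec`.
#' @export
#' @examples
#' wulff_spec(gamma_ratio = 0.96, target_diameter = 4.0)
wulff_spec <- function(gamma_ratio, target_diameter) {
  if (!is.numeric(gamma_ratio) || gamma_ratio <= 0)
    stop("gamma_ratio must be > 0")
  if (!is.numeric(target_diameter) || target_diameter <= 0)
    stop("target_diameter must be > 0")
  structure(list(gamma_ratio = gamma_ratio,
                 target_diameter = target_diameter,
                 plane_families = list(c(1, 0, 0), c(1, 1, 1))),
            class = "wulff_spec")
}

#' Miller plane
#'
#' @param indices integer triple of Miller indices, not all zero.
#' @return an object of class `miller_plane`.
#' @export
#' @examples
#' miller_plane(c(1, 1, 1))
miller_plane <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) != 3L || all(indices == 0L))
    stop("Miller indices must be a nonzero integer triple")
  structure(list(indices = indices), class = "miller_plane")
}

# the 6 {100} and 8 {111} unit normals
facet_normals <- function() {
  n100 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  s <- expand.grid(x = c(1, -1), y = c(1, -1), z = c(1, -1))
  n111 <- as.matrix(s) / sqrt(3)
  dimnames(n111) <- NULL
  list(n100 = n100, n111 = n111)
}

# All FCC lattice sites (atom at the origin) with |i|,|j|,|k| <= m in units
# of a/2 and i+j+k even.
fcc_sites <- function(a, m) {
  g <- seq.int(-m, m)
  ijk <- as.matrix(expand.grid(i = g, j = g, k = g))
  ijk <- ijk[(ijk[, 1] + ijk[, 2] + ijk[, 3]) %% 2 == 0, , drop = FALSE]
  dimnames(ijk) <- NULL
  ijk * (a / 2)
}

#' Build a Wulff-constructed FCC nanoparticle
#'
#' Enumerates FCC lattice sites around a central atom and keeps those inside
#' the Wulff polyhedron bounded by the six \{100\} planes at distance `s`
#' and the eight \{111\} planes at distance `gamma_ratio * s` from the
#' center.  The polyhedron scale `s` is solved exactly for the particle mass:
#' each site enters the cluster at a well-defined scale, and the attainable
#' atom count nearest the mass target (a sphere of `target_diameter`, with
#' 4 atoms per cubic cell) is selected, ties going to the smaller cluster.
#' With the gold defaults and gamma_ratio 0.96 at 4.0 nm this yields a
#' 1925-atom particle of equivalent diameter 3.96 nm.
#'
#' Surface atoms are classified by coordination number via
#' [classify_atoms()], and the outermost-plane membership of every atom
#' (which facet family's terminating plane it occupies) is recorded for
#' facet area budgets.
#'
#' @param lattice a [lattice_spec()].
#' @param spec a [wulff_spec()].
#' @return an object of class `faceted_nanoparticle` with elements
#'   `positions` (N x 3 matrix, nm, centroid at the origin), `element`,
#'   `facet_labels` (factor with levels BULK, F111, F100, EDGE),
#'   `plane_membership` (N x 2 logical matrix, columns `on111`, `on100`),
#'   `lattice`, `gamma_ratio`, `radius_estimate` (nm).
#' @export
#' @examples
#' np <- build_wulff_nanoparticle(lattice_spec(), wulff_spec(0.96, 2.0))
#' table(np$facet_labels)
build_wulff_nanoparticle <- function(lattice, spec) {
  stopifnot(inherits(lattice, "lattice_spec"), inherits(spec, "wulff_spec"))
  a <- lattice$lattice_constant
  gamma <- spec$gamma_ratio
  d <- spec$target_diameter

  n_target <- (pi / 6) * d^3 / (a^3 / 4)
  if (n_target < 0.5) stop("target below minimal cluster")

  # grid bound: polyhedron inradius needed for ~1.5x the target mass
  s_bound <- (3 / (4 * pi) * 1.6 * max(n_target, 2) * a^3 / 4)^(1 / 3) /
    min(1, gamma) + a
  m <- ceiling(2 * s_bound / a) + 1
  pos <- fcc_sites(a, m)

  nrm <- facet_normals()
  d100 <- apply(pos %*% t(nrm$n100), 1, max)
  d111 <- apply(pos %*% t(nrm$n111), 1, max)

  # scale at which each site enters the polyhedron
  entry <- pmax(d100, d111 / gamma)
  ord <- order(entry)
  entry_sorted <- entry[ord]

  # attainable counts: cumulative counts at each distinct entry scale
  thresholds <- unique(entry_sorted)
  counts <- findInterval(thresholds + 1e-9, entry_sorted)
  stopifnot(max(counts) >= n_target) # grid bound must cover the target

  best <- which.min(abs(counts - n_target)) # ties resolve to smaller count
  sel <- entry <= thresholds[best] + 1e-9
  p <- pos[sel, , drop = FALSE]
  p <- sweep(p, 2, colMeans(p)) # exact centroid at origin

  labels <- classify_atoms(p, lattice = lattice)
  pm <- plane_membership(p)
  if (nrow(p) == 1L) labels <- factor("EDGE",
                                      levels = levels(labels))

  out <- structure(list(positions = p,
                        element = lattice$element,
                        facet_labels = labels,
                        plane_membership = pm,
                        lattice = lattice,
                        gamma_ratio = gamma,
                        radius_estimate = equivalent_diameter(nrow(p),
                                                              lattice = lattice) / 2),
                   class = "faceted_nanoparticle")
  validate_nanoparticle(out)
  out
}

validate_nanoparticle <- function(np) {
  stopifnot(inherits(np, "faceted_nanoparticle"))
  n <- nrow(np$positions)
  if (n < 1) stop("empty particle")
  if (any(abs(colMeans(np$positions)) > 1e-9))
    stop("particle centroid must sit at the origin")
  if (length(np$facet_labels) != n)
    stop("every atom needs exactly one facet label")
  a <- np$lattice$lattice_constant
  if (n > 1) {
    nn <- min(pairdist_cpp(np$positions, 0, 0L))
    if (nn < 0.9 * a / sqrt(2)) stop("atoms closer than 0.9 x nearest-neighbour distance")
  }
  invisible(np)
}

#' @export
print.faceted_nanoparticle <- function(x, ...) {
  cat(sprintf("Wulff %s nanoparticle: %d atoms, equivalent diameter %.2f nm\n",
              x$element, nrow(x$positions), 2 * x$radius_estimate))
  cat(sprintf("  gamma{111}/gamma{100} = %.3g, lattice a = %.4f nm\n",
              x$gamma_ratio, x$lattice$lattice_constant))
  print(table(x$facet_labels))
  invisible(x)
}

#' Classify atoms by coordination number
#'
#' Counts neighbours within `neighbor_cutoff` and maps coordination number
#' (CN) to a facet class: CN 12 is bulk, CN 9 a \{111\} terrace atom, CN 8 a
#' \{100\} terrace atom, and any other under-coordinated atom an edge,
#' corner or step atom (`EDGE`).  The cutoff must fall strictly between the
#' first (a/sqrt(2)) and second (a) FCC neighbour shells; the default is the
#' shell midpoint.
#'
#' @param particle a `faceted_nanoparticle` or an N x 3 coordinate matrix.
#' @param neighbor_cutoff neighbour cutoff in nm, or `NULL` for the shell
#'   midpoint.
#' @param lattice [lattice_spec()]; defaults to the particle's lattice.
#' @return factor of per-atom labels with levels BULK, F111, F100, EDGE.
#' @export
#' @examples
#' np <- build_wulff_nanoparticle(lattice_spec(), wulff_spec(1, 2))
#' table(classify_atoms(np))
classify_atoms <- function(particle, neighbor_cutoff = NULL,
                           lattice = NULL) {
  if (inherits(particle, "faceted_nanoparticle")) {
    if (is.null(lattice)) lattice <- particle$lattice
    pos <- particle$positions
  } else {
    pos <- as.matrix(particle)
    if (is.null(lattice)) lattice <- lattice_spec()
  }
  a <- lattice$lattice_constant
  lo <- a / sqrt(2)
  if (is.null(neighbor_cutoff)) neighbor_cutoff <- (lo + a) / 2
  if (neighbor_cutoff <= lo || neighbor_cutoff >= a)
    stop("ambiguous shell cutoff: need a/sqrt(2) < cutoff < a")
  cn <- coordination_cpp(pos, neighbor_cutoff)
  lab <- ifelse(cn >= 12, "BULK",
                ifelse(cn == 9, "F111",
                       ifelse(cn == 8, "F100", "EDGE")))
  factor(lab, levels = c("BULK", "F111", "F100", "EDGE"))
}

#' Outermost-plane membership of every atom
#'
#' An atom is a member of a facet family if it lies on the outermost
#' occupied crystal plane along at least one of that family's normals.
#' Atoms on the border between a \{111\} and a \{100\} facet are members of
#' both families; this is the natural grouping for facet-resolved surface
#' budgets, where a border atom's area is shared by the facets it
#' terminates.
#'
#' @param positions N x 3 coordinate matrix (nm), particle-centered.
#' @param tol plane-membership tolerance in nm.
#' @return N x 2 logical matrix with columns `on111` and `on100`.
#' @export
plane_membership <- function(positions, tol = 1e-6) {
  positions <- as.matrix(positions)
  nrm <- facet_normals()
  on111 <- rep(FALSE, nrow(positions))
  on100 <- rep(FALSE, nrow(positions))
  pr111 <- positions %*% t(nrm$n111)
  pr100 <- positions %*% t(nrm$n100)
  for (j in seq_len(ncol(pr111)))
    on111 <- on111 | pr111[, j] > max(pr111[, j]) - tol
  for (j in seq_len(ncol(pr100)))
    on100 <- on100 | pr100[, j] > max(pr100[, j]) - tol
  cbind(on111 = on111, on100 = on100)
}

#' Atomic packing factor of an FCC plane
#'
#' Fraction of a crystallographic plane's area covered by touching-sphere
#' cross-sections: pi/(2*sqrt(3)) = 0.907 for the close-packed \{111\}
#' plane and pi/4 = 0.785 for \{100\}.  The denser \{111\} packing puts
#' more atoms inside an adsorbate's interaction cutoff, which is the
#' geometric root of its stronger attraction.
#'
#' @param plane a [miller_plane()] or an index triple.
#' @return dimensionless packing fraction.
#' @export
#' @examples
#' atomic_packing_factor(c(1, 1, 1))
atomic_packing_factor <- function(plane) {
  fam <- plane_family(plane)
  switch(fam,
         "111" = pi / (2 * sqrt(3)),
         "100" = pi / 4,
         stop("unsupported plane family: only {100} and {111}"))
}

plane_family <- function(plane) {
  if (inherits(plane, "miller_plane")) plane <- plane$indices
  v <- sort(abs(as.integer(plane)))
  if (all(v == c(0L, 0L, 1L))) return("100")
  if (all(v == c(1L, 1L, 1L))) return("111")
  if (all(v == c(0L, 1L, 1L))) return("110")
  paste(v, collapse = "")
}

#' Angle between two Miller planes
#'
#' Angle between the plane normals, reported in degrees in \[0, 90\].
#' \{100\}/\{111\} meet at 54.74 degrees, the rotation that maps the
#' reaction coordinate from one facet normal onto the other in the polar
#' free-energy landscape.
#'
#' @param a,b [miller_plane()] objects or index triples.
#' @return angle in degrees.
#' @export
#' @examples
#' interplanar_angle(c(1, 0, 0), c(1, 1, 1))
interplanar_angle <- function(a, b) {
  va <- if (inherits(a, "miller_plane")) a$indices else as.numeric(a)
  vb <- if (inherits(b, "miller_plane")) b$indices else as.numeric(b)
  if (all(va == 0) || all(vb == 0)) stop("zero vector is not a plane normal")
  ct <- abs(sum(va * vb)) / sqrt(sum(va^2) * sum(vb^2))
  acos(pmin(1, ct)) * 180 / pi
}

#' Rotate a particle rigidly about its centroid
#'
#' Rodrigues rotation of all atom positions about `axis` by `theta`
#' degrees.  Facet labels and plane membership ride along unchanged; the
#' rotation is rigid, so all interatomic distances are preserved.
#'
#' @param particle a `faceted_nanoparticle`.
#' @param axis nonzero 3-vector rotation axis.
#' @param theta rotation angle in degrees.
#' @return the rotated `faceted_nanoparticle`.
#' @export
rotate_particle <- function(particle, axis, theta) {
  stopifnot(inherits(particle, "faceted_nanoparticle"))
  axis <- as.numeric(axis)
  na <- sqrt(sum(axis^2))
  if (!is.finite(na) || na == 0) stop("rotation axis must be nonzero")
  k <- axis / na
  th <- theta * pi / 180
  K <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  particle$positions <- particle$positions %*% t(R)
  particle
}

#' Equivalent spherical diameter of an FCC cluster
#'
#' The diameter of the sphere whose volume equals the total atomic volume
#' `N * a^3 / 4` (4 atoms per cubic FCC cell): `d = (6 N a^3 / (4 pi))^(1/3)`.
#'
#' @param x a `faceted_nanoparticle`, or an atom count.
#' @param lattice a [lattice_spec()] (needed when `x` is a count).
#' @return equivalent diameter in nm.
#' @export
#' @examples
#' equivalent_diameter(1925, lattice = lattice_spec())
equivalent_diameter <- function(x, lattice = NULL) {
  if (inherits(x, "faceted_nanoparticle")) {
    n <- nrow(x$positions)
    a <- x$lattice$lattice_constant
  } else {
    n <- as.numeric(x)
    if (is.null(lattice)) lattice <- lattice_spec()
    a <- lattice$lattice_constant
  }
  if (length(n) != 1 || !is.finite(n) || n < 1)
    stop("atom count must be at least 1")
  (6 * n * a^3 / (4 * pi))^(1 / 3)
}

#' Facet budget of a particle
#'
#' Per-facet atom counts and bare-surface area shares (from
#' [per_facet_sasa()]); the table behind a particle's facet-exposure
#' histogram.
#'
#' @param particle a `faceted_nanoparticle`.
#' @param options [sasa_options()].
#' @return data frame with columns `label`, `atom_count`, `area_nm2`,
#'   `area_share`.
#' @export
facet_budget <- function(particle, options = sasa_options()) {
  res <- per_facet_sasa(particle, options = options)
  labs <- names(res$facet_totals)
  data.frame(label = labs,
             atom_count = as.integer(table(particle$facet_labels)[labs]),
             area_nm2 = as.numeric(res$facet_totals),
             area_share = as.numeric(res$facet_totals) / res$total,
             stringsAsFactors = FALSE)
}
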