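# Structure and trajectory I/O.  All coordinates are nm on disk and in
# memory: GRO is natively nm, and XYZ files written by this package declare
# nm in their comment line (a JSON tag that also carries the lattice
# constant and facet labels, so a particle round-trips losslessly).

#' Write a structure file (XYZ or GRO)
#'
#' @param x a `faceted_nanoparticle`, or an N x 3 coordinate matrix.
#' @param path output path; format inferred from the extension unless
#'   `format` is given.
#' @param format `"xyz"` or `"gro"`.
#' @param elements per-atom element symbols (recycled) when `x` is a bare
#'   matrix.
#' @param box optional cubic box edge (nm), written to GRO and the XYZ tag.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, format = NULL, elements = "Au",
                            box = NULL) {
  format <- infer_format(path, format)
  if (inherits(x, "faceted_nanoparticle")) {
    pos <- x$positions
    elements <- rep(x$element, nrow(pos))
    tag <- list(units = "nm",
                lattice_constant = x$lattice$lattice_constant,
                gamma_ratio = x$gamma_ratio,
                facet_labels = paste(as.character(x$facet_labels),
                                     collapse = ","))
    if (!is.null(box)) tag$box <- box
  } else {
    pos <- as.matrix(x)
    elements <- rep_len(elements, nrow(pos))
    tag <- list(units = "nm")
    if (!is.null(box)) tag$box <- box
  }
  if (format == "xyz") {
    lines <- c(nrow(pos),
               as.character(jsonlite::toJSON(tag, auto_unbox = TRUE,
                                             digits = NA)),
               sprintf("%-3s %14.8f %14.8f %14.8f", elements,
                       pos[, 1], pos[, 2], pos[, 3]))
    writeLines(lines, path)
  } else {
    bx <- if (!is.null(box)) box else 2 * max(abs(pos)) + 1
    lines <- c("structure written by npadsorb (nm)",
               sprintf("%5d", nrow(pos)),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       1L, "NP", substr(elements, 1, 5),
                       seq_len(nrow(pos)) %% 100000L,
                       pos[, 1], pos[, 2], pos[, 3]),
               sprintf("%10.5f%10.5f%10.5f", bx, bx, bx))
    writeLines(lines, path)
  }
  invisible(path)
}

infer_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(tolower(format), c("xyz", "gro")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "gro")) ext else
    stop("cannot infer structure format from extension: ", path)
}

#' Read a structure file (XYZ or GRO)
#'
#' Coordinates are returned in nm.  XYZ files written by this package
#' carry a JSON comment tag with the lattice constant and facet labels;
#' when present, these are returned too.  Malformed records raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @param format `"xyz"` or `"gro"` (inferred from the extension when
#'   `NULL`).
#' @return list with `positions`, `elements`, and (when available)
#'   `facet_labels`, `lattice_constant`, `gamma_ratio`, `box`.
#' @export
read_structure <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  lines <- readLines(path)
  if (format == "xyz") {
    if (length(lines) < 2) stop("truncated file at line ", length(lines))
    n <- suppressWarnings(as.integer(trimws(lines[1])))
    if (is.na(n)) stop("malformed atom count at line 1")
    if (length(lines) < n + 2) stop("truncated file at line ", length(lines))
    tag <- tryCatch(jsonlite::fromJSON(lines[2]), error = function(e) NULL)
    pos <- matrix(NA_real_, n, 3)
    el <- character(n)
    for (i in seq_len(n)) {
      toks <- strsplit(trimws(lines[i + 2]), "\\s+")[[1]]
      if (length(toks) < 4) stop("malformed record at line ", i + 2)
      v <- suppressWarnings(as.numeric(toks[2:4]))
      if (anyNA(v)) stop("malformed record at line ", i + 2)
      el[i] <- toks[1]
      pos[i, ] <- v
    }
    out <- list(positions = pos, elements = el)
    if (!is.null(tag)) {
      if (!is.null(tag$facet_labels)) {
        labs <- strsplit(tag$facet_labels, ",")[[1]]
        if (length(labs) == n)
          out$facet_labels <- factor(labs,
                                     levels = c("BULK", "F111", "F100",
                                                "EDGE"))
      }
      out$lattice_constant <- tag$lattice_constant
      out$gamma_ratio <- tag$gamma_ratio
      out$box <- tag$box
    }
    out
  } else {
    if (length(lines) < 3) stop("truncated file at line ", length(lines))
    n <- suppressWarnings(as.integer(trimws(lines[2])))
    if (is.na(n)) stop("malformed atom count at line 2")
    if (length(lines) < n + 3) stop("truncated file at line ", length(lines))
    pos <- matrix(NA_real_, n, 3)
    el <- character(n)
    for (i in seq_len(n)) {
      ln <- lines[i + 2]
      if (nchar(ln) < 44) stop("malformed record at line ", i + 2)
      el[i] <- trimws(substr(ln, 11, 15))
      v <- suppressWarnings(as.numeric(c(substr(ln, 21, 28),
                                         substr(ln, 29, 36),
                                         substr(ln, 37, 44))))
      if (anyNA(v)) stop("malformed record at line ", i + 2)
      pos[i, ] <- v
    }
    bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[n + 3]),
                                               "\\s+")[[1]]))
    list(positions = pos, elements = el,
         box = if (length(bx) >= 1 && !anyNA(bx[1])) bx[1] else NULL)
  }
}

#' Read a nanoparticle written by [write_structure()]
#'
#' Rebuilds a `faceted_nanoparticle` from an XYZ file with the package's
#' JSON tag (facet labels are re-derived when the tag is missing).
#'
#' @param path XYZ file path.
#' @return a `faceted_nanoparticle`.
#' @export
read_nanoparticle <- function(path) {
  s <- read_structure(path)
  a <- if (!is.null(s$lattice_constant)) s$lattice_constant else 0.4078
  lat <- lattice_spec(element = s$elements[1], lattice_constant = a)
  pos <- sweep(s$positions, 2, colMeans(s$positions))
  labels <- if (!is.null(s$facet_labels)) s$facet_labels else
    classify_atoms(pos, lattice = lat)
  structure(list(positions = pos, element = s$elements[1],
                 facet_labels = labels,
                 plane_membership = plane_membership(pos),
                 lattice = lat,
                 gamma_ratio = s$gamma_ratio,
                 radius_estimate = equivalent_diameter(nrow(pos),
                                                       lattice = lat) / 2),
            class = "faceted_nanoparticle")
}

#' Write a trajectory as multi-frame XYZ
#'
#' One XYZ block per recorded frame; the comment line carries the time in
#' ps and the box edge in nm.
#'
#' @param traj a `synthetic_trajectory`.
#' @param path output path.
#' @param site_element element symbol written for oligomer sites.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path, site_element = "C") {
  n <- dim(traj$sites)[1]
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  seed_tag <- if (!is.null(traj$params$seed))
    sprintf(" seed=%d", traj$params$seed) else ""
  for (k in seq_along(traj$times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("t_ps=%.6g box_nm=%.6g%s", traj$times[k],
                       traj$box_edge, seed_tag), con)
    p <- traj$sites[, , k, drop = FALSE][, , 1, drop = TRUE]
    writeLines(sprintf("%-3s %14.8f %14.8f %14.8f", site_element,
                       p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file path.
#' @param box_edge box edge override (taken from the comment lines when
#'   `NULL`).
#' @return a `synthetic_trajectory` (without ground-truth log).
#' @export
read_trajectory_xyz <- function(path, box_edge = NULL) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  box <- box_edge
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed atom count at line ", i)
    if (length(lines) < i + 1 + n) stop("truncated file at line ",
                                        length(lines))
    cm <- lines[i + 1]
    tm <- regmatches(cm, regexec("t_ps=([0-9eE.+-]+)", cm))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else
      length(frames) + 1)
    if (is.null(box)) {
      bm <- regmatches(cm, regexec("box_nm=([0-9eE.+-]+)", cm))[[1]]
      if (length(bm) == 2) box <- as.numeric(bm[2])
    }
    block <- lines[(i + 2):(i + 1 + n)]
    toks <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(toks, length, integer(1)) < 4)
    if (length(bad)) stop("malformed record at line ", i + 1 + bad[1])
    pos <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (anyNA(pos)) stop("malformed record near line ", i + 2)
    frames[[length(frames) + 1L]] <- pos
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames in ", path)
  n <- nrow(frames[[1]])
  sites <- array(NA_real_, c(n, 3, length(frames)))
  for (k in seq_along(frames)) sites[, , k] <- frames[[k]]
  structure(list(sites = sites, times = times,
                 oligomer_id = rep(NA_integer_, n),
                 membership = NULL,
                 truth_log = data.frame(),
                 box_edge = if (is.null(box)) 2 * max(abs(sites)) else box,
                 particle = NULL, params = NULL),
            class = "synthetic_trajectory")
}

#' Write the ground-truth event log as TSV
#'
#' @param traj a `synthetic_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_log <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(output_header(traj$params$seed,
                           list(n_oligomers = traj$params$n_oligomers)),
             con)
  utils::write.table(traj$truth_log, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
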