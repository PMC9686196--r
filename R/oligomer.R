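# Residue-level bookkeeping for PLGA oligomers.  Chains are described at
# formula level: each lactic (LA) ester residue contributes C3H4O2 and each
# glycolic (GA) ester residue C2H2O2; a protonated chain carries an extra H
# at the head and an OH at the tail (one condensation water in total).

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999)

.RESIDUE_FORMULA <- list(
  LA = c(C = 3, H = 4, O = 2),
  GA = c(C = 2, H = 2, O = 2)
)

#' Build a PLGA oligomer specification
#'
#' Constructs a poly(lactic-co-glycolic acid) chain of `n_la` lactic and
#' `n_ga` glycolic ester residues.  The reference oligomer of the adsorption
#' study is 6 LA + 2 GA, protonated (a 75:25 LA/GA ratio, 566 g/mol,
#' 69 atoms).  The arrangement of residues along the chain is configurable
#' because all composition-level quantities (mass, atom count) are
#' arrangement-independent.
#'
#' @param n_la number of lactic residues.
#' @param n_ga number of glycolic residues.
#' @param protonated logical; protonated chains carry acid caps (H/OH
#'   termini), deprotonated chains lack the acidic hydrogen.
#' @param arrangement `"block"` (default, LA block then GA block),
#'   `"alternating"`, or an explicit character vector of `"LA"`/`"GA"` with
#'   matching composition.
#' @return an object of class `oligomer_spec`.
#' @export
#' @examples
#' plga <- build_plga(6, 2)
#' molecular_weight(plga)
#' atom_count(plga)
build_plga <- function(n_la, n_ga, protonated = TRUE,
                       arrangement = "block") {
  n_la <- as.integer(n_la); n_ga <- as.integer(n_ga)
  if (n_la < 0 || n_ga < 0 || n_la + n_ga < 1)
    stop("a chain needs at least one residue")
  seq_res <- if (is.character(arrangement) && length(arrangement) > 1) {
    if (sum(arrangement == "LA") != n_la || sum(arrangement == "GA") != n_ga)
      stop("explicit sequence does not match residue counts")
    arrangement
  } else if (identical(arrangement, "alternating")) {
    out <- character(0)
    la <- n_la; ga <- n_ga
    while (la + ga > 0) {
      if (la > 0) { out <- c(out, "LA"); la <- la - 1 }
      if (ga > 0) { out <- c(out, "GA"); ga <- ga - 1 }
    }
    out
  } else {
    c(rep("LA", n_la), rep("GA", n_ga))
  }
  structure(list(sequence = seq_res, protonated = isTRUE(protonated)),
            class = "oligomer_spec")
}

#' @export
print.oligomer_spec <- function(x, ...) {
  cat(sprintf("PLGA oligomer: %d residues (%d LA, %d GA), %s\n",
              length(x$sequence), sum(x$sequence == "LA"),
              sum(x$sequence == "GA"),
              if (x$protonated) "protonated" else "deprotonated"))
  cat(sprintf("  M = %.2f g/mol, %d atoms\n", molecular_weight(x),
              atom_count(x)))
  invisible(x)
}

#' Molecular formula of an oligomer
#'
#' @param o an `oligomer_spec`.
#' @return named integer vector of element counts (C, H, O).
#' @export
oligomer_formula <- function(o) {
  stopifnot(inherits(o, "oligomer_spec"))
  f <- c(C = 0, H = 0, O = 0)
  for (r in o$sequence) f <- f + .RESIDUE_FORMULA[[r]]
  # termini: protonated head H + tail OH; deprotonated lacks the acid H
  f <- f + if (o$protonated) c(C = 0, H = 2, O = 1) else c(C = 0, H = 1, O = 1)
  f
}

#' Molecular weight of an oligomer
#'
#' Sum of standard atomic masses (C 12.011, H 1.008, O 15.999) over the
#' chain formula.  The 6 LA + 2 GA protonated reference chain weighs
#' 566 g/mol.
#'
#' @param o an `oligomer_spec`.
#' @return mass in g/mol.
#' @export
molecular_weight <- function(o) {
  f <- oligomer_formula(o)
  sum(f * .ATOMIC_MASS[names(f)])
}

#' Atom count of an oligomer
#'
#' Total atoms including hydrogens: 9 per LA residue, 6 per GA residue,
#' plus 3 terminal atoms when protonated (2 when deprotonated).  The
#' reference 6 LA + 2 GA protonated chain has 69 atoms — the site count
#' used for its point-cloud representation and the natural smallest
#' cluster size in the density-based cluster analysis.
#'
#' @param o an `oligomer_spec`.
#' @return integer atom count.
#' @export
atom_count <- function(o) {
  as.integer(sum(oligomer_formula(o)))
}

#' Randomly place oligomer site clouds in a periodic box
#'
#' Each oligomer is represented as a cloud of `sites_per_oligomer` points
#' drawn uniformly within `gyration_radius` of its center — positional
#' statistics are all the downstream analyses need.  Centers are sampled
#' uniformly in the cubic box with a hard pairwise minimum-image separation
#' of `min_separation`, emulating an initially dispersed solution.
#'
#' @param n number of oligomers.
#' @param box_edge cubic box edge in nm.
#' @param sites_per_oligomer sites per cloud (69 for the reference chain).
#' @param gyration_radius cloud radius in nm.
#' @param min_separation minimum center-center distance in nm
#'   (minimum image).
#' @param seed integer seed for reproducibility.
#' @param max_tries rejection-sampling budget per oligomer.
#' @param exclusion_center optional length-3 point (nm) around which no
#'   oligomer center may be placed — the nanoparticle's spot in the box.
#' @param exclusion_radius keep-out radius around `exclusion_center`, nm.
#' @return list with `sites` (n*spo x 3 matrix), `oligomer_id` (integer
#'   vector), `centers` (n x 3), `offsets` (spo x 3 x n array of site
#'   offsets), `box_edge`.
#' @export
#' @examples
#' p <- place_oligomers(5, 8, sites_per_oligomer = 10, seed = 1)
#' nrow(p$sites)
place_oligomers <- function(n, box_edge, sites_per_oligomer = 69,
                            gyration_radius = 0.5, min_separation = 1.5,
                            seed = NULL, max_tries = 2000L,
                            exclusion_center = NULL,
                            exclusion_radius = 0) {
  stopifnot(n >= 1, box_edge > 0, sites_per_oligomer >= 1,
            gyration_radius > 0, min_separation >= 0)
  # hard-sphere feasibility guard
  if (n * (4 / 3) * pi * (min_separation / 2)^3 > box_edge^3)
    stop("infeasible packing: exclusion volume exceeds the box")
  with_seed(seed, {
    centers <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- runif(3, 0, box_edge)
        if (!is.null(exclusion_center) && exclusion_radius > 0) {
          dc <- min_image(cand - exclusion_center, box_edge)
          if (sum(dc^2) < exclusion_radius^2) next
        }
        if (i == 1L) { ok <- TRUE } else {
          d <- sweep(centers[seq_len(i - 1), , drop = FALSE], 2, cand)
          d <- min_image(d, box_edge)
          ok <- all(rowSums(d^2) >= min_separation^2)
        }
        if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("infeasible packing after bounded retries")
    }
    # uniform-in-ball site offsets, one rigid cloud per oligomer
    offsets <- array(0, c(sites_per_oligomer, 3, n))
    for (i in seq_len(n)) {
      u <- matrix(rnorm(3 * sites_per_oligomer), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- gyration_radius * runif(sites_per_oligomer)^(1 / 3)
      offsets[, , i] <- u * r
    }
    sites <- do.call(rbind, lapply(seq_len(n), function(i)
      sweep(offsets[, , i, drop = FALSE][, , 1, drop = TRUE],
            2, centers[i, ], "+")))
    list(sites = wrap_box(sites, box_edge),
         oligomer_id = rep(seq_len(n), each = sites_per_oligomer),
         centers = centers, offsets = offsets, box_edge = box_edge)
  })
}

#' Serialize an oligomer spec to JSON
#'
#' @param o an `oligomer_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_oligomer_json <- function(o, path) {
  stopifnot(inherits(o, "oligomer_spec"))
  x <- list(sequence = paste(substr(o$sequence, 1, 1), collapse = " "),
            protonated = o$protonated,
            molecular_weight = molecular_weight(o),
            atom_count = atom_count(o))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an oligomer spec from JSON
#'
#' @param path JSON file written by [write_oligomer_json()].
#' @return an `oligomer_spec`.
#' @export
read_oligomer_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  toks <- strsplit(trimws(x$sequence), "\\s+")[[1]]
  seq_res <- ifelse(toks %in% c("L", "LA"), "LA",
                    ifelse(toks %in% c("G", "GA"), "GA", NA))
  if (anyNA(seq_res)) stop("unknown residue code in sequence string")
  build_plga(sum(seq_res == "LA"), sum(seq_res == "GA"),
             protonated = isTRUE(x$protonated), arrangement = seq_res)
}
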