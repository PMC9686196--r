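#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded package functions do not disturb user code.
#'
#' @param seed integer seed, or `NULL` to leave the RNG stream untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Derive a named substream seed from a master seed
#'
#' All randomness in a run flows from one configuration seed; each stage
#' draws from its own substream so that, e.g., adding umbrella windows does
#' not shift the trajectory stream.  The substream seed is a deterministic
#' 31-bit hash of the master seed and the stage label.
#'
#' @param seed master integer seed.
#' @param label character stage label, e.g. `"trajectory"`.
#' @return an integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' substream_seed(1, "trajectory")
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- as.double(seed) %% 2147483647
  for (b in utf8ToInt(label)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# wrap coordinates into [0, box)
wrap_box <- function(x, box) {
  x - box * floor(x / box)
}

# minimum-image displacement (componentwise), cubic box
min_image <- function(d, box) {
  d - box * round(d / box)
}

#' Molar concentration of solutes in a cubic box
#'
#' Converts a molecule count in a cubic periodic box to a molar
#' concentration.  Sixty oligomers in a 13 nm box correspond to about
#' 45 mM, the most concentrated condition studied.
#'
#' @param n number of molecules.
#' @param box_edge cubic box edge in nm.
#' @return concentration in mM.
#' @export
#' @examples
#' molar_concentration(60, 13)
molar_concentration <- function(n, box_edge) {
  stopifnot(n >= 0, box_edge > 0)
  vol_l <- (box_edge * 1e-8)^3 # nm^3 -> dm^3
  1000 * n / (.NA_CONST * vol_l)
}

# short md5 of a serialized parameter list, used in output headers
params_hash <- function(params) {
  f <- tempfile()
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  substr(unname(tools::md5sum(f)), 1, 12)
}

# standard header lines written on top of every text output
output_header <- function(seed = NULL, params = list()) {
  c(sprintf("# npadsorb %s",
            as.character(utils::packageVersion("npadsorb"))),
    sprintf("# seed=%s params_hash=%s",
            if (is.null(seed)) "NA" else format(seed),
            params_hash(params)))
}

#' Write a data frame as CSV with a reproducibility header
#'
#' Every tabular output carries comment lines with the package version, the
#' run seed and a hash of the generating parameters, so a file can be traced
#' back to its configuration.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param seed integer seed recorded in the header (`NULL` for none).
#' @param params list of parameters hashed into the header.
#' @return `path`, invisibly.
#' @export
write_output_csv <- function(df, path, seed = NULL, params = list()) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(output_header(seed, params), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_output_csv()]
#'
#' @param path file path.
#' @return a data frame (header comment lines are skipped).
#' @export
read_output_csv <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", comment.char = "#",
                    stringsAsFactors = FALSE)
}
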