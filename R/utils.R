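#' Derive a child seed from a master seed
#'
#' All randomness in the package flows from a single master seed. Each
#' component (ancestry, drivers, expression, copy number, outcomes, ...)
#' receives its own child seed through this fixed scheme so that components
#' can be re-simulated independently and cohorts are reproducible across
#' platforms.
#'
#' The scheme is `(seed * 48271 + 1000003 * index) mod (2^31 - 1)`, kept
#' strictly below `2^31` so it is always a valid R integer seed.
#'
#' @param seed Integer master seed.
#' @param index Non-negative integer component index.
#' @return An integer seed.
#' @export
childSeed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  m <- 2147483647
  as.integer((abs(seed) %% m * 48271 + 1000003 * index) %% m)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assert that a value is a single finite number
#' @noRd
assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' File manifest with checksums
#'
#' @param files Character vector of file paths.
#' @param root Optional directory against which paths are relativised.
#' @return A data.frame with columns `file`, `bytes` and `md5`.
#' @export
fileManifest <- function(files, root = NULL) {
  stopifnot(all(file.exists(files)))
  md5 <- unname(tools::md5sum(files))
  rel <- if (is.null(root)) files else {
    np <- normalizePath(files); nr <- paste0(normalizePath(root), "/")
    ifelse(startsWith(np, nr), substring(np, nchar(nr) + 1L), np)
  }
  data.frame(file = rel, bytes = unname(file.size(files)), md5 = md5,
             stringsAsFactors = FALSE)
}
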