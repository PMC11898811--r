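#' @useDynLib forceseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans median rnorm runif
#' @importFrom utils write.csv
NULL

# Run code with a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_forceseg <- function(msg, class, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

as_image_array <- function(image) {
  if (is.matrix(image)) image <- array(image, c(dim(image), 1L))
  if (length(dim(image)) != 3L)
    stop("expected an H x W x C array")
  image
}

check_rgb <- function(image) {
  image <- as_image_array(image)
  if (dim(image)[3] != 3L)
    stop_forceseg(sprintf("expected a 3-channel image, got %d channel(s)",
                          dim(image)[3]), "forceseg_shape_error")
  image
}

# 0-based (row, col) point helper used throughout the package.
pt <- function(row, col) c(row = as.numeric(row), col = as.numeric(col))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
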