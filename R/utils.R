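# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the RNG seeded at `seed` and restores the caller's
#' `.Random.seed` afterwards, so seeded operations never perturb the global
#' random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# upper-triangle (off-diagonal) vectorization, column-major, fixed ordering
ut <- function(m) m[upper.tri(m)]

# rebuild a symmetric matrix (unit diagonal by default) from an ut() vector
unvec_ut <- function(v, n, diag = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- diag
  m
}

fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-15), 1 - 1e-15))
inv_fisher_z <- function(z) tanh(z)

# fast column-wise Pearson correlation of y (vector) with columns of X
cor_vec_mat <- function(y, X) {
  y <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X), "-")
  num <- as.vector(crossprod(Xc, y))
  den <- sqrt(sum(y^2) * colSums(Xc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
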