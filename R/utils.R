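#' @keywords internal
"_PACKAGE"

#' @import Matrix
#' @importFrom stats cor dgamma pt rnorm sd setNames t.test var
#' @importFrom methods is
#' @importFrom rlang .data
NULL

.stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("chalign_invalid_argument", "error")))
}

.assert <- function(ok, ...) {
  if (!ok) .stop_invalid(...)
}

# Population (divisor n) standard deviation of each column.
.col_sd_pop <- function(X) {
  m <- colMeans(X)
  sqrt(colMeans(X^2) - m^2)
}

# Z-score columns with the population convention; columns with (near-)zero
# variance become all-zero and are reported in the "degenerate" attribute.
.zscore_cols <- function(X, tol = 1e-12) {
  m <- colMeans(X)
  Xc <- sweep(X, 2L, m, "-")
  s <- sqrt(colMeans(Xc^2))
  degen <- !is.finite(s) | s <= tol
  s[degen] <- 1
  Z <- sweep(Xc, 2L, s, "/")
  Z[, degen] <- 0
  attr(Z, "degenerate") <- degen
  Z
}

# Deterministic child seed from a master seed and a path of labels.
# Polynomial rolling hash over the UTF-8 bytes, kept below 2^31.
.child_seed <- function(master_seed, ...) {
  labels <- paste(c(format(master_seed, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- as.double(master_seed %% 2147483647)
  for (b in bytes) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate an expression under a local RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Random orthogonal matrix (Haar, reflections allowed) via QR of a Gaussian.
.random_orthogonal <- function(p) {
  qr_ <- qr(matrix(rnorm(p * p), p, p))
  Q <- qr.Q(qr_)
  # Fix the QR sign ambiguity so the draw is Haar-distributed.
  Q * rep(sign(diag(qr.R(qr_))), each = p)
}

# Random rotation whose largest eigenplane angle equals max_deg: the matrix
# exponential of a random skew-symmetric matrix rescaled so its extreme
# eigenvalue magnitude is max_deg in radians. max_deg = Inf falls back to a
# Haar-uniform orthogonal draw (reflections allowed).
.random_rotation <- function(p, max_deg) {
  if (is.infinite(max_deg)) {
    if (p == 1) return(matrix(sample(c(-1, 1), 1)))
    return(.random_orthogonal(p))
  }
  if (p == 1) return(matrix(1))
  G <- matrix(rnorm(p * p), p, p)
  K <- (G - t(G)) / 2
  w <- max(abs(Im(eigen(K, only.values = TRUE)$values)))
  if (w <= 0) return(diag(p))
  as.matrix(Matrix::expm(K * (max_deg * pi / 180 / w)))
}
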