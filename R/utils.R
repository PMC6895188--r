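# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Flatten a p x 3 x n landmark array to an n x 3p matrix (specimens as rows).
flatten_coords <- function(A) {
  stopifnot(length(dim(A)) == 3L)
  n <- dim(A)[3L]
  out <- t(apply(A, 3L, as.vector))
  if (n == 1L) out <- matrix(as.vector(A), nrow = 1L)
  rownames(out) <- dimnames(A)[[3L]]
  out
}

# Inverse of flatten_coords for a single configuration.
unflatten_config <- function(v, p) matrix(v, nrow = p, ncol = 3L)

# Symmetric inverse square root of a positive-definite matrix.
inv_sqrt_sym <- function(C, tol = 1e-12) {
  e <- eigen(C, symmetric = TRUE)
  if (any(e$values < tol * max(e$values)))
    stop("matrix is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Proper (det = +1) rotation carrying configuration X onto Y in the
# least-squares sense, i.e. minimising ||X R - Y||_F. Reflections are
# excluded unless allow_reflection = TRUE.
optimal_rotation <- function(X, Y, allow_reflection = FALSE) {
  M <- crossprod(X, Y)
  sv <- svd(M)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    u <- sv$u
    u[, 3L] <- -u[, 3L]
    R <- u %*% t(sv$v)
  }
  R
}

# Deterministic sub-seed derivation from a user seed. Drawn from the
# Mersenne-Twister stream seeded once with `seed` (the `offset`-th draw), so
# that sub-seeds for different offsets -- and for linearly related user
# seeds -- are mutually unrelated; arithmetic on the seed itself composes
# badly with the generator's own seed scrambling. Values stay inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  stopifnot(offset >= 1L, offset <= 1000L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  s <- sample.int(2147483646L, offset)[offset]
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  s
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
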