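# Independent oracle implementations used across the test files. These
# deliberately avoid the package's own code paths.

# Closed-form ordinary Procrustes distance between two configurations:
# center, scale to unit centroid size, optimal proper rotation via SVD.
opa_distance <- function(A, B) {
  X <- sweep(A, 2, colMeans(A)); X <- X / sqrt(sum(X^2))
  Y <- sweep(B, 2, colMeans(B)); Y <- Y / sqrt(sum(Y^2))
  s <- svd(crossprod(X, Y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) { u <- s$u; u[, 3] <- -u[, 3]; R <- u %*% t(s$v) }
  sqrt(sum((X %*% R - Y)^2))
}

# Grid-scan oracle for the Johnson-Neyman region: evaluate the squared
# t-statistic on a fine covariate grid and report sign-change boundaries.
jn_grid_oracle <- function(di, ds, var_di, var_ds, cov_is, tcrit2,
                           range, step = 1e-6) {
  x <- seq(range[1], range[2], by = step)
  d2 <- (di + ds * x)^2
  v <- var_di + 2 * x * cov_is + x^2 * var_ds
  sig <- d2 / v >= tcrit2
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  ivs <- cbind(x[starts[r$values]], x[ends[r$values]])
  ivs
}

# Direct tie-corrected Kruskal-Wallis H (independent of the package).
kw_oracle_H <- function(x, g) {
  r <- rank(x); N <- length(x)
  Rj <- tapply(r, g, sum); nj <- table(g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# Exhaustive permutation p-value for Kruskal-Wallis with two groups of
# sizes na, nb (enumerates all label assignments).
kw_oracle_exact_p <- function(x, g) {
  g <- factor(g)
  sizes <- table(g)
  N <- length(x)
  Hobs <- kw_oracle_H(x, g)
  picks <- utils::combn(N, sizes[1], simplify = FALSE)
  stopifnot(nlevels(g) == 2)
  Hs <- vapply(picks, function(p) {
    gg <- rep(2L, N); gg[p] <- 1L
    kw_oracle_H(x, factor(gg))
  }, numeric(1))
  mean(Hs >= Hobs - 1e-12)
}

# Balanced random mode map used by several simulations.
balanced_modes <- function(species, k) {
  stats::setNames(rep(paste0("mode", seq_len(k)), length.out =
                        length(species)), species)
}

# Small fixed tree strings.
cherry3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
quartet <- function() ape::read.tree(text = "((t1:1,t2:1):1,(t3:1,t4:1):1);")

star_tree <- function(n, labels = sprintf("sp%02d", seq_len(n))) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, n)
  tr$tip.label <- labels
  tr
}
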