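# Volume allometry across locomotor modes: Pagel's-lambda GLS regression
# lines of log cerebellar on log whole-brain volume, a slope-homogeneity
# gate, Johnson-Neyman regions of significance when slopes are
# heterogeneous, and phylogenetic ANOVA on the volume ratio.
#
# Volumes are mm^3 and logs are natural logs.

#' Construct a volume table
#'
#' @param species character species ids.
#' @param brain_volume,cerebellum_volume positive volumes in mm^3 with
#'   `cerebellum_volume < brain_volume`.
#' @param mode locomotor mode label per species.
#' @return a `data.frame` of class `volume_table`.
#' @export
volume_table <- function(species, brain_volume, cerebellum_volume, mode) {
  if (any(brain_volume <= 0) || any(cerebellum_volume <= 0))
    stop("volumes must be strictly positive")
  if (any(cerebellum_volume >= brain_volume))
    stop("cerebellum volume must be smaller than whole-brain volume")
  structure(data.frame(species = as.character(species),
                       brain_volume = brain_volume,
                       cerebellum_volume = cerebellum_volume,
                       mode = as.character(mode),
                       stringsAsFactors = FALSE),
            class = c("volume_table", "data.frame"))
}

# Profile Pagel's-lambda GLS fit of y on design X with tip covariance C.
# V(lambda) = lambda * C + (1 - lambda) * diag(C); lambda estimated by
# restricted maximum likelihood (REML) by default -- less biased than ML at
# comparative sample sizes and better-calibrated downstream F tests -- with
# ML available. Returns coefficients, their covariance (residual-df
# scaled), lambda, and the transformed-data residual sum of squares.
pgls_lambda_fit <- function(y, X, C, lambda = NULL, method = "REML") {
  n <- length(y)
  X <- as.matrix(X)
  dC <- diag(diag(C))
  reml <- identical(method, "REML")
  fit_at <- function(lam) {
    V <- lam * C + (1 - lam) * dC
    cho <- chol(V)
    yt <- backsolve(cho, y, transpose = TRUE)
    Xt <- backsolve(cho, X, transpose = TRUE)
    qrx <- qr(Xt)
    if (qrx$rank < ncol(Xt)) stop("rank-deficient design")
    beta <- qr.coef(qrx, yt)
    rss <- sum(qr.resid(qrx, yt)^2)
    ldet <- 2 * sum(log(diag(cho)))
    ll <- if (reml) {
      q <- ncol(X)
      ldetX <- 2 * sum(log(abs(diag(qr.R(qrx)))))
      -0.5 * ((n - q) * (log(2 * pi * rss / (n - q)) + 1) + ldet + ldetX)
    } else {
      -0.5 * (n * log(2 * pi * rss / n) + n + ldet)
    }
    list(beta = beta, rss = rss, loglik = ll, chol = cho, qr = qrx)
  }
  if (is.null(lambda)) {
    obj <- function(lam) -fit_at(lam)$loglik
    opt <- stats::optimize(obj, c(0, 1), tol = 1e-8)
    # compare against the boundaries explicitly
    cand <- c(opt$minimum, 0, 1)
    vals <- vapply(cand, obj, numeric(1))
    lambda <- cand[which.min(vals)]
  }
  f <- fit_at(lambda)
  df_resid <- n - ncol(X)
  sigma2 <- f$rss / df_resid
  XtX_inv <- chol2inv(qr.R(f$qr))
  vcov <- sigma2 * XtX_inv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coef = stats::setNames(f$beta, colnames(X)), vcov = vcov,
       lambda = lambda, sigma2 = sigma2, rss = f$rss,
       loglik = f$loglik, df_resid = df_resid, n = n)
}

#' Per-mode PGLS allometry lines for cerebellar volume
#'
#' Fits log cerebellar volume on log whole-brain volume jointly across
#' locomotor modes under a Pagel's-lambda GLS model (lambda by ML), with a
#' separate intercept per mode and, when `per_mode = TRUE`, a separate slope
#' per mode.
#'
#' @param volumes a `volume_table` (or data.frame with the same columns).
#' @param tree phylogeny covering all species.
#' @param per_mode fit mode-specific slopes (default TRUE).
#' @param lambda optionally fix lambda instead of estimating it.
#' @return an `ancova_fit`: per-mode `lines` (intercept, slope),
#'   coefficient `vcov`, `lambda`, residual `df`, and the observed
#'   log-brain-volume `range`.
#' @export
fit_pgls_lines <- function(volumes, tree, per_mode = TRUE, lambda = NULL) {
  v <- as.data.frame(volumes)
  mode <- factor(v$mode)
  if (any(table(mode) < 3L))
    stop("each mode needs at least three species (offending: ",
         paste(levels(mode)[table(mode) < 3L], collapse = ", "), ")")
  x <- log(v$brain_volume); y <- log(v$cerebellum_volume)
  C <- phylo_covariance(tree, v$species)
  M <- vapply(levels(mode), function(l) as.numeric(mode == l),
              numeric(length(mode)))
  if (per_mode) {
    Xs <- M * x
    colnames(Xs) <- paste0(levels(mode), ":logbrain")
    X <- cbind(M, Xs)
  } else {
    X <- cbind(M, logbrain = x)
  }
  f <- pgls_lambda_fit(y, X, C, lambda)
  k <- nlevels(mode)
  lines <- data.frame(mode = levels(mode),
                      intercept = f$coef[seq_len(k)],
                      slope = if (per_mode) f$coef[k + seq_len(k)]
                              else rep(f$coef[k + 1L], k),
                      row.names = NULL)
  structure(list(lines = lines, coef = f$coef, vcov = f$vcov,
                 lambda = f$lambda, sigma2 = f$sigma2,
                 df_resid = f$df_resid, n = f$n, per_mode = per_mode,
                 range = range(x), modes = levels(mode)),
            class = "ancova_fit")
}

#' @export
print.ancova_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic ANCOVA fit (lambda = %.3f, n = %d)\n",
              x$lambda, x$n))
  print(x$lines, row.names = FALSE)
  invisible(x)
}

#' Slope-homogeneity test for the volume allometries
#'
#' Tests the mode x log-brain-volume interaction in the Pagel's-lambda
#' phylogenetic linear model: an F test of the mode-specific-slopes model
#' against the common-slope model, both evaluated at the ML lambda of the
#' full model. Rejection means the conventional ANCOVA assumption is
#' violated and comparisons should proceed via the Johnson-Neyman region.
#'
#' @param volumes a `volume_table`.
#' @param tree phylogeny.
#' @return list with `p`, `F`, `df`, and the fitted `lambda`.
#' @export
slope_homogeneity_test <- function(volumes, tree) {
  v <- as.data.frame(volumes)
  mode <- factor(v$mode)
  if (nlevels(mode) < 2L) stop("need at least two modes")
  x <- log(v$brain_volume); y <- log(v$cerebellum_volume)
  C <- phylo_covariance(tree, v$species)
  M <- stats::model.matrix(~ 0 + mode)
  Xfull <- cbind(M, M * x)
  Xred <- cbind(M, x)
  full <- pgls_lambda_fit(y, Xfull, C)
  red <- pgls_lambda_fit(y, Xred, C, lambda = full$lambda)
  df1 <- ncol(Xfull) - ncol(Xred)
  df2 <- full$df_resid
  Fstat <- ((red$rss - full$rss) / df1) / (full$rss / df2)
  list(p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       F = Fstat, df = c(df1, df2), lambda = full$lambda)
}

#' Johnson-Neyman region of significance for two allometry lines
#'
#' For the group difference d(x) = delta_intercept + delta_slope * x with
#' variance v(x) from the coefficient covariance, the significance region is
#' the set of covariate values where d(x)^2 / v(x) >= t^2(alpha/2, df);
#' its boundaries are roots of the quadratic
#' (ds^2 - t^2 var_ds) x^2 + 2 (ds di - t^2 cov) x + (di^2 - t^2 var_di).
#'
#' @param fit an `ancova_fit` with per-mode slopes.
#' @param pair character vector of two mode labels.
#' @param alpha significance level.
#' @param range covariate interval to intersect with (defaults to the
#'   observed log brain-volume range).
#' @param df degrees of freedom for the t critical value; defaults to
#'   n - 4 (two lines, two parameters each).
#' @return a `jn_region`: list of significant `intervals` (with per-interval
#'   `direction`, the sign of the first group minus the second) plus the
#'   quadratic coefficients and inputs.
#' @export
johnson_neyman <- function(fit, pair, alpha = 0.05, range = NULL, df = NULL) {
  stopifnot(inherits(fit, "ancova_fit"))
  if (!fit$per_mode) stop("fit must contain per-mode slopes")
  if (length(pair) != 2L || !all(pair %in% fit$modes))
    stop("pair must name two fitted modes")
  range <- range %||% fit$range
  df <- df %||% (fit$n - 4L)
  ia <- match(pair[1L], fit$modes); ib <- match(pair[2L], fit$modes)
  k <- length(fit$modes)
  # contrast vectors picking delta-intercept and delta-slope
  ci <- rep(0, 2L * k); ci[ia] <- 1; ci[ib] <- -1
  cs <- rep(0, 2L * k); cs[k + ia] <- 1; cs[k + ib] <- -1
  di <- sum(ci * fit$coef); ds <- sum(cs * fit$coef)
  var_di <- drop(ci %*% fit$vcov %*% ci)
  var_ds <- drop(cs %*% fit$vcov %*% cs)
  cov_is <- drop(ci %*% fit$vcov %*% cs)
  t2 <- stats::qt(1 - alpha / 2, df)^2
  A <- ds^2 - t2 * var_ds
  B <- 2 * (ds * di - t2 * cov_is)
  Cc <- di^2 - t2 * var_di
  lo <- range[1L]; hi <- range[2L]

  sig_intervals <- list()
  add <- function(l, h) {
    l2 <- max(l, lo); h2 <- min(h, hi)
    if (l2 < h2)
      sig_intervals[[length(sig_intervals) + 1L]] <<- c(lower = l2, upper = h2)
  }
  if (abs(A) < 1e-300 * max(1, abs(B), abs(Cc))) {
    # degenerate quadratic: linear or constant in x
    if (abs(B) > 0) {
      r <- -Cc / B
      if (B > 0) add(r, Inf) else add(-Inf, r)
    } else if (Cc >= 0) add(-Inf, Inf)
  } else {
    disc <- B^2 - 4 * A * Cc
    if (disc <= 0) {
      if (A > 0) add(-Inf, Inf)      # positive everywhere (or tangent)
    } else {
      r <- sort(c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A)))
      if (A > 0) { add(-Inf, r[1L]); add(r[2L], Inf) } else add(r[1L], r[2L])
    }
  }
  direction <- vapply(sig_intervals, function(iv)
    sign(di + ds * mean(iv)), numeric(1))
  structure(list(pair = pair, alpha = alpha, df = df,
                 intervals = sig_intervals, direction = direction,
                 quadratic = c(A = A, B = B, C = Cc),
                 delta = c(intercept = di, slope = ds),
                 range = c(lo, hi)),
            class = "jn_region")
}

#' @export
print.jn_region <- function(x, ...) {
  cat("Johnson-Neyman region (", x$pair[1L], " vs ", x$pair[2L],
      ", alpha = ", x$alpha, "):\n", sep = "")
  if (!length(x$intervals)) cat("  empty within observed range\n")
  for (i in seq_along(x$intervals))
    cat(sprintf("  [%.4f, %.4f]  direction %s\n",
                x$intervals[[i]]["lower"], x$intervals[[i]]["upper"],
                ifelse(x$direction[i] > 0, "+", "-")))
  invisible(x)
}

#' Phylogenetic ANOVA on the cerebellum-to-brain volume ratio
#'
#' The ratio (in percent) is analysed with the univariate D-PGLS/RRPP
#' machinery, with pairwise post hoc comparisons between modes.
#'
#' @param volumes a `volume_table`.
#' @param tree phylogeny.
#' @param permutations RRPP permutations.
#' @param seed RNG seed.
#' @return an `anova_result` (see [phylo_procrustes_anova()]).
#' @export
ratio_anova <- function(volumes, tree, permutations = 999L, seed = 1L) {
  v <- as.data.frame(volumes)
  ratio <- matrix(100 * v$cerebellum_volume / v$brain_volume,
                  dimnames = list(v$species, "ratio_pct"))
  groups <- stats::setNames(v$mode, v$species)
  phylo_procrustes_anova(ratio, groups, tree, permutations, seed)
}
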