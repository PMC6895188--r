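# Landmark-based geometric morphometrics: superimposition, size, ordination,
# thin-plate-spline warping and group mean-shape deviation fields.
#
# Landmark data are handled as p x 3 x n arrays (p landmarks, 3 coordinates,
# n specimens), the layout used throughout 3D morphometrics. Coordinates are
# in micrometres and right-handed.

#' Construct a landmark set
#'
#' Bundles per-specimen 3D landmark configurations with specimen metadata and
#' named landmark subsets (one subset per brain subdivision, e.g. the
#' whole-brain configuration and a cerebellum configuration that adds extra
#' landmarks at the mesencephalon--cerebellum interface).
#'
#' @param coords numeric array, `p x 3 x n`, with specimen ids as the third
#'   dimnames. Units are micrometres.
#' @param species character vector of species ids, one per specimen.
#' @param subsets named list of integer vectors (1-based landmark indices).
#'   Defaults to a single subset `all` covering every landmark.
#' @return an object of class `landmark_set`.
#' @export
landmark_set <- function(coords, species, subsets = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2L] == 3L)
  n <- dim(coords)[3L]
  if (length(species) != n)
    stop("`species` must have one entry per specimen")
  if (!all(is.finite(coords)))
    stop("landmark coordinates must be finite")
  if (is.null(dimnames(coords)[[3L]]))
    dimnames(coords)[[3L]] <- paste0("spec", seq_len(n))
  subsets <- subsets %||% list(all = seq_len(dim(coords)[1L]))
  for (s in names(subsets)) {
    idx <- subsets[[s]]
    if (any(idx < 1L | idx > dim(coords)[1L]))
      stop("subset '", s, "' has out-of-range landmark indices")
  }
  structure(list(coords = coords,
                 specimens = data.frame(specimen = dimnames(coords)[[3L]],
                                        species = as.character(species),
                                        stringsAsFactors = FALSE),
                 subsets = subsets),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  d <- dim(x$coords)
  cat("Landmark set:", d[3L], "specimens,", d[1L], "landmarks,",
      length(x$subsets), "subset(s)\n")
  invisible(x)
}

#' Average replicate landmarking sessions
#'
#' Digitisation error is usually estimated by landmarking each specimen in
#' independent sessions; the sessions are then averaged coordinate-wise and
#' the mean configuration used for all downstream analyses.
#'
#' @param sessions list of `landmark_set` objects with identical specimen and
#'   landmark indexing.
#' @return a `landmark_set` of coordinate-wise means.
#' @export
average_replicates <- function(sessions) {
  if (!length(sessions)) stop("no sessions supplied")
  ref <- sessions[[1L]]
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    if (!identical(dim(s$coords), dim(ref$coords)) ||
        !identical(dimnames(s$coords)[[3L]], dimnames(ref$coords)[[3L]]))
      stop("session ", i, " has mismatched specimen/landmark indexing: ",
           paste(utils::head(setdiff(dimnames(s$coords)[[3L]],
                                     dimnames(ref$coords)[[3L]]), 5L),
                 collapse = ", "))
  }
  acc <- Reduce(`+`, lapply(sessions, `[[`, "coords"))
  out <- ref
  out$coords <- acc / length(sessions)
  out
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all landmarks from their
#' centroid; the size measure that generalized Procrustes analysis separates
#' from shape.
#'
#' @param config numeric `p x 3` matrix.
#' @return non-negative scalar, zero iff all landmarks coincide.
#' @export
centroid_size <- function(config) {
  if (is.null(dim(config)) || nrow(config) < 1L)
    stop("configuration must have at least one landmark")
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2L, ctr)^2))
}

#' Procrustes distance between two superimposed configurations
#'
#' @param a,b numeric `p x 3` matrices (already superimposed).
#' @return square root of summed squared coordinate differences.
#' @export
procrustes_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("configurations differ in shape")
  sqrt(sum((a - b)^2))
}

#' Generalized Procrustes analysis
#'
#' Simultaneously superimposes all configurations by iteratively centering,
#' scaling to unit centroid size, rotating each configuration onto the
#' current consensus, and updating the consensus, until the consensus
#' root-mean-square change falls below `tol`. Fitting rotations are proper
#' (no reflections) by default, respecting landmark homology.
#'
#' @param landmarks a `landmark_set` or a `p x 3 x n` array.
#' @param subset name of the landmark subset to superimpose (ignored for
#'   plain arrays).
#' @param tol convergence tolerance on the consensus RMS change.
#' @param max_iter iteration cap.
#' @param allow_reflection permit improper rotations in the fit.
#' @return an `aligned_shapes` object: superimposed `coords` (unit centroid
#'   size), original `centroid_sizes`, consensus `mean_shape`, and species
#'   labels when available.
#' @export
gpa <- function(landmarks, subset = NULL, tol = 1e-10, max_iter = 100L,
                allow_reflection = FALSE) {
  species <- NULL
  if (inherits(landmarks, "landmark_set")) {
    A <- landmarks$coords
    species <- landmarks$specimens$species
    if (!is.null(subset)) {
      if (!subset %in% names(landmarks$subsets))
        stop("unknown landmark subset '", subset, "'")
      A <- A[landmarks$subsets[[subset]], , , drop = FALSE]
    }
  } else A <- landmarks
  stopifnot(length(dim(A)) == 3L)
  n <- dim(A)[3L]; p <- dim(A)[1L]
  if (n < 2L) stop("GPA needs at least two specimens")
  ids <- dimnames(A)[[3L]] %||% paste0("spec", seq_len(n))

  cs <- numeric(n)
  for (i in seq_len(n)) {
    cfg <- A[, , i]
    cfg <- sweep(cfg, 2L, colMeans(cfg))
    cs[i] <- sqrt(sum(cfg^2))
    if (cs[i] <= 0)
      stop("degenerate (all-coincident) configuration for specimen ", ids[i])
    A[, , i] <- cfg / cs[i]
  }
  names(cs) <- ids

  consensus <- A[, , 1L]
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      R <- optimal_rotation(A[, , i], consensus, allow_reflection)
      A[, , i] <- A[, , i] %*% R
    }
    new_cons <- apply(A, c(1L, 2L), mean)
    new_cons <- sweep(new_cons, 2L, colMeans(new_cons))
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol) break
  }
  # final rotation pass onto the converged consensus
  for (i in seq_len(n)) {
    R <- optimal_rotation(A[, , i], consensus, allow_reflection)
    A[, , i] <- A[, , i] %*% R
  }
  # canonical orientation: consensus on its principal axes, deterministic
  # signs, right-handed. Fixes the rotational gauge so GPA is idempotent.
  R0 <- svd(consensus)$v
  Bc <- consensus %*% R0
  for (j in 1:2)
    if (Bc[which.max(abs(Bc[, j])), j] < 0) R0[, j] <- -R0[, j]
  R0[, 3L] <- c(R0[2, 1] * R0[3, 2] - R0[3, 1] * R0[2, 2],
                R0[3, 1] * R0[1, 2] - R0[1, 1] * R0[3, 2],
                R0[1, 1] * R0[2, 2] - R0[2, 1] * R0[1, 2])
  consensus <- consensus %*% R0
  for (i in seq_len(n)) A[, , i] <- A[, , i] %*% R0
  if (is.null(dimnames(A)[[3L]])) dimnames(A)[[3L]] <- ids
  structure(list(coords = A, centroid_sizes = cs, mean_shape = consensus,
                 species = species %||% ids, specimens = ids),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  d <- dim(x$coords)
  cat("Aligned shapes:", d[3L], "specimens,", d[1L], "landmarks\n")
  invisible(x)
}

#' Shape PCA
#'
#' Principal component analysis of the specimen covariance matrix of the
#' flattened Procrustes coordinates. Components are ordered by decreasing
#' eigenvalue; each component's sign is fixed so that its largest-magnitude
#' loading is positive.
#'
#' @param shapes an `aligned_shapes` object (or an n x q data matrix).
#' @return a `shape_space` with `scores`, `eigenvalues`, `percent_variance`
#'   and `loadings`.
#' @export
shape_pca <- function(shapes) {
  Y <- if (inherits(shapes, "aligned_shapes")) flatten_coords(shapes$coords)
       else as.matrix(shapes)
  n <- nrow(Y)
  if (n < 3L) stop("shape PCA needs at least three specimens")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, ctr)
  sv <- svd(Yc)
  ev <- sv$d^2 / (n - 1L)
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  V <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Yc %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(ncol(V)))
  rownames(scores) <- rownames(Y)
  structure(list(scores = scores, eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev),
                 loadings = V, center = ctr),
            class = "shape_space")
}

#' @export
print.shape_space <- function(x, ...) {
  k <- min(3L, length(x$percent_variance))
  cat("Shape space:", ncol(x$scores), "components; first",
      k, "explain", round(sum(x$percent_variance[seq_len(k)]), 2), "%\n")
  invisible(x)
}

#' Between-group PCA
#'
#' Eigenvectors are computed from the covariance of the group mean shapes;
#' all specimens are then projected onto those axes. With g groups there are
#' at most g - 1 non-null axes.
#'
#' @param shapes an `aligned_shapes` object or data matrix.
#' @param groups group label per specimen.
#' @return a `shape_space`; `percent_variance` refers to the group-mean
#'   covariance.
#' @export
between_group_pca <- function(shapes, groups) {
  Y <- if (inherits(shapes, "aligned_shapes")) flatten_coords(shapes$coords)
       else as.matrix(shapes)
  groups <- as.factor(groups)
  if (length(groups) != nrow(Y)) stop("one group label per specimen required")
  if (any(table(groups) == 0L)) stop("empty group level present")
  if (nlevels(groups) < 2L) stop("need at least two groups")
  M <- do.call(rbind, lapply(levels(groups),
                             function(g) colMeans(Y[groups == g, , drop = FALSE])))
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr)
  sv <- svd(Mc)
  ev <- sv$d^2 / max(1L, nrow(M) - 1L)
  keep <- which(ev > max(ev, 1e-300) * 1e-10)
  V <- sv$v[, keep, drop = FALSE]
  ev <- ev[keep]
  for (j in seq_len(ncol(V))) {
    m <- which.max(abs(V[, j]))
    if (V[m, j] < 0) V[, j] <- -V[, j]
  }
  scores <- sweep(Y, 2L, ctr) %*% V
  if (length(ev)) {
    colnames(scores) <- colnames(V) <- paste0("bgPC", seq_along(ev))
  }
  structure(list(scores = scores, eigenvalues = ev,
                 percent_variance = if (length(ev)) 100 * ev / sum(ev)
                                    else numeric(0),
                 loadings = V, center = ctr, group_means = Mc %*% V,
                 groups = groups),
            class = "shape_space")
}

#' Bootstrap confidence ellipse for a group mean
#'
#' Resamples the group's specimens with replacement, recomputes the group
#' mean score each time, and summarises the bootstrap scatter of means by a
#' covariance ellipse whose radius is the stated coverage quantile of the
#' Mahalanobis distances.
#'
#' @param scores numeric score matrix (specimens x components).
#' @param groups group label per specimen.
#' @param group the group to summarise.
#' @param axes which two components to use.
#' @param coverage coverage probability (default 68.27%).
#' @param replicates bootstrap replicates (default 5000).
#' @param seed RNG seed.
#' @return list with `center`, `axes` (semi-axis lengths), `orientation`
#'   (rotation matrix of ellipse axes) and the bootstrap `cov`.
#' @export
group_confidence_ellipse <- function(scores, groups, group, axes = c(1L, 2L),
                                     coverage = 0.6827, replicates = 5000L,
                                     seed = 1L) {
  S <- as.matrix(scores)[groups == group, axes, drop = FALSE]
  if (nrow(S) < 3L) stop("group must have at least three specimens")
  set.seed(seed)
  ctr <- colMeans(S)
  idx <- matrix(sample.int(nrow(S), nrow(S) * replicates, replace = TRUE),
                nrow = replicates)
  bm <- t(apply(idx, 1L, function(i) colMeans(S[i, , drop = FALSE])))
  if (all(abs(sweep(bm, 2L, ctr)) < 1e-12)) {      # zero-variance group
    return(list(center = ctr, axes = c(0, 0), orientation = diag(2),
                cov = matrix(0, 2, 2), coverage = coverage))
  }
  V <- stats::cov(bm)
  e <- eigen(V, symmetric = TRUE)
  md <- stats::mahalanobis(bm, colMeans(bm), V)
  r2 <- stats::quantile(md, coverage, names = FALSE)
  list(center = ctr, axes = sqrt(pmax(e$values, 0) * r2),
       orientation = e$vectors, cov = V, coverage = coverage)
}

#' Specimen closest to the consensus shape
#'
#' @param shapes an `aligned_shapes` object.
#' @return the specimen id minimising the Procrustes distance to the
#'   consensus; ties are broken by input order.
#' @export
find_mean_spec <- function(shapes) {
  stopifnot(inherits(shapes, "aligned_shapes"))
  n <- dim(shapes$coords)[3L]
  d <- vapply(seq_len(n),
              function(i) procrustes_distance(shapes$coords[, , i],
                                              shapes$mean_shape),
              numeric(1))
  shapes$specimens[which.min(d)]
}

#' Thin-plate-spline warp in 3D
#'
#' Interpolating deformation with the 3D biharmonic kernel U(r) = r: exact at
#' the landmarks and exactly reproducing any affine source-to-target map.
#'
#' @param source_landmarks,target_landmarks matching `p x 3` matrices
#'   (p >= 5, non-coplanar source).
#' @param vertices `m x 3` matrix of points to deform.
#' @return `m x 3` matrix of warped vertices.
#' @export
tps_warp <- function(source_landmarks, target_landmarks, vertices) {
  S <- as.matrix(source_landmarks); Tm <- as.matrix(target_landmarks)
  if (!identical(dim(S), dim(Tm))) stop("landmark sets differ in shape")
  p <- nrow(S)
  if (p < 5L) stop("need at least five landmarks")
  K <- as.matrix(stats::dist(S))           # U(r) = r in 3D
  P <- cbind(1, S)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4L, 4L)))
  rhs <- rbind(Tm, matrix(0, 4L, 3L))
  W <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system (coincident or coplanar source landmarks)"))
  w <- W[seq_len(p), , drop = FALSE]
  a <- W[p + 1:4, , drop = FALSE]
  V <- as.matrix(vertices)
  # pairwise distances from each vertex to each source landmark
  D <- sqrt(pmax(outer(rowSums(V^2), rowSums(S^2), `+`) -
                   2 * V %*% t(S), 0))
  cbind(1, V) %*% a + D %*% w
}

#' Per-group mean-shape deviation fields
#'
#' For each group, warps the supplied mesh vertices (registered to the
#' overall mean configuration) from the overall mean to the group mean
#' configuration with a thin-plate spline, and reports the per-vertex
#' Euclidean displacement in the input units.
#'
#' @param shapes an `aligned_shapes` object.
#' @param groups group label per specimen.
#' @param vertices `m x 3` mesh vertices registered to the mean shape.
#' @return `m x g` matrix of non-negative displacement magnitudes, one
#'   column per group.
#' @export
group_mean_deviation_map <- function(shapes, groups, vertices) {
  Y <- flatten_coords(shapes$coords)
  groups <- as.factor(groups)
  p <- dim(shapes$coords)[1L]
  overall <- unflatten_config(colMeans(Y), p)
  out <- matrix(NA_real_, nrow(as.matrix(vertices)), nlevels(groups),
                dimnames = list(NULL, levels(groups)))
  for (g in levels(groups)) {
    gm <- unflatten_config(colMeans(Y[groups == g, , drop = FALSE]), p)
    wv <- tps_warp(overall, gm, vertices)
    out[, g] <- sqrt(rowSums((wv - as.matrix(vertices))^2))
  }
  out
}
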