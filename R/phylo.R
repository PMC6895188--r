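# Phylogenetic comparative statistics on multivariate shape data: tip
# covariance, multivariate Blomberg's K, distance-based phylogenetic
# regression/ANOVA with residual-randomization permutation (RRPP), and
# distance-based convergence measures C1-C4.
#
# All GLS steps use the Brownian-motion tip covariance C and the symmetric
# inverse square root P = C^(-1/2) from its eigendecomposition; permutation
# p-values use the (b + 1)/(B + 1) estimator with ties counted as >=.

#' Brownian-motion tip covariance from a phylogeny
#'
#' `C[i, j]` is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths.
#'
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param species optional species order; must all be tips of the tree.
#' @param prune_extra drop tree tips absent from `species` (default TRUE);
#'   if FALSE extra tips are an error.
#' @return symmetric positive-definite covariance matrix in `species` order.
#' @export
phylo_covariance <- function(tree, species = NULL, prune_extra = TRUE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(species)) {
    missing <- setdiff(species, tree$tip.label)
    if (length(missing))
      stop("species missing from tree: ", paste(missing, collapse = ", "))
    extra <- setdiff(tree$tip.label, species)
    if (length(extra)) {
      if (!prune_extra)
        stop("tree has extra tips: ", paste(extra, collapse = ", "))
      tree <- ape::drop.tip(tree, extra)
    }
  }
  C <- ape::vcv.phylo(tree)
  if (!is.null(species)) C <- C[species, species]
  C
}

# Shared D-PGLS engine. Y: n x p response, X: full design, X0: reduced
# design (both with rows in the order of C). Returns sums of squares, F,
# R^2, RRPP p-value and GLS coefficients of the full model.
dpgls_fit <- function(Y, X, X0, C, permutations = 999L, seed = NULL) {
  Y <- as.matrix(Y); X <- as.matrix(X); X0 <- as.matrix(X0)
  n <- nrow(Y)
  stopifnot(nrow(X) == n, nrow(X0) == n, nrow(C) == n)
  P <- inv_sqrt_sym(C)
  Yt <- P %*% Y; Xt <- P %*% X; X0t <- P %*% X0
  hat_of <- function(M) {
    q <- qr(M)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H <- hat_of(Xt); H0 <- hat_of(X0t)
  rk <- qr(Xt)$rank; rk0 <- qr(X0t)$rank
  df1 <- rk - rk0; df2 <- n - rk
  if (df1 < 1L) stop("full design does not extend the reduced design")
  R0 <- Yt - H0 %*% Yt          # reduced-model residuals (RRPP pool)
  F0 <- H0 %*% Yt
  ss <- function(M) sum(M^2)
  ss_model <- ss((H - H0) %*% Yt)
  ss_res <- ss(Yt - H %*% Yt)
  ss_total <- ss(R0)
  Fobs <- (ss_model / df1) / (ss_res / df2)
  p <- NA_real_
  if (permutations > 0L) {
    if (!is.null(seed)) set.seed(seed)
    Hd <- H - H0
    ge <- 0L
    for (b in seq_len(permutations)) {
      Yp <- F0 + R0[sample.int(n), , drop = FALSE]
      sm <- ss(Hd %*% Yp)
      sr <- ss(Yp - H %*% Yp)
      if ((sm / df1) / (sr / df2) >= Fobs - 1e-12) ge <- ge + 1L
    }
    p <- (ge + 1) / (permutations + 1)
  }
  beta <- qr.coef(qr(Xt), Yt)
  beta[is.na(beta)] <- 0
  list(SS_effect = ss_model, SS_res = ss_res, SS_total = ss_total,
       R2 = if (ss_total > 0) ss_model / ss_total else NA_real_,
       F = Fobs, p = p, df = c(df1, df2), coef = beta, P = P,
       n_permutations = permutations)
}

# Extract a species-rowed data matrix from aligned shapes or a plain matrix.
species_matrix <- function(shapes) {
  if (inherits(shapes, "aligned_shapes")) {
    Y <- flatten_coords(shapes$coords)
    sp <- shapes$species
    if (anyDuplicated(sp))
      stop("replicate specimens per species present; average replicates first")
    rownames(Y) <- sp
    Y
  } else {
    Y <- as.matrix(shapes)
    if (is.null(rownames(Y))) stop("data matrix needs species rownames")
    Y
  }
}

#' Multivariate phylogenetic signal (Kmult)
#'
#' Generalisation of Blomberg's K to multivariate data: the ratio of observed
#' to Brownian-expected signal, with K = 1 under pure Brownian motion on the
#' given tree. Significance is assessed by permuting data across the tips.
#'
#' @param shapes `aligned_shapes` (one configuration per species) or a
#'   species x traits matrix with species rownames.
#' @param tree `ape::phylo` phylogeny containing all species.
#' @param permutations number of tip permutations.
#' @param seed RNG seed.
#' @return a `signal_result` list: `K`, `p`, `n_permutations`.
#' @export
k_mult <- function(shapes, tree, permutations = 999L, seed = 1L) {
  Y <- species_matrix(shapes)
  C <- phylo_covariance(tree, rownames(Y))
  n <- nrow(Y)
  Ci <- solve(C)
  one <- matrix(1, n, 1L)
  denom_scale <- (sum(diag(C)) - n / sum(Ci)) / (n - 1L)
  k_of <- function(Y) {
    a <- colSums(Ci %*% Y) / sum(Ci)
    D <- sweep(Y, 2L, a)
    (sum(D * D) / sum(D * (Ci %*% D))) / denom_scale
  }
  K <- k_of(Y)
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(permutations)) {
    if (k_of(Y[sample.int(n), , drop = FALSE]) >= K - 1e-12) ge <- ge + 1L
  }
  structure(list(K = K, p = (ge + 1) / (permutations + 1),
                 n_permutations = permutations),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Kmult = %.4f, p = %.4g (%d permutations)\n",
              x$K, x$p, x$n_permutations))
  invisible(x)
}

#' Phylogenetic multivariate regression of shape on a covariate
#'
#' Distance-based PGLS (D-PGLS): responses and design are transformed by
#' C^(-1/2), the linear model is fitted by least squares, and significance
#' comes from residual-randomization permutation of the reduced
#' (intercept-only) model. The reported R^2 is the "percentage predicted"
#' of the evolutionary allometry test when the covariate is log centroid
#' size.
#'
#' @param shapes `aligned_shapes` or species x traits matrix.
#' @param covariate named per-species numeric covariate.
#' @param tree phylogeny.
#' @param permutations RRPP permutations.
#' @param seed RNG seed.
#' @return an `anova_result`; `$residuals` holds per-species residual shapes
#'   (original space) for size-corrected reuse.
#' @export
pgls_shape_regression <- function(shapes, covariate, tree,
                                  permutations = 999L, seed = 1L) {
  Y <- species_matrix(shapes)
  x <- covariate[rownames(Y)]
  if (any(is.na(x)) || !all(is.finite(x)))
    stop("covariate missing or non-finite for some species")
  if (stats::sd(x) == 0) stop("constant covariate")
  C <- phylo_covariance(tree, rownames(Y))
  X <- cbind(1, x); X0 <- matrix(1, nrow(Y), 1L)
  fit <- dpgls_fit(Y, X, X0, C, permutations, seed)
  res <- Y - X %*% fit$coef
  rownames(res) <- rownames(Y)
  structure(list(SS_effect = fit$SS_effect, SS_total = fit$SS_total,
                 R2 = fit$R2, F = fit$F, p = fit$p, df = fit$df,
                 coef = fit$coef, residuals = res,
                 n_permutations = permutations),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("F = %.4f, R2 = %.4f (%.1f%% predicted), p = %.4g\n",
              x$F, x$R2, 100 * x$R2, x$p))
  if (!is.null(x$pairwise_p)) {
    cat("Pairwise p-values:\n")
    print(round(x$pairwise_p, 4))
  }
  invisible(x)
}

#' Phylogenetic Procrustes ANOVA with pairwise post hoc tests
#'
#' D-PGLS with a group-indicator design and RRPP significance. Pairwise
#' post hoc comparisons use Euclidean distances between GLS-estimated group
#' means, each referred to its own RRPP null. An optional covariate (e.g.
#' log centroid size) yields allometry-corrected tests.
#'
#' @param shapes `aligned_shapes` or species x traits matrix.
#' @param groups named per-species group labels.
#' @param tree phylogeny.
#' @param permutations RRPP permutations.
#' @param seed RNG seed.
#' @param covariate optional named per-species covariate included in both
#'   full and reduced designs.
#' @param adjust apply Benjamini-Hochberg adjustment to pairwise p-values
#'   (default FALSE: unadjusted, with the adjustment available as a flag).
#' @return an `anova_result` with `pairwise_d` and `pairwise_p` matrices.
#' @export
phylo_procrustes_anova <- function(shapes, groups, tree, permutations = 999L,
                                   seed = 1L, covariate = NULL,
                                   adjust = FALSE) {
  Y <- species_matrix(shapes)
  g <- factor(groups[rownames(Y)])
  if (any(is.na(g))) stop("group label missing for some species")
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L))
    warning("singleton group(s) present: ",
            paste(levels(g)[table(g) < 2L], collapse = ", "))
  C <- phylo_covariance(tree, rownames(Y))
  n <- nrow(Y)
  Xg <- stats::model.matrix(~ g)           # intercept + contrasts
  if (is.null(covariate)) {
    X0 <- matrix(1, n, 1L)
    X <- Xg
  } else {
    x <- covariate[rownames(Y)]
    if (any(is.na(x))) stop("covariate missing for some species")
    X0 <- cbind(1, x)
    X <- cbind(Xg, x)
  }
  fit <- dpgls_fit(Y, X, X0, C, permutations, seed)

  # pairwise distances between GLS group means (cell-means coding)
  P <- fit$P
  Yt <- P %*% Y
  Xcell <- stats::model.matrix(~ 0 + g)
  if (!is.null(covariate)) Xcell <- cbind(Xcell, x = X[, ncol(X)])
  Xct <- P %*% Xcell
  qr_c <- qr(Xct)
  means_of <- function(Yt) {
    B <- qr.coef(qr_c, Yt)
    B[seq_len(nlevels(g)), , drop = FALSE]
  }
  dist_of <- function(M) as.matrix(stats::dist(M))
  Dobs <- dist_of(means_of(Yt))
  dimnames(Dobs) <- list(levels(g), levels(g))
  # RRPP null for the pairwise distances (reduced model residual shuffle)
  hat0 <- {
    q0 <- qr(P %*% X0); Q0 <- qr.Q(q0)[, seq_len(q0$rank), drop = FALSE]
    tcrossprod(Q0)
  }
  R0 <- Yt - hat0 %*% Yt; F0 <- hat0 %*% Yt
  set.seed(seed)
  ge <- matrix(0L, nlevels(g), nlevels(g))
  for (b in seq_len(permutations)) {
    Dp <- dist_of(means_of(F0 + R0[sample.int(n), , drop = FALSE]))
    ge <- ge + (Dp >= Dobs - 1e-12)
  }
  Pp <- (ge + 1) / (permutations + 1)
  diag(Pp) <- NA_real_
  if (adjust) {
    lo <- lower.tri(Pp)
    Pp[lo] <- stats::p.adjust(Pp[lo], method = "BH")
    Pp[upper.tri(Pp)] <- t(Pp)[upper.tri(Pp)]
  }
  dimnames(Pp) <- dimnames(Dobs)
  structure(list(SS_effect = fit$SS_effect, SS_total = fit$SS_total,
                 R2 = fit$R2, F = fit$F, p = fit$p, df = fit$df,
                 coef = fit$coef, pairwise_d = Dobs, pairwise_p = Pp,
                 groups = g, n_permutations = permutations),
            class = "anova_result")
}

# Joint ML (weighted squared-change parsimony) ancestral states under
# Brownian motion: minimises sum over edges of (state change)^2 / length,
# with tip states fixed. Solves one sparse linear system for all traits.
ancestral_states_bm <- function(tree, Y) {
  Y <- as.matrix(Y)
  n <- length(tree$tip.label)
  m <- tree$Nnode
  Y <- Y[tree$tip.label, , drop = FALSE]
  L <- matrix(0, m, m)
  B <- matrix(0, m, ncol(Y))
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    w <- 1 / tree$edge.length[e]
    ai <- a - n
    L[ai, ai] <- L[ai, ai] + w
    if (b > n) {                 # internal-internal edge
      bi <- b - n
      L[bi, bi] <- L[bi, bi] + w
      L[ai, bi] <- L[ai, bi] - w
      L[bi, ai] <- L[bi, ai] - w
    } else {                     # tip edge
      B[ai, ] <- B[ai, ] + w * Y[b, ]
    }
  }
  A <- solve(L, B)
  rownames(A) <- as.character(n + seq_len(m))
  A
}

# Node path (node indices) from a tip back to an ancestor, both inclusive.
path_to_ancestor <- function(tree, tip, anc) {
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- tip
  node <- tip
  while (node != anc) {
    node <- parent[node]
    if (node == 0L) stop("ancestor not on the tip's root path")
    path <- c(path, node)
  }
  path
}

# C1-C4 for one focal pair given a full node-state matrix (tips then
# internal nodes, ape numbering).
c_measures_pair <- function(tree, states, t1, t2) {
  mrca <- ape::getMRCA(tree, c(t1, t2))
  p1 <- path_to_ancestor(tree, t1, mrca)
  p2 <- path_to_ancestor(tree, t2, mrca)
  S1 <- states[p1, , drop = FALSE]; S2 <- states[p2, , drop = FALSE]
  cross <- sqrt(pmax(outer(rowSums(S1^2), rowSums(S2^2), `+`) -
                       2 * S1 %*% t(S2), 0))
  dtip <- cross[1L, 1L]
  dmax <- max(cross)
  path_change <- function(p) {
    d <- diff_states <- states[p[-1L], , drop = FALSE] -
      states[p[-length(p)], , drop = FALSE]
    sum(sqrt(rowSums(d^2)))
  }
  total_path <- path_change(p1) + path_change(p2)
  # total phenotypic change over every edge of the clade descending from MRCA
  clade_nodes <- c(mrca)
  total_clade <- 0
  repeat {
    kids <- tree$edge[tree$edge[, 1L] %in% clade_nodes &
                        !(tree$edge[, 2L] %in% clade_nodes), 2L]
    if (!length(kids)) break
    for (k in kids) {
      par <- tree$edge[tree$edge[, 2L] == k, 1L]
      total_clade <- total_clade +
        sqrt(sum((states[k, ] - states[par, ])^2))
    }
    clade_nodes <- c(clade_nodes, kids)
  }
  if (dmax <= 0)
    return(c(C1 = NA_real_, C2 = NA_real_, C3 = NA_real_, C4 = NA_real_))
  c(C1 = 1 - dtip / dmax,
    C2 = dmax - dtip,
    C3 = if (total_path > 0) (dmax - dtip) / total_path else NA_real_,
    C4 = if (total_clade > 0) (dmax - dtip) / total_clade else NA_real_)
}

#' Distance-based convergence measures C1-C4
#'
#' Quantifies convergence among focal taxa as the fraction (C1) and amount
#' (C2) of the maximum past phenotypic distance between their lineages that
#' evolution has closed, scaled by the total change along the lineages (C3)
#' or in the whole clade descending from their MRCA (C4). Ancestral states
#' are joint ML estimates under Brownian motion; significance comes from
#' Brownian simulations with the rate matrix estimated from the data
#' (phylogenetic independent contrasts).
#'
#' @param data species x traits matrix (e.g. PC scores) with species
#'   rownames, or `aligned_shapes`.
#' @param tree phylogeny.
#' @param focal_taxa character vector (>= 2) of convergent tips.
#' @param n_sim Brownian simulations for the null.
#' @param seed RNG seed.
#' @param anc_states optional fixed node-state matrix (internal nodes,
#'   rownames = ape node numbers) overriding the ML estimates (used for
#'   oracle checks).
#' @return a `convergence_result` with observed C1-C4 (pairwise averages),
#'   simulation p-values, and `n_simulations`.
#' @export
convergence_c_measures <- function(data, tree, focal_taxa, n_sim = 1000L,
                                   seed = 1L, anc_states = NULL) {
  Y <- species_matrix(data)
  missing <- setdiff(focal_taxa, tree$tip.label)
  if (length(missing))
    stop("focal taxa not in tree: ", paste(missing, collapse = ", "))
  if (length(focal_taxa) < 2L) stop("need at least two focal taxa")
  Y <- Y[tree$tip.label, , drop = FALSE]
  n <- nrow(Y)
  tipidx <- match(focal_taxa, tree$tip.label)
  pairs <- utils::combn(tipidx, 2L)

  measure_all <- function(Y, anc = NULL) {
    A <- anc %||% ancestral_states_bm(tree, Y)
    states <- rbind(Y, A)    # rows 1..n tips, n+1..n+m internals
    vals <- apply(pairs, 2L, function(pr)
      c_measures_pair(tree, states, pr[1L], pr[2L]))
    rowMeans(vals, na.rm = TRUE)
  }
  obs <- measure_all(Y, anc_states)

  p <- rep(NA_real_, 4L)
  if (n_sim > 0L) {
    C <- phylo_covariance(tree, tree$tip.label)
    pic <- apply(Y, 2L, function(y) ape::pic(y, tree))
    R <- crossprod(as.matrix(pic)) / (n - 1L)
    Ci1 <- solve(C, rep(1, n))
    root <- colSums(Y * Ci1) / sum(Ci1)
    Lc <- t(chol(C))
    Lr <- tryCatch(chol(R), error = function(e)
      chol(R + diag(1e-10 * max(diag(R)), nrow(R))))
    set.seed(seed)
    ge <- rep(0L, 4L)
    for (s in seq_len(n_sim)) {
      Z <- matrix(stats::rnorm(n * ncol(Y)), n)
      Ys <- sweep(Lc %*% Z %*% Lr, 2L, root, `+`)
      rownames(Ys) <- tree$tip.label
      sim <- measure_all(Ys)
      ge <- ge + (!is.na(sim) & !is.na(obs) & sim >= obs - 1e-12)
    }
    p <- (ge + 1) / (n_sim + 1)
  }
  names(p) <- paste0("p", 1:4)
  structure(list(C = obs, p = p, n_simulations = n_sim,
                 focal_taxa = focal_taxa),
            class = "convergence_result")
}

#' @export
print.convergence_result <- function(x, ...) {
  cat("Convergence measures (", length(x$focal_taxa), " focal taxa):\n",
      sep = "")
  print(round(rbind(value = x$C, p = x$p), 4))
  invisible(x)
}
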