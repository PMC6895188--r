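# Purkinje-cell scattering statistics: normalized depth in the molecular
# layer, Kruskal-Wallis across species (exact enumeration for tiny samples),
# Dwass-Steel-Critchlow-Fligner pairwise post hoc tests, and partition of
# species into positioning patterns (ordered monolayer ... totally
# scattered).

#' Construct a cell-depth table
#'
#' Per-cell records of the shortest distance from the Purkinje soma center
#' to the inner granule-cell-layer border and the local molecular-layer
#' thickness, both in micrometres.
#'
#' @param species species id per cell.
#' @param cell_id cell identifier.
#' @param dist_gcl distance to the GCL inner border (>= 0).
#' @param ml_thickness local ML thickness (> 0), with
#'   `dist_gcl <= ml_thickness`.
#' @return a `data.frame` of class `cell_depth_table`.
#' @export
cell_depth_table <- function(species, cell_id, dist_gcl, ml_thickness) {
  if (any(dist_gcl < 0) || any(ml_thickness <= 0))
    stop("distances must be >= 0 and thicknesses > 0")
  bad <- which(dist_gcl > ml_thickness)
  if (length(bad))
    stop("dist_gcl exceeds ml_thickness for cells: ",
         paste(utils::head(cell_id[bad], 10L), collapse = ", "))
  d <- data.frame(species = as.character(species), cell_id = cell_id,
                  dist_gcl = dist_gcl, ml_thickness = ml_thickness,
                  stringsAsFactors = FALSE)
  cnt <- table(d$species)
  if (any(cnt < 250L | cnt > 750L))
    warning("cell counts outside the expected 250-750 range for: ",
            paste(names(cnt)[cnt < 250L | cnt > 750L], collapse = ", "))
  structure(d, class = c("cell_depth_table", "data.frame"))
}

#' Normalize cell depths to the local molecular-layer thickness
#'
#' @param table a `cell_depth_table` (or data.frame with `dist_gcl` and
#'   `ml_thickness` columns).
#' @return the table with a `depth_pct` column,
#'   `100 * dist_gcl / ml_thickness`, 0 at the GCL border and 100 at the
#'   pial surface.
#' @export
normalize_depths <- function(table) {
  d <- as.data.frame(table)
  bad <- which(d$dist_gcl > d$ml_thickness)
  if (length(bad))
    stop("dist_gcl exceeds ml_thickness for cells: ",
         paste(utils::head(d$cell_id[bad], 10L), collapse = ", "))
  d$depth_pct <- 100 * d$dist_gcl / d$ml_thickness
  d
}

# All distinct assignments of N items to groups of sizes `sizes`;
# used for exact small-sample null distributions.
multiset_assignments <- function(sizes) {
  N <- sum(sizes)
  # recursive construction: choose positions for each group in turn
  build <- function(avail, gi) {
    if (gi > length(sizes)) return(list(integer(0)))
    k <- sizes[gi]
    if (length(avail) == k) {
      rest <- build(integer(0), gi + 1L)
      return(lapply(rest, function(r) c(stats::setNames(rep(gi, k), avail), r)))
    }
    picks <- utils::combn(avail, k, simplify = FALSE)
    res <- list()
    for (pk in picks) {
      rest <- build(setdiff(avail, pk), gi + 1L)
      res <- c(res, lapply(rest, function(r)
        c(stats::setNames(rep(gi, k), pk), r)))
    }
    res
  }
  asg <- build(seq_len(N), 1L)
  lapply(asg, function(a) {
    g <- integer(N); g[as.integer(names(a))] <- a; g
  })
}

# Tie-corrected Kruskal-Wallis H for values x and group factor g.
kw_statistic <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr > 0) H <- H / corr
  H
}

#' Kruskal-Wallis test on normalized depths by species
#'
#' Rank-based H with tie correction; the p-value comes from the chi-square
#' approximation (k - 1 df) or, automatically for total sample sizes
#' N <= 10, from exact enumeration of all group-label assignments.
#'
#' @param depths numeric values (e.g. `depth_pct`).
#' @param groups group (species) label per value.
#' @return list with `H`, `p`, `df` and `method`.
#' @export
kruskal_wallis <- function(depths, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups")
  if (any(table(g) < 2L)) stop("each group needs at least two observations")
  x <- as.numeric(depths)
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = nlevels(g) - 1L, method = "degenerate"))
  H <- kw_statistic(x, g)
  N <- length(x)
  if (N <= 10L) {
    sizes <- as.integer(table(g))
    perms <- multiset_assignments(sizes)
    Hs <- vapply(perms, function(gg) kw_statistic(x, factor(gg)), numeric(1))
    p <- mean(Hs >= H - 1e-12)
    method <- "exact enumeration"
  } else {
    p <- stats::pchisq(H, df = nlevels(g) - 1L, lower.tail = FALSE)
    method <- "chi-square approximation"
  }
  list(H = H, p = p, df = nlevels(g) - 1L, method = method)
}

#' Dwass-Steel-Critchlow-Fligner pairwise post hoc tests
#'
#' For each pair of groups, ranks the pooled pair, forms the tie-corrected
#' standardized Wilcoxon rank-sum statistic W*, and refers sqrt(2)|W*| to
#' the Studentized range distribution with k groups (infinite df), giving
#' family-wise-controlled pairwise p-values.
#'
#' @param depths numeric values.
#' @param groups group label per value.
#' @return symmetric matrix of pairwise p-values (diagonal NA), with the
#'   standardized statistics in attribute `statistic`.
#' @export
dscf_posthoc <- function(depths, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  if (k < 2L) stop("need at least two groups")
  x <- as.numeric(depths)
  P <- W <- matrix(NA_real_, k, k, dimnames = list(levels(g), levels(g)))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    xi <- x[g == levels(g)[i]]; xj <- x[g == levels(g)[j]]
    ni <- length(xi); nj <- length(xj); N <- ni + nj
    r <- rank(c(xi, xj))
    Wj <- sum(r[(ni + 1L):N])
    ties <- table(c(xi, xj))
    vw <- ni * nj / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
    ws <- (Wj - nj * (N + 1) / 2) / sqrt(vw)
    W[i, j] <- W[j, i] <- ws
    P[i, j] <- P[j, i] <- stats::ptukey(sqrt(2) * abs(ws), nmeans = k,
                                        df = Inf, lower.tail = FALSE)
  }
  attr(P, "statistic") <- W
  P
}

# Minimal union-find over 1..n.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(edges)) for (e in edges) {
    a <- find(e[1L]); b <- find(e[2L])
    if (a != b) parent[b] <- a
  }
  vapply(seq_len(n), find, integer(1))
}

#' Partition species into Purkinje-cell positioning patterns
#'
#' Builds a graph joining species pairs that are NOT significantly different
#' (pairwise p >= alpha) and takes connected components as positioning
#' patterns, labelled I, II, ... by ascending median normalized depth. A
#' confirmation Kruskal-Wallis test is re-run between the resulting
#' patterns. The result records whether the non-significance graph was
#' transitive (components = cliques); when it is not, component membership
#' chains through intermediate species.
#'
#' @param pairwise_p symmetric species x species p-value matrix (e.g. from
#'   [dscf_posthoc()]).
#' @param depths numeric depth values (for pattern ordering and the
#'   confirmation test).
#' @param groups species label per depth value.
#' @param alpha membership threshold.
#' @return a `scatter_groups` list: `assignment` (species -> pattern),
#'   `medians`, `kw_between` confirmation test, and `transitive` flag.
#' @export
partition_patterns <- function(pairwise_p, depths, groups, alpha = 0.05) {
  sp <- rownames(pairwise_p)
  n <- length(sp)
  med <- tapply(as.numeric(depths), factor(groups, levels = sp), stats::median)
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (!is.na(pairwise_p[i, j]) && pairwise_p[i, j] >= alpha)
      edges[[length(edges) + 1L]] <- c(i, j)
  comp <- uf_components(n, edges)
  # transitivity: within every component, all pairs must be non-significant
  transitive <- TRUE
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) > 1L) {
      sub <- pairwise_p[idx, idx]
      if (any(sub[upper.tri(sub)] < alpha, na.rm = TRUE)) transitive <- FALSE
    }
  }
  comp_med <- tapply(med, comp, stats::median)
  ord <- order(comp_med)
  roman <- as.character(utils::as.roman(seq_along(ord)))
  relab <- stats::setNames(roman, names(comp_med)[ord])
  assignment <- stats::setNames(relab[as.character(comp)], sp)
  kw_between <- if (length(unique(assignment)) > 1L) {
    pat_of_value <- assignment[as.character(groups)]
    kruskal_wallis(depths, pat_of_value)
  } else NULL
  if (!transitive)
    message("non-significance graph is not transitive; ",
            "patterns chain through intermediate species")
  structure(list(assignment = assignment, medians = med,
                 kw_between = kw_between, transitive = transitive,
                 alpha = alpha),
            class = "scatter_groups")
}

#' @export
print.scatter_groups <- function(x, ...) {
  cat("Positioning patterns (alpha =", x$alpha, "):\n")
  for (p in unique(x$assignment))
    cat("  ", p, ": ", paste(names(x$assignment)[x$assignment == p],
                             collapse = ", "), "\n", sep = "")
  if (!is.null(x$kw_between))
    cat(sprintf("Between-pattern KW: H = %.2f, p = %.3g\n",
                x$kw_between$H, x$kw_between$p))
  invisible(x)
}
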