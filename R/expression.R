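# Downstream transcriptomic comparisons on an ortholog FPKM matrix:
# expression filtering, row z-scoring, hierarchical clustering of genes and
# species, pairwise correlation, multiscale-bootstrap AU support for the
# species dendrogram, and hypergeometric GO enrichment with FDR control.
#
# The matrix is genes x species, FPKM scale, non-negative.

#' Filter orthologs by expression level
#'
#' Keeps genes whose maximum FPKM across species is strictly above the
#' threshold (default 0.5 FPKM), removing noise-level transcripts.
#'
#' @param matrix genes x species numeric matrix, FPKM >= 0.
#' @param threshold expression threshold; a gene at exactly the threshold is
#'   removed (strict "above").
#' @return the filtered matrix.
#' @export
filter_orthologs <- function(matrix, threshold = 0.5) {
  m <- as.matrix(matrix)
  if (any(m < 0)) stop("FPKM values must be non-negative")
  keep <- apply(m, 1L, max) > threshold
  if (!any(keep))
    stop("no gene passes the ", threshold,
         " FPKM filter; lower the threshold")
  m[keep, , drop = FALSE]
}

#' Row-wise z-scoring
#'
#' Per gene: subtract the mean and divide by the sample standard deviation.
#' Constant rows are set to all-zero and flagged in attribute
#' `constant_rows`.
#'
#' @param matrix genes x species numeric matrix.
#' @return scaled matrix with zero row means and unit row SDs.
#' @export
zscore_rows <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) stop("need at least two species")
  mu <- rowMeans(m)
  sd <- apply(m, 1L, stats::sd)
  const <- sd == 0
  sd[const] <- 1
  out <- (m - mu) / sd
  out[const, ] <- 0
  attr(out, "constant_rows") <- rownames(m)[const]
  out
}

expr_dist <- function(m, metric) {
  switch(metric,
         euclidean = stats::dist(m),
         pearson = stats::as.dist(1 - stats::cor(t(m))),
         spearman = stats::as.dist(1 - stats::cor(t(m), method = "spearman")),
         stop("invalid metric '", metric,
              "'; use euclidean, pearson or spearman"))
}

#' Agglomerative hierarchical clustering of genes or species
#'
#' @param matrix genes x species numeric matrix (pre-transformed as
#'   desired, e.g. z-scored for the gene axis).
#' @param axis cluster `"genes"` (rows) or `"species"` (columns).
#' @param metric `"euclidean"`, `"pearson"` (distance 1 - r) or
#'   `"spearman"` (1 - rank r).
#' @param linkage agglomeration method (default `"average"`).
#' @param k optional number of clusters to cut the dendrogram into
#'   (k = 3 for the gene-archetype analysis).
#' @return a `cluster_result`: `hclust` object, optional `labels` from the
#'   k-cut, and the metric name.
#' @export
hierarchical_cluster <- function(matrix, axis = c("genes", "species"),
                                 metric = c("euclidean", "pearson",
                                            "spearman"),
                                 linkage = "average", k = NULL) {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  m <- as.matrix(matrix)
  if (axis == "species") m <- t(m)
  if (nrow(m) < 3L) stop("need at least three items to cluster")
  hc <- stats::hclust(expr_dist(m, metric), method = linkage)
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  structure(list(hclust = hc, labels = labels, metric = metric,
                 linkage = linkage, axis = axis),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$hclust$labels), x$axis,
      "(", x$metric, "distance,", x$linkage, "linkage )\n")
  if (!is.null(x$labels))
    cat("Cut sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise Pearson correlation between species
#'
#' @param matrix genes x species numeric matrix.
#' @return symmetric species x species correlation matrix with unit
#'   diagonal; feed `1 - r` to [hierarchical_cluster()] for the species
#'   dendrogram.
#' @export
pairwise_correlation <- function(matrix) {
  m <- as.matrix(matrix)
  if (ncol(m) < 2L) stop("need at least two species")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant expression column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  stats::cor(m)
}

#' Multiscale bootstrap AU support for the species dendrogram
#'
#' Species are clustered from gene-resampled replicates at several resample
#' scales r (resample size round(r * n_genes), with replacement). For each
#' internal node, the per-scale bootstrap probability BP(r) is the fraction
#' of replicates whose dendrogram contains the identical tip set; the curve
#' z(r) = qnorm(1 - BP(r)) is fitted as v*sqrt(r) + c/sqrt(r) by weighted
#' least squares and extrapolated to the approximately unbiased support
#' AU = 100 * (1 - pnorm(v - c)).
#'
#' Scales where BP is exactly 0 or 1 carry no curvature information and are
#' excluded from the fit; a node degenerate at (nearly) all scales is
#' assigned AU = 100 * (1 - eps) or 100 * eps with eps = 1/(2 * iterations),
#' and a node never observed at any scale gets AU = 0 with a flag.
#'
#' @param matrix genes x species matrix used for the reference clustering.
#' @param scales resample scale factors.
#' @param iterations bootstrap replicates per scale.
#' @param seed RNG seed.
#' @param metric,linkage passed to the clustering (defaults: 1 - Pearson,
#'   average linkage).
#' @return a `cluster_result` with a `support` data.frame per internal
#'   node: `au` and `bp` (percent), fit coefficients `v` and `c`, and the
#'   node's tip set.
#' @export
multiscale_bootstrap_au <- function(matrix, scales = seq(0.5, 1.4, by = 0.1),
                                    iterations = 1000L, seed = 1L,
                                    metric = "pearson",
                                    linkage = "average") {
  m <- as.matrix(matrix)
  ng <- nrow(m); ns <- ncol(m)
  if (ns < 3L) stop("need at least three species")
  hc <- stats::hclust(expr_dist(t(m), metric), method = linkage)
  node_sets <- node_tip_sets(hc)
  keys <- vapply(node_sets, paste, character(1), collapse = "\r")
  eps <- 1 / (2 * iterations)

  set.seed(seed)
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(NULL, paste0("r", scales)))
  for (si in seq_along(scales)) {
    msize <- max(2L, round(scales[si] * ng))
    counts <- stats::setNames(numeric(length(keys)), keys)
    for (b in seq_len(iterations)) {
      idx <- sample.int(ng, msize, replace = TRUE)
      hb <- tryCatch(
        stats::hclust(expr_dist(t(m[idx, , drop = FALSE]), metric),
                      method = linkage),
        error = function(e) NULL)
      if (is.null(hb)) next
      kb <- vapply(node_tip_sets(hb), paste, character(1), collapse = "\r")
      hit <- keys %in% kb
      counts[hit] <- counts[hit] + 1
    }
    bp[, si] <- counts / iterations
  }

  r <- scales
  au <- v <- cc <- rep(NA_real_, length(keys))
  flag <- rep("", length(keys))
  sat <- 20 / iterations       # saturation margin: too few misses (or hits)
  for (i in seq_along(keys)) {
    b <- bp[i, ]
    use <- b > 0 & b < 1
    if (all(b == 0)) {
      au[i] <- 0; flag[i] <- "never observed"
    } else if (all(b >= 1 - sat) || all(b <= sat)) {
      # fewer than ~20 discordant replicates per scale: no usable curvature
      # information, node reported at the resolution limit
      au[i] <- if (mean(b) >= 0.5) 100 * (1 - eps) else 100 * eps
      flag[i] <- "saturated"
    } else if (sum(use) < 2L) {
      au[i] <- if (mean(b) >= 0.5) 100 * (1 - eps) else 100 * eps
      flag[i] <- "degenerate"
    } else {
      z <- stats::qnorm(1 - b[use])
      w <- iterations * stats::dnorm(z)^2 / (b[use] * (1 - b[use]))
      X <- cbind(sqrt(r[use]), 1 / sqrt(r[use]))
      cf <- stats::lm.wfit(X, z, w)$coefficients
      v[i] <- cf[1L]; cc[i] <- cf[2L]
      au[i] <- 100 * (1 - stats::pnorm(cf[1L] - cf[2L]))
      au[i] <- min(max(au[i], 100 * eps), 100 * (1 - eps))
    }
  }
  i1 <- which.min(abs(r - 1))
  support <- data.frame(node = seq_along(keys), au = au,
                        bp = 100 * bp[, i1], v = v, c = cc,
                        flag = flag, stringsAsFactors = FALSE)
  support$tips <- node_sets
  structure(list(hclust = hc, support = support, metric = metric,
                 linkage = linkage, axis = "species",
                 scales = scales, iterations = iterations),
            class = "cluster_result")
}

# Tip-label sets of each internal node of an hclust tree, sorted for
# canonical comparison.
node_tip_sets <- function(hc) {
  n <- length(hc$labels %||% seq_len(nrow(hc$merge) + 1L))
  labs <- hc$labels %||% as.character(seq_len(n))
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    pick <- function(j) if (j < 0) labs[-j] else sets[[j]]
    sets[[i]] <- sort(c(pick(hc$merge[i, 1L]), pick(hc$merge[i, 2L])))
  }
  sets
}

#' Hypergeometric GO enrichment
#'
#' Per GO term: upper-tail hypergeometric probability of observing at least
#' k annotated genes in the gene set, given K annotated among N background
#' genes and a set of size n; Benjamini-Hochberg adjustment across terms.
#' Reported hits require adjusted p < `p_cutoff` and at least `min_genes`
#' set genes carrying the term.
#'
#' @param gene_set character vector, subset of `background`.
#' @param annotation data.frame with columns `gene`, `go_id`, `term`.
#' @param background character vector of all genes considered.
#' @param p_cutoff significance threshold on the adjusted p-value.
#' @param min_genes minimum annotated set genes per reported term.
#' @return an `enrichment_result` data.frame (one row per tested term) with
#'   counts, `p`, `p_adj` and a `significant` flag.
#' @export
go_enrichment <- function(gene_set, annotation, background,
                          p_cutoff = 0.01, min_genes = 10L) {
  if (!all(gene_set %in% background))
    stop("gene_set must be a subset of background")
  ann <- annotation[annotation$gene %in% background, , drop = FALSE]
  skipped <- setdiff(unique(annotation$go_id), unique(ann$go_id))
  if (length(skipped))
    message("terms absent from background skipped: ",
            paste(skipped, collapse = ", "))
  N <- length(unique(background))
  n <- length(unique(gene_set))
  terms <- unique(ann[, c("go_id", "term")])
  res <- lapply(seq_len(nrow(terms)), function(i) {
    genes_t <- unique(ann$gene[ann$go_id == terms$go_id[i]])
    K <- length(genes_t)
    k <- length(intersect(genes_t, gene_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(go_id = terms$go_id[i], term = terms$term[i],
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < p_cutoff & out$k >= min_genes
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("enrichment_result", "data.frame"))
}
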