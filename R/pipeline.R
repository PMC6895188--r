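# Pipeline orchestration: run the five analysis stages (morphometry,
# phylogenetic statistics, volumetrics, cell scattering, expression) on a
# config-declared dataset -- either files on disk or a synthetic bundle --
# with one global seed and a machine-readable JSON report.

#' Assemble a pipeline configuration
#'
#' @param simulate a `sim_config` to generate the inputs, or NULL to read
#'   them from `paths`.
#' @param paths named list of input files (`tree`, `landmarks`, `modes`,
#'   `volumes`, `depths`, `expression`, `go`) when not simulating.
#' @param stages character subset of
#'   `c("morphometry", "phylo", "volumetrics", "scatter", "expression")`.
#' @param seed global seed for every stochastic step.
#' @param permutations RRPP/permutation count.
#' @param n_sim convergence-null simulations.
#' @param alpha significance level for gates and pattern membership.
#' @param bootstrap_iterations multiscale-bootstrap replicates per scale.
#' @param k_gene_clusters dendrogram cut for the gene archetypes.
#' @param fpkm_threshold ortholog expression filter.
#' @param subset landmark subset analysed (default `cerebellum`).
#' @param out_dir optional directory for the JSON report and TSV tables.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), paths = NULL,
                            stages = c("morphometry", "phylo", "volumetrics",
                                       "scatter", "expression"),
                            seed = 1L, permutations = 999L, n_sim = 200L,
                            alpha = 0.05, bootstrap_iterations = 1000L,
                            k_gene_clusters = 3L, fpkm_threshold = 0.5,
                            subset = "cerebellum", out_dir = NULL) {
  if (is.null(simulate) && is.null(paths))
    stop("either `simulate` or `paths` must be given")
  if (!is.null(paths)) {
    missing <- !vapply(paths, file.exists, logical(1))
    if (any(missing))
      stop("input files not found: ",
           paste(unlist(paths[missing]), collapse = ", "))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' The YAML mirrors [pipeline_config()]; a `simulate:` block holds
#' [sim_config()] fields.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(sim_config, y$simulate) else NULL
  args <- y[setdiff(names(y), "simulate")]
  cfg <- do.call(pipeline_config, c(list(simulate = sim), args))
  attr(cfg, "config_md5") <- unname(tools::md5sum(path))
  cfg
}

#' Run the multi-level analysis pipeline
#'
#' Executes the enabled stages in order on the configured dataset. The
#' volumetrics stage applies the decision gate: when the slope-homogeneity
#' test rejects AND the fitted Pagel's lambda is negligible, locomotor
#' groups are compared through Johnson-Neyman regions; otherwise the
#' standard phylogenetic ANCOVA (common-slope) fit is reported. The branch
#' taken is recorded in the report.
#'
#' @param config a `pipeline_config` (or path to its YAML file).
#' @return a `pipeline_report` list, additionally written as JSON (plus TSV
#'   tables) when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    sim$seed <- derive_seed(seed, 7L)
    bundle <- simulate_bundle(sim)
    tree <- bundle$tree; modes <- bundle$modes
    landmarks <- bundle$landmarks; volumes <- bundle$volumes
    depths <- bundle$depths
    expression <- bundle$expression; go <- bundle$go
  } else {
    p <- config$paths
    tree <- ape::read.tree(p$tree)
    modes <- read_modes(p$modes)
    landmarks <- if (!is.null(p$landmarks)) read_landmarks(p$landmarks)
    volumes <- if (!is.null(p$volumes)) read_volumes(p$volumes, modes)
    depths <- if (!is.null(p$depths)) read_depths(p$depths)
    expression <- if (!is.null(p$expression)) read_expression(p$expression)
    go <- if (!is.null(p$go)) read_go(p$go)
  }

  report <- list(provenance = list(
    package_version = as.character(utils::packageVersion("cerebrotype")),
    seed = seed,
    config_md5 = attr(config, "config_md5") %||% NA_character_,
    stages = config$stages))
  stage_on <- function(s) s %in% config$stages

  aligned <- NULL
  if (stage_on("morphometry") && !is.null(landmarks)) {
    subset <- if (config$subset %in% names(landmarks$subsets))
      config$subset else names(landmarks$subsets)[1L]
    aligned <- gpa(landmarks, subset = subset)
    space <- shape_pca(aligned)
    report$morphometry <- list(
      subset = subset,
      n_specimens = dim(aligned$coords)[3L],
      percent_variance = round(space$percent_variance[
        seq_len(min(5L, length(space$percent_variance)))], 4),
      mean_spec = find_mean_spec(aligned))
    report$.morpho <- list(aligned = aligned, space = space)
  }

  if (stage_on("phylo") && !is.null(aligned)) {
    sig <- k_mult(aligned, tree, permutations = config$permutations,
                  seed = derive_seed(seed, 31L))
    allo <- pgls_shape_regression(
      aligned, log(aligned$centroid_sizes), tree,
      permutations = config$permutations, seed = derive_seed(seed, 32L))
    anova <- phylo_procrustes_anova(
      aligned, modes, tree, permutations = config$permutations,
      seed = derive_seed(seed, 33L))
    # convergence of the first mode's species (the focal limbless group)
    focal_mode <- sort(unique(modes))[1L]
    focal <- names(modes)[modes == focal_mode]
    conv <- if (length(focal) >= 2L) {
      sc <- shape_pca(aligned)$scores
      q <- min(5L, ncol(sc))
      convergence_c_measures(sc[, seq_len(q), drop = FALSE], tree, focal,
                             n_sim = min(config$n_sim, 500L),
                             seed = derive_seed(seed, 34L))
    }
    report$phylo <- list(
      K = sig$K, K_p = sig$p,
      allometry_pct_predicted = 100 * allo$R2, allometry_p = allo$p,
      anova_R2 = anova$R2, anova_F = anova$F, anova_p = anova$p,
      pairwise_p = anova$pairwise_p,
      convergence = if (!is.null(conv))
        list(focal_mode = focal_mode, C = conv$C, p = conv$p))
  }

  if (stage_on("volumetrics") && !is.null(volumes)) {
    fit <- fit_pgls_lines(volumes, tree, per_mode = TRUE)
    homog <- slope_homogeneity_test(volumes, tree)
    gate_jn <- homog$p < config$alpha && fit$lambda < 0.1
    jn <- NULL; ancova <- NULL
    if (gate_jn) {
      ref <- fit$modes[1L]
      jn <- lapply(fit$modes[-1L], function(m)
        johnson_neyman(fit, c(ref, m), alpha = config$alpha))
      names(jn) <- fit$modes[-1L]
    } else {
      ancova <- fit_pgls_lines(volumes, tree, per_mode = FALSE)
    }
    ratio <- ratio_anova(volumes, tree, permutations = config$permutations,
                         seed = derive_seed(seed, 41L))
    report$volumetrics <- list(
      lambda = fit$lambda, lines = fit$lines,
      homogeneity_p = homog$p, branch = if (gate_jn) "johnson-neyman"
                                        else "phylogenetic ANCOVA",
      jn_regions = if (!is.null(jn)) lapply(jn, function(r)
        list(pair = r$pair, intervals = r$intervals,
             direction = r$direction)),
      ancova_common_slope = if (!is.null(ancova)) ancova$lines,
      ratio_p = ratio$p, ratio_pairwise_p = ratio$pairwise_p)
  }

  if (stage_on("scatter") && !is.null(depths)) {
    nd <- normalize_depths(depths)
    kw <- kruskal_wallis(nd$depth_pct, nd$species)
    pw <- dscf_posthoc(nd$depth_pct, nd$species)
    pat <- partition_patterns(pw, nd$depth_pct, nd$species,
                              alpha = config$alpha)
    report$scatter <- list(
      kw_H = kw$H, kw_p = kw$p,
      patterns = split(names(pat$assignment), pat$assignment),
      pattern_kw_p = if (!is.null(pat$kw_between)) pat$kw_between$p,
      transitive = pat$transitive)
    report$.scatter <- list(pairwise_p = pw, patterns = pat)
  }

  if (stage_on("expression") && !is.null(expression)) {
    filt <- filter_orthologs(expression, config$fpkm_threshold)
    z <- zscore_rows(filt)
    genes <- hierarchical_cluster(z, axis = "genes", metric = "euclidean",
                                  k = config$k_gene_clusters)
    au <- multiscale_bootstrap_au(
      filt, iterations = config$bootstrap_iterations,
      seed = derive_seed(seed, 51L))
    enrich <- lapply(sort(unique(genes$labels)), function(cl)
      go_enrichment(names(genes$labels)[genes$labels == cl], go,
                    rownames(filt)))
    names(enrich) <- paste0("cluster", sort(unique(genes$labels)))
    report$expression <- list(
      n_genes_kept = nrow(filt),
      gene_cluster_sizes = as.integer(table(genes$labels)),
      species_dendrogram_merge = au$hclust$merge,
      au_support = au$support[, c("node", "au", "bp", "flag")],
      enriched_terms = lapply(enrich, function(e)
        e[e$significant, c("go_id", "term", "k", "K", "p", "p_adj")]))
    report$.expression <- list(filtered = filt, gene_clusters = genes,
                               au = au, enrichment = enrich)
  }

  class(report) <- "pipeline_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' JSON report (stages, statistics, provenance) plus TSV side-tables for
#' the pairwise matrices. Internal heavyweight objects (names starting
#' with a dot) are not serialized.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return invisibly, the JSON path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pub <- report[!startsWith(names(report), ".")]
  path <- file.path(dir, "report.json")
  jsonlite::write_json(pub, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  if (!is.null(report$phylo$pairwise_p))
    utils::write.table(report$phylo$pairwise_p,
                       file.path(dir, "anova_pairwise_p.tsv"),
                       sep = "\t", quote = FALSE)
  if (!is.null(report$.scatter$pairwise_p))
    utils::write.table(report$.scatter$pairwise_p,
                       file.path(dir, "dscf_pairwise_p.tsv"),
                       sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report; stages:",
      paste(setdiff(names(x), c("provenance",
                                grep("^\\.", names(x), value = TRUE))),
            collapse = ", "), "\n")
  invisible(x)
}
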