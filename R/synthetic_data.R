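# Synthetic-data generators emulating the statistical structure of the
# multi-level cerebellum dataset: a pure-birth phylogeny, Brownian-motion
# landmark evolution with locomotor-mode mean shifts and allometry,
# mode-specific volume allometries, Beta-distributed Purkinje-cell depth
# archetypes, and a log-normal ortholog expression matrix with three gene
# archetypes plus GO annotations.
#
# Defaults reproduce the study conditions: 40 species, 61 whole-brain
# landmarks + 5 cerebellum extras, 7 locomotor modes, 630 genes. One shared
# integer seed drives everything through deterministic sub-streams.

#' Simulation configuration
#'
#' @param n_species number of species (default 40).
#' @param n_landmarks whole-brain landmarks (default 61).
#' @param n_cereb_extra extra cerebellum-interface landmarks (default 5).
#' @param n_modes locomotor modes (default 7).
#' @param bm_rate Brownian variance per unit branch length per coordinate.
#' @param mode_effect per-coordinate SD of the fixed mode displacement
#'   (shape units; the consensus has unit centroid size).
#' @param noise_sd i.i.d. per-coordinate specimen noise SD.
#' @param allometry_coeff shape change per unit log centroid size.
#' @param volume_slopes per-mode allometric slope of log cerebellar on log
#'   brain volume.
#' @param volume_intercepts per-mode intercept (natural-log scale).
#' @param volume_noise_sd residual SD of log cerebellar volume.
#' @param volume_lambda Pagel's lambda of the volume residuals (0 = no
#'   phylogenetic structure, matching the negligible signal reported for
#'   the volumetric ANCOVA).
#' @param depth_archetypes data.frame with columns `mean_pct` and
#'   `concentration`: Beta-distribution parameters of the four scattering
#'   archetypes (ordered monolayer, ordered multilayer, scattered
#'   multilayer, totally scattered).
#' @param mode_archetype integer map from mode index to archetype row.
#' @param n_genes ortholog count (default 630).
#' @param cluster_props proportions of the three expression archetypes
#'   (shared up, shared down, group-differential); must sum to 1.
#' @param expr_effect log-scale mean shift of archetype-3 genes between the
#'   limbless and quadrupedal mode groups.
#' @param expr_noise_sd log-scale expression noise SD.
#' @param expr_species_sd SD of the shared per-species expression factor
#'   that archetype-1 genes load positively and archetype-2 genes load
#'   negatively (the coherent up-/down-regulated bands of the z-scored heat
#'   map); 0 removes all species-profile structure.
#' @param n_go_terms number of GO terms to annotate.
#' @param seed integer seed; a fixed seed gives byte-identical bundles.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 40L, n_landmarks = 61L,
                       n_cereb_extra = 5L, n_modes = 7L,
                       bm_rate = 5e-4, mode_effect = 0.015,
                       noise_sd = 0.005, allometry_coeff = 0.25,
                       volume_slopes = c(1.2, 1, 1, 1, 1, 1, 1),
                       volume_intercepts = c(-2.6, -2.2, -2.2, -2.2,
                                             -2.2, -2.2, -2.2),
                       volume_noise_sd = 0.1, volume_lambda = 0,
                       depth_archetypes = data.frame(
                         mean_pct = c(12, 28, 38, 50),
                         concentration = c(60, 20, 12, 2)),
                       mode_archetype = c(2L, 2L, 3L, 4L, 1L, 1L, 1L),
                       n_genes = 630L, cluster_props = c(0.4, 0.35, 0.25),
                       expr_effect = 2, expr_noise_sd = 0.3,
                       expr_species_sd = 0.5,
                       n_go_terms = 12L, seed = 1L) {
  if (!is_count(n_species, 2L) || !is_count(n_landmarks, 2L) ||
      !is_count(n_modes, 2L) || !is_count(n_genes, 2L))
    stop("all counts must be integers >= 2")
  if (abs(sum(cluster_props) - 1) > 1e-8)
    stop("cluster_props must sum to 1")
  if (length(volume_slopes) != n_modes ||
      length(volume_intercepts) != n_modes)
    stop("volume_slopes/intercepts need one entry per mode")
  if (any(depth_archetypes$mean_pct <= 0 | depth_archetypes$mean_pct >= 100))
    stop("archetype mean depths must lie strictly inside (0, 100)%")
  if (length(mode_archetype) != n_modes ||
      any(mode_archetype < 1L | mode_archetype > nrow(depth_archetypes)))
    stop("mode_archetype must map every mode to an archetype row")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a pure-birth phylogeny
#'
#' Rooted binary tree with strictly positive branch lengths and unique tip
#' labels, total depth rescaled to 1.
#'
#' @param n_species number of tips (>= 2).
#' @param seed RNG seed.
#' @return an `ape::phylo` object, tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(n_species, seed = 1L) {
  if (!is_count(n_species, 2L)) stop("n_species must be an integer >= 2")
  set.seed(seed)
  tr <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tr
}

#' Assign locomotor modes to species
#'
#' Balanced random assignment of mode labels `mode1..modeK` to tips.
#'
#' @param tree phylogeny.
#' @param n_modes number of modes.
#' @param seed RNG seed.
#' @return named character vector, species -> mode.
#' @export
assign_modes <- function(tree, n_modes, seed = 1L) {
  n <- length(tree$tip.label)
  set.seed(seed)
  lab <- paste0("mode", seq_len(n_modes))
  pool <- rep(lab, length.out = n)
  stats::setNames(sample(pool), tree$tip.label)
}

# Sample a species x q matrix of Brownian tip deviations (zero root state).
bm_tips <- function(tree, q, rate) {
  C <- phylo_covariance(tree, tree$tip.label)
  L <- t(chol(C))
  out <- sqrt(rate) * (L %*% matrix(stats::rnorm(nrow(C) * q), nrow(C)))
  rownames(out) <- tree$tip.label
  out
}

#' Simulate landmark configurations on a tree
#'
#' Per species: coordinates are a fixed base shape plus Brownian-motion
#' deviations evolved on the tree, a mode-specific fixed displacement, an
#' allometric term proportional to the species' log-centroid-size
#' deviation, and i.i.d. digitisation noise; the configuration is then
#' scaled to the species' centroid size (micrometres). The generating
#' displacements are recorded in `attr(, "truth")`.
#'
#' @param tree phylogeny.
#' @param modes named species -> mode map covering every tip.
#' @param config a `sim_config`.
#' @return a `landmark_set` with subsets `whole_brain` and `cerebellum`
#'   (a subset of the whole-brain landmarks plus the extra interface
#'   landmarks).
#' @export
simulate_landmarks <- function(tree, modes, config) {
  missing <- setdiff(tree$tip.label, names(modes))
  if (length(missing))
    stop("mode map missing species: ", paste(missing, collapse = ", "))
  p <- config$n_landmarks + config$n_cereb_extra
  q <- 3L * p
  n <- length(tree$tip.label)
  set.seed(derive_seed(config$seed, 11L))
  base <- matrix(stats::rnorm(q), p, 3L)
  base <- sweep(base, 2L, colMeans(base))
  base <- base / sqrt(sum(base^2))          # unit-CS base shape
  mode_levels <- sort(unique(modes))
  shift <- lapply(mode_levels, function(m)
    matrix(stats::rnorm(q, sd = config$mode_effect), p, 3L))
  names(shift) <- mode_levels
  allo_dir <- matrix(stats::rnorm(q), p, 3L)
  allo_dir <- allo_dir / sqrt(sum(allo_dir^2))
  log_cs <- stats::rnorm(n, mean = log(2000), sd = 0.4)
  names(log_cs) <- tree$tip.label
  bm <- bm_tips(tree, q, config$bm_rate)
  coords <- array(NA_real_, c(p, 3L, n),
                  dimnames = list(NULL, c("x", "y", "z"), tree$tip.label))
  cls_dev <- log_cs - mean(log_cs)
  for (i in seq_len(n)) {
    sp <- tree$tip.label[i]
    cfg <- base + matrix(bm[sp, ], p, 3L) + shift[[modes[[sp]]]] +
      config$allometry_coeff * cls_dev[sp] * allo_dir +
      matrix(stats::rnorm(q, sd = config$noise_sd), p, 3L)
    coords[, , i] <- cfg * exp(log_cs[sp])
  }
  lm <- landmark_set(coords, species = tree$tip.label,
                     subsets = list(
                       whole_brain = seq_len(config$n_landmarks),
                       cerebellum = c(seq(1L, config$n_landmarks,
                                          length.out = min(20L,
                                                           config$n_landmarks)),
                                      config$n_landmarks +
                                        seq_len(config$n_cereb_extra))))
  lm$subsets <- lapply(lm$subsets, function(i) sort(unique(as.integer(i))))
  attr(lm, "truth") <- list(base = base, mode_shift = shift,
                            allometry_dir = allo_dir, log_cs = log_cs,
                            bm = bm, modes = modes)
  lm
}

#' Simulate whole-brain and cerebellum volumes
#'
#' Log cerebellar volume follows a mode-specific line in log whole-brain
#' volume plus residuals with Pagel's-lambda phylogenetic structure. The
#' default slopes/intercepts cross inside the observed range so that the
#' slope-homogeneity gate and Johnson-Neyman branch are exercised.
#'
#' @param tree phylogeny.
#' @param modes species -> mode map.
#' @param config a `sim_config`.
#' @return a `volume_table` with `attr(, "truth")`.
#' @export
simulate_volumes <- function(tree, modes, config) {
  n <- length(tree$tip.label)
  set.seed(derive_seed(config$seed, 22L))
  mode_levels <- sort(unique(modes))
  mi <- match(modes[tree$tip.label], mode_levels)
  log_brain <- stats::runif(n, 0.5, 4.5)
  C <- phylo_covariance(tree, tree$tip.label)
  lam <- config$volume_lambda
  V <- lam * C + (1 - lam) * diag(diag(C))
  eps <- config$volume_noise_sd *
    drop(t(chol(V / mean(diag(V)))) %*% stats::rnorm(n))
  slopes <- config$volume_slopes[mi]
  ints <- config$volume_intercepts[mi]
  log_cb <- ints + slopes * log_brain + eps
  log_cb <- pmin(log_cb, log_brain - 0.05)   # cerebellum < whole brain
  vt <- volume_table(tree$tip.label, exp(log_brain), exp(log_cb),
                     modes[tree$tip.label])
  attr(vt, "truth") <- list(slopes = config$volume_slopes,
                            intercepts = config$volume_intercepts,
                            lambda = lam, modes = modes)
  vt
}

#' Simulate Purkinje-cell depth tables
#'
#' Per species, between 250 and 750 cells with normalized depths drawn from
#' the Beta distribution of the species' archetype (monolayer: low mean and
#' variance; totally scattered: near-uniform); raw distance/thickness pairs
#' reproduce the drawn percentage exactly.
#'
#' @param modes species -> mode map.
#' @param config a `sim_config`.
#' @return a `cell_depth_table` with `attr(, "truth")` recording the
#'   archetype per species.
#' @export
simulate_cell_depths <- function(modes, config) {
  arch <- config$depth_archetypes
  if (any(arch$mean_pct <= 0 | arch$mean_pct >= 100))
    stop("archetype mean depths must lie strictly inside (0, 100)%")
  set.seed(derive_seed(config$seed, 33L))
  mode_levels <- sort(unique(modes))
  sp_arch <- config$mode_archetype[match(modes, mode_levels)]
  names(sp_arch) <- names(modes)
  rows <- lapply(names(modes), function(sp) {
    a <- arch[sp_arch[[sp]], ]
    ncell <- sample(250:750, 1L)
    mu <- a$mean_pct / 100
    depth <- stats::rbeta(ncell, mu * a$concentration,
                          (1 - mu) * a$concentration)
    thick <- exp(stats::rnorm(ncell, log(150), 0.2))
    data.frame(species = sp,
               cell_id = paste0(sp, "_c", seq_len(ncell)),
               dist_gcl = depth * thick, ml_thickness = thick,
               stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  out <- cell_depth_table(d$species, d$cell_id, d$dist_gcl, d$ml_thickness)
  attr(out, "truth") <- list(archetype = sp_arch, params = arch)
  out
}

#' Simulate the ortholog expression matrix and GO annotations
#'
#' FPKM values are log-normal. Archetype-1 genes are highly expressed in
#' every species and load positively on a shared per-species expression
#' factor; archetype-2 genes are lowly expressed and load negatively (the
#' coherent up- and down-regulated bands of a row-z-scored heat map);
#' archetype-3 genes shift their mean between the limbless (modes 1-4) and
#' quadrupedal (modes 5-7) groups. One GO term is preferentially assigned
#' to archetype-3 genes so that enrichment is recoverable; the remaining
#' terms are assigned at random.
#'
#' @param modes species -> mode map.
#' @param config a `sim_config`.
#' @return list with `matrix` (genes x species FPKM), `go` annotation
#'   data.frame (`gene`, `go_id`, `term`), and `truth` (gene archetypes).
#' @export
simulate_expression <- function(modes, config) {
  if (config$n_genes < config$n_go_terms)
    stop("n_genes must be at least the number of GO terms")
  set.seed(derive_seed(config$seed, 44L))
  n_sp <- length(modes)
  sp <- names(modes)
  mode_levels <- sort(unique(modes))
  mode_idx <- match(modes, mode_levels)
  limbless <- mode_idx <= ceiling(length(mode_levels) / 2)
  props <- config$cluster_props
  ng <- config$n_genes
  sizes <- diff(round(c(0, cumsum(props)) * ng))
  archetype <- rep(1:3, times = sizes)
  mu_base <- c(stats::rnorm(sizes[1L], 3.5, 0.5),
               stats::rnorm(sizes[2L], 0.8, 0.4),
               stats::rnorm(sizes[3L], 2.0, 0.5))
  loading <- c(1, -1, 0)[archetype]           # shared species-factor loading
  species_factor <- stats::rnorm(n_sp, 0, config$expr_species_sd)
  M <- matrix(NA_real_, ng, n_sp,
              dimnames = list(sprintf("gene%04d", seq_len(ng)), sp))
  half <- config$expr_effect / 2
  is3 <- archetype == 3L
  for (j in seq_len(n_sp)) {
    mu <- mu_base + loading * species_factor[j]
    mu[is3] <- mu[is3] + if (limbless[j]) half else -half
    M[, j] <- exp(stats::rnorm(ng, mu, config$expr_noise_sd))
  }
  terms <- data.frame(
    go_id = sprintf("GO:%07d", seq_len(config$n_go_terms)),
    term = c("locomotory behaviour",
             paste0("process_", seq_len(config$n_go_terms - 1L))),
    stringsAsFactors = FALSE)
  ann <- list()
  p_assign <- ifelse(archetype == 3L, 0.35, 0.02)
  hit <- stats::runif(ng) < p_assign
  ann[[1L]] <- data.frame(gene = rownames(M)[hit], go_id = terms$go_id[1L],
                          term = terms$term[1L], stringsAsFactors = FALSE)
  for (t in 2:config$n_go_terms) {
    hit <- stats::runif(ng) < 0.1
    ann[[t]] <- data.frame(gene = rownames(M)[hit], go_id = terms$go_id[t],
                           term = terms$term[t], stringsAsFactors = FALSE)
  }
  go <- do.call(rbind, ann)
  list(matrix = M, go = go,
       truth = list(archetype = stats::setNames(archetype, rownames(M)),
                    species_factor = stats::setNames(species_factor, sp),
                    limbless = stats::setNames(limbless, sp)))
}

#' Simulate a complete synthetic bundle
#'
#' Generates the tree, mode map, landmarks, volumes, cell depths,
#' expression matrix and GO annotations from one configuration and one
#' seed; all tables share the same species label set and the generating
#' parameters are collected in `$truth`.
#'
#' @param config a `sim_config`.
#' @return a `synthetic_bundle` list.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config$n_species, derive_seed(config$seed, 1L))
  modes <- assign_modes(tree, config$n_modes, derive_seed(config$seed, 2L))
  landmarks <- simulate_landmarks(tree, modes, config)
  volumes <- simulate_volumes(tree, modes, config)
  depths <- simulate_cell_depths(modes, config)
  expr <- simulate_expression(modes, config)
  structure(list(tree = tree, modes = modes, landmarks = landmarks,
                 volumes = volumes, depths = depths,
                 expression = expr$matrix, go = expr$go,
                 truth = list(config = config,
                              landmarks = attr(landmarks, "truth"),
                              volumes = attr(volumes, "truth"),
                              depths = attr(depths, "truth"),
                              expression = expr$truth)),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic bundle:", length(x$tree$tip.label), "species,",
      dim(x$landmarks$coords)[1L], "landmarks,",
      nrow(x$expression), "genes\n")
  invisible(x)
}

#' Write a synthetic bundle to plain-text files
#'
#' Emits the Newick tree, landmark CSV
#' (`specimen,species,landmark_id,x,y,z`, 0-based landmark ids), mode CSV,
#' volume CSV, cell-depth CSV, expression TSV (genes x species) and GO TSV.
#'
#' @param bundle a `synthetic_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             landmarks = file.path(dir, "landmarks.csv"),
             modes = file.path(dir, "modes.csv"),
             volumes = file.path(dir, "volumes.csv"),
             depths = file.path(dir, "depths.csv"),
             expression = file.path(dir, "expression.tsv"),
             go = file.path(dir, "go.tsv"))
  ape::write.tree(bundle$tree, paths["tree"])
  write_landmarks(bundle$landmarks, paths["landmarks"])
  utils::write.csv(data.frame(species = names(bundle$modes),
                              mode = unname(bundle$modes)),
                   paths["modes"], row.names = FALSE, quote = FALSE)
  v <- as.data.frame(bundle$volumes)
  utils::write.csv(data.frame(species = v$species,
                              brain_mm3 = v$brain_volume,
                              cerebellum_mm3 = v$cerebellum_volume,
                              mode = v$mode),
                   paths["volumes"], row.names = FALSE, quote = FALSE)
  d <- as.data.frame(bundle$depths)
  utils::write.csv(data.frame(species = d$species, cell_id = d$cell_id,
                              dist_gcl_um = d$dist_gcl,
                              ml_thickness_um = d$ml_thickness),
                   paths["depths"], row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(gene = rownames(bundle$expression),
                                bundle$expression, check.names = FALSE),
                     paths["expression"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(bundle$go, paths["go"], sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(paths)
}
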