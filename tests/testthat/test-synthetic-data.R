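# Synthetic-data generators: determinism, declared invariants, and the
# statistical structure downstream stages rely on.

test_that("pure-birth trees are valid, scaled and deterministic", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2)
  expect_true(ape::is.binary(t2))

  tr1 <- simulate_tree(40, seed = 1)
  tr2 <- simulate_tree(40, seed = 1)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_true(all(tr1$edge.length > 0))
  expect_false(anyDuplicated(tr1$tip.label) > 0)
  expect_equal(max(ape::node.depth.edgelength(tr1)), 1, tolerance = 1e-12)

  C <- phylo_covariance(tr1, tr1$tip.label)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(1, 40), tolerance = 1e-10)
  expect_error(simulate_tree(1), "2")
})

test_that("landmark simulation honours its degenerate and error cases", {
  tr <- simulate_tree(8, seed = 2)
  modes <- balanced_modes(tr$tip.label, 2)
  cfg <- sim_config(n_species = 8, n_modes = 2, n_landmarks = 10,
                    volume_slopes = c(1, 1), volume_intercepts = c(-2, -2),
                    mode_archetype = c(1L, 4L),
                    bm_rate = 0, mode_effect = 0, noise_sd = 0,
                    allometry_coeff = 0, seed = 3)
  lm <- simulate_landmarks(tr, modes, cfg)
  # zero rates: all specimens share one shape (configurations differ only
  # by species size)
  shapes <- sapply(seq_len(8), function(i) {
    cfg_i <- lm$coords[, , i]
    as.vector(cfg_i / centroid_size(cfg_i))
  })
  expect_lt(max(abs(shapes - shapes[, 1])), 1e-12)

  cfg2 <- sim_config(n_species = 8, n_modes = 2, n_landmarks = 10,
                     volume_slopes = c(1, 1), volume_intercepts = c(-2, -2),
                     mode_archetype = c(1L, 4L), seed = 4)
  lm1 <- simulate_landmarks(tr, modes, cfg2)
  lm2 <- simulate_landmarks(tr, modes, cfg2)
  expect_identical(lm1$coords, lm2$coords)
  expect_error(simulate_landmarks(tr, modes[-1], cfg2), tr$tip.label[1])

  # subsets present: whole-brain and cerebellum (with extras)
  expect_named(lm1$subsets, c("whole_brain", "cerebellum"))
  expect_equal(max(lm1$subsets$cerebellum), 10 + cfg2$n_cereb_extra)
})

test_that("volume simulation triggers the Johnson-Neyman branch as designed", {
  tr <- simulate_tree(40, seed = 5)
  modes <- balanced_modes(tr$tip.label, 2)
  cfg <- sim_config(n_species = 40, n_modes = 2,
                    volume_slopes = c(0.8, 1.2),
                    volume_intercepts = c(-1.4, -2.4),
                    volume_noise_sd = 0.05,
                    mode_archetype = c(1L, 4L), seed = 6)
  vt <- simulate_volumes(tr, modes, cfg)
  expect_true(all(vt$cerebellum_volume < vt$brain_volume))
  expect_identical(as.data.frame(simulate_volumes(tr, modes, cfg)),
                   as.data.frame(vt))

  fit <- fit_pgls_lines(vt, tr)
  jn <- johnson_neyman(fit, fit$modes)
  expect_gt(length(jn$intervals), 0)
  # boundaries agree with the fine-grid oracle
  k <- 2
  ci <- c(1, -1, 0, 0); cs <- c(0, 0, 1, -1)
  o <- jn_grid_oracle(sum(ci * fit$coef), sum(cs * fit$coef),
                      drop(ci %*% fit$vcov %*% ci),
                      drop(cs %*% fit$vcov %*% cs),
                      drop(ci %*% fit$vcov %*% cs),
                      stats::qt(0.975, fit$n - 4)^2, fit$range)
  got <- do.call(rbind, jn$intervals)
  expect_equal(nrow(got), nrow(o))
  expect_lt(max(abs(got - o)), 2e-6)
})

test_that("cell depth archetypes collapse correctly in the limit", {
  modes <- stats::setNames(c("mode1", "mode1"), c("a", "b"))
  cfg <- sim_config(n_species = 2, n_modes = 2, volume_slopes = c(1, 1),
                    volume_intercepts = c(-2, -2),
                    depth_archetypes = data.frame(mean_pct = c(30, 50),
                                                  concentration = c(1e6, 2)),
                    mode_archetype = c(1L, 2L), seed = 7)
  d <- normalize_depths(simulate_cell_depths(modes, cfg))
  expect_lt(max(abs(d$depth_pct - 30)), 1)      # variance -> 0 limit
  expect_true(all(d$dist_gcl <= d$ml_thickness))
  expect_true(all(table(d$species) >= 250 & table(d$species) <= 750))

  bad <- sim_config
  expect_error(sim_config(depth_archetypes = data.frame(
    mean_pct = c(10, 20, 30, 120), concentration = rep(5, 4))),
    "inside")
})

test_that("expression simulation degenerates to unit correlations", {
  modes <- balanced_modes(paste0("s", 1:8), 4)
  cfg <- sim_config(n_species = 8, n_modes = 4, volume_slopes = rep(1, 4),
                    volume_intercepts = rep(-2, 4),
                    mode_archetype = c(1L, 2L, 3L, 4L),
                    cluster_props = c(0.5, 0.5, 0), expr_species_sd = 0,
                    expr_noise_sd = 0.05, n_genes = 200, seed = 8)
  ex <- simulate_expression(modes, cfg)
  r <- pairwise_correlation(ex$matrix)
  expect_gt(min(r), 0.98)

  ex2 <- simulate_expression(modes, cfg)
  expect_identical(ex$matrix, ex2$matrix)
  expect_error(simulate_expression(
    modes, sim_config(n_species = 8, n_modes = 4,
                      volume_slopes = rep(1, 4),
                      volume_intercepts = rep(-2, 4),
                      mode_archetype = c(1L, 2L, 3L, 4L),
                      n_genes = 5, n_go_terms = 12, seed = 1)),
    "GO terms")
})

test_that("bundles share one species set and are byte-identical per seed", {
  cfg <- sim_config(n_species = 12, n_landmarks = 10, n_modes = 4,
                    volume_slopes = rep(1, 4), volume_intercepts = rep(-2, 4),
                    mode_archetype = c(1L, 2L, 3L, 4L), n_genes = 50,
                    seed = 9)
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(b1$landmarks$coords, b2$landmarks$coords)
  expect_identical(as.data.frame(b1$volumes), as.data.frame(b2$volumes))
  expect_identical(as.data.frame(b1$depths), as.data.frame(b2$depths))
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$go, b2$go)

  sp <- b1$tree$tip.label
  expect_setequal(names(b1$modes), sp)
  expect_setequal(unique(b1$landmarks$specimens$species), sp)
  expect_setequal(b1$volumes$species, sp)
  expect_setequal(unique(b1$depths$species), sp)
  expect_setequal(colnames(b1$expression), sp)
  expect_true(all(c("config", "landmarks", "volumes", "depths",
                    "expression") %in% names(b1$truth)))
})

test_that("generating mode displacements are recoverable from group means", {
  tr <- simulate_tree(40, seed = 11)
  errs <- sapply(1:40, function(i) {
    modes <- assign_modes(tr, 7, 800 + i)
    cfg <- sim_config(n_species = 40, n_landmarks = 12, n_cereb_extra = 0,
                      allometry_coeff = 0, seed = 800 + i)
    lm <- simulate_landmarks(tr, modes, cfg)
    truth <- attr(lm, "truth")
    al <- gpa(lm)
    Y <- t(apply(al$coords, 3, as.vector))
    g <- factor(modes[dimnames(al$coords)[[3]]])
    gm <- t(sapply(levels(g), function(m) colMeans(Y[g == m, , drop = FALSE])))
    grand <- colSums(gm * as.vector(table(g))) / nrow(Y)
    est <- sqrt(rowSums(sweep(gm, 2, grand)^2))
    shift <- t(sapply(levels(g), function(m)
      as.vector(truth$mode_shift[[m]])))
    tg <- colSums(shift * as.vector(table(g))) / nrow(Y)
    tru <- sqrt(rowSums(sweep(shift, 2, tg)^2))
    mean(abs(est - tru) / tru)
  })
  expect_lt(mean(errs), 0.15)
})
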