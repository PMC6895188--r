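# Phylogenetic comparative statistics: tip covariance, multivariate K,
# D-PGLS regression/ANOVA with RRPP, convergence measures.

test_that("tip covariance matches path arithmetic and brute force", {
  st <- star_tree(4, LETTERS[1:4])
  expect_equal(phylo_covariance(st, LETTERS[1:4]),
               diag(4), ignore_attr = TRUE)

  C <- phylo_covariance(cherry3(), c("A", "B", "C"))
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "C"], 0)
  expect_equal(unname(diag(C)), c(2, 2, 2))

  # random tree against a brute-force MRCA root-path enumeration
  tr <- simulate_tree(12, seed = 5)
  C2 <- phylo_covariance(tr, tr$tip.label)
  depths <- ape::node.depth.edgelength(tr)
  for (i in 1:12) for (j in 1:12) {
    anc <- if (i == j) i else ape::getMRCA(tr, c(i, j))
    expect_equal(C2[i, j], depths[anc], tolerance = 1e-12)
  }

  expect_error(phylo_covariance(tr, c(tr$tip.label, "nope")), "nope")
  expect_error(phylo_covariance(tr, tr$tip.label[1:5], prune_extra = FALSE),
               "extra tips")
  expect_equal(dim(phylo_covariance(tr, tr$tip.label[1:5])), c(5L, 5L))
})

test_that("Kmult is exactly 1 on star trees and matches Blomberg's K", {
  st <- star_tree(9)
  set.seed(1)
  Y <- matrix(rnorm(9 * 7), 9, dimnames = list(st$tip.label, NULL))
  expect_equal(k_mult(Y, st, permutations = 19)$K, 1, tolerance = 1e-12)

  # univariate Kmult equals Blomberg's K (independent phytools oracle)
  skip_if_not_installed("phytools")
  tr <- simulate_tree(20, seed = 3)
  set.seed(2)
  y <- stats::setNames(rnorm(20), tr$tip.label)
  K1 <- k_mult(matrix(y, dimnames = list(names(y), NULL)), tr,
               permutations = 0)$K
  K2 <- unname(phytools::phylosig(tr, y, method = "K"))
  expect_equal(K1, as.numeric(K2), tolerance = 1e-8)
})

test_that("Kmult permutation p-values are reproducible and valid", {
  tr <- simulate_tree(15, seed = 7)
  set.seed(3)
  Y <- cerebrotype:::bm_tips(tr, 4, 1)
  r1 <- k_mult(Y, tr, permutations = 99, seed = 5)
  r2 <- k_mult(Y, tr, permutations = 99, seed = 5)
  expect_identical(r1, r2)
  expect_gte(r1$p, 1 / 100)
  expect_lte(r1$p, 1)
  # replicate specimens per species are refused
  al <- gpa(array(rnorm(4 * 3 * 6), c(4, 3, 6)))
  al$species <- rep(c("a", "b", "c"), 2)
  expect_error(k_mult(al, tr), "average")
})

test_that("D-PGLS regression reduces to OLS on star trees", {
  st <- star_tree(12)
  set.seed(4)
  x <- stats::setNames(rnorm(12), st$tip.label)
  Y <- matrix(rnorm(12 * 5), 12, dimnames = list(st$tip.label, NULL))
  fit <- pgls_shape_regression(Y, x, st, permutations = 99, seed = 1)
  # OLS oracle: R^2 from per-column regressions on centred data
  Xc <- cbind(1, x)
  H <- Xc %*% solve(crossprod(Xc), t(Xc))
  ss_tot <- sum(scale(Y, scale = FALSE)^2)
  ss_res <- sum((Y - H %*% Y)^2)
  expect_equal(fit$R2, (ss_tot - ss_res) / ss_tot, tolerance = 1e-8)

  # exact linear dependence: R^2 = 1
  Ylin <- outer(x, c(1, -2, 0.5))
  rownames(Ylin) <- st$tip.label
  expect_equal(pgls_shape_regression(Ylin, x, st, permutations = 0)$R2, 1,
               tolerance = 1e-10)
  expect_error(pgls_shape_regression(Y, stats::setNames(rep(1, 12),
                                                        st$tip.label), st),
               "constant")
})

test_that("phylogenetic ANOVA equals the OLS Goodall F on star trees", {
  st <- star_tree(14)
  set.seed(5)
  Y <- matrix(rnorm(14 * 6), 14, dimnames = list(st$tip.label, NULL))
  g <- stats::setNames(rep(c("a", "b"), 7), st$tip.label)
  fit <- phylo_procrustes_anova(Y, g, st, permutations = 99, seed = 2)
  # longhand one-way multivariate (Goodall) F from sums of squares
  gm <- rowsum(Y, g[rownames(Y)]) / as.vector(table(g))
  grand <- colMeans(Y)
  ssm <- sum((gm[g[rownames(Y)], ] - rep(grand, each = 14))^2)
  ssr <- sum((Y - gm[g[rownames(Y)], ])^2)
  For <- (ssm / 1) / (ssr / 12)
  expect_equal(fit$F, For, tolerance = 1e-8)
  expect_equal(fit$pairwise_d, t(fit$pairwise_d))

  expect_error(phylo_procrustes_anova(Y, stats::setNames(rep("a", 14),
                                                         st$tip.label), st),
               "two groups")
  gs <- g; gs[1] <- "c"
  expect_warning(phylo_procrustes_anova(Y, gs, st, permutations = 9),
                 "singleton")
})

test_that("ancestral states equal the ML oracle", {
  skip_if_not_installed("phytools")
  tr <- simulate_tree(15, seed = 9)
  set.seed(6)
  Y <- cerebrotype:::bm_tips(tr, 3, 1)
  A <- cerebrotype:::ancestral_states_bm(tr, Y)
  fa <- sapply(1:3, function(j)
    phytools::fastAnc(tr, stats::setNames(Y[, j], rownames(Y))))
  expect_equal(unname(A), unname(fa), tolerance = 1e-10)
})

test_that("convergence measures match a hand-enumerated 4-tip oracle", {
  tr <- quartet()
  Y <- rbind(t1 = c(0, 0), t2 = c(4, 0), t3 = c(0.5, 0), t4 = c(5, 0))
  anc <- rbind(`5` = c(10, 0), `6` = c(8, 0), `7` = c(9, 0))
  res <- convergence_c_measures(Y, tr, c("t1", "t3"), n_sim = 0,
                                anc_states = anc)
  # hand enumeration: Dtip = 0.5; Dmax = |t1 - root| = 10
  expect_equal(unname(res$C["C1"]), 1 - 0.5 / 10, tolerance = 1e-12)
  expect_equal(unname(res$C["C2"]), 9.5, tolerance = 1e-12)
  expect_equal(unname(res$C["C3"]), 9.5 / (10 + 9.5), tolerance = 1e-12)
  expect_equal(unname(res$C["C4"]), 9.5 / 27.5, tolerance = 1e-12)
})

test_that("convergence limiting cases give C1 of one and zero", {
  tr <- quartet()
  # identical focal tips with distinct ancestors: all past divergence closed
  Y1 <- rbind(t1 = c(1, 1), t2 = c(5, 0), t3 = c(1, 1), t4 = c(-5, 0))
  anc <- rbind(`5` = c(0, 0), `6` = c(3, 0), `7` = c(-3, 0))
  r1 <- convergence_c_measures(Y1, tr, c("t1", "t3"), n_sim = 0,
                               anc_states = anc)
  expect_equal(unname(r1$C["C1"]), 1, tolerance = 1e-12)

  # monotone divergence: tips are the most distant nodes, C1 = 0
  Y2 <- rbind(t1 = c(6, 0), t2 = c(0, 1), t3 = c(-6, 0), t4 = c(0, -1))
  anc2 <- rbind(`5` = c(0, 0), `6` = c(3, 0), `7` = c(-3, 0))
  r2 <- convergence_c_measures(Y2, tr, c("t1", "t3"), n_sim = 0,
                               anc_states = anc2)
  expect_equal(unname(r2$C["C1"]), 0, tolerance = 1e-12)

  expect_error(convergence_c_measures(Y2, tr, "t1", n_sim = 0), "two focal")
  expect_error(convergence_c_measures(Y2, tr, c("t1", "zz"), n_sim = 0),
               "zz")
})

test_that("convergence simulation p-values are reproducible and bounded", {
  tr <- simulate_tree(10, seed = 13)
  set.seed(8)
  Y <- cerebrotype:::bm_tips(tr, 3, 1)
  r1 <- convergence_c_measures(Y, tr, tr$tip.label[c(1, 6)], n_sim = 49,
                               seed = 3)
  r2 <- convergence_c_measures(Y, tr, tr$tip.label[c(1, 6)], n_sim = 49,
                               seed = 3)
  expect_identical(r1, r2)
  expect_true(all(r1$p >= 1 / 50 & r1$p <= 1))
})
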