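# Geometric-morphometric core: superimposition, size, ordination, warping.

test_that("replicate landmarking sessions average coordinate-wise", {
  set.seed(1)
  A <- array(rnorm(5 * 3 * 4), c(5, 3, 4),
             dimnames = list(NULL, NULL, paste0("s", 1:4)))
  ls1 <- landmark_set(A, species = paste0("sp", 1:4))

  expect_equal(average_replicates(list(ls1, ls1))$coords, ls1$coords)

  delta <- array(0.5, dim(A))
  ls2 <- ls1; ls2$coords <- A + 2 * delta
  expect_equal(average_replicates(list(ls1, ls2))$coords, A + delta)

  ls3 <- ls1; ls3$coords <- A * 2
  brute <- (ls1$coords + ls2$coords + ls3$coords) / 3
  expect_equal(average_replicates(list(ls1, ls2, ls3))$coords, brute)

  bad <- ls1; dimnames(bad$coords)[[3]] <- paste0("x", 1:4)
  expect_error(average_replicates(list(ls1, bad)), "mismatched")
})

test_that("centroid size matches its definition and invariances", {
  expect_equal(centroid_size(matrix(c(1, 2, 3), 1)), 0)
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(centroid_size(cube), sqrt(6))

  set.seed(2)
  cfg <- matrix(rnorm(66 * 3), 66)
  longhand <- sqrt(sum(apply(cfg, 2, function(v) sum((v - mean(v))^2))))
  expect_equal(centroid_size(cfg), longhand)

  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(centroid_size(cfg %*% R + 5), centroid_size(cfg))
  expect_equal(centroid_size(cfg * 3.7), 3.7 * centroid_size(cfg))
  expect_error(centroid_size(cfg[0, , drop = FALSE]), "at least one")
})

test_that("GPA removes similarity transforms and matches the OPA oracle", {
  set.seed(3)
  A <- matrix(rnorm(30), 10)
  th <- 0.8
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  B <- 2.2 * (A %*% R) + matrix(rep(c(3, -1, 2), each = 10), 10)
  arr <- array(c(A, B), c(10, 3, 2))
  al <- gpa(arr, tol = 1e-12)
  expect_lt(procrustes_distance(al$coords[, , 1], al$coords[, , 2]), 1e-10)
  expect_equal(unname(al$centroid_sizes[2] / al$centroid_sizes[1]), 2.2,
               tolerance = 1e-8)

  # two distinct tetrahedra: pairwise distance equals closed-form OPA
  for (i in 1:10) {
    set.seed(100 + i)
    X <- matrix(rnorm(12), 4); Y <- matrix(rnorm(12), 4)
    al2 <- gpa(array(c(X, Y), c(4, 3, 2)), tol = 1e-12)
    expect_lt(abs(procrustes_distance(al2$coords[, , 1], al2$coords[, , 2]) -
                    opa_distance(X, Y)), 1e-10)
  }

  # degenerate configuration is rejected by specimen name
  bad <- array(rnorm(24), c(4, 3, 2), dimnames = list(NULL, NULL, c("a", "b")))
  bad[, , 2] <- 1
  expect_error(gpa(bad), "b")
})

test_that("GPA is idempotent and invariant to input similarity transforms", {
  set.seed(4)
  arr <- array(rnorm(8 * 3 * 6), c(8, 3, 6))
  al <- gpa(arr)
  al2 <- gpa(al$coords)
  expect_lt(max(abs(al$coords - al2$coords)), 1e-8)

  # random rotation/translation/scale leaves pairwise distances unchanged
  d0 <- as.matrix(stats::dist(t(apply(al$coords, 3, as.vector))))
  arr2 <- arr
  for (i in 1:6) {
    set.seed(40 + i)
    M <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(M) < 0) M[, 1] <- -M[, 1]
    arr2[, , i] <- exp(rnorm(1)) * arr[, , i] %*% M + rnorm(3)[col(arr[, , i])]
  }
  alt <- gpa(arr2)
  d1 <- as.matrix(stats::dist(t(apply(alt$coords, 3, as.vector))))
  expect_lt(max(abs(d0 - d1)), 1e-8)
})

test_that("Procrustes distance is a symmetric metric", {
  set.seed(5)
  a <- matrix(rnorm(18), 6)
  b <- matrix(rnorm(18), 6)
  expect_equal(procrustes_distance(a, a), 0)
  expect_equal(procrustes_distance(a, b), procrustes_distance(b, a))
  for (i in 1:100) {
    set.seed(i)
    x <- matrix(rnorm(18), 6); y <- matrix(rnorm(18), 6)
    z <- matrix(rnorm(18), 6)
    expect_lte(procrustes_distance(x, z),
               procrustes_distance(x, y) + procrustes_distance(y, z) + 1e-12)
  }
  expect_error(procrustes_distance(a, b[1:3, ]), "differ")
})

test_that("shape PCA reproduces variance structure and distances", {
  # collinear data: one component carries everything
  base <- matrix(rnorm(15), 5)
  arr <- array(NA_real_, c(5, 3, 4))
  for (i in 1:4) arr[, , i] <- base + i * 0.1
  sp <- shape_pca(flatten_mat <- t(apply(arr, 3, as.vector)))
  expect_equal(sp$percent_variance[1], 100, tolerance = 1e-9)

  set.seed(6)
  al <- gpa(array(rnorm(7 * 3 * 9), c(7, 3, 9)))
  sp2 <- shape_pca(al)
  expect_equal(sum(sp2$percent_variance), 100, tolerance = 1e-9)
  expect_lt(max(abs(colMeans(sp2$scores))), 1e-12)
  # score distances equal Procrustes-coordinate distances
  Y <- t(apply(al$coords, 3, as.vector))
  expect_equal(as.matrix(stats::dist(sp2$scores)),
               unname(as.matrix(stats::dist(Y))), tolerance = 1e-8,
               ignore_attr = TRUE)
  # total variance equals summed per-coordinate variance
  expect_equal(sum(sp2$eigenvalues), sum(apply(Y, 2, stats::var)),
               tolerance = 1e-10)
  expect_error(shape_pca(Y[1:2, ]), "three")
})

test_that("between-group PCA spans group means and separates groups", {
  set.seed(7)
  Y <- matrix(rnorm(20 * 6, sd = 0.1), 20)
  g <- rep(c("a", "b"), each = 10)
  Y[g == "b", 1] <- Y[g == "b", 1] + 3
  bg <- between_group_pca(Y, g)
  expect_equal(length(bg$eigenvalues), 1)   # two groups: one non-null axis

  # identical group means: no axes survive
  Y0 <- rbind(matrix(1:6, 3, 6, byrow = TRUE), matrix(1:6, 3, 6, byrow = TRUE))
  bg0 <- between_group_pca(Y0, rep(c("a", "b"), each = 3))
  expect_equal(length(bg0$eigenvalues), 0)

  # three separated groups recoverable by nearest projected group mean
  g3 <- rep(c("a", "b", "c"), each = 12)
  Y3 <- matrix(rnorm(36 * 5, sd = 0.2), 36)
  Y3[g3 == "b", 2] <- Y3[g3 == "b", 2] + 4
  Y3[g3 == "c", 4] <- Y3[g3 == "c", 4] - 4
  bg3 <- between_group_pca(Y3, g3)
  nearest <- apply(bg3$scores, 1, function(s)
    which.min(colSums((t(bg3$group_means) - s)^2)))
  expect_equal(unname(nearest), as.integer(factor(g3)))

  expect_error(between_group_pca(Y3, factor(g3, levels = c("a", "b", "c", "d"))),
               "empty group")
})

test_that("bootstrap group-mean ellipses behave and reproduce", {
  set.seed(8)
  sc <- matrix(rnorm(200 * 2), 200)
  g <- rep("a", 200)
  e1 <- group_confidence_ellipse(sc, g, "a", replicates = 2000, seed = 9)
  expect_lt(max(e1$axes) / min(e1$axes), 1.3)  # isotropic: near-circular
  e2 <- group_confidence_ellipse(sc, g, "a", replicates = 2000, seed = 9)
  expect_identical(e1, e2)

  degen <- matrix(1, 5, 2)
  e3 <- group_confidence_ellipse(degen, rep("a", 5), "a", replicates = 50,
                                 seed = 1)
  expect_equal(e3$axes, c(0, 0))
  expect_error(group_confidence_ellipse(sc[1:2, ], rep("a", 2), "a"),
               "three")
})

test_that("find_mean_spec equals the brute-force argmin", {
  set.seed(9)
  al <- gpa(array(rnorm(6 * 3 * 8), c(6, 3, 8)))
  d <- sapply(1:8, function(i)
    procrustes_distance(al$coords[, , i], al$mean_shape))
  expect_equal(find_mean_spec(al), al$specimens[which.min(d)])
})

test_that("TPS warp interpolates exactly and reproduces affine maps", {
  set.seed(10)
  S <- matrix(rnorm(24), 8)
  V <- matrix(rnorm(150), 50)

  expect_equal(tps_warp(S, S, V), V, tolerance = 1e-9)

  shift <- c(2, -1, 0.5)
  expect_equal(tps_warp(S, sweep(S, 2, shift, `+`), V),
               sweep(V, 2, shift, `+`), tolerance = 1e-8)

  M <- matrix(rnorm(9), 3); t0 <- c(1, 2, 3)
  expect_equal(tps_warp(S, S %*% M + rep(t0, each = 8), V),
               V %*% M + rep(t0, each = 50), tolerance = 1e-8)

  Tg <- S + matrix(rnorm(24, sd = 0.2), 8)
  expect_equal(tps_warp(S, Tg, S), Tg, tolerance = 1e-8)

  Sbad <- S; Sbad[2, ] <- Sbad[1, ]
  expect_error(tps_warp(Sbad, Tg, V), "singular")
})

test_that("group mean deviation fields localize and vanish appropriately", {
  set.seed(11)
  base <- matrix(rnorm(24), 8)
  arr <- array(NA_real_, c(8, 3, 10),
               dimnames = list(NULL, NULL, paste0("s", 1:10)))
  g <- rep(c("a", "b"), each = 5)
  for (i in 1:10) {
    cfg <- base
    if (g[i] == "b") cfg[1, ] <- cfg[1, ] + c(0.8, 0, 0)  # displace lm 1
    arr[, , i] <- cfg
  }
  al <- list(coords = arr, species = paste0("s", 1:10))
  class(al) <- "aligned_shapes"
  # probe vertices inside the landmark hull (convex mixtures), where the
  # interpolating spline -- not its affine extrapolation -- dominates
  set.seed(12)
  W <- matrix(rexp(60 * 8), 60); W <- W / rowSums(W)
  V <- W %*% base
  f <- group_mean_deviation_map(al, g, V)
  expect_true(all(f >= 0))
  # displacement field is larger near the displaced landmark (rank check)
  dist_lm1 <- sqrt(rowSums(sweep(V, 2, base[1, ])^2))
  expect_lt(stats::cor(dist_lm1, f[, "b"], method = "spearman"), -0.5)

  # a group whose mean equals the overall mean maps to a zero field
  arr0 <- array(rep(base, 4), c(8, 3, 4),
                dimnames = list(NULL, NULL, paste0("t", 1:4)))
  al0 <- list(coords = arr0, species = paste0("t", 1:4))
  class(al0) <- "aligned_shapes"
  f0 <- group_mean_deviation_map(al0, rep(c("a", "b"), 2), V)
  expect_lt(max(f0), 1e-8)
})
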