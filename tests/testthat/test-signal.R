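test_that("Moran's I matches its quadratic form, null moments and reference", {
  # 3-taxon chain, row-standardized
  W <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  W <- W / rowSums(W)
  z <- c(1, 0, -1)
  m <- morans_i(z, W)
  expect_equal(m$statistic, moran_stat_brute(z, W), tolerance = 1e-12)
  expect_equal(m$expectation, -0.5)
  # permutation mean over all relabelings equals -1/(n-1) exactly
  P <- all_perms(1:5)
  set.seed(40)
  z5 <- rnorm(5); W5 <- matrix(runif(25), 5, 5); diag(W5) <- 0
  vals <- apply(P, 1, function(p) moran_stat_brute(z5[p], W5))
  expect_equal(mean(vals), -1 / 4, tolerance = 1e-12)
  # analytic randomization sd equals the exact permutation sd
  m5 <- morans_i(z5, W5)
  expect_equal(m5$sd, sqrt(mean(vals^2) - mean(vals)^2), tolerance = 1e-10)
  # reference implementation row-normalizes its weights; do the same
  W5r <- W5 / rowSums(W5)
  ref <- ape::Moran.I(z5, W5r)
  m5r <- morans_i(z5, W5r)
  expect_equal(m5r$statistic, ref$observed, tolerance = 1e-10)
  expect_equal(m5r$sd, ref$sd, tolerance = 1e-10)
})

test_that("ordered values on a chain give positive Moran's I with small p", {
  n <- 12
  W <- matrix(0, n, n)
  for (i in 1:(n - 1)) W[i, i + 1] <- W[i + 1, i] <- 1
  W <- W / rowSums(W)
  z <- seq_len(n)
  res <- morans_i_mc(z, W, n_perm = 999, seed = 3)
  expect_gt(res$statistic, 0)
  expect_lt(res$p_mc, 0.01)
})

test_that("Geary's C null moments match exhaustive enumeration", {
  set.seed(41)
  z <- rnorm(6); W <- matrix(runif(36), 6, 6); diag(W) <- 0
  g <- gearys_c(z, W)
  P <- all_perms(1:6)
  vals <- apply(P, 1, function(p) geary_stat_brute(z[p], W))
  expect_equal(mean(vals), 1, tolerance = 1e-12)
  expect_equal(g$sd, sd(vals) * sqrt((nrow(P) - 1) / nrow(P)),
               tolerance = 1e-10)
  # clustered neighbors push C below 1
  n <- 10
  Wc <- matrix(0, n, n)
  for (i in 1:(n - 1)) Wc[i, i + 1] <- Wc[i + 1, i] <- 1
  zc <- c(rep(0, 5), rep(5, 5)) + rnorm(n, sd = 0.01)
  expect_lt(gearys_c(zc, Wc / rowSums(Wc))$statistic, 1)
})

test_that("Blomberg's K is exactly 1 on star phylogenies and matches references", {
  star <- ape::read.tree(text = paste0("(",
    paste0("t", 1:12, ":2", collapse = ","), ");"))
  set.seed(42)
  for (i in 1:20) {
    y <- setNames(rnorm(12), star$tip.label)
    expect_equal(blombergs_k(y, star)$statistic, 1, tolerance = 1e-10)
  }
  skip_if_no("picante")
  ty <- simulate_yule(40, seed = 50)
  y <- simulate_bm(ty, seed = 51)
  expect_equal(blombergs_k(y, ty)$statistic,
               unname(picante::Kcalc(y[ty$tip.label], ty)[[1]]),
               tolerance = 1e-8)
  skip_if_no("phytools")
  expect_equal(blombergs_k(y, ty)$statistic,
               unname(phytools::phylosig(ty, y[ty$tip.label], method = "K")[[1]]),
               tolerance = 1e-8)
})

test_that("K separates Brownian from independent traits directionally", {
  # deep balanced tree: iid traits give K well below 1
  bal <- ape::stree(128, "balanced")
  bal$edge.length <- rep(1, nrow(bal$edge))
  set.seed(60)
  y_iid <- setNames(rnorm(128), bal$tip.label)
  expect_lt(blombergs_k(y_iid, bal)$statistic, 0.5)
  # BM traits on Yule trees: K near 1 on average (small run)
  ks <- vapply(1:40, function(i) {
    ty <- simulate_yule(50, seed = 600 + i)
    blombergs_k(simulate_bm(ty, seed = 700 + i), ty)$statistic
  }, numeric(1))
  expect_gt(mean(ks), 0.8); expect_lt(mean(ks), 1.2)
})

test_that("Mantel correlation equals direct lower-triangle Pearson", {
  set.seed(43)
  M <- matrix(rnorm(8), 4, 2)
  DX <- as.matrix(dist(M))
  DY <- as.matrix(dist(M + rnorm(8, sd = 0.5)))
  r <- mantel_r(DX, DY)$statistic
  expect_equal(r, cor(DX[lower.tri(DX)], DY[lower.tri(DY)]),
               tolerance = 1e-12)
  expect_equal(mantel_r(DX, DX)$statistic, 1)
  expect_equal(mantel_r(DX, 3 * DX + 2)$statistic, 1, tolerance = 1e-12)
  expect_error(mantel_r(DX, matrix(1, 4, 4) - diag(1, 4)), "constant")
  skip_if_no("vegan")
  expect_equal(r, unname(vegan::mantel(DX, DY, permutations = 0)$statistic),
               tolerance = 1e-10)
})

test_that("all four statistics are location-scale invariant", {
  ty <- simulate_yule(18, seed = 70)
  z <- simulate_bm(ty, seed = 71)
  W <- distance_to_weights(ape::cophenetic.phylo(ty))
  z2 <- 7.3 * z + 101
  expect_equal(morans_i(z2, W)$statistic, morans_i(z, W)$statistic,
               tolerance = 1e-10)
  expect_equal(gearys_c(z2, W)$statistic, gearys_c(z, W)$statistic,
               tolerance = 1e-10)
  expect_equal(blombergs_k(z2, ty)$statistic, blombergs_k(z, ty)$statistic,
               tolerance = 1e-10)
  D1 <- as.matrix(dist(z)); D2 <- ape::cophenetic.phylo(ty)[names(z), names(z)]
  expect_equal(mantel_r(as.matrix(dist(z2)), D2)$statistic,
               mantel_r(D1, D2)$statistic, tolerance = 1e-10)
})

test_that("Monte-Carlo tests are seed-deterministic with valid p ranges", {
  ty <- simulate_yule(15, seed = 80)
  z <- simulate_bm(ty, seed = 81)
  W <- distance_to_weights(ape::cophenetic.phylo(ty))
  a <- morans_i_mc(z, W, n_perm = 500, seed = 9)
  b <- morans_i_mc(z, W, n_perm = 500, seed = 9)
  expect_identical(a$p_mc, b$p_mc)
  expect_gte(a$p_mc, 1 / 501); expect_lte(a$p_mc, 1)
  k1 <- blombergs_k_mc(z, ty, n_perm = 300, seed = 5)
  k2 <- blombergs_k_mc(z, ty, n_perm = 300, seed = 5)
  expect_identical(k1$p_mc, k2$p_mc)
  D1 <- as.matrix(dist(z)); D2 <- ape::cophenetic.phylo(ty)[names(z), names(z)]
  m1 <- mantel_mc(D1, D2, n_perm = 300, seed = 5)
  expect_identical(m1$p_mc, mantel_mc(D1, D2, n_perm = 300, seed = 5)$p_mc)
  g1 <- gearys_c_mc(z, W, n_perm = 300, seed = 5)
  expect_identical(g1$p_mc, gearys_c_mc(z, W, n_perm = 300, seed = 5)$p_mc)
})

test_that("bootstrap Mantel sample behaves at the degenerate and large-n ends", {
  set.seed(44)
  M <- matrix(rnorm(40), 20, 2)
  DX <- as.matrix(dist(M))
  bs <- mantel_bootstrap(DX, DX, n_iter = 200, seed = 3)
  expect_true(all(abs(bs$boot - 1) < 1e-12))
  # determinism
  DY <- as.matrix(dist(M + rnorm(40, sd = 1)))
  b1 <- mantel_bootstrap(DX, DY, n_iter = 200, seed = 4)
  b2 <- mantel_bootstrap(DX, DY, n_iter = 200, seed = 4)
  expect_identical(b1$boot, b2$boot)
  # small bias at n = 60
  ty <- simulate_yule(60, seed = 90)
  z <- simulate_bm(ty, seed = 91)
  D1 <- as.matrix(dist(z))
  D2 <- ape::cophenetic.phylo(ty)[names(z), names(z)]
  bs2 <- mantel_bootstrap(D1, D2, n_iter = 500, seed = 5)
  expect_lt(abs(mean(bs2$boot) - bs2$r), 0.05)
  expect_error(mantel_bootstrap(DX[1:4, 1:4], DY[1:4, 1:4], frac = 0.5),
               "subsample")
})
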