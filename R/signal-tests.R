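# permutation values exactly tied with the observed statistic must count as
# at-least-as-extreme (conservative); the epsilon absorbs float jitter from
# recomputing an identical statistic along a different summation order
.tie_eps <- function(stat) 1e-9 * (1 + abs(stat))

new_signal_test <- function(test, statistic, expectation, sd = NA_real_,
                            p_mc = NA_real_, n_perm = NA_integer_,
                            seed = NA_integer_, alternative = NA_character_,
                            distance_model = NA_character_,
                            group = NA_character_, extra = list()) {
  structure(c(list(test = test, statistic = statistic,
                   expectation = expectation, sd = sd,
                   std_deviate = (statistic - expectation) / sd,
                   p_mc = p_mc, n_perm = n_perm, seed = seed,
                   alternative = alternative,
                   distance_model = distance_model, group = group),
              extra),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f (null expectation %.4f)\n",
              x$test, x$statistic, x$expectation))
  if (is.finite(x$std_deviate))
    cat(sprintf("  standard deviate = %.3f\n", x$std_deviate))
  if (is.finite(x$p_mc))
    cat(sprintf("  permutation p = %.4g (%d permutations, %s tail, seed %s)\n",
                x$p_mc, x$n_perm, x$alternative, x$seed))
  invisible(x)
}

.check_zw <- function(z, W) {
  stopifnot(is.numeric(z), is.matrix(W), nrow(W) == ncol(W),
            length(z) == nrow(W))
  if (any(diag(W) != 0)) {
    diag(W) <- 0  # proximity matrices carry a diagonal; drop it for weights
  }
  if (any(W < 0)) stop("negative weights")
  if (stats::sd(z) == 0) stop("constant trait vector: statistic undefined")
  if (!is.null(names(z)) && !is.null(rownames(W))) {
    if (!setequal(names(z), rownames(W))) stop("taxa of z and W differ")
    z <- z[rownames(W)]
  }
  list(z = z, W = W)
}

# Moran's I for each column of Z (already centered); constants precomputed
.moran_stat <- function(Zc, W, S0) {
  n <- nrow(Zc)
  (n / S0) * colSums(Zc * (W %*% Zc)) / colSums(Zc^2)
}

.geary_num <- function(Z, W, rs, cs) {
  colSums(Z^2 * (rs + cs)) - 2 * colSums(Z * (W %*% Z))
}

#' Moran's I with the randomization-moment standard deviate
#'
#' `I = (n/S0) sum_ij w_ij z~_i z~_j / sum z~_i^2` with `z~` centered and
#' `S0` the total weight. The null expectation is `-1/(n-1)`; the variance
#' is taken under the randomization (permutation) assumption, so the
#' standard deviate does not assume normal traits.
#'
#' @param z Named trait (residual) vector.
#' @param W Weight matrix (zero diagonal, nonnegative), e.g. from
#'   [distance_to_weights()] or [abouheif_proximity()] (whose diagonal is
#'   dropped).
#' @return A `signal_test` object.
#' @export
morans_i <- function(z, W) {
  zw <- .check_zw(z, W); z <- zw$z; W <- zw$W
  n <- length(z)
  zc <- z - mean(z)
  S0 <- sum(W)
  S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  I <- unname(.moran_stat(cbind(zc), W, S0))
  E <- -1 / (n - 1)
  b2 <- n * sum(zc^4) / sum(zc^2)^2
  V <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
        b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
       ((n - 1) * (n - 2) * (n - 3) * S0^2) - E^2
  new_signal_test("morans_i", I, E, sd = sqrt(V), alternative = "greater")
}

#' Monte-Carlo Moran's I
#'
#' Permutes trait values across taxa; the p-value is upper-tailed
#' (positive autocorrelation), with the add-one convention
#' `p = (1 + #\{I_perm >= I_obs\}) / (1 + n_perm)`.
#'
#' @inheritParams morans_i
#' @param n_perm Number of permutations.
#' @param seed Integer seed (recorded in the result).
#' @return A `signal_test` object with `p_mc` set.
#' @export
morans_i_mc <- function(z, W, n_perm = 10000, seed = 1L) {
  res <- morans_i(z, W)
  zw <- .check_zw(z, W); z <- zw$z; W <- zw$W
  zc <- z - mean(z)
  S0 <- sum(W)
  set.seed(seed)
  Zp <- vapply(seq_len(n_perm), function(i) zc[sample.int(length(z))],
               numeric(length(z)))
  Ip <- .moran_stat(Zp, W, S0)
  res$p_mc <- (1 + sum(Ip >= res$statistic - .tie_eps(res$statistic))) /
    (1 + n_perm)
  res$n_perm <- as.integer(n_perm)
  res$seed <- seed
  res
}

#' Geary's C with the randomization-moment standard deviate
#'
#' `C = ((n-1)/(2 S0)) sum_ij w_ij (z_i - z_j)^2 / sum z~_i^2`. The null
#' expectation is 1; positive autocorrelation pushes C below 1, so the
#' Monte-Carlo p-value is lower-tailed.
#'
#' @inheritParams morans_i
#' @return A `signal_test` object.
#' @export
gearys_c <- function(z, W) {
  zw <- .check_zw(z, W); z <- zw$z; W <- zw$W
  n <- length(z)
  zc <- z - mean(z)
  S0 <- sum(W); S1 <- sum((W + t(W))^2) / 2
  S2 <- sum((rowSums(W) + colSums(W))^2)
  C <- unname((n - 1) / (2 * S0) *
    .geary_num(cbind(z), W, rowSums(W), colSums(W)) / sum(zc^2))
  b2 <- n * sum(zc^4) / sum(zc^2)^2
  V <- ((n - 1) * S1 * (n^2 - 3 * n + 3 - (n - 1) * b2) -
        (1 / 4) * (n - 1) * S2 * (n^2 + 3 * n - 6 - (n^2 - n + 2) * b2) +
        S0^2 * (n^2 - 3 - (n - 1)^2 * b2)) /
       (n * (n - 2) * (n - 3) * S0^2)
  new_signal_test("gearys_c", C, 1, sd = sqrt(V), alternative = "less")
}

#' Monte-Carlo Geary's C (lower-tailed)
#'
#' @inheritParams morans_i_mc
#' @return A `signal_test` object with `p_mc` set.
#' @export
gearys_c_mc <- function(z, W, n_perm = 10000, seed = 1L) {
  res <- gearys_c(z, W)
  zw <- .check_zw(z, W); z <- zw$z; W <- zw$W
  n <- length(z)
  zc <- z - mean(z)
  scale <- (n - 1) / (2 * sum(W)) / sum(zc^2)
  rs <- rowSums(W); cs <- colSums(W)
  set.seed(seed)
  Zp <- vapply(seq_len(n_perm), function(i) z[sample.int(n)], numeric(n))
  Cp <- scale * .geary_num(Zp, W, rs, cs)
  res$p_mc <- (1 + sum(Cp <= res$statistic + .tie_eps(res$statistic))) /
    (1 + n_perm)
  res$n_perm <- as.integer(n_perm)
  res$seed <- seed
  res
}

# K numerator/denominator machinery, vectorized over columns of Y
.k_stat <- function(Y, Cinv, ones_Cinv, denom_a, expected_ratio, n) {
  a <- drop(crossprod(ones_Cinv, Y)) / denom_a          # phylogenetic mean
  Yc <- sweep(Y, 2, a)
  mse0 <- colSums(Yc^2) / (n - 1)
  mse <- colSums(Yc * (Cinv %*% Yc)) / (n - 1)
  (mse0 / mse) / expected_ratio
}

#' Blomberg's K
#'
#' Ratio of the observed mean-squared-error ratio (trait variance about the
#' phylogenetic mean over the phylogenetically corrected error) to its
#' expectation under Brownian motion on the given tree. K = 1 matches BM;
#' K near 0 indicates phylogenetic independence; K > 1 indicates stronger
#' than-BM similarity among relatives.
#'
#' @param y Named trait vector (names = tip labels).
#' @param tree Rooted `phylo` with branch lengths, or a precomputed BM
#'   covariance matrix (see [bm_vcv()]).
#' @return A `signal_test` object (no analytic standard deviate; use
#'   [blombergs_k_mc()] for inference).
#' @export
blombergs_k <- function(y, tree) {
  C <- if (inherits(tree, "phylo")) bm_vcv(tree) else tree
  stopifnot(is.matrix(C), nrow(C) == length(y))
  if (!is.null(names(y)) && !is.null(rownames(C))) {
    if (!setequal(names(y), rownames(C))) stop("taxa of y and tree differ")
    y <- y[rownames(C)]
  }
  n <- length(y)
  Cinv <- tryCatch(chol2inv(chol(C)),
                   error = function(e) stop("singular covariance matrix"))
  ones_Cinv <- Cinv %*% rep(1, n)
  denom_a <- sum(ones_Cinv)
  expected_ratio <- (sum(diag(C)) - n / denom_a) / (n - 1)
  K <- unname(.k_stat(cbind(y), Cinv, ones_Cinv, denom_a, expected_ratio, n))
  new_signal_test("blombergs_k", K, 1, alternative = "greater",
                  distance_model = "bm_vcv")
}

#' Monte-Carlo Blomberg's K
#'
#' Permutes trait values across tips; upper-tailed add-one p-value. The
#' standard deviate is taken against the permutation distribution's mean
#' and sd.
#'
#' @inheritParams blombergs_k
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `signal_test` object with `p_mc` set.
#' @export
blombergs_k_mc <- function(y, tree, n_perm = 10000, seed = 1L) {
  res <- blombergs_k(y, tree)
  C <- if (inherits(tree, "phylo")) bm_vcv(tree) else tree
  if (!is.null(names(y)) && !is.null(rownames(C))) y <- y[rownames(C)]
  n <- length(y)
  Cinv <- chol2inv(chol(C))
  ones_Cinv <- Cinv %*% rep(1, n)
  denom_a <- sum(ones_Cinv)
  expected_ratio <- (sum(diag(C)) - n / denom_a) / (n - 1)
  set.seed(seed)
  Yp <- vapply(seq_len(n_perm), function(i) y[sample.int(n)], numeric(n))
  Kp <- .k_stat(Yp, Cinv, ones_Cinv, denom_a, expected_ratio, n)
  res$expectation <- mean(Kp)
  res$sd <- stats::sd(Kp)
  res$std_deviate <- (res$statistic - res$expectation) / res$sd
  res$p_mc <- (1 + sum(Kp >= res$statistic - .tie_eps(res$statistic))) /
    (1 + n_perm)
  res$n_perm <- as.integer(n_perm)
  res$seed <- seed
  res
}

.check_dd <- function(DX, DY) {
  stopifnot(is.matrix(DX), is.matrix(DY), all(dim(DX) == dim(DY)),
            nrow(DX) == ncol(DX))
  if (!is.null(rownames(DX)) && !is.null(rownames(DY))) {
    if (!setequal(rownames(DX), rownames(DY)))
      stop("taxa of the two matrices differ")
    DY <- DY[rownames(DX), rownames(DX)]
  }
  lt <- lower.tri(DX)
  if (stats::sd(DX[lt]) == 0 || stats::sd(DY[lt]) == 0)
    stop("constant off-diagonal entries: Mantel correlation undefined")
  list(DX = DX, DY = DY)
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation of the vectorized strict lower triangles.
#'
#' @param DX,DY Symmetric zero-diagonal matrices over the same taxa.
#' @return A `signal_test` object (statistic = r; use [mantel_mc()] for a
#'   permutation p-value).
#' @export
mantel_r <- function(DX, DY) {
  m <- .check_dd(DX, DY)
  lt <- lower.tri(m$DX)
  r <- stats::cor(m$DX[lt], m$DY[lt])
  new_signal_test("mantel", r, 0, alternative = "greater")
}

#' Monte-Carlo Mantel test
#'
#' Permutes the taxon labels of one matrix (simultaneous row/column
#' permutation); upper-tailed add-one p-value.
#'
#' @inheritParams mantel_r
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `signal_test` object with `p_mc` set.
#' @export
mantel_mc <- function(DX, DY, n_perm = 10000, seed = 1L) {
  m <- .check_dd(DX, DY)
  res <- mantel_r(m$DX, m$DY)
  n <- nrow(m$DX)
  lt <- lower.tri(m$DX)
  vx <- m$DX[lt]
  set.seed(seed)
  rp <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    stats::cor(vx, m$DY[p, p][lt])
  }, numeric(1))
  res$expectation <- mean(rp)
  res$sd <- stats::sd(rp)
  res$std_deviate <- (res$statistic - res$expectation) / res$sd
  res$p_mc <- (1 + sum(rp >= res$statistic - .tie_eps(res$statistic))) /
    (1 + n_perm)
  res$n_perm <- as.integer(n_perm)
  res$seed <- seed
  res
}

#' Bootstrap sample of the Mantel correlation
#'
#' Each iteration draws `ceiling(frac * n)` taxa without replacement
#' (with-replacement draws would create zero self-distances that corrupt a
#' distance matrix) and recomputes r on the induced submatrices.
#'
#' @inheritParams mantel_r
#' @param n_iter Number of bootstrap iterations.
#' @param frac Fraction of taxa kept per iteration.
#' @param seed Integer seed.
#' @return List with `r` (full-sample correlation), `boot` (the r sample)
#'   and `quantiles` (2.5/5/50/95/97.5 percent).
#' @export
mantel_bootstrap <- function(DX, DY, n_iter = 10000, frac = 0.9, seed = 1L) {
  m <- .check_dd(DX, DY)
  n <- nrow(m$DX)
  k <- ceiling(frac * n)
  if (k < 4) stop("subsample too small for bootstrap (frac * n < 4)")
  lt_k <- lower.tri(matrix(0, k, k))
  set.seed(seed)
  boot <- numeric(n_iter)
  i <- 1L; guard <- 0L
  while (i <= n_iter) {
    s <- sample.int(n, k)
    vx <- m$DX[s, s][lt_k]; vy <- m$DY[s, s][lt_k]
    if (stats::sd(vx) == 0 || stats::sd(vy) == 0) {
      guard <- guard + 1L  # degenerate subsample: redraw
      if (guard > 100L * n_iter) stop("bootstrap cannot find non-degenerate subsamples")
      next
    }
    boot[i] <- stats::cor(vx, vy)
    i <- i + 1L
  }
  lt <- lower.tri(m$DX)
  list(r = stats::cor(m$DX[lt], m$DY[lt]), boot = boot,
       quantiles = stats::quantile(boot, c(0.025, 0.05, 0.5, 0.95, 0.975)),
       n_iter = n_iter, frac = frac, seed = seed)
}
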