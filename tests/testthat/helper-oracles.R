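# enumeration and brute-force oracles shared across tests

# all permutations of a vector (rows), feasible for n <= 7
all_perms <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# raw statistic values, independent of package internals
moran_stat_brute <- function(z, W) {
  n <- length(z); zc <- z - mean(z)
  (n / sum(W)) * sum(W * outer(zc, zc)) / sum(zc^2)
}

geary_stat_brute <- function(z, W) {
  n <- length(z); zc <- z - mean(z)
  (n - 1) / (2 * sum(W)) * sum(W * outer(z, z, function(a, b) (a - b)^2)) /
    sum(zc^2)
}

k_stat_brute <- function(y, C) {
  n <- length(y)
  Cinv <- solve(C)
  a <- sum(Cinv %*% y) / sum(Cinv)
  mse0 <- sum((y - a)^2) / (n - 1)
  mse <- drop(t(y - a) %*% Cinv %*% (y - a)) / (n - 1)
  (mse0 / mse) / ((sum(diag(C)) - n / sum(Cinv)) / (n - 1))
}

mantel_stat_brute <- function(DX, DY) {
  lt <- lower.tri(DX)
  cor(DX[lt], DY[lt])
}

# exact permutation p-value (upper or lower tail) by full enumeration
exact_perm_p <- function(obs, stat_fn, n, upper = TRUE) {
  P <- all_perms(seq_len(n))
  vals <- apply(P, 1, stat_fn)
  if (upper) mean(vals >= obs - 1e-12) else mean(vals <= obs + 1e-12)
}

skip_if_no <- function(pkg) {
  testthat::skip_if_not_installed(pkg)
}
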