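#' Phylogenetic generalized least squares regression
#'
#' Fits `y ~ x` by GLS with error covariance proportional to a
#' phylogenetic variance-covariance matrix `C` (Brownian motion, lambda
#' fixed at 1): `beta = (X' C^-1 X)^-1 X' C^-1 y` with `X = [1, x]`.
#' Residuals are returned on the ordinary scale, `y - X beta` (not
#' whitened), which is the construction used for phylogenetic
#' size-correction; whitened residuals `L^-1 (y - X beta)` (with
#' `C = L L'`) are available via `residuals(fit, type = "whitened")`.
#'
#' @param y Named response vector (names = taxa).
#' @param x Named covariate vector.
#' @param C Phylogenetic covariance matrix (see [bm_vcv()]); must be
#'   positive definite and share the taxa of `y` and `x`.
#' @return An object of class `callphylo_pgls` with `coefficients`,
#'   `residuals`, `fitted`, and the inputs.
#' @export
pgls_fit <- function(y, x, C) {
  stopifnot(length(y) == length(x), nrow(C) == length(y), ncol(C) == nrow(C))
  taxa <- rownames(C)
  if (!is.null(taxa) && !is.null(names(y))) {
    if (!setequal(names(y), taxa)) stop("taxa of y and C differ")
    y <- y[taxa]
    if (!is.null(names(x))) x <- x[taxa]
  }
  if (anyNA(y) || anyNA(x)) stop("missing values in y or x")
  L <- tryCatch(chol(C), error = function(e)
    stop("covariance matrix is not positive definite: ", conditionMessage(e)))
  X <- cbind(`(Intercept)` = 1, x = x)
  # whiten by the Cholesky factor, then ordinary least squares
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qr_x <- qr(Xw)
  if (qr_x$rank < 2) stop("design matrix is rank deficient (constant x?)")
  beta <- qr.coef(qr_x, yw)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  names(res) <- names(fitted) <- taxa %||% names(y)
  structure(list(coefficients = beta, residuals = res, fitted = fitted,
                 residuals_whitened = drop(backsolve(L, res, transpose = TRUE)),
                 y = y, x = x, C = C),
            class = "callphylo_pgls")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.callphylo_pgls <- function(object, ...) object$coefficients

#' @export
residuals.callphylo_pgls <- function(object,
                                     type = c("ordinary", "whitened"), ...) {
  type <- match.arg(type)
  if (type == "ordinary") object$residuals else object$residuals_whitened
}

#' @export
fitted.callphylo_pgls <- function(object, ...) object$fitted

#' @export
print.callphylo_pgls <- function(x, ...) {
  cat("Phylogenetic GLS fit (Brownian covariance)\n")
  cat(sprintf("  n = %d taxa; intercept = %.4g, slope = %.4g\n",
              length(x$y), x$coefficients[1], x$coefficients[2]))
  invisible(x)
}

#' Phylogenetic size-correction of the acoustic trait table
#'
#' Regresses each acoustic trait on log-SVL by PGLS and collects the
#' residuals. With `grouping = "all"` a single regression per trait uses
#' the full tree; with `grouping = "per_clade"` the tree is pruned to each
#' clade and separate regressions are fitted (clades with fewer than 3
#' species are skipped with a warning).
#'
#' @param traits Trait table from [species_trait_table()] (columns
#'   `species_id, clade, cva, logdf, logsf, logsi, logton, logsvl`).
#' @param tree Rooted `phylo` containing all trait species as tips.
#' @param grouping `"all"` or `"per_clade"`.
#' @return Data frame `species_id, clade, group, cva, logdf, logsf, logsi,
#'   logton` of residuals (one row per species within each group fitted).
#' @export
size_correct <- function(traits, tree, grouping = c("all", "per_clade")) {
  grouping <- match.arg(grouping)
  trait_cols <- c("cva", "logdf", "logsf", "logsi", "logton")
  stopifnot(all(c("species_id", "clade", "logsvl", trait_cols) %in%
                names(traits)))
  missing_tips <- setdiff(traits$species_id, tree$tip.label)
  if (length(missing_tips))
    stop("species not on the tree: ", paste(missing_tips, collapse = ", "))
  one_group <- function(sub, group_label) {
    sub_tree <- ape::keep.tip(tree, sub$species_id)
    C <- bm_vcv(sub_tree)
    sub <- sub[match(rownames(C), sub$species_id), ]
    out <- sub[c("species_id", "clade")]
    out$group <- group_label
    x <- stats::setNames(sub$logsvl, sub$species_id)
    for (tc in trait_cols) {
      y <- stats::setNames(sub[[tc]], sub$species_id)
      out[[tc]] <- unname(residuals(pgls_fit(y, x, C)))
    }
    out
  }
  if (grouping == "all") return(one_group(traits, "all"))
  res <- lapply(split(traits, traits$clade), function(sub) {
    if (nrow(sub) < 3) {
      warning("clade ", sub$clade[1], " has fewer than 3 species; skipped")
      return(NULL)
    }
    one_group(sub, sub$clade[1])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Standardize residual columns to zero mean and unit variance
#'
#' Gives equal weight to all traits before Euclidean multivariate trait
#' distances. The sd uses the n-1 denominator.
#'
#' @param residuals Residual table from [size_correct()] (or any data frame
#'   whose numeric columns should be z-scored).
#' @return Same data frame with each numeric trait column standardized.
#' @export
standardize_residuals <- function(residuals) {
  num <- vapply(residuals, is.numeric, logical(1))
  if (nrow(residuals) < 2) stop("standardization needs at least 2 species")
  for (cn in names(residuals)[num]) {
    s <- stats::sd(residuals[[cn]])
    if (!is.finite(s) || s == 0)
      stop("zero-variance residual column: ", cn)
    residuals[[cn]] <- (residuals[[cn]] - mean(residuals[[cn]])) / s
  }
  residuals
}
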