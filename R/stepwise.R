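#' Euclidean multivariate trait distances
#'
#' Pairwise Euclidean distances between species over a subset of
#' standardized residual trait columns.
#'
#' @param residuals Standardized residual table (see
#'   [standardize_residuals()]) with a `species_id` column.
#' @param traits Character vector of trait column names (subset of
#'   `cva, logdf, logsf, logsi, logton`).
#' @return Symmetric distance matrix keyed by species, attribute
#'   `kind = "distance"`.
#' @export
euclidean_trait_distance <- function(residuals, traits) {
  stopifnot(length(traits) >= 1)
  unknown <- setdiff(traits, names(residuals))
  if (length(unknown))
    stop("unknown trait name(s): ", paste(unknown, collapse = ", "))
  M <- as.matrix(residuals[, traits, drop = FALSE])
  rownames(M) <- residuals$species_id
  D <- as.matrix(stats::dist(M))
  attr(D, "kind") <- "distance"
  D
}

#' Forward stepwise selection of a multivariate trait distance by Mantel
#' correlation
#'
#' Starts from the single trait with the highest Mantel correlation to the
#' genetic dissimilarity matrix, then repeatedly tries to add the candidate
#' that yields the highest correlation. An addition is accepted only when
#' the new coefficient exceeds at least `exceedance` (default 95 percent)
#' of a bootstrap sample of the incumbent model's coefficient; the
#' procedure stops at the first rejection. Bootstrap seeds are derived
#' deterministically from `seed`, the step number and the candidate index,
#' so the outcome does not depend on candidate ordering.
#'
#' @param residuals Standardized residual table.
#' @param genetic Genetic dissimilarity matrix over the same species (use
#'   [proximity_to_dissimilarity()] for Abouheif proximities).
#' @param candidates Trait column names to consider.
#' @param n_boot Bootstrap iterations per comparison.
#' @param exceedance Acceptance threshold (proportion of the incumbent's
#'   bootstrap sample that the challenger must exceed).
#' @param frac Taxon fraction per bootstrap draw.
#' @param n_perm Permutations for the final Mantel p-value.
#' @param seed Integer seed.
#' @return A `stepwise_trace` object: list with `selected` (trait names),
#'   `r` (final Mantel r), `p_mc`, and `steps` (one entry per evaluated
#'   addition, with candidate, r before/after, exceedance proportion and
#'   accept flag).
#' @export
forward_stepwise <- function(residuals, genetic, candidates,
                             n_boot = 10000, exceedance = 0.95, frac = 0.9,
                             n_perm = 10000, seed = 1L) {
  stopifnot(length(candidates) >= 1)
  genetic <- genetic[residuals$species_id, residuals$species_id]
  r_of <- function(traits)
    mantel_r(euclidean_trait_distance(residuals, traits), genetic)$statistic
  r_single <- vapply(candidates, function(tr) r_of(tr), numeric(1))
  best <- which.max(r_single)  # ties: first in candidate order
  selected <- candidates[best]
  r_cur <- r_single[[best]]
  steps <- list(list(candidate = selected, r_before = NA_real_,
                     r_after = r_cur, exceedance = NA_real_, accepted = TRUE,
                     note = "best single trait (start)"))
  if (length(candidates) > 1) {
    step_i <- 1L
    repeat {
      remaining <- setdiff(candidates, selected)
      if (length(remaining) == 0) break
      r_try <- vapply(remaining, function(tr) r_of(c(selected, tr)),
                      numeric(1))
      j <- which.max(r_try)
      cand <- remaining[j]
      cand_idx <- match(cand, candidates)
      boot <- mantel_bootstrap(
        euclidean_trait_distance(residuals, selected), genetic,
        n_iter = n_boot, frac = frac,
        seed = (seed + 1009L * step_i + cand_idx) %% .Machine$integer.max)
      exceed <- mean(r_try[[j]] > boot$boot)
      accepted <- exceed >= exceedance && r_try[[j]] > r_cur
      steps[[length(steps) + 1L]] <-
        list(candidate = cand, r_before = r_cur, r_after = r_try[[j]],
             exceedance = exceed, accepted = accepted, note = "")
      if (!accepted) break
      selected <- c(selected, cand)
      r_cur <- r_try[[j]]
      step_i <- step_i + 1L
    }
  }
  final_p <- mantel_mc(euclidean_trait_distance(residuals, selected),
                       genetic, n_perm = n_perm, seed = seed)$p_mc
  structure(list(selected = selected, r = r_cur, p_mc = final_p,
                 steps = steps, n_boot = n_boot, exceedance = exceedance,
                 seed = seed),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Forward stepwise Mantel selection\n")
  cat("  selected:", paste(x$selected, collapse = " + "),
      sprintf(" (r = %.4f, p = %.4g)\n", x$r, x$p_mc))
  for (s in x$steps)
    cat(sprintf("  %s %-8s r %.4f -> %.4f  exceedance %s\n",
                if (isTRUE(s$accepted)) "+" else "x", s$candidate,
                if (is.na(s$r_before)) s$r_after else s$r_before, s$r_after,
                ifelse(is.na(s$exceedance), "-",
                       sprintf("%.3f", s$exceedance))))
  invisible(x)
}
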