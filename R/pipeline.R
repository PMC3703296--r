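#' Cross-check species identifiers across pipeline inputs
#'
#' @param species Character vector of species ids (e.g. from the metadata
#'   or trait table).
#' @param tree Rooted `phylo`.
#' @param alignment Optional `DNAbin` alignment.
#' @param prune Drop tree tips / alignment rows absent from `species`
#'   instead of failing; species missing from the tree always fail.
#' @return List with the validated `tree`, `alignment` and a data frame
#'   `orphans` describing what was dropped (empty when consistent).
#' @export
validate_inputs <- function(species, tree, alignment = NULL, prune = FALSE) {
  orphans <- data.frame(where = character(0), id = character(0))
  missing_tips <- setdiff(species, tree$tip.label)
  if (length(missing_tips))
    stop("species missing from tree: ", paste(missing_tips, collapse = ", "))
  extra_tips <- setdiff(tree$tip.label, species)
  if (length(extra_tips)) {
    if (!prune)
      stop("tree tips without species data: ",
           paste(extra_tips, collapse = ", "), " (set prune = TRUE to drop)")
    tree <- ape::keep.tip(tree, intersect(tree$tip.label, species))
    orphans <- rbind(orphans, data.frame(where = "tree", id = extra_tips))
  }
  if (!is.null(alignment)) {
    taxa <- rownames(alignment)
    missing_seq <- setdiff(species, taxa)
    if (length(missing_seq))
      stop("species missing from alignment: ",
           paste(missing_seq, collapse = ", "))
    extra_seq <- setdiff(taxa, species)
    if (length(extra_seq)) {
      if (!prune)
        stop("alignment taxa without species data: ",
             paste(extra_seq, collapse = ", "))
      alignment <- alignment[setdiff(taxa, extra_seq), ]
      orphans <- rbind(orphans, data.frame(where = "alignment",
                                           id = extra_seq))
    }
  }
  list(tree = tree, alignment = alignment, orphans = orphans)
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

# one row of the results table from a signal_test object
.result_row <- function(st, group, trait, test, model) {
  data.frame(group = group, trait = trait, test = test,
             distance_model = model, statistic = st$statistic,
             expectation = st$expectation, std_deviate = st$std_deviate,
             p_mc = st$p_mc, stars = .stars(st$p_mc), n_perm = st$n_perm,
             seed = st$seed, stringsAsFactors = FALSE)
}

#' Full phylogenetic-signal analysis of an acoustic trait table
#'
#' Orchestrates the pipeline on species-level traits: PGLS size-correction
#' against log-SVL (whole-sample and per-clade), univariate signal tests
#' (Moran's I and Geary's C on inverse-distance weights from pairwise
#' genetic distances, Moran's I on Abouheif proximities, Blomberg's K on
#' the BM covariance), a forward stepwise multivariate Mantel selection on
#' the whole sample for each genetic model, and clade-level Mantel tests of
#' the whole-sample-selected trait subsets. Residuals are standardized
#' within each analysis group.
#'
#' @param traits Species trait table (see [species_trait_table()]).
#' @param tree Rooted `phylo` with branch lengths covering all species.
#' @param alignment Optional `DNAbin` alignment (used to compute pairwise
#'   distances when `genetic_distance` is NULL).
#' @param genetic_distance Optional precomputed pairwise distance matrix
#'   (the escape hatch for externally computed distances).
#' @param distance_model Substitution model for [pairwise_distance()].
#' @param n_perm Permutations per test.
#' @param n_boot Bootstrap iterations per stepwise comparison.
#' @param per_clade Also run per-clade analyses.
#' @param stepwise Run the forward stepwise selection (whole sample only).
#' @param seed Integer seed.
#' @return List with `residuals` (per group), `results` (long data frame,
#'   one row per group x trait x test x distance model), `stepwise` (one
#'   trace per genetic model) and `provenance`.
#' @export
run_analysis <- function(traits, tree, alignment = NULL,
                         genetic_distance = NULL, distance_model = "jc69",
                         n_perm = 10000, n_boot = 10000, per_clade = TRUE,
                         stepwise = TRUE, seed = 1L) {
  v <- validate_inputs(traits$species_id, tree, alignment, prune = TRUE)
  tree <- v$tree; alignment <- v$alignment
  if (is.null(genetic_distance)) {
    if (is.null(alignment))
      stop("need either an alignment or a precomputed genetic distance")
    genetic_distance <- pairwise_distance(alignment, distance_model)
  }
  trait_cols <- c("cva", "logdf", "logsf", "logsi", "logton")

  groups <- list(all = traits)
  if (per_clade)
    groups <- c(groups,
                split(traits, traits$clade)[
                  names(which(table(traits$clade) >= 4))])

  residual_tabs <- list()
  rows <- list()
  stepwise_traces <- list()
  for (g in names(groups)) {
    sub <- groups[[g]]
    sub_tree <- ape::keep.tip(tree, sub$species_id)
    res <- size_correct(sub, sub_tree,
                        grouping = if (g == "all") "all" else "all")
    res$group <- g
    res_std <- standardize_residuals(res)
    residual_tabs[[g]] <- res_std
    ids <- res$species_id
    D_gen <- genetic_distance[ids, ids]
    W_pair <- distance_to_weights(D_gen)
    A <- abouheif_proximity(sub_tree)[ids, ids]
    C <- bm_vcv(sub_tree)[ids, ids]
    for (tr in trait_cols) {
      z <- stats::setNames(res[[tr]], ids)
      rows[[length(rows) + 1]] <- .result_row(
        morans_i_mc(z, W_pair, n_perm, seed), g, tr, "morans_i", "pairwise")
      rows[[length(rows) + 1]] <- .result_row(
        morans_i_mc(z, A, n_perm, seed), g, tr, "morans_i", "abouheif")
      rows[[length(rows) + 1]] <- .result_row(
        gearys_c_mc(z, W_pair, n_perm, seed), g, tr, "gearys_c", "pairwise")
      rows[[length(rows) + 1]] <- .result_row(
        blombergs_k_mc(z, C, n_perm, seed), g, tr, "blombergs_k", "bm_vcv")
    }
  }

  if (stepwise) {
    res_all <- residual_tabs[["all"]]
    ids <- res_all$species_id
    gen_models <- list(
      pairwise = genetic_distance[ids, ids],
      abouheif = proximity_to_dissimilarity(
        abouheif_proximity(ape::keep.tip(tree, ids))[ids, ids]))
    for (gm in names(gen_models)) {
      trace <- forward_stepwise(res_all, gen_models[[gm]], trait_cols,
                                n_boot = n_boot, n_perm = n_perm, seed = seed)
      stepwise_traces[[gm]] <- trace
      rows[[length(rows) + 1]] <- data.frame(
        group = "all", trait = paste(trace$selected, collapse = "+"),
        test = "mantel", distance_model = gm, statistic = trace$r,
        expectation = 0, std_deviate = NA_real_, p_mc = trace$p_mc,
        stars = .stars(trace$p_mc), n_perm = n_perm, seed = seed,
        stringsAsFactors = FALSE)
      # clade-level Mantel of the whole-sample-selected trait subset
      if (per_clade) {
        for (g in setdiff(names(residual_tabs), "all")) {
          res_g <- residual_tabs[[g]]
          ids_g <- res_g$species_id
          D_gen_g <- if (gm == "pairwise") genetic_distance[ids_g, ids_g]
            else proximity_to_dissimilarity(
              abouheif_proximity(ape::keep.tip(tree, ids_g))[ids_g, ids_g])
          mt <- mantel_mc(euclidean_trait_distance(res_g, trace$selected),
                          D_gen_g, n_perm = n_perm, seed = seed)
          rows[[length(rows) + 1]] <- .result_row(
            mt, g, paste(trace$selected, collapse = "+"), "mantel", gm)
        }
      }
    }
  }

  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(residuals = residual_tabs, results = results,
       stepwise = stepwise_traces,
       provenance = list(n_perm = n_perm, n_boot = n_boot, seed = seed,
                         distance_model = distance_model,
                         n_species = nrow(traits),
                         r_version = R.version.string))
}
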