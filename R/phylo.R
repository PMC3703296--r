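#' Read a phylogenetic tree
#'
#' Thin wrapper over ape's Newick/Nexus parsers with validation: tip labels
#' must be unique and, unless `allow_topology_only = TRUE`, branch lengths
#' must be present.
#'
#' @param path Tree file path.
#' @param format `"newick"` or `"nexus"`.
#' @param allow_topology_only If the tree has no branch lengths, assign unit
#'   lengths (with a warning) instead of failing.
#' @return An [ape::phylo] object (rooted).
#' @export
read_tree <- function(path, format = c("newick", "nexus"),
                      allow_topology_only = FALSE) {
  format <- match.arg(format)
  tree <- if (format == "newick") ape::read.tree(path) else ape::read.nexus(path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  if (is.null(tree)) stop("could not parse tree file: ", path)
  validate_tree(tree, allow_topology_only = allow_topology_only)
}

validate_tree <- function(tree, allow_topology_only = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    if (!allow_topology_only)
      stop("tree has no branch lengths (set allow_topology_only = TRUE ",
           "to use unit lengths)")
    warning("tree has no branch lengths; using unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Brownian-motion variance-covariance matrix of a tree
#'
#' The covariance between two tips is the branch length from the root to
#' their most recent common ancestor; the diagonal holds root-to-tip path
#' lengths. This is the trait covariance implied by Brownian motion with
#' unit rate.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames and attribute `kind = "covariance"`.
#' @export
bm_vcv <- function(tree) {
  tree <- validate_tree(tree)
  C <- ape::vcv.phylo(tree)
  attr(C, "kind") <- "covariance"
  C
}

#' Abouheif's matrix of phylogenetic proximities
#'
#' Topology-only relatedness: the proximity of tips i and j is the product,
#' over the interior nodes on the path between them, of one over the number
#' of direct descendants of the node. The diagonal is filled so that every
#' row sums to one (the "oriAbouheif" construction). Branch lengths are
#' ignored; zero-length internal branches are collapsed to polytomies first.
#'
#' @param tree A rooted `phylo`.
#' @return Symmetric matrix with rows summing to 1, attribute
#'   `kind = "proximity"`.
#' @export
abouheif_proximity <- function(tree) {
  tree <- validate_tree(tree, allow_topology_only = TRUE)
  if (!is.null(tree$edge.length) && any(tree$edge.length == 0) &&
      ape::Ntip(tree) > 2)
    tree <- ape::di2multi(tree)
  n <- ape::Ntip(tree)
  # number of direct descendants of each internal node
  ndesc <- tabulate(tree$edge[, 1], nbins = n + tree$Nnode)
  A <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      path <- ape::nodepath(tree, i, j)
      interior <- path[path > n]
      A[i, j] <- A[j, i] <- prod(1 / ndesc[interior])
    }
  }
  diag(A) <- 1 - rowSums(A)
  attr(A, "kind") <- "proximity"
  A
}

#' Read a FASTA alignment
#'
#' @param path FASTA file of aligned nucleotide sequences (equal lengths;
#'   case-insensitive).
#' @return A `DNAbin` matrix (taxa x sites).
#' @export
read_fasta <- function(path) {
  aln <- ape::read.FASTA(path)
  if (length(aln) < 2) stop("alignment needs at least 2 sequences: ", path)
  lens <- lengths(aln)
  if (length(unique(lens)) != 1)
    stop("ragged alignment; offending record(s): ",
         paste(names(aln)[lens != stats::median(lens)], collapse = ", "))
  as.matrix(aln)
}

#' Pairwise genetic distances from an alignment
#'
#' Distances in expected substitutions per site under the p (raw mismatch
#' proportion), Jukes-Cantor 1969 or Kimura two-parameter model. Sites with
#' a gap or ambiguous base in either member of a pair are dropped for that
#' pair (pairwise deletion).
#'
#' @param aln A `DNAbin` matrix (see [read_fasta()]).
#' @param model One of `"p"`, `"jc69"`, `"k2p"`.
#' @return Symmetric distance matrix, zero diagonal, attribute
#'   `kind = "distance"`.
#' @export
pairwise_distance <- function(aln, model = c("p", "jc69", "k2p")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "DNAbin"))
  ape_model <- c(p = "raw", jc69 = "JC69", k2p = "K80")[[model]]
  D <- as.matrix(ape::dist.dna(aln, model = ape_model,
                               pairwise.deletion = TRUE))
  if (any(!is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    stop("undefined ", model, " distance (saturated or no shared sites) for ",
         "pair(s): ",
         paste(rownames(D)[bad[, 1]], colnames(D)[bad[, 2]],
               sep = "-", collapse = ", "))
  }
  attr(D, "kind") <- "distance"
  D
}

#' Row-standardized inverse-distance weights
#'
#' Converts a pairwise distance matrix into a spatial-style weight matrix
#' for Moran's I and Geary's C: off-diagonal weights are reciprocal
#' distances (`"inverse"`, default), squared reciprocals or reverse ranks,
#' then each row is rescaled to sum to one. Zero off-diagonal distances are
#' replaced by half the smallest positive distance before inversion.
#'
#' @param D Symmetric distance matrix with zero diagonal.
#' @param scheme `"inverse"`, `"inverse_squared"` or `"rank"`.
#' @return Row-standardized weight matrix, zero diagonal, attribute
#'   `kind = "weight"`.
#' @export
distance_to_weights <- function(D,
                                scheme = c("inverse", "inverse_squared",
                                           "rank")) {
  scheme <- match.arg(scheme)
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  off <- D[upper.tri(D)]
  if (all(off == 0)) stop("degenerate distance matrix: all distances zero")
  eps <- min(off[off > 0]) / 2
  Dp <- pmax(D, eps)
  W <- switch(scheme,
    inverse = 1 / Dp,
    inverse_squared = 1 / Dp^2,
    rank = {
      r <- matrix(0, nrow(D), ncol(D))
      r[upper.tri(r)] <- rank(off)
      r <- r + t(r)
      max(r) + 1 - r
    })
  diag(W) <- 0
  W <- W / rowSums(W)
  dimnames(W) <- dimnames(D)
  attr(W, "kind") <- "weight"
  W
}

#' Dissimilarity from an Abouheif proximity matrix
#'
#' The Mantel test correlates two distance matrices, while Abouheif
#' proximities measure closeness; this maps proximities to dissimilarities
#' by subtracting each off-diagonal entry from the largest off-diagonal
#' proximity (diagonal set to zero). Mantel r is invariant to positive
#' affine transforms of the entries, so this simply flips the sign of the
#' correlation relative to using proximities directly.
#'
#' @param A Proximity matrix from [abouheif_proximity()].
#' @return Dissimilarity matrix, zero diagonal, attribute
#'   `kind = "distance"`.
#' @export
proximity_to_dissimilarity <- function(A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  off_max <- max(A[row(A) != col(A)])
  D <- off_max - A
  diag(D) <- 0
  attr(D, "kind") <- "distance"
  D
}
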