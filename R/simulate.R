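#' Simulate an ultrametric Yule (pure-birth) tree
#'
#' Forward simulation conditioned on the number of tips: while k lineages
#' exist the waiting time to the next speciation is exponential with rate
#' `k * birth_rate`; a uniformly chosen lineage splits at each event, and a
#' final waiting period with all `n_tips` lineages extant is appended, so
#' the expected root height is `sum_{k=2}^{n} 1/(k * birth_rate)`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (events per unit time).
#' @param seed Optional integer seed.
#' @return An ultrametric rooted `phylo` with tips `t1..tn`.
#' @export
simulate_yule <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  waits <- stats::rexp(n_tips - 1, rate = (2:n_tips) * birth_rate)
  event_t <- cumsum(waits)[-(n_tips - 1)]      # split times (k -> k+1)
  total_t <- sum(waits)
  n_nodes <- 2L * n_tips - 1L
  root <- n_tips + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  # active lineages: parent node id and birth time of the pending edge
  act_parent <- c(root, root); act_birth <- c(0, 0)
  next_internal <- root + 1L
  for (t in event_t) {
    i <- sample.int(length(act_parent), 1)
    parent <- c(parent, act_parent[i]); child <- c(child, next_internal)
    elen <- c(elen, t - act_birth[i])
    act_parent <- c(act_parent[-i], next_internal, next_internal)
    act_birth <- c(act_birth[-i], t, t)
    next_internal <- next_internal + 1L
  }
  tip_ids <- seq_len(n_tips)
  parent <- c(parent, act_parent); child <- c(child, tip_ids)
  elen <- c(elen, total_t - act_birth)
  tree <- structure(list(edge = cbind(parent, child, deparse.level = 0),
                         edge.length = elen,
                         tip.label = paste0("t", tip_ids),
                         Nnode = n_tips - 1L),
                    class = "phylo")
  # canonicalize edge ordering through ape's parser
  ape::read.tree(text = ape::write.tree(tree))
}

# BM covariance with off-diagonal entries diluted by lambda
.lambda_vcv <- function(tree, sigma2 = 1, lambda_signal = 1) {
  stopifnot(lambda_signal >= 0, lambda_signal <= 1, sigma2 > 0)
  C <- bm_vcv(tree)
  d <- diag(C)
  C <- C * lambda_signal
  diag(C) <- d
  sigma2 * C
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Tip values are drawn from a multivariate normal with mean `root_value`
#' and covariance `sigma2 * C(lambda)`, where `C(lambda)` is the BM
#' variance-covariance matrix with off-diagonal entries multiplied by
#' `lambda_signal`. `lambda_signal = 1` is pure BM; 0 gives
#' phylogeny-free independent noise (with the BM tip variances).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param sigma2 BM rate (trait variance per unit branch length).
#' @param root_value Trait value at the root.
#' @param lambda_signal Signal strength in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Named trait vector over the tips.
#' @export
simulate_bm <- function(tree, sigma2 = 1, root_value = 0, lambda_signal = 1,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  V <- .lambda_vcv(tree, sigma2, lambda_signal)
  n <- nrow(V)
  y <- root_value + drop(crossprod(chol(V), stats::rnorm(n)))
  stats::setNames(y, rownames(V))
}

#' Simulate an allometric trait-body-size pair
#'
#' Body size (log-SVL) evolves by Brownian motion; the trait is
#' `a + b * logSVL + e`, where the residual `e` evolves under BM with rate
#' `sigma2_resid` and signal strength `lambda_signal`. Ground truth for
#' both the allometric slope and the residual phylogenetic signal is
#' therefore known.
#'
#' @param tree Rooted `phylo`.
#' @param a,b Allometric intercept and slope.
#' @param sigma2_svl,sigma2_resid BM rates of log-SVL and of the residual.
#' @param lambda_signal Signal strength of the residual component.
#' @param lambda_svl Signal strength of log-SVL itself (defaults to
#'   `lambda_signal`: a fully signal-free study has phylogeny-free body
#'   size too, which keeps the size-correction step's covariance model
#'   consistent with the data it sees).
#' @param svl_root Root value of log-SVL.
#' @param seed Optional integer seed.
#' @return List with named vectors `logsvl` and `trait`.
#' @export
simulate_allometric <- function(tree, a = 0, b = -0.33, sigma2_svl = 1,
                                sigma2_resid = 1, lambda_signal = 1,
                                lambda_svl = lambda_signal,
                                svl_root = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  logsvl <- simulate_bm(tree, sigma2_svl, root_value = svl_root,
                        lambda_signal = lambda_svl)
  e <- simulate_bm(tree, sigma2_resid, lambda_signal = lambda_signal)
  list(logsvl = logsvl, trait = a + b * logsvl + e)
}

#' Simulate nucleotide sequences under Jukes-Cantor on a tree
#'
#' The root sequence is uniform over A/C/G/T; along each branch of length d
#' (expected substitutions per site) every site changes with probability
#' `(3/4) (1 - exp(-4 d / 3))`, to a uniformly chosen different base.
#'
#' @param tree Rooted `phylo` with branch lengths in substitutions/site.
#' @param seq_length Alignment length in bp.
#' @param seed Optional integer seed.
#' @return A `DNAbin` matrix (tips x sites).
#' @export
simulate_jc_sequences <- function(tree, seq_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  n <- ape::Ntip(tree)
  n_nodes <- n + tree$Nnode
  root <- n + 1L
  seqs <- matrix(NA_integer_, n_nodes, seq_length)
  seqs[root, ] <- sample.int(4, seq_length, replace = TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    d <- tree$edge.length[e]
    psub <- 0.75 * (1 - exp(-4 * d / 3))
    s <- seqs[p, ]
    hit <- stats::runif(seq_length) < psub
    if (any(hit))
      s[hit] <- 1L + (s[hit] - 1L + sample.int(3, sum(hit), replace = TRUE)) %% 4L
    seqs[ch, ] <- s
  }
  chars <- matrix(c("a", "c", "g", "t")[seqs[seq_len(n), ]], nrow = n,
                  dimnames = list(tree$tip.label, NULL))
  ape::as.DNAbin(chars)
}

#' Synthesize a parametric advertisement-call recording
#'
#' A harmonic stack at `f0` with a fixed per-harmonic rolloff, sinusoidal
#' amplitude modulation and optional additive white noise. Ground truth is
#' attached as attribute `"truth"`: expected dominant frequency `f0` and
#' expected CVA `am_depth / sqrt(2)`.
#'
#' @param f0 Fundamental frequency (Hz; must be below Nyquist).
#' @param n_harmonics Number of harmonics (those above Nyquist are dropped
#'   with a message).
#' @param rolloff_db Amplitude decrease per harmonic step, in dB.
#' @param am_rate Amplitude-modulation rate (Hz).
#' @param am_depth Modulation depth in \[0, 1\].
#' @param noise_snr Signal-to-noise ratio in dB (`Inf` = no noise,
#'   `-Inf` = noise only).
#' @param duration Seconds (>= 0.5).
#' @param sample_rate Hz.
#' @param seed Optional integer seed (noise and phases).
#' @param species_id,recording_id Identifiers for the result.
#' @return A `recording` with attribute `truth`.
#' @export
synth_call <- function(f0 = 1000, n_harmonics = 1, rolloff_db = 6,
                       am_rate = 10, am_depth = 0, noise_snr = Inf,
                       duration = 1, sample_rate = 44100, seed = NULL,
                       species_id = NA_character_,
                       recording_id = NA_character_) {
  stopifnot(f0 < sample_rate / 2, duration >= 0.5,
            am_depth >= 0, am_depth <= 1)
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration, by = 1 / sample_rate)[-1]
  harm <- seq_len(n_harmonics)
  alive <- harm * f0 < sample_rate / 2
  if (!all(alive))
    message(sum(!alive), " harmonic(s) above Nyquist dropped")
  harm <- harm[alive]
  sig <- 0
  for (h in harm)
    sig <- sig + 10^(-rolloff_db * (h - 1) / 20) *
      sin(2 * pi * h * f0 * t + stats::runif(1, 0, 2 * pi))
  env <- 1 + am_depth * sin(2 * pi * am_rate * t)
  x <- env * sig
  if (is.finite(noise_snr)) {
    noise_sd <- sqrt(mean(x^2) / 10^(noise_snr / 10))
    x <- x + stats::rnorm(length(x), sd = noise_sd)
  } else if (noise_snr == -Inf) {
    x <- stats::rnorm(length(t))
  }
  x <- 0.9 * x / max(abs(x))
  rec <- recording(x, sample_rate, species_id = species_id,
                   recording_id = recording_id)
  attr(rec, "truth") <- list(df = f0, cva = am_depth / sqrt(2))
  rec
}

#' Simulate a complete synthetic study
#'
#' Generates the full data structure of a comparative bioacoustic study:
#' an ultrametric Yule tree whose tips are partitioned into clades (by
#' cutting the tree into its basal subtrees), Brownian log-SVL, five
#' acoustic traits with an allometric body-size link on the dominant
#' frequency and residual signal strength `lambda_signal`, a Jukes-Cantor
#' alignment evolved on the (rescaled) tree, and optionally one parametric
#' call recording per species whose fundamental frequency and modulation
#' depth realize the simulated logDF and CVA.
#'
#' @param n_species Number of species (tips).
#' @param n_clades Number of clade labels.
#' @param birth_rate Yule speciation rate.
#' @param lambda_signal Residual signal strength in \[0, 1\] shared by all
#'   traits.
#' @param seq_length Alignment length (bp).
#' @param tree_scale Root height of the tree used for sequence evolution,
#'   in substitutions/site.
#' @param audio Generate per-species recordings (slower).
#' @param dir If non-NULL, write the dataset (Newick tree, FASTA alignment,
#'   metadata TSV, trait TSV, WAV files if `audio`, and `truth.json`) into
#'   this directory.
#' @param seed Integer seed.
#' @return List with `tree`, `metadata` (species_id, clade, svl_mm),
#'   `traits` (the simulated species trait table), `alignment`,
#'   `recordings` (or NULL), and `truth` (generator parameters).
#' @export
simulate_study <- function(n_species = 90, n_clades = 4, birth_rate = 1,
                           lambda_signal = 1, seq_length = 900,
                           tree_scale = 0.25, audio = FALSE, dir = NULL,
                           seed = 1L) {
  set.seed(seed)
  tree <- simulate_yule(n_species, birth_rate)
  clades <- stats::cutree(stats::as.hclust(tree), k = n_clades)
  clades <- stats::setNames(paste0("clade", clades), names(clades))
  logsvl <- simulate_bm(tree, sigma2 = 0.01, root_value = log10(50),
                        lambda_signal = lambda_signal)
  # dominant frequency is allometric (larger animals call lower); the other
  # four traits carry phylogenetic signal with no size dependence
  e_df <- simulate_bm(tree, 0.02, lambda_signal = lambda_signal)
  logdf <- 4.8 - 1.0 * logsvl + e_df
  cva_v <- pmax(0.35 + simulate_bm(tree, 0.005, lambda_signal = lambda_signal),
                0.02)
  logsf <- 0.5 + simulate_bm(tree, 0.02, lambda_signal = lambda_signal)
  logsi <- -0.7 + simulate_bm(tree, 0.02, lambda_signal = lambda_signal)
  logton <- -1.2 + simulate_bm(tree, 0.01, lambda_signal = lambda_signal)
  traits <- data.frame(species_id = tree$tip.label,
                       clade = unname(clades[tree$tip.label]),
                       cva = unname(cva_v[tree$tip.label]),
                       logdf = unname(logdf[tree$tip.label]),
                       logsf = unname(logsf[tree$tip.label]),
                       logsi = unname(logsi[tree$tip.label]),
                       logton = unname(logton[tree$tip.label]),
                       logsvl = unname(logsvl[tree$tip.label]),
                       stringsAsFactors = FALSE)
  metadata <- data.frame(species_id = traits$species_id,
                         clade = traits$clade,
                         svl_mm = 10^traits$logsvl,
                         stringsAsFactors = FALSE)
  seq_tree <- tree
  seq_tree$edge.length <- seq_tree$edge.length *
    tree_scale / max(ape::node.depth.edgelength(tree))
  alignment <- simulate_jc_sequences(seq_tree, seq_length)
  recordings <- NULL
  if (audio) {
    recordings <- lapply(seq_len(n_species), function(i) {
      synth_call(f0 = min(10^traits$logdf[i], 9000),
                 n_harmonics = 5, rolloff_db = 8, am_rate = 15,
                 am_depth = min(traits$cva[i] * sqrt(2), 0.95),
                 noise_snr = 25, duration = 1, sample_rate = 22050,
                 species_id = traits$species_id[i],
                 recording_id = paste0(traits$species_id[i], "_r1"))
    })
  }
  truth <- list(n_species = n_species, n_clades = n_clades,
                birth_rate = birth_rate, lambda_signal = lambda_signal,
                allometry = list(trait = "logdf", a = 4.8, b = -1.0),
                seq_length = seq_length, tree_scale = tree_scale,
                seed = seed,
                clade_sizes = as.list(table(traits$clade)))
  study <- list(tree = tree, metadata = metadata, traits = traits,
                alignment = alignment, recordings = recordings,
                truth = truth)
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' Write a simulated study to disk in the formats the pipeline reads
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(study$tree, file.path(dir, "tree.nwk"))
  ape::write.FASTA(study$alignment, file.path(dir, "alignment.fasta"))
  md <- study$metadata
  if (!is.null(study$recordings)) {
    audio_dir <- file.path(dir, "audio")
    dir.create(audio_dir, showWarnings = FALSE)
    md$wav_paths <- vapply(study$recordings, function(r) {
      p <- file.path(audio_dir, paste0(r$recording_id, ".wav"))
      write_wav(r, p)
      p
    }, character(1))
  }
  utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$traits, file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
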