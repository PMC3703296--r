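#' Short-time frame decomposition of a recording
#'
#' Slices a recording into overlapping analysis frames and computes, per
#' frame, the root-mean-square amplitude (on the raw samples) and the
#' one-sided magnitude spectrum of the Hann-windowed frame. The FFT length
#' equals the window length (no zero padding); bin k maps to frequency
#' `k * sample_rate / n_fft`.
#'
#' @param rec A `recording` object.
#' @param window_ms Analysis window length in milliseconds (default 40).
#' @param hop_ms Hop between frame starts in milliseconds (default 20).
#' @return A `frame_series` object: list with `frame_rms` (length m),
#'   `frame_spectra` (bins x m matrix of linear magnitudes), `bin_freqs`
#'   (Hz), `window_ms`, `hop_ms`, `sample_rate`.
#' @export
compute_frames <- function(rec, window_ms = 40, hop_ms = 20) {
  stopifnot(inherits(rec, "recording"), window_ms > 0, hop_ms > 0)
  sr <- rec$sample_rate
  win <- as.integer(round(window_ms * sr / 1000))
  hop <- as.integer(round(hop_ms * sr / 1000))
  x <- rec$samples
  if (length(x) < win)
    stop("recording shorter than one analysis window (",
         length(x), " < ", win, " samples)")
  m <- (length(x) - win) %/% hop + 1L
  starts <- (seq_len(m) - 1L) * hop + 1L
  frames <- vapply(starts, function(s) x[s:(s + win - 1L)], numeric(win))
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))
  n_bins <- win %/% 2L + 1L
  spec <- abs(stats::mvfft(frames * hann))[seq_len(n_bins), , drop = FALSE]
  structure(list(
    frame_rms = sqrt(colMeans(frames^2)),
    frame_spectra = spec,
    bin_freqs = (seq_len(n_bins) - 1L) * sr / win,
    window_ms = window_ms, hop_ms = hop_ms, sample_rate = sr),
    class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d frames (%g/%g ms window/hop), %d bins\n",
              length(x$frame_rms), x$window_ms, x$hop_ms,
              nrow(x$frame_spectra)))
  invisible(x)
}

# frames with RMS below this are treated as silence for spectral descriptors
.silence_rms <- 1e-6

.nonsilent <- function(fs) which(fs$frame_rms >= .silence_rms)

#' Coefficient of variation of frame RMS amplitude (CVA)
#'
#' Standard deviation of the per-frame RMS envelope divided by its mean.
#' A gain-invariant measure of amplitude modulation; for a sinusoidally
#' modulated envelope of depth m it approaches m/sqrt(2). All frames enter
#' the computation, including silent ones (envelope variation is the
#' measurand).
#'
#' @param fs A `frame_series`.
#' @return Non-negative scalar.
#' @export
cva <- function(fs) {
  stopifnot(inherits(fs, "frame_series"))
  if (length(fs$frame_rms) < 2) stop("CVA needs at least 2 frames")
  mu <- mean(fs$frame_rms)
  if (mu <= 0) stop("CVA undefined for an all-zero signal")
  stats::sd(fs$frame_rms) / mu
}

#' Dominant frequency (DF)
#'
#' Frequency of the maximal-magnitude spectral bin, per frame, averaged over
#' all non-silent frames.
#'
#' @param fs A `frame_series`.
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(fs) {
  stopifnot(inherits(fs, "frame_series"))
  keep <- .nonsilent(fs)
  if (length(keep) == 0) stop("dominant frequency undefined: all frames silent")
  idx <- apply(fs$frame_spectra[, keep, drop = FALSE], 2, which.max)
  mean(fs$bin_freqs[idx])
}

#' Spectral flux (SF)
#'
#' Euclidean distance between consecutive frame magnitude spectra, averaged
#' over all consecutive frame pairs. The only gain-sensitive descriptor:
#' it scales linearly with a global gain.
#'
#' @param fs A `frame_series`.
#' @return Non-negative scalar (linear magnitude units).
#' @export
spectral_flux <- function(fs) {
  stopifnot(inherits(fs, "frame_series"))
  m <- ncol(fs$frame_spectra)
  if (m < 2) stop("spectral flux needs at least 2 frames")
  d <- fs$frame_spectra[, -1, drop = FALSE] - fs$frame_spectra[, -m, drop = FALSE]
  mean(sqrt(colSums(d^2)))
}

# local maxima of a magnitude spectrum above a relative dB floor
.spectral_peaks <- function(a, floor_db = -40) {
  n <- length(a)
  if (n < 3) return(integer(0))
  thr <- max(a) * 10^(floor_db / 20)
  i <- 2:(n - 1)
  which(a[i] > a[i - 1] & a[i] >= a[i + 1] & a[i] >= thr) + 1L
}

#' Spectral irregularity (SI)
#'
#' Per frame, the partials are taken as spectral peaks (local maxima within
#' 40 dB of the frame maximum). The irregularity is the sum of squared
#' amplitude differences between adjoining partials, with an implicit
#' trailing zero, normalized by the summed squared partial amplitudes
#' (so a lone partial scores 1 and an equal-amplitude comb of many partials
#' tends to 0). Averaged over non-silent frames. Set `normalized = FALSE`
#' for the raw (gain-dependent) sum of squared differences.
#'
#' @param fs A `frame_series`.
#' @param normalized Divide by the summed squared partial amplitudes
#'   (default TRUE; makes SI gain-invariant).
#' @return Non-negative scalar.
#' @export
spectral_irregularity <- function(fs, normalized = TRUE) {
  stopifnot(inherits(fs, "frame_series"))
  keep <- .nonsilent(fs)
  if (length(keep) == 0) stop("spectral irregularity undefined: all frames silent")
  vals <- vapply(keep, function(j) {
    a <- fs$frame_spectra[, j]
    pk <- a[.spectral_peaks(a)]
    if (length(pk) == 0) return(NA_real_)
    num <- sum(diff(c(pk, 0))^2)
    if (normalized) num / sum(pk^2) else num
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) stop("spectral irregularity undefined: no peaks found")
  mean(vals)
}

#' Spectral flatness / tonality (TON)
#'
#' Ratio of geometric to arithmetic mean of the power spectrum, per frame,
#' averaged over non-silent frames. Values near 1 indicate noise-like flat
#' spectra; values near 0 indicate spiky, tonal spectra. Power bins are
#' floored at 1e-12 times the frame maximum before the geometric mean.
#'
#' @param fs A `frame_series`.
#' @return Scalar in (0, 1].
#' @export
tonality <- function(fs) {
  stopifnot(inherits(fs, "frame_series"))
  keep <- .nonsilent(fs)
  if (length(keep) == 0) stop("tonality undefined: all frames silent")
  vals <- vapply(keep, function(j) {
    p <- fs$frame_spectra[, j]^2
    p <- pmax(p, max(p) * 1e-12)
    exp(mean(log(p))) / mean(p)
  }, numeric(1))
  mean(vals)
}

#' All five acoustic descriptors of a recording
#'
#' @param rec A `recording`.
#' @param window_ms,hop_ms Frame parameters passed to [compute_frames()].
#' @return Named numeric vector `c(cva, df, sf, si, ton)` on the linear
#'   (untransformed) scale.
#' @export
extract_features <- function(rec, window_ms = 40, hop_ms = 20) {
  fs <- compute_frames(rec, window_ms, hop_ms)
  c(cva = cva(fs), df = dominant_frequency(fs), sf = spectral_flux(fs),
    si = spectral_irregularity(fs), ton = tonality(fs))
}

#' Species-level trait table from per-recording features
#'
#' Averages the per-recording descriptor values for each species on the
#' linear scale (species have one or two recordings), then log10-transforms
#' DF, SF, SI, TON and SVL; CVA is left untransformed.
#'
#' @param recordings List of `recording` objects with `species_id` set, or a
#'   data frame of per-recording feature rows with columns
#'   `species_id, cva, df, sf, si, ton`.
#' @param metadata Data frame with columns `species_id`, `clade`, `svl_mm`.
#' @param window_ms,hop_ms Frame parameters (used when `recordings` is a
#'   list of `recording` objects).
#' @return Data frame with columns
#'   `species_id, clade, cva, logdf, logsf, logsi, logton, logsvl`.
#' @export
species_trait_table <- function(recordings, metadata,
                                window_ms = 40, hop_ms = 20) {
  stopifnot(all(c("species_id", "clade", "svl_mm") %in% names(metadata)))
  feats <- if (is.data.frame(recordings)) {
    recordings
  } else {
    do.call(rbind, lapply(recordings, function(r) {
      stopifnot(inherits(r, "recording"))
      data.frame(species_id = r$species_id,
                 t(extract_features(r, window_ms, hop_ms)))
    }))
  }
  missing_rec <- setdiff(metadata$species_id, feats$species_id)
  if (length(missing_rec))
    stop("species without recordings: ", paste(missing_rec, collapse = ", "))
  bad_svl <- metadata$species_id[!is.finite(metadata$svl_mm) |
                                 metadata$svl_mm <= 0]
  if (length(bad_svl))
    stop("species with missing or non-positive SVL: ",
         paste(bad_svl, collapse = ", "))
  agg <- stats::aggregate(feats[c("cva", "df", "sf", "si", "ton")],
                          by = list(species_id = feats$species_id), FUN = mean)
  tab <- merge(metadata[c("species_id", "clade", "svl_mm")], agg,
               by = "species_id")
  data.frame(species_id = tab$species_id, clade = tab$clade,
             cva = tab$cva, logdf = log10(tab$df), logsf = log10(tab$sf),
             logsi = log10(tab$si), logton = log10(tab$ton),
             logsvl = log10(tab$svl_mm), stringsAsFactors = FALSE)
}
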