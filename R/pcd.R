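#' Per-session passive cavitation detection record
#'
#' Bundles the hydrophone voltage traces recorded during each FUS pulse of
#' one sonication session with their common sampling rate. All pulses must
#' have the same length; the microbubble-activation metric is computed from
#' the pulses appended in acquisition order.
#'
#' @param pulses list of numeric vectors (volts), one per pulse, equal
#'   lengths.
#' @param fs sampling rate in Hz.
#' @return an object of class `waveform_record`.
#' @export
waveform_record <- function(pulses, fs) {
  if (!is.list(pulses) || length(pulses) == 0L) {
    stop_fustx("'pulses' must be a nonempty list of numeric vectors")
  }
  lens <- lengths(pulses)
  if (any(lens == 0L)) stop_fustx("pulses must be nonempty")
  if (length(unique(lens)) != 1L) stop_fustx("all pulses must have the same length")
  if (!all(vapply(pulses, is.numeric, logical(1)))) {
    stop_fustx("pulses must be numeric")
  }
  check_number(fs, "fs", lower = .Machine$double.eps)
  structure(list(pulses = pulses, fs = fs), class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat(sprintf("waveform_record: %d pulses x %d samples @ %.4g Hz (%.3g s total)\n",
              length(x$pulses), length(x$pulses[[1]]), x$fs,
              length(x$pulses) * length(x$pulses[[1]]) / x$fs))
  invisible(x)
}

#' Spectral configuration for the microbubble-activation metric
#'
#' Defines the two 200 Hz analysis bands of the MBA ratio: one centred on
#' the second harmonic of the FUS drive (2.22 MHz by default) where the
#' hydrophone is sensitive, and one in a broadband reference region where it
#' is not. The reference centre is hardware-specific and therefore has no
#' default.
#'
#' @param reference_center reference band centre frequency (Hz); required.
#' @param harmonic_center harmonic band centre frequency (Hz).
#' @param band_width width of both bands (Hz).
#' @param n_peaks number of top peaks averaged per band.
#' @param window FFT window: `"rectangular"` (default) or `"hann"`.
#' @return an object of class `spectral_config`.
#' @export
spectral_config <- function(reference_center, harmonic_center = 2.22e6,
                            band_width = 200, n_peaks = 5L,
                            window = c("rectangular", "hann")) {
  check_number(reference_center, "reference_center", lower = .Machine$double.eps)
  check_number(harmonic_center, "harmonic_center", lower = .Machine$double.eps)
  check_number(band_width, "band_width", lower = .Machine$double.eps)
  n_peaks <- check_count(n_peaks, "n_peaks", lower = 1L)
  window <- match.arg(window)
  if (abs(harmonic_center - reference_center) < band_width) {
    stop_fustx("harmonic and reference bands must be disjoint")
  }
  structure(list(harmonic_center = harmonic_center,
                 reference_center = reference_center,
                 band_width = band_width, n_peaks = n_peaks, window = window),
            class = "spectral_config")
}

#' One-sided magnitude spectrum of appended pulses
#'
#' Concatenates the session's pulses in acquisition order into a single
#' series and returns its one-sided FFT magnitude spectrum. Amplitudes are
#' scaled so that a full-scale sinusoid at a bin-aligned frequency appears
#' with its time-domain amplitude. Bin width is `fs / total_samples`.
#'
#' @param rec a [waveform_record()].
#' @param window `"rectangular"` (no window, default) or `"hann"`, applied
#'   to the appended series before the FFT.
#' @return a list of class `fus_spectrum` with `freq` (Hz), `amp`
#'   (one-sided magnitude), `fs`, and `n` (total samples).
#' @export
appended_spectrum <- function(rec, window = c("rectangular", "hann")) {
  stopifnot(inherits(rec, "waveform_record"))
  window <- match.arg(window)
  x <- unlist(rec$pulses, use.names = FALSE)
  n <- length(x)
  if (n == 0L) stop_fustx("empty waveform record")
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)
    # coherent gain correction keeps a bin-aligned tone at its amplitude
    x <- x * w / mean(w)
  }
  nh <- n %/% 2 + 1L
  amp <- Mod(stats::fft(x))[seq_len(nh)] * (2 / n)
  amp[1L] <- amp[1L] / 2
  if (n %% 2L == 0L) amp[nh] <- amp[nh] / 2
  structure(list(freq = (seq_len(nh) - 1) * rec$fs / n, amp = amp,
                 fs = rec$fs, n = n),
            class = "fus_spectrum")
}

band_indices <- function(spectrum, center, width) {
  which(spectrum$freq >= center - width / 2 & spectrum$freq <= center + width / 2)
}

#' Top peak amplitudes within a spectral band
#'
#' Finds the `k` largest local-maximum amplitudes inside the band
#' `[center - width/2, center + width/2]`. A local maximum is a bin strictly
#' larger than both spectral neighbours. If the band holds fewer than `k`
#' local maxima (e.g. a flat or smooth band), the result is padded with the
#' largest remaining bin amplitudes, so ties and plateaus never fail.
#'
#' @param spectrum a `fus_spectrum` from [appended_spectrum()].
#' @param center band centre (Hz).
#' @param width band width (Hz).
#' @param k number of peak amplitudes to return.
#' @return numeric vector of `k` amplitudes in descending order.
#' @export
band_top_peaks <- function(spectrum, center, width, k = 5L) {
  stopifnot(inherits(spectrum, "fus_spectrum"))
  k <- check_count(k, "k", lower = 1L)
  idx <- band_indices(spectrum, center, width)
  if (length(idx) < k) {
    need <- ceiling(k * spectrum$fs / width)
    stop_fustx(sprintf(paste0(
      "band [%g, %g] Hz holds only %d bins (< %d): acquire at least %d total ",
      "samples (bin width <= %g Hz) for this band width"),
      center - width / 2, center + width / 2, length(idx), k, need, width / k))
  }
  amp <- spectrum$amp
  n <- length(amp)
  is_max <- vapply(idx, function(i) {
    left <- if (i > 1L) amp[i - 1L] else -Inf
    right <- if (i < n) amp[i + 1L] else -Inf
    amp[i] > left && amp[i] > right
  }, logical(1))
  peaks <- sort(amp[idx[is_max]], decreasing = TRUE)
  if (length(peaks) >= k) return(peaks[seq_len(k)])
  rest <- sort(amp[idx[!is_max]], decreasing = TRUE)
  sort(c(peaks, rest[seq_len(k - length(peaks))]), decreasing = TRUE)
}

#' Microbubble activation (MBA) from a cavitation record
#'
#' MBA is the ratio of the mean amplitude of the top `n_peaks` peaks in a
#' narrow band around the second harmonic of the FUS drive to the same
#' statistic in a broadband reference band where the hydrophone is
#' insensitive. It is dimensionless and scale invariant: noise-only records
#' give MBA near 1, and stronger harmonic emissions (stronger microbubble
#' activation) push it above 1.
#'
#' @param rec a [waveform_record()].
#' @param cfg a [spectral_config()].
#' @return a list of class `mba_result` with `mba`, `harmonic_top_mean`,
#'   `reference_top_mean`, `n_bins_harmonic`, `n_bins_reference`.
#' @export
compute_mba <- function(rec, cfg) {
  stopifnot(inherits(cfg, "spectral_config"))
  spec <- appended_spectrum(rec, window = cfg$window)
  nyq <- rec$fs / 2
  for (ctr in c(cfg$harmonic_center, cfg$reference_center)) {
    if (ctr + cfg$band_width / 2 >= nyq) {
      stop_fustx(sprintf("band at %g Hz exceeds the Nyquist frequency %g Hz",
                         ctr, nyq))
    }
  }
  hpk <- band_top_peaks(spec, cfg$harmonic_center, cfg$band_width, cfg$n_peaks)
  rpk <- band_top_peaks(spec, cfg$reference_center, cfg$band_width, cfg$n_peaks)
  rmean <- mean(rpk)
  if (rmean <= 0) {
    stop_fustx("reference band mean amplitude is zero; degenerate noiseless input")
  }
  structure(list(
    mba = mean(hpk) / rmean,
    harmonic_top_mean = mean(hpk),
    reference_top_mean = rmean,
    n_bins_harmonic = length(band_indices(spec, cfg$harmonic_center, cfg$band_width)),
    n_bins_reference = length(band_indices(spec, cfg$reference_center, cfg$band_width))
  ), class = "mba_result")
}

#' @export
print.mba_result <- function(x, ...) {
  cat(sprintf("MBA = %.4g (harmonic %.4g / reference %.4g; %d/%d band bins)\n",
              x$mba, x$harmonic_top_mean, x$reference_top_mean,
              x$n_bins_harmonic, x$n_bins_reference))
  invisible(x)
}
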