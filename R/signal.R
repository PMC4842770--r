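#' Multichannel iEEG recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz, > 0.
#' @param events integer vector of stimulus-onset sample indices (1-based),
#'   all within the recording.
#' @param channel_names optional channel labels.
#' @return object of class \code{recording}.
#' @export
recording <- function(data, fs, events = integer(0), channel_names = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  events <- as.integer(events)
  if (length(events) > 0 &&
      (min(events) < 1L || max(events) > ncol(data)))
    stop("events must lie within [1, samples]")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(data)))
  structure(list(data = data, fs = as.numeric(fs), events = events,
                 channel_names = channel_names),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("recording: %d channel(s) x %d samples at %g Hz (%.1f s), %d event(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              length(x$events)))
  invisible(x)
}

#' Canonical iEEG frequency bands
#'
#' Delta 1-4 Hz, Theta 4-8 Hz, Alpha 8-16 Hz, Beta 16-30 Hz, Low Gamma
#' 30-80 Hz, High Gamma 80-250 Hz.
#'
#' @return named list of \code{c(lo, hi)} pairs in Hz.
#' @export
ieeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 16),
       beta = c(16, 30), low_gamma = c(30, 80), high_gamma = c(80, 250))
}

resolve_band <- function(band, fs) {
  if (is.character(band)) {
    bands <- ieeg_bands()
    if (!band %in% names(bands))
      stop("unknown band '", band, "'; known: ",
           paste(names(bands), collapse = ", "))
    band <- bands[[band]]
  }
  band <- as.numeric(band)
  if (length(band) != 2 || band[1] <= 0 || band[1] >= band[2])
    stop("domain error: band must be c(lo, hi) with 0 < lo < hi")
  if (band[2] >= fs / 2)
    stop("Nyquist error: band upper edge ", band[2],
         " Hz must be below fs/2 = ", fs / 2, " Hz")
  band
}

# forward-backward Butterworth with odd-reflection padding at both ends,
# which keeps the effective impulse response symmetric (zero phase) well
# away from machine precision
filtfilt_padded <- function(b_a, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(b_a, c(pre, x, post))
  y[(npad + 1):(npad + n)]
}

bandpass_matrix <- function(data, fs, lo, hi, order = 4) {
  flt <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  npad <- as.integer(min(ncol(data) - 1L, ceiling(3 * fs / lo)))
  t(apply(data, 1L, function(ch) filtfilt_padded(flt, ch, npad)))
}

#' Zero-phase band-pass filter
#'
#' Filters every channel with a Butterworth band-pass (default 4th order)
#' applied forward and backward, so the net phase response is zero and ERP
#' latencies are not shifted. Signal edges are padded by odd reflection
#' before filtering to suppress end transients. The defaults (0.5-250 Hz)
#' are the usual broad-band cleanup applied before epoching.
#'
#' @param rec a \code{recording} (or channels x samples matrix with
#'   \code{fs} supplied).
#' @param lo,hi band edges in Hz, 0 < lo < hi < fs/2.
#' @param order Butterworth order of each pass.
#' @param fs sampling rate, required when \code{rec} is a bare matrix.
#' @return a \code{recording} with filtered data (events preserved).
#' @export
bandpass_zero_phase <- function(rec, lo = 0.5, hi = 250, order = 4,
                                fs = NULL) {
  if (!inherits(rec, "recording")) {
    if (is.null(fs)) stop("fs required when rec is a matrix")
    rec <- recording(rec, fs)
  }
  band <- resolve_band(c(lo, hi), rec$fs)
  out <- bandpass_matrix(rec$data, rec$fs, band[1], band[2], order)
  recording(out, rec$fs, rec$events, rec$channel_names)
}

#' Segment a recording into stimulus-locked epochs
#'
#' Extracts the half-open window \code{[onset + pre_ms, onset + post_ms)}
#' around every event, so each epoch spans exactly \code{post_ms - pre_ms}
#' milliseconds, i.e. \code{(post_ms - pre_ms) * fs / 1000} samples. Events
#' too close to the recording edges for a full window are skipped with a
#' warning.
#'
#' @param rec a \code{recording} with events.
#' @param pre_ms window start relative to onset in ms (negative = before
#'   onset); default -800.
#' @param post_ms window end relative to onset in ms; default 3500.
#' @return object of class \code{epoch_set}: list with \code{data} (trials x
#'   channels x samples array), \code{fs}, \code{window} = c(pre_ms,
#'   post_ms) and \code{channel_names}.
#' @export
segment_epochs <- function(rec, pre_ms = -800, post_ms = 3500) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  if (pre_ms >= post_ms) stop("pre_ms must be < post_ms")
  ns <- round((post_ms - pre_ms) * rec$fs / 1000)
  off <- round(pre_ms * rec$fs / 1000)
  nsamp <- ncol(rec$data)
  starts <- rec$events + off
  ok <- starts >= 1L & (starts + ns - 1L) <= nsamp
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; skipped")
  starts <- starts[ok]
  arr <- array(NA_real_, c(length(starts), nrow(rec$data), ns))
  for (tr in seq_along(starts))
    arr[tr, , ] <- rec$data[, starts[tr]:(starts[tr] + ns - 1L)]
  structure(list(data = arr, fs = rec$fs, window = c(pre_ms, post_ms),
                 channel_names = rec$channel_names),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("epoch_set: %d trial(s) x %d channel(s) x %d samples, window [%g, %g] ms at %g Hz\n",
              d[1], d[2], d[3], x$window[1], x$window[2], x$fs))
  invisible(x)
}

#' Drop epochs with apparent amplitude artifacts
#'
#' A deterministic surrogate for manual "apparent noise" rejection: an epoch
#' is dropped when, on any channel, its peak-to-peak amplitude exceeds
#' \code{amp_thresh_sd} times that channel's robust standard deviation
#' (median absolute deviation x 1.4826) computed over that channel's samples
#' pooled across all epochs. Surviving epochs are returned unchanged.
#'
#' @param epochs an \code{epoch_set}.
#' @param amp_thresh_sd rejection threshold in robust-SD units, > 0;
#'   default 6. \code{Inf} keeps everything.
#' @return the \code{epoch_set} restricted to surviving trials; the dropped
#'   trial indices are recorded in attribute \code{"dropped"}.
#' @export
reject_epochs <- function(epochs, amp_thresh_sd = 6) {
  if (!is.numeric(amp_thresh_sd) || amp_thresh_sd <= 0)
    stop("amp_thresh_sd must be > 0")
  d <- dim(epochs$data)
  if (d[1] == 0) return(epochs)
  drop <- rep(FALSE, d[1])
  for (ch in seq_len(d[2])) {
    pooled <- as.vector(epochs$data[, ch, ])
    rsd <- stats::mad(pooled)
    if (rsd == 0) next
    p2p <- apply(epochs$data[, ch, , drop = FALSE], 1L,
                 function(x) max(x) - min(x))
    drop <- drop | p2p > amp_thresh_sd * rsd
  }
  out <- epochs
  out$data <- epochs$data[!drop, , , drop = FALSE]
  attr(out, "dropped") <- which(drop)
  out
}

#' Average stimulus-aligned epochs into an ERP
#'
#' Pointwise arithmetic mean over trials.
#'
#' @param epochs an \code{epoch_set} with at least one trial.
#' @return channels x samples numeric matrix (the event-related potential).
#' @export
average_erp <- function(epochs) {
  d <- dim(epochs$data)
  if (d[1] < 1) stop("empty error: no trials to average")
  erp <- apply(epochs$data, c(2L, 3L), mean)
  rownames(erp) <- epochs$channel_names
  erp
}

#' Instantaneous phase via the analytic signal
#'
#' One-sided FFT construction of the analytic signal; returns its argument.
#'
#' @param x numeric vector.
#' @return phase in radians, same length as \code{x}.
#' @export
analytic_phase <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Arg(stats::fft(X * h, inverse = TRUE) / n)
}

# channels x samples phases -> PLV matrix
plv_from_phases <- function(phases) {
  Z <- exp(1i * phases)
  M <- Mod(Z %*% Conj(t(Z))) / ncol(phases)
  dimnames(M) <- NULL
  M <- (M + t(M)) / 2
  M[M > 1] <- 1
  diag(M) <- 1
  M
}

#' Phase-locking-value connectivity matrix
#'
#' For every channel pair, band-passes the signals (zero phase), extracts
#' instantaneous phases from the analytic signal, and computes the
#' phase-locking value \code{PLV = |mean_t exp(i (phi_i - phi_j))|}: 0 for
#' no phase coupling, 1 for a constant phase lag. The first and last 10% of
#' samples of each segment are discarded before averaging to avoid filter
#' and Hilbert edge effects. For an \code{epoch_set}, phases are trimmed per
#' trial and concatenated across trials before averaging (per-trial
#' averaging is available via \code{per_trial = TRUE}).
#'
#' The result is symmetric with unit diagonal and entries in [0, 1], is
#' invariant to amplitude scaling of any channel and to a common phase
#' offset, and can be written with \code{\link{write_table_file}} as a
#' correlation-matrix file.
#'
#' @param x a \code{recording}, an \code{epoch_set}, or a channels x samples
#'   matrix (then supply \code{fs}).
#' @param band band name (see \code{\link{ieeg_bands}}) or \code{c(lo, hi)}
#'   in Hz; \code{NULL} skips filtering and uses raw analytic phases.
#' @param fs sampling rate for matrix input.
#' @param trim fraction of samples discarded at each segment end (default
#'   0.1).
#' @param order Butterworth order for the band-pass.
#' @param per_trial average PLV per trial instead of concatenating phases.
#' @return n x n symmetric PLV matrix.
#' @export
plv_matrix <- function(x, band = NULL, fs = NULL, trim = 0.1, order = 4,
                       per_trial = FALSE) {
  if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    if (d[1] < 1) stop("empty error: no trials")
    segs <- lapply(seq_len(d[1]), function(tr)
      matrix(x$data[tr, , ], nrow = d[2]))
    fs <- x$fs
  } else if (inherits(x, "recording")) {
    segs <- list(x$data)
    fs <- x$fs
  } else {
    if (is.null(fs)) stop("fs required for matrix input")
    segs <- list(as.matrix(x))
  }
  nch <- nrow(segs[[1]])
  if (nch < 2) stop("need at least 2 channels")
  if (!is.null(band)) band <- resolve_band(band, fs)
  seg_phases <- lapply(segs, function(s) {
    if (!is.null(band)) s <- bandpass_matrix(s, fs, band[1], band[2], order)
    ph <- t(apply(s, 1L, analytic_phase))
    ncut <- floor(trim * ncol(ph))
    keep <- (ncut + 1):(ncol(ph) - ncut)
    ph[, keep, drop = FALSE]
  })
  if (per_trial && length(seg_phases) > 1) {
    mats <- lapply(seg_phases, plv_from_phases)
    M <- Reduce(`+`, mats) / length(mats)
    diag(M) <- 1
    M
  } else {
    plv_from_phases(do.call(cbind, seg_phases))
  }
}
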