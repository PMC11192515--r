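#' Zero-phase band-pass filter and integer-factor downsampling
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass — a
#' second-order high-pass at `band[1]` cascaded with a `lp_order`-th order
#' low-pass at `band[2]` — then decimates by the integer factor
#' `fs / fs_new`. The low-pass doubles as the anti-alias filter, so `band[2]`
#' must lie below the new Nyquist frequency.
#'
#' @param epoch Matrix (sensors x samples) or numeric vector.
#' @param band Length-2 numeric `(low, high)` in Hz.
#' @param fs Sampling rate of `epoch`, Hz (taken from `attr(epoch, "fs")` if
#'   missing).
#' @param fs_new Target sampling rate, Hz; `fs / fs_new` must be an integer.
#' @param lp_order Low-pass Butterworth order (default 10; forward-backward
#'   application squares the magnitude response).
#' @return Filtered, decimated matrix with `fs` attribute set to `fs_new`.
#' @export
filter_and_downsample <- function(epoch, band, fs = attr(epoch, "fs"), fs_new,
                                  lp_order = 10L) {
  vec <- is.null(dim(epoch))
  x <- if (vec) matrix(epoch, nrow = 1L) else as.matrix(epoch)
  if (is.null(fs)) stop("sampling rate `fs` is required", call. = FALSE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  stopifnot_scalar_number(fs_new, "fs_new", positive = TRUE)
  if (length(band) != 2L || band[1] >= band[2]) {
    stop("`band` must be (low, high) with low < high", call. = FALSE)
  }
  if (band[1] <= 0) stop("band low edge must be > 0", call. = FALSE)
  if (fs_new > fs) stop("fs_new must not exceed fs", call. = FALSE)
  q <- fs / fs_new
  if (abs(q - round(q)) > 1e-9) {
    stop(sprintf("fs / fs_new = %.4f is not an integer decimation factor", q), call. = FALSE)
  }
  q <- as.integer(round(q))
  if (band[2] >= fs_new / 2) stop("band high edge must be below fs_new / 2", call. = FALSE)

  hp <- signal::butter(2, band[1] / (fs / 2), type = "high")
  lp <- signal::butter(lp_order, band[2] / (fs / 2), type = "low")
  y <- t(apply(x, 1L, function(r) {
    signal::filtfilt(lp, signal::filtfilt(hp, r))
  }))
  y <- y[, seq(1L, ncol(y), by = q), drop = FALSE]
  rownames(y) <- rownames(x)
  if (vec) {
    y <- drop(y)
  }
  attr(y, "fs") <- fs_new
  attr(y, "t0") <- attr(epoch, "t0") %||% 0
  y
}

#' Average epochs over trials
#'
#' Arithmetic mean across the trial axis (coherent averaging: phase-locked
#' components survive, noise power shrinks by the trial count).
#'
#' @param trials An `epoch_set`, or a trials x sensors x samples array.
#' @return Matrix (sensors x samples); `fs` attribute preserved when known.
#' @export
average_epochs <- function(trials) {
  fs <- NULL
  if (inherits(trials, "epoch_set")) {
    fs <- trials$fs
    trials <- trials$data
  }
  if (is.matrix(trials)) trials <- array(trials, dim = c(1L, dim(trials)),
                                         dimnames = c(list(NULL), dimnames(trials)))
  if (length(dim(trials)) != 3L) stop("`trials` must be a 3-d array (trial x sensor x time)", call. = FALSE)
  if (dim(trials)[1] < 1L) stop("at least one trial is required", call. = FALSE)
  if (anyNA(trials) || !all(is.finite(trials))) stop("non-finite values in trials", call. = FALSE)
  avg <- colMeans(trials)       # collapses the first (trial) dimension
  dimnames(avg) <- dimnames(trials)[2:3]
  if (!is.null(fs)) attr(avg, "fs") <- fs
  avg
}

#' One-sided amplitude spectrum of an epoch
#'
#' Computes the FFT and normalizes amplitudes to `2|X_k|/N` for `k > 0`
#' (`|X_0|/N` at DC), so a bin-aligned sinusoid of amplitude `A` reads exactly
#' `A` at its bin. Resolution is `fs/N = 1/duration`.
#'
#' @param epoch Matrix (sensors x samples) or vector.
#' @param fs Sampling rate in Hz (taken from `attr(epoch, "fs")` if missing).
#' @return An `amplitude_spectrum`: `amplitudes` (sensors x bins), `freqs`,
#'   `resolution`, `corrected = FALSE`.
#' @export
compute_spectrum <- function(epoch, fs = attr(epoch, "fs")) {
  vec <- is.null(dim(epoch))
  x <- if (vec) matrix(epoch, nrow = 1L) else as.matrix(epoch)
  if (is.null(fs)) stop("sampling rate `fs` is required", call. = FALSE)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  n <- ncol(x)
  if (n < 2L) stop("epoch must have at least 2 samples", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x))) stop("non-finite values in epoch", call. = FALSE)

  X <- stats::mvfft(t(x))                      # columns = sensors
  n_bins <- floor(n / 2) + 1L
  amp <- 2 * Mod(t(X[seq_len(n_bins), , drop = FALSE])) / n
  amp[, 1L] <- amp[, 1L] / 2                   # DC bin is not doubled
  rownames(amp) <- rownames(x)
  structure(list(
    amplitudes = amp,
    freqs = (seq_len(n_bins) - 1L) * fs / n,
    resolution = fs / n,
    corrected = FALSE
  ), class = "amplitude_spectrum")
}

#' @export
print.amplitude_spectrum <- function(x, ...) {
  cat(sprintf(
    "<amplitude_spectrum> %d sensor(s) x %d bins, resolution %.4f Hz, %s\n",
    nrow(x$amplitudes), ncol(x$amplitudes), x$resolution,
    if (x$corrected) "baseline-corrected" else "uncorrected"
  ))
  invisible(x)
}

#' Combine planar gradiometer pairs
#'
#' Replaces the two sensors of each planar pair with their root-sum-of-squares
#' per frequency bin — the conventional scalar magnitude of the two orthogonal
#' planar gradients.
#'
#' @param spectrum An `amplitude_spectrum` whose rows include the gradiometers.
#' @param layout The `sensor_layout` providing `pair_id`.
#' @return An `amplitude_spectrum` with one row per pair (rownames = pair_id).
#' @export
combine_planar <- function(spectrum, layout) {
  layout <- validate_sensor_layout(layout)
  g <- layout[layout$kind == "grad", , drop = FALSE]
  pids <- unique(g$pair_id)
  if (!length(pids) || any(!nzchar(pids))) {
    stop("layout gradiometers must all carry a pair_id", call. = FALSE)
  }
  amp <- spectrum$amplitudes
  out <- matrix(NA_real_, nrow = length(pids), ncol = ncol(amp),
                dimnames = list(pids, colnames(amp)))
  for (i in seq_along(pids)) {
    members <- g$sensor_id[g$pair_id == pids[i]]
    if (length(members) != 2L || !all(members %in% rownames(amp))) {
      stop("incomplete gradiometer pair in spectrum: ", pids[i], call. = FALSE)
    }
    out[i, ] <- sqrt(amp[members[1], ]^2 + amp[members[2], ]^2)
  }
  structure(list(
    amplitudes = out, freqs = spectrum$freqs,
    resolution = spectrum$resolution, corrected = spectrum$corrected
  ), class = "amplitude_spectrum")
}

#' Baseline-correction configuration
#'
#' Parameters of the surrounding-bin correction: from each frequency bin the
#' mean of 2 x `n_used_per_side` neighbouring bins is subtracted, where per
#' side the `n_adjacent_excluded` immediately adjacent bins are skipped and —
#' when `exclude_extremes` — the single largest and single smallest value of
#' the pooled candidate set are dropped before averaging. The defaults
#' reproduce the convention of subtracting the mean of 20 surrounding bins,
#' 10 per side, excluding adjacent bins and the local extremes.
#'
#' @param n_used_per_side Bins contributing per side after exclusions (default 10).
#' @param n_adjacent_excluded Immediately adjacent bins skipped per side (default 1).
#' @param exclude_extremes Drop the pooled max and min candidate (default TRUE).
#' @return A `baseline_config` list.
#' @export
baseline_config <- function(n_used_per_side = 10L, n_adjacent_excluded = 1L,
                            exclude_extremes = TRUE) {
  stopifnot_scalar_number(n_used_per_side, "n_used_per_side", positive = TRUE)
  if (n_adjacent_excluded < 0) stop("n_adjacent_excluded must be >= 0", call. = FALSE)
  structure(list(
    n_used_per_side = as.integer(n_used_per_side),
    n_adjacent_excluded = as.integer(n_adjacent_excluded),
    exclude_extremes = isTRUE(exclude_extremes)
  ), class = "baseline_config")
}

#' Baseline-correct an amplitude spectrum
#'
#' Subtracts from every bin the mean of its surrounding bins per
#' [baseline_config()]: per side the next `n_adjacent_excluded +
#' n_used_per_side (+ 1 if extremes are excluded)` bins are taken, the
#' adjacent ones skipped, both sides pooled, the single pooled maximum and
#' minimum dropped (when configured), and the mean of the remaining
#' `2 * n_used_per_side` bins subtracted — independently for every sensor.
#' Bins whose window would cross the spectrum edge are set to `NA` (undefined)
#' rather than corrected with an asymmetric window.
#'
#' @param spectrum An uncorrected `amplitude_spectrum`.
#' @param cfg A [baseline_config()].
#' @param bins Optional integer vector of bin indices to correct; other bins
#'   are left `NA`. Default corrects every bin with a full window. Restricting
#'   to the target bin makes per-subject pipelines much cheaper.
#' @return The corrected `amplitude_spectrum` (`corrected = TRUE`); frequencies
#'   and resolution are unchanged. Attribute `undefined_bins` lists the edge
#'   bins left undefined.
#' @export
baseline_correct <- function(spectrum, cfg = baseline_config(), bins = NULL) {
  if (!inherits(spectrum, "amplitude_spectrum")) {
    stop("`spectrum` must be an amplitude_spectrum", call. = FALSE)
  }
  if (isTRUE(spectrum$corrected)) stop("spectrum is already baseline-corrected", call. = FALSE)
  if (!inherits(cfg, "baseline_config")) stop("`cfg` must be a baseline_config", call. = FALSE)

  amp <- spectrum$amplitudes
  n_bins <- ncol(amp)
  cps <- cfg$n_used_per_side + as.integer(cfg$exclude_extremes)  # candidates per side
  offsets <- c(-( (cfg$n_adjacent_excluded + 1L):(cfg$n_adjacent_excluded + cps) ),
               (cfg$n_adjacent_excluded + 1L):(cfg$n_adjacent_excluded + cps))
  reach <- cfg$n_adjacent_excluded + cps
  if (2L * reach + 1L > n_bins) stop("spectrum too short for the correction window", call. = FALSE)

  valid <- (reach + 1L):(n_bins - reach)
  if (!is.null(bins)) {
    bins <- as.integer(bins)
    if (any(bins < 1L | bins > n_bins)) stop("`bins` out of range", call. = FALSE)
    if (!all(bins %in% valid)) {
      stop("requested bin(s) lack a full correction window (too close to the spectrum edge)",
           call. = FALSE)
    }
    valid <- sort(unique(bins))
  }
  total <- matrix(0, nrow = nrow(amp), ncol = length(valid))
  if (cfg$exclude_extremes) {
    mx <- matrix(-Inf, nrow = nrow(amp), ncol = length(valid))
    mn <- matrix(Inf, nrow = nrow(amp), ncol = length(valid))
  }
  for (off in offsets) {
    block <- amp[, valid + off, drop = FALSE]
    total <- total + block
    if (cfg$exclude_extremes) {
      mx <- pmax(mx, block)
      mn <- pmin(mn, block)
    }
  }
  denom <- 2L * cfg$n_used_per_side
  baseline <- if (cfg$exclude_extremes) (total - mx - mn) / denom else total / denom

  out <- matrix(NA_real_, nrow = nrow(amp), ncol = n_bins, dimnames = dimnames(amp))
  out[, valid] <- amp[, valid, drop = FALSE] - baseline
  undefined <- setdiff(seq_len(n_bins), valid)
  if (is.null(bins) && length(undefined)) {
    message(sprintf("baseline_correct: %d edge bin(s) left undefined (window exceeds spectrum edge)",
                    length(undefined)))
  }
  res <- structure(list(
    amplitudes = out, freqs = spectrum$freqs,
    resolution = spectrum$resolution, corrected = TRUE
  ), class = "amplitude_spectrum")
  attr(res, "undefined_bins") <- undefined
  res
}

#' Extract the per-sensor response at a target frequency
#'
#' Reads the baseline-corrected amplitude at the bin nearest `f_target`. The
#' target must be bin-aligned: if the nearest bin is more than half a
#' resolution step away the call errors and names the nearest available bin,
#' to surface misaligned analyses instead of silently shifting them.
#'
#' @param spectrum A corrected `amplitude_spectrum`.
#' @param f_target Target frequency in Hz (e.g. the 3 Hz oddball rate).
#' @param subject_id,condition Optional labels carried into the result.
#' @return A `response_map`: named `values` per sensor, `f_target`,
#'   `subject_id`, `condition`.
#' @export
extract_response <- function(spectrum, f_target, subject_id = NULL, condition = NULL) {
  if (!inherits(spectrum, "amplitude_spectrum")) {
    stop("`spectrum` must be an amplitude_spectrum", call. = FALSE)
  }
  if (!isTRUE(spectrum$corrected)) stop("spectrum must be baseline-corrected first", call. = FALSE)
  stopifnot_scalar_number(f_target, "f_target", positive = TRUE)
  if (f_target > max(spectrum$freqs)) stop("f_target outside spectrum range", call. = FALSE)
  i <- which.min(abs(spectrum$freqs - f_target))
  miss <- abs(spectrum$freqs[i] - f_target)
  if (miss > spectrum$resolution / 2 + 1e-9) {
    stop(sprintf(
      "f_target = %g Hz is not bin-aligned (off by %.6f Hz); nearest bin is %.6f Hz",
      f_target, miss, spectrum$freqs[i]
    ), call. = FALSE)
  }
  v <- spectrum$amplitudes[, i]
  if (anyNA(v)) {
    stop(sprintf("target bin %.6f Hz is undefined after edge handling", spectrum$freqs[i]),
         call. = FALSE)
  }
  structure(list(
    values = v, f_target = f_target,
    subject_id = subject_id, condition = condition
  ), class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat(sprintf(
    "<response_map> %d node(s) at %g Hz%s%s\n",
    length(x$values), x$f_target,
    if (!is.null(x$subject_id)) paste0(", subject ", x$subject_id) else "",
    if (!is.null(x$condition)) paste0(", condition '", x$condition, "'") else ""
  ))
  invisible(x)
}

#' Stack response maps into a subjects x nodes matrix
#'
#' @param maps List of `response_map`s sharing one node set.
#' @return Numeric matrix, rownames = subject ids, colnames = node ids.
#' @export
response_matrix <- function(maps) {
  if (!length(maps)) stop("no response maps supplied", call. = FALSE)
  ids <- names(maps[[1]]$values)
  m <- do.call(rbind, lapply(maps, function(r) {
    if (!identical(names(r$values), ids)) stop("response maps have mismatched node sets", call. = FALSE)
    r$values
  }))
  rownames(m) <- unname(vapply(maps, function(r) r$subject_id %||% "", character(1)))
  m
}
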