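# Waveform containers: uniformly sampled flow/pressure time series per vessel,
# plus the set container holding one recording for all inlets and outlets.

#' Construct a waveform
#'
#' A `waveform` is a uniformly sampled time series of one physical quantity
#' (volumetric flow in mL/min or static gauge pressure in mmHg) measured at one
#' vessel.
#'
#' @param values numeric vector of samples (length >= 2, all finite).
#' @param sample_rate sampling rate in Hz (> 0).
#' @param vessel vessel label, e.g. `"LICA"`.
#' @param quantity `"flow"` or `"pressure"`.
#' @param unit unit string; defaults to `"mL/min"` for flow and `"mmHg"` for
#'   pressure.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `waveform`.
#' @export
#' @examples
#' w <- waveform(sin(2 * pi * seq(0, 1, by = 1e-3)), 1000, "LICA", "flow")
#' length(w$values)
waveform <- function(values, sample_rate, vessel = NA_character_,
                     quantity = c("flow", "pressure"), unit = NULL, t0 = 0) {
  quantity <- match.arg(quantity)
  if (is.null(unit)) unit <- if (quantity == "flow") "mL/min" else "mmHg"
  w <- structure(
    list(values = as.numeric(values), sample_rate = sample_rate,
         vessel = vessel, quantity = quantity, unit = unit, t0 = t0),
    class = "waveform"
  )
  validate_waveform(w)
  w
}

validate_waveform <- function(w) {
  stopifnot(inherits(w, "waveform"))
  if (!is.numeric(w$sample_rate) || length(w$sample_rate) != 1 || w$sample_rate <= 0)
    stop("sample_rate must be a single positive number", call. = FALSE)
  if (length(w$values) < 2)
    stop("waveform needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(w$values)))
    stop("waveform values must all be finite", call. = FALSE)
  ok_units <- list(flow = "mL/min", pressure = "mmHg")
  if (!identical(w$unit, ok_units[[w$quantity]]))
    stop(sprintf("unit '%s' inconsistent with quantity '%s'", w$unit, w$quantity),
         call. = FALSE)
  invisible(w)
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s %s [%s], %d samples @ %g Hz (%.3g s)\n",
              x$vessel, x$quantity, x$unit, length(x$values),
              x$sample_rate, length(x$values) / x$sample_rate))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$values)

#' Sample times of a waveform
#'
#' @param w a [waveform].
#' @return Numeric vector of sample times in seconds.
#' @export
waveform_times <- function(w) {
  w$t0 + (seq_along(w$values) - 1) / w$sample_rate
}

wf_key <- function(vessel, quantity) {
  paste0(vessel, if (quantity == "flow") "_q" else "_p")
}

#' Construct a waveform set
#'
#' A `waveform_set` collects waveforms keyed by (vessel, quantity) together
#' with the role (inlet/outlet) of each vessel. All member waveforms must share
#' sample rate and length.
#'
#' @param waveforms list of [waveform] objects.
#' @param vessel_roles named character vector mapping vessel label to
#'   `"inlet"` or `"outlet"`; by default inferred from the canonical
#'   Circle-of-Willis labels ([cow_vessels()]).
#' @return An object of class `waveform_set`.
#' @export
waveform_set <- function(waveforms, vessel_roles = NULL) {
  stopifnot(is.list(waveforms), length(waveforms) >= 1)
  lapply(waveforms, validate_waveform)
  keys <- vapply(waveforms, function(w) wf_key(w$vessel, w$quantity), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (vessel, quantity) entries: ",
         paste(keys[duplicated(keys)], collapse = ", "), call. = FALSE)
  names(waveforms) <- keys
  ns <- vapply(waveforms, function(w) length(w$values), integer(1))
  fs <- vapply(waveforms, function(w) w$sample_rate, numeric(1))
  if (length(unique(ns)) != 1)
    stop("all waveforms in a set must have the same length", call. = FALSE)
  if (length(unique(fs)) != 1)
    stop("all waveforms in a set must share one sample rate", call. = FALSE)
  vessels <- unique(vapply(waveforms, function(w) w$vessel, character(1)))
  if (is.null(vessel_roles)) {
    cv <- cow_vessels()
    vessel_roles <- setNames(
      ifelse(vessels %in% cv$inlets, "inlet",
             ifelse(vessels %in% cv$outlets, "outlet", NA_character_)),
      vessels
    )
  }
  structure(list(waveforms = waveforms, vessel_roles = vessel_roles),
            class = "waveform_set")
}

#' @export
print.waveform_set <- function(x, ...) {
  n <- length(x$waveforms)
  w1 <- x$waveforms[[1]]
  cat(sprintf("<waveform_set> %d waveforms (%d vessels), %d samples @ %g Hz\n",
              n, length(unique(ws_vessels(x))), length(w1$values), w1$sample_rate))
  invisible(x)
}

ws_vessels <- function(ws) {
  unique(vapply(ws$waveforms, function(w) w$vessel, character(1)))
}

#' Extract one waveform from a set
#'
#' @param ws a [waveform_set].
#' @param vessel vessel label.
#' @param quantity `"flow"` or `"pressure"`.
#' @return The requested [waveform]; error if absent.
#' @export
ws_get <- function(ws, vessel, quantity = c("flow", "pressure")) {
  quantity <- match.arg(quantity)
  key <- wf_key(vessel, quantity)
  w <- ws$waveforms[[key]]
  if (is.null(w)) stop("no waveform '", key, "' in set", call. = FALSE)
  w
}

ws_sample_rate <- function(ws) ws$waveforms[[1]]$sample_rate
ws_n_samples <- function(ws) length(ws$waveforms[[1]]$values)

#' Cycle index: fixed-period segmentation of a recording
#'
#' @param period cardiac period in seconds.
#' @param cycle_starts integer sample indices (1-based) where each complete
#'   cycle begins.
#' @param sample_rate sampling rate of the segmented waveform in Hz.
#' @param systole_fraction fraction of the cycle occupied by systole
#'   (in (0, 1)); a pump setting carried as metadata.
#' @return An object of class `cycle_index`.
#' @export
cycle_index <- function(period, cycle_starts, sample_rate,
                        systole_fraction = 0.4) {
  stopifnot(period > 0, length(cycle_starts) >= 1,
            systole_fraction > 0, systole_fraction < 1)
  cycle_starts <- as.integer(cycle_starts)
  if (length(cycle_starts) > 1) {
    d <- diff(cycle_starts)
    if (any(abs(d - period * sample_rate) > 1 + 1e-9))
      stop("cycle starts are not spaced by one period (within +/-1 sample)",
           call. = FALSE)
  }
  structure(list(period = period, cycle_starts = cycle_starts,
                 sample_rate = sample_rate,
                 systole_fraction = systole_fraction),
            class = "cycle_index")
}

#' Segment a waveform into cardiac cycles
#'
#' Default mode places fixed windows of length `1/f` anchored at the start of
#' the recording, appropriate when the pump frequency is fixed and known. An
#' optional foot-detection mode anchors at the global minimum of the first
#' cycle of the (flow) signal instead.
#'
#' @param w a [waveform].
#' @param f cardiac (pump) frequency in Hz.
#' @param anchor `"t0"` (default, fixed windows from the first sample) or
#'   `"foot"` (windows anchored at the detected waveform minimum).
#' @param systole_fraction stored in the result as metadata (default 0.4, i.e.
#'   40:60 systole:diastole).
#' @return A [cycle_index] with `floor(duration * f)` complete cycles.
#' @export
#' @examples
#' w <- waveform(rep(1, 3000), 1000, "LICA", "flow")
#' segment_cycles(w, 1)$cycle_starts
segment_cycles <- function(w, f, anchor = c("t0", "foot"),
                           systole_fraction = 0.4) {
  validate_waveform(w)
  anchor <- match.arg(anchor)
  stopifnot(f > 0)
  n <- length(w$values)
  duration <- n / w$sample_rate
  period <- 1 / f
  per_samp <- w$sample_rate / f
  offset <- 0L
  if (anchor == "foot") {
    first <- w$values[seq_len(min(n, floor(per_samp)))]
    offset <- which.min(first) - 1L
  }
  n_cycles <- floor((duration - offset / w$sample_rate) * f)
  if (n_cycles < 1)
    stop("waveform shorter than one cardiac period (", duration, " s < ",
         period, " s)", call. = FALSE)
  starts <- offset + round((seq_len(n_cycles) - 1) * per_samp) + 1L
  cycle_index(period, starts, w$sample_rate, systole_fraction)
}

# resolve a cycle selector ("all", "last", or integer indices) to indices
select_cycles <- function(ci, which) {
  n <- length(ci$cycle_starts)
  if (identical(which, "all")) return(seq_len(n))
  if (identical(which, "last")) return(n)
  idx <- as.integer(which)
  if (any(idx < 1 | idx > n))
    stop("cycle selector out of range: recording has ", n, " complete cycles",
         call. = FALSE)
  idx
}

# sample indices of one cycle window
cycle_window <- function(ci, k) {
  per_samp <- round(ci$period * ci$sample_rate)
  ci$cycle_starts[k] + seq_len(per_samp) - 1L
}

#' Cycle-averaged value of a waveform
#'
#' Arithmetic mean of all samples inside the selected cycle window(s).
#'
#' @param w a [waveform].
#' @param ci a [cycle_index] for `w`.
#' @param which cycle selector: `"all"`, `"last"`, or integer cycle indices.
#' @return Scalar mean in the waveform's unit.
#' @export
cycle_average <- function(w, ci, which = "all") {
  idx <- unlist(lapply(select_cycles(ci, which), cycle_window, ci = ci))
  if (max(idx) > length(w$values))
    stop("cycle window extends beyond the recording", call. = FALSE)
  mean(w$values[idx])
}

#' Low-pass filter a waveform (Butterworth)
#'
#' Digital Butterworth low-pass with unit DC gain. The default is a causal
#' single pass; `zero_phase = TRUE` applies forward–backward filtering
#' (zero phase, squared magnitude response). Because recordings are whole
#' numbers of cardiac cycles, `extend = "periodic"` tiles the signal before
#' filtering and crops afterwards, which removes start-up transients for
#' periodic signals.
#'
#' @param w a [waveform].
#' @param order filter order (default 6).
#' @param cutoff cutoff frequency in Hz (default 7); must be below Nyquist.
#' @param zero_phase logical; forward–backward filtering instead of a causal
#'   single pass.
#' @param extend `"none"` or `"periodic"`; periodic extension assumes the
#'   recorded span is a whole number of periods.
#' @return The filtered [waveform] (same length).
#' @export
lowpass_filter <- function(w, order = 6, cutoff = 7, zero_phase = FALSE,
                           extend = c("none", "periodic")) {
  validate_waveform(w)
  extend <- match.arg(extend)
  stopifnot(order >= 1)
  nyq <- w$sample_rate / 2
  if (cutoff >= nyq)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         nyq, " Hz)", call. = FALSE)
  bf <- signal::butter(order, cutoff / nyq, type = "low")
  x <- w$values
  n <- length(x)
  if (extend == "periodic") {
    x <- c(x, x, x)
  }
  y <- if (zero_phase) signal::filtfilt(bf, x) else
    as.numeric(signal::filter(bf, x))
  if (extend == "periodic") {
    y <- y[(n + 1):(2 * n)]
  }
  out <- w
  out$values <- y
  out
}

#' Resample a waveform by linear interpolation
#'
#' Values outside the recorded span use periodic extension (period equal to
#' the recorded span by default, or `1/f` if `f` is given), supporting
#' multi-cycle playback of single-cycle recordings.
#'
#' @param w a [waveform].
#' @param dt new sampling interval in seconds (> 0).
#' @param duration output duration in seconds (default: the recorded span).
#' @param f optional periodic-extension frequency in Hz; default uses the full
#'   recorded span as the period.
#' @return A resampled [waveform] with `sample_rate = 1/dt`.
#' @export
resample_linear <- function(w, dt, duration = NULL, f = NULL) {
  validate_waveform(w)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  span <- length(w$values) / w$sample_rate
  if (is.null(duration)) duration <- span
  period <- if (is.null(f)) span else 1 / f
  tq <- seq(0, duration - dt / 2, by = dt)
  out <- w
  out$values <- wf_interp(w, w$t0 + tq, period)
  out$sample_rate <- 1 / dt
  out
}

# periodic linear interpolation of waveform values at absolute times t
wf_interp <- function(w, t, period = NULL) {
  n <- length(w$values)
  span <- n / w$sample_rate
  if (is.null(period)) period <- span
  tr <- (t - w$t0) %% period
  # fractional sample position on the original grid, with wrap-around between
  # the last and (periodically extended) first sample
  pos <- tr * w$sample_rate
  i0 <- floor(pos)
  frac <- pos - i0
  v <- w$values
  vnext <- c(v[-1], v[1])
  idx <- (i0 %% n) + 1
  v[idx] * (1 - frac) + vnext[idx] * frac
}
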