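# Scalar waveform descriptors: pulsatility index, pulse pressure, pressure
# pulsatility, total-flow distribution, RMSD/NRMSD.

#' Flow pulsatility index
#'
#' `PI = (Q_systolic - Q_diastolic) / Qbar`, with the peak-systolic and
#' end-diastolic flows taken as the per-cycle maximum and minimum. Extrema and
#' means are computed within each selected cycle, averaged across cycles, and
#' PI is formed from the averaged components. Ties in the extrema are broken
#' by first occurrence.
#'
#' @param Q a flow [waveform].
#' @param ci a [cycle_index] for `Q`.
#' @param which cycle selector (`"all"`, `"last"`, or indices).
#' @return A list of class `pulsatility_result` with `vessel`, `q_systolic`,
#'   `q_diastolic`, `q_mean`, `pi`, and a per-cycle data frame `per_cycle`
#'   (including per-cycle PI values, whose SD is the usual reported spread).
#' @export
pulsatility_index <- function(Q, ci, which = "all") {
  ks <- select_cycles(ci, which)
  per <- t(vapply(ks, function(k) {
    x <- Q$values[cycle_window(ci, k)]
    c(max = max(x), min = min(x), mean = mean(x))
  }, numeric(3)))
  q_sys <- mean(per[, "max"])
  q_dia <- mean(per[, "min"])
  q_bar <- mean(per[, "mean"])
  if (abs(q_bar) < .Machine$double.eps * max(abs(per)))
    stop("PI undefined: cycle-mean flow is zero", call. = FALSE)
  per_cycle <- data.frame(cycle = ks, q_systolic = per[, "max"],
                          q_diastolic = per[, "min"], q_mean = per[, "mean"],
                          pi = (per[, "max"] - per[, "min"]) / per[, "mean"])
  structure(list(vessel = Q$vessel, q_systolic = q_sys, q_diastolic = q_dia,
                 q_mean = q_bar, pi = (q_sys - q_dia) / q_bar,
                 per_cycle = per_cycle),
            class = "pulsatility_result")
}

#' Pulse pressure
#'
#' Per-cycle (max - min), averaged across the selected cycles.
#'
#' @param p a pressure [waveform].
#' @param ci a [cycle_index] for `p`.
#' @param which cycle selector.
#' @return Scalar pulse pressure in the waveform's unit.
#' @export
pulse_pressure <- function(p, ci, which = "all") {
  ks <- select_cycles(ci, which)
  mean(vapply(ks, function(k) {
    x <- p$values[cycle_window(ci, k)]
    max(x) - min(x)
  }, numeric(1)))
}

#' Pressure pulsatility
#'
#' Ratio of pulse pressure to cycle-mean pressure (the pressure analogue of
#' the flow PI).
#'
#' @inheritParams pulse_pressure
#' @return Scalar dimensionless pulsatility.
#' @export
pressure_pulsatility <- function(p, ci, which = "all") {
  m <- cycle_average(p, ci, which)
  if (abs(m) < .Machine$double.eps * max(abs(p$values), 1))
    stop("pressure pulsatility undefined: cycle mean is zero", call. = FALSE)
  pulse_pressure(p, ci, which) / m
}

#' Distribution of total cerebral blood flow over the outlets
#'
#' Cycle-mean flow per outlet, their sum (tCBF), and each outlet's fraction
#' of the total.
#'
#' @param ws a [waveform_set] containing the six canonical outlet flows.
#' @param ci a [cycle_index].
#' @param which cycle selector.
#' @return A list of class `distribution_result` with `outlet_means` (named,
#'   mL/min), `tcbf` (mL/min) and `fractions` (named, summing to 1).
#' @export
tcbf_distribution <- function(ws, ci, which = "all") {
  outlets <- cow_vessels()$outlets
  have <- vapply(outlets, function(v) !is.null(ws$waveforms[[wf_key(v, "flow")]]),
                 logical(1))
  if (!all(have))
    stop("missing outlet flow waveform(s): ",
         paste(outlets[!have], collapse = ", "), call. = FALSE)
  means <- vapply(outlets, function(v) cycle_average(ws_get(ws, v, "flow"), ci, which),
                  numeric(1))
  tcbf <- sum(means)
  structure(list(outlet_means = means, tcbf = tcbf, fractions = means / tcbf),
            class = "distribution_result")
}

#' Root mean squared deviation between two waveforms
#'
#' @param sim,exp waveforms of equal length and sample rate.
#' @return Scalar RMSD in the waveforms' unit.
#' @export
rmsd <- function(sim, exp) {
  validate_waveform(sim); validate_waveform(exp)
  if (length(sim$values) != length(exp$values))
    stop("waveform length mismatch (", length(sim$values), " vs ",
         length(exp$values), ")", call. = FALSE)
  if (abs(sim$sample_rate - exp$sample_rate) > 1e-9 * exp$sample_rate)
    stop("waveform sample-rate mismatch", call. = FALSE)
  sqrt(mean((sim$values - exp$values)^2))
}

#' Normalised RMSD
#'
#' RMSD divided by the absolute cycle-averaged reference value (the
#' `normalizer`). Reported as a fraction; multiply by 100 for percent.
#'
#' @inheritParams rmsd
#' @param normalizer cycle-averaged experimental reference value (non-zero).
#' @return A list of class `deviation_result` with `rmsd`, `nrmsd` and
#'   `normalizer`.
#' @export
nrmsd <- function(sim, exp, normalizer) {
  if (!is.numeric(normalizer) || length(normalizer) != 1 || normalizer == 0)
    stop("normalizer must be a single non-zero number", call. = FALSE)
  r <- rmsd(sim, exp)
  structure(list(vessel = exp$vessel, quantity = exp$quantity, rmsd = r,
                 nrmsd = r / abs(normalizer), normalizer = normalizer),
            class = "deviation_result")
}
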