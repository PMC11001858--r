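# Orchestration: fit every requested BC from a reference recording, simulate,
# and score against the reference (tCBF distribution, PI, pulse pressure,
# RMSD/NRMSD), plus the calibration-table reproduction.

#' Calibration report of a recording
#'
#' Per-vessel cycle statistics in the layout of the benchtop calibration
#' table: mean flow +/- SD across cycles, tCBF fraction, flow PI +/- SD
#' (computed, per the reference protocol, on low-pass-filtered flows:
#' 6th-order Butterworth, 7 Hz cutoff, zero-phase with periodic extension),
#' plus separate inlet/outlet tCBF totals and a pressure summary with the
#' inlet-to-outlet mean-pressure and pulse-pressure percentage decreases.
#'
#' @param ws a [waveform_set] with all 10 canonical vessels.
#' @param f cardiac frequency in Hz.
#' @param which cycle selector for the averages (default `"all"`).
#' @param filter_pi logical; low-pass filter flows before the PI computation
#'   (default TRUE, matching the reference post-processing).
#' @param filter_order,filter_cutoff Butterworth settings.
#' @return A list of class `table1_report`: `flows` (data frame), `totals`
#'   (tcbf_in/tcbf_out) and `pressures` (per-vessel means and pulse pressures
#'   plus the percentage decreases).
#' @export
table1_report <- function(ws, f = 1, which = "all", filter_pi = TRUE,
                          filter_order = 6, filter_cutoff = 7) {
  cv <- cow_vessels()
  vessels <- c(cv$inlets, cv$outlets)
  missing <- vessels[!vapply(vessels, function(v)
    !is.null(ws$waveforms[[wf_key(v, "flow")]]) &&
      !is.null(ws$waveforms[[wf_key(v, "pressure")]]), logical(1))]
  if (length(missing))
    stop("recording lacks vessel(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  ci <- segment_cycles(ws_get(ws, vessels[1], "flow"), f)
  rows <- lapply(vessels, function(v) {
    qw <- ws_get(ws, v, "flow")
    qf <- if (filter_pi)
      lowpass_filter(qw, filter_order, filter_cutoff, zero_phase = TRUE,
                     extend = "periodic") else qw
    pr <- pulsatility_index(qf, ci, which)
    data.frame(
      vessel = v,
      role = ws$vessel_roles[[v]],
      flow_mean = mean(pr$per_cycle$q_mean),
      flow_sd = stats::sd(pr$per_cycle$q_mean),
      pi = pr$pi,
      pi_sd = stats::sd(pr$per_cycle$pi)
    )
  })
  flows <- do.call(rbind, rows)
  tcbf_in <- sum(flows$flow_mean[flows$role == "inlet"])
  tcbf_out <- sum(flows$flow_mean[flows$role == "outlet"])
  flows$tcbf_fraction <- ifelse(flows$role == "inlet",
                                flows$flow_mean / tcbf_in,
                                flows$flow_mean / tcbf_out)
  pr_rows <- lapply(vessels, function(v) {
    pw <- ws_get(ws, v, "pressure")
    data.frame(vessel = v, role = ws$vessel_roles[[v]],
               p_mean = cycle_average(pw, ci, which),
               pulse_pressure = pulse_pressure(pw, ci, which))
  })
  pressures <- do.call(rbind, pr_rows)
  pin <- pressures[pressures$role == "inlet", ]
  pout <- pressures[pressures$role == "outlet", ]
  mean_drop <- 100 * (mean(pin$p_mean) - mean(pout$p_mean)) / mean(pin$p_mean)
  pp_drop <- 100 * (mean(pin$pulse_pressure) - mean(pout$pulse_pressure)) /
    mean(pin$pulse_pressure)
  structure(list(
    flows = flows,
    totals = list(tcbf_in = tcbf_in, tcbf_out = tcbf_out),
    pressures = list(per_vessel = pressures,
                     mean_pressure_decrease_pct = mean_drop,
                     pulse_pressure_decrease_pct = pp_drop)
  ), class = "table1_report")
}

#' @export
print.table1_report <- function(x, digits = 4, ...) {
  cat("Calibration report (cycle-averaged)\n")
  f <- x$flows
  f$tcbf_fraction <- 100 * f$tcbf_fraction
  names(f)[names(f) == "tcbf_fraction"] <- "tcbf_pct"
  print(format(f, digits = digits), row.names = FALSE)
  cat(sprintf("tCBF in  %.1f mL/min\ntCBF out %.1f mL/min\n",
              x$totals$tcbf_in, x$totals$tcbf_out))
  cat(sprintf("inlet->outlet mean pressure decrease  %.1f%%\n",
              x$pressures$mean_pressure_decrease_pct))
  cat(sprintf("inlet->outlet pulse pressure decrease %.1f%%\n",
              x$pressures$pulse_pressure_decrease_pct))
  invisible(x)
}

# last-cycle window of a simulated/reference waveform pair on the reference
# grid; both are uniformly sampled at the same rate by construction
last_cycle_values <- function(w, ci) {
  w$values[cycle_window(ci, length(ci$cycle_starts))]
}

#' Run the full boundary-condition comparison
#'
#' For each requested BC set: derive its parameters from the reference
#' recording, run the transient 0D network simulation driven by the
#' recording's inlet flows, align the last cardiac cycles, and score the
#' simulation against the reference. Metrics follow the reference protocol:
#' RMSD/NRMSD of outlet pressures, inlet pressures and outlet flows
#' (normalised by the cycle-averaged reference value), cycle-mean outlet
#' flows and tCBF fractions, flow PI and pulse pressure.
#'
#' The 0D resistive-inertial surrogate stands in for a 3D CFD solve; its
#' NRMSD magnitudes are surrogate-specific and are labelled as such in the
#' report.
#'
#' @param dataset reference [waveform_set]; default: the calibrated synthetic
#'   recording from [default_config()].
#' @param net network model; default: [build_network()] on [cow_geometry()].
#' @param bcs subset of `c("zp", "sp", "dep", "wm", "pm")`.
#' @param dt,n_cycles,f simulation settings.
#' @param which cycle selector for parameter derivation (default `"all"`).
#' @param C_MCA,c_n Windkessel / symmetrical-pressure configuration.
#' @param out_dir optional directory; when given, writes `report.csv` (tidy
#'   long format: solver, bc, vessel, quantity, metric, value) and
#'   `summary.json` (settings, seeds and fitted parameters).
#' @return A list of class `cow_evaluation` with `report` (tidy data frame),
#'   `table1` (calibration report of the reference), `sims` (per-BC
#'   `cow_sim`), and `specs` (fitted BC specs).
#' @export
run_evaluation <- function(dataset = NULL, net = NULL,
                           bcs = c("zp", "sp", "dep", "wm", "pm"),
                           dt = 1e-3, n_cycles = 3, f = 1, which = "all",
                           C_MCA = 8e-11, c_n = NULL, out_dir = NULL) {
  bcs <- match.arg(bcs, several.ok = TRUE)
  if (is.null(dataset)) dataset <- generate_waveform_set(default_config())
  if (is.null(net)) net <- build_network(cow_geometry())
  cv <- cow_vessels()
  ci_ref <- segment_cycles(ws_get(dataset, cv$inlets[1], "flow"), f)
  tab1 <- table1_report(dataset, f, which)
  ref_dist <- tcbf_distribution(dataset, ci_ref, "last")

  sims <- list(); specs <- list(); rows <- list()
  for (bc in bcs) {
    sim <- tryCatch(
      run_bc_set(net, dataset, bc, dt = dt, n_cycles = n_cycles, f = f,
                 which = which, C_MCA = C_MCA, c_n = c_n),
      error = function(e) stop("stage '", bc, "' failed: ",
                               conditionMessage(e), call. = FALSE)
    )
    sims[[bc]] <- sim
    specs[[bc]] <- attr(sim, "bc_spec")
    ci_sim <- segment_cycles(sim$outlet_flow[[1]], f)
    sim_dist <- tcbf_distribution(
      waveform_set(unname(sim$outlet_flow)), ci_sim, "last")

    add <- function(vessel, quantity, metric, value) {
      rows[[length(rows) + 1]] <<- data.frame(
        solver = "0D surrogate", bc = bc, vessel = vessel,
        quantity = quantity, metric = metric, value = value,
        stringsAsFactors = FALSE)
    }
    for (v in cv$outlets) {
      ref_q <- ws_get(dataset, v, "flow")
      ref_p <- ws_get(dataset, v, "pressure")
      sim_q <- sim$outlet_flow[[v]]
      sim_p <- sim$outlet_pressure[[v]]
      wq <- waveform(last_cycle_values(sim_q, ci_sim), f, v, "flow")
      wq_ref <- waveform(last_cycle_values(ref_q, ci_ref), f, v, "flow")
      wp <- waveform(last_cycle_values(sim_p, ci_sim), f, v, "pressure")
      wp_ref <- waveform(last_cycle_values(ref_p, ci_ref), f, v, "pressure")
      dq <- nrmsd(wq, wq_ref, cycle_average(ref_q, ci_ref, "last"))
      dp <- nrmsd(wp, wp_ref, cycle_average(ref_p, ci_ref, "last"))
      add(v, "flow", "rmsd", dq$rmsd)
      add(v, "flow", "nrmsd", dq$nrmsd)
      add(v, "pressure", "rmsd", dp$rmsd)
      add(v, "pressure", "nrmsd", dp$nrmsd)
      add(v, "flow", "cycle_mean", sim_dist$outlet_means[[v]])
      add(v, "flow", "tcbf_fraction", sim_dist$fractions[[v]])
      add(v, "flow", "tcbf_fraction_error",
          sim_dist$fractions[[v]] - ref_dist$fractions[[v]])
      add(v, "flow", "pi", pulsatility_index(sim_q, ci_sim, "last")$pi)
      add(v, "pressure", "pulse_pressure",
          pulse_pressure(sim_p, ci_sim, "last"))
    }
    for (v in cv$inlets) {
      ref_p <- ws_get(dataset, v, "pressure")
      sim_p <- sim$inlet_pressure[[v]]
      wp <- waveform(last_cycle_values(sim_p, ci_sim), f, v, "pressure")
      wp_ref <- waveform(last_cycle_values(ref_p, ci_ref), f, v, "pressure")
      dp <- nrmsd(wp, wp_ref, cycle_average(ref_p, ci_ref, "last"))
      add(v, "pressure", "rmsd", dp$rmsd)
      add(v, "pressure", "nrmsd", dp$nrmsd)
      add(v, "pressure", "cycle_mean", cycle_average(sim_p, ci_sim, "last"))
    }
  }
  report <- do.call(rbind, rows)
  out <- structure(list(report = report, table1 = tab1, sims = sims,
                        specs = specs,
                        settings = list(dt = dt, n_cycles = n_cycles, f = f,
                                        which = which, C_MCA = C_MCA)),
                   class = "cow_evaluation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
    cfg <- attr(dataset, "config")
    summary <- list(
      solver = "0D surrogate",
      settings = out$settings,
      dataset_seed = if (!is.null(cfg)) cfg$seed else NA,
      package_version = as.character(utils::packageVersion("cowbc")),
      bc_parameters = lapply(specs, function(s)
        s[setdiff(names(s), c("pressures", "outlets"))])
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' @export
print.cow_evaluation <- function(x, ...) {
  cat("Boundary-condition evaluation (0D surrogate)\n")
  nr <- x$report[x$report$metric == "nrmsd", ]
  agg <- stats::aggregate(value ~ bc + quantity, nr,
                          function(v) c(min = min(v), max = max(v)))
  cat("NRMSD ranges (fraction of cycle-mean reference):\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-3s %-8s %.3f - %.3f\n", agg$bc[i], agg$quantity[i],
                agg$value[i, "min"], agg$value[i, "max"]))
  }
  invisible(x)
}
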