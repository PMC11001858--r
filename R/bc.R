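# The five outlet pressure boundary-condition parameterisations.
#
# All specs answer bc_pressure(spec, outlet, t, Q) in mmHg with identical
# semantics; the Windkessel is the only stateful one (its pressure is the
# integrated RC state, advanced by wm_step / wm_update).

#' Outlet boundary-condition pressure
#'
#' Common interface of the five outlet BC parameterisations: the gauge
#' pressure (mmHg) imposed at `outlet` at time `t`. The symmetrical-pressure
#' BC additionally uses the instantaneous outlet flow `Q` for its quadratic
#' dynamic term; the others ignore it. The Windkessel spec returns its current
#' state (advance it with [wm_step()]).
#'
#' @param spec a BC spec ([bc_zp()], [bc_sp()], [bc_dep()], [bc_wm()],
#'   [bc_pm()]).
#' @param outlet outlet vessel label.
#' @param t time in seconds (vectorised for the stateless BCs).
#' @param Q outlet volumetric flow in mL/min (used by the SP dynamic term).
#' @param ... unused.
#' @return Pressure in mmHg.
#' @export
bc_pressure <- function(spec, outlet, t, Q = 0, ...) UseMethod("bc_pressure")

check_outlet <- function(spec, outlet) {
  if (!outlet %in% spec$outlets)
    stop("unknown outlet '", outlet, "' for this boundary-condition spec",
         call. = FALSE)
  invisible(outlet)
}

# ---- ZP: one stationary static pressure for all outlets --------------------

#' Zero-pressure (single stationary pressure) outlet BC
#'
#' One stationary static gauge pressure applied to every outlet. Despite its
#' conventional name it need not be literally zero: the reference value is the
#' cycle average over all experimental outlet pressures (87 mmHg for the
#' calibrated default recording).
#'
#' @param p_zp stationary gauge pressure in mmHg.
#' @param outlets outlet labels the spec answers for.
#' @return An object of classes `bc_zp`, `bc_spec`.
#' @export
bc_zp <- function(p_zp, outlets = cow_vessels()$outlets) {
  stopifnot(is.numeric(p_zp), length(p_zp) == 1, is.finite(p_zp))
  structure(list(p_zp = p_zp, outlets = outlets, kind = "zp"),
            class = c("bc_zp", "bc_spec"))
}

#' @export
bc_pressure.bc_zp <- function(spec, outlet, t, Q = 0, ...) {
  check_outlet(spec, outlet)
  rep_len(spec$p_zp, length(t))
}

# ---- SP: side-averaged stationary pressures + quadratic dynamic term -------

#' Symmetrical-pressure outlet BC
#'
#' `p = pbar_n + 1/2 * c_n * rho * (Q/A)^2`: a stationary side-averaged mean
#' static pressure per vessel class plus a hydraulic (quadratic) dynamic term.
#' The left and right members of each class (ACA, MCA, PCA) share `pbar_n`.
#'
#' @param p_mean named vector of mean gauge pressures in mmHg (one per
#'   outlet; left/right members of a class are expected to be equal).
#' @param c_n named vector of dimensionless hydraulic loss coefficients per
#'   outlet (recycled from per-class values if named by class).
#' @param area named vector of outlet cross-sectional areas in m^2.
#' @param rho fluid density in kg/m^3.
#' @return An object of classes `bc_sp`, `bc_spec`.
#' @export
bc_sp <- function(p_mean, c_n, area, rho = fluid_props()$rho) {
  outlets <- names(p_mean)
  stopifnot(!is.null(outlets), all(area[outlets] > 0))
  cls <- cow_outlet_class(outlets)
  if (!all(outlets %in% names(c_n)) && all(cls %in% names(c_n)))
    c_n <- setNames(c_n[cls], outlets)
  structure(list(p_mean = p_mean, c_n = c_n[outlets], area = area[outlets],
                 rho = rho, outlets = outlets, kind = "sp"),
            class = c("bc_sp", "bc_spec"))
}

#' @export
bc_pressure.bc_sp <- function(spec, outlet, t, Q = 0, ...) {
  check_outlet(spec, outlet)
  q_si <- mlmin_to_m3s(Q)
  dyn_pa <- 0.5 * spec$c_n[[outlet]] * spec$rho *
    (q_si / spec$area[[outlet]])^2
  rep_len(spec$p_mean[[outlet]], max(length(t), length(Q))) +
    Pa_to_mmHg(dyn_pa)
}

# ---- DEP: direct playback of experimental outlet pressures -----------------

#' Direct-experimental-pressure outlet BC
#'
#' Plays back the recorded transient outlet pressures, linearly interpolated
#' with periodic extension. Serves as the reference (metric floor) among the
#' BC sets.
#'
#' @param pressures named list of pressure [waveform]s, one per outlet,
#'   covering at least one period.
#' @param f cardiac frequency in Hz; the periodic-extension period is `1/f`
#'   times the number of whole cycles recorded (i.e. the full recorded span).
#' @return An object of classes `bc_dep`, `bc_spec`.
#' @export
bc_dep <- function(pressures, f = 1) {
  stopifnot(is.list(pressures), !is.null(names(pressures)))
  lapply(pressures, validate_waveform)
  span <- length(pressures[[1]]$values) / pressures[[1]]$sample_rate
  if (span < 1 / f - 1e-12)
    stop("DEP pressure recording must cover at least one period", call. = FALSE)
  structure(list(pressures = pressures, f = f, outlets = names(pressures),
                 kind = "dep"),
            class = c("bc_dep", "bc_spec"))
}

#' @export
bc_pressure.bc_dep <- function(spec, outlet, t, Q = 0, ...) {
  check_outlet(spec, outlet)
  wf_interp(spec$pressures[[outlet]], t)
}

# ---- PM: phase-modulated pressure waveform ---------------------------------

#' Phase-modulation outlet BC
#'
#' Closed-form transient pressure
#' `p(t) = pbar_n * (1 + PI_p/2 * cos(2*pi*f*t + phi + beta*cos(2*pi*f*t + phi)))`
#' with a single shared parameter set (`PI_p`, `phi`, `beta`) for all outlets;
#' only the mean pressure level `pbar_n` varies per outlet.
#'
#' @param p_mean named vector of mean gauge pressures in mmHg per outlet.
#' @param pi_p shared pressure pulsatility (pulse pressure over mean).
#' @param f cardiac frequency in Hz.
#' @param phi shared phase in radians.
#' @param beta shared modulation index.
#' @return An object of classes `bc_pm`, `bc_spec`.
#' @export
bc_pm <- function(p_mean, pi_p, f = 1, phi = 0, beta = 0) {
  stopifnot(!is.null(names(p_mean)), f > 0, pi_p >= 0)
  structure(list(p_mean = p_mean, pi_p = pi_p, f = f, phi = phi, beta = beta,
                 outlets = names(p_mean), kind = "pm"),
            class = c("bc_pm", "bc_spec"))
}

#' @export
bc_pressure.bc_pm <- function(spec, outlet, t, Q = 0, ...) {
  check_outlet(spec, outlet)
  spec$p_mean[[outlet]] *
    (1 + spec$pi_p / 2 * pm_cosine(t, spec$f, spec$phi, spec$beta))
}

# ---- WM: two-element Windkessel --------------------------------------------

#' One explicit-Euler update of the two-element Windkessel state
#'
#' The parallel-RC outlet element obeys `C dp/dt = Q - p/R` (gauge pressure
#' against a zero venous datum). One explicit Euler step:
#' `p_next = p + dt/C * (Q - p/R)`. Unit-agnostic: use any coherent unit
#' system (the solver uses SI).
#'
#' @param p current pressure state.
#' @param Q outflow through the element.
#' @param R peripheral resistance (> 0).
#' @param C compliance (> 0).
#' @param dt time step (> 0); explicit Euler is unstable for `dt >= 2*R*C`.
#' @return Updated pressure.
#' @export
#' @examples
#' wm_update(1, 0, R = 1, C = 1, dt = 0.1)  # 0.9
wm_update <- function(p, Q, R, C, dt) {
  stopifnot(dt > 0, all(R > 0), all(C > 0))
  ratio <- dt / (R * C)
  if (any(ratio >= 2))
    stop("explicit Euler unstable: dt/tau = ", signif(max(ratio), 3),
         " >= 2", call. = FALSE)
  if (any(ratio > 0.5))
    warning("dt/tau = ", signif(max(ratio), 3),
            " > 0.5: explicit Euler is poorly resolved", call. = FALSE)
  p + dt / C * (Q - p / R)
}

#' Two-element Windkessel outlet BC
#'
#' Per-outlet peripheral resistance and compliance, with the characteristic
#' time `tau = R*C` uniform across outlets. The imposed pressure is the
#' integrated state, initialised to `p0` (typically the cycle-averaged outlet
#' pressure, which suppresses the start-up transient).
#'
#' @param R named vector of peripheral resistances in Pa s/m^3.
#' @param C named vector of compliances in m^3/Pa (same names).
#' @param p0 named vector of initial pressures in mmHg.
#' @return An object of classes `bc_wm`, `bc_spec` with state `p_state` (Pa).
#' @export
bc_wm <- function(R, C, p0) {
  outlets <- names(R)
  stopifnot(!is.null(outlets), all(R > 0), all(C[outlets] > 0))
  tau <- R * C[outlets]
  if (diff(range(tau)) > 1e-9 * mean(tau))
    warning("tau = R*C is not uniform across outlets", call. = FALSE)
  structure(list(R = R, C = C[outlets], p_state = mmHg_to_Pa(p0[outlets]),
                 tau = unname(tau[1]), outlets = outlets, kind = "wm"),
            class = c("bc_wm", "bc_spec"))
}

#' @export
bc_pressure.bc_wm <- function(spec, outlet, t, Q = 0, ...) {
  check_outlet(spec, outlet)
  rep_len(Pa_to_mmHg(spec$p_state[[outlet]]), length(t))
}

#' Advance the Windkessel states of a spec by one time step
#'
#' @param spec a [bc_wm()] spec.
#' @param Q_out named vector of outlet flows in mL/min (names matching the
#'   spec's outlets; missing outlets keep their state).
#' @param dt time step in seconds.
#' @return The spec with updated `p_state`.
#' @export
wm_step <- function(spec, Q_out, dt) {
  stopifnot(inherits(spec, "bc_wm"))
  o <- intersect(spec$outlets, names(Q_out))
  spec$p_state[o] <- wm_update(spec$p_state[o], mlmin_to_m3s(Q_out[o]),
                               spec$R[o], spec$C[o], dt)
  spec
}

#' @export
print.bc_spec <- function(x, ...) {
  cat(sprintf("<bc_%s> outlets: %s\n", x$kind, paste(x$outlets, collapse = ", ")))
  invisible(x)
}
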