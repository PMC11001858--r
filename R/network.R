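# 0D resistive-inertial network model of the Circle of Willis and its
# transient nodal solver. Segments follow the lumped Poiseuille/inertance
# laws; the nodal system is Kirchhoff's current law with imposed inlet flows
# and imposed (BC) outlet pressures, discretised by backward Euler in the
# segment inertance and solved by one sparse Cholesky factorisation reused
# over all time steps.

#' Synthetic Circle-of-Willis segment geometry
#'
#' A literature-typical complete Circle-of-Willis geometry (synthetic, not
#' patient-derived): the four feeding vessels, the basilar trunk, the A1/M1/P1
#' segments, the distal A2/P2 segments, and the three communicating arteries
#' closing the ring. Lengths and diameters are representative adult values.
#' The same table ships as
#' `system.file("extdata", "cow_geometry_synthetic.csv", package = "cowbc")`.
#'
#' @return A data frame with columns `segment`, `node_a`, `node_b`,
#'   `length_mm`, `diameter_mm`. Terminal nodes carry the canonical vessel
#'   labels.
#' @export
cow_geometry <- function() {
  g <- read.csv(system.file("extdata", "cow_geometry_synthetic.csv",
                            package = "cowbc"), stringsAsFactors = FALSE)
  g
}

#' Build a lumped-parameter vessel network
#'
#' Each geometry row becomes a segment with Poiseuille resistance
#' `R = 128*mu*l / (pi*d^4)` and inertance `L = 4*rho*l / (pi*d^2)`. Node
#' roles are assigned from the canonical vessel labels: a node named like an
#' inlet/outlet vessel is a terminal (and must have degree 1); all others are
#' junctions. A complete Circle of Willis is cyclic (cycle rank >= 1); a
#' missing communicating artery only triggers a warning, supporting
#' incomplete-ring experiments.
#'
#' @param geometry data frame with columns `segment`, `node_a`, `node_b`,
#'   `length_mm`, `diameter_mm` (see [cow_geometry()]).
#' @param fluid a [fluid_props()].
#' @param outlet_areas optional named vector of outlet cross-sections in m^2;
#'   default is the lumen area `pi*d^2/4` of the terminal segment.
#' @return An object of class `cow_network`.
#' @export
build_network <- function(geometry, fluid = fluid_props(),
                          outlet_areas = NULL) {
  need <- c("segment", "node_a", "node_b", "length_mm", "diameter_mm")
  if (!all(need %in% names(geometry)))
    stop("geometry needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(geometry$length_mm <= 0) || any(geometry$diameter_mm <= 0))
    stop("segment lengths and diameters must be positive", call. = FALSE)
  len <- geometry$length_mm / 1000
  dia <- geometry$diameter_mm / 1000
  R_seg <- 128 * fluid$mu * len / (pi * dia^4)
  L_seg <- 4 * fluid$rho * len / (pi * dia^2)
  nodes <- unique(c(geometry$node_a, geometry$node_b))
  cv <- cow_vessels()
  roles <- setNames(rep("junction", length(nodes)), nodes)
  roles[nodes %in% cv$inlets] <- "inlet"
  roles[nodes %in% cv$outlets] <- "outlet"
  deg <- table(c(geometry$node_a, geometry$node_b))
  term <- nodes[roles[nodes] != "junction"]
  if (any(deg[term] != 1))
    stop("terminal node(s) must have degree 1: ",
         paste(term[deg[term] != 1], collapse = ", "), call. = FALSE)
  # connectivity (BFS over the undirected graph)
  adj <- lapply(setNames(nodes, nodes), function(n) {
    unique(c(geometry$node_b[geometry$node_a == n],
             geometry$node_a[geometry$node_b == n]))
  })
  seen <- nodes[1]; frontier <- nodes[1]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  if (length(seen) < length(nodes))
    stop("network graph is disconnected (unreached: ",
         paste(setdiff(nodes, seen), collapse = ", "), ")", call. = FALSE)
  cycle_rank <- nrow(geometry) - length(nodes) + 1
  if (cycle_rank < 1 && sum(roles == "inlet") > 1)
    warning("network is acyclic: the communicating arteries of a complete ",
            "Circle of Willis are absent", call. = FALSE)
  segs <- data.frame(segment = geometry$segment, node_a = geometry$node_a,
                     node_b = geometry$node_b, length = len, diameter = dia,
                     R_seg = R_seg, L_seg = L_seg, stringsAsFactors = FALSE)
  outlets <- nodes[roles[nodes] == "outlet"]
  if (is.null(outlet_areas)) {
    outlet_areas <- vapply(outlets, function(o) {
      d <- segs$diameter[segs$node_a == o | segs$node_b == o][1]
      pi * d^2 / 4
    }, numeric(1))
  }
  structure(list(nodes = nodes, roles = roles, segments = segs,
                 inlets = nodes[roles[nodes] == "inlet"], outlets = outlets,
                 outlet_areas = outlet_areas, cycle_rank = cycle_rank,
                 fluid = fluid),
            class = "cow_network")
}

#' @export
print.cow_network <- function(x, ...) {
  cat(sprintf("<cow_network> %d segments, %d nodes (%d inlets, %d outlets), cycle rank %d\n",
              nrow(x$segments), length(x$nodes), length(x$inlets),
              length(x$outlets), x$cycle_rank))
  invisible(x)
}

# signed incidence structure and conductance assembly; G in SI (m^3/s/Pa)
assemble_system <- function(net, G) {
  segs <- net$segments
  unknown <- net$nodes[net$roles[net$nodes] != "outlet"]
  iu <- setNames(seq_along(unknown), unknown)
  io <- setNames(seq_along(net$outlets), net$outlets)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  bout_i <- integer(0); bout_j <- integer(0); bout_x <- numeric(0)
  for (s in seq_len(nrow(segs))) {
    a <- segs$node_a[s]; b <- segs$node_b[s]; g <- G[s]
    for (nd in c(a, b)) {
      other <- if (nd == a) b else a
      if (is.na(iu[nd])) next
      trip_i <- c(trip_i, iu[[nd]]); trip_j <- c(trip_j, iu[[nd]])
      trip_x <- c(trip_x, g)
      if (!is.na(iu[other])) {
        trip_i <- c(trip_i, iu[[nd]]); trip_j <- c(trip_j, iu[[other]])
        trip_x <- c(trip_x, -g)
      } else {
        bout_i <- c(bout_i, iu[[nd]]); bout_j <- c(bout_j, io[[other]])
        bout_x <- c(bout_x, g)
      }
    }
  }
  A <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(length(unknown), length(unknown)))
  B <- Matrix::sparseMatrix(i = bout_i, j = bout_j, x = bout_x,
                            dims = c(length(unknown), length(net$outlets)))
  list(A = A, B = B, unknown = unknown, iu = iu)
}

# flows per segment (SI, oriented node_a -> node_b) from full nodal pressures
segment_flows <- function(net, p_all, G, hist = 0) {
  segs <- net$segments
  G * (p_all[segs$node_a] - p_all[segs$node_b]) + hist
}

# net inflow into each outlet node (SI)
outlet_inflows <- function(net, q) {
  segs <- net$segments
  vapply(net$outlets, function(o) {
    sum(q[segs$node_b == o]) - sum(q[segs$node_a == o])
  }, numeric(1))
}

#' Steady resistive solve of a vessel network
#'
#' Solves the purely resistive network (inertance off) once, for constant
#' inlet flows and constant outlet pressures; the long-time limit of
#' [simulate_network()] under constant inputs.
#'
#' @param net a [build_network()] model.
#' @param inlet_flows named vector of inlet flows in mL/min (positive into
#'   the network).
#' @param outlet_pressures named vector of outlet gauge pressures in mmHg.
#' @return A list with `node_pressures` (mmHg, all nodes), `segment_flows`
#'   (mL/min, oriented `node_a -> node_b`), `outlet_flows` (mL/min, positive
#'   out of the network), and the mass-conservation `residual` (relative).
#' @export
steady_solve <- function(net, inlet_flows, outlet_pressures) {
  stopifnot(inherits(net, "cow_network"))
  if (!all(net$inlets %in% names(inlet_flows)))
    stop("inlet_flows must name every inlet: ",
         paste(net$inlets, collapse = ", "), call. = FALSE)
  if (!all(net$outlets %in% names(outlet_pressures)))
    stop("outlet_pressures must name every outlet", call. = FALSE)
  G <- 1 / net$segments$R_seg
  sys <- assemble_system(net, G)
  I <- setNames(numeric(length(sys$unknown)), sys$unknown)
  I[net$inlets] <- mlmin_to_m3s(inlet_flows[net$inlets])
  p_out <- mmHg_to_Pa(outlet_pressures[net$outlets])
  rhs <- I + as.numeric(sys$B %*% p_out)
  p_u <- as.numeric(Matrix::solve(sys$A, rhs))
  p_all <- setNames(numeric(length(net$nodes)), net$nodes)
  p_all[sys$unknown] <- p_u
  p_all[net$outlets] <- p_out
  q <- segment_flows(net, p_all, G)
  q_out <- outlet_inflows(net, q)
  tot_in <- sum(I)
  resid <- abs(tot_in - sum(q_out)) / max(abs(tot_in), 1e-30)
  list(node_pressures = Pa_to_mmHg(p_all),
       segment_flows = setNames(m3s_to_mlmin(q), net$segments$segment),
       outlet_flows = m3s_to_mlmin(q_out),
       residual = resid)
}

#' Transient simulation of the network with pluggable outlet BCs
#'
#' Per time step: (1) evaluate the outlet BC pressures (the Windkessel from
#' its state, the symmetrical-pressure dynamic term from the previous step's
#' outlet flows); (2) solve the nodal Kirchhoff system with the segment law
#' `p_a - p_b = R q + L dq/dt` discretised by backward Euler; (3) advance the
#' Windkessel states with the computed outlet flows by explicit Euler, in the
#' same time step. The sparse nodal matrix is factorised once and reused.
#'
#' @param net a [build_network()] model.
#' @param inlet_flows named list of flow [waveform]s (mL/min), one per inlet;
#'   periodically extended to cover the simulated horizon.
#' @param bc an outlet BC spec covering every outlet of `net`.
#' @param dt time step in seconds (default 1 ms).
#' @param n_cycles number of cardiac cycles to simulate (default 3; the last
#'   cycle is the evaluation window).
#' @param f cardiac frequency in Hz (default 1).
#' @param inertance logical; `FALSE` drops the inertial term (purely
#'   resistive transient).
#' @param init `"steady"` (default; segment-flow history initialised from a
#'   steady solve at t = 0) or `"zero"`.
#' @return An object of class `cow_sim`: named lists of [waveform]s
#'   `inlet_pressure` (mmHg, computed), `outlet_pressure` (mmHg, imposed) and
#'   `outlet_flow` (mL/min, computed), the per-step relative conservation
#'   `residual`, and the simulation settings.
#' @export
simulate_network <- function(net, inlet_flows, bc, dt = 1e-3, n_cycles = 3,
                             f = 1, inertance = TRUE,
                             init = c("steady", "zero")) {
  stopifnot(inherits(net, "cow_network"), dt > 0, n_cycles >= 1)
  init <- match.arg(init)
  if (!all(net$inlets %in% names(inlet_flows)))
    stop("inlet_flows must name every inlet", call. = FALSE)
  if (!all(net$outlets %in% bc$outlets))
    stop("BC spec does not cover outlet(s): ",
         paste(setdiff(net$outlets, bc$outlets), collapse = ", "),
         call. = FALSE)
  if (inherits(bc, "bc_wm") && dt / bc$tau >= 2)
    stop("explicit Euler unstable for the Windkessel state: dt/tau = ",
         signif(dt / bc$tau, 3), " >= 2", call. = FALSE)

  n_steps <- round(n_cycles / f / dt)
  times <- (seq_len(n_steps) - 1) * dt
  segs <- net$segments
  L_eff <- if (inertance) segs$L_seg else numeric(nrow(segs))
  G <- 1 / (segs$R_seg + L_eff / dt)
  wgt <- (L_eff / dt) * G      # history weight: q_k = G*dp + wgt*q_{k-1}
  sys <- assemble_system(net, G)
  A <- Matrix::forceSymmetric(sys$A)
  ch <- Matrix::Cholesky(A, LDL = FALSE)

  # incidence of the inertial history term on the unknown-node equations:
  # rhs_hist[n] = sum_{b(s)=n} hist[s] - sum_{a(s)=n} hist[s]
  ib <- match(segs$node_b, sys$unknown)
  ia <- match(segs$node_a, sys$unknown)
  kb <- which(!is.na(ib)); ka <- which(!is.na(ia))
  Mh <- Matrix::sparseMatrix(
    i = c(ib[kb], ia[ka]), j = c(kb, ka),
    x = c(rep(1, length(kb)), rep(-1, length(ka))),
    dims = c(length(sys$unknown), nrow(segs))
  )

  # imposed inlet flows on the solver grid (SI), periodic extension
  Q_in <- vapply(net$inlets, function(v) {
    mlmin_to_m3s(wf_interp(inlet_flows[[v]], times))
  }, numeric(n_steps))
  if (n_steps == 1) Q_in <- matrix(Q_in, nrow = 1,
                                   dimnames = list(NULL, net$inlets))

  # stateless, flow-independent BCs can be evaluated up front
  P_out <- NULL
  if (inherits(bc, c("bc_zp", "bc_dep", "bc_pm"))) {
    P_out <- vapply(net$outlets, function(o) bc_pressure(bc, o, times),
                    numeric(n_steps))
    if (n_steps == 1) P_out <- matrix(P_out, nrow = 1,
                                      dimnames = list(NULL, net$outlets))
  }

  # initial histories from a steady resistive solve at t = 0
  q_prev <- numeric(nrow(segs))
  q_out_prev <- setNames(numeric(length(net$outlets)), net$outlets)
  if (init == "steady") {
    p0 <- vapply(net$outlets, function(o) bc_pressure(bc, o, 0, Q = 0),
                 numeric(1))
    st <- steady_solve(net, m3s_to_mlmin(setNames(Q_in[1, ], net$inlets)),
                       setNames(p0, net$outlets))
    q_prev <- mlmin_to_m3s(unname(st$segment_flows))
    q_out_prev <- mlmin_to_m3s(st$outlet_flows)
  }

  n_out <- length(net$outlets)
  rec_pin <- matrix(NA_real_, n_steps, length(net$inlets),
                    dimnames = list(NULL, net$inlets))
  rec_pout <- matrix(NA_real_, n_steps, n_out,
                     dimnames = list(NULL, net$outlets))
  rec_qout <- matrix(NA_real_, n_steps, n_out,
                     dimnames = list(NULL, net$outlets))
  resid <- numeric(n_steps)
  I <- setNames(numeric(length(sys$unknown)), sys$unknown)

  for (k in seq_len(n_steps)) {
    p_out_k <- if (!is.null(P_out)) P_out[k, ] else {
      if (inherits(bc, "bc_wm")) {
        Pa_to_mmHg(bc$p_state[net$outlets])
      } else {  # bc_sp: quadratic term lagged by one step
        vapply(net$outlets, function(o) {
          bc_pressure(bc, o, times[k], Q = m3s_to_mlmin(q_out_prev[[o]]))
        }, numeric(1))
      }
    }
    p_out_si <- mmHg_to_Pa(as.numeric(p_out_k))
    hist <- wgt * q_prev
    I[net$inlets] <- Q_in[k, ]
    rhs <- I + as.numeric(Mh %*% hist) + as.numeric(sys$B %*% p_out_si)
    p_u <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    p_all <- setNames(numeric(length(net$nodes)), net$nodes)
    p_all[sys$unknown] <- p_u
    p_all[net$outlets] <- p_out_si
    q <- segment_flows(net, p_all, G, hist)
    q_out <- outlet_inflows(net, q)
    tot_in <- sum(Q_in[k, ])
    resid[k] <- abs(tot_in - sum(q_out)) / max(abs(tot_in), 1e-30)
    rec_pin[k, ] <- Pa_to_mmHg(p_all[net$inlets])
    rec_pout[k, ] <- as.numeric(p_out_k)
    rec_qout[k, ] <- m3s_to_mlmin(q_out)
    if (inherits(bc, "bc_wm"))
      bc <- wm_step(bc, m3s_to_mlmin(q_out), dt)
    q_prev <- q
    q_out_prev <- q_out
  }

  as_wf <- function(mat, quantity) {
    setNames(lapply(colnames(mat), function(v) {
      waveform(mat[, v], 1 / dt, v, quantity)
    }), colnames(mat))
  }
  structure(list(
    inlet_pressure = as_wf(rec_pin, "pressure"),
    outlet_pressure = as_wf(rec_pout, "pressure"),
    outlet_flow = as_wf(rec_qout, "flow"),
    residual = resid, dt = dt, n_cycles = n_cycles, f = f,
    bc_kind = bc$kind, bc_final = bc
  ), class = "cow_sim")
}

#' @export
print.cow_sim <- function(x, ...) {
  cat(sprintf("<cow_sim> bc = %s, %d steps @ dt = %g s (%d cycles), max residual %.2e\n",
              x$bc_kind, length(x$residual), x$dt, x$n_cycles,
              max(x$residual)))
  invisible(x)
}

#' Run one boundary-condition set against a reference recording
#'
#' Derives the requested BC's parameters from the reference recording (unless
#' a ready spec is supplied), wires it to every outlet, and simulates with the
#' recording's inlet flows.
#'
#' @param net a [build_network()] model.
#' @param dataset reference [waveform_set] (inlet flows drive the simulation;
#'   outlet pressures parameterise the BCs).
#' @param bc_kind one of `"zp"`, `"sp"`, `"dep"`, `"wm"`, `"pm"`.
#' @param params optional ready-made BC spec; when `NULL`, parameters are
#'   fitted from `dataset` ([derive_zp()], [derive_sp_params()],
#'   [derive_dep()], [fit_wm_params()], [fit_pm_params()] with the
#'   side-averaged SP mean pressures).
#' @param dt,n_cycles,f simulation settings, see [simulate_network()].
#' @param which cycle selector used for the parameter derivations.
#' @param C_MCA MCA compliance for the Windkessel derivation (m^3/Pa).
#' @param c_n,areas symmetrical-pressure configuration; `areas` defaults to
#'   the network's outlet areas.
#' @param ... passed on to [simulate_network()].
#' @return A `cow_sim`; the spec used is attached as attribute `"bc_spec"`.
#' @export
run_bc_set <- function(net, dataset, bc_kind = c("zp", "sp", "dep", "wm", "pm"),
                       params = NULL, dt = 1e-3, n_cycles = 3, f = 1,
                       which = "all", C_MCA = 8e-11, c_n = NULL,
                       areas = NULL, ...) {
  bc_kind <- match.arg(bc_kind)
  cv <- cow_vessels()
  ci <- segment_cycles(ws_get(dataset, cv$outlets[1], "pressure"), f)
  if (is.null(areas)) areas <- net$outlet_areas
  spec <- params
  if (is.null(spec)) {
    spec <- switch(bc_kind,
      zp = derive_zp(dataset, ci, which),
      sp = derive_sp_params(dataset, c_n, areas, net$fluid$rho, ci, which),
      dep = derive_dep(dataset, f),
      wm = fit_wm_params(dataset, ci, C_MCA, which = which),
      pm = {
        outlets <- cv$outlets
        pw <- setNames(lapply(outlets, ws_get, ws = dataset,
                              quantity = "pressure"), outlets)
        fit_pm_params(pw, f, p_mean = side_averaged_means(dataset, ci, which))
      }
    )
  }
  inflows <- setNames(lapply(cv$inlets, ws_get, ws = dataset,
                             quantity = "flow"), cv$inlets)
  sim <- simulate_network(net, inflows, spec, dt = dt, n_cycles = n_cycles,
                          f = f, ...)
  attr(sim, "bc_spec") <- spec
  sim
}
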