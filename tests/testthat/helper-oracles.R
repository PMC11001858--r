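# Shared fixtures and independent oracles, built in code at test time.

# a sinusoidal waveform m*(1 + a*sin(2*pi*f*t)) sampled at fs
make_sine <- function(mean = 100, amp_frac = 0.25, f = 1, fs = 1000,
                      n_cycles = 3, vessel = "LICA", quantity = "flow",
                      phase = 0) {
  t <- (seq_len(round(n_cycles * fs / f)) - 1) / fs
  waveform(mean * (1 + amp_frac * sin(2 * pi * f * t + phase)), fs,
           vessel, quantity)
}

# Y-shaped test network: one inlet segment into a junction, two branches to
# the MCA outlets. Branch lengths scale the branch resistances.
y_geometry <- function(len_b1 = 10, len_b2 = 10, dia = 3) {
  data.frame(
    segment = c("IN", "B1", "B2"),
    node_a = c("LICA", "J", "J"),
    node_b = c("J", "LMCA", "RMCA"),
    length_mm = c(10, len_b1, len_b2),
    diameter_mm = c(4, dia, dia),
    stringsAsFactors = FALSE
  )
}

# two-segment pipe: inlet -> junction -> single outlet
pipe_geometry <- function() {
  data.frame(
    segment = c("IN", "OUT"),
    node_a = c("LICA", "J"),
    node_b = c("J", "LMCA"),
    length_mm = c(20, 20),
    diameter_mm = c(4, 3),
    stringsAsFactors = FALSE
  )
}

# Independent dense steady-state oracle: assembles the full nodal Laplacian
# as a dense base-R matrix from segment resistances (SI), imposes Dirichlet
# outlet pressures by row substitution, and solves with base::solve.
# inflow: named vector (m^3/s) at inlet nodes; p_out: named vector (Pa).
dense_steady_oracle <- function(geom, R_si, inflow_si, p_out_si) {
  nodes <- unique(c(geom$node_a, geom$node_b))
  n <- length(nodes)
  Lap <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (s in seq_len(nrow(geom))) {
    a <- geom$node_a[s]; b <- geom$node_b[s]; g <- 1 / R_si[s]
    Lap[a, a] <- Lap[a, a] + g
    Lap[b, b] <- Lap[b, b] + g
    Lap[a, b] <- Lap[a, b] - g
    Lap[b, a] <- Lap[b, a] - g
  }
  known <- names(p_out_si)
  unknown <- setdiff(nodes, known)
  rhs <- setNames(numeric(length(unknown)), unknown)
  rhs[names(inflow_si)] <- inflow_si
  rhs <- rhs - as.numeric(Lap[unknown, known, drop = FALSE] %*% p_out_si[known])
  p <- setNames(numeric(n), nodes)
  p[unknown] <- solve(Lap[unknown, unknown, drop = FALSE], rhs)
  p[known] <- p_out_si[known]
  q <- vapply(seq_len(nrow(geom)), function(s) {
    (p[[geom$node_a[s]]] - p[[geom$node_b[s]]]) / R_si[s]
  }, numeric(1))
  list(p = p, q = setNames(q, geom$segment))
}

# Poiseuille resistances of a geometry table, computed independently of the
# package (plain arithmetic on the table)
poiseuille_R <- function(geom, mu = 4.01e-3) {
  128 * mu * (geom$length_mm / 1000) / (pi * (geom$diameter_mm / 1000)^4)
}

# noise-free default synthetic recording (shared across tests)
quiet_default_ws <- function(...) {
  generate_waveform_set(default_config(noise_sd_flow = 0,
                                       noise_sd_pressure = 0, ...))
}

# brute-force extremum oracle for the phase-modulated cosine family:
# max/min of m*(1 + a/2*cos(th + beta*cos(th))) over a dense grid
pm_extrema_oracle <- function(mean, amp, beta, phi = 0, n = 2e5) {
  th <- seq(0, 2 * pi, length.out = n)
  x <- mean * (1 + amp / 2 * cos(th + phi + beta * cos(th + phi)))
  c(max = max(x), min = min(x))
}
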