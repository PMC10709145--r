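# shared fixtures and a per-session cache for expensive simulation runs

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# straight filament along +x with the head (bead 1) at the largest x
straight_state <- function(params, box_L = 42, y = box_L / 2,
                           head_x = box_L / 2 + params$spec$Lf / 2) {
  N <- params$spec$n_bonds
  system_state(cbind(head_x - (0:N) * params$spec$r0, y), N, box_L)
}

# filament at its chiral rest shape (arc of radius ~ r0/dtheta), head last
# laid anticlockwise so the head leads
rest_arc_state <- function(params, box_L = 42) {
  N <- params$spec$n_bonds
  r0 <- params$spec$r0
  dth <- params$spec$dtheta
  R <- r0 / (2 * sin(dth / 2))
  angs <- ((N):0) * dth            # head (bead 1) at the largest angle
  pos <- cbind(box_L / 2 + R * cos(angs * 1), box_L / 2 + R * sin(angs * 1))
  # chord length between consecutive beads on this circle is exactly r0
  system_state(pos, N, box_L)
}

# random mildly-bent chains for gradient tests (kept clear of the boundary)
random_chain_state <- function(n_filaments = 2, n_bonds = 5, seed = 1,
                               box_L = 42, bend_sd = 0.3) {
  set.seed(seed)
  r0 <- bead_r0()
  M <- n_bonds + 1
  pos <- NULL
  for (f in seq_len(n_filaments)) {
    start <- runif(2, 10, box_L - 10)
    ang <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n_bonds - 1, 0, bend_sd)))
    P <- rbind(start, start + cbind(cumsum(r0 * cos(ang)),
                                    cumsum(r0 * sin(ang))))
    pos <- rbind(pos, P)
  }
  system_state(pos, n_bonds, box_L)
}

# numerical gradient of the total potential
numerical_forces <- function(state, params, h = 1e-6) {
  n <- nrow(state$pos)
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) for (k in 1:2) {
    pp <- state$pos; pp[i, k] <- pp[i, k] + h
    pm <- state$pos; pm[i, k] <- pm[i, k] - h
    ep <- potential_energy(system_state(pp, state$M - 1L, state$box_L), params)
    em <- potential_energy(system_state(pm, state$M - 1L, state$box_L), params)
    out[i, k] <- -(ep - em) / (2 * h)
  }
  out
}

# turn angles of plain coordinate chains (head-to-tail traversal)
chain_turns <- function(P) {
  b <- diff(P)
  a <- atan2(b[, 2], b[, 1])
  d <- diff(a)
  (d + pi) %% (2 * pi) - pi
}

frames_positions <- function(traj) lapply(traj$frames, `[[`, "pos")
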