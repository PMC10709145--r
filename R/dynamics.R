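#' Force-field components of a state
#'
#' Evaluates the conservative forces (bond stretching, chiral bending,
#' shifted soft Lennard-Jones pairs) and the tangential propulsion force for
#' every bead, together with the potential energies.  Forces are minus the
#' potential gradient.
#'
#' @param state an [system_state()].
#' @param params an [model_params()].
#' @param use_cells use the cell-list neighbour search (exact; falls back to
#'   brute force in small boxes).
#' @return list with per-bead force matrices `bond`, `bend`, `pair`,
#'   `propulsion` and energies `e_bond`, `e_bend`, `e_pair`.
#' @export
force_components <- function(state, params, use_cells = TRUE) {
  stopifnot(inherits(state, "awlc_state"), inherits(params, "awlc_params"))
  cpp_force_components(state$pos, state$M, state$box_L,
                       .cpp_params(params), use_cells)
}

#' Total potential energy of a state
#' @inheritParams force_components
#' @return total of bond, bend and pair energies (kBT units).
#' @export
potential_energy <- function(state, params, use_cells = TRUE) {
  cpp_potential_energy(state$pos, state$M, state$box_L,
                       .cpp_params(params), use_cells)
}

#' Thermal noise forces
#'
#' White noise with zero mean and total two-dimensional variance
#' 4*kBT*gamma/dt, i.e. variance 2*kBT*gamma/dt per Cartesian component,
#' which reproduces the Einstein relation D = kBT/gamma under the
#' Euler-Maruyama update.
#'
#' @param n number of beads.
#' @param params an [model_params()].
#' @param seed integer seed for the deterministic generator.
#' @return (n x 2) matrix of noise forces.
#' @export
thermal_noise <- function(n, params, seed) {
  cpp_noise_forces(n, params$kBT, params$gamma, params$dt, seed)
}

#' Integrate the equations of motion
#'
#' Overdamped Euler-Maruyama integration
#' `r <- r + dt/gamma * (F_bond + F_bend + F_pair + F_prop + F_noise)` with
#' periodic wrapping.  Bit-reproducible given (state, params, seed).
#'
#' @param state initial [system_state()].
#' @param params an [model_params()].
#' @param n_steps number of timesteps.
#' @param save_every save a frame every this many steps (frame 0 is always
#'   saved; so is the final step).
#' @param seed integer seed; all randomness flows from it.
#' @param use_cells use the cell-list pair path (brute force otherwise; both
#'   yield bit-identical trajectories).
#' @param equilibration_tau frames with `time < equilibration_tau` are
#'   flagged (not removed) so analyses can exclude the equilibration window
#'   uniformly.
#' @return an `awlc_traj`: list with `frames` (list of `awlc_state`),
#'   `times`, `params`, `seed`, `equilibration_tau`.
#' @export
simulate_awlc <- function(state, params, n_steps, save_every = n_steps,
                          seed = 1, use_cells = TRUE,
                          equilibration_tau = 0) {
  stopifnot(inherits(state, "awlc_state"), inherits(params, "awlc_params"),
            n_steps >= 0)
  if (params$attraction && params$r_cut > state$box_L / 2)
    stop("pair cutoff ", params$r_cut, " exceeds box_L/2: minimum image invalid")
  res <- cpp_simulate(state$pos, state$M, state$box_L, .cpp_params(params),
                      as.integer(n_steps), as.integer(max(1, save_every)),
                      seed, state$time, use_cells)
  arr <- res$frames
  times <- res$times
  frames <- lapply(seq_along(times), function(k)
    system_state(arr[, , k], state$M - 1L, state$box_L, time = times[k]))
  structure(list(frames = frames, times = times, params = params,
                 seed = seed, equilibration_tau = equilibration_tau),
            class = "awlc_traj")
}

#' @describeIn simulate_awlc convenience wrapper with durations in tau:
#'   runs `total_tau` and saves every `save_every_tau`.
#' @param total_tau,save_every_tau durations in units of tau.
#' @export
simulate_tau <- function(state, params, total_tau, save_every_tau = 0.2,
                         seed = 1, use_cells = TRUE, equilibration_tau = 4) {
  n_steps <- round(total_tau / params$dt)
  simulate_awlc(state, params, n_steps,
                save_every = max(1, round(save_every_tau / params$dt)),
                seed = seed, use_cells = use_cells,
                equilibration_tau = equilibration_tau)
}

#' @export
print.awlc_traj <- function(x, ...) {
  cat(sprintf(
    "awlc_traj: %d frames, t = %.3g .. %.3g tau (%d filaments, box %g d)\n",
    length(x$frames), min(x$times), max(x$times),
    n_filaments(x$frames[[1]]), x$frames[[1]]$box_L))
  invisible(x)
}

#' @describeIn simulate_awlc single integration step.
#' @export
step_state <- function(state, params, seed = 1, use_cells = TRUE) {
  simulate_awlc(state, params, 1L, save_every = 1L, seed = seed,
                use_cells = use_cells)$frames[[2]]
}

#' Frames of a trajectory after the equilibration window
#'
#' @param traj an `awlc_traj`.
#' @param discard_tau equilibration window to exclude; defaults to the
#'   trajectory's own flag.
#' @return list of `awlc_state` frames with `time >= discard_tau`.
#' @export
production_frames <- function(traj, discard_tau = traj$equilibration_tau) {
  keep <- traj$times >= discard_tau - 1e-9
  if (!any(keep)) stop("no frames after the equilibration window")
  traj$frames[keep]
}
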