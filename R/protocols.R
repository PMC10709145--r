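#' Desk-scale study protocols
#'
#' The canonical study conditions bound into the package, each runnable on
#' one CPU in minutes.  All of them work in the 42 d box at packing
#' fraction 0.4 (the conditions under which the density-fluctuation scaling
#' and the mutant persistence length are quantified) unless noted; problem
#' sizes and run lengths are the package's desk-scale choices, documented
#' in the methods vignette.
#'
#' `study_gnf_active()` — active wild-type preset from a nematic lattice:
#' 4 tau equilibration (discarded) plus `sample_tau` of production frames;
#' returns the sub-box fluctuation scan.
#'
#' `study_gnf_passive()` — the passive (v0 = 0) counterpart at matched
#' mechanics, initialised by stepwise compression (mixed start).  Passive
#' density relaxation is purely diffusive: box-scale modes relax on tens
#' of tau and are effectively frozen at their initialization draw within
#' any desk-scale window, so the study pools the frames of two
#' independent replicas (different compression seeds) — averaging over
#' two draws of the slow modes — each with `equil_tau` discarded and
#' `sample_tau` sampled at 0.5 tau cadence.  Passive production runs at a
#' coarser timestep (2.5e-5 tau, stability factor ~1.2 for the stiffest
#' bending mode), which is immaterial for density observables.
#'
#' `study_l169r_lp()` — the printed mutant parameter set; after a coarse
#' equilibration at the standard timestep, curvature is sampled in a
#' refined-timestep window (delta t = 4.5e-6 tau, where the Euler
#' discretisation error on the joint-angle variance is below ~8%; see the
#' vignette) until at least 1e5 local-curvature samples are pooled, and
#' Lp = 1/(sigma^2 delta_s) is applied in the model's contour measure.
#'
#' `study_charge_neutrality()` — a dense (phi = 0.9) small-box wild-type
#' run; returns the defect detection of the final snapshot, whose total
#' topological charge must vanish.
#'
#' @param seed integer seed (single entropy source per study).
#' @param phi packing fraction.
#' @param box_L box side (d).
#' @param sample_tau production sampling window (tau).
#' @param equil_tau equilibration window (tau).
#' @return see each description; all results carry the generating
#'   trajectory parameters.
#' @name studies
NULL

#' @rdname studies
#' @export
study_gnf_active <- function(seed = 1, phi = 0.4, box_L = 42,
                             sample_tau = 2.5, equil_tau = 4) {
  p <- params_wt()
  st <- lattice_nematic_init(p, box_L, phi = phi, seed = seed)
  traj <- simulate_tau(st, p, total_tau = equil_tau + sample_tau,
                       save_every_tau = 0.15, seed = seed + 1L,
                       equilibration_tau = equil_tau)
  density_fluctuations(traj)
}

#' @rdname studies
#' @export
study_gnf_passive <- function(seed = 1, phi = 0.4, box_L = 42,
                              sample_tau = 6, equil_tau = 8,
                              n_replicas = 2) {
  p <- params_passive(params_wt(dt = 2.5e-5))
  frames <- list()
  for (r in seq_len(n_replicas)) {
    sd_r <- seed + (r - 1L) * 5000L
    st <- stepwise_compression(p, phi, box_L, seed = sd_r)
    traj <- simulate_tau(st, p, total_tau = equil_tau + sample_tau,
                         save_every_tau = 0.5, seed = sd_r + 1L,
                         equilibration_tau = equil_tau)
    frames <- c(frames, production_frames(traj))
  }
  density_fluctuations(frames)
}

#' @rdname studies
#' @param min_samples minimum pooled curvature samples.
#' @export
study_l169r_lp <- function(seed = 1, phi = 0.4, box_L = 42,
                           equil_tau = 4, min_samples = 1e5) {
  p <- params_l169r()
  st <- lattice_nematic_init(p, box_L, phi = phi, seed = seed)
  eq <- simulate_tau(st, p, total_tau = equil_tau,
                     save_every_tau = equil_tau, seed = seed + 1L,
                     equilibration_tau = 0)
  st_eq <- eq$frames[[length(eq$frames)]]
  # refined-timestep sampling window
  p_fine <- params_l169r(dt = 4.5e-6)
  nf <- n_filaments(st_eq)
  samples_per_frame <- nf * (st_eq$M - 2L)
  n_frames <- ceiling(min_samples / samples_per_frame)
  # joint angles decorrelate in ~gamma*r0^2*d/k_bend ~ 1e-4 tau, far below
  # any practical cadence, so frames are statistically independent
  cadence <- 0.025
  tr <- simulate_tau(st_eq, p_fine, total_tau = n_frames * cadence,
                     save_every_tau = cadence, seed = seed + 2L,
                     equilibration_tau = 0)
  res <- sim_persistence_length(tr$frames[-1], units = unit_system())
  res$params <- p
  res
}

#' @rdname studies
#' @param run_tau duration of the generating run.
#' @export
study_charge_neutrality <- function(seed = 1, phi = 0.9, box_L = 30,
                                    run_tau = 1.5) {
  p <- params_wt()
  st <- lattice_nematic_init(p, box_L, phi = phi, seed = seed)
  traj <- simulate_tau(st, p, total_tau = run_tau, save_every_tau = run_tau,
                       seed = seed + 1L, equilibration_tau = 0)
  fin <- traj$frames[[length(traj$frames)]]
  out <- detect_defects(director_field(fin))
  out$state <- fin
  out
}
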