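#' Nematic lattice initial condition
#'
#' Straight filaments are placed on a rectangular lattice, each one
#' independently flipped to point left or right with probability 1/2 (a
#' nematic, polarity-balanced start).  Rows are spaced so that no two beads
#' of distinct filaments are closer than sigma.
#'
#' @param params an [model_params()].
#' @param box_L box side in units of d.
#' @param phi requested packing fraction (used when `n_filaments` is NULL;
#'   converted with [filaments_for_phi()]).
#' @param n_filaments explicit filament count (overrides `phi`).
#' @param seed seed for the orientation coin flips and row jitter.
#' @param jitter fraction of the free axial gap used to jitter filament
#'   x-offsets (breaks the perfect columnar register without ever
#'   producing overlaps; 0 disables).
#' @return an [system_state()] at time 0.
#' @export
lattice_nematic_init <- function(params, box_L, phi = NULL,
                                 n_filaments = NULL, seed = 1,
                                 jitter = 0.5) {
  stopifnot(inherits(params, "awlc_params"), box_L > 0)
  spec <- params$spec
  N <- spec$n_bonds
  M <- N + 1L
  if (is.null(n_filaments)) {
    if (is.null(phi)) stop("give either phi or n_filaments")
    n_filaments <- filaments_for_phi(phi, N, box_L, spec$r0)
  }
  if (n_filaments < 1) stop("no filaments requested")
  Lf_real <- N * spec$r0
  ncol_ <- max(1L, floor(box_L / (Lf_real + params$sigma)))
  nrow_ <- ceiling(n_filaments / ncol_)
  dy <- box_L / nrow_
  if (dy < params$sigma) {
    max_nf <- floor(box_L / params$sigma) * ncol_
    stop("requested phi ", signif(packing_fraction(N, n_filaments, box_L), 3),
         " unreachable on a non-overlapping lattice; maximum feasible phi is ",
         signif(packing_fraction(N, max_nf, box_L), 3))
  }
  dx <- box_L / ncol_
  slack <- dx - Lf_real - params$sigma   # free axial gap per lattice slot
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  pos <- matrix(0, n_filaments * M, 2)
  for (f in seq_len(n_filaments)) {
    row <- (f - 1) %/% ncol_
    col <- (f - 1) %% ncol_
    y0 <- (row + 0.5) * dy
    xoff <- if (jitter > 0 && slack > 0) runif(1, 0, jitter * slack) else 0
    x0 <- col * dx + params$sigma / 2 + xoff
    xs <- x0 + (0:N) * spec$r0
    if (runif(1) < 0.5) xs <- rev(xs)     # head-left vs head-right
    pos[(f - 1) * M + seq_len(M), ] <- cbind(xs, y0)
  }
  system_state(pos, N, box_L)
}

# swap R's RNG state for a locally seeded stream, restoring afterwards
.seed_swap <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Stepwise-compression initial condition
#'
#' For dense systems that must start well mixed: filaments are first placed
#' at low density (phi <= 0.25) on a nematic lattice in an enlarged box,
#' mixed under strong thermal noise, then the box is shrunk affinely in
#' small steps, each followed by a short relaxation run, until the target
#' packing fraction is reached.
#'
#' The mixing temperature is chosen so that the mixing-stage Peclet number
#' is `mixing_Pe` (for passive systems, where Pe is undefined, the
#' temperature is raised by the same factor relative to the production
#' temperature).
#'
#' @param params an [model_params()].
#' @param phi_target target packing fraction (> 0 and <= ~1).
#' @param box_L_target final box side; the filament count is chosen as
#'   [filaments_for_phi()] at the target.
#' @param phi_start starting packing fraction for the mixing stage.
#' @param mixing_Pe Peclet number of the mixing stage.
#' @param mixing_tau duration of the mixing run, in tau.
#' @param shrink fractional box-side reduction per compression step.
#' @param relax_tau relaxation run after each shrink, in tau.
#' @param seed integer seed; all stages draw from it deterministically.
#' @param verbose print the protocol as it runs.
#' @return an [system_state()] at the target phi (time reset to 0).
#' @export
stepwise_compression <- function(params, phi_target, box_L_target,
                                 phi_start = 0.25, mixing_Pe = 100,
                                 mixing_tau = 1, shrink = 0.05,
                                 relax_tau = 0.2, seed = 1,
                                 verbose = FALSE) {
  stopifnot(inherits(params, "awlc_params"), phi_target > 0,
            phi_start > 0, phi_start <= 0.25 + 1e-9, shrink > 0, shrink < 0.5)
  spec <- params$spec
  nf <- filaments_for_phi(phi_target, spec$n_bonds, box_L_target, spec$r0)
  if (nf < 1) stop("target phi yields no filaments")
  phi_start <- min(phi_start, phi_target)
  L0 <- max(box_L_target, sqrt(spec$n_bonds * nf * spec$r0 / phi_start))
  st <- lattice_nematic_init(params, L0, n_filaments = nf, seed = seed)

  # mixing stage: high thermal noise.  The hot stage runs at a quarter of
  # the production timestep: the strong noise lets beads climb far up the
  # soft repulsion, where the pair stiffness would make the full timestep
  # marginal.
  p_mix <- params
  p_mix$kBT <- if (params$f_p > 0) params$f_p * spec$Lf^2 / mixing_Pe
               else params$kBT * mixing_Pe / 10
  p_mix$dt <- params$dt / 4
  if (verbose)
    message(sprintf("mixing: L = %.2f d (phi = %.3f), kBT = %.3g, %g tau",
                    L0, state_phi(st), p_mix$kBT, mixing_tau))
  tr <- simulate_tau(st, p_mix, mixing_tau, save_every_tau = mixing_tau,
                     seed = seed + 1L, equilibration_tau = 0)
  st <- tr$frames[[length(tr$frames)]]

  # compression ladder
  k <- 2L
  while (st$box_L > box_L_target * (1 + 1e-12)) {
    Lnew <- max(box_L_target, st$box_L * (1 - shrink))
    scale <- Lnew / st$box_L
    st <- system_state(st$pos * scale, spec$n_bonds, Lnew, time = st$time)
    tr <- simulate_tau(st, params, relax_tau, save_every_tau = relax_tau,
                       seed = seed + k, equilibration_tau = 0)
    st <- tr$frames[[length(tr$frames)]]
    if (verbose)
      message(sprintf("  shrink -> L = %.2f d (phi = %.3f)", Lnew, state_phi(st)))
    k <- k + 1L
  }

  # overlap guard: retry relaxation a bounded number of times.  At kBT = 1
  # the soft pair potential thermally allows occasional contacts slightly
  # below 0.5*sigma (the barrier there is only a few kBT), so the guard
  # triggers at 0.35*sigma, where the Boltzmann weight is negligible and
  # any contact indicates a genuinely unrelaxed overlap.
  for (try in 1:3) {
    if (.min_interfilament_dist(st) >= 0.35 * params$sigma) break
    if (try == 3)
      stop("stepwise compression failed to relax overlaps below 0.35*sigma")
    tr <- simulate_tau(st, params, relax_tau, save_every_tau = relax_tau,
                       seed = seed + 1000L + try, equilibration_tau = 0)
    st <- tr$frames[[length(tr$frames)]]
  }
  st$time <- 0
  st
}

# minimum inter-filament bead distance under the minimum image
.min_interfilament_dist <- function(state) {
  P <- state$pos
  L <- state$box_L
  f <- filament_of(state)
  n <- nrow(P)
  ## chunked to bound memory
  best <- Inf
  step <- 512L
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(n, i0 + step - 1L)
    dx <- abs(outer(P[ii, 1], P[, 1], "-")); dx <- pmin(dx, L - dx)
    dy <- abs(outer(P[ii, 2], P[, 2], "-")); dy <- pmin(dy, L - dy)
    d2 <- dx^2 + dy^2
    same <- outer(f[ii], f, "==")
    d2[same] <- Inf
    best <- min(best, min(d2))
  }
  sqrt(best)
}
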