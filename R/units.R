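#' @useDynLib activewlc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd mad rnorm runif coef nls median setNames
#' @importFrom utils head tail
NULL

# Bond rest length and bead radius in units of the effective bead diameter d:
# the overlapping-bead construction fixes d = 2*sqrt(2)*r0.
.r0 <- 1 / (2 * sqrt(2))

#' Bond length / bead radius in reduced units
#'
#' The chain is built from beads of radius r0 placed one bond length r0
#' apart, so neighbouring beads overlap; the effective filament diameter is
#' d = 2*sqrt(2)*r0 = 1 in reduced units.
#' @return r0 in units of d (a number, 1/(2*sqrt(2))).
#' @export
bead_r0 <- function() .r0

#' Reduced-unit system and physical mapping
#'
#' Lengths are measured in units of the effective bead diameter d, energies
#' in units of the thermal energy kBT, and times in units of the rotation
#' period tau of a single isolated wild-type filament without noise.  The
#' physical mapping used for FtsZ on supported bilayers is 1 d = 50 nm and
#' tau = 78.5 s (the period of a ring of 1 um diameter treadmilling at
#' 0.04 um/s).
#'
#' @param nm_per_d physical length of one reduced length unit, in nm.
#' @param s_per_tau physical duration of one reduced time unit, in s.
#' @param d,tau,kBT reduced base units; must be 1 for the reduced system
#'   used throughout (kept explicit for auditability).
#' @return an object of class `awlc_units`.
#' @export
unit_system <- function(nm_per_d = 50, s_per_tau = 78.5,
                        d = 1, tau = 1, kBT = 1) {
  stopifnot(nm_per_d > 0, s_per_tau > 0, d > 0, tau > 0, kBT > 0)
  structure(list(d = d, tau = tau, kBT = kBT,
                 nm_per_d = nm_per_d, s_per_tau = s_per_tau),
            class = "awlc_units")
}

.unit_factor <- function(kind, units) {
  nm <- units$nm_per_d
  s <- units$s_per_tau
  switch(kind,
    length    = nm,                 # d      -> nm
    time      = s,                  # tau    -> s
    speed     = (nm / 1000) / s,    # d/tau  -> um/s
    curvature = 1 / (nm / 1000),    # rad/d  -> rad/um
    area      = (nm / 1000)^2,      # d^2    -> um^2
    area_density = 1 / (nm / 1000)^2,  # 1/d^2 -> 1/um^2
    stop("unknown unit kind: ", kind)
  )
}

#' Convert reduced quantities to physical units (and back)
#'
#' Multiplicative conversion using the mapping stored in an `awlc_units`
#' object.  Kinds and physical units: `length` (nm), `time` (s), `speed`
#' (um/s), `curvature` (rad/um), `area` (um^2), `area_density` (1/um^2).
#'
#' @param x numeric vector in reduced units (or physical units for
#'   [from_physical()]).
#' @param kind one of the unit kinds listed above.
#' @param units an [unit_system()] object.
#' @return numeric vector in the corresponding physical (or reduced) units.
#' @examples
#' to_physical(0.174, "curvature")   # ~3.48 rad/um
#' to_physical(1, "length")          # 50 nm
#' @export
to_physical <- function(x, kind = c("length", "time", "speed", "curvature",
                                    "area", "area_density"),
                        units = unit_system()) {
  kind <- match.arg(kind)
  x * .unit_factor(kind, units)
}

#' @rdname to_physical
#' @export
from_physical <- function(x, kind = c("length", "time", "speed", "curvature",
                                      "area", "area_density"),
                          units = unit_system()) {
  kind <- match.arg(kind)
  x / .unit_factor(kind, units)
}

#' Rotation period of a treadmilling ring
#'
#' The reduced time unit tau is defined as the rotation period of a single
#' isolated wild-type filament; for a circular path this is
#' pi * diameter / speed.  With the canonical ring diameter of 1 um and
#' treadmilling speed 0.04 um/s this reproduces tau = 78.5 s.
#'
#' @param diameter_um ring diameter in um.
#' @param speed_um_s treadmilling speed in um/s.
#' @return period in seconds.
#' @export
ring_period_s <- function(diameter_um = 1, speed_um_s = 0.04) {
  stopifnot(diameter_um > 0, speed_um_s > 0)
  pi * diameter_um / speed_um_s
}

#' Filament geometry
#'
#' A filament is N+1 beads of radius r0 joined by N bonds of rest length r0,
#' with intrinsic (chiral) bending angle dtheta per joint.  The rest interior
#' angle is theta0 = pi - dtheta; the rest shape is an arc of geometric
#' curvature dtheta/r0.
#'
#' @param n_bonds integer number of bonds N (>= 2).
#' @param dtheta signed intrinsic bending angle per joint, radians.
#' @param r0 bond length and bead radius in units of d.
#' @return an object of class `awlc_filament` with fields `n_bonds`, `r0`,
#'   `Lf` (= N*r0), `dtheta`, `theta0`.
#' @export
filament_spec <- function(n_bonds = 23, dtheta = wt_dtheta(), r0 = bead_r0()) {
  n_bonds <- as.integer(n_bonds)
  stopifnot(n_bonds >= 2, r0 > 0, is.finite(dtheta))
  structure(list(n_bonds = n_bonds, r0 = r0, Lf = n_bonds * r0,
                 dtheta = dtheta, theta0 = pi - dtheta),
            class = "awlc_filament")
}

#' @describeIn filament_spec build a spec from a requested contour length;
#'   N is rounded to the nearest integer at fixed r0 and the realised Lf is
#'   recorded (length error below 2 percent for the presets).
#' @param Lf requested filament length in units of d.
#' @export
filament_spec_from_length <- function(Lf, dtheta = 0, r0 = bead_r0()) {
  filament_spec(round(Lf / r0), dtheta = dtheta, r0 = r0)
}

#' Wild-type intrinsic bending angle
#'
#' Derived from the intrinsic filament curvature of 3.48 rad/um under the
#' 1 d = 50 nm mapping: kappa = 0.174 rad/d, and dtheta = kappa * r0.  The
#' corresponding single-filament rotation diameter is 2 r0/dtheta ~ 575 nm.
#' @return dtheta in radians.
#' @export
wt_dtheta <- function() {
  from_physical(3.48, "curvature") * bead_r0()
}

#' Model parameters for the chiral active worm-like chain
#'
#' Resolves the full parameter set from the dimensionless groups.  The
#' propulsion force per unit length is `f_p = gamma*v0/d` (each bead carries
#' a tangential force of magnitude `gamma*v0`, accounted per unit of the
#' reduced length unit d), so for active filaments
#' `gamma = f_p/v0`, `kBT = f_p*Lf^2/Pe` and `k_bend = f_p*Lf^3/Fn`.
#' With `kBT = 1` (the reduced energy unit) this fixes `f_p = Pe/Lf^2`.
#'
#' For passive filaments (`v0 = 0`) the groups vanish and `gamma` and
#' `k_bend` must be supplied explicitly (conventionally those of the active
#' system being compared against).
#'
#' @param spec an [filament_spec()].
#' @param v0 self-propulsion speed in d/tau (0 for passive).
#' @param Pe Peclet number f_p*Lf^2/kBT (active only).
#' @param Fn flexure number f_p*Lf^3/k_bend (active only).
#' @param gamma friction coefficient; derived from (Pe, v0) when NULL.
#' @param k_bend bending rigidity (energy x length); derived from Fn when NULL.
#' @param kBT effective temperature (energy units).
#' @param k_bond bond spring constant (energy/length^2); large enough to keep
#'   bonds near r0.
#' @param epsilon pair-well depth in kBT.
#' @param attraction logical; FALSE truncates the pair potential at its
#'   minimum sqrt(2)*sigma (purely repulsive), TRUE keeps the attractive
#'   well out to `r_cut_factor * sigma`.
#' @param r_cut_factor cutoff in units of sigma for attractive interactions.
#' @param dt integration timestep in tau.
#' @param Lf_group nominal filament length used in the dimensionless
#'   groups (defaults to the realised `spec$Lf`); the printed parameter
#'   sets quote round lengths (8 d, 16 d) while bond-count rounding makes
#'   the realised contour slightly longer.
#' @param units an [unit_system()].
#' @return an object of class `awlc_params`.
#' @examples
#' p <- params_l169r()
#' p$k_bend            # 240 kBT d
#' dimensionless_groups(p)
#' @export
model_params <- function(spec, v0, Pe = NULL, Fn = NULL, gamma = NULL,
                         k_bend = NULL, kBT = 1, k_bond = 2000,
                         epsilon = 0.1, attraction = TRUE,
                         r_cut_factor = 2.5, dt = 1.8e-5,
                         Lf_group = spec$Lf, units = unit_system()) {
  stopifnot(inherits(spec, "awlc_filament"), v0 >= 0, kBT >= 0, k_bond > 0,
            epsilon >= 0, dt > 0, Lf_group > 0)
  sigma <- 2 * spec$r0
  Lf <- Lf_group
  if (v0 > 0) {
    if (is.null(Pe) && is.null(gamma))
      stop("active filaments need either Pe or gamma")
    if (!is.null(Pe)) {
      if (kBT <= 0) stop("Pe is undefined at kBT = 0; pass gamma instead")
      f_p <- Pe * kBT / Lf^2
      gamma <- f_p / v0
    } else {
      f_p <- gamma * v0
    }
    if (is.null(k_bend)) {
      if (is.null(Fn)) stop("active filaments need either Fn or k_bend")
      stopifnot(Fn > 0)
      k_bend <- f_p * Lf^3 / Fn
    }
  } else {
    f_p <- 0
    if (is.null(gamma) || is.null(k_bend))
      stop("passive filaments (v0 = 0) need explicit gamma and k_bend")
  }
  stopifnot(gamma > 0, k_bend > 0)
  r_cut <- if (attraction && epsilon > 0) r_cut_factor * sigma else sqrt(2) * sigma
  structure(list(spec = spec, Lf_group = Lf_group, v0 = v0, f_p = f_p,
                 gamma = gamma,
                 k_bend = k_bend, kBT = kBT, k_bond = k_bond,
                 epsilon = epsilon, sigma = sigma, r_cut = r_cut,
                 attraction = attraction && epsilon > 0,
                 dt = dt, units = units),
            class = "awlc_params")
}

#' @export
print.awlc_params <- function(x, ...) {
  g <- dimensionless_groups(x)
  cat(sprintf(
    "chiral active worm-like chain parameters\n  N = %d bonds, r0 = %.4f d, Lf = %.3f d, dtheta = %.4f rad\n  v0 = %g d/tau, f_p = %.4g kBT/d^2, gamma = %.4g, kBT = %g\n  k_bond = %g, k_bend = %.4g kBT d, epsilon = %g kBT\n  sigma = %.4f d, r_cut = %.4f d (%s), dt = %g tau\n  Pe = %.4g, flexure number = %.4g\n",
    x$spec$n_bonds, x$spec$r0, x$spec$Lf, x$spec$dtheta,
    x$v0, x$f_p, x$gamma, x$kBT,
    x$k_bond, x$k_bend, x$epsilon,
    x$sigma, x$r_cut, if (x$attraction) "attractive" else "repulsive-only",
    x$dt, g$Pe, g$Fn))
  invisible(x)
}

#' Dimensionless groups of a parameter set
#'
#' Pe = f_p*Lf^2/kBT (propulsion vs thermal forces) and the flexure number
#' Fn = f_p*Lf^3/k_bend (propulsion vs bending rigidity).  Their ratio obeys
#' Pe/Fn = k_bend/(kBT*Lf).
#'
#' @param params an [model_params()] object.
#' @return list with `Pe` and `Fn`.
#' @export
dimensionless_groups <- function(params) {
  stopifnot(inherits(params, "awlc_params"))
  if (params$kBT <= 0 || params$k_bend <= 0)
    stop("dimensionless groups undefined: kBT and k_bend must be positive")
  Lf <- if (!is.null(params$Lf_group)) params$Lf_group else params$spec$Lf
  list(Pe = params$f_p * Lf^2 / params$kBT,
       Fn = params$f_p * Lf^3 / params$k_bend)
}

#' @describeIn dimensionless_groups inverse helper: solve for (k_bend, kBT)
#'   given the groups, the speed, the filament length and the friction.
#' @param Pe,Fn,v0,Lf,gamma scalars; see [model_params()] for meanings.
#' @export
solve_stiffness <- function(Pe, Fn, v0, Lf, gamma) {
  stopifnot(Pe > 0, Fn > 0, v0 > 0, Lf > 0, gamma > 0)
  f_p <- gamma * v0
  list(k_bend = f_p * Lf^3 / Fn, kBT = f_p * Lf^2 / Pe)
}

#' Packing fraction
#'
#' phi = N * Nf * d * r0 / L^2: each filament covers an area of N bonds times
#' (d x r0).
#'
#' @param n_bonds bonds per filament N.
#' @param n_filaments number of filaments Nf.
#' @param box_L box side in units of d.
#' @param r0 bond length.
#' @return packing fraction (dimensionless).
#' @examples
#' packing_fraction(23, 87, 42)   # ~0.40
#' @export
packing_fraction <- function(n_bonds, n_filaments, box_L, r0 = bead_r0()) {
  stopifnot(box_L > 0, n_bonds >= 1, n_filaments >= 0)
  n_bonds * n_filaments * 1 * r0 / box_L^2
}

#' @describeIn packing_fraction number of filaments matching a requested
#'   packing fraction (rounded down).
#' @param phi requested packing fraction.
#' @export
filaments_for_phi <- function(phi, n_bonds, box_L, r0 = bead_r0()) {
  stopifnot(phi >= 0)
  as.integer(floor(phi * box_L^2 / (n_bonds * r0)))
}

# ---- presets -------------------------------------------------------------

#' Preset parameter sets
#'
#' `params_wt()` is the wild-type FtsZ best-match set: Lf = 8 d (N = 23),
#' flexure number 40, epsilon = 0.1 kBT with attraction, intrinsic curvature
#' 3.48 rad/um, Pe = 900 and v0 = 29 d/tau (the midpoint reading of the
#' reported Pe range 700-1300 together with the mutant set being three times
#' lower in Pe and eight times lower in v0).
#'
#' `params_l169r()` is the printed mutant set: v0 = 3.625 d/tau, Pe = 300,
#' flexure number 20, Lf = 16 d (N = 46), dtheta = 0, giving
#' k_bend = 240 kBT d.
#'
#' `params_passive()` takes any active set and switches off propulsion while
#' keeping gamma, k_bend, kBT and the interaction parameters, for
#' active-vs-passive comparisons at matched mechanics.
#'
#' @param dt integration timestep in tau.
#' @param ... passed on to [model_params()].
#' @return an `awlc_params` object.
#' @export
params_wt <- function(dt = 1.8e-5, ...) {
  model_params(filament_spec(n_bonds = 23, dtheta = wt_dtheta()),
               v0 = 29, Pe = 900, Fn = 40, epsilon = 0.1,
               attraction = TRUE, dt = dt, Lf_group = 8, ...)
}

#' @rdname params_wt
#' @export
params_l169r <- function(dt = 1.8e-5, ...) {
  model_params(filament_spec(n_bonds = 46, dtheta = 0),
               v0 = 3.625, Pe = 300, Fn = 20, epsilon = 0.1,
               attraction = TRUE, dt = dt, Lf_group = 16, ...)
}

#' @rdname params_wt
#' @param params an active `awlc_params` object to make passive.
#' @export
params_passive <- function(params, dt = params$dt) {
  stopifnot(inherits(params, "awlc_params"))
  model_params(params$spec, v0 = 0, gamma = params$gamma,
               k_bend = params$k_bend, kBT = params$kBT,
               k_bond = params$k_bond, epsilon = params$epsilon,
               attraction = params$attraction,
               r_cut_factor = params$r_cut / params$sigma,
               dt = dt, Lf_group = params$Lf_group, units = params$units)
}

# parameter list handed to the C++ core
.cpp_params <- function(params) {
  list(r0 = params$spec$r0, dtheta = params$spec$dtheta,
       k_bond = params$k_bond, k_bend = params$k_bend,
       epsilon = params$epsilon, sigma = params$sigma,
       r_cut = params$r_cut, gamma = params$gamma, v0 = params$v0,
       kBT = params$kBT, dt = params$dt)
}
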