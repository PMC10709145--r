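#' Synthetic director field with prescribed defects
#'
#' Builds the director grid angle(r) = sum_k q_k * atan2(y - y_k, x - x_k)
#' + const, reduced mod pi — the canonical nematic texture with topological
#' charges q_k at positions (x_k, y_k).  On a periodic grid the total
#' charge must vanish.
#'
#' @param charges data.frame with `x`, `y` (in d) and `q` (each in
#'   {-1, -1/2, 1/2, 1}).
#' @param n_grid cells per side.
#' @param pitch grid pitch (d per cell).
#' @param const global angle offset (rad).
#' @param periodic enforce charge neutrality (TRUE for periodic fixtures).
#' @return an `awlc_director` with full occupancy.
#' @export
make_defect_field <- function(charges, n_grid = 12, pitch = 4.7, const = 0,
                              periodic = TRUE) {
  stopifnot(all(abs(charges$q * 2 - round(charges$q * 2)) < 1e-9))
  if (periodic && abs(sum(charges$q)) > 1e-9)
    stop("periodic defect field requires zero total charge")
  ctr <- (seq_len(n_grid) - 0.5) * pitch
  ang <- matrix(const, n_grid, n_grid)
  for (k in seq_len(nrow(charges))) {
    ang <- ang + charges$q[k] *
      outer(ctr - charges$x[k], ctr - charges$y[k],
            function(dx, dy) atan2(dy, dx))
  }
  structure(list(angle = ang %% pi,
                 occupancy = matrix(1L, n_grid, n_grid),
                 pitch = pitch, n_grid = n_grid, box_L = n_grid * pitch,
                 time = 0),
            class = "awlc_director")
}

#' Sample discrete worm-like chains
#'
#' 2D discrete worm-like chains with independent Gaussian joint angles:
#' mean `dtheta_mean` (spontaneous curvature) and variance
#' `delta_s / Lp` — the 2D convention under which the curvature estimator
#' Lp = 1/(sigma^2 delta_s) and the tangent-correlation e-folding length
#' 2*Lp are exact.
#'
#' @param Lp persistence length (same length unit as `delta_s`).
#' @param n_chains number of chains.
#' @param n_bonds bonds per chain.
#' @param delta_s contour spacing between beads.
#' @param dtheta_mean mean turn per joint (rad).
#' @param seed integer seed.
#' @return list of ((n_bonds+1) x 2) coordinate matrices.
#' @export
sample_wlc_chains <- function(Lp, n_chains, n_bonds, delta_s = bead_r0(),
                              dtheta_mean = 0, seed = 1) {
  stopifnot(Lp > 0, n_bonds >= 2)
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  sdv <- sqrt(delta_s / Lp)
  lapply(seq_len(n_chains), function(k) {
    turns <- rnorm(n_bonds - 1, dtheta_mean, sdv)
    ang <- cumsum(c(runif(1, 0, 2 * pi), turns))
    P <- rbind(c(0, 0), cbind(cumsum(delta_s * cos(ang)),
                              cumsum(delta_s * sin(ang))))
    P
  })
}

#' Poisson gas and lattice gas point fixtures
#'
#' `poisson_gas()` draws uniform random points (count fluctuation exponent
#' 1/2); `lattice_gas()` places a perfect square lattice (strongly
#' suppressed fluctuations).  Both are anchors for
#' [density_fluctuations()].
#'
#' @param n number of points.
#' @param box_L box side.
#' @param seed integer seed.
#' @return (n x 2) coordinate matrix.
#' @export
poisson_gas <- function(n, box_L, seed = 1) {
  stopifnot(n > 0, box_L > 0)
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  cbind(runif(n, 0, box_L), runif(n, 0, box_L))
}

#' @rdname poisson_gas
#' @param spacing lattice constant.
#' @export
lattice_gas <- function(spacing, box_L) {
  stopifnot(spacing > 0, box_L >= spacing)
  g <- seq(spacing / 2, box_L, by = spacing)
  as.matrix(expand.grid(x = g, y = g))
}

#' Synthetic ring scene
#'
#' Builds an [system_state()] containing `n_rings` closed rings — arc-shaped
#' filaments arranged tangentially around circles, polarity-balanced by
#' construction — plus `clutter` straight filaments scattered away from the
#' rings.  Ground truth for the ring-detection pipeline.
#'
#' @param n_rings number of rings.
#' @param radius ring radius (d).
#' @param members filaments per ring (> 10 to pass the size filter).
#' @param clutter number of scattered straight filaments.
#' @param box_L box side.
#' @param n_bonds bonds per filament.
#' @param seed integer seed (clutter placement and ring centres).
#' @param open_arcs if TRUE, build open arcs: all member filaments oriented
#'   the same way (fails the polarity filter) instead of tangentially
#'   closed.
#' @return an `awlc_state`; ring centres are attached as attribute
#'   `ring_centers`.
#' @export
ring_scene <- function(n_rings = 1, radius = 4, members = 15, clutter = 0,
                       box_L = 42, n_bonds = 23, seed = 1,
                       open_arcs = FALSE) {
  r0 <- bead_r0()
  M <- n_bonds + 1L
  old <- .seed_swap(seed)
  on.exit(.seed_restore(old))
  # ring centres on a coarse grid to guarantee separation
  ngrid <- floor(box_L / (2 * radius + 3))
  if (ngrid^2 < n_rings)
    stop("rings do not fit the box without overlap")
  slots <- as.matrix(expand.grid(seq_len(ngrid), seq_len(ngrid)))
  slots <- slots[sample(nrow(slots), n_rings), , drop = FALSE]
  centers <- (slots - 0.5) * box_L / ngrid
  pos <- NULL
  dphi <- r0 / radius                     # angular step per bead on the arc
  for (rg in seq_len(n_rings)) {
    for (m in seq_len(members)) {
      if (open_arcs) {
        # every member is the same arc segment at a slightly different
        # radius: rotation centres still cluster at the ring centre, but
        # all orientations coincide, so the polarity filter must reject
        rad_m <- radius + (m - 1) * 0.12
        angs <- ((M - 1):0) * (r0 / rad_m)
      } else {
        # members tile the circle tangentially; heads lead anticlockwise
        # (head = bead 1 at the largest angle), so orientations cancel
        rad_m <- radius
        phase <- 2 * pi * (m - 1) / members
        angs <- phase + ((M - 1):0) * dphi
      }
      pos <- rbind(pos, cbind(centers[rg, 1] + rad_m * cos(angs),
                              centers[rg, 2] + rad_m * sin(angs)))
    }
  }
  # clutter: straight filaments placed away from every ring
  placed <- 0
  while (placed < clutter) {
    p0 <- runif(2, 0, box_L)
    a <- runif(1, 0, 2 * pi)
    P <- cbind(p0[1] + (0:n_bonds) * r0 * cos(a),
               p0[2] + (0:n_bonds) * r0 * sin(a))
    dmin <- min(sqrt(outer(P[, 1], centers[, 1], "-")^2 +
                     outer(P[, 2], centers[, 2], "-")^2))
    if (dmin < 2 * radius + 1) next
    pos <- rbind(pos, P)
    placed <- placed + 1
  }
  st <- system_state(pos, n_bonds, box_L)
  attr(st, "ring_centers") <- centers
  st
}
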