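#' Instantaneous rotation centres of filaments
#'
#' Algebraic (Taubin) circle fit to each filament's unwrapped bead
#' coordinates.  Near-straight filaments — collinear beads or a fit radius
#' exceeding the box size — are flagged and excluded from downstream
#' clustering rather than treated as errors.
#'
#' @param state an [system_state()].
#' @param max_radius fit radii above this are flagged as straight
#'   (default: the box side).
#' @return data.frame with `filament`, `cx`, `cy` (wrapped into the box),
#'   `radius`, `straight` (logical flag).
#' @export
rotation_centers <- function(state, max_radius = state$box_L) {
  cs <- filament_coords(state)
  L <- state$box_L
  out <- lapply(seq_along(cs), function(f) {
    fit <- .taubin_circle(cs[[f]])
    if (is.null(fit) || !is.finite(fit$r) || fit$r > max_radius)
      return(data.frame(filament = f, cx = NA_real_, cy = NA_real_,
                        radius = if (is.null(fit)) Inf else fit$r,
                        straight = TRUE))
    data.frame(filament = f, cx = fit$cx %% L, cy = fit$cy %% L,
               radius = fit$r, straight = FALSE)
  })
  do.call(rbind, out)
}

# Taubin algebraic circle fit; returns NULL for degenerate (collinear) input
.taubin_circle <- function(P) {
  x <- P[, 1] - mean(P[, 1])
  y <- P[, 2] - mean(P[, 2])
  z <- x^2 + y^2
  Zm <- mean(z)
  # solve the Taubin eigenproblem via the characteristic polynomial
  Mxx <- mean(x * x); Myy <- mean(y * y); Mxy <- mean(x * y)
  Mxz <- mean(x * z); Myz <- mean(y * z); Mzz <- mean(z * z)
  # Newton iteration on the Taubin characteristic polynomial
  Mz <- Mxx + Myy
  Cov_xy <- Mxx * Myy - Mxy * Mxy
  A3 <- 4 * Mz
  A2 <- -3 * Mz * Mz - Mzz
  A1 <- Mzz * Mz + 4 * Cov_xy * Mz - Mxz * Mxz - Myz * Myz - Mz * Mz * Mz
  A0 <- Mxz * Mxz * Myy + Myz * Myz * Mxx - Mzz * Cov_xy -
    2 * Mxz * Myz * Mxy + Mz * Mz * Cov_xy
  t <- 0
  for (i in 1:30) {
    Dy <- A1 + t * (2 * A2 + t * 3 * A3)
    ynew <- A0 + t * (A1 + t * (A2 + t * A3))
    if (abs(Dy) < 1e-14) break
    tnew <- t - ynew / Dy
    if (!is.finite(tnew) || abs(tnew - t) < 1e-14) { t <- tnew; break }
    t <- tnew
  }
  DET <- t * t - t * Mz + Cov_xy
  if (!is.finite(DET) || abs(DET) < 1e-12) return(NULL)
  cx <- (Mxz * (Myy - t) - Myz * Mxy) / DET / 2
  cy <- (Myz * (Mxx - t) - Mxz * Mxy) / DET / 2
  r <- sqrt(cx^2 + cy^2 + Mz - 2 * t)
  list(cx = cx + mean(P[, 1]), cy = cy + mean(P[, 2]), r = r)
}

#' Single-linkage clustering under a distance cutoff
#'
#' Connected components of the graph joining points closer than `cutoff`
#' under the minimum image.  The canonical cutoff for rotation-centre
#' clustering is half the mean inter-filament distance, L/(2*sqrt(Nf)).
#'
#' @param points matrix (n x 2), or data.frame with `cx`, `cy`.
#' @param box_L box side (set to `Inf` for open space).
#' @param cutoff linking distance.
#' @return integer vector of cluster labels (1-based, arbitrary order).
#' @export
cluster_points <- function(points, box_L, cutoff) {
  if (is.data.frame(points)) points <- cbind(points$cx, points$cy)
  n <- nrow(points)
  if (n == 0) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  dx <- abs(outer(points[, 1], points[, 1], "-"))
  dy <- abs(outer(points[, 2], points[, 2], "-"))
  if (is.finite(box_L)) { dx <- pmin(dx, box_L - dx); dy <- pmin(dy, box_L - dy) }
  near <- dx^2 + dy^2 <= cutoff^2
  for (i in seq_len(n - 1)) for (j in which(near[i, (i + 1):n]) + i) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, 1L)
  as.integer(factor(roots))
}

#' @describeIn cluster_points canonical rotation-centre linking cutoff
#'   L/(2*sqrt(Nf)).
#' @param n_filaments number of filaments in the system.
#' @export
ring_cluster_cutoff <- function(box_L, n_filaments) box_L / (2 * sqrt(n_filaments))

#' Detect rotating rings in a snapshot
#'
#' Pipeline: fit rotation centres ([rotation_centers()]), single-linkage
#' cluster them at L/(2*sqrt(Nf)), then apply four acceptance filters in
#' order:
#' \enumerate{
#'   \item cluster size strictly greater than `min_members`;
#'   \item normalized radius (radius of gyration of the member centres
#'     divided by the member count) below `max_norm_radius`;
#'   \item normalized polarity (norm of the sum of member filament
#'     orientations divided by the member count) below `max_norm_polarity`
#'     — closed rings have tangentially arranged filaments whose
#'     orientations cancel;
#'   \item local packing fraction at the ring centre (cutoff 2 d) below
#'     `max_center_phi` — true rings are hollow.
#' }
#' Rejections are reported per cluster with the failed criterion.
#'
#' @param state an [system_state()].
#' @param min_members minimum member count (exclusive bound).
#' @param max_norm_radius threshold on radius-of-gyration/size (d).
#' @param max_norm_polarity threshold on |sum of orientations|/size.
#' @param max_center_phi threshold on the centre packing fraction.
#' @return list with `rings` (data.frame: `ring`, `cx`, `cy`, `n_members`,
#'   `diameter`, `norm_radius`, `norm_polarity`, `center_phi`, and the
#'   member filament ids as a list column `members`) and `rejected`
#'   (data.frame of failed clusters with `reason`).
#' @export
detect_rings <- function(state, min_members = 10, max_norm_radius = 0.1,
                         max_norm_polarity = 0.25, max_center_phi = 0.5) {
  rc <- rotation_centers(state)
  ok <- !rc$straight
  L <- state$box_L
  nf <- n_filaments(state)
  empty <- data.frame(ring = integer(0), cx = numeric(0), cy = numeric(0),
                      n_members = integer(0), diameter = numeric(0),
                      norm_radius = numeric(0), norm_polarity = numeric(0),
                      center_phi = numeric(0))
  if (!any(ok))
    return(list(rings = empty, rejected = data.frame()))
  pts <- rc[ok, ]
  lab <- cluster_points(pts, L, ring_cluster_cutoff(L, nf))
  ft <- filament_table(state)
  r0 <- bead_r0()
  rings <- list(); rejected <- list(); ring_id <- 0L
  for (cl in unique(lab)) {
    mem <- pts$filament[lab == cl]
    sz <- length(mem)
    # periodic-aware cluster centre: anchor at first member, average
    # minimum-image offsets
    p0 <- c(pts$cx[lab == cl][1], pts$cy[lab == cl][1])
    off <- cbind(.mi(pts$cx[lab == cl] - p0[1], L),
                 .mi(pts$cy[lab == cl] - p0[2], L))
    ctr <- (p0 + colMeans(off)) %% L
    reject <- function(reason) {
      rejected[[length(rejected) + 1L]] <<-
        data.frame(n_members = sz, cx = ctr[1], cy = ctr[2], reason = reason)
    }
    if (sz <= min_members) { reject("size"); next }
    rg <- sqrt(mean(rowSums(sweep(off, 2, colMeans(off))^2)))
    norm_radius <- rg / sz
    if (norm_radius >= max_norm_radius) { reject("norm_radius"); next }
    u <- ft[ft$filament %in% mem, c("ux", "uy")]
    norm_pol <- sqrt(sum(colSums(u)^2)) / sz
    if (norm_pol >= max_norm_polarity) { reject("norm_polarity"); next }
    dxc <- abs(state$pos[, 1] - ctr[1]); dxc <- pmin(dxc, L - dxc)
    dyc <- abs(state$pos[, 2] - ctr[2]); dyc <- pmin(dyc, L - dyc)
    cnt <- sum(dxc^2 + dyc^2 <= 4)
    center_phi <- cnt * r0 / (4 * pi)
    if (center_phi >= max_center_phi) { reject("center_density"); next }
    # diameter: 2 x mean distance of the member filaments' beads from the
    # ring centre (a ring of radius R reports diameter 2R exactly)
    bead_sel <- filament_of(state) %in% mem
    dxm <- .mi(state$pos[bead_sel, 1] - ctr[1], L)
    dym <- .mi(state$pos[bead_sel, 2] - ctr[2], L)
    diameter <- 2 * mean(sqrt(dxm^2 + dym^2))
    ring_id <- ring_id + 1L
    row <- data.frame(ring = ring_id, cx = ctr[1], cy = ctr[2],
                      n_members = sz, diameter = diameter,
                      norm_radius = norm_radius, norm_polarity = norm_pol,
                      center_phi = center_phi)
    row$members <- I(list(mem))
    rings[[ring_id]] <- row
  }
  list(rings = if (length(rings)) do.call(rbind, rings) else empty,
       rejected = if (length(rejected)) do.call(rbind, rejected)
                  else data.frame())
}

#' Track ring detections over time
#'
#' Stable rings translate little, so detections are clustered jointly over
#' all frames by position (single-linkage, cutoff `link_cutoff`); each
#' spatial cluster is one ring track.  Tracks with fewer than `min_track`
#' detections are discarded as spurious.  Lifetime is the time between the
#' last and first detection of the track.
#'
#' @param detections data.frame of per-frame ring records (must carry
#'   `frame`, `time`, `cx`, `cy`, `diameter`), e.g. rows accumulated from
#'   [detect_rings()] over frames (see [analyze_rings()]).
#' @param box_L box side.
#' @param link_cutoff spatial linking cutoff (d).
#' @param min_track minimum detections per track.
#' @return data.frame with one row per track: `track`, `cx`, `cy`,
#'   `n_detections`, `t_first`, `t_last`, `lifetime`, `diameter` (mean over
#'   detections).
#' @export
track_rings <- function(detections, box_L, link_cutoff = 3, min_track = 3) {
  if (nrow(detections) == 0)
    return(data.frame(track = integer(0), cx = numeric(0), cy = numeric(0),
                      n_detections = integer(0), t_first = numeric(0),
                      t_last = numeric(0), lifetime = numeric(0),
                      diameter = numeric(0)))
  lab <- cluster_points(detections, box_L, link_cutoff)
  out <- lapply(unique(lab), function(cl) {
    d <- detections[lab == cl, ]
    if (nrow(d) < min_track) return(NULL)
    data.frame(track = cl, cx = mean(d$cx), cy = mean(d$cy),
               n_detections = nrow(d), t_first = min(d$time),
               t_last = max(d$time), lifetime = max(d$time) - min(d$time),
               diameter = mean(d$diameter))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(track = integer(0), cx = numeric(0), cy = numeric(0),
                      n_detections = integer(0), t_first = numeric(0),
                      t_last = numeric(0), lifetime = numeric(0),
                      diameter = numeric(0)))
  out$track <- seq_len(nrow(out))
  out
}

#' Ring analysis over a trajectory
#'
#' Runs [detect_rings()] on every production frame, tracks the detections
#' with [track_rings()], and summarises ring density and diameters.
#'
#' @param traj an `awlc_traj`.
#' @param discard_tau equilibration exclusion (defaults to the trajectory
#'   flag).
#' @param units optional [unit_system()] to add physical-unit columns.
#' @param ... thresholds passed to [detect_rings()].
#' @return list with `detections`, `tracks`, `density` (mean accepted rings
#'   per frame / L^2, in rings/d^2, plus rings/um^2 when units are given)
#'   and `diameters` (per-track mean diameters).
#' @export
analyze_rings <- function(traj, discard_tau = NULL, units = NULL, ...) {
  if (is.null(discard_tau)) discard_tau <- traj$equilibration_tau
  frames <- production_frames(traj, discard_tau)
  times <- vapply(frames, function(s) s$time, 1.0)
  L <- frames[[1]]$box_L
  det <- NULL
  for (k in seq_along(frames)) {
    r <- detect_rings(frames[[k]], ...)$rings
    if (nrow(r)) {
      r$frame <- k; r$time <- times[k]
      det <- rbind(det, r[, c("frame", "time", "cx", "cy", "n_members",
                              "diameter", "norm_radius", "norm_polarity",
                              "center_phi")])
    }
  }
  if (is.null(det)) det <- data.frame(frame = integer(0), time = numeric(0),
                                      cx = numeric(0), cy = numeric(0),
                                      n_members = integer(0),
                                      diameter = numeric(0))
  tracks <- track_rings(det, L)
  # density counts only detections belonging to retained tracks
  n_valid <- if (nrow(tracks) > 0 && nrow(det) > 0) {
    lab <- cluster_points(det, L, 3)
    keep <- lab %in% lab[duplicated(lab) | rev(duplicated(rev(lab)))]
    sizes <- table(lab)
    sum(sizes[sizes >= 3])
  } else 0
  density <- n_valid / length(frames) / L^2
  out <- list(detections = det, tracks = tracks, density = density,
              diameters = tracks$diameter)
  if (!is.null(units)) {
    out$density_per_um2 <- to_physical(density, "area_density", units)
    out$diameters_nm <- to_physical(tracks$diameter, "length", units)
  }
  out
}
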