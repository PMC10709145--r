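#' Nematic director field on a grid
#'
#' Bond midpoints and orientations are binned on a square grid and each
#' cell's director is the principal axis of the nematic orientation tensor
#' (headless average: bonds at alpha and alpha+pi are equivalent).  The
#' number of cells per side is forced even so that the overlapping 3x3
#' winding loops evaluated on the even sublattice tile the periodic box
#' exactly; periodicity is handled by modular indexing (equivalent to
#' extending the grid edges by one ghost point).
#'
#' @param state an [system_state()].
#' @param spacing requested grid pitch in d (default 4.7 d); the realised
#'   pitch is `box_L / n_grid`.
#' @return object of class `awlc_director`: list with `angle` (n x n matrix
#'   in `[0, pi)`, NA for empty cells), `occupancy` (bond counts), `pitch`,
#'   `n_grid`, `box_L`, `time`.
#' @export
director_field <- function(state, spacing = 4.7) {
  L <- state$box_L
  nc <- max(4L, 2L * round(L / (2 * spacing)))
  pitch <- L / nc
  b <- bond_table(state)
  ix <- pmin(floor(b$x / pitch), nc - 1L)
  iy <- pmin(floor(b$y / pitch), nc - 1L)
  cell <- iy * nc + ix + 1L
  a2 <- 2 * atan2(b$uy, b$ux)
  cs <- vapply(split(cos(a2), cell), sum, 1.0)
  sn <- vapply(split(sin(a2), cell), sum, 1.0)
  occ_cells <- as.integer(names(cs))
  ang <- matrix(NA_real_, nc, nc)     # [ix, iy] indexing
  occ <- matrix(0L, nc, nc)
  dir_a <- (atan2(sn, cs) / 2) %% pi
  for (k in seq_along(occ_cells)) {
    c0 <- occ_cells[k] - 1L
    ang[c0 %% nc + 1L, c0 %/% nc + 1L] <- dir_a[k]
  }
  cnt <- table(cell)
  for (k in seq_along(cnt)) {
    c0 <- as.integer(names(cnt)[k]) - 1L
    occ[c0 %% nc + 1L, c0 %/% nc + 1L] <- as.integer(cnt[k])
  }
  structure(list(angle = ang, occupancy = occ, pitch = pitch, n_grid = nc,
                 box_L = L, time = state$time),
            class = "awlc_director")
}

# wrap a nematic angle difference into (-pi/2, pi/2]
.nematic_wrap <- function(d) {
  d <- d %% pi
  ifelse(d > pi / 2, d - pi, d)
}

#' Winding number of a 3x3 director loop
#'
#' Sums the nematic angle differences (each wrapped into `(-pi/2, pi/2]`,
#' the only convention under which half-integer charges are well defined)
#' around the eight perimeter cells of the 3x3 loop centred at grid cell
#' `(i, j)`, traversed anticlockwise.  The topological charge is the
#' accumulated angle divided by 2*pi.
#'
#' @param grid an [director_field()] (or any list with `angle`, `n_grid`).
#' @param i,j 1-based centre cell indices.
#' @return accumulated angle in radians, or NA if any perimeter cell is
#'   unoccupied.
#' @export
winding_number <- function(grid, i, j) {
  nc <- grid$n_grid
  A <- grid$angle
  offs <- cbind(c(1, 1, 1, 0, -1, -1, -1, 0),
                c(-1, 0, 1, 1, 1, 0, -1, -1))   # anticlockwise perimeter
  ii <- (i - 1 + offs[, 1]) %% nc + 1L
  jj <- (j - 1 + offs[, 2]) %% nc + 1L
  a <- A[cbind(ii, jj)]
  if (anyNA(a)) return(NA_real_)
  a <- c(a, a[1])
  sum(.nematic_wrap(diff(a)))
}

#' Detect topological defects from a director grid
#'
#' Evaluates [winding_number()] on the 3x3 loop around every grid cell.
#' Windings are snapped to the nearest value in {-2*pi, -pi, +pi, +2*pi}
#' within `snap_tol` (charges -1, -1/2, +1/2, +1); loops that fail to snap
#' are flagged.  A defect core is surrounded by several overlapping loops
#' that enclose it, and a loop whose perimeter passes close to a core can
#' under-read an integer charge as a half-integer (the nematic angle wrap
#' loses pi), so same-sign readings from adjacent loops are clustered and
#' each cluster is assigned the charge of its best-centred loops — those
#' with the largest winding magnitude — at their mean position.  Unoccupied
#' cells can be in-painted from the nearest occupied cell for loop
#' completion (such loops are flagged as `inpainted`).  A frame is valid
#' only if the total charge is zero and no loop failed to snap.
#'
#' @param grid an [director_field()].
#' @param snap_tol tolerance (rad) for snapping windings to charge values.
#' @param inpaint fill empty cells from their nearest occupied neighbour.
#' @return list with `defects` (data.frame: `x`, `y`, `winding`, `charge`,
#'   `inpainted`), `total_charge`, `n_unsnapped`, `valid`.
#' @export
detect_defects <- function(grid, snap_tol = 0.3, inpaint = TRUE) {
  nc <- grid$n_grid
  g <- grid
  painted <- matrix(FALSE, nc, nc)
  if (inpaint && anyNA(g$angle)) {
    filled <- .inpaint_nearest(g$angle, nc)
    painted <- filled$painted
    g$angle <- filled$angle
  }
  rows <- list(); n_unsnap <- 0L
  for (i in seq_len(nc)) for (j in seq_len(nc)) {
    w <- winding_number(g, i, j)
    if (is.na(w)) { n_unsnap <- n_unsnap + 1L; next }
    k <- round(w / pi)
    if (k == 0) next
    if (abs(w - k * pi) > snap_tol || abs(k) > 2) { n_unsnap <- n_unsnap + 1L; next }
    offs <- cbind(c(1, 1, 1, 0, -1, -1, -1, 0, 0),
                  c(-1, 0, 1, 1, 1, 0, -1, -1, 0))
    ii <- (i - 1 + offs[, 1]) %% nc + 1L
    jj <- (j - 1 + offs[, 2]) %% nc + 1L
    rows[[length(rows) + 1L]] <- data.frame(
      x = (i - 0.5) * grid$pitch, y = (j - 0.5) * grid$pitch,
      k = k, inpainted = any(painted[cbind(ii, jj)]))
  }
  empty <- data.frame(x = numeric(0), y = numeric(0), winding = numeric(0),
                      charge = numeric(0), inpainted = logical(0))
  if (!length(rows))
    return(list(defects = empty, total_charge = 0, n_unsnapped = n_unsnap,
                valid = n_unsnap == 0L))
  raw <- do.call(rbind, rows)
  merged <- list()
  for (s_ in c(-1, 1)) {
    d <- raw[sign(raw$k) == s_, , drop = FALSE]
    if (!nrow(d)) next
    lab <- cluster_points(cbind(d$x, d$y), grid$box_L,
                          cutoff = 1.6 * grid$pitch)
    for (cl in unique(lab)) {
      dd <- d[lab == cl, , drop = FALSE]
      best <- dd[abs(dd$k) == max(abs(dd$k)), , drop = FALSE]
      ox <- .mi(best$x - best$x[1], grid$box_L)
      oy <- .mi(best$y - best$y[1], grid$box_L)
      merged[[length(merged) + 1L]] <- data.frame(
        x = (best$x[1] + mean(ox)) %% grid$box_L,
        y = (best$y[1] + mean(oy)) %% grid$box_L,
        winding = best$k[1] * pi, charge = best$k[1] / 2,
        inpainted = any(dd$inpainted))
    }
  }
  defects <- do.call(rbind, merged)
  defects <- defects[order(defects$x, defects$y), , drop = FALSE]
  rownames(defects) <- NULL
  total <- sum(defects$charge)
  list(defects = defects, total_charge = total, n_unsnapped = n_unsnap,
       valid = n_unsnap == 0L && isTRUE(all.equal(total, 0)))
}

# fill NA cells with the angle of the nearest occupied cell (BFS on the
# torus; deterministic scan order)
.inpaint_nearest <- function(A, nc) {
  painted <- is.na(A)
  if (!any(painted)) return(list(angle = A, painted = painted))
  filled <- A
  frontier <- which(!is.na(A), arr.ind = TRUE)
  if (nrow(frontier) == 0) stop("director grid entirely empty")
  while (anyNA(filled)) {
    nxt <- NULL
    for (r in seq_len(nrow(frontier))) {
      i <- frontier[r, 1]; j <- frontier[r, 2]
      for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        ii <- (i - 1 + o[1]) %% nc + 1L
        jj <- (j - 1 + o[2]) %% nc + 1L
        if (is.na(filled[ii, jj])) {
          filled[ii, jj] <- filled[i, j]
          nxt <- rbind(nxt, c(ii, jj))
        }
      }
    }
    if (is.null(nxt)) break
    frontier <- nxt
  }
  list(angle = filled, painted = painted)
}

#' Track topological defects across frames
#'
#' Each charge species is tracked separately with nearest-neighbour linking
#' (gate: `max_disp_cells` grid cells between consecutive detections),
#' allowing a single missing frame to be bridged, and the per-species
#' tracks are recombined.  Tracks shorter than `min_track` frames are
#' flagged as random detections and excluded.
#'
#' @param detections data.frame accumulated over frames (needs `frame`,
#'   `time`, `x`, `y`, `charge`), e.g. from [analyze_defects()].
#' @param pitch grid pitch (d per cell).
#' @param box_L box side.
#' @param max_disp_cells linking gate in grid cells.
#' @param max_gap maximum number of missing frames bridged (1 = one frame).
#' @param min_track minimum detections per retained track.
#' @return list with `tracks` (data.frame: `track`, `charge`, `n_frames`,
#'   `t_first`, `t_last`, `lifetime`) and `points` (per-detection track
#'   assignment, for MSD analysis).
#' @export
track_defects <- function(detections, pitch, box_L, max_disp_cells = 3,
                          max_gap = 1, min_track = 3) {
  gate <- max_disp_cells * pitch
  pts <- detections
  pts$track <- NA_integer_
  next_id <- 1L
  for (q in sort(unique(pts$charge))) {
    sel <- which(pts$charge == q)
    sub <- pts[sel, ]
    active <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                         frame = integer(0))
    for (fr in sort(unique(sub$frame))) {
      di <- which(sub$frame == fr)
      # drop stale tracks
      active <- active[fr - active$frame <= max_gap + 1L, , drop = FALSE]
      if (nrow(active) && length(di)) {
        dx <- abs(outer(sub$x[di], active$x, "-")); dx <- pmin(dx, box_L - dx)
        dy <- abs(outer(sub$y[di], active$y, "-")); dy <- pmin(dy, box_L - dy)
        D <- sqrt(dx^2 + dy^2)
        D[D > gate] <- NA
        # greedy matching by increasing distance
        while (any(is.finite(D))) {
          m <- which(D == min(D, na.rm = TRUE), arr.ind = TRUE)[1, ]
          det_k <- di[m[1]]; trk <- active$id[m[2]]
          sub$track[det_k] <- trk
          active$x[m[2]] <- sub$x[det_k]
          active$y[m[2]] <- sub$y[det_k]
          active$frame[m[2]] <- fr
          D[m[1], ] <- NA; D[, m[2]] <- NA
        }
      }
      for (k in di[is.na(sub$track[di])]) {
        sub$track[k] <- next_id
        active <- rbind(active, data.frame(id = next_id, x = sub$x[k],
                                           y = sub$y[k], frame = fr))
        next_id <- next_id + 1L
      }
    }
    pts$track[sel] <- sub$track
  }
  sizes <- table(pts$track)
  keep <- as.integer(names(sizes)[sizes >= min_track])
  pts <- pts[pts$track %in% keep, , drop = FALSE]
  tracks <- do.call(rbind, lapply(split(pts, pts$track), function(d)
    data.frame(track = d$track[1], charge = d$charge[1],
               n_frames = nrow(d), t_first = min(d$time),
               t_last = max(d$time), lifetime = max(d$time) - min(d$time))))
  if (is.null(tracks))
    tracks <- data.frame(track = integer(0), charge = numeric(0),
                         n_frames = integer(0), t_first = numeric(0),
                         t_last = numeric(0), lifetime = numeric(0))
  list(tracks = tracks, points = pts)
}

#' Mean-squared displacement of defect tracks
#'
#' @param tracking output of [track_defects()].
#' @param box_L box side (minimum-image unwrapping of consecutive steps).
#' @return data.frame with `lag` (frames) and `msd` (d^2), averaged over
#'   tracks.
#' @export
defect_msd <- function(tracking, box_L) {
  pts <- tracking$points
  if (nrow(pts) == 0) return(data.frame(lag = integer(0), msd = numeric(0)))
  acc <- list()
  for (tr in unique(pts$track)) {
    d <- pts[pts$track == tr, ]
    d <- d[order(d$frame), ]
    if (nrow(d) < 2) next
    # unwrap successive displacements
    steps <- cbind(.mi(diff(d$x), box_L), .mi(diff(d$y), box_L))
    cum <- rbind(c(0, 0), apply(steps, 2, cumsum))
    for (lag in seq_len(nrow(d) - 1)) {
      dd <- cum[seq_len(nrow(d) - lag) + lag, , drop = FALSE] -
            cum[seq_len(nrow(d) - lag), , drop = FALSE]
      acc[[as.character(lag)]] <- c(acc[[as.character(lag)]], rowSums(dd^2))
    }
  }
  if (!length(acc)) return(data.frame(lag = integer(0), msd = numeric(0)))
  data.frame(lag = as.integer(names(acc)),
             msd = vapply(acc, mean, 1.0), row.names = NULL)
}

#' Defect analysis over a trajectory
#'
#' Builds the director field for every production frame, detects defects,
#' keeps valid (charge-neutral) frames for density statistics, and tracks
#' the defects.
#'
#' @param traj an `awlc_traj`.
#' @param spacing director grid pitch (d).
#' @param discard_tau equilibration exclusion.
#' @param ... passed to [detect_defects()].
#' @return list with `detections`, `per_frame` (frame validity and counts),
#'   `density` (defects per d^2 over valid frames), `tracking`.
#' @export
analyze_defects <- function(traj, spacing = 4.7, discard_tau = NULL, ...) {
  if (is.null(discard_tau)) discard_tau <- traj$equilibration_tau
  frames <- production_frames(traj, discard_tau)
  L <- frames[[1]]$box_L
  det <- NULL; per_frame <- NULL; pitch <- NA_real_
  for (k in seq_along(frames)) {
    g <- director_field(frames[[k]], spacing)
    pitch <- g$pitch
    dd <- detect_defects(g, ...)
    per_frame <- rbind(per_frame, data.frame(
      frame = k, time = frames[[k]]$time, n_defects = nrow(dd$defects),
      total_charge = dd$total_charge, valid = dd$valid))
    if (nrow(dd$defects)) {
      d <- dd$defects; d$frame <- k; d$time <- frames[[k]]$time
      det <- rbind(det, d)
    }
  }
  if (is.null(det))
    det <- data.frame(i = integer(0), j = integer(0), x = numeric(0),
                      y = numeric(0), winding = numeric(0),
                      charge = numeric(0), inpainted = logical(0),
                      frame = integer(0), time = numeric(0))
  valid_frames <- per_frame$frame[per_frame$valid]
  density <- if (length(valid_frames))
    mean(per_frame$n_defects[per_frame$valid]) / L^2 else NA_real_
  tracking <- track_defects(det[det$frame %in% valid_frames, , drop = FALSE],
                            pitch, L)
  list(detections = det, per_frame = per_frame, density = density,
       tracking = tracking, pitch = pitch)
}
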