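#' Signed turn angles at every interior joint
#'
#' The turn angle phi at joint j is the signed angle (2D cross-product
#' convention) between consecutive bond vectors traversed from head to tail;
#' the rest shape of a chiral filament has phi = -dtheta at every joint.
#'
#' @param state an [system_state()].
#' @return data.frame with `filament`, `joint` (2 .. M-1) and `phi` (rad).
#' @export
joint_angles <- function(state) {
  cs <- filament_coords(state)
  out <- lapply(seq_along(cs), function(f) {
    P <- cs[[f]]
    b <- diff(P)                      # bond vectors head -> tail
    n <- nrow(b)
    if (n < 2) return(NULL)
    cr <- b[-n, 1] * b[-1, 2] - b[-n, 2] * b[-1, 1]
    dt <- b[-n, 1] * b[-1, 1] + b[-n, 2] * b[-1, 2]
    data.frame(filament = f, joint = seq_len(n - 1) + 1L,
               phi = atan2(cr, dt))
  })
  do.call(rbind, out)
}

#' Local signed curvature
#'
#' kappa = -phi / delta_s at every interior joint, evaluated head to tail,
#' so that a filament at its chiral rest shape has kappa = +dtheta/delta_s
#' (the geometric curvature of the rest arc when `delta_s = r0`).
#'
#' Two contour measures are meaningful for this model and both are used in
#' the package: the geometric bond length `delta_s = r0` (shape observables,
#' e.g. curvature in rad/um) and the model's energy contour measure
#' `delta_s = d = 1` under which the bending rigidity k_bend is the
#' continuum modulus (persistence-length calibration); see the methods
#' vignette.
#'
#' @param state an [system_state()].
#' @param delta_s contour spacing used to convert turn angles to curvature.
#' @return object of class `awlc_curvature`: data.frame (`filament`,
#'   `joint`, `kappa`) with attribute `delta_s`.
#' @export
local_curvatures <- function(state, delta_s = bead_r0()) {
  stopifnot(delta_s > 0)
  ja <- joint_angles(state)
  out <- data.frame(filament = ja$filament, joint = ja$joint,
                    kappa = -ja$phi / delta_s)
  attr(out, "delta_s") <- delta_s
  class(out) <- c("awlc_curvature", "data.frame")
  out
}

#' @describeIn local_curvatures per-filament mean curvature and its
#'   snapshot average (mean of filament means).
#' @export
snapshot_mean_curvature <- function(state, delta_s = bead_r0()) {
  k <- local_curvatures(state, delta_s)
  per_fil <- tapply(k$kappa, k$filament, mean)
  list(per_filament = as.numeric(per_fil), mean = mean(per_fil))
}

#' Persistence length from the curvature distribution
#'
#' Fits a Gaussian to pooled local-curvature samples (location free, to
#' accommodate spontaneous curvature) and returns Lp = 1/(sigma^2 *
#' delta_s).  The default fit is moment matching after trimming samples
#' further than `trim_mads` median absolute deviations from the median;
#' `method = "fit"` instead least-squares fits a Gaussian to the histogram.
#'
#' @param kappa an `awlc_curvature` object, or a numeric vector of curvature
#'   samples (then `delta_s` must be given).
#' @param delta_s contour spacing; taken from the curvature object when
#'   available.
#' @param method "moments" (trimmed moment matching) or "fit" (histogram
#'   least squares).
#' @param trim_mads outlier trim for the moment method.
#' @return list with `Lp` (length; `Inf` with `degenerate = TRUE` when the
#'   variance vanishes), `sigma`, `mu`, `n`.
#' @examples
#' k <- rnorm(5000, 0, 0.1)
#' persistence_length_curvature(k, delta_s = 0.3536)$Lp  # ~1/(0.01*0.3536)
#' @export
persistence_length_curvature <- function(kappa, delta_s = NULL,
                                         method = c("moments", "fit"),
                                         trim_mads = 5) {
  method <- match.arg(method)
  if (inherits(kappa, "awlc_curvature")) {
    if (is.null(delta_s)) delta_s <- attr(kappa, "delta_s")
    kappa <- kappa$kappa
  }
  if (is.null(delta_s)) stop("delta_s must be supplied for raw samples")
  kappa <- kappa[is.finite(kappa)]
  n <- length(kappa)
  if (n < 10) stop("need at least 10 curvature samples")
  if (method == "moments") {
    md <- median(kappa)
    dev <- mad(kappa)
    keep <- if (dev > 0) abs(kappa - md) <= trim_mads * dev else rep(TRUE, n)
    mu <- mean(kappa[keep])
    sigma <- sd(kappa[keep])
  } else {
    h <- hist(kappa, breaks = max(30, ceiling(sqrt(n))), plot = FALSE)
    xs <- h$mids; ys <- h$density
    mu0 <- mean(kappa); s0 <- sd(kappa)
    fit <- tryCatch(
      nls(ys ~ exp(-(xs - m)^2 / (2 * s^2)) / (s * sqrt(2 * pi)),
          start = list(m = mu0, s = s0),
          control = list(warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) { mu <- mu0; sigma <- s0 }
    else { cf <- coef(fit); mu <- cf[["m"]]; sigma <- abs(cf[["s"]]) }
  }
  if (!is.finite(sigma) || sigma <= 0)
    return(list(Lp = Inf, sigma = 0, mu = mu, n = n, degenerate = TRUE))
  list(Lp = 1 / (sigma^2 * delta_s), sigma = sigma, mu = mu, n = n,
       degenerate = FALSE)
}

#' Simulation persistence-length pipeline
#'
#' Pools interior joint angles over frames, converts them to curvatures in
#' the model's energy contour measure (delta_s = d, under which the
#' thermal-equilibrium expectation is Lp = k_bend/kBT) and applies
#' [persistence_length_curvature()].  Optionally converts to nanometres.
#'
#' @param frames list of [system_state()] frames (e.g.
#'   [production_frames()]).
#' @param units NULL for reduced units, or an [unit_system()] to report nm.
#' @param ... passed to [persistence_length_curvature()].
#' @return as [persistence_length_curvature()], with `Lp_nm` added when
#'   units are given.
#' @export
sim_persistence_length <- function(frames, units = NULL, ...) {
  if (inherits(frames, "awlc_state")) frames <- list(frames)
  ks <- unlist(lapply(frames, function(s) local_curvatures(s, delta_s = 1)$kappa))
  res <- persistence_length_curvature(ks, delta_s = 1, ...)
  if (!is.null(units)) res$Lp_nm <- to_physical(res$Lp, "length", units)
  res
}

#' Mean-squared end-to-end distance of the worm-like chain
#'
#' msed(x) = 4*Lp*(x - 2*Lp*(1 - exp(-x/(2*Lp)))): the expected squared
#' Euclidean separation of two points a contour distance x apart on a 2D
#' worm-like chain of persistence length Lp.  Limits: x<<Lp gives x^2
#' (rigid rod), x>>Lp gives slope 4*Lp.
#'
#' @param x contour separation(s).
#' @param Lp persistence length.
#' @return expected squared end-to-end distance.
#' @export
wlc_msed <- function(x, Lp) 4 * Lp * (x - 2 * Lp * (1 - exp(-x / (2 * Lp))))

#' Persistence length from mean-squared end-to-end distances
#'
#' Computes the mean squared Euclidean separation between trace points as a
#' function of their contour separation, pooled over traces, and fits
#' [wlc_msed()] by nonlinear least squares.
#'
#' @param traces list of (n x 2) coordinate matrices (unwrapped), e.g.
#'   [filament_coords()] output or [sample_wlc_chains()] chains.
#' @param delta_s contour spacing between consecutive trace points.
#' @param min_pairs minimum pooled pairs per separation retained.
#' @return list with `Lp`, `fit` (the nls object) and the pooled `table`
#'   (columns `x`, `y2`, `n`).
#' @export
persistence_length_msed <- function(traces, delta_s = bead_r0(),
                                    min_pairs = 10) {
  stopifnot(length(traces) >= 1, delta_s > 0)
  nmax <- max(vapply(traces, nrow, 1L)) - 1L
  ssq <- vector("list", nmax)
  for (P in traces) {
    m <- nrow(P)
    for (k in seq_len(m - 1)) {
      d2 <- rowSums((P[seq_len(m - k) + k, , drop = FALSE] -
                     P[seq_len(m - k), , drop = FALSE])^2)
      ssq[[k]] <- c(ssq[[k]], d2)
    }
  }
  n <- vapply(ssq, length, 1L)
  keep <- n >= min_pairs
  tab <- data.frame(x = which(keep) * delta_s,
                    y2 = vapply(ssq[keep], mean, 1.0),
                    n = n[keep])
  if (nrow(tab) < 4) stop("too few separations for the msed fit")
  # start value: asymptotic slope / 4 or rod limit
  Lp0 <- max(tail(tab$y2, 1) / (4 * tail(tab$x, 1)), delta_s)
  fitter <- if (requireNamespace("minpack.lm", quietly = TRUE))
    function(...) minpack.lm::nlsLM(...) else function(...) nls(...)
  fit <- tryCatch(
    fitter(y2 ~ wlc_msed(x, Lp), data = tab, start = list(Lp = Lp0)),
    error = function(e)
      stop("msed fit did not converge: ", conditionMessage(e),
           "; residual range ", paste(signif(range(tab$y2), 3), collapse = " ")))
  list(Lp = coef(fit)[["Lp"]], fit = fit, table = tab)
}

#' Contour length
#'
#' Sum of bond lengths per filament; with several frames, the average over
#' frames is reported per filament.
#'
#' @param x an `awlc_state`, a list of states, or a list of coordinate
#'   matrices.
#' @return numeric vector of contour lengths (one per filament).
#' @export
contour_length <- function(x) {
  states <- if (inherits(x, "awlc_state")) list(x)
            else if (is.list(x) && inherits(x[[1]], "awlc_state")) x
            else NULL
  one <- function(P) sum(sqrt(rowSums(diff(P)^2)))
  if (is.null(states)) return(vapply(x, one, 1.0))
  per_frame <- vapply(states,
                      function(s) vapply(filament_coords(s), one, 1.0),
                      numeric(n_filaments(states[[1]])))
  if (is.matrix(per_frame)) rowMeans(per_frame) else mean(per_frame)
}

#' Filament centre-of-mass speeds
#'
#' Displacement of each filament's centre of mass between consecutive saved
#' frames (minimum image applied to the centre displacement), divided by
#' the frame interval.
#'
#' @param traj an `awlc_traj`.
#' @param discard_tau exclude frames before this time.
#' @return data.frame with `filament`, `t0`, `t1`, `speed` (d/tau).
#' @export
filament_velocity <- function(traj, discard_tau = 0) {
  frames <- traj$frames[traj$times >= discard_tau - 1e-9]
  times <- traj$times[traj$times >= discard_tau - 1e-9]
  if (length(frames) < 2) stop("need at least 2 frames")
  L <- frames[[1]]$box_L
  coms <- lapply(frames, function(s)
    do.call(rbind, lapply(filament_coords(s), colMeans)) %% L)
  out <- NULL
  for (k in seq_len(length(frames) - 1)) {
    dtau <- times[k + 1] - times[k]
    d <- .mi(coms[[k + 1]] - coms[[k]], L)
    sp <- sqrt(rowSums(d^2)) / dtau
    if (any(sqrt(rowSums(d^2)) > L / 4))
      warning("frame gap allows > L/4 travel; speeds may be aliased")
    out <- rbind(out, data.frame(filament = seq_len(nrow(d)),
                                 t0 = times[k], t1 = times[k + 1],
                                 speed = sp))
  }
  out
}

#' Local packing fraction around each filament
#'
#' Counts beads of any filament (excluding the probe bead itself) within
#' `cutoff` of each filament's central bead, and converts the count to a
#' packing fraction with the per-bead coverage d*r0:
#' phi_local = count * d * r0 / (pi * cutoff^2).
#'
#' @param state an [system_state()].
#' @param cutoff neighbourhood radius (d units).
#' @return data.frame with `filament`, `count`, `phi_local`.
#' @export
local_density <- function(state, cutoff = 2) {
  M <- state$M; L <- state$box_L
  nf <- n_filaments(state)
  centre_rank <- ceiling(M / 2)
  probe_idx <- (seq_len(nf) - 1) * M + centre_rank
  P <- state$pos
  cnt <- integer(nf)
  for (k in seq_len(nf)) {
    dx <- abs(P[, 1] - P[probe_idx[k], 1]); dx <- pmin(dx, L - dx)
    dy <- abs(P[, 2] - P[probe_idx[k], 2]); dy <- pmin(dy, L - dy)
    within <- (dx^2 + dy^2) <= cutoff^2
    within[probe_idx[k]] <- FALSE
    cnt[k] <- sum(within)
  }
  r0 <- bead_r0()
  data.frame(filament = seq_len(nf), count = cnt,
             phi_local = cnt * r0 / (pi * cutoff^2))
}

#' Sub-box density-fluctuation scaling
#'
#' The box is tiled with non-overlapping square sub-boxes over a ladder of
#' sizes; bead counts are pooled over tiles and frames, and the scaling
#' exponent is the least-squares slope of log sd(N) against log mean(N).
#' Equilibrium systems give exponent 1/2; giant number fluctuations in
#' active ordered phases give larger exponents (~0.8 here).
#'
#' The default ladder spans `n_sizes` log-spaced sizes from `s_min` up to
#' `box_L/3`, so that every size is tiled by at least nine sub-boxes: at a
#' fixed total bead count, the partition of the box into very few tiles
#' measures a conserved quantity, whose variance is suppressed far below
#' the free (grand-canonical) fluctuation that the scaling exponent is
#' about, at any run length.  Explicit ladders may go up to `box_L/2`.
#'
#' @param x an `awlc_traj`, a list of `awlc_state` frames, or a list of
#'   plain (n x 2) point matrices (then `box_L` must be given).
#' @param box_L box side (required for plain point sets).
#' @param sizes explicit ladder of sub-box sizes; default is `n_sizes`
#'   log-spaced sizes from `s_min` to `box_L * s_max_frac`.
#' @param n_sizes,s_min,s_max_frac ladder parameters.
#' @param discard_tau for trajectories, exclude frames before this time
#'   (defaults to the trajectory's equilibration flag).
#' @return object of class `awlc_gnf`: list with `table` (size, meanN, sdN,
#'   n_samples), `exponent`, `fit`.
#' @export
density_fluctuations <- function(x, box_L = NULL, sizes = NULL, n_sizes = 8,
                                 s_min = 2, s_max_frac = 1 / 3,
                                 discard_tau = NULL) {
  if (inherits(x, "awlc_traj")) {
    if (is.null(discard_tau)) discard_tau <- x$equilibration_tau
    frames <- production_frames(x, discard_tau)
    pts <- lapply(frames, function(s) s$pos)
    box_L <- frames[[1]]$box_L
  } else if (is.list(x) && inherits(x[[1]], "awlc_state")) {
    pts <- lapply(x, function(s) s$pos)
    box_L <- x[[1]]$box_L
  } else {
    if (is.null(box_L)) stop("box_L required for plain point sets")
    pts <- if (is.matrix(x)) list(x) else x
  }
  if (is.null(sizes))
    sizes <- exp(seq(log(s_min), log(box_L * s_max_frac),
                     length.out = n_sizes))
  sizes <- sort(unique(sizes))
  stopifnot(all(sizes > 0), max(sizes) <= box_L / 2 + 1e-9)
  if (length(sizes) < 3) stop("need at least 3 ladder sizes")
  rows <- lapply(sizes, function(s) {
    ntile <- floor(box_L / s)
    counts <- unlist(lapply(pts, function(P) {
      ix <- floor(P[, 1] / s); iy <- floor(P[, 2] / s)
      ok <- ix < ntile & iy < ntile       # drop the partial edge strip
      tabulate(iy[ok] * ntile + ix[ok] + 1L, nbins = ntile * ntile)
    }))
    data.frame(size = s, meanN = mean(counts), sdN = sd(counts),
               n_samples = length(counts))
  })
  tab <- do.call(rbind, rows)
  ok <- tab$sdN > 0 & tab$meanN > 0
  if (sum(ok) < 3) {
    if (all(tab$sdN == 0))
      # e.g. a perfect lattice tiled commensurately: complete suppression
      return(structure(list(table = tab, exponent = 0, fit = NULL,
                            suppressed = TRUE), class = "awlc_gnf"))
    stop("fewer than 3 usable ladder points")
  }
  fit <- stats::lm(log(sdN) ~ log(meanN), data = tab[ok, ])
  structure(list(table = tab, exponent = unname(coef(fit)[2]), fit = fit,
                 suppressed = FALSE),
            class = "awlc_gnf")
}

#' @export
print.awlc_gnf <- function(x, ...) {
  cat(sprintf("density-fluctuation scan: %d sizes, exponent = %.3f\n",
              nrow(x$table), x$exponent))
  invisible(x)
}

#' Polar alignment fraction
#'
#' Over all pairs of beads on distinct filaments within `r_cut`, the
#' fraction whose bond orientations (head-ward) make an angle below 90
#' degrees; pairs at exactly 90 degrees count as antiparallel.
#'
#' @param state an [system_state()].
#' @param r_cut neighbour distance threshold (defaults in callers to the
#'   pair-potential cutoff).
#' @return list with `fraction` (NA with `undefined = TRUE` when no pairs),
#'   `n_parallel`, `n_antiparallel`.
#' @export
polar_alignment_fraction <- function(state, r_cut) {
  M <- state$M; L <- state$box_L
  P <- state$pos
  n <- nrow(P)
  f <- filament_of(state)
  r <- bead_rank(state)
  # head-ward orientation of each bead: bond to predecessor (head bead uses
  # its first bond)
  prev <- ifelse(r == 1, seq_len(n) , seq_len(n) - 1L)
  nxt  <- ifelse(r == 1, seq_len(n) + 1L, seq_len(n))
  ux <- .mi(P[prev, 1] - P[nxt, 1], L)
  uy <- .mi(P[prev, 2] - P[nxt, 2], L)
  nn <- sqrt(ux^2 + uy^2)
  ux <- ux / nn; uy <- uy / nn
  npar <- 0; nanti <- 0
  step <- 512L
  for (i0 in seq(1L, n, by = step)) {
    ii <- i0:min(n, i0 + step - 1L)
    dx <- abs(outer(P[ii, 1], P[, 1], "-")); dx <- pmin(dx, L - dx)
    dy <- abs(outer(P[ii, 2], P[, 2], "-")); dy <- pmin(dy, L - dy)
    near <- (dx^2 + dy^2) <= r_cut^2 & outer(f[ii], f, "!=")
    # count each unordered pair once: global index j > global index i
    near <- near & outer(ii, seq_len(n), "<")
    if (!any(near)) next
    idx <- which(near, arr.ind = TRUE)
    gi <- ii[idx[, 1]]; gj <- idx[, 2]
    dp <- ux[gi] * ux[gj] + uy[gi] * uy[gj]
    npar <- npar + sum(dp > 0)
    nanti <- nanti + sum(dp <= 0)
  }
  if (npar + nanti == 0)
    return(list(fraction = NA_real_, n_parallel = 0L, n_antiparallel = 0L,
                undefined = TRUE))
  list(fraction = npar / (npar + nanti), n_parallel = npar,
       n_antiparallel = nanti, undefined = FALSE)
}

#' Binary collision assay
#'
#' Places a target filament at the box centre (along +x) and shoots a second
#' filament at it with incoming angle `angle_in`, then classifies the
#' post-collision state as parallel or antiparallel from the sign of the
#' mean orientation dot product once the interaction window has elapsed;
#' runs that never bring the filaments within the pair cutoff are counted
#' as misses.
#'
#' @param angle_in incoming angle in radians (0 = parallel approach).
#' @param params an [model_params()].
#' @param seeds vector of integer seeds (one run each).
#' @param window_tau interaction window per run.
#' @param box_L box side for the two-filament arena.
#' @return table of outcomes over seeds (`parallel`, `antiparallel`,
#'   `miss`).
#' @export
collision_assay <- function(angle_in, params, seeds = 1:10, window_tau = 0.5,
                            box_L = 30) {
  spec <- params$spec
  N <- spec$n_bonds; M <- N + 1L
  r0 <- spec$r0
  mk <- function() {
    c0 <- c(box_L / 2, box_L / 2)
    # target along +x (head at +x end)
    tgt <- cbind(c0[1] + (N:0 - N / 2) * r0, c0[2])
    # incomer: head just clear of the target footprint, aimed at its centre
    u <- c(cos(angle_in), sin(angle_in))
    clear <- spec$Lf / 2 + 1.2
    head0 <- c0 - clear * u
    inc <- cbind(head0[1] - u[1] * (0:N) * r0, head0[2] - u[2] * (0:N) * r0)
    system_state(rbind(tgt, inc), N, box_L)
  }
  outcome <- vapply(seeds, function(sd) {
    tr <- simulate_tau(mk(), params, window_tau,
                       save_every_tau = window_tau / 5,
                       seed = sd, equilibration_tau = 0)
    # a run is a miss only if the filaments never came within the pair
    # cutoff in any saved frame
    touched <- any(vapply(tr$frames, function(s)
      .min_interfilament_dist(s) <= params$r_cut, logical(1)))
    if (!touched) return("miss")
    ft <- filament_table(tr$frames[[length(tr$frames)]])
    dp <- ft$ux[1] * ft$ux[2] + ft$uy[1] * ft$uy[2]
    if (dp > 0) "parallel" else "antiparallel"
  }, character(1))
  table(factor(outcome, levels = c("parallel", "antiparallel", "miss")))
}
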