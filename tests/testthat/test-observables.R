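test_that("local curvature: straight chains, circles, and the rest shape", {
  p <- params_wt()
  st <- straight_state(p)
  expect_equal(max(abs(local_curvatures(st)$kappa)), 0, tolerance = 1e-12)
  # beads on a circle of radius R: kappa = 1/R up to O((ds/R)^2)
  r0 <- bead_r0()
  for (R in c(3, 6)) {
    angs <- rev((0:23) * (r0 / R))      # head leads anticlockwise
    stc <- system_state(cbind(21 + R * cos(angs), 21 + R * sin(angs)), 23, 42)
    kap <- local_curvatures(stc)$kappa
    # equal arc steps: the turn between consecutive chords equals the arc
    # angle exactly, so kappa = 1/R with no discretisation error here
    expect_equal(mean(kap), 1 / R, tolerance = 1e-9)
    expect_lt(diff(range(kap)), 1e-9)
  }
  # WT rest shape reproduces the intrinsic curvature 0.174 rad/d
  strest <- rest_arc_state(p)
  expect_equal(mean(local_curvatures(strest)$kappa),
               from_physical(3.48, "curvature"), tolerance = 1e-6)
  # mirror flips the sign globally
  stm <- system_state(cbind(strest$pos[, 1], 42 - strest$pos[, 2]), 23, 42)
  expect_equal(local_curvatures(stm)$kappa, -local_curvatures(strest)$kappa,
               tolerance = 1e-12)
})

test_that("curvature persistence estimator inverts known Gaussians", {
  set.seed(4)
  ds <- bead_r0()
  kap <- rnorm(20000, 0.05, 0.1)       # sigma^2 = 0.01 -> Lp = 1/(0.01*ds)
  est <- persistence_length_curvature(kap, delta_s = ds)
  expect_equal(est$Lp, 1 / (0.01 * ds), tolerance = 0.05)
  expect_equal(est$Lp, 283, tolerance = 0.05)
  # location-free: the spontaneous-curvature mean does not bias sigma
  expect_equal(est$mu, 0.05, tolerance = 0.1)
  # histogram-fit route agrees
  est2 <- persistence_length_curvature(kap, delta_s = ds, method = "fit")
  expect_equal(est2$Lp, est$Lp, tolerance = 0.1)
  # degenerate variance flags infinite Lp
  flat <- persistence_length_curvature(rep(0.2, 100), delta_s = ds)
  expect_true(is.infinite(flat$Lp))
  expect_true(flat$degenerate)
})

test_that("msed model has the rod and random-coil limits", {
  Lp <- 50
  x <- 1e-4
  expect_equal(wlc_msed(x, Lp), x^2, tolerance = 1e-4)        # rigid rod
  xs <- c(2000, 2100)
  slope <- diff(wlc_msed(xs, Lp)) / diff(xs)
  expect_equal(slope, 4 * Lp, tolerance = 1e-6)               # asymptote
})

test_that("both persistence estimators recover WLC ground truth and agree", {
  ds <- bead_r0()
  for (Lp_in in c(20, 100, 500)) {
    ch <- cached(paste0("wlc_", Lp_in),
                 sample_wlc_chains(Lp_in, n_chains = 400, n_bonds = 60,
                                   delta_s = ds, seed = Lp_in))
    turns <- unlist(lapply(ch, chain_turns))
    est_c <- persistence_length_curvature(-turns / ds, delta_s = ds)
    expect_lt(abs(est_c$Lp - Lp_in) / Lp_in, 0.05)
    est_m <- persistence_length_msed(ch, delta_s = ds)
    expect_lt(abs(est_m$Lp - Lp_in) / Lp_in, 0.10)
    expect_lt(abs(est_m$Lp - est_c$Lp) / est_c$Lp, 0.15)
  }
  # tangent-correlation e-folding of the same ensemble is ~2 Lp (2D)
  ch <- cached("wlc_100", sample_wlc_chains(100, 400, 60, ds, seed = 100))
  corr <- sapply(c(5, 10, 20, 30), function(lag) {
    mean(unlist(lapply(ch, function(P) {
      b <- diff(P); a <- atan2(b[, 2], b[, 1])
      cos(a[seq_len(length(a) - lag) + lag] - a[seq_len(length(a) - lag)])
    })))
  })
  fit <- stats::lm(log(corr) ~ I(c(5, 10, 20, 30) * ds))
  expect_equal(-1 / coef(fit)[[2]], 2 * 100, tolerance = 0.1)
})

test_that("contour length sums bonds and averages over frames", {
  p <- params_wt()
  st <- straight_state(p)
  expect_equal(contour_length(st), 23 * bead_r0())
  # a stretched bond adds its excess exactly
  pos <- st$pos; pos[1, 1] <- pos[1, 1] + 0.1
  expect_equal(contour_length(system_state(pos, 23, 42)),
               23 * bead_r0() + 0.1, tolerance = 1e-12)
})

test_that("filament speeds: static frames give zero, free active gives v0-scale", {
  p <- params_wt()
  st <- straight_state(p)
  traj <- structure(list(frames = list(st, st, st), times = c(0, 0.1, 0.2),
                         params = p, seed = 1, equilibration_tau = 0),
                    class = "awlc_traj")
  expect_equal(max(filament_velocity(traj)$speed), 0)
})

test_that("local density counts the printed neighbourhood", {
  p <- params_wt()
  st <- straight_state(p)
  ld <- local_density(st)
  # isolated straight chain: beads within 2 d of the central bead are the
  # 5 on each side (5 r0 = 1.77 < 2 < 6 r0), probe excluded
  expect_equal(ld$count, 10L)
  expect_equal(ld$phi_local, 10 * bead_r0() / (4 * pi), tolerance = 1e-12)
  # empty neighbourhood
  st1 <- system_state(cbind(c(1, 1 + bead_r0(), 1 + 2 * bead_r0()),
                            c(1, 1, 1)), 2, 42)
  expect_equal(local_density(st1, cutoff = 0.01)$count, 0L)
  # uniform random beads at bulk phi: mean phi_local ~ bulk phi (Monte
  # Carlo check of the count-to-packing conversion factor)
  set.seed(8)
  L <- 42; M <- 24
  n_beads <- round(0.4 * L^2 / bead_r0() / M) * M
  stu <- system_state(cbind(runif(n_beads, 0, L), runif(n_beads, 0, L)),
                      M - 1, L)
  bulk <- n_beads * bead_r0() / L^2
  expect_equal(mean(local_density(stu)$phi_local), bulk, tolerance = 0.05)
})

test_that("density-fluctuation anchors: Poisson 1/2, lattice suppressed", {
  ps <- lapply(1:8, function(s) poisson_gas(2000, 42, seed = s))
  g <- density_fluctuations(ps, box_L = 42)
  expect_lt(abs(g$exponent - 0.5), 0.05)
  # perfect lattice tiled commensurately: complete suppression
  lg <- lattice_gas(1, 42)
  gl <- density_fluctuations(list(lg), box_L = 42, sizes = c(2, 3, 6, 7))
  expect_lt(gl$exponent, 0.2)
  # ladder validation
  expect_error(density_fluctuations(ps, box_L = 42, sizes = c(2, 3)),
               "3 ladder")
  expect_error(density_fluctuations(list(poisson_gas(10, 42, 1))[0],
                                    box_L = 42))
})

test_that("polar alignment classifier follows the 90-degree rule", {
  p <- params_wt()
  r0 <- bead_r0()
  mk2 <- function(ang, antiparallel = FALSE, sep = 0.5) {
    a <- cbind(21 - (0:5) * r0, 21)
    dir <- if (antiparallel) -1 else 1
    b0 <- c(21 - 2.5 * r0 * dir, 21 + sep)
    b <- cbind(b0[1] + dir * (5:0 - 2.5) * r0 * cos(ang),
               b0[2] + (5:0 - 2.5) * r0 * sin(ang))
    system_state(rbind(a, b), 5, 42)
  }
  expect_equal(polar_alignment_fraction(mk2(0), 2)$fraction, 1)
  expect_equal(polar_alignment_fraction(mk2(0, antiparallel = TRUE), 2)$fraction, 0)
  # crossing at 30 degrees is parallel, at 150 antiparallel
  expect_equal(polar_alignment_fraction(mk2(pi / 6), 2)$fraction, 1)
  expect_equal(polar_alignment_fraction(mk2(5 * pi / 6), 2)$fraction, 0)
  # no neighbours within cutoff: undefined flag
  far <- system_state(rbind(cbind(5 - (0:5) * r0, 5),
                            cbind(35 - (0:5) * r0, 35)), 5, 42)
  out <- polar_alignment_fraction(far, 2)
  expect_true(out$undefined)
})

test_that("collision assay: aligned approach stays parallel, head-on flips", {
  p <- params_wt(); p$kBT <- 0          # deterministic collisions
  co0 <- collision_assay(0, p, seeds = 1, window_tau = 0.15)
  expect_equal(unname(co0["parallel"]), 1L)
  co180 <- collision_assay(pi, p, seeds = 1, window_tau = 0.15)
  expect_equal(unname(co180["antiparallel"]), 1L)
  # chirality symmetry: mirroring the approach angle with the opposite
  # handedness gives the same outcome
  pm <- params_wt(); pm$kBT <- 0; pm$spec$dtheta <- -p$spec$dtheta
  co_p <- collision_assay(pi / 3, p, seeds = 1, window_tau = 0.15)
  co_m <- collision_assay(-pi / 3, pm, seeds = 1, window_tau = 0.15)
  expect_equal(as.vector(co_p), as.vector(co_m))
})

test_that("achiral passive ensembles have zero mean curvature", {
  pmech <- model_params(filament_spec(10, dtheta = 0), v0 = 0, gamma = 0.3,
                        k_bend = 5, kBT = 1, k_bond = 400, epsilon = 0,
                        dt = 1e-4)
  st <- straight_state(pmech, box_L = 42, head_x = 24)
  tr <- simulate_awlc(st, pmech, 60000, save_every = 600, seed = 31)
  ks <- unlist(lapply(tr$frames[-(1:20)], function(s)
    local_curvatures(s)$kappa))
  se <- sd(ks) / sqrt(length(ks) / 10)   # generous correlation discount
  expect_lt(abs(mean(ks)), 4 * se)
})
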