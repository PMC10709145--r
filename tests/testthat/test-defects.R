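test_that("director field: nematic averaging and trivial cases", {
  p <- params_wt()
  # all bonds at one angle: every occupied cell carries that angle mod pi
  st <- straight_state(p)
  g <- director_field(st)
  occ <- which(!is.na(g$angle))
  expect_gt(length(occ), 0)
  expect_true(all(abs(g$angle[occ] %% pi) < 1e-9 |
                  abs(g$angle[occ] %% pi - pi) < 1e-9))
  # two bonds at alpha and alpha+pi in one cell average to alpha
  r0 <- bead_r0()
  a <- 0.7
  fil1 <- cbind(21 - (0:2) * r0 * cos(a), 21 - (0:2) * r0 * sin(a))
  fil2 <- cbind(21.2 + (0:2) * r0 * cos(a), 21.1 + (0:2) * r0 * sin(a))
  st2 <- system_state(rbind(fil1, fil2), 2, 42)
  g2 <- director_field(st2)
  cell <- g2$angle[!is.na(g2$angle)]
  expect_equal(unname(cell[1]) %% pi, a, tolerance = 1e-9)
  # grid has an even number of cells per side (loop tiling requirement)
  expect_equal(g$n_grid %% 2, 0)
})

test_that("winding numbers on canonical textures snap to the charge table", {
  # uniform field: zero everywhere
  uni <- make_defect_field(data.frame(x = numeric(0), y = numeric(0),
                                      q = numeric(0)), n_grid = 10,
                           pitch = 4.7, const = 0.4)
  expect_equal(winding_number(uni, 5, 5), 0)
  dd_uni <- detect_defects(uni)
  expect_equal(nrow(dd_uni$defects), 0L)
  expect_true(dd_uni$valid)
  # +1/2 texture: angle = atan2/2 around the core -> winding +pi
  half <- make_defect_field(data.frame(x = 28.2, y = 28.2, q = 0.5),
                            n_grid = 12, pitch = 4.7, periodic = FALSE)
  w <- winding_number(half, 7, 7)
  expect_equal(w, pi, tolerance = 1e-9)
  # -1 texture: angle = -atan2 -> winding -2 pi (core at the loop centre;
  # integer windings are only faithful when the core is interior)
  ctr <- (7 - 0.5) * 4.7
  mone <- make_defect_field(data.frame(x = ctr, y = ctr, q = -1),
                            n_grid = 12, pitch = 4.7, periodic = FALSE)
  expect_equal(winding_number(mone, 7, 7), -2 * pi, tolerance = 1e-9)
})

test_that("synthetic defect pairs are recovered exactly with zero total", {
  g <- make_defect_field(data.frame(x = c(14.1, 42.3), y = c(14.1, 42.3),
                                    q = c(0.5, -0.5)), n_grid = 12,
                         pitch = 4.7)
  dd <- detect_defects(g)
  expect_equal(nrow(dd$defects), 2L)
  expect_equal(sort(dd$defects$charge), c(-0.5, 0.5))
  expect_equal(dd$total_charge, 0)
  expect_true(dd$valid)
  # positions within one grid cell of the seeded cores (per axis; loop
  # centres live on the even sublattice)
  for (k in 1:2) {
    err <- min(pmax(abs(dd$defects$x - c(14.1, 42.3)[k]),
                    abs(dd$defects$y - c(14.1, 42.3)[k])))
    expect_lt(err, 1.5 * g$pitch)
  }
  # nonzero net charge is rejected on periodic grids
  expect_error(make_defect_field(data.frame(x = 1, y = 1, q = 0.5),
                                 n_grid = 8), "zero total charge")
})

test_that("detector is exact on a randomized four-charge suite", {
  set.seed(5)
  for (rep in 1:5) {
    qs <- c(0.5, -0.5, 1, -1)
    n_grid <- 16; pitch <- 4.7; L <- n_grid * pitch
    # well-separated cores on a jittered 2x2 arrangement
    base <- as.matrix(expand.grid(c(0.25, 0.75) * L, c(0.25, 0.75) * L))
    base <- base + matrix(runif(8, -3, 3), 4, 2)
    perm <- sample(4)
    ch <- data.frame(x = base[, 1], y = base[, 2], q = qs[perm])
    g <- make_defect_field(ch, n_grid = n_grid, pitch = pitch,
                           const = runif(1, 0, pi))
    dd <- detect_defects(g)
    expect_equal(dd$total_charge, 0)
    expect_true(dd$valid)
    expect_equal(nrow(dd$defects), 4L)            # precision = recall = 1
    # each seeded core matched by a detection of the right charge nearby
    for (k in 1:4) {
      i <- which.min((dd$defects$x - ch$x[k])^2 + (dd$defects$y - ch$y[k])^2)
      expect_equal(dd$defects$charge[i], ch$q[k])
      expect_lt(max(abs(dd$defects$x[i] - ch$x[k]),
                    abs(dd$defects$y[i] - ch$y[k])), 2 * pitch)
    }
  }
})

test_that("charges are invariant under global director rotation", {
  g <- make_defect_field(data.frame(x = c(14.1, 42.3), y = c(42.3, 14.1),
                                    q = c(1, -1)), n_grid = 12, pitch = 4.7)
  d0 <- detect_defects(g)
  for (rot in c(0.3, 1.1, 2.9)) {
    g2 <- g
    g2$angle <- (g$angle + rot) %% pi
    d2 <- detect_defects(g2)
    expect_equal(sort(d2$defects$charge), sort(d0$defects$charge))
    expect_equal(d2$total_charge, 0)
  }
})

test_that("defect tracking: gating, gap bridging, flicker removal", {
  mk <- function(frame, x, y, q) data.frame(frame = frame, time = frame * 0.2,
                                            x = x, y = y, charge = q)
  pitch <- 4.7; L <- 12 * 4.7
  # defect moving one cell per frame for 10 frames: one track, lifetime 9
  mov <- do.call(rbind, lapply(1:10, function(f) mk(f, 5 + f * pitch, 10, 0.5)))
  tr <- track_defects(mov, pitch, L)
  expect_equal(nrow(tr$tracks), 1L)
  expect_equal(tr$tracks$n_frames, 10L)
  expect_equal(tr$tracks$lifetime, 9 * 0.2)
  # one missing middle frame is bridged into a single track
  gap <- mov[mov$frame != 5, ]
  trg <- track_defects(gap, pitch, L)
  expect_equal(nrow(trg$tracks), 1L)
  expect_equal(trg$tracks$n_frames, 9L)
  # two-frame flicker is excluded
  fl <- rbind(mov, mk(3, 40, 40, -0.5), mk(4, 40, 40, -0.5))
  trf <- track_defects(fl, pitch, L)
  expect_equal(nrow(trf$tracks), 1L)
  # displacements beyond three cells break the link
  jump <- rbind(mk(1, 10, 10, 0.5), mk(2, 10 + 4 * pitch, 10, 0.5),
                mk(3, 10 + 8 * pitch, 10, 0.5))
  expect_equal(nrow(track_defects(jump, pitch, L)$tracks), 0L)
  # opposite charges are tracked independently even when close
  two <- do.call(rbind, lapply(1:5, function(f)
    rbind(mk(f, 10 + f * pitch, 10, 0.5), mk(f, 10 + f * pitch, 11, -0.5))))
  trt <- track_defects(two, pitch, L)
  expect_equal(nrow(trt$tracks), 2L)
  expect_equal(sort(trt$tracks$charge), c(-0.5, 0.5))
  # MSD of the uniformly moving defect grows quadratically
  msd <- defect_msd(tr, L)
  expect_equal(msd$msd[1], pitch^2, tolerance = 1e-9)
  expect_equal(msd$msd[3], 9 * pitch^2, tolerance = 1e-9)
})
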