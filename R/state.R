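#' System state: bead positions with filament membership
#'
#' Beads are stored filament-contiguously: bead `(f-1)*M + j` is the j-th
#' bead of filament f, with j = 1 the head (leading end).  Coordinates are
#' wrapped into `[0, box_L)` in both axes.
#'
#' @param pos numeric matrix (n x 2) of bead coordinates in units of d.
#' @param n_bonds bonds per filament; every filament has `n_bonds + 1` beads.
#' @param box_L box side length in units of d.
#' @param time simulation time in tau.
#' @return an object of class `awlc_state`.
#' @export
system_state <- function(pos, n_bonds, box_L, time = 0) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 2, box_L > 0, n_bonds >= 2)
  M <- as.integer(n_bonds) + 1L
  if (nrow(pos) %% M != 0)
    stop("bead count ", nrow(pos), " is not a multiple of beads per filament ", M)
  pos <- pos %% box_L
  structure(list(pos = pos, M = M, box_L = box_L, time = time),
            class = "awlc_state")
}

#' @describeIn system_state filament index of every bead.
#' @param state an `awlc_state`.
#' @export
filament_of <- function(state) {
  rep(seq_len(nrow(state$pos) / state$M), each = state$M)
}

#' @describeIn system_state rank of every bead along its filament
#'   (1 = head).
#' @export
bead_rank <- function(state) {
  rep(seq_len(state$M), times = nrow(state$pos) / state$M)
}

#' @describeIn system_state number of filaments.
#' @export
n_filaments <- function(state) nrow(state$pos) / state$M

#' @export
print.awlc_state <- function(x, ...) {
  cat(sprintf("awlc_state: %d filaments x %d beads, box %g d, t = %g tau\n",
              n_filaments(x), x$M, x$box_L, x$time))
  invisible(x)
}

# minimum-image separation (vectorised)
.mi <- function(dx, L) dx - L * round(dx / L)

# per-filament coordinates unwrapped across the periodic boundary, anchored
# at the head bead
.unwrap_filament <- function(P, L) {
  d <- apply(P, 2, function(z) c(0, cumsum(.mi(diff(z), L))))
  sweep(d, 2, P[1, ], "+")
}

#' Split a state into per-filament unwrapped coordinate matrices
#'
#' Each filament's beads are unwrapped across the periodic boundary
#' (consecutive beads moved by minimum image), anchored at the head bead.
#' @param state an `awlc_state`.
#' @return list of (M x 2) matrices, one per filament, head first.
#' @export
filament_coords <- function(state) {
  f <- filament_of(state)
  lapply(split.data.frame(state$pos, f),
         .unwrap_filament, L = state$box_L)
}

#' Packing fraction of a state
#' @param state an `awlc_state`.
#' @param r0 bond length.
#' @return phi = N*Nf*d*r0/L^2 for this state.
#' @export
state_phi <- function(state, r0 = bead_r0()) {
  packing_fraction(state$M - 1L, n_filaments(state), state$box_L, r0)
}

#' Orientation of every bond
#'
#' Bond k of a filament joins beads k and k+1 (head to tail); its
#' orientation is reported head-ward (from bead k+1 towards bead k), the
#' direction of motion of the treadmilling filament.
#'
#' @param state an `awlc_state`.
#' @return data.frame with columns `filament`, `bond`, `x`, `y` (midpoint,
#'   wrapped into the box) and `ux`, `uy` (unit orientation).
#' @export
bond_table <- function(state) {
  M <- state$M; L <- state$box_L
  nf <- n_filaments(state)
  idx_a <- rep((seq_len(nf) - 1) * M, each = M - 1) +
    rep(seq_len(M - 1), times = nf)   # bead k (closer to head)
  idx_b <- idx_a + 1L
  dx <- .mi(state$pos[idx_a, 1] - state$pos[idx_b, 1], L)
  dy <- .mi(state$pos[idx_a, 2] - state$pos[idx_b, 2], L)
  len <- sqrt(dx^2 + dy^2)
  data.frame(
    filament = rep(seq_len(nf), each = M - 1),
    bond = rep(seq_len(M - 1), times = nf),
    x = (state$pos[idx_b, 1] + dx / 2) %% L,
    y = (state$pos[idx_b, 2] + dy / 2) %% L,
    ux = dx / len, uy = dy / len, length = len)
}

#' Per-filament centres of mass and orientations
#'
#' The filament orientation is the unit chord from tail to head (the polar
#' direction of motion).
#' @param state an `awlc_state`.
#' @return data.frame with `filament`, `x`, `y` (centre of mass, wrapped),
#'   `ux`, `uy` (unit tail-to-head chord).
#' @export
filament_table <- function(state) {
  cs <- filament_coords(state)
  L <- state$box_L
  out <- do.call(rbind, lapply(cs, function(P) {
    com <- colMeans(P)
    e2e <- P[1, ] - P[nrow(P), ]
    n <- sqrt(sum(e2e^2))
    u <- if (n > 0) e2e / n else c(NA_real_, NA_real_)
    c(com[1] %% L, com[2] %% L, u)
  }))
  data.frame(filament = seq_len(nrow(out)), x = out[, 1], y = out[, 2],
             ux = out[, 3], uy = out[, 4])
}
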