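# Independent brute-force dip oracle (pure R).
#
# dip(F) = min over unimodal G of sup|F - G|.  Feasibility of a band
# half-width d is decided by enumerating the mode position (each atom, and
# a dense set of points inside every between-atom segment and the two outer
# segments).  A unimodal G is convex and nondecreasing left of the mode,
# concave and nondecreasing right of it, with a possible upward jump at the
# mode only.  On each side the constraint set is: G within
# [F(t) - d, F(t^-) + d] at every atom t (intersected with [0, 1]), G
# monotone, slopes monotone (convexity/concavity).  For a convex function
# through such boxes:
#   - feasibility <=> the lower convex hull of the box tops lies above
#     every box bottom;
#   - the largest achievable value at the side's endpoint is the endpoint's
#     box top (when feasible);
#   - the smallest achievable value at the endpoint tau is
#       max( box bottoms, max over pairs i<j of the chord through
#            (t_i, top_i), (t_j, bottom_j) extended to tau )
#     (monotonicity gives the first term; nondecreasing slopes give the
#     second).
# The two sides join iff min achievable left value <= max achievable right
# value (the mode jump is upward).  The concave side is the mirror image of
# the convex side.  The dip is found by bisection on d, then floored at
# 1/(2n) (the statistic's conventional lower bound).

# convex-side helper: boxes (t_i, [lo_i, hi_i]) with t increasing, endpoint
# at t_k; returns c(feasible, zmin, zmax) at the endpoint
convex_side <- function(t, lo, hi) {
  k <- length(t)
  if (k == 0L) return(c(TRUE, 0, 1))
  if (any(lo > hi)) return(c(FALSE, NA, NA))
  # lower convex hull of the tops must clear the bottoms
  vx <- c(); vy <- c()
  for (i in seq_len(k)) {
    while (length(vx) >= 2) {
      m <- length(vx)
      cr <- (vy[m] - vy[m - 1]) * (t[i] - vx[m - 1]) -
            (hi[i] - vy[m - 1]) * (vx[m] - vx[m - 1])
      if (cr < 0) break
      vx <- vx[-m]; vy <- vy[-m]
    }
    vx <- c(vx, t[i]); vy <- c(vy, hi[i])
  }
  hull_at <- function(q) {
    if (length(vx) == 1L) return(vy[1L])
    j <- findInterval(q, vx, rightmost.closed = TRUE)
    j <- max(1L, min(j, length(vx) - 1L))
    if (vx[j + 1] == vx[j]) return(min(vy[j], vy[j + 1]))
    vy[j] + (vy[j + 1] - vy[j]) * (q - vx[j]) / (vx[j + 1] - vx[j])
  }
  for (i in seq_len(k)) {
    if (hull_at(t[i]) < lo[i] - 1e-12) return(c(FALSE, NA, NA))
  }
  # smallest achievable endpoint value
  zmin <- max(lo)
  if (k >= 2) {
    for (j in 2:k) {
      for (i in 1:(j - 1)) {
        if (t[j] > t[i]) {
          s <- (lo[j] - hi[i]) / (t[j] - t[i])
          zmin <- max(zmin, lo[j] + s * (t[k] - t[j]))
        }
      }
    }
  }
  if (zmin > hi[k] + 1e-12) return(c(FALSE, NA, NA))
  c(TRUE, zmin, hi[k])
}

dip_oracle <- function(x, grid_pts = 21L, tol = 1e-9) {
  x <- sort(x)
  n <- length(x)
  ux <- unique(x)
  u <- length(ux)
  if (u == 1L) return(1 / (2 * n))
  cnt <- as.numeric(table(match(x, ux)))
  cum <- cumsum(cnt) / n
  cuml <- c(0, cum[-u])
  rng <- diff(range(ux))
  pad <- 0.75 * rng / max(1L, u - 1L)

  feasible <- function(d) {
    boxes <- function(idx) { # atom boxes clipped to [0,1]
      list(t = ux[idx], lo = pmax(cum[idx] - d, 0),
           hi = pmin(cuml[idx] + d, 1))
    }
    # mode at atom a (index j): left endpoint is the pre-jump value at a,
    # right endpoint the post-jump value
    for (j in seq_len(u)) {
      lft <- if (j == 1L) c(TRUE, 0, min(cuml[1L] + d, 1)) else {
        b <- boxes(seq_len(j - 1L))
        convex_side(c(b$t, ux[j]), c(b$lo, max(cuml[j] - d, 0)),
                    c(b$hi, min(cuml[j] + d, 1)))
      }
      if (!lft[1L]) next
      rgt <- if (j == u) c(TRUE, max(1 - d, 0), 1) else {
        b <- boxes(seq.int(j + 1L, u))
        mir <- convex_side(c(-rev(b$t), -ux[j]),
                           c(1 - rev(b$hi), max(1 - (cum[j] + d), 0)),
                           c(1 - rev(b$lo), min(1 - (cum[j] - d), 1)))
        c(mir[1L], 1 - mir[3L], 1 - mir[2L])
      }
      if (!rgt[1L]) next
      if (lft[2L] <= rgt[3L] + 1e-12) return(TRUE)
    }
    # mode inside a segment (including the outer segments): no jump, G
    # continuous at the mode with value in the segment's band
    seg_lo <- c(ux[1L] - pad, ux)
    seg_hi <- c(ux, ux[u] + pad)
    seg_F <- c(0, cum) # F on the open segment
    for (s in seq_len(u + 1L)) {
      ms <- seq(seg_lo[s], seg_hi[s], length.out = grid_pts + 2L)
      ms <- ms[-c(1L, length(ms))]
      for (m in ms) {
        band_lo <- max(seg_F[s] - d, 0)
        band_hi <- min(seg_F[s] + d, 1)
        if (band_lo > band_hi) break
        lft <- if (s == 1L) c(TRUE, 0, band_hi) else {
          b <- boxes(seq_len(s - 1L))
          convex_side(c(b$t, m), c(b$lo, band_lo), c(b$hi, band_hi))
        }
        if (!lft[1L]) next
        rgt <- if (s == u + 1L) c(TRUE, max(1 - d, 0), 1) else {
          b <- boxes(seq.int(s, u))
          mir <- convex_side(c(-rev(b$t), -m),
                             c(1 - rev(b$hi), band_lo),
                             c(1 - rev(b$lo), band_hi))
          c(mir[1L], 1 - mir[3L], 1 - mir[2L])
        }
        if (!rgt[1L]) next
        if (lft[2L] <= rgt[3L] + 1e-12) return(TRUE)
      }
    }
    FALSE
  }

  lo <- 0; hi <- 0.5
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  max(hi, 1 / (2 * n))
}
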