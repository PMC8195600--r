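# Independent oracles used across the suite. These deliberately use different
# algorithms from the package internals so agreement is meaningful.

# Lattice-point count of a filled axis-aligned ellipse: brute loop over a
# bounding box, quadratic-form test per pixel center.
oracle_ellipse_area <- function(center, axes) {
  r0 <- floor(center[1] - axes[1]):ceiling(center[1] + axes[1])
  c0 <- floor(center[2] - axes[2]):ceiling(center[2] + axes[2])
  n <- 0L
  for (r in r0) for (c in c0)
    if (((r - center[1]) / axes[1])^2 + ((c - center[2]) / axes[2])^2 <= 1)
      n <- n + 1L
  n
}

# Point-in-polygon by winding number (sum of signed angles), plus explicit
# on-boundary test; equals even-odd membership for simple polygons.
oracle_point_in_polygon <- function(pt, verts) {
  n <- nrow(verts)
  ang <- 0
  for (i in seq_len(n)) {
    a <- verts[i, ] - pt
    b <- verts[if (i == n) 1L else i + 1L, ] - pt
    cross <- a[1] * b[2] - a[2] * b[1]
    dot <- sum(a * b)
    # on-vertex or on-edge
    if (all(a == 0) || all(b == 0)) return(TRUE)
    if (cross == 0 && dot <= 0) return(TRUE)
    ang <- ang + atan2(cross, dot)
  }
  abs(ang) > pi  # winding number != 0
}

oracle_rasterize <- function(verts, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (r in 0:(shape[1] - 1)) for (c in 0:(shape[2] - 1))
    m[r + 1, c + 1] <- oracle_point_in_polygon(c(r, c), verts)
  m
}

# Exact two-sided Mann-Whitney p by full enumeration of all group-1 subsets
# of the pooled sample (no ties assumed).
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(id) sum(rk[id]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(u_all <= u_obs)
  p_hi <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Closed-form simple linear regression (normal equations).
oracle_ols <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(slope = slope, intercept = (sy - slope * sx) / n)
}

# A small random simple polygon: star-shaped around its center with evenly
# spaced, jittered angles. Every angular gap stays below pi (jitter < 0.4 of
# the spacing, nv >= 4), which guarantees simplicity by construction.
random_simple_polygon <- function(center, rmin, rmax, nv) {
  stopifnot(nv >= 4)
  spacing <- 2 * pi / nv
  ang <- (seq_len(nv) - 1) * spacing + runif(nv, -0.4, 0.4) * spacing
  rad <- runif(nv, rmin, rmax)
  cbind(center[1] + rad * sin(ang), center[2] + rad * cos(ang))
}

# The 29 planted-inhibitor ids used in screen recovery experiments: step 43
# is coprime with 80 wells/plate, so all 29 land on distinct plate positions.
planted_inhibitor_ids <- function() sprintf("C%04d", 20 + 43 * (0:28))
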