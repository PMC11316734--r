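# Internal geometry helpers. Convention throughout the package:
# coordinates and lengths in millimetres, radii in micrometres.
# Conversions are explicit at module boundaries, never implicit.

MM_PER_UM <- 1e-3
UM_PER_MM <- 1e3
PA_PER_MMHG <- 133.322
M3S_PER_ULMIN <- 1e-9 / 60  # 1 uL/min in m^3/s

vnorm <- function(v) sqrt(sum(v * v))

rownorms <- function(m) sqrt(rowSums(m * m))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalise a zero vector")
  v / n
}

# Arc length of a polyline (k x 3 matrix), mm.
polyline_length <- function(path) {
  if (nrow(path) < 2) return(0)
  sum(rownorms(diff(path)))
}

# Cumulative arc length at each path point, mm.
polyline_cumlen <- function(path) {
  if (nrow(path) < 2) return(0)
  c(0, cumsum(rownorms(diff(path))))
}

# Rotate 2D vectors (in the xy-plane) by angle theta (radians).
rot2 <- function(v, theta) {
  c(cos(theta) * v[1] - sin(theta) * v[2],
    sin(theta) * v[1] + cos(theta) * v[2])
}

# Distance from points (n x 2|3) to a single segment a-b; returns list(d, t)
# with t the normalised projection parameter clamped to [0, 1].
point_segment_distance <- function(p, a, b) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  ab <- b - a
  len2 <- sum(ab * ab)
  if (len2 == 0) {
    d <- sqrt(rowSums(sweep(p, 2, a)^2))
    return(list(d = d, t = rep(0, nrow(p))))
  }
  ap <- sweep(p, 2, a)
  t <- pmin(1, pmax(0, as.vector(ap %*% ab) / len2))
  proj <- outer(t, ab) + matrix(a, nrow(p), length(a), byrow = TRUE)
  list(d = sqrt(rowSums((p - proj)^2)), t = t)
}

# Scalar 2D point-to-segment distance; returns c(d, t). Hot path.
psd1 <- function(px, py, ax, ay, bx, by) {
  abx <- bx - ax; aby <- by - ay
  len2 <- abx * abx + aby * aby
  if (len2 == 0) {
    dx <- px - ax; dy <- py - ay
    return(c(sqrt(dx * dx + dy * dy), 0))
  }
  t <- ((px - ax) * abx + (py - ay) * aby) / len2
  t <- if (t < 0) 0 else if (t > 1) 1 else t
  dx <- px - (ax + t * abx); dy <- py - (ay + t * aby)
  c(sqrt(dx * dx + dy * dy), t)
}

# Minimum distance between two 2D segments p1-p2 and q1-q2 (xy only).
segseg_distance_2d <- function(p1, p2, q1, q2) {
  # proper intersection test first
  d1 <- cross2(q2 - q1, p1 - q1)
  d2 <- cross2(q2 - q1, p2 - q1)
  d3 <- cross2(p2 - p1, q1 - p1)
  d4 <- cross2(p2 - p1, q2 - p1)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
    return(0)
  }
  min(point_segment_distance(rbind(p1, p2), q1, q2)$d,
      point_segment_distance(rbind(q1, q2), p1, p2)$d)
}

cross2 <- function(u, v) u[1] * v[2] - u[2] * v[1]

# Resample a polyline so that no inter-point spacing exceeds max_step (mm).
# Keeps original vertices; linear interpolation of per-point values in `vals`
# (a matrix/vector aligned with rows of path) if supplied.
densify_polyline <- function(path, max_step, vals = NULL) {
  if (nrow(path) < 2 || max_step <= 0) {
    return(list(path = path, vals = vals))
  }
  out <- list(path[1, , drop = FALSE])
  vout <- if (!is.null(vals)) list(vals[1]) else NULL
  for (i in seq_len(nrow(path) - 1)) {
    a <- path[i, ]; b <- path[i + 1, ]
    L <- vnorm(b - a)
    nseg <- max(1L, ceiling(L / max_step))
    tt <- seq_len(nseg) / nseg
    pts <- outer(tt, b - a) + matrix(a, nseg, 3, byrow = TRUE)
    out[[length(out) + 1L]] <- pts
    if (!is.null(vals)) {
      vout[[length(vout) + 1L]] <- vals[i] + tt * (vals[i + 1] - vals[i])
    }
  }
  list(path = do.call(rbind, out),
       vals = if (!is.null(vals)) unlist(vout) else NULL)
}

# Deterministic per-stage seed derived from a root seed and a stage name,
# kept below 2^31 so set.seed() accepts it on all platforms.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# package-local memoisation (e.g. the parameter table)
.retinavasc_cache <- new.env(parent = emptyenv())
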