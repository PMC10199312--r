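# Polyline geometry helpers. Points are row-wise 3-vectors in voxel units;
# arc lengths are physical (micrometre) when a voxel_size is supplied.

as_points <- function(p) {
  p <- as.matrix(p)
  if (is.null(dim(p)) || ncol(p) != 3) stop("points must be an n x 3 matrix")
  storage.mode(p) <- "double"
  p
}

vnorm <- function(v) sqrt(sum(v^2))

seg_lengths <- function(points, voxel_size = c(1, 1, 1)) {
  points <- as_points(points)
  if (nrow(points) < 2) return(numeric(0))
  d <- sweep(diff(points), 2, voxel_size, `*`)
  sqrt(rowSums(d^2))
}

#' Arc length of a polyline
#'
#' @param points n x 3 matrix of positions (voxel units).
#' @param voxel_size numeric(3) micrometre per voxel.
#' @return total arc length in micrometre.
#' @export
arc_length <- function(points, voxel_size = c(1, 1, 1)) {
  sum(seg_lengths(points, voxel_size))
}

#' Resample a polyline at a fixed arc-length step
#'
#' Walks the polyline and emits points every `step` micrometre of arc
#' length; the first and last input points are preserved exactly and the
#' final gap may be shorter than `step`.
#'
#' @param points n x 3 matrix (n >= 2), voxel units.
#' @param step arc-length step in micrometre, > 0.
#' @param voxel_size numeric(3) micrometre per voxel.
#' @param values optional numeric vector (length n) interpolated alongside
#'   the positions (e.g. per-node radii); returned as attribute `values`.
#' @return m x 3 matrix of resampled positions.
#' @export
resample_polyline <- function(points, step, voxel_size = c(1, 1, 1),
                              values = NULL) {
  points <- as_points(points)
  if (nrow(points) < 2) stop("need at least 2 points to resample")
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0)
    stop("`step` must be a positive number")
  L <- c(0, cumsum(seg_lengths(points, voxel_size)))
  total <- L[length(L)]
  if (total <= 0) stop("degenerate polyline: zero arc length")
  targets <- seq(0, total, by = step)
  if (targets[length(targets)] < total - 1e-9) targets <- c(targets, total)
  out <- interp_at_arc(points, L, targets)
  # pin endpoints exactly
  out[1, ] <- points[1, ]
  out[nrow(out), ] <- points[nrow(points), ]
  if (!is.null(values)) {
    attr(out, "values") <- interp_values_at_arc(values, L, targets)
  }
  out
}

# positions at given cumulative arc lengths (L = cumulative lengths of pts)
interp_at_arc <- function(points, L, targets) {
  n <- nrow(points)
  seg <- findInterval(targets, L, rightmost.closed = TRUE)
  seg[seg < 1] <- 1L
  seg[seg > n - 1] <- n - 1L
  len <- L[seg + 1] - L[seg]
  t <- ifelse(len > 0, (targets - L[seg]) / len, 0)
  points[seg, , drop = FALSE] +
    (points[seg + 1, , drop = FALSE] - points[seg, , drop = FALSE]) * t
}

interp_values_at_arc <- function(values, L, targets) {
  n <- length(values)
  seg <- findInterval(targets, L, rightmost.closed = TRUE)
  seg[seg < 1] <- 1L
  seg[seg > n - 1] <- n - 1L
  len <- L[seg + 1] - L[seg]
  t <- ifelse(len > 0, (targets - L[seg]) / len, 0)
  values[seg] + (values[seg + 1] - values[seg]) * t
}

# point at half arc length of a polyline
curve_midpoint <- function(points, voxel_size = c(1, 1, 1)) {
  points <- as_points(points)
  L <- c(0, cumsum(seg_lengths(points, voxel_size)))
  drop(interp_at_arc(points, L, L[length(L)] / 2))
}

# split a polyline at its arc-length midpoint; the midpoint is inserted in
# both halves so first[last] == second[first] == midpoint
split_at_midpoint <- function(points, voxel_size = c(1, 1, 1)) {
  points <- as_points(points)
  L <- c(0, cumsum(seg_lengths(points, voxel_size)))
  half <- L[length(L)] / 2
  mid <- drop(interp_at_arc(points, L, half))
  before <- which(L < half - 1e-9)
  after <- which(L > half + 1e-9)
  first <- rbind(points[before, , drop = FALSE], mid)
  second <- rbind(mid, points[after, , drop = FALSE])
  list(first = dedupe_points(first), second = dedupe_points(second),
       midpoint = mid)
}

# drop consecutive (near-)duplicate points
dedupe_points <- function(points, tol = 1e-9) {
  points <- as_points(points)
  if (nrow(points) < 2) return(points)
  d <- sqrt(rowSums(diff(points)^2))
  keep <- c(TRUE, d > tol)
  points[keep, , drop = FALSE]
}

# minimum distance from each point in P to polyline Q (point-to-segment),
# in micrometre under voxel_size
dist_to_polyline <- function(P, Q, voxel_size = c(1, 1, 1)) {
  P <- sweep(as_points(P), 2, voxel_size, `*`)
  Q <- sweep(as_points(Q), 2, voxel_size, `*`)
  n <- nrow(Q)
  if (n == 1) {
    return(sqrt(rowSums(sweep(P, 2, Q[1, ])^2)))
  }
  best <- rep(Inf, nrow(P))
  for (i in seq_len(n - 1)) {
    a <- Q[i, ]
    ab <- Q[i + 1, ] - a
    ab2 <- sum(ab^2)
    ap <- sweep(P, 2, a)
    t <- if (ab2 > 0) pmin(1, pmax(0, (ap %*% ab) / ab2)) else 0
    proj <- ap - outer(drop(t), ab)
    best <- pmin(best, rowSums(proj^2))
  }
  sqrt(best)
}

# minimum distance from each point in P to a set of polylines
dist_to_polylines <- function(P, polylines, voxel_size = c(1, 1, 1)) {
  best <- rep(Inf, nrow(as_points(P)))
  for (Q in polylines) best <- pmin(best, dist_to_polyline(P, Q, voxel_size))
  best
}

# turning angle (radians) at each interior vertex of a polyline
turning_angles <- function(points) {
  points <- as_points(points)
  n <- nrow(points)
  if (n < 3) return(numeric(0))
  d <- diff(points)
  len <- sqrt(rowSums(d^2))
  u <- d / pmax(len, 1e-12)
  dots <- rowSums(u[-nrow(u), , drop = FALSE] * u[-1, , drop = FALSE])
  acos(pmin(1, pmax(-1, dots)))
}

# a random unit 3-vector (uses the current RNG stream)
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vnorm(v)
    if (n > 1e-6) return(v / n)
  }
}
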