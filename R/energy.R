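#' Energy / tracer parameters
#'
#' Coefficients of the deformable-model energy
#' `E = alpha * E_image + beta * E_length + gamma * E_smoothness` and the
#' constants of its image terms. `lambda_I` controls how steeply the
#' intensity metric `gI = exp(lambda_I (1 - I/Imax)^2)` penalises dark
#' voxels (it spans `[1, exp(lambda_I)]`); `lambda_C` weights the
#' centre-of-signal term; `r` is the neighbourhood radius (voxels) used by
#' the image terms.
#'
#' @param alpha,beta,gamma non-negative energy coefficients
#'   (`alpha + beta + gamma > 0`).
#' @param lambda_I positive constant of the intensity metric.
#' @param lambda_C positive constant of the centring term.
#' @param r neighbourhood radius in voxels, positive.
#' @param max_deform_iters iteration cap of the deform step.
#' @param energy_tol convergence tolerance on the energy decrease.
#' @param step_size damping of the coordinate-wise deform update, in (0, 1].
#' @return a list of class `energy_params`.
#' @export
energy_params <- function(alpha = 1, beta = 0.2, gamma = 0.2,
                          lambda_I = 10, lambda_C = 1, r = 4,
                          max_deform_iters = 100, energy_tol = 1e-4,
                          step_size = 0.5) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0)
  if (alpha + beta + gamma <= 0) stop("alpha + beta + gamma must be > 0")
  stopifnot(lambda_I > 0, lambda_C > 0, r > 0,
            max_deform_iters >= 1, energy_tol > 0,
            step_size > 0, step_size <= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 lambda_I = lambda_I, lambda_C = lambda_C, r = r,
                 max_deform_iters = as.integer(max_deform_iters),
                 energy_tol = energy_tol, step_size = step_size),
            class = "energy_params")
}

#' Intensity metric of the voxel graph
#'
#' `gI(v) = exp(lambda_I * (1 - I(v)/Imax)^2)`: 1 at the block maximum and
#' `exp(lambda_I)` at zero intensity, strictly decreasing in `I_v`.
#'
#' @param I_v voxel intensity (vectorised), in `[0, Imax]`.
#' @param Imax block maximum intensity, > 0.
#' @param lambda_I positive constant.
#' @return numeric vector of metric values in `[1, exp(lambda_I)]`.
#' @export
intensity_metric <- function(I_v, Imax, lambda_I = 10) {
  if (!is.numeric(Imax) || length(Imax) != 1 || Imax <= 0)
    stop("degenerate block: Imax must be > 0")
  if (any(I_v < 0 | I_v > Imax)) stop("intensities must lie in [0, Imax]")
  exp(lambda_I * (1 - I_v / Imax)^2)
}

#' Edge weight of the intensity-weighted voxel graph
#'
#' For 26-neighbouring voxels `v0`, `v1`:
#' `e = ||v0 - v1|| * (gI(v0) + gI(v1)) / 2`, with the geometric length
#' measured in physical units via the block voxel size. High-intensity
#' voxels yield cheap edges, so shortest paths follow bright signal.
#'
#' @param v0,v1 integer voxel coordinates (0-based, length 3), 26-neighbours.
#' @param block an [image_block()].
#' @param lambda_I positive constant of [intensity_metric()].
#' @return positive edge weight.
#' @export
edge_weight <- function(v0, v1, block, lambda_I = 10) {
  v0 <- as.numeric(v0); v1 <- as.numeric(v1)
  d <- v1 - v0
  if (all(d == 0) || any(abs(d) > 1))
    stop("contract violation: voxels are not 26-neighbours")
  Imax <- max(block$data)
  i0 <- block$data[v0[1] + 1, v0[2] + 1, v0[3] + 1]
  i1 <- block$data[v1[1] + 1, v1[2] + 1, v1[3] + 1]
  len <- vnorm(d * block$voxel_size)
  len * (intensity_metric(i0, Imax, lambda_I) +
           intensity_metric(i1, Imax, lambda_I)) / 2
}

#' Deformable-model energy terms
#'
#' `energy_length` is the sum of squared gaps over consecutive control
#' points; `energy_smoothness` sums, over interior points, the squared
#' distance of each point from the midpoint of its neighbours (zero for
#' equally spaced collinear points); `energy_image` sums per-point intensity
#' and centring terms
#' `EI_k = lambda_I (1 - I(C_k) / max_{q in Theta(C_k, r)} I(q))^2` and
#' `EC_k = lambda_C * sum_q ||C_k - q||^2 I(q) / sum_q I(q)`,
#' where `Theta(C_k, r)` is the set of voxels within Euclidean distance `r`
#' of `C_k` clipped to the block. A control point in an all-zero
#' neighbourhood contributes the fallback `lambda_I` (flagged via the
#' `dark_points` attribute).
#'
#' @param curve K x 3 matrix of control points (continuous voxel coords).
#' @param block an [image_block()].
#' @param params an [energy_params()].
#' @return scalar energy; `energy_image` carries attributes `ei`, `ec`,
#'   `dark_points`.
#' @export
energy_length <- function(curve) {
  curve <- as_points(curve)
  if (nrow(curve) < 2) return(0)
  sum(diff(curve)^2)
}

#' @rdname energy_length
#' @export
energy_smoothness <- function(curve) {
  curve <- as_points(curve)
  K <- nrow(curve)
  if (K < 3) return(0)
  mid <- (curve[-c(K - 1, K), , drop = FALSE] +
            curve[-c(1, 2), , drop = FALSE]) / 2
  sum((curve[2:(K - 1), , drop = FALSE] - mid)^2)
}

#' @rdname energy_length
#' @export
energy_image <- function(curve, block, params = energy_params()) {
  curve <- as_points(curve)
  res <- cpp_energy_image(curve, as.double(block$data),
                          as.integer(block_dim(block)),
                          params$lambda_I, params$lambda_C, params$r)
  out <- sum(res$ei + res$ec)
  attr(out, "ei") <- res$ei
  attr(out, "ec") <- res$ec
  attr(out, "dark_points") <- which(res$dark)
  out
}

#' @rdname energy_length
#' @export
total_energy <- function(curve, block, params = energy_params()) {
  as.numeric(params$alpha * energy_image(curve, block, params) +
               params$beta * energy_length(curve) +
               params$gamma * energy_smoothness(curve))
}
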