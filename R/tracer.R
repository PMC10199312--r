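#' Shortest path on the intensity-weighted voxel graph
#'
#' Runs Dijkstra's algorithm over the 26-connected voxel graph of `block`
#' with edge weights `||v0 - v1|| * (gI(v0) + gI(v1)) / 2` (see
#' [edge_weight()]), returning a minimum-total-weight voxel path from
#' `start` to `end`. Ties are broken deterministically. Blocks larger than
#' `max_voxels` are refused with an instruction to crop.
#'
#' @param block an [image_block()] with positive maximum intensity.
#' @param start,end integer voxel coordinates (0-based, block-local).
#' @param lambda_I positive constant of the intensity metric.
#' @param max_voxels memory guard on the number of block voxels
#'   (default 512 * 512 * 256).
#' @return K x 3 numeric matrix of voxel coordinates, first row `start`,
#'   last row `end`; attribute `total_weight` holds the path weight.
#' @export
graph_shortest_path <- function(block, start, end, lambda_I = 10,
                                max_voxels = 512 * 512 * 256) {
  if (!is_image_block(block)) stop("`block` must be an image_block")
  dims <- block_dim(block)
  if (prod(dims) > max_voxels) {
    stop(sprintf(paste0("size error: block has %d voxels (budget %d); ",
                        "crop the volume into smaller blocks"),
                 prod(dims), max_voxels))
  }
  start <- as.integer(round(start)); end <- as.integer(round(end))
  for (p in list(start, end)) {
    if (length(p) != 3 || any(p < 0) || any(p > dims - 1))
      stop("start/end voxel outside the block")
  }
  if (all(start == end)) stop("start and end voxels must differ")
  path <- cpp_dijkstra(as.double(block$data), as.integer(dims),
                       start, end, lambda_I, as.double(block$voxel_size))
  out <- matrix(as.numeric(path), ncol = 3)
  attr(out, "total_weight") <- attr(path, "total_weight")
  out
}

#' Deform a curve by local energy minimisation
#'
#' Refines the interior control points of `curve` so that the total energy
#' (see [total_energy()]) decreases monotonically; endpoints stay fixed and
#' interior points move with sub-voxel precision. Iteration stops when the
#' energy decrease falls below `params$energy_tol` or after
#' `params$max_deform_iters` sweeps (non-convergence is not an error; the
#' best curve found is returned).
#'
#' @param curve K x 3 matrix of control points (block-local, continuous).
#' @param block an [image_block()].
#' @param params an [energy_params()].
#' @return deformed K x 3 curve with attributes `energy_trace` (monotone
#'   non-increasing), `iterations` and `converged`.
#' @export
deform <- function(curve, block, params = energy_params()) {
  curve <- as_points(curve)
  if (nrow(curve) <= 2) {
    attr(curve, "energy_trace") <- total_energy(curve, block, params)
    attr(curve, "iterations") <- 0L
    attr(curve, "converged") <- TRUE
    return(curve)
  }
  res <- cpp_deform(curve, as.double(block$data),
                    as.integer(block_dim(block)),
                    params$alpha, params$beta, params$gamma,
                    params$lambda_I, params$lambda_C, params$r,
                    params$step_size, params$energy_tol,
                    params$max_deform_iters)
  out <- res$curve
  out[1, ] <- curve[1, ]
  out[nrow(out), ] <- curve[nrow(curve), ]
  attr(out, "energy_trace") <- res$energy
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- res$converged
  out
}

#' Two-point tracing: graph step then deform step
#'
#' Traces an optimal path between two endpoints inside an image block: a
#' Dijkstra shortest path between the rounded endpoints on the
#' intensity-weighted voxel graph (graph step), then energy-minimising
#' deformation of that path (deform step). The returned curve's endpoints
#' are restored to the exact (possibly sub-voxel) input points.
#'
#' @param block an [image_block()] with positive maximum intensity.
#' @param p0,p1 endpoints in block-local continuous voxel coordinates.
#' @param params an [energy_params()].
#' @param max_voxels memory guard forwarded to [graph_shortest_path()].
#' @return K x 3 curve; attributes `energy_pre` / `energy_post` record the
#'   total energy before and after the deform step.
#' @export
trace <- function(block, p0, p1, params = energy_params(),
                  max_voxels = 512 * 512 * 256) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (all(abs(p0 - p1) < 1e-12)) {
    warning("trace called with identical endpoints; returning degenerate curve")
    return(rbind(p0, p1))
  }
  dims <- block_dim(block)
  clamp <- function(p) pmin(pmax(p, 0), dims - 1)
  v0 <- clamp(round(p0)); v1 <- clamp(round(p1))
  if (all(v0 == v1)) {
    # endpoints fall in the same voxel: nothing for the graph step to do
    curve <- rbind(p0, p1)
    attr(curve, "energy_pre") <- total_energy(curve, block, params)
    attr(curve, "energy_post") <- attr(curve, "energy_pre")
    return(curve)
  }
  path <- graph_shortest_path(block, v0, v1, lambda_I = params$lambda_I,
                              max_voxels = max_voxels)
  e_pre <- total_energy(path, block, params)
  curve <- deform(path, block, params)
  curve[1, ] <- p0
  curve[nrow(curve), ] <- p1
  e_post <- utils::tail(attr(curve, "energy_trace"), 1)
  attr(curve, "energy_pre") <- e_pre
  attr(curve, "energy_post") <- e_post
  curve
}
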