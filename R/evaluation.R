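# branch polylines of a tree (list of n x 3 matrices)
tree_polylines <- function(tree) {
  branches <- decompose_branches(tree)
  if (!length(branches)) stop("tree has no edges")
  lapply(branches, `[[`, "positions")
}

# resample every branch of a tree; returns a matrix of points (optionally
# with interpolated per-point radii as attribute "radii")
resampled_tree_points <- function(tree, step, with_radii = FALSE) {
  branches <- decompose_branches(tree)
  if (!length(branches)) stop("tree has no edges")
  pts <- list()
  rad <- list()
  for (b in branches) {
    P <- dedupe_points(b$positions)
    if (nrow(P) < 2) next
    keep <- c(TRUE, sqrt(rowSums(diff(b$positions)^2)) > 1e-9)
    r <- resample_polyline(b$positions[keep, , drop = FALSE], step,
                           tree$voxel_size,
                           values = if (with_radii) b$radii[keep])
    pts[[length(pts) + 1]] <- r
    if (with_radii) rad[[length(rad) + 1]] <- attr(r, "values")
  }
  out <- do.call(rbind, pts)
  if (with_radii) attr(out, "radii") <- unlist(rad)
  out
}

#' Skeleton deviation between two reconstructions
#'
#' Resamples the test tree at `resample_step` micrometre and returns the
#' mean, over test points, of the distance to the nearest point on the
#' ground-truth polyline (point-to-segment, not point-to-node), in
#' micrometre (equal to voxels for unit voxel size).
#'
#' @param test,gt [neuron_tree()] objects on the same coordinate grid.
#' @param resample_step resampling interval in micrometre (default 2).
#' @return mean nearest-point distance.
#' @export
skeleton_deviation <- function(test, gt, resample_step = 2) {
  P <- resampled_tree_points(test, resample_step)
  mean(dist_to_polylines(P, tree_polylines(gt), gt$voxel_size))
}

# sorted descendant-tip signature per bifurcation (tips are fixed by the
# refinement contract, so signatures match exactly across methods)
bifurcation_signatures <- function(tree) {
  ids <- bifurcation_ids(tree)
  if (!length(ids)) return(list())
  ch <- children_index(tree)
  nch <- lengths(ch)
  pos <- node_positions(tree)
  out <- list()
  for (id in ids) {
    row <- match(id, tree$nodes$id)
    # collect descendant tips
    stack <- ch[[row]]
    tips <- integer(0)
    while (length(stack)) {
      i <- stack[1]; stack <- stack[-1]
      if (nch[i] == 0) tips <- c(tips, i) else stack <- c(stack, ch[[i]])
    }
    sig <- paste(sort(apply(pos[tips, , drop = FALSE], 1, function(p)
      sprintf("%.6f,%.6f,%.6f", p[1], p[2], p[3]))), collapse = "|")
    out[[sig]] <- pos[row, ]
  }
  out
}

#' Bifurcation deviation between two reconstructions
#'
#' Mean Euclidean distance between topologically corresponding bifurcation
#' points. Correspondence is established by branch adjacency (each
#' bifurcation is identified by the set of terminal tips it subtends, which
#' refinement leaves fixed), not by nearest-neighbour matching.
#'
#' @param test,gt [neuron_tree()] objects with equal bifurcation counts.
#' @return mean distance in micrometre; `NA` if neither tree has a
#'   bifurcation.
#' @export
bifurcation_deviation <- function(test, gt) {
  st <- bifurcation_signatures(test)
  sg <- bifurcation_signatures(gt)
  if (length(st) != length(sg))
    stop("topology mismatch: differing bifurcation counts")
  if (!length(sg)) return(NA_real_)
  miss <- setdiff(names(sg), names(st))
  if (length(miss))
    stop("topology mismatch: unmatched junction (tip signature ", miss[1], ")")
  vs <- gt$voxel_size
  mean(vapply(names(sg), function(s) {
    vnorm((st[[s]] - sg[[s]]) * vs)
  }, numeric(1)))
}

#' Estimate node radii from the image
#'
#' For each node, the radius is the largest `r` on the half-voxel grid
#' `0.5, 1.0, ..., r_max` such that at least `coverage` of the voxels within
#' distance `r` of the node exceed `bg_threshold`. Nodes in fully dark
#' regions receive radius 0 and are flagged in the `dark_nodes` attribute.
#'
#' @param tree a [neuron_tree()] with nodes inside `image`.
#' @param image an [image_block()].
#' @param bg_threshold background intensity threshold (default: half the
#'   block amplitude).
#' @param r_max largest radius probed, voxels.
#' @param coverage required above-threshold voxel fraction (default 0.95).
#' @return the tree with its `radius` column replaced by the estimates.
#' @export
radius_estimate <- function(tree, image, bg_threshold = NULL, r_max = 6,
                            coverage = 0.95) {
  if (is.null(bg_threshold))
    bg_threshold <- (max(image$data) + min(image$data)) / 2
  dims <- block_dim(image)
  pos <- sweep(node_positions(tree), 2, image$origin)
  radii_grid <- seq(0.5, r_max, by = 0.5)
  R <- ceiling(r_max)
  est <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    p <- pos[i, ]
    lo <- pmax(floor(p) - R, 0)
    hi <- pmin(ceiling(p) + R, dims - 1)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    gx <- rep(xs, times = length(ys) * length(zs))
    gy <- rep(rep(ys, each = length(xs)), times = length(zs))
    gz <- rep(zs, each = length(xs) * length(ys))
    d2 <- (gx - p[1])^2 + (gy - p[2])^2 + (gz - p[3])^2
    bright <- image$data[cbind(gx + 1, gy + 1, gz + 1)] > bg_threshold
    best <- 0
    for (r in radii_grid) {
      inside <- d2 <= r^2
      if (!any(inside)) next
      if (mean(bright[inside]) >= coverage) best <- r
    }
    est[i] <- best
  }
  out <- tree
  out$nodes$radius <- est
  attr(out, "dark_nodes") <- which(est == 0)
  out
}

#' Mean interpolated intensity at reconstruction nodes
#'
#' @param tree a [neuron_tree()].
#' @param image an [image_block()].
#' @return mean of trilinearly interpolated intensities at node positions.
#' @export
intensity_extraction <- function(tree, image) {
  P <- sweep(node_positions(tree), 2, image$origin)
  mean(interp_intensity(image, P))
}

# voxel keys covered by the union of spheres along a resampled skeleton
sphere_union_keys <- function(points, radii) {
  offset <- 256L  # keep keys positive for skeletons near the origin
  K <- 8192
  keys <- vector("list", nrow(points))
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    r <- radii[i]
    R <- ceiling(r)
    xs <- (floor(p[1]) - R):(ceiling(p[1]) + R)
    ys <- (floor(p[2]) - R):(ceiling(p[2]) + R)
    zs <- (floor(p[3]) - R):(ceiling(p[3]) + R)
    gx <- rep(xs, times = length(ys) * length(zs))
    gy <- rep(rep(ys, each = length(xs)), times = length(zs))
    gz <- rep(zs, each = length(xs) * length(ys))
    d2 <- (gx - p[1])^2 + (gy - p[2])^2 + (gz - p[3])^2
    inside <- d2 <= r^2
    keys[[i]] <- (gx[inside] + offset) +
      K * ((gy[inside] + offset) + K * (gz[inside] + offset))
  }
  unique(unlist(keys))
}

#' Information extraction rate
#'
#' Voxelises the ground-truth signal volume as the union of spheres of the
#' ground-truth radii along the resampled ground-truth skeleton, voxelises
#' the test reconstruction the same way with its own radii, and returns the
#' fraction of the ground-truth volume covered:
#' `|S_test intersect S_gt| / |S_gt|`. The information loss rate reported by
#' the benchmark is `1 -` this value.
#'
#' @param test,gt [neuron_tree()] objects; `gt` must carry positive radii.
#' @param resample_step skeleton resampling interval in micrometre.
#' @return a fraction in `[0, 1]`.
#' @export
information_extraction_rate <- function(test, gt, resample_step = 2) {
  Pg <- resampled_tree_points(gt, resample_step, with_radii = TRUE)
  Pt <- resampled_tree_points(test, resample_step, with_radii = TRUE)
  sg <- sphere_union_keys(Pg, attr(Pg, "radii"))
  if (!length(sg)) stop("empty ground-truth signal volume")
  st <- sphere_union_keys(Pt, attr(Pt, "radii"))
  length(intersect(st, sg)) / length(sg)
}

#' Node count and serialized size of a reconstruction
#'
#' @param tree a [neuron_tree()].
#' @param as_written if TRUE, the byte size is measured from the canonical
#'   SWC serialisation written to a temporary file.
#' @return list with `node_count` and `file_bytes`.
#' @export
storage_size <- function(tree, as_written = TRUE) {
  bytes <- NA_integer_
  if (as_written) {
    tmp <- tempfile(fileext = ".swc")
    on.exit(unlink(tmp))
    write_swc(tree, tmp)
    bytes <- file.size(tmp)
  }
  list(node_count = nrow(tree$nodes), file_bytes = as.integer(bytes))
}

#' Mean-Shift refinement baseline
#'
#' Moves each internal node (root and tips excluded, matching the
#' refinement contract) to the intensity-weighted centroid of the voxels
#' within `search_radius`, iterating until the displacement falls below
#' `tol` voxels or `max_iters` is reached. The maximum searching distance
#' also constrains the solution space: the total displacement of a node is
#' capped at `search_radius`, so a node deviating farther than the search
#' radius from the signal cannot be recovered — the classical limitation of
#' Mean-Shift that motivates re-tracing. Nodes whose window carries no
#' intensity stay unmoved.
#'
#' @param tree a [neuron_tree()].
#' @param image an [image_block()].
#' @param search_radius window radius in voxels (> 0).
#' @param max_iters iteration cap per node.
#' @param tol convergence displacement in voxels.
#' @return the refined [neuron_tree()] (topology unchanged).
#' @export
mean_shift_refine <- function(tree, image, search_radius = 5, max_iters = 30,
                              tol = 0.1) {
  stopifnot(search_radius > 0)
  dims <- block_dim(image)
  ch <- children_index(tree)
  nch <- lengths(ch)
  movable <- which(nch > 0 & tree$nodes$parent != -1L)
  img <- as.double(image$data)
  idims <- as.integer(dims)
  out <- tree
  for (i in movable) {
    p0 <- c(out$nodes$x[i], out$nodes$y[i], out$nodes$z[i]) - image$origin
    p <- p0
    for (it in seq_len(max_iters)) {
      cen <- ms_centroid(img, idims, p, search_radius)
      if (is.null(cen)) break
      # solution space is constrained by the maximum searching distance
      d0 <- vnorm(cen - p0)
      if (d0 > search_radius) cen <- p0 + (cen - p0) * search_radius / d0
      shift <- vnorm(cen - p)
      p <- cen
      if (shift < tol) break
    }
    p <- p + image$origin
    out$nodes$x[i] <- p[1]; out$nodes$y[i] <- p[2]; out$nodes$z[i] <- p[3]
  }
  out
}

# intensity-weighted centroid of voxels within `r` of continuous point p
ms_centroid <- function(img, dims, p, r) {
  cen <- cpp_ms_centroid(img, dims, p[1], p[2], p[3], r)
  if (anyNA(cen)) NULL else cen
}

#' Auto-parameter Mean-Shift baseline
#'
#' A simplified automatic-parameter variant of Mean-Shift: every branch is
#' first resampled at 1-voxel steps (so the output has at least as many
#' nodes as the input), then each node is shifted with a per-node search
#' radius of twice its image-estimated radius (minimum 2 voxels).
#'
#' @param tree a [neuron_tree()].
#' @param image an [image_block()].
#' @param max_iters iteration cap per node.
#' @return the refined [neuron_tree()].
#' @export
auto_mean_shift_refine <- function(tree, image, max_iters = 30) {
  branches <- decompose_branches(tree)
  if (!length(branches)) return(tree)
  polys <- lapply(branches, function(b) {
    P <- dedupe_points(b$positions)
    if (nrow(P) < 2) return(b$positions)
    resample_polyline(P, 1, tree$voxel_size)
  })
  dense <- stitch(polys, tree)
  est <- radius_estimate(dense, image)
  radii <- pmax(2, 2 * est$nodes$radius)
  dims <- block_dim(image)
  ch <- children_index(dense)
  nch <- lengths(ch)
  movable <- which(nch > 0 & dense$nodes$parent != -1L)
  img <- as.double(image$data)
  idims <- as.integer(dims)
  out <- dense
  for (i in movable) {
    p <- c(out$nodes$x[i], out$nodes$y[i], out$nodes$z[i]) - image$origin
    for (it in seq_len(max_iters)) {
      cen <- ms_centroid(img, idims, p, radii[i])
      if (is.null(cen)) break
      shift <- vnorm(cen - p)
      p <- cen
      if (shift < 0.1) break
    }
    p <- p + image$origin
    out$nodes$x[i] <- p[1]; out$nodes$y[i] <- p[2]; out$nodes$z[i] <- p[3]
  }
  out
}

#' Benchmark refinement methods on a synthetic dataset
#'
#' Runs each method on every sample and computes the metric suite against
#' the ground truth, always including the unrefined input (`"input"`) as the
#' baseline row. Per-method aggregate means and post/pre deviation ratios
#' (in percent, ratio of the global means) are returned alongside the
#' per-sample records; per-sample ratios are included in the records.
#'
#' @param dataset list of `synthetic_sample` objects
#'   (see [generate_dataset()]).
#' @param methods character subset of `"nrrs"`, `"ms"`, `"ams"`,
#'   `"identity"`.
#' @param config a [refine_config()] for the `"nrrs"` method.
#' @param ms_search_radius Mean-Shift search radius, voxels.
#' @param resample_step metric resampling interval, micrometre.
#' @param out_dir if non-NULL, writes `metrics.csv` and `summary.json`.
#' @param keep_going if TRUE (default), a method failure on a sample is
#'   recorded and excluded from aggregates instead of aborting.
#' @return list of class `nrrs_benchmark` with `records` (data.frame) and
#'   `summary` (per-method list).
#' @export
run_benchmark <- function(dataset, methods = c("nrrs", "ms", "ams"),
                          config = refine_config(), ms_search_radius = 5,
                          resample_step = 2, out_dir = NULL,
                          keep_going = TRUE) {
  known <- c("nrrs", "ms", "ams", "identity")
  bad <- setdiff(methods, known)
  if (length(bad)) {
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; known methods: ", paste(known, collapse = ", "))
  }
  rows <- list()
  for (si in seq_along(dataset)) {
    smp <- dataset[[si]]
    gt <- smp$ground_truth
    rows[[length(rows) + 1]] <-
      metrics_row(si, smp$case_label, "input", smp$perturbed, gt, smp$image,
                  resample_step)
    for (m in methods) {
      refined <- tryCatch(switch(
        m,
        nrrs = refine_neuron(smp$perturbed, smp$image, config)$tree,
        ms = mean_shift_refine(smp$perturbed, smp$image,
                               search_radius = ms_search_radius),
        ams = auto_mean_shift_refine(smp$perturbed, smp$image),
        identity = smp$perturbed
      ), error = function(e) e)
      if (inherits(refined, "error")) {
        if (!keep_going) stop("method ", m, " failed on sample ", si, ": ",
                              conditionMessage(refined))
        rows[[length(rows) + 1]] <- failed_row(si, smp$case_label, m,
                                               conditionMessage(refined))
      } else {
        rows[[length(rows) + 1]] <-
          metrics_row(si, smp$case_label, m, refined, gt, smp$image,
                      resample_step)
      }
    }
  }
  records <- do.call(rbind, rows)
  summary <- benchmark_summary(records)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(records, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(records = records, summary = summary),
            class = "nrrs_benchmark")
}

metrics_row <- function(si, case, method, test, gt, image, resample_step) {
  sk <- skeleton_deviation(test, gt, resample_step)
  bf <- bifurcation_deviation(test, gt)
  est <- radius_estimate(test, image)
  gt_r <- gt$nodes$radius[1]
  rmae <- mean(abs(est$nodes$radius - gt_r))
  inten <- intensity_extraction(test, image)
  rate <- information_extraction_rate(test, gt, resample_step)
  sz <- storage_size(test)
  # fraction of resampled test points farther than the local ground-truth
  # tube radius from the ground-truth centerline
  P <- resampled_tree_points(test, resample_step)
  d <- dist_to_polylines(P, tree_polylines(gt), gt$voxel_size)
  Pg <- resampled_tree_points(gt, resample_step, with_radii = TRUE)
  local_r <- attr(Pg, "radii")[apply_nearest(P, Pg)]
  pct_out <- 100 * mean(d > local_r)
  data.frame(sample = si, case = case, method = method,
             skeleton_deviation = sk, bifurcation_deviation = bf,
             radius_mae = rmae, intensity_mean = inten,
             info_extraction_rate = rate,
             pct_outside_radius = pct_out,
             node_count = sz$node_count, file_bytes = sz$file_bytes,
             failed = NA_character_)
}

failed_row <- function(si, case, method, msg) {
  data.frame(sample = si, case = case, method = method,
             skeleton_deviation = NA_real_, bifurcation_deviation = NA_real_,
             radius_mae = NA_real_, intensity_mean = NA_real_,
             info_extraction_rate = NA_real_, pct_outside_radius = NA_real_,
             node_count = NA_integer_, file_bytes = NA_integer_,
             failed = msg)
}

# index of the nearest row of Q for each row of P
apply_nearest <- function(P, Q) {
  vapply(seq_len(nrow(P)), function(i) {
    which.min(colSums((t(Q) - P[i, ])^2))
  }, integer(1))
}

benchmark_summary <- function(records) {
  ok <- records[is.na(records$failed), ]
  base <- ok[ok$method == "input", ]
  out <- list()
  for (m in unique(ok$method)) {
    rows <- ok[ok$method == m, ]
    common <- intersect(rows$sample, base$sample)
    r <- rows[match(common, rows$sample), ]
    b <- base[match(common, base$sample), ]
    ratio <- function(x, y) {
      keep <- is.finite(x) & is.finite(y)
      if (!any(keep) || mean(y[keep]) == 0) return(NA_real_)
      100 * mean(x[keep]) / mean(y[keep])
    }
    out[[m]] <- list(
      n = nrow(r),
      mean_skeleton_deviation = mean(r$skeleton_deviation, na.rm = TRUE),
      mean_bifurcation_deviation = mean(r$bifurcation_deviation, na.rm = TRUE),
      skeleton_ratio_pct = ratio(r$skeleton_deviation, b$skeleton_deviation),
      bifurcation_ratio_pct = ratio(r$bifurcation_deviation,
                                    b$bifurcation_deviation),
      mean_radius_mae = mean(r$radius_mae, na.rm = TRUE),
      mean_intensity = mean(r$intensity_mean, na.rm = TRUE),
      info_loss_pct = 100 * (1 - mean(r$info_extraction_rate, na.rm = TRUE)),
      mean_pct_outside_radius = mean(r$pct_outside_radius, na.rm = TRUE),
      mean_node_count = mean(r$node_count, na.rm = TRUE),
      mean_file_bytes = mean(r$file_bytes, na.rm = TRUE),
      n_failed = sum(records$method == m & !is.na(records$failed))
    )
  }
  out
}

#' @export
print.nrrs_benchmark <- function(x, ...) {
  cat("Synthetic refinement benchmark\n")
  for (m in names(x$summary)) {
    s <- x$summary[[m]]
    cat(sprintf(
      "  %-8s skel dev %.3f (ratio %s%%)  bif dev %s (ratio %s%%)  info loss %.1f%%\n",
      m, s$mean_skeleton_deviation, fmt_pct(s$skeleton_ratio_pct),
      fmt_num(s$mean_bifurcation_deviation), fmt_pct(s$bifurcation_ratio_pct),
      s$info_loss_pct))
  }
  invisible(x)
}

fmt_pct <- function(x) if (is.na(x)) "NA" else sprintf("%.1f", x)
fmt_num <- function(x) if (is.na(x)) "NA" else sprintf("%.3f", x)
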