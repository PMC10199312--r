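#' Tube appearance model for synthetic neurite images
#'
#' Parameters of the image-formation model: noise-free intensity at voxel
#' `v` is `background + (peak - background) * exp(-d(v)^2 / (2 sigma^2))`
#' where `d(v)` is the distance from the voxel centre to the skeleton.
#' Gaussian noise is added, values are clipped at zero and quantised to
#' 8-bit. By default `profile_sigma = radius / sqrt(2 log 2)`, so the
#' half-amplitude isosurface of the tube sits at the skeleton radius.
#'
#' @param radius tube (skeleton) radius in voxels.
#' @param peak_intensity noise-free centerline intensity (8-bit scale).
#' @param profile_sigma Gaussian profile sigma in voxels.
#' @param background_level constant background intensity.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @return list of class `tube_model`.
#' @export
tube_model <- function(radius = 2, peak_intensity = 96,
                       profile_sigma = radius / sqrt(2 * log(2)),
                       background_level = 12, noise_sigma = 6) {
  stopifnot(radius > 0, peak_intensity > background_level,
            background_level >= 0, profile_sigma > 0, noise_sigma >= 0)
  structure(list(radius = radius, peak_intensity = peak_intensity,
                 profile_sigma = profile_sigma,
                 background_level = background_level,
                 noise_sigma = noise_sigma),
            class = "tube_model")
}

# cubic Bezier curve sampled at n parameter values
bezier_points <- function(P0, P1, P2, P3, n = 600) {
  t <- seq(0, 1, length.out = n)
  b0 <- (1 - t)^3; b1 <- 3 * (1 - t)^2 * t; b2 <- 3 * (1 - t) * t^2; b3 <- t^3
  outer(b0, P0) + outer(b1, P1) + outer(b2, P2) + outer(b3, P3)
}

# max cumulative turning (radians) over sliding windows of `w` vertices
max_window_turning <- function(points, w = 10) {
  ang <- turning_angles(points)
  if (!length(ang)) return(0)
  if (length(ang) <= w) return(sum(ang))
  cs <- c(0, cumsum(ang))
  max(cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)])
}

#' Generate a synthetic neuron skeleton
#'
#' Draws a smooth cubic Bezier polyline running from one block face region
#' to a face on a different axis (which guarantees a pronounced bend),
#' sampled at 1-voxel arc steps, optionally with a second Bezier branch
#' attached at a random interior point at a 40-80 degree angle. All points
#' keep a safety margin of `max(2 * radius + 1, 10)` voxels from the block
#' border so that perturbed skeletons remain inside the block.
#'
#' @param block_shape integer(3), at least 32 voxels per axis.
#' @param with_bifurcation if TRUE, attach one branch (1 bifurcation,
#'   3 branches).
#' @param seed RNG seed (same seed, same tree).
#' @param radius node radius written into the tree, voxels.
#' @return a [neuron_tree()] with 1-voxel node spacing, voxel size 1 um.
#' @export
generate_skeleton <- function(block_shape = c(128, 128, 64),
                              with_bifurcation = FALSE, seed = NULL,
                              radius = 2) {
  block_shape <- as.integer(block_shape)
  if (length(block_shape) != 3 || any(block_shape < 32))
    stop("`block_shape` must be >= 32 voxels per axis")
  with_seed(seed, {
    m <- max(2 * radius + 1, 10)
    lo <- rep(m, 3)
    hi <- block_shape - 1 - m
    main <- NULL
    for (try in 1:60) {
      ax <- sample(1:2, 2)  # two different face axes among x, y
      P0 <- lo + runif(3) * (hi - lo)
      P3 <- lo + runif(3) * (hi - lo)
      side0 <- sample(c(0, 1), 1); side3 <- sample(c(0, 1), 1)
      P0[ax[1]] <- if (side0 == 0) lo[ax[1]] else hi[ax[1]]
      P3[ax[2]] <- if (side3 == 0) lo[ax[2]] else hi[ax[2]]
      t0 <- c(0, 0, 0); t0[ax[1]] <- if (side0 == 0) 1 else -1
      t3 <- c(0, 0, 0); t3[ax[2]] <- if (side3 == 0) 1 else -1
      L <- vnorm(P3 - P0)
      if (L < 45) next
      jitter <- function() {
        v <- stats::rnorm(3, sd = 0.12 * L)
        v
      }
      P1 <- pmin(pmax(P0 + t0 * runif(1, 0.35, 0.7) * L + jitter(), lo), hi)
      P2 <- pmin(pmax(P3 + t3 * runif(1, 0.35, 0.7) * L + jitter(), lo), hi)
      pts <- bezier_points(P0, P1, P2, P3)
      pts <- resample_polyline(pts, step = 1)
      if (any(sweep(pts, 2, lo, `<`)) || any(sweep(pts, 2, hi, `>`))) next
      if (max_window_turning(pts, w = 10) < 30 * pi / 180) next
      if (arc_length(pts) < 45) next
      main <- pts
      break
    }
    if (is.null(main)) stop("could not generate a skeleton in this block")

    branch <- NULL
    attach_idx <- NA_integer_
    if (with_bifurcation) {
      n <- nrow(main)
      for (try in 1:80) {
        attach_idx <- sample(seq(ceiling(0.35 * n), floor(0.65 * n)), 1)
        Q0 <- main[attach_idx, ]
        tangent <- main[min(attach_idx + 1, n), ] - main[max(attach_idx - 1, 1), ]
        tangent <- tangent / vnorm(tangent)
        w <- random_unit_vector()
        w <- w - sum(w * tangent) * tangent
        if (vnorm(w) < 1e-6) next
        w <- w / vnorm(w)
        theta <- runif(1, 40, 80) * pi / 180
        d <- cos(theta) * tangent + sin(theta) * w
        Lc <- runif(1, 25, 40)
        Q3 <- Q0 + d * Lc
        if (any(Q3 < lo) || any(Q3 > hi)) next
        perp <- random_unit_vector() * runif(1, 0, 3)
        Q1 <- Q0 + d * Lc / 3
        Q2 <- pmin(pmax(Q0 + d * 2 * Lc / 3 + perp, lo), hi)
        pts <- bezier_points(Q0, Q1, Q2, Q3, n = 300)
        pts <- resample_polyline(pts, step = 1)
        if (any(sweep(pts, 2, lo, `<`)) || any(sweep(pts, 2, hi, `>`))) next
        branch <- pts[-1, , drop = FALSE]  # first point is the attach node
        break
      }
      if (is.null(branch)) stop("could not attach a branch in this block")
    }

    n_main <- nrow(main)
    nodes <- data.frame(
      id = seq_len(n_main),
      type = c(1L, rep(3L, n_main - 1)),
      x = main[, 1], y = main[, 2], z = main[, 3],
      radius = radius,
      parent = c(-1L, seq_len(n_main - 1))
    )
    if (!is.null(branch)) {
      nb <- nrow(branch)
      nodes <- rbind(nodes, data.frame(
        id = n_main + seq_len(nb),
        type = 3L,
        x = branch[, 1], y = branch[, 2], z = branch[, 3],
        radius = radius,
        parent = c(attach_idx, n_main + seq_len(nb - 1))
      ))
    }
    neuron_tree(nodes, voxel_size = c(1, 1, 1))
  })
}

#' Render a synthetic neurite image from a skeleton
#'
#' Applies the tube appearance model of [tube_model()]: each voxel takes the
#' noise-free intensity determined by its exact distance to the skeleton
#' polyline (point-to-segment, so centerline voxels attain the block
#' maximum), plus Gaussian noise, clipped at zero and quantised to 8-bit.
#'
#' @param tree a [neuron_tree()] lying inside the block.
#' @param block_shape integer(3) block dimensions in voxels.
#' @param tube a [tube_model()].
#' @param seed RNG seed for the noise (same seed, bit-identical image).
#' @return an [image_block()] of integers in 0..255.
#' @export
render_image <- function(tree, block_shape = c(128, 128, 64),
                         tube = tube_model(), seed = NULL) {
  block_shape <- as.integer(block_shape)
  pos <- node_positions(tree)
  if (any(pos < 0) || any(sweep(pos, 2, block_shape - 1, `>`)))
    stop("tree must lie inside the block")
  sigma <- tube$profile_sigma
  amp <- tube$peak_intensity - tube$background_level
  cut <- ceiling(sigma * sqrt(2 * log(max(4 * amp, 2))))
  nx <- block_shape[1]; ny <- block_shape[2]; nz <- block_shape[3]
  d2 <- rep(Inf, nx * ny * nz)

  pidx <- match(tree$nodes$parent, tree$nodes$id)
  for (i in which(!is.na(pidx))) {
    p <- pos[pidx[i], ]
    q <- pos[i, ]
    lo <- pmax(floor(pmin(p, q)) - cut, 0)
    hi <- pmin(ceiling(pmax(p, q)) + cut, block_shape - 1)
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    nxb <- length(xs); nyb <- length(ys); nzb <- length(zs)
    gx <- rep(xs, times = nyb * nzb)
    gy <- rep(rep(ys, each = nxb), times = nzb)
    gz <- rep(zs, each = nxb * nyb)
    ab <- q - p
    ab2 <- sum(ab^2)
    apx <- gx - p[1]; apy <- gy - p[2]; apz <- gz - p[3]
    t <- if (ab2 > 0) {
      pmin(1, pmax(0, (apx * ab[1] + apy * ab[2] + apz * ab[3]) / ab2))
    } else 0
    dx <- apx - t * ab[1]; dy <- apy - t * ab[2]; dz <- apz - t * ab[3]
    dist2 <- dx * dx + dy * dy + dz * dz
    idx <- 1 + gx + nx * (gy + ny * gz)
    d2[idx] <- pmin(d2[idx], dist2)
  }

  img <- tube$background_level + amp * exp(-d2 / (2 * sigma^2))
  if (tube$noise_sigma > 0) {
    noise <- with_seed(seed, stats::rnorm(length(img), 0, tube$noise_sigma))
    img <- img + noise
  }
  img <- round(pmin(pmax(img, 0), 255))
  arr <- array(as.integer(img), dim = block_shape)
  image_block(arr, origin = c(0, 0, 0), voxel_size = tree$voxel_size)
}

#' Perturb a skeleton with one of the canonical deviation cases
#'
#' * `case1_bend`: the most-bent interior window (about 20 voxels of arc) of
#'   a branch is replaced by the straight chord between its ends, resampled,
#'   emulating a reconstruction that misses a bend of the signal.
#' * `case2_bifurcation`: the bifurcation node is translated by `magnitude`
#'   voxels in a random direction, with the displacement blended linearly
#'   into the nearest 10 nodes of each incident branch.
#' * `case3_shift`: all interior nodes are translated by one random
#'   direction vector of length `magnitude` (drawn uniformly from 3-8
#'   voxels when `magnitude` is NULL), tapering to zero over the 5 nodes
#'   nearest the root and each tip, which stay fixed.
#'
#' Topology, the root and all tips are preserved exactly in every case.
#'
#' @param tree a [neuron_tree()].
#' @param case_label one of `"case1_bend"`, `"case2_bifurcation"`,
#'   `"case3_shift"`.
#' @param seed RNG seed.
#' @param magnitude displacement in voxels (defaults: case 2 -> 6,
#'   case 3 -> uniform in 3..8; unused by case 1).
#' @param window case-1 window arc length in voxels.
#' @return the perturbed [neuron_tree()].
#' @export
perturb <- function(tree, case_label, seed = NULL, magnitude = NULL,
                    window = 20) {
  validate_neuron_tree(tree)
  case_label <- as.character(case_label)
  if (!case_label %in% c("case1_bend", "case2_bifurcation", "case3_shift"))
    stop("unknown case label: ", case_label)
  with_seed(seed, {
    switch(case_label,
           case1_bend = perturb_case1(tree, window),
           case2_bifurcation = perturb_case2(tree, magnitude %||% 6),
           case3_shift = perturb_case3(tree, magnitude))
  })
}

perturb_case1 <- function(tree, window = 20) {
  branches <- decompose_branches(tree)
  best <- NULL
  best_score <- -Inf
  for (b in branches) {
    P <- b$positions
    n <- nrow(P)
    w <- window
    if (n < w + 5) next
    ang <- c(0, turning_angles(P), 0)  # per-vertex turning
    cs <- cumsum(ang)
    # window [i, i+w] over interior vertices (2 .. n-1)
    for (i in 2:(n - w - 1)) {
      score <- cs[i + w] - cs[i]
      if (score > best_score) {
        best_score <- score
        best <- list(branch = b, i = i, j = i + w)
      }
    }
  }
  if (is.null(best)) stop("tree too short for a case-1 bend window")
  b <- best$branch
  i <- best$i; j <- best$j
  e1 <- b$positions[i, ]; e2 <- b$positions[j, ]
  inner <- (i + 1):(j - 1)
  # place interior window nodes evenly along the chord
  tfrac <- seq_along(inner) / (length(inner) + 1)
  newpos <- outer(rep(1, length(inner)), e1) + outer(tfrac, e2 - e1)
  out <- tree
  rows <- b$node_idx[inner]
  out$nodes$x[rows] <- newpos[, 1]
  out$nodes$y[rows] <- newpos[, 2]
  out$nodes$z[rows] <- newpos[, 3]
  attr(out, "perturbed_node_idx") <- rows
  out
}

perturb_case2 <- function(tree, magnitude) {
  bifs <- bifurcation_ids(tree)
  if (!length(bifs)) stop("case 2 requires a bifurcation")
  bif_id <- bifs[1]
  bif_row <- match(bif_id, tree$nodes$id)
  dir <- random_unit_vector()
  ch <- children_index(tree)
  nch <- lengths(ch)
  pidx <- match(tree$nodes$parent, tree$nodes$id)
  disp <- matrix(0, nrow(tree$nodes), 3)
  disp[bif_row, ] <- magnitude * dir

  blend <- function(rows_chain) {
    # rows_chain: rows walking away from the bifurcation, nearest first
    depth <- length(rows_chain)
    if (!depth) return()
    denom <- min(10, depth + 1)
    for (jj in seq_along(rows_chain)) {
      f <- max(0, 1 - jj / denom)
      if (f <= 0) break
      disp[rows_chain[jj], ] <<- disp[rows_chain[jj], ] + f * magnitude * dir
    }
  }
  # upstream chain (towards root, stop before root/bifurcation)
  up <- integer(0)
  cur <- pidx[bif_row]
  while (!is.na(cur) && length(up) < 10 &&
         tree$nodes$parent[cur] != -1L && nch[cur] == 1) {
    up <- c(up, cur)
    cur <- pidx[cur]
  }
  blend(up)
  # downstream chains (stop before tips/bifurcations)
  for (c0 in ch[[bif_row]]) {
    down <- integer(0)
    cur <- c0
    while (length(down) < 10 && nch[cur] == 1) {
      down <- c(down, cur)
      cur <- ch[[cur]][1]
    }
    blend(down)
  }
  out <- tree
  out$nodes$x <- out$nodes$x + disp[, 1]
  out$nodes$y <- out$nodes$y + disp[, 2]
  out$nodes$z <- out$nodes$z + disp[, 3]
  attr(out, "perturbed_node_idx") <- which(rowSums(abs(disp)) > 0)
  out
}

perturb_case3 <- function(tree, magnitude = NULL, taper_nodes = 5) {
  len <- magnitude %||% runif(1, 3, 8)
  dir <- random_unit_vector()
  # node-steps to the nearest fixed endpoint (root or tip), over the
  # undirected tree
  ch <- children_index(tree)
  nch <- lengths(ch)
  pidx <- match(tree$nodes$parent, tree$nodes$id)
  n <- nrow(tree$nodes)
  fixed <- which(nch == 0 | tree$nodes$parent == -1L)
  dist <- rep(Inf, n)
  dist[fixed] <- 0
  queue <- fixed
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nbrs <- c(ch[[i]], pidx[i])
    nbrs <- nbrs[!is.na(nbrs)]
    for (j in nbrs) {
      if (dist[j] > dist[i] + 1) {
        dist[j] <- dist[i] + 1
        queue <- c(queue, j)
      }
    }
  }
  f <- pmin(1, dist / taper_nodes)
  out <- tree
  out$nodes$x <- out$nodes$x + f * len * dir[1]
  out$nodes$y <- out$nodes$y + f * len * dir[2]
  out$nodes$z <- out$nodes$z + f * len * dir[3]
  attr(out, "perturbed_node_idx") <- which(f > 0)
  attr(out, "shift") <- len * dir
  out
}

#' Generate one synthetic benchmark sample
#'
#' A sample pairs a ground-truth skeleton, a perturbed (test) skeleton with
#' identical topology, and the rendered image of the ground truth.
#'
#' @param case_label deviation case, see [perturb()].
#' @param seed sample seed (sub-seeds for skeleton, rendering and
#'   perturbation are derived from it).
#' @param block_shape integer(3) block dimensions.
#' @param tube a [tube_model()].
#' @param with_bifurcation include a bifurcation (default TRUE).
#' @param magnitude perturbation magnitude forwarded to [perturb()].
#' @return list of class `synthetic_sample` with elements `ground_truth`,
#'   `perturbed`, `image`, `case_label`, `gen_params`.
#' @export
generate_sample <- function(case_label, seed, block_shape = c(128, 128, 64),
                            tube = tube_model(), with_bifurcation = TRUE,
                            magnitude = NULL) {
  gt <- generate_skeleton(block_shape, with_bifurcation = with_bifurcation,
                          seed = seed, radius = tube$radius)
  img <- render_image(gt, block_shape, tube, seed = seed + 1L)
  test <- perturb(gt, case_label, seed = seed + 2L, magnitude = magnitude)
  structure(list(
    ground_truth = gt,
    perturbed = test,
    image = img,
    case_label = case_label,
    gen_params = list(seed = seed, block_shape = block_shape,
                      tube = unclass(tube),
                      with_bifurcation = with_bifurcation,
                      magnitude = magnitude)
  ), class = "synthetic_sample")
}

#' Generate a synthetic benchmark dataset
#'
#' @param n number of samples (>= 1).
#' @param seed master seed; per-sample seeds are derived from it, so the
#'   dataset is a pure function of its arguments.
#' @param case_mix named proportions over the three cases (must sum to 1).
#' @param out_dir if non-NULL, each sample is serialised to
#'   `out_dir/sample_###/` as `gt.swc`, `test.swc`, `image.tif`,
#'   `params.json`.
#' @param block_shape,tube,with_bifurcation,magnitude forwarded to
#'   [generate_sample()].
#' @return list of `synthetic_sample` objects.
#' @export
generate_dataset <- function(n, seed, case_mix = c(case1_bend = 1 / 3,
                                                   case2_bifurcation = 1 / 3,
                                                   case3_shift = 1 / 3),
                             out_dir = NULL, block_shape = c(128, 128, 64),
                             tube = tube_model(), with_bifurcation = TRUE,
                             magnitude = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  n <- as.integer(n)
  if (abs(sum(case_mix) - 1) > 1e-8) stop("`case_mix` must sum to 1")
  labels <- names(case_mix)
  if (is.null(labels)) labels <- c("case1_bend", "case2_bifurcation",
                                   "case3_shift")[seq_along(case_mix)]
  counts <- floor(n * case_mix)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * case_mix - counts
    extra <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  case_labels <- rep(labels, counts)
  sample_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 3L, n))
  samples <- lapply(seq_len(n), function(i) {
    generate_sample(case_labels[i], seed = sample_seeds[i],
                    block_shape = block_shape, tube = tube,
                    with_bifurcation = with_bifurcation,
                    magnitude = magnitude)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_sample(samples[[i]], file.path(out_dir, sprintf("sample_%03d", i)))
    }
  }
  samples
}

#' @rdname generate_dataset
#' @param sample a `synthetic_sample`.
#' @param dir output directory for one sample.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_swc(sample$ground_truth, file.path(dir, "gt.swc"))
  write_swc(sample$perturbed, file.path(dir, "test.swc"))
  write_image_volume(sample$image, file.path(dir, "image.tif"))
  params <- c(list(case_label = sample$case_label), sample$gen_params)
  jsonlite::write_json(params, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read one serialised sample directory
#'
#' @param dir directory written by [write_sample()].
#' @return a `synthetic_sample`.
#' @export
read_sample <- function(dir) {
  params <- jsonlite::read_json(file.path(dir, "params.json"),
                                simplifyVector = TRUE)
  structure(list(
    ground_truth = read_swc(file.path(dir, "gt.swc")),
    perturbed = read_swc(file.path(dir, "test.swc")),
    image = read_image_volume(file.path(dir, "image.tif")),
    case_label = params$case_label,
    gen_params = params[setdiff(names(params), "case_label")]
  ), class = "synthetic_sample")
}
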