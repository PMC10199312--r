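#' Refinement configuration
#'
#' Bundles the parameters of the two-pass refinement. The first re-tracing
#' step weights the image term heavily (`alpha = 1`, `beta = gamma = 0.2`)
#' because its task is to find the correct signal; the second step starts
#' from endpoints already on the signal, so smoothness and length matter
#' more (`alpha = beta = gamma = 0.5`).
#'
#' @param max_segment_len first-partition segment length bound, micrometre.
#' @param step1_params [energy_params()] for the first re-tracing step.
#' @param step2_params [energy_params()] for the second re-tracing step.
#' @param crop_margin dilation (voxels) of the per-segment image crop.
#' @param resample_step_out optional output resampling step (micrometre)
#'   applied to refined branches before stitching; NULL keeps traced nodes.
#' @param max_block_voxels memory guard for the graph step.
#' @param relocation_tol common-prefix tolerance (voxels) of the
#'   bifurcation relocation rule.
#' @return list of class `refine_config`.
#' @export
refine_config <- function(max_segment_len = 50,
                          step1_params = energy_params(alpha = 1, beta = 0.2,
                                                       gamma = 0.2),
                          step2_params = energy_params(alpha = 0.5, beta = 0.5,
                                                       gamma = 0.5),
                          crop_margin = 16,
                          resample_step_out = NULL,
                          max_block_voxels = 512 * 512 * 256,
                          relocation_tol = 1.0) {
  stopifnot(max_segment_len > 0, crop_margin >= 0,
            inherits(step1_params, "energy_params"),
            inherits(step2_params, "energy_params"),
            max_block_voxels > 0, relocation_tol > 0)
  structure(list(max_segment_len = max_segment_len,
                 step1_params = step1_params, step2_params = step2_params,
                 crop_margin = crop_margin,
                 resample_step_out = resample_step_out,
                 max_block_voxels = max_block_voxels,
                 relocation_tol = relocation_tol),
            class = "refine_config")
}

# trace between two global points inside a cropped sub-block; returns the
# curve in global coordinates, or a fallback polyline when the block is
# dark or the tracer fails
trace_in_volume <- function(volume, p0, p1, span, params, margin,
                            max_voxels, fallback) {
  res <- tryCatch({
    block <- crop_block(volume, rbind(span, p0, p1), margin)
    if (max(block$data) <= 0) stop("all-zero image block")
    curve <- trace(block, p0 - block$origin, p1 - block$origin, params,
                   max_voxels = max_voxels)
    list(curve = sweep(curve, 2, block$origin, `+`),
         fallback = NA_character_,
         energy_pre = attr(curve, "energy_pre") %||% NA_real_,
         energy_post = attr(curve, "energy_post") %||% NA_real_)
  }, error = function(e) {
    list(curve = dedupe_points(fallback), fallback = conditionMessage(e),
         energy_pre = NA_real_, energy_post = NA_real_)
  })
  res
}

#' First re-tracing step
#'
#' Traces one curve per first-partition segment with the graph-augmented
#' deformable tracer; curve endpoints equal the segment anchors. Segments
#' whose image crop carries no signal (or whose trace fails) fall back to
#' the original polyline and are flagged in the report.
#'
#' @param segments list from [first_partition()].
#' @param volume the full [image_block()] volume.
#' @param config a [refine_config()].
#' @return list with `curves` (global coordinates, one per segment) and
#'   `report` (one data.frame row per segment).
#' @export
retrace_step1 <- function(segments, volume, config = refine_config()) {
  curves <- vector("list", length(segments))
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    res <- trace_in_volume(volume, seg$positions[1, ],
                           seg$positions[nrow(seg$positions), ],
                           span = seg$positions,
                           params = config$step1_params,
                           margin = config$crop_margin,
                           max_voxels = config$max_block_voxels,
                           fallback = seg$positions)
    curves[[i]] <- res$curve
    rows[[i]] <- data.frame(stage = "step1", branch = seg$branch_id,
                            piece = seg$piece_index, pair_type = NA_character_,
                            fallback = res$fallback,
                            energy_pre = res$energy_pre,
                            energy_post = res$energy_post,
                            n_in = nrow(seg$positions),
                            n_out = nrow(res$curve))
  }
  list(curves = curves, report = do.call(rbind, rows))
}

#' Second re-tracing step
#'
#' Traces one curve per adjacent-midpoint pair from [second_partition()]
#' using the second-step coefficients. The crop spans the two step-1 curve
#' halves between the midpoints, so junction-crossing pairs see the full
#' bifurcation neighbourhood.
#'
#' @param pairs list from [second_partition()]; each pair may carry a
#'   `span` matrix (defaults to the straight chord between its midpoints).
#' @param volume the full [image_block()] volume.
#' @param config a [refine_config()].
#' @return list with `curves` and `report` as in [retrace_step1()].
#' @export
retrace_step2 <- function(pairs, volume, config = refine_config()) {
  curves <- vector("list", length(pairs))
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    span <- pr$span %||% rbind(pr$p0, pr$p1)
    res <- trace_in_volume(volume, pr$p0, pr$p1, span = span,
                           params = config$step2_params,
                           margin = config$crop_margin,
                           max_voxels = config$max_block_voxels,
                           fallback = span)
    curves[[i]] <- res$curve
    rows[[i]] <- data.frame(stage = "step2", branch = pr$branch,
                            piece = NA_integer_, pair_type = pr$type,
                            fallback = res$fallback,
                            energy_pre = res$energy_pre,
                            energy_post = res$energy_post,
                            n_in = nrow(span), n_out = nrow(res$curve))
  }
  list(curves = curves, report = do.call(rbind, rows))
}

#' Relocate a bifurcation from two junction-crossing curves
#'
#' The two second-pass curves both start at the parent branch's midpoint and
#' run through the junction to the midpoints of the two child branches.
#' After arc-length alignment (resampling both curves at `step` voxels),
#' the new bifurcation is the point where the curves diverge: the last
#' sample of their maximal common prefix under a pointwise tolerance of
#' `tol` voxels. The curves are split there into the parent tail (averaged
#' common prefix) and one head polyline per child.
#'
#' @param curve_a,curve_b junction-crossing curves sharing their first point.
#' @param tol pointwise divergence tolerance in voxels.
#' @param step arc-length alignment step in voxels.
#' @return NULL when the curves share no common prefix (caller falls back);
#'   otherwise a list with `junction`, `parent_tail`, `children`
#'   (list of two head polylines starting at the junction) and `prefix_len`.
#' @export
relocate_bifurcation <- function(curve_a, curve_b, tol = 1.0, step = 0.25) {
  A <- resample_polyline(dedupe_points(curve_a), step)
  B <- resample_polyline(dedupe_points(curve_b), step)
  if (vnorm(A[1, ] - B[1, ]) > tol) return(NULL)
  n <- min(nrow(A), nrow(B))
  d <- sqrt(rowSums((A[seq_len(n), , drop = FALSE] -
                       B[seq_len(n), , drop = FALSE])^2))
  within <- which(d > tol)
  s <- if (length(within)) within[1] - 1L else n
  if (s < 2) return(NULL)
  J <- (A[s, ] + B[s, ]) / 2
  prefix <- (A[seq_len(s), , drop = FALSE] + B[seq_len(s), , drop = FALSE]) / 2
  prefix[s, ] <- J
  child_a <- dedupe_points(rbind(J, A[min(s + 1, nrow(A)):nrow(A), ,
                                      drop = FALSE]))
  child_b <- dedupe_points(rbind(J, B[min(s + 1, nrow(B)):nrow(B), ,
                                      drop = FALSE]))
  list(junction = J, parent_tail = dedupe_points(prefix),
       children = list(child_a, child_b), prefix_len = s)
}

#' Stitch refined branch polylines into a neuron tree
#'
#' Rebuilds a valid tree from per-branch refined polylines (ordered as the
#' branches of [decompose_branches()]): node ids are renumbered
#' consecutively, duplicate junction points are merged, and radii and type
#' codes are carried over from the input branch by matching arc-length
#' fraction. The root position, every tip position and the branching
#' topology must be preserved; a topology change is a hard failure.
#'
#' @param branch_polylines list of n x 3 matrices, parallel to the branch
#'   decomposition of `tree`; each runs from the branch's start anchor (or
#'   relocated junction) to its end anchor (or relocated junction).
#' @param tree the input [neuron_tree()] (source of radii, types, ids).
#' @param resample_step_out optional resampling step (micrometre) applied to
#'   each polyline before node creation.
#' @return a refined [neuron_tree()].
#' @export
stitch <- function(branch_polylines, tree, resample_step_out = NULL) {
  branches <- decompose_branches(tree)
  if (length(branch_polylines) != length(branches))
    stop("stitch: one polyline per branch is required")
  vs <- tree$voxel_size
  root_row <- root_index(tree)
  root_node <- tree$nodes[root_row, ]

  ids <- 1L
  out <- data.frame(id = 1L, type = root_node$type,
                    x = root_node$x, y = root_node$y, z = root_node$z,
                    radius = root_node$radius, parent = -1L)
  # id of the node at which each branch's children attach
  branch_end_id <- integer(length(branches))

  for (bi in seq_along(branches)) {
    b <- branches[[bi]]
    P <- dedupe_points(as_points(branch_polylines[[bi]]))
    if (!is.null(resample_step_out) && nrow(P) >= 2) {
      P <- resample_polyline(P, resample_step_out, vs)
    }
    attach_id <- if (is.na(b$parent_branch)) 1L else
      branch_end_id[b$parent_branch]
    if (nrow(P) < 2) stop("stitch: degenerate branch polyline")
    # radii / types by arc-length fraction of the original branch
    Lo <- c(0, cumsum(seg_lengths(b$positions, vs)))
    Ln <- c(0, cumsum(seg_lengths(P, vs)))
    tfrac <- if (Ln[length(Ln)] > 0) Ln / Ln[length(Ln)] else Ln
    src <- vapply(tfrac, function(t) {
      which.min(abs(Lo - t * Lo[length(Lo)]))
    }, integer(1))
    new_idx <- 2:nrow(P)
    new_ids <- ids + seq_along(new_idx)
    parents <- c(attach_id, new_ids[-length(new_ids)])
    out <- rbind(out, data.frame(
      id = new_ids, type = b$types[src[new_idx]],
      x = P[new_idx, 1], y = P[new_idx, 2], z = P[new_idx, 3],
      radius = b$radii[src[new_idx]], parent = parents))
    ids <- max(new_ids)
    branch_end_id[bi] <- new_ids[length(new_ids)]
  }

  refined <- neuron_tree(out, voxel_size = vs, header = tree$header)

  # topology guard
  old_tips <- sort_positions(tip_positions(tree))
  new_tips <- sort_positions(tip_positions(refined))
  if (length(bifurcation_ids(refined)) != length(bifurcation_ids(tree)) ||
      nrow(old_tips) != nrow(new_tips) ||
      max(abs(old_tips - new_tips)) > 1e-9) {
    stop("stitch: topology change detected (tips or bifurcation count differ)")
  }
  refined
}

tip_positions <- function(tree) {
  rows <- match(tip_ids(tree), tree$nodes$id)
  node_positions(tree)[rows, , drop = FALSE]
}

sort_positions <- function(P) {
  P[order(P[, 1], P[, 2], P[, 3]), , drop = FALSE]
}

#' Refine a neuron reconstruction by two-pass re-tracing
#'
#' Runs the full refinement: first partition of branches into sub-50-um
#' segments, first re-tracing of each segment (anchors fixed), midpoint
#' partition of the traced curves, second re-tracing across the original
#' anchors (including bifurcations, which are relocated to the divergence
#' point of the junction-crossing curves), and stitching back into a valid
#' tree. The soma (root) and all terminal tips are assumed correct and are
#' never moved; refinement acts on internal nodes only.
#'
#' @param tree a [neuron_tree()] to refine.
#' @param volume the corresponding [image_block()] volume.
#' @param config a [refine_config()].
#' @return an object of class `nrrs_result`: list with `tree` (refined
#'   [neuron_tree()]), `report` (per-segment records and summary counts),
#'   `input` and `config`.
#' @export
refine_neuron <- function(tree, volume, config = refine_config()) {
  validate_neuron_tree(tree)
  if (!is_image_block(volume)) stop("`volume` must be an image_block")
  branches <- decompose_branches(tree)
  empty_report <- list(segments = data.frame(), summary = list(
    n_segments = 0L, n_traces = 0L, n_fallbacks = 0L))
  if (length(branches) == 0) {
    return(new_nrrs_result(tree, tree, empty_report, config))
  }
  # a lone 2-node branch between fixed endpoints has no internal nodes
  if (length(branches) == 1 && nrow(branches[[1]]$positions) <= 2 &&
      branches[[1]]$start_kind == "root" && branches[[1]]$end_kind == "tip") {
    return(new_nrrs_result(tree, tree, empty_report, config))
  }

  segments <- first_partition(tree, config$max_segment_len)
  step1 <- retrace_step1(segments, volume, config)
  branch_of_path <- vapply(segments, `[[`, integer(1), "branch_id")
  halves <- lapply(step1$curves, split_at_midpoint,
                   voxel_size = tree$voxel_size)

  branch_parent <- vapply(branches, function(b) {
    if (is.na(b$parent_branch)) NA_integer_ else as.integer(b$parent_branch)
  }, integer(1))
  pairs <- second_partition(step1$curves, branch_of_path, branch_parent,
                            voxel_size = tree$voxel_size)
  # span for cropping/fallback: the two step-1 curve halves between midpoints
  for (i in seq_along(pairs)) {
    pairs[[i]]$span <- dedupe_points(rbind(
      halves[[pairs[[i]]$path_i]]$second,
      halves[[pairs[[i]]$path_j]]$first))
  }
  step2 <- retrace_step2(pairs, volume, config)

  pair_type <- vapply(pairs, `[[`, character(1), "type")
  # within-branch step-2 curves per branch, in order
  core_of <- vector("list", length(branches))
  for (i in which(pair_type == "within")) {
    b <- pairs[[i]]$branch
    core_of[[b]] <- c(core_of[[b]], list(step2$curves[[i]]))
  }

  # junction relocation per parent branch
  junction_rows <- list()
  head_of <- vector("list", length(branches))  # per child branch
  tail_of <- vector("list", length(branches))  # per parent branch
  for (p in seq_along(branches)) {
    kids <- which(branch_parent == p)
    if (!length(kids)) next
    jidx <- vapply(kids, function(b) {
      which(pair_type == "junction" &
              vapply(pairs, function(x) identical(x$child_branch, b),
                     logical(1)))[1]
    }, integer(1))
    relocated <- NULL
    if (length(kids) == 2 &&
        all(is.na(step2$report$fallback[jidx]))) {
      relocated <- relocate_bifurcation(step2$curves[[jidx[1]]],
                                        step2$curves[[jidx[2]]],
                                        tol = config$relocation_tol)
    }
    last_p <- utils::tail(which(branch_of_path == p), 1)
    if (is.null(relocated)) {
      # fall back to the step-1 geometry around the original anchor
      tail_of[[p]] <- halves[[last_p]]$second
      for (b in kids) {
        first_b <- which(branch_of_path == b)[1]
        head_of[[b]] <- halves[[first_b]]$first
      }
      junction_rows[[length(junction_rows) + 1]] <- data.frame(
        stage = "junction", branch = p, piece = NA_integer_,
        pair_type = "relocation",
        fallback = "no common prefix or >2 children; kept step-1 anchor",
        energy_pre = NA_real_, energy_post = NA_real_,
        n_in = length(kids), n_out = NA_integer_)
    } else {
      tail_of[[p]] <- relocated$parent_tail
      head_of[[kids[1]]] <- relocated$children[[1]]
      head_of[[kids[2]]] <- relocated$children[[2]]
      junction_rows[[length(junction_rows) + 1]] <- data.frame(
        stage = "junction", branch = p, piece = NA_integer_,
        pair_type = "relocation", fallback = NA_character_,
        energy_pre = NA_real_, energy_post = NA_real_,
        n_in = length(kids), n_out = relocated$prefix_len)
    }
  }

  # assemble per-branch refined polylines
  polys <- vector("list", length(branches))
  for (b in seq_along(branches)) {
    idx <- which(branch_of_path == b)
    head_piece <- if (branches[[b]]$start_kind == "root") {
      halves[[idx[1]]]$first
    } else {
      head_of[[b]] %||% halves[[idx[1]]]$first
    }
    tail_piece <- if (branches[[b]]$end_kind == "tip") {
      halves[[idx[length(idx)]]]$second
    } else {
      tail_of[[b]] %||% halves[[idx[length(idx)]]]$second
    }
    poly <- head_piece
    for (cv in core_of[[b]]) poly <- rbind(poly, cv[-1, , drop = FALSE])
    poly <- rbind(poly, tail_piece[-1, , drop = FALSE])
    polys[[b]] <- dedupe_points(poly)
  }

  refined <- stitch(polys, tree, resample_step_out = config$resample_step_out)

  seg_report <- rbind(step1$report, step2$report,
                      if (length(junction_rows)) do.call(rbind, junction_rows))
  report <- list(
    segments = seg_report,
    summary = list(
      n_segments = length(segments),
      n_traces = nrow(step1$report) + nrow(step2$report),
      n_fallbacks = sum(!is.na(seg_report$fallback))
    ))
  new_nrrs_result(refined, tree, report, config)
}

new_nrrs_result <- function(tree, input, report, config) {
  structure(list(tree = tree, input = input, report = report,
                 config = config),
            class = "nrrs_result")
}

#' @export
print.nrrs_result <- function(x, ...) {
  s <- x$report$summary
  cat("Two-pass re-tracing refinement\n")
  cat(sprintf("  input : %d nodes\n", nrow(x$input$nodes)))
  cat(sprintf("  output: %d nodes\n", nrow(x$tree$nodes)))
  cat(sprintf("  segments: %d, traces: %d, fallbacks: %d\n",
              s$n_segments, s$n_traces, s$n_fallbacks))
  invisible(x)
}

#' @export
summary.nrrs_result <- function(object, ...) {
  seg <- object$report$segments
  cat("Two-pass re-tracing refinement\n")
  if (nrow(seg)) {
    for (st in unique(seg$stage)) {
      rows <- seg[seg$stage == st, ]
      de <- rows$energy_pre - rows$energy_post
      cat(sprintf("  %-8s %2d trace(s), %d fallback(s), median energy drop %.3g\n",
                  st, nrow(rows), sum(!is.na(rows$fallback)),
                  median(de, na.rm = TRUE)))
    }
  } else {
    cat("  nothing refinable (no internal nodes)\n")
  }
  invisible(object)
}

#' Plot a refinement result over a maximum intensity projection
#'
#' @param x an `nrrs_result`.
#' @param volume the [image_block()] used for refinement.
#' @param ... passed to [graphics::image()].
#' @export
plot.nrrs_result <- function(x, volume, ...) {
  mip <- make_mip(volume)
  graphics::image(0:(nrow(mip)), 0:(ncol(mip)), mip,
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x (voxels)", ylab = "y (voxels)", useRaster = TRUE,
                  ...)
  graphics::points(x$input$nodes$x, x$input$nodes$y, col = "red",
                   pch = 16, cex = 0.3)
  graphics::points(x$tree$nodes$x, x$tree$nodes$y, col = "cyan",
                   pch = 16, cex = 0.3)
  graphics::legend("topright", legend = c("input", "refined"),
                   col = c("red", "cyan"), pch = 16, bg = "white")
  invisible(x)
}
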