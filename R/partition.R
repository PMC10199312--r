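#' Decompose a neuron tree into branches
#'
#' A branch is a maximal path between critical nodes (root, bifurcation or
#' tip) whose interior nodes have exactly one child. The union of branches
#' covers every tree edge exactly once. Branches are returned in
#' breadth-first order from the root, each with the index of its parent
#' branch, so downstream code can reason about branch adjacency.
#'
#' @param tree a [neuron_tree()].
#' @return list of branches; each branch is a list with `positions` (n x 3),
#'   `node_idx` (row indices into `tree$nodes`), `radii`, `types`,
#'   `start_kind` ("root"/"bifurcation"), `end_kind` ("bifurcation"/"tip"),
#'   `parent_branch` (index or NA) and `start_node_id`/`end_node_id`.
#' @export
decompose_branches <- function(tree) {
  validate_neuron_tree(tree)
  nodes <- tree$nodes
  n <- nrow(nodes)
  if (n == 1) return(list())
  ch <- children_index(tree)
  nch <- lengths(ch)
  root <- root_index(tree)
  pos <- node_positions(tree)

  branches <- list()
  # queue entries: (start row index, child row index, parent branch index)
  queue <- lapply(ch[[root]], function(c0) list(start = root, child = c0,
                                                parent = NA_integer_))
  while (length(queue)) {
    item <- queue[[1]]
    queue <- queue[-1]
    path <- c(item$start, item$child)
    cur <- item$child
    while (nch[cur] == 1) {
      cur <- ch[[cur]][1]
      path <- c(path, cur)
    }
    b <- list(
      positions = pos[path, , drop = FALSE],
      node_idx = path,
      radii = nodes$radius[path],
      types = nodes$type[path],
      start_kind = if (item$start == root) "root" else "bifurcation",
      end_kind = if (nch[cur] == 0) "tip" else "bifurcation",
      parent_branch = item$parent,
      start_node_id = nodes$id[item$start],
      end_node_id = nodes$id[cur]
    )
    branches[[length(branches) + 1]] <- b
    bi <- length(branches)
    if (nch[cur] >= 2) {
      for (c0 in ch[[cur]]) {
        queue[[length(queue) + 1]] <- list(start = cur, child = c0,
                                           parent = bi)
      }
    }
  }
  branches
}

#' First partition: break branches into short segments
#'
#' Each branch longer than `max_segment_len` is split into equal-arc-length
#' pieces (`floor(L / max_segment_len) + 1` of them, so every piece is
#' strictly shorter than the limit), with each cut snapped to the existing
#' reconstruction node nearest the ideal cut position. If snapping leaves a
#' piece at or above the limit the piece count is increased; should a single
#' edge itself exceed the limit, exact interpolated cut points are inserted
#' as a last resort.
#'
#' @param tree a [neuron_tree()].
#' @param max_segment_len maximum segment arc length in micrometre
#'   (default 50).
#' @return list of segments; each has `positions`, `kind = "branch_piece"`,
#'   `branch_id`, `piece_index`, `start_anchor`, `end_anchor`.
#' @export
first_partition <- function(tree, max_segment_len = 50) {
  if (!is.numeric(max_segment_len) || length(max_segment_len) != 1 ||
      !is.finite(max_segment_len) || max_segment_len <= 0)
    stop("`max_segment_len` must be a positive number (um)")
  branches <- decompose_branches(tree)
  vs <- tree$voxel_size
  segments <- list()
  for (bi in seq_along(branches)) {
    pieces <- split_branch(branches[[bi]]$positions, max_segment_len, vs)
    for (pi in seq_along(pieces)) {
      P <- pieces[[pi]]
      segments[[length(segments) + 1]] <- list(
        positions = P,
        kind = "branch_piece",
        branch_id = bi,
        piece_index = pi,
        start_anchor = P[1, ],
        end_anchor = P[nrow(P), ]
      )
    }
  }
  segments
}

# split one branch polyline into pieces each strictly shorter than max_len
split_branch <- function(positions, max_len, voxel_size) {
  positions <- dedupe_points(as_points(positions))
  L <- c(0, cumsum(seg_lengths(positions, voxel_size)))
  total <- L[length(L)]
  if (total < max_len) return(list(positions))
  n_nodes <- nrow(positions)
  n_pieces <- floor(total / max_len) + 1
  repeat {
    ideal <- total * seq_len(n_pieces - 1) / n_pieces
    cuts <- vapply(ideal, function(s) which.min(abs(L - s)), integer(1))
    cuts <- pmin(pmax(cuts, 2L), n_nodes - 1L)
    cuts <- sort(unique(cuts))
    bounds <- c(1L, cuts, n_nodes)
    piece_len <- L[bounds[-1]] - L[bounds[-length(bounds)]]
    ok <- length(cuts) == n_pieces - 1 && all(piece_len < max_len)
    if (ok) {
      return(lapply(seq_len(length(bounds) - 1), function(i) {
        positions[bounds[i]:bounds[i + 1], , drop = FALSE]
      }))
    }
    if (n_pieces >= n_nodes - 1) break  # snapping cannot work; interpolate
    n_pieces <- n_pieces + 1
  }
  # fallback: exact interpolated cut points (very sparse input nodes)
  n_pieces <- floor(total / max_len) + 1
  targets <- total * seq(0, n_pieces, 1) / n_pieces
  lapply(seq_len(n_pieces), function(i) {
    lo <- targets[i]; hi <- targets[i + 1]
    inner <- which(L > lo + 1e-9 & L < hi - 1e-9)
    dedupe_points(rbind(interp_at_arc(positions, L, lo),
                        positions[inner, , drop = FALSE],
                        interp_at_arc(positions, L, hi)))
  })
}

#' Second partition: adjacent midpoint pairs
#'
#' Takes the curves produced by the first re-tracing step, ordered along
#' each branch, computes the half-arc-length midpoint of every curve, and
#' pairs the midpoints of adjacent curves (curves sharing a first-pass
#' anchor). When branch structure is supplied, pairs are also formed across
#' bifurcations, between the midpoint of the parent branch's last curve and
#' the midpoint of each child branch's first curve, so every interior anchor
#' (including bifurcation anchors) lies strictly inside some pair's span.
#'
#' @param paths list of curves (n x 3 matrices), ordered along each branch.
#' @param branch_of_path integer vector: branch index of each path (NULL =
#'   all paths belong to one branch).
#' @param branch_parent integer vector: parent branch index per branch
#'   (NA for root branches); only needed for cross-bifurcation pairs.
#' @param voxel_size numeric(3) micrometre per voxel.
#' @return list of pairs; each has `p0`, `p1` (midpoints), `type`
#'   ("within" or "junction"), `path_i`, `path_j` (indices into `paths`)
#'   and for junction pairs `child_branch`.
#' @export
second_partition <- function(paths, branch_of_path = NULL,
                             branch_parent = NULL,
                             voxel_size = c(1, 1, 1)) {
  if (!length(paths)) return(list())
  for (P in paths) {
    if (nrow(as_points(P)) < 2) stop("each traced path needs >= 2 points")
  }
  if (is.null(branch_of_path)) branch_of_path <- rep(1L, length(paths))
  mids <- lapply(paths, curve_midpoint, voxel_size = voxel_size)
  pairs <- list()
  # within-branch adjacency
  for (b in unique(branch_of_path)) {
    idx <- which(branch_of_path == b)
    if (length(idx) < 2) next
    for (j in seq_len(length(idx) - 1)) {
      pairs[[length(pairs) + 1]] <- list(
        p0 = mids[[idx[j]]], p1 = mids[[idx[j + 1]]],
        type = "within", path_i = idx[j], path_j = idx[j + 1],
        branch = b)
    }
  }
  # across bifurcations: parent's last curve midpoint -> child's first
  if (!is.null(branch_parent)) {
    for (b in unique(branch_of_path)) {
      p <- branch_parent[b]
      if (is.na(p)) next
      pi <- which(branch_of_path == p)
      bi <- which(branch_of_path == b)
      if (!length(pi) || !length(bi)) next
      i <- pi[length(pi)]
      j <- bi[1]
      pairs[[length(pairs) + 1]] <- list(
        p0 = mids[[i]], p1 = mids[[j]],
        type = "junction", path_i = i, path_j = j,
        branch = p, child_branch = b)
    }
  }
  pairs
}
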