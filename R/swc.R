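#' Neuron reconstruction tree
#'
#' A `neuron_tree` holds an SWC-style neuron reconstruction: one row per
#' node with its SWC id, structure type code, 3D position, radius and the id
#' of its parent node (-1 for the root). Positions are voxel-indexed
#' (0-based, axes matching the image axes); physical units enter only
#' through `voxel_size` (micrometre per voxel, per axis).
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @param voxel_size numeric(3), micrometre per voxel along x, y, z.
#' @param header character vector of `#` comment lines to preserve on write.
#' @return An object of class `neuron_tree`.
#' @export
neuron_tree <- function(nodes, voxel_size = c(1, 1, 1), header = character()) {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    stop("`nodes` must be a data.frame with columns ",
         paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes[required])
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    stop("`voxel_size` must be 3 positive numbers (um per voxel)")
  }
  tree <- structure(list(nodes = nodes, voxel_size = voxel_size,
                         header = header),
                    class = "neuron_tree")
  validate_neuron_tree(tree)
  tree
}

#' @export
print.neuron_tree <- function(x, ...) {
  nb <- length(bifurcation_ids(x))
  nt <- length(tip_ids(x))
  cat(sprintf("<neuron_tree> %d nodes, %d bifurcation(s), %d tip(s), voxel size %s um\n",
              nrow(x$nodes), nb, nt,
              paste(format(x$voxel_size), collapse = " x ")))
  invisible(x)
}

is_neuron_tree <- function(x) inherits(x, "neuron_tree")

# Structural validation: unique ids, resolvable parents, a single root and
# no cycles. Broken topology is rejected rather than repaired.
validate_neuron_tree <- function(tree) {
  nodes <- tree$nodes
  if (nrow(nodes) == 0) stop("neuron tree has no nodes")
  if (anyDuplicated(nodes$id)) stop("structural error: duplicate node ids")
  if (any(nodes$id <= 0)) stop("structural error: node ids must be positive")
  if (any(!is.finite(as.matrix(nodes[c("x", "y", "z")]))))
    stop("structural error: non-finite coordinates")
  if (any(nodes$radius < 0)) stop("structural error: negative radius")
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0) stop("structural error: no root node (parent -1)")
  if (length(roots) > 1) stop("structural error: multiple roots")
  pidx <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent != -1L & is.na(pidx))
  if (length(bad)) {
    stop(sprintf("structural error: node id %d has dangling parent id %d",
                 nodes$id[bad[1]], nodes$parent[bad[1]]))
  }
  # cycle check: every node must reach the root
  n <- nrow(nodes)
  depth <- rep(NA_integer_, n)
  depth[roots] <- 0L
  for (pass in seq_len(n)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    ready <- todo[!is.na(depth[pidx[todo]])]
    if (!length(ready)) stop("structural error: cycle in parent links")
    depth[ready] <- depth[pidx[ready]] + 1L
  }
  if (anyNA(depth)) stop("structural error: cycle in parent links")
  invisible(tree)
}

node_positions <- function(tree) {
  as.matrix(tree$nodes[c("x", "y", "z")])
}

# children indices (row numbers) per node row
children_index <- function(tree) {
  nodes <- tree$nodes
  pidx <- match(nodes$parent, nodes$id)
  out <- vector("list", nrow(nodes))
  kids <- which(!is.na(pidx))
  for (i in kids) out[[pidx[i]]] <- c(out[[pidx[i]]], i)
  out
}

root_index <- function(tree) which(tree$nodes$parent == -1L)

#' Node ids of bifurcations and tips
#'
#' Bifurcations are non-root nodes with two or more children; tips are nodes
#' with no children.
#' @param tree a `neuron_tree`.
#' @return integer vector of SWC node ids.
#' @export
bifurcation_ids <- function(tree) {
  nch <- lengths(children_index(tree))
  ids <- tree$nodes$id[nch >= 2 & tree$nodes$parent != -1L]
  as.integer(ids)
}

#' @rdname bifurcation_ids
#' @export
tip_ids <- function(tree) {
  nch <- lengths(children_index(tree))
  as.integer(tree$nodes$id[nch == 0])
}

#' Read an SWC reconstruction file
#'
#' Parses the standard whitespace-separated 7-column SWC format
#' (`id type x y z radius parent`). Comment lines starting with `#` are
#' preserved for round-tripping. Files with multiple roots, dangling parent
#' references or cycles are rejected.
#'
#' @param path path to an SWC file.
#' @param voxel_size numeric(3), micrometre per voxel (SWC coordinates are
#'   interpreted as voxel-indexed).
#' @return a [neuron_tree()].
#' @export
read_swc <- function(path, voxel_size = c(1, 1, 1)) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  header <- lines[startsWith(trimws(lines), "#")]
  body_idx <- which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("SWC parse error: file has no node lines")
  fields <- strsplit(trimws(lines[body_idx]), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    bad <- body_idx[which(nf != 7)[1]]
    stop(sprintf("SWC parse error at line %d: expected 7 fields, got %d",
                 bad, nf[which(nf != 7)[1]]))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  if (any(!is.finite(vals))) {
    bad <- body_idx[which(rowSums(!is.finite(vals)) > 0)[1]]
    stop(sprintf("SWC parse error at line %d: non-numeric field", bad))
  }
  nodes <- data.frame(id = as.integer(vals[, 1]), type = as.integer(vals[, 2]),
                      x = vals[, 3], y = vals[, 4], z = vals[, 5],
                      radius = vals[, 6], parent = as.integer(vals[, 7]))
  neuron_tree(nodes, voxel_size = voxel_size, header = header)
}

#' Write a neuron tree to an SWC file
#'
#' Nodes are written in a topological order (parents before children) with
#' coordinates and radii formatted to three decimal places; ids are
#' preserved verbatim. Preserved header comment lines are written first.
#'
#' @param tree a [neuron_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  if (!is_neuron_tree(tree)) stop("`tree` must be a neuron_tree")
  if (nrow(tree$nodes) == 0) stop("refusing to write an empty tree")
  validate_neuron_tree(tree)
  nodes <- tree$nodes[topological_order(tree), , drop = FALSE]
  lines <- c(tree$header,
             sprintf("%d %d %.3f %.3f %.3f %.3f %d",
                     nodes$id, nodes$type, nodes$x, nodes$y, nodes$z,
                     nodes$radius, nodes$parent))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con)
  invisible(path)
}

# Row order with every parent before its children (BFS from the root).
topological_order <- function(tree) {
  ch <- children_index(tree)
  order <- integer(nrow(tree$nodes))
  queue <- root_index(tree)
  k <- 0L
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    k <- k + 1L
    order[k] <- i
    queue <- c(queue, ch[[i]])
  }
  order
}
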