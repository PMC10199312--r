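# Fixtures are built in code at test time.

# simple chain tree along +x with given node spacing (voxels)
chain_tree <- function(n = 10, spacing = 1, voxel_size = c(1, 1, 1)) {
  neuron_tree(data.frame(
    id = seq_len(n), type = 3L,
    x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    radius = 1, parent = c(-1L, seq_len(n - 1))
  ), voxel_size = voxel_size)
}

# Y-shaped tree: root - stem - bifurcation - two tips
y_tree <- function() {
  neuron_tree(data.frame(
    id = 1:5, type = 3L,
    x = c(0, 1, 2, 3, 3),
    y = c(0, 0, 0, 1, -1),
    z = 0,
    radius = 1,
    parent = c(-1L, 1L, 2L, 3L, 3L)
  ))
}

# binary tree with 3 bifurcations and 4 tips (all unit steps)
binary_tree3 <- function() {
  # root(1)-2-3[bif] -> 4-5[bif] -> tips 6,7 ; and 8-9[bif] -> tips 10,11
  neuron_tree(data.frame(
    id = 1:11, type = 3L,
    x = c(0, 1, 2, 3, 4, 5, 5, 3, 4, 5, 5),
    y = c(0, 0, 0, 1, 2, 3, 1, -1, -2, -3, -1),
    z = 0,
    radius = 1,
    parent = c(-1L, 1L, 2L, 3L, 4L, 5L, 5L, 3L, 8L, 9L, 9L)
  ))
}

# uniform-intensity block
uniform_block <- function(dims = c(7, 7, 3), value = 100) {
  image_block(array(value, dim = dims))
}

# straight bright tube along x at (y0, z0), Gaussian cross-section
straight_tube_block <- function(dims = c(40, 21, 21), y0 = 10, z0 = 10,
                                sigma = 1.7, peak = 96, bg = 12) {
  tree <- neuron_tree(data.frame(
    id = 1:2, type = 3L, x = c(0, dims[1] - 1), y = y0, z = z0,
    radius = 2, parent = c(-1L, 1L)))
  render_image(tree, dims,
               tube_model(radius = 2, peak_intensity = peak,
                          profile_sigma = sigma, background_level = bg,
                          noise_sigma = 0))
}

# L-bent tube: along x then along y, noise-free
l_tube_block <- function(dims = c(40, 40, 15), z0 = 7) {
  tree <- neuron_tree(data.frame(
    id = 1:3, type = 3L,
    x = c(5, 30, 30), y = c(8, 8, 32), z = z0,
    radius = 2, parent = c(-1L, 1L, 2L)))
  list(tree = tree,
       block = render_image(tree, dims,
                            tube_model(radius = 2, noise_sigma = 0)))
}

# independent Dijkstra oracle on small blocks via igraph, using the
# package's R-level edge_weight as the weight definition
igraph_shortest_weight <- function(block, start, end, lambda_I) {
  dims <- dim(block$data)
  coords <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                                  z = 0:(dims[3] - 1)))
  idx_of <- function(v) 1 + v[1] + dims[1] * (v[2] + dims[2] * v[3])
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (i in seq_len(nrow(coords))) {
    v0 <- coords[i, ]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      v1 <- v0 + c(dx, dy, dz)
      if (any(v1 < 0) || any(v1 > dims - 1)) next
      j <- idx_of(v1)
      if (j <= i) next  # undirected, add each edge once
      from <- c(from, i); to <- c(to, j)
      w <- c(w, edge_weight(v0, v1, block, lambda_I))
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  igraph::distances(g, v = idx_of(start), to = idx_of(end))[1, 1]
}

# memoised 60-sample acceptance benchmark (20 per case, master seed 42)
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_benchmark <- function() {
  if (is.null(.acceptance_cache$bench)) {
    ds <- generate_dataset(60, seed = 42)
    .acceptance_cache$bench <- run_benchmark(ds, methods = c("nrrs", "ms", "ams"))
  }
  .acceptance_cache$bench
}
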