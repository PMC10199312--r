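test_that("shortest path on trivial blocks", {
  blk <- uniform_block(c(3, 1, 1), 10)
  path <- graph_shortest_path(blk, c(0, 0, 0), c(2, 0, 0))
  expect_equal(nrow(path), 3)
  expect_equal(path[1, ], c(0, 0, 0))
  expect_equal(path[3, ], c(2, 0, 0))

  # uniform intensity, axis-aligned endpoints: the straight voxel line
  blk <- uniform_block(c(7, 5, 3), 10)
  path <- graph_shortest_path(blk, c(0, 2, 1), c(6, 2, 1))
  expect_equal(nrow(path), 7)
  expect_equal(attr(path, "total_weight"), 6, tolerance = 1e-9)

  expect_error(graph_shortest_path(blk, c(1, 1, 1), c(1, 1, 1)), "differ")
  expect_error(graph_shortest_path(blk, c(0, 0, 0), c(9, 0, 0)), "outside")
  expect_error(graph_shortest_path(blk, c(0, 0, 0), c(6, 2, 1),
                                   max_voxels = 10), "crop")
  dark <- image_block(array(0, dim = c(3, 3, 1)))
  expect_error(graph_shortest_path(dark, c(0, 0, 0), c(2, 0, 0)),
               "degenerate")
})

test_that("path follows a bright L-shaped ridge instead of the dark diagonal", {
  img <- array(0, dim = c(7, 7, 1))
  img[, 1, 1] <- 100          # ridge along y = 0
  img[7, , 1] <- 100          # ridge along x = 6
  img[img == 0] <- 1e-3       # keep all edge weights finite
  blk <- image_block(img)
  path <- graph_shortest_path(blk, c(0, 0, 0), c(6, 6, 0), lambda_I = 5)
  # every path voxel sits on the ridge
  on_ridge <- apply(path, 1, function(v) v[2] == 0 || v[1] == 6)
  expect_true(all(on_ridge))
  # oracle equivalence on the same block
  w <- igraph_shortest_weight(blk, c(0, 0, 0), c(6, 6, 0), lambda_I = 5)
  expect_equal(attr(path, "total_weight"), w, tolerance = 1e-9)
})

test_that("Dijkstra equals the brute-force all-paths minimum on small blocks", {
  set.seed(7)
  for (i in 1:6) {
    dims <- c(sample(3:5, 1), sample(3:5, 1), sample(1:2, 1))
    blk <- image_block(array(sample(1:255, prod(dims), replace = TRUE),
                             dim = dims))
    start <- c(0, 0, 0)
    end <- dims - 1
    path <- graph_shortest_path(blk, start, end, lambda_I = 6)
    w <- igraph_shortest_weight(blk, start, end, lambda_I = 6)
    expect_equal(attr(path, "total_weight"), w, tolerance = 1e-9)
  }
})

test_that("deform is energy-monotone and keeps endpoints fixed", {
  blk <- straight_tube_block()
  set.seed(3)
  K <- 12
  zig <- cbind(seq(2, 37, length.out = K),
               10 + rep(c(-2, 2), length.out = K),
               10 + rep(c(1.5, -1.5), length.out = K))
  zig[1, 2:3] <- 10; zig[K, 2:3] <- 10
  p <- energy_params()
  out <- deform(zig, blk, p)
  tr <- attr(out, "energy_trace")
  expect_true(all(diff(tr) <= 0))
  expect_identical(out[1, ], zig[1, ])
  expect_identical(out[K, ], zig[K, ])
  # zig-zag in a straight bright tube ends within 0.5 voxel RMS of the axis
  interior <- out[2:(K - 1), ]
  rms <- sqrt(mean((interior[, 2] - 10)^2 + (interior[, 3] - 10)^2))
  expect_lt(rms, 0.5)
  # K = 2: returned unchanged
  two <- rbind(c(1, 10, 10), c(30, 10, 10))
  expect_equal(deform(two, blk, p), two, ignore_attr = TRUE)
})

test_that("a curve on the centerline of a straight tube is a near fixed point", {
  blk <- straight_tube_block()
  onaxis <- cbind(seq(3, 36, by = 1.5), 10, 10)
  out <- deform(onaxis, blk, energy_params())
  rms <- sqrt(mean(rowSums((out - onaxis)^2)))
  expect_lt(rms, 0.25)
})

test_that("trace recovers tube centerlines", {
  blk <- straight_tube_block()
  for (lam in c(5, 10, 15)) {
    cv <- trace(blk, c(2, 10, 10), c(37, 10, 10),
                energy_params(lambda_I = lam))
    rms <- sqrt(mean((cv[, 2] - 10)^2 + (cv[, 3] - 10)^2))
    expect_lt(rms, 0.5)
  }
  # endpoints restored exactly, including sub-voxel ones
  p0 <- c(2.25, 10.1, 9.9); p1 <- c(36.75, 10, 10.2)
  cv <- trace(blk, p0, p1, energy_params())
  expect_identical(cv[1, ], p0)
  expect_identical(cv[nrow(cv), ], p1)
})

test_that("trace follows an L-bend without corner cutting", {
  fix <- l_tube_block()
  cv <- trace(fix$block, c(5, 8, 7), c(30, 32, 7), energy_params())
  d <- nrrs:::dist_to_polyline(cv, nrrs:::node_positions(fix$tree))
  expect_lt(max(d), 2)  # never farther than the tube radius
})

test_that("endpoints displaced into darkness still trace along the tube", {
  blk <- straight_tube_block()
  cv <- trace(blk, c(2, 14, 10), c(37, 14, 10), energy_params())
  interior <- cv[5:(nrow(cv) - 4), , drop = FALSE]
  d_axis <- sqrt((interior[, 2] - 10)^2 + (interior[, 3] - 10)^2)
  expect_lt(mean(d_axis), 1.5)  # interior attracted onto the signal
})

test_that("tracing is equivariant under block translation", {
  fix <- l_tube_block()
  cv <- trace(fix$block, c(5, 8, 7), c(30, 32, 7), energy_params())
  # embed the same content translated inside a larger block
  off <- c(4, 3, 2)
  dims <- dim(fix$block$data)
  big <- array(12, dim = dims + c(8, 8, 5))  # background level
  big[off[1] + seq_len(dims[1]), off[2] + seq_len(dims[2]),
      off[3] + seq_len(dims[3])] <- fix$block$data
  cv2 <- trace(image_block(big), c(5, 8, 7) + off, c(30, 32, 7) + off,
               energy_params())
  cv2 <- sweep(cv2, 2, off)
  expect_equal(nrow(cv), nrow(cv2))
  expect_lt(max(abs(cv - cv2)), 0.1)
  # degenerate call
  expect_warning(trace(fix$block, c(5, 8, 7), c(5, 8, 7)), "identical")
})
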