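test_that("skeleton deviation matches simple geometry", {
  tree <- chain_tree(21)
  expect_equal(skeleton_deviation(tree, tree), 0)
  shifted <- tree
  shifted$nodes$y <- shifted$nodes$y + 3
  expect_equal(skeleton_deviation(shifted, tree), 3, tolerance = 1e-9)
  # invariance under global translation of both trees and node re-ordering
  t2 <- tree; s2 <- shifted
  t2$nodes[c("x", "y", "z")] <- t2$nodes[c("x", "y", "z")] + 11
  s2$nodes[c("x", "y", "z")] <- s2$nodes[c("x", "y", "z")] + 11
  expect_equal(skeleton_deviation(s2, t2), 3, tolerance = 1e-9)
})

test_that("skeleton deviation agrees with a dense-sampling oracle", {
  # chord vs circular arc, chord endpoints on the arc
  R <- 20
  theta <- seq(-pi / 3, pi / 3, length.out = 400)
  arc <- cbind(R * cos(theta), R * sin(theta), 0)
  chord <- rbind(arc[1, ], arc[nrow(arc), ])
  arc_tree <- neuron_tree(data.frame(
    id = seq_len(nrow(arc)), type = 3L, x = arc[, 1] + 30, y = arc[, 2] + 30,
    z = 5, radius = 1, parent = c(-1L, seq_len(nrow(arc) - 1))))
  chord_tree <- neuron_tree(data.frame(
    id = 1:2, type = 3L, x = chord[, 1] + 30, y = chord[, 2] + 30, z = 5,
    radius = 1, parent = c(-1L, 1L)))
  got <- skeleton_deviation(chord_tree, arc_tree, resample_step = 0.1)
  # oracle: numeric integral of the exact point-to-circle distance along
  # the chord (the chord is at x = R cos(pi/3); the arc spans wider angles,
  # so the nearest arc point is the radial projection)
  xc <- R * cos(pi / 3)
  ys <- seq(-R * sin(pi / 3), R * sin(pi / 3), length.out = 20001)
  d <- R - sqrt(xc^2 + ys^2)
  oracle <- mean(d)
  expect_equal(got, oracle, tolerance = 0.02 * oracle)

  # random smooth polyline pair
  set.seed(12)
  base <- cbind(seq(0, 40, 0.5), 5 * sin(seq(0, 40, 0.5) / 6), 0) + 10
  warp <- base + cbind(0, 1.5 * cos(base[, 1] / 9), 0.8)
  mk <- function(P) neuron_tree(data.frame(
    id = seq_len(nrow(P)), type = 3L, x = P[, 1], y = P[, 2], z = P[, 3],
    radius = 1, parent = c(-1L, seq_len(nrow(P) - 1))))
  got <- skeleton_deviation(mk(warp), mk(base), resample_step = 2)
  dense_P <- resample_polyline(warp, 0.1)
  oracle <- mean(nrrs:::dist_to_polyline(dense_P, base))
  expect_equal(got, oracle, tolerance = 0.02 * oracle)
})

test_that("bifurcation deviation matches topologically corresponding junctions", {
  tree <- binary_tree3()
  expect_equal(bifurcation_deviation(tree, tree), 0)
  # single displaced bifurcation
  y <- y_tree()
  y2 <- y_tree()
  y2$nodes$y[3] <- y2$nodes$y[3] + 4
  expect_equal(bifurcation_deviation(y2, y), 4)
  # two bifurcations displaced 2 and 6 -> mean 4 (displace along z so the
  # tips stay put and topology matching still works)
  b2 <- binary_tree3()
  bif_rows <- match(bifurcation_ids(b2), b2$nodes$id)
  b2$nodes$z[bif_rows[2]] <- b2$nodes$z[bif_rows[2]] + 2
  b2$nodes$z[bif_rows[3]] <- b2$nodes$z[bif_rows[3]] + 6
  expect_equal(bifurcation_deviation(b2, binary_tree3()), (0 + 2 + 6) / 3)
  # no bifurcations: NA
  expect_true(is.na(bifurcation_deviation(chain_tree(5), chain_tree(5))))
  # mismatched counts
  expect_error(bifurcation_deviation(chain_tree(5), y), "mismatch")
})

test_that("radius estimation recovers tube half-amplitude radius", {
  img <- straight_tube_block()  # radius-2 tube via sigma = 1.7
  on_axis <- neuron_tree(data.frame(id = 1:2, type = 3L, x = c(15, 25),
                                    y = 10, z = 10, radius = 0,
                                    parent = c(-1L, 1L)))
  est <- radius_estimate(on_axis, img)
  expect_true(all(abs(est$nodes$radius - 2) <= 1))
  off_axis <- on_axis
  off_axis$nodes$y <- off_axis$nodes$y + 2
  est_off <- radius_estimate(off_axis, img)
  expect_true(all(est_off$nodes$radius < est$nodes$radius))
  # fully dark image: radius 0, flagged
  dark <- image_block(array(0, dim = c(32, 21, 21)))
  est0 <- radius_estimate(on_axis, dark, bg_threshold = 10)
  expect_equal(est0$nodes$radius, c(0, 0))
  expect_equal(attr(est0, "dark_nodes"), 1:2)
})

test_that("intensity extraction interpolates node intensities", {
  img <- straight_tube_block()  # peak 96, bg 12, noise-free
  on_axis <- neuron_tree(data.frame(id = 1:2, type = 3L, x = c(15, 25),
                                    y = 10, z = 10, radius = 1,
                                    parent = c(-1L, 1L)))
  expect_equal(intensity_extraction(on_axis, img), 96)
  bg <- on_axis
  bg$nodes$y <- 2  # far from the tube
  expect_equal(intensity_extraction(bg, img), 12)
  half <- on_axis
  half$nodes$y[2] <- 2  # one node on axis, one in background
  expect_equal(intensity_extraction(half, img), (96 + 12) / 2)
})

test_that("information extraction rate is a volume overlap", {
  tree <- chain_tree(31)
  tree$nodes$radius <- 2
  tree$nodes$y <- tree$nodes$y + 10; tree$nodes$z <- tree$nodes$z + 10
  expect_equal(information_extraction_rate(tree, tree), 1)
  far <- tree
  far$nodes$y <- far$nodes$y + 10  # > 2 * radius: disjoint volumes
  expect_equal(information_extraction_rate(far, tree), 0)
  # 2-voxel shift matches a brute-force voxel-count oracle
  sh <- tree
  sh$nodes$y <- sh$nodes$y + 2
  got <- information_extraction_rate(sh, tree)
  in_union <- function(v, P, r) any(colSums((t(P) - v)^2) <= r^2)
  Pg <- resample_polyline(nrrs:::node_positions(tree), 2)
  Ps <- resample_polyline(nrrs:::node_positions(sh), 2)
  grid <- as.matrix(expand.grid(x = -5:35, y = 0:25, z = 0:25))
  gt_in <- apply(grid, 1, in_union, P = Pg, r = 2)
  sh_in <- apply(grid, 1, in_union, P = Ps, r = 2)
  expect_equal(got, sum(gt_in & sh_in) / sum(gt_in))
})

test_that("storage size reports node count and written bytes", {
  y <- y_tree()
  s <- storage_size(y)
  expect_equal(s$node_count, 5)
  f <- withr::local_tempfile(fileext = ".swc")
  write_swc(y, f)
  expect_equal(s$file_bytes, file.size(f))
  # finer resampling strictly increases the node count
  dense <- stitch(lapply(decompose_branches(chain_tree(11)),
                         `[[`, "positions"),
                  chain_tree(11), resample_step_out = 0.25)
  expect_gt(storage_size(dense)$node_count, 11)
})

test_that("mean shift converges onto symmetric signal and respects its cap", {
  # node at the centroid of a symmetric bright sphere is a fixed point
  dims <- c(21, 21, 21)
  g <- expand.grid(x = 0:20, y = 0:20, z = 0:20)
  d2 <- (g$x - 10)^2 + (g$y - 10)^2 + (g$z - 10)^2
  sphere <- image_block(array(100 * exp(-d2 / 10), dim = dims))
  tree <- neuron_tree(data.frame(id = 1:3, type = 3L, x = c(2, 10, 18),
                                 y = 10, z = 10, radius = 1,
                                 parent = c(-1L, 1L, 2L)))
  ms <- mean_shift_refine(tree, sphere, search_radius = 4)
  expect_lt(abs(ms$nodes$x[2] - 10), 1e-6)
  expect_equal(ms$nodes$x[c(1, 3)], c(2, 18))  # root and tip never move

  # node 2 voxels off a straight tube converges onto the axis
  img <- straight_tube_block()
  off <- neuron_tree(data.frame(id = 1:3, type = 3L, x = c(10, 20, 30),
                                y = c(10, 12, 10), z = 10, radius = 1,
                                parent = c(-1L, 1L, 2L)))
  ms <- mean_shift_refine(off, img, search_radius = 4)
  expect_lt(abs(ms$nodes$y[2] - 10), 0.5)

  # a node beyond the searching distance cannot be fully recovered
  far <- neuron_tree(data.frame(id = 1:3, type = 3L, x = c(10, 20, 30),
                                y = c(10, 19, 10), z = 10, radius = 1,
                                parent = c(-1L, 1L, 2L)))
  ms <- mean_shift_refine(far, img, search_radius = 5)
  moved <- nrrs:::vnorm(c(ms$nodes$x[2] - 20, ms$nodes$y[2] - 19,
                          ms$nodes$z[2] - 10))
  expect_lte(moved, 5 + 1e-9)
  expect_gt(abs(ms$nodes$y[2] - 10), 3.9)

  # all-zero window: node unmoved
  dark <- image_block(array(0, dim = c(31, 21, 21)))
  dark$data[1, 1, 1] <- 1
  ms <- mean_shift_refine(far, dark, search_radius = 3)
  expect_equal(ms$nodes$y[2], 19)
})

test_that("auto mean shift resamples and behaves like MS near signal", {
  img <- straight_tube_block()
  off <- neuron_tree(data.frame(id = 1:3, type = 3L, x = c(5, 20, 35),
                                y = c(10, 12, 10), z = 10, radius = 1,
                                parent = c(-1L, 1L, 2L)))
  ams <- auto_mean_shift_refine(off, img)
  expect_gte(nrow(ams$nodes), nrow(off$nodes))
  # interior nodes end on the axis
  interior <- ams$nodes[ams$nodes$parent != -1 &
                          ams$nodes$id %in% ams$nodes$parent, ]
  expect_lt(mean(abs(interior$y - 10)), 0.8)
  # dark region: nodes unmoved
  dark <- image_block(array(0, dim = c(41, 21, 21)))
  dark$data[1, 1, 1] <- 1
  ams0 <- auto_mean_shift_refine(off, dark)
  d <- nrrs:::dist_to_polylines(nrrs:::node_positions(ams0),
                                list(nrrs:::node_positions(off)))
  expect_lt(max(d), 1e-6)
})

test_that("maximum intensity projections", {
  vol <- array(0, dim = c(8, 6, 4))
  expect_true(all(make_mip(vol) == 0))
  vol[3, 2, 4] <- 17
  mip <- make_mip(vol)
  expect_equal(dim(mip), c(8, 6))
  expect_equal(mip[3, 2], 17)
  expect_equal(max(mip), max(vol))
  expect_equal(dim(make_mip(vol, axis = "x")), c(6, 4))
})

test_that("benchmark on identity method yields 100% ratios", {
  ds <- generate_dataset(2, seed = 15, block_shape = c(64, 64, 48))
  bench <- run_benchmark(ds, methods = "identity")
  expect_equal(bench$summary$identity$skeleton_ratio_pct, 100)
  expect_equal(bench$summary$identity$bifurcation_ratio_pct, 100)
  # ground truth as test input: zero deviations
  ds0 <- ds
  ds0[[1]]$perturbed <- ds0[[1]]$ground_truth
  b0 <- run_benchmark(ds0[1], methods = "identity")
  expect_equal(b0$summary$input$mean_skeleton_deviation, 0)
  expect_equal(b0$summary$input$info_loss_pct, 0, tolerance = 1e-9)
  expect_error(run_benchmark(ds, methods = "bogus"), "unknown method")
})
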