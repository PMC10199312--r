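test_that("skeleton generation is deterministic and well-formed", {
  t1 <- generate_skeleton(seed = 21)
  t2 <- generate_skeleton(seed = 21)
  expect_identical(t1$nodes, t2$nodes)
  expect_equal(length(bifurcation_ids(t1)), 0)

  tb <- generate_skeleton(seed = 22, with_bifurcation = TRUE)
  expect_equal(length(bifurcation_ids(tb)), 1)
  expect_equal(length(decompose_branches(tb)), 3)
  expect_error(generate_skeleton(c(16, 64, 64)), ">= 32")
})

test_that("every generated skeleton has a pronounced bend and stays in bounds", {
  shape <- c(128, 128, 64)
  for (seed in 1:10) {
    tree <- generate_skeleton(shape, with_bifurcation = TRUE, seed = seed)
    pos <- nrrs:::node_positions(tree)
    expect_true(all(pos >= 2 * tree$nodes$radius[1]))
    expect_true(all(sweep(pos, 2, shape - 1 - 2 * tree$nodes$radius[1], `<=`)))
  }
  # the bend guarantee applies to the main polyline (a single branch when
  # no bifurcation is attached)
  for (seed in 11:20) {
    tree <- generate_skeleton(shape, with_bifurcation = FALSE, seed = seed)
    main <- decompose_branches(tree)[[1]]
    turn <- nrrs:::max_window_turning(main$positions, 10)
    expect_gte(turn, 30 * pi / 180)
  }
})

test_that("rendered images follow the Gaussian tube model", {
  dims <- c(40, 21, 21)
  tree <- neuron_tree(data.frame(id = 1:2, type = 3L, x = c(0, 39),
                                 y = 10, z = 10, radius = 2,
                                 parent = c(-1L, 1L)))
  sigma <- 2 / sqrt(2 * log(2))
  tube <- tube_model(radius = 2, peak_intensity = 96, profile_sigma = sigma,
                     background_level = 12, noise_sigma = 0)
  img <- render_image(tree, dims, tube)
  # on-centerline voxel attains the peak (= block max, noise-free)
  expect_equal(img$data[20, 11, 11], 96)
  expect_equal(max(img$data), 96)
  # half-amplitude at distance sigma * sqrt(2 ln 2) = 2 voxels
  expect_equal(img$data[20, 13, 11], round(12 + (96 - 12) / 2), tolerance = 1)
  # determinism with noise
  tube_n <- tube_model(noise_sigma = 6)
  i1 <- render_image(tree, dims, tube_n, seed = 5)
  i2 <- render_image(tree, dims, tube_n, seed = 5)
  expect_identical(i1$data, i2$data)
})

test_that("centerline voxels are local maxima orthogonal to the skeleton", {
  img <- straight_tube_block()
  for (x in c(5, 15, 30)) {
    centre <- img$data[x + 1, 11, 11]
    ortho <- c(img$data[x + 1, 10, 11], img$data[x + 1, 12, 11],
               img$data[x + 1, 11, 10], img$data[x + 1, 11, 12])
    expect_true(all(centre >= ortho))
  }
})

test_that("case 1 replaces the most-bent window by a shorter chord", {
  gt <- generate_skeleton(seed = 31, with_bifurcation = TRUE)
  pt <- perturb(gt, "case1_bend", seed = 32)
  expect_identical(pt$nodes$parent, gt$nodes$parent)
  expect_identical(pt$nodes$id, gt$nodes$id)
  # chord shortcut: perturbed arc length does not exceed the ground truth
  bl_gt <- sum(vapply(decompose_branches(gt),
                      function(b) arc_length(b$positions), numeric(1)))
  bl_pt <- sum(vapply(decompose_branches(pt),
                      function(b) arc_length(b$positions), numeric(1)))
  expect_lte(bl_pt, bl_gt)
  # deviation concentrated in the window is substantial
  rows <- attr(pt, "perturbed_node_idx")
  moved <- nrrs:::node_positions(pt)[rows, ]
  d <- nrrs:::dist_to_polylines(moved, lapply(decompose_branches(gt),
                                              `[[`, "positions"))
  expect_gt(mean(d), 1)
  # root and tips fixed
  expect_identical(pt$nodes[pt$nodes$parent == -1, c("x", "y", "z")],
                   gt$nodes[gt$nodes$parent == -1, c("x", "y", "z")])
})

test_that("case 2 displaces the bifurcation by the requested magnitude", {
  gt <- generate_skeleton(seed = 41, with_bifurcation = TRUE)
  pt <- perturb(gt, "case2_bifurcation", seed = 42, magnitude = 6)
  bif <- match(bifurcation_ids(gt), gt$nodes$id)
  d <- sqrt(sum((nrrs:::node_positions(pt)[bif, ] -
                   nrrs:::node_positions(gt)[bif, ])^2))
  expect_equal(d, 6, tolerance = 1e-9)
  # exactly one node moves by the full magnitude
  all_d <- sqrt(rowSums((nrrs:::node_positions(pt) -
                           nrrs:::node_positions(gt))^2))
  expect_equal(sum(abs(all_d - 6) < 1e-9), 1)
  # tips unmoved
  tips <- match(tip_ids(gt), gt$nodes$id)
  expect_true(all(all_d[tips] == 0))
})

test_that("case 3 translates interior nodes with an endpoint taper", {
  gt <- generate_skeleton(seed = 51, with_bifurcation = TRUE)
  pt <- perturb(gt, "case3_shift", seed = 52, magnitude = 5)
  all_d <- sqrt(rowSums((nrrs:::node_positions(pt) -
                           nrrs:::node_positions(gt))^2))
  fixed <- c(match(tip_ids(gt), gt$nodes$id), nrrs:::root_index(gt))
  expect_true(all(all_d[fixed] == 0))
  interior <- setdiff(seq_along(all_d), fixed)
  expect_true(mean(all_d[interior]) >= 3.5 && mean(all_d[interior]) <= 5)
  expect_true(all(all_d <= 5 + 1e-9))
  # default magnitude drawn from 3..8 voxels
  pt2 <- perturb(gt, "case3_shift", seed = 53)
  shift <- nrrs:::vnorm(attr(pt2, "shift"))
  expect_true(shift >= 3 && shift <= 8)
  expect_error(perturb(gt, "case9"), "unknown case")
})

test_that("perturbations leave measurable work for refinement", {
  # tree-wide mean deviation for the whole-neurite shift; local mean
  # deviation (over the perturbed span) for the two local cases
  for (seed in 61:64) {
    gt <- generate_skeleton(seed = seed, with_bifurcation = TRUE)
    gt_polys <- lapply(decompose_branches(gt), `[[`, "positions")
    p3 <- perturb(gt, "case3_shift", seed = seed + 100)
    expect_gt(skeleton_deviation(p3, gt), 1)
    for (cs in c("case1_bend", "case2_bifurcation")) {
      p <- perturb(gt, cs, seed = seed + 200)
      rows <- attr(p, "perturbed_node_idx")
      d <- nrrs:::dist_to_polylines(nrrs:::node_positions(p)[rows, ,
                                                             drop = FALSE],
                                    gt_polys)
      expect_gt(mean(d), 1)
    }
  }
})

test_that("datasets respect the case mix and serialise deterministically", {
  ds <- generate_dataset(9, seed = 7, block_shape = c(64, 64, 48))
  expect_equal(as.vector(table(vapply(ds, `[[`, character(1),
                                      "case_label"))),
               c(3L, 3L, 3L))
  for (smp in ds) {
    expect_identical(smp$ground_truth$nodes$parent,
                     smp$perturbed$nodes$parent)
    # image carries signal along the ground truth within the tube radius
    pos <- round(nrrs:::node_positions(smp$ground_truth))
    vals <- smp$image$data[pos + 1]
    expect_gt(min(vals), smp$gen_params$tube$background_level)
  }

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(2, seed = 99, out_dir = d1, block_shape = c(64, 64, 48))
  generate_dataset(2, seed = 99, out_dir = d2, block_shape = c(64, 64, 48))
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  expect_true(length(f1) == 8)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # round trip through the serialised form
  smp <- read_sample(file.path(d1, "sample_001"))
  orig <- generate_dataset(2, seed = 99, block_shape = c(64, 64, 48))[[1]]
  ord <- match(orig$ground_truth$nodes$id, smp$ground_truth$nodes$id)
  expect_lt(max(abs(smp$ground_truth$nodes$x[ord] -
                      orig$ground_truth$nodes$x)), 1e-3)
  expect_identical(smp$image$data, orig$image$data)
  expect_error(generate_dataset(0, seed = 1), ">= 1")
})
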