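params_default <- segmentation_params()

test_that("histogram counts the values it is given", {
  h <- build_histogram(c(40, 40, 40, 70, 70, 70), bin_width = 10,
                       smoothing_bandwidth = 0)
  expect_identical(sum(h$counts), 6L)
  expect_identical(h$counts[h$counts > 0], c(3L, 3L))
  # 40s in the first bin, 70s in the last (closed) bin
  occupied <- h$mids[h$counts > 0]
  expect_equal(occupied, c(45, 65))
  # raw counts conserve mass for any bandwidth
  for (bw in c(0.5, 2, 8)) {
    hb <- build_histogram(rnorm(500, 50, 5), bin_width = 1,
                          smoothing_bandwidth = bw)
    expect_identical(sum(hb$counts), 500L)
  }
  expect_error(build_histogram(numeric(0)), "no T2 values")
})

test_that("a bimodal mixture yields exactly two prominent smoothed modes and a valley between them", {
  set.seed(31)
  vals <- c(rnorm(5000, 45, 3), rnorm(5000, 70, 3))
  h <- build_histogram(vals, 1, 2)
  peaks <- oracle_peaks(h$smoothed)
  prom <- vapply(peaks, function(i) oracle_prominence(h$smoothed, i),
                 numeric(1))
  big <- peaks[prom >= 0.05 * max(h$smoothed)]
  expect_length(big, 2L)
  v <- find_valley(h)
  expect_true(v >= 50 && v <= 65)
  # equals the exhaustive minimum scan between the two detected peaks
  between <- (big[1L] + 1L):(big[2L] - 1L)
  expect_equal(v, h$mids[between[which.min(h$smoothed[between])]])
})

test_that("forced and degenerate valley cases behave as documented", {
  # two spikes with a zero run between them: valley in the gap
  h <- build_histogram(c(rep(40, 50), rep(70, 50)), 1, 2)
  v <- find_valley(h)
  expect_true(v > 45 && v < 65)
  # strictly unimodal: no valley
  set.seed(5)
  h1 <- build_histogram(rnorm(2000, 50, 4), 1, 2)
  expect_null(find_valley(h1))
})

test_that("uniform region is a single leaf with its value as mode", {
  node <- hierarchical_split(rep(45, 100), params = params_default)
  expect_length(node$children, 0L)
  expect_null(node$split_threshold)
  expect_equal(node$mode_t2, 45.5)  # centre of the [45, 46) bin
})

test_that("two separated blobs split once into leaves with the right modes", {
  set.seed(17)
  vals <- c(rnorm(400, 45, 1.5), rnorm(400, 70, 1.5))
  node <- hierarchical_split(vals, params = params_default)
  expect_length(node$children, 2L)
  kids <- node$children
  expect_true(all(vapply(kids, function(k) length(k$children) == 0L,
                         logical(1))))
  expect_equal(kids[[1L]]$mode_t2, 45, tolerance = 2)
  expect_equal(kids[[2L]]$mode_t2, 70, tolerance = 2)
  expect_identical(sort(c(kids[[1L]]$voxel_ids, kids[[2L]]$voxel_ids)),
                   seq_along(vals))
})

test_that("recursion matches the brute-force oracle on mixtures", {
  set.seed(23)
  cases <- list(
    c(rnorm(300, 40, 2), rnorm(350, 55, 2), rnorm(350, 75, 3)),
    c(rnorm(500, 45, 3), rnorm(500, 70, 3)),
    rnorm(800, 50, 4),
    c(rnorm(200, 30, 2), rnorm(300, 48, 3), rnorm(300, 60, 2.5),
      rnorm(200, 80, 3)))
  for (vals in cases) {
    ids <- seq_along(vals)
    tree <- hierarchical_split(vals, ids, params_default)
    got <- classify_leaves(tree, params_default)
    got <- got[match(ids, as.integer(names(got)))]
    want <- oracle_segment_with_override(vals, ids, params_default)
    expect_identical(unname(got), unname(want))
  }
})

test_that("traversal order does not change the segmentation", {
  set.seed(29)
  vals <- c(rnorm(400, 45, 3), rnorm(400, 70, 3))
  ids <- seq_along(vals)
  perm <- sample(length(vals))
  lab1 <- classify_leaves(hierarchical_split(vals, ids, params_default),
                          params_default)
  lab2 <- classify_leaves(
    hierarchical_split(vals[perm], ids[perm], params_default),
    params_default)
  lab1 <- lab1[order(as.integer(names(lab1)))]
  lab2 <- lab2[order(as.integer(names(lab2)))]
  expect_identical(lab1, lab2)
})

test_that("threshold semantics are strict at both boundaries", {
  # a leaf whose mode lands exactly on the core threshold stays penumbra
  leaf <- structure(list(voxel_ids = 1:10, t2_values = rep(55.7, 10),
                         mode_t2 = 56, split_threshold = NULL,
                         children = list(), depth = 0L),
                    class = "region_node")
  expect_true(all(classify_leaves(leaf, params_default) == 2L))
  leaf$mode_t2 <- 56 + 1e-9
  expect_true(all(classify_leaves(leaf, params_default) == 3L))
  # voxelwise uninjured override is strict too
  leaf$mode_t2 <- 50
  leaf$t2_values <- c(32.9, 33, rep(50, 8))
  lab <- classify_leaves(leaf, params_default)
  expect_identical(unname(lab[1L]), 1L)
  expect_identical(unname(lab[2L]), 2L)
})

test_that("raising the core threshold never increases core volume", {
  set.seed(37)
  vals <- c(rnorm(400, 50, 4), rnorm(400, 62, 4), rnorm(200, 75, 3))
  prev <- Inf
  for (thr in c(45, 56, 65, 80)) {
    p <- segmentation_params(core_mode_threshold = thr)
    lab <- classify_leaves(hierarchical_split(vals, params = p), p)
    n_core <- sum(lab == 3L)
    expect_lte(n_core, prev)
    prev <- n_core
  }
})

test_that("segment_lesion composes the pipeline and labels a partition", {
  sp <- small_phantom_spec(noise_sigma = 0, seed = 13)
  ph <- make_phantom(sp)
  map <- fit_t2_map(ph$volume, brain_mask = ph$lesion_mask)
  seg <- segment_lesion(map, ph$lesion_mask)
  # noiseless separable classes: labels equal ground truth voxel-for-voxel
  expect_identical(seg$labels[ph$lesion_mask],
                   ph$truth$labels[ph$lesion_mask])
  expect_true(all(seg$labels[!ph$lesion_mask] == 0L))
  # every masked valid voxel got exactly one nonzero label
  expect_true(all(seg$labels[ph$lesion_mask & map$valid] > 0L))
  counts <- table(factor(seg$labels, levels = 0:3))
  expect_identical(as.integer(sum(counts)), as.integer(prod(sp$grid_shape)))
})

test_that("a mask with no core voxels yields pure penumbra", {
  sp <- small_phantom_spec(noise_sigma = 0, seed = 13)
  ph <- make_phantom(sp)
  pen_only <- ph$truth$labels == 2L
  map <- fit_t2_map(ph$volume, brain_mask = pen_only)
  seg <- segment_lesion(map, pen_only)
  expect_true(all(seg$labels[pen_only] == 2L))
  expect_identical(sum(seg$labels == 3L), 0L)
})

test_that("degenerate segmentation inputs are rejected", {
  sp <- small_phantom_spec(noise_sigma = 0, seed = 13)
  ph <- make_phantom(sp)
  map <- fit_t2_map(ph$volume, brain_mask = ph$lesion_mask)
  expect_error(segment_lesion(map, array(FALSE, dim = sp$grid_shape)),
               "empty effective mask")
  expect_error(hierarchical_split(c(40, NA, 50)), "invalid")
  expect_error(segmentation_params(uninjured_t2_threshold = 60),
               "uninjured_t2_threshold")
})
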