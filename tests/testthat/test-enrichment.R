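# Marker enrichment profiles and the associated tests

test_that("profile arithmetic matches the hand-computed example", {
  D <- c(1000, 500, 250, 125, 75, 30, 20)
  M <- c(10, 10, 5, 2, 1, 1, 1)
  pr <- enrichment_profile(D, M)
  expect_equal(pr$expected[1], 0.5)
  expect_equal(pr$observed[1], 1 / 3)
  expect_equal(pr$enrichment[1], (1 / 3) / (1 / 2) - 1)
  expect_equal(sum(pr$expected), 1)
  expect_equal(sum(pr$observed), 1)
  expect_true(all(pr$enrichment >= -1))
})

test_that("proportional marker counts give zero enrichment everywhere", {
  D <- c(4000, 2000, 1200, 800, 400, 240, 80)
  M <- D / 40
  pr <- enrichment_profile(D, as.integer(M))
  expect_equal(pr$enrichment, rep(0, 7), tolerance = 1e-12)
  gt <- gof_test(pr)
  expect_equal(gt$statistic, 0)
  expect_equal(gt$p_value, 1)
})

test_that("marker confined to the top class has the closed-form profile", {
  D <- c(500, 400, 300, 200, 100, 60, 40)
  M <- c(0, 0, 0, 0, 0, 0, 64)
  pr <- enrichment_profile(D, M)
  expect_equal(pr$enrichment[7], sum(D) / D[7] - 1)
  expect_equal(pr$enrichment[1:6], rep(-1, 6))
})

test_that("gof statistic and p match the two-class worked example", {
  pr <- enrichment_profile(c(100, 100), c(70, 30))
  gt <- gof_test(pr)
  expect_equal(gt$statistic, 16)    # (20^2/50) + (20^2/50)
  expect_equal(gt$df, 1L)
  expect_equal(gt$p_value, 6.334e-5, tolerance = 1e-3)
})

test_that("profile errors and class dropping behave as specified", {
  expect_error(enrichment_profile(c(10, 10), c(0, 0)), "no marker")
  expect_warning(pr <- enrichment_profile(c(10, 0, 10), c(2, 0, 3)),
                 "zero region")
  expect_equal(nrow(pr), 2L)
  expect_error(gof_test(enrichment_profile(10, 5)), "at least 2")
})

test_that("masked-voxel path counts markers per class correctly", {
  sim <- suppressWarnings(
    gen_mitotic_stack(small_mitotic(seed = 41, noise = c(0, 0),
                                    n_marker_voxels = 3000L)))
  cm <- classify_voxels(sim$stack, "DAPI",
                        boundaries = sim$truth$boundaries)
  mm <- marker_mask(sim$stack, "NUP153")
  # recall 1.0 at the true punctum voxels in the noise-free stack
  expect_equal(mean(mm[unique(sim$truth$marker_positions)]), 1)
  pr <- enrichment_profile(cm, mm)
  expect_equal(attr(pr, "n_region"), prod(dim(sim$stack)))
  # the mask covers at least the punctum cores (blur halos may add)
  upos <- unique(sim$truth$marker_positions)
  expect_gte(sum(pr$M), length(upos))
})

test_that("marker mask separates clean bimodal puncta exactly", {
  a <- array(10, dim = c(12, 12, 4))
  idx <- cbind(c(3, 7, 9), c(4, 8, 2), c(2, 3, 4))
  a[idx] <- 200
  st <- image_stack(list(NUP153 = a), voxel_dims = c(100, 100, 200))
  mm <- marker_mask(st, "NUP153")
  expect_equal(sum(mm), 3L)
  expect_true(all(mm[idx]))
  cst <- image_stack(list(NUP153 = array(5, dim = c(6, 6, 2))),
                     voxel_dims = c(100, 100, 200))
  expect_error(marker_mask(cst, "NUP153"), "constant")
})

test_that("pairwise class test matches exact hypergeometric enumeration", {
  # 2x2 (M, D-M) = (8,2) vs (1,9)
  pr <- enrichment_profile(c(10, 10), c(8, 1))
  pt <- pairwise_class_test(pr, 1, 2)
  # independent oracle: two-sided Fisher p by dhyper enumeration
  x <- 0:9
  probs <- dhyper(x, 10, 10, 9)
  p_oracle <- sum(probs[probs <= dhyper(8, 10, 10, 9) * (1 + 1e-7)])
  expect_equal(pt$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(pt$p_value, 0.005477, tolerance = 1e-3)
})

test_that("identical densities give a non-significant pairwise test", {
  pr <- enrichment_profile(c(10000, 20000), c(500, 1000))
  pt <- pairwise_class_test(pr, 1, 2)
  expect_gt(pt$p_value, 0.9)
})

test_that("enrichment estimates recover generator weights over seeds", {
  # monotone response: raising a class weight raises its estimated
  # enrichment, and density ratios track the weights
  for (seed in c(51, 52)) {
    m <- suppressWarnings(gen_mitotic_stack(
      small_mitotic(seed = seed, class_weights = c(1, 2.5, 1, 1, 1, 1, 1),
                    voxel_dims = c(80, 80, 200),
                    n_marker_voxels = 50000L)))
    pr <- enrichment_profile(m$truth$D, m$truth$marker_counts)
    dens <- pr$M / pr$D
    expect_equal(dens[2] / dens[1], 2.5, tolerance = 0.15)
    expect_gt(pr$enrichment[2], 0)
  }
})

test_that("underflowing p-values are reported as a bound with the statistic", {
  D <- c(5e5, 5e5)
  M <- c(4e5, 1e5)
  gt <- gof_test(enrichment_profile(D, M))
  expect_equal(gt$p_label, "< 1e-300")
  expect_lt(gt$log10_p, -300)
  expect_true(is.finite(gt$statistic))
})
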