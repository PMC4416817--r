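# Nucleus segmentation, volume measurement, group comparison

test_that("volume is count times voxel volume, in cubic micrometres", {
  m <- array(FALSE, dim = c(20, 10, 10))
  m[1:10, 1:10, 1:10] <- TRUE   # 1000 voxels
  expect_equal(nuclear_volume(m, c(100, 100, 100)), 1.0)
  # anisotropic 3D-SIM voxels: 1e6 voxels of 39.5 x 39.5 x 125 nm
  v1e6 <- 1e6 * 39.5 * 39.5 * 125 * 1e-9
  m2 <- array(TRUE, dim = c(100, 100, 100))
  expect_equal(nuclear_volume(m2, c(39.5, 39.5, 125)), v1e6)
  expect_equal(round(v1e6, 1), 195.0)
  expect_error(nuclear_volume(array(FALSE, dim = c(3, 3, 3)),
                              c(100, 100, 100)), "empty")
})

test_that("digitized sphere volume is within 3% of the analytic value", {
  r <- 20
  d <- c(45, 45, 45)
  ctr <- (d + 1) / 2
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  m <- array((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2 <=
               r^2, dim = d)
  vol <- nuclear_volume(m, c(100, 100, 100))   # r = 2 um
  expect_lt(abs(vol - 4 / 3 * pi * 2^3) / (4 / 3 * pi * 2^3), 0.03)
})

test_that("volume is translation invariant and scales with voxel dims", {
  m <- array(FALSE, dim = c(20, 20, 20))
  m[3:8, 3:8, 3:8] <- TRUE
  m2 <- array(FALSE, dim = c(20, 20, 20))
  m2[10:15, 10:15, 10:15] <- TRUE
  expect_equal(nuclear_volume(m, c(50, 60, 70)),
               nuclear_volume(m2, c(50, 60, 70)))
  expect_equal(nuclear_volume(m, c(100, 60, 70)),
               2 * nuclear_volume(m, c(50, 60, 70)))
})

test_that("segmentation recovers the post-MGA truth mask", {
  # near-native lateral sampling: boundary discretisation dominates the
  # recovery error, so the check runs at 79 nm pixels
  sim <- gen_nucleus_stack(small_nucleus(seed = 21,
                                         phenotype = "post_mga",
                                         voxel_dims = c(79, 79, 250),
                                         noise = c(0, 0)))
  mask <- segment_nucleus(sim$stack, channel = "DAPI")
  truth <- sim$truth$nucleus_mask
  jac <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jac, 0.95)
  v <- nuclear_volume(mask, sim$stack)
  expect_lt(abs(v - sim$truth$volume_um3) / sim$truth$volume_um3, 0.05)
})

test_that("interior lacuna is hole-filled into the nucleus mask", {
  sim <- gen_nucleus_stack(small_nucleus(
    seed = 22, chromatin_contact_fraction = 1,
    lacuna_radius_fraction = 0.45, noise = c(0, 0)))
  mask <- segment_nucleus(sim$stack, channel = "DAPI")
  ctr <- round(dim(mask) / 2)
  # the DNA-void centre must still be inside the mask
  expect_true(mask[ctr[1], ctr[2], ctr[3]])
})

test_that("degenerate images raise segmentation errors", {
  z <- image_stack(list(DAPI = array(0, dim = c(10, 10, 5))),
                   voxel_dims = c(100, 100, 200))
  expect_error(segment_nucleus(z), "constant")
})

test_that("volume comparison: Welch tests with Bonferroni capping", {
  rec <- data.frame(stage = rep(c("a", "b"), each = 10),
                    volume = rep(c(100, 100), each = 10) +
                      rep(c(0.001, -0.001), 10))
  out <- volume_comparison(rec, list(c("a", "b")))
  expect_gt(out$p_raw, 0.95)
  expect_equal(out$p_adjusted, 1)

  set.seed(31)
  rec2 <- data.frame(stage = rep(c("large", "small"), each = 10),
                     volume = c(rnorm(10, 100, 5), rnorm(10, 50, 5)))
  out2 <- volume_comparison(rec2, list(c("large", "small")))
  expect_lt(out2$p_adjusted, 1e-6)

  set.seed(32)
  rec3 <- data.frame(stage = rep(c("a", "b", "c"), each = 6),
                     volume = c(rnorm(6, 100), rnorm(6, 101),
                                rnorm(6, 140)))
  out3 <- volume_comparison(rec3)
  expect_equal(nrow(out3), 3L)
  expect_equal(out3$p_adjusted,
               pmin(1, out3$p_raw * 3), tolerance = 1e-12)
  expect_true(all(out3$p_adjusted >= out3$p_raw))

  expect_error(volume_comparison(
    data.frame(stage = c("a", "b", "b"), volume = c(1, 2, 3)),
    list(c("a", "b"))), "fewer than 2")
})
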