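# Lamina shell, concordance, structure detection and censuses

test_that("shell voxel count approximates the analytic band volume", {
  # digitized sphere r = 2 um at isotropic 100 nm voxels
  d <- c(51, 51, 51)
  ctr <- (d + 1) / 2
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  r2 <- (g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2
  mask <- array(r2 <= 20^2, dim = d)
  dummy <- image_stack(list(DAPI = array(runif(prod(d)), dim = d),
                            NUP153 = array(runif(prod(d)), dim = d)),
                       voxel_dims = c(100, 100, 100))
  sh <- lamina_shell(mask, dummy, thickness_nm = 200)
  # analytic band sphere(r+t) - sphere(r-t); outside voxels measure
  # their distance to inside voxel centres, overestimating the distance
  # to the surface by about half a voxel (h/2 = 50 nm), which trims the
  # outer band edge accordingly on the discrete grid
  band_um3 <- 4 / 3 * pi * ((2 + 0.2 - 0.05)^3 - (2 - 0.2)^3)
  got_um3 <- sum(sh$shell) * 1e-3
  expect_lt(abs(got_um3 - band_um3) / band_um3, 0.10)
})

test_that("shell parameter errors: tiny mask, excessive thickness", {
  d <- c(10, 10, 10)
  st <- image_stack(list(DAPI = array(1 + runif(1000), dim = d),
                         NUP153 = array(1 + runif(1000), dim = d)),
                    voxel_dims = c(100, 100, 100))
  m1 <- array(FALSE, dim = d); m1[5, 5, 5] <- TRUE
  expect_error(lamina_shell(m1, st), "small")
  m2 <- array(FALSE, dim = d); m2[3:8, 3:8, 3:8] <- TRUE
  expect_error(lamina_shell(m2, st, thickness_nm = 5000), "radius")
})

test_that("pre-MGA contacted fraction tracks the generator setting", {
  sim <- gen_nucleus_stack(small_nucleus(seed = 61,
                                         chromatin_contact_fraction = 0.5))
  mask <- segment_nucleus(sim$stack, channel = "laminB")
  sh <- lamina_shell(mask, sim$stack, thickness_nm = 250)
  expect_lt(abs(mean(sh$contact[sh$boundary]) -
                  sim$truth$contact_fraction), 0.07)
})

test_that("concordance arithmetic matches the exact 2x2 oracle", {
  co <- rep(c(TRUE, FALSE), c(100, 100))
  np <- c(rep(TRUE, 90), rep(FALSE, 10), rep(TRUE, 5), rep(FALSE, 95))
  cc <- npc_chromatin_concordance(fake_shell(co, np))
  expect_equal(unname(cc$table[1, ]), c(90, 10))
  expect_equal(unname(cc$table[2, ]), c(5, 95))
  expect_equal(cc$odds_ratio, (90 * 95) / (10 * 5))
  expect_equal(cc$p_value,
               fisher.test(matrix(c(90, 10, 5, 95), 2,
                                  byrow = TRUE))$p.value)
  expect_lt(cc$p_value, 1e-15)
  expect_equal(cc$fraction_npc_noncontacted, 0.05)
})

test_that("degenerate contact tables are flagged, fractions reported", {
  cc <- npc_chromatin_concordance(
    fake_shell(rep(TRUE, 50), rep(c(TRUE, FALSE), 25)))
  expect_true(cc$degenerate)
  expect_true(is.na(cc$odds_ratio))
  expect_equal(cc$fraction_npc_contacted, 0.5)
})

test_that("haldane correction engages on zero cells", {
  cc <- npc_chromatin_concordance(
    fake_shell(rep(c(TRUE, FALSE), c(40, 40)),
               rep(c(TRUE, FALSE), c(40, 40))))
  expect_equal(cc$odds_ratio, (40.5 * 40.5) / (0.5 * 0.5))
})

test_that("structure detection recovers the generator layout exactly", {
  sim <- gen_nucleus_stack(structure_scene(seed = 62))
  mask <- segment_nucleus(sim$stack, channel = "laminB")
  sh <- lamina_shell(mask, sim$stack, thickness_nm = 250)
  st <- detect_structures(sim$stack, mask, sh)
  df <- as.data.frame(st)
  inv <- df[df$location == "invagination", ]
  expect_equal(nrow(inv), 6L)
  expect_equal(sum(df$location == "interior_vesicle"), 2L)
  ph <- sort(paste0(ifelse(inv$nup_pos, "N", ""),
                    ifelse(inv$lamin_pos, "L", "")))
  expect_equal(ph, c("L", "L", "N", "NL", "NL", "NL"))
  # detected invagination centroids match truth within ~0.5 um
  tr <- sim$truth$structures
  tr_inv <- tr[tr$location == "invagination", ]
  for (i in seq_len(nrow(inv))) {
    dd <- sqrt((tr_inv$x_um - inv$x_um[i])^2 +
                 (tr_inv$y_um - inv$y_um[i])^2 +
                 (tr_inv$z_um - inv$z_um[i])^2)
    expect_lt(min(dd), 0.6)
  }
})

test_that("interior ring not touching the shell is a vesicle", {
  d <- c(30, 30, 12)
  lam <- array(2, dim = d)
  mask <- array(FALSE, dim = d)
  mask[4:27, 4:27, 3:10] <- TRUE
  # hollow ring at the centre, well away from the boundary
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  rr <- sqrt((g$x - 15.5)^2 + (g$y - 15.5)^2)
  ring <- array(rr > 3 & rr < 5.5 & g$z >= 6 & g$z <= 7, dim = d)
  lam[ring] <- 150
  st <- image_stack(list(laminB = lam,
                         NUP153 = array(2, dim = d),
                         DAPI = array(2, dim = d)),
                    voxel_dims = c(100, 100, 250))
  sh <- lamina_shell(mask, st, thickness_nm = 250,
                     dapi_threshold = 10, nup_threshold = 10)
  det <- detect_structures(st, mask, sh, lamin_threshold = 10,
                           nup_threshold = 10)
  df <- as.data.frame(det)
  expect_equal(nrow(df), 1L)
  expect_equal(df$location, "interior_vesicle")
  expect_false(df$nup_pos)
})

test_that("empty marker channels yield an empty structure list", {
  d <- c(16, 16, 8)
  mask <- array(FALSE, dim = d); mask[4:13, 4:13, 3:6] <- TRUE
  st <- image_stack(list(laminB = array(2, dim = d),
                         NUP153 = array(2, dim = d),
                         DAPI = array(2, dim = d)),
                    voxel_dims = c(100, 100, 250))
  sh <- lamina_shell(mask, st, thickness_nm = 250, dapi_threshold = 10,
                     nup_threshold = 10)
  det <- detect_structures(st, mask, sh)
  expect_length(det, 0L)
  cen <- structure_census(det)
  expect_equal(cen$n_structures, 0L)
})

test_that("census reproduces the 62/16/12 percentage partition", {
  fx <- data.frame(
    location = "invagination",
    lamin_pos = rep(c(TRUE, TRUE, FALSE), c(62, 16, 12)),
    nup_pos = rep(c(TRUE, FALSE, TRUE), c(62, 16, 12)),
    nucleus = rep(1:90, length.out = 90))
  cen <- structure_census(fx)
  pct <- cen$invagination_percent
  expect_equal(unname(pct), c(62, 16, 12) / 90 * 100, tolerance = 1e-10)
  expect_equal(unname(round(pct)), c(69, 18, 13))
  expect_equal(sum(pct), 100)
  expect_equal(cen$n_structures, 90L)
})

test_that("single structure census is 100% its own type", {
  one <- data.frame(location = "invagination", lamin_pos = TRUE,
                    nup_pos = FALSE)
  cen <- structure_census(one)
  expect_equal(unname(cen$invagination_percent["NUP-/LAM+"]), 100)
})

test_that("extranuclear clusters classify dispersed vs proximal scenes", {
  for (mode in c("dispersed", "envelope_proximal")) {
    sim <- gen_nucleus_stack(small_nucleus(
      seed = 63, extranuclear_cluster_mode = mode, cluster_count = 12))
    mask <- segment_nucleus(sim$stack, channel = "laminB")
    cl <- extranuclear_clusters(sim$stack, mask)
    expect_equal(attr(cl, "classification"), mode)
    expect_true(all(cl$distance_um >= 0))
  }
  sim0 <- gen_nucleus_stack(small_nucleus(seed = 64,
                                          extranuclear_cluster_mode = "none"))
  mask0 <- segment_nucleus(sim0$stack, channel = "laminB")
  cl0 <- extranuclear_clusters(sim0$stack, mask0)
  expect_equal(nrow(cl0), 0L)
  expect_equal(attr(cl0, "classification"), "none")
})
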