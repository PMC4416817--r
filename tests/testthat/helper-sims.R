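# Shared fixture builders. All stacks use coarsened voxels so the suite
# stays fast; resolution-sensitive checks use the native 3D-SIM voxel
# size where it matters (see test-acceptance.R).

coarse_vox <- c(100, 100, 250)

small_nucleus <- function(seed = 1, phenotype = "pre_mga",
                          semi_axes_um = c(2, 1.8, 1.6),
                          voxel_dims = coarse_vox, ...) {
  nucleus_params(phenotype = phenotype, semi_axes_um = semi_axes_um,
                 voxel_dims = voxel_dims, seed = seed, ...)
}

# the three-immunophenotype invagination layout used throughout
inv_spec_321 <- data.frame(
  type = c("NUPpos_LAMpos", "NUPneg_LAMpos", "NUPpos_LAMneg"),
  count = c(3, 2, 1),
  depth_um = c(1.2, 1.0, 0.9))

structure_scene <- function(seed = 1) {
  nucleus_params(phenotype = "pre_mga", semi_axes_um = c(2.6, 2.3, 2.0),
                 voxel_dims = coarse_vox, seed = seed, noise = c(0, 0),
                 invagination_spec = inv_spec_321, vesicle_count = 2)
}

small_mitotic <- function(seed = 1, voxel_dims = c(150, 150, 400),
                          n_marker_voxels = 10000L, ...) {
  mitotic_params(plate_semi_axes_um = c(1.8, 1.8, 0.9), margin_um = 1,
                 voxel_dims = voxel_dims,
                 n_marker_voxels = n_marker_voxels, seed = seed, ...)
}

# single-intron toy gene: exons 1-200 and 801-1000, intron 201-800
toy_gene <- function() {
  gene_model("TOY", "chr1", 1, 1000,
             data.frame(start = c(1, 801), end = c(200, 1000)))
}

# two-gene set for aggregation tests
toy_genes2 <- function() {
  list(toy_gene(),
       gene_model("TOY2", "chr2", 101, 2100,
                  data.frame(start = c(101, 701, 1801),
                             end = c(400, 900, 2100))))
}

# independent brute-force refinement oracle for equal-variance cuts:
# coordinate descent over admissible cut positions minimising the CV of
# the per-class population variances directly (exhaustive per cut)
oracle_equal_variance_cuts <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  s1 <- c(0, cumsum(x)); s2 <- c(0, cumsum(x * x))
  sv <- function(i, ps) {
    m <- ps - i
    mu <- (s1[ps + 1] - s1[i + 1]) / m
    (s2[ps + 1] - s2[i + 1]) / m - mu * mu
  }
  vars_of <- function(cuts) {
    b <- c(0L, cuts, n)
    vapply(seq_len(k), function(i) sv(b[i], b[i + 1]), 0)
  }
  cv_of <- function(v) sqrt(sum((v - mean(v))^2) / k) / mean(v)
  cutpos <- which(diff(x) > 0)
  cuts <- cutpos[round(seq(1, length(cutpos), length.out = k + 1))][2:k]
  for (sweep in 1:200) {
    improved <- FALSE
    for (i in seq_len(k - 1)) {
      left <- if (i == 1) 0L else cuts[i - 1]
      right <- if (i == k - 1) n else cuts[i + 1]
      cand <- cutpos[cutpos > left & cutpos < right]
      if (length(cand) > 20000) {
        at <- findInterval(cuts[i], cand)
        cand <- cand[max(1, at - 10000):min(length(cand), at + 10000)]
      }
      v <- vars_of(cuts)
      vl <- sv(left, cand)
      vr <- sv(cand, right)
      others <- sum(v) - v[i] - v[i + 1]
      mu <- (vl + vr + others) / k
      ss <- (vl - mu)^2 + (vr - mu)^2
      for (j in setdiff(seq_len(k), c(i, i + 1)))
        ss <- ss + (v[j] - mu)^2
      best <- cand[which.min(sqrt(ss / k) / mu)]
      if (best != cuts[i]) { cuts[i] <- best; improved <- TRUE }
    }
    if (!improved) break
  }
  list(cuts = cuts, boundaries = c(x[1], (x[cuts] + x[cuts + 1]) / 2,
                                   x[n]),
       cv = cv_of(vars_of(cuts)))
}

# a hand-built shell_mask-like object for direct concordance arithmetic
fake_shell <- function(contact, npc) {
  n <- length(contact)
  structure(list(boundary = array(TRUE, dim = c(n, 1, 1)),
                 contact = array(contact, dim = c(n, 1, 1)),
                 npc = array(npc, dim = c(n, 1, 1))),
            class = "shell_mask")
}
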