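#' Parameters for the synthetic mitotic-plate generator
#'
#' Describes a mitotic chromatin plate (metaphase plate / anaphase
#' rosette) rendered as a DNA-stain channel with a radial intensity
#' gradient, plus a marker channel whose puncta are placed with
#' controlled per-intensity-class densities. The class system is the
#' seven-class equal-variance partition; `class_weights[c]` scales the
#' probability that a marker punctum lands in a voxel of class `c`
#' relative to class 1 (background/cytoplasm), so the all-ones vector is
#' the proportional (random placement) null.
#'
#' @param n_chromatids number of chromatid lobes modulating the plate
#'   azimuthally (cosmetic texture; 0 for a smooth plate).
#' @param plate_semi_axes_um semi-axes of the plate ellipsoid (um).
#' @param density_gradient list with `amplitude`, `gamma` (radial decay
#'   exponent of the noise-free intensity profile
#'   `background + amplitude * (1 - rho^2)^gamma`) and `background`.
#' @param class_weights strictly positive length-7 vector of marker
#'   placement density per intensity class, relative to class 1.
#' @param n_marker_voxels number of marker punctum draws (multinomial
#'   over classes, voxel positions uniform within a class).
#' @param margin_um cytoplasm margin around the plate.
#' @param psf_fwhm_nm,noise,voxel_dims,seed as in [nucleus_params()].
#' @return a validated `mitotic_params` list.
#' @export
mitotic_params <- function(n_chromatids = 12,
                           plate_semi_axes_um = c(3, 3, 1.2),
                           density_gradient = list(amplitude = 100,
                                                   gamma = 1.5,
                                                   background = 2),
                           class_weights = rep(1, 7),
                           n_marker_voxels = 20000L,
                           margin_um = 1,
                           psf_fwhm_nm = c(130, 300),
                           noise = c(poisson_scale = 30, gaussian_sd = 1),
                           voxel_dims = c(39.5, 39.5, 125),
                           seed = 1L) {
  class_weights <- as.numeric(class_weights)
  if (length(class_weights) != 7L || any(class_weights <= 0))
    stop("parameter error: class_weights must be 7 strictly positive values")
  n_marker_voxels <- as.integer(n_marker_voxels)
  if (is.na(n_marker_voxels) || n_marker_voxels < 1L)
    stop("parameter error: n_marker_voxels must be at least 1")
  if (any(as.numeric(plate_semi_axes_um) <= 0))
    stop("parameter error: plate semi-axes must be positive")
  if (any(as.numeric(voxel_dims) <= 0))
    stop("parameter error: voxel_dims must be positive")
  structure(list(n_chromatids = as.integer(n_chromatids),
                 plate_semi_axes_um = as.numeric(plate_semi_axes_um),
                 density_gradient = density_gradient,
                 class_weights = class_weights,
                 n_marker_voxels = n_marker_voxels,
                 margin_um = margin_um,
                 psf_fwhm_nm = as.numeric(psf_fwhm_nm),
                 noise = as.numeric(noise),
                 voxel_dims = as.numeric(voxel_dims),
                 seed = as.integer(seed)),
            class = "mitotic_params")
}

#' Generate a ground-truthed synthetic mitotic stack
#'
#' Renders the DNA-stain plate, fits the seven-class equal-variance
#' partition on the noise-free channel to obtain the truth class map,
#' draws marker puncta multinomially with per-class probability
#' proportional to `class_weights[c] * D_c` (where `D_c` is the voxel
#' count of class `c`), renders them into the marker channel and applies
#' point-spread blur and noise.
#'
#' @param params a [mitotic_params()] object.
#' @return list of class `mitotic_sim` with `stack` (channels `DAPI`,
#'   `NUP153`) and `truth`: `class_map` (integer array), `boundaries`
#'   (the `class_boundaries` fit), `D` (per-class voxel counts),
#'   `marker_counts` (per-class punctum draw counts `M_c`),
#'   `marker_positions` (voxel indices, one row per draw) and
#'   `class_weights`.
#' @export
gen_mitotic_stack <- function(params) {
  p <- if (inherits(params, "mitotic_params")) params
       else do.call(mitotic_params, params)
  vd <- p$voxel_dims
  ax_nm <- p$plate_semi_axes_um * 1000
  extent_nm <- 2 * ax_nm + 2 * p$margin_um * 1000
  dims <- pmax(as.integer(ceiling(extent_nm / vd)), 8L)
  ctr <- (dims - 1) / 2 * vd
  n_vox <- prod(dims)
  if (p$n_marker_voxels > n_vox)
    stop("parameter error: n_marker_voxels exceeds available voxels")

  qx <- ((0:(dims[1] - 1)) * vd[1] - ctr[1]) / ax_nm[1]
  qy <- ((0:(dims[2] - 1)) * vd[2] - ctr[2]) / ax_nm[2]
  qz <- ((0:(dims[3] - 1)) * vd[3] - ctr[3]) / ax_nm[3]
  rho2 <- outer(outer(qx^2, qy^2, "+"), qz^2, "+")
  g <- p$density_gradient
  dapi <- array(g$background, dim = dims)
  inside <- rho2 < 1
  prof <- (1 - rho2[inside])^g$gamma
  if (p$n_chromatids > 0) {
    phi <- outer(qx, qy, function(a, b) atan2(b, a))
    mod <- 1 + 0.15 * cos(p$n_chromatids * phi)
    mod3 <- array(rep(mod, dims[3]), dim = dims)
    prof <- prof * mod3[inside]
  }
  dapi[inside] <- g$background + g$amplitude * prof

  # chromatid-scale intensity texture plus a smooth cytoplasmic
  # autofluorescence haze (substream 1); the haze keeps the background
  # class from being a degenerate constant plateau
  dapi <- with_seed(substream(p$seed, 1L), {
    f <- array(stats::rnorm(n_vox), dim = dims)
    f <- blur_gaussian3d(f, c(300 / vd[1], 300 / vd[2], 300 / vd[3]))
    f <- (f - mean(f)) / stats::sd(f)
    out <- dapi
    out[inside] <- out[inside] * (1 + 0.1 * f[inside])
    out <- out + 0.5 * stats::pnorm(f)
    pmax(out, 0)
  })

  # noise-free rendered channel defines the truth classes
  sig_vox <- c(p$psf_fwhm_nm[1] / 2.3548 / vd[1],
               p$psf_fwhm_nm[1] / 2.3548 / vd[2],
               p$psf_fwhm_nm[2] / 2.3548 / vd[3])
  dapi_nf <- if (any(sig_vox > 0)) blur_gaussian3d(dapi, sig_vox) else dapi
  fit <- fit_class_boundaries(dapi_nf, k = 7L, tol = 1e-3)
  class_map <- array(predict(fit, as.vector(dapi_nf)), dim = dims)
  D <- tabulate(class_map, nbins = 7L)

  # multinomial marker draws over classes, uniform voxel within class
  # (substream 2)
  probs <- p$class_weights * D
  probs <- probs / sum(probs)
  sim <- with_seed(substream(p$seed, 2L), {
    M <- as.vector(stats::rmultinom(1, p$n_marker_voxels, probs))
    pos <- vector("list", 7L)
    for (cc in 1:7) {
      if (M[cc] == 0L) next
      vox_c <- which(class_map == cc)
      pos[[cc]] <- vox_c[sample.int(length(vox_c), M[cc], replace = TRUE)]
    }
    list(M = M, pos = unlist(pos))
  })

  # puncta are rendered as single-voxel impulses; compensate the
  # point-spread attenuation so an isolated punctum peaks near 150
  # intensity units regardless of the grid
  atten <- prod(pmax(1, sqrt(2 * pi) * sig_vox))
  nup <- array(g$background, dim = dims)
  upos <- unique(sim$pos)
  nup[upos] <- nup[upos] + 150 * atten

  ch <- list(DAPI = dapi, NUP153 = nup)
  ch <- apply_psf_noise(ch, c(p, list()))   # uses psf/noise/seed fields

  truth <- list(class_map = class_map, boundaries = fit, D = D,
                marker_counts = sim$M, marker_positions = sim$pos,
                class_weights = p$class_weights)
  structure(list(stack = image_stack(ch, voxel_dims = vd), truth = truth,
                 params = p),
            class = "mitotic_sim")
}

#' @export
print.mitotic_sim <- function(x, ...) {
  cat("Synthetic mitotic plate:", paste(dim(x$stack)[1:3],
                                        collapse = " x "),
      "voxels;", sum(x$truth$marker_counts), "marker draws over 7",
      "intensity classes\n")
  cat("  true per-class draw counts:",
      paste(x$truth$marker_counts, collapse = ", "), "\n")
  invisible(x)
}
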