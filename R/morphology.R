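# 3-D morphology built on an exact anisotropic Euclidean distance
# transform (src/morph3d.cpp). All radii/thicknesses are physical (nm),
# so anisotropic voxels are handled uniformly.

edt_nm <- function(src, voxel_dims) {
  d <- dim(src)
  if (is.null(d) || length(d) != 3L) stop("expected a 3-D array")
  if (!any(src)) return(array(sqrt(1e30), dim = d))
  array(cpp_edt3d(as.logical(src), as.integer(d), as.numeric(voxel_dims)),
        dim = d)
}

label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  array(cpp_label3d(as.logical(mask), as.integer(d),
                    as.integer(connectivity)), dim = d)
}

dilate_nm <- function(mask, r_nm, voxel_dims) {
  if (r_nm <= 0) return(mask)
  edt_nm(mask, voxel_dims) <= r_nm
}

erode_nm <- function(mask, r_nm, voxel_dims) {
  if (r_nm <= 0) return(mask)
  mask & (edt_nm(!mask, voxel_dims) > r_nm)
}

close_nm <- function(mask, r_nm, voxel_dims) {
  erode_nm(dilate_nm(mask, r_nm, voxel_dims), r_nm, voxel_dims)
}

#' Fill interior cavities of a 3-D mask
#'
#' Background components (6-connected) that do not touch the array
#' border are cavities and become foreground. This is what keeps the
#' DNA-void interior lacuna of a peripheral-chromatin nucleus inside its
#' segmentation mask.
#' @noRd
fill_holes3d <- function(mask) {
  d <- dim(mask)
  bg <- label_components(!mask, connectivity = 6L)
  border_labels <- unique(c(bg[1, , ], bg[d[1], , ],
                            bg[, 1, ], bg[, d[2], ],
                            bg[, , 1], bg[, , d[3]]))
  border_labels <- border_labels[border_labels != 0L]
  mask | (bg != 0L & !(bg %in% border_labels))
}

largest_component <- function(mask, connectivity = 26L) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) stop("empty mask: no components")
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

# separable Gaussian blur with per-axis sigma in voxels; edges handled by
# normalised convolution (no darkening at borders)
blur_gaussian3d <- function(a, sigma_vox) {
  stopifnot(length(dim(a)) == 3L, length(sigma_vox) == 3L)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, axis)
  }
  a
}

# convolve along one axis with kernel k (odd length), normalising by the
# convolved all-ones array so truncated kernels at the edges keep unit mass
conv_axis <- function(a, k, axis) {
  d <- dim(a)
  r <- (length(k) - 1L) %/% 2L
  out <- array(0, dim = d)
  wt <- array(0, dim = d)
  n <- d[axis]
  for (off in -r:r) {
    w <- k[off + r + 1L]
    src <- seq_len(n) - off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    dst_idx <- which(keep)
    src_idx <- src[keep]
    if (axis == 1L) {
      out[dst_idx, , ] <- out[dst_idx, , ] + w * a[src_idx, , ]
      wt[dst_idx, , ] <- wt[dst_idx, , ] + w
    } else if (axis == 2L) {
      out[, dst_idx, ] <- out[, dst_idx, ] + w * a[, src_idx, ]
      wt[, dst_idx, ] <- wt[, dst_idx, ] + w
    } else {
      out[, , dst_idx] <- out[, , dst_idx] + w * a[, , src_idx]
      wt[, , dst_idx] <- wt[, , dst_idx] + w
    }
  }
  out / wt
}
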