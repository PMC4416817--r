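#' Parameters for the synthetic nucleus generator
#'
#' Describes one ellipsoidal nucleus to be rendered as a three-channel
#' (DAPI / lamin B / NUP153) 3-D stack, in one of two phenotypes:
#'
#' * `"pre_mga"`: peripheral chromatin restricted to the fraction of the
#'   envelope it contacts, a DNA-void interior lacuna, and (with
#'   `npc_conditional = TRUE`, the default for this phenotype) nuclear
#'   pore puncta placed only on the chromatin-contacted surface.
#' * `"post_mga"`: a uniform chromatin rim contacting the whole envelope
#'   and uniformly distributed pore puncta.
#'
#' @param phenotype `"pre_mga"` or `"post_mga"`.
#' @param semi_axes_um ellipsoid semi-axes (a, b, c) in micrometres.
#' @param margin_um cytoplasm margin around the ellipsoid (>= 2 um so
#'   extranuclear structures fit in the grid).
#' @param lacuna_radius_fraction radius of the guaranteed DNA-void
#'   interior (fraction of the semi-axes), pre-MGA phenotype.
#' @param chromatin_contact_fraction fraction of the envelope surface
#'   contacted by chromatin (pre-MGA; post-MGA uses 1).
#' @param rim_thickness_nm physical thickness of the chromatin rim.
#' @param npc_density pore puncta per um^2 of (contacted) surface.
#' @param npc_conditional place puncta only on chromatin-contacted
#'   surface; defaults to `TRUE` for pre-MGA, `FALSE` for post-MGA.
#' @param invagination_spec data frame with columns `type` (one of
#'   `"NUPpos_LAMpos"`, `"NUPneg_LAMpos"`, `"NUPpos_LAMneg"`), `count`
#'   and `depth_um`; `NULL` for none.
#' @param invagination_radius_nm tube radius of rendered invaginations.
#' @param vesicle_count number of interior vesicles (disconnected from
#'   the envelope).
#' @param vesicle_type immunophenotype of interior vesicles (default
#'   lamin-only, the dominant type seen inside nuclei).
#' @param extranuclear_cluster_mode `"none"`, `"dispersed"` (cytoplasmic
#'   clusters well away from the envelope) or `"envelope_proximal"`.
#' @param cluster_count number of extranuclear marker clusters.
#' @param psf_fwhm_nm point-spread FWHM (lateral, axial) in nm; the
#'   default 130/300 nm approximates 3D-SIM resolution.
#' @param noise length-2 numeric `(poisson_scale, gaussian_sd)`; Poisson
#'   noise is applied as counts at `poisson_scale` photons per intensity
#'   unit (0 disables), then additive Gaussian read noise. The default
#'   30 photons per unit (~3000 at signal peaks, ~2% shot noise)
#'   reflects the high signal-to-noise of reconstructed 3D-SIM data.
#' @param voxel_dims voxel edge lengths (dx, dy, dz) in nm.
#' @param seed master seed; every stochastic component draws from its
#'   own substream (order: chromatin texture, pore puncta,
#'   invaginations, vesicles, clusters, noise), so identical parameters
#'   and seed give bit-identical stacks.
#' @return a validated `nucleus_params` list.
#' @export
nucleus_params <- function(phenotype = c("pre_mga", "post_mga"),
                           semi_axes_um = c(2.5, 2.2, 2.0),
                           margin_um = 2,
                           lacuna_radius_fraction = 0.45,
                           chromatin_contact_fraction = 0.5,
                           rim_thickness_nm = 400,
                           npc_density = 8,
                           npc_conditional = NULL,
                           invagination_spec = NULL,
                           invagination_radius_nm = 150,
                           vesicle_count = 0,
                           vesicle_type = "NUPneg_LAMpos",
                           extranuclear_cluster_mode = c("none", "dispersed",
                                                         "envelope_proximal"),
                           cluster_count = 30,
                           psf_fwhm_nm = c(130, 300),
                           noise = c(poisson_scale = 30, gaussian_sd = 1),
                           voxel_dims = c(39.5, 39.5, 125),
                           seed = 1L) {
  phenotype <- match.arg(phenotype)
  extranuclear_cluster_mode <- match.arg(extranuclear_cluster_mode)
  semi_axes_um <- as.numeric(semi_axes_um)
  if (length(semi_axes_um) != 3L || any(semi_axes_um <= 0))
    stop("parameter error: semi-axes must be three positive lengths (um)")
  if (lacuna_radius_fraction < 0 || lacuna_radius_fraction > 1 ||
      chromatin_contact_fraction < 0 || chromatin_contact_fraction > 1)
    stop("parameter error: fractions must lie in [0, 1]")
  if (any(as.numeric(voxel_dims) <= 0))
    stop("parameter error: voxel_dims must be positive")
  if (margin_um < 2)
    stop("parameter error: cytoplasm margin must be at least 2 um")
  if (vesicle_count < 0 || cluster_count < 0)
    stop("parameter error: counts must be non-negative")
  if (!is.null(invagination_spec)) {
    invagination_spec <- as.data.frame(invagination_spec)
    stopifnot(all(c("type", "count", "depth_um") %in%
                    names(invagination_spec)))
    ok_types <- c("NUPpos_LAMpos", "NUPneg_LAMpos", "NUPpos_LAMneg")
    if (!all(invagination_spec$type %in% ok_types))
      stop("parameter error: unknown invagination type")
    if (any(invagination_spec$count < 0))
      stop("parameter error: negative invagination count")
    if (any(invagination_spec$depth_um * 1000 >= min(semi_axes_um) * 1000))
      stop("parameter error: invagination depth exceeds the smallest ",
           "semi-axis")
  }
  if (is.null(npc_conditional))
    npc_conditional <- phenotype == "pre_mga"
  if (phenotype == "post_mga") chromatin_contact_fraction <- 1
  structure(list(phenotype = phenotype, semi_axes_um = semi_axes_um,
                 margin_um = margin_um,
                 lacuna_radius_fraction = lacuna_radius_fraction,
                 chromatin_contact_fraction = chromatin_contact_fraction,
                 rim_thickness_nm = rim_thickness_nm,
                 npc_density = npc_density,
                 npc_conditional = npc_conditional,
                 invagination_spec = invagination_spec,
                 invagination_radius_nm = invagination_radius_nm,
                 vesicle_count = as.integer(vesicle_count),
                 vesicle_type = vesicle_type,
                 extranuclear_cluster_mode = extranuclear_cluster_mode,
                 cluster_count = as.integer(cluster_count),
                 psf_fwhm_nm = as.numeric(psf_fwhm_nm),
                 noise = as.numeric(noise),
                 voxel_dims = as.numeric(voxel_dims),
                 seed = as.integer(seed)),
            class = "nucleus_params")
}

# Thomsen approximation of the ellipsoid surface area (um^2)
ellipsoid_area_um2 <- function(ax) {
  p <- 1.6075
  4 * pi * ((ax[1]^p * ax[2]^p + ax[1]^p * ax[3]^p +
               ax[2]^p * ax[3]^p) / 3)^(1 / p)
}

# area-weighted sampling of n directions on the unit sphere mapped to an
# ellipsoid surface; optionally restricted to the polar cap u3 >= tau
sample_surface_dirs <- function(n, ax, tau = -1) {
  if (n == 0L) return(matrix(numeric(0), ncol = 3))
  wmax <- max(ax[2] * ax[3], ax[1] * ax[3], ax[1] * ax[2])
  out <- matrix(NA_real_, nrow = n, ncol = 3)
  got <- 0L
  while (got < n) {
    m <- max(64L, 2L * (n - got))
    u <- matrix(stats::rnorm(3 * m), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    w <- sqrt((u[, 1] * ax[2] * ax[3])^2 + (u[, 2] * ax[1] * ax[3])^2 +
                (u[, 3] * ax[1] * ax[2])^2)
    keep <- stats::runif(m) < w / wmax & u[, 3] >= tau
    u <- u[keep, , drop = FALSE]
    take <- min(nrow(u), n - got)
    if (take > 0) {
      out[(got + 1L):(got + take), ] <- u[seq_len(take), , drop = FALSE]
      got <- got + take
    }
  }
  out
}

# punctum rendering radius: the physical punctum size, but never so
# small that a punctum could fall between voxel centres on a coarse grid
punctum_radius_nm <- function(vd, r_phys = 120) {
  max(r_phys, 0.72 * max(vd))
}

# render a solid tube (capsule) of radius r around segment p0->p1 into
# `a` (amplitude added); all coordinates in nm; computed on a local
# bounding box only
render_capsule <- function(a, p0, p1, r, vd, amp) {
  d <- dim(a)
  lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
  i0 <- pmax(floor(lo / vd) + 1L, 1L)
  i1 <- pmin(ceiling(hi / vd) + 1L, d)
  xs <- (i0[1]:i1[1] - 1L) * vd[1]
  ys <- (i0[2]:i1[2] - 1L) * vd[2]
  zs <- (i0[3]:i1[3] - 1L) * vd[3]
  g <- expand.grid(x = xs, y = ys, z = zs)
  v <- p1 - p0
  L2 <- sum(v^2)
  w <- cbind(g$x - p0[1], g$y - p0[2], g$z - p0[3])
  t <- if (L2 > 0) pmin(pmax((w %*% v) / L2, 0), 1) else rep(0, nrow(w))
  dx <- w - t %*% t(v)
  inside <- rowSums(dx^2) <= r^2
  if (!any(inside)) return(a)
  sub <- a[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3], drop = FALSE]
  sub[inside] <- sub[inside] + amp
  a[i0[1]:i1[1], i0[2]:i1[2], i0[3]:i1[3]] <- sub
  a
}

apply_psf_noise <- function(ch, p) {
  sig_vox <- c(p$psf_fwhm_nm[1] / 2.3548 / p$voxel_dims[1],
               p$psf_fwhm_nm[1] / 2.3548 / p$voxel_dims[2],
               p$psf_fwhm_nm[2] / 2.3548 / p$voxel_dims[3])
  for (nm in names(ch)) {
    if (any(sig_vox > 0)) ch[[nm]] <- blur_gaussian3d(ch[[nm]], sig_vox)
  }
  with_seed(substream(p$seed, 6L), {
    for (nm in names(ch)) {
      a <- ch[[nm]]
      if (p$noise[1] > 0) {
        a <- array(stats::rpois(length(a), pmax(a, 0) * p$noise[1]) /
                     p$noise[1], dim = dim(a))
      }
      if (p$noise[2] > 0) {
        a <- a + array(stats::rnorm(length(a), 0, p$noise[2]),
                       dim = dim(a))
        a[a < 0] <- 0
      }
      ch[[nm]] <- a
    }
  })
  ch
}

#' Generate a ground-truthed synthetic nucleus stack
#'
#' Renders the three-channel nucleus described by a [nucleus_params()]
#' object and returns the stack together with the exact ground truth
#' (masks, punctum centres, structure table, cluster centres) recorded
#' before the point-spread blur and noise are applied.
#'
#' @param params a [nucleus_params()] object.
#' @return list of class `nucleus_sim` with elements `stack`
#'   ([image_stack()]) and `truth` (see Details).
#' @details The `truth` element holds: `nucleus_mask` (noise-free
#'   ellipsoid mask), `chromatin_mask`, `contact_tau` (polar-cap
#'   threshold defining the contacted surface in direction space),
#'   `contact_fraction` (realised fraction of boundary voxels
#'   contacted), `npc_centers_um` and `npc_dirs` (punctum centres and
#'   surface directions), `structures` (data frame: id, location, type,
#'   depth/size, centre), `cluster_centers_um`, `cluster_mode`, and
#'   `volume_um3` of the true ellipsoid mask.
#' @export
gen_nucleus_stack <- function(params) {
  p <- if (inherits(params, "nucleus_params")) params
       else do.call(nucleus_params, params)
  vd <- p$voxel_dims
  ax_nm <- p$semi_axes_um * 1000
  extent_nm <- 2 * ax_nm + 2 * p$margin_um * 1000
  dims <- pmax(as.integer(ceiling(extent_nm / vd)), 8L)
  ctr <- (dims - 1) / 2 * vd
  if (prod(dims) > 2.5e8) stop("grid too large; coarsen voxel_dims")

  qx <- ((0:(dims[1] - 1)) * vd[1] - ctr[1]) / ax_nm[1]
  qy <- ((0:(dims[2] - 1)) * vd[2] - ctr[2]) / ax_nm[2]
  qz <- ((0:(dims[3] - 1)) * vd[3] - ctr[3]) / ax_nm[3]
  rho2 <- outer(outer(qx^2, qy^2, "+"), qz^2, "+")
  nucleus <- rho2 <= 1
  if (!any(nucleus)) stop("parameter error: zero-volume ellipsoid on grid")
  rho <- sqrt(rho2)
  uz <- array(rep(qz, each = dims[1] * dims[2]), dim = dims) /
    pmax(rho, 1e-9)

  dist_in <- edt_nm(!nucleus, vd)       # distance to exterior (inside)
  tau <- 1 - 2 * p$chromatin_contact_fraction

  bg <- 2
  amp_dapi <- 100; amp_lam <- 120; amp_npc <- 150
  dapi <- array(bg, dim = dims)
  lam <- array(bg, dim = dims)
  nup <- array(bg, dim = dims)

  # chromatin rim with a smooth random texture (substream 1)
  rim <- nucleus & dist_in <= p$rim_thickness_nm &
    rho >= p$lacuna_radius_fraction
  if (p$phenotype == "pre_mga") rim <- rim & uz >= tau
  tex <- with_seed(substream(p$seed, 1L), {
    f <- array(stats::rnorm(prod(dims)), dim = dims)
    f <- blur_gaussian3d(f, c(250 / vd[1], 250 / vd[2], 250 / vd[3]))
    f <- (f - mean(f)) / stats::sd(f)
    0.6 + 0.8 * stats::pnorm(1.5 * f)
  })
  dapi[rim] <- dapi[rim] + amp_dapi * tex[rim]

  # lamina: thin uniform band beneath the envelope; never thinner than
  # one voxel on the coarsest axis, so the rendered envelope is closed
  lam_band <- nucleus & dist_in <= max(150, 1.05 * max(vd))
  lam[lam_band] <- lam[lam_band] + amp_lam

  # NPC puncta (substream 2)
  area <- ellipsoid_area_um2(p$semi_axes_um)
  area_target <- if (p$npc_conditional)
    area * p$chromatin_contact_fraction else area
  n_npc <- max(0L, round(p$npc_density * area_target))
  npc_dirs <- with_seed(substream(p$seed, 2L),
                        sample_surface_dirs(n_npc, p$semi_axes_um,
                                            tau = if (p$npc_conditional)
                                              tau else -1))
  npc_nm <- sweep(npc_dirs, 2, ax_nm, "*") +
    matrix(ctr, nrow = nrow(npc_dirs), ncol = 3, byrow = TRUE)
  r_punct <- punctum_radius_nm(vd)
  for (i in seq_len(nrow(npc_nm)))
    nup <- render_capsule(nup, npc_nm[i, ], npc_nm[i, ], r_punct, vd,
                          amp_npc)

  # invaginations (substream 3): tubes from the surface inward
  structures <- data.frame(id = integer(0), location = character(0),
                           type = character(0), depth_um = numeric(0),
                           x_um = numeric(0), y_um = numeric(0),
                           z_um = numeric(0))
  inv_segments <- list()
  if (!is.null(p$invagination_spec) && sum(p$invagination_spec$count) > 0) {
    spec <- p$invagination_spec
    types <- rep(spec$type, spec$count)
    depths <- rep(spec$depth_um, spec$count) * 1000
    n_inv <- length(types)
    # whole tubes (not just their surface anchors) must stay disjoint,
    # or two deep invaginations converging towards the centre would
    # merge into one component and break the truth-count invariant
    segseg_dist <- function(a0, a1, b0, b1) {
      best <- Inf
      for (t in seq(0, 1, length.out = 9L)) {
        q <- a0 + t * (a1 - a0)
        v <- b1 - b0; L2 <- sum(v^2)
        u <- if (L2 > 0) min(max(sum((q - b0) * v) / L2, 0), 1) else 0
        best <- min(best, sqrt(sum((b0 + u * v - q)^2)))
      }
      best
    }
    segs <- with_seed(substream(p$seed, 3L), {
      acc <- list()
      tries <- 0L
      clearance <- 2 * p$invagination_radius_nm + 500
      while (length(acc) < n_inv && tries < 10000L) {
        tries <- tries + 1L
        i <- length(acc) + 1L
        cand <- as.vector(sample_surface_dirs(1L, p$semi_axes_um))
        q0 <- cand * ax_nm + ctr
        inw <- -cand * ax_nm
        inw <- inw / sqrt(sum(inw^2))
        q1 <- q0 + inw * depths[i]
        ok <- TRUE
        for (sg in acc)
          if (segseg_dist(q0, q1, sg$p0, sg$p1) < clearance) {
            ok <- FALSE; break
          }
        if (ok) acc[[i]] <- list(p0 = q0, p1 = q1, inward = inw)
      }
      if (length(acc) < n_inv)
        stop("could not place invaginations with the required separation")
      acc
    })
    for (i in seq_len(n_inv)) {
      p0 <- segs[[i]]$p0
      inward <- segs[[i]]$inward
      p_out <- p0 - inward * 300          # protrude slightly outside
      p1 <- segs[[i]]$p1
      # double-membrane fold: two apposed lamina layers, twice the
      # rim amplitude (also offsets thin-tube blur attenuation)
      if (types[i] %in% c("NUPpos_LAMpos", "NUPneg_LAMpos"))
        lam <- render_capsule(lam, p_out, p1, p$invagination_radius_nm,
                              vd, 2 * amp_lam)
      if (types[i] %in% c("NUPpos_LAMpos", "NUPpos_LAMneg"))
        nup <- render_capsule(nup, p_out, p1, p$invagination_radius_nm,
                              vd, amp_npc)
      inv_segments[[length(inv_segments) + 1L]] <- list(p0 = p0, p1 = p1)
      mid <- (p0 + p1) / 2
      structures <- rbind(structures, data.frame(
        id = i, location = "invagination", type = types[i],
        depth_um = depths[i] / 1000,
        x_um = mid[1] / 1000, y_um = mid[2] / 1000, z_um = mid[3] / 1000))
    }
  }

  # interior vesicles (substream 4): spheres well inside the nucleus,
  # kept clear of every invagination tube so components stay disjoint
  if (p$vesicle_count > 0) {
    ves_r <- 250
    seg_dist <- function(pt, a, b) {
      v <- b - a; L2 <- sum(v^2)
      t <- if (L2 > 0) min(max(sum((pt - a) * v) / L2, 0), 1) else 0
      sqrt(sum((a + t * v - pt)^2))
    }
    clear_of_tubes <- function(pt) {
      if (!length(inv_segments)) return(TRUE)
      for (sg in inv_segments)
        if (seg_dist(pt, sg$p0, sg$p1) <
            ves_r + p$invagination_radius_nm + 350) return(FALSE)
      TRUE
    }
    centers <- with_seed(substream(p$seed, 4L), {
      acc <- matrix(numeric(0), ncol = 3)
      tries <- 0L
      while (nrow(acc) < p$vesicle_count && tries < 5000L) {
        tries <- tries + 1L
        cand <- stats::rnorm(3)
        cand <- cand / sqrt(sum(cand^2)) * stats::runif(1)^(1 / 3) * 0.5
        pt <- cand * ax_nm + ctr
        if ((nrow(acc) == 0 ||
             min(sqrt(rowSums(sweep(acc, 2, pt)^2))) > 4 * ves_r) &&
            clear_of_tubes(pt))
          acc <- rbind(acc, matrix(pt, 1))
      }
      if (nrow(acc) < p$vesicle_count)
        stop("could not place vesicles clear of invaginations")
      acc
    })
    for (i in seq_len(nrow(centers))) {
      ci <- centers[i, ]
      if (p$vesicle_type %in% c("NUPpos_LAMpos", "NUPneg_LAMpos"))
        lam <- render_capsule(lam, ci, ci, ves_r, vd, amp_lam)
      if (p$vesicle_type %in% c("NUPpos_LAMpos", "NUPpos_LAMneg"))
        nup <- render_capsule(nup, ci, ci, ves_r, vd, amp_npc)
      structures <- rbind(structures, data.frame(
        id = nrow(structures) + 1L, location = "interior_vesicle",
        type = p$vesicle_type, depth_um = NA_real_,
        x_um = ci[1] / 1000, y_um = ci[2] / 1000, z_um = ci[3] / 1000))
    }
  }

  # extranuclear marker clusters (substream 5)
  cluster_centers <- matrix(numeric(0), ncol = 3)
  if (p$extranuclear_cluster_mode != "none" && p$cluster_count > 0) {
    clus_r <- 200
    dist_rng <- if (p$extranuclear_cluster_mode == "dispersed")
      c(800, max(900, p$margin_um * 1000 - 500)) else c(350, 480)
    cluster_centers <- with_seed(substream(p$seed, 5L), {
      dirs <- sample_surface_dirs(p$cluster_count, p$semi_axes_um)
      dd <- stats::runif(p$cluster_count, dist_rng[1], dist_rng[2])
      surf <- sweep(dirs, 2, ax_nm, "*")
      outward <- surf / sqrt(rowSums(surf^2))
      surf + outward * dd +
        matrix(ctr, p$cluster_count, 3, byrow = TRUE)
    })
    for (i in seq_len(nrow(cluster_centers)))
      nup <- render_capsule(nup, cluster_centers[i, ], cluster_centers[i, ],
                            clus_r, vd, amp_npc)
  }

  # realised contacted fraction over the discrete boundary layer
  boundary <- nucleus & dist_in <= max(vd)
  contact_frac <- if (p$phenotype == "post_mga") 1 else
    mean(uz[boundary] >= tau)

  truth <- list(nucleus_mask = nucleus,
                chromatin_mask = rim,
                contact_tau = tau,
                contact_fraction = contact_frac,
                npc_centers_um = npc_nm / 1000,
                npc_dirs = npc_dirs,
                structures = structures,
                cluster_centers_um = cluster_centers / 1000,
                cluster_mode = p$extranuclear_cluster_mode,
                volume_um3 = sum(nucleus) * prod(vd) * 1e-9)

  ch <- apply_psf_noise(list(DAPI = dapi, laminB = lam, NUP153 = nup), p)
  structure(list(stack = image_stack(ch, voxel_dims = vd), truth = truth,
                 params = p),
            class = "nucleus_sim")
}

#' @export
print.nucleus_sim <- function(x, ...) {
  cat("Synthetic", x$params$phenotype, "nucleus:",
      paste(dim(x$stack)[1:3], collapse = " x "), "voxels;",
      nrow(x$truth$npc_centers_um), "NPC puncta;",
      nrow(x$truth$structures), "structure(s);",
      "true volume", round(x$truth$volume_um3, 1), "um^3\n")
  invisible(x)
}
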