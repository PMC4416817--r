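#' Extract the lamina shell and its per-voxel attributes
#'
#' The shell is the band of voxels within physical distance
#' `thickness_nm` of the nucleus boundary (on either side). Each shell
#' voxel carries a chromatin-contact flag (a DNA-stain-positive voxel of
#' the nuclear interior lies within `contact_nm`) and an NPC flag (a
#' marker-positive voxel lies within `npc_nm`, of the order of the outer
#' NPC diameter), plus the raw channel intensities for export.
#' Concordance statistics operate on the one-voxel boundary layer of
#' the mask (the discrete surface), so contact and NPC flags are
#' sampled at the same depth.
#'
#' @param mask logical 3-D nucleus mask (e.g. from [segment_nucleus()]).
#' @param stack the [image_stack()] the mask belongs to.
#' @param thickness_nm shell half-thickness (default 200 nm).
#' @param contact_nm chromatin contact distance (default 200 nm).
#' @param npc_nm NPC search radius (default 150 nm).
#' @param dapi_channel,nup_channel channel names.
#' @param dapi_threshold,nup_threshold positivity thresholds; `NULL`
#'   uses Otsu's threshold on each channel.
#' @return an object of class `shell_mask`: list with logical arrays
#'   `shell`, `boundary` (discrete surface layer), `contact`, `npc`,
#'   the thresholds used and the voxel dimensions.
#' @export
lamina_shell <- function(mask, stack, thickness_nm = 200,
                         contact_nm = 200, npc_nm = 150,
                         dapi_channel = "DAPI", nup_channel = "NUP153",
                         dapi_threshold = NULL, nup_threshold = NULL) {
  vd <- stack$voxel_dims
  if (!any(mask)) stop("parameter error: empty mask")
  if (sum(mask) < 8L)
    stop("parameter error: mask too small to carry a shell")
  if (thickness_nm < max(vd))
    stop("parameter error: shell thickness below one voxel on the ",
         "coarsest axis")
  dist_in <- edt_nm(!mask, vd)    # inside voxels: distance to exterior
  if (thickness_nm >= max(dist_in[mask]))
    stop("parameter error: shell thickness exceeds the nucleus radius")
  dist_out <- edt_nm(mask, vd)    # outside voxels: distance to nucleus
  shell <- (mask & dist_in <= thickness_nm) |
    (!mask & dist_out <= thickness_nm)
  boundary <- mask & dist_in <= max(vd)

  dapi <- get_channel(stack, dapi_channel)
  nup <- get_channel(stack, nup_channel)
  thr_d <- dapi_threshold %||% otsu_threshold(dapi)
  thr_n <- nup_threshold %||% otsu_threshold(nup)
  chrom_interior <- (dapi > thr_d) & mask
  contact <- if (any(chrom_interior))
    edt_nm(chrom_interior, vd) <= contact_nm
  else array(FALSE, dim = dim(mask))
  nup_pos <- nup > thr_n
  npc <- if (any(nup_pos)) edt_nm(nup_pos, vd) <= npc_nm
  else array(FALSE, dim = dim(mask))

  structure(list(shell = shell, boundary = boundary, contact = contact,
                 npc = npc, dist_in = dist_in, dist_out = dist_out,
                 dapi_threshold = thr_d, nup_threshold = thr_n,
                 thickness_nm = thickness_nm, contact_nm = contact_nm,
                 npc_nm = npc_nm, voxel_dims = vd,
                 dapi = dapi, nup = nup, mask = mask),
            class = "shell_mask")
}

#' @export
print.shell_mask <- function(x, ...) {
  cat("lamina shell:", sum(x$shell), "voxels (band +/-", x$thickness_nm,
      "nm);", sum(x$boundary), "surface elements\n")
  cat("  contacted surface fraction:",
      signif(mean(x$contact[x$boundary]), 3),
      "; NPC-positive surface fraction:",
      signif(mean(x$npc[x$boundary]), 3), "\n")
  invisible(x)
}

#' Export per-shell-voxel intensity pairs
#'
#' One row per shell voxel with its coordinates (um), DNA-stain and
#' marker intensities and the contact/NPC flags — the tabular analogue
#' of paired intensity line profiles along the lamina.
#'
#' @param shell a [lamina_shell()] result.
#' @param surface_only restrict to the boundary layer (default TRUE).
#' @return data frame.
#' @export
shell_intensity_pairs <- function(shell, surface_only = TRUE) {
  sel <- if (surface_only) shell$boundary else shell$shell
  idx <- which(sel, arr.ind = TRUE)
  vd <- shell$voxel_dims
  data.frame(x_um = (idx[, 1] - 1) * vd[1] / 1000,
             y_um = (idx[, 2] - 1) * vd[2] / 1000,
             z_um = (idx[, 3] - 1) * vd[3] / 1000,
             dapi = shell$dapi[sel], nup = shell$nup[sel],
             contact = shell$contact[sel], npc = shell$npc[sel])
}

#' NPC-chromatin contact concordance on the nuclear surface
#'
#' Cross-tabulates chromatin contact against NPC presence over the
#' surface elements of the shell and tests their association: odds
#' ratio (Haldane-corrected when a cell is empty) and two-sided Fisher
#' p. A strict concordance — pores only where chromatin touches the
#' envelope — shows up as a large odds ratio and a near-zero
#' NPC-positive fraction among non-contacted elements.
#'
#' @param shell a [lamina_shell()] result.
#' @return object of class `concordance_result`: list with `table`
#'   (2x2: contact x NPC), `odds_ratio`, `p_value`,
#'   `fraction_npc_contacted`, `fraction_npc_noncontacted`,
#'   `degenerate` (TRUE when all elements fall in one contact
#'   category; the odds ratio is then undefined but fractions are still
#'   reported).
#' @export
npc_chromatin_concordance <- function(shell) {
  stopifnot(inherits(shell, "shell_mask"))
  sel <- shell$boundary
  if (!any(sel)) stop("empty shell")
  co <- shell$contact[sel]
  np <- shell$npc[sel]
  a <- sum(co & np); b <- sum(co & !np)
  c_ <- sum(!co & np); d <- sum(!co & !np)
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(contact = c("yes", "no"),
                                npc = c("yes", "no")))
  degenerate <- (a + b) == 0L || (c_ + d) == 0L
  if (degenerate) {
    or <- NA_real_
    p <- NA_real_
  } else {
    if (min(tab) == 0L) {
      or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
    } else {
      or <- (a * d) / (b * c_)
    }
    p <- stats::fisher.test(tab)$p.value
  }
  structure(list(table = tab, odds_ratio = or, p_value = p,
                 fraction_npc_contacted =
                   if ((a + b) > 0) a / (a + b) else NA_real_,
                 fraction_npc_noncontacted =
                   if ((c_ + d) > 0) c_ / (c_ + d) else NA_real_,
                 degenerate = degenerate,
                 n_elements = sum(sel)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("NPC-chromatin contact concordance over", x$n_elements,
      "surface elements\n")
  print(x$table)
  if (x$degenerate) {
    cat("  degenerate: all surface elements in one contact category\n")
  } else {
    cat("  odds ratio:", signif(x$odds_ratio, 4),
        "; Fisher p:", format(x$p_value, digits = 3), "\n")
  }
  cat("  NPC-positive fraction | contacted:",
      signif(x$fraction_npc_contacted, 3),
      "| non-contacted:", signif(x$fraction_npc_noncontacted, 3), "\n")
  invisible(x)
}

#' Detect envelope-associated structures
#'
#' Finds connected components of lamin- or marker-positive voxels
#' outside the shell band and classifies them by 3-D topology:
#'
#' * `invagination`: connected to the envelope and (mostly) inside the
#'   nucleus, i.e. an infolding reaching deeper than the shell;
#' * `interior_vesicle`: inside the nucleus, 26-disconnected from the
#'   envelope;
#' * `extrusion`: outside the nucleus, connected to the envelope;
#' * `extranuclear_segment`: outside, disconnected.
#'
#' @param stack an [image_stack()].
#' @param mask logical nucleus mask.
#' @param shell a [lamina_shell()] result for the same mask.
#' @param lamin_channel,nup_channel channel names.
#' @param lamin_threshold,nup_threshold positivity thresholds (`NULL`:
#'   Otsu per channel; a constant channel yields an empty positive set).
#' @param min_size_vox discard components below this size (default 5).
#' @param f_pos fraction of structure voxels that must exceed a channel
#'   threshold for the structure to be called positive in that channel.
#' @param exclusion_nm half-thickness of the band excluded around the
#'   envelope when forming candidate voxels; defaults to the shell
#'   thickness plus 150 nm so that the blurred lamina rim itself is not
#'   picked up as a structure.
#' @return object of class `envelope_structures`: list of structures,
#'   each with `voxels` (linear indices), `location`, `lamin_pos`,
#'   `nup_pos`, `size_um3`, `centroid_um`, `connected_to_envelope`.
#' @export
detect_structures <- function(stack, mask, shell,
                              lamin_channel = "laminB",
                              nup_channel = "NUP153",
                              lamin_threshold = NULL,
                              nup_threshold = NULL,
                              min_size_vox = 5L, f_pos = 0.25,
                              exclusion_nm = NULL) {
  if (!all(c(lamin_channel, nup_channel) %in% names(stack$channels)))
    stop("input error: lamin and marker channels are required")
  vd <- stack$voxel_dims
  lam <- get_channel(stack, lamin_channel)
  nup <- get_channel(stack, nup_channel)
  pos_of <- function(a, thr) {
    if (max(a) == min(a)) return(array(FALSE, dim = dim(a)))
    a > (thr %||% otsu_threshold(a))
  }
  lam_pos <- pos_of(lam, lamin_threshold)
  nup_pos <- pos_of(nup, nup_threshold)
  excl <- exclusion_nm %||% (shell$thickness_nm + 150)
  near_env <- (mask & shell$dist_in <= excl) |
    (!mask & shell$dist_out <= excl)
  cand <- (lam_pos | nup_pos) & !near_env
  out <- list()
  if (any(cand)) {
    lab <- label_components(cand, 26L)
    n_comp <- max(lab)
    sizes <- tabulate(lab[lab > 0L], nbins = n_comp)
    # distance to the envelope band decides 26-adjacency to it
    d_env <- edt_nm(near_env, vd)
    adj_lim <- sqrt(sum(vd^2)) + 1e-6
    voxvol <- prod(vd) * 1e-9
    keep <- which(sizes >= min_size_vox)
    for (ci in keep) {
      vox <- which(lab == ci)
      inside <- mean(mask[vox]) > 0.5
      connected <- min(d_env[vox]) <= adj_lim
      location <- if (inside && connected) "invagination"
      else if (inside) "interior_vesicle"
      else if (connected) "extrusion"
      else "extranuclear_segment"
      idx <- arrayInd(vox, dim(mask))
      centroid <- colMeans(sweep(idx - 1, 2, vd, "*")) / 1000
      out[[length(out) + 1L]] <- list(
        voxels = vox, location = location,
        lamin_pos = mean(lam_pos[vox]) >= f_pos,
        nup_pos = mean(nup_pos[vox]) >= f_pos,
        size_um3 = length(vox) * voxvol,
        centroid_um = centroid,
        connected_to_envelope = connected)
    }
  }
  structure(out, class = "envelope_structures")
}

#' @export
print.envelope_structures <- function(x, ...) {
  if (!length(x)) {
    cat("no envelope structures detected\n")
    return(invisible(x))
  }
  df <- as.data.frame(x)
  cat("envelope structures (", nrow(df), "):\n", sep = "")
  print(df, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.envelope_structures <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(id = integer(0), location = character(0),
                      lamin_pos = logical(0), nup_pos = logical(0),
                      size_um3 = numeric(0), x_um = numeric(0),
                      y_um = numeric(0), z_um = numeric(0)))
  }
  data.frame(id = seq_along(x),
             location = vapply(x, `[[`, "", "location"),
             lamin_pos = vapply(x, `[[`, TRUE, "lamin_pos"),
             nup_pos = vapply(x, `[[`, TRUE, "nup_pos"),
             size_um3 = vapply(x, `[[`, 0, "size_um3"),
             x_um = vapply(x, function(s) s$centroid_um[1], 0),
             y_um = vapply(x, function(s) s$centroid_um[2], 0),
             z_um = vapply(x, function(s) s$centroid_um[3], 0))
}

#' Immunophenotype of a single structure
#'
#' Per channel, a structure is positive when at least a fraction
#' `f_pos` of its voxels exceed the channel threshold. Returns the
#' (lamin, marker) flag pair distinguishing the three invagination
#' immunophenotypes: NUP+/lamin B+, NUP-/lamin B+ and NUP+/lamin B-.
#'
#' @param structure one element of an `envelope_structures` list (or any
#'   list with a `voxels` index vector).
#' @param stack an [image_stack()].
#' @param lamin_threshold,nup_threshold channel thresholds (`NULL`:
#'   Otsu).
#' @param f_pos positivity fraction (default 0.25).
#' @param lamin_channel,nup_channel channel names.
#' @return named logical vector `c(lamin_pos = , nup_pos = )`.
#' @export
classify_positivity <- function(structure, stack,
                                lamin_threshold = NULL,
                                nup_threshold = NULL, f_pos = 0.25,
                                lamin_channel = "laminB",
                                nup_channel = "NUP153") {
  vox <- structure$voxels
  if (!length(vox)) stop("empty structure")
  lam <- get_channel(stack, lamin_channel)
  nup <- get_channel(stack, nup_channel)
  thr_l <- lamin_threshold %||% otsu_threshold(lam)
  thr_n <- nup_threshold %||% otsu_threshold(nup)
  c(lamin_pos = mean(lam[vox] > thr_l) >= f_pos,
    nup_pos = mean(nup[vox] > thr_n) >= f_pos)
}

phenotype_label <- function(lamin_pos, nup_pos) {
  ifelse(nup_pos & lamin_pos, "NUP+/LAM+",
         ifelse(!nup_pos & lamin_pos, "NUP-/LAM+",
                ifelse(nup_pos & !lamin_pos, "NUP+/LAM-", "NUP-/LAM-")))
}

#' Census of envelope structures
#'
#' Tallies structures by location and immunophenotype, per nucleus and
#' per group, and derives the percentage partition of invaginations
#' over the three immunophenotypes (NUP+/lamin+, NUP-/lamin+,
#' NUP+/lamin-). Group summaries report mean count per nucleus with its
#' standard error.
#'
#' @param structures an `envelope_structures` list, a list of them (one
#'   per nucleus), or a data frame with columns `location`,
#'   `lamin_pos`, `nup_pos` and optionally `nucleus` and `group`.
#' @param group_by optional vector assigning each nucleus to a group
#'   (e.g. a developmental stage).
#' @return object of class `structure_census`: list with `counts`
#'   (nucleus x location x phenotype), `invagination_percent` (named
#'   percentages over the three immunophenotypes, summing to 100) and
#'   `group_summary` (mean count per nucleus and standard error, per
#'   group x location).
#' @export
structure_census <- function(structures, group_by = NULL) {
  if (is.data.frame(structures)) {
    df <- structures
    if (!"nucleus" %in% names(df)) df$nucleus <- 1L
  } else if (inherits(structures, "envelope_structures")) {
    df <- as.data.frame(structures)
    df$nucleus <- rep(1L, nrow(df))
  } else {
    df <- do.call(rbind, lapply(seq_along(structures), function(i) {
      d <- as.data.frame(structures[[i]])
      d$nucleus <- rep(i, nrow(d))
      d
    }))
    if (is.null(df))
      df <- data.frame(location = character(0), lamin_pos = logical(0),
                       nup_pos = logical(0), nucleus = integer(0))
  }
  if (!nrow(df)) {
    return(structure(list(counts = data.frame(),
                          invagination_percent =
                            c(`NUP+/LAM+` = NA_real_,
                              `NUP-/LAM+` = NA_real_,
                              `NUP+/LAM-` = NA_real_),
                          group_summary = data.frame(),
                          n_structures = 0L),
                     class = "structure_census"))
  }
  df$phenotype <- phenotype_label(df$lamin_pos, df$nup_pos)
  counts <- as.data.frame(table(nucleus = df$nucleus,
                                location = df$location,
                                phenotype = df$phenotype),
                          responseName = "count")
  inv <- df[df$location == "invagination" &
              df$phenotype %in% c("NUP+/LAM+", "NUP-/LAM+", "NUP+/LAM-"), ]
  pct <- c(`NUP+/LAM+` = NA_real_, `NUP-/LAM+` = NA_real_,
           `NUP+/LAM-` = NA_real_)
  if (nrow(inv)) {
    tb <- table(factor(inv$phenotype,
                       levels = c("NUP+/LAM+", "NUP-/LAM+", "NUP+/LAM-")))
    pct <- 100 * as.numeric(tb) / sum(tb)
    names(pct) <- c("NUP+/LAM+", "NUP-/LAM+", "NUP+/LAM-")
  }
  group_summary <- data.frame()
  nuclei <- sort(unique(df$nucleus))
  grp <- if (is.null(group_by)) rep("all", length(nuclei)) else
    as.character(group_by[seq_along(nuclei)])
  per_nuc <- as.data.frame(table(nucleus = df$nucleus,
                                 location = df$location),
                           responseName = "count")
  per_nuc$group <- grp[match(per_nuc$nucleus, as.character(nuclei))]
  group_summary <- do.call(rbind, lapply(
    split(per_nuc, list(per_nuc$group, per_nuc$location), drop = TRUE),
    function(d) data.frame(group = d$group[1], location = d$location[1],
                           mean_count = mean(d$count),
                           se = stats::sd(d$count) /
                             sqrt(nrow(d)))))
  rownames(group_summary) <- NULL
  structure(list(counts = counts, invagination_percent = pct,
                 group_summary = group_summary,
                 n_structures = nrow(df)),
            class = "structure_census")
}

#' @export
print.structure_census <- function(x, ...) {
  cat("structure census:", x$n_structures, "structure(s)\n")
  if (!all(is.na(x$invagination_percent))) {
    cat("  invagination immunophenotypes (%):\n")
    print(round(x$invagination_percent, 1))
  }
  if (nrow(x$group_summary)) {
    cat("  mean count per nucleus by group:\n")
    print(x$group_summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Extranuclear marker clusters
#'
#' Connected marker-positive components outside the nucleus (beyond a
#' small exclusion band so envelope pores are not picked up), with
#' their physical distance to the envelope. The scene is classified
#' `envelope_proximal` when the median centroid distance is at most
#' `d_prox_um`, `dispersed` otherwise.
#'
#' @param stack an [image_stack()].
#' @param mask logical nucleus mask.
#' @param nup_channel marker channel name.
#' @param nup_threshold positivity threshold (`NULL`: Otsu).
#' @param min_size_vox minimum cluster size (default 5 voxels).
#' @param exclusion_nm band around the envelope excluded from the
#'   search, wide enough that envelope pore signal bleeding outward is
#'   not mistaken for a cluster (default 250 nm).
#' @param d_prox_um proximity threshold on the median distance
#'   (default 0.5 um).
#' @return object of class `cluster_profile`: data frame of clusters
#'   (`id`, `size_um3`, `distance_um`, centroid) with attributes
#'   `classification` (`"dispersed"`, `"envelope_proximal"` or
#'   `"none"`) and `median_distance_um`.
#' @export
extranuclear_clusters <- function(stack, mask, nup_channel = "NUP153",
                                  nup_threshold = NULL,
                                  min_size_vox = 5L,
                                  exclusion_nm = 250, d_prox_um = 0.5) {
  nup <- get_channel(stack, nup_channel)
  vd <- stack$voxel_dims
  if (max(nup) == min(nup)) {
    pos <- array(FALSE, dim = dim(nup))
  } else {
    pos <- nup > (nup_threshold %||% otsu_threshold(nup))
  }
  dist_out <- edt_nm(mask, vd)
  cand <- pos & !mask & dist_out > exclusion_nm
  rows <- list()
  if (any(cand)) {
    lab <- label_components(cand, 26L)
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    voxvol <- prod(vd) * 1e-9
    for (ci in which(sizes >= min_size_vox)) {
      vox <- which(lab == ci)
      idx <- arrayInd(vox, dim(mask))
      centroid <- colMeans(sweep(idx - 1, 2, vd, "*")) / 1000
      ci_vox <- round(centroid * 1000 / vd) + 1
      ci_vox <- pmin(pmax(ci_vox, 1), dim(mask))
      rows[[length(rows) + 1L]] <- data.frame(
        size_um3 = length(vox) * voxvol,
        distance_um = dist_out[ci_vox[1], ci_vox[2], ci_vox[3]] / 1000,
        x_um = centroid[1], y_um = centroid[2], z_um = centroid[3])
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size_um3 = numeric(0), distance_um = numeric(0),
               x_um = numeric(0), y_um = numeric(0), z_um = numeric(0))
  df <- cbind(id = seq_len(nrow(df)), df)
  med <- if (nrow(df)) stats::median(df$distance_um) else NA_real_
  attr(df, "median_distance_um") <- med
  attr(df, "classification") <- if (!nrow(df)) "none"
  else if (med <= d_prox_um) "envelope_proximal" else "dispersed"
  class(df) <- c("cluster_profile", "data.frame")
  df
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("extranuclear marker clusters:", nrow(x), "(",
      attr(x, "classification"), ")\n")
  if (nrow(x)) {
    cat("  median distance to envelope:",
        signif(attr(x, "median_distance_um"), 3), "um\n")
    print.data.frame(utils::head(x, 10), row.names = FALSE, digits = 3)
    if (nrow(x) > 10) cat("  ...\n")
  }
  invisible(x)
}
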