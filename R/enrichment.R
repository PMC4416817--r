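#' Marker-positive voxel mask
#'
#' Thresholds a marker channel (e.g. the nuclear pore marker NUP153)
#' within an analysis region. Default positivity criterion is the
#' robust background rule `median + k_mad * MAD` of the region's
#' intensities: marker-positive voxels are typically a small fraction of
#' the region, a regime where histogram-split thresholds (Otsu) land
#' inside the dominant background mode instead of between background
#' and signal. Otsu (on log intensities) and a fixed threshold remain
#' available; the threshold used is always recorded.
#'
#' @param stack an [image_stack()].
#' @param channel marker channel name.
#' @param region logical array; analysis region (default: whole stack).
#' @param method `"background"` (default), `"otsu"` or `"fixed"`.
#' @param threshold numeric threshold when `method = "fixed"`.
#' @param k_mad MAD multiplier for the background rule (default 8).
#' @return logical array of marker-positive voxels (FALSE outside the
#'   region), with the threshold used stored in attribute `"threshold"`.
#' @export
marker_mask <- function(stack, channel = "NUP153", region = NULL,
                        method = c("background", "otsu", "fixed"),
                        threshold = NULL, k_mad = 8) {
  method <- match.arg(method)
  a <- get_channel(stack, channel)
  if (is.null(region)) region <- array(TRUE, dim = dim(a))
  vals <- a[region]
  thr <- switch(method,
                background = {
                  if (max(vals) == min(vals))
                    stop("thresholding error: constant marker channel")
                  stats::median(vals) + k_mad * stats::mad(vals)
                },
                otsu = otsu_threshold(vals, log_scale = TRUE),
                fixed = {
                  if (is.null(threshold))
                    stop("method = 'fixed' requires a threshold")
                  threshold
                })
  m <- array(FALSE, dim = dim(a))
  m[region] <- vals > thr
  attr(m, "threshold") <- thr
  attr(m, "method") <- method
  m
}

#' Marker enrichment profile across intensity classes
#'
#' For each intensity class `c` counts the region voxels `D_c` and the
#' marker-positive voxels `M_c`, and derives the expected fraction
#' `e_c = D_c / sum(D)` (the fraction expected under random, proportional
#' marker placement), the observed fraction `o_c = M_c / sum(M)` and the
#' relative enrichment `r_c = o_c / e_c - 1` (positive: accumulation,
#' negative: depletion, `-1`: complete absence).
#'
#' @param classmap an `intensity_class_map` from [classify_voxels()],
#'   or an integer vector of per-class region voxel counts `D_c`.
#' @param marker a logical marker mask (same shape as the class map), or
#'   an integer vector of per-class marker counts `M_c` when `classmap`
#'   is given as counts or when marker draws are tallied directly (e.g.
#'   generator truth counts).
#' @return an `enrichment_profile`: data frame with columns `class`,
#'   `D`, `M`, `expected`, `observed`, `enrichment`, plus attributes
#'   `n_region`, `n_marker`, `dropped` (classes with `D_c = 0`).
#' @export
enrichment_profile <- function(classmap, marker) {
  if (inherits(classmap, "intensity_class_map")) {
    k <- classmap$boundaries$k
    D <- classmap$counts
    if (is.logical(marker) || is.array(marker)) {
      if (!identical(dim(marker), dim(classmap$labels)))
        stop("marker mask shape does not match the class map")
      if (any(marker & !classmap$region))
        stop("marker mask must be a subset of the analysis region")
      M <- tabulate(classmap$labels[marker], nbins = k)
    } else {
      M <- as.integer(marker)
    }
  } else {
    D <- as.integer(classmap)
    M <- as.integer(marker)
    k <- length(D)
  }
  if (length(M) != k) stop("per-class counts of different lengths")
  if (any(D < 0) || any(M < 0)) stop("negative counts")
  if (sum(M) == 0) stop("no marker signal: sum(M) = 0")
  dropped <- which(D == 0L)
  if (length(dropped)) {
    warning("dropping ", length(dropped),
            " class(es) with zero region voxels: ",
            paste(dropped, collapse = ", "))
    keep <- D > 0L
  } else keep <- rep(TRUE, k)
  cls <- seq_len(k)[keep]
  D <- D[keep]; M <- M[keep]
  e <- D / sum(D)
  o <- M / sum(M)
  out <- data.frame(class = cls, D = D, M = M, expected = e, observed = o,
                    enrichment = o / e - 1)
  attr(out, "n_region") <- sum(D)
  attr(out, "n_marker") <- sum(M)
  attr(out, "dropped") <- dropped
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' @export
print.enrichment_profile <- function(x, ...) {
  cat("Marker enrichment across", nrow(x), "intensity classes (",
      attr(x, "n_marker"), "marker /", attr(x, "n_region"),
      "region voxels)\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Goodness-of-fit test of proportional marker placement
#'
#' Tests the null hypothesis that marker-positive voxels are distributed
#' over the intensity classes in proportion to the class voxel counts
#' (i.e. the marker fraction of each class equals its region-voxel
#' fraction). Pearson chi-square statistic
#' `sum((M_c - sum(M) e_c)^2 / (sum(M) e_c))` with `df = #classes - 1`
#' and an upper-tail chi-square p-value. When any expected count falls
#' below 5 the result carries `small_expected = TRUE`, flagging that an
#' exact multinomial computation would be preferable.
#'
#' @param profile an [enrichment_profile()].
#' @return a `nucarch_test` list: `statistic`, `df`, `p_value`,
#'   `log10_p` (finite even when `p_value` underflows; p-values below
#'   1e-300 are reported as the bound `"< 1e-300"` in `p_label`),
#'   `method`, `small_expected`.
#' @export
gof_test <- function(profile) {
  stopifnot(inherits(profile, "enrichment_profile"))
  if (nrow(profile) < 2)
    stop("need at least 2 classes with region voxels")
  M <- profile$M
  expM <- sum(M) * profile$expected
  stat <- sum((M - expM)^2 / expM)
  df <- nrow(profile) - 1L
  logp <- stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE)
  p <- exp(logp)
  structure(list(statistic = stat, df = df, p_value = p,
                 log10_p = logp / log(10),
                 p_label = if (p < 1e-300) "< 1e-300" else
                   format(p, digits = 4),
                 method = "Pearson chi-square goodness of fit",
                 small_expected = any(expM < 5),
                 comparison = "marker distribution vs proportional null"),
            class = "nucarch_test")
}

#' @export
print.nucarch_test <- function(x, ...) {
  cat(x$method, "\n  ", x$comparison, "\n", sep = "")
  cat("  statistic =", format(x$statistic, digits = 6),
      if (!is.null(x$df) && !is.na(x$df)) paste(", df =", x$df) else "",
      ", p", if (startsWith(x$p_label, "<")) "" else "=", x$p_label, "\n")
  if (isTRUE(x$small_expected))
    cat("  note: expected counts < 5; interpret asymptotic p with care\n")
  invisible(x)
}

#' Pairwise marker-density comparison between classes
#'
#' Compares the marker density `M_a / D_a` of class `class_a` with the
#' pooled density of the classes in `class_set_b` via the 2x2 table
#' `((M_a, D_a - M_a), (M_b, D_b - M_b))`: Fisher's exact test for small
#' counts (any expected cell below `fisher_limit`), otherwise a
#' chi-square test with continuity correction. Two-sided.
#'
#' @param profile an [enrichment_profile()].
#' @param class_a single class label.
#' @param class_set_b one or more class labels to pool.
#' @param fisher_limit expected-count limit below which Fisher's exact
#'   test is used (default 5).
#' @return a `nucarch_test` list, with `densities` (density of a, pooled
#'   density of b) attached.
#' @export
pairwise_class_test <- function(profile, class_a, class_set_b,
                                fisher_limit = 5) {
  stopifnot(inherits(profile, "enrichment_profile"))
  ra <- profile[profile$class == class_a, ]
  rb <- profile[profile$class %in% class_set_b, ]
  if (nrow(ra) != 1L || nrow(rb) < 1L)
    stop("requested classes not present in the profile")
  Ma <- ra$M; Da <- ra$D
  Mb <- sum(rb$M); Db <- sum(rb$D)
  if (Da == 0 || Db == 0) stop("zero denominator in class comparison")
  tab <- matrix(c(Ma, Da - Ma, Mb, Db - Mb), nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  use_fisher <- any(expd < fisher_limit)
  if (use_fisher) {
    ft <- stats::fisher.test(tab)
    stat <- unname(ft$estimate)
    df <- NA_integer_
    p <- ft$p.value
    logp <- log(max(p, .Machine$double.xmin))
    method <- "Fisher exact test (2x2 marker density)"
  } else {
    # Pearson chi-square with continuity correction, log-scale p so that
    # extreme significance does not underflow
    e <- expd
    stat <- sum((abs(tab - e) - 0.5)^2 / e)
    df <- 1L
    logp <- stats::pchisq(stat, df, lower.tail = FALSE, log.p = TRUE)
    p <- exp(logp)
    method <- "Chi-square test with continuity correction (2x2 marker density)"
  }
  structure(list(statistic = stat, df = df, p_value = p,
                 log10_p = logp / log(10),
                 p_label = if (p < 1e-300) "< 1e-300" else
                   format(p, digits = 4),
                 method = method,
                 small_expected = use_fisher,
                 densities = c(a = Ma / Da, b = Mb / Db),
                 comparison = sprintf("class %s vs class(es) %s", class_a,
                                      paste(class_set_b, collapse = ","))),
            class = "nucarch_test")
}
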