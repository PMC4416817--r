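# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so library
#' code never perturbs the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Deterministic per-component substream seed
#'
#' Each stochastic component of a generator draws from its own substream
#' derived from the master seed and a fixed component index, so adding a
#' component never perturbs the draws of the others. Kept within the
#' 32-bit integer range.
#' @noRd
substream <- function(seed, component) {
  as.integer((as.numeric(seed) * 2654435761 + component * 40503) %%
               2147483647)
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based maximisation of between-class variance over `n_bins`
#' equal-width bins spanning the observed range. Used for marker
#' positivity and nucleus foreground thresholds on 3-D volumes.
#'
#' @param x numeric vector or array of intensities.
#' @param n_bins number of histogram bins.
#' @param log_scale compute the threshold on `log1p` intensities and map
#'   it back; appropriate for punctate channels whose bright overlaps
#'   span a much wider range than single puncta.
#' @return scalar threshold; voxels strictly above it are "positive".
#' @export
otsu_threshold <- function(x, n_bins = 256L, log_scale = FALSE) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (log_scale) return(expm1(otsu_threshold(log1p(x), n_bins)))
  rng <- range(x)
  if (!length(x) || rng[1] == rng[2])
    stop("otsu_threshold: constant or empty intensity sample")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  # between-class variance for a cut after each bin
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, n_bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  # the criterion is flat across empty gaps between modes; take the
  # middle of the maximising plateau (standard convention)
  mx <- max(sigma_b)
  k <- as.integer(floor(stats::median(
    which(sigma_b >= mx - 1e-9 * abs(mx)))))
  breaks[k + 1L]
}

# squared population variance helpers used by the class-boundary fit
pop_var <- function(x) {
  m <- length(x)
  if (m == 0L) return(NA_real_)
  mu <- sum(x) / m
  sum((x - mu)^2) / m
}
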