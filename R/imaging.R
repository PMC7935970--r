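# Confocal z-stack quantitation: z-profiles (mean intensity per slice),
# membrane peak-intensity time courses, and baseline-subtracted peak areas.

#' Confocal z-stack time series
#'
#' Wraps an intensity array indexed `(time, channel, z)` (pre-collapsed
#' profiles) or `(time, channel, z, y, x)` (full stacks) with its z
#' calibration.
#'
#' @param intensity Non-negative numeric array, 3- or 5-dimensional.
#' @param dz_um Uniform z spacing in micrometres.
#' @param times Time stamps (min), length = first dimension.
#' @param channels Channel labels, length = second dimension.
#' @param z0_um z position of the first slice (default 0).
#' @return Object of class `zstack_series`.
#' @export
zstack_series <- function(intensity, dz_um, times = NULL, channels = NULL,
                          z0_um = 0) {
  stopifnot(is.array(intensity))
  nd <- length(dim(intensity))
  if (!(nd %in% c(3L, 5L))) stop("intensity must be (t, c, z) or (t, c, z, y, x)")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  if (dz_um <= 0) stop("dz_um must be positive")
  d <- dim(intensity)
  if (is.null(times)) times <- seq_len(d[1]) - 1
  if (is.null(channels)) channels <- paste0("ch", seq_len(d[2]))
  stopifnot(length(times) == d[1], length(channels) == d[2])
  structure(list(intensity = intensity, dz_um = dz_um, z0_um = z0_um,
                 times = times, channels = channels),
            class = "zstack_series")
}

#' @export
print.zstack_series <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<zstack_series> %d time points, channels [%s], %d slices (dz = %g um)%s\n",
              d[1], paste(x$channels, collapse = ", "), d[3], x$dz_um,
              if (length(d) == 5) sprintf(", %dx%d px", d[4], d[5]) else ""))
  invisible(x)
}

z_positions <- function(series) {
  series$z0_um + (seq_len(dim(series$intensity)[3]) - 1) * series$dz_um
}

channel_index <- function(series, channel) {
  if (is.character(channel)) {
    i <- match(channel, series$channels)
    if (is.na(i)) stop(sprintf("unknown channel '%s' (have: %s)", channel,
                               paste(series$channels, collapse = ", ")))
    i
  } else as.integer(channel)
}

#' z-profile of one channel at one time point
#'
#' The profile value of slice i is the mean intensity over the (y, x) pixels
#' of that slice (for pre-collapsed input, the stored slice value). Linear
#' in any intensity scaling of the stack.
#'
#' @param series A [zstack_series()].
#' @param channel Channel label or index.
#' @param time_index Time point index (1-based; default 1).
#' @return Data frame (class `z_profile`) with columns `z_um`, `intensity`;
#'   channel and time stamp attached as attributes.
#' @export
z_profile <- function(series, channel, time_index = 1L) {
  stopifnot(inherits(series, "zstack_series"))
  ci <- channel_index(series, channel)
  arr <- series$intensity
  prof <- if (length(dim(arr)) == 3L) {
    arr[time_index, ci, ]
  } else {
    apply(arr[time_index, ci, , , , drop = FALSE], 3, mean)
  }
  out <- data.frame(z_um = z_positions(series), intensity = as.numeric(prof))
  class(out) <- c("z_profile", "data.frame")
  attr(out, "channel") <- series$channels[ci]
  attr(out, "time") <- series$times[time_index]
  out
}

#' Membrane peak-intensity time course
#'
#' For every time point, takes the maximum of that time's z-profile (the
#' membrane-localized intensity) and returns it against time, ready for
#' [fit_rise()].
#'
#' @param series A [zstack_series()].
#' @param channel Channel label or index.
#' @return `time_course` data frame with columns `time`, `intensity` (and
#'   `peak_z_um`, the argmax position).
#' @export
peak_intensity_timecourse <- function(series, channel) {
  stopifnot(inherits(series, "zstack_series"))
  nt <- dim(series$intensity)[1]
  if (nt < 1) stop("series has no time points")
  z <- z_positions(series)
  vals <- numeric(nt)
  zpos <- numeric(nt)
  for (i in seq_len(nt)) {
    p <- z_profile(series, channel, i)
    j <- which.max(p$intensity)
    vals[i] <- p$intensity[j]
    zpos[i] <- z[j]
  }
  out <- data.frame(time = series$times, intensity = vals, peak_z_um = zpos)
  as_time_course(out, "peak_intensity", NULL)
}

#' Baseline-subtracted peak area of a z-profile
#'
#' Integrates `profile - baseline` over the peak window by the trapezoidal
#' rule. The baseline is a straight line through the medians of two flanking
#' windows (`flank` slices on each side of the peak window), an automated
#' stand-in for manual bulk-background subtraction. Negative areas are
#' possible and reported (no clipping).
#'
#' @param profile A [z_profile()] (or data frame `z_um`, `intensity`).
#' @param window Integer indices of the peak window; default the argmax
#'   +/- `half_width` slices.
#' @param half_width Half-width (slices) of the default window.
#' @param flank Number of slices in each flanking baseline window.
#' @return Area in intensity x um, with attribute `baseline` (the per-window
#'   baseline values).
#' @export
peak_area <- function(profile, window = NULL, half_width = 3L, flank = 3L) {
  df <- as.data.frame(profile)
  z <- df$z_um
  v <- df$intensity
  n <- length(v)
  if (is.null(window)) {
    j <- which.max(v)
    window <- max(1L, j - half_width):min(n, j + half_width)
  }
  window <- sort(unique(as.integer(window)))
  if (length(window) < 3L) stop("peak window needs at least 3 slices")
  if (window[1] < 1L || window[length(window)] > n) {
    stop("peak window outside the profile")
  }
  lo <- window[1]
  hi <- window[length(window)]
  left <- if (lo > 1L) max(1L, lo - flank):(lo - 1L) else integer(0)
  right <- if (hi < n) (hi + 1L):min(n, hi + flank) else integer(0)
  if (length(left) < 1L || length(right) < 1L) {
    warning("peak window touches the profile edge; baseline flank unavailable on that side")
  }
  # line through the flank medians; single-sided fallback: flat baseline
  if (length(left) >= 1L && length(right) >= 1L) {
    xl <- median(z[left]); yl <- median(v[left])
    xr <- median(z[right]); yr <- median(v[right])
    slope <- (yr - yl) / (xr - xl)
    base <- yl + slope * (z[window] - xl)
  } else {
    flk <- c(left, right)
    base <- rep(if (length(flk)) median(v[flk]) else 0, length(window))
  }
  h <- v[window] - base
  zz <- z[window]
  area <- sum(diff(zz) * (h[-1] + h[-length(h)]) / 2)
  structure(area, baseline = base)
}

#' Check colocalization of membrane peaks across channels
#'
#' @param profiles List of [z_profile()]s on the same z grid (>= 2).
#' @param tol_um Maximum peak-position difference to call colocalized;
#'   default one slice spacing.
#' @return List with `delta_um` (matrix of pairwise |argmax| differences)
#'   and `colocalized` (TRUE when all deltas <= tolerance).
#' @export
colocalization_check <- function(profiles, tol_um = NULL) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  grids <- lapply(profiles, function(p) as.data.frame(p)$z_um)
  for (g in grids[-1]) {
    if (!isTRUE(all.equal(g, grids[[1]]))) stop("profiles must share a z grid")
  }
  z <- grids[[1]]
  if (is.null(tol_um)) tol_um <- if (length(z) > 1) z[2] - z[1] else 0
  peaks <- vapply(profiles, function(p) z[which.max(as.data.frame(p)$intensity)],
                  numeric(1))
  nm <- names(profiles) %||% vapply(profiles, function(p) {
    attr(p, "channel") %||% "ch"
  }, character(1))
  delta <- abs(outer(peaks, peaks, "-"))
  dimnames(delta) <- list(nm, nm)
  list(peak_z_um = setNames(peaks, nm), delta_um = delta,
       colocalized = all(delta <= tol_um + 1e-12))
}

# ---- TIFF input/output ------------------------------------------------------

#' Write a z-stack series to multi-page TIFF
#'
#' Pages are written in the nested order given by `axes` (default `"tcz"`:
#' time slowest, z fastest) as 32-bit float, intensities divided by `scale`.
#' TIFF carries no calibration here, so the reader must be told the axis
#' order, counts and z spacing.
#'
#' @param series A [zstack_series()] with pixel data `(t, c, z, y, x)`.
#' @param path Output path.
#' @param axes Page order, a permutation of `"tcz"`.
#' @param scale Intensity divisor so stored values fit the TIFF range.
#' @return `path`, invisibly.
#' @export
write_zstack_tiff <- function(series, path, axes = "tcz",
                              scale = max(series$intensity)) {
  stopifnot(inherits(series, "zstack_series"))
  d <- dim(series$intensity)
  if (length(d) != 5L) stop("TIFF export needs full (t, c, z, y, x) pixel data")
  ax <- strsplit(axes, "")[[1]]
  if (!identical(sort(ax), c("c", "t", "z"))) stop("axes must be a permutation of 'tcz'")
  sizes <- c(t = d[1], c = d[2], z = d[3])
  pages <- list()
  k <- 0L
  for (i1 in seq_len(sizes[ax[1]])) for (i2 in seq_len(sizes[ax[2]])) {
    for (i3 in seq_len(sizes[ax[3]])) {
      idx <- setNames(c(i1, i2, i3), ax)
      k <- k + 1L
      pages[[k]] <- series$intensity[idx["t"], idx["c"], idx["z"], , ] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a z-stack series from multi-page TIFF
#'
#' @param path TIFF written by [write_zstack_tiff()] (or any page stack).
#' @param n_t,n_c,n_z Axis sizes; their product must equal the page count.
#' @param axes Page order used when writing.
#' @param dz_um z spacing (um).
#' @param times,channels,z0_um,scale Calibration to restore (see
#'   [zstack_series()]; `scale` re-multiplies intensities).
#' @return A [zstack_series()].
#' @export
read_zstack_tiff <- function(path, n_t, n_c, n_z, axes = "tcz", dz_um = 0.25,
                             times = NULL, channels = NULL, z0_um = 0,
                             scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n_t * n_c * n_z) {
    stop(sprintf("page count %d does not match t*c*z = %d",
                 length(pages), n_t * n_c * n_z))
  }
  ax <- strsplit(axes, "")[[1]]
  sizes <- c(t = n_t, c = n_c, z = n_z)
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])
  arr <- array(0, dim = c(n_t, n_c, n_z, ny, nx))
  k <- 0L
  for (i1 in seq_len(sizes[ax[1]])) for (i2 in seq_len(sizes[ax[2]])) {
    for (i3 in seq_len(sizes[ax[3]])) {
      idx <- setNames(c(i1, i2, i3), ax)
      k <- k + 1L
      arr[idx["t"], idx["c"], idx["z"], , ] <- pages[[k]] * scale
    }
  }
  zstack_series(arr, dz_um = dz_um, times = times, channels = channels,
                z0_um = z0_um)
}
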